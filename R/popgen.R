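#' Stack the repeat units of a population into a pool
#'
#' Every repeat unit of every included allele becomes one pool member
#' ("taking each repeat unit as an individual allele"), retaining identical
#' units with their multiplicity. With `per_variant = TRUE`, alleles with
#' identical unit arrays (nucleotide-level) are collapsed to a single
#' representative before pooling — the alternative reading of stacking,
#' exposed so both can be compared.
#'
#' @param alleles a `minisat_alleles` set.
#' @param population population label to pool; `NULL` pools every allele
#'   passed in (useful for hemisphere-level pools).
#' @param masked build the pool on masked unit sequences (default `FALSE`).
#' @param per_variant collapse identical whole alleles first (default
#'   `FALSE`).
#' @param mask the [mask_spec()].
#' @return An object of class `repeat_pool`: list with `population`,
#'   `units` (character matrix, one row per pooled unit, one column per
#'   site), `n` rows and compared length `L`.
#' @export
stack_pool <- function(alleles, population = NULL, masked = FALSE,
                       per_variant = FALSE, mask = mask_spec()) {
  sel <- if (is.null(population)) seq_along(alleles)
         else which(vapply(alleles, `[[`, "", "population") == population)
  if (length(sel) == 0L)
    stop("no alleles in population '", population, "'")
  arrays <- lapply(unclass(alleles)[sel], `[[`, "units")
  if (per_variant)
    arrays <- arrays[!duplicated(vapply(arrays, paste, "", collapse = "|"))]
  units <- unlist(arrays, use.names = FALSE)
  if (masked) units <- vapply(units, mask_seq, "", mask = mask,
                              USE.NAMES = FALSE)
  m <- do.call(rbind, strsplit(units, "", fixed = TRUE))
  structure(list(population = if (is.null(population)) "ALL" else population,
                 units = m, n = nrow(m), L = ncol(m), masked = masked),
            class = "repeat_pool")
}

#' @export
print.repeat_pool <- function(x, ...) {
  cat(sprintf("repeat_pool %s: n=%d units, L=%d nt%s\n", x$population,
              x$n, x$L, if (x$masked) " (masked)" else ""))
  invisible(x)
}

#' Count segregating sites in a repeat pool
#'
#' Number of columns carrying at least two distinct observed non-`N`
#' states.
#'
#' @param pool a [stack_pool()] result (n >= 2).
#' @return Integer count, at most `L`.
#' @export
segregating_sites <- function(pool) {
  if (pool$n < 2L) stop("segregating sites require a pool of n >= 2")
  sum(apply(pool$units, 2L, function(col) {
    states <- unique(col[col != "N"])
    length(states) >= 2L
  }))
}

#' Watterson's estimator of the population mutation rate
#'
#' theta_W = S / a1 with a1 the harmonic number of n - 1; the per-site
#' value divides by the compared length L.
#'
#' @param S segregating-site count (or a `repeat_pool`, from which `S`,
#'   `n`, `L` are taken).
#' @param n number of sequences in the pool (>= 2).
#' @param L compared length in nt.
#' @return List with `theta_locus` and `theta_site`.
#' @examples
#' watterson_theta(4, 5, 84)$theta_locus  # 1.92
#' @export
watterson_theta <- function(S, n = NULL, L = NULL) {
  if (inherits(S, "repeat_pool")) {
    pool <- S; S <- segregating_sites(pool); n <- pool$n; L <- pool$L
  }
  if (n < 2L) stop("Watterson's estimator requires n >= 2")
  a1 <- sum(1 / seq_len(n - 1L))
  list(theta_locus = S / a1, theta_site = S / a1 / L)
}

#' Average pairwise nucleotide diversity of a repeat pool
#'
#' pi is the mean pairwise mismatch count over all sequence pairs, divided
#' by the compared length L; per pair, sites where either sequence has `N`
#' are skipped. The standard error is the square root of Nei's (1987)
#' variance of the estimate,
#' `V = pi (n+1) / (3 (n-1) L) + 2 (n^2 + n + 3) pi^2 / (9 n (n-1))`.
#'
#' @param pool a [stack_pool()] result (n >= 2).
#' @return List with `pi` (per site), `pi_se`, and `mean_pairwise_diff`
#'   (per locus: mean mismatch count per pair).
#' @export
nucleotide_diversity <- function(pool) {
  if (pool$n < 2L) stop("nucleotide diversity requires a pool of n >= 2")
  n <- pool$n; L <- pool$L
  # per-site tally over non-N pairs: mismatching pairs at a site are
  # C(v,2) - sum_k C(v_k,2) with v the non-N count, v_k per-base counts
  total_mm <- 0
  for (s in seq_len(L)) {
    col <- pool$units[, s]
    col <- col[col != "N"]
    v <- length(col)
    if (v < 2L) next
    tab <- tabulate(factor(col, levels = c("A", "C", "G", "T")), nbins = 4L)
    total_mm <- total_mm + choose(v, 2L) - sum(choose(tab, 2L))
  }
  npairs <- choose(n, 2L)
  pi <- total_mm / (npairs * L)
  v <- pi * (n + 1) / (3 * (n - 1) * L) +
       2 * (n^2 + n + 3) * pi^2 / (9 * n * (n - 1))
  list(pi = pi, pi_se = sqrt(v), mean_pairwise_diff = total_mm / npairs)
}

#' Per-population diversity summary
#'
#' Convenience wrapper: builds each population's pool (masked and
#' unmasked), and reports n, L, segregating sites, Watterson theta (per
#' locus and per site) and pi with its standard error.
#'
#' @param alleles a `minisat_alleles` set.
#' @param populations populations to summarise (default: all present).
#' @param per_variant see [stack_pool()].
#' @param mask the [mask_spec()].
#' @return data.frame with one row per population x mask setting.
#' @export
diversity_table <- function(alleles, populations = NULL,
                            per_variant = FALSE, mask = mask_spec()) {
  pops <- vapply(alleles, `[[`, "", "population")
  if (is.null(populations)) populations <- unique(pops)
  rows <- list()
  for (pop in populations) for (masked in c(FALSE, TRUE)) {
    pool <- stack_pool(alleles, pop, masked = masked,
                       per_variant = per_variant, mask = mask)
    S <- segregating_sites(pool)
    th <- watterson_theta(S, pool$n, pool$L)
    nd <- nucleotide_diversity(pool)
    rows[[length(rows) + 1L]] <- data.frame(
      population = pop, n = pool$n, L = pool$L, S = S,
      theta_locus = th$theta_locus, theta_site = th$theta_site,
      pi = nd$pi, pi_se = nd$pi_se, masked = masked,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# per-site Hs/Ht for a set of pools at one site, optionally with the
# Nei & Chesser small-sample corrections
site_hsht <- function(cols, corrected) {
  counts <- lapply(cols, function(col) {
    col <- col[col != "N"]
    tabulate(factor(col, levels = c("A", "C", "G", "T")), nbins = 4L)
  })
  ns <- vapply(counts, sum, 0)
  keep <- ns > 0           # populations with only N at this site drop out
  if (sum(keep) < 2L) return(NULL)
  counts <- counts[keep]; ns <- ns[keep]
  s <- length(counts)
  freqs <- mapply(function(ct, n) ct / n, counts, ns, SIMPLIFY = FALSE)
  hs_raw <- mean(vapply(freqs, function(p) 1 - sum(p^2), 0))
  pbar <- Reduce(`+`, freqs) / s   # unweighted population mean
  ht_raw <- 1 - sum(pbar^2)
  if (!corrected) return(c(hs = hs_raw, ht = ht_raw))
  ntilde <- s / sum(1 / ns)        # harmonic mean sample size
  hs <- ntilde / (ntilde - 1) * hs_raw
  ht <- ht_raw + hs / (ntilde * s)
  c(hs = hs, ht = ht)
}

gst_jost <- function(hs, ht, k) {
  gst <- if (ht == 0) 0 else (ht - hs) / ht
  dj <- if (hs >= 1) 0 else ((ht - hs) / (1 - hs)) * (k / (k - 1))
  c(Gst = gst, JostD = dj)
}

#' Population differentiation from repeat pools: Nei Gst and Jost's D
#'
#' Per nucleotide site, base frequencies are computed per population and
#' combined into within- (Hs) and total- (Ht) heterozygosity with the
#' Nei & Chesser (1983) sample-size corrections (harmonic-mean n,
#' unweighted population means); the corrections permit small negative Gst
#' and D estimates. Site values are averaged over all compared sites, and
#' `Gst = (Ht - Hs)/Ht`, `D = ((Ht - Hs)/(1 - Hs)) * k/(k - 1)` are taken
#' from the averaged Hs and Ht. Sites where a population shows only `N`
#' drop that population at that site; sites with fewer than two informative
#' populations are skipped.
#'
#' @param pools list of [stack_pool()] results sharing L (>= 2 pools).
#' @param corrected apply the sample-size corrections (default `TRUE`).
#' @return List with `pairwise` (data.frame `pop1 pop2 Hs Ht Gst JostD`)
#'   and `overall` (all pools jointly, with `k` populations).
#' @export
differentiation <- function(pools, corrected = TRUE) {
  if (length(pools) < 2L) stop("need at least 2 pools")
  Ls <- vapply(pools, `[[`, 0L, "L")
  if (length(unique(Ls)) != 1L)
    stop("pools have mismatched compared lengths: ",
         paste(unique(Ls), collapse = ", "))
  L <- Ls[1L]
  labels <- vapply(pools, `[[`, "", "population")
  run <- function(idx) {
    acc <- c(hs = 0, ht = 0); used <- 0L
    for (s in seq_len(L)) {
      cols <- lapply(pools[idx], function(p) p$units[, s])
      v <- site_hsht(cols, corrected)
      if (is.null(v)) next
      acc <- acc + v; used <- used + 1L
    }
    if (used == 0L) stop("no informative sites shared by the pools")
    hs <- acc[["hs"]] / used; ht <- acc[["ht"]] / used
    c(Hs = hs, Ht = ht, gst_jost(hs, ht, length(idx)))
  }
  prs <- combn(length(pools), 2L)
  pw <- apply(prs, 2L, function(p) run(p))
  pairwise <- data.frame(pop1 = labels[prs[1L, ]], pop2 = labels[prs[2L, ]],
                         t(pw), stringsAsFactors = FALSE)
  overall <- as.list(run(seq_along(pools)))
  overall$k <- length(pools)
  list(pairwise = pairwise, overall = overall)
}
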