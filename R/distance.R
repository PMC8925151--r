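#' Weighting scheme for the repeat-array edit distance
#'
#' Costs for the minimum-cost monotone alignment of two repeat arrays:
#' `w_mut` per mismatching nucleotide between aligned units, `w_indel` per
#' inserted/deleted unit, reduced to `w_slippage` when the indel'd unit is
#' an exact copy (on the compared region) of one of its neighbours in its
#' own array — the signature of replication slippage, which duplicates or
#' deletes a copy of an adjacent repeat. Defaults are `w_mut = 1`,
#' `w_indel = 3.5`, `w_slippage = 1.75`.
#'
#' @param w_mut cost per nucleotide mismatch (default 1).
#' @param w_indel cost per unit insertion/deletion (default 3.5).
#' @param w_slippage cost per slippage-eligible unit indel (default 1.75).
#' @param masked compare masked unit sequences (hypervariable codons
#'   excised) when `TRUE` (default `FALSE`).
#' @param mask the [mask_spec()] used when `masked = TRUE`.
#' @return An object of class `repeat_dist_params`.
#' @export
repeat_dist_params <- function(w_mut = 1, w_indel = 3.5, w_slippage = 1.75,
                               masked = FALSE, mask = mask_spec()) {
  if (any(c(w_mut, w_indel, w_slippage) < 0))
    stop("all weights must be non-negative")
  if (w_slippage > w_indel)
    warning("w_slippage > w_indel: slippage events cost more than plain indels")
  structure(list(w_mut = w_mut, w_indel = w_indel, w_slippage = w_slippage,
                 masked = isTRUE(masked), mask = mask),
            class = "repeat_dist_params")
}

# raw-byte hamming; N (and any non-ACGT byte) mismatches everything,
# including another N
hamming_chars <- function(x, y) {
  a <- charToRaw(x); b <- charToRaw(y)
  if (length(a) != length(b))
    stop("compared sequences have unequal lengths (", length(a), " vs ",
         length(b), ")")
  n <- charToRaw("N")
  sum(a != b | a == n | b == n)
}

#' Hamming distance between two repeat units
#'
#' Number of mismatching positions between two equal-length units, on the
#' full sequence or (with `masked = TRUE`) after excising the hypervariable
#' codons. `N` mismatches every base, including another `N` (conservative).
#'
#' @param u,v repeat units (strings or `repeat_unit` objects).
#' @param masked compare masked sequences (default `FALSE`).
#' @param mask the [mask_spec()].
#' @return Integer mismatch count.
#' @export
unit_hamming <- function(u, v, masked = FALSE, mask = mask_spec()) {
  su <- unit_seq(u); sv <- unit_seq(v)
  if (masked) { su <- mask_seq(su, mask); sv <- mask_seq(sv, mask) }
  as.integer(hamming_chars(su, sv))
}

# unit strings of an allele-like object, in compared space
compared_units <- function(x, p) {
  units <- if (inherits(x, "minisat_allele")) x$units
           else toupper(as.character(x))
  if (p$masked) vapply(units, mask_seq, "", mask = p$mask, USE.NAMES = FALSE)
  else units
}

# per-unit indel cost: slippage price iff the unit equals a neighbour of its
# own (original) array on the compared region
gap_costs <- function(units, p) {
  k <- length(units)
  if (k == 0L) return(numeric(0))
  slip <- vapply(seq_len(k), function(i)
    (i > 1L && units[i] == units[i - 1L]) ||
    (i < k  && units[i] == units[i + 1L]), NA)
  ifelse(slip, p$w_slippage, p$w_indel)
}

# dynamic programme over substitution matrix H (already scaled by w_mut) and
# per-unit gap costs; optionally returns the traceback
aed_dp <- function(H, del, ins, trace = FALSE) {
  m <- length(del); n <- length(ins)
  D <- matrix(0, m + 1L, n + 1L)
  if (m > 0L) D[-1L, 1L] <- cumsum(del)
  if (n > 0L) D[1L, -1L] <- cumsum(ins)
  if (m > 0L && n > 0L) {
    for (i in seq_len(m)) for (j in seq_len(n)) {
      D[i + 1L, j + 1L] <- min(D[i, j] + H[i, j],
                               D[i, j + 1L] + del[i],
                               D[i + 1L, j] + ins[j])
    }
  }
  if (!trace) return(D[m + 1L, n + 1L])
  # traceback, ties preferring match > deletion > insertion
  i <- m; j <- n; steps <- list()
  eps <- 1e-9
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        abs(D[i + 1L, j + 1L] - (D[i, j] + H[i, j])) < eps) {
      steps[[length(steps) + 1L]] <- c(op = "match", i = i, j = j)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L &&
               abs(D[i + 1L, j + 1L] - (D[i, j + 1L] + del[i])) < eps) {
      steps[[length(steps) + 1L]] <- c(op = "delete", i = i, j = NA)
      i <- i - 1L
    } else {
      steps[[length(steps) + 1L]] <- c(op = "insert", i = NA, j = j)
      j <- j - 1L
    }
  }
  list(cost = D[m + 1L, n + 1L],
       alignment = do.call(rbind, rev(steps)))
}

#' Weighted edit distance between two repeat arrays
#'
#' Minimum total cost over all monotone alignments of the units of `a` to
#' the units of `b`. Aligning unit `a[i]` to `b[j]` costs
#' `w_mut * unit_hamming(a[i], b[j])`; an unmatched unit costs `w_slippage`
#' if it exactly matches an adjacent unit of its own array on the compared
#' region (slippage), else `w_indel`. Neighbour context is taken from the
#' original arrays, so the distance is well defined independently of
#' alignment order. The empty array is allowed: its distance to any array
#' is that array's pure-indel cost (with a warning).
#'
#' The distance is symmetric and scales linearly with the weights, but the
#' triangle inequality is not guaranteed (gap costs are context-dependent);
#' downstream neighbour-joining tolerates non-metric input.
#'
#' @param a,b repeat arrays: `minisat_allele` objects or character vectors
#'   of equal-length unit sequences.
#' @param params a [repeat_dist_params()].
#' @param trace also return the (deterministically tie-broken) alignment,
#'   ties preferring match over deletion over insertion.
#' @return The cost (numeric scalar), or with `trace = TRUE` a list with
#'   `cost` and `alignment`.
#' @examples
#' u1 <- strrep("A", 84); u2 <- paste0("C", strrep("A", 83))
#' array_edit_distance(c(u1, u1), c(u1, u2))          # 1 mismatch -> 1
#' array_edit_distance(c(u1, u2), c(u1, u1, u2))      # duplicate insert -> 1.75
#' @export
array_edit_distance <- function(a, b, params = repeat_dist_params(),
                                trace = FALSE) {
  ua <- compared_units(a, params)
  ub <- compared_units(b, params)
  if (length(ua) == 0L || length(ub) == 0L)
    warning("empty repeat array: distance is the pure-indel cost of the other")
  if (length(ua) > 0L && length(ub) > 0L &&
      nchar(ua[1L]) != nchar(ub[1L]))
    stop("arrays have different unit lengths in the compared space")
  H <- outer(seq_along(ua), seq_along(ub),
             Vectorize(function(i, j) hamming_chars(ua[i], ub[j])))
  if (length(H) == 0L) H <- matrix(0, length(ua), length(ub))
  aed_dp(params$w_mut * H, gap_costs(ua, params), gap_costs(ub, params),
         trace = trace)
}

#' Exhaustive brute-force oracle for the array edit distance
#'
#' Enumerates every monotone alignment — every set of matched index pairs
#' strictly increasing in both coordinates, including the empty set — and
#' applies the cost rules of [array_edit_distance()] literally, returning
#' the minimum. Each matching is visited exactly once (identified by its
#' successive pairs; no memoization), so the search is exponential in the
#' array lengths and refuses arrays longer than `max_units`. Shares no
#' code with the dynamic-programming path and exists to verify it.
#'
#' @inheritParams array_edit_distance
#' @param max_units refusal bound on either array length (default 4).
#' @return The minimum cost.
#' @export
brute_force_distance <- function(a, b, params = repeat_dist_params(),
                                 max_units = 4L) {
  ua <- compared_units(a, params)
  ub <- compared_units(b, params)
  m <- length(ua); n <- length(ub)
  if (m > max_units || n > max_units)
    stop("brute-force oracle refuses arrays longer than ", max_units, " units")
  # independent hamming (character split, N mismatches everything)
  ham <- function(x, y) {
    cx <- strsplit(x, "", fixed = TRUE)[[1L]]
    cy <- strsplit(y, "", fixed = TRUE)[[1L]]
    sum(cx != cy | cx == "N" | cy == "N")
  }
  slip_cost <- function(units) {
    k <- length(units)
    vapply(seq_len(k), function(i) {
      if ((i > 1L && units[i] == units[i - 1L]) ||
          (i < k && units[i] == units[i + 1L])) params$w_slippage
      else params$w_indel
    }, 0)
  }
  del <- slip_cost(ua); ins <- slip_cost(ub)
  H <- matrix(0, m, n)
  if (m > 0L && n > 0L)
    for (i in 1:m) for (j in 1:n) H[i, j] <- ham(ua[i], ub[j])
  # suffix gap sums: sdel[i] = cost of deleting a[i..m]
  sdel <- rev(cumsum(rev(c(del, 0))))
  sins <- rev(cumsum(rev(c(ins, 0))))
  # minimum over every matching whose pairs all lie in [i0..m] x [j0..n];
  # each matching is enumerated exactly once by its first (smallest) pair.
  # No memoization: this is a literal exhaustive enumeration.
  bestfrom <- function(i0, j0) {
    best <- sdel[i0] + sins[j0]          # leave everything unmatched
    if (i0 <= m && j0 <= n) {
      for (i in i0:m) for (j in j0:n) {
        cost <- (sdel[i0] - sdel[i]) + (sins[j0] - sins[j]) +
          params$w_mut * H[i, j] + bestfrom(i + 1L, j + 1L)
        if (cost < best) best <- cost
      }
    }
    best
  }
  bestfrom(1L, 1L)
}

#' Pairwise edit-distance matrix over a set of alleles
#'
#' Computes all pairwise [array_edit_distance()] values. With
#' `dedupe = TRUE`, alleles whose unit arrays are identical in the compared
#' space are collapsed to one representative (the first by input order);
#' the representative's multiplicity is recorded in the `carriers`
#' attribute.
#'
#' @param alleles a `minisat_alleles` set, or a list of unit-sequence
#'   character vectors (named for labels).
#' @param params a [repeat_dist_params()].
#' @param dedupe collapse identical arrays first (default `FALSE`).
#' @return A symmetric numeric matrix with zero diagonal, labelled by
#'   allele id; attributes `carriers` (named counts) and `members` (list of
#'   allele ids per representative) when `dedupe = TRUE`.
#' @export
distance_matrix <- function(alleles, params = repeat_dist_params(),
                            dedupe = FALSE) {
  if (length(alleles) < 2L) stop("need at least 2 alleles")
  labels <- if (inherits(alleles, "minisat_alleles") ||
                all(vapply(alleles, inherits, NA, "minisat_allele")))
    vapply(alleles, `[[`, "", "allele_id") else names(alleles)
  if (is.null(labels) || anyNA(labels) || any(labels == ""))
    labels <- paste0("a", seq_along(alleles))
  arrays <- lapply(alleles, compared_units, p = params)
  ul <- unique(nchar(unlist(arrays)))
  if (length(ul) > 1L)
    stop("mixed unit lengths across alleles: ", paste(ul, collapse = ", "))
  carriers <- NULL; members <- NULL
  if (dedupe) {
    key <- vapply(arrays, paste, "", collapse = "|")
    first <- !duplicated(key)
    members <- split(labels, factor(key, levels = key[first]))
    names(members) <- labels[first]
    carriers <- lengths(members)
    arrays <- arrays[first]
    labels <- labels[first]
  }
  # hamming between unique unit strings, computed once
  uniq <- unique(unlist(arrays))
  idx <- lapply(arrays, match, table = uniq)
  k <- length(uniq)
  Hu <- matrix(0, k, k)
  if (k > 1L) for (i in 1:(k - 1L)) for (j in (i + 1L):k)
    Hu[i, j] <- Hu[j, i] <- hamming_chars(uniq[i], uniq[j])
  gaps <- lapply(arrays, gap_costs, p = params)
  nA <- length(arrays)
  D <- matrix(0, nA, nA, dimnames = list(labels, labels))
  if (nA > 1L) for (i in 1:(nA - 1L)) for (j in (i + 1L):nA) {
    H <- params$w_mut * Hu[idx[[i]], idx[[j]], drop = FALSE]
    D[i, j] <- D[j, i] <- aed_dp(H, gaps[[i]], gaps[[j]])
  }
  attr(D, "carriers") <- carriers
  attr(D, "members") <- members
  attr(D, "masked") <- params$masked
  D
}

#' Write a distance matrix in square PHYLIP format
#'
#' Relaxed PHYLIP: names up to 32 characters padded with spaces (or, with
#' `tabbed = TRUE`, a tab-separated dialect), distances printed with 6
#' decimals.
#'
#' @param m labelled symmetric matrix from [distance_matrix()].
#' @param path output file.
#' @param tabbed use the tab-separated dialect (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_phylip <- function(m, path, tabbed = FALSE) {
  m <- as.matrix(m)
  labels <- substr(rownames(m), 1L, 32L)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    vals <- sprintf("%.6f", m[i, ])
    if (tabbed) writeLines(paste(c(labels[i], vals), collapse = "\t"), con)
    else writeLines(paste(c(formatC(labels[i], width = -33L), vals),
                          collapse = " "), con)
  }
  invisible(path)
}

#' Write a distance matrix as long-format TSV
#'
#' Columns `id1 id2 distance` (6 decimals), one row per unordered pair.
#'
#' @inheritParams write_phylip
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(m, path) {
  m <- as.matrix(m)
  p <- combn(nrow(m), 2L)
  df <- data.frame(id1 = rownames(m)[p[1L, ]],
                   id2 = rownames(m)[p[2L, ]],
                   distance = sprintf("%.6f", m[cbind(p[1L, ], p[2L, ])]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
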