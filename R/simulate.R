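#' Synthetic reference repeat unit (84 nt)
#'
#' A synthetic stand-in for the conserved first zinc finger of the baleen
#' whale array: an in-frame 84-nt unit translating to a canonical
#' 28-residue C2H2 finger with cysteine anchors at positions 8 and 11,
#' histidine anchors at 24 and 28, and the DNA-contact residues
#' Asp/Ser/Lys ("DSK") at positions 13/16/19. It is a constructed
#' consensus, not a database sequence; the same unit ships as
#' `inst/extdata/synthetic_reference_unit.fasta`.
#'
#' With `random = TRUE`, draws a random stop-free in-frame unit of the
#' requested length with the C2H2 anchors forced (requires at least 28
#' codons), for simulations that should not start from the fixture.
#'
#' @param unit_length unit length in nt (default 84; multiple of 3).
#' @param random draw a random unit instead of the fixture.
#' @return A nucleotide string.
#' @examples
#' translate_unit(ancestral_unit())$contact_code  # "DSK"
#' @export
ancestral_unit <- function(unit_length = 84L, random = FALSE) {
  fixture <- paste0(
    "ACCGGAGAGAAGCCCTACGTGTGC",   # aa 1-8   ...C
    "AGAGAATGTGGC",               # aa 9-12  ..C.
    "GATGAGCGGAGCGTCAGGAAA",      # aa 13-19 contact D..S..K
    "CACCTGCGCATCCAT",            # aa 20-24 ....H
    "CAGCGTACACAC")               # aa 25-28 ...H
  if (!random && unit_length == 84L) return(fixture)
  if (unit_length %% 3L != 0L) stop("unit_length must be a multiple of 3")
  k <- unit_length %/% 3L
  codons <- names(Biostrings::GENETIC_CODE)
  codons <- codons[Biostrings::GENETIC_CODE != "*"]
  unit <- sample(codons, k, replace = TRUE)
  if (k >= 28L) {
    unit[c(8L, 11L)] <- "TGC"   # Cys
    unit[c(24L, 28L)] <- "CAC"  # His
  }
  paste(unit, collapse = "")
}

#' Define a forward-time minisatellite evolution scenario
#'
#' The generative model behind the synthetic data: a haploid Wright-Fisher
#' pool of `pop_size` gene copies per population evolves in discrete
#' generations. Each nucleotide mutates with probability `mu` per
#' generation, multiplied by `hv_multiplier` inside the three DNA-contact
#' codons (the hypervariable positions); each unit duplicates in place
#' (slippage: the copy is inserted adjacent to its template) with
#' probability `dup_rate` and deletes with `del_rate`, subject to the
#' `min_units`/`max_units` guards (violating events are skipped and
#' counted). The population tree is
#' `((ANV:t1, ANIV:t1):t2, (NA:t1, NP:t1):t2)` with a shared burn-in of
#' `burn_in` generations before the first split; `t2 >> t1` gives strong
#' between-hemisphere and weak within-hemisphere differentiation. At the
#' end, `2 * n_per_pop` gene copies are sampled per population and paired
#' into diploid individuals.
#'
#' Defaults are scaled for desk-sized runs: pool of 40 copies, burn-in 400,
#' `t2 = 600`, `t1 = 30` generations, `mu = 7e-6` (giving repeat-pool
#' diversities of the order seen in real minisatellite data), contact
#' codons 10x faster, duplication and deletion at `1e-4` per unit per
#' generation (keeping sampled arrays mostly in the 6-11 unit range around
#' the 9-unit ancestor).
#'
#' @param seed integer seed; a fixed seed makes the simulation output
#'   byte-identical across runs.
#' @param unit_length,ancestral_units geometry of the ancestral array.
#' @param mu point-mutation rate per nt per generation.
#' @param hv_multiplier rate multiplier at the contact codons.
#' @param dup_rate,del_rate slippage duplication / unit deletion rates per
#'   unit per generation.
#' @param pop_size gene copies per population pool.
#' @param n_per_pop diploid individuals sampled per population
#'   (`2 * n_per_pop <= pop_size`).
#' @param t1,t2,burn_in split times and shared burn-in, in generations.
#' @param min_units,max_units array-size guards.
#' @param contact_positions hypervariable amino-acid positions.
#' @param populations named character vector mapping population label to
#'   hemisphere; the first half splits from the second at `t2`.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(seed = 1L, unit_length = 84L, ancestral_units = 9L,
                         mu = 7e-6, hv_multiplier = 10,
                         dup_rate = 1e-4, del_rate = 1e-4,
                         pop_size = 40L, n_per_pop = 10L,
                         t1 = 30L, t2 = 600L, burn_in = 400L,
                         min_units = 4L, max_units = 14L,
                         contact_positions = c(13L, 16L, 19L),
                         populations = c(ANV = "SH", ANIV = "SH",
                                         "NA" = "NH", NP = "NH")) {
  stopifnot(mu >= 0, hv_multiplier >= 0, dup_rate >= 0, del_rate >= 0,
            min_units >= 1L, ancestral_units >= min_units,
            ancestral_units <= max_units,
            2L * n_per_pop <= pop_size,
            length(populations) == 4L)
  structure(list(seed = as.integer(seed), unit_length = as.integer(unit_length),
                 ancestral_units = as.integer(ancestral_units),
                 mu = mu, hv_multiplier = hv_multiplier,
                 dup_rate = dup_rate, del_rate = del_rate,
                 pop_size = as.integer(pop_size),
                 n_per_pop = as.integer(n_per_pop),
                 t1 = as.integer(t1), t2 = as.integer(t2),
                 burn_in = as.integer(burn_in),
                 min_units = as.integer(min_units),
                 max_units = as.integer(max_units),
                 contact_positions = as.integer(contact_positions),
                 populations = populations),
            class = "sim_scenario")
}

# evolve one population pool for `gens` generations; returns the pool and
# appends events to the collector environment
evolve_pool <- function(pool, gens, sc, label, gen0, ev) {
  if (gens <= 0L) return(pool)
  N <- length(pool)
  hv_keep <- mask_spec(sc$contact_positions, sc$unit_length)$keep
  w <- ifelse(hv_keep, 1, sc$hv_multiplier)
  mu_unit <- sc$mu * sum(w)      # expected mutations per unit per generation
  bases <- c("A", "C", "G", "T")
  for (g in seq_len(gens)) {
    pool <- pool[sample.int(N, N, replace = TRUE)]
    sizes <- lengths(pool)
    total <- sum(sizes)
    # point mutations
    nmut <- rpois(1L, total * mu_unit)
    for (k in seq_len(nmut)) {
      a <- sample.int(N, 1L, prob = sizes)
      u <- sample.int(sizes[a], 1L)
      pos <- sample.int(sc$unit_length, 1L, prob = w)
      old <- substr(pool[[a]][u], pos, pos)
      new <- sample(setdiff(bases, old), 1L)
      substr(pool[[a]][u], pos, pos) <- new
      ev$events[[length(ev$events) + 1L]] <-
        c(gen0 + g, label, a, "mutation", paste0(u, ":", pos, old, ">", new))
    }
    # slippage duplications
    ndup <- rpois(1L, total * sc$dup_rate)
    for (k in seq_len(ndup)) {
      a <- sample.int(N, 1L, prob = sizes)
      if (sizes[a] >= sc$max_units) { ev$redraws <- ev$redraws + 1L; next }
      u <- sample.int(sizes[a], 1L)
      pool[[a]] <- append(pool[[a]], pool[[a]][u], after = u)
      sizes[a] <- sizes[a] + 1L
      ev$events[[length(ev$events) + 1L]] <-
        c(gen0 + g, label, a, "duplication", as.character(u))
    }
    # unit deletions
    ndel <- rpois(1L, total * sc$del_rate)
    for (k in seq_len(ndel)) {
      a <- sample.int(N, 1L, prob = sizes)
      if (sizes[a] <= sc$min_units) { ev$redraws <- ev$redraws + 1L; next }
      u <- sample.int(sizes[a], 1L)
      pool[[a]] <- pool[[a]][-u]
      sizes[a] <- sizes[a] - 1L
      ev$events[[length(ev$events) + 1L]] <-
        c(gen0 + g, label, a, "deletion", as.character(u))
    }
  }
  pool
}

#' Simulate minisatellite alleles along the population tree
#'
#' Runs the forward-time model of [sim_scenario()] and returns sampled
#' alleles with full ground truth. The same seed yields byte-identical
#' output.
#'
#' @param scenario a [sim_scenario()].
#' @return An object of class `minisat_sim`: list with `alleles` (a
#'   `minisat_alleles` set), `samples` (data.frame `allele_id
#'   individual_id population hemisphere`), `truth` (list: `pop_tree`
#'   newick string, `events` data.frame with one row per mutation /
#'   duplication / deletion, `theta_site_expected = 2 * pop_size * mu` at
#'   background sites, `redraws` count of guard-skipped events, `ancestor`)
#'   and `scenario`.
#' @seealso [write_sim()] to emit the FASTA/TSV dialect read by
#'   [read_alleles()].
#' @export
simulate_minisat <- function(scenario = sim_scenario()) {
  sc <- scenario
  set.seed(sc$seed)
  anc <- ancestral_unit(sc$unit_length)
  ev <- new.env()
  ev$events <- list(); ev$redraws <- 0L
  root <- replicate(sc$pop_size, rep(anc, sc$ancestral_units),
                    simplify = FALSE)
  root <- evolve_pool(root, sc$burn_in, sc, "ROOT", 0L, ev)
  g1 <- sc$burn_in
  hems <- split(names(sc$populations), sc$populations)
  # hemisphere branches share the burnt-in pool, then evolve independently
  branch <- list()
  for (h in names(hems))
    branch[[h]] <- evolve_pool(root, sc$t2, sc, h, g1, ev)
  g2 <- g1 + sc$t2
  pools <- list()
  for (h in names(hems)) for (pop in hems[[h]])
    pools[[pop]] <- evolve_pool(branch[[h]], sc$t1, sc, pop, g2, ev)
  # sample diploid individuals
  alleles <- list(); samples <- list()
  for (pop in names(sc$populations)) {
    idx <- sample.int(sc$pop_size, 2L * sc$n_per_pop)
    for (j in seq_len(sc$n_per_pop)) {
      for (ph in 1:2) {
        id <- sprintf("%s_i%02d_%s", pop, j, c("a", "b")[ph])
        alleles[[length(alleles) + 1L]] <- minisat_allele(
          allele_id = id,
          individual_id = sprintf("%s_i%02d", pop, j),
          population = pop, hemisphere = sc$populations[[pop]],
          units = pools[[pop]][[idx[2L * (j - 1L) + ph]]],
          unit_length = sc$unit_length)
        samples[[length(samples) + 1L]] <- data.frame(
          allele_id = id, individual_id = sprintf("%s_i%02d", pop, j),
          population = pop, hemisphere = sc$populations[[pop]],
          stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(ev$events) > 0L) {
    m <- do.call(rbind, ev$events)
    data.frame(generation = as.integer(m[, 1L]), lineage = m[, 2L],
               copy = as.integer(m[, 3L]), type = m[, 4L],
               detail = m[, 5L], stringsAsFactors = FALSE)
  } else data.frame(generation = integer(0), lineage = character(0),
                    copy = integer(0), type = character(0),
                    detail = character(0))
  hems_pops <- split(names(sc$populations), sc$populations)
  tree <- sprintf("((%s:%d,%s:%d):%d,(%s:%d,%s:%d):%d);",
                  hems_pops[[1]][1], sc$t1, hems_pops[[1]][2], sc$t1, sc$t2,
                  hems_pops[[2]][1], sc$t1, hems_pops[[2]][2], sc$t1, sc$t2)
  structure(list(alleles = new_allele_set(alleles, sc$unit_length),
                 samples = do.call(rbind, samples),
                 truth = list(pop_tree = tree, events = events,
                              theta_site_expected = 2 * sc$pop_size * sc$mu,
                              redraws = ev$redraws, ancestor = anc),
                 scenario = sc),
            class = "minisat_sim")
}

#' @export
print.minisat_sim <- function(x, ...) {
  cat(sprintf("minisat_sim: %d alleles from %d populations (seed %d)\n",
              length(x$alleles), length(unique(x$samples$population)),
              x$scenario$seed))
  cat(sprintf("  events: %d (redraws %d); pop tree %s\n",
              nrow(x$truth$events), x$truth$redraws, x$truth$pop_tree))
  invisible(x)
}

#' Write simulated data in the dialect read by read_alleles()
#'
#' Emits `alleles.fasta` (one unwrapped record per allele; the description
#' carries the scenario seed), `samples.tsv` (the sample table) and
#' `truth.tsv` (one event per line, with the population tree, expected
#' theta and seed in `#` header comments).
#'
#' @param sim a [simulate_minisat()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "alleles.fasta")
  tsv <- file.path(dir, "samples.tsv")
  truth <- file.path(dir, "truth.tsv")
  ids <- vapply(sim$alleles, `[[`, "", "allele_id")
  seqs <- vapply(sim$alleles, function(a) paste(a$units, collapse = ""), "")
  writeLines(paste0(">", ids, " seed=", sim$scenario$seed, "\n", seqs), fasta)
  write.table(sim$samples, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(truth, "w")
  writeLines(c(paste0("# seed=", sim$scenario$seed),
               paste0("# pop_tree=", sim$truth$pop_tree),
               paste0("# theta_site_expected=",
                      format(sim$truth$theta_site_expected)),
               paste0("# redraws=", sim$truth$redraws)), con)
  close(con)
  suppressWarnings(write.table(sim$truth$events, truth, sep = "\t",
                               quote = FALSE, row.names = FALSE,
                               append = TRUE))
  invisible(c(fasta = fasta, samples = tsv, truth = truth))
}
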