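#' Catalogue zinc-finger types across individuals
#'
#' Types are distinct by full 28-residue amino-acid sequence (not merely by
#' contact code: fingers sharing a contact code such as LNG may still differ
#' at other residues). Each type is labelled *common* when carried by more
#' than one individual and *unique* when seen in a single individual. Only
#' valid fingers (no stop, no ambiguous codon) enter the catalogue.
#'
#' @param alleles a `minisat_alleles` set, or a data.frame with columns
#'   `aa`, `contact_code`, `individual_id`, `valid` (as from [unit_table()]).
#' @param ... passed to [unit_table()] when `alleles` is an allele set.
#' @return A data.frame of class `znf_catalog` with columns `type_id`
#'   (`ZF01`, `ZF02`, ... ordered by descending occurrence then amino-acid
#'   sequence), `aa`, `contact_code`, `n_individuals`, `occurrence_count`,
#'   `status` (`common`/`unique`). Ordering, and hence type ids, are
#'   invariant under permutation of the input.
#' @export
build_catalog <- function(alleles, ...) {
  tab <- if (is.data.frame(alleles)) alleles else unit_table(alleles, ...)
  tab <- tab[tab$valid, , drop = FALSE]
  if (nrow(tab) == 0L) {
    warning("no valid zinc fingers; catalogue is empty")
    out <- data.frame(type_id = character(0), aa = character(0),
                      contact_code = character(0),
                      n_individuals = integer(0),
                      occurrence_count = integer(0), status = character(0))
    class(out) <- c("znf_catalog", "data.frame")
    return(out)
  }
  occ <- tapply(rep(1L, nrow(tab)), tab$aa, sum)
  carriers <- tapply(tab$individual_id, tab$aa,
                     function(x) length(unique(x)))
  codes <- tapply(tab$contact_code, tab$aa, `[`, 1L)
  aa <- names(occ)
  ord <- order(-as.integer(occ), aa)
  out <- data.frame(
    type_id = sprintf("ZF%02d", seq_along(aa)),
    aa = aa[ord],
    contact_code = unname(codes[ord]),
    n_individuals = as.integer(carriers[ord]),
    occurrence_count = as.integer(occ[ord]),
    stringsAsFactors = FALSE)
  out$status <- ifelse(out$n_individuals > 1L, "common", "unique")
  class(out) <- c("znf_catalog", "data.frame")
  out
}

#' @export
print.znf_catalog <- function(x, ...) {
  cat(sprintf("znf_catalog: %d types (%d common, %d unique)\n",
              nrow(x), sum(x$status == "common"), sum(x$status == "unique")))
  print.data.frame(x, ...)
  invisible(x)
}

# protein- or nucleotide-level array signature of one allele
allele_signature <- function(a, level = c("protein", "nucleotide"),
                             frame_offset = 0L) {
  level <- match.arg(level)
  if (level == "nucleotide") return(paste(a$units, collapse = "|"))
  aas <- vapply(a$units, function(u)
    translate_unit(u, frame_offset = frame_offset)$aa, "")
  paste(aas, collapse = "|")
}

# letter sequence A, B, ..., Z, AA, AB, ... for within-group variant labels
variant_letters <- function(n) {
  single <- LETTERS
  if (n <= 26L) return(single[seq_len(n)])
  double <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(single, double)[seq_len(n)]
}

#' Name allele variants by hemisphere and zinc-finger count
#'
#' Alleles with identical array signatures (by default the ordered
#' amino-acid sequences of their units; set `level = "nucleotide"` for
#' finer splitting) are collapsed into variants named
#' `<HEM><total>_<letter>`, where `total` counts the array units plus the
#' proximal zinc knuckle(s) (`knuckle_count`, default 1): an 11-unit
#' Northern-Hemisphere array is `NH12_A`. Letters are assigned within each
#' (hemisphere, total) group by descending number of member alleles, ties
#' broken lexicographically on the signature, so names are deterministic
#' and permutation-invariant.
#'
#' @param alleles a `minisat_alleles` set with hemisphere labels.
#' @param knuckle_count zinc knuckles outside the array counted in the
#'   total (default 1).
#' @param level `"protein"` (default) or `"nucleotide"` variant identity.
#' @param frame_offset see [translate_unit()].
#' @return A list with `variants` (data.frame `variant_id`, `hemisphere`,
#'   `total_znfs`, `n_units`, `signature`, `n_alleles`, `n_individuals`) and
#'   `assignment` (data.frame `allele_id`, `variant_id`).
#' @export
name_alleles <- function(alleles, knuckle_count = 1L,
                         level = c("protein", "nucleotide"),
                         frame_offset = 0L) {
  level <- match.arg(level)
  sig <- vapply(alleles, allele_signature, "", level = level,
                frame_offset = frame_offset)
  hem <- vapply(alleles, `[[`, "", "hemisphere")
  nun <- vapply(alleles, function(a) length(a$units), 0L)
  ids <- vapply(alleles, `[[`, "", "allele_id")
  ind <- vapply(alleles, `[[`, "", "individual_id")
  total <- nun + as.integer(knuckle_count)
  key <- paste(hem, total, sig, sep = "\r")
  grp <- split(seq_along(alleles), key)
  vtab <- data.frame(
    hemisphere = vapply(grp, function(i) hem[i[1L]], ""),
    total_znfs = vapply(grp, function(i) total[i[1L]], 0L),
    n_units = vapply(grp, function(i) nun[i[1L]], 0L),
    signature = vapply(grp, function(i) sig[i[1L]], ""),
    n_alleles = lengths(grp),
    n_individuals = vapply(grp, function(i) length(unique(ind[i])), 0L),
    stringsAsFactors = FALSE)
  vtab$members <- unname(grp)
  vtab$variant_id <- NA_character_
  for (g in split(seq_len(nrow(vtab)),
                  paste(vtab$hemisphere, vtab$total_znfs))) {
    ord <- g[order(-vtab$n_alleles[g], vtab$signature[g])]
    vtab$variant_id[ord] <- sprintf("%s%d_%s",
                                    vtab$hemisphere[ord],
                                    vtab$total_znfs[ord],
                                    variant_letters(length(ord)))
  }
  vtab <- vtab[order(vtab$hemisphere, vtab$total_znfs, vtab$variant_id), ]
  assignment <- data.frame(
    allele_id = ids,
    variant_id = rep(NA_character_, length(ids)),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(vtab)))
    assignment$variant_id[vtab$members[[i]]] <- vtab$variant_id[i]
  vtab$representative <- vapply(vtab$members, function(m) min(ids[m]), "")
  vtab$members <- NULL
  rownames(vtab) <- NULL
  list(variants = vtab[, c("variant_id", "hemisphere", "total_znfs",
                           "n_units", "signature", "n_alleles",
                           "n_individuals", "representative")],
       assignment = assignment)
}

#' Extract the core contact-code motif of an array
#'
#' The core motif is the ordered list of DNA-contact codes of the array
#' fingers most important for binding, by default array positions 3-6
#' (1-based on the array, excluding the zinc knuckle).
#'
#' @param allele a `minisat_allele` (the variant representative when
#'   comparing variants), or a character vector of per-unit contact codes.
#' @param window inclusive 1-based array-index range, default `c(3, 6)`.
#' @param frame_offset,contact_positions see [translate_unit()].
#' @return An object of class `core_motif`: list with `window` and `codes`.
#' @export
core_motif <- function(allele, window = c(3L, 6L), frame_offset = 0L,
                       contact_positions = c(13L, 16L, 19L)) {
  codes <- if (inherits(allele, "minisat_allele")) {
    vapply(allele$units, function(u)
      translate_unit(u, frame_offset = frame_offset,
                     contact_positions = contact_positions)$contact_code, "")
  } else as.character(allele)
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] > window[2L])
    stop("window must be an increasing pair of array indices")
  if (window[1L] < 1L || window[2L] > length(codes))
    stop("window [", window[1L], ",", window[2L],
         "] exceeds array of ", length(codes), " units")
  structure(list(window = window,
                 codes = unname(codes[window[1L]:window[2L]])),
            class = "core_motif")
}

#' @export
print.core_motif <- function(x, ...) {
  cat(sprintf("core_motif [%d,%d]: %s\n", x$window[1L], x$window[2L],
              paste(x$codes, collapse = "-")))
  invisible(x)
}

#' Classify a pair of core motifs
#'
#' Identical motifs predict fully symmetric binding of the two variants'
#' recombination-initiation targets; motifs differing at every position
#' predict asymmetric binding; anything in between is partial. The raw
#' per-position match count is attached so users can re-threshold.
#'
#' @param m1,m2 `core_motif` objects with equal window spans. A missing
#'   contact code (`NA`, from a stop or ambiguity inside a contact codon)
#'   matches nothing, conservatively.
#' @return `"symmetric"`, `"partial"` or `"asymmetric"`, with attributes
#'   `n_match` and `n_positions`.
#' @export
classify_pair <- function(m1, m2) {
  c1 <- if (inherits(m1, "core_motif")) m1$codes else as.character(m1)
  c2 <- if (inherits(m2, "core_motif")) m2$codes else as.character(m2)
  if (length(c1) != length(c2))
    stop("core motifs span different numbers of positions")
  match <- sum(!is.na(c1) & !is.na(c2) & c1 == c2)
  cls <- if (match == length(c1)) "symmetric"
         else if (match == 0L) "asymmetric" else "partial"
  structure(cls, n_match = match, n_positions = length(c1))
}

#' Pairwise core-motif report for named variants
#'
#' @param alleles a `minisat_alleles` set.
#' @param window core-motif window (default `c(3, 6)`), clipped per variant
#'   pair is not attempted: variants whose arrays are shorter than the
#'   window are dropped with a message.
#' @param ... passed to [name_alleles()].
#' @return data.frame `variant1 variant2 motif1 motif2 n_match n_positions
#'   class`, one row per unordered variant pair.
#' @export
motif_report <- function(alleles, window = c(3L, 6L), ...) {
  nm <- name_alleles(alleles, ...)
  v <- nm$variants
  ids <- vapply(alleles, `[[`, "", "allele_id")
  reps <- lapply(v$representative, function(r) alleles[[match(r, ids)]])
  ok <- vapply(reps, function(a) length(a$units) >= window[2L], NA)
  if (any(!ok))
    message("dropping ", sum(!ok), " variant(s) shorter than the motif window")
  v <- v[ok, , drop = FALSE]; reps <- reps[ok]
  motifs <- lapply(reps, core_motif, window = window)
  if (nrow(v) < 2L)
    return(data.frame(variant1 = character(0), variant2 = character(0),
                      motif1 = character(0), motif2 = character(0),
                      n_match = integer(0), n_positions = integer(0),
                      class = character(0)))
  pairs <- combn(nrow(v), 2L)
  rows <- apply(pairs, 2L, function(p) {
    cl <- classify_pair(motifs[[p[1L]]], motifs[[p[2L]]])
    data.frame(variant1 = v$variant_id[p[1L]],
               variant2 = v$variant_id[p[2L]],
               motif1 = paste(motifs[[p[1L]]]$codes, collapse = "-"),
               motif2 = paste(motifs[[p[2L]]]$codes, collapse = "-"),
               n_match = attr(cl, "n_match"),
               n_positions = attr(cl, "n_positions"),
               class = as.character(cl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
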