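#' Hypervariable-codon mask specification
#'
#' The DNA-contact residues of a C2H2 zinc finger sit at alpha-helix
#' positions -1, +3 and +6, which for an 84-bp repeat unit are amino acids
#' 13, 16 and 19. Because these codons evolve under diversifying selection,
#' distance and diversity computations are optionally run after excising
#' them. A `mask_spec` records the 1-based amino-acid positions to excise
#' and the nucleotide ranges they imply (codon k spans nt `3k-2 .. 3k`).
#'
#' @param contact_positions strictly increasing 1-based amino-acid indices
#'   (default `c(13, 16, 19)`).
#' @param unit_length repeat-unit length in nucleotides; must be a multiple
#'   of 3 and contain all masked codons (default 84).
#' @return An object of class `mask_spec` with elements `contact_positions`,
#'   `unit_length`, `nt_ranges` (two-column matrix of 1-based closed ranges)
#'   and `keep` (logical vector over unit positions, `FALSE` at masked nt).
#' @examples
#' m <- mask_spec()
#' m$nt_ranges  # 37-39, 46-48, 55-57
#' @export
mask_spec <- function(contact_positions = c(13L, 16L, 19L), unit_length = 84L) {
  contact_positions <- as.integer(contact_positions)
  unit_length <- as.integer(unit_length)
  if (unit_length < 3L || unit_length %% 3L != 0L)
    stop("unit_length must be a positive multiple of 3")
  if (length(contact_positions) == 0L ||
      any(diff(contact_positions) <= 0L))
    stop("contact_positions must be strictly increasing")
  if (any(contact_positions < 1L) ||
      any(contact_positions > unit_length %/% 3L))
    stop("mask position out of range for unit_length ", unit_length)
  ranges <- cbind(start = 3L * contact_positions - 2L,
                  end   = 3L * contact_positions)
  keep <- rep(TRUE, unit_length)
  for (i in seq_len(nrow(ranges))) keep[ranges[i, 1L]:ranges[i, 2L]] <- FALSE
  structure(list(contact_positions = contact_positions,
                 unit_length = unit_length,
                 nt_ranges = ranges,
                 keep = keep),
            class = "mask_spec")
}

#' @export
print.mask_spec <- function(x, ...) {
  cat("mask_spec: unit", x$unit_length, "nt; codons",
      paste(x$contact_positions, collapse = ","),
      "-> nt", paste(sprintf("%d-%d", x$nt_ranges[, 1], x$nt_ranges[, 2]),
                     collapse = ", "), "excised\n")
  invisible(x)
}

# mask a bare nucleotide string (internal; no class dispatch)
mask_seq <- function(seq, mask) {
  if (nchar(seq) != mask$unit_length)
    stop("sequence length ", nchar(seq), " does not match mask unit_length ",
         mask$unit_length)
  paste(strsplit(seq, "", fixed = TRUE)[[1L]][mask$keep], collapse = "")
}

#' Excise the hypervariable codons from a repeat unit
#'
#' Removes the nucleotides coding for the DNA-contact amino acids
#' (by default codons 13, 16 and 19, i.e. nt 37-39, 46-48 and 55-57 of an
#' 84-nt unit), preserving the order of the remaining positions. For the
#' default mask an 84-nt unit yields a 75-nt string.
#'
#' @param unit a repeat unit: a nucleotide string, or a `repeat_unit` as
#'   produced by [partition_allele()].
#' @param mask a [mask_spec()].
#' @return The masked nucleotide string.
#' @examples
#' mask_unit(strrep("ACGT", 21))  # 75 characters
#' @export
mask_unit <- function(unit, mask = mask_spec()) {
  seq <- unit_seq(unit)
  mask_seq(seq, mask)
}
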