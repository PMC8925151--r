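#' Translate a repeat unit into a zinc finger
#'
#' Standard genetic-code translation of the unit in frame 1 (an optional
#' circular frame offset accommodates amplicons whose repeat phase differs
#' from the coding frame). A unit of 84 nt yields a 28-residue zinc finger.
#' An internal stop codon or any codon containing `N` marks the finger
#' invalid; the three-letter contact code (residues at the DNA-contact
#' positions, default amino acids 13/16/19) is extracted whenever those
#' three codons are unambiguous, valid or not.
#'
#' @param unit a repeat unit (string or `repeat_unit`).
#' @param frame_offset circular rotation of the unit in nt before
#'   translation (default 0; tandem-repeat phase is circular).
#' @param contact_positions 1-based amino-acid positions of the DNA-contact
#'   residues (default `c(13, 16, 19)`).
#' @return An object of class `znf` with fields `aa` (ambiguous codons as
#'   `X`, stops as `*`), `contact_code` (3 characters or `NA`), `valid`,
#'   `reason` (`""`, `"stop"` or `"ambiguous"`), `unit_index`.
#' @examples
#' zf <- translate_unit(ancestral_unit())
#' zf$contact_code  # "DSK"
#' @export
translate_unit <- function(unit, frame_offset = 0L,
                           contact_positions = c(13L, 16L, 19L)) {
  seq <- unit_seq(unit)
  idx <- if (inherits(unit, "repeat_unit")) unit$index else NA_integer_
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("unit length ", n, " is not a multiple of 3")
  frame_offset <- as.integer(frame_offset) %% n
  if (frame_offset > 0L)
    seq <- paste0(substr(seq, frame_offset + 1L, n),
                  substr(seq, 1L, frame_offset))
  codons <- substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  ambiguous <- is.na(aa)
  aa[ambiguous] <- "X"
  reason <- if (any(aa == "*")) "stop" else if (any(ambiguous)) "ambiguous" else ""
  if (max(contact_positions) > length(aa))
    stop("contact position beyond translated length")
  contact <- aa[contact_positions]
  contact_code <- if (any(contact %in% c("X", "*"))) NA_character_ else
    paste(contact, collapse = "")
  structure(list(aa = paste(aa, collapse = ""),
                 contact_code = contact_code,
                 valid = reason == "",
                 reason = reason,
                 unit_index = idx),
            class = "znf")
}

#' @export
print.znf <- function(x, ...) {
  cat(sprintf("znf[%s] %s contact=%s valid=%s%s\n",
              ifelse(is.na(x$unit_index), "-", x$unit_index), x$aa,
              ifelse(is.na(x$contact_code), "?", x$contact_code),
              x$valid, ifelse(x$reason == "", "", paste0(" (", x$reason, ")"))))
  invisible(x)
}

#' Check the C2H2 anchor residues of a zinc finger
#'
#' A structurally sound C2H2 finger carries two cysteines and two
#' histidines at fixed offsets; the default offsets (C8, C11, H24, H28 of
#' the 28-residue unit) follow the canonical layout of the conserved first
#' finger of the baleen-whale array (see [ancestral_unit()]). Returns
#' `TRUE` iff the anchors are present and the translation has no stop.
#'
#' @param zf a `znf` from [translate_unit()] (or a 28-residue amino-acid
#'   string).
#' @param anchor_offsets 1-based positions of the C,C,H,H anchors.
#' @return Logical flag.
#' @export
validate_znf <- function(zf, anchor_offsets = c(8L, 11L, 24L, 28L)) {
  aa <- if (inherits(zf, "znf")) zf$aa else as.character(zf)
  if (length(anchor_offsets) != 4L)
    stop("anchor_offsets must give the four C,C,H,H positions")
  if (max(anchor_offsets) > nchar(aa)) return(FALSE)
  if (grepl("*", aa, fixed = TRUE)) return(FALSE)
  res <- strsplit(aa, "", fixed = TRUE)[[1L]][anchor_offsets]
  all(res == c("C", "C", "H", "H"))
}
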