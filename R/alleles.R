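#' @rdname partition_allele
#' @export
repeat_unit <- function(seq, index = 1L) {
  seq <- toupper(seq)
  if (!grepl("^[ACGTN]*$", seq))
    stop("repeat unit contains characters outside {A,C,G,T,N}")
  structure(list(seq = seq, index = as.integer(index)), class = "repeat_unit")
}

# nucleotide string of a unit in any accepted representation
unit_seq <- function(unit) {
  if (inherits(unit, "repeat_unit")) unit$seq
  else if (is.character(unit) && length(unit) == 1L) toupper(unit)
  else stop("expected a repeat unit (string or repeat_unit object)")
}

#' Partition a minisatellite sequence into repeat units
#'
#' Cuts an array sequence into consecutive, non-overlapping units of
#' `unit_length` nucleotides, 5' to 3', indexed 1..n. Joining the unit
#' sequences back together reproduces the input exactly.
#'
#' @param seq nucleotide string whose length is a multiple of `unit_length`.
#' @param unit_length repeat-unit length in nt (default 84).
#' @return A list of `repeat_unit` objects (fields `seq`, `index`).
#' @examples
#' u <- partition_allele(strrep("A", 168), 84)
#' length(u)      # 2
#' u[[2]]$index   # 2
#' @export
partition_allele <- function(seq, unit_length = 84L) {
  seq <- toupper(seq)
  unit_length <- as.integer(unit_length)
  n <- nchar(seq)
  if (unit_length < 1L) stop("unit_length must be >= 1")
  if (n == 0L || n %% unit_length != 0L)
    stop("sequence length ", n, " is not a positive multiple of unit_length ",
         unit_length)
  k <- n %/% unit_length
  starts <- (seq_len(k) - 1L) * unit_length + 1L
  lapply(seq_len(k), function(i)
    repeat_unit(substr(seq, starts[i], starts[i] + unit_length - 1L), i))
}

#' Construct a minisatellite allele
#'
#' An allele is an ordered array of equal-length repeat units attributed to
#' an individual and population. `units` may be given as a character vector
#' of unit sequences or as the whole array sequence (partitioned with
#' `unit_length`).
#'
#' @param allele_id,individual_id identifiers.
#' @param population population label (e.g. `"ANV"`, `"ANIV"`, `"NA"`,
#'   `"NP"`).
#' @param hemisphere `"NH"` or `"SH"`.
#' @param units character vector of unit sequences, or a single array
#'   sequence.
#' @param unit_length unit length in nt (default 84).
#' @param flank5,flank3 flanking sequence retained for provenance (default
#'   empty).
#' @return An object of class `minisat_allele`.
#' @export
minisat_allele <- function(allele_id, individual_id = allele_id,
                           population = "POP", hemisphere = NA_character_,
                           units, unit_length = 84L,
                           flank5 = "", flank3 = "") {
  if (length(units) == 1L && nchar(units) > unit_length)
    units <- vapply(partition_allele(units, unit_length), `[[`, "", "seq")
  units <- toupper(as.character(units))
  if (length(units) < 1L) stop("allele must contain at least one unit")
  if (any(nchar(units) != unit_length))
    stop("allele ", allele_id, ": units are not all of length ", unit_length)
  if (!all(grepl("^[ACGTN]+$", units)))
    stop("allele ", allele_id, ": units contain characters outside {A,C,G,T,N}")
  structure(list(allele_id = as.character(allele_id),
                 individual_id = as.character(individual_id),
                 population = as.character(population),
                 hemisphere = as.character(hemisphere),
                 units = units,
                 unit_length = as.integer(unit_length),
                 flank5 = flank5, flank3 = flank3),
            class = "minisat_allele")
}

#' @export
print.minisat_allele <- function(x, ...) {
  cat(sprintf("minisat_allele %s (%s, %s/%s): %d x %d nt units\n",
              x$allele_id, x$individual_id, x$population, x$hemisphere,
              length(x$units), x$unit_length))
  invisible(x)
}

new_allele_set <- function(alleles, unit_length) {
  structure(alleles, unit_length = as.integer(unit_length),
            class = "minisat_alleles")
}

#' @export
print.minisat_alleles <- function(x, ...) {
  pops <- table(vapply(x, `[[`, "", "population"))
  cat(sprintf("minisat_alleles: %d alleles, unit length %d nt\n",
              length(x), attr(x, "unit_length")))
  cat("  populations:",
      paste(sprintf("%s=%d", names(pops), pops), collapse = " "), "\n")
  invisible(x)
}

#' @export
`[.minisat_alleles` <- function(x, i) {
  new_allele_set(unclass(x)[i], attr(x, "unit_length"))
}

# read a sample table; "NA" is a real population label (North Atlantic),
# so nothing may be interpreted as missing
read_sample_table <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character",
                    na.strings = character(0), comment.char = "#",
                    check.names = FALSE)
  need <- c("allele_id", "individual_id", "population", "hemisphere")
  if (!all(need %in% names(tab)))
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  tab[need]
}

#' Read minisatellite alleles from FASTA plus a sample table
#'
#' Reads one record per (phased) allele, trims declared 5'/3' flanks, and
#' partitions each record into repeat units. Record order is preserved.
#' The sample table is tab-separated with header columns
#' `allele_id individual_id population hemisphere`; the string `"NA"` is a
#' valid population label and is never treated as missing.
#'
#' @param fasta_path path to a (wrapped or unwrapped) multi-record FASTA.
#' @param samples_path path to the sample table TSV.
#' @param unit_length repeat-unit length in nt (default 84).
#' @param flank5_len,flank3_len number of nt to trim from each end before
#'   partitioning (default 0).
#' @return A `minisat_alleles` set (list of [minisat_allele()] objects).
#' @seealso [partition_allele()], [simulate_minisat()] which emits this
#'   dialect.
#' @export
read_alleles <- function(fasta_path, samples_path, unit_length = 84L,
                         flank5_len = 0L, flank3_len = 0L) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("no FASTA records in ", fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  tab <- read_sample_table(samples_path)
  missing <- setdiff(ids, tab$allele_id)
  if (length(missing) > 0L)
    stop("records absent from sample table: ",
         paste(missing, collapse = ", "))
  meta <- tab[match(ids, tab$allele_id), ]
  alleles <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- toupper(as.character(seqs[[i]]))
    n <- nchar(s)
    if (n <= flank5_len + flank3_len)
      stop("record ", ids[i], ": shorter than its declared flanks")
    core <- substr(s, flank5_len + 1L, n - flank3_len)
    if (nchar(core) %% unit_length != 0L)
      stop("record ", ids[i], ": trimmed length ", nchar(core),
           " is not a multiple of unit_length ", unit_length)
    alleles[[i]] <- minisat_allele(
      allele_id = ids[i], individual_id = meta$individual_id[i],
      population = meta$population[i], hemisphere = meta$hemisphere[i],
      units = core, unit_length = unit_length,
      flank5 = if (flank5_len > 0L) substr(s, 1L, flank5_len) else "",
      flank3 = if (flank3_len > 0L) substr(s, n - flank3_len + 1L, n) else "")
  }
  new_allele_set(alleles, unit_length)
}

#' Tabulate repeat units and their zinc-finger translations
#'
#' One row per repeat unit of every allele, with the unit sequence, its
#' translation, contact code and validity flag.
#'
#' @param alleles a `minisat_alleles` set.
#' @param contact_positions contact amino-acid positions (default 13,16,19).
#' @param frame_offset see [translate_unit()].
#' @return A data.frame with columns `allele_id`, `individual_id`,
#'   `population`, `hemisphere`, `unit_index`, `unit_seq`, `aa`,
#'   `contact_code`, `valid`, `reason`.
#' @export
unit_table <- function(alleles, contact_positions = c(13L, 16L, 19L),
                       frame_offset = 0L) {
  rows <- lapply(alleles, function(a) {
    zfs <- lapply(seq_along(a$units), function(i)
      translate_unit(repeat_unit(a$units[i], i),
                     frame_offset = frame_offset,
                     contact_positions = contact_positions))
    data.frame(allele_id = a$allele_id,
               individual_id = a$individual_id,
               population = a$population,
               hemisphere = a$hemisphere,
               unit_index = seq_along(a$units),
               unit_seq = a$units,
               aa = vapply(zfs, `[[`, "", "aa"),
               contact_code = vapply(zfs, `[[`, "", "contact_code"),
               valid = vapply(zfs, `[[`, NA, "valid"),
               reason = vapply(zfs, `[[`, "", "reason"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
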