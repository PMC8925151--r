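# shared fixtures: unit variants derived from the synthetic reference unit,
# and small on-disk FASTA/TSV inputs built at test time

ref_unit <- function() ancestral_unit()

# substitute single bases (1-based positions) in a unit string
edit_unit <- function(u, pos, base) {
  for (k in seq_along(pos)) substr(u, pos[k], pos[k]) <- base[k]
  u
}

# three-unit alphabet: U2 differs from U1 only inside hypervariable codons
# (masked-identical), U3 differs at three background positions
unit_alphabet <- function() {
  u1 <- ref_unit()
  u2 <- edit_unit(u1, c(37L, 46L), c("A", "C"))
  u3 <- edit_unit(u1, c(1L, 2L, 3L), c("G", "T", "A"))
  c(u1, u2, u3)
}

# all arrays of lengths 0..max_len over the unit alphabet
all_arrays <- function(max_len = 3L, alphabet = unit_alphabet()) {
  arrays <- list(character(0))
  for (len in seq_len(max_len)) {
    g <- expand.grid(rep(list(seq_along(alphabet)), len))
    arrays <- c(arrays, lapply(seq_len(nrow(g)),
                               function(i) alphabet[as.integer(g[i, ])]))
  }
  arrays
}

# a small four-population allele set written to disk; returns paths + set
write_toy_inputs <- function(dir = tempfile("minisat")) {
  dir.create(dir)
  a <- unit_alphabet()
  arrays <- list(
    NA1_a  = c(a[1], a[1], a[2]),
    NA1_b  = c(a[1], a[1], a[2]),
    NP1_a  = c(a[1], a[1], a[2]),
    NP1_b  = c(a[1], a[3], a[2]),
    ANV1_a = c(a[3], a[3], a[2], a[2]),
    ANV1_b = c(a[3], a[3], a[2]),
    ANIV1_a = c(a[3], a[2], a[2], a[2]),
    ANIV1_b = c(a[3], a[3], a[2], a[1])
  )
  pop <- c("NA", "NA", "NP", "NP", "ANV", "ANV", "ANIV", "ANIV")
  hem <- c("NH", "NH", "NH", "NH", "SH", "SH", "SH", "SH")
  fasta <- file.path(dir, "alleles.fasta")
  writeLines(paste0(">", names(arrays), "\n",
                    vapply(arrays, paste, "", collapse = "")), fasta)
  samples <- file.path(dir, "samples.tsv")
  write.table(data.frame(allele_id = names(arrays),
                         individual_id = sub("_[ab]$", "", names(arrays)),
                         population = pop, hemisphere = hem),
              samples, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, samples = samples, arrays = arrays,
       pop = pop, hem = hem, dir = dir)
}

# pool built directly from unit strings
pool_from_units <- function(units, population = "P", masked = FALSE) {
  alleles <- lapply(seq_along(units), function(i)
    minisat_allele(paste0("x", i), population = population,
                   units = units[i], unit_length = nchar(units[i])))
  stack_pool(new_set(alleles, nchar(units[1])), population, masked = masked,
             mask = mask_spec(unit_length = nchar(units[1])))
}

# minimal allele-set constructor for tests (mirrors the internal one)
new_set <- function(alleles, unit_length) {
  structure(alleles, unit_length = as.integer(unit_length),
            class = "minisat_alleles")
}

# single-site pool (L = 1) built directly from a base vector
single_site_pool <- function(bases, pop) {
  structure(list(population = pop, units = matrix(bases, ncol = 1),
                 n = length(bases), L = 1L, masked = FALSE),
            class = "repeat_pool")
}

# does the unrooted tree contain the split separating `tips` from the rest?
has_split <- function(tree, tips) {
  other <- setdiff(tree$tip.label, tips)
  if (length(tips) == 0L || length(other) == 0L) return(NA)
  rooted <- ape::root(tree, outgroup = other[1], resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips)
}
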