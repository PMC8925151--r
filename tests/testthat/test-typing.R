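make_typed_set <- function() {
  a <- unit_alphabet()
  # NH: one 11-unit protein variant shared by two individuals;
  # SH: two 9-unit variants with unequal carrier counts
  arrays <- list(
    NAi1_a = rep(a[1], 11), NAi2_a = rep(a[1], 11),
    SHa_a = c(rep(a[1], 8), a[2]), SHb_a = c(rep(a[1], 8), a[2]),
    SHc_a = c(rep(a[1], 8), a[3])
  )
  pops <- c("NA", "NA", "ANV", "ANV", "ANIV")
  hems <- c("NH", "NH", "SH", "SH", "SH")
  alleles <- lapply(seq_along(arrays), function(i)
    minisat_allele(names(arrays)[i],
                   individual_id = sub("_a$", "", names(arrays)[i]),
                   population = pops[i], hemisphere = hems[i],
                   units = arrays[[i]]))
  new_set(alleles, 84L)
}

test_that("catalogue types by full amino-acid sequence with common/unique status", {
  a <- unit_alphabet()
  mk <- function(id, ind, units) minisat_allele(id, ind, "NP", "NH", units)
  set <- new_set(list(mk("x1", "i1", c(a[1], a[1])),
                      mk("x2", "i2", a[1]),
                      mk("x3", "i2", a[2])), 84L)
  cat <- build_catalog(set)
  expect_equal(nrow(cat), 2L)           # a1 vs a2 differ in protein
  expect_equal(cat$status, c("common", "unique"))
  expect_equal(cat$occurrence_count, c(3L, 1L))
  # occurrence conservation
  expect_equal(sum(cat$occurrence_count), 4L)

  # two units differing only at a contact residue are distinct types
  cat2 <- build_catalog(new_set(list(mk("y1", "i1", a[1]),
                                     mk("y2", "i2", a[2])), 84L))
  expect_equal(nrow(cat2), 2L)
})

test_that("invalid fingers are excluded and empty input warns", {
  u <- ref_unit(); substr(u, 13, 15) <- "TAA"
  set <- new_set(list(minisat_allele("s1", "i1", "NP", "NH", u)), 84L)
  expect_warning(cat <- build_catalog(set), "empty")
  expect_equal(nrow(cat), 0L)
})

test_that("catalogue and names are invariant under input permutation", {
  set <- make_typed_set()
  perm <- new_set(unclass(set)[c(4, 1, 5, 2, 3)], 84L)
  expect_equal(build_catalog(set), build_catalog(perm))
  n1 <- name_alleles(set); n2 <- name_alleles(perm)
  expect_equal(n1$variants[order(n1$variants$variant_id), ],
               n2$variants[order(n2$variants$variant_id), ],
               ignore_attr = TRUE)
  expect_equal(sort(n1$assignment$variant_id), sort(n2$assignment$variant_id))
})

test_that("variant naming follows <HEM><total>_<letter> with carrier-count letters", {
  nm <- name_alleles(make_typed_set(), knuckle_count = 1)
  v <- nm$variants
  expect_equal(v$variant_id[v$hemisphere == "NH"], "NH12_A")
  sh <- v[v$hemisphere == "SH", ]
  expect_equal(sort(sh$variant_id), c("SH10_A", "SH10_B"))
  # A goes to the 2-carrier variant
  expect_equal(sh$n_alleles[sh$variant_id == "SH10_A"], 2L)
  expect_equal(sh$n_alleles[sh$variant_id == "SH10_B"], 1L)
})

test_that("nucleotide-level naming splits protein-synonymous arrays", {
  u <- ref_unit()
  syn <- u
  substr(syn, 6, 6) <- "G"  # GGA -> GGG, both Gly
  expect_equal(translate_unit(u)$aa, translate_unit(syn)$aa)
  set <- new_set(list(minisat_allele("p1", "i1", "ANV", "SH", u),
                      minisat_allele("p2", "i2", "ANV", "SH", syn)), 84L)
  expect_equal(nrow(name_alleles(set)$variants), 1L)
  expect_equal(nrow(name_alleles(set, level = "nucleotide")$variants), 2L)
})

test_that("core motifs window the array contact codes", {
  a <- unit_alphabet()
  allele <- minisat_allele("m1", "i1", "ANV", "SH",
                           c(rep(a[1], 4), rep(a[2], 5)))
  cm <- core_motif(allele)
  expect_equal(cm$window, c(3L, 6L))
  expect_equal(cm$codes, c("DSK", "DSK", "NRK", "NRK"))
  expect_equal(core_motif(allele, c(1, 1))$codes, "DSK")
  expect_error(core_motif(allele, c(3, 12)), "exceeds")
})

test_that("pair classification is three-way, symmetric and reflexive", {
  m1 <- core_motif(c("DSK", "DSK", "NRK", "LNG"), c(1, 4))
  m2 <- core_motif(c("DSK", "DSK", "LNG", "NRK"), c(1, 4))
  m3 <- core_motif(c("AAA", "BBB", "CCC", "DDD"), c(1, 4))
  expect_equal(as.character(classify_pair(m1, m1)), "symmetric")
  cl <- classify_pair(m1, m2)
  expect_equal(as.character(cl), "partial")
  expect_equal(attr(cl, "n_match"), 2L)
  expect_equal(attr(cl, "n_positions"), 4L)
  expect_equal(as.character(classify_pair(m1, m3)), "asymmetric")
  # argument symmetry and reflexivity over random motifs
  set.seed(3)
  codes <- c("DSK", "NRK", "LNG")
  for (k in 1:20) {
    x <- core_motif(sample(codes, 4, TRUE), c(1, 4))
    y <- core_motif(sample(codes, 4, TRUE), c(1, 4))
    expect_identical(as.character(classify_pair(x, y)),
                     as.character(classify_pair(y, x)))
    expect_equal(as.character(classify_pair(x, x)), "symmetric")
  }
  expect_error(classify_pair(core_motif(c("DSK"), c(1, 1)), m1), "different")
})

test_that("motif report covers every variant pair with match counts", {
  toy <- write_toy_inputs()
  alleles <- read_alleles(toy$fasta, toy$samples)
  rep <- suppressMessages(motif_report(alleles, window = c(1L, 3L)))
  nv <- nrow(name_alleles(alleles)$variants)
  expect_equal(nrow(rep), choose(nv, 2))
  expect_true(all(rep$class %in% c("symmetric", "partial", "asymmetric")))
  expect_true(all(rep$n_match <= rep$n_positions))
})
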