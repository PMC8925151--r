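test_that("stacking retains unit multiplicity; per_variant collapses alleles", {
  u <- ref_unit()
  mk <- function(id, units) minisat_allele(id, id, "ANV", "SH", units)
  set <- new_set(list(mk("a1", rep(u, 9)), mk("a2", rep(u, 9))), 84L)
  expect_equal(stack_pool(set, "ANV")$n, 18L)
  expect_equal(stack_pool(set, "ANV", masked = TRUE)$L, 75L)
  expect_equal(stack_pool(set, "ANV", per_variant = TRUE)$n, 9L)
  expect_error(stack_pool(set, "NP"), "no alleles")
})

test_that("segregating sites count columns with two non-N states", {
  u <- ref_unit()
  same <- pool_from_units(c(u, u, u))
  expect_equal(segregating_sites(same), 0L)
  v <- edit_unit(u, c(3L, 9L, 30L), c("T", "T", "T"))
  expect_equal(segregating_sites(pool_from_units(c(u, u, v, v))), 3L)
  # a column A/A/G segregates once; an N-only difference does not
  w <- edit_unit(u, 3L, "N")
  expect_equal(segregating_sites(pool_from_units(c(u, u, w))), 0L)
})

test_that("Watterson's estimator matches hand-computed values", {
  expect_equal(watterson_theta(0, 10, 84)$theta_locus, 0)
  expect_equal(watterson_theta(5, 2, 84)$theta_locus, 5)
  th <- watterson_theta(4, 5, 84)
  expect_equal(th$theta_locus, 1.92)   # a1 = 25/12
  expect_equal(th$theta_site, 1.92 / 84)
  expect_error(watterson_theta(1, 1, 84), "n >= 2")
})

test_that("pi matches direct enumeration and its Nei variance formula", {
  u <- ref_unit()
  same <- pool_from_units(c(u, u))
  nd0 <- nucleotide_diversity(same)
  expect_equal(nd0$pi, 0); expect_equal(nd0$pi_se, 0)

  # n=2 with 3 mismatches over L=75 (masked)
  v <- edit_unit(u, c(2L, 9L, 30L), c("T", "T", "T"))
  ndm <- nucleotide_diversity(pool_from_units(c(u, v), masked = TRUE))
  expect_equal(ndm$pi, 3 / 75)

  # n=3 with pairwise differences 2,2,0 over L=84
  w <- edit_unit(u, c(2L, 9L), c("T", "T"))
  nd3 <- nucleotide_diversity(pool_from_units(c(u, w, w)))
  expect_equal(nd3$pi, 4 / (3 * 84))
  n <- 3; L <- 84; pi <- nd3$pi
  expect_equal(nd3$pi_se,
               sqrt(pi * (n + 1) / (3 * (n - 1) * L) +
                    2 * (n^2 + n + 3) * pi^2 / (9 * n * (n - 1))))
})

test_that("pi agrees with ape's raw pairwise distances on N-free pools", {
  set.seed(41)
  u <- ref_unit()
  units <- vapply(1:8, function(i) {
    pos <- sample(84, sample(0:6, 1))
    edit_unit(u, pos, sample(c("A", "C", "G", "T"), length(pos), TRUE))
  }, "")
  pool <- pool_from_units(units)
  nd <- nucleotide_diversity(pool)
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(units), ""), identity)))
  d <- ape::dist.dna(bin, model = "raw")
  expect_equal(nd$pi, mean(d), tolerance = 1e-12)
  # cross-module consistency: pi is the mean unit_hamming / L over pairs
  pairs <- combn(length(units), 2)
  hm <- mean(apply(pairs, 2, function(p) unit_hamming(units[p[1]], units[p[2]])))
  expect_equal(nd$pi, hm / 84, tolerance = 1e-12)
})

test_that("pairs with N skip those sites in the mismatch count", {
  u <- ref_unit()
  v <- edit_unit(u, c(2L, 9L), c("N", "T"))  # one N site, one real mismatch
  nd <- nucleotide_diversity(pool_from_units(c(u, v)))
  expect_equal(nd$pi, 1 / 84)
})

test_that("differentiation limits: identity gives 0, fixed difference gives 1", {
  # identical frequency distributions
  same <- differentiation(list(single_site_pool(c("A", "A", "T"), "P1"),
                               single_site_pool(c("A", "A", "T"), "P2")),
                          corrected = FALSE)
  expect_equal(same$pairwise$Gst, 0)
  expect_equal(same$pairwise$JostD, 0)
  # complete fixation of different bases (uncorrected estimators)
  fixed <- differentiation(list(single_site_pool(rep("T", 6), "P1"),
                                single_site_pool(rep("G", 6), "P2")),
                           corrected = FALSE)
  expect_equal(fixed$pairwise$Gst, 1)
  expect_equal(fixed$pairwise$JostD, 1)
})

test_that("hand-computed frequencies reproduce Gst and Jost's D", {
  # one site with frequencies (0.8, 0.2) vs (0.2, 0.8):
  # Hs = 0.32, Ht = 0.5, Gst = 0.36, D = (0.18/0.68)*2 = 0.529412
  p1 <- single_site_pool(c(rep("A", 8), rep("T", 2)), "P1")
  p2 <- single_site_pool(c(rep("A", 2), rep("T", 8)), "P2")
  d <- differentiation(list(p1, p2), corrected = FALSE)
  expect_equal(d$pairwise$Hs, 0.32, tolerance = 1e-12)
  expect_equal(d$pairwise$Ht, 0.5, tolerance = 1e-12)
  expect_equal(d$pairwise$Gst, 0.36, tolerance = 1e-12)
  expect_equal(d$pairwise$JostD, 0.18 / 0.68 * 2, tolerance = 1e-12)
  # the same frequencies diluted across an 84-nt unit leave Gst unchanged
  u <- ref_unit()
  v <- edit_unit(u, 2L, "T")
  q1 <- pool_from_units(c(rep(u, 8), rep(v, 2)), "P1")
  q2 <- pool_from_units(c(rep(u, 2), rep(v, 8)), "P2")
  dq <- differentiation(list(q1, q2), corrected = FALSE)
  expect_equal(dq$pairwise$Gst, 0.36, tolerance = 1e-12)
})

test_that("corrected estimators permit small negative values near panmixia", {
  set.seed(53)
  u <- ref_unit()
  variants <- vapply(1:4, function(i)
    edit_unit(u, sample(84, 2), sample(c("A", "C", "G", "T"), 2, TRUE)), "")
  draws <- sample(variants, 40, replace = TRUE)
  p1 <- pool_from_units(draws[1:20], "P1")
  p2 <- pool_from_units(draws[21:40], "P2")
  d <- differentiation(list(p1, p2))
  expect_lt(abs(d$pairwise$Gst), 0.2)
  expect_true(d$pairwise$Gst <= 1 && d$pairwise$JostD <= 1)
})

test_that("sites where one population is all-N drop that population", {
  u <- ref_unit()
  vN <- edit_unit(u, 2L, "N")
  v <- edit_unit(u, 2L, "T")
  p1 <- pool_from_units(c(vN, vN, vN), "P1")  # site 2 uninformative in P1
  p2 <- pool_from_units(c(u, v, v), "P2")
  expect_no_error(d <- differentiation(list(p1, p2)))
  expect_true(is.finite(d$pairwise$Gst))
})

test_that("mismatched pool lengths are rejected", {
  u <- ref_unit()
  p1 <- pool_from_units(c(u, u), "P1")
  p2 <- pool_from_units(c(u, u), "P2", masked = TRUE)
  expect_error(differentiation(list(p1, p2)), "mismatched")
})

test_that("diversity_table summarises each population in both mask settings", {
  toy <- write_toy_inputs()
  alleles <- read_alleles(toy$fasta, toy$samples)
  tab <- diversity_table(alleles)
  expect_equal(nrow(tab), 8L)  # 4 populations x 2 mask settings
  expect_setequal(unique(tab$L), c(84L, 75L))
  expect_true(all(tab$S <= tab$L))
  expect_true(all(tab$pi >= 0 & tab$pi <= 1))
  # masked pi never exceeds unmasked pi for the same population
  for (pop in unique(tab$population)) {
    expect_lte(tab$pi[tab$population == pop & tab$masked],
               tab$pi[tab$population == pop & !tab$masked] + 1e-12)
  }
})
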