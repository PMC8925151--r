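test_that("unit hamming counts mismatches, N conservatively", {
  u <- ref_unit()
  expect_equal(unit_hamming(u, u), 0L)
  v <- edit_unit(u, c(2L, 9L), c("T", "T"))
  expect_equal(unit_hamming(u, v), 2L)
  # N mismatches everything, including N
  n1 <- edit_unit(u, 5L, "N")
  expect_equal(unit_hamming(u, n1), 1L)
  expect_equal(unit_hamming(n1, n1), 1L)
  # masked comparison ignores contact-codon differences
  w <- edit_unit(u, 47L, "T")  # inside codon 16
  expect_equal(unit_hamming(u, w), 1L)
  expect_equal(unit_hamming(u, w, masked = TRUE), 0L)
  expect_error(unit_hamming(u, "ACGT"), "unequal")
})

test_that("forced-cost cases hit the configured weights exactly", {
  a <- unit_alphabet()
  p <- repeat_dist_params()  # 1 / 3.5 / 1.75
  # pure substitutions: hamming(U1,U3) = 3
  expect_equal(array_edit_distance(c(a[1], a[1]), c(a[1], a[3]), p), 3)
  one <- edit_unit(a[1], 10L, "T")
  expect_equal(array_edit_distance(c(a[1], a[1]), c(a[1], one), p), 1)
  # adjacent-duplicate insertion costs w_slippage
  expect_equal(array_edit_distance(c(a[1], a[3]), c(a[1], a[1], a[3]), p), 1.75)
  # insertion of a unit far from both neighbours costs w_indel
  far <- edit_unit(a[1], c(10L, 20L, 30L, 40L, 50L), rep("T", 5))
  expect_equal(array_edit_distance(c(a[1], a[1], a[1]),
                                   c(a[1], a[1], far, a[1]), p), 3.5)
  # (A,B,C) vs (A,B',C) with hamming(B,B') = 2 and no slippage opportunity
  b <- edit_unit(a[3], 20L, "C")
  b2 <- edit_unit(a[3], c(20L, 21L), c("G", "C"))
  expect_equal(unit_hamming(b, b2), 2L)
  expect_equal(array_edit_distance(c(a[1], b, a[2]), c(a[1], b2, a[2]), p), 2)
  # self distance
  expect_equal(array_edit_distance(c(a[1], a[2], a[3]), c(a[1], a[2], a[3]), p), 0)
})

test_that("empty arrays fall back to pure indel cost with a warning", {
  a <- unit_alphabet()
  p <- repeat_dist_params()
  expect_warning(d0 <- array_edit_distance(a[1], character(0), p), "empty")
  expect_equal(d0, 3.5)
  expect_warning(dd <- array_edit_distance(c(a[1], a[1]), character(0), p))
  expect_equal(dd, 2 * 1.75)  # both units duplicate their neighbour
  expect_warning(dz <- array_edit_distance(character(0), character(0), p))
  expect_equal(dz, 0)
})

test_that("brute-force oracle matches the DP on a small exhaustive sweep", {
  arrays <- all_arrays(3L)
  for (masked in c(FALSE, TRUE)) {
    p <- repeat_dist_params(masked = masked)
    for (i in seq_along(arrays)) for (j in i:length(arrays)) {
      bf <- brute_force_distance(arrays[[i]], arrays[[j]], p)
      dp <- suppressWarnings(array_edit_distance(arrays[[i]], arrays[[j]], p))
      expect_equal(dp, bf, tolerance = 1e-12)
    }
  }
})

test_that("oracle refuses long arrays and handles singletons", {
  a <- unit_alphabet()
  p <- repeat_dist_params()
  expect_error(brute_force_distance(rep(a[1], 5), a[1], p), "refuses")
  expect_equal(brute_force_distance(a[1], a[1], p), 0)
  expect_equal(brute_force_distance(a[1], character(0), p), 3.5)
})

test_that("distance is symmetric and reduces to hamming on single units", {
  set.seed(21)
  arrays <- all_arrays(3L)
  p <- repeat_dist_params()
  pm <- repeat_dist_params(masked = TRUE)
  for (k in 1:2000) {
    i <- sample(length(arrays), 1L); j <- sample(length(arrays), 1L)
    d1 <- suppressWarnings(array_edit_distance(arrays[[i]], arrays[[j]], p))
    d2 <- suppressWarnings(array_edit_distance(arrays[[j]], arrays[[i]], p))
    expect_identical(d1, d2)
    # monotone masking
    dm <- suppressWarnings(array_edit_distance(arrays[[i]], arrays[[j]], pm))
    expect_lte(dm, d1 + 1e-12)
  }
  a <- unit_alphabet()
  for (i in 1:3) for (j in 1:3)
    expect_equal(array_edit_distance(a[i], a[j], p),
                 p$w_mut * unit_hamming(a[i], a[j]))
})

test_that("distances scale linearly with the weights", {
  arrays <- all_arrays(3L)
  set.seed(31)
  p1 <- repeat_dist_params(1, 3.5, 1.75)
  p3 <- repeat_dist_params(3, 10.5, 5.25)
  for (k in 1:50) {
    i <- sample(length(arrays), 1L); j <- sample(length(arrays), 1L)
    d1 <- suppressWarnings(array_edit_distance(arrays[[i]], arrays[[j]], p1))
    d3 <- suppressWarnings(array_edit_distance(arrays[[i]], arrays[[j]], p3))
    expect_equal(d3, 3 * d1, tolerance = 1e-12)
  }
})

test_that("parameter validation warns on inverted slippage weights", {
  expect_warning(repeat_dist_params(w_slippage = 4), "w_slippage")
  expect_error(repeat_dist_params(w_mut = -1), "non-negative")
})

test_that("traceback prefers match over deletion over insertion", {
  a <- unit_alphabet()
  tr <- array_edit_distance(c(a[1], a[2]), c(a[1], a[2]), trace = TRUE)
  expect_equal(tr$cost, 0)
  expect_equal(unname(tr$alignment[, "op"]), c("match", "match"))
})

test_that("distance_matrix is symmetric, dedupes and respects masking", {
  a <- unit_alphabet()
  ids <- letters[1:4]
  mk <- function(id, units) minisat_allele(id, id, "ANV", "SH", units)
  set <- new_set(list(mk("a", c(a[1], a[2])), mk("b", c(a[1], a[2])),
                      mk("c", c(a[1], a[3])), mk("d", c(a[1], a[1], a[2]))),
                 84L)
  D <- distance_matrix(set)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_equal(D["a", "b"], 0)
  Dd <- distance_matrix(set, dedupe = TRUE)
  expect_equal(nrow(Dd), 3L)
  expect_equal(attr(Dd, "carriers")[["a"]], 2L)
  # masked never exceeds unmasked, elementwise
  Dm <- distance_matrix(set, repeat_dist_params(masked = TRUE))
  expect_true(all(Dm <= D + 1e-12))
  # identical alleles give the zero matrix
  z <- distance_matrix(new_set(list(mk("x", a[1]), mk("y", a[1]),
                                    mk("z", a[1])), 84L))
  expect_true(all(z == 0))
})

test_that("mixed unit lengths are rejected", {
  l1 <- minisat_allele("s", "s", "NP", "NH", strrep("ACG", 28), unit_length = 84)
  l2 <- minisat_allele("t", "t", "NP", "NH", strrep("AC", 3), unit_length = 6)
  expect_error(distance_matrix(new_set(list(l1, l2), 84L)), "unit lengths")
})

test_that("PHYLIP and long-format writers round-trip the values", {
  a <- unit_alphabet()
  mk <- function(id, units) minisat_allele(id, id, "ANV", "SH", units)
  set <- new_set(list(mk("al1", c(a[1], a[2])), mk("al2", c(a[1], a[3])),
                      mk("al3", c(a[2], a[3]))), 84L)
  D <- distance_matrix(set)
  phy <- tempfile(fileext = ".phy")
  write_phylip(D, phy)
  lines <- readLines(phy)
  expect_equal(as.integer(trimws(lines[1])), 3L)
  row2 <- strsplit(trimws(lines[3]), " +")[[1]]
  expect_equal(row2[1], "al2")
  expect_equal(as.numeric(row2[-1]), unname(D["al2", ]), tolerance = 1e-6)

  tsv <- tempfile(fileext = ".tsv")
  write_distance_tsv(D, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$distance[tab$id1 == "al1" & tab$id2 == "al3"],
               unname(D["al1", "al3"]), tolerance = 1e-6)
})
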