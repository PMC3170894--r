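test_that("GC content excludes gaps/N and splits by codon position", {
  expect_equal(gc_content("GGCC")$gc_total, 100)
  expect_equal(gc_content("ATAT")$gc_total, 0)
  g <- gc_content("ATGGCC", codon_aligned = TRUE)
  expect_equal(g$gc_total, 100 * 4 / 6, tolerance = 1e-9)
  expect_equal(c(g$gc1, g$gc2, g$gc3), c(50, 50, 100))
  # gap and N bases drop out of numerator and denominator
  expect_equal(gc_content("GGN-AT")$gc_total, 50)
  expect_error(gc_content("NN--"), "countable")

  # pooled total equals the count-weighted mean of positional values
  set.seed(23)
  for (rep in 1:5) {
    x <- random_nt_alignment(4, 3 * sample(10:40, 1))
    g <- gc_content(x, codon_aligned = TRUE)
    w <- g$counted[c("pos1", "pos2", "pos3")]
    expect_equal(g$gc_total,
                 sum(c(g$gc1, g$gc2, g$gc3) * w) / sum(w), tolerance = 1e-9)
  }
})

test_that("RSCU follows the family-mean normalisation", {
  # four CTG codons: Leu family of 6, mean count 4/6, RSCU = 6
  r <- rscu(strrep("CTG", 4))
  leu <- r[r$aa == "L", ]
  expect_equal(leu$rscu[leu$codon == "CTG"], 6)
  expect_equal(sum(leu$rscu), 6, tolerance = 1e-9)  # family sum = size
  expect_equal(r$rscu[r$codon == "ATG"], NA_real_)  # Met unobserved

  expect_equal(rscu("ATG")$rscu[rscu("ATG")$codon == "ATG"], 1.0)

  # uniform usage within every family gives RSCU exactly 1.00
  uni <- paste(names(halomark:::GENETIC_CODE_STD)[
    halomark:::GENETIC_CODE_STD != "*"], collapse = "")
  r <- rscu(uni)
  expect_equal(r$rscu, rep(1, nrow(r)), tolerance = 1e-9)

  expect_error(rscu("ACGTA"), "divisible")
  expect_error(rscu("NNN"), "codons")
})

test_that("family RSCU sums equal family size on random coding sets", {
  set.seed(29)
  for (rep in 1:5) {
    cs <- generate_coding_set(n_seq = 3, n_codons = 80,
                              gc3 = runif(1, 0.35, 0.8), pab = runif(1, -5, 20))
    r <- rscu(cs$nt)
    sums <- tapply(r$rscu, r$aa, sum)
    sizes <- tapply(r$family_size, r$aa, unique)
    observed <- !is.na(sums)
    expect_equal(unname(sums[observed]), unname(sizes[observed]),
                 tolerance = 1e-9)
  }
})

test_that("stop codons join the table only when requested", {
  r <- rscu("ATGTAA", include_stop = TRUE)
  expect_true("TAA" %in% r$codon)
  expect_equal(unique(r$family_size[r$aa == "*"]), 3L)
  expect_false("TAA" %in% rscu("ATGAAA")$codon)
})

test_that("correspondence analysis reproduces the chi-square decomposition", {
  # proportional rows: independence, zero inertia
  expect_equal(rscu_correspondence(rbind(a = c(1, 2, 3),
                                         b = c(2, 4, 6)))$total_inertia, 0)

  # diagonal 2x2: one axis carries all inertia, inertia = chi2/n = 1
  ca <- rscu_correspondence(matrix(c(10, 0, 0, 10), 2, 2,
                                   dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(ca$total_inertia, 1, tolerance = 1e-9)
  expect_equal(ca$prop_inertia[1], 1, tolerance = 1e-9)

  set.seed(31)
  m <- matrix(rpois(15, 25) + 1, 3, 5,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:5)))
  ca <- rscu_correspondence(m)
  chi2 <- suppressWarnings(stats::chisq.test(m))$statistic
  expect_equal(ca$total_inertia, unname(chi2) / sum(m), tolerance = 1e-9)

  # row permutation permutes row coordinates identically
  perm <- c(3, 1, 2)
  ca2 <- rscu_correspondence(m[perm, ])
  expect_equal(abs(ca2$row_coords), abs(ca$row_coords[perm, ]),
               tolerance = 1e-9)
  expect_equal(ca2$inertia, ca$inertia, tolerance = 1e-9)

  expect_error(rscu_correspondence(matrix(0, 2, 2)), "2 x 2")
})

test_that("CA coordinates agree with an independent implementation", {
  set.seed(37)
  m <- matrix(rpois(24, 30) + 1, 4, 6)
  dimnames(m) <- list(paste0("r", 1:4), paste0("c", 1:6))
  ca <- rscu_correspondence(m)
  ref <- MASS::corresp(m, nf = 2)
  # MASS reports standard coordinates and canonical correlations
  expect_equal(sqrt(ca$inertia[1:2]), ref$cor[1:2], tolerance = 1e-8)
  expect_equal(abs(ca$row_coords[, 1]),
               abs(ref$rscore[, 1] * ref$cor[1]), tolerance = 1e-8)
  expect_equal(abs(ca$col_coords[, 2]),
               abs(ref$cscore[, 2] * ref$cor[2]), tolerance = 1e-8)
})

test_that("group RSCU matrices pool counts and drop unobserved families", {
  set.seed(41)
  gs <- list(g1 = generate_coding_set(2, 60, seed = 1)$nt,
             g2 = generate_coding_set(2, 60, seed = 2)$nt)
  m <- rscu_matrix(gs)
  expect_equal(rownames(m), c("g1", "g2"))
  expect_false(any(is.na(m)))
  # pooling: group row reproduces rscu() on the concatenated sequences
  r1 <- rscu(gs$g1)
  expect_equal(unname(m["g1", colnames(m)]),
               r1$rscu[match(colnames(m), r1$codon)], tolerance = 1e-12)
})
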