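test_that("the JTT model is a valid normalised reversible rate matrix", {
  m <- jtt_model()
  expect_equal(sum(m$freqs), 1, tolerance = 1e-12)
  expect_equal(max(abs(rowSums(m$Q))), 0, tolerance = 1e-12)
  expect_equal(-sum(m$freqs * diag(m$Q)), 1, tolerance = 1e-12)  # mean rate 1
  # detailed balance pi_a Q_ab = pi_b Q_ba
  flux <- m$freqs * m$Q
  expect_equal(max(abs(flux - t(flux))), 0, tolerance = 1e-12)
  P <- transition_probabilities(m, 0.7)
  expect_equal(unname(rowSums(P)), rep(1, 20), tolerance = 1e-9)
  expect_error(jtt_model(-1), "positive")
})

test_that("transition probabilities match the matrix-exponential oracle", {
  m <- jtt_model()
  for (t in c(0.1, 0.5, 2)) {
    oracle <- as.matrix(Matrix::expm(m$Q * t))
    expect_equal(unname(transition_probabilities(m, t)), unname(oracle),
                 tolerance = 1e-8)
  }
})

test_that("JTT distances are symmetric, zero for identical sequences", {
  m <- jtt_model()
  expect_equal(jtt_distance("MKDE", "MKDE", m), 0)
  set.seed(53)
  a <- random_aa_seq(120)
  b <- random_aa_seq(120)
  expect_equal(jtt_distance(a, b, m), jtt_distance(b, a, m),
               tolerance = 1e-9)
  # gap/X columns are deleted pairwise
  expect_equal(jtt_distance("MK-E", "MKDE", m), 0)
  expect_error(jtt_distance("--", "KD", m), "comparable")
})

test_that("large gamma shape converges to the equal-rates distance", {
  set.seed(59)
  two <- ape::read.tree(text = "(A:0.2,B:0.2);")
  s <- evolve_on_tree(two, jtt_model(), sites = 300, seed = 61)
  d0 <- jtt_distance(s$seq[1], s$seq[2], jtt_model())
  dg <- jtt_distance(s$seq[1], s$seq[2], jtt_model(gamma_shape = 1e4))
  expect_lt(abs(dg - d0), 1e-3)
  # small shape inflates the distance for the same data
  dsmall <- jtt_distance(s$seq[1], s$seq[2], jtt_model(gamma_shape = 0.5))
  expect_gt(dsmall, d0)
})

test_that("equal-rates JTT distances agree with an independent ML engine", {
  set.seed(67)
  aln <- evolve_on_tree(ape::rtree(5), jtt_model(), sites = 250, seed = 71)
  mine <- jtt_dist_matrix(aln, jtt_model())
  chars <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(chars) <- aln$id
  ph <- phangorn::phyDat(chars, type = "AA")
  ref <- as.matrix(phangorn::dist.ml(ph, model = "JTT"))[aln$id, aln$id]
  expect_equal(unname(mine), unname(ref), tolerance = 0.02)
})

test_that("JTT distance is monotone in simulated divergence", {
  m <- jtt_model()
  set.seed(73)
  est <- vapply(c(0.1, 0.5, 1.0, 2.0), function(t) {
    two <- ape::read.tree(text = sprintf("(A:%g,B:0);", t))
    mean(replicate(5, {
      s <- evolve_on_tree(two, m, sites = 400)
      jtt_distance(s$seq[1], s$seq[2], m)
    }))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("neighbor joining solves 3 taxa in closed form", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  expect_equal(sort(ape::cophenetic.phylo(tr)[c("A", "B", "C"),
                                              c("A", "B", "C")]),
               sort(d), tolerance = 1e-12)
  expect_error(neighbor_joining(d[1:2, 1:2]), "3 taxa")
  d2 <- d; d2[1, 2] <- 4
  expect_error(neighbor_joining(d2), "symmetric")
})

test_that("NJ recovers random trees exactly from additive matrices", {
  set.seed(79)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
    D <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(D)
    expect_equal(bipartitions(est), bipartitions(tr))
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
    # independent agglomeration engine agrees on the topology
    expect_equal(bipartitions(ape::nj(D)), bipartitions(est))
  }
})

test_that("NJ tie-break on equal distances is deterministic", {
  d <- matrix(1, 4, 4, dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  # smallest (i, j) pair merges first: t1 and t2 are siblings
  expect_true("t1,t2|t3,t4" %in% bipartitions(t1))
})

test_that("bootstrap consensus reports supports and collapses weak splits", {
  tre <- ape::read.tree(text = "((A:0.05,B:0.05):0.4,(C:0.05,D:0.05):0.4);")
  aln <- evolve_on_tree(tre, jtt_model(), sites = 200, seed = 83)

  # single replicate: consensus is that replicate's tree, supports 100
  one <- bootstrap_consensus(aln, jtt_model(), replicates = 1, seed = 5)
  expect_true(all(as.numeric(one$node.label[one$node.label != ""]) == 100))

  # clean signal: the AB|CD split is recovered with strong support
  cons <- bootstrap_consensus(aln, jtt_model(), replicates = 100, seed = 5)
  expect_true("A,B|C,D" %in% bipartitions(cons))
  supp <- as.numeric(cons$node.label[cons$node.label != ""])
  expect_true(all(supp >= 90))

  # threshold above 100 collapses everything to a star
  star <- bootstrap_consensus(aln, jtt_model(), replicates = 20,
                              collapse_threshold = 101, seed = 5)
  expect_equal(star$Nnode, 1L)
  expect_error(bootstrap_consensus(aln[1:3, ], jtt_model()), "4 sequences")
})

test_that("PHYLIP distance matrices round-trip", {
  set.seed(89)
  D <- ape::cophenetic.phylo(ape::rtree(5))
  f <- tempfile(fileext = ".phy")
  write_phylip_dist(D, f)
  back <- read_phylip_dist(f)
  expect_equal(back[rownames(D), colnames(D)], D, tolerance = 1e-6)
})
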