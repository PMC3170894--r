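test_that("FASTA I/O round-trips records in order and infers alphabets", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">p desc", "MKDE"), f)
  x <- read_fasta(f)
  expect_equal(x$id, c("a", "p"))
  expect_equal(x$seq, c("ACGT", "MKDE"))
  expect_equal(alphabet(x), "aa")  # mixed set: K,D,E force amino-acid

  writeLines(c(">a", "ACGT"), f)
  expect_equal(alphabet(read_fasta(f)), "nt")

  writeLines(c(">x", "ACGT", ">x", "ACGA"), f)
  expect_error(read_fasta(f), "duplicate.*x")
  writeLines(character(0), f)
  expect_error(read_fasta(f))

  set.seed(101)
  for (rep in 1:5) {
    n <- sample(2:8, 1)
    x <- seq_set(paste0("s", seq_len(n)),
                 vapply(sample(10:80, n, replace = TRUE), random_nt_seq,
                        character(1)))
    g <- tempfile(fileext = ".fasta")
    write_fasta(x, g, width = 17)  # odd wrap: round-trip up to wrapping
    y <- read_fasta(g)
    expect_equal(y$id, x$id)
    expect_equal(y$seq, x$seq)
  }
})

test_that("group-label sidecar attaches metadata by id", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGA"), f)
  g <- tempfile(fileext = ".tsv")
  writeLines(c("id\tgroup\tclade\tseason", "b\thalophile\tX\twinter"), g)
  x <- read_fasta(f, group_table = g)
  expect_equal(x$group, c(NA, "halophile"))
  expect_equal(x$season, c(NA, "winter"))
})

test_that("translation follows the standard code in every frame", {
  expect_equal(translate_frame("ATGGCC", 1), "MA")
  expect_equal(translate_frame("ATGTAA", 1), "M*")
  # frame -1 is frame +1 of the reverse complement (GGCCAT -> G, H)
  expect_equal(translate_frame("ATGGCC", -1), "GH")
  expect_equal(translate_frame("ATGNCC", 1), "MX")
  expect_error(translate_frame("ATGGCC", 4), "frame")

  set.seed(7)
  for (rep in 1:10) {
    s <- random_nt_seq(sample(9:60, 1))
    rc <- reverse_complement(s)
    for (f in 1:3) {
      expect_equal(nchar(translate_frame(s, f)), (nchar(s) - (f - 1)) %/% 3)
      # negative frames read the reverse complement forward
      expect_equal(translate_frame(s, -f), translate_frame(rc, f))
    }
    # the three forward frames tile every position of the strand once
    used <- sum(vapply(1:3, function(f)
      3 * nchar(translate_frame(s, f)), numeric(1)))
    expect_gte(used, nchar(s) - 3)
  }
})

test_that("best frame minimises internal stops with fixed tie order", {
  expect_equal(best_frame("ATGGCCGAA"),
               list(frame = 1L, aa = "MAE", stops = 0L, flagged = FALSE))

  internal_stops <- function(aa) {
    s <- strsplit(aa, "")[[1]]
    n <- sum(s == "*")
    if (n > 0 && s[length(s)] == "*") n - 1 else n
  }
  # clean ORF on +1; the other five frames get stops by construction
  set.seed(21)
  for (rep in 1:10) {
    orf <- paste(sample(names(halomark:::GENETIC_CODE_STD)[
      halomark:::GENETIC_CODE_STD %in% c("L", "S", "R")], 40,
      replace = TRUE), collapse = "")
    bf <- best_frame(orf)
    oracle <- vapply(c(1L, 2L, 3L, -1L, -2L, -3L), function(f)
      internal_stops(translate_frame(orf, f)), numeric(1))
    expect_equal(bf$stops, min(oracle))
    expect_equal(bf$frame,
                 c(1L, 2L, 3L, -1L, -2L, -3L)[which.min(oracle)])
  }
  # a sequence with stops in every frame is flagged
  set.seed(22)
  repeat {
    stopped <- random_nt_seq(45)
    worst <- min(vapply(c(1L, 2L, 3L, -1L, -2L, -3L), function(f)
      internal_stops(translate_frame(stopped, f)), numeric(1)))
    if (worst > 0) break
  }
  bf <- best_frame(stopped)
  expect_true(bf$flagged)
  expect_gt(bf$stops, 0)
})

test_that("greedy identity clustering groups by alignment identity", {
  x <- seq_set(c("a", "b"), c("ACGTACGT", "ACGTACGT"))
  expect_equal(max(greedy_identity_cluster(x, 1.0)$membership$cluster), 1L)

  x <- seq_set(c("a", "b"), c("AAAA", "TTTT"))
  expect_equal(max(greedy_identity_cluster(x, 0.9)$membership$cluster), 2L)

  # pairwise identity 9/10 joins at threshold 0.9
  x <- seq_set(c("a", "b"), c("AAAAAAAAAA", "AAAAAAAAAT"))
  cl <- greedy_identity_cluster(x, 0.9)
  expect_equal(max(cl$membership$cluster), 1L)
  expect_equal(cl$representatives$id, "a")

  expect_error(greedy_identity_cluster(x, 0), "threshold")
  expect_error(greedy_identity_cluster(x, 1.1), "threshold")

  # threshold 1.0 on equal-length records = exact deduplication
  set.seed(5)
  pool <- vapply(1:4, function(i) random_nt_seq(30), character(1))
  seqs <- sample(pool, 12, replace = TRUE)
  x <- seq_set(paste0("s", 1:12), seqs)
  cl <- greedy_identity_cluster(x, 1.0)
  expect_equal(sort(unique(cl$representatives$seq)), sort(unique(seqs)))
  expect_equal(nrow(cl$representatives), length(unique(seqs)))
})

test_that("newick round-trip preserves topology, lengths and supports", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  f <- tempfile(fileext = ".nwk")
  write_newick(star, f)
  expect_equal(bipartitions(read_newick(f)), bipartitions(star))

  set.seed(11)
  tr <- ape::rtree(8)
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(bipartitions(back), bipartitions(tr))
  expect_equal(sort(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label]),
               sort(ape::cophenetic.phylo(tr)), tolerance = 1e-9)

  tr$node.label <- c("", "87", rep("", tr$Nnode - 2))
  write_newick(tr, f)
  expect_match(paste(readLines(f), collapse = ""), "87")
})
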