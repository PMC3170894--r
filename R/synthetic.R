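# Synthetic-data generators: codon sets with controlled positional GC and
# acidic excess, sequence evolution on trees under the JTT model, neutral
# coalescent alignments, and DGGE band tables. Every generator is a
# deterministic function of its parameters and seed.

codon_weight_table <- function(gc1, gc2, gc3) {
  code <- GENETIC_CODE_STD[GENETIC_CODE_STD != "*"]
  bases <- strsplit(names(code), "")
  g <- c(gc1, gc2, gc3)
  w <- vapply(bases, function(b) {
    prod(ifelse(b %in% c("G", "C"), g, 1 - g))
  }, numeric(1))
  names(w) <- names(code)
  w
}

# expected GC3 of the codon distribution given per-position tilts and
# amino-acid weights
expected_gc3 <- function(g3, gc1, gc2, aa_weights) {
  w <- codon_weight_table(gc1, gc2, g3)
  code <- GENETIC_CODE_STD[names(w)]
  is_gc3 <- substr(names(w), 3, 3) %in% c("G", "C")
  total <- 0
  for (aa in names(aa_weights)) {
    fam <- names(code)[code == aa]
    wf <- w[fam]
    if (sum(wf) == 0)
      stop("infeasible GC targets: family ", aa,
           " has zero weight under gc1/gc2/gc3 tilts")
    total <- total + aa_weights[[aa]] * sum(wf[is_gc3[match(fam, names(w))]]) / sum(wf)
  }
  total
}

#' Generate a synthetic coding-sequence set with controlled composition
#'
#' Draws codons i.i.d. from a distribution constructed to match target
#' positional GC fractions and a target PAB (acidic excess): amino-acid
#' weights start uniform (1/20) and the fixed total mass 0.30 of the six
#' residues entering PAB is split between \{Asn, Asp, Gln, Glu\} and
#' \{Arg, Lys\} so that the expected PAB of the translations equals
#' \code{pab} exactly. Within each synonymous family, codons are weighted
#' by independent per-position GC tilts; the third-position tilt is then
#' calibrated by a root solve so the expected GC3 of the distribution
#' equals \code{gc3} exactly (the Met/Trp/Ile families bound what is
#' achievable), while GC1/GC2 tilts only reweight within-family options
#' and are approximate. Stop codons are excluded. Defaults mirror a
#' 20-sequence, 125-codon marker-gene group with GC3 76\% and PAB 2.87.
#'
#' @param n_seq number of sequences.
#' @param n_codons codons per sequence.
#' @param gc1,gc2,gc3 target GC fractions at codon positions 1-3, in
#'   (0, 1).
#' @param pab target PAB in percentage points (|pab| < 30).
#' @param seed optional integer seed.
#' @param prefix sequence id prefix.
#' @param group optional group label attached to every record.
#' @return List with \code{nt} (nucleotide \code{seq_set}), \code{aa}
#'   (translations), \code{codon_probs} (the sampling distribution) and
#'   \code{expected} (exact expected \code{gc3} and \code{pab}).
#' @export
generate_coding_set <- function(n_seq = 20, n_codons = 125, gc1 = 0.542,
                                gc2 = 0.424, gc3 = 0.760, pab = 2.87,
                                seed = NULL, prefix = "syn", group = NULL) {
  stopifnot(n_seq >= 1, n_codons >= 1)
  for (g in c(gc1, gc2, gc3))
    if (g <= 0 || g >= 1) stop("GC targets must be in (0, 1)")
  acid_mass <- (0.3 + pab / 100) / 2
  base_mass <- (0.3 - pab / 100) / 2
  if (acid_mass < 0 || base_mass < 0)
    stop("infeasible PAB target ", pab,
         ": requires negative residue mass (|pab| must be < 30)")
  aa_w <- stats::setNames(rep(1 / 20, 20), AA20)
  aa_w[c("N", "D", "Q", "E")] <- acid_mass / 4
  aa_w[c("R", "K")] <- base_mass / 2
  f <- function(g) expected_gc3(g, gc1, gc2, aa_w) - gc3
  lo <- 1e-6; hi <- 1 - 1e-6
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf(paste0("infeasible GC3 target %.3f: achievable expected ",
                        "GC3 range is [%.3f, %.3f] under these amino-acid ",
                        "weights"), gc3, expected_gc3(lo, gc1, gc2, aa_w),
                 expected_gc3(hi, gc1, gc2, aa_w)))
  g3_tilt <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  w <- codon_weight_table(gc1, gc2, g3_tilt)
  code <- GENETIC_CODE_STD[names(w)]
  probs <- numeric(length(w))
  names(probs) <- names(w)
  for (aa in AA20) {
    fam <- names(code)[code == aa]
    probs[fam] <- aa_w[[aa]] * w[fam] / sum(w[fam])
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- sample(names(probs), n_seq * n_codons, replace = TRUE, prob = probs)
  nt <- vapply(seq_len(n_seq), function(i)
    paste(draws[((i - 1) * n_codons + 1):(i * n_codons)], collapse = ""),
    character(1))
  ids <- sprintf("%s_%02d", prefix, seq_len(n_seq))
  nt_set <- as_alignment(seq_set(ids, nt, alphabet = "nt", group = group),
                         codon_aligned = TRUE)
  aa_set <- as_alignment(seq_set(ids, vapply(nt, translate_frame, character(1)),
                                 alphabet = "aa", group = group))
  list(nt = nt_set, aa = aa_set, codon_probs = probs,
       expected = list(gc3 = 100 * gc3, pab = pab, g3_tilt = g3_tilt))
}

#' Evolve amino-acid sequences down a tree
#'
#' Simulates a gap-free amino-acid alignment under a
#' \code{\link{jtt_model}}: the root sequence is drawn from the
#' equilibrium frequencies and each site evolves independently along the
#' branches by sampling from the transition probabilities P(t). When the
#' model carries a gamma shape, per-site rates are drawn from
#' Gamma(alpha, alpha) (mean 1) and branch lengths scaled per site.
#'
#' @param tree \pkg{ape} \code{phylo} with nonnegative branch lengths.
#' @param model a \code{\link{jtt_model}}.
#' @param sites number of sites.
#' @param seed optional integer seed.
#' @return An amino-acid \code{alignment} with one record per tip.
#' @export
evolve_on_tree <- function(tree, model = jtt_model(), sites = 100,
                           seed = NULL) {
  stopifnot(inherits(tree, "phylo"), sites >= 1)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  rates <- if (is.null(model$alpha)) rep(1, sites) else
    stats::rgamma(sites, shape = model$alpha, rate = model$alpha)
  # explicit site rates carry the gamma variation here, so branch
  # transitions use the plain (equal-rates) kernel, not the
  # gamma-integrated one
  plain <- model
  plain$alpha <- NULL
  states <- matrix(NA_integer_, ntip + tree$Nnode, sites)
  states[ntip + 1L, ] <- sample.int(20L, sites, replace = TRUE,
                                    prob = model$freqs)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    len <- ord$edge.length[k]
    if (len == 0) {
      states[child, ] <- states[parent, ]
      next
    }
    if (is.null(model$alpha)) {
      P <- transition_probabilities(plain, len)
      states[child, ] <- vapply(seq_len(sites), function(s)
        sample.int(20L, 1L, prob = P[states[parent, s], ]), integer(1))
    } else {
      states[child, ] <- vapply(seq_len(sites), function(s) {
        P <- transition_probabilities(plain, len * rates[s])
        sample.int(20L, 1L, prob = P[states[parent, s], ])
      }, integer(1))
    }
  }
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L,
                function(v) paste(AA20[v], collapse = ""))
  as_alignment(seq_set(tree$tip.label, seqs, alphabet = "aa"))
}

#' Neutral coalescent alignment under the infinite-sites model
#'
#' Simulates a Kingman genealogy for n samples (exponential coalescence
#' times with rate k(k-1)/2 while k lineages remain), drops mutations on
#' branches as a Poisson process with rate theta/2 per lineage per unit
#' coalescent time, and maps each mutation to its own alignment column
#' (binary states encoded as A ancestral / G derived, so downstream
#' nucleotide statistics are exact). Expected number of segregating
#' sites is theta * a1(n).
#'
#' @param n number of sequences (>= 2).
#' @param theta scaled mutation rate (> 0).
#' @param sites alignment length; monomorphic columns are padded with A.
#' @param seed optional integer seed.
#' @param on_overflow \code{"error"} or \code{"resample"} when the
#'   realised mutation count exceeds \code{sites}.
#' @return A nucleotide \code{alignment} of n sequences.
#' @export
coalescent_alignment <- function(n, theta, sites, seed = NULL,
                                 on_overflow = c("error", "resample")) {
  on_overflow <- match.arg(on_overflow)
  stopifnot(n >= 2, theta > 0, sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in 1:1000) {
    lineages <- lapply(seq_len(n), identity)  # leaf sets
    birth <- rep(0, n)
    branch_sets <- list()
    branch_len <- numeric(0)
    time <- 0
    while (length(lineages) > 1L) {
      k <- length(lineages)
      time <- time + stats::rexp(1, rate = k * (k - 1) / 2)
      pair <- sample.int(k, 2L)
      for (p in pair) {
        branch_sets[[length(branch_sets) + 1L]] <- lineages[[p]]
        branch_len <- c(branch_len, time - birth[p])
      }
      merged <- sort(c(lineages[[pair[1]]], lineages[[pair[2]]]))
      lineages <- c(lineages[-pair], list(merged))
      birth <- c(birth[-pair], time)
    }
    m <- stats::rpois(1, theta / 2 * sum(branch_len))
    if (m <= sites) break
    if (on_overflow == "error")
      stop("realised mutations (", m, ") exceed sites (", sites, ")")
  }
  if (m > sites) stop("could not fit mutations into ", sites, " sites")
  mat <- matrix("A", n, sites)
  if (m > 0) {
    hit <- sample.int(length(branch_len), m, replace = TRUE,
                      prob = branch_len)
    for (j in seq_len(m)) mat[branch_sets[[hit[j]]], j] <- "G"
  }
  seqs <- apply(mat, 1L, paste, collapse = "")
  as_alignment(seq_set(sprintf("s%02d", seq_len(n)), seqs, alphabet = "nt"))
}

#' Generate a synthetic DGGE band table
#'
#' Two seasonal groups of lanes share a random base band profile; the
#' second group's profile flips each band with probability
#' \code{between_shift}, and every lane then flips each band with
#' probability \code{within_noise}. Profiles (and lanes) are resampled
#' until non-empty so the band-matrix invariant holds. With
#' \code{between_shift = 1, within_noise = 0} the groups are perfectly
#' separable; with \code{between_shift = 0} the grouping carries no
#' signal (null calibration).
#'
#' @param lanes_per_group lanes in each group.
#' @param bands number of band positions.
#' @param within_noise,between_shift probabilities in [0, 1].
#' @param seed optional integer seed.
#' @param groups two group labels (default winter/summer).
#' @return A \code{band_matrix} with season and depth attributes.
#' @export
generate_band_table <- function(lanes_per_group = 4, bands = 20,
                                within_noise = 0.1, between_shift = 0.5,
                                seed = NULL,
                                groups = c("winter", "summer")) {
  stopifnot(lanes_per_group >= 1, bands >= 1,
            within_noise >= 0, within_noise <= 1,
            between_shift >= 0, between_shift <= 1)
  if (!is.null(seed)) set.seed(seed)
  repeat {
    p0 <- stats::rbinom(bands, 1, 0.5)
    flip <- stats::rbinom(bands, 1, between_shift)
    p1 <- ifelse(flip == 1, 1 - p0, p0)
    if (sum(p0) > 0 && sum(p1) > 0) break
  }
  profiles <- list(p0, p1)
  rows <- list()
  season <- character(0)
  for (g in 1:2) {
    for (l in seq_len(lanes_per_group)) {
      repeat {
        lane <- abs(profiles[[g]] - stats::rbinom(bands, 1, within_noise))
        if (sum(lane) > 0) break
      }
      rows[[length(rows) + 1L]] <- lane
      season <- c(season, groups[g])
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- paste0(season, "_", rep(seq_len(lanes_per_group), 2))
  colnames(m) <- sprintf("band%02d", seq_len(bands))
  band_matrix(m, season = season,
              depth = rep(seq_len(lanes_per_group), 2))
}
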