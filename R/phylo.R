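# Neighbor-joining, bootstrap majority-rule consensus with
# support-threshold collapsing, and PHYLIP distance-matrix I/O.

as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion
#' Q_ij = (r-2) d_ij - R_i - R_j. Ties on the minimum are broken by the
#' lexicographically smallest (i, j) index pair in the current matrix
#' order (merged nodes take the position of their first member).
#' Negative branch-length estimates are clamped to zero. The result is
#' the usual unrooted tree with a basal trifurcation.
#'
#' @param d symmetric distance matrix (or \code{dist}) over >= 3 labels.
#' @return An \pkg{ape} \code{phylo}.
#' @export
neighbor_joining <- function(d) {
  D <- as_dist_matrix(d)
  r <- nrow(D)
  if (r < 3L) stop("neighbor joining needs at least 3 taxa")
  frag <- rownames(D)
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  while (r > 3L) {
    Rs <- rowSums(D)
    Q <- (r - 2) * D - outer(Rs, Rs, "+")
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    m <- min(Q)
    cand <- which(Q == m, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- 0.5 * D[i, j] + (Rs[i] - Rs[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    frag[i] <- paste0("(", frag[i], ":", fmt(vi), ",", frag[j], ":", fmt(vj), ")")
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    D[i, ] <- D[, i] <- dnew
    D[i, i] <- 0
    keep <- setdiff(seq_len(r), j)
    D <- D[keep, keep, drop = FALSE]
    frag <- frag[keep]
    r <- r - 1L
  }
  x1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  x2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  x3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(x1), ",", frag[2], ":", fmt(x2),
                ",", frag[3], ":", fmt(x3), ");")
  ape::read.tree(text = nwk)
}

consensus_with_supports <- function(trees, collapse_threshold) {
  B <- length(trees)
  if (B == 1L) {
    cons <- trees[[1]]
    cons$edge.length <- NULL
    supp <- rep(100, cons$Nnode)
  } else {
    cons <- ape::consensus(trees, p = 0.5)
    counts <- ape::prop.clades(cons, part = ape::prop.part(trees),
                               rooted = FALSE)
    supp <- 100 * counts / B
    supp[is.na(supp)] <- 100       # trivial splits
  }
  ntip <- length(cons$tip.label)
  children <- vector("list", ntip + cons$Nnode)
  for (k in seq_len(nrow(cons$edge)))
    children[[cons$edge[k, 1]]] <- c(children[[cons$edge[k, 1]]],
                                     cons$edge[k, 2])
  root <- ntip + 1L
  eff <- function(node) {
    out <- character(0)
    for (ch in children[[node]]) {
      if (ch <= ntip) {
        out <- c(out, cons$tip.label[ch])
      } else if (supp[ch - ntip] < collapse_threshold) {
        out <- c(out, eff(ch))      # collapse: splice children upward
      } else {
        out <- c(out, paste0("(", paste(eff(ch), collapse = ","), ")",
                             round(supp[ch - ntip])))
      }
    }
    out
  }
  nwk <- paste0("(", paste(eff(root), collapse = ","), ");")
  ape::read.tree(text = nwk)
}

#' Bootstrap neighbor-joining with majority-rule consensus
#'
#' Resamples alignment columns with replacement, rebuilds the JTT(+Gamma)
#' distance matrix and NJ tree per replicate, takes the majority-rule
#' (>50\%) consensus, and collapses internal branches whose bipartition
#' appears in fewer than \code{collapse_threshold} percent of replicates
#' into polytomies. Supports (percent of replicates) are attached as
#' internal node labels on the remaining branches.
#'
#' @param aln an amino-acid \code{alignment} with >= 4 sequences.
#' @param model a \code{\link{jtt_model}}.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param collapse_threshold support percentage below which branches are
#'   collapsed (default 60).
#' @param seed optional integer seed for the column resampler.
#' @return A \code{phylo} consensus tree (no branch lengths) with
#'   integer percent supports in \code{node.label}.
#' @export
bootstrap_consensus <- function(aln, model = jtt_model(), replicates = 100,
                                collapse_threshold = 60, seed = NULL) {
  stopifnot(inherits(aln, "seq_set"), alphabet(aln) == "aa")
  if (nrow(aln) < 4L) stop("bootstrap consensus requires >= 4 sequences")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  L <- ncol(mat)
  trees <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    boot <- aln
    boot$seq <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
    trees[[b]] <- neighbor_joining(jtt_dist_matrix(boot, model))
  }
  class(trees) <- "multiPhylo"
  consensus_with_supports(trees, collapse_threshold)
}

#' Write / read a PHYLIP square distance matrix
#'
#' @param d symmetric matrix with labels.
#' @param path file path.
#' @return \code{path} (write) or a labelled matrix (read).
#' @export
write_phylip_dist <- function(d, path) {
  D <- as_dist_matrix(d)
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i)
               paste0(sprintf("%-10s", rownames(D)[i]),
                      paste(sprintf("%.6f", D[i, ]), collapse = "  ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  labels <- vapply(parts, `[`, character(1), 1L)
  D <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
  dimnames(D) <- list(labels, labels)
  D
}
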