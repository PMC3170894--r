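# Tajima's D neutrality test for nucleotide alignments.

#' Tajima test constants
#'
#' The standard constants a1, a2, b1, b2, c1, c2, e1, e2 for a sample of
#' n sequences: a1 = sum(1/i) and a2 = sum(1/i^2) for i in 1..n-1,
#' b1 = (n+1)/(3(n-1)), b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2 + a2).
#'
#' @param n number of sequences (>= 2).
#' @return Named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  if (n < 2L) stop("need n >= 2")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Tajima's D for a nucleotide alignment
#'
#' Contrasts mean pairwise nucleotide diversity with Watterson's
#' estimator: D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1)). Segregating
#' sites count each polymorphic column once regardless of allele number;
#' pairwise differences count any mismatch. Columns containing a gap or N
#' are removed first under the default complete-deletion rule; with
#' pairwise deletion each pair is compared over its own ungapped columns
#' (S is still computed on complete columns).
#'
#' @param aln a nucleotide \code{alignment} (or \code{seq_set} of equal
#'   lengths) with at least 4 sequences.
#' @param deletion \code{"complete"} (default) or \code{"pairwise"}.
#' @return A \code{tajima_result}: list with \code{n}, \code{sites}
#'   (columns analysed), \code{S}, \code{pi_hat}, the constants, and
#'   \code{D} (\code{NA} when S = 0).
#' @export
tajimas_d <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "seq_set"))
  n <- nrow(aln)
  if (n < 4L) stop("Tajima's D requires at least 4 sequences")
  mat <- do.call(rbind, strsplit(toupper(aln$seq), ""))
  if (ncol(mat) == 0L) stop("empty alignment")
  ok_base <- matrix(mat %in% c("A", "C", "G", "T"), nrow = n)
  complete <- colSums(ok_base) == n
  cmat <- mat[, complete, drop = FALSE]
  S <- sum(apply(cmat, 2L, function(col) length(unique(col)) > 1L))
  pairs <- utils::combn(n, 2L)
  if (deletion == "complete") {
    diffs <- apply(pairs, 2L, function(p)
      sum(cmat[p[1], ] != cmat[p[2], ]))
  } else {
    diffs <- apply(pairs, 2L, function(p) {
      use <- ok_base[p[1], ] & ok_base[p[2], ]
      sum(mat[p[1], use] != mat[p[2], use])
    })
  }
  pi_hat <- mean(diffs)
  k <- tajima_constants(n)
  D <- if (S == 0L) NA_real_ else
    (pi_hat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  out <- c(list(n = n, sites = ncol(cmat), S = S, pi_hat = pi_hat), k,
           list(D = D))
  class(out) <- "tajima_result"
  out
}

#' @export
print.tajima_result <- function(x, ...) {
  cat(sprintf("Tajima's neutrality test: n = %d, %d sites, S = %d, pi = %.4f, D = %s\n",
              x$n, x$sites, x$S, x$pi_hat,
              if (is.na(x$D)) "undefined (S = 0)" else sprintf("%.4f", x$D)))
  invisible(x)
}

#' Tabulate Tajima results for several markers
#'
#' @param results named list of \code{tajima_result} objects (names are
#'   marker labels).
#' @return Data frame with columns \code{marker}, \code{n}, \code{S},
#'   \code{pi_hat}, \code{D}.
#' @export
tajima_table <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(marker = nm, n = r$n, S = r$S, pi_hat = r$pi_hat, D = r$D,
               stringsAsFactors = FALSE)
  }))
}
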