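# GC content (total and by codon position), relative synonymous codon
# usage, and correspondence analysis of RSCU tables.

#' GC content, total and by codon position
#'
#' GC\% = (G + C) / (G + C + A + T) * 100; gaps and N are excluded from
#' numerator and denominator. Positional percentages (GC1, GC2, GC3)
#' require a codon-aligned (or in-frame) input, positions being taken
#' from the column index modulo 3.
#'
#' @param x a nucleotide \code{seq_set} or a character vector of
#'   sequences; counts are pooled across sequences.
#' @param codon_aligned logical; compute per-position percentages. For an
#'   \code{alignment} the stored flag is the default.
#' @return A \code{gc_profile}: list with \code{gc_total}, \code{gc1},
#'   \code{gc2}, \code{gc3} (percent) and \code{counted} bases per
#'   position (NA positional entries when not codon aligned).
#' @examples
#' gc_content("GGCC")$gc_total  # 100
#' gc_content("ATGGCC", codon_aligned = TRUE)$gc3  # 100
#' @export
gc_content <- function(x, codon_aligned = NULL) {
  seqs <- if (inherits(x, "seq_set")) x$seq else as.character(x)
  if (is.null(codon_aligned))
    codon_aligned <- isTRUE(attr(x, "codon_aligned"))
  if (codon_aligned && any(nchar(seqs) %% 3L != 0L))
    stop("codon-aligned GC requires lengths divisible by 3")
  gc_of <- function(chars) {
    gc <- sum(chars %in% c("G", "C"))
    at <- sum(chars %in% c("A", "T"))
    c(gc = gc, counted = gc + at)
  }
  all_chars <- strsplit(toupper(seqs), "")
  tot <- rowSums(vapply(all_chars, gc_of, numeric(2)))
  if (tot[["counted"]] == 0L) stop("no countable bases")
  out <- list(gc_total = 100 * tot[["gc"]] / tot[["counted"]],
              gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_,
              counted = c(total = unname(tot[["counted"]]),
                          pos1 = NA, pos2 = NA, pos3 = NA))
  if (codon_aligned) {
    for (k in 1:3) {
      pk <- rowSums(vapply(all_chars, function(ch)
        gc_of(ch[seq(k, length(ch), by = 3L)]), numeric(2)))
      if (pk[["counted"]] == 0L) stop("no countable bases at codon position ", k)
      out[[paste0("gc", k)]] <- 100 * pk[["gc"]] / pk[["counted"]]
      out$counted[[paste0("pos", k)]] <- unname(pk[["counted"]])
    }
  }
  class(out) <- "gc_profile"
  out
}

#' @export
print.gc_profile <- function(x, ...) {
  cat(sprintf("gc_profile: total %.2f%%", x$gc_total))
  if (!is.na(x$gc1))
    cat(sprintf("  (GC1 %.2f, GC2 %.2f, GC3 %.2f)", x$gc1, x$gc2, x$gc3))
  cat("\n")
  invisible(x)
}

#' Per-sequence GC profiles
#'
#' @inheritParams gc_content
#' @return Data frame with one row per sequence: \code{id},
#'   \code{gc_total}, \code{gc1}, \code{gc2}, \code{gc3}.
#' @export
gc_profiles <- function(x, codon_aligned = NULL) {
  stopifnot(inherits(x, "seq_set"))
  if (is.null(codon_aligned))
    codon_aligned <- isTRUE(attr(x, "codon_aligned"))
  rows <- lapply(seq_len(nrow(x)), function(i) {
    g <- gc_content(x$seq[i], codon_aligned = codon_aligned)
    data.frame(id = x$id[i], gc_total = g$gc_total, gc1 = g$gc1,
               gc2 = g$gc2, gc3 = g$gc3, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

codon_families <- function(include_stop = FALSE) {
  code <- GENETIC_CODE_STD
  if (!include_stop) code <- code[code != "*"]
  split(names(code), code)
}

#' Relative synonymous codon usage
#'
#' RSCU for codon i is its observed count divided by the mean count over
#' its synonymous family: X_i / (sum(family) / n), with n the family
#' size, so RSCU = 1.00 for every codon under unbiased usage and the
#' family RSCU values sum to n. Counts are pooled over the input
#' sequences (group-level usage); codons containing gaps or N are
#' skipped. Families never observed are reported \code{NA} (not 0);
#' single-codon families (Met, Trp) are 1.0 whenever observed.
#'
#' @param x a nucleotide \code{seq_set} or character vector, read in
#'   frame (lengths divisible by 3).
#' @param include_stop treat the three stop codons as a family (display
#'   parity with codon-usage plots); excluded by default.
#' @return Data frame with \code{codon}, \code{aa}, \code{count},
#'   \code{family_size}, \code{rscu}.
#' @export
rscu <- function(x, include_stop = FALSE) {
  seqs <- if (inherits(x, "seq_set")) x$seq else as.character(x)
  if (any(nchar(seqs) %% 3L != 0L))
    stop("in-frame sequences required (length divisible by 3)")
  codons <- unlist(lapply(toupper(seqs), split_codons))
  codons <- codons[!grepl("[^ACGT]", codons)]
  if (length(codons) == 0L) stop("no complete ungapped codons")
  fams <- codon_families(include_stop)
  counts <- table(factor(codons, levels = unlist(fams, use.names = FALSE)))
  rows <- lapply(names(fams), function(aa) {
    cd <- fams[[aa]]
    n <- length(cd)
    cnt <- as.numeric(counts[cd])
    total <- sum(cnt)
    val <- if (total == 0) rep(NA_real_, n) else cnt / (total / n)
    data.frame(codon = cd, aa = aa, count = cnt, family_size = n,
               rscu = val, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aa, out$codon), ]
  rownames(out) <- NULL
  out
}

#' RSCU matrix across sequence groups
#'
#' Pools codon counts within each group and assembles a groups x codons
#' RSCU matrix suitable for correspondence analysis. Codons whose family
#' is unobserved in any group are dropped (missing, not zero, keeps the
#' analysis well defined).
#'
#' @param groups named list of nucleotide \code{seq_set}s (or character
#'   vectors), one per group.
#' @param include_stop as in \code{\link{rscu}}.
#' @return Numeric matrix, rownames = group names, colnames = codons.
#' @export
rscu_matrix <- function(groups, include_stop = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2L, !is.null(names(groups)))
  tabs <- lapply(groups, rscu, include_stop = include_stop)
  codons <- tabs[[1]]$codon
  m <- do.call(rbind, lapply(tabs, function(t) t$rscu[match(codons, t$codon)]))
  dimnames(m) <- list(names(groups), codons)
  m[, colSums(is.na(m)) == 0L, drop = FALSE]
}

#' Correspondence analysis of a nonnegative table
#'
#' Standard correspondence analysis via singular value decomposition of
#' the standardised residuals of the row/column-profile matrix:
#' S = (P - r c')/sqrt(r c') with P the table over its grand total. Total
#' inertia equals the table's chi-square statistic divided by the grand
#' total; principal coordinates are returned for rows and columns.
#'
#' @param m nonnegative numeric matrix (e.g. from
#'   \code{\link{rscu_matrix}}); all-zero rows/columns are dropped.
#' @return List with \code{row_coords}, \code{col_coords} (principal
#'   coordinates), \code{inertia} (per axis), \code{prop_inertia},
#'   \code{total_inertia}.
#' @export
rscu_correspondence <- function(m) {
  m <- as.matrix(m)
  if (any(is.na(m)) || any(m < 0)) stop("matrix must be nonnegative, no NA")
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least a 2 x 2 table after dropping empty rows/columns")
  P <- m / sum(m)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  keep <- which(sv$d > 1e-12)
  if (length(keep) == 0L) {                 # independence: zero inertia
    k <- min(nrow(m), ncol(m)) - 1L
    zero <- matrix(0, nrow(m), k, dimnames = list(rownames(m), NULL))
    return(list(row_coords = zero,
                col_coords = matrix(0, ncol(m), k,
                                    dimnames = list(colnames(m), NULL)),
                inertia = rep(0, k), prop_inertia = rep(NA_real_, k),
                total_inertia = 0))
  }
  d <- sv$d[keep]
  row_coords <- sweep(sv$u[, keep, drop = FALSE], 1, sqrt(r), "/") %*% diag(d, length(d))
  col_coords <- sweep(sv$v[, keep, drop = FALSE], 1, sqrt(cc), "/") %*% diag(d, length(d))
  rownames(row_coords) <- rownames(m)
  rownames(col_coords) <- colnames(m)
  inertia <- d^2
  list(row_coords = row_coords, col_coords = col_coords,
       inertia = inertia, prop_inertia = inertia / sum(inertia),
       total_inertia = sum(inertia))
}
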