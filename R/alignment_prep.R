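# Column masks (informative-site selection consumed as input) and
# catalytic-site conservation checks.

#' Read an alignment column mask
#'
#' One 1-based column index per line; indices must be strictly
#' increasing. Masks are produced upstream by conserved-block selection
#' and are consumed here, not recomputed.
#'
#' @param path text file of indices.
#' @return Integer vector of class \code{column_mask}.
#' @export
read_mask <- function(path) {
  idx <- as.integer(scan(path, what = integer(), quiet = TRUE))
  column_mask(idx)
}

#' @rdname read_mask
#' @param keep integer vector of 1-based columns to keep.
#' @export
column_mask <- function(keep) {
  keep <- as.integer(keep)
  if (length(keep) == 0L) stop("empty mask")
  if (any(is.na(keep)) || any(keep < 1L)) stop("mask indices must be >= 1")
  if (any(diff(keep) <= 0L)) stop("mask indices must be strictly increasing")
  structure(keep, class = "column_mask")
}

subset_columns <- function(x, cols) {
  mat <- do.call(rbind, strsplit(x$seq, ""))
  x$seq <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
  x
}

#' Apply a column mask to an amino-acid alignment
#'
#' @param aln an amino-acid \code{alignment}.
#' @param mask a \code{column_mask} of 1-based amino-acid columns.
#' @return The masked alignment (length \code{length(mask)}).
#' @export
apply_mask <- function(aln, mask) {
  stopifnot(inherits(aln, "alignment"))
  mask <- unclass(mask)
  if (max(mask) > n_columns(aln))
    stop("mask index ", max(mask), " outside alignment length ",
         n_columns(aln))
  as_alignment(subset_columns(aln, mask),
               codon_aligned = isTRUE(attr(aln, "codon_aligned")))
}

#' Apply an amino-acid column mask to the matching codon alignment
#'
#' Amino-acid column i corresponds to nucleotide columns 3i-2..3i
#' (1-based), so the kept nucleotide columns are exactly the codon
#' triplets of the masked amino-acid columns.
#'
#' @param aln a codon-aligned nucleotide \code{alignment}.
#' @param mask a \code{column_mask} in amino-acid column units.
#' @return Masked nucleotide alignment of length \code{3 * length(mask)}.
#' @export
codon_mask <- function(aln, mask) {
  stopifnot(inherits(aln, "alignment"))
  if (!isTRUE(attr(aln, "codon_aligned")))
    stop("codon_mask requires a codon-aligned nucleotide alignment")
  mask <- unclass(mask)
  if (max(mask) * 3L > n_columns(aln))
    stop("mask index ", max(mask), " outside codon alignment (",
         n_columns(aln) %/% 3L, " codons)")
  nt_cols <- as.vector(rbind(3L * mask - 2L, 3L * mask - 1L, 3L * mask))
  as_alignment(subset_columns(aln, nt_cols), codon_aligned = TRUE)
}

#' Read a catalytic-site specification table
#'
#' TSV with header and columns \code{name}, \code{residue},
#' \code{column}: e.g. an active-site arginine expected at a given
#' (masked) alignment column.
#'
#' @param path TSV file.
#' @return Data frame with those three columns.
#' @export
read_site_specs <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "residue", "column")
  if (!all(need %in% names(s)))
    stop("site spec table needs columns: ", paste(need, collapse = ", "))
  s$column <- as.integer(s$column)
  s
}

#' Catalytic-site conservation across an alignment
#'
#' For each site specification, the fraction of sequences carrying the
#' expected residue at that column. Gaps (and any other residue) count as
#' non-conserved.
#'
#' @param aln an amino-acid \code{alignment} (typically masked).
#' @param sites data frame as from \code{\link{read_site_specs}}.
#' @return Data frame with \code{name}, \code{residue}, \code{column},
#'   \code{fraction} and \code{nonmatching} (comma-separated ids).
#' @export
site_conservation <- function(aln, sites) {
  stopifnot(inherits(aln, "alignment"))
  if (any(sites$column < 1L | sites$column > n_columns(aln)))
    stop("site column outside alignment length ", n_columns(aln))
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  out <- lapply(seq_len(nrow(sites)), function(i) {
    col <- mat[, sites$column[i]]
    hit <- col == toupper(sites$residue[i])
    data.frame(name = sites$name[i], residue = sites$residue[i],
               column = sites$column[i], fraction = mean(hit),
               nonmatching = paste(aln$id[!hit], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
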