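# Amino-acid composition and the PAB / AB "salt-in" haloadaptation
# indicators, with Table-1-style group summaries.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_CATEGORIES <- list(
  hydrophobic = c("G", "L", "V", "I", "F", "M", "A", "W", "P"),
  polar       = c("S", "T", "C", "Y", "Q", "N"),
  basic       = c("H", "R", "K"),
  acidic      = c("E", "D"))

#' Amino-acid composition profile of one sequence
#'
#' Percentages of the 20 amino acids (0-100 scale) over the countable
#' residues of a sequence; gaps, \code{X} and \code{*} are excluded from
#' both numerator and denominator. Category sums use the fixed
#' memberships: hydrophobic G,L,V,I,F,M,A,W,P; polar S,T,C,Y,Q,N; basic
#' H,R,K; acidic E,D.
#'
#' @param aa_seq amino-acid string.
#' @return A \code{composition_profile}: list with \code{percent} (named
#'   length-20 vector), \code{categories}, \code{pab}, \code{ab},
#'   \code{asp_to_lys} and \code{n_residues}.
#' @examples
#' p <- composition_profile("DEKR")
#' p$categories[["acidic"]]  # 50
#' @export
composition_profile <- function(aa_seq) {
  chars <- strsplit(toupper(aa_seq), "")[[1]]
  chars <- chars[chars %in% AA20]
  if (length(chars) == 0L) stop("no countable residues in sequence")
  counts <- table(factor(chars, levels = AA20))
  percent <- 100 * as.numeric(counts) / length(chars)
  names(percent) <- AA20
  categories <- vapply(AA_CATEGORIES, function(m) sum(percent[m]), numeric(1))
  p <- list(percent = percent, categories = categories,
            n_residues = length(chars))
  p$pab <- pab(percent)
  p$ab <- ab_ratio(percent)
  p$asp_to_lys <- if (percent[["K"]] > 0) percent[["D"]] / percent[["K"]] else NA_real_
  class(p) <- "composition_profile"
  p
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("composition_profile: %d residues, PAB = %.2f, AB = %s\n",
              x$n_residues, x$pab,
              if (is.na(x$ab)) "undefined" else sprintf("%.2f", x$ab)))
  invisible(x)
}

#' PAB haloadaptation indicator
#'
#' Surplus of polar+acidic over polar+basic residues,
#' PAB = [Asx + Glx] - [Arg + Lys], in percentage points of the
#' composition. Sequence residues are unambiguous, so Asx = Asn + Asp and
#' Glx = Gln + Glu. "Salt-in" acidified proteomes score high (bulk
#' protein is roughly 15.85 for Escherichia coli vs 25.36 for
#' Halobacterium salinarum).
#'
#' @param x a \code{composition_profile}, or a named numeric vector of
#'   amino-acid percentages (one-letter names).
#' @return PAB in percentage points (may be negative).
#' @seealso \code{\link{pab_components}} to apply the formula to
#'   already-tabulated Asx+Glx, Arg and Lys percentages.
#' @export
pab <- function(x) {
  p <- if (inherits(x, "composition_profile")) x$percent else x
  pab_components(p[["N"]] + p[["D"]] + p[["Q"]] + p[["E"]],
                 arg = p[["R"]], lys = p[["K"]])
}

#' @rdname pab
#' @param asx_glx combined Asx + Glx percentage.
#' @param arg,lys Arg and Lys percentages.
#' @export
pab_components <- function(asx_glx, arg, lys) asx_glx - (arg + lys)

#' AB haloadaptation indicator
#'
#' Acidic-to-basic ratio AB = [Asp + Glu] : [His + Arg + Lys]. Undefined
#' (reported as \code{NA}, never infinity) when the sequence has no basic
#' residues.
#'
#' @inheritParams pab
#' @return Nonnegative ratio, or \code{NA}.
#' @export
ab_ratio <- function(x) {
  p <- if (inherits(x, "composition_profile")) x$percent else x
  basic <- p[["H"]] + p[["R"]] + p[["K"]]
  if (basic == 0) return(NA_real_)
  (p[["D"]] + p[["E"]]) / basic
}

#' Composition profiles for a sequence set
#'
#' One row per sequence with the Table-1-style metrics: Asx+Glx, PAB, AB,
#' Lys, Asp:Lys, Arg, the four category sums, and all 20 percentages.
#' When the set is an alignment, gap columns are excluded per sequence
#' (composition over the aligned region), matching the convention of
#' computing composition from the alignment used for the phylogeny; pass
#' an unaligned set for full-fragment mode.
#'
#' @param x a \code{seq_set} or \code{alignment} of amino-acid sequences.
#' @return Data frame, one row per sequence.
#' @export
composition_profiles <- function(x) {
  stopifnot(inherits(x, "seq_set"), alphabet(x) == "aa")
  rows <- lapply(seq_len(nrow(x)), function(i) {
    p <- composition_profile(x$seq[i])
    cbind(data.frame(id = x$id[i], group = x$group[i], clade = x$clade[i],
                     asx_glx = sum(p$percent[c("N", "D", "Q", "E")]),
                     pab = p$pab, ab = p$ab, lys = p$percent[["K"]],
                     asp_to_lys = p$asp_to_lys, arg = p$percent[["R"]],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(p$categories)),
          as.data.frame(as.list(p$percent)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group mean and standard deviation of composition metrics
#'
#' Summarises numeric metric columns by a grouping label, reporting the
#' mean and the sample standard deviation (n-1 denominator; 0 for
#' singleton groups). Group order follows first appearance in
#' \code{labels}.
#'
#' @param profiles data frame as from \code{\link{composition_profiles}}
#'   (or any data frame of numeric metrics).
#' @param labels grouping label per row; defaults to the \code{group}
#'   column of \code{profiles}.
#' @param metrics character vector of columns to summarise; defaults to
#'   all numeric columns.
#' @return Data frame: \code{group}, \code{n}, then \code{<metric>_mean}
#'   and \code{<metric>_sd} pairs.
#' @export
group_summary <- function(profiles, labels = profiles$group, metrics = NULL) {
  labels <- as.character(labels)
  if (length(labels) != nrow(profiles))
    stop("one label per profile row required")
  if (any(is.na(labels))) stop("unknown (missing) group label")
  if (is.null(metrics))
    metrics <- names(profiles)[vapply(profiles, is.numeric, logical(1))]
  groups <- unique(labels)
  rows <- lapply(groups, function(g) {
    sub <- profiles[labels == g, metrics, drop = FALSE]
    m <- vapply(sub, function(v) mean(v, na.rm = TRUE), numeric(1))
    s <- vapply(sub, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) 0 else stats::sd(v)
    }, numeric(1))
    row <- as.data.frame(as.list(c(rbind(m, s))))
    names(row) <- as.vector(rbind(paste0(metrics, "_mean"),
                                  paste0(metrics, "_sd")))
    cbind(data.frame(group = g, n = nrow(sub), stringsAsFactors = FALSE), row)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bulk-proteome reference rows for report context
#'
#' Published bulk-protein composition indicators for reference strains,
#' shipped as constants (not recomputed from proteomes) so composition
#' reports can juxtapose marker-gene groups with the classic "salt-in"
#' extremes. Values are on the percentage scale used throughout. Note the
#' Halomonas elongata PAB as published (17.56) does not equal
#' \code{pab_components(25.98, 5.25, 3.7)} = 17.03; the published value
#' is carried unmodified.
#'
#' @return Data frame with columns \code{strain}, \code{asx_glx},
#'   \code{pab}, \code{lys}, \code{arg}, \code{gc_total}.
#' @export
reference_strain_rows <- function() {
  data.frame(
    strain = c("Halobacterium salinarum", "Halomonas elongata",
               "Escherichia coli"),
    asx_glx = c(31.80, 25.98, 26.04),
    pab = c(25.36, 17.56, 15.85),
    lys = c(2.34, 3.70, 6.03),
    arg = c(4.10, 5.25, 4.16),
    gc_total = c(65.7, NA, 50.3),
    stringsAsFactors = FALSE)
}
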