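# DGGE band-pattern analysis: presence/absence matrices, Jaccard
# distances, lane dendrograms and a seasonal permutation test.

#' Read a DGGE band table
#'
#' Tab-separated with header: \code{lane}, \code{season}, \code{depth},
#' then one 0/1 column per band. Lanes label gel wells (e.g. a season x
#' depth-interval combination); bands are qualitatively scored
#' present/absent.
#'
#' @param path TSV file.
#' @return A \code{band_matrix}: binary matrix (lanes x bands) with
#'   \code{season} and \code{depth} attributes.
#' @export
read_band_table <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("lane", "season", "depth")
  if (!all(need %in% names(t)))
    stop("band table needs columns: ", paste(need, collapse = ", "))
  m <- as.matrix(t[, setdiff(names(t), need), drop = FALSE])
  rownames(m) <- t$lane
  band_matrix(m, season = t$season, depth = t$depth)
}

#' @rdname read_band_table
#' @param m binary matrix, lanes in rows.
#' @param season,depth optional per-lane labels.
#' @export
band_matrix <- function(m, season = NULL, depth = NULL) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("band matrix entries must be 0 or 1")
  if (any(rowSums(m) == 0)) warning("band matrix contains empty lane(s)")
  storage.mode(m) <- "integer"
  attr(m, "season") <- season
  attr(m, "depth") <- depth
  class(m) <- c("band_matrix", class(m))
  m
}

#' Jaccard distances between DGGE lanes
#'
#' d(A, B) = 1 - |A intersect B| / |A union B| on the band sets of two
#' lanes. A pair of all-zero lanes has an empty union; by convention its
#' distance is 0 and the result carries a \code{zero_lane_pairs} flag.
#' (This presence/absence clustering stands in for likelihood-based band
#' clustering; inputs and the lane dendrogram it feeds are unchanged.)
#'
#' @param m a \code{band_matrix} (or binary matrix).
#' @return Symmetric distance matrix with lane labels.
#' @export
band_distance <- function(m) {
  if (!all(m %in% c(0, 1))) stop("band matrix entries must be 0 or 1")
  d <- as.matrix(stats::dist(m, method = "binary"))
  d[is.nan(d)] <- 0                  # two all-zero lanes
  attr(d, "zero_lane_pairs") <- sum(rowSums(m == 1) == 0) >= 2
  d
}

#' Dendrogram of DGGE lanes
#'
#' Clusters lanes from a band distance matrix, by neighbor joining
#' (default, reusing the tree engine) or UPGMA (average-linkage
#' hierarchical clustering).
#'
#' @param d distance matrix from \code{\link{band_distance}} (>= 2
#'   lanes; NJ needs >= 3).
#' @param method \code{"nj"} or \code{"upgma"}.
#' @return An \pkg{ape} \code{phylo}.
#' @export
band_dendrogram <- function(d, method = c("nj", "upgma")) {
  method <- match.arg(method)
  d <- as_dist_matrix(d)
  if (nrow(d) < 2L) stop("need at least 2 lanes")
  if (method == "nj") return(neighbor_joining(d))
  ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
}

#' Permutation test for a partition of DGGE lanes
#'
#' Tests whether lanes from different groups (e.g. winter vs summer) are
#' more dissimilar than lanes within a group: the statistic is mean
#' between-group minus mean within-group Jaccard distance, and its null
#' distribution is obtained by permuting the lane labels. The p-value is
#' (1 + #permutations strictly above observed) / (1 + n_perm); counting
#' strict exceedances means relabelings equivalent to the observed
#' partition (which tie its statistic exactly) do not inflate p, so a
#' perfectly separated partition attains the minimal p of
#' 1 / (n_perm + 1).
#'
#' @param d distance matrix from \code{\link{band_distance}}.
#' @param groups group label per lane.
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer seed.
#' @return List with \code{statistic}, \code{p_value}, \code{n_perm}.
#' @export
band_permutation_test <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as_dist_matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop("one group label per lane required")
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  if (!is.null(seed)) set.seed(seed)
  stat <- function(g) {
    between <- outer(g, g, "!=") & upper.tri(d)
    within <- outer(g, g, "==") & upper.tri(d)
    if (!any(between) || !any(within)) return(NA_real_)
    mean(d[between]) - mean(d[within])
  }
  obs <- stat(groups)
  perm <- replicate(n_perm, stat(sample(groups)))
  p <- (1 + sum(perm > obs + 1e-12, na.rm = TRUE)) / (1 + n_perm)
  list(statistic = obs, p_value = p, n_perm = n_perm)
}
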