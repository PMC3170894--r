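# End-to-end orchestration: translate -> mask -> composition/codon stats
# -> neutrality -> phylogeny -> DGGE, with TSV reports and a run manifest.

#' Read a plain-text key=value pipeline configuration
#'
#' One \code{key=value} pair per line; blank lines and lines starting
#' with \code{#} are ignored. Recognised keys: \code{fasta},
#' \code{groups}, \code{aa_mask}, \code{site_specs}, \code{bands}
#' (paths); \code{marker}, \code{gamma_shape}, \code{replicates},
#' \code{collapse_threshold}, \code{identity_threshold}, \code{seed}.
#'
#' @param path config file.
#' @return Named list of (character) values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) trimws(paste(p[-1], collapse = "="))),
                  vapply(kv, function(p) trimws(p[1]), character(1)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

cfg_num <- function(config, key, default) {
  if (is.null(config[[key]])) default else as.numeric(config[[key]])
}

#' Run the composition-based haloadaptation pipeline
#'
#' Orchestrates the stages on one marker: read nucleotide FASTA and
#' group labels, translate each fragment in its best frame, optionally
#' deduplicate phylotypes by identity clustering, apply the informative
#' -site mask (amino-acid and codon versions), compute composition
#' (PAB/AB) and GC/RSCU group reports, correspondence analysis of RSCU,
#' Tajima's D, the JTT+Gamma NJ tree with bootstrap consensus, and the
#' DGGE band dendrogram with a seasonal permutation test. Stages whose
#' inputs are absent from the config are skipped with a warning. All
#' outputs are TSV/Newick files plus a manifest recording the config
#' hash, seeds and package version; reruns with the same config and
#' seeds are byte-identical.
#'
#' @param config named list (see \code{\link{read_config}}) or path to a
#'   config file.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a named list of the file paths written.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config_path <- config)
  else config_path <- NULL
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  seed <- as.integer(cfg_num(config, "seed", 1))

  if (is.null(config$fasta)) stop("config is missing required input: fasta")
  nt <- read_fasta(config$fasta, group_table = config$groups,
                   alphabet = "nt")

  # best-frame translation of every fragment
  tr <- lapply(nt$seq, best_frame)
  aa <- seq_set(nt$id, vapply(tr, `[[`, character(1), "aa"),
                alphabet = "aa", group = nt$group, clade = nt$clade,
                season = nt$season)
  frames <- data.frame(id = nt$id,
                       frame = vapply(tr, `[[`, integer(1), "frame"),
                       internal_stops = vapply(tr, `[[`, integer(1), "stops"))
  out$frames <- write_tsv(frames, file.path(out_dir, "frames.tsv"))

  thr <- cfg_num(config, "identity_threshold", NA)
  if (!is.na(thr)) {
    cl <- greedy_identity_cluster(nt, thr)
    out$clusters <- write_tsv(cl$membership,
                              file.path(out_dir, "clusters.tsv"))
    keep <- nt$id %in% cl$membership$representative
    nt <- nt[keep, , drop = FALSE]
    aa <- aa[keep, , drop = FALSE]
  }

  aa_aln <- as_alignment(aa)
  nt_aln <- as_alignment(nt, codon_aligned = TRUE)
  if (!is.null(config$aa_mask)) {
    mask <- read_mask(config$aa_mask)
    aa_aln <- apply_mask(aa_aln, mask)
    nt_aln <- codon_mask(nt_aln, mask)
  } else {
    warning("no column mask in config; composition and codon statistics ",
            "computed on full fragments")
  }

  if (!is.null(config$site_specs)) {
    sites <- read_site_specs(config$site_specs)
    out$site_conservation <- write_tsv(
      site_conservation(aa_aln, sites),
      file.path(out_dir, "site_conservation.tsv"))
  }

  # Table-1-style group summary: composition metrics + GC columns
  prof <- composition_profiles(aa_aln)
  gc <- gc_profiles(nt_aln, codon_aligned = TRUE)
  prof <- cbind(prof, gc[match(prof$id, gc$id),
                         c("gc_total", "gc1", "gc2", "gc3")])
  metrics <- c("asx_glx", "pab", "ab", "lys", "asp_to_lys", "arg",
               "gc_total", "gc3")
  if (!all(is.na(prof$group)))
    out$composition_groups <- write_tsv(
      group_summary(prof, prof$group, metrics),
      file.path(out_dir, "composition_groups.tsv"))
  if (!all(is.na(prof$clade)))
    out$composition_clades <- write_tsv(
      group_summary(prof[!is.na(prof$clade), ],
                    prof$clade[!is.na(prof$clade)], metrics),
      file.path(out_dir, "composition_clades.tsv"))
  out$composition <- write_tsv(prof, file.path(out_dir, "composition.tsv"))

  # RSCU per adaptation group + correspondence analysis
  if (!all(is.na(nt_aln$group))) {
    grp_seqs <- split(nt_aln$seq, nt_aln$group)
    rscu_tabs <- lapply(names(grp_seqs), function(g) {
      t <- rscu(grp_seqs[[g]])
      t$group <- g
      t
    })
    out$rscu <- write_tsv(do.call(rbind, rscu_tabs),
                          file.path(out_dir, "rscu.tsv"))
    if (length(grp_seqs) >= 2L) {
      ca <- rscu_correspondence(rscu_matrix(grp_seqs))
      coords <- rbind(
        data.frame(label = rownames(ca$row_coords), type = "group",
                   axis1 = ca$row_coords[, 1],
                   axis2 = if (ncol(ca$row_coords) > 1) ca$row_coords[, 2] else NA),
        data.frame(label = rownames(ca$col_coords), type = "codon",
                   axis1 = ca$col_coords[, 1],
                   axis2 = if (ncol(ca$col_coords) > 1) ca$col_coords[, 2] else NA))
      out$ca <- write_tsv(coords, file.path(out_dir, "ca_coordinates.tsv"))
    }
  }

  # neutrality
  marker <- if (is.null(config$marker)) "marker" else config$marker
  td <- tajimas_d(nt_aln)
  out$tajima <- write_tsv(tajima_table(stats::setNames(list(td), marker)),
                          file.path(out_dir, "tajima.tsv"))

  # phylogeny
  model <- jtt_model(gamma_shape = cfg_num(config, "gamma_shape", 0.9))
  d <- jtt_dist_matrix(aa_aln, model)
  out$distances <- write_phylip_dist(d, file.path(out_dir, "distances.phy"))
  out$nj_tree <- write_newick(neighbor_joining(d),
                              file.path(out_dir, "nj_tree.nwk"))
  if (nrow(aa_aln) >= 4L) {
    cons <- bootstrap_consensus(
      aa_aln, model,
      replicates = cfg_num(config, "replicates", 100),
      collapse_threshold = cfg_num(config, "collapse_threshold", 60),
      seed = seed)
    out$consensus_tree <- write_newick(cons,
                                       file.path(out_dir, "consensus_tree.nwk"))
  }

  # DGGE
  if (!is.null(config$bands)) {
    bm <- read_band_table(config$bands)
    bd <- band_distance(bm)
    out$dgge_tree <- write_newick(band_dendrogram(bd, method = "upgma"),
                                  file.path(out_dir, "dgge_dendrogram.nwk"))
    pt <- band_permutation_test(bd, attr(bm, "season"),
                                n_perm = cfg_num(config, "n_perm", 999),
                                seed = seed)
    out$dgge_test <- write_tsv(
      data.frame(statistic = pt$statistic, p_value = pt$p_value,
                 n_perm = pt$n_perm),
      file.path(out_dir, "dgge_permutation.tsv"))
  }

  manifest <- c(
    sprintf("package_version=%s", as.character(utils::packageVersion("halomark"))),
    sprintf("r_version=%s", R.version.string),
    sprintf("seed=%d", seed),
    if (!is.null(config_path))
      sprintf("config_md5=%s", unname(tools::md5sum(config_path))),
    vapply(names(config), function(k)
      sprintf("config.%s=%s", k, config[[k]]), character(1)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  out$manifest <- file.path(out_dir, "manifest.txt")
  invisible(out)
}
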