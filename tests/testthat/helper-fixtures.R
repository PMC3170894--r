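# Shared fixture builders; everything is generated in code.

random_nt_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_aa_seq <- function(len) {
  paste(sample(halomark:::AA20, len, replace = TRUE), collapse = "")
}

random_nt_alignment <- function(n, len, gap_prob = 0) {
  seqs <- vapply(seq_len(n), function(i) {
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (gap_prob > 0) {
      g <- runif(len) < gap_prob
      chars[g] <- "-"
    }
    paste(chars, collapse = "")
  }, character(1))
  as_alignment(seq_set(sprintf("r%02d", seq_len(n)), seqs, alphabet = "nt"))
}

# unrooted bipartition set of a tree, as sorted tip-label splits
bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  parts <- ape::prop.part(tree)
  tips <- attr(parts, "labels")
  out <- lapply(parts, function(p) {
    side <- sort(tips[p])
    other <- sort(setdiff(tips, side))
    if (length(side) <= 1 || length(other) <= 1) return(NULL)
    paste(paste(side, collapse = ","), paste(other, collapse = ","),
          sep = "|")
  })
  sort(unlist(lapply(out, function(s)
    if (is.null(s)) NULL else min(s, sub("(.*)\\|(.*)", "\\2|\\1", s)))))
}
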