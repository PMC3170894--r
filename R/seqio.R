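# Sequence container, FASTA/Newick I/O, translation and identity clustering.

NT_CHARS <- c("A", "C", "G", "T", "N", "-")
AA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*", "-")

#' Labelled sequence set
#'
#' Container for nucleotide or amino-acid sequences with optional group
#' metadata (adaptation class, taxonomic clade, season). Implemented as a
#' data frame with columns \code{id}, \code{seq}, \code{group},
#' \code{clade}, \code{season} and an \code{alphabet} attribute.
#'
#' @param id character vector of unique sequence identifiers.
#' @param seq character vector of sequences (same length as \code{id}).
#' @param alphabet \code{"nt"} or \code{"aa"}; inferred from the residues
#'   when \code{NULL}. Inference calls a set nucleotide only when every
#'   character is one of \code{A,C,G,T,N,-}.
#' @param group,clade,season optional per-sequence labels.
#' @return An object of class \code{seq_set}.
#' @examples
#' s <- seq_set(c("a", "b"), c("ACGT", "ACGA"))
#' alphabet(s)
#' @export
seq_set <- function(id, seq, alphabet = NULL, group = NULL, clade = NULL,
                    season = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq))
    stop("'id' and 'seq' must have the same length")
  if (length(id) == 0L) stop("empty sequence set")
  if (any(!nzchar(seq))) stop("empty sequence for id: ",
                              paste(id[!nzchar(seq)], collapse = ", "))
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate sequence id: ", paste(dup, collapse = ", "))
  seq <- gsub("U", "T", seq, fixed = TRUE)
  if (is.null(alphabet)) alphabet <- infer_alphabet(seq)
  alphabet <- match.arg(alphabet, c("nt", "aa"))
  allowed <- if (alphabet == "nt") NT_CHARS else AA_CHARS
  bad <- setdiff(unique(unlist(strsplit(seq, ""))), allowed)
  if (length(bad))
    stop("characters not in ", alphabet, " alphabet: ",
         paste(bad, collapse = ", "))
  x <- data.frame(id = id, seq = seq,
                  group = if (is.null(group)) NA_character_ else as.character(group),
                  clade = if (is.null(clade)) NA_character_ else as.character(clade),
                  season = if (is.null(season)) NA_character_ else as.character(season),
                  stringsAsFactors = FALSE)
  attr(x, "alphabet") <- alphabet
  class(x) <- c("seq_set", "data.frame")
  x
}

infer_alphabet <- function(seq) {
  chars <- unique(unlist(strsplit(seq, "")))
  if (all(chars %in% NT_CHARS)) "nt" else "aa"
}

#' @rdname seq_set
#' @param x a \code{seq_set}.
#' @export
alphabet <- function(x) attr(x, "alphabet")

#' Named character vector of the sequences in a set
#' @param x a \code{seq_set}.
#' @export
sequences <- function(x) stats::setNames(x$seq, x$id)

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set: %d %s sequence(s), lengths %d-%d\n",
              nrow(x), alphabet(x), min(nchar(x$seq)), max(nchar(x$seq))))
  if (isTRUE(attr(x, "codon_aligned"))) cat("codon-aligned\n")
  invisible(x)
}

#' @export
`[.seq_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "alphabet") <- attr(x, "alphabet")
    attr(out, "codon_aligned") <- attr(x, "codon_aligned")
    class(out) <- class(x)
  }
  out
}

#' Mark a sequence set as an alignment
#'
#' Checks that all sequences have equal length and, for codon alignments,
#' that the length is divisible by 3 (amino-acid column i then maps to
#' nucleotide columns 3i-2..3i, 1-based).
#'
#' @param x a \code{seq_set}.
#' @param codon_aligned logical; only meaningful for nucleotide sets.
#' @return \code{x} with class \code{alignment} prepended.
#' @export
as_alignment <- function(x, codon_aligned = FALSE) {
  stopifnot(inherits(x, "seq_set"))
  len <- unique(nchar(x$seq))
  if (length(len) != 1L)
    stop("sequences have unequal lengths: ", paste(len, collapse = ", "))
  if (codon_aligned) {
    if (alphabet(x) != "nt") stop("codon_aligned requires nucleotide sequences")
    if (len %% 3L != 0L) stop("codon-aligned length must be divisible by 3")
  }
  attr(x, "codon_aligned") <- codon_aligned
  if (!inherits(x, "alignment")) class(x) <- c("alignment", class(x))
  x
}

#' Number of alignment columns
#' @param x an \code{alignment}.
#' @export
n_columns <- function(x) nchar(x$seq[1L])

#' Read sequences from a FASTA file
#'
#' Order of records is preserved. An optional tab-separated group table
#' (columns \code{id}, \code{group}, \code{clade}, \code{season}; header
#' required) attaches metadata by id.
#'
#' @param path FASTA file.
#' @param group_table optional path to a TSV label table.
#' @param alphabet forced alphabet, or \code{NULL} to infer.
#' @return A \code{seq_set}.
#' @export
read_fasta <- function(path, group_table = NULL, alphabet = NULL) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  x <- seq_set(ids, as.character(ss), alphabet = alphabet)
  if (!is.null(group_table)) {
    g <- read_group_table(group_table)
    m <- match(x$id, g$id)
    for (col in c("group", "clade", "season"))
      if (col %in% names(g)) x[[col]] <- g[[col]][m]
  }
  x
}

#' Write a sequence set to FASTA
#'
#' @param x a \code{seq_set}.
#' @param path output file.
#' @param width line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  ss <- Biostrings::BStringSet(sequences(x))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a sequence group-label table
#'
#' Tab-separated with a header; must contain an \code{id} column, and may
#' contain \code{group} (adaptation class, e.g. tirez / halophile /
#' nonhalophile), \code{clade} and \code{season} (winter / summer).
#'
#' @param path TSV file.
#' @export
read_group_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(g)) stop("group table must have an 'id' column")
  g$id <- as.character(g$id)
  g
}

# standard genetic code, DNA alphabet
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Reverse complement of a DNA string
#' @param seq nucleotide string (gaps and N preserved).
#' @export
reverse_complement <- function(seq) {
  chartr("ACGTN-", "TGCAN-", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a nucleotide sequence in a given reading frame
#'
#' Frames +1..+3 read the forward strand starting at offsets 0..2; frames
#' -1..-3 read the reverse complement the same way. The incomplete
#' trailing codon is dropped; stop codons are rendered \code{*}; codons
#' containing \code{N} translate to \code{X}; all-gap codons translate to
#' \code{-} and codons with partial gaps to \code{X}. Standard genetic
#' code only.
#'
#' @param seq nucleotide string.
#' @param frame one of +1, +2, +3, -1, -2, -3.
#' @return Amino-acid string of length \code{floor((len - offset)/3)}.
#' @examples
#' translate_frame("ATGGCC", 1)   # "MA"
#' translate_frame("ATGTAA", 1)   # "M*"
#' @export
translate_frame <- function(seq, frame = 1L) {
  if (!frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
    stop("frame must be one of +1, +2, +3, -1, -2, -3")
  seq <- toupper(seq)
  if (frame < 0L) seq <- reverse_complement(seq)
  offset <- abs(frame) - 1L
  if (nchar(seq) - offset < 3L) stop("sequence too short for frame ", frame)
  seq <- substring(seq, offset + 1L)
  codons <- split_codons(seq)
  aa <- GENETIC_CODE_STD[codons]
  aa[is.na(aa)] <- vapply(codons[is.na(aa)], function(cd) {
    if (cd == "---") "-" else "X"
  }, character(1))
  paste(aa, collapse = "")
}

#' Select the reading frame with the fewest internal stops
#'
#' All six frames are translated and the frame minimising the internal
#' stop count is returned; ties are broken in the order +1, +2, +3, -1,
#' -2, -3. A stop at the very end of the translated fragment is not
#' counted as internal. When even the best frame contains an internal
#' stop the result is flagged, mirroring the screening step in which
#' unstopped reading frames identify the coding strand of an
#' environmental amplicon.
#'
#' @param seq nucleotide string, length >= 3.
#' @return List with \code{frame}, \code{aa}, \code{stops} (internal stop
#'   count) and \code{flagged}.
#' @export
best_frame <- function(seq) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  aa <- vapply(frames, function(f) translate_frame(seq, f), character(1))
  internal_stops <- vapply(aa, function(a) {
    s <- strsplit(a, "")[[1]]
    n <- sum(s == "*")
    if (n > 0L && s[length(s)] == "*") n <- n - 1L
    n
  }, numeric(1))
  k <- which.min(internal_stops)  # first minimum = preferred frame order
  list(frame = frames[k], aa = unname(aa[k]),
       stops = as.integer(internal_stops[k]),
       flagged = unname(internal_stops[k] > 0))
}

pairwise_identity <- function(a, b) {
  chars <- unique(unlist(strsplit(c(a, b), "")))
  m <- diag(1, length(chars))
  dimnames(m) <- list(chars, chars)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = m,
                                       gapOpening = 0, gapExtension = 1)
  width <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / width
}

#' Greedy identity clustering of sequences
#'
#' Removes redundant phylotypes the way a longest-first greedy clusterer
#' does: records are sorted by decreasing length (stable), each record
#' joins the first existing cluster whose representative has pairwise
#' identity >= \code{threshold}, otherwise it founds a new cluster.
#' Identity is matches divided by the aligned length of a global pairwise
#' alignment (match +1, mismatch 0, linear gap -1). The representative is
#' the longest member (ties by input order), which under this scheme is
#' always the founder. At \code{threshold = 1} the clustering reduces to
#' exact deduplication of identical sequences.
#'
#' @param x a \code{seq_set}.
#' @param threshold identity threshold in (0, 1].
#' @return List with \code{membership} (data frame id, cluster,
#'   representative) and \code{representatives} (a \code{seq_set} of one
#'   record per cluster, in cluster order).
#' @export
greedy_identity_cluster <- function(x, threshold = 0.9) {
  stopifnot(inherits(x, "seq_set"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  ord <- order(-nchar(x$seq))          # stable: ties keep input order
  reps <- integer(0)                   # row indices of representatives
  cluster_of <- integer(nrow(x))
  for (i in ord) {
    assigned <- 0L
    for (k in seq_along(reps)) {
      if (pairwise_identity(x$seq[i], x$seq[reps[k]]) >= threshold) {
        assigned <- k
        break
      }
    }
    if (assigned == 0L) {
      reps <- c(reps, i)
      assigned <- length(reps)
    }
    cluster_of[i] <- assigned
  }
  membership <- data.frame(id = x$id, cluster = cluster_of,
                           representative = x$id[reps][cluster_of],
                           stringsAsFactors = FALSE)
  rep_set <- x[reps, , drop = FALSE]
  attr(rep_set, "alphabet") <- alphabet(x)
  class(rep_set) <- c("seq_set", "data.frame")
  list(membership = membership, representatives = rep_set)
}

#' Write / read a tree in Newick format
#'
#' Thin wrappers around \pkg{ape}; integer bootstrap supports stored in
#' \code{tree$node.label} are emitted as internal node labels.
#'
#' @param tree an \pkg{ape} \code{phylo} object.
#' @param path file path.
#' @return \code{path} (write) or a \code{phylo} (read).
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
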