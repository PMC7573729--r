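#' Aligned sequence set
#'
#' Light container for a multiple sequence alignment: a set of equal-length
#' gapped sequences with unique identifiers and a declared alphabet.
#' Ambiguity codes (IUPAC codes beyond ACGT for nucleotide, `X` for
#' amino-acid) are accepted and treated as missing data by all downstream
#' likelihood and counting computations; the gap symbol is `-`.
#'
#' @param seqs named character vector of aligned sequences (names are ids).
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @return an object of class `gene_alignment` with elements `ids`, `seqs`,
#'   `alphabet`.
#' @export
gene_alignment <- function(seqs, alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("all sequences must carry non-empty ids", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(seqs))
  names(seqs) <- ids
  lens <- nchar(seqs)
  if (length(seqs) < 1L || any(lens < 1L)) {
    stop("alignment must contain non-empty sequences", call. = FALSE)
  }
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths differ (",
         paste(range(lens), collapse = "-"), ")", call. = FALSE)
  }
  legal <- alphabet_chars(alphabet)
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!(ch %in% legal))
    if (length(bad)) {
      stop(sprintf("illegal character '%s' for %s alphabet in '%s' at position %d",
                   ch[bad[1]], alphabet, ids[i], bad[1]), call. = FALSE)
    }
  }
  structure(list(ids = ids, seqs = seqs, alphabet = alphabet, gap = "-"),
            class = "gene_alignment")
}

alphabet_chars <- function(alphabet) {
  if (alphabet == "nucleotide") {
    c("A", "C", "G", "T", "U",
      "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "-")
  } else {
    c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "B", "Z", "-")
  }
}

#' Core (unambiguous) states of an alphabet
#' @keywords internal
core_states <- function(alphabet) {
  if (alphabet == "nucleotide") c("A", "C", "G", "T")
  else strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %d %s sequences of length %d\n",
              length(x$ids), x$alphabet, nchar(x$seqs[[1]])))
  invisible(x)
}

#' @export
length.gene_alignment <- function(x) length(x$ids)

#' Number of alignment columns
#' @param a a `gene_alignment`
#' @export
aln_width <- function(a) nchar(a$seqs[[1]])

#' Alignment as a character matrix (rows = sequences)
#' @param a a `gene_alignment`
#' @return character matrix with rownames = ids
#' @export
aln_matrix <- function(a) {
  m <- do.call(rbind, strsplit(a$seqs, "", fixed = TRUE))
  rownames(m) <- a$ids
  m
}

#' Subset an alignment by sequence ids or columns
#' @param a a `gene_alignment`
#' @param ids sequence ids to keep (default all)
#' @param cols column indices to keep (default all)
#' @export
aln_subset <- function(a, ids = a$ids, cols = NULL) {
  stopifnot(all(ids %in% a$ids))
  s <- a$seqs[ids]
  if (!is.null(cols)) {
    m <- do.call(rbind, strsplit(s, "", fixed = TRUE))
    s <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    names(s) <- ids
  }
  out <- gene_alignment(s, a$alphabet)
  if (inherits(a, "codon_alignment") && aln_width(out) %% 3L == 0L) {
    class(out) <- c("codon_alignment", class(out))
  }
  out
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file of pre-aligned sequences.
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @return a [gene_alignment]
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  recs <- seqinr::read.fasta(path, seqtype = if (alphabet == "nucleotide") "DNA" else "AA",
                             as.string = TRUE, forceDNAtolower = FALSE,
                             seqonly = FALSE)
  if (!length(recs)) stop("empty FASTA: ", path, call. = FALSE)
  seqs <- vapply(recs, function(r) toupper(as.character(r)[1]), character(1))
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1))
  gene_alignment(seqs, alphabet)
}

#' Write an alignment to FASTA
#' @param a a [gene_alignment]
#' @param path output file
#' @export
write_fasta <- function(a, path) {
  seqinr::write.fasta(as.list(a$seqs), names = a$ids, file.out = path,
                      nbchar = 70)
  invisible(path)
}

#' Codon alignment constructor
#'
#' A [gene_alignment] restricted to nucleotides whose width is a multiple of
#' three, suitable for codon-level Dn/Ds counting.
#' @inheritParams gene_alignment
#' @export
codon_alignment <- function(seqs) {
  a <- gene_alignment(seqs, "nucleotide")
  if (aln_width(a) %% 3L != 0L) {
    stop("codon alignment width ", aln_width(a), " is not divisible by 3",
         call. = FALSE)
  }
  class(a) <- c("codon_alignment", class(a))
  a
}

#' Read a codon (in-frame nucleotide) FASTA alignment
#' @param path FASTA file
#' @export
read_codon_fasta <- function(path) {
  a <- read_fasta(path, "nucleotide")
  codon_alignment(a$seqs)
}
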