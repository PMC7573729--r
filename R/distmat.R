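#' Labeled pairwise distance matrix
#'
#' The common currency of the pipeline: a symmetric, zero-diagonal,
#' non-negative matrix over a set of labels, with an optional mask marking
#' pairs whose distance is undefined (e.g. saturated ML distances, invalid
#' Dn/Ds ratios). The mask is always symmetric and the diagonal never masked.
#'
#' @param values square numeric matrix with dimnames, or labels supplied via
#'   `labels`.
#' @param mask logical matrix of the same shape; `TRUE` marks an undefined
#'   pair. Default: nothing masked. `NA` entries in `values` are masked
#'   automatically.
#' @param labels optional character vector of labels overriding dimnames.
#' @return object of class `pair_dist` with elements `labels`, `values`,
#'   `mask`.
#' @export
pair_dist <- function(values, mask = NULL, labels = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n != ncol(values)) stop("distance matrix must be square", call. = FALSE)
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- paste0("item", seq_len(n))
  if (anyDuplicated(labels)) stop("duplicate labels", call. = FALSE)
  dimnames(values) <- list(labels, labels)
  if (is.null(mask)) mask <- matrix(FALSE, n, n)
  mask <- mask | is.na(values)
  mask <- mask | t(mask)          # masking is symmetric
  diag(mask) <- FALSE
  dimnames(mask) <- dimnames(values)
  vals <- values
  vals[mask] <- NA_real_
  off <- vals[!mask]
  if (any(!is.finite(off))) stop("non-finite unmasked distances", call. = FALSE)
  if (max(abs(vals - t(vals)), na.rm = TRUE) > 1e-12) {
    stop("distance matrix is not symmetric (tolerance 1e-12)", call. = FALSE)
  }
  vals <- (vals + t(vals)) / 2
  if (any(diag(vals) != 0)) stop("diagonal must be exactly zero", call. = FALSE)
  if (any(off < 0)) stop("negative distances", call. = FALSE)
  structure(list(labels = labels, values = vals, mask = mask),
            class = "pair_dist")
}

#' @export
print.pair_dist <- function(x, ...) {
  cat(sprintf("<pair_dist> %d labels, %d/%d pairs masked\n",
              length(x$labels), sum(x$mask[upper.tri(x$mask)]),
              length(x$labels) * (length(x$labels) - 1L) / 2L))
  invisible(x)
}

#' @export
as.matrix.pair_dist <- function(x, ...) x$values

#' @export
labels.pair_dist <- function(object, ...) object$labels

#' Is any pair masked?
#' @param d a [pair_dist]
#' @export
has_masked <- function(d) any(d$mask)

#' Off-diagonal pair values of a distance matrix
#'
#' @param d a [pair_dist]
#' @param drop_masked drop masked pairs (default) or return them as `NA`.
#' @return data.frame with columns `a`, `b`, `value` (one row per unordered
#'   pair, upper triangle order).
#' @export
dist_pairs <- function(d, drop_masked = TRUE) {
  ut <- upper.tri(d$values)
  idx <- which(ut, arr.ind = TRUE)
  out <- data.frame(a = d$labels[idx[, 1]], b = d$labels[idx[, 2]],
                    value = d$values[ut], stringsAsFactors = FALSE)
  if (drop_masked) out <- out[!d$mask[ut], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reorder a pair_dist to a given label order
#' @param d a [pair_dist]
#' @param labels permutation of `d$labels`
#' @export
dist_reorder <- function(d, labels) {
  if (!setequal(labels, d$labels) || length(labels) != length(d$labels)) {
    stop("labels are not a permutation of the matrix labels", call. = FALSE)
  }
  pair_dist(d$values[labels, labels], d$mask[labels, labels])
}

#' Write / read a labeled distance matrix as TSV
#'
#' Tab-separated, UTF-8, `.` decimal; first column holds labels, header row
#' repeats them. Masked entries are written as `NA`. Full precision (17
#' significant digits) so round trips are lossless to 1e-12.
#'
#' @param d a [pair_dist]
#' @param path output path
#' @export
write_dist_tsv <- function(d, path) {
  m <- d$values
  df <- data.frame(label = d$labels,
                   formatC(m, format = "g", digits = 17),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("label", d$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
read_dist_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")  # literal NA = masked pair
  rownames(m) <- labels
  colnames(m) <- names(df)[-1]
  pair_dist(m[, labels, drop = FALSE])
}

#' Read a gene-by-sample expression table
#'
#' Expects a header row of sample ids and a first column of gene ids (the
#' layout of gene-per-row expression supplements). All cells must parse as
#' finite reals.
#'
#' @param path TSV file
#' @return numeric matrix, genes in rows, samples in columns
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          quote = "")
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  m <- matrix(NA_real_, nrow(df), length(samples),
              dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric expression value '%s' at row %d, column '%s'",
                   df[[j + 1L]][bad[1]], bad[1], samples[j]), call. = FALSE)
    }
    m[, j] <- v
  }
  m
}

#' Write a gene-by-sample expression table as TSV
#' @param m numeric matrix with dimnames
#' @param path output path
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m),
                   formatC(m, format = "g", digits = 17),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Newick tree IO
#'
#' Thin wrappers over ape's Newick reader/writer: bootstrap supports travel
#' as internal node labels, branch lengths at full precision.
#'
#' @param path Newick file
#' @return an ape `phylo`
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error in ", path, call. = FALSE)
  tr
}

#' @rdname read_newick
#' @param tree an ape `phylo`
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 17)
  invisible(path)
}
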