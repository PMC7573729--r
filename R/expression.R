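#' Row-standardize an expression matrix
#'
#' Scales each gene (row) to mean zero and sample (n-1) standard deviation
#' one across samples. Constant rows cannot be standardized; they are
#' dropped and reported in the `dropped` attribute, with a warning.
#'
#' @param e numeric gene-by-sample matrix with dimnames
#' @return scaled matrix; attribute `dropped` holds the ids of constant rows
#' @export
scale_rows <- function(e) {
  e <- as.matrix(e)
  if (ncol(e) < 2L) stop("need >= 2 samples per gene to scale", call. = FALSE)
  mu <- rowMeans(e)
  sdv <- apply(e, 1L, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  if (any(const)) {
    warning("dropping constant expression rows: ",
            paste(rownames(e)[const], collapse = ", "))
  }
  out <- (e[!const, , drop = FALSE] - mu[!const]) / sdv[!const]
  attr(out, "dropped") <- rownames(e)[const]
  out
}

#' Pairwise Pearson correlation distances between genes
#'
#' d(i, j) = 1 - Pearson r of the two genes' expression profiles across
#' samples, giving distances in `[0, 2]`. Pearson r is invariant to the row
#' scaling performed by [scale_rows], so scaled and unscaled input give the
#' same distances.
#'
#' @param e numeric gene-by-sample matrix (>= 3 samples, no constant rows)
#' @return a [pair_dist] over the gene ids
#' @export
correlation_distance <- function(e) {
  e <- as.matrix(e)
  if (ncol(e) < 3L) stop("need >= 3 samples", call. = FALSE)
  sdv <- apply(e, 1L, stats::sd)
  if (any(sdv == 0)) {
    stop("correlation undefined for constant gene(s): ",
         paste(rownames(e)[sdv == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(t(e))
  d <- 1 - r
  d[d < 0] <- 0               # r can exceed 1 by round-off
  diag(d) <- 0
  pair_dist((d + t(d)) / 2)
}

#' Centroid-linkage agglomerative clustering of a distance matrix
#'
#' Lance–Williams centroid recursion (via `stats::hclust`) on the supplied
#' dissimilarities, as used for gene expression heatmap row ordering.
#' Centroid linkage can produce height inversions (a merge lower than an
#' earlier one); these are preserved, not repaired.
#'
#' @param d a complete (unmasked) [pair_dist]
#' @return an object of class `hclust` (merges, heights, labels)
#' @export
cluster_centroid <- function(d) {
  if (has_masked(d)) stop("incomplete distance matrix: masked pairs present",
                          call. = FALSE)
  stats::hclust(stats::as.dist(d$values), method = "centroid")
}

#' Dendrogram merge table
#'
#' @param h an `hclust` object
#' @return data.frame with columns `merge_a`, `merge_b` (negative = leaf
#'   index, positive = earlier merge), `height`, `size`
#' @export
dendrogram_table <- function(h) {
  sizes <- integer(nrow(h$merge))
  for (i in seq_len(nrow(h$merge))) {
    sz <- function(x) if (x < 0) 1L else sizes[x]
    sizes[i] <- sz(h$merge[i, 1]) + sz(h$merge[i, 2])
  }
  data.frame(merge_a = h$merge[, 1], merge_b = h$merge[, 2],
             height = h$height, size = sizes)
}

#' Write a dendrogram as Newick and as a merge-table TSV
#'
#' @param h an `hclust` object
#' @param newick_path,table_path output paths (either may be `NULL` to skip)
#' @export
write_dendrogram <- function(h, newick_path = NULL, table_path = NULL) {
  if (!is.null(newick_path)) {
    write_newick(ape::as.phylo(h), newick_path)
  }
  if (!is.null(table_path)) {
    utils::write.table(dendrogram_table(h), table_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(h)
}
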