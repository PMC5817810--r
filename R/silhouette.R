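#' Silhouette widths of a clustering
#'
#' For sample i with mean intra-cluster distance `a(i)` (excluding itself)
#' and `b(i)` the smallest mean distance to any other cluster,
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`. Members of singleton clusters
#' get `s(i) = 0` by convention. Computed via `cluster::silhouette`.
#'
#' @param d sample x sample distance matrix (e.g. [pearson_distance()] or
#'   `1 -` a consensus matrix).
#' @param labels cluster assignment per sample, covering >= 2 clusters.
#' @return object of class `silhouette_result`: `widths` data.frame
#'   (`sample_id`, `cluster`, `width`), `cluster_means`, `overall_mean`.
#' @export
silhouette_widths <- function(d, labels) {
  if (!is.null(names(labels)) && !is.null(rownames(d)))
    labels <- labels[rownames(d)]
  if (length(labels) != nrow(d))
    stop("labels must align with the distance matrix")
  cl <- as.integer(as.factor(labels))
  if (length(unique(cl)) < 2L)
    stop("silhouette requires at least 2 clusters")
  sil <- cluster::silhouette(cl, dmatrix = as.matrix(d))
  w <- sil[, "sil_width"]
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  widths <- data.frame(sample_id = ids,
                       cluster = as.character(labels),
                       width = as.numeric(w),
                       stringsAsFactors = FALSE)
  cm <- tapply(widths$width, widths$cluster, mean)
  structure(list(widths = widths,
                 cluster_means = cm,
                 overall_mean = mean(widths$width)),
            class = "silhouette_result")
}

#' @export
print.silhouette_result <- function(x, ...) {
  cat("silhouette: overall mean width", round(x$overall_mean, 3),
      "( per-cluster:",
      paste(sprintf("%s=%.3f", names(x$cluster_means), x$cluster_means),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Retain core samples with strictly positive silhouette width
#'
#' Samples whose silhouette width is <= 0 sit on or across a cluster
#' boundary; dropping them yields the coherent core used to train the
#' subtype classifier.
#'
#' @param sil a `silhouette_result`.
#' @return character vector of retained sample ids.
#' @export
filter_positive_silhouette <- function(sil) {
  stopifnot(inherits(sil, "silhouette_result"))
  keep <- sil$widths$sample_id[sil$widths$width > 0]
  if (!length(keep)) stop("no sample has positive silhouette width")
  keep
}

#' Write a silhouette report as TSV
#' @param sil a `silhouette_result`.
#' @param path output file.
#' @export
write_silhouette <- function(sil, path) {
  utils::write.table(sil$widths, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sil)
}
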