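#' Pearson correlation distance between samples
#'
#' `D(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation between the
#' expression profiles of samples i and j. The distance lies in `[0, 2]` and
#' is the standard dissimilarity for expression-based hierarchical
#' clustering.
#'
#' @param x expression matrix, features x samples.
#' @return symmetric sample x sample distance matrix with zero diagonal.
#' @export
pearson_distance <- function(x) {
  if (nrow(x) < 2L) stop("need at least 2 features per sample profile")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample profile(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(x)
  diag(d) <- 0
  d
}

# average-linkage hierarchical clustering on a distance matrix, hard cut at k
hclust_cut <- function(d, k) {
  stats::cutree(stats::hclust(stats::as.dist(d), method = "average"), k = k)
}

#' RNG seed for one consensus iteration
#'
#' Iteration `i` of a consensus run with global seed `seed` draws its
#' subsample after `set.seed(consensus_iteration_seed(seed, i))` followed by
#' `sample.int(n, size)`. The scheme is exported so the subsample draws can
#' be replayed independently (e.g. by a brute-force reimplementation).
#'
#' @param seed global run seed.
#' @param i iteration index, 1-based.
#' @return integer seed.
#' @export
consensus_iteration_seed <- function(seed, i) substream_seed(seed, 100L + i)

#' Subsampled hierarchical consensus clustering
#'
#' Repeatedly subsamples `ceiling(subsample_fraction * n)` samples without
#' replacement, clusters each subsample by average-linkage hierarchical
#' clustering on the Pearson correlation distance, cuts at `k`, and records
#' co-cluster and co-sample counts. The consensus matrix is
#' `M(i, j) = times co-clustered / times co-sampled`; its diagonal is 1 by
#' convention and pairs never drawn together get 0 with a warning. Hard
#' labels come from average-linkage clustering of `1 - M` cut at `k`.
#'
#' @param x expression matrix, features x samples.
#' @param k number of clusters, >= 2.
#' @param n_iter subsampling iterations (1000 by default).
#' @param subsample_fraction fraction of samples drawn per iteration
#'   (0.9 by default).
#' @param seed integer seed; iteration i uses the sub-stream
#'   [consensus_iteration_seed()]`(seed, i)`.
#' @return object of class `consensus_result`: `k`, `consensus`,
#'   `cosample_counts`, `labels` (named integer), `n_iter`,
#'   `subsample_fraction`, `seed`.
#' @export
consensus_cluster <- function(x, k, n_iter = 1000L, subsample_fraction = 0.9,
                              seed = 1L) {
  validate_expression(x)
  n <- ncol(x)
  if (k < 2L) stop("k must be >= 2")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]")
  size <- ceiling(subsample_fraction * n)
  if (size < k) stop("subsample size (", size, ") smaller than k (", k, ")")

  co_clust <- matrix(0L, n, n)
  co_samp <- matrix(0L, n, n)
  full_d <- if (subsample_fraction == 1) pearson_distance(x) else NULL
  for (i in seq_len(n_iter)) {
    idx <- if (size == n) {
      seq_len(n)
    } else {
      set.seed(consensus_iteration_seed(seed, i))
      sample.int(n, size)
    }
    d <- if (is.null(full_d)) pearson_distance(x[, idx, drop = FALSE])
         else full_d
    cl <- hclust_cut(d, k)
    co_samp[idx, idx] <- co_samp[idx, idx] + 1L
    same <- outer(cl, cl, `==`)
    co_clust[idx, idx] <- co_clust[idx, idx] + same
  }
  m <- ifelse(co_samp > 0, co_clust / pmax(co_samp, 1L), 0)
  never <- sum(co_samp[upper.tri(co_samp)] == 0)
  if (never > 0)
    warning(never, " sample pair(s) never co-sampled; their consensus is 0")
  diag(m) <- 1
  dimnames(m) <- list(colnames(x), colnames(x))
  dimnames(co_samp) <- dimnames(m)

  labels <- hclust_cut(1 - m, k)
  names(labels) <- colnames(x)
  structure(list(k = k, consensus = m, cosample_counts = co_samp,
                 labels = labels, n_iter = n_iter,
                 subsample_fraction = subsample_fraction, seed = seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus clustering: k =", x$k, ",", ncol(x$consensus), "samples,",
      x$n_iter, "iterations at fraction", x$subsample_fraction, "\n")
  cat("  cluster sizes:", paste(table(x$labels), collapse = " / "), "\n")
  invisible(x)
}

#' Write a consensus matrix and labels as TSV
#' @param cr a `consensus_result`.
#' @param matrix_path,labels_path output files (either may be NULL to skip).
#' @export
write_consensus <- function(cr, matrix_path = NULL, labels_path = NULL) {
  if (!is.null(matrix_path)) {
    df <- data.frame(sample_id = rownames(cr$consensus), cr$consensus,
                     check.names = FALSE)
    utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(labels_path)) {
    utils::write.table(
      data.frame(sample_id = names(cr$labels), cluster = cr$labels),
      labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(cr)
}
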