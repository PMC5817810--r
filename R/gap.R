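#' Within-cluster dispersion W_k
#'
#' `W_k = sum over clusters of D_r / (2 n_r)` where `D_r` is the sum of
#' pairwise distances over ordered pairs within cluster r (equivalently the
#' unordered-pair sum divided by `n_r`).
#'
#' @param d sample x sample distance matrix.
#' @param labels cluster assignment per sample.
#' @return scalar dispersion.
#' @export
within_dispersion <- function(d, labels) {
  w <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) > 1L)
      w <- w + sum(d[idx, idx]) / (2 * length(idx))
  }
  w
}

#' Gap statistic for choosing the number of clusters
#'
#' Compares the observed log within-cluster dispersion against its
#' expectation under a reference null in which each feature is drawn
#' uniformly over its observed range. Both observed and reference data are
#' clustered with the same base clusterer used throughout the package:
#' average-linkage hierarchical clustering on the Pearson correlation
#' distance. `gap(k) = mean_ref log W*_k - log W_k`, with standard error
#' `sd_ref(log W*_k) * sqrt(1 + 1/n_refs)`.
#'
#' The selected k is the global argmax of the gap curve (first maximum on
#' ties); `rule = "firstSEmax"` instead applies the one-standard-error rule
#' (smallest k with `gap(k) >= gap(k+1) - se(k+1)`).
#'
#' @param x expression matrix, features x samples.
#' @param k_range integer vector of cluster counts to evaluate.
#' @param n_refs number of reference data sets.
#' @param seed integer seed for the reference draws.
#' @param rule `"globalmax"` (default) or `"firstSEmax"`.
#' @return object of class `gap_result`: `k_values`, `log_Wk`, `gap`, `se`,
#'   `chosen_k`.
#' @export
gap_statistic <- function(x, k_range = 2:6, n_refs = 50L, seed = 1L,
                          rule = c("globalmax", "firstSEmax")) {
  validate_expression(x)
  rule <- match.arg(rule)
  n <- ncol(x)
  if (any(k_range < 1L) || any(k_range > n - 1L))
    stop("k_range must lie within [1, n_samples - 1]")
  if (n_refs < 1L) stop("n_refs must be >= 1")
  k_range <- sort(unique(as.integer(k_range)))

  d_obs <- pearson_distance(x)
  cluster_at <- function(d, k) if (k == 1L) rep(1L, ncol(d)) else hclust_cut(d, k)

  lo <- apply(x, 1L, min); hi <- apply(x, 1L, max)
  set.seed(substream_seed(seed, 7L))
  ref_seeds <- sample.int(2147483646L, n_refs)
  log_wk <- numeric(length(k_range))
  log_wk_ref <- matrix(NA_real_, n_refs, length(k_range))
  ok <- rep(TRUE, length(k_range))
  for (j in seq_along(k_range)) {
    res <- try(within_dispersion(d_obs, cluster_at(d_obs, k_range[j])),
               silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(log(res))) {
      warning("k = ", k_range[j], " skipped (degenerate clustering)")
      ok[j] <- FALSE
    } else log_wk[j] <- log(res)
  }
  for (b in seq_len(n_refs)) {
    set.seed(ref_seeds[b])
    xr <- matrix(stats::runif(nrow(x) * n, rep(lo, n), rep(hi, n)), nrow(x), n)
    dimnames(xr) <- dimnames(x)
    dr <- pearson_distance(xr)
    for (j in seq_along(k_range)) {
      if (!ok[j]) next
      log_wk_ref[b, j] <- log(within_dispersion(dr, cluster_at(dr, k_range[j])))
    }
  }
  gap <- colMeans(log_wk_ref) - log_wk
  se <- apply(log_wk_ref, 2L, stats::sd) * sqrt(1 + 1 / n_refs)
  gap[!ok] <- NA_real_; se[!ok] <- NA_real_

  kv <- k_range[ok]; gv <- gap[ok]; sv <- se[ok]
  chosen <- if (rule == "globalmax") {
    kv[which.max(gv)]
  } else {
    pick <- kv[length(kv)]
    for (j in seq_along(kv)[-length(kv)]) {
      if (gv[j] >= gv[j + 1] - sv[j + 1]) { pick <- kv[j]; break }
    }
    pick
  }
  structure(list(k_values = k_range, log_Wk = log_wk, gap = gap, se = se,
                 chosen_k = chosen, n_refs = n_refs, rule = rule),
            class = "gap_result")
}

#' @export
print.gap_result <- function(x, ...) {
  cat("gap statistic over k =", paste(range(x$k_values), collapse = ".."),
      "(", x$n_refs, "reference sets ):  chosen k =", x$chosen_k, "\n")
  print(data.frame(k = x$k_values, logW = round(x$log_Wk, 4),
                   gap = round(x$gap, 4), se = round(x$se, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Write a gap curve as TSV
#' @param gr a `gap_result`.
#' @param path output file.
#' @export
write_gap <- function(gr, path) {
  utils::write.table(
    data.frame(k = gr$k_values, logW = gr$log_Wk, gap = gr$gap, se = gr$se),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(gr)
}
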