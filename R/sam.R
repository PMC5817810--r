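#' SAM d-statistic
#'
#' Regularized difference-of-means statistic of Significance Analysis of
#' Microarrays: `d(i) = (mean_1(i) - mean_2(i)) / (s(i) + s0)` where `s(i)`
#' is the pooled standard error of the group-mean difference and `s0` a
#' fudge factor stabilising small variances. Group 1 is the first level of
#' `labels`.
#'
#' @param x expression matrix, features x samples.
#' @param labels two-level factor (or coercible) aligned with samples.
#' @param s0 fudge factor; `NULL` (default) uses the median of the
#'   per-feature pooled standard errors, a standard SAM convention.
#' @return list with `d`, `s` (pooled SE per feature), `s0`,
#'   `mean_diff`.
#' @export
sam_statistic <- function(x, labels, s0 = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly 2 levels")
  g1 <- labels == levels(labels)[1L]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  ss1 <- rowSums((x[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, g2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  if (is.null(s0)) s0 <- stats::median(s)
  d <- (m1 - m2) / (s + s0)
  d[s + s0 == 0] <- 0
  list(d = d, s = s, s0 = s0, mean_diff = m1 - m2)
}

# all distinct assignments of n1 labelled positions among n (as a matrix of
# index sets), used when exhaustive permutation is feasible
all_label_permutations <- function(n, n1) {
  utils::combn(n, n1)
}

#' Permutation false-discovery estimates for SAM
#'
#' Computes per-feature q-values from the permutation null of the SAM
#' d-statistic: labels are permuted, `d` is recomputed with the observed-data
#' fudge factor, and the q-value of a feature with score `|d_i|` is the
#' expected number of null features exceeding `|d_i|` divided by the number
#' of observed features exceeding it, capped at 1 and monotonized so that q
#' is non-increasing in `|d|`. When the label multiset admits no more than
#' `exhaustive_cap` distinct permutations (or fewer than `n_perm`), all of
#' them are enumerated instead of sampled.
#'
#' @inheritParams sam_statistic
#' @param n_perm permutations to draw (default 1000).
#' @param seed integer seed for sampled permutations.
#' @param exhaustive_cap enumerate exhaustively when the number of distinct
#'   label permutations is at most this (default 10000).
#' @return object of class `sam_result`: `d`, `q`, `s0`, `n_perm`
#'   (permutations actually used), `exhaustive` flag.
#' @export
sam_fdr <- function(x, labels, n_perm = 1000L, seed = 1L,
                    exhaustive_cap = 10000L) {
  labels <- as.factor(labels)
  obs <- sam_statistic(x, labels)
  n <- length(labels)
  n1 <- sum(labels == levels(labels)[1L])
  n_distinct <- choose(n, n1)
  exhaustive <- n_distinct <= exhaustive_cap || n_distinct <= n_perm

  perm_d <- if (exhaustive) {
    sets <- all_label_permutations(n, n1)
    vapply(seq_len(ncol(sets)), function(j) {
      lab <- factor(ifelse(seq_len(n) %in% sets[, j],
                           levels(labels)[1L], levels(labels)[2L]),
                    levels = levels(labels))
      sam_statistic(x, lab, s0 = obs$s0)$d
    }, numeric(nrow(x)))
  } else {
    set.seed(substream_seed(seed, 11L))
    vapply(seq_len(n_perm), function(j) {
      sam_statistic(x, sample(labels), s0 = obs$s0)$d
    }, numeric(nrow(x)))
  }
  if (exhaustive && n_distinct > exhaustive_cap)
    message("exhaustive enumeration of ", ncol(perm_d), " label permutations")
  perm_abs <- abs(as.numeric(perm_d))
  n_used <- ncol(perm_d)

  a <- abs(obs$d)
  ord <- order(a, decreasing = TRUE)
  r <- vapply(a[ord], function(t) sum(a >= t), integer(1))  # observed >= t
  efp <- vapply(a[ord], function(t) sum(perm_abs >= t) / n_used, numeric(1))
  q_sorted <- pmin(1, efp / r)
  q_sorted <- rev(cummin(rev(q_sorted)))   # non-increasing in |d|
  q <- numeric(length(a)); q[ord] <- q_sorted
  names(q) <- names(obs$d)
  structure(list(d = obs$d, q = q, s0 = obs$s0, n_perm = n_used,
                 exhaustive = exhaustive),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("SAM:", length(x$d), "features,", x$n_perm,
      if (x$exhaustive) "exhaustive" else "sampled", "permutations, s0 =",
      signif(x$s0, 4), "\n")
  cat("  features at q < 0.01:", sum(x$q < 0.01), "\n")
  invisible(x)
}
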