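#' Restrict two cohorts to their common features
#'
#' Cross-cohort classification requires both expression matrices on the same
#' feature set; only features present in both are retained, in sorted order.
#'
#' @param a,b expression matrices (features x samples).
#' @return list with elements `a` and `b`, both row-subset to the sorted
#'   intersection of feature ids.
#' @export
intersect_features <- function(a, b) {
  validate_expression(a); validate_expression(b)
  common <- sort(intersect(rownames(a), rownames(b)))
  if (!length(common)) stop("no features in common between the two matrices")
  list(a = a[common, , drop = FALSE], b = b[common, , drop = FALSE])
}

#' Remove batch effects with parametric empirical-Bayes adjustment
#'
#' Location/scale batch correction (ComBat): each feature is standardized,
#' per-batch shift and scale parameters are estimated and shrunk toward
#' across-feature priors, then removed. Wraps `sva::ComBat` without
#' covariates. A single-batch input is returned unchanged with a message.
#'
#' @param x expression matrix, features x samples.
#' @param batch batch label per sample (vector aligned with `colnames(x)`,
#'   or named by sample id).
#' @return adjusted matrix, same shape and dimnames.
#' @export
combat_adjust <- function(x, batch) {
  validate_expression(x)
  if (!is.null(names(batch))) {
    miss <- setdiff(colnames(x), names(batch))
    if (length(miss)) stop("no batch label for sample(s): ",
                           paste(miss, collapse = ", "))
    batch <- batch[colnames(x)]
  }
  if (length(batch) != ncol(x))
    stop("batch must assign exactly one label per sample")
  batch <- as.factor(batch)
  if (nlevels(batch) < 2L) {
    message("single batch: returning input unchanged")
    return(x)
  }
  small <- table(batch) < 2L
  if (any(small))
    stop("batch(es) with fewer than 2 samples: ",
         paste(names(which(small)), collapse = ", "))
  out <- sva::ComBat(dat = x, batch = batch, mod = NULL,
                     par.prior = TRUE, prior.plots = FALSE)
  dimnames(out) <- dimnames(x)
  out
}

row_mad <- function(x) {
  # raw median absolute deviation, no consistency constant: ranking only
  apply(x, 1L, function(v) stats::median(abs(v - stats::median(v))))
}

#' Select the most variable features by median absolute deviation
#'
#' Ranks features by raw MAD, `median(|x - median(x)|)`, and keeps the `n`
#' largest; ties are broken lexicographically by feature id so the selection
#' is deterministic. The returned matrix preserves the input row order.
#'
#' @param x expression matrix.
#' @param n number of features to keep (default 300, the conventional
#'   most-variable-miRNA cut for subtype discovery).
#' @return row-subset of `x`.
#' @export
select_top_mad <- function(x, n = 300L) {
  validate_expression(x)
  if (n < 1L) stop("n must be >= 1")
  if (n > nrow(x)) {
    warning("n (", n, ") exceeds feature count (", nrow(x),
            "); returning all features")
    return(x)
  }
  m <- row_mad(x)
  ord <- order(-m, rownames(x))
  keep <- rownames(x)[ord[seq_len(n)]]
  x[rownames(x) %in% keep, , drop = FALSE]
}

#' Center (and optionally scale) each feature across samples
#'
#' Row normalization ahead of correlation-based clustering or classification:
#' subtracts each feature's mean or median across samples; with
#' `scale = TRUE` also divides by the feature's standard deviation.
#' Zero-variance features are left unscaled with a message.
#'
#' @param x expression matrix.
#' @param method location statistic, `"mean"` or `"median"`.
#' @param scale divide by per-feature sd after centering.
#' @return transformed matrix.
#' @export
center_features <- function(x, method = c("mean", "median"), scale = FALSE) {
  validate_expression(x)
  method <- match.arg(method)
  loc <- if (method == "mean") rowMeans(x) else apply(x, 1L, stats::median)
  out <- x - loc
  if (scale) {
    if (ncol(x) < 2L) stop("scaling requires at least 2 samples")
    s <- apply(out, 1L, stats::sd)
    zero <- s == 0
    if (any(zero)) {
      message(sum(zero), " zero-variance feature(s) left unscaled")
      s[zero] <- 1
    }
    out <- out / s
  }
  out
}

#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Fold change of a target transcript relative to an endogenous reference,
#' normalized to a calibrator sample:
#' `2^-((ct_target - ct_reference) - (ct_target_calibrator - ct_reference_calibrator))`.
#'
#' @param ct_target,ct_reference Ct values in the sample of interest.
#' @param ct_target_calibrator,ct_reference_calibrator Ct values in the
#'   calibrator sample.
#' @return fold change (vectorized over inputs).
#' @export
ddct_fold_change <- function(ct_target, ct_reference,
                             ct_target_calibrator, ct_reference_calibrator) {
  ct <- cbind(ct_target, ct_reference, ct_target_calibrator,
              ct_reference_calibrator)
  if (any(!is.finite(ct))) stop("all Ct values must be finite")
  ddct <- (ct_target - ct_reference) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}
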