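#' Area under the ROC curve for one feature
#'
#' Mann-Whitney form: the probability that a positive-class sample scores
#' above a negative-class one, ties counted half,
#' `AUC = (#\{pos > neg\} + 0.5 #\{pos = neg\}) / (n_pos * n_neg)`.
#'
#' @param x numeric vector, one feature's values across samples.
#' @param positive logical (or two-level factor whose first level is taken
#'   as positive) marking the positive class.
#' @return AUC in `[0, 1]`.
#' @export
feature_auc <- function(x, positive) {
  if (is.factor(positive) || is.character(positive)) {
    f <- as.factor(positive)
    if (nlevels(f) != 2L) stop("positive must be binary")
    positive <- f == levels(f)[1L]
  }
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty")
  r <- rank(x)                       # midranks handle ties
  u <- sum(r[positive]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Select a subtype signature by SAM FDR and AUC filters
#'
#' One-vs-rest per subtype: a feature survives if, for at least one subtype
#' contrast, its permutation q-value is below `fdr_thr` and its separation
#' `max(AUC, 1 - AUC)` (subtype as positive class) exceeds `auc_thr`. The
#' symmetrized form makes the filter direction-agnostic, so markers
#' suppressed in a subtype (AUC near 0 in their own contrast) rank as
#' discriminative as induced ones. The union of survivors across subtypes,
#' sorted lexicographically, is the signature.
#'
#' @param x expression matrix, features x samples.
#' @param labels subtype assignment per sample (>= 2 subtypes).
#' @param fdr_thr SAM q-value threshold (default 0.01).
#' @param auc_thr AUC threshold, strict (default 0.9).
#' @param n_perm,seed passed to [sam_fdr()].
#' @return object of class `signature_selection`: `signature` (sorted
#'   feature ids), `per_class` (data.frame of feature, class, q, auc,
#'   survives).
#' @export
select_signature <- function(x, labels, fdr_thr = 0.01, auc_thr = 0.9,
                             n_perm = 1000L, seed = 1L) {
  labels <- as.factor(labels)
  if (!is.null(names(labels))) labels <- labels[colnames(x)]
  if (nlevels(labels) < 2L) stop("need at least 2 subtypes")
  per <- list()
  for (cl in levels(labels)) {
    ovr <- factor(ifelse(labels == cl, cl, "rest"), levels = c(cl, "rest"))
    sam <- sam_fdr(x, ovr, n_perm = n_perm, seed = seed)
    auc <- apply(x, 1L, feature_auc, positive = labels == cl)
    sep <- pmax(auc, 1 - auc)
    per[[cl]] <- data.frame(feature_id = rownames(x), class = cl,
                            q = as.numeric(sam$q), auc = as.numeric(auc),
                            separation = as.numeric(sep),
                            survives = sam$q < fdr_thr & sep > auc_thr,
                            stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  sig <- sort(unique(per$feature_id[per$survives]))
  if (!length(sig))
    stop("no feature passes FDR < ", fdr_thr, " and AUC > ", auc_thr,
         "; consider relaxing the thresholds")
  structure(list(signature = sig, per_class = per,
                 fdr_thr = fdr_thr, auc_thr = auc_thr),
            class = "signature_selection")
}

#' @export
print.signature_selection <- function(x, ...) {
  cat("signature:", length(x$signature), "features at q <", x$fdr_thr,
      "and AUC >", x$auc_thr, "\n  ",
      paste(x$signature, collapse = ", "), "\n")
  invisible(x)
}
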