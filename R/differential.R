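#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: sort p ascending, take `q(i) = min_{j >= i}
#' p(j) * m / j`, cap at 1 and restore input order. Delegates to
#' `stats::p.adjust(method = "BH")` after validating the input.
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Subtype-vs-rest differential expression
#'
#' Tests each feature for a mean difference between the subtype of interest
#' and the rest, on the (already log2) expression scale, so the group-mean
#' difference is the log2 fold change; sign convention is
#' subtype-of-interest minus rest. By default p-values come from limma's
#' empirical-Bayes moderated t (variances shrunk toward a common prior);
#' `moderated = FALSE` uses a per-feature Welch t instead. Significance
#' requires both `|logFC| > logfc_thr` and BH-adjusted `p < alpha`.
#'
#' @param x expression matrix, features x samples.
#' @param group logical (TRUE = subtype of interest) or two-level factor
#'   whose FIRST level is the subtype of interest, aligned with samples.
#' @param logfc_thr absolute log2 fold-change threshold (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param moderated use the moderated statistic (default TRUE).
#' @return data.frame of class `differential_result`: `feature_id`, `logFC`,
#'   `p`, `adj_p`, `significant`, ordered as the input features.
#' @export
differential_expression <- function(x, group, logfc_thr = 1, alpha = 0.05,
                                    moderated = TRUE) {
  validate_expression(x)
  if (is.factor(group) || is.character(group)) {
    f <- as.factor(group)
    if (nlevels(f) != 2L) stop("group must be binary")
    group <- f == levels(f)[1L]
  }
  if (length(group) != ncol(x)) stop("group must align with samples")
  n1 <- sum(group); n0 <- sum(!group)
  if (n1 < 3L || n0 < 3L) stop("each group needs at least 3 samples")

  if (moderated) {
    design <- cbind(rest = 1, interest = as.integer(group))
    fit <- limma::eBayes(limma::lmFit(x, design))
    logfc <- fit$coefficients[, "interest"]
    p <- fit$p.value[, "interest"]
  } else {
    m1 <- rowMeans(x[, group, drop = FALSE])
    m0 <- rowMeans(x[, !group, drop = FALSE])
    v1 <- apply(x[, group, drop = FALSE], 1L, stats::var)
    v0 <- apply(x[, !group, drop = FALSE], 1L, stats::var)
    se2 <- v1 / n1 + v0 / n0
    tstat <- (m1 - m0) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    logfc <- m1 - m0
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  adj <- bh_adjust(p)
  out <- data.frame(feature_id = rownames(x), logFC = as.numeric(logfc),
                    p = as.numeric(p), adj_p = as.numeric(adj),
                    significant = abs(logfc) > logfc_thr & adj < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("differential_result", class(out))
  out
}

#' Write a differential-expression table as TSV
#' @param de a `differential_result`.
#' @param path output file.
#' @export
write_differential <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(de)
}
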