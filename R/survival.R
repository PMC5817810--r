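#' Kaplan-Meier survival curve
#'
#' Product-limit estimator over the distinct event times, via
#' `survival::survfit`.
#'
#' @param time follow-up times, >= 0.
#' @param event event indicators, 0 = censored, 1 = event.
#' @return object of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_curve <- function(time, event) {
  check_surv_input(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event),
            class = "km_curve")
}

check_surv_input <- function(time, event) {
  if (!length(time)) stop("empty survival input")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(time < 0)) stop("times must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  bad <- time == 0 & event == 1
  if (any(bad))
    stop(sum(bad), " sample(s) with time = 0 and event = 1; ill-posed input")
  invisible(TRUE)
}

#' Evaluate a KM curve at arbitrary times
#' @param km a `km_curve`.
#' @param t times at which to evaluate S(t).
#' @return survival probabilities (S(t) = 1 before the first event time).
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (!length(i)) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Log-rank test for survival differences between groups
#'
#' Observed-minus-expected chi-square statistic summed over event times
#' (`survival::survdiff`, rho = 0); df = number of groups - 1.
#'
#' @param time,event as in [km_curve()].
#' @param group group label per subject, >= 2 groups.
#' @return list `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  check_surv_input(time, event)
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("log-rank test needs at least 2 groups")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  df <- nlevels(group) - 1L
  list(chisq = as.numeric(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the partial likelihood via `survival::coxph` (Newton-Raphson;
#' Efron tie correction by default, Breslow behind the flag for parity with
#' simpler hand computations). Constant covariates and clear monotone
#' likelihood (perfect separation) are rejected with the offending covariate
#' named.
#'
#' @param covariates numeric matrix or data.frame, samples x covariates,
#'   with column names.
#' @param time,event as in [km_curve()].
#' @param ties `"efron"` or `"breslow"`.
#' @return object of class `cox_model`: `features`, `coef`, `se`, `loglik`
#'   (at the optimum), `ties`, `cutoff` (NULL until set by
#'   [risk_stratify()]), `fit` (the underlying coxph object).
#' @export
cox_fit <- function(covariates, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_surv_input(time, event)
  if (sum(event) < 1L) stop("need at least one event")
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  if (any(!is.finite(covariates))) stop("covariates must be finite")
  const <- apply(covariates, 2L, function(v) stats::var(v) == 0)
  if (any(const))
    stop("constant covariate(s): ",
         paste(colnames(covariates)[const], collapse = ", "))
  df <- data.frame(covariates, check.names = FALSE)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ .,
                    data = df, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  bad <- !is.finite(beta) | !is.finite(se) | abs(beta) > 15 | se > 50
  if (any(bad))
    stop("monotone likelihood (perfect separation) for covariate(s): ",
         paste(names(beta)[bad], collapse = ", "))
  structure(list(features = colnames(covariates), coef = beta, se = se,
                 loglik = fit$loglik[length(fit$loglik)], ties = ties,
                 cutoff = NULL, fit = fit),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat("Cox model (", x$ties, "ties ):\n")
  print(data.frame(feature = x$features, coef = round(x$coef, 4),
                   se = round(x$se, 4), HR = round(exp(x$coef), 4)),
        row.names = FALSE)
  if (!is.null(x$cutoff)) cat("  risk cutoff:", signif(x$cutoff, 4), "\n")
  invisible(x)
}

#' Univariate Cox screen over expression features
#'
#' One single-covariate Cox fit per feature; per-feature failures are
#' reported as NA rows with a warning, never fatal.
#'
#' @param x expression matrix, features x samples (samples aligned with
#'   `time`/`event`).
#' @param time,event as in [km_curve()].
#' @param ties tie handling, as in [cox_fit()].
#' @return data.frame `feature_id`, `coef`, `HR`, `ci_lo`, `ci_hi`
#'   (Wald 95%), `p`.
#' @export
univariate_screen <- function(x, time, event, ties = "efron") {
  validate_expression(x)
  rows <- lapply(rownames(x), function(f) {
    fit <- try(cox_fit(matrix(x[f, ], ncol = 1,
                              dimnames = list(NULL, f)),
                       time, event, ties = ties), silent = TRUE)
    if (inherits(fit, "try-error"))
      return(data.frame(feature_id = f, coef = NA_real_, HR = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_))
    b <- fit$coef[1]; s <- fit$se[1]
    data.frame(feature_id = f, coef = b, HR = exp(b),
               ci_lo = exp(b - 1.96 * s), ci_hi = exp(b + 1.96 * s),
               p = 2 * stats::pnorm(-abs(b / s)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(is.na(out$coef)))
    warning(sum(is.na(out$coef)), " feature(s) failed the univariate fit")
  out
}

#' Stratify samples into high and low risk by the Cox linear predictor
#'
#' Scores each sample as `beta . x`, splits at the cutoff (the median score
#' when none is supplied, which is then stored in the returned model copy),
#' and quantifies the separation by a one-covariate Cox fit on the group
#' indicator (HR of high vs low with Wald 95% CI) plus a log-rank p.
#' Scores strictly above the cutoff are high risk; scores equal to the
#' cutoff go to the low-risk group.
#'
#' @param model a `cox_model` whose features are rows of `x`.
#' @param x expression matrix, features x samples.
#' @param time,event survival endpoint aligned with samples.
#' @param cutoff risk-score cutoff; default `model$cutoff`, falling back to
#'   the median of the scores computed here.
#' @return object of class `risk_stratification`: `samples` data.frame
#'   (`sample_id`, `score`, `group`), `cutoff`, `hr`, `ci_lo`, `ci_hi`,
#'   `logrank_p`, `model` (with cutoff filled in).
#' @export
risk_stratify <- function(model, x, time, event, cutoff = NULL) {
  stopifnot(inherits(model, "cox_model"))
  miss <- setdiff(model$features, rownames(x))
  if (length(miss))
    stop("model feature(s) absent from matrix: ", paste(miss, collapse = ", "))
  score <- as.numeric(crossprod(x[model$features, , drop = FALSE], model$coef))
  names(score) <- colnames(x)
  if (is.null(cutoff)) cutoff <- model$cutoff
  if (is.null(cutoff)) cutoff <- stats::median(score)
  group <- factor(ifelse(score > cutoff, "high", "low"),
                  levels = c("low", "high"))
  if (nlevels(droplevels(group)) < 2L)
    stop("all samples fall on one side of the cutoff (", signif(cutoff, 4), ")")
  gfit <- cox_fit(matrix(as.integer(group == "high"), ncol = 1,
                         dimnames = list(NULL, "high_risk")),
                  time, event)
  lr <- logrank_test(time, event, group)
  model$cutoff <- cutoff
  structure(list(samples = data.frame(sample_id = colnames(x), score = score,
                                      group = as.character(group),
                                      stringsAsFactors = FALSE),
                 cutoff = cutoff,
                 hr = exp(gfit$coef[1]),
                 ci_lo = exp(gfit$coef[1] - 1.96 * gfit$se[1]),
                 ci_hi = exp(gfit$coef[1] + 1.96 * gfit$se[1]),
                 logrank_p = lr$p, model = model),
            class = "risk_stratification")
}

#' @export
print.risk_stratification <- function(x, ...) {
  tab <- table(x$samples$group)
  cat(sprintf("risk stratification at cutoff %.4g: %d high / %d low\n",
              x$cutoff, tab[["high"]], tab[["low"]]))
  cat(sprintf("  HR (high vs low) %.3g (95%% CI %.3g-%.3g), log-rank p = %.3g\n",
              x$hr, x$ci_lo, x$ci_hi, x$logrank_p))
  invisible(x)
}

#' Evaluate a prognostic signature across cohorts
#'
#' Fits the multivariate Cox model for the signature on the training cohort,
#' freezes its coefficients and median-score cutoff, then scores every
#' validation cohort with the frozen model and reports HR, Wald CI and
#' log-rank p per cohort. A cohort missing any signature feature is skipped
#' with a warning. This is the harness for comparing competing signatures on
#' identical footing.
#'
#' @param signature character vector of feature ids.
#' @param train list with `expression`, `time`, `event`.
#' @param validation named list of cohorts shaped like `train`.
#' @param refit_cutoff if TRUE, each validation cohort is split at its own
#'   median score instead of the frozen training cutoff.
#' @param ties tie handling for the Cox fits.
#' @return object of class `signature_report`: `model` (`cox_model` with
#'   cutoff), `results` data.frame (`cohort`, `n`, `hr`, `ci_lo`, `ci_hi`,
#'   `logrank_p`, `cutoff`).
#' @export
evaluate_signature <- function(signature, train, validation = list(),
                               refit_cutoff = FALSE, ties = "efron") {
  miss <- setdiff(signature, rownames(train$expression))
  if (length(miss))
    stop("training cohort lacks signature feature(s): ",
         paste(miss, collapse = ", "))
  covar <- t(train$expression[signature, , drop = FALSE])
  model <- cox_fit(covar, train$time, train$event, ties = ties)
  strat <- risk_stratify(model, train$expression, train$time, train$event)
  model <- strat$model   # cutoff frozen at the training median

  one_row <- function(name, st, n) {
    data.frame(cohort = name, n = n, hr = st$hr, ci_lo = st$ci_lo,
               ci_hi = st$ci_hi, logrank_p = st$logrank_p,
               cutoff = st$cutoff, stringsAsFactors = FALSE)
  }
  res <- one_row("training", strat, ncol(train$expression))
  for (nm in names(validation)) {
    coh <- validation[[nm]]
    if (length(setdiff(signature, rownames(coh$expression)))) {
      warning("cohort '", nm, "' skipped: missing signature feature(s)")
      next
    }
    st <- try(risk_stratify(model, coh$expression, coh$time, coh$event,
                            cutoff = if (refit_cutoff) {
                              stats::median(as.numeric(crossprod(
                                coh$expression[signature, , drop = FALSE],
                                model$coef)))
                            } else NULL),
              silent = TRUE)
    if (inherits(st, "try-error")) {
      warning("cohort '", nm, "' skipped: ", attr(st, "condition")$message)
      next
    }
    res <- rbind(res, one_row(nm, st, ncol(coh$expression)))
  }
  rownames(res) <- NULL
  structure(list(model = model, results = res, signature = signature,
                 refit_cutoff = refit_cutoff),
            class = "signature_report")
}

#' @export
print.signature_report <- function(x, ...) {
  cat("signature [", paste(x$signature, collapse = ", "), "]\n")
  r <- x$results
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-10s n=%4d  HR %.3g (%.3g-%.3g)  log-rank p %.3g\n",
                r$cohort[i], r$n[i], r$hr[i], r$ci_lo[i], r$ci_hi[i],
                r$logrank_p[i]))
  invisible(x)
}
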