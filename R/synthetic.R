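#' Marker specification for a planted subtype
#'
#' Declares which features are dysregulated in one latent subtype and by how
#' much, as a signed mean shift on the log2 scale (negative = suppressed in
#' that subtype, emulating tumor-suppressor miRNA loss).
#'
#' @param subtype subtype label.
#' @param features character vector of marker feature ids.
#' @param effect signed log2 mean shift, scalar or one per feature.
#' @return object of class `marker_spec`.
#' @export
marker_spec <- function(subtype, features, effect) {
  if (!length(features)) stop("marker_spec needs at least one feature")
  if (any(!is.finite(effect)) || any(effect == 0))
    stop("marker effects must be finite and nonzero")
  effect <- rep_len(effect, length(features))
  structure(list(subtype = as.character(subtype),
                 features = as.character(features),
                 effect = as.numeric(effect)),
            class = "marker_spec")
}

#' Survival specification for synthetic cohorts
#'
#' Proportional-hazards event-time generator: times are drawn from an
#' exponential (default) or Weibull baseline with rate
#' `baseline_rate * exp(linear predictor)`, then administratively censored at
#' `censor_time`.
#'
#' @param baseline_rate events per unit time, > 0.
#' @param beta named log-hazard coefficients (per covariate) or a single
#'   coefficient when hazards are driven by one score.
#' @param censor_time administrative censoring horizon (same units as the
#'   generated times; `Inf` disables censoring).
#' @param time_unit unit label, informational only.
#' @param shape Weibull shape; 1 (default) gives the exponential model.
#' @return object of class `survival_spec`.
#' @export
survival_spec <- function(baseline_rate, beta = 0, censor_time = Inf,
                          time_unit = "months", shape = 1) {
  if (!is.finite(baseline_rate) || baseline_rate <= 0)
    stop("baseline_rate must be > 0")
  if (censor_time < 0) stop("censor_time must be >= 0")
  if (shape <= 0) stop("shape must be > 0")
  structure(list(baseline_rate = baseline_rate, beta = beta,
                 censor_time = censor_time, time_unit = time_unit,
                 shape = shape),
            class = "survival_spec")
}

# deterministic per-stage RNG sub-stream derived from one global seed, so
# each stage of a cohort is independently reproducible
substream_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 15485863 * stage) %% 2147483647)
}

#' Simulate a subtype-structured expression matrix
#'
#' Each sample's profile is a per-feature global baseline, plus its subtype's
#' marker shifts, plus an optional per-batch per-feature additive shift, plus
#' Gaussian residual noise (optionally variance-scaled per batch). All on the
#' log2 scale. With `noise_sd = 0` every sample equals its subtype template
#' exactly, which makes separability tests exact.
#'
#' @param n_samples number of samples.
#' @param n_features number of features; ids are `mir0001`, `mir0002`, ...
#'   unless markers introduce their own ids within that universe.
#' @param subtype_proportions named numeric vector summing to 1.
#' @param markers list of [marker_spec()]; marker feature sets must be
#'   disjoint and lie inside the feature universe.
#' @param noise_sd residual standard deviation (log2 units).
#' @param batch optional list: `n_batches`, `shift_sd` (sd of the additive
#'   per-batch per-feature shift) and `scale` (per-batch noise sd
#'   multipliers, length `n_batches`).
#' @param baseline_mean,baseline_sd distribution of the per-feature global
#'   baseline (log2 abundance).
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param baseline_seed seed of the per-feature baseline substream; defaults
#'   to `seed`. Pass one value to several cohorts to give them a shared
#'   abundance profile, as real cohorts measured on one platform have.
#' @return list of class `synthetic_cohort` with `expression`, `labels`
#'   (named factor), `markers`, `batch` (named factor or NULL), `seed`.
#' @export
simulate_expression <- function(n_samples, n_features, subtype_proportions,
                                markers = list(), noise_sd = 1, batch = NULL,
                                baseline_mean = 7, baseline_sd = 1.5, seed = 1L,
                                baseline_seed = seed) {
  if (abs(sum(subtype_proportions) - 1) > 1e-9)
    stop("subtype_proportions must sum to 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(names(subtype_proportions)))
    names(subtype_proportions) <- paste0("S", seq_along(subtype_proportions))
  features <- sprintf("mir%04d", seq_len(n_features))
  marker_ids <- unlist(lapply(markers, `[[`, "features"))
  if (anyDuplicated(marker_ids))
    stop("marker feature sets must be disjoint across subtypes")
  bad <- setdiff(marker_ids, features)
  if (length(bad))
    stop("marker feature(s) outside the feature universe: ",
         paste(bad, collapse = ", "))
  samples <- sprintf("samp%04d", seq_len(n_samples))

  # fixed label layout: largest-remainder rounding of the proportions
  counts <- floor(subtype_proportions * n_samples)
  rem <- n_samples - sum(counts)
  if (rem > 0) {
    extra <- order(subtype_proportions * n_samples - counts, decreasing = TRUE)
    counts[extra[seq_len(rem)]] <- counts[extra[seq_len(rem)]] + 1
  }
  labels <- factor(rep(names(subtype_proportions), counts),
                   levels = names(subtype_proportions))
  names(labels) <- samples

  set.seed(substream_seed(baseline_seed, 1L))
  baseline <- stats::rnorm(n_features, baseline_mean, baseline_sd)

  template <- matrix(baseline, n_features, nlevels(labels),
                     dimnames = list(features, levels(labels)))
  for (m in markers) {
    if (!m$subtype %in% levels(labels))
      stop("marker subtype '", m$subtype, "' not among the cohort subtypes")
    template[m$features, m$subtype] <-
      template[m$features, m$subtype] + m$effect
  }

  batch_assign <- NULL
  batch_shift <- 0
  noise_scale <- rep(1, n_samples)
  if (!is.null(batch)) {
    nb <- batch$n_batches
    set.seed(substream_seed(seed, 2L))
    batch_assign <- factor(sample(paste0("B", seq_len(nb)), n_samples,
                                  replace = TRUE))
    names(batch_assign) <- samples
    shift_sd <- if (is.null(batch$shift_sd)) 0 else batch$shift_sd
    gamma <- matrix(stats::rnorm(n_features * nb, 0, shift_sd), n_features, nb)
    batch_shift <- gamma[, as.integer(batch_assign), drop = FALSE]
    if (!is.null(batch$scale))
      noise_scale <- rep_len(batch$scale, nb)[as.integer(batch_assign)]
  }

  set.seed(substream_seed(seed, 3L))
  noise <- matrix(stats::rnorm(n_features * n_samples, 0, noise_sd),
                  n_features, n_samples)
  noise <- sweep(noise, 2L, noise_scale, `*`)

  expr <- template[, as.integer(labels), drop = FALSE] + batch_shift + noise
  dimnames(expr) <- list(features, samples)
  structure(list(expression = expr, labels = labels, markers = markers,
                 batch = batch_assign, seed = seed),
            class = "synthetic_cohort")
}

#' Simulate proportional-hazards survival times
#'
#' Event times follow a Weibull (exponential when `shape = 1`) hazard scaled
#' by `exp(linear predictor)`; draws exceeding the administrative horizon are
#' censored at the horizon (`event = 0`).
#'
#' @param x per-sample covariates: a named numeric vector/matrix (samples x
#'   covariates) multiplied by `spec$beta`, or a factor of group labels whose
#'   non-reference levels get one coefficient each.
#' @param spec a [survival_spec()].
#' @param seed integer seed.
#' @param extra_censor_rate optional rate of an additional independent
#'   exponential censoring process (0 disables it).
#' @return data.frame with `sample_id`, `time`, `event`.
#' @export
simulate_survival <- function(x, spec, seed = 1L, extra_censor_rate = 0) {
  stopifnot(inherits(spec, "survival_spec"))
  if (is.factor(x) || is.character(x)) {
    f <- as.factor(x)
    mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
    x <- mm
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L, dimnames = list(names(x), NULL))
  beta <- rep_len(spec$beta, ncol(x))
  lp <- as.numeric(x %*% beta)
  n <- length(lp)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("samp%04d", seq_len(n))

  set.seed(substream_seed(seed, 4L))
  u <- stats::rexp(n, rate = 1)
  t_event <- (u / (spec$baseline_rate * exp(lp)))^(1 / spec$shape)
  t_cens <- rep(spec$censor_time, n)
  if (extra_censor_rate > 0) {
    set.seed(substream_seed(seed, 5L))
    t_cens <- pmin(t_cens, stats::rexp(n, rate = extra_censor_rate))
  }
  event <- as.integer(t_event <= t_cens)
  time <- pmin(t_event, t_cens)
  data.frame(sample_id = ids, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Simulate a full cohort: expression, labels and survival
#'
#' Convenience wrapper joining [simulate_expression()] and
#' [simulate_survival()]. Hazards can depend on subtype membership
#' (`hazard_by = "subtype"`, one log-hazard per non-reference subtype) or on
#' a linear score over a set of marker features
#' (`hazard_by = "score"`).
#'
#' @inheritParams simulate_expression
#' @param spec a [survival_spec()].
#' @param hazard_by `"subtype"` or `"score"`.
#' @param score_features,score_weights features and weights defining the
#'   prognostic score when `hazard_by = "score"`; the score is centered
#'   across the cohort before entering the hazard, so `baseline_rate` keeps
#'   its meaning as the typical sample's event rate.
#' @param endpoint endpoint label written into the clinical table.
#' @return `synthetic_cohort` with an added `clinical` data.frame
#'   (`sample_id`, `time`, `event`, `endpoint`, `batch` if present) and
#'   `truth_beta = spec`.
#' @export
simulate_cohort <- function(n_samples, n_features, subtype_proportions,
                            markers = list(), noise_sd = 1, batch = NULL,
                            spec = survival_spec(0.02, beta = 0),
                            hazard_by = c("subtype", "score"),
                            score_features = NULL, score_weights = 1,
                            endpoint = "DMFS", seed = 1L, ...) {
  hazard_by <- match.arg(hazard_by)
  coh <- simulate_expression(n_samples, n_features, subtype_proportions,
                             markers = markers, noise_sd = noise_sd,
                             batch = batch, seed = seed, ...)
  x <- if (hazard_by == "subtype") {
    coh$labels
  } else {
    if (is.null(score_features)) stop("score_features required for hazard_by='score'")
    sc <- as.numeric(crossprod(coh$expression[score_features, , drop = FALSE],
                               rep_len(score_weights, length(score_features))))
    # centered so baseline_rate stays the typical-sample event rate
    sc <- sc - mean(sc)
    names(sc) <- colnames(coh$expression)
    sc
  }
  surv <- simulate_survival(x, spec, seed = seed)
  surv$sample_id <- colnames(coh$expression)
  clin <- data.frame(sample_id = surv$sample_id, time = surv$time,
                     event = surv$event, endpoint = endpoint,
                     stringsAsFactors = FALSE)
  if (!is.null(coh$batch)) clin$batch <- as.character(coh$batch[clin$sample_id])
  coh$clinical <- clin
  coh$truth_beta <- spec
  coh
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic cohort:", ncol(x$expression), "samples x",
      nrow(x$expression), "features;",
      nlevels(x$labels), "subtypes (", paste(levels(x$labels), collapse = ", "),
      ")\n")
  if (!is.null(x$clinical))
    cat("  clinical:", sum(x$clinical$event), "events /",
        nrow(x$clinical), "samples (", x$clinical$endpoint[1], ")\n")
  invisible(x)
}
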