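#' Pipeline configuration
#'
#' Bundles every tunable stage parameter with the defaults used throughout:
#' 300 most-variable features, consensus clustering with 1000 iterations at
#' 0.9 subsampling over k = 2..6, SAM FDR < 0.01 with AUC > 0.9 for the
#' signature, |log2FC| > 1 with BH-adjusted p < 0.05 for the differential
#' screen, mean centering, Efron ties.
#'
#' @param n_top_mad features kept by MAD ranking.
#' @param k_range candidate cluster counts.
#' @param n_iter,subsample consensus iterations and subsampling fraction.
#' @param n_refs gap-statistic reference sets.
#' @param fdr_thr,auc_thr signature-selection thresholds.
#' @param n_perm SAM permutations.
#' @param logfc_thr,alpha differential-expression thresholds.
#' @param centering `"mean"` or `"median"`.
#' @param ties Cox tie handling.
#' @param endpoint survival endpoint selector (OS, DFS or DMFS).
#' @param seed integer seed driving every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_top_mad = 300L, k_range = 2:6, n_iter = 1000L,
                            subsample = 0.9, n_refs = 50L, fdr_thr = 0.01,
                            auc_thr = 0.9, n_perm = 1000L, logfc_thr = 1,
                            alpha = 0.05, centering = "mean", ties = "efron",
                            endpoint = "DMFS", seed = 1L) {
  cfg <- list(n_top_mad = as.integer(n_top_mad), k_range = as.integer(k_range),
              n_iter = as.integer(n_iter), subsample = subsample,
              n_refs = as.integer(n_refs), fdr_thr = fdr_thr,
              auc_thr = auc_thr, n_perm = as.integer(n_perm),
              logfc_thr = logfc_thr, alpha = alpha,
              centering = match.arg(centering, c("mean", "median")),
              ties = match.arg(ties, c("efron", "breslow")),
              endpoint = match.arg(endpoint, c("DMFS", "DFS", "OS")),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

manifest_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2)
  unname(tools::md5sum(f))
}

#' Discover subtypes and train the classifier
#'
#' Runs the discovery arm end to end: MAD feature selection, row
#' normalization (mean centering; variance is deliberately left unscaled so
#' high-MAD marker features keep their weight), consensus clustering at
#' the gap-selected k, silhouette filtering to the coherent core, SAM + AUC
#' signature selection on the core samples, and SVM training. Returns every
#' intermediate artifact plus a manifest (effective config, seed, input
#' hash) sufficient to reproduce the run.
#'
#' @param x expression matrix, features x samples (log2 scale).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, labels, consensus matrix,
#'   gap curve, silhouette report, model JSON and manifest JSON are written
#'   there.
#' @return list of class `discovery_run`: `chosen_k`, `gap`, `consensus`,
#'   `silhouette`, `core_samples`, `labels` (full cohort, named), `signature`,
#'   `model`, `manifest`.
#' @export
run_discovery <- function(x, config = pipeline_config(), out_dir = NULL) {
  validate_expression(x)
  xm <- select_top_mad(x, config$n_top_mad)
  xn <- center_features(xm, method = "mean")

  gap <- gap_statistic(xn, k_range = config$k_range, n_refs = config$n_refs,
                       seed = config$seed)
  if (length(config$k_range) == 1L)
    warning("k_range has a single value; chosen_k = ", gap$chosen_k,
            " by default")
  cons <- consensus_cluster(xn, k = gap$chosen_k, n_iter = config$n_iter,
                            subsample_fraction = config$subsample,
                            seed = config$seed)
  sil <- silhouette_widths(1 - cons$consensus, cons$labels)
  core <- filter_positive_silhouette(sil)
  core_labels <- cons$labels[core]

  sig <- select_signature(xn[, core, drop = FALSE],
                          paste0("NPC", core_labels),
                          fdr_thr = config$fdr_thr, auc_thr = config$auc_thr,
                          n_perm = config$n_perm, seed = config$seed)
  model <- train_subtype_classifier(x[, core, drop = FALSE],
                                    paste0("NPC", core_labels),
                                    signature = sig$signature,
                                    centering = config$centering)
  full_labels <- classify_cohort(model, x)
  labels <- stats::setNames(full_labels$subtype, full_labels$sample_id)

  manifest <- list(stage = "discovery",
                   config = unclass(config),
                   input_hash = manifest_hash(x),
                   n_samples = ncol(x), n_features = nrow(x),
                   chosen_k = gap$chosen_k,
                   n_core = length(core),
                   mean_silhouette = sil$overall_mean,
                   signature = sig$signature,
                   centering = config$centering, ties = config$ties,
                   r_version = as.character(getRversion()))
  run <- structure(list(chosen_k = gap$chosen_k, gap = gap, consensus = cons,
                        silhouette = sil, core_samples = core,
                        labels = labels, signature = sig, model = model,
                        manifest = manifest),
                   class = "discovery_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_consensus(cons, file.path(out_dir, "consensus.tsv"),
                    file.path(out_dir, "clusters.tsv"))
    write_gap(gap, file.path(out_dir, "gap.tsv"))
    write_silhouette(sil, file.path(out_dir, "silhouette.tsv"))
    write_subtype_model(model, file.path(out_dir, "model.json"))
    utils::write.table(
      data.frame(sample_id = names(labels), subtype = labels),
      file.path(out_dir, "labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

#' Classify a cohort with a frozen model
#'
#' Thin orchestration over [classify_cohort()] that optionally writes the
#' label/margin table as TSV.
#'
#' @param model a `subtype_model` or path to a model JSON.
#' @param x expression matrix.
#' @param centering optional centering override.
#' @param out_path optional TSV output path.
#' @return the prediction data.frame from [classify_cohort()].
#' @export
run_classify <- function(model, x, centering = NULL, out_path = NULL) {
  if (is.character(model)) model <- read_subtype_model(model)
  pred <- classify_cohort(model, x, centering = centering)
  if (!is.null(out_path))
    utils::write.table(pred, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  pred
}

#' Build and evaluate the metastasis-risk model
#'
#' The risk arm: differential expression of the designated risk subtype
#' versus the rest, univariate Cox screening of the significant features,
#' a multivariate Cox model on the univariate survivors (Wald p < 0.05),
#' median risk-score stratification with log-rank assessment, and an
#' optional comparison of competing signatures on the same cohorts.
#'
#' @param x expression matrix, features x samples.
#' @param clinical clinical data.frame (see [read_clinical()]); rows are
#'   matched to samples by `sample_id` and filtered to `config$endpoint`.
#' @param labels named subtype assignment covering the samples.
#' @param risk_class label of the subtype whose contrast defines the
#'   differential screen (the poor-prognosis subtype).
#' @param config a [pipeline_config()].
#' @param signatures optional named list of competing signatures (character
#'   vectors) evaluated with [evaluate_signature()] on the same cohort.
#' @param validation optional named list of validation cohorts, each a list
#'   with `expression` and `clinical`.
#' @return list of class `risk_run`: `differential`, `screen`
#'   (univariate table of significant features), `selected` (features in the
#'   model), `model`, `stratification`, `comparison` (signature reports,
#'   possibly empty), `manifest`.
#' @export
run_risk_model <- function(x, clinical, labels, risk_class,
                           config = pipeline_config(), signatures = list(),
                           validation = list()) {
  validate_expression(x)
  validate_clinical(clinical)
  clin <- clinical[clinical$endpoint == config$endpoint, , drop = FALSE]
  if (!nrow(clin)) stop("no clinical rows for endpoint ", config$endpoint)
  common <- intersect(colnames(x), clin$sample_id)
  if (!length(common)) stop("no samples shared by expression and clinical")
  x <- x[, common, drop = FALSE]
  clin <- clin[match(common, clin$sample_id), , drop = FALSE]
  labels <- labels[common]
  if (any(is.na(labels))) stop("labels do not cover the cohort")
  if (!risk_class %in% labels)
    stop("risk_class '", risk_class, "' not present in labels")

  de <- differential_expression(x, labels == risk_class,
                                logfc_thr = config$logfc_thr,
                                alpha = config$alpha)
  de_sig <- de$feature_id[de$significant]
  if (!length(de_sig))
    stop("risk-model stage failed: no differentially expressed feature")
  screen <- univariate_screen(x[de_sig, , drop = FALSE],
                              clin$time, clin$event, ties = config$ties)
  selected <- screen$feature_id[!is.na(screen$p) & screen$p < 0.05]
  if (!length(selected))
    stop("risk-model stage failed: no feature passes the univariate screen",
         " (p < 0.05)")
  model <- cox_fit(t(x[selected, , drop = FALSE]), clin$time, clin$event,
                   ties = config$ties)
  strat <- risk_stratify(model, x, clin$time, clin$event)

  comparison <- list()
  if (length(signatures)) {
    train <- list(expression = x, time = clin$time, event = clin$event)
    vals <- lapply(validation, function(v) {
      vc <- v$clinical[v$clinical$endpoint == config$endpoint, , drop = FALSE]
      com <- intersect(colnames(v$expression), vc$sample_id)
      vc <- vc[match(com, vc$sample_id), , drop = FALSE]
      list(expression = v$expression[, com, drop = FALSE],
           time = vc$time, event = vc$event)
    })
    comparison <- lapply(signatures, function(s) {
      tryCatch(evaluate_signature(s, train, vals, ties = config$ties),
               error = function(e) {
                 warning("signature skipped: ", conditionMessage(e))
                 NULL
               })
    })
  }
  manifest <- list(stage = "risk",
                   config = unclass(config),
                   input_hash = manifest_hash(list(x, clin, labels)),
                   n_samples = ncol(x), endpoint = config$endpoint,
                   risk_class = risk_class,
                   n_differential = length(de_sig),
                   selected = selected,
                   cutoff = strat$cutoff,
                   centering = config$centering, ties = config$ties)
  structure(list(differential = de, screen = screen, selected = selected,
                 model = strat$model, stratification = strat,
                 comparison = comparison, manifest = manifest),
            class = "risk_run")
}
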