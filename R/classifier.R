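#' Train the subtype classifier on a signature
#'
#' Fits a support vector machine (linear kernel, cost 1, libsvm's
#' one-vs-one multiclass voting via `e1071::svm`) on the signature features.
#' The training matrix is centered per feature across the training samples
#' with the chosen statistic before fitting; new cohorts are centered across
#' their own samples at prediction time, which makes subtype calls invariant
#' to global additive shifts between cohorts.
#'
#' @param x expression matrix restricted to (or containing) the signature
#'   features, features x samples.
#' @param labels subtype assignment per training sample.
#' @param signature feature ids to use; defaults to all rows of `x`.
#' @param centering `"mean"` or `"median"` per-feature centering scheme,
#'   stored in the model and reused at prediction time.
#' @param cost SVM cost parameter.
#' @param kernel SVM kernel (linear by default; 10 features / ~80 samples
#'   favor a linear margin).
#' @return object of class `subtype_model`: `signature`, `centering`,
#'   `classes`, `cost`, `kernel`, `svm` (fitted e1071 model), `training`
#'   (centered matrix + labels kept for exact re-training on
#'   deserialization).
#' @export
train_subtype_classifier <- function(x, labels, signature = rownames(x),
                                     centering = c("mean", "median"),
                                     cost = 1, kernel = "linear") {
  centering <- match.arg(centering)
  labels <- as.factor(labels)
  if (!is.null(names(labels))) labels <- labels[colnames(x)]
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (any(table(labels) < 2L)) stop("each class needs at least 2 samples")
  miss <- setdiff(signature, rownames(x))
  if (length(miss))
    stop("signature feature(s) missing from training matrix: ",
         paste(miss, collapse = ", "))
  xs <- center_features(x[signature, , drop = FALSE], method = centering)
  fit <- e1071::svm(x = t(xs), y = labels, kernel = kernel, cost = cost,
                    scale = FALSE, probability = FALSE)
  structure(list(signature = signature, centering = centering,
                 classes = levels(labels), cost = cost, kernel = kernel,
                 svm = fit,
                 training = list(x = xs, labels = labels)),
            class = "subtype_model")
}

#' Classify a new cohort with a trained subtype model
#'
#' Restricts the cohort to the model's signature, centers each feature
#' across the cohort's own samples with the model's (or an overriding)
#' centering statistic, and scores with the trained SVM. Missing signature
#' features are a hard error; there is no silent imputation.
#'
#' @param model a `subtype_model`.
#' @param x_new expression matrix, features x samples.
#' @param centering optional override of the model's centering scheme.
#' @return data.frame `sample_id`, `subtype`, plus one decision-value
#'   column per binary class pair.
#' @export
classify_cohort <- function(model, x_new, centering = NULL) {
  stopifnot(inherits(model, "subtype_model"))
  if (ncol(x_new) == 0L) stop("empty cohort")
  miss <- setdiff(model$signature, rownames(x_new))
  if (length(miss))
    stop("signature feature(s) absent from cohort: ",
         paste(miss, collapse = ", "))
  ctr <- if (is.null(centering)) model$centering else
    match.arg(centering, c("mean", "median"))
  xs <- center_features(x_new[model$signature, , drop = FALSE], method = ctr)
  pred <- stats::predict(model$svm, t(xs), decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  out <- data.frame(sample_id = colnames(x_new),
                    subtype = as.character(pred),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(dv, check.names = FALSE))
}

#' Serialize / restore a subtype model as JSON
#'
#' The decision function is fully determined by the centered training matrix
#' plus hyperparameters, and SVM training is deterministic, so the JSON
#' stores those and `read_subtype_model` re-trains. Subtype calls are
#' reproduced exactly; decision margins agree to the decimal precision of
#' the JSON text. The file stays plain text.
#'
#' @param model a `subtype_model`.
#' @param path JSON file.
#' @export
write_subtype_model <- function(model, path) {
  stopifnot(inherits(model, "subtype_model"))
  obj <- list(signature = model$signature, centering = model$centering,
              classes = model$classes, cost = model$cost,
              kernel = model$kernel,
              training_samples = colnames(model$training$x),
              training_labels = as.character(model$training$labels),
              training_matrix = unname(model$training$x))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_subtype_model
#' @export
read_subtype_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- obj$training_matrix
  dimnames(x) <- list(obj$signature, obj$training_samples)
  labels <- factor(obj$training_labels, levels = obj$classes)
  fit <- e1071::svm(x = t(x), y = labels, kernel = obj$kernel,
                    cost = obj$cost, scale = FALSE, probability = FALSE)
  structure(list(signature = obj$signature, centering = obj$centering,
                 classes = obj$classes, cost = obj$cost, kernel = obj$kernel,
                 svm = fit, training = list(x = x, labels = labels)),
            class = "subtype_model")
}

#' @export
print.subtype_model <- function(x, ...) {
  cat("subtype classifier:", x$kernel, "SVM (cost", x$cost, ") on",
      length(x$signature), "features;", length(x$classes), "classes:",
      paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}
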