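test_that("AUC follows the Mann-Whitney pair count, including ties", {
  expect_equal(feature_auc(c(1, 2, 2, 3), c(FALSE, FALSE, TRUE, TRUE)),
               (3 + 0.5) / 4)
  # perfectly separated groups
  expect_equal(feature_auc(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE)), 1)
  # label swap complements
  x <- c(0.3, 1.2, 0.8, 2.0, 1.1)
  pos <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  expect_equal(feature_auc(x, pos), 1 - feature_auc(x, !pos))
  expect_error(feature_auc(1:4, rep(TRUE, 4)), "non-empty")
})

test_that("AUC equals exhaustive pair enumeration on random small inputs", {
  for (s in 1:20) {
    set.seed(900 + s)
    n <- sample(4:12, 1)
    x <- sample(1:6, n, replace = TRUE) + round(rnorm(n), 1)
    pos <- rep(FALSE, n)
    pos[sample(n, sample(seq_len(n - 1), 1))] <- TRUE
    if (!any(pos) || all(pos)) next
    expect_equal(feature_auc(x, pos), oracle_auc(x, pos))
  }
})

test_that("signature selection recovers exactly the planted markers", {
  coh <- planted_cohort3(seed = 31)
  sel <- select_signature(coh$expression, coh$labels, n_perm = 300, seed = 1)
  planted <- sort(unlist(lapply(coh$markers, `[[`, "features")))
  expect_equal(sel$signature, planted)
})

test_that("signature selection is monotone in its thresholds", {
  coh <- planted_cohort3(n = 45, nf = 80, seed = 32)
  loose <- select_signature(coh$expression, coh$labels, fdr_thr = 0.05,
                            auc_thr = 0.8, n_perm = 200, seed = 2)
  tight <- select_signature(coh$expression, coh$labels, fdr_thr = 0.01,
                            auc_thr = 0.9, n_perm = 200, seed = 2)
  expect_true(all(tight$signature %in% loose$signature))
  expect_error(select_signature(coh$expression, coh$labels, fdr_thr = 0,
                                auc_thr = 1.01, n_perm = 50, seed = 2),
               "relaxing")
})

test_that("the classifier is exact on noiseless separable cohorts", {
  mk <- list(marker_spec("A", sprintf("mir%04d", 1:3), 2),
             marker_spec("B", sprintf("mir%04d", 4:6), 2),
             marker_spec("C", sprintf("mir%04d", 7:9), 2))
  coh <- simulate_expression(30, 20, c(A = 1/3, B = 1/3, C = 1/3),
                             markers = mk, noise_sd = 0, seed = 33)
  model <- train_subtype_classifier(coh$expression, coh$labels,
                                    signature = sprintf("mir%04d", 1:9))
  pred <- classify_cohort(model, coh$expression)
  expect_equal(pred$subtype, as.character(coh$labels))
})

test_that("training is deterministic and held-out accuracy is high", {
  tr <- planted_cohort3(n = 150, seed = 34)
  te <- planted_cohort3(n = 150, seed = 35)
  sig <- sprintf("mir%04d", 1:30)
  m1 <- train_subtype_classifier(tr$expression, paste0("C", tr$labels),
                                 signature = sig)
  m2 <- train_subtype_classifier(tr$expression, paste0("C", tr$labels),
                                 signature = sig)
  p1 <- classify_cohort(m1, te$expression)
  p2 <- classify_cohort(m2, te$expression)
  expect_identical(p1, p2)
  acc <- mean(p1$subtype == paste0("C", te$labels))
  expect_gte(acc, 0.95)
  # noise level doubled relative to training still classifies well: the
  # planted effect is 2 with sd 1 in this check
  te2 <- planted_cohort3(n = 150, noise = 1, seed = 36)
  acc2 <- mean(classify_cohort(m1, te2$expression)$subtype ==
                 paste0("C", te2$labels))
  expect_gte(acc2, 0.95)
})

test_that("predictions are invariant to global shifts and sample order", {
  tr <- planted_cohort3(n = 60, nf = 60, seed = 37)
  model <- train_subtype_classifier(tr$expression, tr$labels,
                                    signature = sprintf("mir%04d", 1:30))
  te <- planted_cohort3(n = 40, nf = 60, seed = 38)$expression
  base <- classify_cohort(model, te)
  shifted <- classify_cohort(model, te + 5)
  expect_equal(shifted$subtype, base$subtype)
  perm <- sample(ncol(te))
  reord <- classify_cohort(model, te[, perm])
  expect_equal(reord$subtype, base$subtype[perm])
})

test_that("missing signature features are a hard error", {
  tr <- planted_cohort3(n = 45, nf = 40, seed = 39)
  model <- train_subtype_classifier(tr$expression, tr$labels,
                                    signature = sprintf("mir%04d", 1:10))
  te <- tr$expression[-1, ]
  expect_error(classify_cohort(model, te), "mir0001")
  expect_error(train_subtype_classifier(tr$expression, tr$labels,
                                        signature = c("mir0001", "nope")),
               "nope")
  expect_error(classify_cohort(model, tr$expression[, 0]), "empty cohort")
})

test_that("model JSON round-trips to identical predictions", {
  tr <- planted_cohort3(n = 45, nf = 40, seed = 40)
  model <- train_subtype_classifier(tr$expression, tr$labels,
                                    signature = sprintf("mir%04d", 1:10),
                                    centering = "median")
  f <- withr::local_tempfile(fileext = ".json")
  write_subtype_model(model, f)
  back <- read_subtype_model(f)
  expect_equal(back$signature, model$signature)
  expect_equal(back$centering, "median")
  te <- planted_cohort3(n = 30, nf = 40, seed = 41)$expression
  p_model <- classify_cohort(model, te)
  p_back <- classify_cohort(back, te)
  expect_identical(p_back$subtype, p_model$subtype)
  # margins agree to the JSON text precision of the training matrix
  expect_equal(p_back[, -(1:2)], p_model[, -(1:2)], tolerance = 1e-8)
})
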