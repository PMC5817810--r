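test_that("the KM estimator matches the hand product-limit toy", {
  km <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_surv_at(km, 1), 2 / 3)
  expect_equal(km_surv_at(km, 2.5), 2 / 3)   # censoring does not drop S
  expect_equal(km_surv_at(km, 3), 0)
  expect_equal(km_surv_at(km, 0.5), 1)
})

test_that("without censoring KM equals the empirical survivor fraction", {
  set.seed(80)
  t <- round(rexp(60, 0.1), 1) + 0.1
  km <- km_curve(t, rep(1, 60))
  o <- oracle_km(t, rep(1, 60))
  expect_equal(km$time, o$time)
  expect_equal(km$surv, o$surv)
  for (tt in c(2, 5, 10))
    expect_equal(km_surv_at(km, tt), mean(t > tt))
})

test_that("all-censored input keeps S at 1 and bad input errors", {
  km <- km_curve(c(2, 5, 9), c(0, 0, 0))
  expect_equal(km_surv_at(km, 100), 1)
  expect_error(km_curve(numeric(0), numeric(0)), "empty")
  expect_error(km_curve(c(0, 1), c(1, 1)), "time = 0")
  expect_error(km_curve(c(-1, 1), c(0, 1)), "non-negative")
  expect_error(km_curve(c(1, 2), c(1, 2)), "0/1")
})

test_that("the log-rank statistic matches the brute-force O-E table", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  group <- c("a", "b", "a", "b", "a", "b")
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chisq, oracle_logrank(time, event, group), tolerance = 1e-9)
  expect_equal(lr$df, 1)
  # null case: two identical copies of one group
  t2 <- c(time, time); e2 <- c(event, event)
  g2 <- rep(c("x", "y"), each = 6)
  expect_lt(logrank_test(t2, e2, g2)$chisq, 1e-10)
  # invariance to group relabeling and to time translation
  lr_m <- logrank_test(time + 7, event, rev(group))
  expect_equal(lr_m$chisq, lr$chisq, tolerance = 1e-9)
  # three groups give df = 2
  expect_equal(logrank_test(c(time, 7, 8), c(event, 1, 0),
                            c(group, "c", "c"))$df, 2)
  expect_error(logrank_test(time, event, rep("a", 6)), "2 groups")
})

sim_binary_surv <- function(n, beta, seed, rate = 0.05, censor = 40) {
  g <- rep(c(0, 1), length.out = n)
  surv <- simulate_survival(matrix(g, ncol = 1),
                            survival_spec(rate, beta = beta,
                                          censor_time = censor),
                            seed = seed)
  list(g = g, time = surv$time, event = surv$event)
}

test_that("cox_fit matches grid maximization of the explicit partial likelihood", {
  d <- sim_binary_surv(40, log(2), seed = 81, censor = Inf)
  # continuous times: no ties, Breslow = Efron = the oracle's likelihood
  expect_equal(length(unique(d$time)), 40)
  fit <- cox_fit(matrix(d$g, ncol = 1, dimnames = list(NULL, "g")),
                 d$time, d$event)
  b_grid <- oracle_cox_beta(d$g, d$time, d$event)
  expect_lt(abs(unname(fit$coef[1]) - b_grid), 1e-4)
  # local optimality of the reported optimum
  ll_hat <- oracle_cox_loglik(fit$coef[1], d$g, d$time, d$event)
  for (eps in c(-0.1, -0.01, 0.01, 0.1))
    expect_lte(oracle_cox_loglik(fit$coef[1] + eps, d$g, d$time, d$event),
               ll_hat + 1e-12)
})

test_that("a planted log-hazard is recovered and a null one is not invented", {
  d <- sim_binary_surv(2000, log(2), seed = 82)
  fit <- cox_fit(matrix(d$g, ncol = 1, dimnames = list(NULL, "g")),
                 d$time, d$event)
  expect_lt(abs(unname(fit$coef[1]) - log(2)), 3 * fit$se[1])
  d0 <- sim_binary_surv(2000, 0, seed = 83)
  fit0 <- cox_fit(matrix(d0$g, ncol = 1, dimnames = list(NULL, "g")),
                  d0$time, d0$event)
  expect_lt(abs(unname(fit0$coef[1])), 3 * fit0$se[1])
})

test_that("Efron and Breslow coincide when all event times are distinct", {
  d <- sim_binary_surv(30, 0.7, seed = 84, censor = Inf)
  x <- matrix(d$g, ncol = 1, dimnames = list(NULL, "g"))
  fe <- cox_fit(x, d$time, d$event, ties = "efron")
  fb <- cox_fit(x, d$time, d$event, ties = "breslow")
  expect_lt(abs(fe$coef[1] - fb$coef[1]), 1e-10)
})

test_that("degenerate Cox inputs are rejected with the covariate named", {
  d <- sim_binary_surv(20, 0, seed = 85)
  expect_error(cox_fit(matrix(1, 20, 1, dimnames = list(NULL, "flat")),
                       d$time, d$event), "constant.*flat")
  # perfect separation: covariate orders the event times exactly
  t <- 1:20
  x <- matrix(20:1, ncol = 1, dimnames = list(NULL, "sep"))
  expect_error(cox_fit(x, t, rep(1, 20)), "separation.*sep")
  expect_error(cox_fit(matrix(rnorm(20), ncol = 1), d$time, rep(0, 20)),
               "at least one event")
})

test_that("the univariate screen reports HR, CI and p per feature", {
  set.seed(86)
  n <- 2000
  x <- rbind(prog = rep(c(0, 1), each = n / 2), noise = rnorm(n))
  colnames(x) <- paste0("s", 1:n)
  surv <- simulate_survival(matrix(x["prog", ], ncol = 1),
                            survival_spec(0.05, beta = log(2),
                                          censor_time = 40), seed = 87)
  scr <- univariate_screen(x, surv$time, surv$event)
  expect_equal(scr$feature_id, c("prog", "noise"))
  prog <- scr[1, ]
  expect_gt(prog$HR, 1.7); expect_lt(prog$HR, 2.35)
  noise <- scr[2, ]
  expect_true(noise$ci_lo < 1 && noise$ci_hi > 1)
  expect_equal(scr$HR, exp(scr$coef))
})

test_that("risk stratification splits at the median with ties going low", {
  set.seed(88)
  x <- matrix(c(1:6), 1, 6, dimnames = list("f", paste0("s", 1:6)))
  model <- structure(list(features = "f", coef = c(f = 1), se = c(f = 0.1),
                          loglik = 0, ties = "efron", cutoff = NULL,
                          fit = NULL), class = "cox_model")
  time <- c(5, 1, 6, 2, 4, 3); event <- c(1, 1, 1, 1, 0, 1)
  rs <- risk_stratify(model, x, time, event)
  expect_equal(sum(rs$samples$group == "high"), 3)   # even split
  expect_equal(rs$cutoff, median(1:6))
  # a score exactly at the cutoff goes low
  rs2 <- risk_stratify(model, x, time, event, cutoff = 4)
  expect_equal(rs2$samples$group[x[1, ] == 4], "low")
  expect_error(risk_stratify(model, x, time, event, cutoff = 100),
               "one side")
})

test_that("a planted high/low hazard ratio of 3 is recovered", {
  set.seed(89)
  n <- 400
  f <- c(rnorm(n / 2, 0, 0.1), rnorm(n / 2, 1, 0.1))
  x <- matrix(f, 1, n, dimnames = list("score", paste0("s", 1:n)))
  grp <- as.integer(f > median(f))
  surv <- simulate_survival(matrix(grp, ncol = 1),
                            survival_spec(0.03, beta = log(3),
                                          censor_time = 40), seed = 90)
  model <- cox_fit(t(x), surv$time, surv$event)
  rs <- risk_stratify(model, x, surv$time, surv$event)
  expect_gt(rs$hr, 2.2); expect_lt(rs$hr, 4.1)
  expect_lt(rs$logrank_p, 0.01)
})

test_that("signature evaluation freezes the training model and cutoff", {
  mk <- list(marker_spec("B", sprintf("mir%04d", 1:4), -2))
  make <- function(seed) {
    # one baseline_seed across cohorts: same platform abundance profile
    coh <- simulate_cohort(250, 40, c(A = 0.5, B = 0.5), markers = mk,
                           noise_sd = 0.5,
                           spec = survival_spec(0.05, beta = -0.5,
                                                censor_time = 60),
                           hazard_by = "score",
                           score_features = sprintf("mir%04d", 1:4),
                           score_weights = 0.25, seed = seed,
                           baseline_seed = 91)
    list(expression = coh$expression, time = coh$clinical$time,
         event = coh$clinical$event)
  }
  train <- make(91); valid <- make(92)
  sig <- sprintf("mir%04d", 1:4)
  rep1 <- evaluate_signature(sig, train, list(val = valid))
  expect_equal(rep1$results$cohort, c("training", "val"))
  expect_true(all(rep1$results$hr > 1))
  expect_true(all(rep1$results$logrank_p < 0.01))
  # frozen cutoff equals the training cutoff in both rows
  expect_equal(rep1$results$cutoff[2], rep1$results$cutoff[1])
  # self-consistency with risk_stratify on the training cohort
  covar <- t(train$expression[sig, ])
  model <- cox_fit(covar, train$time, train$event)
  rs <- risk_stratify(model, train$expression, train$time, train$event)
  expect_equal(rep1$results$hr[1], unname(rs$hr))
  expect_equal(rep1$results$logrank_p[1], rs$logrank_p)
  # validation scoring is invariant to the validation sample order
  perm <- sample(ncol(valid$expression))
  valid_p <- list(expression = valid$expression[, perm],
                  time = valid$time[perm], event = valid$event[perm])
  rep2 <- evaluate_signature(sig, train, list(val = valid_p))
  expect_equal(rep2$results$hr[2], rep1$results$hr[2], tolerance = 1e-10)
  # cohorts missing a feature are skipped with a warning, not fatal
  short <- list(expression = valid$expression[-1, ], time = valid$time,
                event = valid$event)
  expect_warning(rep3 <- evaluate_signature(sig, train, list(bad = short)),
                 "skipped")
  expect_equal(rep3$results$cohort, "training")
})

test_that("a pure-noise signature shows no spurious prognostic power", {
  set.seed(93)
  nf <- 6; n <- 2000
  x <- matrix(rnorm(nf * n), nf, n,
              dimnames = list(paste0("f", 1:nf), paste0("s", 1:n)))
  surv <- simulate_survival(rep(0, n), survival_spec(0.05, censor_time = 40),
                            seed = 94)
  rep0 <- evaluate_signature(paste0("f", 1:4),
                             list(expression = x, time = surv$time,
                                  event = surv$event))
  expect_gt(rep0$results$hr, 0.8)
  expect_lt(rep0$results$hr, 1.25)
})
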