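# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops and closed forms only.

# Pearson correlation of two vectors from first principles
oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# silhouette width of sample i from a distance matrix and labels
oracle_silhouette <- function(d, labels, i) {
  own <- which(labels == labels[i])
  if (length(own) == 1L) return(0)
  a <- mean(d[i, setdiff(own, i)])
  b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
    mean(d[i, labels == cl])
  }, numeric(1)))
  (b - a) / max(a, b)
}

# within-cluster dispersion: double loop over ordered pairs / (2 n_r)
oracle_wk <- function(d, labels) {
  total <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    s <- 0
    for (i in idx) for (j in idx) s <- s + d[i, j]
    total <- total + s / (2 * length(idx))
  }
  total
}

# AUC by exhaustive pair enumeration
oracle_auc <- function(x, positive) {
  pos <- x[positive]; neg <- x[!positive]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# SAM d-statistic from the definition, group1 = first level
oracle_sam_d <- function(x, g1, s0) {
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, !g1, drop = FALSE])
  n1 <- sum(g1); n2 <- sum(!g1)
  ss <- rowSums((x[, g1, drop = FALSE] - m1)^2) +
        rowSums((x[, !g1, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  (m1 - m2) / (s + s0)
}

# exhaustive-permutation SAM q-values from the definition
oracle_sam_q <- function(x, g1) {
  n <- length(g1); n1 <- sum(g1)
  m1 <- rowMeans(x[, g1, drop = FALSE]); m2 <- rowMeans(x[, !g1, drop = FALSE])
  ss <- rowSums((x[, g1, drop = FALSE] - m1)^2) +
        rowSums((x[, !g1, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / (n - n1)) * ss / (n - 2))
  s0 <- median(s)
  d_obs <- oracle_sam_d(x, g1, s0)
  sets <- combn(n, n1)
  perm_abs <- c()
  for (j in seq_len(ncol(sets))) {
    g <- seq_len(n) %in% sets[, j]
    perm_abs <- c(perm_abs, abs(oracle_sam_d(x, g, s0)))
  }
  a <- abs(d_obs)
  q <- numeric(length(a))
  for (i in seq_along(a)) {
    efp <- sum(perm_abs >= a[i]) / ncol(sets)
    q[i] <- min(1, efp / sum(a >= a[i]))
  }
  ord <- order(a, decreasing = TRUE)
  qs <- q[ord]
  qs <- rev(cummin(rev(qs)))
  q[ord] <- qs
  q
}

# Cox log partial likelihood for a single covariate, Breslow ties
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# grid + refinement maximizer of the 1-D partial likelihood
oracle_cox_beta <- function(x, time, event, lo = -5, hi = 5) {
  for (pass in 1:4) {
    grid <- seq(lo, hi, length.out = 201)
    ll <- vapply(grid, oracle_cox_loglik, numeric(1), x = x,
                 time = time, event = event)
    b <- grid[which.max(ll)]
    step <- grid[2] - grid[1]
    lo <- b - step; hi <- b + step
  }
  b
}

# log-rank chi-square from the O-E table at each distinct event time
oracle_logrank <- function(time, event, group) {
  group <- as.factor(group)
  g1 <- levels(group)[1]
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# product-limit estimator by hand at the distinct event times
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    out[i] <- s
  }
  list(time = ts, surv = out)
}

# adjusted Rand index (mclust's reference implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small labelled random expression matrix
rand_expr <- function(nf, ns, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nf * ns), nf, ns,
         dimnames = list(paste0("f", seq_len(nf)), paste0("s", seq_len(ns))))
}

# planted three-subtype cohort at the study's standard conditions
planted_cohort3 <- function(n = 90, nf = 300, effect = 2, noise = 0.5,
                            seed = 1) {
  mk <- list(marker_spec("S1", sprintf("mir%04d", 1:10), effect),
             marker_spec("S2", sprintf("mir%04d", 11:20), -effect),
             marker_spec("S3", sprintf("mir%04d", 21:30), effect))
  simulate_expression(n, nf, c(S1 = 0.4, S2 = 0.35, S3 = 0.25),
                      markers = mk, noise_sd = noise, seed = seed)
}
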