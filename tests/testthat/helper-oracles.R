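# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the package implementations they check.

# Piecewise-linear month-midpoint interpolation to a 365-day series,
# wrapping December to January.
oracle_daily <- function(v) {
  len <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  starts <- cumsum(c(1, len[-12]))
  mids <- starts + (len - 1) / 2
  xs <- c(mids[12] - 365, mids, mids[1] + 365)
  ys <- c(v[12], v, v[1])
  out <- numeric(365)
  for (d in 1:365) {
    i <- max(which(xs <= d))
    out[d] <- ys[i] + (ys[i + 1] - ys[i]) * (d - xs[i]) / (xs[i + 1] - xs[i])
  }
  out
}

oracle_dd <- function(tmean, base, direction) {
  daily <- oracle_daily(tmean)
  total <- 0
  for (d in 1:365) {
    x <- if (direction == "above") daily[d] - base else base - daily[d]
    if (x > 0) total <- total + x
  }
  total
}

oracle_nffd <- function(tmin) {
  daily <- oracle_daily(tmin)
  n <- 0
  for (d in 1:365) if (daily[d] > 0) n <- n + 1
  n
}

# All-pairs Mann-Whitney AUC with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Closed-form balanced one-way ANOVA variance-component estimators:
# sigma2_e = MS_within, sigma2_P = (MS_between - MS_within) / n_per_group.
oracle_oneway_components <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- length(values) / k
  gm <- tapply(values, groups, mean)
  ms_b <- n * sum((gm - mean(values))^2) / (k - 1)
  ms_w <- sum((values - gm[groups])^2) / (k * (n - 1))
  c(provenance = (ms_b - ms_w) / n, residual = ms_w)
}
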