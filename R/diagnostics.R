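# MCMC convergence diagnostics: split-R-hat and effective sample size.
# Standard split-chain formulations; chains are halved before computing
# between/within variances so within-chain drift inflates R-hat.

split_into_halves <- function(x, chain_id) {
  out <- list()
  for (ch in unique(chain_id)) {
    v <- x[chain_id == ch]
    n <- length(v)
    if (n < 4L) next
    half <- n %/% 2L
    out <- c(out, list(v[seq_len(half)], v[(n - half + 1L):n]))
  }
  out
}

split_rhat <- function(x, chain_id) {
  halves <- split_into_halves(x, chain_id)
  m <- length(halves)
  if (m < 2L) return(NA_real_)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(v) v[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# ESS for the mean, Stan-style: combined autocorrelation estimate across
# split chains with Geyer's initial monotone positive sequence.
ess_mean <- function(x, chain_id) {
  halves <- split_into_halves(x, chain_id)
  m <- length(halves)
  if (m < 2L) return(NA_real_)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(v) v[seq_len(n)])
  if (n < 8L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus <= 0) return(m * n)
  max_lag <- min(n - 2L, 1000L)
  acov <- vapply(halves, function(v) {
    a <- stats::acf(v, lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(max_lag + 1L))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  rho[1L] <- 1
  # Geyer initial monotone positive sequence over consecutive lag pairs:
  # tau = -1 + 2 * sum_k P_k, P_k = rho_{2k} + rho_{2k+1}, truncated at the
  # first negative pair and forced non-increasing.
  tau_sum <- 0
  pair_prev <- Inf
  k <- 0L
  while (2L * k + 2L <= length(rho)) {
    pair <- rho[2L * k + 1L] + rho[2L * k + 2L]
    if (pair < 0) break
    pair <- min(pair, pair_prev)
    pair_prev <- pair
    tau_sum <- tau_sum + pair
    k <- k + 1L
  }
  tau_hat <- max(-1 + 2 * tau_sum, 1 / (m * n))
  ess <- m * n / tau_hat
  min(ess, m * n * log10(m * n))
}
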