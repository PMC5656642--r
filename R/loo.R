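# Pareto-smoothed importance-sampling leave-one-out cross-validation
# (PSIS-LOO) for the Bernoulli-logit fits.

# Profile-likelihood generalized Pareto fit (Zhang & Stephens 2009) to
# exceedances x > 0, with a weak prior pulling k toward 0.5.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  jhalf <- seq_len(m) - 0.5
  xq <- x[max(1L, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / jhalf)) / (prior_bs * xq)
  # profile log-likelihood in the tail-shape parametrization xi = -b*sigma
  xi_of_b <- vapply(b, function(bi) mean(log1p(-bi * x)), numeric(1))
  l <- n * (log(-b / xi_of_b) - xi_of_b - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l - l[j])), numeric(1))
  b_hat <- sum(b * w)
  xi_hat <- mean(log1p(-b_hat * x))
  sigma <- -xi_hat / b_hat
  # weakly informative prior regularization pulling xi toward 0.5
  xi_hat <- (n * xi_hat + 10 * 0.5) / (n + 10)
  list(k = xi_hat, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smooth a vector of log importance ratios. Returns the smoothed
# log-weights (max-normalized) and the tail-shape estimate k.
psis_smooth <- function(log_ratios, tail_frac = 0.2) {
  s <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  m <- ceiling(tail_frac * s)
  if (m < 5L || stats::sd(lw) < 1e-12) {
    return(list(log_weights = lw, k = -Inf))
  }
  ord <- order(lw)
  tail_idx <- ord[(s - m + 1L):s]
  cutoff <- lw[ord[s - m]]
  exceed <- exp(lw[tail_idx]) - exp(cutoff)
  if (max(exceed) <= 0) return(list(log_weights = lw, k = -Inf))
  fit <- gpd_fit(exceed[exceed > 0])
  # replace tail order statistics by expected GPD order statistics
  pq <- (seq_len(m) - 0.5) / m
  smoothed <- log(qgpd(pq, fit$k, fit$sigma) + exp(cutoff))
  smoothed <- pmin(smoothed, 0)  # cap at the max raw weight (already 0)
  lw[tail_idx[order(lw[tail_idx])]] <- smoothed
  list(log_weights = lw, k = fit$k)
}

#' PSIS-LOO expected log predictive density
#'
#' Estimates leave-one-out predictive accuracy of a fitted Bernoulli-logit
#' model by Pareto-smoothed importance sampling: per observation, raw
#' importance ratios 1/p(y_i | beta_l) are stabilized by fitting a
#' generalized Pareto distribution to the largest 20\% and replacing them
#' with expected order statistics. Reports the expected log pointwise
#' predictive density (ELPD), the LOO information criterion
#' LOOIC = -2 * ELPD, and per-observation Pareto-k diagnostics (warning
#' when any k > 0.7).
#'
#' @param draws A \code{posterior_draws} object.
#' @param X Covariate matrix matching the fit (or \code{NULL}).
#' @param y 0/1 outcomes.
#' @return A \code{loo_result}: list with \code{elpd}, \code{looic},
#'   \code{pointwise} (per-observation elpd), \code{pareto_k}.
#' @export
psis_loo <- function(draws, X = NULL, y) {
  if (is.null(draws) || !inherits(draws, "posterior_draws")) {
    stop("'draws' must be a posterior_draws object", call. = FALSE)
  }
  y <- as.numeric(y)
  n <- length(y)
  if (n == 0L) stop("empty data", call. = FALSE)
  design <- cbind(rep(1, n), if (!is.null(X)) as.matrix(X))
  if (ncol(design) != ncol(draws)) {
    stop("design columns must match coefficient count", call. = FALSE)
  }
  eta <- design %*% t(unclass(draws))             # n x S
  loglik <- y * stats::plogis(eta, log.p = TRUE) +
    (1 - y) * stats::plogis(-eta, log.p = TRUE)   # n x S
  pointwise <- numeric(n)
  ks <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-loglik[i, ])
    lw <- sm$log_weights
    ks[i] <- sm$k
    # elpd_i = log( sum w * lik / sum w )
    pointwise[i] <- log_sum_exp(lw + loglik[i, ]) -
      log_sum_exp(lw)
  }
  if (any(ks > 0.7)) {
    warning(sprintf("%d observation(s) with Pareto k > 0.7; PSIS-LOO may be unreliable",
                    sum(ks > 0.7)), call. = FALSE)
  }
  out <- list(
    elpd = sum(pointwise),
    looic = -2 * sum(pointwise),
    pointwise = pointwise,
    pareto_k = ks
  )
  class(out) <- "loo_result"
  out
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("elpd = %.2f   looic = %.2f   max Pareto k = %.2f\n",
              x$elpd, x$looic, max(x$pareto_k)))
  invisible(x)
}
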