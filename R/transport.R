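# Bayesian and maximum-likelihood logistic regression for the car
# transport probability, plus posterior pushforwards.

#' Cauchy prior specification for logistic-regression coefficients
#'
#' The model places independent Cauchy priors on each coefficient
#' (intercept first) on the logit scale. The default, location 0 and
#' scale 2.5, is the standard weakly informative choice for
#' rare-event logistic regression.
#'
#' @param location Numeric vector of prior locations (recycled across
#'   coefficients).
#' @param scale Numeric vector of prior scales, all > 0 (recycled).
#' @param autoscale If \code{TRUE}, each non-intercept coefficient's scale is
#'   divided by the sample standard deviation of its predictor at fit time.
#'   Default \code{FALSE}: scales are applied literally on the logit scale.
#' @return A \code{logistic_prior} object.
#' @export
logistic_prior <- function(location = 0, scale = 2.5, autoscale = FALSE) {
  if (any(scale <= 0)) stop("prior scale must be > 0", call. = FALSE)
  structure(list(location = location, scale = scale, autoscale = autoscale),
            class = "logistic_prior")
}

log_posterior_factory <- function(design, y, loc, scl) {
  # Bernoulli-logit likelihood + independent Cauchy priors, on logit scale.
  function(beta) {
    eta <- drop(design %*% beta)
    ll <- sum(y * stats::plogis(eta, log.p = TRUE) +
              (1 - y) * stats::plogis(-eta, log.p = TRUE))
    ll + sum(stats::dcauchy(beta, loc, scl, log = TRUE))
  }
}

#' Fit a Bayesian logistic regression by adaptive Markov chain Monte Carlo
#'
#' Samples the posterior of a Bernoulli-logit model with independent Cauchy
#' priors using adaptive random-walk Metropolis (proposal covariance adapted
#' during warm-up, then frozen). An intercept is always included; \code{X}
#' supplies additional covariate columns. Convergence is assessed with
#' split-R-hat and effective sample size per coefficient; a warning is
#' attached (and emitted) when split-R-hat >= 1.01 or ESS <= 400.
#'
#' @param X Covariate matrix/data.frame (no intercept column), or \code{NULL}
#'   for an intercept-only model.
#' @param y 0/1 outcome vector. A zero-length \code{y} (with \code{X = NULL})
#'   samples the prior; a missing \code{y} is an error.
#' @param prior A \code{\link{logistic_prior}}.
#' @param chains,iter,warmup MCMC configuration: number of chains, retained
#'   draws per chain, and warm-up iterations (discarded).
#' @param seed Integer seed; fixes the draws bit-for-bit.
#' @return A \code{posterior_draws} object: numeric matrix
#'   (\code{chains * iter} rows, one column per coefficient) with attributes
#'   \code{chain_id}, \code{diagnostics} (data.frame with \code{rhat},
#'   \code{ess}), and \code{convergence_warning}.
#' @examples
#' fit <- fit_bayes_logistic(NULL, c(rep(1, 2), rep(0, 18)),
#'                           chains = 2, iter = 500, warmup = 250)
#' summarize_draws(inv_logit(fit[, 1]))
#' @export
fit_bayes_logistic <- function(X = NULL, y, prior = logistic_prior(),
                               chains = 4, iter = 2000, warmup = 1000,
                               seed = 1L) {
  if (missing(y) || is.null(y)) stop("'y' is required", call. = FALSE)
  y <- as.numeric(y)
  if (any(!y %in% c(0, 1))) stop("'y' must be 0/1", call. = FALSE)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (!is.numeric(X)) stop("'X' must be numeric", call. = FALSE)
    if (nrow(X) != length(y)) stop("rows of X must match y", call. = FALSE)
    if (length(y) == 0L) X <- NULL
  }
  p <- 1L + if (is.null(X)) 0L else ncol(X)
  design <- if (is.null(X)) {
    matrix(1, length(y), 1L)
  } else {
    cbind(rep(1, length(y)), X)
  }
  cn <- c("(Intercept)",
          if (!is.null(X)) colnames(X) %||% paste0("x", seq_len(p - 1L)))
  cn[!nzchar(cn)] <- paste0("x", which(!nzchar(cn)) - 1L)
  colnames(design) <- cn

  loc <- rep_len(prior$location, p)
  scl <- rep_len(prior$scale, p)
  if (isTRUE(prior$autoscale) && p > 1L && length(y) > 1L) {
    sds <- apply(design[, -1L, drop = FALSE], 2, stats::sd)
    scl[-1L] <- scl[-1L] / ifelse(sds > 0, sds, 1)
  }

  log_post <- log_posterior_factory(design, y, loc, scl)

  # initialize at the ML estimate when it is finite, else at the prior
  # location; separation pushes the MLE to +/-Inf so clamp hard.
  init <- loc
  if (length(y) > 0L) {
    ml <- try(fit_ml_logistic(X, y), silent = TRUE)
    if (!inherits(ml, "try-error") && all(is.finite(ml$coefficients))) {
      init <- pmin(pmax(ml$coefficients, -10), 10)
    }
  }

  total <- warmup + iter
  draws <- matrix(NA_real_, chains * iter, p, dimnames = list(NULL, cn))
  chain_id <- rep(seq_len(chains), each = iter)

  for (ch in seq_len(chains)) {
    set.seed(derive_seed(seed, ch))
    beta <- init + stats::rnorm(p, 0, 0.1)
    lp <- log_post(beta)
    prop_chol <- diag(0.5, p)
    log_lambda <- 0
    hist_mat <- matrix(NA_real_, total, p)
    for (it in seq_len(total)) {
      indep <- stats::runif(1) < 0.05
      if (indep) {
        # independence proposal from the prior: exact for prior-dominated
        # targets (heavy Cauchy tails that random walks explore poorly)
        cand <- stats::rcauchy(p, loc, scl)
        lp_cand <- log_post(cand)
        log_ratio <- (lp_cand - lp) +
          sum(stats::dcauchy(beta, loc, scl, log = TRUE)) -
          sum(stats::dcauchy(cand, loc, scl, log = TRUE))
      } else {
        cand <- beta + exp(log_lambda) * drop(prop_chol %*% stats::rnorm(p))
        lp_cand <- log_post(cand)
        log_ratio <- lp_cand - lp
      }
      acc <- log_ratio > log(stats::runif(1))
      if (acc) {
        beta <- cand
        lp <- lp_cand
      }
      hist_mat[it, ] <- beta
      if (it <= warmup && !indep) {
        # Robbins-Monro scale adaptation toward 0.35 acceptance, plus
        # covariance adaptation from the warm-up history (Haario-style).
        log_lambda <- log_lambda + (as.numeric(acc) - 0.35) / sqrt(it)
        if (it >= 100 && it %% 50 == 0) {
          S <- stats::cov(hist_mat[seq(max(1, it - 500), it), , drop = FALSE])
          S <- S * (2.38^2 / p) + diag(1e-8, p)
          ch_try <- try(chol(S), silent = TRUE)
          if (!inherits(ch_try, "try-error")) prop_chol <- t(ch_try)
        }
      }
    }
    draws[chain_id == ch, ] <- hist_mat[(warmup + 1):total, , drop = FALSE]
  }

  diag_df <- data.frame(
    coefficient = cn,
    rhat = vapply(seq_len(p), function(j) split_rhat(draws[, j], chain_id),
                  numeric(1)),
    ess = vapply(seq_len(p), function(j) ess_mean(draws[, j], chain_id),
                 numeric(1))
  )
  warn <- any(diag_df$rhat >= 1.01, na.rm = TRUE) ||
    any(diag_df$ess <= 400, na.rm = TRUE)
  if (warn) {
    warning(sprintf(
      "possible non-convergence: max split-Rhat %.3f, min ESS %.0f",
      max(diag_df$rhat, na.rm = TRUE), min(diag_df$ess, na.rm = TRUE)
    ), call. = FALSE)
  }
  structure(draws,
            chain_id = chain_id,
            diagnostics = diag_df,
            convergence_warning = warn,
            prior = list(location = loc, scale = scl),
            class = c("posterior_draws", "matrix", "array"))
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d draws x %d coefficients (%d chains)\n",
              nrow(x), ncol(x), length(unique(attr(x, "chain_id")))))
  print(attr(x, "diagnostics"), row.names = FALSE)
  invisible(x)
}

#' Posterior predictive transport probability at an alert probability
#'
#' Pushes coefficient draws through the inverse logit at a single covariate
#' value: theta_l = inv_logit(alpha_l + beta_l * x). For an intercept-only
#' fit, \code{x} may be omitted.
#'
#' @param draws A \code{posterior_draws} object.
#' @param x Origin alert probability in [0, 1]; omitted for the naive model.
#' @return A \code{theta_draws} vector (attribute \code{adjusted = FALSE}).
#' @export
posterior_predictive <- function(draws, x = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (is.null(x)) {
    eta <- draws[, 1L]
  } else {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop("'x' must be a single alert probability in [0, 1]", call. = FALSE)
    }
    if (ncol(draws) < 2L) {
      eta <- draws[, 1L]
    } else {
      eta <- draws[, 1L] + draws[, 2L] * x
    }
  }
  theta_draws(inv_logit(eta), adjusted = FALSE)
}

theta_draws <- function(values, adjusted = FALSE) {
  structure(as.numeric(values), adjusted = adjusted, class = "theta_draws")
}

#' @export
print.theta_draws <- function(x, ...) {
  cat(sprintf("theta_draws: %d transport-probability draws (%s)\n",
              length(x),
              if (isTRUE(attr(x, "adjusted"))) "efficiency-adjusted"
              else "unadjusted"))
  print(summarize_draws(x))
  invisible(x)
}

#' Deterministic quadrature posterior for the intercept-only model
#'
#' Independent oracle for the naive transport model: the posterior
#' proportional to Cauchy(alpha; location, scale) * theta^s *
#' (1 - theta)^(n - s), theta = inv_logit(alpha), is integrated on a grid
#' of equal prior-mass cells (alpha evaluated at prior quantiles), which
#' handles the Cauchy tails without truncation artefacts. Errors if the
#' grid fails to cover at least 99.999% of the posterior mass, using an
#' analytic bound on the likelihood outside the grid.
#'
#' @param successes,trials Detection count and number of sampled cars
#'   (trials >= successes >= 0).
#' @param prior A \code{\link{logistic_prior}}; only the first
#'   location/scale entry is used.
#' @param grid List with \code{n} (number of points, default 200001) and
#'   either \code{tail} (prior mass excluded per side, default 1e-7) or
#'   explicit \code{lower}/\code{upper} alpha bounds.
#' @param probs Quantile pair for the interval (default 90\%).
#' @return A \code{fit_summary} for theta.
#' @examples
#' quadrature_posterior(4, 770)
#' @export
quadrature_posterior <- function(successes, trials,
                                 prior = logistic_prior(),
                                 grid = list(n = 200001L, tail = 1e-7),
                                 probs = c(0.05, 0.95)) {
  if (trials < successes || successes < 0) {
    stop("need trials >= successes >= 0", call. = FALSE)
  }
  loc <- prior$location[1L]
  scl <- prior$scale[1L]
  n_grid <- grid$n %||% 200001L
  if (!is.null(grid$lower) || !is.null(grid$upper)) {
    u_lo <- stats::pcauchy(grid$lower, loc, scl)
    u_hi <- stats::pcauchy(grid$upper, loc, scl)
  } else {
    u_lo <- grid$tail %||% 1e-7
    u_hi <- 1 - u_lo
  }
  u <- seq(u_lo, u_hi, length.out = n_grid)
  a <- stats::qcauchy(u, loc, scl)
  llik <- function(a) {
    successes * stats::plogis(a, log.p = TRUE) +
      (trials - successes) * stats::plogis(-a, log.p = TRUE)
  }
  ll <- llik(a)
  mx <- max(ll)
  w <- exp(ll - mx)                      # mass per equal-prior-mass cell
  du <- (u_hi - u_lo) / (n_grid - 1)
  mass_in <- sum(w) * du

  # bound the posterior mass outside the grid: the likelihood out in each
  # tail is at most its value at the grid edge, or at the MLE if the mode
  # lies outside the grid (s = 0 / s = n push the mode to +-infinity,
  # where the likelihood tends to 1 resp. its supremum)
  mode_a <- if (successes == 0) -Inf
            else if (successes == trials) Inf
            else stats::qlogis(successes / trials)
  lmax <- if (is.finite(mode_a)) llik(mode_a) else 0   # log sup of L
  l_left <- if (mode_a <= a[1L]) exp(lmax - mx) else exp(ll[1L] - mx)
  l_right <- if (mode_a >= a[n_grid]) exp(lmax - mx) else exp(ll[n_grid] - mx)
  mass_out <- l_left * u_lo + l_right * (1 - u_hi)
  frac_out <- mass_out / (mass_in + mass_out)
  if (frac_out > 1e-5) {
    stop(sprintf(
      "quadrature grid covers only %.5f%% of posterior mass; widen it",
      100 * (1 - frac_out)
    ), call. = FALSE)
  }

  w <- w / sum(w)
  theta <- inv_logit(a)
  cdf <- cumsum(w)
  qfun <- function(p) {
    i <- which.max(cdf >= p)
    if (i == 1L) return(theta[1L])
    # linear interpolation of the inverse CDF between grid points
    t0 <- theta[i - 1L]; t1 <- theta[i]
    c0 <- cdf[i - 1L]; c1 <- cdf[i]
    if (c1 == c0) t1 else t0 + (p - c0) / (c1 - c0) * (t1 - t0)
  }
  out <- list(
    median = qfun(0.5), q05 = qfun(probs[1]), q95 = qfun(probs[2]),
    prob_positive = 1,  # theta = inv_logit(alpha) > 0 everywhere
    probs = probs
  )
  class(out) <- "fit_summary"
  out
}

#' Maximum-likelihood logistic regression by IRLS
#'
#' Iteratively reweighted least squares for the Bernoulli-logit model, with
#' Wald standard errors and p-values. Complete or quasi-complete separation
#' is detected (diverging coefficients / vanishing curvature) and reported
#' via \code{converged = FALSE} and a warning rather than an error.
#'
#' @param X Covariate matrix (no intercept column) or \code{NULL}.
#' @param y 0/1 outcomes.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   deviance change.
#' @return An \code{ml_fit} object: list with \code{coefficients},
#'   \code{std_errors}, \code{p_values}, \code{converged}, \code{deviance}.
#' @examples
#' fit_ml_logistic(NULL, c(rep(1, 4), rep(0, 766)))  # intercept = logit(4/770)
#' @export
fit_ml_logistic <- function(X = NULL, y, max_iter = 100L, tol = 1e-10) {
  y <- as.numeric(y)
  if (length(y) == 0L) stop("empty data", call. = FALSE)
  if (any(!y %in% c(0, 1))) stop("'y' must be 0/1", call. = FALSE)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != length(y)) stop("rows of X must match y", call. = FALSE)
  }
  design <- cbind(`(Intercept)` = rep(1, length(y)), X)
  p <- ncol(design)
  beta <- rep(0, p)
  dev_old <- Inf
  converged <- FALSE
  singular <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(design %*% beta)
    mu <- inv_logit(eta)
    w <- mu * (1 - mu)
    if (all(w < 1e-10)) { singular <- TRUE; break }
    z <- eta + (y - mu) / pmax(w, 1e-10)
    fit <- try(
      stats::lm.wfit(design, z, pmax(w, 1e-10)),
      silent = TRUE
    )
    if (inherits(fit, "try-error")) { singular <- TRUE; break }
    beta <- fit$coefficients
    if (anyNA(beta)) { singular <- TRUE; break }
    eta <- drop(design %*% beta)
    dev <- -2 * sum(y * stats::plogis(eta, log.p = TRUE) +
                    (1 - y) * stats::plogis(-eta, log.p = TRUE))
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) { converged <- TRUE; break }
    dev_old <- dev
  }
  separated <- singular || any(abs(beta) > 15)
  if (separated) converged <- FALSE
  se <- rep(NA_real_, p)
  if (!singular) {
    eta <- drop(design %*% beta)
    mu <- inv_logit(eta)
    w <- mu * (1 - mu)
    info <- crossprod(design * sqrt(w))
    inv <- try(solve(info), silent = TRUE)
    if (!inherits(inv, "try-error")) se <- sqrt(pmax(diag(inv), 0))
  }
  if (!converged) {
    warning("ML fit did not converge (possible separation)", call. = FALSE)
  }
  zval <- beta / se
  out <- list(
    coefficients = stats::setNames(beta, colnames(design)),
    std_errors = stats::setNames(se, colnames(design)),
    p_values = stats::setNames(2 * stats::pnorm(-abs(zval)), colnames(design)),
    converged = converged,
    deviance = if (exists("dev", inherits = FALSE)) dev else NA_real_
  )
  class(out) <- "ml_fit"
  out
}

#' @export
print.ml_fit <- function(x, ...) {
  tab <- data.frame(
    estimate = x$coefficients, std_error = x$std_errors,
    p_value = x$p_values
  )
  print(tab)
  cat(sprintf("converged: %s\n", x$converged))
  invisible(x)
}
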