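# Recapture-experiment analysis and efficiency adjustment of the
# transport-probability posterior.

recapture_conditions <- c("T5", "T10", "T10AC")
recapture_outcomes <- c("captured", "escaped", "lost")

#' Summarize a recapture experiment
#'
#' Computes overall and per-condition capture/escape/lost rates from a
#' mark-recapture trial table. The capture rate \code{r} is the sampling
#' efficiency used to rescale transport-probability posteriors.
#'
#' @param trials Data frame with columns \code{condition} (one of
#'   \code{"T5"}, \code{"T10"}, \code{"T10AC"}: vacuuming after 5 min,
#'   10 min, 10 min with air conditioning) and \code{outcome} (one of
#'   \code{"captured"}, \code{"escaped"}, \code{"lost"}).
#' @param lost_as_escaped If \code{TRUE}, individuals lost from sight are
#'   folded into the escape rate (they are assumed to have escaped); the
#'   default keeps the three categories separate.
#' @return An \code{efficiency_estimate}: list with \code{r} (capture rate),
#'   \code{escape_rate}, \code{lost_rate}, \code{counts} (named overall
#'   counts), and \code{per_condition} (data.frame of counts and rates).
#' @examples
#' tr <- data.frame(
#'   condition = rep("T5", 48),
#'   outcome = rep(c("captured", "escaped", "lost"), c(33, 6, 9))
#' )
#' recapture_summary(tr)$r  # 0.6875
#' @export
recapture_summary <- function(trials, lost_as_escaped = FALSE) {
  if (is.null(trials) || nrow(trials) == 0L) {
    stop("empty recapture table", call. = FALSE)
  }
  if (!all(c("condition", "outcome") %in% names(trials))) {
    stop("recapture table needs 'condition' and 'outcome' columns",
         call. = FALSE)
  }
  bad_out <- setdiff(unique(trials$outcome), recapture_outcomes)
  if (length(bad_out)) {
    stop(sprintf("unknown outcome label(s): %s",
                 paste(bad_out, collapse = ", ")), call. = FALSE)
  }
  bad_cond <- setdiff(unique(trials$condition), recapture_conditions)
  if (length(bad_cond)) {
    stop(sprintf("unknown condition label(s): %s",
                 paste(bad_cond, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(trials)
  counts <- vapply(recapture_outcomes,
                   function(o) sum(trials$outcome == o), numeric(1))
  per_cond <- do.call(rbind, lapply(recapture_conditions, function(cc) {
    sub <- trials[trials$condition == cc, , drop = FALSE]
    m <- nrow(sub)
    data.frame(
      condition = cc, n = m,
      captured = sum(sub$outcome == "captured"),
      escaped = sum(sub$outcome == "escaped"),
      lost = sum(sub$outcome == "lost"),
      r = if (m > 0) sum(sub$outcome == "captured") / m else NA_real_
    )
  }))
  escape_rate <- counts[["escaped"]] / n
  lost_rate <- counts[["lost"]] / n
  if (lost_as_escaped) {
    escape_rate <- escape_rate + lost_rate
    lost_rate <- 0
  }
  out <- list(
    r = counts[["captured"]] / n,
    escape_rate = escape_rate,
    lost_rate = lost_rate,
    counts = counts,
    n = n,
    per_condition = per_cond
  )
  class(out) <- "efficiency_estimate"
  out
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("recapture rate r = %.4f (%d/%d); escaped %.4f; lost %.4f\n",
              x$r, x$counts[["captured"]], x$n, x$escape_rate, x$lost_rate))
  print(x$per_condition, row.names = FALSE)
  invisible(x)
}

#' Regress recapture success on the experimental treatments
#'
#' Builds the design implied by the trial conditions (elapsed time 5 or 10
#' minutes; air conditioning on/off) and fits recapture success
#' (outcome == "captured") both by Bayesian logistic regression and by
#' maximum likelihood, as a consistency pair.
#'
#' @param trials Recapture trial table (see \code{\link{recapture_summary}}).
#' @param design One of \code{"constant"} (intercept only),
#'   \code{"condition"} (three-level factor, baseline T5), \code{"time"}
#'   (minutes, centered at 5), \code{"ac"} (indicator), \code{"time_ac"}
#'   (both).
#' @param prior,chains,iter,warmup,seed Passed to
#'   \code{\link{fit_bayes_logistic}}.
#' @return List with components \code{bayes} (\code{posterior_draws}) and
#'   \code{ml} (\code{ml_fit}).
#' @export
fit_treatment_effects <- function(trials,
                                  design = c("constant", "condition",
                                             "time", "ac", "time_ac"),
                                  prior = logistic_prior(),
                                  chains = 4, iter = 1000, warmup = 500,
                                  seed = 1L) {
  design <- match.arg(design)
  est <- recapture_summary(trials)  # validates labels
  y <- as.numeric(trials$outcome == "captured")
  time_min <- ifelse(trials$condition == "T5", 5, 10)
  ac <- as.numeric(trials$condition == "T10AC")
  X <- switch(design,
    constant = NULL,
    condition = cbind(T10 = as.numeric(trials$condition == "T10"),
                      T10AC = ac),
    time = cbind(time = time_min - 5),
    ac = cbind(ac = ac),
    time_ac = cbind(time = time_min - 5, ac = ac)
  )
  bayes <- fit_bayes_logistic(X, y, prior = prior, chains = chains,
                              iter = iter, warmup = warmup, seed = seed)
  ml <- suppressWarnings(fit_ml_logistic(X, y))
  list(bayes = bayes, ml = ml, efficiency = est)
}

#' Rescale transport-probability draws for imperfect sampling efficiency
#'
#' Divides each posterior draw of the transport probability by the
#' recapture rate \code{r} (capping at 1), turning the "probability that a
#' mosquito present is detected and captured" into an estimate of the
#' probability that a mosquito is present at all.
#'
#' @param theta A \code{theta_draws} vector (or plain numeric draws).
#' @param r Recapture rate in (0, 1], or an \code{efficiency_estimate}.
#' @param method \code{"point"} (default) divides by the point estimate;
#'   \code{"beta"} propagates binomial uncertainty by dividing each draw by
#'   an independent Beta(captured + 1, missed + 1) draw (requires an
#'   \code{efficiency_estimate} for the counts).
#' @param seed Seed for the \code{"beta"} method.
#' @return A \code{theta_draws} vector with \code{adjusted = TRUE}.
#' @examples
#' adjust_for_efficiency(theta_vals <- c(0.005, 0.9), r = 0.6875)
#' @export
adjust_for_efficiency <- function(theta, r, method = c("point", "beta"),
                                  seed = 1L) {
  method <- match.arg(method)
  est <- NULL
  if (inherits(r, "efficiency_estimate")) {
    est <- r
    r <- est$r
  }
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1) {
    stop("'r' must be a single recapture rate in (0, 1]", call. = FALSE)
  }
  values <- as.numeric(theta)
  if (method == "point") {
    adj <- pmin(values / r, 1)
  } else {
    if (is.null(est)) {
      stop("method = 'beta' needs an efficiency_estimate for its counts",
           call. = FALSE)
    }
    set.seed(derive_seed(seed, 11L))
    r_draws <- stats::rbeta(length(values),
                            est$counts[["captured"]] + 1,
                            est$n - est$counts[["captured"]] + 1)
    adj <- pmin(values / r_draws, 1)
  }
  theta_draws(adj, adjusted = TRUE)
}
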