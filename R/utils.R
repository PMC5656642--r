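# Internal helpers shared across modules.

inv_logit <- function(x) stats::plogis(x)

logit <- function(p) stats::qlogis(p)

#' Summarize a vector of posterior draws
#'
#' Computes the median, a lower/upper quantile pair (linear-interpolation
#' quantiles, i.e. \code{type = 7}), and the fraction of draws above zero.
#'
#' @param values Numeric vector of draws (length >= 2), or a
#'   \code{theta_draws} object.
#' @param probs Length-2 numeric giving the lower and upper quantile
#'   probabilities. Default \code{c(0.05, 0.95)}, the 90\% credible interval.
#' @return A \code{fit_summary} object: list with \code{median}, \code{q05},
#'   \code{q95}, \code{prob_positive} and the \code{probs} used. \code{q05}
#'   and \code{q95} name the lower and upper requested quantiles regardless
#'   of \code{probs}.
#' @examples
#' summarize_draws(c(-1, 1, 2, 3))
#' @export
summarize_draws <- function(values, probs = c(0.05, 0.95)) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("need at least 2 values to summarize", call. = FALSE)
  }
  if (length(probs) != 2L || any(probs < 0) || any(probs > 1) ||
      probs[1] >= probs[2]) {
    stop("'probs' must be an increasing pair in [0, 1]", call. = FALSE)
  }
  qs <- stats::quantile(values, probs = c(probs[1], 0.5, probs[2]),
                        names = FALSE, type = 7)
  out <- list(
    median = qs[2], q05 = qs[1], q95 = qs[3],
    prob_positive = mean(values > 0),
    probs = probs
  )
  class(out) <- "fit_summary"
  out
}

#' @export
print.fit_summary <- function(x, digits = 4, ...) {
  cat(sprintf(
    "median %.*f  [%g%%, %g%%] = (%.*f, %.*f)  P(>0) = %.3f\n",
    digits, x$median, 100 * x$probs[1], 100 * x$probs[2],
    digits, x$q05, digits, x$q95, x$prob_positive
  ))
  invisible(x)
}

# Derive a stream-specific 32-bit seed from a master seed; keeps every
# generator seeded below .Machine$integer.max.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 2654435761 + stream * 97) %% 2147483647
}

# FNV-1a 32-bit hash of a character scalar, for run manifests.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                      # xor only touches the low byte
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
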