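# Inter-province mosquito flux model: commuter-flow downscaling, the
# per-municipality-day flux equation, and sample-preserving aggregation.
#
# Flow of mosquitoes from municipality i to municipality j on day k is
#   M_ijk = (F_ij + F_ji) * P_ik
# where F are commuter counts in each direction and P_ik is the transport
# probability of the ORIGIN municipality on day k. Uncertainty is carried
# as L aligned posterior samples through every aggregation (province pairs,
# out/in/net flows, months, season), and quantiles are computed last.

#' Province-level origin-destination commuter matrix
#'
#' @param counts Square numeric matrix of commuter counts with province ids
#'   as dimnames; nonnegative, zero diagonal.
#' @return A \code{province_od} object.
#' @export
province_od <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || is.null(rownames(counts))) {
    stop("'counts' must be a square matrix with province ids as dimnames",
         call. = FALSE)
  }
  if (any(counts < 0)) stop("commuter counts must be >= 0", call. = FALSE)
  if (any(diag(counts) != 0)) {
    stop("intra-province commuting is not modelled: diagonal must be zero",
         call. = FALSE)
  }
  structure(counts, class = c("province_od", "matrix", "array"))
}

#' Downscale province commuter flows to municipality pairs
#'
#' Splits each province-pair flow across municipality pairs proportionally
#' to population shares: F_ij = F_AB * (pop_i / pop_A) * (pop_j / pop_B)
#' for i in province A, j in province B. Flows are conserved exactly:
#' summing F_ij over a province pair recovers F_AB.
#'
#' @param provincial A \code{province_od} matrix.
#' @param geography A \code{geography} with municipal populations.
#' @return A \code{municipal_od}: municipality x municipality matrix with a
#'   \code{province} attribute mapping municipalities to provinces.
#' @export
downscale_od <- function(provincial, geography) {
  stopifnot(inherits(provincial, "province_od"))
  mun <- geography$municipalities
  provs <- rownames(provincial)
  if (!all(unique(mun$province_id) %in% provs)) {
    stop("OD matrix missing provinces present in the geography",
         call. = FALSE)
  }
  pop_prov <- tapply(mun$population, mun$province_id, sum)
  for (a in provs) {
    if ((any(provincial[a, ] > 0) || any(provincial[, a] > 0)) &&
        (is.na(pop_prov[a]) || pop_prov[a] <= 0)) {
      stop(sprintf("province %s has nonzero commuter flow but zero population",
                   a), call. = FALSE)
    }
  }
  share <- mun$population / pop_prov[mun$province_id]
  share[!is.finite(share)] <- 0
  n <- nrow(mun)
  F_ab <- provincial[mun$province_id, mun$province_id, drop = FALSE]
  out <- F_ab * tcrossprod(share)
  dimnames(out) <- list(mun$municipality_id, mun$municipality_id)
  structure(out,
            province = stats::setNames(mun$province_id, mun$municipality_id),
            class = c("municipal_od", "matrix", "array"))
}

#' Build the municipality-day transport-probability field
#'
#' For each municipality i and day k, draws L transport probabilities by
#' independently pairing a coefficient draw (alpha_l, beta_l) with a
#' prevalence draw x for the bi-weekly period containing k, and applying
#' inv_logit(alpha_l + beta_l * x). With an intercept-only fit the
#' prevalence covariate is ignored.
#'
#' @param prev A masked \code{municipal_prevalence}.
#' @param draws A \code{posterior_draws} from the transport model.
#' @param days Integer vector of days of year to cover.
#' @param L Samples per municipality-day (default 400).
#' @param seed Integer seed.
#' @param shared_coef If \code{TRUE}, the same L coefficient draws are
#'   reused for every municipality-day (inducing cross-unit correlation);
#'   default \code{FALSE} draws independently, matching aggregation of
#'   independent random variables.
#' @param efficiency Optional recapture rate in (0, 1] (or an
#'   \code{efficiency_estimate}); when supplied, each probability is
#'   divided by it and capped at 1.
#' @return A \code{transport_field}: array municipality x day x L with a
#'   \code{days} attribute.
#' @export
transport_field <- function(prev, draws, days, L = 400L, seed = 1L,
                            shared_coef = FALSE, efficiency = NULL) {
  stopifnot(inherits(prev, "municipal_prevalence"),
            inherits(draws, "posterior_draws"))
  if (!isTRUE(attr(prev, "mask_applied"))) {
    warning("prevalence is not confirmation-masked; flux from unconfirmed municipalities will not be zeroed",
            call. = FALSE)
  }
  days <- as.integer(days)
  periods <- period_index(days)  # errors on out-of-range days
  if (max(periods) > dim(prev)[2]) {
    stop("prevalence does not cover the requested periods", call. = FALSE)
  }
  if (inherits(efficiency, "efficiency_estimate")) efficiency <- efficiency$r
  if (!is.null(efficiency) &&
      (efficiency <= 0 || efficiency > 1)) {
    stop("'efficiency' must be in (0, 1]", call. = FALSE)
  }
  munis <- dimnames(prev)[[1]]
  S <- nrow(draws)
  n_prev <- dim(prev)[3]
  has_slope <- ncol(draws) >= 2L
  out <- array(NA_real_, c(length(munis), length(days), L),
               dimnames = list(munis, NULL, NULL))
  set.seed(derive_seed(seed, 31L))
  if (shared_coef) shared_idx <- sample.int(S, L, replace = TRUE)
  for (ki in seq_along(days)) {
    t <- periods[ki]
    for (mi in seq_along(munis)) {
      ci <- if (shared_coef) shared_idx else sample.int(S, L, replace = TRUE)
      xi <- prev[mi, t, sample.int(n_prev, L, replace = TRUE)]
      eta <- draws[ci, 1L] + if (has_slope) draws[ci, 2L] * xi else 0
      out[mi, ki, ] <- inv_logit(eta)
    }
  }
  if (!is.null(efficiency)) out <- pmin(out / efficiency, 1)
  structure(out, days = days, adjusted = !is.null(efficiency),
            masked_municipalities = attr(prev, "masked_municipalities"),
            class = c("transport_field", "array"))
}

flow_samples <- function(values, key, quantity, level, days) {
  structure(list(values = values, key = key, quantity = quantity,
                 level = level, days = days),
            class = "flow_samples")
}

#' @export
print.flow_samples <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("flow_samples [%s, %s]: %d keys x %d time bins x %d samples\n",
              x$quantity, x$level, d[1], d[2], d[3]))
  invisible(x)
}

#' Per-municipality-pair daily mosquito flux
#'
#' Applies the flux equation M_ijkl = (F_ij + F_ji) * P_ikl for every
#' ordered municipality pair (i, j) in different provinces with nonzero
#' bidirectional commuter flow, each covered day k, and each sample l.
#'
#' @param mun_od A \code{municipal_od} matrix.
#' @param field A \code{transport_field} covering the same municipalities.
#' @return A \code{flow_samples} object (quantity \code{"pairflow"}, level
#'   \code{"municipality"}): values array is pair x day x L, keys give the
#'   origin and destination municipality and province.
#' @export
municipal_flux <- function(mun_od, field) {
  stopifnot(inherits(mun_od, "municipal_od"),
            inherits(field, "transport_field"))
  munis <- dimnames(field)[[1]]
  if (!all(rownames(mun_od) %in% munis)) {
    stop("transport field missing municipalities present in the OD matrix",
         call. = FALSE)
  }
  prov <- attr(mun_od, "province")
  tot <- mun_od + t(mun_od)                 # F_ij + F_ji
  # confirmation mask zeroes all outgoing flux from masked origins
  masked <- attr(field, "masked_municipalities")
  if (length(masked)) tot[rownames(tot) %in% masked, ] <- 0
  keep <- which(tot > 0 & outer(prov, prov, "!="), arr.ind = TRUE)
  if (nrow(keep) == 0L) {
    stop("no inter-province municipality pairs with positive flow",
         call. = FALSE)
  }
  o <- rownames(mun_od)[keep[, 1]]
  d <- colnames(mun_od)[keep[, 2]]
  n_day <- dim(field)[2]
  L <- dim(field)[3]
  vals <- array(NA_real_, c(nrow(keep), n_day, L))
  fij <- tot[keep]
  oi <- match(o, munis)
  for (ki in seq_len(n_day)) {
    vals[, ki, ] <- fij * field[oi, ki, , drop = FALSE][, 1, ]
  }
  key <- data.frame(origin = o, destination = d,
                    origin_province = unname(prov[o]),
                    destination_province = unname(prov[d]),
                    stringsAsFactors = FALSE)
  flow_samples(vals, key, "pairflow", "municipality", attr(field, "days"))
}

#' Aggregate flow samples over space and time
#'
#' Sums flux samples to coarser keys while keeping the L samples aligned
#' by index: municipal pair flows to province pairs, then to per-province
#' outflow, inflow, or net flow (outflow - inflow); days to calendar months
#' or to the whole covered window ("year"). Aggregating to a level the data
#' already has (or coarser) is an error.
#'
#' @param flows A \code{flow_samples} object.
#' @param level Target spatial level: \code{"province_pair"}, \code{"out"},
#'   \code{"in"}, \code{"net"}, or \code{NULL} to keep the current one.
#' @param time Target time resolution: \code{"day"} (keep), \code{"month"}
#'   (calendar months of a non-leap year), or \code{"year"} (sum the whole
#'   covered window).
#' @return A \code{flow_samples} object at the requested granularity.
#' @export
aggregate_flows <- function(flows, level = NULL, time = c("day", "month", "year")) {
  stopifnot(inherits(flows, "flow_samples"))
  time <- match.arg(time)
  vals <- flows$values
  key <- flows$key
  quantity <- flows$quantity
  lev <- flows$level

  if (!is.null(level)) {
    if (level == "province_pair") {
      if (quantity != "pairflow") {
        stop("province_pair aggregation needs pairflow input", call. = FALSE)
      }
      if (lev == "province") {
        stop("data is already at province level", call. = FALSE)
      }
      grp <- paste(key$origin_province, key$destination_province, sep = "\r")
      vals <- rowsum_3d(vals, grp)
      ids <- strsplit(rownames(vals), "\r", fixed = TRUE)
      key <- data.frame(origin = vapply(ids, `[`, "", 1),
                        destination = vapply(ids, `[`, "", 2),
                        stringsAsFactors = FALSE)
      quantity <- "pairflow"
      lev <- "province"
    } else if (level %in% c("out", "in", "net")) {
      if (quantity != "pairflow") {
        stop("out/in/net aggregation needs pairflow input", call. = FALSE)
      }
      if (lev == "municipality") {
        pp <- aggregate_flows(flows, level = "province_pair")
        vals <- pp$values
        key <- pp$key
      }
      units <- sort(unique(c(key$origin, key$destination)))
      out_v <- rowsum_3d(vals, key$origin, groups = units)
      in_v <- rowsum_3d(vals, key$destination, groups = units)
      vals <- switch(level, out = out_v, `in` = in_v, net = out_v - in_v)
      key <- data.frame(province = units, stringsAsFactors = FALSE)
      quantity <- switch(level, out = "outflow", `in` = "inflow",
                         net = "netflow")
      lev <- "province"
    } else {
      stop("unknown aggregation level: ", level, call. = FALSE)
    }
  }

  days <- flows$days
  if (time == "month") {
    if (is.null(days)) stop("data has no day axis left", call. = FALSE)
    month <- day_to_month(days)
    d <- dim(vals)
    m2 <- matrix(aperm(vals, c(2, 1, 3)), d[2], d[1] * d[3])
    rs <- rowsum(m2, month)
    vals <- aperm(array(rs, c(nrow(rs), d[1], d[3])), c(2, 1, 3))
    days <- sort(unique(month))
    flows_time <- "month"
  } else if (time == "year") {
    if (is.null(days)) stop("data has no day axis left", call. = FALSE)
    vals <- apply(vals, c(1, 3), sum)
    dim(vals) <- c(dim(vals)[1], 1L, dim(vals)[2])
    days <- NULL
    flows_time <- "year"
  } else {
    flows_time <- "day"
  }

  dimnames(vals) <- NULL
  out <- flow_samples(vals, key, quantity, lev, days)
  out$time <- flows_time
  out
}

# rowsum over the first margin of a 3-d array, preserving the other two.
rowsum_3d <- function(a, grp, groups = NULL) {
  d <- dim(a)
  m <- matrix(a, d[1], d[2] * d[3])
  rs <- rowsum(m, grp)
  if (!is.null(groups)) {
    full <- matrix(0, length(groups), ncol(rs),
                   dimnames = list(groups, NULL))
    full[rownames(rs)[rownames(rs) %in% groups], ] <-
      rs[rownames(rs) %in% groups, , drop = FALSE]
    rs <- full
  }
  out <- array(rs, c(nrow(rs), d[2], d[3]))
  rownames(out) <- rownames(rs)
  out
}

day_to_month <- function(days) {
  # non-leap calendar (the study year); day 366, if present, joins December
  ends <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  pmin(findInterval(pmin(days, 365) - 1, c(0, ends)), 12L)
}

#' Quantile summary of flow samples
#'
#' @param flows A \code{flow_samples} object with >= 2 samples.
#' @param probs Lower/upper quantile pair (default 90\% interval).
#' @return A data.frame with the key columns plus \code{time}, \code{median},
#'   \code{q05}, \code{q95} (mosquitoes per day, month, or covered window).
#' @export
summarize_flows <- function(flows, probs = c(0.05, 0.95)) {
  stopifnot(inherits(flows, "flow_samples"))
  d <- dim(flows$values)
  if (d[3] < 2L) stop("need >= 2 samples per key", call. = FALSE)
  time_labels <- flows$days %||% "all"
  rows <- vector("list", d[1] * d[2])
  idx <- 1L
  for (ki in seq_len(d[2])) {
    slab <- matrix(flows$values[, ki, ], nrow = d[1])
    qs <- t(apply(slab, 1, stats::quantile,
                  probs = c(probs[1], 0.5, probs[2]), names = FALSE, type = 7))
    if (d[1] == 1L && ncol(qs) != 3L) qs <- t(qs)
    for (ri in seq_len(d[1])) {
      rows[[idx]] <- cbind(flows$key[ri, , drop = FALSE],
                           data.frame(time = time_labels[ki],
                                      median = qs[ri, 2],
                                      q05 = qs[ri, 1],
                                      q95 = qs[ri, 3]))
      idx <- idx + 1L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Daily car trips that involve mosquito displacement
#'
#' Multiplies a daily trip count by the lower and upper credible-interval
#' endpoints of the transport probability, after rounding those endpoints
#' to the configured number of decimals (the printed precision of the
#' interval), and rounds to whole trips.
#'
#' @param daily_trips Nonnegative trip count.
#' @param theta_summary A \code{fit_summary} of transport probability.
#' @param decimals Decimals to which the interval endpoints are rounded
#'   before multiplying (default 4); \code{Inf} skips rounding.
#' @return Named numeric of length 2: \code{low}, \code{high}.
#' @examples
#' s <- structure(list(median = 0.0051, q05 = 0.0018, q95 = 0.0108,
#'                     prob_positive = 1, probs = c(.05, .95)),
#'                class = "fit_summary")
#' trips_with_mosquitoes(6528979, s)  # 11752, 70513
#' @export
trips_with_mosquitoes <- function(daily_trips, theta_summary, decimals = 4) {
  if (!is.numeric(daily_trips) || daily_trips < 0) {
    stop("'daily_trips' must be >= 0", call. = FALSE)
  }
  q <- c(theta_summary$q05, theta_summary$q95)
  if (is.finite(decimals)) q <- round(q, decimals)
  out <- round(daily_trips * q)
  names(out) <- c("low", "high")
  out
}
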