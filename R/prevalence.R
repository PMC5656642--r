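# Downscaling of gridded alert-probability posteriors to municipalities.
#
# Cell-level posterior draws live on a 0.05-degree sampling grid; the flux
# model needs municipality-level prevalence. Each municipal sample value is
# drawn by first picking an overlapping cell with probability equal to the
# fraction of the municipality's area it covers, then drawing uniformly
# from that cell's posterior draws -- equivalent to evaluating the alert
# probability at a spatially random point within the municipality.

#' Map a day of year to a bi-weekly period
#'
#' Periods are 14-day blocks anchored at day 1; period 26 absorbs the
#' leftover days 351-366.
#'
#' @param day_of_year Integer vector in 1-366.
#' @return Integer vector of periods in 1-26.
#' @examples
#' period_index(c(1, 14, 15, 200, 365))  # 1 1 2 15 26
#' @export
period_index <- function(day_of_year) {
  day_of_year <- as.integer(day_of_year)
  if (any(is.na(day_of_year)) || any(day_of_year < 1L | day_of_year > 366L)) {
    stop("day_of_year must be in 1..366", call. = FALSE)
  }
  pmin((day_of_year - 1L) %/% 14L + 1L, 26L)
}

#' Construct a cell posterior set
#'
#' @param values 3-d array of posterior draws, dimensions
#'   cell x period x draw, with cell ids as the first dimnames; all values
#'   in [0, 1].
#' @return A \code{cell_posteriors} object.
#' @export
cell_posteriors <- function(values) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (is.null(dimnames(values)[[1]])) {
    stop("cell dimension must be named with cell ids", call. = FALSE)
  }
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    stop("cell posterior draws must lie in [0, 1]", call. = FALSE)
  }
  structure(values, class = c("cell_posteriors", "array"))
}

#' Resample cell posteriors to municipalities
#'
#' @param cells A \code{cell_posteriors} array (cell x period x draw).
#' @param geography A \code{geography} object whose \code{overlaps} table
#'   gives the area fraction of each municipality covered by each cell
#'   (weights sum to 1 per municipality).
#' @param n_draws Municipal sample size per period (default 1000).
#' @param seed Integer seed.
#' @return A \code{municipal_prevalence} object: array
#'   municipality x period x draw with attribute \code{mask_applied = FALSE}.
#' @export
resample_to_municipalities <- function(cells, geography, n_draws = 1000L,
                                       seed = 1L) {
  stopifnot(inherits(cells, "cell_posteriors"))
  ov <- geography$overlaps
  cell_ids <- dimnames(cells)[[1]]
  missing_cells <- setdiff(unique(ov$cell_id), cell_ids)
  if (length(missing_cells)) {
    stop(sprintf("overlap table references cells absent from the posterior set: %s",
                 paste(utils::head(missing_cells, 5), collapse = ", ")),
         call. = FALSE)
  }
  wsum <- tapply(ov$weight, ov$municipality_id, sum)
  if (any(abs(wsum - 1) > 1e-9)) {
    stop("overlap weights must sum to 1 for every municipality",
         call. = FALSE)
  }
  munis <- geography$municipalities$municipality_id
  n_periods <- dim(cells)[2]
  n_cell_draws <- dim(cells)[3]
  out <- array(NA_real_, c(length(munis), n_periods, n_draws),
               dimnames = list(munis, NULL, NULL))
  set.seed(derive_seed(seed, 23L))
  for (mi in seq_along(munis)) {
    sub <- ov[ov$municipality_id == munis[mi], , drop = FALSE]
    ci <- match(sub$cell_id, cell_ids)
    for (t in seq_len(n_periods)) {
      pick <- sample.int(length(ci), n_draws, replace = TRUE,
                         prob = sub$weight)
      di <- sample.int(n_cell_draws, n_draws, replace = TRUE)
      out[mi, t, ] <- cells[cbind(ci[pick], t, di)]
    }
  }
  structure(out, mask_applied = FALSE,
            class = c("municipal_prevalence", "array"))
}

#' Zero out prevalence in municipalities without confirmed presence
#'
#' Alert probabilities are a proxy for prevalence only where the species is
#' officially confirmed; to keep flux estimates conservative, samples for
#' unconfirmed municipalities are replaced by zeros before any downstream
#' flux is computed.
#'
#' @param prev A \code{municipal_prevalence} object.
#' @param geography A \code{geography} with a \code{confirmed} flag per
#'   municipality.
#' @return The masked \code{municipal_prevalence}
#'   (\code{mask_applied = TRUE}).
#' @export
apply_confirmation_mask <- function(prev, geography) {
  stopifnot(inherits(prev, "municipal_prevalence"))
  munis <- dimnames(prev)[[1]]
  idx <- match(munis, geography$municipalities$municipality_id)
  if (anyNA(idx)) {
    stop("municipality missing from geography: ",
         paste(munis[is.na(idx)][1], collapse = ", "), call. = FALSE)
  }
  confirmed <- geography$municipalities$confirmed[idx]
  if (anyNA(confirmed)) {
    stop("missing confirmed flag for some municipalities", call. = FALSE)
  }
  prev[!confirmed, , ] <- 0
  attr(prev, "mask_applied") <- TRUE
  # the mask is authoritative for flux: downstream outgoing flow from these
  # municipalities is zeroed, not just their covariate
  attr(prev, "masked_municipalities") <- munis[!confirmed]
  prev
}

#' @export
print.municipal_prevalence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "municipal_prevalence: %d municipalities x %d periods x %d draws (mask %s)\n",
    d[1], d[2], d[3],
    if (isTRUE(attr(x, "mask_applied"))) "applied" else "not applied"
  ))
  invisible(x)
}
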