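# Shared fixtures: all built in code, no files.

# 2 provinces x 4 municipalities, hand-set populations and confirmation.
tiny_geography <- function(confirmed = c(TRUE, TRUE, TRUE, FALSE)) {
  geo <- list(
    provinces = c("A", "B"),
    municipalities = data.frame(
      municipality_id = c("m1", "m2", "m3", "m4"),
      province_id = c("A", "A", "B", "B"),
      population = c(2000, 8000, 3000, 7000),
      confirmed = confirmed,
      stringsAsFactors = FALSE
    ),
    cells = c("c1", "c2", "c3"),
    overlaps = data.frame(
      municipality_id = c("m1", "m1", "m2", "m3", "m3", "m4"),
      cell_id = c("c1", "c2", "c2", "c2", "c3", "c3"),
      weight = c(0.5, 0.5, 1, 0.25, 0.75, 1),
      stringsAsFactors = FALSE
    )
  )
  class(geo) <- "geography"
  geo
}

# cell posteriors where every draw of a cell equals a constant
point_cells <- function(values = c(c1 = 0.1, c2 = 0.2, c3 = 0.3),
                        n_periods = 26, n_draws = 20) {
  a <- array(rep(values, n_periods * n_draws),
             c(length(values), n_periods, n_draws),
             dimnames = list(names(values), NULL, NULL))
  tigerflux::cell_posteriors(a)
}

# wrap a bare coefficient matrix as posterior draws (degenerate fits for
# deterministic flux tests)
as_posterior_draws <- function(mat, chains = 1L) {
  mat <- as.matrix(mat)
  structure(mat,
            chain_id = rep(seq_len(chains), length.out = nrow(mat)),
            diagnostics = data.frame(
              coefficient = colnames(mat) %||% paste0("b", seq_len(ncol(mat))),
              rhat = NA_real_, ess = NA_real_
            ),
            convergence_warning = FALSE,
            class = c("posterior_draws", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# municipal prevalence with constant value per municipality
flat_prevalence <- function(munis, value = 0, n_periods = 26, n_draws = 10,
                            masked = character()) {
  a <- array(value, c(length(munis), n_periods, n_draws),
             dimnames = list(munis, NULL, NULL))
  structure(a, mask_applied = TRUE, masked_municipalities = masked,
            class = c("municipal_prevalence", "array"))
}

# recapture table with the published margins: 33 captured, 6 escaped, 9 lost
paper_recapture <- function() {
  data.frame(
    trial_id = sprintf("R%02d", 1:48),
    condition = rep(c("T5", "T10", "T10AC"), c(18, 14, 16)),
    # per-condition splits chosen to reproduce the overall 33/6/9 margins
    outcome = c(rep(c("captured", "escaped", "lost"), c(10, 3, 5)),   # T5
                rep(c("captured", "escaped", "lost"), c(10, 2, 2)),   # T10
                rep(c("captured", "escaped", "lost"), c(13, 1, 2))),  # T10AC
    stringsAsFactors = FALSE
  )
}
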