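# Synthetic-data generator: structure, seeded determinism, and the
# statistical properties the downstream pipeline assumes.

test_that("gen_geography builds a valid geography", {
  cfg <- synthetic_config(n_provinces = 2, n_municipalities = 6, seed = 11)
  geo <- gen_geography(cfg)
  expect_equal(nrow(geo$municipalities), 6)
  expect_true(all(geo$municipalities$province_id %in% geo$provinces))
  wsum <- tapply(geo$overlaps$weight, geo$overlaps$municipality_id, sum)
  expect_true(all(abs(wsum - 1) < 1e-9))
  expect_true(any(!geo$municipalities$confirmed))
  expect_true(all(geo$municipalities$population >= 0))

  # degenerate case: one municipality, one cell -> single weight 1
  geo1 <- gen_geography(synthetic_config(n_provinces = 1,
                                         n_municipalities = 1,
                                         n_cells = 1, seed = 2))
  expect_equal(nrow(geo1$overlaps), 1)
  expect_equal(geo1$overlaps$weight, 1)

  # default scale: most municipalities overlapped by several cells
  geod <- gen_geography(synthetic_config(seed = 5))
  per_mun <- table(geod$overlaps$municipality_id)
  expect_gte(stats::median(per_mun), 2)

  expect_error(synthetic_config(n_cells = 0), "positive")
})

test_that("gen_cell_posteriors is seasonal and bounded", {
  cfg <- synthetic_config(seed = 7, draws_per_cell = 40,
                          seasonal_peak_period = 17)
  geo <- gen_geography(cfg)
  cells <- gen_cell_posteriors(geo, cfg)
  expect_equal(dim(cells), c(50, 26, 40))
  expect_true(all(cells >= 0 & cells <= 1))
  # peak-period mean exceeds trough mean across >1000 draws
  expect_gt(mean(cells[, 17, ]), mean(cells[, 3, ]))
})

test_that("gen_car_stops matches its Bernoulli model", {
  cfg <- synthetic_config(seed = 3, true_slope = 0,
                          true_intercept = qlogis(4 / 770))
  geo <- gen_geography(cfg)
  cells <- gen_cell_posteriors(geo, cfg)
  prev <- resample_to_municipalities(cells, geo, n_draws = 100, seed = 4)

  # n = 0 -> empty table with full schema
  cfg0 <- synthetic_config(seed = 3, n_stops = 0)
  empty <- gen_car_stops(geo, prev, cfg0)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("stop_id", "detected", "alert_prob") %in% names(empty)))

  # with slope 0 and intercept logit(4/770), expected detections = 4;
  # check the replicate mean within 3 standard errors (sd per replicate
  # sqrt(770 * p * (1-p)) ~ 1.99)
  n_rep <- 300
  counts <- vapply(seq_len(n_rep), function(r) {
    sum(gen_car_stops(geo, prev,
                      synthetic_config(seed = 1000 + r, true_slope = 0,
                                       true_intercept = qlogis(4 / 770))
                      )$detected)
  }, numeric(1))
  se <- sqrt(770 * (4 / 770) * (1 - 4 / 770)) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - 4), 3 * se)

  # strong positive slope -> higher detection rate in high-prevalence origins
  det_hi <- det_lo <- n_hi <- n_lo <- 0
  for (r in 1:40) {
    st <- gen_car_stops(geo, prev,
                        synthetic_config(seed = 500 + r, true_slope = 12,
                                         true_intercept = qlogis(4 / 770)))
    qs <- stats::quantile(st$alert_prob, c(0.25, 0.75))
    hi <- st$alert_prob >= qs[2]; lo <- st$alert_prob <= qs[1]
    det_hi <- det_hi + sum(st$detected[hi]); n_hi <- n_hi + sum(hi)
    det_lo <- det_lo + sum(st$detected[lo]); n_lo <- n_lo + sum(lo)
  }
  expect_gt(det_hi / n_hi, det_lo / n_lo)

  expect_error(
    gen_car_stops(list(municipalities = data.frame()), prev, cfg),
    "empty"
  )
})

test_that("gen_recapture_trials draws the configured trinomials", {
  cfg <- synthetic_config(seed = 9)
  tr <- gen_recapture_trials(cfg)
  expect_equal(nrow(tr), 48)
  expect_equal(as.integer(table(tr$condition)[c("T5", "T10", "T10AC")]),
               c(18L, 14L, 16L))

  # capture probability 1 -> everything captured
  p1 <- matrix(c(1, 0, 0), 3, 3, byrow = FALSE,
               dimnames = list(c("T5", "T10", "T10AC"),
                               c("captured", "escaped", "lost")))
  p1[, 1] <- 1; p1[, 2:3] <- 0
  tr1 <- gen_recapture_trials(synthetic_config(seed = 1,
                                               recapture_probs = p1))
  expect_true(all(tr1$outcome == "captured"))

  # uniform capture prob 0.6875: replicate mean of captured near 33
  pu <- cbind(captured = rep(33 / 48, 3), escaped = rep(6 / 48, 3),
              lost = rep(9 / 48, 3))
  rownames(pu) <- c("T5", "T10", "T10AC")
  n_rep <- 1000
  caps <- vapply(seq_len(n_rep), function(r) {
    sum(gen_recapture_trials(
      synthetic_config(seed = 2000 + r, recapture_probs = pu)
    )$outcome == "captured")
  }, numeric(1))
  se <- sqrt(48 * (33 / 48) * (15 / 48)) / sqrt(n_rep)
  expect_lt(abs(mean(caps) - 33), 3 * se)

  bad <- pu; bad[1, 1] <- 0.9
  expect_error(synthetic_config(recapture_probs = bad), "sum")
})

test_that("gen_commuters is gravity-like with a zero diagonal", {
  cfg <- synthetic_config(seed = 13)
  geo <- gen_geography(cfg)
  od <- gen_commuters(geo, cfg)
  expect_true(all(diag(od) == 0))
  expect_true(all(od >= 0))

  od0 <- gen_commuters(geo, synthetic_config(seed = 13, od_scale = 0))
  expect_true(all(od0 == 0))

  # unequal provinces: the most populous pair dominates the least populous
  geo4 <- tiny_geography()
  geo4$provinces <- c("A", "B", "C", "D")
  geo4$municipalities <- data.frame(
    municipality_id = paste0("m", 1:4),
    province_id = c("A", "B", "C", "D"),
    population = c(1e6, 9e5, 2e3, 1e3),
    confirmed = TRUE, stringsAsFactors = FALSE
  )
  big <- small <- 0
  for (r in 1:30) {
    odr <- gen_commuters(geo4, synthetic_config(seed = 100 + r,
                                                od_scale = 5000))
    big <- big + odr["A", "B"]
    small <- small + odr["C", "D"]
  }
  expect_gt(big, small)

  geo1 <- gen_geography(synthetic_config(n_provinces = 1,
                                         n_municipalities = 2, seed = 1))
  expect_error(gen_commuters(geo1, cfg), "2 provinces")
})

test_that("fixed seed fixes every generated table bit-for-bit", {
  w1 <- gen_world(synthetic_config(seed = 77), n_prev_draws = 50)
  w2 <- gen_world(synthetic_config(seed = 77), n_prev_draws = 50)
  expect_identical(w1$car_stops, w2$car_stops)
  expect_identical(w1$recapture, w2$recapture)
  expect_identical(unclass(w1$od), unclass(w2$od))
  expect_identical(as.vector(w1$prevalence), as.vector(w2$prevalence))
  w3 <- gen_world(synthetic_config(seed = 78), n_prev_draws = 50)
  expect_false(identical(w1$car_stops, w3$car_stops))
})

test_that("pipeline recovers known coefficients at roughly nominal coverage", {
  # reduced-count analogue of the 100-replicate recovery study: the naive
  # (intercept-only) route is checked with the deterministic quadrature
  # posterior; the covariate route with a few MCMC fits.
  a0 <- qlogis(4 / 770)
  covered <- 0
  for (r in 1:20) {
    cfg <- synthetic_config(seed = 3000 + r, true_slope = 0,
                            true_intercept = a0,
                            n_municipalities = 12, n_cells = 15)
    geo <- gen_geography(cfg)
    cells <- gen_cell_posteriors(geo, cfg)
    prev <- resample_to_municipalities(cells, geo, n_draws = 60,
                                       seed = cfg$seed)
    stops <- gen_car_stops(geo, prev, cfg)
    q <- quadrature_posterior(sum(stops$detected), nrow(stops))
    covered <- covered + (q$q05 <= plogis(a0) && plogis(a0) <= q$q95)
  }
  expect_gte(covered, 14)  # ~90% nominal, loose binomial bound at n = 20

  cov_a <- cov_b <- 0
  for (r in 1:8) {
    cfg <- synthetic_config(seed = 4000 + r, true_slope = 6,
                            true_intercept = a0,
                            n_municipalities = 12, n_cells = 15)
    geo <- gen_geography(cfg)
    cells <- gen_cell_posteriors(geo, cfg)
    prev <- resample_to_municipalities(cells, geo, n_draws = 60,
                                       seed = cfg$seed)
    stops <- gen_car_stops(geo, prev, cfg)
    fit <- suppressWarnings(fit_bayes_logistic(
      cbind(alert = stops$alert_prob), stops$detected,
      chains = 2, iter = 700, warmup = 500, seed = r
    ))
    sa <- summarize_draws(fit[, 1]); sb <- summarize_draws(fit[, 2])
    cov_a <- cov_a + (sa$q05 <= a0 && a0 <= sa$q95)
    cov_b <- cov_b + (sb$q05 <= 6 && 6 <= sb$q95)
  }
  expect_gte(cov_a, 5)
  expect_gte(cov_b, 5)
})
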