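# Commuter-flow downscaling and the flux equations, checked against
# closed forms and a brute-force nested-loop oracle.

mk_mun_od <- function(m, prov) {
  structure(m, province = prov,
            class = c("municipal_od", "matrix", "array"))
}

mk_field <- function(values, munis, days) {
  structure(values, days = days, adjusted = FALSE,
            masked_municipalities = character(),
            class = c("transport_field", "array"))
}

test_that("downscale_od splits flows by population shares", {
  geo <- tiny_geography()   # pops A: 2000+8000, B: 3000+7000
  od <- province_od(matrix(c(0, 1000, 500, 0), 2, byrow = TRUE,
                           dimnames = list(c("A", "B"), c("A", "B"))))
  mun <- downscale_od(od, geo)
  # F_m1,m3 = 1000 * (2000/10000) * (3000/10000) = 60
  expect_equal(mun["m1", "m3"], 60)
  expect_equal(mun["m2", "m4"], 1000 * 0.8 * 0.7)
  # conservation over the pair
  expect_equal(sum(mun[c("m1", "m2"), c("m3", "m4")]), 1000)
  expect_equal(sum(mun[c("m3", "m4"), c("m1", "m2")]), 500)

  geo0 <- geo
  geo0$municipalities$population[1] <- 0
  mun0 <- downscale_od(od, geo0)
  expect_true(all(mun0["m1", ] == 0) && all(mun0[, "m1"] == 0))

  geoz <- geo
  geoz$municipalities$population[geoz$municipalities$province_id == "B"] <- 0
  expect_error(downscale_od(od, geoz), "zero population")

  expect_error(province_od(matrix(c(1, 2, 3, 4), 2,
                                  dimnames = list(c("A", "B"), c("A", "B")))),
               "diagonal")
})

test_that("transport_field applies the model pointwise", {
  munis <- c("m1", "m2")
  prev0 <- flat_prevalence(munis, value = 0, n_draws = 5)
  # degenerate posterior: single draw alpha = logit(0.01), beta = 0
  d <- as_posterior_draws(cbind(a = qlogis(0.01), b = 0))
  f <- transport_field(prev0, d, days = 1:3, L = 10, seed = 1)
  expect_equal(as.vector(f), rep(0.01, 2 * 3 * 10))

  # zero prevalence: P = inv-logit(alpha_l) regardless of slope
  d2 <- as_posterior_draws(cbind(a = c(-2, -1, 0), b = c(5, 5, 5)))
  f2 <- transport_field(prev0, d2, days = 10, L = 200, seed = 2)
  expect_true(all(as.vector(f2) %in% plogis(c(-2, -1, 0))))
  expect_true(all(f2 >= 0 & f2 <= 1))

  # unmasked prevalence warns
  prev_u <- flat_prevalence(munis, 0.1)
  attr(prev_u, "mask_applied") <- FALSE
  expect_warning(transport_field(prev_u, d, days = 1, L = 5, seed = 1),
                 "mask")
  # out-of-range day errors via the period grid
  expect_error(transport_field(prev0, d, days = 400, L = 5, seed = 1),
               "1..366")
})

test_that("municipal_flux computes (F_ij + F_ji) * P_ik", {
  prov <- c(m1 = "A", m2 = "B")
  Fm <- matrix(c(0, 100, 50, 0), 2, byrow = TRUE,
               dimnames = list(c("m1", "m2"), c("m1", "m2")))
  od <- mk_mun_od(Fm, prov)
  field <- mk_field(array(0.01, c(2, 1, 4),
                          dimnames = list(c("m1", "m2"), NULL, NULL)),
                    days = 244)
  fl <- municipal_flux(od, field)
  m12 <- fl$values[fl$key$origin == "m1", 1, ]
  expect_equal(as.numeric(m12), rep(1.5, 4))   # (100 + 50) * 0.01

  # zero probability -> zero flux
  field0 <- mk_field(array(0, c(2, 1, 4),
                           dimnames = list(c("m1", "m2"), NULL, NULL)),
                     days = 244)
  expect_equal(sum(municipal_flux(od, field0)$values), 0)

  # quantiles scale linearly in (F_ij + F_ji)
  set.seed(4)
  pvals <- runif(60, 0, 0.02)
  fieldr <- mk_field(array(rep(pvals, each = 2), c(2, 1, 60),
                           dimnames = list(c("m1", "m2"), NULL, NULL)),
                     days = 1)
  flr <- municipal_flux(od, fieldr)
  q_m1 <- quantile(flr$values[flr$key$origin == "m1", 1, ], c(.05, .5, .95))
  expect_equal(unname(q_m1), unname(150 * quantile(pvals, c(.05, .5, .95))))
})

test_that("aggregations match a brute-force nested-loop oracle", {
  geo <- tiny_geography(confirmed = rep(TRUE, 4))
  munis <- geo$municipalities$municipality_id
  prov <- stats::setNames(geo$municipalities$province_id, munis)
  set.seed(77)
  Fm <- matrix(runif(16, 0, 100), 4, dimnames = list(munis, munis))
  diag(Fm) <- 0
  Fm[prov[row(Fm)] == prov[col(Fm)]] <- 0   # inter-province only
  od <- mk_mun_od(Fm, prov)
  days <- c(244, 245, 246)
  L <- 5
  P <- array(runif(4 * 3 * L, 0, 0.05), c(4, 3, L),
             dimnames = list(munis, NULL, NULL))
  field <- mk_field(P, days = days)

  fl <- municipal_flux(od, field)
  pair <- aggregate_flows(fl, level = "province_pair")
  out <- aggregate_flows(fl, level = "out")
  inn <- aggregate_flows(fl, level = "in")
  net <- aggregate_flows(fl, level = "net")

  provs <- c("A", "B")
  for (k in 1:3) for (l in 1:L) {
    # oracle: loop every ordered municipality pair
    M <- matrix(0, 4, 4, dimnames = list(munis, munis))
    for (i in 1:4) for (j in 1:4) {
      if (i != j && prov[i] != prov[j] && (Fm[i, j] + Fm[j, i]) > 0) {
        M[i, j] <- (Fm[i, j] + Fm[j, i]) * P[i, k, l]
      }
    }
    for (a in provs) for (b in provs) {
      if (a == b) next
      expected <- sum(M[prov[munis] == a, prov[munis] == b])
      got <- pair$values[pair$key$origin == a & pair$key$destination == b,
                         k, l]
      expect_equal(got, expected, tolerance = 1e-12)
    }
    for (a in provs) {
      O_a <- sum(M[prov[munis] == a, ])
      I_a <- sum(M[, prov[munis] == a])
      expect_equal(out$values[out$key$province == a, k, l], O_a,
                   tolerance = 1e-12)
      expect_equal(inn$values[inn$key$province == a, k, l], I_a,
                   tolerance = 1e-12)
      expect_equal(net$values[net$key$province == a, k, l], O_a - I_a,
                   tolerance = 1e-12)
    }
    # mass conservation and zero-sum net flow per (k, l)
    expect_equal(sum(pair$values[, k, l]), sum(fl$values[, k, l]),
                 tolerance = 1e-12)
    expect_equal(sum(net$values[, k, l]), 0, tolerance = 1e-10)
  }
})

test_that("one-directional toy gives O_a = I_b and N_a = -N_b", {
  prov <- c(m1 = "A", m2 = "B")
  Fm <- matrix(c(0, 80, 0, 0), 2, byrow = TRUE,
               dimnames = list(c("m1", "m2"), c("m1", "m2")))
  od <- mk_mun_od(Fm, prov)
  # give m2 zero probability so flux flows only A -> B
  P <- array(c(0.02, 0), c(2, 1, 3), dimnames = list(c("m1", "m2"), NULL, NULL))
  field <- mk_field(P, days = 100)
  fl <- municipal_flux(od, field)
  out <- aggregate_flows(fl, level = "out")
  inn <- aggregate_flows(fl, level = "in")
  net <- aggregate_flows(fl, level = "net")
  expect_equal(out$values[out$key$province == "A", 1, ],
               inn$values[inn$key$province == "B", 1, ])
  expect_equal(net$values[net$key$province == "A", 1, ],
               -net$values[net$key$province == "B", 1, ])
})

test_that("time aggregation sums days into months and the season", {
  prov <- c(m1 = "A", m2 = "B")
  Fm <- matrix(c(0, 10, 10, 0), 2, dimnames = list(c("m1", "m2"),
                                                   c("m1", "m2")))
  od <- mk_mun_od(Fm, prov)
  days <- c(59, 60, 61, 91)  # Feb 28, Mar 1, Mar 2, Apr 1
  P <- array(0.01, c(2, 4, 2), dimnames = list(c("m1", "m2"), NULL, NULL))
  field <- mk_field(P, days = days)
  fl <- municipal_flux(od, field)
  mo <- aggregate_flows(fl, time = "month")
  expect_equal(mo$days, c(2L, 3L, 4L))
  a_row <- which(mo$key$origin == "m1")
  expect_equal(mo$values[a_row, , 1], c(0.2, 0.4, 0.2))
  yr <- aggregate_flows(fl, time = "year")
  expect_equal(yr$values[a_row, 1, 1], 0.8)
  expect_error(aggregate_flows(aggregate_flows(fl, level = "province_pair"),
                               level = "province_pair"), "already")
})

test_that("masked origin municipalities contribute zero outgoing flux", {
  geo <- tiny_geography(confirmed = c(TRUE, TRUE, FALSE, FALSE))  # B masked
  cells <- point_cells()
  prev <- resample_to_municipalities(cells, geo, n_draws = 30, seed = 1)
  prev <- apply_confirmation_mask(prev, geo)
  od <- downscale_od(
    province_od(matrix(c(0, 500, 700, 0), 2, byrow = TRUE,
                       dimnames = list(c("A", "B"), c("A", "B")))), geo)
  d <- as_posterior_draws(cbind(a = rep(qlogis(0.01), 6), b = rep(2, 6)))
  field <- transport_field(prev, d, days = 244, L = 20, seed = 3)
  fl <- municipal_flux(od, field)
  out <- aggregate_flows(fl, level = "out")
  expect_true(all(out$values[out$key$province == "B", , ] == 0))
  expect_true(all(out$values[out$key$province == "A", , ] > 0))
})

test_that("summarize_flows orders quantiles and shrinks relative spread", {
  prov <- c(m1 = "A", m2 = "B")
  Fm <- matrix(c(0, 10, 10, 0), 2, dimnames = list(c("m1", "m2"),
                                                   c("m1", "m2")))
  od <- mk_mun_od(Fm, prov)
  set.seed(11)
  days <- 60:119
  P <- array(runif(2 * 60 * 100, 0, 0.03), c(2, 60, 100),
             dimnames = list(c("m1", "m2"), NULL, NULL))
  field <- mk_field(P, days = days)
  fl <- municipal_flux(od, field)
  s <- summarize_flows(fl)
  expect_true(all(s$q05 <= s$median & s$median <= s$q95))

  # aggregation of independent samples reduces the coefficient of variation
  cv <- function(v) sd(v) / mean(v)
  yr <- aggregate_flows(aggregate_flows(fl, level = "out"), time = "year")
  cv_year <- cv(yr$values[1, 1, ])
  cv_day <- cv(fl$values[1, 1, ])
  expect_lt(cv_year, cv_day)

  const <- mk_field(array(0.01, c(2, 1, 5),
                          dimnames = list(c("m1", "m2"), NULL, NULL)),
                    days = 1)
  sc <- summarize_flows(municipal_flux(od, const))
  expect_equal(sc$q05, sc$q95)
})

test_that("seasonal prevalence propagates into monthly outflows", {
  geo <- tiny_geography(confirmed = rep(TRUE, 4))
  cfg <- synthetic_config(seed = 21, seasonal_peak_period = 17)
  cells <- gen_cell_posteriors(geo, cfg)
  prev <- apply_confirmation_mask(
    resample_to_municipalities(cells, geo, n_draws = 80, seed = 2), geo)
  od <- downscale_od(
    province_od(matrix(c(0, 800, 900, 0), 2, byrow = TRUE,
                       dimnames = list(c("A", "B"), c("A", "B")))), geo)
  d <- as_posterior_draws(cbind(a = rep(qlogis(0.005), 30),
                                b = rep(8, 30)))
  field <- transport_field(prev, d, days = seq(70, 350, by = 7), L = 40,
                           seed = 5)
  mo <- aggregate_flows(aggregate_flows(municipal_flux(od, field),
                                        level = "out"), time = "month")
  med <- apply(mo$values[1, , ], 1, median)
  # seasonal mean prevalence per month (period 17 ~ mid-August peak)
  season <- (1 + cos(2 * pi * (period_index(seq(70, 350, by = 7)) - 17) / 26)) / 2
  month_season <- tapply(season, tigerflux:::day_to_month(seq(70, 350, by = 7)),
                         mean)
  expect_gt(cor(med, month_season, method = "spearman"), 0)
})

test_that("trips_with_mosquitoes reproduces the printed arithmetic", {
  s <- summarize_draws(c(0.0018, 0.0051, 0.0108))  # any summary container
  s$q05 <- 0.0018; s$q95 <- 0.0108
  expect_equal(unname(trips_with_mosquitoes(6528979, s)), c(11752, 70513))
  expect_equal(unname(trips_with_mosquitoes(0, s)), c(0, 0))
  expect_error(trips_with_mosquitoes(-1, s), ">= 0")

  # efficiency-adjusted quantiles scale the endpoints by ~1/r below the cap
  s2 <- s; r <- 33 / 48
  s2$q05 <- s$q05 / r; s2$q95 <- s$q95 / r
  t1 <- trips_with_mosquitoes(6528979, s, decimals = Inf)
  t2 <- trips_with_mosquitoes(6528979, s2, decimals = Inf)
  expect_equal(unname(t2 / t1), c(1 / r, 1 / r), tolerance = 1e-4)
})
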