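test_that("the multiplier of a series matches hand arithmetic", {
  expect_equal(growth_multiplier_series(c(1000, 1100, 990)),
               sqrt(1.1 * 0.9), tolerance = 1e-12)
  expect_equal(growth_multiplier_series(c(1000, 1100, 990)), 0.994987,
               tolerance = 1e-6)
  expect_equal(growth_multiplier_series(rep(640, 8)), 1)
  # occupancy gap: only the first pair contributes
  expect_equal(growth_multiplier_series(c(100, 110, 0, 130)), 1.1)
  expect_true(is.na(growth_multiplier_series(c(0, 100, 0))))
})

test_that("reversing a series inverts its multiplier", {
  set.seed(50)
  for (i in 1:100) {
    N <- exp(cumsum(rnorm(sample(3:12, 1), 0, 0.4))) * 500
    m <- growth_multiplier_series(N)
    expect_equal(growth_multiplier_series(rev(N)), 1 / m, tolerance = 1e-10)
  }
})

test_that("actual multipliers aggregate draws with occupancy-aware pairs", {
  logN <- array(NA_real_, c(2, 1, 4), list(NULL, "A", 2000:2003))
  logN[1, 1, ] <- log(c(1000, 1100, 990, 990))
  logN[2, 1, ] <- log(c(500, 550, 605, 665.5))
  z <- array(1, dim(logN), dimnames(logN))
  fit <- make_fake_fit(logN, z = z)
  gm <- growth_multipliers(fit, "actual")
  expect_equal(unname(gm$draws[1, "A"]), (1.1 * 0.9 * 1)^(1/3),
               tolerance = 1e-10)
  expect_equal(unname(gm$draws[2, "A"]), 1.1, tolerance = 1e-10)

  # draw 2 loses the middle pairs to an occupancy gap
  z2 <- z; z2[2, 1, 3] <- 0
  fit2 <- make_fake_fit(logN, z = z2)
  gm2 <- growth_multipliers(fit2, "actual")
  expect_equal(unname(gm2$draws[2, "A"]), 1.1, tolerance = 1e-10)

  # a draw with no occupied pair is excluded and counted
  z3 <- z; z3[2, 1, c(2, 4)] <- 0
  fit3 <- make_fake_fit(logN, z = z3)
  gm3 <- growth_multipliers(fit3, "actual")
  expect_true(is.na(gm3$draws[2, "A"]))
  expect_equal(gm3$summary$n_excluded, 1)
})

test_that("predicted multipliers equal exp(r) and match actuals when noise-free", {
  # constant r = beta1 = 0.05, no covariate or year effects
  TT <- 5
  logN <- array(rep(log(800) + 0.05 * (0:(TT - 1)), each = 3), c(3, 1, TT),
                list(NULL, "A", 2000:2004))
  fit <- make_fake_fit(logN, params = list(beta1 = 0.05, beta2 = 0,
                                           beta3 = 0, sigma_process = 1e-12))
  pred <- growth_multipliers(fit, "predicted")
  act <- growth_multipliers(fit, "actual")
  expect_equal(unname(pred$draws[, "A"]), rep(exp(0.05), 3), tolerance = 1e-10)
  expect_equal(pred$draws, act$draws, tolerance = 1e-10)
})

test_that("predicted and actual multipliers diverge as process noise grows", {
  set.seed(51)
  gap <- sapply(c(0.05, 0.4), function(sig) {
    TT <- 15
    steps <- matrix(rnorm(200 * (TT - 1), 0.02, sig), 200)
    logN <- array(NA_real_, c(200, 1, TT), list(NULL, "A", 2000:2014))
    logN[, 1, ] <- cbind(log(1000), log(1000) + t(apply(steps, 1, cumsum)))
    fit <- make_fake_fit(logN, params = list(beta1 = 0.02, beta2 = 0,
                                             beta3 = 0, sigma_process = sig))
    a <- growth_multipliers(fit, "actual")$draws[, 1]
    p <- growth_multipliers(fit, "predicted")$draws[, 1]
    mean(abs(a - p))
  })
  expect_gt(gap[2], gap[1])
})

test_that("aggregation is additive draw by draw", {
  # degenerate posteriors 100 and 200 -> aggregate exactly 300, zero width
  logN <- array(NA_real_, c(4, 2, 2), list(NULL, c("A", "B"), 2000:2001))
  logN[, 1, ] <- log(100); logN[, 2, ] <- log(200)
  fit <- make_fake_fit(logN)
  agg <- apd_aggregate(fit, regions = c(A = "48.1", B = "48.1"))
  expect_equal(as.numeric(agg$draws), rep(300, 8), tolerance = 1e-12)
  expect_equal(agg$summary$lower, agg$summary$upper)  # zero-width intervals
  # additivity is exact draw by draw, not merely in expectation
  expect_identical(agg$draws[, 1, ], exp(logN[, 1, ]) + exp(logN[, 2, ]))

  # a singleton region reproduces the site posterior exactly
  agg2 <- apd_aggregate(fit, regions = c(A = "r1", B = "r2"))
  expect_equal(agg2$draws[, "r1", ], exp(logN[, 1, ]) * 1,
               ignore_attr = TRUE)

  # exact additivity on a real fit
  fit_real <- shared_small_fit()
  agg3 <- apd_aggregate(fit_real)
  N <- abundance_draws(fit_real)
  expect_equal(agg3$draws[, 1, ], apply(N, c(1, 3), sum), ignore_attr = TRUE)
})

test_that("the aggregate median is not the sum of site medians in general", {
  logN <- array(NA_real_, c(3, 2, 1), list(NULL, c("A", "B"), 2000))
  logN[, 1, 1] <- log(c(1, 2, 10))
  logN[, 2, 1] <- log(c(10, 2, 1))
  fit <- make_fake_fit(logN)
  agg <- apd_aggregate(fit, regions = c(A = "r", B = "r"))
  med_sum <- median(c(11, 4, 11))
  sum_med <- 2 + 2
  expect_equal(agg$summary$median, med_sum)
  expect_false(isTRUE(all.equal(med_sum, sum_med)))

  # comonotone draws: equality holds
  logN2 <- logN; logN2[, 2, 1] <- log(c(1, 2, 10))
  fit2 <- make_fake_fit(logN2)
  agg2 <- apd_aggregate(fit2, regions = c(A = "r", B = "r"))
  expect_equal(agg2$summary$median, 2 + 2)
})

test_that("finite-population SDs match hand arithmetic and scale linearly", {
  TT <- 3
  logN <- array(log(500), c(2, 1, TT), list(NULL, "A", 2000:2002))
  fit <- make_fake_fit(logN, params = list(eps = matrix(c(-1, 1, -1, 1),
                                                        2, 2, byrow = FALSE)))
  # each draw's realized year effects are {-1, +1}: sd = sqrt(2)
  fit$params[, "eps[2000]"] <- c(-1, -1)
  fit$params[, "eps[2001]"] <- c(1, 1)
  fp <- finite_population_sd(fit)
  expect_equal(unname(fp$draws[, "year_effects"]), rep(sqrt(2), 2),
               tolerance = 1e-12)

  # all-equal year effects give SD zero
  fit$params[, "eps[2000]"] <- 0.3
  fit$params[, "eps[2001]"] <- 0.3
  fp0 <- finite_population_sd(fit)
  expect_equal(unname(fp0$draws[, "year_effects"]), c(0, 0))

  # scaling beta2 by c scales the winter-term SD by |c|
  xw <- matrix(seq(-1, 1, length.out = 3), 1, 3,
               dimnames = list("A", 2000:2002))
  f1 <- make_fake_fit(logN, params = list(beta2 = 0.05), x_winter = xw)
  f2 <- make_fake_fit(logN, params = list(beta2 = -0.15), x_winter = xw)
  s1 <- finite_population_sd(f1)$draws[, "winter"]
  s2 <- finite_population_sd(f2)$draws[, "winter"]
  expect_equal(s2, 3 * s1, tolerance = 1e-12)
})

test_that("the obs-vs-process fraction counts codes below the process draw", {
  # constructed oracle: codes {1,1,5,5}, sigma_process between the scales
  expect_equal(obs_process_fraction(0.1, c(1, 1, 5, 5)), 0.5)
  expect_equal(obs_process_fraction(0, c(1, 1, 5, 5)), 0)
  expect_equal(obs_process_fraction(0.5, c(1, 1, 5, 5)), 1)
  # monotone nondecreasing in the process draw
  grid <- seq(0, 0.5, by = 0.01)
  fr <- obs_process_fraction(grid, c(1, 2, 3, 4, 5, 5))
  expect_true(all(diff(fr) >= 0))
})

test_that("obs_vs_process on a fit uses the recorded accuracy codes", {
  counts <- data.frame(site_id = "A", season = c(2000, 2000, 2001, 2001),
                       count_type = c("nest", "chick", "nest", "chick"),
                       count = c(50L, 40L, 60L, 45L),
                       accuracy = c(1L, 1L, 5L, 5L), stringsAsFactors = FALSE)
  sites <- data.frame(site_id = "A", region = "48.1")
  ice <- data.frame(site_id = "A", season = 1996:2001,
                    winter_peak = seq(0.2, 0.7, 0.1),
                    summer_peak = seq(0.7, 0.2, -0.1))
  ds <- apd_dataset(counts, sites, ice, season_range = c(2000, 2001))
  logN <- array(log(50), c(10, 1, 2), list(NULL, "A", 2000:2001))
  fit <- make_fake_fit(logN, params = list(sigma_process = 0.1), dataset = ds)
  ov <- obs_vs_process(fit)
  expect_equal(ov$median, 0.5)
  expect_equal(unname(ov$draws), rep(0.5, 10))
  expect_equal(ov$n_counts, 4)
})

test_that("year-effect correlations behave under affine, null and degenerate indices", {
  TT <- 21
  logN <- array(log(100), c(50, 1, TT), list(NULL, "A", 1990:2010))
  set.seed(52)
  eps_draws <- matrix(rnorm(50 * (TT - 1), 0, 0.2), 50)
  fit <- make_fake_fit(logN, params = list(eps = eps_draws))
  eps_med <- apply(eps_draws, 2, median)
  seasons <- as.character(1990:2009)

  # affine transform of the posterior-median effects: correlation 1 there
  idx <- setNames(3 * eps_med + 0.7, seasons)
  yc <- year_effect_correlation(fit, idx)
  expect_equal(yc$median_based, 1, tolerance = 1e-10)

  # independent white noise: small posterior-median correlation
  idx2 <- setNames(rnorm(20), seasons)
  yc2 <- year_effect_correlation(fit, idx2)
  expect_lt(abs(yc2$median), 0.5)
  expect_true(mean(abs(yc2$draws) < 0.5) > 0.5)

  expect_error(year_effect_correlation(fit, setNames(rep(1, 20), seasons)),
               "zero variance")
  expect_error(year_effect_correlation(fit, setNames(rnorm(2),
                                                     c("1990", "1991"))),
               "fewer than 3")
})

test_that("density dependence diagnostics flag a ceiling but not a null", {
  set.seed(53)
  TT <- 60
  r <- 0.05; sig <- 0.15; cap <- log(4000)
  ln_null <- numeric(TT); ln_null[1] <- log(500)
  ln_cap <- ln_null
  for (t in 2:TT) {
    ln_null[t] <- ln_null[t - 1] + r + rnorm(1, 0, sig)
    ln_cap[t] <- min(ln_cap[t - 1] + r + rnorm(1, 0, sig), cap)
  }
  wrap <- function(ln) {
    a <- array(rep(ln, each = 2), c(2, 1, TT),
               list(NULL, "A", seq(1950, length.out = TT)))
    make_fake_fit(a, params = list(beta1 = r, beta2 = 0, beta3 = 0,
                                   sigma_process = sig))
  }
  dd_null <- density_dependence(wrap(ln_null))
  expect_equal(nrow(dd_null), TT - 1)
  expect_lt(abs(cor(dd_null$N, dd_null$r_realized - dd_null$r_predicted)),
            0.4)
  dd_cap <- density_dependence(wrap(ln_cap))
  big <- dd_cap$N > 0.8 * exp(cap)
  expect_gt(sum(big), 3)
  expect_lt(mean((dd_cap$r_realized - dd_cap$r_predicted)[big]), 0)

  # a single season cannot form pairs
  one <- make_fake_fit(array(log(100), c(2, 1, 1), list(NULL, "A", 2000)))
  expect_warning(dd1 <- density_dependence(one), "two seasons")
  expect_equal(nrow(dd1), 0)
})

test_that("posterior-predictive intervals collapse without noise and scale with alpha", {
  tiny <- apd_spec(accuracy_envelopes = c(1e-9, 2e-9, 3e-9, 4e-9, 5e-9))
  counts <- data.frame(site_id = "A", season = c(2000, 2000),
                       count_type = c("nest", "chick"),
                       count = c(500L, 600L), accuracy = c(1L, 1L),
                       stringsAsFactors = FALSE)
  sites <- data.frame(site_id = "A", region = "48.1")
  ice <- data.frame(site_id = "A", season = 1996:2000,
                    winter_peak = seq(0.2, 0.6, 0.1),
                    summer_peak = seq(0.6, 0.2, -0.1))
  ds <- apd_dataset(counts, sites, ice, season_range = c(2000, 2000))
  logN <- array(log(500), c(20, 1, 1), list(NULL, "A", 2000))
  alpha <- array(1.2, dim(logN), dimnames(logN))
  fit <- make_fake_fit(logN, alpha = alpha, dataset = ds, spec = tiny)
  pp <- posterior_predictive_counts(fit, seed = 1)
  expect_equal(pp$pred_lower, pp$pred_upper)           # degenerate intervals
  expect_equal(pp$pred_median[pp$count_type == "nest"], 500)
  # chick interval centre = nest centre x alpha
  expect_equal(pp$pred_median[pp$count_type == "chick"], 500 * 1.2)
  expect_true(all(pp$inside))
})

test_that("posterior-predictive coverage on synthetic data is near nominal", {
  fit <- shared_small_fit()
  pp <- posterior_predictive_counts(fit, level = 0.9, seed = 2)
  expect_gt(mean(pp$inside), 0.75)
  expect_lte(mean(pp$inside), 1)
})
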