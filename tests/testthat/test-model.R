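test_that("growth rate is the linear predictor plus the shared year effect", {
  expect_equal(growth_rate(0.03, 0.1, -0.2, 0, 0, 0), 0.03)
  expect_equal(growth_rate(0.02, 0.05, -0.01, 1, 1, 0), 0.06)
  # the year effect cancels in between-site contrasts
  rA <- growth_rate(0.02, 0.05, -0.01, 1.3, -0.4, 0.7)
  rB <- growth_rate(0.02, 0.05, -0.01, -0.2, 0.9, 0.7)
  rA0 <- growth_rate(0.02, 0.05, -0.01, 1.3, -0.4, 0)
  rB0 <- growth_rate(0.02, 0.05, -0.01, -0.2, 0.9, 0)
  expect_equal(rA - rB, rA0 - rB0)
})

test_that("abundance step is lognormal with the documented moments", {
  expect_equal(step_abundance(log(1000), 0.05, 0), log(1000) + 0.05)
  expect_error(step_abundance(log(10), 0, -0.1), ">= 0")

  set.seed(5)
  n <- 1e5
  draws <- exp(step_abundance(rep(log(1000), n), 0.05, 0.3))
  expect_equal(median(draws), 1000 * exp(0.05), tolerance = 0.01)
  expect_equal(mean(draws), 1000 * exp(0.05 + 0.3^2 / 2), tolerance = 0.01)
})

test_that("occupancy switch has the right limits and stationary fraction", {
  z <- rep(c(0, 1), 10)
  expect_equal(step_occupancy(z, 0, 0)$z, z)      # absorbing identity
  expect_equal(step_occupancy(rep(1, 20), 1, 0)$z, rep(0, 20))

  set.seed(6)
  p_ext <- 0.2; p_col <- 0.3
  zc <- 1
  occ <- logical(2e4)
  for (t in seq_along(occ)) {
    zc <- step_occupancy(zc, p_ext, p_col)$z
    occ[t] <- zc == 1
  }
  expect_equal(mean(occ), p_col / (p_ext + p_col), tolerance = 0.03)
})

test_that("colonization re-founds abundance from the colonization prior", {
  set.seed(9)
  st <- step_occupancy(rep(0, 5000), 0, 1, colonize_mean = log(20),
                       colonize_sd = 0.5)
  expect_true(all(st$z == 1))
  expect_equal(mean(st$logN_init), log(20), tolerance = 0.03)
})

test_that("accuracy codes map to the stated lognormal scales", {
  expect_equal(accuracy_sigma(5), log(1.5) / qnorm(0.975), tolerance = 1e-12)
  expect_equal(accuracy_sigma(5), 0.2069, tolerance = 1e-3)
  expect_equal(accuracy_sigma(1), log(1.05) / qnorm(0.975), tolerance = 1e-12)
  expect_equal(accuracy_sigma(1), 0.0249, tolerance = 1e-3)
  expect_true(all(diff(accuracy_sigma(1:5)) > 0))
  expect_error(accuracy_sigma(0), "1..5")
  expect_error(accuracy_sigma(6), "1..5")
})

test_that("counts reduce to rounded expectations in the noise-free limit", {
  tiny <- apd_spec(accuracy_envelopes = c(1e-9, 2e-9, 3e-9, 4e-9, 5e-9))
  expect_equal(observe_count(log(500), "nest", code = 1, spec = tiny), 500L)
  expect_equal(observe_count(log(500), "chick", alpha = 1.2, code = 1,
                             spec = tiny), 600L)
  expect_equal(observe_count(log(500), "nest", code = 1, spec = tiny,
                             occupied = FALSE), 0L)
})

test_that("code-5 counts fall inside the +/-50% envelope 95% of the time", {
  set.seed(10)
  n <- 1e5
  counts <- observe_count(rep(log(1000), n), "nest", code = 5)
  covered <- mean(counts >= 1000 / 1.5 & counts <= 1000 * 1.5)
  expect_equal(covered, 0.95, tolerance = 0.011)
})

# ---- joint density -------------------------------------------------------

toy_state <- function(S = 2, TT = 3, counts = NULL, z = NULL) {
  seasons <- 1990:(1990 + TT - 1)
  site_ids <- LETTERS[seq_len(S)]
  if (is.null(counts))
    counts <- data.frame(site_id = "A", season = 1990, count_type = "nest",
                         count = 100L, accuracy = 2L, stringsAsFactors = FALSE)
  sites <- data.frame(site_id = site_ids, region = "48.1",
                      stringsAsFactors = FALSE)
  ice <- expand.grid(site_id = site_ids, season = (1990 - 4):(seasons[TT]),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # strictly increasing series so the windowed statistics are distinct
  ice$winter_peak <- seq(0.05, 0.95, length.out = nrow(ice))
  ice$summer_peak <- seq(0.9, 0.1, length.out = nrow(ice))
  ds <- apd_dataset(counts, sites, ice, season_range = c(1990, seasons[TT]))
  cov <- apd_covariates(ds)
  params <- list(beta1 = 0.02, beta2 = 0.04, beta3 = -0.03,
                 eps = seq(-0.1, 0.1, length.out = TT - 1),
                 sigma_process = 0.2, sigma_eps = 0.15,
                 mu_alpha = 0.9, sigma_alpha = 0.3, p_ext = 0.1, p_col = 0.1,
                 logN = matrix(log(100) + seq_len(S * TT) / 10, S, TT),
                 z = z %||% matrix(1, S, TT),
                 alpha = matrix(0.8, S, TT))
  list(params = params, ds = ds, cov = cov)
}

test_that("the joint density decomposes additively over observations", {
  st <- toy_state(counts = data.frame(
    site_id = c("A", "A", "B"), season = c(1990, 1991, 1992),
    count_type = c("nest", "chick", "nest"),
    count = c(90L, 80L, 120L), accuracy = c(2L, 3L, 5L),
    stringsAsFactors = FALSE))
  lp_full <- log_joint_density(st$params, st$ds, st$cov)

  # drop the chick record: the change is exactly its observation term
  ds_minus <- apd_dataset(st$ds$counts[-1, ], st$ds$sites, st$ds$ice,
                          season_range = st$ds$season_range)
  dropped <- st$ds$counts[1, ]  # records are sorted: (A, 1990, nest) first
  lp_minus <- log_joint_density(st$params, ds_minus, st$cov)
  mu <- st$params$logN[1, 1]
  term <- dlnorm(dropped$count, mu, accuracy_sigma(dropped$accuracy),
                 log = TRUE)
  expect_equal(lp_full - lp_minus, term, tolerance = 1e-10)
})

test_that("a two-season no-count model matches the hand-written density", {
  st <- toy_state(S = 1, TT = 2, counts = data.frame(
    site_id = "A", season = 1990, count_type = "nest", count = 0L,
    accuracy = 1L, stringsAsFactors = FALSE),
    z = matrix(0, 1, 2))
  # unoccupied both seasons, one zero count: only priors + occupancy terms
  p <- st$params
  spec <- apd_spec()
  lp <- log_joint_density(p, st$ds, st$cov, spec)
  pr <- spec$priors
  by_hand <-
    sum(dnorm(c(p$beta1, p$beta2, p$beta3), 0, pr$beta_sd, log = TRUE)) +
    dnorm(p$sigma_process, 0, pr$sigma_process_scale, log = TRUE) + log(2) +
    dnorm(p$sigma_eps, 0, pr$sigma_eps_scale, log = TRUE) + log(2) +
    dnorm(p$mu_alpha, pr$mu_alpha_mean, pr$mu_alpha_sd, log = TRUE) -
      log(pnorm(2, pr$mu_alpha_mean, pr$mu_alpha_sd) -
            pnorm(0, pr$mu_alpha_mean, pr$mu_alpha_sd)) +
    dnorm(p$sigma_alpha, 0, pr$sigma_alpha_scale, log = TRUE) + log(2) +
    dbeta(p$p_ext, 1, 9, log = TRUE) + dbeta(p$p_col, 1, 9, log = TRUE) +
    sum(dnorm(p$eps, 0, p$sigma_eps, log = TRUE)) +
    log(1 - pr$psi0) +                      # z[1,1] = 0
    log(1 - p$p_col) +                      # z[1,2] = 0 given z[1,1] = 0
    sum(dnorm(p$alpha, p$mu_alpha, p$sigma_alpha, log = TRUE) -
          log(pnorm(2, p$mu_alpha, p$sigma_alpha) -
                pnorm(0, p$mu_alpha, p$sigma_alpha)))
  expect_equal(lp, by_hand, tolerance = 1e-10)
})

test_that("an occupied process chain contributes one normal term per step", {
  st <- toy_state(S = 1, TT = 2, counts = data.frame(
    site_id = "A", season = 1990, count_type = "nest", count = 100L,
    accuracy = 1L, stringsAsFactors = FALSE))
  p <- st$params
  lp1 <- log_joint_density(p, st$ds, st$cov)
  # nudge logN[1,2]: only the single process term changes
  p2 <- p
  p2$logN[1, 2] <- p$logN[1, 2] + 0.3
  lp2 <- log_joint_density(p2, st$ds, st$cov)
  r <- growth_rate(p$beta1, p$beta2, p$beta3, st$cov$x_winter[1, 1],
                   st$cov$x_summer[1, 1], p$eps[1])
  d1 <- dnorm(p$logN[1, 2], p$logN[1, 1] + r, p$sigma_process, log = TRUE)
  d2 <- dnorm(p2$logN[1, 2], p$logN[1, 1] + r, p$sigma_process, log = TRUE)
  expect_equal(lp2 - lp1, d2 - d1, tolerance = 1e-10)
})

test_that("perturbing a year effect touches every occupied site that season", {
  st <- toy_state(S = 3, TT = 3)
  p <- st$params
  lp1 <- log_joint_density(p, st$ds, st$cov)
  p2 <- p; p2$eps[1] <- p$eps[1] + 0.05
  lp2 <- log_joint_density(p2, st$ds, st$cov)
  # expected change: year-effect prior term + process terms of all 3 sites
  d_prior <- dnorm(p2$eps[1], 0, p$sigma_eps, log = TRUE) -
    dnorm(p$eps[1], 0, p$sigma_eps, log = TRUE)
  d_proc <- 0
  for (s in 1:3) {
    r1 <- growth_rate(p$beta1, p$beta2, p$beta3, st$cov$x_winter[s, 1],
                      st$cov$x_summer[s, 1], p$eps[1])
    r2 <- r1 + 0.05
    d_proc <- d_proc +
      dnorm(p$logN[s, 2], p$logN[s, 1] + r2, p$sigma_process, log = TRUE) -
      dnorm(p$logN[s, 2], p$logN[s, 1] + r1, p$sigma_process, log = TRUE)
  }
  expect_equal(lp2 - lp1, d_prior + d_proc, tolerance = 1e-10)
})

test_that("invalid states raise errors rather than silent -Inf", {
  st <- toy_state()
  p <- st$params
  p$sigma_process <- -1
  expect_error(log_joint_density(p, st$ds, st$cov), "sigma_process")
  p <- st$params
  p$alpha[1, 1] <- 3
  expect_error(log_joint_density(p, st$ds, st$cov), "alpha")
  p <- st$params
  p$z[] <- 0
  expect_error(log_joint_density(p, st$ds, st$cov), "unoccupied")
})

test_that("forward-simulated states have finite joint density", {
  sim <- shared_small_sim()
  tr <- sim$truth
  S <- nrow(tr$logN); TT <- ncol(tr$logN)
  logN <- tr$logN
  logN[is.na(logN)] <- 0  # unoccupied entries are ignored by the density
  params <- c(tr$params[c("beta1", "beta2", "beta3", "sigma_process",
                          "sigma_eps", "mu_alpha", "sigma_alpha",
                          "p_ext", "p_col")],
              list(eps = tr$params$eps, logN = logN, z = tr$z,
                   alpha = tr$alpha))
  params$p_ext <- max(params$p_ext, 1e-6)  # beta(1,9) density finite at 0 anyway
  spec <- apd_spec(priors = list(psi0 = 0.999))  # generator used psi0 = 1
  lp <- log_joint_density(params, sim$dataset, tr$covariates, spec)
  expect_true(is.finite(lp))

  # the truth scores higher than a randomly perturbed truth
  set.seed(4)
  worse <- replicate(5, {
    pp <- params
    pp$logN <- pp$logN + rnorm(length(pp$logN), 0, 1)
    log_joint_density(pp, sim$dataset, tr$covariates, spec)
  })
  expect_true(mean(lp > worse) > 0.5)
})

test_that("noise-free simulation is exact exponential growth", {
  sc <- apd_scenario(n_sites = 3, first_season = 1990, last_season = 1999,
                     params = list(sigma_process = 1e-12, sigma_eps = 0,
                                   beta2 = 0, beta3 = 0, beta1 = 0.05),
                     survey_prob = 0)
  sim <- simulate_dataset(sc, seed = 2)
  tr <- sim$truth
  for (s in 1:3) {
    expect_equal(tr$logN[s, ], tr$logN[s, 1] + 0.05 * (0:9),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})
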