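# Shared fixtures, built in code.

# Reduced sampler settings for unit tests that need a real fit but not
# publication-grade chains.
fast_spec <- function(...) {
  apd_spec(sampler = list(n_adapt = 300L, n_burnin = 500L,
                          n_iter = 2000L, thin = 2L),
           convergence = list(on_fail = "none"), ...)
}

# A small simulated dataset + fit, computed once per test run.
.apd_cache <- new.env(parent = emptyenv())

shared_small_sim <- function() {
  if (is.null(.apd_cache$sim))
    .apd_cache$sim <- simulate_dataset(scenario_presets("small"), seed = 42)
  .apd_cache$sim
}

shared_small_fit <- function() {
  if (is.null(.apd_cache$fit))
    .apd_cache$fit <- apd_fit(shared_small_sim()$dataset, spec = fast_spec(),
                              seed = 11)
  .apd_cache$fit
}

# Minimal well-formed tables for data_io tests.
toy_tables <- function() {
  counts <- data.frame(
    site_id = c("A", "A", "B"), season = c(1990, 1991, 1990),
    count_type = c("nest", "chick", "nest"),
    count = c(100L, 120L, 0L), accuracy = c(1L, 2L, 5L),
    stringsAsFactors = FALSE)
  sites <- data.frame(site_id = c("A", "B"), region = c("48.1", "48.2"),
                      stringsAsFactors = FALSE)
  ice <- expand.grid(site_id = c("A", "B"), season = 1986:1991,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ice$winter_peak <- round(seq(0.2, 0.8, length.out = nrow(ice)), 3)
  ice$summer_peak <- round(seq(0.1, 0.5, length.out = nrow(ice)), 3)
  list(counts = counts, sites = sites, ice = ice)
}

toy_dataset <- function() {
  tt <- toy_tables()
  apd_dataset(tt$counts, tt$sites, tt$ice, season_range = c(1990, 1991))
}

# Hand-built fit object with fully controlled draws, for testing
# post-fit operations in isolation from the sampler.
make_fake_fit <- function(logN, z = NULL, alpha = NULL, params = list(),
                          x_winter = NULL, x_summer = NULL, dataset = NULL,
                          spec = apd_spec()) {
  stopifnot(length(dim(logN)) == 3)
  n_draw <- dim(logN)[1]; S <- dim(logN)[2]; TT <- dim(logN)[3]
  site_ids <- dimnames(logN)[[2]] %||%
    sprintf("S%02d", seq_len(S))
  seasons <- dimnames(logN)[[3]] %||% as.character(2000 + seq_len(TT))
  dimnames(logN) <- list(NULL, site_ids, seasons)
  if (is.null(z)) z <- array(1, dim(logN), dimnames(logN))
  if (is.null(alpha)) alpha <- array(0.9, dim(logN), dimnames(logN))
  dimnames(z) <- dimnames(logN); dimnames(alpha) <- dimnames(logN)

  p <- utils::modifyList(list(
    beta1 = 0.02, beta2 = 0.03, beta3 = -0.01, sigma_process = 0.2,
    sigma_eps = 0.15, mu_alpha = 0.9, sigma_alpha = 0.3,
    p_ext = 0.05, p_col = 0.05,
    eps = matrix(0, n_draw, TT - 1)), params)
  eps <- p$eps
  if (is.null(dim(eps))) eps <- matrix(eps, n_draw, TT - 1, byrow = TRUE)
  scalar <- function(v) if (length(v) == 1) rep(v, n_draw) else v
  pm <- cbind(beta1 = scalar(p$beta1), beta2 = scalar(p$beta2),
              beta3 = scalar(p$beta3),
              sigma_process = scalar(p$sigma_process),
              sigma_eps = scalar(p$sigma_eps),
              mu_alpha = scalar(p$mu_alpha),
              sigma_alpha = scalar(p$sigma_alpha),
              p_ext = scalar(p$p_ext), p_col = scalar(p$p_col), eps)
  colnames(pm)[-(1:9)] <- paste0("eps[", seasons[-TT], "]")
  attr(pm, "chain") <- rep(1L, n_draw)

  if (is.null(x_winter))
    x_winter <- matrix(0, S, TT, dimnames = list(site_ids, seasons))
  if (is.null(x_summer))
    x_summer <- matrix(0, S, TT, dimnames = list(site_ids, seasons))
  cov <- structure(list(x_winter = x_winter, x_summer = x_summer,
                        raw_winter = x_winter, raw_summer = x_summer,
                        constants = list(winter = c(center = 0, scale = 1),
                                         summer = c(center = 0, scale = 1)),
                        winter_stat = "max"),
                   class = "apd_covariates")
  if (is.null(dataset)) {
    counts <- data.frame(site_id = site_ids[1],
                         season = as.integer(seasons[1]),
                         count_type = "nest", count = 100L, accuracy = 1L,
                         stringsAsFactors = FALSE)
    sites <- data.frame(site_id = site_ids,
                        region = rep("48.1", S), stringsAsFactors = FALSE)
    ice <- expand.grid(site_id = site_ids,
                       season = seq(as.integer(seasons[1]) - 4L,
                                    as.integer(seasons[TT])),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ice$winter_peak <- seq(0.1, 0.9, length.out = nrow(ice))
    ice$summer_peak <- seq(0.2, 0.6, length.out = nrow(ice))
    dataset <- apd_dataset(counts, sites, ice,
                           season_range = as.integer(c(seasons[1],
                                                       seasons[TT])))
  }
  structure(list(params = pm, logN = logN, z = z, alpha = alpha,
                 diagnostics = data.frame(parameter = colnames(pm)[1:7],
                                          rhat = 1, ess = n_draw),
                 dataset = dataset, covariates = cov, spec = spec,
                 seed = 1L, call = quote(make_fake_fit())),
            class = "apd_fit")
}

# Deterministic fake fit on a log-linear trajectory, for hindcast and
# forecast identities.
noise_free_fit <- function(n_draw = 5, S = 2, TT = 4, first = 1994) {
  seasons <- as.character(seq(first, length.out = TT))
  site_ids <- c("A", "B")
  logN <- array(rep(log(1000) + 0.05 * (seq_len(TT) - 1),
                    each = n_draw * S),
                c(n_draw, S, TT), list(NULL, site_ids, seasons))
  counts <- data.frame(site_id = "A", season = first, count_type = "nest",
                       count = 1000L, accuracy = 1L, stringsAsFactors = FALSE)
  sites <- data.frame(site_id = site_ids, region = "48.1",
                      stringsAsFactors = FALSE)
  ice <- expand.grid(site_id = site_ids, season = (first - 14):(first + TT - 1),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ice$winter_peak <- seq(0.2, 0.8, length.out = nrow(ice))
  ice$summer_peak <- seq(0.7, 0.3, length.out = nrow(ice))
  ds <- apd_dataset(counts, sites, ice, season_range = c(first, first + TT - 1))
  make_fake_fit(logN,
                params = list(beta1 = 0.05, beta2 = 0, beta3 = 0,
                              sigma_process = 1e-15, sigma_eps = 1e-15),
                dataset = ds)
}

expect_validation_error <- function(expr, pattern) {
  err <- tryCatch(expr, error = function(e) e)
  expect_s3_class(err, "apd_validation_error")
  for (p in pattern) expect_match(conditionMessage(err), p)
  invisible(err)
}
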