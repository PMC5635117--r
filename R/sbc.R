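#' Simulation-based calibration of the sampler
#'
#' Repeatedly draws the hyperparameters from their priors, simulates a
#' dataset from them under a scenario's layout and sampling design, refits
#' the model, and records the rank of each true value within its thinned
#' posterior draws.  If the sampler targets the exact posterior, the ranks
#' are uniform on `{0, ..., n_bins*m}`; departures indicate bias or
#' miscalibrated uncertainty.  Uniformity is assessed per parameter with a
#' coarse chi-square test over equal-width rank bins.
#'
#' Parameters checked: `beta1`, `beta2`, `beta3`, `sigma_process`,
#' `sigma_eps`.  All hyperparameters -- including the occupancy
#' probabilities, initial-abundance and colonization priors -- are drawn
#' from (or aligned with) the fitting priors, so generation and inference
#' share one joint distribution, as the rank-uniformity argument requires.
#'
#' @param scenario an `"apd_scenario"` supplying layout and design
#'   (default: the `small` preset).
#' @param replicates number of prior draws / refits.
#' @param spec an `"apd_spec"`; convergence failures are warnings here.
#' @param n_rank_draws posterior draws (equally spaced thinning) used for
#'   the rank, default 100.
#' @param n_bins bins for the chi-square check, default 4.
#' @param seed integer seed.
#' @return object of class `"apd_sbc"`: `ranks` (matrix
#'   `[replicate, parameter]`, values in `0..n_rank_draws`), `p_values`
#'   (chi-square uniformity p per parameter), `n_rank_draws`, `n_bins`.
#' @export
apd_sbc <- function(scenario = scenario_presets("small"), replicates = 20,
                    spec = apd_spec(), n_rank_draws = 100, n_bins = 4,
                    seed = 1L) {
  stopifnot(inherits(scenario, "apd_scenario"), replicates >= 2)
  pars <- c("beta1", "beta2", "beta3", "sigma_process", "sigma_eps")
  pr <- spec$priors
  ranks <- matrix(NA_integer_, replicates, length(pars),
                  dimnames = list(NULL, pars))
  for (k in seq_len(replicates)) {
    set.seed(child_seed(seed, k))
    truth <- list(beta1 = stats::rnorm(1, pr$beta_mean, pr$beta_sd),
                  beta2 = stats::rnorm(1, pr$beta_mean, pr$beta_sd),
                  beta3 = stats::rnorm(1, pr$beta_mean, pr$beta_sd),
                  sigma_process = abs(stats::rnorm(1, 0, pr$sigma_process_scale)),
                  sigma_eps = abs(stats::rnorm(1, 0, pr$sigma_eps_scale)),
                  mu_alpha = rtnorm(1, pr$mu_alpha_mean, pr$mu_alpha_sd,
                                    0, spec$alpha_max),
                  sigma_alpha = abs(stats::rnorm(1, 0, pr$sigma_alpha_scale)),
                  p_ext = stats::rbeta(1, pr$p_ext_shape[1], pr$p_ext_shape[2]),
                  p_col = stats::rbeta(1, pr$p_col_shape[1], pr$p_col_shape[2]))
    sc <- scenario
    sc$params <- utils::modifyList(sc$params, truth)
    sc$psi0 <- pr$psi0
    sc$logN0_mean <- pr$logN0_mean; sc$logN0_sd <- pr$logN0_sd
    sc$colonize_mean <- pr$colonize_mean; sc$colonize_sd <- pr$colonize_sd
    sim <- simulate_dataset(sc, seed = child_seed(seed, 1000L + k))
    fit <- apd_fit(sim$dataset, spec = spec,
                   seed = child_seed(seed, 2000L + k))
    for (j in seq_along(pars)) {
      draws <- fit$params[, pars[j]]
      idx <- round(seq(1, length(draws), length.out = n_rank_draws))
      ranks[k, j] <- sum(draws[idx] < truth[[pars[j]]])
    }
  }
  p_values <- apply(ranks, 2, function(rk) {
    br <- seq(0, n_rank_draws, length.out = n_bins + 1)
    obs <- table(cut(rk, breaks = br, include.lowest = TRUE))
    suppressWarnings(stats::chisq.test(as.numeric(obs))$p.value)
  })
  structure(list(ranks = ranks, p_values = p_values,
                 n_rank_draws = n_rank_draws, n_bins = n_bins,
                 replicates = replicates, seed = seed),
            class = "apd_sbc")
}

#' @export
print.apd_sbc <- function(x, ...) {
  cat(sprintf("Simulation-based calibration: %d replicates, ranks over %d draws\n",
              x$replicates, x$n_rank_draws))
  cat("chi-square uniformity p-values:\n")
  print(round(x$p_values, 3))
  invisible(x)
}
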