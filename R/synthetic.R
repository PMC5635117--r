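#' Define a synthetic census scenario
#'
#' A scenario bundles everything needed to simulate a census dataset from
#' known parameters: the site/region layout, the season range, the true
#' model parameters, the sea-ice field generator, and the sampling design
#' (how often sites are surveyed, the nest/chick mix, and the accuracy-code
#' distribution).  The generative mechanism is exactly the model fitted by
#' [apd_fit()], so scenarios are the backbone of parameter-recovery and
#' calibration checks.
#'
#' Default true parameters reflect the fitted system: a process error scale
#' of `log(1.5)/qnorm(0.975) ~= 0.207` (process noise equivalent to a
#' +/-50% census), year effects of scale 0.15 (the dominant deterministic
#' variance source), a small positive winter-ice effect and a weakly
#' negative summer-ice effect, and mean productivity of 0.9 chicks per
#' nest.  The default accuracy-code distribution puts 15% of surveys in the
#' lowest-precision category (code 5).
#'
#' @param n_sites number of colonies.
#' @param n_regions number of regions; sites are assigned round-robin to
#'   labels `"48.1", "48.2", ...`.
#' @param first_season,last_season modelled season range (split-year
#'   labels; default 1982-2015).
#' @param params named list of true parameters, overriding the defaults:
#'   `beta1`, `beta2`, `beta3`, `sigma_process`, `sigma_eps`, `mu_alpha`,
#'   `sigma_alpha`, `p_ext`, `p_col`.
#' @param psi0 probability a site is occupied in the first season.
#' @param logN0_mean,logN0_sd distribution of initial log abundance.
#' @param colonize_mean,colonize_sd re-founding log abundance after a
#'   colonization.
#' @param ice named list for the sea-ice generator: `ar` (AR(1)
#'   autocorrelation on the logit scale, default 0.3), `sd` (innovation sd,
#'   default 0.6), `site_sd` (sd of site-level mean logits, default 0.8).
#' @param survey_prob probability a site-season is surveyed.
#' @param nest_prob probability a surveyed site-season yields a nest count.
#' @param chick_prob probability it (also) yields a chick count.
#' @param accuracy_probs probabilities of accuracy codes 1..5 (must sum
#'   to 1; default has mass 0.15 on code 5).
#' @return list of class `"apd_scenario"`.
#' @seealso [simulate_dataset()], [scenario_presets()].
#' @export
apd_scenario <- function(n_sites = 5, n_regions = 1,
                         first_season = 1982, last_season = 2015,
                         params = list(), psi0 = 1,
                         logN0_mean = log(500), logN0_sd = 1,
                         colonize_mean = log(10), colonize_sd = 1,
                         ice = list(), survey_prob = 0.8,
                         nest_prob = 0.85, chick_prob = 0.35,
                         accuracy_probs = c(0.25, 0.25, 0.20, 0.15, 0.15)) {
  p <- utils::modifyList(list(
    beta1 = 0.02, beta2 = 0.03, beta3 = -0.01,
    sigma_process = log(1.5) / stats::qnorm(0.975), sigma_eps = 0.15,
    mu_alpha = 0.9, sigma_alpha = 0.3, p_ext = 0, p_col = 0), params)
  ic <- utils::modifyList(list(ar = 0.3, sd = 0.6, site_sd = 0.8), ice)
  stopifnot(n_sites >= 1, last_season > first_season,
            p$sigma_process > 0, p$sigma_eps >= 0,
            p$p_ext >= 0, p$p_ext <= 1, p$p_col >= 0, p$p_col <= 1,
            psi0 >= 0, psi0 <= 1, survey_prob >= 0, survey_prob <= 1,
            nest_prob >= 0, nest_prob <= 1, chick_prob >= 0, chick_prob <= 1,
            length(accuracy_probs) == 5, all(accuracy_probs >= 0),
            abs(sum(accuracy_probs) - 1) < 1e-8)
  structure(list(n_sites = as.integer(n_sites),
                 n_regions = as.integer(n_regions),
                 first_season = as.integer(first_season),
                 last_season = as.integer(last_season),
                 params = p, psi0 = psi0,
                 logN0_mean = logN0_mean, logN0_sd = logN0_sd,
                 colonize_mean = colonize_mean, colonize_sd = colonize_sd,
                 ice = ic, survey_prob = survey_prob,
                 nest_prob = nest_prob, chick_prob = chick_prob,
                 accuracy_probs = accuracy_probs),
            class = "apd_scenario")
}

#' Named scenario presets
#'
#' \describe{
#'   \item{`small`}{5 sites x 10 seasons (1982-1991), fully occupied, no
#'     extinction; fast enough for repeated refitting in calibration
#'     studies.}
#'   \item{`continental`}{50 sites x 34 seasons (1982-2015) in 4 regions,
#'     sparse surveys (35% of site-seasons), rare extinctions -- the shape
#'     of a real continent-wide census compilation.}
#'   \item{`extinction`}{10 sites x 15 seasons with a high extinction rate
#'     and slow recolonization, so zero-count runs and terminal
#'     extinctions occur.}
#' }
#'
#' @param name preset name; omit to get the full named list.
#' @return an `"apd_scenario"`, or a named list of them.
#' @export
scenario_presets <- function(name = NULL) {
  presets <- list(
    small = apd_scenario(n_sites = 5, n_regions = 1,
                         first_season = 1982, last_season = 1991,
                         survey_prob = 0.8),
    continental = apd_scenario(n_sites = 50, n_regions = 4,
                             first_season = 1982, last_season = 2015,
                             params = list(p_ext = 0.01, p_col = 0.05),
                             psi0 = 0.95, survey_prob = 0.35),
    extinction = apd_scenario(n_sites = 10, n_regions = 1,
                              first_season = 1982, last_season = 1996,
                              params = list(p_ext = 0.15, p_col = 0.02),
                              psi0 = 1, survey_prob = 0.8))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Simulate a census dataset from known parameters
#'
#' Runs the full generative model forward: smooth bounded sea-ice series
#' per site (AR(1) on the logit scale), standardized covariates, latent
#' occupancy and abundance trajectories via [step_occupancy()] /
#' [step_abundance()], hierarchical productivities, and accuracy-coded
#' nest/chick counts via [observe_count()] under the scenario's sampling
#' design.  Surveying an unoccupied site records a legitimate zero count.
#' Both the observable dataset and the hidden truth are returned, so
#' recovery studies never need to re-simulate.
#'
#' @param scenario an `"apd_scenario"`.
#' @param seed integer seed; the result is a deterministic function of
#'   `(scenario, seed)`.
#' @return object of class `"apd_sim"`: list with
#'   \describe{
#'     \item{dataset}{a validated `"apd_dataset"`.}
#'     \item{truth}{list: `params` (including the realized year-effect
#'       vector `eps`), matrices `logN`, `z`, `alpha` (`[site, season]`),
#'       and the `"apd_covariates"` used.}
#'     \item{scenario, seed}{the inputs.}
#'   }
#' @export
simulate_dataset <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "apd_scenario"))
  sc <- scenario
  set.seed(seed)
  seasons <- seq(sc$first_season, sc$last_season)
  TT <- length(seasons)
  S <- sc$n_sites
  site_ids <- sprintf("SIM%03d", seq_len(S))
  regions <- paste0("48.", 1 + (seq_len(S) - 1) %% sc$n_regions)

  ice <- generate_ice(S, site_ids, sc$first_season - 4L, sc$last_season,
                      sc$ice)
  sites <- data.frame(site_id = site_ids, region = regions,
                      latitude = round(-77 + 13 * stats::runif(S), 3),
                      longitude = round(-180 + 360 * stats::runif(S), 3),
                      stringsAsFactors = FALSE)
  empty_counts <- data.frame(site_id = character(0), season = integer(0),
                             count_type = character(0), count = integer(0),
                             accuracy = integer(0), stringsAsFactors = FALSE)
  ds0 <- apd_dataset(empty_counts, sites, ice,
                     season_range = c(sc$first_season, sc$last_season))
  cov <- apd_covariates(ds0)

  p <- sc$params
  eps <- stats::rnorm(TT - 1, 0, p$sigma_eps)
  z <- matrix(0, S, TT, dimnames = list(site_ids, seasons))
  logN <- matrix(NA_real_, S, TT, dimnames = list(site_ids, seasons))
  z[, 1] <- stats::rbinom(S, 1, sc$psi0)
  logN[z[, 1] == 1, 1] <- stats::rnorm(sum(z[, 1]), sc$logN0_mean, sc$logN0_sd)
  for (t in 2:TT) {
    r <- growth_rate(p$beta1, p$beta2, p$beta3,
                     cov$x_winter[, t - 1], cov$x_summer[, t - 1],
                     eps[t - 1])
    st <- step_occupancy(z[, t - 1], p$p_ext, p$p_col,
                         sc$colonize_mean, sc$colonize_sd)
    z[, t] <- st$z
    surv <- z[, t - 1] == 1 & z[, t] == 1
    logN[surv, t] <- step_abundance(logN[surv, t - 1], r[surv],
                                    p$sigma_process)
    col <- z[, t - 1] == 0 & z[, t] == 1
    logN[col, t] <- st$logN_init[col]
  }
  alpha <- matrix(rtnorm(S * TT, p$mu_alpha, p$sigma_alpha, 0, 2), S, TT,
                  dimnames = list(site_ids, seasons))

  # sampling design
  spec <- apd_spec()
  recs <- list()
  for (s in seq_len(S)) for (t in seq_len(TT)) {
    if (stats::runif(1) > sc$survey_prob) next
    types <- c(if (stats::runif(1) < sc$nest_prob) "nest",
               if (stats::runif(1) < sc$chick_prob) "chick")
    for (ty in types) {
      code <- sample.int(5, 1, prob = sc$accuracy_probs)
      cnt <- if (z[s, t] == 1)
        observe_count(logN[s, t], ty, alpha[s, t], code, spec,
                      occupied = TRUE)
      else 0L
      recs[[length(recs) + 1]] <- data.frame(
        site_id = site_ids[s], season = seasons[t], count_type = ty,
        count = cnt, accuracy = code, stringsAsFactors = FALSE)
    }
  }
  counts <- if (length(recs) > 0) do.call(rbind, recs) else empty_counts

  dataset <- apd_dataset(counts, sites, ice,
                         season_range = c(sc$first_season, sc$last_season))
  truth <- list(params = c(p, list(eps = eps)), logN = logN, z = z,
                alpha = alpha, covariates = cov)
  structure(list(dataset = dataset, truth = truth, scenario = sc,
                 seed = seed),
            class = "apd_sim")
}

generate_ice <- function(S, site_ids, first, last, ic) {
  seasons <- seq(first, last)
  out <- list()
  for (s in seq_len(S)) {
    mw <- stats::rnorm(1, 0, ic$site_sd)
    ms <- stats::rnorm(1, 0, ic$site_sd)
    w <- ar1_logit(length(seasons), ic$ar, ic$sd, mw)
    su <- ar1_logit(length(seasons), ic$ar, ic$sd, ms)
    out[[s]] <- data.frame(site_id = site_ids[s], season = seasons,
                           winter_peak = w, summer_peak = su,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Stationary AR(1) on the logit scale mapped through plogis: smooth,
# autocorrelated, bounded in (0, 1).
ar1_logit <- function(n, ar, sd, mean_logit) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd / sqrt(1 - ar^2))
  for (t in 2:n) x[t] <- ar * x[t - 1] + stats::rnorm(1, 0, sd)
  stats::plogis(mean_logit + x)
}

#' @export
print.apd_sim <- function(x, ...) {
  cat(sprintf("Synthetic census dataset (seed %d)\n", x$seed))
  print(x$dataset)
  cat(sprintf("  true beta = (%.3f, %.3f, %.3f), sigma_process = %.3f, sigma_eps = %.3f\n",
              x$truth$params$beta1, x$truth$params$beta2,
              x$truth$params$beta3, x$truth$params$sigma_process,
              x$truth$params$sigma_eps))
  invisible(x)
}

#' Write a simulated dataset (and its truth) to files
#'
#' Writes `counts.csv`, `sites.csv`, `ice.csv` via [write_dataset()], the
#' true parameters as `truth_params.yaml`, and the latent states as
#' `truth_states.csv` (long format: site, season, logN, z, alpha).
#'
#' @param sim an `"apd_sim"`.
#' @param dir output directory.
#' @return invisibly, the vector of written paths.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "apd_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_dataset(sim$dataset, dir)
  py <- file.path(dir, "truth_params.yaml")
  yaml::write_yaml(lapply(sim$truth$params, as.numeric), py)
  st <- expand.grid(site_id = rownames(sim$truth$logN),
                    season = as.integer(colnames(sim$truth$logN)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  st$logN <- as.numeric(sim$truth$logN)
  st$z <- as.numeric(sim$truth$z)
  st$alpha <- as.numeric(sim$truth$alpha)
  ps <- file.path(dir, "truth_states.csv")
  utils::write.csv(st, ps, row.names = FALSE)
  invisible(c(paths, py, ps))
}
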