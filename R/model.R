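#' Growth-rate linear predictor
#'
#' The intrinsic (log-scale) population growth rate for a site-season:
#' `r = beta1 + beta2 * x_winter + beta3 * x_summer + eps`, where `beta1` is
#' the growth rate at average winter and summer peak sea-ice concentration,
#' `beta2`/`beta3` are effects of a one standard deviation change in the
#' winter/summer covariate, and `eps` is the year effect shared by all sites
#' in that season.  The seasonal abundance multiplier is `exp(r)`.
#'
#' @param beta1,beta2,beta3 scalar coefficients.
#' @param x_winter,x_summer standardized covariate values (vectorized).
#' @param eps year effect (scalar or conformable vector), default 0.
#' @return numeric vector of growth rates.
#' @export
growth_rate <- function(beta1, beta2, beta3, x_winter, x_summer, eps = 0) {
  beta1 + beta2 * x_winter + beta3 * x_summer + eps
}

#' One process step of latent log abundance
#'
#' `logN_next ~ Normal(logN + r, sigma_process)`: exponential growth at rate
#' `r` with multiplicative (lognormal) process noise.  With
#' `sigma_process = 0` the map is deterministic.
#'
#' @param logN current log nest abundance (vectorized).
#' @param r growth rate(s) from [growth_rate()].
#' @param sigma_process process error scale (log scale), `>= 0`.
#' @return numeric vector of next-season log abundances.
#' @export
step_abundance <- function(logN, r, sigma_process) {
  if (sigma_process < 0) stop("sigma_process must be >= 0")
  stats::rnorm(length(logN), logN + r, sigma_process)
}

#' One occupancy step
#'
#' Constant-rate Markov switch on the occupancy indicator: an occupied site
#' goes extinct with probability `p_ext`; an unoccupied site is colonized
#' with probability `p_col`, drawing a re-founding log abundance from the
#' colonization prior `Normal(colonize_mean, colonize_sd)`.
#'
#' @param z 0/1 occupancy vector.
#' @param p_ext,p_col transition probabilities in `[0, 1]`.
#' @param colonize_mean,colonize_sd colonization prior for log abundance.
#' @return list with `z` (next-season occupancy) and `logN_init` (re-founded
#'   log abundance where a colonization occurred, `NA` elsewhere).
#' @export
step_occupancy <- function(z, p_ext, p_col,
                           colonize_mean = log(10), colonize_sd = 1) {
  stopifnot(all(z %in% c(0, 1)), p_ext >= 0, p_ext <= 1, p_col >= 0, p_col <= 1)
  u <- stats::runif(length(z))
  z_new <- ifelse(z == 1, as.numeric(u >= p_ext), as.numeric(u < p_col))
  logN_init <- rep(NA_real_, length(z))
  col <- z == 0 & z_new == 1
  if (any(col))
    logN_init[col] <- stats::rnorm(sum(col), colonize_mean, colonize_sd)
  list(z = z_new, logN_init = logN_init)
}

#' Simulate an observed census count
#'
#' Draws a count from the accuracy-coded observation model: a nest count is
#' `round(Lognormal(logN, sigma_obs(code)))`; a chick count is
#' `round(Lognormal(logN + log(alpha), sigma_obs(code)))` where `alpha` is
#' the site-season breeding productivity (chicks per nest).  Unoccupied
#' sites yield count 0 exactly.
#'
#' @param logN latent log nest abundance (vectorized).
#' @param count_type `"nest"` or `"chick"` (recycled).
#' @param alpha breeding productivity, used for chick counts.
#' @param code accuracy code(s) in 1..5.
#' @param spec an `"apd_spec"`.
#' @param occupied logical/0-1 occupancy (recycled), default occupied.
#' @return integer vector of counts.
#' @export
observe_count <- function(logN, count_type = "nest", alpha = 1, code, spec = apd_spec(),
                          occupied = TRUE) {
  stopifnot(all(count_type %in% c("nest", "chick")))
  n <- max(length(logN), length(code), length(count_type), length(occupied))
  logN <- rep_len(logN, n); code <- rep_len(code, n)
  count_type <- rep_len(count_type, n); occupied <- rep_len(as.numeric(occupied), n)
  alpha <- rep_len(alpha, n)
  sig <- accuracy_sigma(code, spec)
  mu <- logN + ifelse(count_type == "chick", log(alpha), 0)
  cnt <- as.integer(round(exp(stats::rnorm(n, mu, sig))))
  cnt[occupied == 0] <- 0L
  cnt
}

# ---- joint density -------------------------------------------------------

#' Log joint density of the full state-space model
#'
#' Evaluates the sum of prior, occupancy, process, productivity, and
#' observation log densities at a complete latent state.  This is the same
#' joint distribution that [apd_fit()] samples from (and that
#' [simulate_dataset()] simulates forward from), implemented independently
#' in R, so simulation, inference and density evaluation can be
#' cross-checked against each other.
#'
#' `params` is a list with elements `beta1`, `beta2`, `beta3`, `eps`
#' (year effects for transitions, length `T - 1`), `sigma_process`,
#' `sigma_eps`, `mu_alpha`, `sigma_alpha`, `p_ext`, `p_col`, and matrices
#' `logN`, `z`, `alpha` of dimension `[site, season]` (ordered like the
#' covariate matrices).  `logN` entries at unoccupied site-seasons are
#' ignored (the model has no abundance there).  Observation densities are
#' evaluated on the continuous scale at the recorded count (zero counts from
#' occupied sites at the rounding boundary 0.5), standard practice for large
#' censuses.
#'
#' @param params named list of parameter and latent state values.
#' @param dataset an `"apd_dataset"`.
#' @param covariates an `"apd_covariates"`.
#' @param spec an `"apd_spec"`.
#' @return scalar log density; finite for any state the model can generate.
#'   Invariant violations (negative scales, occupancy/count contradictions,
#'   productivity out of bounds) raise an error rather than returning
#'   `-Inf` silently.
#' @export
log_joint_density <- function(params, dataset, covariates, spec = apd_spec()) {
  p <- params
  S <- nrow(covariates$x_winter); TT <- ncol(covariates$x_winter)
  site_ids <- rownames(covariates$x_winter)
  seasons <- as.integer(colnames(covariates$x_winter))

  if (p$sigma_process <= 0) stop("sigma_process must be > 0")
  if (p$sigma_eps < 0) stop("sigma_eps must be >= 0")
  if (p$p_ext < 0 || p$p_ext > 1 || p$p_col < 0 || p$p_col > 1)
    stop("p_ext and p_col must lie in [0, 1]")
  stopifnot(is.matrix(p$logN), is.matrix(p$z), is.matrix(p$alpha),
            all(dim(p$logN) == c(S, TT)), all(dim(p$z) == c(S, TT)),
            all(dim(p$alpha) == c(S, TT)), length(p$eps) == TT - 1)
  if (!all(p$z %in% c(0, 1))) stop("z must be 0/1")
  if (any(p$alpha < 0 | p$alpha > spec$alpha_max))
    stop("alpha outside [0, alpha_max]")
  if (any(!is.finite(p$logN[p$z == 1])))
    stop("logN must be finite wherever z = 1")

  pr <- spec$priors
  lp <- 0
  # parameter priors
  lp <- lp + sum(stats::dnorm(c(p$beta1, p$beta2, p$beta3),
                              pr$beta_mean, pr$beta_sd, log = TRUE))
  lp <- lp + dhalfnorm_log(p$sigma_process, pr$sigma_process_scale)
  lp <- lp + dhalfnorm_log(p$sigma_eps, pr$sigma_eps_scale)
  lp <- lp + dtnorm_log(p$mu_alpha, pr$mu_alpha_mean, pr$mu_alpha_sd,
                        0, spec$alpha_max)
  lp <- lp + dhalfnorm_log(p$sigma_alpha, pr$sigma_alpha_scale)
  lp <- lp + stats::dbeta(p$p_ext, pr$p_ext_shape[1], pr$p_ext_shape[2], log = TRUE)
  lp <- lp + stats::dbeta(p$p_col, pr$p_col_shape[1], pr$p_col_shape[2], log = TRUE)
  # year effects
  lp <- lp + sum(stats::dnorm(p$eps, 0, p$sigma_eps, log = TRUE))
  # initial occupancy and abundance
  lp <- lp + sum(stats::dbinom(p$z[, 1], 1, pr$psi0, log = TRUE))
  occ1 <- p$z[, 1] == 1
  lp <- lp + sum(stats::dnorm(p$logN[occ1, 1], pr$logN0_mean, pr$logN0_sd,
                              log = TRUE))
  # occupancy and process transitions
  for (t in 2:TT) {
    zp <- p$z[, t - 1]; zt <- p$z[, t]
    pr_occ <- zp * (1 - p$p_ext) + (1 - zp) * p$p_col
    lp <- lp + sum(stats::dbinom(zt, 1, pr_occ, log = TRUE))
    r <- growth_rate(p$beta1, p$beta2, p$beta3,
                     covariates$x_winter[, t - 1], covariates$x_summer[, t - 1],
                     p$eps[t - 1])
    surv <- zp == 1 & zt == 1      # persisting populations: process step
    col <- zp == 0 & zt == 1       # colonizations: re-founding prior
    lp <- lp + sum(stats::dnorm(p$logN[surv, t],
                                p$logN[surv, t - 1] + r[surv],
                                p$sigma_process, log = TRUE))
    lp <- lp + sum(stats::dnorm(p$logN[col, t], pr$colonize_mean,
                                pr$colonize_sd, log = TRUE))
  }
  # productivity (all site-seasons, as in the sampler)
  lp <- lp + sum(dtnorm_log(p$alpha, p$mu_alpha, p$sigma_alpha,
                            0, spec$alpha_max))
  # observations
  cnt <- dataset$counts
  si <- match(cnt$site_id, site_ids)
  ti <- match(cnt$season, seasons)
  if (any(is.na(si)) || any(is.na(ti)))
    stop("counts refer to sites/seasons absent from the covariate matrices")
  sig <- accuracy_sigma(cnt$accuracy, spec)
  for (i in seq_len(nrow(cnt))) {
    zi <- p$z[si[i], ti[i]]
    if (zi == 0) {
      if (cnt$count[i] > 0)
        stop(sprintf("positive count at unoccupied site-season (%s, %d)",
                     cnt$site_id[i], cnt$season[i]))
      next  # point mass at zero: contributes 0
    }
    mu <- p$logN[si[i], ti[i]] +
      if (cnt$count_type[i] == "chick") log(p$alpha[si[i], ti[i]]) else 0
    lp <- lp + stats::dlnorm(max(cnt$count[i], 0.5), mu, sig[i], log = TRUE)
  }
  lp
}

# ---- JAGS representation -------------------------------------------------

# The sampler-facing form of the model.  Latent logN is defined over all
# site-seasons with occupancy-gated mean/precision; values at unoccupied
# site-seasons are never referenced by any likelihood term and integrate
# out, so the marginal joint equals log_joint_density() over the model's
# actual variables.  The observation block is dropped when no count enters
# the lognormal likelihood (n_obs = 0), e.g. all-zero-count datasets.
jags_model_string <- function(n_obs = 1) {
  if (n_obs > 0) return(jags_model_core)
  lines <- strsplit(jags_model_core, "\n", fixed = TRUE)[[1]]
  from <- grep("for (i in 1:n_obs)", lines, fixed = TRUE)
  close <- from + grep("}", lines[-seq_len(from)], fixed = TRUE)[1]
  paste(lines[-(from:close)], collapse = "\n")
}

jags_model_core <-
"model {
  beta1 ~ dnorm(beta_mean, pow(beta_sd, -2))
  beta2 ~ dnorm(beta_mean, pow(beta_sd, -2))
  beta3 ~ dnorm(beta_mean, pow(beta_sd, -2))
  sigma_proc ~ dnorm(0, pow(sigma_proc_scale, -2)) T(0,)
  sigma_eps ~ dnorm(0, pow(sigma_eps_scale, -2)) T(0,)
  tau_proc <- pow(sigma_proc, -2)
  mu_alpha ~ dnorm(mu_alpha_mean, pow(mu_alpha_sd, -2)) T(0, alpha_max)
  sigma_alpha ~ dnorm(0, pow(sigma_alpha_scale, -2)) T(0,)
  tau_alpha <- pow(sigma_alpha, -2)
  p_ext ~ dbeta(p_ext_a, p_ext_b)
  p_col ~ dbeta(p_col_a, p_col_b)
  for (t in 1:(T-1)) { eps[t] ~ dnorm(0, pow(sigma_eps, -2)) }
  for (s in 1:S) {
    z[s, 1] ~ dbern(psi0)
    logN[s, 1] ~ dnorm(logN0_mean, pow(logN0_sd, -2))
    for (t in 2:T) {
      z[s, t] ~ dbern(z[s, t-1] * (1 - p_ext) + (1 - z[s, t-1]) * p_col)
      mu_ln[s, t] <- z[s, t-1] * (logN[s, t-1] + beta1 + beta2 * xw[s, t-1] +
                                  beta3 * xs[s, t-1] + eps[t-1]) +
                     (1 - z[s, t-1]) * colonize_mean
      tau_ln[s, t] <- z[s, t-1] * tau_proc +
                      (1 - z[s, t-1]) * pow(colonize_sd, -2)
      logN[s, t] ~ dnorm(mu_ln[s, t], tau_ln[s, t])
    }
    for (t in 1:T) { alpha[s, t] ~ dnorm(mu_alpha, tau_alpha) T(0, alpha_max) }
  }
  for (i in 1:n_obs) {
    logy[i] ~ dnorm(logN[obs_site[i], obs_season[i]] +
                    obs_chick[i] * log(alpha[obs_site[i], obs_season[i]]),
                    obs_tau[i])
  }
}"

# Occupancy data implied by the counts: a positive count of either type
# means occupied; a zero nest count means unoccupied; a zero chick count
# means unoccupied unless a positive nest count exists for the same
# site-season (total breeding failure).  Everything else is latent (NA).
occupancy_data <- function(dataset, site_ids, seasons) {
  z <- matrix(NA_real_, length(site_ids), length(seasons),
              dimnames = list(site_ids, as.character(seasons)))
  cnt <- dataset$counts
  si <- match(cnt$site_id, site_ids)
  ti <- match(cnt$season, seasons)
  pos <- cnt$count > 0
  z[cbind(si[pos], ti[pos])] <- 1
  zero_nest <- !pos & cnt$count_type == "nest"
  for (i in which(zero_nest)) {
    if (is.na(z[si[i], ti[i]])) z[si[i], ti[i]] <- 0
  }
  zero_chick <- !pos & cnt$count_type == "chick"
  for (i in which(zero_chick)) {
    if (is.na(z[si[i], ti[i]])) z[si[i], ti[i]] <- 0
  }
  z
}

jags_data <- function(dataset, covariates, spec) {
  site_ids <- rownames(covariates$x_winter)
  seasons <- as.integer(colnames(covariates$x_winter))
  z <- occupancy_data(dataset, site_ids, seasons)

  cnt <- dataset$counts
  si <- match(cnt$site_id, site_ids)
  ti <- match(cnt$season, seasons)
  # only counts at known-occupied site-seasons enter the lognormal
  # likelihood; zero counts have already informed z.
  keep <- !is.na(z[cbind(si, ti)]) & z[cbind(si, ti)] == 1
  pr <- spec$priors
  list(S = length(site_ids), T = length(seasons),
       xw = covariates$x_winter, xs = covariates$x_summer,
       z = z,
       n_obs = sum(keep),
       obs_site = si[keep], obs_season = ti[keep],
       obs_chick = as.numeric(cnt$count_type[keep] == "chick"),
       logy = log(pmax(cnt$count[keep], 0.5)),
       obs_tau = 1 / accuracy_sigma(cnt$accuracy[keep], spec)^2,
       beta_mean = pr$beta_mean, beta_sd = pr$beta_sd,
       sigma_proc_scale = pr$sigma_process_scale,
       sigma_eps_scale = pr$sigma_eps_scale,
       mu_alpha_mean = pr$mu_alpha_mean, mu_alpha_sd = pr$mu_alpha_sd,
       sigma_alpha_scale = pr$sigma_alpha_scale,
       p_ext_a = pr$p_ext_shape[1], p_ext_b = pr$p_ext_shape[2],
       p_col_a = pr$p_col_shape[1], p_col_b = pr$p_col_shape[2],
       psi0 = pr$psi0, logN0_mean = pr$logN0_mean, logN0_sd = pr$logN0_sd,
       colonize_mean = pr$colonize_mean, colonize_sd = pr$colonize_sd,
       alpha_max = spec$alpha_max)
}
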