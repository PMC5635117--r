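#' Fit the hierarchical Bayesian state-space model
#'
#' Fits the population dynamics model by MCMC: latent log nest abundance
#' evolves by exponential growth whose rate is a linear function of
#' standardized sea-ice covariates plus a year effect shared by all sites,
#' with lognormal process error; site occupancy follows a constant-rate
#' extinction/colonization switch; breeding productivity (chicks per nest)
#' is drawn hierarchically from a truncated normal; and nest/chick counts
#' are observed with lognormal error whose scale is set by the census
#' accuracy code.  Latent abundance is sampled for every modelled
#' site-season, so seasons without a census are imputed (and seasons before
#' a site's first count are hindcast) as part of the fit.
#'
#' Sampling is delegated to JAGS; the model passed to the sampler is the
#' same joint distribution evaluated by [log_joint_density()].  Occupancy is
#' partially observed: positive counts pin a site-season to occupied and
#' zero nest counts to unoccupied (a zero chick count alongside a positive
#' nest count is breeding failure, not absence); the remaining indicators
#' are sampled.  Convergence is checked on the monitored scalars (`beta1`,
#' `beta2`, `beta3`, `sigma_process`, `sigma_eps`, `mu_alpha`,
#' `sigma_alpha`, every year effect): any split-R-hat above
#' `spec$convergence$rhat_max` or effective sample size below
#' `spec$convergence$ess_min` triggers a warning or error naming the
#' offending scalars, per `spec$convergence$on_fail`.
#'
#' Identical `dataset`, `spec` and `seed` give identical draws.
#'
#' @param dataset an `"apd_dataset"` with at least one census record.
#' @param covariates an `"apd_covariates"`, or `NULL` to build from the
#'   dataset with `spec$winter_stat`.
#' @param spec an `"apd_spec"`.
#' @param seed integer seed controlling all sampler randomness.
#' @param quiet suppress JAGS progress output.
#' @return an object of class `"apd_fit"` with components
#'   \describe{
#'     \item{params}{matrix of parameter draws (rows = pooled draws,
#'       columns named `beta1`, ..., `eps[<season>]`), with a `chain`
#'       attribute.}
#'     \item{logN, z, alpha}{arrays `[draw, site, season]` of latent states.}
#'     \item{diagnostics}{data frame of R-hat and effective sample size per
#'       monitored scalar.}
#'     \item{dataset, covariates, spec, seed}{the inputs.}
#'   }
#' @seealso [summary.apd_fit()], [predict.apd_fit()], [apd_forecast()],
#'   [hindcast()], [apd_aggregate()], [obs_vs_process()].
#' @export
apd_fit <- function(dataset, covariates = NULL, spec = apd_spec(), seed = 1L,
                    quiet = TRUE) {
  stopifnot(inherits(dataset, "apd_dataset"), inherits(spec, "apd_spec"))
  if (nrow(dataset$counts) == 0)
    stop("cannot fit: dataset contains no census records")
  if (is.null(covariates))
    covariates <- apd_covariates(dataset, winter_stat = spec$winter_stat)
  stopifnot(inherits(covariates, "apd_covariates"))

  dat <- jags_data(dataset, covariates, spec)
  site_ids <- rownames(covariates$x_winter)
  seasons <- as.integer(colnames(covariates$x_winter))
  S <- dat$S; TT <- dat$T

  inits <- lapply(seq_len(spec$sampler$n_chains), function(ch) {
    list(.RNG.name = "base::Wichmann-Hill",
         .RNG.seed = child_seed(seed, ch),
         beta1 = 0, beta2 = 0, beta3 = 0,
         sigma_proc = 0.2, sigma_eps = 0.1,
         mu_alpha = spec$priors$mu_alpha_mean, sigma_alpha = 0.2,
         p_ext = 0.05, p_col = 0.05,
         eps = rep(0, TT - 1),
         alpha = matrix(spec$priors$mu_alpha_mean, S, TT),
         logN = init_logN(dataset, site_ids, seasons))
  })

  model_str <- jags_model_string(dat$n_obs)
  if (dat$n_obs == 0)
    dat <- dat[setdiff(names(dat), c("n_obs", "obs_site", "obs_season",
                                     "obs_chick", "logy", "obs_tau"))]
  run <- function() {
    jm <- rjags::jags.model(textConnection(model_str), data = dat,
                            inits = inits, n.chains = spec$sampler$n_chains,
                            n.adapt = spec$sampler$n_adapt, quiet = quiet)
    if (spec$sampler$n_burnin > 0)
      update(jm, spec$sampler$n_burnin, progress.bar = "none")
    rjags::coda.samples(jm,
                        variable.names = c("beta1", "beta2", "beta3",
                                           "sigma_proc", "sigma_eps",
                                           "mu_alpha", "sigma_alpha",
                                           "p_ext", "p_col", "eps",
                                           "logN", "z", "alpha"),
                        n.iter = spec$sampler$n_iter,
                        thin = spec$sampler$thin, progress.bar = "none")
  }
  sm <- if (quiet) suppressWarnings(run()) else run()

  vn <- coda::varnames(sm)
  scalar_names <- c("beta1", "beta2", "beta3", "sigma_proc", "sigma_eps",
                    "mu_alpha", "sigma_alpha", "p_ext", "p_col",
                    grep("^eps\\[", vn, value = TRUE))
  monitored <- setdiff(scalar_names, c("p_ext", "p_col"))

  diag_df <- convergence_diagnostics(sm, monitored)
  check_convergence(diag_df, spec$convergence)

  pooled <- as.matrix(sm)
  n_per <- nrow(sm[[1]])
  chain <- rep(seq_along(sm), each = n_per)

  params <- pooled[, scalar_names, drop = FALSE]
  colnames(params) <- sub("^sigma_proc$", "sigma_process", colnames(params))
  eps_cols <- grep("^eps\\[", colnames(params))
  colnames(params)[eps_cols] <-
    paste0("eps[", seasons[as.integer(gsub("eps\\[|\\]", "",
                                           colnames(params)[eps_cols]))], "]")
  attr(params, "chain") <- chain

  structure(list(params = params,
                 logN = draws_array(pooled, "logN", S, TT, site_ids, seasons),
                 z = draws_array(pooled, "z", S, TT, site_ids, seasons),
                 alpha = draws_array(pooled, "alpha", S, TT, site_ids, seasons),
                 diagnostics = diag_df,
                 dataset = dataset, covariates = covariates, spec = spec,
                 seed = seed, call = match.call()),
            class = "apd_fit")
}

# Initial latent logN: log(count + 1) at censused seasons, linearly
# interpolated across gaps and extended flat beyond the data.
init_logN <- function(dataset, site_ids, seasons) {
  out <- matrix(log(100), length(site_ids), length(seasons))
  cnt <- dataset$counts[dataset$counts$count > 0, ]
  for (i in seq_along(site_ids)) {
    rows <- cnt[cnt$site_id == site_ids[i], ]
    if (nrow(rows) == 0) next
    agg <- tapply(log(rows$count + 1), rows$season, mean)
    x <- as.integer(names(agg))
    out[i, ] <- if (length(x) == 1) as.numeric(agg) else
      stats::approx(x, as.numeric(agg), xout = seasons, rule = 2)$y
  }
  out
}

draws_array <- function(pooled, what, S, TT, site_ids, seasons) {
  cols <- sprintf("%s[%d,%d]", what,
                  rep(seq_len(S), times = TT), rep(seq_len(TT), each = S))
  a <- array(pooled[, cols], dim = c(nrow(pooled), S, TT),
             dimnames = list(NULL, site_ids, as.character(seasons)))
  a
}

convergence_diagnostics <- function(sm, monitored) {
  rhat <- rep(NA_real_, length(monitored))
  if (coda::nchain(sm) > 1) {
    g <- coda::gelman.diag(sm[, monitored, drop = FALSE],
                           multivariate = FALSE, autoburnin = FALSE)
    rhat <- g$psrf[, 1]
  }
  ess <- coda::effectiveSize(sm[, monitored, drop = FALSE])
  data.frame(parameter = monitored, rhat = unname(rhat),
             ess = unname(ess[monitored]), row.names = NULL,
             stringsAsFactors = FALSE)
}

check_convergence <- function(diag_df, cvg) {
  if (cvg$on_fail == "none") return(invisible(TRUE))
  bad_r <- diag_df$parameter[!is.na(diag_df$rhat) & diag_df$rhat > cvg$rhat_max]
  bad_e <- diag_df$parameter[diag_df$ess < cvg$ess_min]
  msgs <- c(
    if (length(bad_r) > 0)
      sprintf("R-hat > %.3f for: %s", cvg$rhat_max, paste(bad_r, collapse = ", ")),
    if (length(bad_e) > 0)
      sprintf("ESS < %g for: %s", cvg$ess_min, paste(bad_e, collapse = ", ")))
  if (length(msgs) > 0) {
    msg <- paste0("convergence check failed:\n  ", paste(msgs, collapse = "\n  "))
    if (cvg$on_fail == "error") stop(msg) else warning(msg, call. = FALSE)
  }
  invisible(length(msgs) == 0)
}

# ---- abundance ------------------------------------------------------------

#' Posterior draws of nest abundance
#'
#' Occupancy-aware abundance per draw: `z * exp(logN)`, zero where the site
#' is unoccupied in that draw.
#'
#' @param fit an `"apd_fit"`.
#' @return numeric array `[draw, site, season]`.
#' @export
abundance_draws <- function(fit) {
  stopifnot(inherits(fit, "apd_fit"))
  fit$z * exp(fit$logN)
}

# ---- methods --------------------------------------------------------------

#' @export
print.apd_fit <- function(x, ...) {
  d <- dim(x$logN)
  cat("Hierarchical state-space model fit (MCMC)\n")
  cat(sprintf("  %d sites x %d seasons, %d census records\n",
              d[2], d[3], nrow(x$dataset$counts)))
  cat(sprintf("  %d draws (%d chain(s)); max R-hat %.3f, min ESS %.0f\n",
              d[1], max(attr(x$params, "chain")),
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess)))
  cat("Posterior medians:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' Quantiles of the main parameters together with convergence diagnostics.
#'
#' @param object an `"apd_fit"`.
#' @param ... unused.
#' @return an object of class `"summary.apd_fit"`: data frame of posterior
#'   quantiles (2.5, 25, 50, 75, 97.5%), R-hat and ESS per parameter.
#' @export
summary.apd_fit <- function(object, ...) {
  keep <- c("beta1", "beta2", "beta3", "sigma_process", "sigma_eps",
            "mu_alpha", "sigma_alpha", "p_ext", "p_col")
  qs <- t(apply(object$params[, keep, drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
  out <- data.frame(parameter = rownames(qs), qs, check.names = FALSE,
                    row.names = NULL)
  dg <- object$diagnostics
  dg$parameter[dg$parameter == "sigma_proc"] <- "sigma_process"
  out <- merge(out, dg, by = "parameter", all.x = TRUE, sort = FALSE)
  class(out) <- c("summary.apd_fit", "data.frame")
  out
}

#' @export
print.summary.apd_fit <- function(x, digits = 4, ...) {
  cat("Posterior summary (quantiles), with split R-hat and bulk ESS:\n")
  y <- x; class(y) <- "data.frame"
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.apd_fit <- function(object, ...) {
  keep <- c("beta1", "beta2", "beta3", "sigma_process", "sigma_eps",
            "mu_alpha", "sigma_alpha", "p_ext", "p_col")
  apply(object$params[, keep, drop = FALSE], 2, stats::median)
}

#' @export
fitted.apd_fit <- function(object, ...) {
  N <- abundance_draws(object)
  apply(N, c(2, 3), stats::median)
}

#' Posterior (and forecast) abundance summaries
#'
#' Per-site, per-season posterior median abundance with credible intervals;
#' with `horizon > 0`, forward forecasts (new year effects and process
#' noise) are appended for seasons beyond the data.
#'
#' @param object an `"apd_fit"`.
#' @param horizon number of seasons to forecast beyond the last modelled
#'   season (default 0).
#' @param level interval mass.
#' @param method `"hpd"` (default, as used for abundance trajectories) or
#'   `"eti"`.
#' @param ... unused.
#' @return data frame with columns `site_id`, `season`, `forecast`,
#'   `median`, `lower`, `upper`.
#' @export
predict.apd_fit <- function(object, horizon = 0, level = 0.9,
                            method = c("hpd", "eti"), ...) {
  method <- match.arg(method)
  out <- posterior_summary(abundance_draws(object), level = level,
                           method = method)
  out$forecast <- FALSE
  if (horizon > 0) {
    fc <- apd_forecast(object, horizon = horizon)
    fs <- posterior_summary(fc$abundance, level = level, method = method)
    fs$forecast <- TRUE
    out <- rbind(out, fs)
  }
  out[order(out$site_id, out$season), c("site_id", "season", "forecast",
                                        "median", "lower", "upper")]
}

#' Posterior-predictive replicated counts
#'
#' For each census record in the fitted dataset, draws replicated counts
#' from the observation model under randomly chosen posterior draws.
#'
#' @param object an `"apd_fit"`.
#' @param nsim number of replicated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame: the census records plus columns `sim_1..sim_nsim`.
#' @export
simulate.apd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cnt <- object$dataset$counts
  site_ids <- dimnames(object$logN)[[2]]
  seasons <- as.integer(dimnames(object$logN)[[3]])
  si <- match(cnt$site_id, site_ids)
  ti <- match(cnt$season, seasons)
  n_draw <- dim(object$logN)[1]
  out <- cnt
  for (k in seq_len(nsim)) {
    d <- sample.int(n_draw, 1)
    ix <- cbind(d, si, ti)
    out[[paste0("sim_", k)]] <-
      observe_count(object$logN[ix], cnt$count_type, object$alpha[ix],
                    cnt$accuracy, object$spec,
                    occupied = object$z[ix])
  }
  out
}

#' Standardized log-scale residuals
#'
#' For each census record: the difference between the observed log count
#' and the posterior-median expected log count, divided by the record's
#' observation error scale.  Records at unoccupied (posterior-median)
#' site-seasons give `NA`.
#'
#' @param object an `"apd_fit"`.
#' @param ... unused.
#' @return numeric vector, one element per census record.
#' @export
residuals.apd_fit <- function(object, ...) {
  cnt <- object$dataset$counts
  site_ids <- dimnames(object$logN)[[2]]
  seasons <- as.integer(dimnames(object$logN)[[3]])
  si <- match(cnt$site_id, site_ids)
  ti <- match(cnt$season, seasons)
  mu <- apply(object$logN, c(2, 3), stats::median)[cbind(si, ti)] +
    ifelse(cnt$count_type == "chick",
           log(apply(object$alpha, c(2, 3), stats::median)[cbind(si, ti)]), 0)
  occ <- apply(object$z, c(2, 3), stats::median)[cbind(si, ti)] >= 0.5
  sig <- accuracy_sigma(cnt$accuracy, object$spec)
  res <- (log(pmax(cnt$count, 0.5)) - mu) / sig
  res[!occ] <- NA_real_
  res
}

#' Plot a fitted abundance trajectory
#'
#' Posterior median and credible band of nest abundance for one site, with
#' the nest (black) and chick (red) counts overlaid; zero counts are drawn
#' as squares on the axis.
#'
#' @param x an `"apd_fit"`.
#' @param site site identifier (default: first site).
#' @param level credible band mass (default 0.75, as conventional for
#'   abundance trajectories).
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.apd_fit <- function(x, site = NULL, level = 0.75, ...) {
  site <- site %||% dimnames(x$logN)[[2]][1]
  N <- abundance_draws(x)
  seasons <- as.integer(dimnames(N)[[3]])
  draws <- N[, site, , drop = TRUE]
  med <- apply(draws, 2, stats::median)
  ci <- apply(draws, 2, hpd_interval, prob = level)
  cnt <- x$dataset$counts[x$dataset$counts$site_id == site, ]
  ylim <- range(0, ci, cnt$count)
  graphics::plot(seasons, med, type = "n", ylim = ylim,
                 xlab = "season", ylab = "nests",
                 main = paste("Site", site), ...)
  graphics::polygon(c(seasons, rev(seasons)), c(ci[1, ], rev(ci[2, ])),
                    col = "grey85", border = NA)
  graphics::lines(seasons, med, lwd = 2)
  nest <- cnt$count_type == "nest"
  graphics::points(cnt$season[nest], cnt$count[nest],
                   pch = ifelse(cnt$count[nest] == 0, 15, 16))
  graphics::points(cnt$season[!nest], cnt$count[!nest], col = "red",
                   pch = ifelse(cnt$count[!nest] == 0, 15, 16))
  invisible(x)
}

# ---- hindcast and forecast ------------------------------------------------

#' Hindcast latent abundance before the modelled range
#'
#' Extends each posterior draw backwards from the first modelled season to
#' season `to` by inverting the growth map:
#' `logN[y] = logN[y+1] - r[s, y] - w`, with process noise
#' `w ~ Normal(0, sigma_process)` and year effects for pre-range seasons
#' drawn from `Normal(0, sigma_eps)` per draw.  Covariates for the
#' hindcast seasons are built from the dataset's ice series (which must
#' reach back to `to - 4`) and projected onto the fit's standardization
#' scale.  Occupancy is held at each draw's first-season state.
#'
#' Seasons inside the modelled range need no special treatment: the fit
#' already samples (imputes) latent abundance for every modelled
#' site-season.
#'
#' @param fit an `"apd_fit"`.
#' @param to first season of the extended range (`<` first modelled season).
#' @param seed optional seed for the hindcast noise.
#' @return array `[draw, site, season]` covering `to .. last`, whose
#'   overlap with the modelled range equals `fit$logN` exactly (`NA` at
#'   unoccupied site-seasons outside the modelled range).
#' @export
hindcast <- function(fit, to, seed = NULL) {
  stopifnot(inherits(fit, "apd_fit"))
  seasons <- as.integer(dimnames(fit$logN)[[3]])
  first <- seasons[1]
  if (to >= first) stop("'to' must precede the first modelled season ", first)
  if (!is.null(seed)) set.seed(seed)

  pre <- seq(to, first - 1L)
  ds2 <- fit$dataset
  ds2$season_range <- c(to, fit$dataset$season_range[2])
  raw_w <- build_winter_covariate(ds2, stat = fit$covariates$winter_stat)
  raw_s <- build_summer_covariate(ds2)
  xw <- standardize_covariate(raw_w[, as.character(pre), drop = FALSE],
                              fit$covariates$constants$winter)$z
  xs <- standardize_covariate(raw_s[, as.character(pre), drop = FALSE],
                              fit$covariates$constants$summer)$z

  n_draw <- dim(fit$logN)[1]; S <- dim(fit$logN)[2]
  site_ids <- dimnames(fit$logN)[[2]]
  ext <- array(NA_real_, dim = c(n_draw, S, length(pre) + length(seasons)),
               dimnames = list(NULL, site_ids,
                               as.character(c(pre, seasons))))
  ext[, , as.character(seasons)] <- fit$logN
  b1 <- fit$params[, "beta1"]; b2 <- fit$params[, "beta2"]
  b3 <- fit$params[, "beta3"]
  sp <- fit$params[, "sigma_process"]; se <- fit$params[, "sigma_eps"]
  occ1 <- matrix(fit$z[, , 1], n_draw, S) == 1  # [draw, site]
  for (y in rev(pre)) {
    eps_y <- stats::rnorm(n_draw, 0, se)       # shared across sites per draw
    for (s in seq_len(S)) {
      r <- growth_rate(b1, b2, b3, xw[s, as.character(y)],
                       xs[s, as.character(y)], eps_y)
      w <- stats::rnorm(n_draw, 0, sp)
      ext[, s, as.character(y)] <-
        ifelse(occ1[, s], ext[, s, as.character(y + 1L)] - r - w, NA_real_)
    }
  }
  ext
}

#' Forecast abundance beyond the last modelled season
#'
#' Steps each posterior draw forward `horizon` seasons: occupancy through
#' the extinction/colonization switch, abundance through the growth map
#' with a newly drawn year effect `Normal(0, sigma_eps)` and process noise
#' per season.  Covariates are carried forward from the last modelled
#' season (future sea ice being unknown).
#'
#' @param fit an `"apd_fit"`.
#' @param horizon number of seasons ahead (`>= 1`).
#' @param seed optional seed (default: derived from the fit's seed, so that
#'   repeated calls on the same fit agree).
#' @return list with arrays `abundance` (`z * exp(logN)`) and `z`, both
#'   `[draw, site, horizon]` with season dimnames.
#' @export
apd_forecast <- function(fit, horizon = 1, seed = NULL) {
  stopifnot(inherits(fit, "apd_fit"))
  if (horizon < 1) stop("horizon must be >= 1")
  set.seed(seed %||% child_seed(fit$seed, 9999L))
  seasons <- as.integer(dimnames(fit$logN)[[3]])
  TT <- length(seasons)
  n_draw <- dim(fit$logN)[1]; S <- dim(fit$logN)[2]
  site_ids <- dimnames(fit$logN)[[2]]
  new_seasons <- seasons[TT] + seq_len(horizon)

  b1 <- fit$params[, "beta1"]; b2 <- fit$params[, "beta2"]
  b3 <- fit$params[, "beta3"]
  sp <- fit$params[, "sigma_process"]; se <- fit$params[, "sigma_eps"]
  p_ext <- fit$params[, "p_ext"]; p_col <- fit$params[, "p_col"]
  pr <- fit$spec$priors

  logN_prev <- matrix(fit$logN[, , TT], n_draw, S)
  z_prev <- matrix(fit$z[, , TT], n_draw, S)
  xw_last <- fit$covariates$x_winter[, TT]
  xs_last <- fit$covariates$x_summer[, TT]

  ab <- array(NA_real_, c(n_draw, S, horizon),
              dimnames = list(NULL, site_ids, as.character(new_seasons)))
  zz <- array(NA_real_, c(n_draw, S, horizon),
              dimnames = list(NULL, site_ids, as.character(new_seasons)))
  for (h in seq_len(horizon)) {
    eps_new <- stats::rnorm(n_draw, 0, se)
    logN_new <- matrix(NA_real_, n_draw, S)
    z_new <- matrix(0, n_draw, S)
    for (s in seq_len(S)) {
      u <- stats::runif(n_draw)
      z_new[, s] <- ifelse(z_prev[, s] == 1, as.numeric(u >= p_ext),
                           as.numeric(u < p_col))
      r <- growth_rate(b1, b2, b3, xw_last[s], xs_last[s], eps_new)
      stepped <- logN_prev[, s] + r + stats::rnorm(n_draw, 0, sp)
      colonized <- stats::rnorm(n_draw, pr$colonize_mean, pr$colonize_sd)
      logN_new[, s] <- ifelse(z_prev[, s] == 1, stepped, colonized)
    }
    ab[, , h] <- z_new * exp(logN_new)
    zz[, , h] <- z_new
    logN_prev <- logN_new
    z_prev <- z_new
  }
  list(abundance = ab, z = zz)
}
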