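#' Geometric-mean growth multiplier of an abundance series
#'
#' Given one abundance series (zeros marking unoccupied seasons), the
#' geometric mean of the ratios `N[y+1] / N[y]` over consecutive pairs with
#' both seasons occupied.  A constant positive series gives exactly 1.
#'
#' @param N numeric abundance series (non-negative; 0 = unoccupied).
#' @return scalar geometric-mean multiplier, or `NA` if no valid pair.
#' @export
growth_multiplier_series <- function(N) {
  stopifnot(all(N >= 0))
  ok <- which(N[-length(N)] > 0 & N[-1] > 0)
  if (length(ok) == 0) return(NA_real_)
  exp(mean(log(N[ok + 1] / N[ok])))
}

#' Posterior growth-rate multipliers per site
#'
#' The "actual" multiplier is, per posterior draw and site, the geometric
#' mean of the ratios of abundance in successive seasons over all
#' consecutive pairs where the site was occupied in that draw.  The
#' "predicted" multiplier replaces the realized ratios by the model's
#' predicted seasonal multipliers `exp(r)` over the same occupied pairs,
#' isolating the deterministic part of growth: the two coincide exactly
#' when the process error is zero, and diverge as process noise grows.
#' Draws with no valid pair for a site are excluded (the count is
#' reported).
#'
#' @param fit an `"apd_fit"`.
#' @param type `"actual"` or `"predicted"`.
#' @param sites site identifiers (default all).
#' @param levels interval masses for the equal-tailed summary intervals.
#' @return list of class `"apd_multipliers"`: `draws` (matrix
#'   `[draw, site]`, `NA` where excluded), `summary` (data frame: site,
#'   posterior median, interval bounds per level, number of excluded
#'   draws), `type`.
#' @export
growth_multipliers <- function(fit, type = c("actual", "predicted"),
                               sites = NULL, levels = c(0.5, 0.95)) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "apd_fit"))
  site_ids <- sites %||% dimnames(fit$logN)[[2]]
  n_draw <- dim(fit$logN)[1]
  TT <- dim(fit$logN)[3]
  draws <- matrix(NA_real_, n_draw, length(site_ids),
                  dimnames = list(NULL, site_ids))

  if (type == "predicted") {
    eps_mat <- fit$params[, grep("^eps\\[", colnames(fit$params)),
                          drop = FALSE]
    b1 <- fit$params[, "beta1"]; b2 <- fit$params[, "beta2"]
    b3 <- fit$params[, "beta3"]
  }
  for (j in seq_along(site_ids)) {
    s <- site_ids[j]
    zs <- matrix(fit$z[, s, ], n_draw, TT)
    pair_ok <- zs[, -TT, drop = FALSE] == 1 & zs[, -1, drop = FALSE] == 1
    if (type == "actual") {
      ln <- matrix(fit$logN[, s, ], n_draw, TT)
      steps <- ln[, -1, drop = FALSE] - ln[, -TT, drop = FALSE]
    } else {
      xw <- fit$covariates$x_winter[s, -TT]
      xs <- fit$covariates$x_summer[s, -TT]
      steps <- b1 + outer(b2, xw) + outer(b3, xs) + eps_mat
    }
    npair <- rowSums(pair_ok)
    g <- exp(rowSums(steps * pair_ok) / npair)
    g[npair == 0] <- NA_real_
    draws[, j] <- g
  }
  summ <- data.frame(site_id = site_ids,
                     median = apply(draws, 2, stats::median, na.rm = TRUE),
                     n_excluded = colSums(is.na(draws)),
                     row.names = NULL, stringsAsFactors = FALSE)
  for (lv in levels) {
    ci <- apply(draws, 2, function(x)
      eti_interval(x[!is.na(x)], prob = lv))
    summ[[sprintf("lower_%g", lv * 100)]] <- ci[1, ]
    summ[[sprintf("upper_%g", lv * 100)]] <- ci[2, ]
  }
  structure(list(draws = draws, summary = summ, type = type),
            class = "apd_multipliers")
}

#' @export
print.apd_multipliers <- function(x, ...) {
  cat(sprintf("Posterior %s growth-rate multipliers (%d sites)\n",
              x$type, ncol(x$draws)))
  print(head(x$summary, 10))
  if (nrow(x$summary) > 10) cat("...\n")
  invisible(x)
}

#' Aggregate posterior abundance over regions
#'
#' Sums abundance draws over the member sites of each region, per draw and
#' season (exact additivity draw by draw -- summing posterior medians would
#' not give the median of the sum), then summarizes with credible
#' intervals.
#'
#' @param fit an `"apd_fit"`.
#' @param regions named assignment `site_id -> region`; default taken from
#'   the dataset's site table.
#' @param level interval mass (default 0.9, highest posterior density).
#' @param method `"hpd"` or `"eti"`.
#' @return object of class `"apd_aggregate"`: `draws` (array
#'   `[draw, region, season]`) and `summary` (data frame: region, season,
#'   median, lower, upper).
#' @export
apd_aggregate <- function(fit, regions = NULL, level = 0.9,
                          method = c("hpd", "eti")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "apd_fit"))
  if (is.null(regions))
    regions <- stats::setNames(fit$dataset$sites$region,
                               fit$dataset$sites$site_id)
  N <- abundance_draws(fit)
  site_ids <- dimnames(N)[[2]]
  reg_of <- regions[site_ids]
  if (any(is.na(reg_of))) stop("region assignment missing for some sites")
  reg_levels <- sort(unique(reg_of))
  n_draw <- dim(N)[1]; TT <- dim(N)[3]
  agg <- array(0, c(n_draw, length(reg_levels), TT),
               dimnames = list(NULL, reg_levels, dimnames(N)[[3]]))
  for (k in seq_along(reg_levels)) {
    members <- which(reg_of == reg_levels[k])
    agg[, k, ] <- apply(N[, members, , drop = FALSE], c(1, 3), sum)
  }
  rows <- expand.grid(region = reg_levels, season = dimnames(N)[[3]],
                      stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    x <- agg[, rows$region[i], rows$season[i]]
    ci <- cred_interval(x, level, method)
    data.frame(region = rows$region[i], season = as.integer(rows$season[i]),
               median = stats::median(x), lower = unname(ci["lower"]),
               upper = unname(ci["upper"]), stringsAsFactors = FALSE)
  }))
  structure(list(draws = agg, summary = summ, level = level, method = method),
            class = "apd_aggregate")
}

#' @export
print.apd_aggregate <- function(x, ...) {
  cat(sprintf("Aggregated posterior abundance: %d region(s) x %d seasons (%d%% %s intervals)\n",
              dim(x$draws)[2], dim(x$draws)[3], round(x$level * 100),
              toupper(x$method)))
  invisible(x)
}

#' @export
plot.apd_aggregate <- function(x, region = NULL, ...) {
  region <- region %||% dimnames(x$draws)[[2]][1]
  d <- x$summary[x$summary$region == region, ]
  graphics::plot(d$season, d$median, type = "n", ylim = range(0, d$upper),
                 xlab = "season", ylab = "aggregated nests",
                 main = paste("Region", region), ...)
  graphics::polygon(c(d$season, rev(d$season)), c(d$lower, rev(d$upper)),
                    col = "grey85", border = NA)
  graphics::lines(d$season, d$median, lwd = 2)
  invisible(x)
}

#' Finite-population standard deviations of growth-rate variance sources
#'
#' Compares the contributions of the model's variance sources to the
#' intrinsic growth rate on a common scale: per posterior draw, the sample
#' standard deviation (n-1 denominator) of the realized values of each
#' source -- the year effects, the winter covariate term `beta2 * x_w`, the
#' summer term `beta3 * x_s` (over the site-season transitions entering the
#' model), and the realized process residuals
#' `logN[y+1] - logN[y] - r` over occupied transitions.
#'
#' @param fit an `"apd_fit"`.
#' @param level interval mass for the equal-tailed summary.
#' @return list of class `"apd_fpsd"`: `draws` (matrix `[draw, source]`)
#'   and `summary` (data frame: source, median, lower, upper).
#' @export
finite_population_sd <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "apd_fit"))
  n_draw <- dim(fit$logN)[1]
  S <- dim(fit$logN)[2]; TT <- dim(fit$logN)[3]
  if (TT < 3) stop("need at least 2 transitions per source")
  eps_mat <- fit$params[, grep("^eps\\[", colnames(fit$params)), drop = FALSE]
  xw <- as.numeric(fit$covariates$x_winter[, -TT])
  xs <- as.numeric(fit$covariates$x_summer[, -TT])

  sd_eps <- apply(eps_mat, 1, stats::sd)
  sd_w <- abs(fit$params[, "beta2"]) * stats::sd(xw)
  sd_s <- abs(fit$params[, "beta3"]) * stats::sd(xs)

  # realized process residuals over occupied->occupied transitions
  sd_proc <- vapply(seq_len(n_draw), function(d) {
    ln <- matrix(fit$logN[d, , ], S, TT)
    zz <- matrix(fit$z[d, , ], S, TT)
    r <- growth_rate(fit$params[d, "beta1"], fit$params[d, "beta2"],
                     fit$params[d, "beta3"],
                     fit$covariates$x_winter[, -TT, drop = FALSE],
                     fit$covariates$x_summer[, -TT, drop = FALSE],
                     matrix(eps_mat[d, ], S, TT - 1, byrow = TRUE))
    w <- ln[, -1, drop = FALSE] - ln[, -TT, drop = FALSE] - r
    ok <- zz[, -TT, drop = FALSE] == 1 & zz[, -1, drop = FALSE] == 1
    v <- w[ok]
    if (length(v) < 2) NA_real_ else stats::sd(v)
  }, numeric(1))

  draws <- cbind(year_effects = sd_eps, winter = sd_w, summer = sd_s,
                 process = sd_proc)
  if (any(colSums(!is.na(draws)) < 1))
    stop("a variance source has fewer than 2 realizations")
  summ <- do.call(rbind, lapply(colnames(draws), function(src) {
    x <- draws[, src]; x <- x[!is.na(x)]
    ci <- eti_interval(x, level)
    data.frame(source = src, median = stats::median(x),
               lower = unname(ci["lower"]), upper = unname(ci["upper"]),
               stringsAsFactors = FALSE)
  }))
  structure(list(draws = draws, summary = summ), class = "apd_fpsd")
}

#' @export
print.apd_fpsd <- function(x, ...) {
  cat("Finite-population SDs of growth-rate variance sources:\n")
  print(transform(x$summary, median = round(median, 4),
                  lower = round(lower, 4), upper = round(upper, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Fraction of counts with observation error below process error
#'
#' Per posterior draw, the fraction of all census counts whose accuracy-code
#' observation error scale is smaller than that draw's process error scale;
#' summarized by the posterior median and a 95% equal-tailed interval.
#' This is the headline comparison of measurement imprecision against
#' intrinsic stochasticity: a fraction near 1 means the system's noise
#' floor is process error, not counting error.
#'
#' @param fit an `"apd_fit"`.
#' @param level interval mass (default 0.95).
#' @return list of class `"apd_obs_vs_process"`: `draws` (per-draw
#'   fractions), `median`, `lower`, `upper`, `n_counts`.
#' @export
obs_vs_process <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "apd_fit"))
  fr <- obs_process_fraction(fit$params[, "sigma_process"],
                             fit$dataset$counts$accuracy, fit$spec)
  ci <- eti_interval(fr, level)
  structure(list(draws = fr, median = stats::median(fr),
                 lower = unname(ci["lower"]), upper = unname(ci["upper"]),
                 n_counts = nrow(fit$dataset$counts)),
            class = "apd_obs_vs_process")
}

#' @rdname obs_vs_process
#' @param sigma_process numeric vector of process error draws.
#' @param codes accuracy codes of the counts being compared.
#' @param spec an `"apd_spec"`.
#' @export
obs_process_fraction <- function(sigma_process, codes, spec = apd_spec()) {
  sig_obs <- accuracy_sigma(codes, spec)
  vapply(sigma_process, function(sp) mean(sig_obs < sp), numeric(1))
}

#' @export
print.apd_obs_vs_process <- function(x, ...) {
  cat(sprintf(
    "Counts with observation error below process error: %.0f%% (95%% CI: %.0f%%, %.0f%%) of %d counts\n",
    100 * x$median, 100 * x$lower, 100 * x$upper, x$n_counts))
  invisible(x)
}

#' Correlation of year effects with an external index
#'
#' Per posterior draw, the Pearson correlation between the year effects and
#' a user-supplied annual index (e.g. a climate mode index) over the
#' overlapping seasons, propagating the posterior uncertainty in the year
#' effects rather than correlating against posterior medians (a
#' median-based value is also reported for comparison).
#'
#' @param fit an `"apd_fit"`.
#' @param index named numeric vector (names = seasons) or data frame with
#'   columns `season`, `value`.
#' @param level interval mass.
#' @return list of class `"apd_year_cor"`: `draws`, `median`, `lower`,
#'   `upper`, `median_based`, `n_overlap`.
#' @export
year_effect_correlation <- function(fit, index, level = 0.95) {
  stopifnot(inherits(fit, "apd_fit"))
  if (is.data.frame(index))
    index <- stats::setNames(index$value, index$season)
  eps_cols <- grep("^eps\\[", colnames(fit$params), value = TRUE)
  eps_seasons <- gsub("eps\\[|\\]", "", eps_cols)
  overlap <- intersect(eps_seasons, names(index))
  if (length(overlap) < 3)
    stop("index overlaps fewer than 3 modelled seasons")
  iv <- index[overlap]
  if (stats::sd(iv) == 0) stop("index has zero variance over the overlap")
  eps_mat <- fit$params[, paste0("eps[", overlap, "]"), drop = FALSE]
  draws <- apply(eps_mat, 1, function(e) stats::cor(e, iv))
  ci <- eti_interval(draws, level)
  structure(list(draws = draws, median = stats::median(draws),
                 lower = unname(ci["lower"]), upper = unname(ci["upper"]),
                 median_based = stats::cor(apply(eps_mat, 2, stats::median), iv),
                 n_overlap = length(overlap)),
            class = "apd_year_cor")
}

#' @export
print.apd_year_cor <- function(x, ...) {
  cat(sprintf("Year-effect / index correlation over %d seasons: median %.3f (CI %.3f, %.3f)\n",
              x$n_overlap, x$median, x$lower, x$upper))
  invisible(x)
}

#' Density-dependence diagnostic
#'
#' Extracts, for every occupied site-season transition, the posterior
#' median abundance at the start of the transition, the realized growth
#' rate `log(N[y+1]/N[y])`, and the model's predicted growth rate `r`.
#' Plotting realized minus predicted growth against abundance reveals
#' unmodelled density dependence: under the fitted (density-independent)
#' model the difference is pure process noise with no trend in abundance,
#' while a ceiling shows up as realized below predicted at large abundance.
#'
#' @param fit an `"apd_fit"`.
#' @return data frame with columns `site_id`, `season`, `N`,
#'   `r_realized`, `r_predicted` (posterior medians per transition); empty
#'   (with a warning) if no transition has both seasons occupied.
#' @export
density_dependence <- function(fit) {
  stopifnot(inherits(fit, "apd_fit"))
  S <- dim(fit$logN)[2]; TT <- dim(fit$logN)[3]
  site_ids <- dimnames(fit$logN)[[2]]
  seasons <- as.integer(dimnames(fit$logN)[[3]])
  if (TT < 2) {
    warning("need at least two seasons for growth-rate pairs")
    return(data.frame(site_id = character(0), season = integer(0),
                      N = numeric(0), r_realized = numeric(0),
                      r_predicted = numeric(0)))
  }
  eps_med <- apply(fit$params[, grep("^eps\\[", colnames(fit$params)),
                              drop = FALSE], 2, stats::median)
  cf <- coef(fit)
  out <- list()
  for (s in seq_len(S)) {
    zs <- matrix(fit$z[, s, ], ncol = TT)
    occ_pair <- colMeans(zs[, -TT, drop = FALSE] == 1 &
                           zs[, -1, drop = FALSE] == 1) >= 0.5
    if (!any(occ_pair)) next
    ln <- matrix(fit$logN[, s, ], ncol = TT)
    ln_med <- apply(ln, 2, stats::median)
    for (t in which(occ_pair)) {
      r_pred <- growth_rate(cf["beta1"], cf["beta2"], cf["beta3"],
                            fit$covariates$x_winter[s, t],
                            fit$covariates$x_summer[s, t], eps_med[t])
      out[[length(out) + 1]] <- data.frame(
        site_id = site_ids[s], season = seasons[t],
        N = exp(ln_med[t]),
        r_realized = ln_med[t + 1] - ln_med[t],
        r_predicted = unname(r_pred), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    warning("no occupied transitions found")
    return(data.frame(site_id = character(0), season = integer(0),
                      N = numeric(0), r_realized = numeric(0),
                      r_predicted = numeric(0)))
  }
  do.call(rbind, out)
}

#' Posterior-predictive intervals for the observed counts
#'
#' For each census record, replicates the count under every posterior draw
#' (drawing fresh observation noise) and summarizes the replicates with a
#' highest-posterior-density interval, giving the calibration check of
#' Fig.-3 style error bars: about `level` of observed counts should fall
#' inside their intervals.
#'
#' @param fit an `"apd_fit"`.
#' @param level interval mass (default 0.9).
#' @param seed optional seed for the replication noise.
#' @return data frame: the census records plus `pred_median`, `pred_lower`,
#'   `pred_upper`, `inside` (logical).
#' @export
posterior_predictive_counts <- function(fit, level = 0.9, seed = NULL) {
  stopifnot(inherits(fit, "apd_fit"))
  if (!is.null(seed)) set.seed(seed)
  cnt <- fit$dataset$counts
  site_ids <- dimnames(fit$logN)[[2]]
  seasons <- as.integer(dimnames(fit$logN)[[3]])
  si <- match(cnt$site_id, site_ids)
  ti <- match(cnt$season, seasons)
  n_draw <- dim(fit$logN)[1]
  sig <- accuracy_sigma(cnt$accuracy, fit$spec)
  out <- cnt
  out$pred_median <- NA_real_; out$pred_lower <- NA_real_
  out$pred_upper <- NA_real_
  for (i in seq_len(nrow(cnt))) {
    mu <- fit$logN[, si[i], ti[i]] +
      if (cnt$count_type[i] == "chick") log(fit$alpha[, si[i], ti[i]]) else 0
    rep_counts <- round(exp(stats::rnorm(n_draw, mu, sig[i]))) *
      fit$z[, si[i], ti[i]]
    ci <- hpd_interval(rep_counts, prob = level)
    out$pred_median[i] <- stats::median(rep_counts)
    out$pred_lower[i] <- ci["lower"]
    out$pred_upper[i] <- ci["upper"]
  }
  out$inside <- out$count >= out$pred_lower & out$count <= out$pred_upper
  out
}
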