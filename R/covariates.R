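#' Raw winter sea-ice covariate
#'
#' For each site and season `y`, summarizes peak winter sea-ice
#' concentration over the five-winter window `y-4 .. y`.  The window
#' statistic is the maximum by default: the covariate is a krill-recruitment
#' surrogate and the biological contrast of interest is an "ice drought" --
#' a run of winters in which extensive ice never forms -- which the window
#' maximum captures directly.  A window mean is available as an alternative.
#'
#' @param dataset an `"apd_dataset"`.
#' @param stat window statistic, `"max"` (default) or `"mean"`.
#' @return numeric matrix `[site, season]` with dimnames, one column per
#'   season in the dataset's range.
#' @export
build_winter_covariate <- function(dataset, stat = c("max", "mean")) {
  stat <- match.arg(stat)
  f <- if (stat == "max") max else mean
  window_covariate(dataset, "winter_peak",
                   needs = function(y) (y - 4):y,
                   fun = function(vals) f(vals))
}

#' Raw summer sea-ice covariate
#'
#' For each site and season `y`, the peak summer sea-ice concentration in
#' season `y-4`: the birth season of the cohort recruiting into the breeding
#' population in season `y`, when summer ice governs colony access.
#'
#' @inheritParams build_winter_covariate
#' @return numeric matrix `[site, season]`.
#' @export
build_summer_covariate <- function(dataset) {
  window_covariate(dataset, "summer_peak",
                   needs = function(y) y - 4,
                   fun = function(vals) vals[[1]])
}

window_covariate <- function(dataset, column, needs, fun) {
  stopifnot(inherits(dataset, "apd_dataset"))
  seasons <- seq(dataset$season_range[1], dataset$season_range[2])
  site_ids <- sort(unique(dataset$sites$site_id))
  out <- matrix(NA_real_, length(site_ids), length(seasons),
                dimnames = list(site_ids, seasons))
  problems <- character(0)
  for (s in site_ids) {
    rows <- dataset$ice[dataset$ice$site_id == s, ]
    vals <- stats::setNames(rows[[column]], rows$season)
    for (j in seq_along(seasons)) {
      y <- seasons[j]
      need_y <- needs(y)
      have <- as.character(need_y) %in% names(vals)
      if (!all(have)) {
        problems <- c(problems, sprintf(
          "site '%s', season %d: ice missing for season(s) %s",
          s, y, paste(need_y[!have], collapse = ", ")))
        next
      }
      out[s, j] <- fun(vals[as.character(need_y)])
    }
  }
  if (length(problems) > 0)
    stop("incomplete ice window:\n  ", paste(problems, collapse = "\n  "))
  out
}

#' Standardize a raw covariate matrix
#'
#' Z-scores a raw covariate over the pooled set of modelled site-seasons
#' (sample standard deviation, `n - 1` denominator).  Standardization is
#' pooled rather than per site because the associated regression
#' coefficients are global.  Pass previously stored `constants` to project
#' new raw values onto an existing scale.
#'
#' @param x numeric matrix (or vector) of raw covariate values.
#' @param constants optional `c(center, scale)` from a previous call.
#' @return list with elements `z` (standardized values, same shape as `x`)
#'   and `constants` (named numeric `c(center, scale)`).
#' @export
standardize_covariate <- function(x, constants = NULL) {
  v <- as.numeric(x)
  if (is.null(constants)) {
    if (length(unique(v)) < 2) stop("cannot standardize: fewer than 2 distinct values")
    constants <- c(center = mean(v), scale = stats::sd(v))
    if (constants["scale"] == 0) stop("cannot standardize: zero variance")
  }
  z <- (x - constants[["center"]]) / constants[["scale"]]
  list(z = z, constants = constants)
}

#' Build standardized sea-ice covariates for a dataset
#'
#' Combines [build_winter_covariate()], [build_summer_covariate()] and
#' [standardize_covariate()] into the covariate object consumed by
#' [apd_fit()] and the forward simulator.  Coefficients on these covariates
#' are therefore effects of a one standard deviation change.
#'
#' @inheritParams build_winter_covariate
#' @param winter_stat five-winter window statistic (`"max"` or `"mean"`).
#' @return an object of class `"apd_covariates"`: list with matrices
#'   `x_winter`, `x_summer` (z-scores, `[site, season]`), the raw matrices,
#'   and the standardization `constants` for each covariate.
#' @export
apd_covariates <- function(dataset, winter_stat = c("max", "mean")) {
  winter_stat <- match.arg(winter_stat)
  raw_w <- build_winter_covariate(dataset, stat = winter_stat)
  raw_s <- build_summer_covariate(dataset)
  zw <- standardize_covariate(raw_w)
  zs <- standardize_covariate(raw_s)
  structure(list(x_winter = zw$z, x_summer = zs$z,
                 raw_winter = raw_w, raw_summer = raw_s,
                 constants = list(winter = zw$constants, summer = zs$constants),
                 winter_stat = winter_stat),
            class = "apd_covariates")
}

#' @export
print.apd_covariates <- function(x, ...) {
  cat(sprintf("Standardized sea-ice covariates: %d sites x %d seasons (winter stat: %s)\n",
              nrow(x$x_winter), ncol(x$x_winter), x$winter_stat))
  invisible(x)
}
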