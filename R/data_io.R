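#' Assemble and validate a census dataset
#'
#' Bundles colony census records, site metadata, and per-site sea-ice series
#' into a validated dataset object, the common input for covariate
#' construction and model fitting.
#'
#' Census records hold one count per row: `site_id`, `season` (the split
#' austral year labelled by its starting calendar year, e.g. season 1982 is
#' the 1982/83 summer), `count_type` (`"nest"` or `"chick"`; adult counts are
#' not modelled), `count` (non-negative integer; zero counts are legitimate
#' records of unoccupied seasons), and `accuracy` (census accuracy code 1-5,
#' 1 = most precise).  Site metadata maps `site_id` to a `region` label (for
#' example a CCAMLR subarea such as `"48.1"`) plus optional coordinates.
#' Ice series give per-site, per-season `winter_peak` and `summer_peak` sea
#' ice concentrations as fractions in \[0, 1\]; because the winter covariate
#' is a five-winter window statistic and the summer covariate is lagged four
#' seasons, the ice series must be complete from `first_season - 4` through
#' `last_season` for every site.
#'
#' Validation is total: every violated invariant in the inputs is collected
#' and reported in a single error (condition class
#' `"apd_validation_error"`), with row context, rather than stopping at the
#' first problem.
#'
#' @param counts data frame with columns `site_id`, `season`, `count_type`,
#'   `count`, `accuracy`.
#' @param sites data frame with columns `site_id`, `region` and optional
#'   `latitude`, `longitude`.
#' @param ice data frame with columns `site_id`, `season`, `winter_peak`,
#'   `summer_peak`.
#' @param season_range integer vector `c(first, last)`; defaults to the range
#'   of seasons present in `counts`.
#' @return an object of class `"apd_dataset"`: a list with elements
#'   `counts`, `sites`, `ice` (cleaned data frames) and `season_range`.
#' @seealso [load_dataset()] to read the three tables from delimited files,
#'   [write_dataset()] for the inverse.
#' @export
apd_dataset <- function(counts, sites, ice, season_range = NULL) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, sprintf(...))

  counts <- check_columns(counts, "counts",
                          c("site_id", "season", "count_type", "count", "accuracy"))
  sites <- check_columns(sites, "sites", c("site_id", "region"))
  ice <- check_columns(ice, "ice",
                       c("site_id", "season", "winter_peak", "summer_peak"))

  counts$site_id <- as.character(counts$site_id)
  sites$site_id <- as.character(sites$site_id)
  sites$region <- as.character(sites$region)
  ice$site_id <- as.character(ice$site_id)
  counts$count_type <- as.character(counts$count_type)

  if (is.null(season_range)) {
    if (nrow(counts) == 0) stop("cannot infer season_range from empty counts")
    season_range <- range(counts$season)
  }
  season_range <- as.integer(season_range)
  stopifnot(length(season_range) == 2, season_range[1] <= season_range[2])

  row_id <- function(df) {
    if (!is.null(df$.row)) df$.row else seq_len(nrow(df))
  }
  crow <- row_id(counts)

  bad <- which(!(counts$count_type %in% c("nest", "chick")))
  for (i in bad) note("counts row %s: count_type '%s' is not 'nest' or 'chick'",
                      crow[i], counts$count_type[i])
  bad <- which(is.na(counts$count) | counts$count < 0 |
                 counts$count != round(counts$count))
  for (i in bad) note("counts row %s: count '%s' is not a non-negative integer",
                      crow[i], counts$count[i])
  bad <- which(!(counts$accuracy %in% 1:5))
  for (i in bad) note("counts row %s: accuracy '%s' is outside 1..5",
                      crow[i], counts$accuracy[i])
  bad <- which(counts$season < season_range[1] | counts$season > season_range[2])
  for (i in bad) note("counts row %s: season %s outside configured range %s..%s",
                      crow[i], counts$season[i], season_range[1], season_range[2])

  key <- paste(counts$site_id, counts$season, counts$count_type)
  for (i in which(duplicated(key))) {
    note("counts row %s: duplicate record for (%s, %s, %s)",
         crow[i], counts$site_id[i], counts$season[i], counts$count_type[i])
  }

  if (anyDuplicated(sites$site_id)) {
    for (i in which(duplicated(sites$site_id)))
      note("sites row %s: duplicate site_id '%s'", row_id(sites)[i], sites$site_id[i])
  }
  bad <- which(is.na(sites$region) | !nzchar(sites$region))
  for (i in bad) note("sites row %s: empty region for site '%s'",
                      row_id(sites)[i], sites$site_id[i])

  unknown <- setdiff(unique(counts$site_id), sites$site_id)
  for (s in unknown) note("counts: site_id '%s' not present in sites table", s)

  bad <- which(is.na(ice$winter_peak) | ice$winter_peak < 0 | ice$winter_peak > 1)
  for (i in bad) note("ice row %s: winter_peak '%s' outside [0, 1]",
                      row_id(ice)[i], ice$winter_peak[i])
  bad <- which(is.na(ice$summer_peak) | ice$summer_peak < 0 | ice$summer_peak > 1)
  for (i in bad) note("ice row %s: summer_peak '%s' outside [0, 1]",
                      row_id(ice)[i], ice$summer_peak[i])

  # Ice completeness over the covariate window for every modelled site.
  needed <- seq(season_range[1] - 4L, season_range[2])
  for (s in sites$site_id) {
    have <- ice$season[ice$site_id == s]
    miss <- setdiff(needed, have)
    if (length(miss) > 0)
      note("ice: site '%s' missing seasons %s (required window %s..%s)",
           s, paste(miss, collapse = ", "), needed[1], needed[length(needed)])
  }

  if (length(problems) > 0) {
    stop(structure(
      class = c("apd_validation_error", "error", "condition"),
      list(message = paste0("dataset validation failed (", length(problems),
                            " problem(s)):\n  ",
                            paste(problems, collapse = "\n  ")),
           call = sys.call(-1), problems = problems)))
  }

  counts$.row <- NULL; sites$.row <- NULL; ice$.row <- NULL
  counts <- counts[order(counts$site_id, counts$season, counts$count_type), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  structure(list(counts = counts, sites = sites, ice = ice,
                 season_range = season_range),
            class = "apd_dataset")
}

check_columns <- function(df, name, required) {
  if (!is.data.frame(df)) stop(sprintf("'%s' must be a data frame", name))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("'%s' is missing required column(s): %s",
                 name, paste(missing, collapse = ", ")))
  df
}

#' Load a census dataset from delimited files
#'
#' Reads the three comma-delimited tables (counts, sites, ice; lower snake
#' case headers, UTF-8) and validates them via [apd_dataset()].  Row numbers
#' in validation messages refer to data rows of the source file (header
#' excluded).
#'
#' @param counts_path,sites_path,ice_path paths to CSV files.
#' @inheritParams apd_dataset
#' @return an `"apd_dataset"`.
#' @export
load_dataset <- function(counts_path, sites_path, ice_path, season_range = NULL) {
  rd <- function(p) {
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    df$.row <- seq_len(nrow(df))
    df
  }
  apd_dataset(rd(counts_path), rd(sites_path), rd(ice_path),
              season_range = season_range)
}

#' Write a dataset back to delimited files
#'
#' Inverse of [load_dataset()]; writes `counts.csv`, `sites.csv` and
#' `ice.csv` into `dir`.  A load/write/load round trip preserves every
#' census record exactly.
#'
#' @param dataset an `"apd_dataset"`.
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "apd_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.csv", "sites.csv", "ice.csv"))
  utils::write.csv(dataset$counts, paths[1], row.names = FALSE)
  utils::write.csv(dataset$sites, paths[2], row.names = FALSE)
  utils::write.csv(dataset$ice, paths[3], row.names = FALSE)
  invisible(paths)
}

#' @export
print.apd_dataset <- function(x, ...) {
  cat("Adelie census dataset\n")
  cat(sprintf("  sites:   %d (%d region(s))\n", nrow(x$sites),
              length(unique(x$sites$region))))
  cat(sprintf("  seasons: %d..%d\n", x$season_range[1], x$season_range[2]))
  cat(sprintf("  counts:  %d records (%d nest, %d chick; %d zero counts)\n",
              nrow(x$counts), sum(x$counts$count_type == "nest"),
              sum(x$counts$count_type == "chick"), sum(x$counts$count == 0)))
  invisible(x)
}

#' Summarize posterior abundance to a tidy table
#'
#' Produces the long-format summary table written by
#' [write_posterior_summary()]: one row per site and season with the
#' posterior median abundance and a credible interval.
#'
#' @param draws an `"apd_fit"` object, or a numeric array of abundance draws
#'   with dimensions `(draw, site, season)` and dimnames on the site and
#'   season margins.
#' @param level interval mass (default 0.9).
#' @param method `"hpd"` (default) or `"eti"`.
#' @return data frame with columns `site_id`, `season`, `quantity`,
#'   `median`, `lower`, `upper`.
#' @export
posterior_summary <- function(draws, level = 0.9, method = c("hpd", "eti")) {
  method <- match.arg(method)
  if (inherits(draws, "apd_fit")) draws <- abundance_draws(draws)
  stopifnot(is.array(draws), length(dim(draws)) == 3)
  if (dim(draws)[1] < 1) stop("empty draws")
  sites <- dimnames(draws)[[2]] %||% as.character(seq_len(dim(draws)[2]))
  seasons <- dimnames(draws)[[3]] %||% as.character(seq_len(dim(draws)[3]))
  grid <- expand.grid(site = seq_along(sites), season = seq_along(seasons))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- draws[, grid$site[i], grid$season[i]]
    ci <- cred_interval(x, level, method)
    data.frame(site_id = sites[grid$site[i]],
               season = as.integer(seasons[grid$season[i]]),
               quantity = "abundance",
               median = stats::median(x),
               lower = unname(ci["lower"]), upper = unname(ci["upper"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$site_id, out$season), , drop = FALSE]
}

#' Write a posterior abundance summary table
#'
#' Writes the tidy table of [posterior_summary()] as CSV at full double
#' precision (15 significant digits), so the table round-trips losslessly
#' through [read_posterior_summary()].
#'
#' @inheritParams posterior_summary
#' @param path output CSV path.
#' @return invisibly, the summary data frame.
#' @export
write_posterior_summary <- function(draws, path, level = 0.9,
                                    method = c("hpd", "eti")) {
  out <- posterior_summary(draws, level = level, method = method)
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "season"
  out_chr <- out
  out_chr[num] <- lapply(out[num], function(x) format(x, digits = 15))
  utils::write.csv(out_chr, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' @rdname write_posterior_summary
#' @export
read_posterior_summary <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
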