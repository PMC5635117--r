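`%||%` <- function(a, b) if (is.null(a)) b else a

#' Highest posterior density interval
#'
#' Shortest interval containing at least the given posterior mass: among
#' all windows of `ceiling(prob * n)` sorted draws, the narrowest.
#'
#' @param x numeric vector of posterior draws.
#' @param prob target mass, in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.9) {
  stopifnot(is.numeric(x), length(x) >= 1, prob > 0, prob < 1)
  xs <- sort(x)
  n <- length(xs)
  k <- max(2L, ceiling(prob * n))
  if (k >= n) return(c(lower = xs[1], upper = xs[n]))
  widths <- xs[k:n] - xs[seq_len(n - k + 1)]
  i <- which.min(widths)
  c(lower = xs[i], upper = xs[i + k - 1])
}

#' Equal-tailed credible interval
#'
#' @param x numeric vector of draws.
#' @param prob interval mass, in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @export
eti_interval <- function(x, prob = 0.9) {
  stopifnot(is.numeric(x), prob > 0, prob < 1)
  q <- stats::quantile(x, c((1 - prob) / 2, 1 - (1 - prob) / 2), names = FALSE)
  c(lower = q[1], upper = q[2])
}

cred_interval <- function(x, prob, method = c("hpd", "eti")) {
  method <- match.arg(method)
  if (method == "hpd") hpd_interval(x, prob) else eti_interval(x, prob)
}

# Truncated normal on [a, b]: log density and random draws (inverse CDF).
dtnorm_log <- function(x, mean, sd, a, b) {
  ifelse(x < a | x > b, -Inf,
         stats::dnorm(x, mean, sd, log = TRUE) -
           log(stats::pnorm(b, mean, sd) - stats::pnorm(a, mean, sd)))
}

rtnorm <- function(n, mean, sd, a, b) {
  pa <- stats::pnorm(a, mean, sd)
  pb <- stats::pnorm(b, mean, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mean, sd)
}

# Half-normal log density (scale parameterization), x >= 0.
dhalfnorm_log <- function(x, scale) {
  ifelse(x < 0, -Inf, stats::dnorm(x, 0, scale, log = TRUE) + log(2))
}

# Derive a 32-bit-safe child seed from a base seed and a stream index.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7907 * as.numeric(k)) %% 2147483629L) + 1L
}
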