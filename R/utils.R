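#' Round half away from zero
#'
#' Reported masses and percent changes follow commercial/tabular rounding
#' (0.725 -> 0.73, -53.5 -> -54), not the IEC round-half-even rule that
#' [base::round()] applies.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Sample from an upper-truncated normal distribution
#'
#' Draws from N(mean, sd^2) conditioned on being <= `upper`, by inversion on
#' the log scale so that far-tail bounds (heavily censored wells) remain
#' numerically stable.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters (vectors recycled to length `n`).
#' @param upper upper truncation bound(s).
#' @return numeric vector of `n` draws, each <= `upper`.
#' @keywords internal
rtnorm_upper <- function(n, mean, sd, upper) {
  lp <- stats::pnorm(upper, mean, sd, log.p = TRUE)
  u <- stats::runif(n)
  out <- stats::qnorm(log(u) + lp, mean = mean, sd = sd, log.p = TRUE)
  # if the bound is so extreme that the cdf underflows, fall back to the bound
  bad <- !is.finite(out)
  if (any(bad)) out[bad] <- rep_len(upper, n)[bad]
  out
}

# Deterministic substreams: one master seed yields a reproducible vector of
# independent stream seeds (for chains, simulation replicates, ...).
derive_stream_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

# Per-horse stream seed: deterministic in (master seed, horse id) only, so a
# horse's simulated data do not depend on which other horses are present.
horse_stream_seed <- function(seed, horse_id) {
  m <- 2147483647
  h <- seed %% m
  for (k in utf8ToInt(as.character(horse_id))) h <- (h * 131 + k) %% m
  as.integer(h %% (m - 1) + 1)
}

# log density of a multivariate normal with mean 0 (small fixed dimension)
ldmvnorm0 <- function(x, Sigma) {
  ch <- chol(Sigma)
  d <- length(x)
  z <- backsolve(ch, x, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# log density of the inverse-Wishart IW(S, nu) at X (X, S: d x d pd matrices)
ldinvwishart <- function(X, S, nu) {
  d <- nrow(X)
  chS <- chol(S)
  chX <- chol(X)
  lmvgamma <- (d * (d - 1) / 4) * log(pi) +
    sum(lgamma((nu + 1 - seq_len(d)) / 2))
  Xinv <- chol2inv(chX)
  (nu / 2) * 2 * sum(log(diag(chS))) -
    (nu * d / 2) * log(2) - lmvgamma -
    ((nu + d + 1) / 2) * 2 * sum(log(diag(chX))) -
    0.5 * sum(diag(S %*% Xinv))
}

# log density of the inverse-gamma distribution (shape a, scale b)
ldinvgamma <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}
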