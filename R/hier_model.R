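#' Derive inverse-gamma hyperparameters from a target mean and variance
#'
#' The variance components carry inverse-gamma priors stated by their first
#' two moments (mean 1, variance 10,000 by default). For an inverse-gamma
#' with shape a and scale b, mean = b/(a-1) (a > 1) and
#' variance = b^2 / ((a-1)^2 (a-2)) (a > 2), which inverts to
#' a = 2 + mean^2/variance, b = mean (a - 1).
#'
#' @param mean,variance target first two moments, both > 0.
#' @return named numeric `c(shape, scale)`.
#' @examples
#' derive_invgamma_hyperparams(1, 10000)  # shape 2.0001, scale 1.0001
#' @export
derive_invgamma_hyperparams <- function(mean, variance) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be > 0")
  if (!is.finite(variance) || variance <= 0) stop("variance must be > 0")
  shape <- 2 + mean^2 / variance
  c(shape = shape, scale = mean * (shape - 1))
}

#' Prior specification for the hierarchical model
#'
#' Uninformative priors: normal(0, 100) on each fixed-effect coefficient
#' (log-scale cell mean); inverse-gamma with mean 1 and variance 10,000 on
#' the well-level variance; a scaled inverse-Wishart on the 5x5
#' random-effect covariance, implemented by parameter expansion as
#' `Sigma_b = diag(xi) Omega diag(xi)` with `Omega ~ IW(scale, df)`
#' (identity scale, df 6 = dimension + 1) and independent normal(0,
#' `xi_sd`) priors on the expansion scales `xi` (`Sigma_b` only involves
#' `xi` through products of pairs, so the sign of `xi` is irrelevant and
#' this matches a half-normal scale prior).
#'
#' @param beta_mean,beta_sd normal prior on fixed effects (default 0, 100).
#' @param sigma2_mean,sigma2_variance target moments of the inverse-gamma
#'   prior on the well-level variance (default 1, 10000).
#' @param wishart_scale,wishart_df inverse-Wishart scale matrix and degrees
#'   of freedom for `Omega` (default identity, 6).
#' @param xi_sd prior SD of the expansion scales (default 1; combined with
#'   the identity-scale inverse-Wishart this places a weakly-informative
#'   prior with scale ~1 on each random-effect SD, appropriate for
#'   log-scale responses whose between-horse SDs are O(0.1-1)).
#' @return object of class `prior_spec`.
#' @export
default_priors <- function(beta_mean = 0, beta_sd = 100,
                           sigma2_mean = 1, sigma2_variance = 10000,
                           wishart_scale = diag(5), wishart_df = 6,
                           xi_sd = 1) {
  ig <- derive_invgamma_hyperparams(sigma2_mean, sigma2_variance)
  d <- nrow(wishart_scale)
  stopifnot(beta_sd > 0, xi_sd > 0, d == ncol(wishart_scale))
  if (wishart_df <= d - 1) {
    stop("inverse-Wishart degrees of freedom must exceed dimension - 1")
  }
  structure(list(beta_mean = beta_mean, beta_sd = beta_sd,
                 sigma2_shape = unname(ig["shape"]),
                 sigma2_scale = unname(ig["scale"]),
                 wishart_scale = wishart_scale, wishart_df = wishart_df,
                 xi_sd = xi_sd),
            class = "prior_spec")
}

#' Build design matrices for one analyte
#'
#' Fixed effects use a cell-means parameterisation: one indicator column
#' per condition present (each row of X selects exactly one condition), so
#' each coefficient is that condition's population mean log response and
#' condition contrasts are coefficient differences. Random effects use
#' Z = (1, LPS indicator, GOS %, FOS %, AOS %) per well, shared across all
#' arms (sugar-control wells have zero oligosaccharide columns), with one
#' 5-vector per horse.
#'
#' @param wells plate data.frame (or `plate_data` object).
#' @param analyte one of `"TNFa"`, `"IL10"`, `"viability"`; analytes are
#'   modelled separately.
#' @param catalogue condition catalogue; every condition in the data must
#'   appear in it.
#' @param conditions optional character vector fixing the fixed-effect
#'   condition set (default: the conditions present for the analyte).
#' @return object of class `model_design`: `y` (log values), `censored`,
#'   `bound` (log detection limit), `cond` (well -> condition index),
#'   `condition_labels`, `Z`, `horse` (well -> horse index),
#'   `horse_labels`, `analyte`.
#' @export
build_design <- function(wells, analyte,
                         catalogue = default_condition_catalogue(),
                         conditions = NULL) {
  if (inherits(wells, "plate_data")) wells <- wells$wells
  stopifnot(analyte %in% analyte_levels())
  w <- wells[wells$analyte == analyte, , drop = FALSE]
  unknown <- setdiff(unique(w$condition), catalogue$label)
  if (length(unknown)) {
    stop("condition(s) not in catalogue: ", paste(unknown, collapse = ", "))
  }
  if (is.null(conditions)) {
    conditions <- catalogue$label[catalogue$label %in% unique(w$condition)]
  } else {
    stopifnot(all(conditions %in% catalogue$label))
    if (!all(w$condition %in% conditions)) {
      stop("data contain conditions outside the requested condition set")
    }
  }
  if (length(conditions) == 0) stop("no conditions to model")
  crows <- catalogue[match(conditions, catalogue$label), , drop = FALSE]
  Zc <- t(vapply(seq_len(nrow(crows)),
                 function(j) z_vector(crows[j, ]), numeric(5)))
  rownames(Zc) <- conditions
  cond <- match(w$condition, conditions)
  horse_labels <- sort(unique(w$horse_id))
  lim <- detection_limits()[[analyte]]
  log_lim <- if (is.finite(lim) && lim > 0) log(lim) else -Inf
  structure(list(
    y = log(w$value),
    censored = as.logical(w$below_detection),
    bound = rep(log_lim, nrow(w)),
    cond = cond,
    condition_labels = conditions,
    Z = Zc[cond, , drop = FALSE],
    Z_condition = Zc,
    horse = match(w$horse_id, horse_labels),
    horse_labels = horse_labels,
    analyte = analyte
  ), class = "model_design")
}

#' @export
print.model_design <- function(x, ...) {
  cat("<model_design> analyte ", x$analyte, ": ", length(x$y), " wells (",
      sum(x$censored), " censored), ", length(x$condition_labels),
      " conditions, ", length(x$horse_labels), " horses\n", sep = "")
  invisible(x)
}

#' Joint log posterior density of the hierarchical model
#'
#' Direct evaluation of the unnormalised log joint: well-level normal
#' likelihood of the log responses given `X beta + Z b_h` and `sigma2`
#' (censored wells enter through their imputed latent log values, which
#' must sit at or below the log detection limit), MVN(0, Sigma_b) on each
#' horse's random effects with `Sigma_b = diag(xi) Omega diag(xi)`, and the
#' priors of [default_priors()]. Used as an independent check on the Gibbs
#' sampler's conditionals.
#'
#' @param state list with `beta` (per condition), `b` (horses x 5 matrix),
#'   `sigma2`, `Omega` (5x5), `xi` (length 5), and `imputed` (latent log
#'   values for the censored wells, in data order).
#' @param design a [build_design()] object.
#' @param priors a [default_priors()] object.
#' @return scalar log density.
#' @export
log_posterior <- function(state, design, priors = default_priors()) {
  stopifnot(inherits(design, "model_design"))
  y <- design$y
  ncens <- sum(design$censored)
  if (ncens > 0) {
    if (length(state$imputed) != ncens) {
      stop("state$imputed must hold one latent value per censored well")
    }
    if (any(state$imputed > design$bound[design$censored] + 1e-12)) {
      stop("imputed latent values must lie at or below the log detection limit")
    }
    y[design$censored] <- state$imputed
  }
  if (!all(is.finite(c(state$beta, state$sigma2, state$xi, state$Omega,
                       if (length(state$b)) state$b, y)))) {
    stop("non-finite values in model state or data")
  }
  if (state$sigma2 <= 0) stop("sigma2 must be > 0")
  H <- length(design$horse_labels)
  b <- state$b
  mu <- state$beta[design$cond]
  if (H > 0 && length(b)) {
    mu <- mu + rowSums(design$Z * b[design$horse, , drop = FALSE])
  }
  lp <- sum(stats::dnorm(y, mu, sqrt(state$sigma2), log = TRUE))
  Sigma_b <- diag(state$xi) %*% state$Omega %*% diag(state$xi)
  if (H > 0 && length(b)) {
    for (h in seq_len(H)) lp <- lp + ldmvnorm0(b[h, ], Sigma_b)
  }
  lp <- lp +
    sum(stats::dnorm(state$beta, priors$beta_mean, priors$beta_sd,
                     log = TRUE)) +
    ldinvgamma(state$sigma2, priors$sigma2_shape, priors$sigma2_scale) +
    ldinvwishart(state$Omega, priors$wishart_scale, priors$wishart_df) +
    sum(stats::dnorm(state$xi, 0, priors$xi_sd, log = TRUE))
  lp
}
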