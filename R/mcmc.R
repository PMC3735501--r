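#' MCMC configuration
#'
#' The full published-scale protocol is four chains of 1,000,000 iterations
#' each, saving every 50th sample and discarding the first half as burn-in.
#' `scaled_down = TRUE` selects a desk-scale profile (4 x 20,000, thin 10)
#' with the same structure, suitable for tests and simulation studies.
#'
#' @param n_chains number of chains (>= 1; >= 2 for convergence checks).
#' @param n_iterations iterations per chain.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param burn_in_fraction fraction of iterations discarded, in (0, 1).
#' @param seed master seed; per-chain substreams are derived from it.
#' @param scaled_down if `TRUE`, use the reduced defaults (4 x 20,000,
#'   thin 10) instead of the full protocol.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4,
                        n_iterations = if (scaled_down) 20000 else 1000000,
                        thin = if (scaled_down) 10 else 50,
                        burn_in_fraction = 0.5, seed = 1,
                        scaled_down = FALSE) {
  stopifnot(n_chains >= 1, n_iterations >= 1, thin >= 1,
            burn_in_fraction > 0, burn_in_fraction < 1)
  n_burn <- floor(n_iterations * burn_in_fraction)
  n_saved <- floor((n_iterations - n_burn) / thin)
  if (n_saved < 1) {
    stop("configuration leaves no saved draws after burn-in and thinning")
  }
  structure(list(n_chains = n_chains, n_iterations = n_iterations,
                 thin = thin, burn_in_fraction = burn_in_fraction,
                 seed = seed, scaled_down = scaled_down,
                 n_burn = n_burn, n_saved = n_saved),
            class = "mcmc_config")
}

#' Fit the hierarchical model by conjugate Gibbs sampling
#'
#' The model is conditionally conjugate throughout, so every update is an
#' exact draw from a full conditional: fixed effects beta (normal),
#' per-horse random effects (multivariate normal, via the expansion
#' `b_h = diag(xi) eta_h`), the well-level variance sigma2 (inverse-gamma),
#' the expanded covariance factors Omega (inverse-Wishart) and xi (scalar
#' normals), and one upper-truncated normal latent log value per
#' below-detection well. Chains start from overdispersed initial values
#' (data cell means plus chain-specific jitter) and differ only by their
#' derived substream seeds.
#'
#' @param design a [build_design()] object.
#' @param priors a [default_priors()] object.
#' @param config an [mcmc_config()].
#' @param random_effects set `FALSE` for a fixed-effects-only model (no
#'   horse terms), e.g. for analytic cross-checks.
#' @param sigma2_fixed if non-`NULL`, hold the well-level variance fixed at
#'   this value instead of sampling it.
#' @param augment_censored if `FALSE`, treat censored wells' recorded
#'   values (the detection limit) as exact instead of imputing latents.
#' @return object of class `posterior_draws`: `samples` (array chains x
#'   saved draws x parameters, parameters named `beta[<condition>]`,
#'   `sigma2`, `Sigma_b[j,k]`), `config`, `design` metadata.
#' @export
run_chains <- function(design, priors = default_priors(),
                       config = mcmc_config(scaled_down = TRUE),
                       random_effects = TRUE, sigma2_fixed = NULL,
                       augment_censored = TRUE) {
  stopifnot(inherits(design, "model_design"), inherits(priors, "prior_spec"),
            inherits(config, "mcmc_config"))
  if (!is.null(sigma2_fixed) && sigma2_fixed <= 0) {
    stop("sigma2_fixed must be > 0")
  }
  params <- c(paste0("beta[", design$condition_labels, "]"),
              if (is.null(sigma2_fixed)) "sigma2",
              if (random_effects)
                paste0("Sigma_b[", 1:5, ",", 1:5, "]"))
  chain_seeds <- derive_stream_seeds(config$seed, config$n_chains)
  samples <- array(NA_real_,
                   dim = c(config$n_chains, config$n_saved, length(params)),
                   dimnames = list(NULL, NULL, params))
  for (ch in seq_len(config$n_chains)) {
    samples[ch, , ] <- gibbs_chain(design, priors, config,
                                   seed = chain_seeds[ch],
                                   random_effects = random_effects,
                                   sigma2_fixed = sigma2_fixed,
                                   augment_censored = augment_censored,
                                   params = params)
  }
  structure(list(samples = samples, parameters = params, config = config,
                 analyte = design$analyte,
                 condition_labels = design$condition_labels,
                 n_wells = length(design$y),
                 n_censored = sum(design$censored),
                 random_effects = random_effects),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("<posterior_draws> analyte ", x$analyte, ": ", dim(x$samples)[1],
      " chains x ", dim(x$samples)[2], " saved draws, ",
      length(x$parameters), " monitored parameters\n", sep = "")
  invisible(x)
}

gibbs_chain <- function(design, priors, config, seed, random_effects,
                        sigma2_fixed, augment_censored, params) {
  set.seed(seed)
  y <- design$y
  n <- length(y)
  cond <- design$cond
  p <- length(design$condition_labels)
  cens <- design$censored & augment_censored
  bound <- design$bound
  Z <- design$Z
  horse <- design$horse
  H <- length(design$horse_labels)
  tau2 <- priors$beta_sd^2
  bmean <- priors$beta_mean
  xs2 <- priors$xi_sd^2

  # condition indicator matrix (cell-means X); n is small, dense is fine
  Xind <- matrix(0, n, p)
  if (n > 0) Xind[cbind(seq_len(n), cond)] <- 1
  n_j <- colSums(Xind)
  hrows <- split(seq_len(n), factor(horse, levels = seq_len(H)))

  # overdispersed initialisation around data cell means
  cellmean <- ifelse(n_j > 0, drop(crossprod(Xind, y)) / pmax(n_j, 1), bmean)
  beta <- cellmean + stats::rnorm(p, 0, 2)
  s0 <- if (n > 1) stats::var(y - cellmean[cond]) else NA_real_
  if (!is.finite(s0) || s0 < 0.01) s0 <- 0.01
  sigma2 <- if (!is.null(sigma2_fixed)) sigma2_fixed else {
    s0 * exp(stats::rnorm(1, 0, 1))
  }
  if (random_effects) {
    eta <- matrix(stats::rnorm(H * 5, 0, 0.5), H, 5)
    xi <- stats::rnorm(5, 1, 0.5)
    Omega <- diag(5)
  }
  if (any(cens)) y[cens] <- bound[cens] - 0.1

  out <- matrix(NA_real_, config$n_saved, length(params))
  isave <- 0L
  chol_or_stop <- function(M, what, it) {
    tryCatch(chol(M), error = function(e) {
      stop("non-positive-definite conditional covariance for ", what,
           " at iteration ", it, call. = FALSE)
    })
  }

  for (it in seq_len(config$n_iterations)) {
    if (random_effects && H > 0) {
      Mraw <- Z * eta[horse, , drop = FALSE]  # z_ik * eta_{h(i),k}
      re <- drop(Mraw %*% xi)
    } else {
      re <- numeric(n)
    }
    mu_well <- beta[cond] + re

    # latent log values for censored wells (upper-truncated at log limit)
    if (any(cens)) {
      y[cens] <- rtnorm_upper(sum(cens), mu_well[cens], sqrt(sigma2),
                              bound[cens])
    }

    # beta | rest: independent normals under the cell-means X
    r <- y - re
    prec <- n_j / sigma2 + 1 / tau2
    m <- (drop(crossprod(Xind, r)) / sigma2 + bmean / tau2) / prec
    beta <- stats::rnorm(p, m, sqrt(1 / prec))

    if (random_effects && H > 0) {
      # eta_h | rest: MVN with design W = Z diag(xi) on this horse's wells
      Oinv <- chol2inv(chol_or_stop(Omega, "Omega", it))
      W <- Z * rep(xi, each = n)
      r2 <- y - beta[cond]
      for (h in seq_len(H)) {
        idx <- hrows[[h]]
        if (length(idx)) {
          Wh <- W[idx, , drop = FALSE]
          A <- crossprod(Wh) / sigma2 + Oinv
          rhs <- crossprod(Wh, r2[idx]) / sigma2
        } else {
          A <- Oinv
          rhs <- numeric(5)
        }
        chA <- chol_or_stop(A, "random effects", it)
        mh <- backsolve(chA, forwardsolve(t(chA), rhs))
        eta[h, ] <- mh + backsolve(chA, stats::rnorm(5))
      }
      # Omega | eta: inverse-Wishart
      Spost <- priors$wishart_scale + crossprod(eta)
      Oinv_draw <- stats::rWishart(1, priors$wishart_df + H,
                                   chol2inv(chol_or_stop(Spost, "Omega scale",
                                                         it)))[, , 1]
      Omega <- chol2inv(chol_or_stop(Oinv_draw, "Omega draw", it))
      # xi_k | rest: scalar normal, regressor c_i = z_ik eta_{h(i),k}
      Mraw <- Z * eta[horse, , drop = FALSE]
      fit_re <- drop(Mraw %*% xi)
      for (k in 1:5) {
        ck <- Mraw[, k]
        r3 <- r2 - fit_re + xi[k] * ck
        pk <- sum(ck^2) / sigma2 + 1 / xs2
        mk <- sum(ck * r3) / sigma2 / pk
        xinew <- stats::rnorm(1, mk, sqrt(1 / pk))
        fit_re <- fit_re + (xinew - xi[k]) * ck
        xi[k] <- xinew
      }
      re <- fit_re
    }

    # sigma2 | rest: inverse-gamma
    if (is.null(sigma2_fixed)) {
      resid <- y - beta[cond] - re
      sigma2 <- 1 / stats::rgamma(1, priors$sigma2_shape + n / 2,
                                  priors$sigma2_scale + sum(resid^2) / 2)
    }

    if (it > config$n_burn && (it - config$n_burn) %% config$thin == 0) {
      isave <- isave + 1L
      if (isave <= nrow(out)) {
        row <- beta
        if (is.null(sigma2_fixed)) row <- c(row, sigma2)
        if (random_effects) {
          Sigma_b <- diag(xi) %*% Omega %*% diag(xi)
          row <- c(row, diag(Sigma_b))
        }
        out[isave, ] <- row
      }
    }
  }
  if (anyNA(out[, 1])) stop("internal error: unsaved draws remain")
  if (any(!is.finite(out))) stop("non-finite values in saved draws")
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classical (non-split) diagnostic on the saved draws of one parameter:
#' with m chains of length n, within-chain variance W = mean of the chain
#' sample variances and between-chain component B = n x variance of the
#' chain means, the statistic is
#' `sqrt(((n - 1)/n * W + B/n) / W)`.
#'
#' @param x matrix of draws, chains in rows (m x n, m >= 2, n >= 2).
#' @return scalar potential scale reduction factor.
#' @examples
#' psrf(rbind(rnorm(1000), rnorm(1000)))
#' @export
psrf <- function(x) {
  x <- as.matrix(x)
  m <- nrow(x)
  n <- ncol(x)
  if (m < 2) stop("at least 2 chains are required")
  if (n < 2) stop("at least 2 draws per chain are required")
  W <- mean(apply(x, 1, stats::var))
  if (!is.finite(W) || W == 0) {
    stop("degenerate chains: within-chain variance is zero")
  }
  B <- n * stats::var(rowMeans(x))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence report over all monitored parameters
#'
#' @param draws a [run_chains()] result (or an array chains x draws x
#'   parameters with parameter dimnames).
#' @param threshold pass threshold for the potential scale reduction factor
#'   (default 1.1).
#' @return data.frame of class `convergence_report` with one row per
#'   monitored parameter (`parameter`, `psrf`, `pass`); attribute
#'   `overall_pass` is `TRUE` iff every parameter passes.
#' @export
check_convergence <- function(draws, threshold = 1.1) {
  samples <- if (inherits(draws, "posterior_draws")) draws$samples else draws
  if (dim(samples)[1] < 2) {
    stop("convergence diagnostics require at least 2 chains")
  }
  params <- dimnames(samples)[[3]]
  r <- vapply(seq_along(params),
              function(k) psrf(samples[, , k]), numeric(1))
  rep_df <- data.frame(parameter = params, psrf = r, pass = r <= threshold,
                       stringsAsFactors = FALSE)
  attr(rep_df, "threshold") <- threshold
  attr(rep_df, "overall_pass") <- all(rep_df$pass)
  class(rep_df) <- c("convergence_report", "data.frame")
  rep_df
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report> threshold ", attr(x, "threshold"), ": ",
      if (attr(x, "overall_pass")) "all parameters converged"
      else paste0(sum(!x$pass), " parameter(s) above threshold: ",
                  paste(utils::head(x$parameter[!x$pass], 5),
                        collapse = ", ")),
      "\n", sep = "")
  cat("  max PSRF ", format(max(x$psrf), digits = 4), " (",
      x$parameter[which.max(x$psrf)], ")\n", sep = "")
  invisible(x)
}
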