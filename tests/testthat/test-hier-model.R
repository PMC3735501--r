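test_that("inverse-gamma hyperparameters reproduce the requested moments", {
  expect_equal(derive_invgamma_hyperparams(1, 10000),
               c(shape = 2.0001, scale = 1.0001))
  expect_equal(derive_invgamma_hyperparams(2, 4), c(shape = 3, scale = 4))
  expect_equal(derive_invgamma_hyperparams(1, 1), c(shape = 3, scale = 2))
  expect_error(derive_invgamma_hyperparams(0, 1), "> 0")
  expect_error(derive_invgamma_hyperparams(1, -1), "> 0")

  # oracle: numerically integrate the inverse-gamma density written from
  # first principles and check the first two moments round-trip
  ig_density <- function(x, a, b) {
    exp(a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x)
  }
  for (mv in list(c(2, 4), c(1, 1), c(0.5, 3))) {
    hp <- derive_invgamma_hyperparams(mv[1], mv[2])
    m1 <- stats::integrate(function(x) x * ig_density(x, hp["shape"], hp["scale"]),
                           0, Inf, rel.tol = 1e-10)$value
    m2 <- stats::integrate(function(x) x^2 * ig_density(x, hp["shape"], hp["scale"]),
                           0, Inf, rel.tol = 1e-10)$value
    expect_equal(m1, mv[1], tolerance = 1e-6)
    expect_equal(m2 - m1^2, mv[2], tolerance = 1e-6)
  }
})

test_that("design matrices encode conditions and random-effect doses", {
  wells <- toy_wells()
  d <- build_design(wells, "TNFa")
  expect_equal(sort(d$condition_labels), sort(c("blank", "LPS", "GOS 2%")))
  # each well selects exactly one condition
  expect_true(all(d$cond >= 1 & d$cond <= 3))
  expect_equal(length(d$cond), 6)

  expect_equal(unname(d$Z_condition["blank", ]), c(1, 0, 0, 0, 0))
  expect_equal(unname(d$Z_condition["LPS", ]), c(1, 1, 0, 0, 0))
  expect_equal(unname(d$Z_condition["GOS 2%", ]), c(1, 0, 2, 0, 0))

  big <- wells
  big$condition[1] <- "LPS + GOS/FOS/AOS 2%"
  dz <- build_design(big, "TNFa")
  expect_equal(unname(dz$Z_condition["LPS + GOS/FOS/AOS 2%", ]),
               c(1, 1, 1.5, 1 / 6, 1 / 3), tolerance = 1e-9)

  sugar <- wells
  sugar$condition[1] <- "LPS + glucose/lactose 2%"
  ds <- build_design(sugar, "TNFa")
  # no oligosaccharide in the random-effect design of sugar controls
  expect_equal(unname(ds$Z_condition["LPS + glucose/lactose 2%", ]),
               c(1, 1, 0, 0, 0))

  bad <- wells
  bad$condition[2] <- "not a condition"
  expect_error(build_design(bad, "TNFa"), "not a condition")
})

test_that("log posterior matches an independently coded density on a toy dataset", {
  wells <- toy_wells()[1:3, ]  # one horse, three wells
  d <- build_design(wells, "TNFa")
  priors <- default_priors()
  state <- list(beta = c(2.5, 7.4, 3.6), b = matrix(c(0.1, -0.2, 0.05, 0, 0.3), 1),
                sigma2 = 0.09, Omega = diag(5) + 0.1, xi = c(1, 0.8, 1.2, 1, 0.9),
                imputed = numeric(0))
  lp <- log_posterior(state, d, priors)

  # direct evaluation, written out from the model definition
  y <- log(wells$value)
  Z <- rbind(c(1, 0, 0, 0, 0), c(1, 1, 0, 0, 0), c(1, 0, 2, 0, 0))
  mu <- state$beta[match(wells$condition, d$condition_labels)] +
    as.vector(Z %*% state$b[1, ])
  Sigma_b <- diag(state$xi) %*% state$Omega %*% diag(state$xi)
  ll <- sum(-0.5 * log(2 * pi * state$sigma2) -
              (y - mu)^2 / (2 * state$sigma2))
  lb <- mvtnorm_logdens <- {
    k <- 5
    -0.5 * (k * log(2 * pi) + determinant(Sigma_b)$modulus[1] +
              drop(state$b %*% solve(Sigma_b) %*% t(state$b)))
  }
  lprior_beta <- sum(-0.5 * log(2 * pi * 100^2) - state$beta^2 / (2 * 100^2))
  a <- priors$sigma2_shape; bb <- priors$sigma2_scale
  lprior_s2 <- a * log(bb) - lgamma(a) - (a + 1) * log(state$sigma2) -
    bb / state$sigma2
  nu <- priors$wishart_df; S <- priors$wishart_scale; W <- state$Omega
  lmvg <- (5 * 4 / 4) * log(pi) + sum(lgamma((nu + 1 - 1:5) / 2))
  lprior_om <- (nu / 2) * determinant(S)$modulus[1] -
    (nu * 5 / 2) * log(2) - lmvg -
    ((nu + 5 + 1) / 2) * determinant(W)$modulus[1] -
    0.5 * sum(diag(S %*% solve(W)))
  lprior_xi <- sum(-0.5 * log(2 * pi * priors$xi_sd^2) -
                     state$xi^2 / (2 * priors$xi_sd^2))
  expect_equal(lp, ll + lb + lprior_beta + lprior_s2 + lprior_om + lprior_xi,
               tolerance = 1e-10)
})

test_that("log posterior is additive in wells and invariant to well order", {
  wells <- toy_wells()
  d <- build_design(wells, "TNFa")
  H <- length(d$horse_labels)
  state <- list(beta = c(3, 7.3, 3.5), b = matrix(0.05, H, 5), sigma2 = 0.2,
                Omega = diag(5), xi = rep(1, 5), imputed = numeric(0))
  lp <- log_posterior(state, d)

  # permuting rows leaves the density unchanged
  perm <- c(4, 2, 6, 1, 3, 5)
  dperm <- build_design(wells[perm, ], "TNFa")
  expect_equal(log_posterior(state, dperm), lp, tolerance = 1e-12)

  # duplicating one well adds exactly that well's log density
  dup <- rbind(wells, wells[1, ])
  ddup <- build_design(dup, "TNFa")
  h <- match(wells$horse_id[1], d$horse_labels)
  j <- match(wells$condition[1], d$condition_labels)
  z <- d$Z_condition[wells$condition[1], ]
  mu1 <- state$beta[j] + sum(z * state$b[h, ])
  extra <- dnorm(log(wells$value[1]), mu1, sqrt(state$sigma2), log = TRUE)
  expect_equal(log_posterior(state, ddup), lp + extra, tolerance = 1e-10)
})

test_that("censored wells enter through bounded latent values", {
  wells <- toy_wells()[1:3, ]
  wells$value[1] <- 15.625
  wells$below_detection[1] <- TRUE
  d <- build_design(wells, "TNFa")
  state <- list(beta = c(3, 7.3, 3.5), b = matrix(0, 1, 5), sigma2 = 0.2,
                Omega = diag(5), xi = rep(1, 5), imputed = log(12))
  expect_silent(log_posterior(state, d))
  state$imputed <- log(20)  # above the detection limit
  expect_error(log_posterior(state, d), "detection limit")
  state$imputed <- numeric(0)
  expect_error(log_posterior(state, d), "one latent value")
})
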