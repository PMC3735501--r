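test_that("potential scale reduction factor matches hand computation", {
  x <- rbind(c(1, 2, 3), c(1, 2, 3))
  # W = 1, B = 0: R = sqrt(((n-1)/n * 1 + 0) / 1) = sqrt(2/3)
  expect_equal(psrf(x), sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(psrf(x), 4), 0.8165)

  set.seed(1)
  same <- rbind(rnorm(10000), rnorm(10000))
  expect_lt(abs(psrf(same) - 1), 0.02)

  apart <- rbind(rnorm(500, 0), rnorm(500, 100))
  expect_gt(psrf(apart), 10)

  expect_error(psrf(matrix(rnorm(10), 1)), "2 chains")
  expect_error(psrf(matrix(c(1, 1), 2, 1)), "2 draws")
  expect_error(psrf(matrix(2, 2, 10)), "degenerate")
})

test_that("convergence report covers every monitored parameter", {
  des <- study_design(n_oligo = 2, n_sugar = 0, n_viability = 0)
  wells <- simulate_dataset(des, seed = 2)
  d <- build_design(wells, "TNFa")
  fit <- run_chains(d, config = mcmc_config(n_chains = 2, n_iterations = 600,
                                            thin = 2, seed = 8))
  rep <- check_convergence(fit)
  expect_equal(rep$parameter, fit$parameters)
  expect_true(all(is.finite(rep$psrf)))

  # a stuck chain trips the diagnostic and names the offending parameter
  broken <- fit$samples
  broken[1, , "sigma2"] <- broken[1, , "sigma2"] + 50
  bad <- check_convergence(broken)
  expect_false(attr(bad, "overall_pass"))
  expect_true("sigma2" %in% bad$parameter[!bad$pass])

  expect_error(check_convergence(fit$samples[1, , , drop = FALSE]),
               "2 chains")
})

test_that("sampler configuration is validated", {
  expect_error(mcmc_config(n_iterations = 100, thin = 100), "no saved draws")
  cfg <- mcmc_config(scaled_down = TRUE)
  expect_equal(cfg$n_iterations, 20000)
  expect_equal(cfg$thin, 10)
  expect_equal(cfg$n_saved, 1000)
  full <- mcmc_config()
  expect_equal(full$n_iterations, 1e6)
  expect_equal(full$thin, 50)
  expect_equal(full$n_chains, 4)
  expect_equal(full$burn_in_fraction, 0.5)
})

test_that("identical seed and configuration give identical draws", {
  wells <- toy_wells()
  d <- build_design(wells, "TNFa")
  cfg <- mcmc_config(n_chains = 2, n_iterations = 400, thin = 2, seed = 4)
  f1 <- run_chains(d, config = cfg)
  f2 <- run_chains(d, config = cfg)
  expect_identical(f1$samples, f2$samples)
  f3 <- run_chains(d, config = mcmc_config(n_chains = 2, n_iterations = 400,
                                           thin = 2, seed = 5))
  expect_false(identical(f1$samples, f3$samples))
})

test_that("fixed-effects posterior matches the conjugate closed form", {
  # known sigma2, no random effects: beta_j | y ~ N(m_j, v_j) exactly, with
  # 1/v_j = n_j/sigma2 + 1/100^2 and m_j = v_j * sum(y_j)/sigma2
  set.seed(31)
  wells <- data.frame(
    horse_id = "H1",
    condition = rep(c("blank", "LPS"), each = 8),
    analyte = "TNFa", replicate = 1,
    value = exp(rnorm(16, rep(c(3, 7.5), each = 8), 0.4)),
    below_detection = FALSE)
  d <- build_design(wells, "TNFa")
  sigma2 <- 0.16
  fit <- run_chains(d, config = mcmc_config(n_chains = 2, n_iterations = 8000,
                                            thin = 2, seed = 12),
                    random_effects = FALSE, sigma2_fixed = sigma2)
  y <- log(wells$value)
  for (j in 1:2) {
    yj <- y[d$cond == j]
    v <- 1 / (length(yj) / sigma2 + 1 / 100^2)
    m <- v * sum(yj) / sigma2
    dr <- as.vector(fit$samples[, , j])
    N <- length(dr)
    expect_lt(abs(mean(dr) - m), 3 * sqrt(v / N))
    expect_lt(abs(sd(dr) - sqrt(v)), 3 * sqrt(v / (2 * N)))
  }
})

test_that("with no data the fixed effects are sampled from their prior", {
  d <- build_design(empty_wells(), "TNFa", conditions = c("blank", "LPS"))
  expect_equal(length(d$y), 0)
  fit <- run_chains(d, config = mcmc_config(n_chains = 2, n_iterations = 4000,
                                            thin = 2, seed = 77),
                    random_effects = FALSE)
  dr <- as.vector(fit$samples[, , "beta[blank]"])
  N <- length(dr)
  expect_lt(abs(mean(dr) - 0), 3 * 100 / sqrt(N))
  expect_lt(abs(sd(dr) - 100), 3 * 100 / sqrt(2 * N))
})

test_that("censoring augmentation is inert when nothing is censored", {
  wells <- toy_wells()
  d <- build_design(wells, "TNFa")
  cfg <- mcmc_config(n_chains = 2, n_iterations = 400, thin = 2, seed = 19)
  with_aug <- run_chains(d, config = cfg, augment_censored = TRUE)
  without <- run_chains(d, config = cfg, augment_censored = FALSE)
  expect_identical(with_aug$samples, without$samples)
})

test_that("censored observations pull the posterior below the detection limit", {
  # all wells of one condition censored at the TNFa limit: the posterior
  # mean response must fall below the limit, not at it
  set.seed(55)
  wells <- data.frame(
    horse_id = rep(c("H1", "H2", "H3"), each = 8),
    condition = rep(rep(c("blank", "GOS 2%"), each = 4), 3),
    analyte = "TNFa", replicate = rep(1:4, 6),
    value = 15.625, below_detection = TRUE)
  obs <- wells$condition == "GOS 2%"
  wells$value[obs] <- exp(rnorm(sum(obs), log(40), 0.3))
  wells$below_detection[obs] <- FALSE
  d <- build_design(wells, "TNFa")
  fit <- run_chains(d, config = mcmc_config(n_chains = 2,
                                            n_iterations = 4000, thin = 2,
                                            seed = 23))
  s <- summarize_condition(fit, "blank")
  expect_lt(s$point_estimate, 15.625)
})
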