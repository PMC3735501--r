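# Shared fixtures, all built in code.

# a posterior_draws object with prescribed per-condition draw matrices
# (chains x n), for testing inference without running the sampler
fake_draws <- function(beta_draws, analyte = "TNFa") {
  labels <- names(beta_draws)
  n_chains <- nrow(beta_draws[[1]])
  n_saved <- ncol(beta_draws[[1]])
  params <- paste0("beta[", labels, "]")
  samples <- array(NA_real_, dim = c(n_chains, n_saved, length(params)),
                   dimnames = list(NULL, NULL, params))
  for (i in seq_along(labels)) samples[, , i] <- beta_draws[[i]]
  structure(list(samples = samples, parameters = params,
                 config = mcmc_config(n_chains = n_chains,
                                      n_iterations = 2 * n_saved, thin = 1,
                                      seed = 0),
                 analyte = analyte, condition_labels = labels,
                 n_wells = 0L, n_censored = 0L, random_effects = FALSE),
            class = "posterior_draws")
}

# an empty well table in the plate schema
empty_wells <- function() {
  data.frame(horse_id = character(), condition = character(),
             analyte = character(), replicate = integer(),
             value = numeric(), below_detection = logical(),
             stringsAsFactors = FALSE)
}

# a tiny valid well table
toy_wells <- function() {
  data.frame(
    horse_id = rep(c("H1", "H2"), each = 3),
    condition = rep(c("blank", "LPS", "GOS 2%"), 2),
    analyte = "TNFa",
    replicate = 1L,
    value = c(20, 1800, 40, 25, 1600, 35),
    below_detection = FALSE,
    stringsAsFactors = FALSE
  )
}

# published per-condition point estimates (pg/ml) used as fixed inputs to
# the contrast arithmetic
published_estimates <- function() {
  c("blank" = 12.6, "LPS" = 1749.4,
    "GOS 0.5%" = 19.7, "GOS 1%" = 24.9, "GOS 2%" = 35.5,
    "GOS/FOS 0.5%" = 30.2, "GOS/FOS 1%" = 63.4, "GOS/FOS 2%" = 127.5,
    "GOS/FOS/AOS 0.5%" = 73.6, "GOS/FOS/AOS 1%" = 133.5,
    "GOS/FOS/AOS 2%" = 61.4,
    "LPS + GOS 0.5%" = 3655.5, "LPS + GOS 1%" = 4989.0,
    "LPS + GOS 2%" = 7754.3,
    "LPS + GOS/FOS 0.5%" = 3601.1, "LPS + GOS/FOS 1%" = 5530.3,
    "LPS + GOS/FOS 2%" = 6721.1,
    "LPS + GOS/FOS/AOS 0.5%" = 4242.9, "LPS + GOS/FOS/AOS 1%" = 3317.6,
    "LPS + GOS/FOS/AOS 2%" = 1029.7,
    "IL10 blank" = 187.2, "IL10 LPS" = 278.1,
    "IL10 LPS + GOS/FOS/AOS 0.5%" = 374.3,
    "IL10 LPS + GOS/FOS/AOS 1%" = 269.6,
    "IL10 LPS + GOS/FOS/AOS 2%" = 180.7)
}
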