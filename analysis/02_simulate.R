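#!/usr/bin/env Rscript
# Generate the synthetic study: plate-level cytokine wells for the
# oligosaccharide arm (5 horses) and the glucose/lactose control arm (4
# horses), plus viability wells (3 horses), in triplicate, with per-horse
# random effects and left-censoring at the ELISA detection limits. The
# generating parameters are written alongside as JSON for recovery checks.
#
# Usage: Rscript analysis/02_simulate.R [seed]

suppressPackageStartupMessages(library(oligopbmc))
dir.create("results", showWarnings = FALSE)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 101

design <- study_design()
params <- default_generative_params(seed = seed)

cyto <- simulate_dataset(design, params)
via <- simulate_viability(design, params)
write_plate_csv(cyto, "results/simulated_cytokines.csv")
write_plate_csv(via, "results/simulated_viability.csv")

jsonlite::write_json(
  list(seed = seed, sigma = params$sigma, Sigma_b = params$Sigma_b,
       replicates = params$replicates, beta = params$beta),
  "results/simulated_truth.json", digits = NA)

for (a in c("TNFa", "IL10")) {
  n <- sum(cyto$analyte == a)
  nc <- sum(cyto$analyte == a & cyto$below_detection)
  message(sprintf("%s: %d wells, %d below detection (%.0f%%)", a, n, nc,
                  100 * nc / n))
}
message(sprintf("viability: %d wells", nrow(via)))
message("wrote results/simulated_{cytokines,viability}.csv and truth sidecar")
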