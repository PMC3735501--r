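#!/usr/bin/env Rscript
# Turn the posterior draws into the reporting objects: per-condition point
# estimates with 95% credible intervals (annotated for significance against
# the challenge reference and the next-lower dose), the full contrast
# tables, and relative-viability summaries.

suppressPackageStartupMessages(library(oligopbmc))
fits <- readRDS("results/fits.rds")

for (a in c("TNFa", "IL10")) {
  rep <- build_report(fits[[a]]$fit, fits[[a]]$convergence)
  print(rep)
  write_summary_csv(rep$summaries, rep$contrasts,
                    sprintf("results/summary_%s.csv", a))
}

vfit <- fits$viability$fit
via <- do.call(rbind, lapply(
  setdiff(vfit$condition_labels, "blank"),
  function(cc) viability_relative(vfit, cc)))
write.csv(via, "results/viability_relative.csv", row.names = FALSE)
message("relative viability (vs blank), significant increases:")
print(via[via$significant_increase, ], digits = 3)
message("wrote results/summary_{TNFa,IL10}.csv and results/viability_relative.csv")
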