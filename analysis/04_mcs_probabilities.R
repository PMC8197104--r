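#!/usr/bin/env Rscript
# Stage 4: Monte Carlo comfort-range probabilities.
#
# Fits a normal PET distribution per accident type and severity from the
# linked synthetic events and estimates P(cold), P(hot) and P(outside
# comfort) with 10^6 draws each. The published distribution parameters are
# run through the same estimator for comparison with the published
# percentages.

library(comfortrisk)
suppressMessages(library(dplyr))

linked <- readr::read_csv("scratch/registry/linked.csv",
                          show_col_types = FALSE)

dists <- fit_pet_distributions(linked)
mcs_synth <- mcs_probabilities(dists, n_draws = 1e6, seed = 42L)
readr::write_csv(mcs_synth, "results/tables/mcs_synthetic.csv")
message("synthetic registry: outside-comfort probabilities span ",
        sprintf("%.1f%%..%.1f%%", 100 * min(mcs_synth$p_outside),
                100 * max(mcs_synth$p_outside)))

pub <- pet_distribution_params("fatal")
mcs_pub <- mcs_probabilities(pub, n_draws = 1e6, seed = 42L)
mcs_pub$published_outside_pct <- pub$published_outside_pct
mcs_pub$delta_outside <- 100 * mcs_pub$p_outside - pub$published_outside_pct
readr::write_csv(mcs_pub, "results/tables/mcs_published_fatal.csv")
message("published fatal parameters: max |delta| vs published outside-range ",
        sprintf("%.2f percentage points", max(abs(mcs_pub$delta_outside))))
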