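#!/usr/bin/env Rscript
# Stage 3 — drive the layer-4 integrate-and-fire neuron with
# controlled-synchrony population inputs over the 6-40 ms minimum-jitter
# sweep and a 5-degree direction grid; write the per-trial spike counts.

suppressPackageStartupMessages(library(thalsync))
config <- desk_config(seed = 1)
world <- build_world(config)

counts <- run_tuning_sweep(world, config)
write.table(counts, "results/cortical_counts.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

low <- min(counts$sigma_min_s)
tun <- fit_tuning(counts[counts$sigma_min_s == low, ])
cat(sprintf("Sweep: %d jitter levels x %d directions x %d trials\n",
            length(unique(counts$sigma_min_s)),
            length(unique(counts$direction_deg)),
            config$analysis$n_trials))
cat(sprintf(
  "At %.0f ms minimum jitter: peak %.1f counts/trial at %d deg, HWHH %.1f deg\n",
  1000 * low, max(tun$stats$lambda), tun$theta_peak, tun$hwhh_deg))
for (sg in sort(unique(counts$sigma_min_s))) {
  tn <- fit_tuning(counts[counts$sigma_min_s == sg, ])
  cat(sprintf("  sigma_min %4.0f ms: peak %5.1f  HWHH %5.1f deg\n",
              1000 * sg, max(tn$stats$lambda), tn$hwhh_deg))
}
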