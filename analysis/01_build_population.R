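#!/usr/bin/env Rscript
# Stage 1 — synthesize the LGN world: template receptive fields, their
# multi-trial drifting-grating responses, and the filled 30-neuron
# convergent population. Writes the tables every later stage reads.

suppressPackageStartupMessages(library(thalsync))
config <- desk_config(seed = 1)
dir.create("results", showWarnings = FALSE)

world <- build_world(config)
write_rf_table(world$templates, "results/templates.tsv")
write_rf_table(world$layout$members, "results/population.tsv")
write_spike_table(world$trains, "results/template_spikes.tsv")
write_layout_provenance(world$layout, "results/provenance.tsv")
write_run_config(config, "results/config.yaml")

seps <- pairwise_separations(world$layout$members)
cat(sprintf(
  "Templates: %d cells, %.1f x %.1f deg centre cluster, RF diameter %.1f deg\n",
  nrow(world$templates), diff(world$layout$region$az),
  diff(world$layout$region$el), world$templates$diameter[1]))
cat(sprintf(
  "Filled population: %d members; pairwise separations %.2f-%.2f RFCD (median %.2f)\n",
  nrow(world$layout$members), min(seps), max(seps), median(seps)))
cat(sprintf("Mean template rate: %.1f Hz over %d trials x %d directions\n",
            nrow(world$trains) / (config$generator$n_trials *
              length(unique(world$trains$direction_deg)) *
              nrow(world$templates)),
            config$generator$n_trials,
            length(unique(world$trains$direction_deg))))
cat(sprintf("Synchrony-preferred drift direction: %d deg\n",
            world$layout$theta_pref))
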