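#!/usr/bin/env Rscript
# Simulate the study cohort: a pseudo-HES event log with four planted
# regional provider communities, written to results/synthetic/.
suppressMessages(library(carefrag))

cfg <- simulation_config(seed = 20130401L)
sim <- generate_event_log(cfg)

dir.create("results/synthetic", recursive = TRUE, showWarnings = FALSE)
write_simulation(sim, "results/synthetic/event_log.csv",
                 "results/synthetic/ground_truth.json")

k <- table(table(sim$events$patient_id) > 1)
cat(sprintf("simulated %d events for %d patients at %d providers\n",
            nrow(sim$events), cfg$n_patients, cfg$n_providers))
cat(sprintf("%.1f%% of patients present more than once (target ~81.3%%)\n",
            100 * k["TRUE"] / cfg$n_patients))
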