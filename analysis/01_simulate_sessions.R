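#!/usr/bin/env Rscript
# Simulate the study's nine sessions -- three animals per condition
# (morphine-like, cocaine-like, saline) -- on the 40 x 90 px sensor at one
# frame per 5 s, 15 min pre- to 225 min post-injection, and write each as a
# multi-page TIFF with a JSON sidecar (including the ground truth) under
# results/sessions/.

suppressPackageStartupMessages(library(cmosdff))

out_root <- file.path("results", "sessions")
sessions <- expand.grid(seed = 1:3,
                        drug = c("morphine_like", "cocaine_like", "saline"),
                        stringsAsFactors = FALSE)

for (i in seq_len(nrow(sessions))) {
  drug <- sessions$drug[i]; seed <- sessions$seed[i]
  id <- sprintf("%s_%d", sub("_like", "", drug), seed)
  sim <- simulate_session(simulation_params(
    kinetics = kinetic_profile(drug), seed = seed,
    pre_min = 15, post_min = 225, sim_fps = 0.2))
  write_session(sim$recording, file.path(out_root, id),
                metadata = session_metadata(
                  fps = 0.2, baseline_window = c(-15, 0),
                  drug_label = drug, animal_id = id, pre_min = 15,
                  seed = seed),
                truth = sim$truth)
  message(sprintf("%-12s %d frames, %d sites, peak kinetic %.3f",
                  id, length(sim$recording$timestamps),
                  length(sim$truth$sites), max(sim$truth$kinetic_curve)))
}
message("sessions written under ", out_root)
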