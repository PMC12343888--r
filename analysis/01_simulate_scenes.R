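#!/usr/bin/env Rscript
# Generate the synthetic imaging scenes used by the downstream analysis
# scripts and save them as TIFF stacks with JSON ground-truth records.

suppressPackageStartupMessages(library(stiffquant))

cfg <- load_config(if (file.exists("analysis/config.yaml")) "analysis/config.yaml")
out <- "results/scenes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## Receptor scenes: ten stiff-substrate (internalizing) and ten
## soft-substrate (static) fields imaged at 0/15/30 min.
for (i in 1:10) {
  for (cond in c("stiff", "soft")) {
    seed <- cfg$seed + i + ifelse(cond == "stiff", 0, 100)
    cf <- make_cell_field(12, field_size = 256, seed = seed)
    sim <- simulate_internalization(
      cf, c(0, 15, 30), f_int = 0.6,
      k_int = if (cond == "stiff") 0.1 else 0,
      noise = list(gaussian_sd = 5, poisson_scale = 0), seed = seed + 500)
    base <- file.path(out, sprintf("receptor_%s_%02d", cond, i))
    write_stack(sim$stack, paste0(base, ".tif"))
    write_ground_truth(sim$gt[setdiff(names(sim$gt),
                                      c("noiseless", "label_image",
                                        "junction_mask", "colony_mask"))],
                       paste0(base, "_gt.json"))
  }
}

## One KTR time-lapse: 25 cells, two reporters, stimulus after frame 6.
k <- simulate_ktr(n_cells = 25, seed = cfg$seed + 300)
write_stack(k$stack, file.path(out, "ktr_timelapse.tif"))
write_ground_truth(k$gt, file.path(out, "ktr_timelapse_gt.json"))

## Endpoint assay inputs.
w <- simulate_wound(closure_fraction = 0.75, seed = cfg$seed + 400)
write_stack(w$stack_0h, file.path(out, "wound_0h.tif"))
write_stack(w$stack_48h, file.path(out, "wound_48h.tif"))
write_ground_truth(w$gt, file.path(out, "wound_gt.json"))

l <- simulate_laurdan(noise_sd_frac = 0.05, seed = cfg$seed + 401)
write_stack(l$stack, file.path(out, "laurdan.tif"))
write_ground_truth(l$gt, file.path(out, "laurdan_gt.json"))

fl <- simulate_flow(shift_fraction_positive = 0.42, seed = cfg$seed + 402)
utils::write.csv(data.frame(isotype = fl$isotype, stained = fl$stained),
                 file.path(out, "flow_events.csv"), row.names = FALSE)
write_ground_truth(fl$gt, file.path(out, "flow_gt.json"))

cat("scenes written to", out, "\n")
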