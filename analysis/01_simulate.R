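#!/usr/bin/env Rscript
# Generate every synthetic dataset used by the downstream analyses, with
# planted ground truth, and write them in standard interchange formats under
# results/simulated/. All downstream drivers (02-05) regenerate their inputs
# from the same seeds, so this script exists to materialize the files for
# inspection and external use.

library(speckletools)

out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2024

message("Multi-cohort expression panel (5 concordant + 2 discordant cohorts, ",
        "100 samples each, survival coupled in cohort C01) ...")
panel <- gen_expression_panel(seed = seed)
write_expression_panel(panel, out)
message("  genes: ", nrow(panel$expr), ", samples: ", ncol(panel$expr))

message("Synthetic proteome (10 planted STMs, 2 decoys per criterion) ...")
pr <- gen_proteome(n_background = 30, n_planted = 10,
                   n_decoys_per_criterion = 2, seed = seed)
write_proteome(pr, out)
message("  proteins: ", length(pr$proteome))

message("SON coverage tracks (6 domains of 1 Mb, 3 depleted at d = 0.4) ...")
tr <- gen_track_truth(seed = seed)
tk <- gen_son_tracks(tr, seed = seed)
write_son_tracks(tk, out)
message("  bins: ", nrow(tk$bins), " x ", ncol(tk$coverage$control),
        " replicates x 2 conditions")

message("Nuclei images (radial bias sweep b = 0, 1, 3) ...")
for (b in c(0, 1, 3)) {
  img <- gen_nuclei_images(n_nuclei = 12, image_size = 256, bias = b,
                           seed = seed + b)
  write_nuclei_images(img, out, prefix = sprintf("nuclei_bias%d", b))
}
message("Done; outputs under ", out)
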