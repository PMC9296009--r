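#!/usr/bin/env Rscript
# Call bait-interacting regions in each wild-type replicate against the
# monotonic distance-decay background and intersect them into consensus
# regions; write per-replicate calls, the consensus BED, smoothed tracks and
# an overview profile figure under results/calls/.

library(loop4c)

ws_dir <- "results/locus_workspace"
out <- "results/calls"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
res <- run_pipeline(file.path(ws_dir, "config.yaml"), out)

message("per-replicate WT calls:")
for (nm in names(res$calls)) {
  message("  ", nm, ": ", nrow(res$calls[[nm]]), " interval(s)")
}
message("consensus region(s):")
print(res$consensus)

# overlayed smoothed profiles per condition (mean of replicates)
libs <- unique(vapply(strsplit(colnames(res$norm), "_r"), `[`, "", 1))
tracks <- lapply(libs, function(cond) {
  cols <- grep(paste0("^", cond, "_r"), colnames(res$norm))
  running_mean(rowMeans(res$norm[, cols, drop = FALSE]), 21)
})
names(tracks) <- libs
plot_profiles(res$fragends_cis, tracks, file.path(out, "profiles.png"),
              bait_pos = 1e6)
message("outputs in ", out)
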