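#!/usr/bin/env Rscript
# Quantile-normalize all libraries within the 1-Mb cis window, sum the
# normalized signal over the Sox2-spanning region per library, and compare
# every deletion condition to wild type by two-sided Welch t-tests.
# Writes the score table and the comparison report under results/scores/.

library(loop4c)

out <- "results/scores"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ws <- simulate_sox2_locus(seed = 1L)
res <- score_4c_experiment(ws$counts, ws$fragends, ws$libraries, ws$config,
                           mask = ws$mask)

write_tsv_report(res$scores, file.path(out, "score_table.tsv"))
write_tsv_report(res$comparisons, file.path(out, "comparisons.tsv"))

sox2 <- res$comparisons[res$comparisons$region == "sox2_region", ]
message("bait-Sox2 interaction, relative to WT:")
for (i in seq_len(nrow(sox2))) {
  message(sprintf("  %-16s %+6.1f%%  (p = %.3g)", sox2$condition_b[i],
                  sox2$percent_change[i], sox2$p[i]))
}
message("reports in ", out)
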