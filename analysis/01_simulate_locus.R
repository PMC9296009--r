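#!/usr/bin/env Rscript
# Build the synthetic Sox2-locus study workspace: a 2-Mb toy chromosome with
# DpnII fragends, a strong bait-Sox2 interaction peak, an SCR-like deletion,
# and NB-distributed 4C libraries mirroring the study design (WT n=4,
# homozygous deletion n=4, heterozygote WT/deletion alleles n=3/n=4).
# Writes per-library count tables, the genome and the locus configuration
# under results/locus_workspace/.

library(loop4c)

seed <- 1L
out <- "results/locus_workspace"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ws <- simulate_sox2_locus(seed = seed)
message("fragends: ", nrow(ws$fragends), "; libraries: ", nrow(ws$libraries))

Biostrings::writeXStringSet(Biostrings::DNAStringSet(ws$genome),
                            file.path(out, "genome.fa"))
write_bed(ws$fragmap, file.path(out, "fragments.bed"))

libs <- lapply(seq_len(nrow(ws$libraries)), function(i) {
  p <- file.path(out, paste0(ws$libraries$sample_id[i], ".counts.tsv"))
  write_count_table(fourc_profile(ws$counts[, i], ws$fragends), p)
  list(sample_id = ws$libraries$sample_id[i],
       condition = ws$libraries$condition[i],
       replicate = ws$libraries$replicate[i],
       allele = ws$libraries$allele[i], counts = p)
})
cfg <- list(genome = file.path(out, "genome.fa"),
            bait_chrom = "chrS", bait_pos = ws$bait_pos, cis_window = 1e6,
            deletion = as.list(ws$deletion),
            libraries = libs,
            regions = lapply(seq_len(nrow(ws$config$regions)), function(r) {
              as.list(ws$config$regions[r, ])
            }))
yaml::write_yaml(cfg, file.path(out, "config.yaml"))
message("workspace written to ", out)
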