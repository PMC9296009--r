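# loop4c

Fragment-level analysis of allele-specific 4C-seq chromatin-interaction
experiments and single-molecule RNA FISH (smFISH) image stacks, built around
the quantitative dissection of the mouse *Sox2* locus in embryonic stem
cells — a locus where an enhancer cluster (the SCR) drives most
transcription while the chromatin architecture it sits in is maintained by
many distributed elements, so transcriptional control and 3D folding can be
measured, and decoupled, separately.

The package covers the full path from raw material to the study's headline
statistics:

- **Fragment space.** In-silico double digestion (`digest_genome`,
  `build_fragends`) builds restriction-fragment and fragment-end maps;
  `apply_allele_edits` re-digests engineered alleles (deletions,
  insertions) with a coordinate lift back to the reference.
- **Reads to counts.** Barcode demultiplexing (`demultiplex`) and exact
  capture-sequence lookup (`assign_reads`) produce per-fragend count
  vectors with full read accounting; external count tables can be imported.
- **Profiles.** RPM tracks, deletion-aware masks and running means
  (`running_mean` bridges deletion gaps and never lets masked fragends
  contribute).
- **Interaction calling.** A monotone (isotonic) distance-decay background
  per bait side (`fit_background`), a dual absolute/fold threshold rule on
  21-fragment running means (`call_interactions`, calibrated to a <=5%
  per-replicate false-call rate on null simulations), and cross-replicate
  consensus regions (`consensus_regions`).
- **Interaction scores.** Joint quantile normalization within 1 Mb of the
  bait (`quantile_normalize`), summed region scores
  (`interaction_score`), Welch/pooled t-tests with percent changes
  (`compare_conditions`), and WT-scaled TAD-leakiness scores
  (`tad_interaction_score`). The score of a region is
  `sum over fragends in region of the quantile-normalized counts`, and the
  interaction score of a condition is the mean over replicates.
- **smFISH.** Otsu + watershed segmentation (`segment_cells`),
  difference-of-Gaussians candidate detection with iterative 3D
  Gaussian-mask localization (`detect_spots`), RNA-equivalent calibration
  on the cytoplasmic median (`rna_equivalents`), transcription-site
  classification at >= 2.5 RNA equivalents (`classify_cells`), and
  Wilcoxon / chi-square sample comparisons (`compare_samples`).
- **Synthetic data.** Seeded generators for 4C libraries
  (negative-binomial counts around a power-law decay with planted,
  attenuable peaks, engineered deletions and TAD leaks) and smFISH stacks
  (cells, nuclei, sub-voxel spots, camera noise) with full ground truth:
  `simulate_4c_counts`, `simulate_smfish`, and the study-design fixture
  `simulate_sox2_locus` (WT n=4; homozygous deletion n=4; heterozygote
  alleles n=3/n=4).

## Worked example

The `analysis/` directory holds the numbered workflow. `01_simulate_locus.R`
writes a complete synthetic workspace (genome FASTA, per-library count
tables, YAML config); `02_call_interactions.R` runs the calling pipeline on
it; `03_interaction_scores.R` computes the headline comparison:

```r
library(loop4c)
ws  <- simulate_sox2_locus(seed = 1)          # 2-Mb locus, 15 libraries
res <- score_4c_experiment(ws$counts, ws$fragends, ws$libraries,
                           ws$config, mask = ws$mask)
subset(res$comparisons, region == "sox2_region")
```

Running `Rscript analysis/03_interaction_scores.R` prints:

```
bait-Sox2 interaction, relative to WT:
  dSCR_hom          -24.0%  (p = 6e-06)
  het_WT_allele      +2.2%  (p = 0.545)
  het_dSCR_allele   -18.8%  (p = 7.81e-06)
```

i.e. on this synthetic replica of the study design, deleting the enhancer
cluster reduces the bait–*Sox2* contact frequency by ~a quarter on the
deleted allele — whether homozygous or heterozygous — while the intact
allele of the same heterozygous cells is indistinguishable from wild type,
the in-cis signature the real experiment was designed to detect.
`04_tad_leakiness.R` adds the boundary statistic (downstream-TAD scaled
score 1.30 for the deletion, p = 3e-07; upstream unchanged in the WT
allele), and `05_smfish.R` runs the imaging arm end to end (control vs
CTCF-insertion cells with identical bursting: Wilcoxon p = 0.28, chi-square
p = 0.44 — no spurious difference).

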