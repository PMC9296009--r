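---
title: "Quantifying allele-specific 4C-seq interactions and smFISH transcription: models and choices"
author: "loop4c"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allele-specific 4C-seq interactions and smFISH transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

loop4c implements the two quantitative arms of an allele-specific dissection
of the mouse *Sox2* locus in embryonic stem cells: fragment-level 4C-seq
analysis (contact profiles of a fixed bait, interaction calling against a
distance-decay background, quantile-normalized region interaction scores,
TAD-boundary leakiness) and single-molecule RNA FISH quantification (spot
detection, RNA-equivalent calibration, transcription-site classification).
This vignette records the models, the tunable parameters, and the design
choices that the published description leaves open, together with what the
synthetic-data generators do and do not emulate.

## The 4C fragment space

4C-seq measures, for one "bait" restriction fragment, how often every other
fragment in the genome was crosslinked and ligated to it. After a
double digestion (a 4-cutter primary enzyme such as DpnII `^GATC` or NlaIII
`CATG^`, then Csp6I `G^TAC` as secondary), the informative sequencing unit is
the *fragment end*: the portion of a primary fragment adjacent to a primary
cut site. `digest_genome()` scans the genome for primary sites (coordinates
are 0-based half-open throughout; `N` never matches, which treats assembly
gaps as uncut), and `build_fragends()` derives two fragends per fragment with
their capture sequence — the first `L` bases read inward from the cut — and a
`blind` flag for fragments lacking a secondary site (these cannot circularize
informatively).

Reads are assigned by exact unique lookup of their first `L` bases against
the capture dictionary (`assign_reads()`, `L` default 36 nt). Capture
sequences shared by several fragends are excluded when the dictionary is
built, and reads carrying them are counted as ambiguous, so
assigned + ambiguous + unmatched always equals the input. This replaces an
external short-read aligner while preserving the fragment-space
representation in which all downstream statistics operate; externally
produced per-fragment count tables can be imported instead
(`read_count_table()`).

Engineered alleles are first-class: `apply_allele_edits()` deletes or inserts
sequence, re-digests, and records a block lift table back to reference
coordinates (deleted sequence has no image; an insertion is labelled as its
own named contig, which is how a short foreign fragment can serve as a
unique bait). On a deletion allele the sequence beyond the deletion becomes
bait-proximal — the familiar artifactually high 4C signal next to a deletion
scar — and the simulator reproduces exactly this geometry.

## Profiles, masks and running means

Display tracks are reads-per-million (`normalize_rpm()`); all statistics use
quantile normalization instead (below). For deletion alleles,
`build_deletion_mask()` masks the fragends inside the deleted interval plus
`flank_frags` fragends on each side (default 2), absorbing ligation artifacts
at the scar. `running_mean()` then drops masked positions *before* smoothing:
the centered window of `W` fragends (default 21, the same scale as the
calling window) runs over the remaining informative fragends, bridging the
deletion gap, and the output is undefined (`NA`, written as no-coverage gaps
in bedGraph, never zeros) at masked positions. A masked fragend therefore
neither receives nor contributes signal anywhere.

## Interaction calling

The background model is the least-squares non-increasing (isotonic) fit of
the normalized counts against distance from the bait, fitted separately
upstream and downstream (`fit_background()`, via pool-adjacent-violators).
Monotone decay is the defining property of polymer background contact
frequency; anything systematically above it is a candidate interaction. The
`exclusion_frags` bait-proximal fragends per side (default 10) are omitted —
they are dominated by self-ligation and re-ligation products — and masked
fragends are excluded.

A fragend is called interacting when the 21-fragment running mean of its
normalized signal exceeds the background both by at least `delta` normalized
counts *and* by at least `rho`-fold; maximal runs of at least `min_frags`
flagged fragends become intervals (`call_interactions()`). Only the window
size (21 fragments) is fixed by the study description; `delta`, `rho` and
`min_frags` are this package's explicit reconstruction of the peak-calling
statistic, frozen after a one-time calibration on background-only
simulations of the study-scale locus (200 negative-binomial replicates,
depth 1e5, dispersion 10): `delta = 1.5`, `rho = 2`, `min_frags = 3` give a
0/200 per-replicate false-call rate (`delta = 1` sat at 5.5%, just over the
5% design bound, and was rejected by the same calibration). The acceptance
suite re-runs this calibration. Raising `delta` or `rho` can only shrink the
called set (asserted as a property test), and calls never span the bait.

Consensus regions (`consensus_regions()`) are the per-position intersection
of the replicate call sets — a position is consensus only if every replicate
called it — matching the "minimal region called in all wild-type replicates"
that defines the scored *Sox2* interval.

## Interaction scores and condition comparisons

All libraries sharing a bait (every condition, allele and replicate) are
quantile-normalized jointly over the fragends within 1 Mb of the bait
(`quantile_normalize()`, limma's implementation; ties receive the mean
reference value over their rank span). Fragends masked on *any* deletion
allele are removed from *all* libraries first, so ranks stay comparable
across alleles. The interaction score of a region is the sum of normalized
signal over fragends whose anchor lies in it (`interaction_score()`), and
conditions are compared on per-replicate scores by two-sided t-tests
(`compare_conditions()`; Welch by default, which is the safe choice at
n = 2–4 replicates, pooled available by flag), reporting
`100 * (mean_B - mean_A) / mean_A` as the percent change.

TAD leakiness uses the same machinery over the two predefined 325-kb TAD
regions, rescaled so the wild-type mean is 1 per region
(`tad_interaction_score()`); upstream and downstream are scored
independently, so a boundary leak planted only downstream leaves the
upstream scaled mean at about 1. `sox2_locus_config()` carries the mm10
coordinates of the scored regions; the downstream region spans 305 kb as
configured even though it is conventionally called the 325-kb region — the
discrepancy is preserved as configured rather than silently fixed.

### A known limitation: quantile normalization compresses percent changes

Joint quantile normalization maps every library onto the mean sorted
profile. When a block of peak fragends moves down through the rank
distribution in one condition, both conditions are pulled toward the pooled
reference, so the between-condition difference is systematically
*understated*. On the synthetic locus the end-to-end recovery study (run by
`scripts/acceptance.R`) quantifies this: the recovered percent change over
the planted-peak region is roughly 0.6–0.75 of the planted attenuation, a
conservative bias that grows with peak prominence and persists across the
peak heights and region widths we scanned. Percent changes reported by this
pipeline (and by any pipeline using the same normalization) should be read
as lower bounds on the underlying contact loss; between-condition *p*-values
are unaffected under the null (the t-test calibration is separately
verified).

## The 4C synthetic-data generator

`simulate_4c_counts()` draws negative-binomial counts around an expected
profile with three components: a power-law background
`lambda(d) = (d + d0)^(-alpha)` scaled to the library depth (defaults
`alpha = 1`, `d0` = 2 kb, depth = 1e5 cis reads, dispersion `phi = 10` — a
shape that visually matches published 4C decay); additive Gaussian
interaction peaks whose amplitude is `(fold - 1)` times the local background
at the peak center (width default 10 kb), attenuated per allele by a factor
`f`; and an optional multiplicative TAD-leak factor over a region. Peaks are
additive because loop-mediated ligation events add to, rather than rescale,
the polymer background. Deletions shorten the coordinate axis before
distances are computed, reproducing the bait-contiguity artifact.

`sox2_locus_design()` assembles the study-scale fixture: a 2-Mb random
chromosome (DpnII sites then occur every ~256 bp, the genome-wide average,
giving ~15,000 fragends), bait at 1 Mb, a fold-15 peak at the "Sox2"
position 100 kb upstream, a 7.3-kb SCR-like deletion just downstream of the
bait, and 325-kb TAD regions mirroring the real locus geometry. The
condition table mirrors the study: WT n = 4, homozygous deletion n = 4, and
the wild-type (n = 3) and deletion (n = 4) alleles of a heterozygote, with
peak attenuations 0.72 and 0.76 on the deletion alleles and a downstream
TAD-leak factor of 1.5 — the attenuations embody the reported interaction
losses, and the leak magnitude (not printed in the study) is a fixture
choice. What the generator does *not* emulate: PCR jackpotting and duplicate
structure, mappability and repeat effects, blind-fragment biases, and
trans-chromosomal contacts; green tests on this fixture therefore say the
algorithms are correct and calibrated, not that every real-data artifact is
handled.

## smFISH quantification

`segment_cells()` segments nuclei by Otsu thresholding of the maximum
projection of the nuclear stain, split by watershed on the distance
transform, and grows cells from the nucleus seeds by seeded propagation into
the above-background probe region (the probe projection is smoothed and used
for the cell threshold so bright spots cannot shift it). Every nucleus lies
in exactly one cell; border-touching cells and sub-`min_size` nuclei are
dropped.

`detect_spots()` finds candidates as local maxima of a
difference-of-Gaussians band-pass (sigma ratio 1.6) above `k` MADs over the
filtered median (`k` default 5; for degenerate noiseless input the threshold
falls back to 10% of the strongest response). Each candidate is refined by
iterative 3D Gaussian-mask centroid fitting after subtracting the median of
the ROI border shell; the integrated intensity is then the least-squares
amplitude of a unit-sum Gaussian template *with a free constant term*, so
residual flat background (e.g. at cell edges) cannot leak into the
intensity. Fits that drift more than one PSF FWHM from their seeding
candidate are discarded — the Gaussian mask is a local refiner, and such
fits belong to a different maximum — and duplicates within one FWHM are
merged keeping the brighter. The PSF default (`sigma` = 1 voxel axially,
1.3 laterally) corresponds to a 1.4-NA objective at ~0.1 um pixels and
0.3-um z-steps; it is fully configurable, as is an optional absolute
intensity floor (`min_intensity`, the detection-threshold parameter; set it
near half the single-RNA intensity to reject sub-single-RNA fits in
low-noise data).

Spot intensities are converted to RNA equivalents by dividing by the median
integrated intensity of all cytoplasmic spots pooled across cells
(`rna_equivalents()`): cytoplasmic spots are almost all single mRNAs, the
median cytoplasmic spot is exactly 1 by construction, and the measure is
invariant to overall image scaling. Per cell, the mRNA content is the sum of
RNA equivalents (so a nuclear focus holding three nascent RNAs contributes
three; a count-spots-once mode exists), and nuclear foci with at least 2.5
RNA equivalents are active transcription sites; cells fall into zero / one /
more-than-one TS categories, with >2 TSs retained in the last category
(`classify_cells()`). Cells with no detected spots never enter the analysis
(in real data they are segmentation failures). Samples are compared by a
two-sided Wilcoxon rank-sum test on mRNA per cell (exact for small samples
without ties, tie-corrected normal approximation otherwise) and a Pearson
chi-square test on the 2x3 TS-category table (`compare_samples()`).

## The smFISH synthetic-data generator

`simulate_smfish()` renders disk-shaped cells with interior nuclei on a
jittered grid, a smooth-edged cytoplasmic autofluorescence slab (smooth both
laterally and axially — real diffuse fluorescence has no sharp edges, and
sharp synthetic edges would masquerade as band-pass features), Poisson
numbers of single mRNAs per cell with log-normal intensity scatter
(CV 0.25), per-allele transcription sites with probability `burst_prob` and
Gamma-distributed nascent loads, and voxel-integrated 3D Gaussian spots at
sub-voxel positions under Poisson shot noise plus Gaussian read noise. The
default stack is 45 planes at 0.3 um, matching the acquisition design; test
and acceptance fixtures use 21–25 planes and 4–8 cells to stay fast, at a
spot density (about 12 mRNAs per reduced-size cell) chosen to match the
per-volume density at which per-spot counting is valid — the same regime the
real experiment works in; denser nascent foci are quantified through
intensity, not counts. Not emulated: optical aberrations, chromatic offsets,
autofluorescent debris, and segmentation-hostile cell clumping.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run the full study-scale locus
(2 Mb, ~15,000 fragends, depth 1e5, 15 libraries), a 200-replicate null
calibration, a 3 x 50-seed attenuation-recovery study, and multi-cell smFISH
stacks up to 25 x 320 x 320 voxels. Every stochastic step flows from a
single seed; identical seeds give bit-identical outputs, and `run_pipeline()`
writes a provenance header (package version and configuration hash) plus a
`params.yaml` recording every frozen default (`W`, `delta`, `rho`,
`flank_frags`, the TS threshold, detection `k`) alongside its outputs.
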