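#' Locus configuration
#'
#' Named scored regions plus bait position and cis window for one 4C
#' experiment. Coordinates are 0-based half-open (BED convention).
#'
#' @param regions data.frame with columns `region`, `chrom`, `start`, `end`.
#' @param bait_chrom,bait_pos Bait location.
#' @param cis_window Half-width of the scoring window around the bait in bp
#'   (default 1e6: counts within 1 Mb of the bait enter normalization and
#'   scoring).
#' @return A `locus_config` object.
#' @export
locus_config <- function(regions, bait_chrom, bait_pos, cis_window = 1e6) {
  stopifnot(all(c("region", "chrom", "start", "end") %in% names(regions)),
            all(regions$start < regions$end))
  off <- regions$chrom == bait_chrom &
    (regions$start < bait_pos - cis_window | regions$end > bait_pos + cis_window)
  if (any(off)) {
    warning("region(s) extend beyond the cis window: ",
            paste(regions$region[off], collapse = ", "))
  }
  structure(list(regions = regions, bait_chrom = bait_chrom,
                 bait_pos = bait_pos, cis_window = cis_window),
            class = "locus_config")
}

#' Sox2 locus configuration (mm10)
#'
#' The predefined regions scored in the Sox2 dissection, in mm10 reference
#' coordinates (converted to 0-based half-open): the minimal Sox2-spanning
#' region interacting with the near-SCR bait in all wild-type replicates, the
#' minimal SCR-spanning region from the insertion-site bait, and the 325-kb
#' upstream/downstream TAD regions used to quantify boundary leakiness. The
#' downstream region as configured spans 305 kb although it is referred to as
#' the 325-kb region; the discrepancy is preserved as configured, not silently
#' fixed.
#'
#' @param bait_pos Bait coordinate; defaults to a position just upstream of
#'   the SCR (the near-SCR bait region; the published coordinate of the bait
#'   fragment itself is not given at bp resolution).
#' @return A `locus_config`.
#' @export
sox2_locus_config <- function(bait_pos = 34744000) {
  regions <- data.frame(
    region = c("sox2_region", "scr_region", "downstream_tad", "upstream_tad"),
    chrom = "chr3",
    start = c(34644921, 34749651, 34800000, 34315000),
    end = c(34664967, 34760919, 35105000, 34640000),
    stringsAsFactors = FALSE)
  locus_config(regions, bait_chrom = "chr3", bait_pos = bait_pos,
               cis_window = 1e6)
}

#' Quantile-normalize 4C libraries within the cis window
#'
#' Makes every library's count distribution identical to the reference
#' distribution (the mean of the per-library sorted counts), so that region
#' scores are comparable across libraries, conditions and alleles. Ties within
#' a library receive the mean of the reference values across their rank span.
#' Computed jointly over all libraries sharing a bait; fragends masked on any
#' deletion allele should be removed from all columns beforehand so ranks stay
#' comparable.
#'
#' @param mat Numeric matrix, fragends x libraries, restricted to the cis
#'   window and with masked fragends removed.
#' @return Matrix of the same shape and dimnames. A single-column input is
#'   returned unchanged with a warning.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) {
    warning("quantile normalization needs >= 2 libraries; returning input")
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Region interaction score for one library
#'
#' The summed normalized 4C signal over the fragends whose anchor position
#' falls in the region. Deletion-masked fragends are excluded. Scores are
#' additive over disjoint regions.
#'
#' @param values Per-fragend normalized signal.
#' @param fragends The matching `fragend_map`.
#' @param region Numeric `c(start, end)` (0-based half-open) or a one-row
#'   data.frame with `chrom`, `start`, `end`.
#' @param chrom Region chromosome (defaults to data.frame column or the single
#'   chromosome present).
#' @param mask Optional masked fragend indices.
#' @return Non-negative numeric score.
#' @export
interaction_score <- function(values, fragends, region, chrom = NULL,
                              mask = NULL) {
  if (is.data.frame(region)) {
    chrom <- region$chrom[1L]
    region <- c(region$start[1L], region$end[1L])
  }
  if (is.null(chrom)) {
    chrom <- unique(fragends$chrom)
    if (length(chrom) != 1L) stop("specify chrom for a multi-chromosome map")
  }
  keep <- fragends$chrom == chrom & fragends$anchor_pos >= region[1L] &
    fragends$anchor_pos < region[2L]
  if (!is.null(mask) && length(mask) > 0L) keep[mask] <- FALSE
  sum(values[keep], na.rm = TRUE)
}

#' Compare interaction scores between two conditions
#'
#' Two-sided two-sample t-test on per-replicate region scores, Welch by
#' default (safe at n = 2-4 replicates); `var_equal = TRUE` gives the pooled
#' test. The percent change is reported on the condition means,
#' `100 * (mean_b - mean_a) / mean_a`.
#'
#' @param scores_a,scores_b Per-replicate scores (reference condition first).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return One-row data.frame: `mean_a`, `mean_b`, `percent_change`, `t`,
#'   `df`, `p`.
#' @export
compare_conditions <- function(scores_a, scores_b, var_equal = FALSE) {
  if (length(scores_a) < 2L || length(scores_b) < 2L) {
    stop("compare_conditions requires >= 2 replicates per condition")
  }
  tt <- tryCatch(stats::t.test(scores_a, scores_b, var.equal = var_equal),
                 error = function(e) NULL)  # zero-variance degenerate input
  data.frame(mean_a = mean(scores_a), mean_b = mean(scores_b),
             percent_change = 100 * (mean(scores_b) - mean(scores_a)) /
               mean(scores_a),
             t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
             df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
             p = if (is.null(tt)) NA_real_ else tt$p.value)
}

#' Score all libraries over all configured regions
#'
#' @param norm_mat Normalized matrix (fragends x libraries).
#' @param fragends Matching `fragend_map`.
#' @param libraries data.frame with one row per column of `norm_mat` and at
#'   least `sample_id`, `condition`, `replicate` (optionally `allele`).
#' @param regions Regions data.frame (`region`, `chrom`, `start`, `end`).
#' @param mask Optional masked fragend indices (excluded for all libraries).
#' @return Long data.frame: library metadata x region with `score`.
#' @export
score_table <- function(norm_mat, fragends, libraries, regions, mask = NULL) {
  stopifnot(ncol(norm_mat) == nrow(libraries))
  out <- list()
  for (r in seq_len(nrow(regions))) {
    sc <- apply(norm_mat, 2L, interaction_score, fragends = fragends,
                region = c(regions$start[r], regions$end[r]),
                chrom = regions$chrom[r], mask = mask)
    out[[r]] <- cbind(libraries, region = regions$region[r], score = unname(sc),
                      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare all conditions against a reference, per region
#'
#' @param scores A [score_table()] result.
#' @param reference Reference condition label (default "WT").
#' @param var_equal Passed to [compare_conditions()].
#' @return data.frame with one row per (region, condition) pair.
#' @export
compare_all_conditions <- function(scores, reference = "WT",
                                   var_equal = FALSE) {
  conds <- setdiff(unique(scores$condition), reference)
  out <- list()
  for (reg in unique(scores$region)) {
    a <- scores$score[scores$region == reg & scores$condition == reference]
    for (cond in conds) {
      b <- scores$score[scores$region == reg & scores$condition == cond]
      cmp <- compare_conditions(a, b, var_equal = var_equal)
      out[[length(out) + 1L]] <- cbind(
        data.frame(region = reg, condition_a = reference, condition_b = cond,
                   stringsAsFactors = FALSE), cmp)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' TAD interaction scores scaled to the wild-type mean
#'
#' Quantifies boundary leakiness: the interaction score of the bait with the
#' upstream and downstream TAD regions, computed per replicate with the same
#' machinery as any region score, then scaled so the reference (wild-type)
#' condition mean equals 1 per region. Upstream and downstream regions are
#' scored independently, so a boundary leak planted downstream leaves the
#' upstream scaled mean at ~1.
#'
#' @param scores A [score_table()] result containing the TAD regions.
#' @param regions Character vector of region names to scale (default the two
#'   TAD regions).
#' @param reference Reference condition (default "WT").
#' @return The input rows for those regions with an added `scaled_score`
#'   column (raw scores are retained).
#' @export
tad_interaction_score <- function(scores,
                                  regions = c("upstream_tad", "downstream_tad"),
                                  reference = "WT") {
  out <- scores[scores$region %in% regions, , drop = FALSE]
  if (nrow(out) == 0L) stop("no rows for the requested regions")
  out$scaled_score <- NA_real_
  for (reg in regions) {
    sel <- out$region == reg
    wt <- out$score[sel & out$condition == reference]
    if (length(wt) == 0L) stop("no ", reference, " replicates for ", reg)
    out$scaled_score[sel] <- out$score[sel] / mean(wt)
  }
  rownames(out) <- NULL
  out
}
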