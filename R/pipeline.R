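#' Normalize, call and score a 4C experiment
#'
#' The full fragment-space analysis for one bait: restrict to the cis window,
#' remove masked fragends from all libraries, quantile-normalize jointly
#' across every library sharing the bait, call interactions per wild-type
#' replicate against the monotonic background and intersect them into
#' consensus regions, score the configured regions per library, and compare
#' each condition to the reference by two-sided t-tests.
#'
#' @param counts Integer matrix, fragends x libraries.
#' @param fragends Matching `fragend_map`.
#' @param libraries data.frame (`sample_id`, `condition`, `replicate`, ...)
#'   with one row per column of `counts`.
#' @param config A [locus_config()].
#' @param mask Optional masked fragend indices (applied to all libraries
#'   before normalization so ranks stay comparable across deletion alleles).
#' @param reference Reference condition (default "WT").
#' @param W,delta,rho,min_frags,exclusion_frags Calling parameters, see
#'   [call_interactions()] and [fit_background()].
#' @param var_equal Pooled instead of Welch t-tests.
#' @return List: `norm` (normalized matrix over retained cis fragends),
#'   `fragends_cis` (their map), `calls` (per reference replicate),
#'   `consensus`, `scores` (long table), `comparisons`, `tad_scores`
#'   (WT-scaled, when TAD regions are configured), and `params`.
#' @export
score_4c_experiment <- function(counts, fragends, libraries, config,
                                mask = NULL, reference = "WT", W = 21L,
                                delta = 1.5, rho = 2, min_frags = 3L,
                                exclusion_frags = 10L, var_equal = FALSE) {
  stopifnot(ncol(counts) == nrow(libraries))
  cis <- fragends$chrom == config$bait_chrom &
    abs(fragends$anchor_pos - config$bait_pos) <= config$cis_window
  keep <- which(cis)
  if (!is.null(mask)) keep <- setdiff(keep, mask)
  fe <- fragends[keep, , drop = FALSE]
  rownames(fe) <- NULL
  class(fe) <- class(fragends)
  norm <- quantile_normalize(counts[keep, , drop = FALSE])

  ref_cols <- which(libraries$condition == reference)
  calls <- lapply(ref_cols, function(j) {
    bg <- fit_background(norm[, j], fe, config$bait_pos,
                         exclusion_frags = exclusion_frags)
    call_interactions(norm[, j], bg, fe, W = W, delta = delta, rho = rho,
                      min_frags = min_frags)
  })
  names(calls) <- libraries$sample_id[ref_cols]
  consensus <- consensus_regions(calls)

  scores <- score_table(norm, fe, libraries, config$regions)
  comparisons <- compare_all_conditions(scores, reference = reference,
                                        var_equal = var_equal)
  tad_regs <- intersect(c("upstream_tad", "downstream_tad"),
                        config$regions$region)
  tad <- if (length(tad_regs) > 0L) {
    tad_interaction_score(scores, regions = tad_regs, reference = reference)
  } else NULL
  list(norm = norm, fragends_cis = fe, calls = calls, consensus = consensus,
       scores = scores, comparisons = comparisons, tad_scores = tad,
       params = list(W = W, delta = delta, rho = rho, min_frags = min_frags,
                     exclusion_frags = exclusion_frags,
                     var_equal = var_equal, reference = reference))
}

#' Run the 4C pipeline from a configuration
#'
#' Reads per-library count tables, assembles the count matrix, runs
#' [score_4c_experiment()] and writes the score table, comparison report,
#' consensus calls (BED) and per-library smoothed tracks (bedGraph) under
#' `out_dir`. Deterministic given the configuration and inputs; every table
#' carries a provenance header (package version + configuration hash). The
#' frozen defaults the configuration does not override (W, delta, rho,
#' flank_frags, exclusion zone) are recorded in `params.yaml` alongside the
#' outputs.
#'
#' @param config A list as returned by [read_run_config()], or a path to a
#'   YAML file. Must provide `genome`, `libraries` (manifest with
#'   `sample_id`, `condition`, `replicate`, `counts` path), `bait_pos`,
#'   `regions`; optionally `bait_chrom`, `enzyme`, `secondary`, `deletion`,
#'   `params`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the [score_4c_experiment()] result.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome_fasta(config$genome)
  enz <- known_enzymes(config$enzyme %||% "DpnII")
  sec <- known_enzymes(config$secondary %||% "Csp6I")
  fragmap <- digest_genome(genome, enz)
  fragends <- build_fragends(fragmap, genome, sec,
                             L = config$L %||% 36L)
  libs <- do.call(rbind, lapply(config$libraries, function(l) {
    data.frame(sample_id = l$sample_id, condition = l$condition,
               replicate = l$replicate,
               allele = l$allele %||% NA_character_,
               counts = l$counts, stringsAsFactors = FALSE)
  }))
  counts <- vapply(libs$counts, function(p) {
    read_count_table(p, fragends)$counts
  }, numeric(nrow(fragends)))
  colnames(counts) <- libs$sample_id
  regions <- do.call(rbind, lapply(config$regions, function(r) {
    data.frame(region = r$region, chrom = r$chrom, start = r$start,
               end = r$end, stringsAsFactors = FALSE)
  }))
  cfg <- locus_config(regions,
                      bait_chrom = config$bait_chrom %||% regions$chrom[1],
                      bait_pos = config$bait_pos,
                      cis_window = config$cis_window %||% 1e6)
  p <- config$params %||% list()
  mask <- NULL
  if (!is.null(config$deletion)) {
    mask <- build_deletion_mask(fragends, unlist(config$deletion),
                                chrom = cfg$bait_chrom,
                                flank_frags = p$flank_frags %||% 2L)
  }
  res <- score_4c_experiment(counts, fragends, libs, cfg, mask = mask,
                             reference = p$reference %||% "WT",
                             W = p$W %||% 21L, delta = p$delta %||% 1.5,
                             rho = p$rho %||% 2,
                             min_frags = p$min_frags %||% 3L,
                             exclusion_frags = p$exclusion_frags %||% 10L,
                             var_equal = isTRUE(p$var_equal))
  write_tsv_report(res$scores, file.path(out_dir, "scores.tsv"), config)
  write_tsv_report(res$comparisons, file.path(out_dir, "comparisons.tsv"),
                   config)
  if (nrow(res$consensus) > 0L) {
    write_bed(res$consensus, file.path(out_dir, "consensus.bed"),
              name = paste0("n", res$consensus$n_replicates))
  }
  for (j in seq_len(ncol(res$norm))) {
    sm <- running_mean(res$norm[, j], W = res$params$W)
    write_bedgraph(res$fragends_cis, sm,
                   file.path(out_dir, paste0(libs$sample_id[j],
                                             ".smooth.bedGraph")))
  }
  yaml::write_yaml(res$params, file.path(out_dir, "params.yaml"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
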