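#' Reads-per-million scaling
#'
#' Scales a count vector (or `fourc_profile`) to sum to one million. Used for
#' cross-library display tracks; the interaction-score statistics use quantile
#' normalization instead.
#'
#' @param x Numeric count vector or [fourc_profile()].
#' @return Object of the same shape scaled so the counts sum to 1e6; an
#'   all-zero input is returned unchanged with a warning.
#' @export
normalize_rpm <- function(x) {
  if (inherits(x, "fourc_profile")) {
    x$counts <- normalize_rpm(x$counts)
    return(x)
  }
  tot <- sum(x, na.rm = TRUE)
  if (tot == 0) {
    warning("all-zero profile; rpm scaling skipped")
    return(x)
  }
  x * 1e6 / tot
}

#' Mask fragends affected by an engineered deletion
#'
#' Fragends whose parent fragment overlaps the deleted interval carry no signal
#' on the deletion allele, and the fragends immediately flanking the deletion
#' scar are perturbed by the novel ligation junction. Both are masked: the
#' in-deletion fragends plus `flank_frags` fragends on each side (in fragend
#' order along the chromosome).
#'
#' @param fragends A `fragend_map`.
#' @param deletion Numeric `c(start, end)`, 0-based half-open, on the reference
#'   axis. A list of such intervals is also accepted.
#' @param chrom Chromosome of the deletion (defaults to the single chromosome
#'   in the map).
#' @param flank_frags Fragends masked on each side of the deletion (default 2).
#' @return Sorted integer vector of masked fragend row indices, class
#'   `deletion_mask`, with the provenance stored as attributes.
#' @export
build_deletion_mask <- function(fragends, deletion, chrom = NULL,
                                flank_frags = 2L) {
  if (is.list(deletion) && !is.numeric(deletion)) {
    masks <- lapply(deletion, build_deletion_mask, fragends = fragends,
                    chrom = chrom, flank_frags = flank_frags)
    out <- sort(unique(unlist(masks)))
    return(structure(out, deletion = deletion, flank_frags = flank_frags,
                     class = "deletion_mask"))
  }
  stopifnot(length(deletion) == 2L, deletion[1] < deletion[2])
  if (is.null(chrom)) {
    chrom <- unique(fragends$chrom)
    if (length(chrom) != 1L) stop("specify chrom for a multi-chromosome map")
  }
  on_chrom <- which(fragends$chrom == chrom)
  hit <- on_chrom[fragends$start[on_chrom] < deletion[2] &
                    fragends$end[on_chrom] > deletion[1]]
  if (length(hit) > 0L && flank_frags > 0L) {
    lo <- match(min(hit), on_chrom)
    hi <- match(max(hit), on_chrom)
    span <- on_chrom[max(1L, lo - flank_frags):min(length(on_chrom),
                                                  hi + flank_frags)]
    hit <- span
  }
  structure(sort(unique(hit)), deletion = deletion, flank_frags = flank_frags,
            class = "deletion_mask")
}

#' Deletion-aware centered running mean
#'
#' Masked positions are removed from the vector before smoothing, so the
#' centered window of width `W` runs over the remaining (unmasked) values --
#' windows bridge deletion gaps using the nearest informative fragends, and are
#' truncated at the chromosome ends. The output is `NA` at masked positions:
#' masked fragends neither receive nor contribute a value.
#'
#' @param values Numeric vector (per-fragend signal; `NA` treated as masked).
#' @param W Odd window size in fragends (default 21, the interaction-calling
#'   window).
#' @param mask Optional integer indices to exclude (e.g. a
#'   [build_deletion_mask()] result).
#' @return Numeric vector of smoothed values, `NA` where masked.
#' @export
running_mean <- function(values, W = 21L, mask = NULL) {
  W <- as.integer(W)
  if (is.na(W) || W < 1L || W %% 2L == 0L) stop("W must be odd and >= 1")
  n <- length(values)
  out <- rep(NA_real_, n)
  ok <- !is.na(values)
  if (!is.null(mask) && length(mask) > 0L) ok[mask] <- FALSE
  idx <- which(ok)
  m <- length(idx)
  if (m == 0L) return(out)
  v <- values[idx]
  h <- (W - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(m) - h, 1L)
  hi <- pmin(seq_len(m) + h, m)
  out[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out
}

#' Plot smoothed 4C profiles
#'
#' Overlay of per-condition smoothed tracks against genomic position,
#' written to a PNG.
#'
#' @param fragends A `fragend_map` (single chromosome).
#' @param tracks Named list of per-fragend smoothed value vectors.
#' @param path Output PNG path.
#' @param bait_pos Optional bait coordinate drawn as a dashed line.
#' @param col Colors, recycled over tracks.
#' @export
plot_profiles <- function(fragends, tracks, path, bait_pos = NULL,
                          col = c("black", "red", "blue", "grey50")) {
  grDevices::png(path, width = 1200, height = 400)
  on.exit(grDevices::dev.off())
  ylim <- range(unlist(tracks), na.rm = TRUE)
  plot(NA, xlim = range(fragends$anchor_pos), ylim = ylim,
       xlab = paste0("position on ", fragends$chrom[1]),
       ylab = "smoothed normalized 4C signal")
  col <- rep_len(col, length(tracks))
  for (i in seq_along(tracks)) {
    graphics::lines(fragends$anchor_pos, tracks[[i]], col = col[i])
  }
  if (!is.null(bait_pos)) graphics::abline(v = bait_pos, lty = 2)
  graphics::legend("topright", legend = names(tracks), col = col, lty = 1,
                   bty = "n")
  invisible(path)
}
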