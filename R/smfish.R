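#' smFISH image stack container
#'
#' Two aligned 3D channels in (z, y, x) order: a nuclear stain (DAPI) and an
#' RNA probe channel.
#'
#' @param dapi,rna 3D numeric arrays, identical dimensions, z first.
#' @param voxel_size Named numeric `c(z=, y=, x=)` in micrometers (metadata
#'   only; all algorithms work in voxel units).
#' @return An `smfish_stack` object.
#' @export
smfish_stack <- function(dapi, rna, voxel_size = c(z = 0.3, y = 0.1, x = 0.1)) {
  stopifnot(length(dim(dapi)) == 3L, identical(dim(dapi), dim(rna)),
            dim(dapi)[1] >= 1L)
  structure(list(dapi = dapi, rna = rna, voxel_size = voxel_size),
            class = "smfish_stack")
}

#' Read a two-channel z-stack from TIFF files
#'
#' @param dapi_path,rna_path Multi-page TIFF files, one z-plane per page.
#' @param voxel_size Passed to [smfish_stack()].
#' @return An `smfish_stack`.
#' @export
read_stack_tiff <- function(dapi_path, rna_path,
                            voxel_size = c(z = 0.3, y = 0.1, x = 0.1)) {
  rd <- function(p) {
    img <- EBImage::readImage(p)
    a <- as.array(img)
    if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
    aperm(a, c(3L, 2L, 1L))  # EBImage is (x, y, frame); we use (z, y, x)
  }
  smfish_stack(rd(dapi_path), rd(rna_path), voxel_size)
}

#' Write a stack channel as multi-page TIFF
#'
#' @param arr 3D array (z, y, x), rescaled to [0, 1] on write.
#' @param path Output file.
#' @export
write_stack_tiff <- function(arr, path) {
  a <- arr / max(arr, 1)
  EBImage::writeImage(EBImage::Image(aperm(a, c(3L, 2L, 1L))), path,
                      type = "tiff")
  invisible(path)
}

# 1-d voxel-integrated Gaussian at integer voxel centers `i`.
gauss1d_int <- function(i, center, sigma) {
  stats::pnorm(i + 0.5, center, sigma) - stats::pnorm(i - 0.5, center, sigma)
}

# Separable Gaussian blur of a 3D array, one dense banded matrix per axis.
gauss_blur3 <- function(arr, sigma) {
  for (d in 1:3) {
    if (sigma[d] <= 0) next
    n <- dim(arr)[d]
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) stats::dnorm(j - i, 0, sigma[d]))
    K[K < 1e-8] <- 0
    K <- K / rowSums(K)
    perm <- c(d, setdiff(1:3, d))
    a <- aperm(arr, perm)
    dm <- dim(a)
    a <- K %*% matrix(a, nrow = n)
    dim(a) <- dm
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Segment cells and nuclei
#'
#' Nuclei are obtained by Otsu thresholding of the maximum projection of the
#' nuclear channel, split by watershed on the distance transform. Cells are
#' grown from the nucleus seeds by seeded watershed (Voronoi-like propagation)
#' into the above-background region of the probe channel, so every nucleus
#' lies inside exactly one cell. Cells touching the image border are excluded,
#' as are nuclei smaller than `min_size` pixels.
#'
#' @param stack An [smfish_stack()].
#' @param min_size Minimum nucleus area in pixels (default 30).
#' @param tolerance Watershed tolerance for splitting touching nuclei.
#' @return List (`smfish_masks`) with integer label matrices `cells` and
#'   `nuclei` in (y, x) orientation.
#' @export
segment_cells <- function(stack, min_size = 30L, tolerance = 1) {
  proj_n <- apply(stack$dapi, c(2L, 3L), max)
  proj_r <- apply(stack$rna, c(2L, 3L), max)
  zero <- matrix(0L, nrow(proj_n), ncol(proj_n))
  if (diff(range(proj_n)) == 0) {
    return(structure(list(cells = zero, nuclei = zero),
                     class = "smfish_masks"))
  }
  sc <- function(m) (m - min(m)) / diff(range(m))
  nimg <- EBImage::Image(sc(proj_n))
  nmask <- nimg > EBImage::otsu(nimg)
  nlab <- EBImage::watershed(EBImage::distmap(nmask), tolerance = tolerance)
  nlab <- as.matrix(EBImage::imageData(nlab))
  # drop undersized nuclei
  sizes <- table(nlab[nlab > 0])
  drop <- as.integer(names(sizes)[sizes < min_size])
  nlab[nlab %in% drop] <- 0L
  if (all(nlab == 0L)) {
    return(structure(list(cells = zero, nuclei = zero),
                     class = "smfish_masks"))
  }
  # smooth the probe projection so isolated bright spots do not dominate the
  # threshold between cell body and background
  proj_s <- gauss_blur3(array(proj_r, c(1L, dim(proj_r))), c(0, 4, 4))[1L, , ]
  rimg <- EBImage::Image(sc(proj_s))
  cmask <- rimg > EBImage::otsu(rimg)
  cmask <- EBImage::fillHull(cmask | (nlab > 0))
  cells <- EBImage::propagate(rimg, seeds = EBImage::Image(nlab), mask = cmask)
  cells <- as.matrix(EBImage::imageData(cells))
  border <- unique(c(cells[1, ], cells[nrow(cells), ],
                     cells[, 1], cells[, ncol(cells)]))
  border <- border[border > 0]
  cells[cells %in% border] <- 0L
  nlab[nlab %in% border] <- 0L
  nlab[cells == 0L] <- 0L
  structure(list(cells = cells, nuclei = nlab), class = "smfish_masks")
}

# 3D Gaussian-mask localization of one candidate; returns center, intensity
# and convergence flag. `arr` is the raw volume, sigma in voxel units.
gaussian_mask_fit <- function(arr, z0, y0, x0, sigma, roi_half, max_iter = 50L,
                              tol = 1e-3) {
  d <- dim(arr)
  zr <- max(1L, z0 - roi_half[1]):min(d[1], z0 + roi_half[1])
  yr <- max(1L, y0 - roi_half[2]):min(d[2], y0 + roi_half[2])
  xr <- max(1L, x0 - roi_half[3]):min(d[3], x0 + roi_half[3])
  roi <- arr[zr, yr, xr, drop = FALSE]
  edge <- slice.index(roi, 1L) %in% c(1L, length(zr)) |
    slice.index(roi, 2L) %in% c(1L, length(yr)) |
    slice.index(roi, 3L) %in% c(1L, length(xr))
  bg <- stats::median(roi[edge])
  S <- roi - bg
  Z <- slice.index(roi, 1L) + zr[1L] - 1L
  Y <- slice.index(roi, 2L) + yr[1L] - 1L
  X <- slice.index(roi, 3L) + xr[1L] - 1L
  center <- c(z0, y0, x0)
  Sp <- pmax(S, 0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wz <- gauss1d_int(zr, center[1], sigma[1])
    wy <- gauss1d_int(yr, center[2], sigma[2])
    wx <- gauss1d_int(xr, center[3], sigma[3])
    w <- outer(outer(wz, wy), wx)
    tot <- sum(Sp * w)
    if (tot <= 0) break
    newc <- c(sum(Sp * w * Z), sum(Sp * w * Y), sum(Sp * w * X)) / tot
    shift <- sqrt(sum((newc - center)^2))
    center <- newc
    if (shift < tol) { converged <- TRUE; break }
  }
  wz <- gauss1d_int(zr, center[1], sigma[1])
  wy <- gauss1d_int(yr, center[2], sigma[2])
  wx <- gauss1d_int(xr, center[3], sigma[3])
  w <- outer(outer(wz, wy), wx)
  G <- w / sum(w)
  # least-squares amplitude with a free constant term, so residual flat
  # background (e.g. at cell edges) does not leak into the intensity
  M <- length(G)
  denom <- sum(G^2) - sum(G)^2 / M
  amp <- (sum(S * G) - sum(S) * sum(G) / M) / denom
  # drift from the seeding candidate in PSF (FWHM) units; the Gaussian mask
  # is a local refiner, so a fit that travels beyond ~1 PSF belongs to a
  # different maximum and is discarded by the caller
  drift <- sqrt(sum(((center - c(z0, y0, x0)) / (2.355 * sigma))^2))
  list(z = center[1], y = center[2], x = center[3],
       intensity = amp, converged = converged, drift = drift)
}

#' Detect and localize RNA spots in 3D
#'
#' Candidate spots are local maxima of a difference-of-Gaussians band-pass
#' filtered volume exceeding `k` median absolute deviations above the filtered
#' median (a per-sample threshold). Each candidate is refined by iterative 3D
#' Gaussian-mask centroid fitting after local background subtraction (the
#' background is the median of the ROI border shell), and its integrated
#' intensity is the background-subtracted signal projected on a unit-sum
#' Gaussian template at the fitted center. Duplicates within one PSF FWHM are
#' merged, keeping the brighter spot. Non-converged fits are kept and flagged.
#'
#' @param stack An [smfish_stack()].
#' @param masks An `smfish_masks` from [segment_cells()]; spots outside any
#'   retained cell are dropped.
#' @param sigma PSF standard deviation in voxels, `c(z, y, x)`; the default
#'   matches a 40x/1.4NA objective with 1.6x optovar and 0.3-um z steps.
#' @param k Detection threshold in MADs above the filtered background
#'   (default 5).
#' @param min_intensity Post-fit floor on integrated intensity in counts
#'   (default 0, i.e. rely on the `k`-MAD candidate threshold); useful to
#'   reject sub-single-RNA fits in low-noise data.
#' @param max_iter,tol Maximum Gaussian-mask iterations and convergence
#'   tolerance in voxels.
#' @return A `spot_table` data.frame: `z`, `y`, `x` (sub-voxel, 1-based voxel
#'   centers), `intensity`, `converged`, `cell`, `compartment`.
#' @export
detect_spots <- function(stack, masks, sigma = c(z = 1, y = 1.3, x = 1.3),
                         k = 5, min_intensity = 0, max_iter = 50L,
                         tol = 1e-3) {
  stopifnot(all(sigma > 0))
  arr <- stack$rna
  d <- dim(arr)
  dog <- gauss_blur3(arr, sigma) - gauss_blur3(arr, 1.6 * sigma)
  thr <- stats::median(dog) + k * stats::mad(dog)
  if (stats::mad(dog) == 0) {
    # degenerate (noiseless) input: fall back to a fraction of the strongest
    # band-pass response
    thr <- 0.1 * max(dog)
  }
  cand <- which(dog > thr, arr.ind = TRUE)
  empty <- data.frame(z = numeric(), y = numeric(), x = numeric(),
                      intensity = numeric(), converged = logical(),
                      cell = integer(), compartment = character(),
                      stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) return(empty)
  is_max <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    z <- cand[i, 1]; y <- cand[i, 2]; x <- cand[i, 3]
    nb <- dog[max(1, z - 1):min(d[1], z + 1),
              max(1, y - 1):min(d[2], y + 1),
              max(1, x - 1):min(d[3], x + 1)]
    is_max[i] <- dog[z, y, x] >= max(nb)
  }
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  roi_half <- pmax(2L, ceiling(4 * sigma))
  fits <- lapply(seq_len(nrow(cand)), function(i) {
    gaussian_mask_fit(arr, cand[i, 1], cand[i, 2], cand[i, 3], sigma,
                      roi_half, max_iter = max_iter, tol = tol)
  })
  sp <- do.call(rbind, lapply(fits, function(f) {
    data.frame(z = f$z, y = f$y, x = f$x, intensity = f$intensity,
               converged = f$converged, drift = f$drift,
               stringsAsFactors = FALSE)
  }))
  sp <- sp[sp$drift <= 1, , drop = FALSE]
  sp$drift <- NULL
  if (any(!sp$converged)) {
    warning(sum(!sp$converged), " spot fit(s) did not converge; kept flagged")
  }
  sp <- sp[sp$intensity > max(0, min_intensity), , drop = FALSE]
  # merge duplicates within one PSF FWHM (2.355 sigma), keep the brighter
  fwhm <- 2.355 * sigma
  sp <- sp[order(-sp$intensity), , drop = FALSE]
  keep <- rep(TRUE, nrow(sp))
  for (i in seq_len(nrow(sp))) {
    if (!keep[i]) next
    if (i < nrow(sp)) {
      j <- (i + 1L):nrow(sp)
      dd <- sqrt(((sp$z[j] - sp$z[i]) / fwhm[1])^2 +
                   ((sp$y[j] - sp$y[i]) / fwhm[2])^2 +
                   ((sp$x[j] - sp$x[i]) / fwhm[3])^2)
      keep[j[dd < 1]] <- FALSE
    }
  }
  sp <- sp[keep, , drop = FALSE]
  yi <- pmin(pmax(round(sp$y), 1L), nrow(masks$cells))
  xi <- pmin(pmax(round(sp$x), 1L), ncol(masks$cells))
  sp$cell <- masks$cells[cbind(yi, xi)]
  sp$compartment <- ifelse(masks$nuclei[cbind(yi, xi)] > 0, "nuclear",
                           "cytoplasmic")
  sp <- sp[sp$cell > 0, , drop = FALSE]
  rownames(sp) <- NULL
  class(sp) <- c("spot_table", "data.frame")
  sp
}

#' Convert spot intensities to single-RNA equivalents
#'
#' The calibration divisor is the median integrated intensity of cytoplasmic
#' spots pooled across all cells of the sample (cytoplasmic spots are almost
#' all single mRNAs); every spot's `rna_equivalents` is its intensity divided
#' by this divisor, making the measure invariant to overall image scaling.
#'
#' @param spots A `spot_table` from [detect_spots()].
#' @return The spot table with an `rna_equivalents` column.
#' @export
rna_equivalents <- function(spots) {
  cyto <- spots$intensity[spots$compartment == "cytoplasmic"]
  if (length(cyto) == 0L) {
    stop("no cytoplasmic spots: cannot calibrate single-RNA intensity")
  }
  spots$rna_equivalents <- spots$intensity / stats::median(cyto)
  spots
}

#' Per-cell mRNA counts and transcription-site classification
#'
#' Per-cell mRNA content is the sum of `rna_equivalents` over the cell's spots
#' (so a focus holding three RNAs contributes three); `mode = "count"` instead
#' counts each spot once. Nuclear foci with at least `tau_ts` RNA equivalents
#' are active transcription sites; cells are partitioned into zero / one /
#' more_than_one active TSs (cells with more than two retained in
#' more_than_one). Cells with zero detected spots never enter the table.
#'
#' @param spots A `spot_table` with `rna_equivalents`.
#' @param tau_ts TS threshold in RNA equivalents (default 2.5, inclusive).
#' @param mode "sum" (RNA equivalents, default) or "count" (spots as one).
#' @return A `cell_table` data.frame: `cell`, `n_spots`, `total_mrna`,
#'   `n_active_ts`, `ts_category`.
#' @export
classify_cells <- function(spots, tau_ts = 2.5, mode = c("sum", "count")) {
  mode <- match.arg(mode)
  stopifnot("rna_equivalents" %in% names(spots))
  cells <- sort(unique(spots$cell))
  out <- do.call(rbind, lapply(cells, function(cc) {
    s <- spots[spots$cell == cc, , drop = FALSE]
    nts <- sum(s$compartment == "nuclear" & s$rna_equivalents >= tau_ts)
    data.frame(cell = cc, n_spots = nrow(s),
               total_mrna = if (mode == "sum") sum(s$rna_equivalents)
                            else nrow(s),
               n_active_ts = nts,
               ts_category = if (nts == 0L) "zero" else
                 if (nts == 1L) "one" else "more_than_one",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Compare two smFISH samples
#'
#' mRNA-per-cell distributions are compared by a two-sided Wilcoxon rank-sum
#' test (exact for small samples without ties, otherwise the tie-corrected
#' normal approximation), and the proportions of cells with zero / one /
#' more than one active transcription site by a Pearson chi-square test on
#' the 2x3 table.
#'
#' @param cells_a,cells_b `cell_table`s from [classify_cells()].
#' @return List with `wilcox_p`, `chisq_p`, `chisq_stat` and the category
#'   `table`.
#' @export
compare_samples <- function(cells_a, cells_b) {
  stopifnot(nrow(cells_a) > 0L, nrow(cells_b) > 0L)
  # with ties the tie-corrected normal approximation is used (no exact test)
  w <- suppressWarnings(stats::wilcox.test(cells_a$total_mrna,
                                           cells_b$total_mrna))
  lev <- c("zero", "one", "more_than_one")
  tab <- rbind(a = table(factor(cells_a$ts_category, levels = lev)),
               b = table(factor(cells_b$ts_category, levels = lev)))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  x2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(wilcox_p = w$p.value, chisq_p = x2$p.value,
       chisq_stat = unname(x2$statistic), table = tab)
}
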