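#' Generate a random toy chromosome
#'
#' Uniform ACGT sequence; a 4-base recognition site then occurs about every
#' 256 bp, matching the genome-wide density of DpnII sites.
#'
#' @param length Chromosome length in bp (default 2e6).
#' @param name Chromosome name.
#' @param seed RNG seed.
#' @return Named character vector of length one.
#' @export
simulate_toy_genome <- function(length = 2e6, name = "chrS", seed = 1L) {
  set.seed(seed)
  stats::setNames(paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                        collapse = ""), name)
}

# Edited-axis coordinate of reference position p under a single deletion.
edited_coord <- function(p, deletion) {
  if (is.null(deletion)) return(p)
  ifelse(p < deletion[1], p,
         ifelse(p >= deletion[2], p - diff(deletion), NA_real_))
}

#' Expected 4C signal for one library
#'
#' The expected fragend count is a power-law distance decay from the bait,
#' `lambda(d) = (d + d0)^(-alpha)`, scaled to the library depth, plus planted
#' interaction peaks: Gaussian profiles whose amplitude is `fold - 1` times
#' the local background at the peak center, attenuated by a factor `f` on
#' designated alleles. Peaks contribute extra (loop-mediated) ligation events
#' on top of the polymer background; an optional TAD-leak factor multiplies
#' the background over a designated region. A deletion shortens the allele's
#' coordinate map, so distances are measured on the edited axis and sequence
#' downstream of the deletion becomes bait-proximal (the "contiguous with the
#' bait" artifact); fragends inside the deletion have expectation zero.
#'
#' @param fragends A `fragend_map` (single chromosome).
#' @param bait_pos Bait coordinate (reference axis).
#' @param depth Expected cis reads in the background component (default 1e5).
#' @param alpha,d0 Decay exponent (default 1) and offset in bp (default 2000).
#' @param peaks data.frame with `center`, `width` (bp), `fold` (peak-to-local-
#'   background enrichment at center), `f` (attenuation in (0, 1], default 1);
#'   may be NULL.
#' @param deletion Optional `c(start, end)` deletion on this allele.
#' @param tad_leak Optional `list(region = c(start, end), factor = ...)`
#'   multiplying the background inside the region.
#' @return Numeric vector of expected counts per fragend.
#' @export
expected_4c <- function(fragends, bait_pos, depth = 1e5, alpha = 1,
                        d0 = 2000, peaks = NULL, deletion = NULL,
                        tad_leak = NULL) {
  stopifnot(alpha > 0, d0 > 0, depth > 0)
  pos <- fragends$anchor_pos
  epos <- edited_coord(pos, deletion)
  ebait <- edited_coord(bait_pos, deletion)
  d <- abs(epos - ebait)
  lam <- (d + d0)^(-alpha)
  lam[is.na(lam)] <- 0  # fragends inside the deletion
  leak <- rep(1, length(pos))
  if (!is.null(tad_leak)) {
    inreg <- pos >= tad_leak$region[1] & pos < tad_leak$region[2]
    leak[inreg] <- tad_leak$factor
  }
  mu <- depth * lam * leak / sum(lam * leak)
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    for (j in seq_len(nrow(peaks))) {
      f <- if ("f" %in% names(peaks)) peaks$f[j] else 1
      stopifnot(f > 0, f <= 1)
      sig <- peaks$width[j] / 2
      ec <- edited_coord(peaks$center[j], deletion)
      local_bg <- depth * (abs(ec - ebait) + d0)^(-alpha) /
        sum(lam * leak)
      mu <- mu + (lam > 0) * f * (peaks$fold[j] - 1) * local_bg *
        exp(-(pos - peaks$center[j])^2 / (2 * sig^2))
    }
  }
  mu
}

#' Simulate one 4C library in fragment space
#'
#' Draws negative-binomial counts around the [expected_4c()] profile.
#'
#' @inheritParams expected_4c
#' @param phi NB dispersion (`size` parameter; default 10).
#' @param seed Optional RNG seed.
#' @return Integer vector of counts per fragend.
#' @export
simulate_4c_counts <- function(fragends, bait_pos, depth = 1e5, alpha = 1,
                               d0 = 2000, phi = 10, peaks = NULL,
                               deletion = NULL, tad_leak = NULL, seed = NULL) {
  stopifnot(phi > 0)
  if (!is.null(seed)) set.seed(seed)
  mu <- expected_4c(fragends, bait_pos, depth = depth, alpha = alpha, d0 = d0,
                    peaks = peaks, deletion = deletion, tad_leak = tad_leak)
  as.integer(stats::rnbinom(length(mu), mu = mu, size = phi))
}

#' Emit reads realizing a fragend count vector
#'
#' Each fragend contributes `counts[i]` copies of its capture sequence
#' (truncated to `L`), shuffled; with unique capture sequences these reads
#' round-trip through [assign_reads()] to exactly the generating counts.
#'
#' @param counts Integer counts per fragend.
#' @param fragends The `fragend_map`.
#' @param L Read length (defaults to the map's capture length).
#' @param seed Optional RNG seed for the shuffle.
#' @return Character vector of reads.
#' @export
simulate_4c_reads <- function(counts, fragends, L = attr(fragends, "L"),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reads <- rep(substr(fragends$capture_seq, 1L, L), counts)
  sample(reads)
}

#' Design of the synthetic Sox2-locus study
#'
#' Builds a toy 2-Mb chromosome with DpnII/Csp6I fragend maps and the locus
#' geometry of the allele-specific dissection, mirrored at reduced scale: a
#' near-SCR bait, a strong interaction peak at the "Sox2" position 100 kb
#' upstream, an SCR-like deletion just downstream of the bait, and 325-kb
#' upstream/downstream TAD regions. The condition table mirrors the study
#' design: wild type (n = 4), homozygous deletion (n = 4), and the wild-type
#' (n = 3) and deletion (n = 4) alleles of a heterozygote. The deletion
#' conditions attenuate the planted Sox2-peak enrichment (factors 0.72
#' homozygous, 0.76 heterozygous deletion allele) and leak contacts into the
#' downstream TAD (factor 1.5).
#'
#' @param seed RNG seed for the toy genome.
#' @param genome_length Toy chromosome length (default 2e6).
#' @param L Capture length for fragends (default 36).
#' @return A `locus_design` list: `genome`, `fragmap`, `fragends`, `bait_pos`,
#'   `config` (a [locus_config()]), `deletion`, `peaks`, `conditions`
#'   (data.frame with per-condition attenuation, deletion and leak),
#'   `libraries` (one row per library).
#' @export
sox2_locus_design <- function(seed = 1L, genome_length = 2e6, L = 36L) {
  genome <- simulate_toy_genome(genome_length, "chrS", seed = seed)
  fragmap <- digest_genome(genome, known_enzymes("DpnII"))
  fragends <- build_fragends(fragmap, genome, known_enzymes("Csp6I"), L = L)
  bait_pos <- 1e6
  peak <- data.frame(center = 9e5, width = 1e4, fold = 15)
  deletion <- c(1004000, 1011300)  # 7.3-kb SCR-like deletion near the bait
  regions <- data.frame(
    region = c("sox2_region", "downstream_tad", "upstream_tad"),
    chrom = "chrS",
    start = c(peak$center - peak$width / 2, 1040000, 555000),
    end = c(peak$center + peak$width / 2, 1365000, 880000),
    stringsAsFactors = FALSE)
  config <- locus_config(regions, "chrS", bait_pos, cis_window = 1e6)
  conditions <- data.frame(
    condition = c("WT", "dSCR_hom", "het_WT_allele", "het_dSCR_allele"),
    allele = c("both", "both", "129", "CAST"),
    n = c(4L, 4L, 3L, 4L),
    f = c(1, 0.72, 1, 0.76),
    deleted = c(FALSE, TRUE, FALSE, TRUE),
    leak = c(1, 1.5, 1, 1.5),
    stringsAsFactors = FALSE)
  libraries <- do.call(rbind, lapply(seq_len(nrow(conditions)), function(i) {
    data.frame(sample_id = paste0(conditions$condition[i], "_r",
                                  seq_len(conditions$n[i])),
               condition = conditions$condition[i],
               allele = conditions$allele[i],
               replicate = seq_len(conditions$n[i]),
               stringsAsFactors = FALSE)
  }))
  structure(list(genome = genome, fragmap = fragmap, fragends = fragends,
                 bait_pos = bait_pos, config = config, deletion = deletion,
                 peaks = peak, conditions = conditions, libraries = libraries),
            class = "locus_design")
}

#' Draw the count matrix for a synthetic locus study
#'
#' @param design A `locus_design` from [sox2_locus_design()].
#' @param seed RNG seed for the count draws.
#' @param depth,phi Library depth and NB dispersion (defaults 1e5 and 10).
#' @return Integer matrix, fragends x libraries, with library sample_ids as
#'   column names.
#' @export
simulate_sox2_counts <- function(design, seed = 1L, depth = 1e5, phi = 10) {
  set.seed(seed)
  libs <- design$libraries
  cond <- design$conditions[match(libs$condition,
                                  design$conditions$condition), ]
  counts <- vapply(seq_len(nrow(libs)), function(i) {
    pk <- design$peaks
    pk$f <- cond$f[i]
    tl <- if (cond$leak[i] != 1) {
      dn <- design$config$regions[design$config$regions$region ==
                                    "downstream_tad", ]
      list(region = c(dn$start, dn$end), factor = cond$leak[i])
    } else NULL
    simulate_4c_counts(design$fragends, design$bait_pos, depth = depth,
                       phi = phi, peaks = pk,
                       deletion = if (cond$deleted[i]) design$deletion else
                         NULL,
                       tad_leak = tl)
  }, integer(nrow(design$fragends)))
  colnames(counts) <- libs$sample_id
  counts
}

#' Ready-to-run synthetic Sox2-locus workspace
#'
#' Convenience wrapper producing the design plus a count matrix and the shared
#' deletion mask, everything needed to exercise normalization, calling and
#' scoring end to end.
#'
#' @param seed RNG seed (drives both the toy genome and the counts).
#' @param ... Passed to [simulate_sox2_counts()].
#' @return List: the `locus_design` fields plus `counts` and `mask`.
#' @export
simulate_sox2_locus <- function(seed = 1L, ...) {
  design <- sox2_locus_design(seed = seed)
  counts <- simulate_sox2_counts(design, seed = seed, ...)
  mask <- build_deletion_mask(design$fragends, design$deletion,
                              flank_frags = 2L)
  c(unclass(design), list(counts = counts, mask = mask))
}

#' Simulate an smFISH image stack with ground truth
#'
#' Places non-overlapping cells (disk-shaped cytoplasm with an interior
#' nucleus), scatters single mRNAs in the cytoplasm (Poisson count per cell)
#' and, per allele, an active transcription site inside the nucleus with
#' probability `burst_prob` carrying a Gamma-distributed nascent-RNA load.
#' Spots are rendered as voxel-integrated 3D Gaussians at sub-voxel positions;
#' camera noise is Poisson shot noise plus Gaussian read noise.
#'
#' @param n_cells Number of cells (default 6).
#' @param dims Stack dimensions `c(z, y, x)` (default 45 x 192 x 192; a
#'   45-plane stack at 0.3-um steps).
#' @param mu_mrna Mean cytoplasmic mRNA count per cell (default 50).
#' @param i1 Mean integrated intensity of a single RNA (default 2000 counts).
#' @param i1_cv Coefficient of variation of single-RNA intensity (default
#'   0.25).
#' @param burst_prob Per-allele probability of an active TS (default 0.3).
#' @param ts_load_mean,ts_load_shape Gamma nascent-load mean (default 6 RNAs)
#'   and shape (default 2).
#' @param sigma PSF standard deviation in voxels `c(z, y, x)`.
#' @param r_cell,r_nuc Cell and nucleus radii in pixels (defaults 20 and 11).
#' @param bg_cell Cytoplasmic baseline intensity (default 25 counts).
#' @param dapi_level Nuclear-stain plateau (default 200 counts).
#' @param read_noise Gaussian read noise SD (default 5 counts).
#' @param noise Apply shot + read noise (default TRUE; FALSE gives the
#'   noiseless expectation image).
#' @param seed RNG seed.
#' @return List with `stack` (an [smfish_stack()]), `spots` (truth table:
#'   `cell`, `type`, `z`, `y`, `x`, `intensity`), and `cells` (truth table:
#'   `cell`, `yc`, `xc`, `n_cyto`, `n_ts`, `ts_category` under the 2.5-RNA
#'   rule on true loads).
#' @export
simulate_smfish <- function(n_cells = 6L, dims = c(z = 45L, y = 192L,
                                                   x = 192L),
                            mu_mrna = 50, i1 = 2000, i1_cv = 0.25,
                            burst_prob = 0.3, ts_load_mean = 6,
                            ts_load_shape = 2, sigma = c(z = 1, y = 1.3,
                                                         x = 1.3),
                            r_cell = 20, r_nuc = 11, bg_cell = 25,
                            dapi_level = 200, read_noise = 5, noise = TRUE,
                            seed = 1L) {
  stopifnot(n_cells >= 1L, mu_mrna > 0, i1 > 0, i1_cv >= 0,
            burst_prob >= 0, burst_prob <= 1, ts_load_mean > 0,
            ts_load_shape > 0, all(sigma > 0))
  set.seed(seed)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  zc <- (nz + 1) / 2
  slab <- max(3, floor(nz / 2) - 3)  # cytoplasm z half-extent
  # non-overlapping cell centers on a jittered grid, away from the border
  margin <- r_cell + 12
  spacing <- 2 * r_cell + 8
  gy <- seq(margin, ny - margin, by = spacing)
  gx <- seq(margin, nx - margin, by = spacing)
  grid <- expand.grid(yc = gy, xc = gx)
  if (nrow(grid) < n_cells) stop("field too small for ", n_cells, " cells")
  grid <- grid[sample(nrow(grid), n_cells), , drop = FALSE]
  grid$yc <- grid$yc + stats::runif(n_cells, -3, 3)
  grid$xc <- grid$xc + stats::runif(n_cells, -3, 3)

  dapi <- array(0, c(nz, ny, nx))
  rna <- array(0, c(nz, ny, nx))
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  zslab <- seq(max(1, round(zc - slab)), min(nz, round(zc + slab)))
  cellbody <- matrix(0, ny, nx)  # smooth-edged cytoplasmic autofluorescence
  spots <- list(); cells <- list()
  for (cc in seq_len(n_cells)) {
    yc <- grid$yc[cc]; xc <- grid$xc[cc]
    r2 <- (yy - yc)^2 + (xx - xc)^2
    cellpix <- which(r2 <= r_cell^2)
    nucpix <- which(r2 <= r_nuc^2)
    cellbody[cellpix] <- bg_cell
    for (z in zslab) {
      dl <- dapi[z, , ]; dl[nucpix] <- dapi_level; dapi[z, , ] <- dl
    }
    n_cyto <- stats::rpois(1, mu_mrna)
    # uniform over the cytoplasmic annulus
    rad <- sqrt(stats::runif(n_cyto, (r_nuc + 2)^2, (r_cell - 2)^2))
    th <- stats::runif(n_cyto, 0, 2 * pi)
    cyto <- data.frame(
      cell = cc, type = "cyto",
      z = stats::runif(n_cyto, zc - slab + 2, zc + slab - 2),
      y = yc + rad * sin(th), x = xc + rad * cos(th),
      intensity = i1 * exp(stats::rnorm(n_cyto, 0, i1_cv)) /
        exp(i1_cv^2 / 2),
      stringsAsFactors = FALSE)
    burst <- stats::runif(2) < burst_prob
    loads <- stats::rgamma(sum(burst), shape = ts_load_shape,
                           scale = ts_load_mean / ts_load_shape)
    ts <- if (sum(burst) > 0) {
      radn <- sqrt(stats::runif(sum(burst), 0, (r_nuc - 2)^2))
      thn <- stats::runif(sum(burst), 0, 2 * pi)
      data.frame(cell = cc, type = "ts",
                 z = stats::runif(sum(burst), zc - 3, zc + 3),
                 y = yc + radn * sin(thn), x = xc + radn * cos(thn),
                 intensity = loads * i1, stringsAsFactors = FALSE)
    } else NULL
    spots[[cc]] <- rbind(cyto, ts)
    nts <- sum(loads >= 2.5)
    cells[[cc]] <- data.frame(
      cell = cc, yc = yc, xc = xc, n_cyto = n_cyto, n_ts = nts,
      ts_category = if (nts == 0) "zero" else if (nts == 1) "one" else
        "more_than_one", stringsAsFactors = FALSE)
  }
  spots <- do.call(rbind, spots)
  cells <- do.call(rbind, cells)
  # cell bodies with smooth edges laterally (3 px) and axially (1.5 planes)
  cellbody <- gauss_blur3(array(cellbody, c(1L, ny, nx)),
                          c(0, 3, 3))[1L, , ]
  zprof <- rep(0, nz); zprof[zslab] <- 1
  zprof <- as.vector(gauss_blur3(array(zprof, c(nz, 1L, 1L)), c(2.5, 0, 0)))
  rna <- rna + outer(zprof, cellbody)
  # render spots as voxel-integrated 3D Gaussians
  h <- pmax(2L, ceiling(4 * sigma))
  for (i in seq_len(nrow(spots))) {
    zr <- max(1, round(spots$z[i]) - h[1]):min(nz, round(spots$z[i]) + h[1])
    yr <- max(1, round(spots$y[i]) - h[2]):min(ny, round(spots$y[i]) + h[2])
    xr <- max(1, round(spots$x[i]) - h[3]):min(nx, round(spots$x[i]) + h[3])
    w <- outer(outer(gauss1d_int(zr, spots$z[i], sigma[1]),
                     gauss1d_int(yr, spots$y[i], sigma[2])),
               gauss1d_int(xr, spots$x[i], sigma[3]))
    rna[zr, yr, xr] <- rna[zr, yr, xr] + spots$intensity[i] * w
  }
  if (noise) {
    rna <- array(stats::rpois(length(rna), pmax(rna, 0)), dim(rna)) +
      array(stats::rnorm(length(rna), 0, read_noise), dim(rna))
    dapi <- array(stats::rpois(length(dapi), pmax(dapi, 0)), dim(dapi)) +
      array(stats::rnorm(length(dapi), 0, read_noise), dim(dapi))
  }
  rownames(spots) <- NULL
  list(stack = smfish_stack(dapi, rna), spots = spots, cells = cells)
}
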