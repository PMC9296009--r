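# Full-field masks for detection tests that bypass segmentation.
whole_field_masks <- function(ny, nx, nucleus = FALSE) {
  structure(list(cells = matrix(1L, ny, nx),
                 nuclei = matrix(if (nucleus) 1L else 0L, ny, nx)),
            class = "smfish_masks")
}

render_spot <- function(dims, z, y, x, intensity,
                        sigma = c(1, 1.3, 1.3)) {
  arr <- array(0, dims)
  zr <- 1:dims[1]; yr <- 1:dims[2]; xr <- 1:dims[3]
  w <- outer(outer(loop4c:::gauss1d_int(zr, z, sigma[1]),
                   loop4c:::gauss1d_int(yr, y, sigma[2])),
             loop4c:::gauss1d_int(xr, x, sigma[3]))
  arr + intensity * w
}

test_that("segmentation separates well-isolated and touching nuclei", {
  sim <- simulate_smfish(n_cells = 2, dims = c(z = 12, y = 96, x = 96),
                         mu_mrna = 15, r_cell = 14, r_nuc = 8, seed = 2)
  masks <- segment_cells(sim$stack)
  expect_equal(length(setdiff(unique(as.vector(masks$nuclei)), 0L)), 2L)
  expect_equal(length(setdiff(unique(as.vector(masks$cells)), 0L)), 2L)
  # every nucleus pixel lies inside the same-label cell
  nz <- masks$nuclei > 0
  expect_true(all(masks$cells[nz] == masks$nuclei[nz]))

  # two touching blobs with a neck are split by the watershed
  ny <- 64; nx <- 64
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  blob <- 200 * (((yy - 32)^2 + (xx - 24)^2 <= 81) |
                   ((yy - 32)^2 + (xx - 41)^2 <= 81))
  dapi <- array(0, c(1, ny, nx)); dapi[1, , ] <- blob
  rna <- array(0, c(1, ny, nx)); rna[1, , ] <- 30 * (blob > 0)
  m2 <- segment_cells(smfish_stack(dapi, rna), min_size = 10)
  expect_equal(length(setdiff(unique(as.vector(m2$nuclei)), 0L)), 2L)

  # a uniform image has nothing to segment
  flat <- array(1, c(2, 32, 32))
  m0 <- segment_cells(smfish_stack(flat, flat))
  expect_equal(sum(m0$cells), 0)
})

test_that("noiseless spots are localized to sub-voxel accuracy", {
  dims <- c(21, 96, 96)
  truth <- c(z = 10.0, y = 50.3, x = 40.7)
  arr <- render_spot(dims, truth[1], truth[2], truth[3], 2000)
  stack <- smfish_stack(array(0, dims), arr)
  sp <- detect_spots(stack, whole_field_masks(96, 96))
  expect_equal(nrow(sp), 1L)
  expect_lt(abs(sp$z - truth["z"]), 0.05)
  expect_lt(abs(sp$y - truth["y"]), 0.05)
  expect_lt(abs(sp$x - truth["x"]), 0.05)
  expect_equal(sp$intensity, 2000, tolerance = 0.02)

  # two spots five PSF widths apart are resolved with intact intensities
  arr2 <- render_spot(dims, 10, 30, 30, 1500) +
    render_spot(dims, 10, 30 + 5 * 2.355 * 1.3, 30, 3000)
  sp2 <- detect_spots(smfish_stack(array(0, dims), arr2),
                      whole_field_masks(96, 96))
  sp2 <- sp2[order(sp2$y), ]
  expect_equal(nrow(sp2), 2L)
  expect_equal(sp2$intensity, c(1500, 3000), tolerance = 0.02)

  # an empty volume yields no records
  empty <- detect_spots(smfish_stack(array(0, dims), array(0, dims)),
                        whole_field_masks(96, 96))
  expect_equal(nrow(empty), 0L)
})

test_that("RNA equivalents are calibrated on the cytoplasmic median", {
  sp <- data.frame(z = 1, y = 1, x = 1,
                   intensity = c(90, 100, 110, 260), converged = TRUE,
                   cell = 1L,
                   compartment = c(rep("cytoplasmic", 3), "nuclear"),
                   stringsAsFactors = FALSE)
  out <- rna_equivalents(sp)
  expect_equal(out$rna_equivalents, c(0.9, 1.0, 1.1, 2.6))
  # the median cytoplasmic spot is exactly one RNA
  expect_equal(stats::median(out$rna_equivalents[out$compartment ==
                                                   "cytoplasmic"]), 1)
  # single cytoplasmic spot calibrates itself
  one <- rna_equivalents(sp[2, ])
  expect_equal(one$rna_equivalents, 1)
  # scaling the image leaves equivalents unchanged
  sc <- sp; sc$intensity <- sc$intensity * 7.3
  expect_equal(rna_equivalents(sc)$rna_equivalents, out$rna_equivalents)

  expect_error(rna_equivalents(sp[4, ]), "cytoplasmic")
})

test_that("transcription-site classification applies the inclusive threshold", {
  sp <- data.frame(z = 1, y = 1, x = 1, intensity = 1, converged = TRUE,
                   cell = c(1, 1, 1, 2),
                   compartment = c("nuclear", "nuclear", "nuclear", "nuclear"),
                   rna_equivalents = c(3.1, 2.5, 1.2, 2.49),
                   stringsAsFactors = FALSE)
  cells <- classify_cells(sp)
  expect_equal(cells$n_active_ts[cells$cell == 1], 2L)  # 2.5 is inclusive
  expect_equal(cells$ts_category[cells$cell == 1], "more_than_one")
  expect_equal(cells$n_active_ts[cells$cell == 2], 0L)
  expect_equal(cells$ts_category[cells$cell == 2], "zero")
  # only cells with detected spots appear
  expect_equal(sort(cells$cell), c(1, 2))
  # total mRNA sums equivalents; count mode counts spots
  expect_equal(cells$total_mrna[cells$cell == 1], 3.1 + 2.5 + 1.2)
  expect_equal(classify_cells(sp, mode = "count")$total_mrna[1], 3)
})

test_that("classification agrees with brute-force reclassification", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 60
    sp <- data.frame(z = 1, y = 1, x = 1, intensity = 1, converged = TRUE,
                     cell = sample(1:8, n, replace = TRUE),
                     compartment = sample(c("nuclear", "cytoplasmic"), n,
                                          replace = TRUE),
                     rna_equivalents = round(rexp(n, 1 / 2), 2),
                     stringsAsFactors = FALSE)
    got <- classify_cells(sp)
    want <- classify_brute_force(sp)
    expect_equal(as.data.frame(got), want)
  }
})

test_that("sample comparison uses exact Wilcoxon and Pearson chi-square", {
  mk <- function(mrna, cat) data.frame(cell = seq_along(mrna), n_spots = 1,
                                       total_mrna = mrna, n_active_ts = 0,
                                       ts_category = cat,
                                       stringsAsFactors = FALSE)
  res <- compare_samples(mk(c(1, 2), c("zero", "zero")),
                         mk(c(3, 4), c("zero", "zero")))
  expect_equal(res$wilcox_p, 1 / 3)

  same <- mk(c(1, 2, 3), c("zero", "one", "one"))
  expect_gt(compare_samples(same, same)$wilcox_p, 0.99)

  a <- mk(rnorm(100, 10), rep(c("zero", "one", "more_than_one"),
                              c(50, 30, 20)))
  res2 <- compare_samples(a, a)
  expect_equal(res2$chisq_stat, 0)
  expect_equal(res2$chisq_p, 1)

  # pooling technical replicates before testing equals testing concatenation
  r1 <- mk(c(5, 6, 7), rep("one", 3)); r2 <- mk(c(8, 9), rep("one", 2))
  pooled <- rbind(r1, r2)
  other <- mk(c(5, 6, 7, 8, 9), rep("one", 5))
  expect_equal(compare_samples(pooled, other)$wilcox_p,
               compare_samples(rbind(r2, r1), other)$wilcox_p)
})
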