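test_that("4C simulation is seed-reproducible and seed-sensitive", {
  design <- sox2_locus_design(seed = 1, genome_length = 3e5)
  c1 <- simulate_sox2_counts(design, seed = 5, depth = 2e4)
  c2 <- simulate_sox2_counts(design, seed = 5, depth = 2e4)
  c3 <- simulate_sox2_counts(design, seed = 6, depth = 2e4)
  expect_identical(c1, c2)
  expect_false(identical(c1, c3))
})

test_that("empirical means track the decay law in the Poisson limit", {
  fe <- regular_fragends(2000, spacing = 500)
  bait <- 5e5
  mu <- expected_4c(fe, bait, depth = 1e6, alpha = 1, d0 = 2000)
  set.seed(8)
  counts <- simulate_4c_counts(fe, bait, depth = 1e6, phi = 1e6)
  # distance deciles: empirical mean / expected within 2 percent
  d <- abs(fe$anchor_pos - bait)
  bin <- cut(rank(d, ties.method = "first"), 10)
  ratio <- tapply(counts, bin, sum) / tapply(mu, bin, sum)
  expect_true(all(abs(ratio - 1) < 0.02))
})

test_that("deletion alleles bring downstream fragends closer to the bait", {
  fe <- regular_fragends(100, spacing = 1000)
  bait <- 10000
  del <- c(20000, 30000)
  mu_ref <- expected_4c(fe, bait, depth = 1e4)
  mu_del <- expected_4c(fe, bait, depth = 1e4, deletion = del)
  inside <- fe$anchor_pos >= del[1] & fe$anchor_pos < del[2]
  expect_true(all(mu_del[inside] == 0))
  # first fragend beyond the deletion now sits where the deletion started
  j <- which(fe$anchor_pos >= del[2])[1]
  near <- which.min(abs(fe$anchor_pos - bait))
  expect_gt(mu_del[j] / sum(mu_del), mu_ref[j] / sum(mu_ref))
})

test_that("the locus fixture mirrors the study design and runs end to end", {
  ws <- simulate_sox2_locus(seed = 3, depth = 3e4)
  reps <- table(ws$libraries$condition)
  expect_equal(as.integer(reps[c("WT", "dSCR_hom", "het_WT_allele",
                                 "het_dSCR_allele")]), c(4L, 4L, 3L, 4L))
  expect_equal(ncol(ws$counts), nrow(ws$libraries))
  res <- score_4c_experiment(ws$counts, ws$fragends, ws$libraries, ws$config,
                             mask = ws$mask)
  expect_true(all(c("sox2_region", "downstream_tad", "upstream_tad") %in%
                    res$scores$region))
  expect_equal(nrow(res$comparisons), 3 * 3)  # 3 regions x 3 non-WT conditions
  # different seeds: different counts, identical configuration
  ws2 <- simulate_sox2_locus(seed = 4, depth = 3e4)
  expect_false(identical(ws$counts, ws2$counts))
  expect_identical(ws$config$regions, ws2$config$regions)
  expect_identical(ws$libraries, ws2$libraries)
})

test_that("null construction: identical attenuation gives exchangeable groups", {
  design <- sox2_locus_design(seed = 2, genome_length = 4e5)
  design$bait_pos <- 2e5
  design$peaks$center <- 1.2e5
  region <- c(design$peaks$center - design$peaks$width / 2,
              design$peaks$center + design$peaks$width / 2)
  set.seed(12)
  p <- replicate(40, {
    mat <- vapply(1:8, function(i) {
      pk <- design$peaks; pk$f <- 1
      simulate_4c_counts(design$fragends, design$bait_pos, depth = 2e4,
                         peaks = pk)
    }, integer(nrow(design$fragends)))
    qn <- quantile_normalize(mat)
    sc <- apply(qn, 2, interaction_score, fragends = design$fragends,
                region = region)
    compare_conditions(sc[1:4], sc[5:8])$p
  })
  expect_lt(mean(p < 0.05), 0.2)
  expect_gt(min(p), 1e-4)
})

test_that("smFISH simulation round-trips through detection when noiseless", {
  sim <- simulate_smfish(n_cells = 1, dims = c(z = 21, y = 96, x = 96),
                         mu_mrna = 8, burst_prob = 0, noise = FALSE,
                         r_cell = 22, r_nuc = 10, seed = 55)
  masks <- segment_cells(sim$stack)
  sp <- detect_spots(sim$stack, masks, min_intensity = 1000)
  expect_equal(nrow(sp), nrow(sim$spots))
  # every planted spot matched within one voxel
  for (i in seq_len(nrow(sim$spots))) {
    dd <- sqrt((sp$z - sim$spots$z[i])^2 + (sp$y - sim$spots$y[i])^2 +
                 (sp$x - sim$spots$x[i])^2)
    expect_lt(min(dd), 1)
  }
})

test_that("burst probability zero yields only inactive cells", {
  sim <- simulate_smfish(n_cells = 4, dims = c(z = 13, y = 120, x = 120),
                         mu_mrna = 8, burst_prob = 0, r_cell = 14, r_nuc = 8,
                         seed = 9)
  expect_true(all(sim$cells$ts_category == "zero"))
  expect_true(all(sim$spots$type == "cyto"))
})

test_that("doubling single-RNA intensity leaves RNA equivalents unchanged", {
  args <- list(n_cells = 2, dims = c(z = 21, y = 128, x = 128), mu_mrna = 12,
               burst_prob = 0.8, noise = FALSE, r_cell = 18, r_nuc = 9,
               seed = 18)
  s1 <- do.call(simulate_smfish, c(args, i1 = 2000))
  s2 <- do.call(simulate_smfish, c(args, i1 = 4000))
  expect_equal(s2$spots$intensity, 2 * s1$spots$intensity)
  # calibration invariance of the analysis: a doubled image gives identical
  # RNA-equivalents, mRNA totals and TS calls
  doubled <- smfish_stack(2 * s1$stack$dapi, 2 * s1$stack$rna)
  run <- function(stack, floor) {
    masks <- segment_cells(stack)
    sp <- suppressWarnings(detect_spots(stack, masks, min_intensity = floor))
    classify_cells(rna_equivalents(sp))
  }
  c1 <- run(s1$stack, 1000); c2 <- run(doubled, 2000)
  expect_equal(c1$ts_category, c2$ts_category)
  expect_equal(c1$total_mrna, c2$total_mrna, tolerance = 1e-8)
})
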