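# Small fragend scaffolds around a bait at one end, so all fragends sit on
# one side ordered by distance.
one_sided <- function(n, spacing = 100) {
  fe <- regular_fragends(n, spacing = spacing)
  fe$anchor_pos <- fe$anchor_pos + spacing  # bait at 0, distances > 0
  fe$start <- fe$anchor_pos
  fe$end <- fe$anchor_pos + spacing
  fe
}

test_that("background fit is the least-squares non-increasing curve", {
  fe <- one_sided(3)
  bg <- fit_background(c(5, 3, 4), fe, bait_pos = 0, exclusion_frags = 0)
  expect_equal(bg$expected, c(5, 3.5, 3.5))
  # already non-increasing values are a fixed point
  bg2 <- fit_background(c(9, 7, 7, 2), one_sided(4), 0, exclusion_frags = 0)
  expect_equal(bg2$expected, c(9, 7, 7, 2))
  # all-zero side: flat zero with warning
  expect_warning(bg0 <- fit_background(rep(0, 5), one_sided(5), 0,
                                       exclusion_frags = 0), "all-zero")
  expect_equal(bg0$expected, rep(0, 5))
})

test_that("fit matches the brute-force monotone oracle on small instances", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    y <- round(runif(n, 0, 10), 2)
    fe <- one_sided(n)
    bg <- fit_background(y, fe, 0, exclusion_frags = 0)
    oracle <- iso_decreasing_oracle(y)
    expect_equal(bg$expected, oracle, tolerance = 1e-9)
    # the fit's SSE is minimal among non-increasing candidates
    expect_lte(sum((y - bg$expected)^2), sum((y - oracle)^2) + 1e-9)
  }
})

test_that("bait-proximal fragends are excluded from the fit", {
  fe <- one_sided(20)
  v <- c(rep(100, 5), rep(2, 15))
  bg <- fit_background(v, fe, 0, exclusion_frags = 5)
  expect_true(all(is.na(bg$expected[1:5])))
  expect_equal(bg$expected[6:20], rep(2, 15))
})

test_that("a planted plateau is called over a flat background", {
  n <- 200
  fe <- one_sided(n)
  flat <- rep(10, n)
  bg <- fit_background(flat, fe, 0, exclusion_frags = 0)
  v <- flat
  plateau <- 90:114  # 25 fragends
  v[plateau] <- 30
  calls <- call_interactions(v, bg, fe, W = 21, delta = 5, rho = 1.5,
                             min_frags = 3)
  expect_equal(nrow(calls), 1L)
  # the interval covers the plateau, within smoothing-edge slack of W
  expect_lte(calls$start, fe$start[min(plateau)])
  expect_gte(calls$end, fe$end[max(plateau)])
  expect_lte(calls$n_frags, length(plateau) + 21)

  # background-only profile yields no calls
  expect_equal(nrow(call_interactions(flat, bg, fe, W = 21, delta = 5,
                                      rho = 1.5)), 0L)
})

test_that("raising delta or rho never enlarges the called set", {
  set.seed(33)
  n <- 300
  fe <- one_sided(n)
  base <- 50 * (seq_len(n) + 20)^-1 * 1000
  v <- rnbinom(n, mu = base, size = 10)
  v[140:160] <- v[140:160] + 40
  bg <- fit_background(base, fe, 0, exclusion_frags = 0)
  cover <- function(delta, rho) {
    calls <- call_interactions(v, bg, fe, W = 11, delta = delta, rho = rho,
                               min_frags = 1)
    if (nrow(calls) == 0) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(calls$start + 1, calls$end))
  }
  for (pair in list(c(1, 5), c(1.5, 1.5), c(2, 2))) {
    lo <- cover(pair[1], pair[2])
    hi_d <- cover(pair[1] * 2, pair[2])
    hi_r <- cover(pair[1], pair[2] * 1.5)
    # containment: stricter thresholds call a subset of positions
    expect_equal(sum(IRanges::width(IRanges::setdiff(hi_d, lo))), 0)
    expect_equal(sum(IRanges::width(IRanges::setdiff(hi_r, lo))), 0)
  }
})

test_that("calls are equivariant under fragend translation", {
  n <- 120
  fe <- one_sided(n)
  flat <- rep(10, n)
  v1 <- flat; v1[50:60] <- 40
  k <- 7
  v2 <- flat; v2[(50:60) + k] <- 40
  bg <- fit_background(flat, fe, 0, exclusion_frags = 0)
  c1 <- call_interactions(v1, bg, fe, W = 5, delta = 5, rho = 1.5)
  c2 <- call_interactions(v2, bg, fe, W = 5, delta = 5, rho = 1.5)
  expect_equal(c2$start, c1$start + k * 100)
  expect_equal(c2$end, c1$end + k * 100)
})

test_that("consensus is the per-position intersection across replicates", {
  mk <- function(s, e) data.frame(chrom = "chrT", start = s, end = e,
                                  n_frags = 1, mean_obs = 1, mean_exp = 1,
                                  side = "down", stringsAsFactors = FALSE)
  cons <- consensus_regions(list(mk(10, 30), mk(15, 40)))
  expect_equal(cons$start, 15)
  expect_equal(cons$end, 30)
  # any empty replicate empties the consensus
  empty <- consensus_regions(list(mk(10, 30), mk(10, 30)[0, ]))
  expect_equal(nrow(empty), 0L)
  # identical replicate calls pass through unchanged
  four <- consensus_regions(list(mk(5, 25), mk(5, 25), mk(5, 25), mk(5, 25)))
  expect_equal(four$start, 5)
  expect_equal(four$end, 25)
  expect_equal(four$n_replicates, 4L)
})

test_that("wild-type consensus recovers the planted interaction region", {
  design <- sox2_locus_design(seed = 1)
  fe <- design$fragends
  reg <- design$config$regions[design$config$regions$region == "sox2_region", ]
  hits <- 0
  for (s in 1:8) {
    set.seed(300 + s)
    mat <- vapply(1:4, function(i) {
      simulate_4c_counts(fe, design$bait_pos, depth = 1e5, phi = 10,
                         peaks = transform(design$peaks, f = 1))
    }, integer(nrow(fe)))
    qn <- quantile_normalize(mat)
    calls <- lapply(1:4, function(j) {
      bg <- fit_background(qn[, j], fe, design$bait_pos)
      call_interactions(qn[, j], bg, fe)
    })
    cons <- consensus_regions(calls)
    if (nrow(cons) > 0 && any(cons$start < reg$end & cons$end > reg$start)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 7)
})
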