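test_that("digestion places fragment boundaries at shifted site occurrences", {
  dpn <- known_enzymes("DpnII")
  fm <- digest_genome(c(chrT = "AAGATCTTGATCAA"), dpn)
  expect_equal(fm$start, c(0, 2, 8))
  expect_equal(fm$end, c(2, 8, 14))
  expect_equal(fm$index, 1:3)

  # no site: single fragment spanning the chromosome
  fm0 <- digest_genome(c(chrT = "AAAA"), dpn)
  expect_equal(nrow(fm0), 1L)
  expect_equal(c(fm0$start, fm0$end), c(0, 4))

  # cut coinciding with the chromosome start produces no boundary
  fm1 <- digest_genome(c(chrT = "GATCAA"), dpn)
  expect_equal(nrow(fm1), 1L)
  expect_equal(c(fm1$start, fm1$end), c(0, 6))

  # cut-offset convention: NlaIII cuts after its site
  fm2 <- digest_genome(c(chrT = "AACATGTT"), known_enzymes("NlaIII"))
  expect_equal(fm2$end[1], 6)  # CATG at 2, cut at 2+4

  expect_error(digest_genome(character(0), dpn), "non-empty")
  # N bases never match
  fmn <- digest_genome(c(chrT = "AAGANCTTAA"), dpn)
  expect_equal(nrow(fmn), 1L)
})

test_that("fragments tile each chromosome and digestion is idempotent", {
  set.seed(7)
  for (rep in 1:3) {
    g <- simulate_toy_genome(5000, "chrZ", seed = rep)
    fm <- digest_genome(g, known_enzymes("DpnII"))
    # tiling: fragment sequences concatenate back to the chromosome
    seqs <- substring(g, fm$start + 1, fm$end)
    expect_identical(paste(seqs, collapse = ""), unname(g))
    expect_true(all(fm$start < fm$end))
    expect_equal(fm$start[-1], fm$end[-nrow(fm)])
    # re-digesting the reassembled chromosome yields the same boundaries
    fm2 <- digest_genome(stats::setNames(paste(seqs, collapse = ""), "chrZ"),
                         known_enzymes("DpnII"))
    expect_equal(fm2$start, fm$start)
    expect_equal(fm2$end, fm$end)
  }
})

test_that("fragends carry captures read inward and blind flags", {
  g <- c(chrT = "AAGATCTTGATCAA")
  fm <- digest_genome(g, known_enzymes("DpnII"))
  fe <- build_fragends(fm, g, known_enzymes("Csp6I"), L = 4)
  expect_equal(nrow(fe), 2L * nrow(fm))
  # 5' capture of fragment [2,8) is bases 2..5
  cap <- fe$capture_seq[fe$frag_index == 2 & fe$side == "5p"]
  expect_identical(cap, "GATC")
  # 3' capture reads inward from the downstream cut (reverse complement)
  cap3 <- fe$capture_seq[fe$frag_index == 2 & fe$side == "3p"]
  expect_identical(cap3, "AAGA")

  # blind iff the fragment lacks the secondary site
  g2 <- c(chrT = "GATCAAGTACAAGATCAAAA")
  fm2 <- digest_genome(g2, known_enzymes("DpnII"))
  fe2 <- build_fragends(fm2, g2, known_enzymes("Csp6I"), L = 6)
  expect_false(any(fe2$blind[fe2$frag_index == 1]))  # contains GTAC
  expect_true(all(fe2$blind[fe2$frag_index == 2]))   # AAAA only

  expect_error(build_fragends(fm, g, known_enzymes("Csp6I"), L = 0), "L")
})

test_that("allele edits re-digest and lift back to reference coordinates", {
  g <- c(chrT = "AAGATCTTGATCAA")
  dpn <- known_enzymes("DpnII")
  # deleting [2,8) leaves AAGATCAA with fragments [0,2),[2,8)
  am <- apply_allele_edits(g, data.frame(type = "deletion", chrom = "chrT",
                                         start = 2, end = 8, seq = NA,
                                         name = NA), dpn, allele = "d1")
  expect_identical(unname(am$genome), "AAGATCAA")
  expect_equal(am$fragmap$start, c(0, 2))
  expect_equal(am$fragmap$end, c(2, 8))
  # length decreases by exactly the deletion size
  expect_equal(nchar(am$genome), nchar(g) - 6)
  # lift: edited position 3 sits in reference [8,14)
  lifted <- lift_to_reference(am, "chrT", c(0, 3))
  expect_equal(lifted$ref_pos, c(0, 9))
  expect_true(all(lifted$source == "reference"))

  # no edits: identity
  am0 <- apply_allele_edits(g, NULL, dpn)
  expect_identical(am0$genome, g)
  expect_equal(am0$fragmap$start, digest_genome(g, dpn)$start)

  # insertion creates a named block with no reference image
  ins_seq <- paste(rep("ACGT", 88), collapse = "")  # 352 bp
  am2 <- apply_allele_edits(g, data.frame(type = "insertion", chrom = "chrT",
                                          start = 8, end = 8, seq = ins_seq,
                                          name = "hs_bait"), dpn)
  expect_equal(nchar(am2$genome), nchar(g) + 352)
  expect_true("hs_bait" %in% am2$lift$source)
  inside <- lift_to_reference(am2, "chrT", 8 + 10)
  expect_identical(inside$source, "hs_bait")
  expect_true(is.na(inside$ref_pos))

  expect_error(apply_allele_edits(g, data.frame(
    type = c("deletion", "deletion"), chrom = "chrT", start = c(2, 4),
    end = c(8, 10), seq = NA, name = NA), dpn), "overlapping")
  expect_error(apply_allele_edits(g, data.frame(
    type = "deletion", chrom = "chrT", start = 2, end = 99, seq = NA,
    name = NA), dpn), "bounds")
})
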