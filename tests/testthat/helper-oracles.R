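# Brute-force least-squares non-increasing fit: enumerate every contiguous
# partition of the sequence, level each block at its mean, keep monotone
# candidates, return the SSE-minimal fit. Independent of the PAVA route.
iso_decreasing_oracle <- function(y) {
  n <- length(y)
  best <- NULL
  best_sse <- Inf
  for (code in 0:(2^(n - 1) - 1)) {
    cutpts <- which(bitwAnd(code, 2^(0:(n - 2))) > 0)
    starts <- c(1, cutpts + 1)
    ends <- c(cutpts, n)
    fit <- numeric(n)
    means <- numeric(length(starts))
    for (b in seq_along(starts)) {
      means[b] <- mean(y[starts[b]:ends[b]])
      fit[starts[b]:ends[b]] <- means[b]
    }
    if (all(diff(means) <= 1e-12)) {
      sse <- sum((y - fit)^2)
      if (sse < best_sse - 1e-12) {
        best_sse <- sse
        best <- fit
      }
    }
  }
  best
}

# Straightforward reclassification of a spot table, written independently of
# classify_cells(): explicit loops, no grouping helpers.
classify_brute_force <- function(spots, tau = 2.5) {
  out <- NULL
  for (cc in sort(unique(spots$cell))) {
    total <- 0
    nts <- 0
    nsp <- 0
    for (i in seq_len(nrow(spots))) {
      if (spots$cell[i] != cc) next
      nsp <- nsp + 1
      total <- total + spots$rna_equivalents[i]
      if (spots$compartment[i] == "nuclear" &&
          spots$rna_equivalents[i] >= tau) {
        nts <- nts + 1
      }
    }
    cat_ <- if (nts == 0) "zero" else if (nts == 1) "one" else "more_than_one"
    out <- rbind(out, data.frame(cell = cc, n_spots = nsp, total_mrna = total,
                                 n_active_ts = nts, ts_category = cat_,
                                 stringsAsFactors = FALSE))
  }
  out
}

# Regularly spaced synthetic fragend table (one row per fragend) for tests
# that only need coordinates, not sequence.
regular_fragends <- function(n, spacing = 100, chrom = "chrT") {
  anchors <- seq(0, by = spacing, length.out = n)
  df <- data.frame(fragend_id = paste0("fe", seq_len(n)), chrom = chrom,
                   frag_index = seq_len(n), side = "5p", start = anchors,
                   end = anchors + spacing, anchor_pos = anchors,
                   capture_seq = NA_character_, blind = FALSE,
                   stringsAsFactors = FALSE)
  class(df) <- c("fragend_map", "data.frame")
  df
}
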