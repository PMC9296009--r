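#' 4C library description
#'
#' One sequencing library corresponds to one bait x allele x condition x
#' replicate combination; allele separation is experimental (SNP-specific
#' digestion before inverse PCR), so allele is a per-library label, not a
#' per-read call.
#'
#' @param sample_id Unique sample identifier.
#' @param bait Bait (viewpoint) name.
#' @param allele Allele label (e.g. "129", "CAST").
#' @param condition Condition/genotype label.
#' @param replicate Replicate number.
#' @param prefix Inline barcode/bait-primer prefix expected at the read start.
#' @return A `library_spec` object.
#' @export
library_spec <- function(sample_id, bait, allele, condition, replicate, prefix) {
  stopifnot(nzchar(prefix))
  structure(list(sample_id = sample_id, bait = bait, allele = allele,
                 condition = condition, replicate = as.integer(replicate),
                 prefix = toupper(prefix)),
            class = "library_spec")
}

hamming_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  sum(strsplit(substr(a, 1, n), "")[[1]] != strsplit(substr(b, 1, n), "")[[1]])
}

#' Demultiplex reads by inline prefix
#'
#' Assigns each read to at most one library by matching the library prefix at
#' the read start with at most `max_mismatch` mismatches, then trims the
#' prefix. Library prefixes must be mutually distinguishable at the chosen
#' mismatch level (pairwise Hamming distance on the shared prefix length
#' greater than `max_mismatch`), otherwise a configuration error is raised.
#' Reads are conserved: assigned plus unassigned equals input.
#'
#' @param reads Character vector of read sequences (names preserved), or a
#'   `DNAStringSet`.
#' @param libraries List of [library_spec()] objects.
#' @param max_mismatch Maximum mismatches tolerated in the prefix (default 0,
#'   exact barcodes).
#' @return List with `assigned` (named list of trimmed read vectors, one per
#'   sample_id) and `unassigned`.
#' @export
demultiplex <- function(reads, libraries, max_mismatch = 0L) {
  if (methods::is(reads, "DNAStringSet")) {
    reads <- stats::setNames(as.character(reads), names(reads))
  }
  stopifnot(is.character(reads))
  prefixes <- vapply(libraries, function(l) l$prefix, character(1))
  ids <- vapply(libraries, function(l) l$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample_id in libraries")
  if (length(prefixes) > 1L) {
    for (i in seq_len(length(prefixes) - 1L)) {
      for (j in seq(i + 1L, length(prefixes))) {
        if (hamming_prefix(prefixes[i], prefixes[j]) <= max_mismatch) {
          stop("prefixes '", prefixes[i], "' and '", prefixes[j],
               "' are ambiguous at max_mismatch = ", max_mismatch)
        }
      }
    }
  }
  assigned <- stats::setNames(vector("list", length(ids)), ids)
  which_lib <- rep(NA_integer_, length(reads))
  for (k in seq_along(prefixes)) {
    p <- prefixes[k]
    np <- nchar(p)
    cand <- which(is.na(which_lib) & nchar(reads) >= np)
    if (max_mismatch == 0L) {
      hit <- cand[startsWith(reads[cand], p)]
    } else {
      mm <- vapply(substr(reads[cand], 1, np), hamming_prefix, integer(1), b = p)
      hit <- cand[mm <= max_mismatch]
    }
    which_lib[hit] <- k
  }
  for (k in seq_along(prefixes)) {
    idx <- which(which_lib == k)
    assigned[[ids[k]]] <- substring(reads[idx], nchar(prefixes[k]) + 1L)
  }
  list(assigned = assigned, unassigned = reads[is.na(which_lib)])
}

#' 4C count profile
#'
#' Container for one library's per-fragend raw or normalized counts.
#'
#' @param counts Numeric vector, one entry per fragend row.
#' @param fragends The `fragend_map` the counts are indexed by.
#' @param library A [library_spec()] or NULL.
#' @param total_reads,ambiguous_reads,unmatched_reads Read accounting.
#' @return A `fourc_profile` object.
#' @export
fourc_profile <- function(counts, fragends, library = NULL,
                          total_reads = sum(counts), ambiguous_reads = 0L,
                          unmatched_reads = 0L) {
  stopifnot(length(counts) == nrow(fragends), all(counts >= 0, na.rm = TRUE))
  structure(list(counts = as.numeric(counts), fragends = fragends,
                 library = library, total_reads = total_reads,
                 assigned_reads = sum(counts),
                 ambiguous_reads = ambiguous_reads,
                 unmatched_reads = unmatched_reads),
            class = "fourc_profile")
}

#' @export
print.fourc_profile <- function(x, ...) {
  cat(sprintf("<fourc_profile> %d fragends, %s assigned / %s total reads\n",
              length(x$counts), format(x$assigned_reads), format(x$total_reads)))
  invisible(x)
}

#' Build the capture-sequence lookup dictionary
#'
#' Keys fragends on the first `L` bases of their capture sequence. Keys shared
#' by more than one fragend (collisions) cannot be assigned uniquely and are
#' excluded at build time; reads carrying a collision key are later counted as
#' ambiguous.
#'
#' @param fragends A `fragend_map`.
#' @param L Key length; defaults to the capture length stored on the map.
#' @return List with `keys` (unique capture keys), `row` (fragend row per key),
#'   `ambiguous_keys`, and `L`.
#' @export
fragend_dictionary <- function(fragends, L = attr(fragends, "L")) {
  if (nrow(fragends) == 0L) stop("empty fragend dictionary")
  keys <- substr(fragends$capture_seq, 1L, L)
  dup <- keys[duplicated(keys)]
  amb <- unique(dup)
  keep <- !(keys %in% amb) & nchar(keys) == L
  list(keys = keys[keep], row = which(keep), ambiguous_keys = amb, L = L)
}

#' Assign reads to fragment ends by exact capture lookup
#'
#' Replaces external genome alignment with an exact unique-match lookup of each
#' read's first `L` bases against the fragend capture dictionary. A read
#' increments exactly one fragend count when its key matches a unique capture
#' sequence; reads matching a collision key are counted as ambiguous, all other
#' non-matching reads as unmatched, so assigned + ambiguous + unmatched equals
#' the input read count.
#'
#' @param reads Character vector of (prefix-trimmed) read sequences.
#' @param fragends A `fragend_map`.
#' @param library Optional [library_spec()] carried on the profile.
#' @param L Key length (defaults to the map's capture length).
#' @return A [fourc_profile()].
#' @export
assign_reads <- function(reads, fragends, library = NULL,
                         L = attr(fragends, "L")) {
  dict <- fragend_dictionary(fragends, L)
  keys <- substr(reads, 1L, dict$L)
  hit <- match(keys, dict$keys)
  ambiguous <- sum(keys %in% dict$ambiguous_keys)
  counts <- integer(nrow(fragends))
  tab <- table(dict$row[hit[!is.na(hit)]])
  counts[as.integer(names(tab))] <- as.integer(tab)
  unmatched <- length(reads) - sum(counts) - ambiguous
  fourc_profile(counts, fragends, library = library,
                total_reads = length(reads), ambiguous_reads = ambiguous,
                unmatched_reads = unmatched)
}

#' Restrict a profile to the bait chromosome (cis)
#'
#' Drops counts outside the bait chromosome and, if `window` is given, outside
#' `bait_pos` +/- `window`. Totals are updated; the fragend table of the
#' returned profile is subset accordingly.
#'
#' @param profile A [fourc_profile()].
#' @param bait_chrom Bait chromosome.
#' @param bait_pos Bait coordinate (needed when `window` is given).
#' @param window Optional half-width in bp (e.g. 1e6 for the 1-Mb scoring
#'   window).
#' @return A [fourc_profile()] restricted to cis fragends.
#' @export
filter_cis <- function(profile, bait_chrom, bait_pos = NULL, window = NULL) {
  stopifnot(inherits(profile, "fourc_profile"))
  keep <- profile$fragends$chrom == bait_chrom
  if (!is.null(window)) {
    if (is.null(bait_pos)) stop("window filtering requires bait_pos")
    keep <- keep & abs(profile$fragends$anchor_pos - bait_pos) <= window
  }
  fe <- profile$fragends[keep, , drop = FALSE]
  rownames(fe) <- NULL
  for (a in c("L", "secondary")) attr(fe, a) <- attr(profile$fragends, a)
  class(fe) <- class(profile$fragends)
  fourc_profile(profile$counts[keep], fe, library = profile$library,
                total_reads = profile$total_reads,
                ambiguous_reads = profile$ambiguous_reads,
                unmatched_reads = profile$unmatched_reads)
}
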