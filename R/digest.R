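#' @importFrom Biostrings DNAStringSet readDNAStringSet matchPattern
#'   vcountPattern reverseComplement subseq
NULL

# Normalise genome input to a named uppercase character vector.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (!is.character(genome) || length(genome) == 0L) {
    stop("genome must be a non-empty named character vector or DNAStringSet")
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("every chromosome must be named")
  }
  genome <- toupper(genome)
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad)) stop("genome contains characters outside ACGTN: ",
                     paste(names(genome)[bad], collapse = ", "))
  genome
}

#' Digest a genome in silico
#'
#' Scans each chromosome for occurrences of the enzyme recognition site and
#' returns the resulting restriction fragments as 0-based half-open intervals
#' that tile the chromosome exactly. `N` bases never match a site, so assembly
#' gaps are treated conservatively as uncut sequence. Cut positions coinciding
#' (e.g. overlapping sites for palindromic enzymes) would yield zero-length
#' fragments; these are dropped and their number reported via `message()`.
#'
#' @param genome Named character vector (or `DNAStringSet`) of chromosome
#'   sequences, uppercase ACGTN.
#' @param enzyme An [enzyme_spec()].
#' @return A `fragment_map`: data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `index` (1-based ordinal along the chromosome),
#'   with chromosome lengths in `attr(, "chrom_lengths")`.
#' @examples
#' digest_genome(c(chrT = "AAGATCTTGATCAA"), known_enzymes("DpnII"))
#' @export
digest_genome <- function(genome, enzyme) {
  genome <- as_genome(genome)
  stopifnot(inherits(enzyme, "enzyme_spec"))
  dropped <- 0L
  frags <- lapply(names(genome), function(chrom) {
    seq <- genome[[chrom]]
    len <- nchar(seq)
    m <- matchPattern(enzyme$site, DNAStringSet(seq)[[1L]], fixed = TRUE)
    cuts <- BiocGenerics::start(m) - 1L + enzyme$cut_offset  # 0-based cut coords
    cuts_all <- cuts[cuts > 0L & cuts < len]
    cuts <- unique(cuts_all)
    dropped <<- dropped + (length(cuts_all) - length(cuts))
    bounds <- c(0L, sort(cuts), len)
    data.frame(chrom = chrom,
               start = bounds[-length(bounds)],
               end = bounds[-1L],
               index = seq_len(length(bounds) - 1L),
               stringsAsFactors = FALSE)
  })
  if (dropped > 0L) message("dropped ", dropped, " zero-length fragment(s)")
  out <- do.call(rbind, frags)
  attr(out, "chrom_lengths") <- stats::setNames(nchar(genome), names(genome))
  attr(out, "enzyme") <- enzyme$name
  class(out) <- c("fragment_map", "data.frame")
  out
}

# Sequence of one fragment row (1-based substring on 0-based coords).
fragment_seq <- function(genome, chrom, start, end) {
  substr(genome[[chrom]], start + 1L, end)
}

#' Build 4C-informative fragment ends
#'
#' Each restriction fragment contributes two fragment ends ("fragends"), one
#' per side adjacent to a primary-enzyme cut. The capture sequence is the first
#' `L` bases of the fragment read inward from the primary site (for the 3'
#' side, the reverse complement of the terminal `L` bases, i.e. the sequence a
#' read entering from that cut would see). Fragments lacking a secondary-enzyme
#' site are flagged `blind`: they cannot form an informative 4C circle.
#'
#' @param fragmap A `fragment_map` from [digest_genome()].
#' @param genome The genome the map was built from.
#' @param secondary The secondary [enzyme_spec()] (e.g. Csp6I).
#' @param L Capture length in bases (default 36, a typical post-trim 4C read
#'   length); capture sequences are truncated at the fragment boundary.
#' @return A `fragend_map`: data.frame with one row per fragend, ordered along
#'   each chromosome by anchor position, with columns `fragend_id`, `chrom`,
#'   `frag_index`, `side` ("5p"/"3p"), `start`, `end` (the parent fragment),
#'   `anchor_pos` (coordinate of the primary cut), `capture_seq`, `blind`.
#' @export
build_fragends <- function(fragmap, genome, secondary, L = 36L) {
  stopifnot(inherits(fragmap, "fragment_map"), inherits(secondary, "enzyme_spec"))
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("capture length L must be >= 1")
  genome <- as_genome(genome)
  seqs <- mapply(fragment_seq, fragmap$chrom, fragmap$start, fragmap$end,
                 MoreArgs = list(genome = genome), USE.NAMES = FALSE)
  blind <- vcountPattern(secondary$site, DNAStringSet(seqs), fixed = TRUE) == 0L
  lens <- fragmap$end - fragmap$start
  cap5 <- substr(seqs, 1L, pmin(L, lens))
  cap3 <- as.character(reverseComplement(
    DNAStringSet(substr(seqs, pmax(1L, lens - L + 1L), lens))))
  two <- function(side, anchor, cap) {
    data.frame(fragend_id = paste0(fragmap$chrom, ":", fragmap$index, ":", side),
               chrom = fragmap$chrom, frag_index = fragmap$index,
               side = side, start = fragmap$start, end = fragmap$end,
               anchor_pos = anchor, capture_seq = cap, blind = blind,
               stringsAsFactors = FALSE)
  }
  fe <- rbind(two("5p", fragmap$start, cap5), two("3p", fragmap$end, cap3))
  fe <- fe[order(match(fe$chrom, unique(fragmap$chrom)), fe$anchor_pos,
                 fe$side), , drop = FALSE]
  rownames(fe) <- NULL
  attr(fe, "L") <- L
  attr(fe, "secondary") <- secondary$name
  class(fe) <- c("fragend_map", "data.frame")
  fe
}

#' Apply engineered-allele edits and re-digest
#'
#' Applies deletions and insertions to the reference genome, re-digests the
#' edited sequence, and records a coordinate-lift table mapping edited-allele
#' intervals back to reference coordinates. Deleted reference sequence has no
#' image on the edited axis; inserted sequence maps to a named synthetic contig
#' (e.g. a short foreign bait fragment), so insertion-derived fragends can be
#' used as baits while remaining distinguishable from reference sequence.
#'
#' @param genome Reference genome (named character vector or `DNAStringSet`).
#' @param edits data.frame with columns `type` ("deletion" or "insertion"),
#'   `chrom`, `start`, `end` (0-based half-open; for insertions `start == end`
#'   is the insertion point), `seq` (inserted sequence, `NA` for deletions) and
#'   `name` (label for inserted contigs, `NA` for deletions).
#' @param enzyme Primary [enzyme_spec()] used to re-digest the edited genome.
#' @param allele Label for the engineered allele (e.g. "129-dSCR").
#' @return An `allele_map`: list with the edited `genome`, its `fragmap`, the
#'   `lift` block table (`chrom`, `edited_start`, `edited_end`, `ref_start`,
#'   `ref_end`, `source`), the `edits`, and the `allele` label.
#' @export
apply_allele_edits <- function(genome, edits, enzyme, allele = "edited") {
  genome <- as_genome(genome)
  if (is.null(edits) || nrow(edits) == 0L) {
    fragmap <- digest_genome(genome, enzyme)
    lift <- data.frame(chrom = names(genome), edited_start = 0L,
                       edited_end = nchar(genome), ref_start = 0L,
                       ref_end = nchar(genome), source = "reference",
                       stringsAsFactors = FALSE)
    return(structure(list(allele = allele, genome = genome, fragmap = fragmap,
                          lift = lift, edits = edits),
                     class = "allele_map"))
  }
  stopifnot(all(c("type", "chrom", "start", "end") %in% names(edits)))
  if (!all(edits$type %in% c("deletion", "insertion"))) {
    stop("edit type must be 'deletion' or 'insertion'")
  }
  edited <- genome
  lift_blocks <- list()
  for (chrom in names(genome)) {
    e <- edits[edits$chrom == chrom, , drop = FALSE]
    len <- nchar(genome[[chrom]])
    if (any(e$start < 0L | e$end > len | e$start > e$end)) {
      stop("edit outside chromosome bounds on ", chrom)
    }
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
      stop("overlapping edits on ", chrom)
    }
    # Walk reference left to right, emitting kept blocks and insertions.
    pieces <- character(0)
    blocks <- list()
    ref_cursor <- 0L
    ed_cursor <- 0L
    emit_ref <- function(from, to) {
      if (to > from) {
        pieces <<- c(pieces, substr(genome[[chrom]], from + 1L, to))
        blocks[[length(blocks) + 1L]] <<- data.frame(
          chrom = chrom, edited_start = ed_cursor,
          edited_end = ed_cursor + (to - from), ref_start = from, ref_end = to,
          source = "reference", stringsAsFactors = FALSE)
        ed_cursor <<- ed_cursor + (to - from)
      }
    }
    for (i in seq_len(nrow(e))) {
      emit_ref(ref_cursor, e$start[i])
      if (e$type[i] == "deletion") {
        ref_cursor <- e$end[i]
      } else {
        ins <- toupper(e$seq[i])
        if (is.na(ins) || !nzchar(ins)) stop("insertion requires a sequence")
        nm <- if (!is.null(e$name) && !is.na(e$name[i])) e$name[i] else
          paste0("ins", i)
        pieces <- c(pieces, ins)
        blocks[[length(blocks) + 1L]] <- data.frame(
          chrom = chrom, edited_start = ed_cursor,
          edited_end = ed_cursor + nchar(ins), ref_start = NA_integer_,
          ref_end = NA_integer_, source = nm, stringsAsFactors = FALSE)
        ed_cursor <- ed_cursor + nchar(ins)
        ref_cursor <- e$end[i]
      }
    }
    emit_ref(ref_cursor, len)
    edited[[chrom]] <- paste(pieces, collapse = "")
    lift_blocks[[chrom]] <- do.call(rbind, blocks)
  }
  lift <- do.call(rbind, lift_blocks)
  rownames(lift) <- NULL
  structure(list(allele = allele, genome = edited,
                 fragmap = digest_genome(edited, enzyme),
                 lift = lift, edits = edits),
            class = "allele_map")
}

#' Lift edited-allele positions back to reference coordinates
#'
#' @param amap An `allele_map` from [apply_allele_edits()].
#' @param chrom Chromosome name(s) on the edited axis.
#' @param pos Position(s), 0-based, on the edited axis.
#' @return data.frame with `ref_pos` (`NA` for insertion-derived positions) and
#'   `source` ("reference" or the insertion name).
#' @export
lift_to_reference <- function(amap, chrom, pos) {
  stopifnot(inherits(amap, "allele_map"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- data.frame(ref_pos = rep(NA_real_, n), source = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    b <- amap$lift[amap$lift$chrom == chrom[i] &
                     amap$lift$edited_start <= pos[i] &
                     amap$lift$edited_end > pos[i], , drop = FALSE]
    if (nrow(b) == 1L) {
      out$source[i] <- b$source
      if (b$source == "reference") {
        out$ref_pos[i] <- b$ref_start + (pos[i] - b$edited_start)
      }
    }
  }
  out
}
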