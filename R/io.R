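#' Read a genome FASTA
#'
#' @param path Multi-record FASTA (wrapped lines allowed; gzip supported).
#' @return Named uppercase character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  as_genome(Biostrings::readDNAStringSet(path))
}

#' Read / write FASTQ
#'
#' Sequence-only FASTQ access (qualities are not used anywhere in the
#' pipeline). Gzip-compressed files are handled transparently.
#'
#' @param path FASTQ file, plain or `.gz`.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  reads <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(reads), names(reads))
}

#' @rdname read_fastq
#' @param reads Named character vector of read sequences.
#' @export
write_fastq <- function(reads, path) {
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), path,
                              format = "fastq")
  invisible(path)
}

df_to_granges <- function(df, score = NULL, name = NULL) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  if (!is.null(score)) gr$score <- score
  if (!is.null(name)) gr$name <- name
  gr
}

#' Write a fragment map or interval table as BED
#'
#' Intervals are stored 0-based half-open internally, matching BED, so
#' round-trips are exact.
#'
#' @param df data.frame with `chrom`, `start`, `end`; fragment maps use their
#'   `index` as the name field, call tables their replicate support.
#' @param path Output path.
#' @param name Optional name column values.
#' @export
write_bed <- function(df, path, name = NULL) {
  if (is.null(name) && "index" %in% names(df)) name <- as.character(df$index)
  gr <- df_to_granges(df, name = name)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write a per-fragend track as bedGraph
#'
#' One interval per fragend with its value. Masked positions (value `NA`) are
#' written as no-coverage gaps, i.e. omitted, never as zeros.
#'
#' @param fragends A `fragend_map`.
#' @param values Per-fragend values (`NA` = no coverage).
#' @param path Output path.
#' @export
write_bedgraph <- function(fragends, values, path) {
  keep <- !is.na(values)
  df <- data.frame(chrom = fragends$chrom[keep],
                   start = fragends$start[keep], end = fragends$end[keep])
  gr <- df_to_granges(df, score = values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write fragend count tables
#'
#' TSV with columns `chrom`, `start`, `end`, `fragend_id`, `count`.
#'
#' @param profile A [fourc_profile()].
#' @param path File path.
#' @export
write_count_table <- function(profile, path) {
  df <- data.frame(chrom = profile$fragends$chrom,
                   start = profile$fragends$start,
                   end = profile$fragends$end,
                   fragend_id = profile$fragends$fragend_id,
                   count = profile$counts, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @param fragends Fragend map to align the counts to (matched on
#'   `fragend_id`).
#' @export
read_count_table <- function(path, fragends) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  counts <- df$count[match(fragends$fragend_id, df$fragend_id)]
  counts[is.na(counts)] <- 0
  fourc_profile(counts, fragends)
}

provenance_header <- function(config = NULL) {
  h <- paste0("# loop4c ",
              as.character(utils::packageVersion("loop4c")))
  if (!is.null(config)) {
    hash <- sum(utf8ToInt(paste(deparse(config), collapse = "")) *
                  seq_along(utf8ToInt(paste(deparse(config),
                                            collapse = "")))) %% 1e9
    h <- c(h, paste0("# config_hash ", format(hash, scientific = FALSE)))
  }
  h
}

#' Write a table as TSV with a provenance header
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param config Optional configuration object hashed into the header.
#' @export
write_tsv_report <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML configuration with paths, enzyme pair, locus regions, library
#' manifest and algorithm parameters. Referenced files must exist; a missing
#' key or file raises an error naming it.
#'
#' @param path YAML file.
#' @return Named list (the parsed config), validated.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("genome", "libraries", "bait_pos", "regions")
  miss <- setdiff(required, names(cfg))
  if (length(miss) > 0L) {
    stop("config is missing required key(s): ", paste(miss, collapse = ", "))
  }
  for (key in c("genome")) {
    if (!file.exists(cfg[[key]])) {
      stop("config key '", key, "' points to a missing file: ", cfg[[key]])
    }
  }
  cfg
}
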