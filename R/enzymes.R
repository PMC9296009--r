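#' Restriction enzyme specification
#'
#' Describes a restriction enzyme by its recognition site and the offset of the
#' cleavage position within the site. The offset is the number of bases between
#' the 5' edge of the site and the cut on the top strand, so `cut_offset = 0`
#' cuts immediately before the site (DpnII, ^GATC) and `cut_offset = 4` cuts
#' after a 4-base site (NlaIII, CATG^).
#'
#' @param name Enzyme name.
#' @param site Recognition sequence, uppercase ACGT.
#' @param cut_offset Integer cut offset in `[0, nchar(site)]`.
#' @return An object of class `enzyme_spec`.
#' @examples
#' enzyme_spec("DpnII", "GATC", 0)
#' @export
enzyme_spec <- function(name, site, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(site), length(site) == 1L, nzchar(site))
  if (!grepl("^[ACGT]+$", site)) {
    stop("enzyme site must be non-empty uppercase ACGT, got '", site, "'")
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(site)) {
    stop("cut_offset must lie in [0, nchar(site)]")
  }
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "enzyme_spec")
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cut <- paste0(substr(x$site, 0, x$cut_offset), "^",
                substr(x$site, x$cut_offset + 1L, nchar(x$site)))
  cat(sprintf("<enzyme_spec> %s  %s\n", x$name, sub("^\\^?", "^", cut)))
  invisible(x)
}

#' Built-in enzyme definitions
#'
#' The enzymes used in the double-digest 4C design around Sox2: DpnII (^GATC)
#' and NlaIII (CATG^) as primary enzymes for the two baits, and Csp6I (G^TAC)
#' as the secondary enzyme. Cut conventions follow REBASE.
#'
#' @param name Optional enzyme name; if missing, the full named list is
#'   returned.
#' @return An `enzyme_spec`, or a named list of them.
#' @export
known_enzymes <- function(name) {
  enz <- list(
    DpnII = enzyme_spec("DpnII", "GATC", 0L),
    NlaIII = enzyme_spec("NlaIII", "CATG", 4L),
    Csp6I = enzyme_spec("Csp6I", "GTAC", 1L)
  )
  if (missing(name)) return(enz)
  if (!name %in% names(enz)) {
    stop("unknown enzyme '", name, "'; define it with enzyme_spec()")
  }
  enz[[name]]
}
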