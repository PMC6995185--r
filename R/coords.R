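#' Genomic interval
#'
#' Lightweight container for a genomic interval. Coordinates are stored
#' 0-based half-open (`start` inclusive, `end` exclusive), the convention used
#' internally throughout the package; all user-facing tables render 1-based
#' inclusive coordinates (see [interval_to_1based()]).
#'
#' @param contig contig / sequence name.
#' @param start 0-based inclusive start.
#' @param end exclusive end; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `genomic_interval`.
#' @export
genomic_interval <- function(contig, start, end, strand = "+") {
  stopifnot(is.character(contig), length(contig) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(contig = contig, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d(%s)\n", x$contig, x$start + 1L, x$end, x$strand))
  invisible(x)
}

#' @export
length.genomic_interval <- function(x) x$end - x$start

#' Convert between internal and reported coordinates
#'
#' Internal storage is 0-based half-open; reports are 1-based inclusive.
#' The two functions are inverses of each other.
#'
#' @param start,end coordinates in the source convention.
#' @return a list with `start` and `end` in the target convention.
#' @export
interval_to_1based <- function(start, end) {
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

#' @rdname interval_to_1based
#' @export
interval_to_0based <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Proviral locus container
#'
#' One genomic ERV locus: its sequence, up to 500 nt of flanking sequence on
#' each side, coordinates, species tag, and a free-form annotation list that
#' downstream stages (annotation, classification, dating) fill in.
#'
#' @param id unique locus identifier.
#' @param species species tag.
#' @param interval a [genomic_interval()].
#' @param sequence locus DNA (A/C/G/T/N).
#' @param flank5,flank3 flanking DNA, possibly empty, each at most 500 nt.
#' @param annotations named list of annotations.
#' @return an object of class `proviral_locus`.
#' @export
proviral_locus <- function(id, species, interval, sequence,
                           flank5 = "", flank3 = "", annotations = list()) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("locus sequence contains characters outside {A,C,G,T,N}")
  }
  structure(list(id = id, species = species, interval = interval,
                 sequence = sequence, flank5 = toupper(flank5),
                 flank3 = toupper(flank3), annotations = annotations),
            class = "proviral_locus")
}

#' @export
print.proviral_locus <- function(x, ...) {
  cat(sprintf("<proviral_locus %s> species=%s len=%d flanks=%d/%d annotations=%s\n",
              x$id, x$species, nchar(x$sequence), nchar(x$flank5),
              nchar(x$flank3),
              if (length(x$annotations)) paste(names(x$annotations),
                                               collapse = ",") else "none"))
  invisible(x)
}
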