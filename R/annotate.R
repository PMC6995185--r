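#' Locate the LTR pair of a proviral sequence
#'
#' LTRs are found as the best near-terminal direct repeat: the 5'-terminal
#' window is locally aligned against the 3'-terminal window and the
#' highest-scoring repeat pair with identity at least `min_identity` and
#' length within `[min_ltr_len, max_ltr_len]` is returned.
#'
#' @param sequence proviral DNA.
#' @param max_ltr_len maximum LTR length considered (nt).
#' @param min_ltr_len minimum LTR length (nt).
#' @param min_identity minimum repeat identity.
#' @param slack extra window length beyond `max_ltr_len` at each terminus.
#' @return `NULL` when no qualifying repeat exists, else a list with
#'   `ltr5`/`ltr3` (0-based half-open `c(start, end)` in `sequence`
#'   coordinates) and `identity`.
#' @export
locate_ltrs <- function(sequence, max_ltr_len = 900L, min_ltr_len = 200L,
                        min_identity = 0.60, slack = 200L) {
  n <- nchar(sequence)
  if (n < 2L * min_ltr_len) {
    stop("sequence shorter than twice min_ltr_len")
  }
  w <- min(n, max_ltr_len + slack)
  w5 <- substr(sequence, 1L, w)
  w3 <- substr(sequence, n - w + 1L, n)
  aln <- align_pair(w5, w3, type = "local")
  len5 <- Biostrings::width(Biostrings::pattern(aln))
  len3 <- Biostrings::width(Biostrings::subject(aln))
  if (length(len5) == 0L || len5 == 0L) return(NULL)
  id <- aln_identity(aln)
  rep_len <- max(len5, len3)
  if (id < min_identity || rep_len < min_ltr_len || rep_len > max_ltr_len) {
    return(NULL)
  }
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  off3 <- n - w
  res <- list(
    ltr5 = c(start = Biostrings::start(p) - 1L, end = Biostrings::end(p)),
    ltr3 = c(start = off3 + Biostrings::start(s) - 1L,
             end = off3 + Biostrings::end(s)),
    identity = id
  )
  # when the terminal windows overlap (short input), the best local hit can
  # be the sequence matching itself; a direct-repeat pair must be disjoint
  if (res$ltr3[["start"]] < res$ltr5[["end"]]) return(NULL)
  res
}

#' Find the primer binding site downstream of the 5'LTR
#'
#' Scans 18-nt windows starting within `pbs_search_window` nt of the 5'LTR
#' end and compares each against every entry of the tRNA PBS library. The
#' best (window, entry) pair by identity wins; ties are broken by smaller
#' offset, then library order.
#'
#' @param sequence locus DNA.
#' @param ltr5_end 0-based position just past the 5'LTR.
#' @param trna_library named vector of 18-nt entries
#'   (see [trna_pbs_library()]).
#' @param search_window how far past the LTR the PBS may start (nt).
#' @param identity_threshold presence calls require identity at or above
#'   this fraction (default 14/18).
#' @return list (`pbs_hit`): `interval` (0-based half-open), `sequence`,
#'   `best_trna`, `identity`, `present`; or a no-call (`present = NA`,
#'   `reason`) when the locus is too short.
#' @export
find_pbs <- function(sequence, ltr5_end, trna_library = trna_pbs_library(),
                     search_window = 30L, identity_threshold = 14 / 18) {
  if (length(trna_library) == 0L) stop("empty tRNA library")
  if (any(nchar(trna_library) != 18L)) stop("library entries must be 18 nt")
  n <- nchar(sequence)
  if (ltr5_end + 18L > n) {
    return(list(present = NA, reason = "locus too short for PBS scan"))
  }
  lib_chars <- strsplit(toupper(unname(trna_library)), "", fixed = TRUE)
  best <- list(identity = -1)
  for (off in 0:search_window) {
    s0 <- ltr5_end + off
    if (s0 + 18L > n) break
    win <- seq_chars(substr(sequence, s0 + 1L, s0 + 18L))
    for (j in seq_along(lib_chars)) {
      idy <- sum(win == lib_chars[[j]]) / 18
      if (idy > best$identity) {
        best <- list(identity = idy, offset = off, lib = j,
                     start = s0, seq = chars_seq(win))
      }
    }
  }
  list(
    interval = c(start = best$start, end = best$start + 18L),
    sequence = best$seq,
    best_trna = names(trna_library)[best$lib],
    identity = best$identity,
    present = best$identity >= identity_threshold
  )
}

MOTIF_PATTERNS <- c(
  ZF1 = "C..C....H....C",   # Cx2Cx4Hx4C
  ZF2 = "C..C...H....C",    # Cx2Cx3Hx4C
  GPYF = "W.GP[FY].V"       # WxGP(F/Y)xV
)

translate_frame <- function(sequence, frame) {
  n <- nchar(sequence)
  sub <- substr(sequence, frame + 1L, frame + 3L * ((n - frame) %/% 3L))
  if (nchar(sub) < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X"))
}

#' Scan for Gag zinc-finger and Pol GPY/F motifs
#'
#' Translates the three forward frames and reports every occurrence of the
#' requested amino-acid patterns (`ZF1` = Cx2Cx4Hx4C, `ZF2` = Cx2Cx3Hx4C,
#' `GPYF` = WxGP\[F/Y\]xV). Spacer positions may match any residue including
#' stops; a hit whose span contains a stop codon is reported with
#' `intact = FALSE` and failure reason `internal_stop`.
#'
#' @param sequence DNA (>= 42 nt for zinc fingers).
#' @param kinds subset of `c("ZF1", "ZF2", "GPYF")`.
#' @return data.frame with one row per hit: `kind, frame, aa_start, nt_start,
#'   nt_end` (0-based half-open), `aa_sequence, intact, failure_reasons`.
#' @export
scan_motifs <- function(sequence, kinds = names(MOTIF_PATTERNS)) {
  kinds <- match.arg(kinds, names(MOTIF_PATTERNS), several.ok = TRUE)
  out <- NULL
  for (frame in 0:2) {
    aa <- translate_frame(sequence, frame)
    if (!nzchar(aa)) next
    for (kind in kinds) {
      pat <- MOTIF_PATTERNS[[kind]]
      m <- gregexpr(pat, aa)[[1]]
      if (m[1] == -1L) next
      lens <- attr(m, "match.length")
      for (i in seq_along(m)) {
        aa_seq <- substr(aa, m[i], m[i] + lens[i] - 1L)
        stop_in <- grepl("*", aa_seq, fixed = TRUE)
        out <- rbind(out, data.frame(
          kind = kind, frame = frame, aa_start = m[i],
          nt_start = frame + 3L * (m[i] - 1L),
          nt_end = frame + 3L * (m[i] - 1L + lens[i]),
          aa_sequence = aa_seq,
          intact = !stop_in,
          failure_reasons = if (stop_in) "internal_stop" else "",
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(kind = character(0), frame = integer(0),
                      aa_start = integer(0), nt_start = integer(0),
                      nt_end = integer(0), aa_sequence = character(0),
                      intact = logical(0), failure_reasons = character(0))
  }
  out
}

#' Motif presence call for one locus
#'
#' A motif kind is "present" iff at least one intact hit lies within the
#' expected gene region (`gag` for zinc fingers, `pol` for GPY/F) when gene
#' boundaries are supplied, else anywhere in the sequence.
#'
#' @param hits data.frame from [scan_motifs()].
#' @param kind motif kind.
#' @param region optional 0-based half-open `c(start, end)` gene region.
#' @return logical.
#' @export
motif_present <- function(hits, kind, region = NULL) {
  h <- hits[hits$kind == kind & hits$intact, , drop = FALSE]
  if (nrow(h) == 0L) return(FALSE)
  if (is.null(region)) return(TRUE)
  any(h$nt_start >= region[1] & h$nt_end <= region[2])
}

#' Nucleotide composition report
#'
#' Base fractions over A/C/G/T, ignoring N and gaps, and the purine bias
#' `(A + G) - (C + T)`.
#'
#' @param sequence DNA string (possibly gapped).
#' @return list: `fractions` (named, rounded to 4 decimals), `counts`,
#'   `purine_bias`.
#' @export
composition <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  ch <- seq_chars(toupper(sequence))
  ch <- ch[ch %in% DNA_BASES]
  if (length(ch) == 0L) stop("undefined composition: no A/C/G/T characters")
  counts <- table(factor(ch, levels = DNA_BASES))
  fr <- as.numeric(counts) / length(ch)
  names(fr) <- DNA_BASES
  list(fractions = round(fr, 4),
       counts = setNames(as.integer(counts), DNA_BASES),
       purine_bias = round((fr["A"] + fr["G"]) - (fr["C"] + fr["T"]), 4))
}

#' Longest ORF in the pre-gag leader
#'
#' Longest ATG-initiated, stop-terminated open reading frame of at least
#' `min_orf_len` nt across the three forward frames; ties broken by 5'-most
#' start. ORF length includes the stop codon.
#'
#' @param sequence pre-gag DNA.
#' @param min_orf_len minimum ORF length in nt (default 300).
#' @return 0-based half-open `c(start, end)` or `NULL`.
#' @export
find_pregag_orf <- function(sequence, min_orf_len = 300L) {
  best <- NULL
  n <- nchar(sequence)
  for (frame in 0:2) {
    aa <- translate_frame(sequence, frame)
    if (!nzchar(aa)) next
    aach <- seq_chars(aa)
    stops <- which(aach == "*")
    starts <- which(aach == "M")
    prev_stop <- 0L
    for (st in stops) {
      ms <- starts[starts > prev_stop & starts < st]
      if (length(ms)) {
        m0 <- ms[1]
        len_nt <- 3L * (st - m0 + 1L)
        if (len_nt >= min_orf_len &&
            (is.null(best) || len_nt > best$len ||
             (len_nt == best$len && frame + 3L * (m0 - 1L) < best$start))) {
          best <- list(start = frame + 3L * (m0 - 1L),
                       end = frame + 3L * st, len = len_nt)
        }
      }
      prev_stop <- st
    }
  }
  if (is.null(best)) return(NULL)
  c(start = best$start, end = best$end)
}

#' Intactness of a sequence versus a reference
#'
#' Dot-plot-style shared-segment coverage: exact `k`-mer matches between
#' sequence and reference are chained along diagonals, chains are merged
#' into segments of at least `min_segment` nt, and coverage is the fraction
#' of reference positions covered by any segment. With a threshold
#' (default 0.6) this reproduces a "reasonably intact" selection step.
#'
#' @param sequence query DNA.
#' @param reference reference DNA.
#' @param k k-mer size (>= 8).
#' @param min_segment minimum merged segment length (nt).
#' @param max_gap maximum within-diagonal gap merged into one segment.
#' @return list: `coverage` (fraction of reference covered), `segments`
#'   (data.frame `qstart, qend, rstart, rend` 0-based half-open).
#' @export
intactness <- function(sequence, reference, k = 12L, min_segment = 30L,
                       max_gap = 25L) {
  if (k < 8L) stop("k must be >= 8")
  m <- kmer_matches(sequence, reference, k)
  rlen <- nchar(reference)
  if (nrow(m) == 0L) {
    return(list(coverage = 0, segments = data.frame(
      qstart = integer(0), qend = integer(0),
      rstart = integer(0), rend = integer(0))))
  }
  m$diag <- m$spos - m$qpos
  segs <- NULL
  for (d in unique(m$diag)) {
    md <- m[m$diag == d, , drop = FALSE]
    iv <- merge_intervals(md$spos, md$spos + k - 1L, gap = max_gap)
    iv <- iv[iv$end - iv$start + 1L >= min_segment, , drop = FALSE]
    if (nrow(iv)) {
      segs <- rbind(segs, data.frame(
        qstart = iv$start - d - 1L, qend = iv$end - d,
        rstart = iv$start - 1L, rend = iv$end))
    }
  }
  if (is.null(segs)) {
    return(list(coverage = 0, segments = data.frame(
      qstart = integer(0), qend = integer(0),
      rstart = integer(0), rend = integer(0))))
  }
  cov_iv <- merge_intervals(segs$rstart + 1L, segs$rend)
  list(coverage = sum(cov_iv$end - cov_iv$start + 1L) / rlen,
       segments = segs[order(segs$rstart), , drop = FALSE])
}

#' Annotate one proviral locus
#'
#' Convenience wrapper chaining [locate_ltrs()], [find_pbs()],
#' [scan_motifs()], [composition()] and [find_pregag_orf()] on a locus
#' sequence. Gene boundaries for motif presence calls are taken from
#' `gene_regions` when given (e.g. consensus-anchored coordinates).
#'
#' @param sequence locus DNA.
#' @param trna_library PBS library.
#' @param gene_regions optional named list of 0-based half-open `c(start,
#'   end)` regions (`gag`, `pol`, `pregag`).
#' @param ... passed to [locate_ltrs()].
#' @return list with elements `ltrs`, `pbs`, `motifs`, `presence`,
#'   `composition`, `pregag_orf`.
#' @export
annotate_provirus <- function(sequence, trna_library = trna_pbs_library(),
                              gene_regions = NULL, ...) {
  ltrs <- locate_ltrs(sequence, ...)
  pbs <- if (!is.null(ltrs)) {
    find_pbs(sequence, ltrs$ltr5[["end"]], trna_library)
  } else {
    list(present = NA, reason = "no LTR pair located")
  }
  hits <- scan_motifs(sequence)
  presence <- c(
    PBS = isTRUE(pbs$present),
    ZF1 = motif_present(hits, "ZF1", gene_regions$gag),
    ZF2 = motif_present(hits, "ZF2", gene_regions$gag),
    GPYF = motif_present(hits, "GPYF", gene_regions$pol)
  )
  orf <- NULL
  if (!is.null(ltrs) && !is.null(gene_regions$gag)) {
    pregag_seq <- substr(sequence, ltrs$ltr5[["end"]] + 1L,
                         gene_regions$gag[1])
    if (nchar(pregag_seq) >= 3L) orf <- find_pregag_orf(pregag_seq)
  }
  list(ltrs = ltrs, pbs = pbs, motifs = hits, presence = presence,
       composition = composition(sequence), pregag_orf = orf)
}
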