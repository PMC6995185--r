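#' Scan a genome for ERV-like insertions
#'
#' Seeded k-mer search replacing a BLAT-style similarity search: exact
#' 12-mer seed matches against the LTR and internal reference probes are
#' clustered (at least `min_seeds` seeds per cluster), clusters closer than
#' `merge_gap` nt are merged into candidate loci, and each candidate is
#' reported once with up to `flank_len` nt of flanking sequence. Both
#' strands are scanned; minus-strand candidates are reported with strand
#' `"-"` and reverse-complemented sequence (flanks swapped accordingly).
#'
#' @param genome genome DNA string.
#' @param ltr_reference LTR probe sequence.
#' @param internal_reference internal-region probe sequence.
#' @param k seed length.
#' @param min_seeds minimum seeds per cluster.
#' @param min_span minimum seed-cluster span (nt) before extension.
#' @param merge_gap clusters closer than this many nt are merged (also the
#'   maximum within-cluster seed gap for the LTR probe; the internal probe
#'   tolerates larger gaps).
#' @param contig contig name used in output.
#' @param flank_len flank length to attach (nt).
#' @return data.frame of candidates: `contig, start, end` (0-based
#'   half-open), `strand, n_seeds, sequence, flank5, flank3`.
#' @export
scan_genome <- function(genome, ltr_reference, internal_reference,
                        k = 12L, min_seeds = 2L, min_span = 30L,
                        merge_gap = 100L, contig = "genome",
                        flank_len = 500L) {
  if (!nzchar(ltr_reference) || !nzchar(internal_reference)) {
    stop("references must be non-empty")
  }
  glen <- nchar(genome)
  band_width <- 40L
  # ungapped x-drop extension along one diagonal; +1 match / -1 mismatch,
  # stops when the running score falls 10 below its maximum (~55% identity
  # drop-off). Returns the number of extra genome positions kept.
  extend_diag <- function(gch, pch, gpos, ppos, step) {
    score <- 0; best <- 0; best_off <- 0L; off <- 0L
    while (TRUE) {
      gi <- gpos + step * (off + 1L); pi <- ppos + step * (off + 1L)
      if (gi < 1L || gi > length(gch) || pi < 1L || pi > length(pch)) break
      off <- off + 1L
      score <- score + if (gch[gi] == pch[pi]) 1 else -1
      if (score > best) { best <- score; best_off <- off }
      if (score < best - 10) break
    }
    best_off
  }
  scan_strand <- function(g) {
    gch <- seq_chars(g)
    iv <- NULL
    probes <- list(list(seq = ltr_reference, gap = merge_gap),
                   list(seq = internal_reference, gap = 400L))
    for (pr in probes) {
      pch <- seq_chars(pr$seq)
      m <- kmer_matches(g, pr$seq, k)
      if (nrow(m) == 0L) next
      m$band <- (m$qpos - m$spos) %/% band_width
      for (b in unique(m$band)) {
        mb <- m[m$band == b, , drop = FALSE]
        cl <- merge_intervals(mb$qpos, mb$qpos + k - 1L, gap = pr$gap)
        for (i in seq_len(nrow(cl))) {
          inb <- mb$qpos >= cl$start[i] & mb$qpos <= cl$end[i]
          if (sum(inb) < min_seeds ||
              cl$end[i] - cl$start[i] + 1L < min_span) next
          q_l <- min(mb$qpos[inb]); s_l <- mb$spos[inb][which.min(mb$qpos[inb])]
          q_r <- max(mb$qpos[inb]); s_r <- mb$spos[inb][which.max(mb$qpos[inb])]
          ext_l <- extend_diag(gch, pch, q_l, s_l, -1L)
          ext_r <- extend_diag(gch, pch, q_r + k - 1L, s_r + k - 1L, 1L)
          iv <- rbind(iv, data.frame(start = cl$start[i] - ext_l,
                                     end = cl$end[i] + ext_r,
                                     n = sum(inb)))
        }
      }
    }
    if (is.null(iv)) return(NULL)
    merged <- merge_intervals(iv$start, iv$end, gap = merge_gap)
    merged$n <- vapply(seq_len(nrow(merged)), function(i) {
      sum(iv$n[iv$start >= merged$start[i] - merge_gap &
                 iv$end <= merged$end[i] + merge_gap])
    }, numeric(1))
    merged
  }
  res <- NULL
  fwd <- scan_strand(genome)
  if (!is.null(fwd)) {
    fwd$strand <- "+"
    res <- rbind(res, fwd)
  }
  rc <- scan_strand(revcomp(genome))
  if (!is.null(rc)) {
    # map back to forward coordinates
    s <- glen - rc$end + 1L
    e <- glen - rc$start + 1L
    rc$start <- s; rc$end <- e
    rc$strand <- "-"
    res <- rbind(res, rc)
  }
  if (is.null(res)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_seeds = numeric(0), sequence = character(0),
                      flank5 = character(0), flank3 = character(0),
                      stringsAsFactors = FALSE))
  }
  # overlapping +/- calls: keep the strand with more supporting seeds
  res <- res[order(-res$n), , drop = FALSE]
  keep <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (res$start[i] <= res$end[j] + merge_gap &&
          res$end[i] >= res$start[j] - merge_gap) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  out <- data.frame(contig = contig, start = res$start - 1L,
                    end = res$end, strand = res$strand,
                    n_seeds = res$n, stringsAsFactors = FALSE)
  seqs <- substr(rep(genome, nrow(out)), out$start + 1L, out$end)
  f5 <- substr(rep(genome, nrow(out)), pmax(0L, out$start - flank_len) + 1L,
               out$start)
  f3 <- substr(rep(genome, nrow(out)), out$end + 1L,
               pmin(glen, out$end + flank_len))
  minus <- out$strand == "-"
  out$sequence <- ifelse(minus, vapply(seqs, revcomp, ""), seqs)
  out$flank5 <- ifelse(minus, vapply(f3, revcomp, ""), f5)
  out$flank3 <- ifelse(minus, vapply(f5, revcomp, ""), f3)
  rownames(out) <- NULL
  out
}

#' Processed-pseudogene hallmark flags
#'
#' A processed pseudogene (LINE-1-retrotransposed proviral mRNA) starts in
#' the 5'LTR R region and ends in the 3'LTR R region, so its 5'LTR lacks U3,
#' its 3'LTR lacks U5, and a poly-A tract lies just downstream. Each
#' hallmark is tested by free-end-gap alignment of the locus terminus to the
#' LTR reference: a region counts as deleted when less than half of its
#' reference columns are covered.
#'
#' @param sequence locus DNA.
#' @param flank3 3' flanking sequence (searched for the poly-A tract).
#' @param ltr_reference LTR reference sequence.
#' @param u3_len,r_len,u5_len U3/R/U5 sub-lengths on the reference
#'   (`u3_len + r_len + u5_len == nchar(ltr_reference)`).
#' @param polya_min minimum poly-A run length (default 12; up to one
#'   mismatch allowed).
#' @param polya_window poly-A run must start within this many nt downstream.
#' @return named logical vector `c(u3_deleted, u5_deleted, polyA)`.
#' @export
pseudogene_hallmarks <- function(sequence, flank3, ltr_reference,
                                 u3_len, r_len, u5_len,
                                 polya_min = 12L, polya_window = 30L) {
  stopifnot(u3_len + r_len + u5_len == nchar(ltr_reference))
  ltr_len <- nchar(ltr_reference)
  end5 <- substr(sequence, 1L, min(nchar(sequence), ltr_len + 150L))
  end3 <- substr(sequence, max(1L, nchar(sequence) - ltr_len - 150L),
                 nchar(sequence))
  ref_cover <- function(query) {
    aln <- align_pair(query, ltr_reference, type = "overlap")
    if (Biostrings::nmatch(aln) < 30L) return(c(0L, 0L)) # no credible hit
    s <- Biostrings::subject(aln)
    c(Biostrings::start(s), Biostrings::end(s))
  }
  cov5 <- ref_cover(end5)
  cov3 <- ref_cover(end3)
  frac_covered <- function(cov, lo, hi) {
    if (cov[2] == 0L) return(0)
    max(0L, min(cov[2], hi) - max(cov[1], lo) + 1L) / (hi - lo + 1L)
  }
  u3_deleted <- frac_covered(cov5, 1L, u3_len) < 0.5
  u5_deleted <- frac_covered(cov3, u3_len + r_len + 1L, ltr_len) < 0.5
  # poly-A: window of length polya_min with <= 1 non-A, starting <=
  # polya_window nt downstream
  polya <- FALSE
  fl <- seq_chars(substr(flank3, 1L, polya_window + polya_min))
  if (length(fl) >= polya_min) {
    is_a <- as.integer(fl == "A")
    runsum <- cumsum(is_a)
    for (s0 in seq_len(min(polya_window, length(fl) - polya_min + 1L))) {
      n_a <- runsum[s0 + polya_min - 1L] - if (s0 > 1L) runsum[s0 - 1L] else 0L
      if (n_a >= polya_min - 1L) { polya <- TRUE; break }
    }
  }
  c(u3_deleted = u3_deleted, u5_deleted = u5_deleted, polyA = polya)
}

#' Classify a candidate locus
#'
#' Solitary LTRs are distinguished from proviral LTRs by the presence of
#' internal proviral sequence: a candidate whose own sequence matches the
#' internal reference is full length (provirus, or processed pseudogene when
#' the U3/U5-truncation and poly-A hallmarks are all present); otherwise the
#' two flanks are checked against 1000-nt terminal probes of the internal
#' reference (coverage >= `internal_coverage` in either flank means the
#' candidate LTR belongs to a provirus), and a candidate with no internal
#' match anywhere is a solitary LTR.
#'
#' @param candidate one row of the [scan_genome()] output (list or
#'   data.frame row with `sequence`, `flank5`, `flank3`).
#' @param internal_reference internal-region reference.
#' @param ltr_reference LTR reference.
#' @param u3_len,r_len,u5_len LTR sub-boundaries on the reference.
#' @param internal_coverage coverage threshold for an internal-region match
#'   (default 0.2).
#' @param probe_len terminal internal probe length (default 1000).
#' @return list: `call` in `provirus, solo_ltr, processed_pseudogene,
#'   proviral_ltr, ambiguous`, `evidence` (named numerics/flags).
#' @export
classify_ltr_locus <- function(candidate, internal_reference, ltr_reference,
                               u3_len = 350L, r_len = 100L, u5_len = 150L,
                               internal_coverage = 0.2, probe_len = 1000L) {
  seqs <- candidate$sequence
  if (is.na(seqs) || !nzchar(seqs)) {
    return(list(call = "ambiguous", evidence = list(reason = "no sequence")))
  }
  own_cov <- intactness(seqs, internal_reference)$coverage
  ltr_len <- nchar(ltr_reference)
  if (own_cov >= internal_coverage &&
      nchar(seqs) > ltr_len + probe_len / 2) {
    flags <- pseudogene_hallmarks(seqs, candidate$flank3, ltr_reference,
                                  u3_len, r_len, u5_len)
    call <- if ((flags[["u3_deleted"]] || flags[["u5_deleted"]]) &&
                flags[["polyA"]]) "processed_pseudogene" else "provirus"
    return(list(call = call,
                evidence = c(list(internal_coverage = own_cov),
                             as.list(flags))))
  }
  # LTR-sized candidate: look for internal sequence in the flanks
  if (!nzchar(candidate$flank5 %||% "") && !nzchar(candidate$flank3 %||% "")) {
    return(list(call = "ambiguous",
                evidence = list(reason = "missing flanks")))
  }
  probe5 <- substr(internal_reference, 1L,
                   min(probe_len, nchar(internal_reference)))
  probe3 <- substr(internal_reference,
                   max(1L, nchar(internal_reference) - probe_len + 1L),
                   nchar(internal_reference))
  cov_down <- intactness(candidate$flank3, probe5)$coverage
  cov_up <- intactness(candidate$flank5, probe3)$coverage
  call <- if (max(cov_down, cov_up) >= internal_coverage) "proviral_ltr"
          else "solo_ltr"
  list(call = call,
       evidence = list(internal_coverage = own_cov,
                       flank_cov_down = cov_down, flank_cov_up = cov_up))
}

#' Scan and classify a whole genome
#'
#' Runs [scan_genome()] and [classify_ltr_locus()] on every candidate.
#'
#' @inheritParams scan_genome
#' @inheritParams classify_ltr_locus
#' @param species species tag for the output table.
#' @return data.frame: candidate columns plus `call` and hallmark evidence.
#' @export
classify_genome <- function(genome, ltr_reference, internal_reference,
                            u3_len = 350L, r_len = 100L, u5_len = 150L,
                            species = "genome", ...) {
  cand <- scan_genome(genome, ltr_reference, internal_reference,
                      contig = species, ...)
  if (nrow(cand) == 0L) {
    cand$call <- character(0)
    return(cand)
  }
  calls <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cl <- classify_ltr_locus(cand[i, ], internal_reference, ltr_reference,
                             u3_len, r_len, u5_len)
    calls[i] <- cl$call
  }
  cand$call <- calls
  cand$species <- species
  cand
}

#' Detect orthologous insertions between two species
#'
#' Scores all locus pairs between species A and B by free-end-gap global
#' alignment identity of their 5' flanks and of their 3' flanks. A pair is
#' supported when both identities reach `threshold` over at least
#' `min_overlap` aligned nt. Each locus joins at most one supported pair
#' (greedy matching by combined identity). Pairs sharing fewer than
#' `prefilter_kmers` exact 12-mers across both flanks are skipped without
#' alignment.
#'
#' @param loci_a,loci_b lists of `proviral_locus` (or data.frames with
#'   `id`/`locus_id`, `flank5`, `flank3` columns).
#' @param threshold identity threshold (default 0.75).
#' @param min_overlap minimum aligned flank overlap (nt).
#' @param prefilter_kmers minimum shared 12-mer seeds before aligning.
#' @return data.frame: `locus_id_A, locus_id_B, flank5_identity,
#'   flank3_identity, supported`.
#' @export
find_orthologs <- function(loci_a, loci_b, threshold = 0.75,
                           min_overlap = 200L, prefilter_kmers = 5L) {
  get_field <- function(x, f) {
    if (is.data.frame(x)) x[[f]] else vapply(x, function(l) {
      if (f == "id") l$id else l[[f]]
    }, character(1))
  }
  ids_a <- get_field(loci_a, if (is.data.frame(loci_a) &&
                                 "locus_id" %in% names(loci_a)) "locus_id"
                     else "id")
  ids_b <- get_field(loci_b, if (is.data.frame(loci_b) &&
                                 "locus_id" %in% names(loci_b)) "locus_id"
                     else "id")
  f5a <- get_field(loci_a, "flank5"); f3a <- get_field(loci_a, "flank3")
  f5b <- get_field(loci_b, "flank5"); f3b <- get_field(loci_b, "flank3")
  pairs <- NULL
  for (i in seq_along(ids_a)) {
    for (j in seq_along(ids_b)) {
      shared <- nrow(kmer_matches(paste0(f5a[i], "N", f3a[i]),
                                  paste0(f5b[j], "N", f3b[j]), 12L))
      if (shared < prefilter_kmers) next
      a5 <- align_pair(f5a[i], f5b[j])
      a3 <- align_pair(f3a[i], f3b[j])
      len5 <- nchar(as.character(Biostrings::alignedPattern(a5)))
      len3 <- nchar(as.character(Biostrings::alignedPattern(a3)))
      id5 <- aln_identity(a5); id3 <- aln_identity(a3)
      supported <- id5 >= threshold && id3 >= threshold &&
        len5 >= min_overlap && len3 >= min_overlap
      pairs <- rbind(pairs, data.frame(
        locus_id_A = ids_a[i], locus_id_B = ids_b[j],
        flank5_identity = id5, flank3_identity = id3,
        supported = supported, stringsAsFactors = FALSE))
    }
  }
  if (is.null(pairs)) {
    return(data.frame(locus_id_A = character(0), locus_id_B = character(0),
                      flank5_identity = numeric(0),
                      flank3_identity = numeric(0), supported = logical(0)))
  }
  # greedy 1-to-1 assignment among supported pairs
  sup <- pairs[pairs$supported, , drop = FALSE]
  sup <- sup[order(-(sup$flank5_identity + sup$flank3_identity)), ,
             drop = FALSE]
  used_a <- character(0); used_b <- character(0); keep <- logical(nrow(sup))
  for (i in seq_len(nrow(sup))) {
    if (!(sup$locus_id_A[i] %in% used_a) &&
        !(sup$locus_id_B[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, sup$locus_id_A[i])
      used_b <- c(used_b, sup$locus_id_B[i])
    }
  }
  sup[keep, , drop = FALSE]
}
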