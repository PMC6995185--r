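#' Pre-gag leader length
#'
#' Length of the leader between the end of the 5'LTR and the gag start
#' codon, in nt (0-based half-open coordinates, so simply
#' `gag_start - ltr5_end`).
#'
#' @param ltr5_end 0-based position just past the 5'LTR.
#' @param gag_start 0-based gag start.
#' @return integer length.
#' @export
leader_length <- function(ltr5_end, gag_start) {
  if (is.null(ltr5_end) || is.null(gag_start) ||
      is.na(ltr5_end) || is.na(gag_start)) {
    stop("leader length needs both the 5'LTR end and the gag start")
  }
  as.integer(gag_start) - as.integer(ltr5_end)
}

#' Detect intron-like splice signals in a pre-gag leader
#'
#' Treats the leader termini as the putative intron boundaries: the splice
#' donor is present when the leader starts `GT`, the splice acceptor when
#' it ends `AG`; a branch-point motif `CTA/GAC/T` (i.e. `CT[AG]A[CT]`) is
#' searched within a window upstream of the acceptor; the polypyrimidine
#' fraction is `(C+T)` over the 20 nt before the acceptor dinucleotide.
#'
#' @param leader leader DNA (>= 30 nt).
#' @param branch_window how far upstream of the acceptor the branch motif
#'   may start (default 60 nt).
#' @param min_branch_gap minimum gap between branch motif and acceptor
#'   (default 10 nt).
#' @param py_window window for the polypyrimidine fraction (default 20 nt).
#' @return list (`splice_signal_set`): `sd_present`, `sa_present`,
#'   `branch_present`, `branch_pos` (0-based, `NA` when absent),
#'   `polypyrimidine_fraction`.
#' @export
detect_splice_signals <- function(leader, branch_window = 60L,
                                  min_branch_gap = 10L, py_window = 20L) {
  n <- nchar(leader)
  if (n < 30L) stop("leader shorter than 30 nt")
  leader <- toupper(leader)
  sd_present <- substr(leader, 1L, 2L) == "GT"
  sa_present <- substr(leader, n - 1L, n) == "AG"
  sa_pos <- n - 2L # 0-based position of the acceptor "A"
  branch_present <- FALSE
  branch_pos <- NA_integer_
  m <- gregexpr("CT[AG]A[CT]", leader)[[1]]
  if (m[1] != -1L) {
    pos0 <- m - 1L # 0-based motif starts
    ok <- pos0 >= sa_pos - branch_window & pos0 <= sa_pos - min_branch_gap
    if (any(ok)) {
      branch_present <- TRUE
      branch_pos <- max(pos0[ok]) # 3'-most qualifying occurrence
    }
  }
  py_start <- max(0L, sa_pos - py_window)
  py <- seq_chars(substr(leader, py_start + 1L, sa_pos))
  pyf <- if (length(py)) sum(py %in% c("C", "T")) / length(py) else NA_real_
  list(sd_present = sd_present, sa_present = sa_present,
       branch_present = branch_present, branch_pos = branch_pos,
       polypyrimidine_fraction = pyf)
}

#' Shared segments between two leader sequences
#'
#' Dot-plot style: exact `k`-mer matches are chained along diagonals and
#' merged into segments of at least `min_segment` nt; each segment's
#' identity is computed from the gap-free comparison of the spanned
#' regions. Segments are reported with 0-based half-open coordinates in
#' both sequences; `shared_segments(A, B)` is the coordinate mirror of
#' `shared_segments(B, A)`.
#'
#' @param leader_a,leader_b DNA sequences (each >= `k` nt).
#' @param k k-mer size (default 12).
#' @param min_segment minimum segment length (default 50 nt).
#' @param max_gap maximum within-diagonal gap chained into one segment.
#' @return data.frame: `a_start, a_end, b_start, b_end, length, identity`.
#' @export
shared_segments <- function(leader_a, leader_b, k = 12L, min_segment = 50L,
                            max_gap = 25L) {
  if (nchar(leader_a) < k || nchar(leader_b) < k) {
    stop("sequences must be at least k nt")
  }
  res <- intactness(leader_a, leader_b, k = k, min_segment = min_segment,
                    max_gap = max_gap)
  segs <- res$segments
  if (nrow(segs) == 0L) {
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      length = integer(0), identity = numeric(0)))
  }
  identity <- vapply(seq_len(nrow(segs)), function(i) {
    a <- seq_chars(substr(leader_a, segs$qstart[i] + 1L, segs$qend[i]))
    b <- seq_chars(substr(leader_b, segs$rstart[i] + 1L, segs$rend[i]))
    mean(a == b)
  }, numeric(1))
  data.frame(a_start = segs$qstart, a_end = segs$qend,
             b_start = segs$rstart, b_end = segs$rend,
             length = segs$qend - segs$qstart, identity = identity)
}

#' Cross-tabulate pre-gag presence against pseudogene calls
#'
#' Checks the expectation that loci lacking the pre-gag portion are
#' processed pseudogenes (the leader is spliced out of the proviral mRNA
#' that a pseudogene derives from). Violations — loci without a pre-gag
#' that are not pseudogenes — are flagged.
#'
#' @param dataset data.frame with columns `locus_id`, `has_pregag`
#'   (logical) and `call` (classification).
#' @return list: `table` (2-way contingency table), `violations`
#'   (data.frame of offending loci), `n_violations`.
#' @export
pregag_presence_splice_consistency <- function(dataset) {
  if (nrow(dataset) == 0L) {
    return(list(table = table(factor(character(0)), factor(character(0))),
                violations = dataset, n_violations = 0L))
  }
  tab <- table(pregag = ifelse(dataset$has_pregag, "present", "absent"),
               call = dataset$call)
  bad <- dataset[!dataset$has_pregag &
                   dataset$call != "processed_pseudogene", , drop = FALSE]
  list(table = tab, violations = bad, n_violations = nrow(bad))
}
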