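#' Remove hypermutable CpG dinucleotide columns from a pairwise alignment
#'
#' Every column belonging to a CpG dinucleotide (C at one position, G at the
#' next, pairing across gaps) is removed; both columns of each CpG are
#' removed. By default a CpG in either row triggers removal (the symmetric
#' rule appropriate for an LTR pair, where neither row is ancestral). With
#' `anchor = "second"` only CpGs of the second row count — the right rule
#' when the second row is an ancestral proxy such as a subgroup consensus,
#' since stripping on the derived row as well would discard genuine
#' substitutions (mutations into C or G that create new CpGs) and bias the
#' divergence down.
#'
#' @param row_i,row_j equal-length gapped DNA strings.
#' @param anchor which row(s) define CpG columns: `"either"` (default),
#'   `"first"`, or `"second"`.
#' @return character vector of the two stripped rows.
#' @export
strip_cpg <- function(row_i, row_j, anchor = c("either", "first", "second")) {
  anchor <- match.arg(anchor)
  a <- seq_chars(toupper(row_i)); b <- seq_chars(toupper(row_j))
  if (length(a) != length(b)) stop("rows must have equal length")
  drop <- logical(length(a))
  rows <- switch(anchor, either = list(a, b), first = list(a),
                 second = list(b))
  for (row in rows) {
    idx <- which(row %in% DNA_BASES) # ungapped positions, in order
    if (length(idx) < 2L) next
    bases <- row[idx]
    cpg <- which(bases[-length(bases)] == "C" & bases[-1L] == "G")
    drop[idx[cpg]] <- TRUE
    drop[idx[cpg + 1L]] <- TRUE
  }
  c(chars_seq(a[!drop]), chars_seq(b[!drop]))
}

#' LTR-LTR molecular-clock age
#'
#' Globally aligns the two LTRs of a provirus (free end gaps), removes CpG
#' columns, computes the p-distance with pairwise deletion, and converts it
#' to an age with `T = D / SR / 2` — halved because each LTR accumulates
#' substitutions independently after integration.
#'
#' @param ltr5,ltr3 LTR sequences (unaligned).
#' @param sr neutral substitution rate (substitutions/nucleotide/My).
#' @param min_sites fewer comparable sites than this flags the estimate as
#'   low-confidence (default 100).
#' @return list: `D`, `T`, `sites`, `low_confidence`; `D`/`T` are `NA` when
#'   no sites are comparable.
#' @export
ltr_age <- function(ltr5, ltr3, sr = 0.0045, min_sites = 100L) {
  stopifnot(sr > 0)
  aln <- align_pair(ltr5, ltr3)
  rows <- aln_strings(aln)
  rows <- strip_cpg(rows[1], rows[2])
  ok <- tryCatch(pairwise_distance(rows[1], rows[2], model = "p"),
                 error = function(e) NULL)
  if (is.null(ok)) {
    return(list(D = NA_real_, T = NA_real_, sites = 0L,
                low_confidence = TRUE))
  }
  list(D = ok$d, T = ok$d / sr / 2, sites = ok$sites_compared,
       low_confidence = ok$sites_compared < min_sites)
}

#' Gene-versus-consensus molecular-clock age
#'
#' Age from the divergence of a proviral gene (typically gag) to the
#' majority consensus of its LTR subgroup: CpG-stripped, pairwise-deleted
#' p-distance, `T = D / SR` (no halving; the consensus approximates the
#' ancestral state).
#'
#' @param gene_seq gene sequence of the locus.
#' @param consensus subgroup gene consensus ([majority_consensus()]).
#' @param sr substitution rate.
#' @param aligned set `TRUE` when the two sequences are already aligned
#'   rows of equal length; otherwise they are globally aligned first.
#' @param anchor CpG-stripping anchor (see [strip_cpg()]); default
#'   `"second"`: the consensus approximates the ancestral state, so its
#'   CpGs define the hypermutable sites.
#' @return list: `D`, `T`, `sites`.
#' @export
gene_consensus_age <- function(gene_seq, consensus, sr = 0.0045,
                               aligned = FALSE, anchor = "second") {
  stopifnot(sr > 0)
  if (!aligned) {
    aln <- align_pair(gene_seq, consensus)
    rows <- aln_strings(aln)
  } else {
    rows <- c(gene_seq, consensus)
  }
  rows <- strip_cpg(rows[1], rows[2], anchor = anchor)
  ok <- tryCatch(pairwise_distance(rows[1], rows[2], model = "p"),
                 error = function(e) NULL)
  if (is.null(ok)) return(list(D = NA_real_, T = NA_real_, sites = 0L))
  list(D = ok$d, T = ok$d / sr, sites = ok$sites_compared)
}

#' Combine per-method age estimates
#'
#' The reported age is the mean of the method estimates, except that when
#' two or more methods disagree too strongly — standard deviation above
#' `cv_threshold`, interpreted relative to the mean (`sd_mode =
#' "relative"`, i.e. a coefficient of variation) or absolute in My
#' (`sd_mode = "absolute"`) — the discordant combination is discarded and
#' the LTR-based estimate (the method applicable to every locus) is kept
#' alone, with the exclusion flagged.
#'
#' @param estimates named numeric vector of per-method ages in My (names
#'   e.g. `ltr`, `gag`); `NA` entries are dropped.
#' @param cv_threshold dispersion threshold (default 0.20).
#' @param sd_mode `"relative"` or `"absolute"`.
#' @return list: `T_combined`, `dispersion` (SD/mean, `NA` with < 2
#'   methods), `methods_used`, `excluded_methods`.
#' @export
combine_ages <- function(estimates, cv_threshold = 0.20,
                         sd_mode = c("relative", "absolute")) {
  sd_mode <- match.arg(sd_mode)
  est <- estimates[!is.na(estimates)]
  if (length(est) == 0L) {
    return(list(T_combined = NA_real_, dispersion = NA_real_,
                methods_used = character(0),
                excluded_methods = character(0),
                reason = "no method estimates"))
  }
  if (length(est) == 1L) {
    return(list(T_combined = unname(est), dispersion = NA_real_,
                methods_used = names(est), excluded_methods = character(0)))
  }
  mu <- mean(est)
  s <- sd(est)
  disp <- if (mu > 0) s / mu else 0
  crit <- if (sd_mode == "relative") disp else s
  if (crit > cv_threshold) {
    keep <- if ("ltr" %in% names(est)) "ltr" else names(est)[1]
    return(list(T_combined = unname(est[[keep]]), dispersion = disp,
                methods_used = keep,
                excluded_methods = setdiff(names(est), keep)))
  }
  list(T_combined = mu, dispersion = disp, methods_used = names(est),
       excluded_methods = character(0))
}

#' Date a set of annotated proviral loci
#'
#' For every locus with a located LTR pair, computes the LTR-LTR clock age;
#' for every locus assigned to a subgroup of at least `min_subgroup_size`
#' members with available gene sequences, additionally the
#' gene-versus-subgroup-consensus age. Per-locus ages are combined with
#' [combine_ages()]. Loci outside any subgroup are dated by the LTR method
#' alone. The summary reports per-subgroup mean/min/max and a Welch t-test
#' of subgroup A ages against all other dated loci.
#'
#' @param loci named list; each element needs `ltr5` and `ltr3` sequences
#'   and optionally `gene` (gag) sequence.
#' @param subgroups data.frame `locus_id, label` (e.g. from
#'   [extract_subgroups()]); may be `NULL`.
#' @param sr substitution rate.
#' @param cv_threshold,sd_mode passed to [combine_ages()].
#' @param min_subgroup_size minimum members for a subgroup consensus.
#' @param consensus_aligned set `TRUE` when gene sequences within a
#'   subgroup are equal-length alignment rows.
#' @return object of class `erv_age_table`: data.frame `locus_id, subgroup,
#'   D_ltr, T_ltr, D_gag, T_gag, T_combined, dispersion, excluded,
#'   low_confidence`, with attributes `summary` (per-subgroup data.frame)
#'   and `t_test` (subgroup A vs rest, or `NULL`).
#' @export
date_dataset <- function(loci, subgroups = NULL, sr = 0.0045,
                         cv_threshold = 0.20, sd_mode = "relative",
                         min_subgroup_size = 5L, consensus_aligned = TRUE) {
  ids <- names(loci)
  if (length(loci) == 0L) {
    out <- data.frame(locus_id = character(0), subgroup = character(0),
                      D_ltr = numeric(0), T_ltr = numeric(0),
                      D_gag = numeric(0), T_gag = numeric(0),
                      T_combined = numeric(0), dispersion = numeric(0),
                      excluded = character(0), low_confidence = logical(0))
    return(structure(out, summary = out[0, 0], t_test = NULL,
                     class = c("erv_age_table", "data.frame")))
  }
  lab <- setNames(rep("other", length(ids)), ids)
  if (!is.null(subgroups)) {
    lab[subgroups$locus_id] <- subgroups$label
  }
  # subgroup gene consensuses (only for labeled subgroups large enough)
  consensuses <- list()
  for (g in setdiff(unique(lab), "other")) {
    members <- ids[lab == g]
    genes <- lapply(loci[members], `[[`, "gene")
    genes <- genes[!vapply(genes, is.null, logical(1))]
    if (length(genes) >= min_subgroup_size &&
        length(unique(nchar(unlist(genes)))) == 1L) {
      consensuses[[g]] <- majority_consensus(
        as_alignment(unlist(genes)))
    }
  }
  rows <- NULL
  for (id in ids) {
    l <- loci[[id]]
    la <- if (!is.null(l$ltr5) && !is.null(l$ltr3)) {
      ltr_age(l$ltr5, l$ltr3, sr)
    } else {
      list(D = NA_real_, T = NA_real_, low_confidence = TRUE)
    }
    ga <- list(D = NA_real_, T = NA_real_)
    g <- lab[[id]]
    if (g %in% names(consensuses) && !is.null(l$gene)) {
      ga <- gene_consensus_age(l$gene, consensuses[[g]], sr,
                               aligned = consensus_aligned &&
                                 nchar(l$gene) == nchar(consensuses[[g]]))
    }
    cmb <- combine_ages(c(ltr = la$T, gag = ga$T), cv_threshold, sd_mode)
    rows <- rbind(rows, data.frame(
      locus_id = id, subgroup = g, D_ltr = la$D, T_ltr = la$T,
      D_gag = ga$D, T_gag = ga$T, T_combined = cmb$T_combined,
      dispersion = cmb$dispersion,
      excluded = paste(cmb$excluded_methods, collapse = ","),
      low_confidence = isTRUE(la$low_confidence),
      stringsAsFactors = FALSE))
  }
  dated <- rows[!is.na(rows$T_combined), , drop = FALSE]
  summ <- do.call(rbind, lapply(split(dated, dated$subgroup), function(d) {
    data.frame(subgroup = d$subgroup[1], n = nrow(d),
               mean_T = mean(d$T_combined), min_T = min(d$T_combined),
               max_T = max(d$T_combined), stringsAsFactors = FALSE)
  }))
  ttest <- NULL
  a_ages <- dated$T_combined[dated$subgroup == "A"]
  rest <- dated$T_combined[dated$subgroup != "A"]
  if (length(a_ages) >= 2L && length(rest) >= 2L &&
      (sd(a_ages) > 0 || sd(rest) > 0)) {
    ttest <- t.test(a_ages, rest)
  }
  structure(rows, summary = summ, t_test = ttest,
            class = c("erv_age_table", "data.frame"))
}

#' @export
print.erv_age_table <- function(x, ...) {
  cat(sprintf("<erv_age_table> %d loci dated (SR-based molecular clock)\n",
              nrow(x)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  summ <- attr(x, "summary")
  if (!is.null(summ) && nrow(summ)) {
    cat("\nPer-subgroup ages (My):\n")
    print.data.frame(summ, digits = 4, row.names = FALSE)
  }
  tt <- attr(x, "t_test")
  if (!is.null(tt)) {
    cat(sprintf("\nWelch t-test, subgroup A vs rest: t = %.3f, p = %.3g\n",
                tt$statistic, tt$p.value))
  }
  invisible(x)
}
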