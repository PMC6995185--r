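#' Read a FASTA file
#'
#' Order of records is preserved. Sequences are upper-cased and RNA `U` is
#' converted to `T`. Characters outside `{A,C,G,T,N,-}` are rejected.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names = full header text
#'   after `>`), in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("FASTA format error at line 1: empty file")
  hdr <- grepl("^>", lines)
  first_content <- which(nzchar(trimws(lines)))[1]
  if (is.na(first_content)) stop("FASTA format error at line 1: empty file")
  if (!hdr[first_content]) {
    stop("FASTA format error at line ", first_content,
         ": expected '>' header")
  }
  ids <- sub("^>\\s*", "", lines[hdr])
  if (any(!nzchar(ids))) {
    stop("FASTA format error at line ", which(hdr & !nzchar(sub("^>\\s*", "", lines)))[1],
         ": empty header")
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(trimws(x), collapse = ""), character(1))
  # records with no sequence lines at all
  out <- setNames(rep("", length(ids)), as.character(seq_along(ids)))
  out[names(seqs)] <- seqs
  out <- toupper(out)
  out <- gsub("U", "T", out, fixed = TRUE)
  bad <- grepl("[^ACGTN-]", out)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("FASTA format error in record '", ids[i],
         "': characters outside {A,C,G,T,N,-}")
  }
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s) == 0L) next
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' All rows must have equal length; gap character is `-`.
#'
#' @param path path to an aligned FASTA file.
#' @return named character vector (class `erv_alignment`) of equal-length
#'   gapped rows.
#' @export
read_alignment <- function(path) {
  seqs <- read_fasta(path)
  as_alignment(seqs)
}

#' Construct an alignment from equal-length gapped sequences
#'
#' @param seqs named character vector.
#' @return the input, validated, with class `erv_alignment`.
#' @export
as_alignment <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("alignment-length error: rows have lengths ",
         paste(unique(lens), collapse = ", "))
  }
  structure(seqs, class = "erv_alignment")
}

#' @export
print.erv_alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d rows x %d columns\n", length(x),
              if (length(x)) nchar(x[[1]]) else 0L))
  invisible(x)
}

# alignment as a character matrix (rows = sequences)
alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(unclass(aln)), "", fixed = TRUE))
}

#' Write a phylogenetic tree to Newick
#'
#' Bootstrap supports (if present as node labels) are written as internal node
#' labels; branch lengths are written with at least 6 significant digits.
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 8)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) ape::read.tree(path)

LOCUS_TABLE_COLS <- c("contig", "start", "end", "strand", "id", "species",
                      "class", "age", "subgroup")

#' Read / write locus tables
#'
#' Locus tables are tab-separated with a fixed BED-like header
#' (`contig, start, end, strand, id, species, class, age, subgroup`).
#' Coordinates in the file are 1-based inclusive; [read_locus_table()]
#' converts them to the internal 0-based half-open convention and
#' [write_locus_table()] converts back, so a round trip is the identity.
#'
#' @param path file path.
#' @return `read_locus_table`: a data.frame with 0-based half-open
#'   `start`/`end`.
#' @export
read_locus_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(LOCUS_TABLE_COLS, names(df))
  if (length(missing)) {
    stop("locus table missing columns: ", paste(missing, collapse = ", "))
  }
  conv <- interval_to_0based(df$start, df$end)
  df$start <- conv$start; df$end <- conv$end
  df
}

#' @rdname read_locus_table
#' @param df data.frame with 0-based half-open coordinates.
#' @export
write_locus_table <- function(df, path) {
  conv <- interval_to_1based(df$start, df$end)
  df$start <- conv$start; df$end <- conv$end
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values that parse
#' as numbers are returned numeric.
#'
#' @param path file path.
#' @return named list of configuration values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("config syntax error: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Default run configuration
#'
#' Central defaults for rates and thresholds used across the pipeline.
#' Every value can be overridden via a config file ([read_config()]) or a
#' function argument.
#'
#' @return named list: `sr` (neutral substitution rate,
#'   substitutions/nucleotide/My), `bootstrap_reps`, `support_threshold`
#'   (percent), `min_subgroup_size`, `pbs_identity_threshold`,
#'   `pbs_search_window` (nt), `min_orf_len` (nt), `intactness_threshold`,
#'   `ortholog_identity_threshold`, `min_flank_overlap` (nt),
#'   `cv_threshold`, `sd_mode`, `cpg_multiplier`, `polya_min` (nt),
#'   `seed`.
#' @export
default_config <- function() {
  list(
    sr = 0.0045,
    bootstrap_reps = 1000,
    support_threshold = 70,
    min_subgroup_size = 5,
    pbs_identity_threshold = 14 / 18,
    pbs_search_window = 30,
    min_orf_len = 300,
    intactness_threshold = 0.6,
    ortholog_identity_threshold = 0.75,
    min_flank_overlap = 200,
    cv_threshold = 0.20,
    sd_mode = "relative",
    cpg_multiplier = 10,
    polya_min = 12,
    seed = 1
  )
}
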