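#' @importFrom stats rbinom runif sd t.test setNames quantile lm coef
#' @importFrom utils read.delim write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# character string -> character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

#' Reverse complement of a DNA string
#'
#' Accepts A/C/G/T/N (and gap "-"); case-insensitive input, uppercase output.
#'
#' @param x single DNA string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# integer codes 0:3 for A/C/G/T, NA for anything else
encode_dna <- function(x) {
  v <- match(seq_chars(toupper(x)), DNA_BASES) - 1L
  v
}

decode_dna <- function(v) chars_seq(DNA_BASES[v + 1L])

# Exact rolling k-mer codes (base-4); NA where the window contains a non-ACGT
# character. Codes fit in integer for k <= 15.
kmer_codes <- function(x, k) {
  v <- if (is.character(x) && length(x) == 1L) encode_dna(x) else x
  n <- length(v)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  code <- integer(m)
  bad <- logical(m)
  for (j in seq_len(k)) {
    vj <- v[j:(j + m - 1L)]
    bad <- bad | is.na(vj)
    vj[is.na(vj)] <- 0L
    code <- code * 4L + vj
  }
  code[bad] <- NA_integer_
  code
}

# All (query_pos, subject_pos) pairs whose k-mers match exactly (1-based).
kmer_matches <- function(query, subject, k) {
  qc <- kmer_codes(query, k)
  sc <- kmer_codes(subject, k)
  qdf <- data.frame(code = qc, qpos = seq_along(qc))
  sdf <- data.frame(code = sc, spos = seq_along(sc))
  qdf <- qdf[!is.na(qdf$code), , drop = FALSE]
  sdf <- sdf[!is.na(sdf$code), , drop = FALSE]
  m <- merge(qdf, sdf, by = "code")
  m[order(m$qpos, m$spos), c("qpos", "spos")]
}

# merge 1-based closed intervals whose gap is <= gap
merge_intervals <- function(starts, ends, gap = 0L) {
  if (length(starts) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1]; out_e <- ends[1]
  res_s <- integer(0); res_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= out_e + gap + 1L) {
      out_e <- max(out_e, ends[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- starts[i]; out_e <- ends[i]
    }
  }
  data.frame(start = c(res_s, out_s), end = c(res_e, out_e))
}

# pairwise global alignment with free end gaps (match +1, mismatch -1, gap -2)
align_pair <- function(a, b, type = "overlap") {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = type, substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2
  )
}

# fraction of identical columns over the aligned region
aln_identity <- function(aln) {
  n <- nchar(as.character(Biostrings::alignedPattern(aln)))
  if (n == 0L) return(0)
  Biostrings::nmatch(aln) / n
}

aln_strings <- function(aln) {
  c(as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
}

random_dna <- function(n) {
  chars_seq(sample(DNA_BASES, n, replace = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
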