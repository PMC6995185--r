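# shared fixtures, built once per test run

fixture_template <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- make_template(seed = 101)
    tpl
  }
})

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  path
}

# extract a template segment by its 0-based half-open coordinates
tpl_segment <- function(tpl, coord) {
  substr(tpl$sequence, coord[["start"]] + 1L, coord[["end"]])
}

# run the full clock-recovery pipeline on simulated proviruses
date_simulated <- function(sim, sr = 0.0045) {
  loci <- list()
  for (l in sim$loci) {
    lt <- locate_ltrs(l$sequence)
    if (is.null(lt)) next
    loci[[l$id]] <- list(
      ltr5 = substr(l$sequence, lt$ltr5[["start"]] + 1L, lt$ltr5[["end"]]),
      ltr3 = substr(l$sequence, lt$ltr3[["start"]] + 1L, lt$ltr3[["end"]]),
      gene = substr(l$sequence, l$annotations$gag[["start"]] + 1L,
                    l$annotations$gag[["end"]]))
  }
  subgroups <- data.frame(locus_id = names(loci),
                          label = "A", stringsAsFactors = FALSE)
  ages <- date_dataset(loci, subgroups, sr = sr)
  merge(as.data.frame(ages), sim$truth, by = "locus_id")
}

# classify both genomes of a make_genome() result against its own templates
classify_both <- function(g) {
  tpl <- g$templates[[1]]
  ltr_ref <- tpl$ltr
  int_ref <- substr(tpl$sequence, tpl$ltr5[["end"]] + 1L, tpl$ltr3[["start"]])
  out <- NULL
  for (sp in names(g$genomes)) {
    cl <- classify_genome(g$genomes[[sp]], ltr_ref, int_ref, species = sp)
    out <- rbind(out, cl)
  }
  out
}

# match candidates to truth rows by overlap; returns truth with matched call
match_truth <- function(candidates, truth) {
  truth$call <- NA_character_
  truth$n_hits <- 0L
  for (i in seq_len(nrow(truth))) {
    ov <- which(candidates$species == truth$species[i] &
                  candidates$start < truth$end[i] &
                  candidates$end > truth$start[i])
    truth$n_hits[i] <- length(ov)
    if (length(ov) == 1L) truth$call[i] <- candidates$call[ov]
  }
  truth
}
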