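test_that("scan_genome reports planted loci once, with accurate bounds", {
  # probe-matched loci (subgroup A, <= 15% divergence from the references)
  g <- make_genome(params = list(n_shared = 0, n_private_provirus = 5,
                                 n_solo = 5, n_pseudo = 0,
                                 private_age_range = c(3, 15),
                                 private_subgroup = "A",
                                 background_len = 80000),
                   seed = 41)
  tpl <- g$templates[[1]]
  int_ref <- substr(tpl$sequence, tpl$ltr5[["end"]] + 1, tpl$ltr3[["start"]])
  cand <- scan_genome(g$genomes[[1]], tpl$ltr, int_ref, contig = "speciesA")
  tr <- g$truth[g$truth$species == "speciesA", ]
  expect_equal(nrow(cand), nrow(tr))
  tr <- tr[order(tr$start), ]
  cand <- cand[order(cand$start), ]
  # divergence <= 15%: coordinates within +/- 20 nt of truth
  expect_true(all(abs(cand$start - tr$start) <= 20))
  expect_true(all(abs(cand$end - tr$end) <= 20))
  expect_true(all(nchar(cand$flank5) == 500))
})

test_that("a genome without insertions yields an empty candidate list", {
  tpl <- fixture_template()
  int_ref <- substr(tpl$sequence, tpl$ltr5[["end"]] + 1, tpl$ltr3[["start"]])
  cand <- scan_genome(random_seq(50000, seed = 42), tpl$ltr, int_ref)
  expect_equal(nrow(cand), 0L)
  expect_error(scan_genome("ACGT", "", int_ref), "non-empty")
})

test_that("minus-strand insertions are reported reverse-complemented", {
  tpl <- fixture_template()
  int_ref <- substr(tpl$sequence, tpl$ltr5[["end"]] + 1, tpl$ltr3[["start"]])
  bg <- random_seq(30000, seed = 43)
  el <- revcomp(tpl$sequence)
  genome <- paste0(substr(bg, 1, 15000), el, substr(bg, 15001, 30000))
  cand <- scan_genome(genome, tpl$ltr, int_ref)
  expect_equal(nrow(cand), 1L)
  expect_identical(cand$strand, "-")
  expect_identical(cand$sequence, tpl$sequence)
  # flank5 of the reported locus is the reverse complement of the genomic
  # right-hand flank
  expect_identical(cand$flank5,
                   revcomp(substr(genome, 15001 + nchar(el),
                                  15500 + nchar(el))))
})

test_that("solo LTRs, proviral LTRs and pseudogenes classify from evidence", {
  tpl <- fixture_template()
  int_ref <- substr(tpl$sequence, tpl$ltr5[["end"]] + 1, tpl$ltr3[["start"]])
  # solitary LTR candidate: LTR sequence, random flanks
  solo <- list(sequence = tpl$ltr, flank5 = random_seq(500, seed = 44),
               flank3 = random_seq(500, seed = 45))
  expect_identical(classify_ltr_locus(solo, int_ref, tpl$ltr)$call,
                   "solo_ltr")
  # 5'LTR of a provirus: downstream flank holds the internal 5' end
  prov5 <- list(sequence = tpl$ltr, flank5 = random_seq(500, seed = 46),
                flank3 = substr(int_ref, 1, 500))
  expect_identical(classify_ltr_locus(prov5, int_ref, tpl$ltr)$call,
                   "proviral_ltr")
  # full-length provirus
  full <- list(sequence = tpl$sequence, flank5 = random_seq(500, seed = 47),
               flank3 = random_seq(500, seed = 48))
  expect_identical(classify_ltr_locus(full, int_ref, tpl$ltr)$call,
                   "provirus")
  # missing flanks are ambiguous
  nof <- list(sequence = tpl$ltr, flank5 = "", flank3 = "")
  expect_identical(classify_ltr_locus(nof, int_ref, tpl$ltr)$call,
                   "ambiguous")
})

test_that("pseudogene hallmarks require truncation plus poly-A", {
  tpl <- fixture_template()
  int_ref <- substr(tpl$sequence, tpl$ltr5[["end"]] + 1, tpl$ltr3[["start"]])
  flags <- pseudogene_hallmarks(tpl$sequence, random_seq(500, seed = 49),
                                tpl$ltr, tpl$u3_len, tpl$r_len, tpl$u5_len)
  expect_false(any(flags)) # intact provirus: all flags off
  # U3-truncated 5'LTR but intact U5 and no poly-A: not a pseudogene
  trunc5 <- substr(tpl$sequence, tpl$u3_len + 1, nchar(tpl$sequence))
  flags2 <- pseudogene_hallmarks(trunc5, random_seq(500, seed = 50),
                                 tpl$ltr, tpl$u3_len, tpl$r_len, tpl$u5_len)
  expect_true(flags2[["u3_deleted"]])
  expect_false(flags2[["u5_deleted"]])
  expect_false(flags2[["polyA"]])
  # full pseudogene: both truncations + poly-A downstream
  body <- paste0(substr(tpl$ltr, tpl$u3_len + 1, tpl$ltr_len), int_ref,
                 substr(tpl$ltr, 1, tpl$u3_len + tpl$r_len))
  flank3 <- paste0("GCGAT", strrep("A", 20), random_seq(475, seed = 51))
  flags3 <- pseudogene_hallmarks(body, flank3, tpl$ltr,
                                 tpl$u3_len, tpl$r_len, tpl$u5_len)
  expect_true(all(flags3))
  cand <- list(sequence = body, flank5 = random_seq(500, seed = 52),
               flank3 = flank3)
  expect_identical(classify_ltr_locus(cand, int_ref, tpl$ltr)$call,
                   "processed_pseudogene")
})

test_that("classification on generated genomes is exact at moderate ages", {
  g <- make_genome(seed = 5) # defaults: ages 5-25 My, both species
  cand <- classify_both(g)
  tr <- match_truth(cand, g$truth)
  expect_true(all(tr$n_hits == 1L))
  expect_equal(mean(tr$call == tr$true_class), 1.0)
  # no spurious candidates
  expect_equal(nrow(cand), nrow(g$truth))
})

test_that("ortholog detection pairs shared insertions and only them", {
  g <- make_genome(params = list(n_shared = 4, n_private_provirus = 4,
                                 n_solo = 0, n_pseudo = 0,
                                 background_len = 80000),
                   seed = 53)
  tr <- g$truth
  la <- g$loci[tr$locus_id[tr$species == "speciesA"]]
  lb <- g$loci[tr$locus_id[tr$species == "speciesB"]]
  ort <- find_orthologs(la, lb)
  truthp <- paste(tr$locus_id[tr$species == "speciesA" &
                                !is.na(tr$ortholog_partner)],
                  tr$ortholog_partner[tr$species == "speciesA" &
                                        !is.na(tr$ortholog_partner)])
  found <- paste(ort$locus_id_A, ort$locus_id_B)
  expect_true(all(found %in% truthp)) # precision 1
  expect_gte(length(found), 3L) # sensitivity on 4 pairs
  expect_true(all(ort$supported))
})

test_that("identical flanks give identity 1 and support", {
  f5 <- random_seq(500, seed = 54); f3 <- random_seq(500, seed = 55)
  a <- list(list(id = "a1", flank5 = f5, flank3 = f3))
  b <- list(list(id = "b1", flank5 = f5, flank3 = f3))
  ort <- find_orthologs(a, b)
  expect_equal(nrow(ort), 1L)
  expect_equal(ort$flank5_identity, 1.0)
  expect_true(ort$supported)
  # unrelated flanks: no pair survives the prefilter
  b2 <- list(list(id = "b2", flank5 = random_seq(500, seed = 56),
                  flank3 = random_seq(500, seed = 57)))
  expect_equal(nrow(find_orthologs(a, b2)), 0L)
})
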