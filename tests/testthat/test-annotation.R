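test_that("locate_ltrs finds exact terminal repeats and rejects noise", {
  tpl <- fixture_template()
  res <- locate_ltrs(tpl$sequence)
  expect_equal(unname(res$ltr5), c(0L, 600L))
  expect_equal(unname(res$ltr3),
               c(nchar(tpl$sequence) - 600L, nchar(tpl$sequence)))
  expect_equal(res$identity, 1.0)
  # random sequence of similar size has no qualifying repeat
  expect_null(locate_ltrs(random_seq(5000, seed = 8)))
  # a solitary LTR must not match itself through the overlapping windows
  expect_null(locate_ltrs(tpl$ltr))
  expect_error(locate_ltrs("ACGT"), "shorter")
})

test_that("locate_ltrs tracks the true repeat in aged proviruses", {
  sim <- simulate_proviruses(5, age_range = rep(15, 5), seed = 9)
  tpl <- sim$templates[[1]]
  for (l in sim$loci) {
    res <- locate_ltrs(l$sequence)
    expect_false(is.null(res))
    expect_lt(abs(res$ltr5[["start"]] - tpl$ltr5[["start"]]), 30)
    expect_lt(abs(res$ltr3[["end"]] - tpl$ltr3[["end"]]), 30)
    # identity ~ 1 - expected pair divergence (2 * 15 * 0.0045, CpG-boosted)
    expect_gt(res$identity, 0.75)
    expect_lt(res$identity, 0.95)
  }
})

test_that("PBS scanning assigns the best library entry above threshold", {
  lib <- trna_pbs_library()
  expect_true(all(nchar(lib) == 18))
  ltr <- random_seq(100, seed = 10)
  # exact Arg entry at offset 0
  locus <- paste0(ltr, lib[["Arg"]], random_seq(50, seed = 11))
  hit <- find_pbs(locus, 100, lib)
  expect_true(hit$present)
  expect_identical(hit$best_trna, "Arg")
  expect_equal(hit$identity, 1.0)
  expect_equal(unname(hit$interval), c(100L, 118L))
})

test_that("PBS below 14/18 identity is called absent", {
  lib <- c(Arg = "AAAAAAAAAAAAAAAAAA", Lys = "CCCCCCCCCCCCCCCCCC")
  # 13/18 As everywhere in the window: below threshold
  locus <- paste0(strrep("G", 50),
                  paste(rep(c("A", "A", "A", "A", "A", "A", "A", "A", "A",
                              "A", "A", "A", "A", "G", "G", "G", "G", "G"),
                            4), collapse = ""))
  hit <- find_pbs(locus, 50, lib, search_window = 0)
  expect_false(hit$present)
  expect_lte(hit$identity, 13 / 18)
})

test_that("PBS ties resolve by identity: 17/18 Arg beats 15/18 Lys", {
  arg <- strrep("A", 18)
  lys <- strrep("C", 18)
  win <- paste0(strrep("A", 17), "C") # 17/18 vs Arg
  win2 <- paste0(strrep("C", 15), "AAA") # 15/18 vs Lys
  locus <- paste0(random_seq(60, seed = 12), win, win2)
  hit <- find_pbs(locus, 60, c(Arg = arg, Lys = lys), search_window = 30)
  expect_identical(hit$best_trna, "Arg")
  expect_equal(hit$identity, 17 / 18)
})

test_that("motif scanning matches patterns and flags internal stops", {
  # in-frame peptide CAACAAAAHAAAAC -> one intact ZF1
  pep <- c("C", "A", "A", "C", "A", "A", "A", "A", "H", "A", "A", "A",
           "A", "C")
  dna <- paste(c(C = "TGT", A = "GCT", H = "CAT")[pep], collapse = "")
  hits <- scan_motifs(dna)
  zf1 <- hits[hits$kind == "ZF1", ]
  expect_equal(nrow(zf1), 1L)
  expect_true(zf1$intact)
  expect_equal(zf1$frame, 0L)
  # same codons with TAA inside the span -> hit with internal_stop
  dna_stop <- paste0(substr(dna, 1, 15), "TAA", substr(dna, 19, nchar(dna)))
  hits2 <- scan_motifs(dna_stop)
  zf1s <- hits2[hits2$kind == "ZF1", ]
  expect_equal(nrow(zf1s), 1L)
  expect_false(zf1s$intact)
  expect_identical(zf1s$failure_reasons, "internal_stop")
  # anchor substitution H -> Y: no ZF hit at all
  pep_y <- pep; pep_y[9] <- "Y"
  dna_y <- paste(c(C = "TGT", A = "GCT", Y = "TAT")[pep_y], collapse = "")
  expect_equal(nrow(scan_motifs(dna_y, "ZF1")), 0L)
})

test_that("GPY/F motif accepts F or Y at the central position", {
  aa_f <- c("W", "A", "G", "P", "F", "S", "V")
  aa_y <- c("W", "A", "G", "P", "Y", "S", "V")
  cod <- c(W = "TGG", A = "GCA", G = "GGA", P = "CCA", F = "TTT",
           S = "TCA", V = "GTA", Y = "TAC")
  hf <- scan_motifs(paste(cod[aa_f], collapse = ""), "GPYF")
  hy <- scan_motifs(paste(cod[aa_y], collapse = ""), "GPYF")
  expect_equal(nrow(hf), 1L)
  expect_equal(nrow(hy), 1L)
  expect_match(hf$aa_sequence, "^W.GPF")
  expect_match(hy$aa_sequence, "^W.GPY")
})

test_that("scanning is pure: identical input gives identical hits", {
  tpl <- fixture_template()
  h1 <- scan_motifs(tpl$sequence)
  h2 <- scan_motifs(paste0(tpl$sequence, ""))
  expect_identical(h1, h2)
})

test_that("composition reports exact fractions and purine bias", {
  cr <- composition("AAAACCGT")
  expect_equal(unname(cr$fractions), c(0.5, 0.25, 0.125, 0.125))
  cr2 <- composition("ACGT")
  expect_equal(unname(cr2$fractions), rep(0.25, 4))
  expect_equal(unname(cr2$purine_bias), 0)
  expect_error(composition("NNNN"), "undefined")
  expect_error(composition(""), "empty")
  # composition of a large uniform sequence converges to 0.25
  cr3 <- composition(random_seq(40000, seed = 13))
  expect_true(all(abs(cr3$fractions - 0.25) < 0.01))
})

test_that("pre-gag ORF finder returns the longest qualifying ORF", {
  tpl <- fixture_template()
  pregag <- tpl_segment(tpl, tpl$pregag)
  orf <- find_pregag_orf(pregag)
  expect_equal(unname(orf),
               unname(tpl$orf - tpl$pregag[["start"]]))
  # stop-rich random sequence holds no >= 300 nt ORF
  expect_null(find_pregag_orf(random_seq(1200, seed = 14)))
  # two ORFs: the longer wins
  orf600 <- paste0("ATG", strrep("GCT", 198), "TAA") # 600 nt
  orf450 <- paste0("ATG", strrep("GCT", 148), "TAA") # 450 nt
  two <- paste0(strrep("T", 30), orf450, strrep("T", 31), orf600)
  found <- find_pregag_orf(two)
  expect_equal(unname(found[["end"]] - found[["start"]]), 600)
  expect_equal(unname(found[["start"]]), 30 + 450 + 31)
})

test_that("intactness coverage reflects shared structure", {
  ref <- random_seq(2000, seed = 15)
  expect_equal(intactness(ref, ref)$coverage, 1.0)
  # unrelated sequence: k = 12 collisions cannot form segments
  other <- random_seq(2000, seed = 16)
  expect_lt(intactness(other, ref)$coverage, 0.01)
  # central 50% deleted -> coverage ~ 0.5
  del <- paste0(substr(ref, 1, 500), substr(ref, 1501, 2000))
  cov <- intactness(del, ref)$coverage
  expect_equal(cov, 0.5, tolerance = 0.05)
  expect_error(intactness(ref, ref, k = 4), "k must be")
})

test_that("motif survival never increases with simulated age", {
  # same per-replicate seed couples the mutation sets across ages (a site
  # mutated at a younger age is also mutated at any older age), so a motif
  # whose anchors are destroyed stays destroyed
  tpl <- fixture_template()
  ages <- c(0, 10, 25, 45)
  pres <- sapply(ages, function(a) {
    n_present <- 0
    for (r in 1:8) {
      s <- evolve(tpl$sequence, a, cpg_multiplier = 10, seed = 170 + r)
      hits <- scan_motifs(s, "ZF1")
      n_present <- n_present +
        any(hits$nt_start == tpl$zf1[["start"]])
    }
    n_present
  })
  expect_true(all(diff(pres) <= 0))
  expect_equal(pres[1], 8) # age 0: always present
})
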