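test_that("pairwise distances follow the closed forms", {
  expect_equal(pairwise_distance("ACGT", "ACGT", "p")$d, 0)
  expect_equal(pairwise_distance("ACGT", "ACGT", "k2p")$d, 0)
  expect_equal(pairwise_distance("ACGT", "ACGA", "p")$d, 0.25)
  # P = 0.1, Q = 0.05 -> d = -1/2 ln(0.75) - 1/4 ln(0.90)
  a <- paste(c(rep("A", 85), rep("A", 10), rep("A", 5)), collapse = "")
  b <- paste(c(rep("A", 85), rep("G", 10), rep("C", 5)), collapse = "")
  r <- pairwise_distance(a, b, "k2p")
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0.05)
  expect_equal(r$d, -0.5 * log(0.75) - 0.25 * log(0.90), tolerance = 1e-9)
  expect_equal(r$d, 0.170181, tolerance = 1e-6)
})

test_that("pairwise deletion excludes gap/N columns from both rows", {
  r <- pairwise_distance("AC-GTN", "ACCG-A", "p")
  expect_equal(r$sites_compared, 3L) # columns 1, 2, 4
  expect_equal(r$d, 0)
  expect_error(pairwise_distance("----", "AAAA"), "zero comparable")
  expect_error(pairwise_distance("ACG", "ACGT"), "equal length")
  # saturation: P + Q too large for the K2P logs
  expect_error(pairwise_distance(strrep("A", 10), strrep("G", 10), "k2p"),
               "saturation")
})

test_that("K2P is at least the p-distance, equal only at zero", {
  set.seed(60)
  anc <- random_seq(800, seed = 61)
  for (age in c(2, 10, 25, 40)) {
    x <- evolve(anc, age)
    y <- evolve(anc, age)
    p <- pairwise_distance(x, y, "p")$d
    k <- pairwise_distance(x, y, "k2p")$d
    if (p == 0) expect_equal(k, 0) else expect_gt(k, p)
  }
})

test_that("distance matrix agrees with an independent implementation", {
  rows <- setNames(sapply(1:5, function(i)
    evolve(random_seq(600, seed = 62), 20, seed = 62 + i)),
    paste0("t", 1:5))
  aln <- as_alignment(rows)
  ours <- distance_matrix(aln, "k2p")
  theirs <- as.matrix(ape::dist.dna(ape::as.DNAbin(
    do.call(rbind, strsplit(tolower(rows), ""))), model = "K80",
    pairwise.deletion = TRUE))
  expect_equal(ours, theirs[rownames(ours), colnames(ours)],
               tolerance = 1e-9, ignore_attr = TRUE)
  oursp <- distance_matrix(aln, "p")
  theirsp <- as.matrix(ape::dist.dna(ape::as.DNAbin(
    do.call(rbind, strsplit(tolower(rows), ""))), model = "raw",
    pairwise.deletion = TRUE))
  expect_equal(oursp, theirsp[rownames(oursp), colnames(oursp)],
               tolerance = 1e-9, ignore_attr = TRUE)
})

# exhaustive least-squares fit over all unrooted topologies (n <= 6)
ls_best_tree <- function(d) {
  taxa <- rownames(d)
  n <- length(taxa)
  # reorder to cladewise: downstream ape routines assume that edge order
  topos <- lapply(phangorn::allTrees(n, rooted = FALSE, tip.label = taxa),
                  ape::reorder.phylo)
  best <- NULL; best_ss <- Inf
  for (tp in topos) {
    X <- sapply(seq_len(nrow(tp$edge)), function(e) {
      tmp <- tp; tmp$edge.length <- replace(rep(0, nrow(tp$edge)), e, 1)
      as.vector(as.dist(ape::cophenetic.phylo(tmp)[taxa, taxa]))
    })
    y <- as.vector(as.dist(d))
    fit <- lm.fit(X, y)
    ss <- sum(fit$residuals^2)
    if (ss < best_ss) {
      best_ss <- ss
      tp$edge.length <- fit$coefficients
      best <- tp
    }
  }
  list(tree = best, ss = best_ss)
}

test_that("NJ recovers additive matrices exactly (vs exhaustive LS oracle)", {
  # the canonical 4-taxon additive matrix
  d4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4["A", "B"] <- 3; d4["A", "C"] <- 5; d4["A", "D"] <- 6
  d4["B", "C"] <- 6; d4["B", "D"] <- 7; d4["C", "D"] <- 7
  d4 <- d4 + t(d4)
  tr <- nj_tree(d4)
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  expect_setequal(round(tr$edge.length, 6), c(1, 2, 3, 4, 1))
  oracle <- ls_best_tree(d4)
  expect_equal(ape::dist.topo(ape::unroot(tr), oracle$tree), 0,
               ignore_attr = TRUE)
  expect_lt(oracle$ss, 1e-12)
  # random additive trees with n = 5, 6: NJ matches the LS oracle
  for (n in 5:6) {
    set.seed(60 + n)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- runif(nrow(true$edge), 0.5, 3)
    dm <- ape::cophenetic.phylo(true)
    tr <- nj_tree(dm)
    oracle <- ls_best_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(true)), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::dist.topo(oracle$tree, ape::unroot(true)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(tr$edge.length), sort(true$edge.length),
                 tolerance = 1e-6)
  }
})

test_that("NJ is invariant to taxon order and validates its input", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  perm <- c("C", "A", "D", "B")
  t1 <- nj_tree(d)
  t2 <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
  dbad <- d; dbad[1, 2] <- 99
  expect_error(nj_tree(dbad), "symmetric")
  dna <- d; dna[1, 2] <- dna[2, 1] <- NA
  expect_error(nj_tree(dna), "non-finite")
  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")
})

test_that("bootstrap supports separate two diverged blocks and are reproducible", {
  anc1 <- fixture_template()$ltr
  anc2 <- evolve(anc1, 40, seed = 65)
  rows <- c(
    setNames(sapply(1:5, function(i) evolve(anc1, 4, seed = 300 + i)),
             paste0("x", 1:5)),
    setNames(sapply(1:5, function(i) evolve(anc2, 4, seed = 400 + i)),
             paste0("y", 1:5)))
  aln <- as_alignment(rows)
  bt1 <- bootstrap_nj(aln, n_reps = 100, seed = 9)
  bt2 <- bootstrap_nj(aln, n_reps = 100, seed = 9)
  expect_identical(bt1$node.label, bt2$node.label)
  # the x|y bipartition is supported in >= 95% of replicates
  sg <- extract_subgroups(bt1, support_threshold = 95, min_size = 5)
  expect_equal(nrow(sg$clades) >= 1, TRUE)
  labx <- sg$assignment$label[grepl("^x", sg$assignment$locus_id)]
  laby <- sg$assignment$label[grepl("^y", sg$assignment$locus_id)]
  expect_equal(length(unique(sub("[0-9]+$", "", labx))), 1L)
  expect_false(sub("[0-9]+$", "", labx[1]) == sub("[0-9]+$", "", laby[1]))
})

test_that("an alignment of identical sequences has no internal structure", {
  rows <- setNames(rep(random_seq(200, seed = 66), 4), paste0("t", 1:4))
  aln <- as_alignment(rows)
  bt <- bootstrap_nj(aln, n_reps = 20, seed = 3)
  sg <- extract_subgroups(bt, support_threshold = 70, min_size = 2)
  expect_equal(nrow(sg$clades), 0L)
  expect_true(all(sg$assignment$label == "other"))
})

test_that("majority consensus applies plurality and gap rules", {
  expect_identical(majority_consensus(as_alignment(
    c(a = "AC", b = "AC", c = "AT"))), "AC")
  # gap-plurality column dropped
  expect_identical(majority_consensus(as_alignment(
    c(a = "A-", b = "A-", c = "AC"))), "A")
  # base ties break alphabetically
  expect_identical(majority_consensus(as_alignment(
    c(a = "G", b = "T"))), "G")
  expect_error(majority_consensus(as_alignment(c(a = "AC"))), "2 rows")
  # idempotence: consensus of {consensus, consensus} is itself
  cons <- majority_consensus(as_alignment(c(a = "ACGT", b = "ACGA")))
  expect_identical(majority_consensus(as_alignment(c(x = cons, y = cons))),
                   cons)
})

test_that("consensus of 30 evolved copies recovers the ancestor", {
  anc <- fixture_template()$ltr
  copies <- setNames(sapply(1:30, function(i)
    evolve(anc, 10, cpg_multiplier = 10, seed = 500 + i)), paste0("c", 1:30))
  cons <- majority_consensus(as_alignment(copies))
  expect_gte(mean(seq_chars(cons) == seq_chars(anc)), 0.99)
})

test_that("subgroup extraction honors support and size thresholds", {
  tr <- ape::read.tree(text = paste0(
    "((a1:1,a2:1,a3:1,a4:1,a5:1,a6:1)95:1,",
    "(b1:1,b2:1,b3:1)80:1,(c1:1,c2:1)50:1);"))
  sg <- extract_subgroups(tr, support_threshold = 70, min_size = 5)
  expect_equal(sg$clades$label, "A")
  expect_equal(sg$clades$support, 95)
  expect_equal(sum(sg$assignment$label == "A"), 6L)
  expect_equal(sum(sg$assignment$label == "other"), 5L)
  # a clade at support 50 never becomes a subgroup
  sg2 <- extract_subgroups(tr, support_threshold = 70, min_size = 2)
  expect_false(any(grepl("^B", sg2$clades$label) &
                     sg2$clades$support < 70))
})

test_that("nested supported clades become sub-labels", {
  tr <- ape::read.tree(text = paste0(
    "((a1:1,a2:1,a3:1,a4:1,a5:1)90:1,",
    "(((b1:1,b2:1,b3:1,b4:1,b5:1)99:1,",
    "(c1:1,c2:1,c3:1,c4:1,c5:1)68:1)90:1,(d1:1,d2:1)40:1):1):0;"))
  sg <- extract_subgroups(tr, support_threshold = 65, min_size = 5)
  # the 10-tip clade at 90 splits into sub-labels at 99 and 68
  big <- sg$clades[sg$clades$size == 10, ]
  expect_equal(nrow(big), 1L)
  subs <- sg$clades[grepl(paste0("^", big$label, "[0-9]"),
                          sg$clades$label), ]
  expect_setequal(subs$support, c(99, 68))
  expect_true(all(table(sg$assignment$label[grepl("^b|^c",
    sg$assignment$locus_id)]) == 5))
})
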