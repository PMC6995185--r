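#' Synthetic tRNA primer-binding-site library
#'
#' A small synthetic library of 18-nt PBS-complementary sequences keyed by
#' amino-acid type, shipped as `inst/extdata/trna_pbs_synthetic.fasta`.
#' The sequences are fixed arbitrary 18-mers, except that the Trp entry is
#' deliberately only 2 nt away from the Arg entry, mirroring the
#' near-identity of the tRNA-Arg and tRNA-Trp primer sites in real
#' gammaretroviruses.
#'
#' @param path path to a PBS library FASTA; defaults to the bundled
#'   synthetic library.
#' @return named character vector of 18-nt sequences, names = amino-acid
#'   labels (e.g. `"Arg"`).
#' @export
trna_pbs_library <- function(path = system.file("extdata",
                                                "trna_pbs_synthetic.fasta",
                                                package = "ervwtools")) {
  lib <- read_fasta(path)
  if (any(nchar(lib) != 18L)) stop("PBS library entries must be 18 nt")
  lib
}

# sample amino acids for motif spacer positions (no stop, avoids anchor
# residues so spacers can never extend an anchor match)
sample_aa <- function(n) {
  sample(c("A", "D", "E", "F", "G", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V"), n, replace = TRUE)
}

# codons per amino acid (standard genetic code)
AA_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

# encode an amino-acid vector, drawing synonymous codons at random
aa_to_dna <- function(aa) {
  paste(vapply(aa, function(x) {
    cods <- AA_CODONS[[x]]
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, character(1)), collapse = "")
}

# random in-frame coding DNA of n_codons codons without stop codons
random_codons <- function(n_codons) {
  aa_to_dna(sample_aa(n_codons))
}

#' Build a synthetic provirus template
#'
#' Constructs an age-zero provirus with the classical gammaretroviral layout
#' `LTR - PBS - pre-gag - gag - pro - pol - env - LTR` and all diagnostic
#' features planted: an 18-nt PBS taken from the tRNA library, Gag
#' nucleocapsid zinc fingers I (`Cx2Cx4Hx4C`) and II (`Cx2Cx3Hx4C`) in frame
#' within gag, the Pol integrase `WxGP[F/Y]xV` motif, and a pre-gag leader
#' carrying splice-donor (`GT...`), branch (`CTAAC`), polypyrimidine and
#' splice-acceptor (`...AG`) signals plus an embedded ORF. The two LTRs are
#' identical, as at the moment of integration.
#'
#' Subgroup variants alter the LTR: subgroup `"B"` carries a 110-nt deletion
#' in U3; subgroup `"B1"` additionally carries a 200-nt insertion.
#'
#' @param params optional list overriding defaults: `ltr_len` (600; split as
#'   `u3_len` 350, `r_len` 100, `u5_len` 150), `pregag_len` (1000),
#'   `gag_len` (1500), `pro_len` (900), `pol_len` (2601), `env_len` (1998),
#'   `orf_len` (933), `pbs_trna` ("Arg"), `subgroup` ("A"), `trna_library`.
#' @param seed integer seed; the template is deterministic given
#'   `(params, seed)`.
#' @return object of class `provirus_template`: the full sequence plus
#'   0-based feature coordinates (LTRs, U3/R/U5 boundaries, PBS, genes,
#'   motifs, pre-gag ORF).
#' @export
make_template <- function(params = list(), seed = 1) {
  p <- utils::modifyList(list(
    ltr_len = 600L, u3_len = 350L, r_len = 100L, u5_len = 150L,
    pregag_len = 1000L, gag_len = 1500L, pro_len = 900L,
    pol_len = 2601L, env_len = 1998L, orf_len = 933L,
    pbs_trna = "Arg", subgroup = "A",
    trna_library = NULL
  ), params)
  stopifnot(p$u3_len + p$r_len + p$u5_len == p$ltr_len)
  if (p$pregag_len < p$orf_len + 40L) {
    stop("pregag_len too short to host the ORF and splice signals")
  }
  if (p$gag_len < 3L * 40L) stop("gag_len too short to host zinc fingers")
  if (p$pol_len < 3L * 30L) stop("pol_len too short to host the GPY/F motif")
  set.seed(seed)

  lib <- p$trna_library %||% trna_pbs_library()
  if (!p$pbs_trna %in% names(lib)) {
    stop("tRNA type '", p$pbs_trna, "' not in library")
  }
  pbs <- unname(lib[[p$pbs_trna]])

  u3 <- random_dna(p$u3_len)
  r <- random_dna(p$r_len)
  u5 <- random_dna(p$u5_len)
  if (p$subgroup %in% c("B", "B1")) {
    if (p$u3_len < 160L) stop("u3_len too short for the subgroup-B deletion")
    u3 <- paste0(substr(u3, 1, 25), substr(u3, 136, p$u3_len))
  }
  if (p$subgroup == "B1") {
    u3 <- paste0(substr(u3, 1, 50), random_dna(200L),
                 substr(u3, 51, nchar(u3)))
  }
  ltr <- paste0(u3, r, u5)
  ltr_len <- nchar(ltr)

  # pre-gag leader: GT | spacer | ORF | spacer | CTAAC | py tract | AG
  orf <- paste0("ATG", random_codons(p$orf_len / 3L - 2L), "TAA")
  tail_len <- 2L + 5L + 15L + 2L # SD + branch + py + SA
  spacer2_len <- 30L
  spacer1_len <- p$pregag_len - 2L - p$orf_len - spacer2_len - 5L - 15L - 2L
  if (spacer1_len < 0L) stop("pregag_len too short")
  orf_start <- 2L + spacer1_len # 0-based within pre-gag
  pregag <- paste0("GT", random_dna(spacer1_len), orf,
                   random_dna(spacer2_len), "CTAAC",
                   chars_seq(sample(c("C", "T"), 15L, replace = TRUE)), "AG")
  stopifnot(nchar(pregag) == p$pregag_len)

  # gag with zinc fingers I and II in frame
  n_gag <- p$gag_len %/% 3L
  zf1_aa <- c("C", sample_aa(2), "C", sample_aa(4), "H", sample_aa(4), "C")
  zf2_aa <- c("C", sample_aa(2), "C", sample_aa(3), "H", sample_aa(4), "C")
  zf1_pos <- round(n_gag * 0.65) # aa offsets within gag
  zf2_pos <- zf1_pos + 22L
  gag_aa <- sample_aa(n_gag)
  gag_aa[zf1_pos:(zf1_pos + 13L)] <- zf1_aa
  gag_aa[zf2_pos:(zf2_pos + 12L)] <- zf2_aa
  gag <- aa_to_dna(gag_aa)

  pro <- random_codons(p$pro_len %/% 3L)

  n_pol <- p$pol_len %/% 3L
  gpyf_aa <- c("W", sample_aa(1), "G", "P", "F", sample_aa(1), "V")
  pol_aa <- sample_aa(n_pol)
  gpyf_pos <- n_pol - 40L
  pol_aa[gpyf_pos:(gpyf_pos + 6L)] <- gpyf_aa
  pol <- aa_to_dna(pol_aa)

  env <- random_codons(p$env_len %/% 3L)

  segs <- c(ltr5 = ltr, pbs = pbs, pregag = pregag, gag = gag,
            pro = pro, pol = pol, env = env, ltr3 = ltr)
  lens <- nchar(segs)
  ends <- cumsum(lens)
  starts <- ends - lens # 0-based starts
  coord <- function(name) {
    c(start = unname(starts[name]), end = unname(ends[name]))
  }
  gag0 <- starts[["gag"]]
  structure(list(
    sequence = paste(segs, collapse = ""),
    params = p,
    segments = segs,
    ltr5 = coord("ltr5"), ltr3 = coord("ltr3"),
    ltr = ltr, ltr_len = ltr_len,
    u3_len = nchar(u3), r_len = p$r_len, u5_len = p$u5_len,
    pbs = coord("pbs"), pbs_trna = p$pbs_trna,
    pregag = coord("pregag"), gag = coord("gag"), pro = coord("pro"),
    pol = coord("pol"), env = coord("env"),
    orf = c(start = unname(starts[["pregag"]]) + orf_start,
            end = unname(starts[["pregag"]]) + orf_start + p$orf_len),
    zf1 = c(start = gag0 + 3L * (zf1_pos - 1L),
            end = gag0 + 3L * (zf1_pos + 13L)),
    zf2 = c(start = gag0 + 3L * (zf2_pos - 1L),
            end = gag0 + 3L * (zf2_pos + 12L)),
    gpyf = c(start = starts[["pol"]] + 3L * (gpyf_pos - 1L),
             end = starts[["pol"]] + 3L * (gpyf_pos + 6L)),
    subgroup = p$subgroup
  ), class = "provirus_template")
}

#' @export
print.provirus_template <- function(x, ...) {
  cat(sprintf("<provirus_template> subgroup=%s length=%d ltr=%d nt\n",
              x$subgroup, nchar(x$sequence), x$ltr_len))
  invisible(x)
}

#' Evolve a sequence under a neutral clock with CpG hypermutability
#'
#' Single-shot neutral substitution: each site mutates with probability
#' `1 - exp(-sr * age_my * m)` where `m = cpg_multiplier` for the C and the G
#' of a CpG dinucleotide (determined on the input sequence) and 1 elsewhere.
#' The substitution target is uniform over the other three bases. No indels.
#'
#' @param sequence DNA string.
#' @param age_my age in million years (>= 0).
#' @param sr neutral substitution rate (substitutions/nucleotide/My).
#' @param cpg_multiplier rate multiplier (>= 1) for CpG sites.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (so callers can drive many calls from one seed).
#' @return the evolved DNA string.
#' @export
evolve <- function(sequence, age_my, sr = 0.0045, cpg_multiplier = 1,
                   seed = NULL) {
  if (age_my < 0) stop("age_my must be >= 0")
  if (sr <= 0) stop("sr must be > 0")
  if (cpg_multiplier < 1) stop("cpg_multiplier must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (age_my == 0) return(sequence)
  v <- encode_dna(sequence)
  n <- length(v)
  mult <- rep(1, n)
  if (n >= 2L) {
    is_cpg_c <- v[-n] == 1L & v[-1L] == 2L # C followed by G
    idx <- which(is_cpg_c)
    mult[idx] <- cpg_multiplier
    mult[idx + 1L] <- cpg_multiplier
  }
  p <- 1 - exp(-sr * age_my * mult)
  hit <- which(runif(n) < p & !is.na(v))
  if (length(hit)) {
    # uniform over the other 3 bases
    shift <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- (v[hit] + shift) %% 4L
  }
  ch <- seq_chars(sequence)
  ch[!is.na(v)] <- DNA_BASES[v[!is.na(v)] + 1L]
  chars_seq(ch)
}

#' Simulate a set of proviral loci of known age
#'
#' Builds one template per requested subgroup and, for each locus, evolves
#' the two LTRs independently and the internal region once, all for the
#' locus's true age. Used for clock parameter-recovery experiments.
#'
#' @param n number of loci.
#' @param age_range ages drawn uniformly from this interval (My), or a
#'   vector of length `n` of explicit ages.
#' @param sr substitution rate.
#' @param cpg_multiplier CpG rate multiplier.
#' @param subgroup subgroup label(s) passed to [make_template()]; loci are
#'   split evenly across subgroups.
#' @param params template parameter overrides.
#' @param seed integer seed.
#' @return list with `loci` (list of `proviral_locus`, each annotated with
#'   true template feature coordinates), `truth` (data.frame of
#'   `locus_id, true_age_my, subgroup`), and `templates` (per subgroup).
#' @export
simulate_proviruses <- function(n, age_range = c(5, 30), sr = 0.0045,
                                cpg_multiplier = 10, subgroup = "A",
                                params = list(), seed = 1) {
  set.seed(seed)
  ages <- if (length(age_range) == n && n > 2) {
    age_range
  } else {
    runif(n, age_range[1], age_range[2])
  }
  templates <- lapply(seq_along(subgroup), function(i) {
    make_template(utils::modifyList(params, list(subgroup = subgroup[i])),
                  seed = seed + 1000L * i)
  })
  names(templates) <- subgroup
  set.seed(seed + 1L) # template creation reset the stream
  grp <- rep_len(subgroup, n)
  loci <- vector("list", n)
  for (i in seq_len(n)) {
    tpl <- templates[[grp[i]]]
    sq <- tpl$sequence
    l5 <- evolve(substr(sq, tpl$ltr5["start"] + 1L, tpl$ltr5["end"]),
                 ages[i], sr, cpg_multiplier)
    int <- evolve(substr(sq, tpl$ltr5["end"] + 1L, tpl$ltr3["start"]),
                  ages[i], sr, cpg_multiplier)
    l3 <- evolve(substr(sq, tpl$ltr3["start"] + 1L, tpl$ltr3["end"]),
                 ages[i], sr, cpg_multiplier)
    id <- sprintf("sim_prov_%03d", i)
    loci[[i]] <- proviral_locus(
      id, "sim", genomic_interval("sim", 0L, nchar(sq)),
      paste0(l5, int, l3),
      annotations = list(template = grp[i],
                         ltr5 = tpl$ltr5, ltr3 = tpl$ltr3,
                         gag = tpl$gag, subgroup = grp[i])
    )
  }
  truth <- data.frame(locus_id = vapply(loci, `[[`, "", "id"),
                      true_age_my = ages, subgroup = grp,
                      stringsAsFactors = FALSE)
  list(loci = loci, truth = truth, templates = templates)
}

#' Simulate pre-gag leaders with splice signals knocked out at random
#'
#' Each simulated leader carries a splice donor (`GT` start), a branch
#' motif (`CTAAC`) in the standard window upstream of the acceptor, a
#' polypyrimidine tract and a splice acceptor (`AG` end); each of the
#' three signals is independently knocked out (mutated so the detector
#' cannot match it) with probability `knockout_prob`.
#'
#' @param n number of leaders.
#' @param leader_len leader length (nt).
#' @param knockout_prob per-signal knockout probability.
#' @param seed integer seed.
#' @return list: `leaders` (character vector), `truth` (data.frame of
#'   logical `sd, branch, sa` — `TRUE` means the signal was left intact).
#' @export
simulate_leaders <- function(n = 48L, leader_len = 1000L,
                             knockout_prob = 0.10, seed = 1L) {
  set.seed(seed)
  leaders <- character(n)
  truth <- data.frame(sd = logical(n), branch = logical(n), sa = logical(n))
  for (i in seq_len(n)) {
    keep <- runif(3) >= knockout_prob
    mid_len <- leader_len - 2L - 30L - 5L - 15L - 2L
    body <- random_dna(mid_len)
    # scrub chance branch motifs from the acceptor-proximal window so the
    # knockout truth is unambiguous
    sdn <- if (keep[1]) "GT" else "GC"
    branch <- if (keep[2]) "CTAAC" else "GGGGG"
    py <- chars_seq(sample(c("C", "T"), 15L, replace = TRUE))
    sa <- if (keep[3]) "AG" else "AC"
    leader <- paste0(sdn, body, random_dna(30L), branch, py, sa)
    tail_start <- nchar(leader) - 70L
    tail_seq <- substr(leader, tail_start + 1L, nchar(leader) - 22L)
    tail_seq <- gsub("CT[AG]A[CT]", "GGGGG", tail_seq)
    if (!keep[2]) tail_seq <- gsub("CTAAC", "GGGGG", tail_seq, fixed = TRUE)
    leader <- paste0(substr(leader, 1L, tail_start), tail_seq,
                     substr(leader, nchar(leader) - 21L, nchar(leader)))
    if (keep[2]) {
      # re-plant the branch motif at its canonical slot
      pos <- nchar(leader) - 22L + 1L
      substr(leader, pos, pos + 4L) <- "CTAAC"
    }
    leaders[i] <- leader
    truth[i, ] <- keep
  }
  list(leaders = leaders, truth = truth)
}

# Apply subgroup founder drift to a template: the founder provirus of a
# younger subgroup has diverged from the family ancestor, but its two LTRs
# are still identical to each other (fresh integrations copy the source
# element's LTR into both positions).
drift_template <- function(tpl, my, sr, cpg_multiplier) {
  if (my <= 0) return(tpl)
  ltr_d <- evolve(tpl$ltr, my, sr, cpg_multiplier)
  internal <- substr(tpl$sequence, tpl$ltr5["end"] + 1L, tpl$ltr3["start"])
  internal_d <- evolve(internal, my, sr, cpg_multiplier)
  tpl$ltr <- ltr_d
  tpl$sequence <- paste0(ltr_d, internal_d, ltr_d)
  tpl
}

# build one locus instance (element sequence planted in a genome) from a
# template, with the two LTRs evolved independently
evolve_element <- function(tpl, age, sr, cpg_multiplier) {
  sq <- tpl$sequence
  l5 <- evolve(substr(sq, tpl$ltr5["start"] + 1L, tpl$ltr5["end"]),
               age, sr, cpg_multiplier)
  int <- evolve(substr(sq, tpl$ltr5["end"] + 1L, tpl$ltr3["start"]),
                age, sr, cpg_multiplier)
  l3 <- evolve(substr(sq, tpl$ltr3["start"] + 1L, tpl$ltr3["end"]),
               age, sr, cpg_multiplier)
  paste0(l5, int, l3)
}

# processed-pseudogene element: 5'LTR lacking U3, 3'LTR lacking U5,
# poly-A run a few nt downstream
pseudogene_element <- function(tpl, age, sr, cpg_multiplier,
                               polya_len = 20L, polya_offset = 5L) {
  sq <- tpl$sequence
  ltr <- tpl$ltr
  l5 <- evolve(substr(ltr, tpl$u3_len + 1L, tpl$ltr_len), age, sr,
               cpg_multiplier) # R + U5
  int <- evolve(substr(sq, tpl$ltr5["end"] + 1L, tpl$ltr3["start"]),
                age, sr, cpg_multiplier)
  l3 <- evolve(substr(ltr, 1L, tpl$u3_len + tpl$r_len), age, sr,
               cpg_multiplier) # U3 + R
  list(body = paste0(l5, int, l3),
       downstream = paste0(chars_seq(random_dna(polya_offset)),
                           strrep("A", polya_len)))
}

#' Generate a two-species synthetic genome pair with ground truth
#'
#' Emulates the evolutionary scenario the analysis assumes: a common
#' ancestral genome carries insertions older than the species split
#' (orthologous in both descendants, sharing flanks); after the split each
#' genome evolves independently under the neutral clock and acquires
#' species-specific proviruses, solitary LTRs and processed pseudogenes.
#' Each insertion gets a 4-nt target-site duplication; each LTR of a
#' provirus evolves independently for the full insertion age.
#'
#' @param params optional list overriding defaults: `background_len`
#'   (120000), `split_my` (19), `n_shared` (orthologous proviruses, 5),
#'   `shared_age_range` (c(20, 25)), `n_private_provirus` per species (5),
#'   `private_age_range` (c(5, 18)), `n_solo` per species (10),
#'   `n_pseudo` per species (2), `sr` (0.0045), `cpg_multiplier` (10),
#'   `tsd_len` (4), `shared_subgroup` ("A"), `private_subgroup` ("B"),
#'   `species` (c("speciesA", "speciesB")), `flank_len` (500), plus
#'   template overrides via `template_params`.
#' @param seed integer seed; output is deterministic given `(params, seed)`.
#' @return list with `genomes` (named character vector, one per species),
#'   `loci` (list of `proviral_locus` with flanks), `truth` (data.frame:
#'   `locus_id, species, contig, start, end, strand, true_class,
#'   true_age_my, true_subgroup, ortholog_partner, u3_deleted, u5_deleted,
#'   polyA`), and `templates`.
#' @export
make_genome <- function(params = list(), seed = 1) {
  p <- utils::modifyList(list(
    background_len = 120000L, split_my = 19,
    n_shared = 5L, shared_age_range = c(20, 25),
    n_private_provirus = 5L, private_age_range = c(5, 18),
    n_solo = 10L, n_pseudo = 2L,
    sr = 0.0045, cpg_multiplier = 10, tsd_len = 4L, subgroup_drift_my = 8,
    shared_subgroup = "A", private_subgroup = "B",
    species = c("speciesA", "speciesB"), flank_len = 500L,
    template_params = list()
  ), params)
  if (p$n_shared > 0L && p$shared_age_range[1] < p$split_my) {
    stop("shared insertions must be at least as old as the species split")
  }
  subs <- unique(c(p$shared_subgroup, p$private_subgroup))
  # all subgroup templates share one family ancestor (same template seed);
  # they differ by the structural LTR variants plus founder drift
  templates <- lapply(seq_along(subs), function(i) {
    tpl <- make_template(utils::modifyList(p$template_params,
                                           list(subgroup = subs[i])),
                         seed = seed + 31L)
    if (i > 1L) {
      set.seed(seed + 97L * i)
      tpl <- drift_template(tpl, p$subgroup_drift_my %||% 8, p$sr,
                            p$cpg_multiplier)
    }
    tpl
  })
  names(templates) <- subs

  set.seed(seed)
  background <- random_dna(p$background_len)

  # per-species plan of private insertions
  n_priv <- p$n_private_provirus + p$n_solo + p$n_pseudo
  total_sites <- p$n_shared + 2L * n_priv
  # insertion points in ancestral coordinates, well separated
  margin <- 1500L
  pts <- sort(sample(seq(margin, p$background_len - margin), total_sites))
  if (total_sites > 1L && min(diff(pts)) < 2L * p$flank_len + 50L) {
    # redraw on a grid to guarantee separation
    grid <- seq(margin, p$background_len - margin,
                length.out = max(total_sites, 2L))
    if (length(grid) < total_sites ||
        (length(grid) > 1 && diff(grid[1:2]) < 2L * p$flank_len + 50L)) {
      stop("background genome too small to host the requested insertions")
    }
    pts <- as.integer(round(grid[seq_len(total_sites)]))
  }
  site_of <- split(seq_len(total_sites),
                   sample(rep(c("shared", "privA", "privB"),
                              c(p$n_shared, n_priv, n_priv))))

  truth <- list()
  # ---- shared (pre-split) insertions, planted in the ancestor ----
  shared_ages <- if (p$n_shared)
    runif(p$n_shared, p$shared_age_range[1], p$shared_age_range[2]) else
    numeric(0)
  insert_plan <- data.frame(pos = integer(0), seq = character(0),
                            id = character(0), class = character(0),
                            age = numeric(0), subgroup = character(0),
                            stringsAsFactors = FALSE)
  for (i in seq_len(p$n_shared)) {
    tpl <- templates[[p$shared_subgroup]]
    el <- evolve_element(tpl, shared_ages[i] - p$split_my, p$sr,
                         p$cpg_multiplier)
    insert_plan <- rbind(insert_plan, data.frame(
      pos = pts[site_of$shared[i]], seq = el,
      id = sprintf("shared_prov_%02d", i), class = "provirus",
      age = shared_ages[i], subgroup = p$shared_subgroup,
      stringsAsFactors = FALSE))
  }
  anc <- assemble_genome(background, insert_plan, p$tsd_len)

  out_genomes <- character(0)
  loci <- list()
  for (si in seq_along(p$species)) {
    sp <- p$species[si]
    g <- evolve(anc$genome, p$split_my, p$sr, p$cpg_multiplier)
    anc_tab <- anc$table
    if (nrow(anc_tab)) {
      anc_tab$species <- sp
      anc_tab$id <- paste0(sp, "_", anc_tab$id)
    }

    # private insertions for this species
    sites <- pts[site_of[[c("privA", "privB")[si]]]]
    # map ancestral points to current coordinates (shift by upstream
    # shared insertions)
    shift <- vapply(sites, function(x) {
      sum(anc$table$ins_len[anc$table$pos0 <= x])
    }, numeric(1))
    sites_cur <- sites + as.integer(shift)
    plan <- NULL
    k <- 0L
    priv_classes <- rep(c("provirus", "solo_ltr", "processed_pseudogene"),
                        c(p$n_private_provirus, p$n_solo, p$n_pseudo))
    for (cls in priv_classes) {
      k <- k + 1L
      age <- runif(1, p$private_age_range[1],
                   min(p$private_age_range[2], p$split_my - 0.5))
      tpl <- templates[[p$private_subgroup]]
      body_len <- NA_integer_
      if (cls == "provirus") {
        el <- evolve_element(tpl, age, p$sr, p$cpg_multiplier)
      } else if (cls == "solo_ltr") {
        el <- evolve(tpl$ltr, age, p$sr, p$cpg_multiplier)
      } else {
        ps <- pseudogene_element(tpl, age, p$sr, p$cpg_multiplier)
        # poly-A hallmark is appended immediately downstream of the body;
        # the reported locus span is the body only
        body_len <- nchar(ps$body)
        el <- paste0(ps$body, ps$downstream)
      }
      tag <- c(provirus = "prov", solo_ltr = "solo",
               processed_pseudogene = "pseudo")[[cls]]
      plan <- rbind(plan, data.frame(
        pos = sites_cur[k], seq = el,
        id = sprintf("%s_%s_%02d", sp, tag, k), class = cls,
        age = age, subgroup = if (cls == "solo_ltr") NA_character_ else
          p$private_subgroup,
        body_len = body_len, stringsAsFactors = FALSE))
    }
    if (is.null(plan)) {
      plan <- data.frame(pos = integer(0), seq = character(0),
                         id = character(0), class = character(0),
                         age = numeric(0), subgroup = character(0),
                         body_len = integer(0), stringsAsFactors = FALSE)
    }
    asm <- assemble_genome(g, plan, p$tsd_len)
    # shift ancestral locus coordinates by private insertions upstream
    if (nrow(anc_tab)) {
      anc_shift <- vapply(anc_tab$start, function(x) {
        sum(asm$table$ins_len[asm$table$pos0 <= x])
      }, numeric(1))
      anc_tab$start <- anc_tab$start + as.integer(anc_shift)
      anc_tab$end <- anc_tab$end + as.integer(anc_shift)
    }
    tab <- rbind(
      asm$table[, c("id", "class", "age", "subgroup", "start", "end",
                    "body_len")],
      if (nrow(anc_tab)) cbind(
        anc_tab[, c("id", "class", "age", "subgroup", "start", "end")],
        body_len = NA_integer_) else NULL
    )
    tab$species <- sp
    tab$contig <- sp
    # pseudogene loci: reported span is the element body (poly-A downstream)
    haspoly <- !is.na(tab$body_len)
    tab$end[haspoly] <- tab$start[haspoly] + tab$body_len[haspoly]
    genome <- asm$genome
    for (j in seq_len(nrow(tab))) {
      fs <- max(0L, tab$start[j] - p$flank_len)
      fe <- min(nchar(genome), tab$end[j] + p$flank_len)
      loci[[tab$id[j]]] <- proviral_locus(
        tab$id[j], sp,
        genomic_interval(sp, tab$start[j], tab$end[j]),
        substr(genome, tab$start[j] + 1L, tab$end[j]),
        flank5 = substr(genome, fs + 1L, tab$start[j]),
        flank3 = substr(genome, tab$end[j] + 1L, fe),
        annotations = list(true_class = tab$class[j],
                           true_age = tab$age[j])
      )
    }
    out_genomes[sp] <- genome
    truth[[sp]] <- tab
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  truth$strand <- "+"
  # ortholog partners: shared ids differ only in the species prefix
  base_id <- sub("^[^_]*_", "", truth$id)
  truth$ortholog_partner <- NA_character_
  shared <- grepl("^shared_", base_id)
  for (i in which(shared)) {
    partner <- truth$id[shared & base_id == base_id[i] &
                          truth$species != truth$species[i]]
    if (length(partner) == 1L) truth$ortholog_partner[i] <- partner
  }
  truth$u3_deleted <- truth$class == "processed_pseudogene"
  truth$u5_deleted <- truth$class == "processed_pseudogene"
  truth$polyA <- truth$class == "processed_pseudogene"
  names(truth)[names(truth) == "id"] <- "locus_id"
  names(truth)[names(truth) == "class"] <- "true_class"
  names(truth)[names(truth) == "age"] <- "true_age_my"
  names(truth)[names(truth) == "subgroup"] <- "true_subgroup"
  truth <- truth[, c("locus_id", "species", "contig", "start", "end",
                     "strand", "true_class", "true_age_my", "true_subgroup",
                     "ortholog_partner", "u3_deleted", "u5_deleted", "polyA")]
  list(genomes = out_genomes, loci = loci, truth = truth,
       templates = templates)
}

# insert elements (with TSD) into a genome; plan must have pos (0-based
# insertion point in current coordinates), seq, id, class, age, subgroup.
# Returns genome + table of realized 0-based [start, end) locus coordinates.
assemble_genome <- function(genome, plan, tsd_len) {
  cols <- c("id", "class", "age", "subgroup")
  if (nrow(plan) == 0L) {
    tab <- data.frame(id = character(0), class = character(0),
                      age = numeric(0), subgroup = character(0),
                      start = integer(0), end = integer(0),
                      pos0 = integer(0), ins_len = integer(0),
                      body_len = integer(0))
    return(list(genome = genome, table = tab))
  }
  plan <- plan[order(plan$pos), , drop = FALSE]
  pieces <- character(0)
  tab <- NULL
  prev <- 0L
  offset <- 0L
  for (i in seq_len(nrow(plan))) {
    pos <- plan$pos[i]
    tsd <- substr(genome, pos + 1L, pos + tsd_len)
    pieces <- c(pieces, substr(genome, prev + 1L, pos), plan$seq[i], tsd)
    start_cur <- pos + offset
    ins_len <- nchar(plan$seq[i]) + tsd_len
    tab <- rbind(tab, data.frame(
      id = plan$id[i], class = plan$class[i], age = plan$age[i],
      subgroup = plan$subgroup[i],
      start = start_cur, end = start_cur + nchar(plan$seq[i]),
      pos0 = pos, ins_len = ins_len,
      body_len = if ("body_len" %in% names(plan)) plan$body_len[i] else
        NA_integer_,
      stringsAsFactors = FALSE))
    offset <- offset + ins_len
    prev <- pos
  }
  pieces <- c(pieces, substr(genome, prev + 1L, nchar(genome)))
  list(genome = paste(pieces, collapse = ""), table = tab)
}
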