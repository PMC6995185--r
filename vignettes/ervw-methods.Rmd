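---
title: "Annotating, classifying and dating ERV-W-like proviruses"
author: "ervwtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating, classifying and dating ERV-W-like proviruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervwtools)
```

## The problem

Endogenous retroviruses (ERVs) are germline-integrated proviruses inherited
vertically. A full-length provirus has the layout
`5'LTR — PBS — (leader) — gag — pro — pol — env — 3'LTR`, with the two long
terminal repeats (LTRs) identical at the moment of integration. Three facts
make ERVs tractable as molecular fossils:

* the two LTRs accumulate substitutions independently after integration, so
  their divergence clocks the insertion age;
* LTR–LTR ectopic recombination leaves behind solitary LTRs, and
  LINE-1-mediated retrotransposition of proviral mRNA leaves processed
  pseudogenes with recognizable truncation hallmarks;
* insertions older than a speciation event are found at orthologous
  positions (identical flanking sequence) in both descendant species.

`ervwtools` implements this analysis for ERV-W-like gammaretroviral
elements: structural annotation (LTRs, PBS/tRNA assignment, Gag
nucleocapsid zinc fingers, Pol integrase GPY/F, nucleotide composition,
pre-gag leader and its ORF and splice signals), genome scanning and
classification (provirus / solitary LTR / processed pseudogene), ortholog
detection between two species, LTR phylogeny with bootstrap-supported
subgroup extraction, and molecular-clock insertion dating. A synthetic
genome generator with full ground truth exercises the pipeline end to end.

## The molecular clock

Insertion ages follow `T = D / SR`, where `D` is the proportion of
divergent nucleotides (p-distance with pairwise deletion, after removal of
hypermutable CpG dinucleotides) and `SR` is the neutral substitution rate.
The package default is `SR = 0.0045` substitutions/nucleotide/My, the human
neutral rate commonly used for primate ERV dating; no Platyrrhini-specific
rate is established, so the value is a configuration key, not a constant.

Two divergence sources are used per locus:

* **LTR–LTR**: the two LTRs of one provirus are globally aligned (free end
  gaps), CpG-stripped, and `T = D / SR / 2` — halved because both LTRs
  drift independently from the single integrated sequence;
* **gene vs subgroup consensus**: the gag region is compared with the
  majority-rule consensus of its LTR subgroup and `T = D / SR` (the
  consensus approximates the subgroup ancestor). Loci that fall outside
  any well-supported subgroup are dated by the LTR method only, because a
  consensus built from a heterogeneous ensemble is unreliable.

Per-locus estimates are averaged unless they disagree strongly. The
dispersion rule is interpreted as a coefficient of variation: methods are
combined only when `SD/mean <= 0.20`, otherwise the LTR-based estimate (the
method applicable to every locus) is kept and the exclusion is flagged. An
absolute-SD reading (`sd_mode = "absolute"`) is also implemented, but an
absolute threshold of 0.2 My would exclude essentially nothing at the
15–25 My scale of interest, so the relative reading is the default.

### CpG stripping

CpG dinucleotides hypermutate via spontaneous deamination of methylated
cytosine, so dating removes them. `strip_cpg()` removes both columns of
every CpG, pairing bases across alignment gaps. Which row defines a "CpG
site" matters:

* for an **LTR pair** neither row is ancestral, and the symmetric rule
  (CpG in either row) is used;
* for **gene vs consensus** the consensus approximates the ancestral
  state, and stripping is anchored on the consensus row only
  (`anchor = "second"`). Stripping on the derived row as well would remove
  columns where a mutation created a new CpG — i.e. preferentially remove
  genuinely divergent sites — and systematically underestimate ages. In
  simulation this choice moves the regression slope of estimated against
  true age from ~0.84 back to ~0.99 for the gene method.

### What recovery looks like

On 50 simulated proviruses with ages uniform on [5, 30] My (600-nt LTRs,
`SR = 0.0045`, CpG rate multiplier 10), the combined estimate achieves a
mean absolute error of ~1.1–1.4 My with a regression slope of ~0.87–0.92.
The slope sits slightly below 1 because the estimator uses the raw
p-distance, which saturates mildly at 25–30 My; this is inherent to the
uncorrected-clock design, and the residual is partly offset by formerly-CpG
sites that escape stripping once both copies have lost the dinucleotide.

## The synthetic generator

`make_template()` builds an age-zero provirus (~9.2 kb, 600-nt LTRs split
U3 350 / R 100 / U5 150) with every diagnostic feature planted: an 18-nt
PBS drawn from a tRNA library, zinc fingers `Cx2Cx4Hx4C` and `Cx2Cx3Hx4C`
in frame within gag, `WxGP[F/Y]xV` near the pol 3' end, and a pre-gag
leader with donor `GT`, branch `CTAAC`, polypyrimidine tract, acceptor
`AG` and an embedded 933-nt ORF. Coding segments use randomly drawn
synonymous codons, which keeps coding regions free of the repeated k-mers
that a fixed codon table would create. Subgroup variants modify the LTR
(B: 110-nt U3 deletion; B1: additional 200-nt insertion) on the same
family template; in `make_genome()` younger subgroups additionally carry
founder drift (default 8 My of substitutions applied once to the founder,
with the two LTR copies kept identical, as a fresh integration would).

`evolve()` applies single-shot neutral substitution: each site mutates
with probability `1 - exp(-SR * age * m)`, `m` being the CpG multiplier
(default 10) for both positions of a CpG determined on the input, and the
target base uniform over the three alternatives. There are no indels. The
published analyses state only that CpG sites hypermutate, not a rate
multiplier; 10 is in the range estimated for mammalian genomes and is an
explicit knob.

`make_genome()` emulates a two-species scenario: insertions older than the
split (default 19 My, within the 20–18 My range accepted for the
marmoset/squirrel-monkey separation) are planted in a common ancestral
genome and then evolve independently in both descendants — their flank
divergence therefore encodes the split time (~0.77 realized identity under
CpG hypermutation, against ~0.83 from the naive `1 - 2 * SR * t`).
Species-specific proviruses, solitary LTRs and processed pseudogenes are
added after the split. Every insertion gets a 4-nt target-site
duplication. Pseudogenes get a U3-truncated 5'LTR, a U5-truncated 3'LTR
and a 20-nt poly-A run starting a few nt downstream (the detection default
is a 12-nt run with at most one mismatch within 30 nt, also a knob — the
published hallmark descriptions carry no lengths). The background genome
is i.i.d. uniform, the simplest null under which the scanners can
demonstrate specificity.

What the generator deliberately does not emulate: indel evolution,
selection, recombination between elements, nested insertions, and
realistic host base composition or repeat content. Passing tests therefore
show correctness of the method's logic under its own model assumptions,
not performance on real genomes, where segmental duplications and other
repeat families would add false-positive pressure the scanners have not
been tuned against.

## Scanning and classification

`scan_genome()` replaces a BLAT-style search with exact 12-mer seeds
grouped into 40-nt diagonal bands, requiring at least 2 seeds per band
cluster and a 30-nt minimum span (random double-hits in one band are then
vanishingly rare), followed by ungapped x-drop extension (+1 match / −1
mismatch, drop 10, i.e. extension stops near a 55% identity drop-off) and
merging of clusters within 100 nt. Overlapping opposite-strand calls keep
the strand with more seeds. At zero age boundaries are exact; at ≤15%
divergence from the probe they land within a few nt of truth.

Classification follows the internal-region logic: a candidate whose own
sequence covers ≥20% of the internal reference is full-length; otherwise
its 500-nt flanks are checked against the 1000-nt terminal probes of the
internal reference (coverage ≥0.2 in either flank makes it a proviral
LTR), and a candidate with no internal match anywhere is a solitary LTR.
Full-length candidates are screened for pseudogene hallmarks; the call
requires (U3-deletion or U5-deletion) *and* the downstream poly-A, per the
definition of an LTR-retrotransposed mRNA copy. Hallmark deletions are
assessed by free-end-gap alignment of the locus termini to the LTR
reference: a region counts as deleted when under half of its reference
columns are covered.

Ortholog detection scores all between-species locus pairs by
free-end-gap global alignment identity of both flanks (threshold 0.75 over
≥200 aligned nt, preceded by a shared 12-mer prefilter) and greedily
enforces 1-to-1 matching. The 0.75 threshold sits between the realized
flank identity of true orthologs at a ~19-My split under CpG
hypermutation (~0.77) and anything unrelated flanks can reach, which makes
precision robust while sensitivity can drop a pair or two in unlucky
draws; the acceptance suite's fixed-seed scenario meets sensitivity ≥0.9
with precision 1.0.

## Phylogeny

Distances are p-distance or Kimura 2-parameter
(`d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`) with pairwise deletion;
saturated pairs (non-positive log arguments) are reported as undefined
rather than clamped. Trees are neighbor-joining (exact on additive
matrices — verified against an exhaustive least-squares topology search at
n ≤ 6); negative branch lengths are clamped to zero with a warning.
Bootstrap resamples alignment columns (default 1000 replicates, the
conventional depth); replicates with undefined distances are skipped and
counted. The reference tree is midpoint-rooted before support extraction
so that well-separated groups appear as clades regardless of the arbitrary
NJ rooting; an all-identical alignment short-circuits to a zero-support
tree rather than reporting spurious structure.

Subgroups are maximal clades with support ≥70% (configurable — published
ERV-W LTR clusters carry supports of 99/90/99/68, and the 68%-supported
cluster would need a threshold ≤68 to be called) and ≥5 tips, labeled
`A`, `B`, ... in decreasing size order, with supported nested clades
becoming `B1`, `B2`, ... Majority-rule consensus takes the plurality base
per column, drops gap-plurality columns, and breaks base ties
alphabetically.

## Pre-gag analysis

The leader between the 5'LTR end and the gag start is treated as the
putative intron: splice donor = leader starts `GT`, acceptor = leader ends
`AG`, branch motif `CT[AG]A[CT]` searched 10–60 nt upstream of the
acceptor (standard intron geometry; the motif itself is the published
one, the window is ours), and the polypyrimidine fraction is computed over
the 20 nt before the acceptor. On random 1-kb leaders the chance
coincidence of all three signals stays below 30% (the GT/AG ends are 1/16
each; measured in the test suite). Shared-segment maps between two leaders
chain exact 12-mer diagonals into segments ≥50 nt with per-segment
identity — the same primitive as the dot-plot intactness screen. A
consistency table cross-checks pre-gag absence against pseudogene calls,
flagging any non-pseudogene locus that lacks the leader.

## Numerical and design choices

* LTR detection accepts repeats ≥200 nt at ≥0.60 identity: random
  1.1-kb windows cannot produce a ≥200-nt repeat at that identity, while
  30-My-old LTR pairs (~0.70–0.72 identity under CpG hypermutation) are
  still found. Ties go to the longer repeat, then the 5'-most.
* PBS presence needs ≥14/18 identity within 30 nt of the 5'LTR end
  (configurable; no published cutoff exists). Ties go to the smaller
  offset, then library order. The bundled tRNA PBS library is synthetic
  (six amino-acid types; the Trp entry deliberately sits 2 nt from Arg to
  mirror their near-identity in real primer sites).
* Motif scanning is forward-frame only; reverse-strand loci are
  reverse-complemented upstream. Spacer positions may be any residue;
  anchors must match exactly, and a stop codon inside a matched span
  flags the hit rather than hiding it.
* Coordinates are 0-based half-open internally and 1-based inclusive in
  every table written to disk; the conversion pair is involutive.
* All stochastic steps take explicit seeds; identical (parameters, seed)
  give byte-identical outputs.
* Problem sizes in the test and acceptance runs — 50 proviruses for clock
  recovery, ~120–200 kb genomes with ~20–60 insertions, 100-replicate
  bootstraps in tests — were chosen so the full validation runs in a few
  minutes on one core while keeping binomial noise well inside the stated
  tolerances.

## Limitations

Real screening pipelines handle nested insertions, indel-rich alignments
and repeat families the scanner here does not model. The clock slope bias
(~5–10% underestimation at 25–30 My) is inherent to uncorrected
p-distance dating. Solo-LTR formation is planted, not modeled as a
recombination process, so solo/provirus ratios test recovery of planted
counts only. Maximum-likelihood tree inference and rooting beyond the
midpoint heuristic are out of scope.
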