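---
title: "Calling, mapping and quantifying the loss of an alternative first exon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling, mapping and quantifying the loss of an alternative first exon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoloss)
```

## The problem

Many mammalian genes produce two protein isoforms from alternative first
exons driven by alternative promoters. When one of the isoforms is
evolutionarily young, its first exon can degenerate repeatedly and
independently in different lineages: the promoter is deleted or rearranged,
start codons mutate, frameshifts and premature stops accumulate, or the
splice donor is lost. `isoloss` turns this qualitative picture into a
reproducible pipeline: rule-based functionality calls from aligned
sequences, a parsimony count of independent losses on a species tree, a
scanning-model check of which start sites could still produce protein, and
an expression classification from exon-level read counts.

All coordinates in the package are 1-based inclusive alignment columns —
the native R convention — in data structures and reports alike.

## Lesion detection

The unit of input is a `region_alignment`: gapped rows over
`A,C,G,T,N,-`, the reference species first, plus a `feature_annotation`
locating five functional blocks on the reference: a promoter block (~500 bp
upstream of ATG1), the conserved block containing the mapped transcription
start site (TSS), two in-frame start codons, the coding block, and the
splice-donor position. Four detectors run per row:

* **Start codons.** Each annotated codon is read at the columns where the
  reference carries it; a codon is intact only if it reads exactly `ATG`.
  Intact codons get a Kozak class from the two context positions with the
  dominant effect on initiation: `strong` if position −3 is a purine *and*
  +4 is `G`, `adequate` if exactly one holds, `weak` otherwise. A window
  truncated by a sequence edge is classified from the available positions
  (a missing position cannot satisfy its rule). Kozak weakness is never a
  loss criterion — the class is positive evidence only.
* **ORF disruptions.** Every maximal indel run inside the coding block
  whose ungapped length is not a multiple of 3 is a `frameshift_indel`.
  Premature stops are found by translating the row's ungapped bases from
  the ATG1 column to the donor; anchoring the frame at the ATG1 *column*
  (not the codon) means upstream indels shift the downstream frame
  cumulatively, and the frame is defined even when ATG1 itself is mutated.
  Columns gapped in both the row and the reference are uninformative and do
  not break an indel run.
* **Splice donor.** Intact only for the canonical `GT`; any other
  dinucleotide — including the minor `GC` donor — and any gapped donor is a
  `donor_loss`. This deliberately scores *conservation* of the donor, not
  spliceability.
* **Promoter.** `absent` when at least 90 % of the promoter block is
  gapped; `rearranged` when a deletion of ≥ 30 bp overlaps the TSS block or
  an insertion of ≥ 30 bp sits within it; `intact` otherwise. The 30-bp
  threshold is far below the archetypal 72-bp replacement insertion and
  far above routine alignment noise; promoter divergence by point
  substitution is deliberately not scored, because no defensible metric
  separates neutral promoter turnover from functional loss without
  expression data.

A row whose whole annotated region is gapped collapses to a single
`region_absent` lesion. An `N` at a scored position makes that feature
unknown rather than lost. Per-species results are aggregated into a
`lesion_report`; reports are deterministic functions of the row.

## Functionality calls

`call_functionality()` maps a report to `functional` / `lost` / `unknown`:
lost iff the promoter is rearranged or absent, the donor is lost, both
ATGs are mutated, any frameshift or premature stop hits the coding block,
or the region is absent. A premature stop or frameshift counts as loss even
with both ATGs intact. One mutated ATG is tolerated: the call stays
functional with `initiation_site` set to the surviving codon, a rule backed
by the scanning model below (a lone ATG2 is a potent initiator).
Coverage-flagged rows, and rows whose verdict would hinge on an `N`, are
`unknown` and are excluded from event counting rather than imputed.

## Dollo mapping and lesion-aware splitting

Under Dollo parsimony the exon was gained once at the root and can only be
lost. The minimum set of loss branches is then exactly the set of maximal
clades whose leaves are all lost-or-unknown with at least one lost leaf;
unknown leaves are wildcards in the standard missing-data sense. Among
equally parsimonious placements we report the one closest to the leaves
(the stem of the MRCA of the event's lost leaves), matching the intuition
that unobserved deeper losses should not be asserted. The degenerate
all-lost input contradicts presence at the root; it returns a single
flagged event with a warning rather than a silent two-branch cover.

Plain Dollo undercounts when sister species lost the exon through
*different* mutations. `split_by_lesion()` therefore partitions each
event's leaves by single linkage over a lesion-homology relation: two
leaves stay together iff they share a lesion of the same type with
overlapping alignment span — and identical ungapped length for indels
(deletions, insertions, frameshifts). Span-overlap tolerance is 0 columns:
in a common alignment, a genuinely inherited lesion occupies the same
columns in every descendant, so any looser tolerance would only invite
false merging. A shared lesion pattern that is incompatible with the tree
would surface as two separate events (homoplasy) rather than trigger any
re-estimation of the tree. Splitting can only refine events, so the
lesion-aware count is always ≥ the plain Dollo count.

## The scanning model of initiation

Reporter constructs (native 5'UTR + exon segment fused in frame to a
reporter ORF) are scanned 5'→3'. Candidate sites are all `ATG` codons plus
near-cognate codons — one substitution away from `ATG`, e.g. `AAG` — in a
*strong* Kozak context only. Products:

* the 5'-most intact exon-segment ATG → `strong` product;
* later in-frame exon-segment ATGs → `leaky` products;
* near-cognates → `faint`, and reporter-internal ATGs → `background`, but
  only when the exon segment retains **no** intact ATG.

The last rule is stricter than gating each near-cognate on sites upstream
of itself. The in vitro observation it encodes is that the faint
near-cognate band appears only in the double-ATG mutant: an intact ATG
anywhere in the segment recruits scanning ribosomes efficiently enough
that near-cognate initiation stays below detection, even at a near-cognate
that is 5' of the surviving ATG. Strengths are ordinal classes, not rates —
band intensities are qualitative — and re-initiation beyond the second site
is not modelled. Product sizes are reported as residues to the reporter
stop, so two sites 3 codons apart differ by exactly 3 residues.

The seven packaged archetype constructs (`make_archetype_constructs()`)
are synthetic stand-ins engineered to carry the documented features (two
strong-context ATGs 30 nt apart, an `AAG` three codons after ATG1, two
reporter-internal ATGs); in the double mutant the ATGs are replaced by
codons two substitutions away from `ATG` so that no artefactual
near-cognate is created at the mutated sites.

## Expression classification

Counts are normalised to per-bp densities (reads / exon length; defaults
228, 245 and 426 bp for exons 1A, 1B and the control exon 6). Coherence is
checked on densities: every transcript carries one first exon and the
control exon, so the *mean* first-exon density should match the
control-exon density; the relative deviation
|d<sub>1A</sub> + d<sub>1B</sub> − 2 d<sub>6</sub>| / (2 d<sub>6</sub>) is
compared to a configurable 20 % tolerance. Working on densities (rather
than raw counts) makes the check exact under even per-transcript coverage;
the raw-count variant is recoverable by setting exon lengths to 1.

The equal-expression null is *equal molar abundance*, not a 50/50 read
split: expected counts are proportional to exon length, which is the only
choice consistent with the per-bp normalisation. The test is the 1-df
Pearson chi-squared (via `stats::chisq.test` with length-proportional
expected probabilities), Bonferroni-corrected with `m_tests` (default 7,
the size of the reference cell-line panel) — the most conservative standard
reading of "corrected for multiple tests". Before testing, a detection
floor declares `B_only` when the exon-1A density falls below 5 % of the
control-exon density (`A_only` symmetrically); the floor is a package
default, chosen because no published threshold exists, and it takes
precedence over the test (a 4 % relative density with enormous counts is
still reported as B-only rather than as a significant ratio).

## The synthetic-data generator

The generator exists so that every stage is testable with exact ground
truth and no downloads. It emulates:

* a reference region template (440-bp promoter, 80-bp TSS block, 40-bp
  5'UTR, 90-bp coding block with two strong-context ATGs and no in-frame
  stop, GT donor);
* neutral divergence by point substitution along a random rooted tree
  (per-site probability 1 − e^(−rate·branch length); default rate 0.05 per
  site per unit length, enough to make rows visibly diverged without
  saturating), with annotated feature positions protected so background
  noise can never masquerade as a lesion — an unprotected stress-test mode
  exists but is excluded from exact-recovery checks;
* clade-inherited lesions planted on branches (`plant_lesions()`), applied
  identically to all descendant leaves, with insertions adding alignment
  columns and shifting the annotation;
* read counts with Poisson (or negative-binomial) noise around
  length-proportional means, with the control-exon mean tied to the
  first-exon densities so simulated libraries satisfy the coherence
  identity in expectation.

What it does **not** emulate: realistic indel evolution, codon models,
alignment error, assembly artefacts, or rate variation across lineages.
Passing recovery tests therefore demonstrates correctness of the calling
and counting logic under clean alignments — not robustness to alignment
error, which is upstream of this package's scope.

The packaged worked-example fixture (`make_fixture_fig2a()`) transcribes a
published 18-species survey: the muroid clade shares an ancestral promoter
rearrangement (80-bp TSS deletion replaced by a 72-bp insertion) with
mosaic coding lesions on top; two octodontoid sisters carry distinct
frameshift/stop lesions; a tenrec combines a 60-bp promoter deletion with a
premature stop; a hedgehog lacks the region entirely; pig and shrew have
lost the splice donor; horse and alpaca have lost only ATG1 and remain
functional via ATG2; two placeholder muroid leaves are coverage-flagged
unknown. The fixture rows are reference-identical apart from the planted
lesions — no background substitutions — so the pipeline output is exactly
deterministic: 7 independent losses, 5 under lesion-ignorant Dollo.

```{r fixture}
fix <- make_fixture_fig2a()
reports <- build_feature_reports(fix$alignment)
calls <- call_all(reports)
nrow(dollo_events(fix$tree, calls))
count_independent_losses(fix$tree, calls, reports)$count
```

## Numerical and design choices

* **Thresholds.** Promoter rearrangement ≥ 30 bp; promoter absence ≥ 90 %
  gaps; expression floor 5 % of control density; coherence tolerance 20 %;
  Bonferroni m = 7. All are arguments with these defaults.
* **Degenerate inputs.** All-zero count libraries return an `NA` category,
  flagged; a zero control exon makes the coherence check `NA`; the all-lost
  tree case is flagged as above; duplicate species or libraries are errors.
* **Tie-breaks.** Event anchors take the placement closest to the leaves.
  Within `split_by_lesion`, grouping is single-linkage, so a chain of
  pairwise-sharing leaves stays one event even if its extremes share
  nothing directly.
* **Determinism.** Detection, calling and mapping are deterministic;
  every stochastic generator takes an explicit integer seed and derives
  independent per-operation streams from it.
* **Problem sizes.** The test suite verifies Dollo counts exhaustively
  against a brute-force edge-cover minimizer on *all* rooted binary
  topologies with 2–6 leaves under every non-degenerate state assignment;
  lesion recovery on 200 seeded 12-taxon scenarios with 1–7 planted events
  (exact recovery required in 100 % of runs); null calibration on 143
  seven-library families at depth 5000 (family-wise error within the
  binomial 95 % envelope of 0.05) and power at an 8-fold molar excess,
  depth 2000 (≥ 99 % `B>A`). These sizes were chosen as the smallest at
  which the corresponding claims are sharp.

## Known limitations

* Inputs must be pre-aligned and pre-oriented to the coding strand; there
  is no reverse-complement handling and no alignment refinement.
* Promoter functionality is assessed from indels only; substitution-level
  promoter death is invisible to the caller (and is the main reason calls
  are conservative: a "functional" call means *no disqualifying lesion*,
  not demonstrated expression).
* The loss count is a minimum for the sampled species; unsampled lineages
  can only add events.
* The scanning model is ordinal and ignores RNA secondary structure and
  re-initiation; it reproduces band patterns, not intensities.
* The expression module consumes exon-level count tables; read extraction
  from alignments is upstream of the package.
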