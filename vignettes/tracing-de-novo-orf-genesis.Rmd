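---
title: "Tracing de novo ORF genesis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing de novo ORF genesis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfgenesis)
```

## The problem

A de novo protein-coding gene arises from ancestrally non-coding sequence.
Establishing where in a species ladder such an ORF began forming is hard for
a structural reason: near the origin there is, by definition, almost nothing
to align. Sequence similarity to the mature ORF decays into the *twilight
zone* — the band where identity and Expect values cannot separate homology
from chance — before it disappears entirely. `orfgenesis` implements a
protocol for working inside that band, organised around the human *SMIM45*
system whose sequences ship with the package:

1. **Synteny anchoring.** For each species the caller supplies the genomic
   segment between two anchor genes known to flank the locus. Within it, a
   deeply conserved *guidepost* ORF (here the 68 aa ORF mRNA, 207 nt) is
   located by local alignment on both strands (`locate_guidepost`). Its
   presence and position certify that the right region is being compared;
   every downstream similarity call carries this synteny flag.
2. **Candidate window.** The `downstream_bp` nucleotides 3′ of the
   guidepost on its strand (`extract_candidate_window`). The default,
   1200 bp, covers the human layout — intervening sequence (324 bp),
   silencer (230 bp, partly inside the intervening sequence) and target
   ORF (324 bp) — with margin.
3. **Similarity calls.** The target ORF sequence is locally aligned against
   the window; identity, aligned length and a Karlin–Altschul Expect value
   are classified as `significant`, `twilight` or `none`
   (`classify_similarity`).
4. **Root inference.** Calls are ordered oldest-first. The root candidates
   are the maximal age-prefix of species with label `none`, provided the
   next-younger species already shows twilight or significant similarity
   (`infer_root`). A species at the root is expected to show *nothing*:
   the sequence has not started forming, or only isolated seed base pairs
   exist, which no alignment can detect.

## Classification thresholds

`twilight_config()` holds the decision rules, applied in order:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | E-value below which a call is `significant` (strict `<`; E exactly at `alpha` falls on the twilight side) |
| `twilight_identity_pct` | 55 % | nominal twilight identity |
| `twilight_slack` | 0.9 | the "~" in "~55 %": identity ≥ 49.5 % qualifies |
| `min_aligned_len` | 15 columns | below this, no call of any kind |

Synteny is a hard prerequisite: without a located guidepost the label is
`none` regardless of alignment quality. One shared configuration is used
for both the silencer-style and ORF-style analyses; nothing in the
procedure distinguishes them.

## Alignment and statistics

Pairwise alignment is affine-gap (a gap of length $L$ costs
$\mathrm{open} + (L-1)\cdot\mathrm{ext}$) and delegates to
`Biostrings::pairwiseAlignment`, with two conventions worth stating:

* **Two scoring regimes.** Similarity *search* (local alignment, E-values)
  uses the blastn "somewhat similar sequences" scheme: match +2, mismatch
  −3, gap open 5, extend 2. Global comparison of *orthologous segments*
  (`align_triple`, `detect_repeat_events`) instead uses
  `ortholog_scheme()` with gap open 12 / extend 6. The reason is
  quantitative: at search-tuned gap costs, sequences a few tens of percent
  diverged accumulate compensating micro-gaps (a 1-gap pays for itself
  whenever it avoids four mismatches), which shifts the register of whole
  segments and corrupts per-column substitution classification. Stiff gaps
  open only where a real insertion or deletion forces one.
* **Karlin–Altschul parameters.** $\lambda$ solves
  $q e^{\lambda a} + (1-q) e^{\lambda b} = 1$ (with $q=\sum_i p_i^2$ the
  identical-letter probability) by bisection to $10^{-9}$; $K$ defaults to
  0.1 and is configurable. These are *ungapped* statistics: Expect values
  are meaningful for ordering and thresholding but are not numerically
  interchangeable with gapped BLAST output, and the package makes no claim
  that they are.
* **Terminal-gap padding.** `pairwiseAlignment` trims terminal gap columns
  from its aligned views when a global alignment starts or ends in an
  indel; `global_align` restores them so global alignments always span
  both sequences.
* **Stops in translated frames.** Translation renders internal stops as
  `*` and continues — frames containing stops are still informative and
  still aligned, with `*` treated as an ordinary symbol.
* **Deterministic behaviour.** Ungapped scans break ties by leftmost
  start; the tandem-repeat scanner reports leftmost maximal runs (so a
  microsatellite may be reported under a rotated unit, e.g. `gaga` rather
  than `agag`, at the same run).

## Identity and display conventions

Two different conventions coexist and both are exact requirements of the
reproduced tables:

* **Integer composition percents are truncated.** 119 G in 324 nt is
  36.73 % and prints as 36. (Some published per-base percentages are
  arithmetically inconsistent with their own counts; only the consistent
  ones are used as checks.)
* **Identity percents are truncated at the displayed precision**, never
  rounded: 12/17 = 70.588 % prints as 70.5. `devseq_identity` implements
  the early-developmental-peptide convention specifically: head-to-head
  ungapped columns over the shorter sequence, with any column containing a
  stop excluded from numerator and denominator. This reproduces every
  internally consistent row of the primate identity ladder; the orangutan
  row of the source table is internally inconsistent (its printed sequence
  differs from the human sequence at one position yet is listed at 100.00)
  and is excluded from all checks while remaining in the fixture.

## The genesis simulator

`simulate_genesis` implements the generative model the tracing procedure
presupposes, so that inference can be scored against logged ground truth.
The region layout is `flank — guidepost — silencer — target — flank`;
evolution runs oldest→youngest along a chain of branches.

| parameter | default | units / meaning |
|---|---|---|
| `panel` | 10 species, 99→0 MYA | age ladder (aardvark … human) |
| `region_len` | 1600 | bp of ancestral region |
| `gc_content` | 0.55 | background GC fraction |
| `n_seeds` | 3 | seeded growth regions spread across the target |
| `growth_rate` | 1.2 | target-matching positions fixed per MY per region |
| `background_rate` | 1.0 | substitutions per site per 100 MY |
| `dead_end_prob` | 0.15 | per-lineage probability of one private indel (1–9 bp, 70 % inside the target locus) |
| `dead_end_tip_my` | 2 | MY of private branch generating per-species dead-end substitutions at `background_rate` |
| `slippage_on_terminal` | TRUE | duplicate one unit of a flanking 4 bp tandem repeat on the terminal branch |
| `ancestor_gap_my` | 5 | branch from the unobserved ancestor to the oldest species |

Model mechanics, and the reasoning behind them:

* **Biased growth with repair.** Each branch draws Poisson growth events
  shared among seed regions in proportion to remaining work. An event
  first *repairs* a previously fixed position knocked out by background
  noise, otherwise *extends* the contiguous grown span by one position
  (nearest-neighbour growth; the very first event in a region is the seed
  itself). Repair expresses the model's premise that fixed positions are
  maintained, and is what keeps per-species target identity effectively
  monotone under noise.
* **Dead-end events are private.** Tip substitutions and indels are
  applied only to the emitted species, never to the evolving chain —
  mirroring mutations "not found in descendant species". Inside the target
  locus, dead-end substitutions never coincide with the target base
  (a change *toward* the target would not be a dead end).
* **Protected loci.** The guidepost evolves only by third-position
  synonymous substitutions at `background_rate`/10, so its amino-acid
  sequence is invariant while its nucleotide identity slowly erodes — the
  "ultra-conserved guidepost" regime. The first 38 bp of the silencer
  (silencer1) are conserved from the panel start; the remaining 192 bp
  (silencer2) grow like the target from one seed.
* **Truth log.** Every event (fixed/growth, inherited background, private
  substitution, indel, slippage) is recorded with species, position and
  states, together with the ancestral sequence, so the entire panel can be
  replayed move by move. The test suite uses an independent replay to
  verify that emitted sequences equal the log's predictions and to score
  the mutation classifier.

**What the simulator does not emulate.** The panel is a chain ordered by
age, not a bifurcating tree; there is no population-genetic realism (no
polymorphism, selection coefficients or coalescent structure); indels are
limited to the three kinds above; divergence ages are taken as given
labels. Passing tests therefore demonstrate that the inference machinery
recovers the model's own ground truth under realistic noise — not that
real genomes satisfy the model. In particular, the fixation mechanism is
the model's premise, with rates as free parameters, not estimates.

## Degenerate inputs and edge behaviour

Empty sequences error in alignment and identity functions; an empty FASTA
yields an empty record list; `composition` of an empty sequence returns a
flagged report with undefined percents. Local alignment of all-mismatch
pairs returns the empty alignment with score 0. A guidepost at the region
edge yields a flagged empty candidate window; a missing guidepost is a
valid "no synteny" result, while passing no guidepost hit to the window
extractor is an error. Panels need at least three species for root
inference and strictly decreasing ages; ties are rejected rather than
silently broken. Ambiguity codes never match in exact scans and score as
mismatches in alignments.

## Problem sizes in the test suite

The suite validates alignment scores against an exhaustive path enumerator
on tiny strings, then against an independently written Gotoh DP: all pairs
over {a, c} up to length 4 exhaustively, plus seeded random pairs up to
length 8. The simulation studies use 200 default-configuration panels for
root recovery and trend, 100 for mutation-classification precision/recall
(pooled), 20 noise-free runs for exactness, and 5 growth-only runs for
monotonicity — sizes chosen to put the binomial uncertainty of the pass
rates well below the asserted margins while the whole suite runs in
minutes on one core.

Two measurement subtleties surfaced while designing these checks and are
worth knowing about. First, the *span* of the best local alignment is not
a monotone quantity even under pure growth: a different growth region can
overtake with a higher score but a smaller span. Panel-level trends are
therefore summarised by a Kendall pair-counting sign over the age ladder
(`progression_table`), while strict per-step monotonicity is asserted on
alignment-free identity coverage of the target locus, where it genuinely
holds. Second, root recovery is scored with "predates panel" counted as
position 0: when the oldest species itself already shows (possibly
chance) similarity, the correct reading is that the root lies at or
beyond the panel edge.

## Known limitations

* E-values are ungapped Karlin–Altschul approximations with a fixed
  default $K$; use them comparatively.
* The root call inherits the twilight rules' sensitivity to chance local
  alignments in short windows; synteny and the `min_aligned_len` floor are
  the only guards, as in the underlying protocol.
* Mutation classification is defined for triples, not general trees, and
  reversions in the descendant are reported as `random_mid`/
  `desc_specific` categories rather than resolved phylogenetically.
* The FASTA reader is deliberately permissive (strips digits and
  whitespace inside sequence blocks); it is not a validator.
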