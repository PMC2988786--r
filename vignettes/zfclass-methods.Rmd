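---
title: "Methods: classifying gli/glis/nkl/zic zinc-finger proteins and evaluating gene-family origins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying gli/glis/nkl/zic zinc-finger proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfclass)
```

## The biological problem

The Gli, Glis, Nkl and Zic transcription-factor sub-families form a single
superfamily defined by five tandem C2H2 zinc fingers (ZFs). Two sequence
characters distinguish Zic proteins from the rest: the number of residues
between the two zinc-coordinating cysteines of the *first* finger (ZF1) is
expanded relative to the canonical 2–4, and many Zic proteins carry two
short conserved regions N-terminal to the fingers — the ZOC domain
(revised consensus `RDFL-(1-2AA)-RR`, earlier published as `(S/T)RDFLxxxR`)
and the ZF-NC domain (`GAF(F/L)RYMRQP-(0-7AA)-IKQE`), the latter sitting
immediately upstream of ZF1.

`zfclass` turns those characters into a reproducible pipeline: detect the
C2H2 fingers, assemble the five-finger architecture, measure ZF1
inter-cysteine spacing, score the two consensus motifs, emit an auditable
subfamily call, optionally refine `gli/glis/nkl-like` calls by
neighbor-joining placement against a labelled panel, and — independently —
count gene gain/loss events for competing origins of the family on a rooted
species tree under Dollo parsimony.

## Finger detection and architecture assembly

A C2H2 finger is modelled as `C-x(2..25)-C-x(9..16)-H-x(3..6)-H`, with all
counts being residues *strictly between* the coordinating positions. The
wide Cys–Cys upper bound exists precisely because the Zic ZF1 spacer is
expanded; all four bounds are configurable through `scan_params()`.
`find_c2h2_hits()` reports **every** quadruple satisfying the bounds —
overlap resolution is deliberately deferred so that the assembly step can be
checked against an exhaustive oracle.

`assemble_architecture()` selects the chain of exactly five non-overlapping
hits, in order, with every inter-finger linker of 0–15 residues
("tandem" is not quantified in the source material; 15 is our default and
configurable), that minimises the total span from the first cysteine to the
last histidine. Ties are broken by leftmost start. A permissive mode
returns the best four-finger chain flagged `partial`, because genuine
superfamily members with an unrecoverable ZF1 occur and are classifiable
from fingers 2–5.

Two trimming rules anchor all downstream coordinates:

* the **ZF region** runs from the ZF1 first cysteine through the ZF5 last
  histidine (inclusive) — this is the region used for distances and trees;
* the **N-terminal region** is the prefix ending two residues after the ZF1
  first cysteine — this is the region scanned for ZOC and ZF-NC.

All coordinates in the package are 1-based with closed intervals, the
native convention of R string handling (`substr`); the two rules above are
stated in that convention and property-tested (prefix + remainder
reconstitutes the input; trimming is idempotent).

## Motif scoring

A consensus pattern is an ordered list of scored positions — fixed residues
or alternative sets such as `F/L` — with one bounded internal spacer whose
residues are never scored. Percent identity is the fraction of scored
positions at which the query carries the consensus residue (any member of
an alternative set counts); percent similarity additionally accepts
residues sharing a physicochemical class with the consensus residue. The
default grouping is

> aliphatic {A,V,L,I,M}, aromatic {F,Y,W}, basic {K,R,H}, acidic {D,E},
> amide {N,Q}, hydroxyl {S,T}, singletons {G}, {P}, {C};

`X` belongs to no class and never matches. This standard partition is the
simple scheme consistent with all four reference values the package's
acceptance tests pin down (AKQE vs IKQE: 75% identical, 100% similar;
GAFFRFMR vs GAFFRYMR: 100% similar; HDYIHH vs RDFLRR: 100% similar;
SPAKDN vs QPIKQE: 50% similar): it must make A–I, F–Y, H–R and I–L similar
while keeping S–Q, D–Q and N–E dissimilar. One documented discrepancy:
direct counting of GAFFRFMR against GAFFRYMR gives 7/8 = 87.5% identity,
whereas the originally reported figure was 86%; the denominator behind 86%
is not recoverable, so the package reports 87.5.

`scan_motif()` scores every start offset and admissible spacer length
gaplessly and returns matches best-first (similarity, then identity, then
leftmost, then shortest spacer). The default reporting threshold is 70%
similarity; sub-threshold best candidates are still surfaced as
"motif-like" so weakly conserved putative domains remain visible. For
ZF-NC, a location check requires the match to end at most 30 residues
(configurable) upstream of the ZF1 first cysteine.

## From evidence to a subfamily call

`rule_classify()` emits one of `zic`, `gli/glis/nkl-like`, or `non-family`,
with an evidence trail (criterion, value, passed) attached to every call:

* no five-finger (or flagged partial) architecture → `non-family`;
* architecture present and ZF1 spacing ≥ 8 (default threshold, midway
  between the canonical 2–4 and the expanded Zic spacers) → `zic`;
* architecture *partial* (no ZF1, hence no spacing) and a passing ZOC or
  ZF-NC motif → `zic`, flagged partial;
* otherwise → `gli/glis/nkl-like`.

The design question of whether motif evidence alone should suffice for a
zic call when ZF1 spacing is canonical was resolved against it: the revised
ZOC consensus scores only six positions, and windows clearing 70%
similarity arise by chance in a percent or so of random N-terminal regions,
so a motif hit is corroborating evidence, not an override of an observed
canonical spacer. Both motifs are computed and reported in the evidence
trail regardless.

Nothing in the stated sequence characters separates gli from glis from nkl;
only placement against a labelled reference panel does. `place_query()`
assigns the panel subfamily with the smallest mean p-distance between
trimmed ZF regions, where the p-distance is 1 minus the identical fraction
under the best gapless sliding offset of the shorter sequence along the
longer. Placement is advisory: it refines `gli/glis/nkl-like` into
`gli`/`glis`/`nkl` and never overturns a rule-based `zic` or `non-family`
call. Exact placement ties are broken by a compatible rule label, then
lexicographically, and flagged. `nj_tree()` (standard neighbor joining)
renders the panel-plus-queries distance matrix as a tree for display.

## Origin scenarios under Dollo parsimony

For a presence/absence map of one gene family over the leaves of a rooted
species tree, `dollo_counts()` fixes a single gain at a candidate origin
node and counts the minimal number of loss events below it, one event per
edge subtending a maximal absent clade. A scenario is infeasible when any
present leaf falls outside the origin's subtree. Two useful facts, both
property-tested: the Dollo total is bounded below by the unordered
(Fitch/Sankoff) minimum-change count, and losses never decrease as the
origin moves rootward — in fact they strictly increase, which is why
distinct feasible origins never tie and `rank_scenarios()` can only flag a
tie when two candidate references resolve to the same node.

The bundled default topology is ladder-like —
`(Porifera,(Ctenophora,(Placozoa,(Cnidaria,Bilateria))))` — reflecting the
prevailing placement of placozoans diverging after both poriferans and
ctenophores; basal metazoan branching remains debated, and any rooted
newick can be supplied instead. On that topology with the family present in
Placozoa + Cnidaria + Bilateria, an origin at their common ancestor costs
one event (1 gain, 0 losses) while an origin at the metazoan root costs
three (1 gain, 2 losses — one per basal lineage), which is the quantitative
content of the "single later divergence" argument.

Polytomies are supported throughout (children are treated independently;
the minimum-change count uses a unit-cost dynamic programme that is exact
on multifurcations).

## The synthetic generator

`make_protein()`/`make_dataset()` build labelled superfamily-like proteins
so the whole pipeline is testable without downloads:

* five tandem fingers with internal geometry CC = 2, Cys–His = 12,
  His–His = 3 and fixed 10-residue linkers;
* ZF1 inter-cysteine spacer drawn from 10–14 for zic and 2–4 for
  gli/glis/nkl ("expanded" is not quantified in the source; these ranges
  keep the two classes cleanly separated around the default threshold
  of 8);
* for zic, exact-consensus ZOC and ZF-NC instances planted N-terminal to
  ZF1 with probability 0.9 each (ZF-NC within the 30-residue location
  window);
* background tails (N: 25–45, C: 10–30 residues) and fillers drawn from
  the 18 non-C/non-H residues, so that at mutation rate 0 the planted
  coordinating residues are the only scanner anchors and ground truth is
  exact;
* per-subfamily core residue templates are deterministic (fixed internal
  per-label seeds), giving p-distance placement a stable signal;
* point mutations at per-residue rate μ, never at the 20 coordinating
  positions — recovery tests therefore measure the pipeline, not generator
  damage. The per-residue uniforms and substitution choices are drawn for
  every eligible residue whatever μ is, so datasets generated from one seed
  at different rates differ only by strictly nested mutation sets and
  degradation with μ is monotone by construction.

What the generator does **not** emulate: realistic amino-acid composition,
indels, substitution-model evolution along a tree, or divergence structure
within a subfamily. Passing recovery tests therefore demonstrates the
pipeline's correctness on sequences whose characters match the stated
consensus definitions, not its sensitivity on deeply diverged real
proteins.

## Problem sizes and numerical choices

The test suite checks the scanners against brute-force enumeration oracles
(cross-product filtering for fingers, per-window scoring for motifs) on
random inputs up to 300 residues; Dollo counting against exhaustive
loss-edge-subset enumeration on random rooted trees of 3–8 leaves;
neighbor joining against the generating topology on 8-leaf additive
matrices; and end-to-end label recovery on 200-protein datasets at
μ = 0 (required: 100%) and μ = 0.02 (required: ≥ 95%). Percentages are
reported to one decimal; comparisons against integer reference values
round to the nearest integer. Degenerate inputs are handled explicitly:
an N-terminal trim reaching past the sequence end returns the available
prefix with a warning, `X` residues are accepted but never match, and `*`
stop characters are stripped with a warning at parse time.

## Known limitations

* The ZF1 spacing threshold (8) is a package default, not a measured
  boundary; real expanded spacers should be inspected via the always-on
  evidence trail.
* gli/glis/nkl refinement is entirely panel-relative; with no panel the
  call remains `gli/glis/nkl-like`.
* The p-distance uses a single gapless offset; it is adequate for trimmed
  ZF regions of near-equal length, not for sequences with internal indels.
* Dollo counting weighs all losses equally; it ranks scenarios by event
  count only and encodes no lineage-specific plausibility arguments.
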