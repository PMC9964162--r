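---
title: "Methods: motif, domain-profile and phylogenetic characterization of GH51 arabinofuranosidases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif, domain-profile and phylogenetic characterization of GH51 arabinofuranosidases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gh51kit)
```

# The problem

Glycoside hydrolase family 51 (GH51) is dominated by
α-L-arabinofuranosidases: exo-acting enzymes that release terminal
α-L-arabinofuranose from arabinoxylan, arabinan and arabinogalactan. Plant
GH51 proteins carry two catalytic glutamates on a (β/α)~8~ barrel — the
acid/base of the conserved `G-N-E` motif and the nucleophile inside
`S-E-Y-x-V` — and many carry an additional N-terminal β-sandwich domain
homologous to family-4 carbohydrate-binding modules (a "CBM4-like" domain)
that lacks the sugar-binding residues of true CBM4s but contains a
conserved `G-x-x-F-E-x-I-x-x-x-G-x-G-G` strand.

`gh51kit` implements the in silico characterization pipeline for such
families as reusable, tested components:

1. **Family validation** — a sequence is accepted when it is at least 350
   residues long and simultaneously carries `G-N-E/Q` and `S-E-Y-x-V`.
2. **Catalytic acid/base classification** — canonical `G-N-E` versus the
   `G-N-Q` / `G-N-D` substitutions and the `G-S-N` variant seen in some
   monocotyledon (clade II) enzymes, where replacing the acid/base E by Q
   potentially inactivates the enzyme.
3. **Domain excision** — the CBM4-like region is delimited in a multiple
   alignment between the conserved `L-x-V-D` and `S-x-x-P` anchor motifs.
4. **Profile HMM** — a match/insert/delete profile is estimated from the
   excised alignment and used to scan sequence collections (a native
   stand-in for `hmmbuild`/`hmmscan`).
5. **Prevalence** — per-kingdom counts of profile possession with Wilson
   95% intervals.
6. **Block trimming** — Gblocks-style removal of ambiguous alignment
   regions before phylogenetics.
7. **Phylogeny** — neighbor joining on p-distances with column-resampling
   bootstrap, clade extraction, and congruence between clade membership
   and catalytic status.
8. **Pairwise identity** — global affine-gap alignment (BLOSUM62) with
   percent identity.

A synthetic-family generator with exact ground truth makes every stage
testable without downloading anything.

# Conventions

All coordinates are 0-based half-open internally; human-readable reports
are 1-based inclusive. The residue alphabet is the 20 canonical amino
acids plus X; B/Z/U/O are mapped to X with a warning, because all motif
rules are defined on canonical residues only. In motifs, the wildcard `x`
matches anything including X, while fixed and alternation tokens never
match X — the conservative choice for ambiguous residues. `.` and `-` are
both accepted as gaps on input; `-` is emitted.

# Motif scanning and validation

Patterns are dash-separated tokens (one residue, a `/`-joined alternation,
or `x`) compiled to per-position allowed-residue sets and scanned over
every window, overlaps allowed, leftmost first. The scanner is checked
against an independent regex-engine oracle on random sequences.

`validate_gh51()` applies the published filtering rule (length ≥ 350 and
both catalytic-region motifs). Because published trees also contain
`G-N-D` and `G-S-N` sequences that this filter would exclude — the source
protocol does not reconcile the two — a `relaxed = TRUE` mode widens the
acid/base token to `N/S` + `E/Q/D/N`. The strict rule is the default; we
do not guess which variant produced any particular published count.

Catalytic classification scans for `G-N-E`, then `G-N-Q`, `G-N-D`,
`G-S-N`, in that precedence (direct scan). When an alignment and a
reference acid/base column are supplied, the call is made from the residue
in that column instead, and a sequence with several direct matches is
resolved at the reference column when possible, otherwise leftmost and
flagged ambiguous. The precedence order is our choice; the source infers
the motif from an alignment figure without stating a procedure.

# Domain excision

`locate_conserved_motif()` slides a pattern over column windows and keeps
the window matched by the largest fraction of rows (gaps disqualify a
row), requiring at least `min_fraction = 0.5`; "conserved" is published
without a threshold, so a strict majority is demanded. Ties break
leftmost. Excision spans the first column of `L-x-V-D` through the last
column of `S-x-x-P`, both anchors included: the end motif sits on the loop
separating the CBM4-like domain from the barrel, so it bounds the domain
inclusively. The protocol only states that columns *after* the end motif
were removed; whether leading columns were removed is unstated, so
removing them is the default (the domain is *between* the motifs) and
`keep_left = TRUE` preserves the literal protocol. Rows that are all-gap
inside the window are flagged and excluded from profile training.

# The profile HMM

**Architecture.** Columns with gap fraction ≤ 0.5 become match states.
Emissions are estimated with a Laplace-style pseudocount mixed with the
background, `(counts + α·bg) / (n + α)`, α = 1; transitions are counted
from each row's observed match/insert/delete path and smoothed the same
way. Weighting is uniform — a documented deviation from `hmmbuild`'s
Henikoff weighting. Note that with additive pseudocounts, duplicating a
training row *does* shift the estimates toward the data; only the
architecture and modal residues are duplication-invariant.

**Scoring.** Scores are log~2~ odds (bits) against an i.i.d. background
null with a geometric length term. In local mode the model enters any
match state uniformly (1/M) and exits any match state with a constant
probability τ = 0.1 (remaining transition mass scaled by 1 − τ);
unannotated flanking residues are emitted by background loop states whose
self-transition equals the null's geometric parameter r = 350/351, so a
flank residue costs exactly 0 bits and each core-consumed residue is
relieved of the null's per-residue r (−log~2~ r ≈ 0.004 bits). The
constant end terms cancel by construction. A glocal switch forces
traversal of the whole model. X emits the background in every state
(0 bits). Forward and Viterbi are exact dynamic programs (C++), verified
against full path enumeration on all small instances (M ≤ 4, sequences
≤ 6 residues) at 10^−9^ log-space tolerance.

**Scanning.** Only sequences longer than 200 residues are searched; the
rest are recorded as skipped, not negative, and never enter prevalence
denominators. The acceptance threshold defaults to **25 bits**. The
original plan of 0 bits proved wrong in implementation: under uniform
local entry/exit, any ~500-residue sequence contains short spurious match
stretches worth a few bits (shuffled decoys reach ~10 bits), while genuine
planted domains score in the hundreds; 25 bits is a conventional
gathering-threshold order of magnitude between those regimes, and it
remains configurable. No E-value calibration is attempted.

# Prevalence

`percent()` rounds half-up to one decimal, matching the dominant reporting
style of the published counts. One published figure cannot be reproduced
under any single rounding rule: 1354/2189 = 61.855%, printed as 61.8,
while 119/133 = 89.47% is printed as 89.5 — truncation in one case,
rounding in the other. The package keeps the half-up rule everywhere and
the acceptance test records the 61.8 expectation as failing; the
discrepancy is an upstream reporting inconsistency, not a computational
degree of freedom. Wilson 95% intervals accompany every proportion.

# Block trimming

Columns are classified with the published parameters: a column with ≥ 50%
gaps is a `gap_position` (gap rule "half"); otherwise `highly_conserved`
when the modal residue reaches 85% of rows, `conserved` at a strict
majority, else `nonconserved`. Trimming removes maximal runs of more than
15 contiguous nonconserved/gap columns, trims each surviving run back to
conserved-or-better columns at both ends, and drops blocks shorter than 2.
This is a declared simplification of Gblocks 0.91b: flank-refinement
sub-steps are omitted, and a short internal run of gap positions inside a
kept block survives here whereas Gblocks removes every gap position.
Correctness is assessed against hand-worked fixtures, not bit-for-bit
Gblocks output.

# Phylogeny

p-distances (mismatches over pairwise-comparable columns; gaps and X
excluded) feed standard Saitou–Nei neighbor joining via `ape::nj`, with
negative branch estimates clamped to zero with a warning. NJ on
p-distances is an explicit stand-in for maximum-likelihood inference with
model selection and ultrafast bootstrap, which is out of scope; congruence
conclusions are therefore qualitative, not a topology reproduction.
Bootstrap support is the classical column-resampling NJ bootstrap,
deterministic given a seed. Clade analysis requires an explicit outgroup
(no automatic rooting), takes the smallest rooted clade containing the
seed taxa, and cross-tabulates catalytic status inside versus outside,
listing exceptions on both sides — mirroring the published eelgrass and
duckweed counter-examples, where tree position and motif state disagree.
Tree position and motif state are always reported separately, never
merged. A report-level filter collapses branches below 90% support.

# Pairwise identity

Needleman–Wunsch with affine gaps (BLOSUM62 from Biostrings; open 10,
extend 0.5; a gap of length g costs open + (g−1)·extend), with
deterministic traceback preference match/mismatch > gap-in-a > gap-in-b,
verified against exhaustive alignment enumeration for short sequences.
Identity defaults to identities over columns where both rows hold residues
(ClustalW-like); the shorter-sequence denominator is exposed because
published identity figures rarely state their convention, and figures
derived from different programs can differ by about a point for that
reason alone.

# The synthetic generator: what it emulates and what it does not

`generate_family()` builds one ancestor per family: a proline linker, then
(optionally, per sequence with probability p) the CBM4-like domain —
`L-x-V-D`, a 40-residue spacer, `G-x-x-F-E-x-I-x-x-x-G-x-G-G`, a
60-residue spacer, `S-x-x-P` (122 residues in all) — then the catalytic
region with `G-N-E` and `S-E-Y-x-V` at fixed offsets. Ancestor length is
drawn so that domain-less rows stay at or above 350 residues within the
350–700 default range. Descendants evolve star-like: substitutions at 0.05
per residue from a flat non-identity model (no empirical exchange matrix —
sufficient for recovery tests), indels at 0.01 per residue with geometric
lengths of mean 2, never inside motifs, so truth labels stay exact.
Catalytic variants are planted per sequence from the composition (default
0.70 E / 0.25 Q / 0.03 D / 0.02 GSN, echoing a clade-II-like Q fraction
with rare D and GSN singletons). Decoys (default 10%) are residue-shuffled
family members. The true alignment is assembled from the known indel
history; decoys, having no homology, are excluded from it.

Two details keep truth exact rather than merely likely: accidental copies
of any planted motif in free ancestor regions are rewritten before
evolution (so leftmost-match classification cannot be confused at zero
noise), and `passes_filter` is computed by actually running the validator
on each emitted sequence. At zero substitution noise the generator
re-scans its own output and asserts classification and anchor presence
against the planted truth.

What a green synthetic test does **not** establish: realistic amino-acid
exchangeabilities, rate heterogeneity, phylogenetic correlation between
sequences (the process is star-like by design), composition bias, or the
behavior of the profile scan on genuinely borderline homologs. Decoy
rejection here is easier than rejecting a distant homolog would be.

# Numerical choices and degenerate inputs

Forward/Viterbi run in log~2~ space with log-sum-exp; the path-enumeration
tolerance is 10^−9^. All emission and transition distributions are
asserted to renormalize to 1 ± 10^−9^ at build time. Profile serialization
prints probabilities with `%.17g`, so reading a profile back reproduces
scores bit-for-bit. Alignment traceback ties and conserved-window ties are
broken deterministically (stated preferences; leftmost). Empty inputs
return empty results (`read_fasta` on an empty file, `filter_set` and
`scan_profile` on empty sets); ragged alignments, duplicate ids, illegal
residues, unknown groups, missing anchors, out-of-order anchors and
all-skipped scans raise typed errors rather than propagating nonsense.
All pipeline randomness flows from one config seed; stage seeds derive
from it by a stable hash, so identical configurations produce
byte-identical artifact bundles.

# Known limitations

- The profile HMM has no E-values, no Henikoff weighting, no multi-domain
  decomposition; threshold choice is in bits.
- NJ + p-distance phylogenies are stand-ins; do not read branch lengths or
  deep topology as ML results.
- The block trimmer is not bit-compatible with Gblocks (by design, see
  above).
- Identity values can differ from web-service figures by about a point
  depending on the denominator convention those services used.
- The 61.8% worked value is unreproducible under any consistent rounding
  rule, as discussed under *Prevalence*.
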