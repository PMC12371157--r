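---
title: "Methods: centromere landscape analysis from CENH3 ChIP repeat enrichment"
author: "centroscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: centromere landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(centroscape)
```

# Scope and model

Plant centromeres of the kind this package targets are defined functionally
by CENH3-bound chromatin and structurally by two repeat classes: tandem
satellite arrays (a basic monomer unit, here in the 120–324 bp range, often
carrying shorter internal subunits) and centrophilic Ty3/*Gypsy*
retrotransposons of the CRM lineage, whose LTRs can themselves embed the
centromeric satellite. The package turns that picture into six testable
stages: repeat enrichment scoring, centromeric-domain calling, satellite
characterization, LTR-element annotation with insertion dating, domain
composition typing, and a synthetic-data generator that plants all of the
above with known truth.

Throughout, coordinates are 0-based half-open; GFF3 output converts to
1-based closed via `rtracklayer`.

# Repeat enrichment

A read is assigned to the library consensus with which it shares the most
canonical k-mers, provided that count reaches `min_fraction` of the read's
k-mer positions; ties go to the lexicographically smallest repeat id, and a
read counts toward at most one repeat. Canonical matching is implemented by
indexing both strands of every consensus and matching forward read k-mers,
which is equivalent and avoids per-read reverse complementing. Defaults
`k = 21`, `min_fraction = 0.5`: 21 is long enough that chance sharing
between a 150-bp read and a few-hundred-bp consensus is negligible, and at
a 2% per-base error the expected intact-k-mer fraction is
`0.98^21 = 0.65`, comfortably above 0.5 for typical reads. The threshold
governs *whether* a read is assigned; the shared-k-mer maximum governs
*which* repeat wins. Reads whose mutations cluster unluckily fall below the
threshold and stay unassigned — the tests therefore check (a) that
assignments agree with a brute-force local-alignment oracle on essentially
every assigned read and (b) that the bulk of reads are assigned at the 2%
regime.

The per-repeat score is the library-size-normalized ChIP/input ratio
`(chip_hits/chip_total) / (input_hits/input_total)`. It is scale-invariant
in the two totals, undefined (flagged, not infinite) at zero input hits,
and rounded only at report time. When a published survey prints raw hit
counts and normalized ratios but not library sizes, the implied constant
`input_total/chip_total` is recovered from any one row
(`calibrate_library_ratio()`); recovering it from one row and reproducing
the other rows at printed precision is both a consistency check on the
table and the package's reference test. For the shipped hop survey the
constant is 2.0826.

One caveat the demo makes visible: the normalized ratio recovers the
planted fold-enrichment only when the enriched interval is a small fraction
of the genome (as real centromeres are of a 2.8-Gb genome). In a 400-kb
demo chromosome whose enriched interval is an eighth of the sequence, ChIP
read mass saturates and ratios compress toward
`p_chip_inside / p_input_inside`; the candidate threshold in
`run_pipeline()` is config-exposed for that reason (default 5 in the demo,
versus 10 for genome-scale data).

# Domain calling

Per-bin enrichment is
`log2(((chip + p)/chip_total) / ((input + p)/input_total))` with
pseudocount `p = 1`, boxcar-smoothed over 5 bins (windows shrink at
chromosome ends), bins of 10 kb — sized for 150-bp reads at tenfold or more
coverage, all config-exposed. The summit is the midpoint of the maximal
smoothed bin; exact ties resolve leftmost, with remaining tied bins kept as
secondary diagnostics. Degenerate inputs are flagged rather than guessed
at: an all-zero ChIP track yields `no_enrichment` and no summit; an exactly
flat profile yields `flat_profile` and bin 1 by the tie rule. The score is
antisymmetric under swapping the channels at equal totals, which the tests
exercise.

The centromeric domain is the fixed window `summit ± 3 Mbp` intersected
with the chromosome — 6 Mbp exactly whenever the summit is at least 3 Mbp
from both ends, clipped and flagged otherwise. Morphology uses the Levan
convention on the arm ratio `q/p`: metacentric below 1.7, submetacentric
below 3.0, acrocentric above; a terminal summit is telocentric/undefined.

A geometric point about summit recovery: the read simulator plants a
*uniform* enrichment plateau over `centromere_center ± halfwidth`. A
plateau has no identifiable sub-plateau summit — any estimator's argmax is
uniform over it — so one-bin recovery is only a meaningful claim when the
plateau is commensurate with the smoothing window (the boxcar of a 5-bin
plateau is a triangle peaked at the center bin). The recovery tests
therefore plant `halfwidth = 25 kb` against 10-kb bins and 5-bin smoothing;
with wider plateaus the domain (a 6-Mbp window) is insensitive to where on
the plateau the summit lands, which is what the 10-Mb acceptance check
exercises at `halfwidth = 50 kb`.

# Satellite tools

**Monomer length** is the argmax of the shifted-match profile
`m(p) = mean(seq[i] == seq[i+p])`. A true tandem period at per-copy
mutation rate `e` peaks near `(1-e)^2 + e^2/3` (both copies independently
mutated); harmonics (2p, 3p, ...) peak equally, so the estimator returns
the *smallest* period within 0.02 of the global peak and reports the rest
as harmonics. Significance is a robust z-score of the peak against the
profile background, *or* an absolute match fraction of 0.8 or more — the
second clause covers exact short-period tandems, whose structured profile
inflates the background spread and deflates the z-score while i.i.d.
sequence cannot reach 0.8 (its profile peaks near 0.3). The profile is a
self-comparison, hence invariant under cyclic rotation of the array.

**Subunits** are found by monomer self-comparison at every shift: a run of
at least `min_len` (20 bp) positions at 80% identity at shift `s` means an
internal repeat of period `s`; the smallest qualifying shift is reported
with copy count and offsets. When the repeat structure covers ~90% of the
monomer, the monomer is itself a tandem of the subunit and is flagged, with
`s` as the candidate true monomer. Reported offsets are accurate to a few
bases (the run boundary is a windowed statistic), which the tests reflect.

**Identity** is everywhere matches / alignment columns, gaps counting
against identity, under match 1 / mismatch −1 / gap open 2 / extend 0.5
(`Biostrings::pairwiseAlignment`; terminal gap columns are included via
`alignedPattern()`, which matters — the optimal global alignment of two
rotations of one sequence is a terminal-gapped overlap that would otherwise
masquerade as 100% identity). The heatmap computes this for every window
pair on both strands (defaults window 5 kb, step 2 kb; `step > window` is
allowed but flagged sparse). **Consensus similarity** additionally searches
all cyclic rotations of the second sequence (stride-4 coarse pass, then
single-base refinement) because satellite monomers have arbitrary phase.
Within the rotation search the gap penalties are stiffened to open 4 /
extend 1: the maximum over ~160 gapped alignments otherwise favours
wrong-phase alignments that fake identity through cheap gaps, biasing the
reported similarity upward by several points at high divergence.

# LTR element annotation

Detection is structure-only self-comparison. Exact 21-mer anchor pairs at
separations of 1–25 kb are grouped by diagonal — syndata mutates by
substitution only, so a true LTR pair shares one exact diagonal — and
clustered (anchor gaps above 500 bp split clusters; k-mers occurring more
than 25 times are not anchors, since at that multiplicity they are
satellite k-mers and would generate quadratically many spurious pairs).
Each cluster is boundary-refined by extension along its diagonal: extension
stops at 4 consecutive mismatches and trims back to the furthest position
whose trailing 10-window holds at least 8 matches. Random sequence reaches
that quality with probability about 4e-4 per position, so chance matches
rarely drag a boundary outward; diverged edges that trim a few bases short
are recovered by the TSD search. Candidates must have LTR length 100–3000
bp and LTR–LTR identity of at least 85% (all config-exposed), and a
candidate whose whole span is tandem-periodic (shifted-match fraction 0.75
or more at any period up to 500 bp) is rejected — that is the signature of
a pair found *inside* a satellite array, never of a real element, even one
whose LTR embeds a satellite monomer copy.

Boundaries are then pinned by an exact-TSD search over a ±10 bp jitter
window: among all (length 4–6, start shift, end shift) combinations whose
flanks are exactly duplicated, the winner maximizes
`t − 0.25·inward − 1.0·outward` shift. The asymmetry encodes that the
extension overshoots (a chance match run beyond the element) far more often
than it stops short; the joint score also prevents two failure modes seen
during development — a sub-duplication of the true TSD at a shifted offset
outranking the full one, and a chance duplication deep inside the LTR body
outranking the true flanking TSD. Candidates without any exact TSD are kept
but flagged. Overlap adjudication prefers TSD-bearing candidates, then the
*shortest* separation (elements sharing an LTR sequence spawn cross-copy
pairs at larger separation; the innermost pairing is the real one), then
identity. Solo LTRs — isolated k-mer footprints of a detected element's LTR
away from any accepted element — are reported separately, never as
elements.

**PBS** detection scans a 30-bp window 3′ of the 5′ LTR (plus a 5-bp lead
into the called LTR, absorbing boundary jitter) for the best catalog motif
at one mismatch or fewer. **Protein domains** are called by local alignment
(BLOSUM62, near-ungapped penalties) of short amino-acid consensus profiles
against all six translation frames; presence requires 60% of the profile
self-score, which random 2-kb sequence never reaches in twenty seeded
trials. The shipped profiles are synthetic fixtures, not biological
consensi. **Autonomy** is a partition: all six domains (GAG, PRO, RT, RH,
INT, CHD) = autonomous; missing exactly the enzymatic core RT/RH/INT =
dominant nonautonomous; missing the core plus more = minor nonautonomous;
anything else (e.g. missing INT alone) = unclassified rather than
force-fitted.

**Insertion age** is `K / (2·rate)` with rate 6.1e-9 substitutions per
site per year and `K` the corrected divergence of a global LTR–LTR
alignment over non-gap columns — Kimura two-parameter by default (raw and
Jukes–Cantor available; the corrections order K2P ≥ JC ≥ raw, verified on
random pairs; saturated corrections return NA with a flag). Pairs aligning
below 60% identity are flagged unreliable and the age withheld. Note the
statistical floor: an element planted at divergence `d` realizes
`Binomial(L, d)/L` substitutions, so for `d = 0.006` and 2-kb LTRs the
realized divergence itself has ~29% relative standard deviation. The
estimator tracks the *realized* divergence to within a fraction of a
percentage point; fixed-seed tests additionally check closeness to the
planted target.

# Composition typing

Masking tiles each consensus into ~100-bp pieces matched with
`Biostrings::matchPattern` at a mismatch budget from `min_identity`
(default 0.7; substitution-only matching, consistent with the generator).
Adjudication is greedy by score over *individual tile hits* — higher score
wins, ties go to the lexicographically smaller family, losers are trimmed
to remainders of at least `min_len` (30 bp) — and accepted pieces are
merged per family afterwards. Adjudicating tile hits rather than merged
family intervals matters when a TE consensus embeds another family's
monomer (the CRM/SaazCEN situation): merged-interval scores are dominated
by interval length and would let the long TE model swallow whole satellite
arrays. Even at tile level, attribution *inside* an array is genuinely
ambiguous between the satellite and the monomer-carrying TE (the competing
tiles cover the same sequence), and the pipeline bridges sub-kilobase gaps
when selecting array regions for monomer estimation. The procedure is
idempotent: re-adjudicating a non-overlapping annotation changes nothing.

The two-type call is: type 2 when any accessory satellite family (satellite
class, not one of the two named major families) occupies at least 2% of the
domain — an inclusive threshold, config-exposed, chosen as a clear margin
above masking noise while far below the tens-of-percent occupancy of real
accessory arrays; the published description of the types is qualitative.
Summit-to-substructure assignment is half-open and exhaustive (ltr, coding,
spacer, outside_element), with coding taking precedence over ltr as a
safety rule should intervals ever overlap.

# The synthetic-data generator

`simulate_genome()` emits i.i.d. background at a specified GC (default
0.4) and overwrites it with plants: satellite arrays (each copy
independently substituted at the given rate; optional single-base indels
default to 0, since divergence bookkeeping and the exact-diagonal detector
assume substitution-dominated decay) and LTR elements emitted as
TSD + 5′LTR + PBS + internal + 3′LTR + TSD, the 3′ LTR substituted at the
target divergence. Truth records are byte-faithful: extracting truth
coordinates reproduces planted sequences exactly, and realized substitution
counts are recorded. One RNG stream per chromosome is derived
deterministically from the global seed, so outputs are reproducible and
chromosome edits do not cross-talk. `simulate_reads()` draws input starts
uniformly and ChIP starts with relative weight `chip_fold` inside
`center ± halfwidth`; both channels get `depth × length / read_length`
reads; reads never cross chromosome ends; minus-strand reads are
reverse-complemented.

Defaults are the study conditions of the test-bed: 150-bp single-end reads
(FASTQ with constant quality on request), fold 20, depth 20×, halfwidth
50 kb. Fold and depth are fixture choices — the assay they emulate does not
publish them — chosen so that enrichment is unmistakable at desk scale yet
binomial noise remains visible.

What the generator does *not* emulate, and hence what green tests do not
establish about real data: sequencing error beyond optional uniform
substitution, paired-end structure, indel-driven LTR decay, nested
insertions, heterozygosity or polyploidy, and repeat structure outside the
plants. The detector's exact-diagonal assumption in particular would need
a banded-alignment extension for indel-rich real elements.

# Problem sizes

The shipped demo (`demo_genome_spec()`) uses two 400-kb chromosomes — one
type-1 centromere (major satellite array of 60 × 284 bp plus three CRM-like
elements) and one type-2 (adding a 100 × 323 bp accessory array) — at depth
10, which the full pipeline traverses in about a minute on one CPU.
Property suites use 2-Mb chromosomes for summit recovery (20 read
simulations), a ~150-kb sequence bearing 20 elements of assorted geometry
for structural recovery, and 30-kb repeat-free backgrounds for
false-positive counts. These sizes are the package's chosen demonstration
scale; all stages accept larger inputs with the same interfaces, with the
all-pairs identity heatmap (quadratic in window count) and de novo element
scan the first to grow expensive.

# Interfaces

The exported functions are the package's interface, with `run_pipeline()`
as the one-call orchestration (config list or YAML; stages abort naming
themselves and the offending input) and `scripts/acceptance.R` as the
reproduction script. Genome and reads are FASTA/FASTQ; truth and
annotations export to BED, bedGraph and Parent-linked GFF3 through
`rtracklayer`; report tables are TSV.

# Known limitations

- Element detection requires near-exact diagonals; indel-rich or highly
  diverged (< 85% LTR identity) elements are out of reach by design.
- TSD pinning assumes the insertion produced an exact duplication; aged
  elements whose TSDs have mutated are kept but flagged, with boundaries
  only as good as the diagonal extension (typically within a few bases).
- Masking attribution between a satellite and a TE embedding it is split,
  not resolved; composition consumers should group such families when the
  distinction matters.
- The normalized ratio compresses when the enriched interval is a large
  genome fraction (see above); candidate thresholds must be chosen for the
  geometry at hand.
- A flagged unreliable LTR pair (< 60% identity) withholds age rather than
  reporting a saturated estimate.
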