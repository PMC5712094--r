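---
title: "Methods: models, parameters and design choices in uvbsrna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in uvbsrna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`uvbsrna` re-implements, as a tested and fully synthetic-data-driven
pipeline, the analysis chain of a two-condition (UVB-treated vs control)
plant small-RNA sequencing study: read cleaning into 18–30 nt unique tags,
annotation-based classification, known-miRNA identification, hairpin-based
novel-miRNA discovery, plant miRNA target prediction under the Allen-style
positional rules, a formulaic RPM / log2 fold-change / ratio differential
expression procedure, and two closed-form phenotype utilities. This
vignette records the models, the tunable parameters and why their defaults
are what they are, and the decisions taken where the design was genuinely
open.

# The stacked-pair folding model

All "minimum free energy" values in the package come from one deliberately
self-contained secondary-structure model rather than a full thermodynamic
parameter set:

* admissible pairs: Watson–Crick plus G:U wobble (wobble can be disabled);
* pseudoknot-free structures with a minimum hairpin loop of 3 nt;
* a pair contributes energy only when stacked directly inside an adjacent
  enclosing pair: −2 (model units, nominally kcal/mol) for G:C, −1 for
  A:U and G:U; isolated and loop-closing pairs contribute 0.

The optimum is computed exactly by dynamic programming (C++, `O(n³)`), and
`fold_hairpin()` is property-tested against an exhaustive enumeration of
all structures for sequences up to 20 nt. The same stacking table scores
miRNA:target duplexes, where the structure is forced (position *i* of the
miRNA faces site position *L−i+1*), so the duplex "MFE" is a simple sum
and the ratio to the perfect-complement MFE is well defined and lies in
[0, 1].

Two consequences of this model are worth knowing:

* **Reverse-complement symmetry holds only without G:U.** Under reverse
  complement a G:U pair maps to C:A, which does not pair; the
  mirror-structure property is therefore only tested with `allow_gu =
  FALSE`.
* **The score scale is not Turner's.** Random and dinucleotide-shuffled
  sequences of precursor size (≈100 nt) already reach −34…−46 under this
  model, while genuine near-perfect hairpin precursors score below −50.
  A hairpin acceptance threshold in the Turner-intuition range (≈ −18)
  accepts essentially every shuffled null. The default
  `hairpin_criteria(score_max = -45)` was therefore calibrated once,
  before any test was frozen, as approximately the 1st percentile of the
  dinucleotide-shuffle null for 60–120 nt sequences; with it, shuffled
  precursors are rejected ≈98–99% of the time while the synthetic
  precursors pass with a ≥5-unit margin.

# Hairpin discovery

Unannotated, genome-mapped tags are clustered (loci within 30 nt merged)
and each cluster is extended by 150 nt per side — typical plant precursor
dimensions. At realistic depth the dispersed intergenic background merges
into clusters much longer than any precursor, so the candidate evaluated
for a window is centred on the window's most abundant tag (the putative
mature): a mature ± flank subwindow is folded, and the precursor is then
trimmed to the pairing span of mature plus star (+10 nt pad) before the
acceptance criteria are applied. Criteria: mature wholly in one arm and
not crossing the terminal loop; ≥16 mature bases paired to the opposite
arm; folding score ≤ `score_max`; trimmed precursor length within
60–300 nt. Clusters with fewer than `min_support = 5` reads are not
folded. Because a mature tag also matches antisense at its own star arm,
two windows can describe one hairpin; accepted candidates are
deduplicated per mature sequence (best score wins) so no tag is counted
twice, and known-matched tags never support a novel candidate.

The discovery stage deliberately over-calls on random intergenic clusters
that happen to contain long paired spans: the flat score threshold is not
length-normalized. This mirrors the high false-positive character of
hairpin-only novel-miRNA prediction; a length-normalized or shuffle-based
per-candidate test would tighten it and is left out by design.

# Target prediction

Rules on a scored duplex, positions 1..L from the miRNA 5′ end
(G:U = 0.5 score but not a mismatch state; mismatch = 1):

a. no run of more than two adjacent mismatches;
b. total score ≤ 4;
c. score over positions 1–12 ≤ 2.5;
d. no mismatch at positions 10–11;
e. no adjacent mismatches within positions 2–12;
f. duplex MFE ≥ 75% of the perfect-complement MFE (fails closed if the
   perfect MFE is 0).

Treating G:U as half a mismatch for the summed rules but not for the
positional rules follows the fractional bound in rule c; whether G:U at
10–11 disqualifies is not derivable from the rule text, and the package
treats it as allowed (recorded in output metadata via the rule engine's
documentation). Only ungapped duplexes are scanned: the rules are stated
on a fixed 1..L index, which is ill-defined under bulges.

# Differential expression

Replicate counts are pooled (summed) per condition — the source formulas
speak of "the treatment library / the control library", singular — then:
RPM = count/total × 10⁶; fold-change = log2(T/CK); an exact two-sided
binomial (Audic–Claverie-style) test of the treatment count against the
sequencing-effort proportion; classes: highly significant (|FC|>1,
p<0.01), significant (|FC|>1, 0.01≤p≤0.05), else not significant;
regulation from the raw ratio with strict 2× / ½× thresholds. Boundary
policy: p = 0.01 is "significant"; ratio exactly 2 or ½ is "unchanged".
A zero count on one side receives a one-read pseudocount before
normalization and the row is flagged; zero on both sides excludes the row
with a reason. No replicate-aware dispersion model and no multiple-testing
correction are applied, deliberately matching the formulaic procedure; the
test choice is a documented stand-in since the source never names one.

# The synthetic world

The generator is the package's stated world, not a tuning knob:

* 3 control (CK1–3) and 3 treatment (T1–3) libraries by default, with the
  expected depth per library set by the design (200k in the acceptance
  run);
* insert lengths follow a categorical distribution over 18–30 nt with the
  21 nt mode carrying about twice the mass of the secondary 24 nt mode;
  miRNA reads use their mature length (mostly 21 nt);
* contaminant fractions per QC category default to a realistic run with a
  dominant too-short fraction (18%), some too-long (6%), adapter-only
  1.5%, and sub-percent N-containing, poly-A, no-adapter and low-quality
  reads; clean reads carry Phred+33 Q40 everywhere, low-quality reads
  have ≥20% of bases below Q10;
* the 3′ adapter defaults to the standard Illumina small-RNA adapter and
  is configurable (the source study never prints its adapter);
* per-library counts are drawn Poisson per origin (equivalently,
  multinomial conditioned on the realized library size); treatment
  libraries multiply planted miRNAs' intensities by their ratios, so the
  expected treatment/control count ratio equals the planted ratio
  exactly, at the cost of the realized depth floating slightly around the
  design depth;
* miRNA baseline weights are log-normal (meanlog 3, sdlog 1.2), giving
  the several-orders-of-magnitude expression spread typical of miRNA
  populations; when the profile is auto-drawn, planted miRNAs are pinned
  to the median baseline weight, because a planted fold-change on a
  composition-dominating miRNA would shift the library total and
  confound the RPM normalization the recovery tests are meant to probe
  (user-supplied profiles are taken as given);
* precursors are built as near-perfect inverted repeats (mature + 15 nt
  extension arm, 11 nt AU-rich loop, 10 nt flanks, ≈103 nt total), the
  "novel" subset absent from both database and annotation.

What the generator does **not** emulate: sequencing errors, isomiRs,
5′-adapter read-through, bulged precursor stems, multi-locus miRNA
families sharing a mature sequence, and chained/overlapping annotation.
A green recovery test therefore establishes that the pipeline's logic is
correct on cleanly-labeled data, not that its thresholds are optimal on
real libraries.

# Numerical and boundary choices

* QC removal precedence (first match wins): N-containing → low-quality →
  adapter-only (insert null) → no-adapter-evidence → poly-A → too-short →
  too-long. The reported categories are disjoint, so an order is
  required; none is derivable from the source.
* Adapter evidence: exact match of the adapter's first 12 nt anywhere in
  the read, else a read-suffix overlap of ≥8 nt with ≤1 mismatch. Reads
  with no adapter evidence are discarded *only when longer than the
  30 nt retention bound*; shorter ones are treated as pre-trimmed
  inserts, which makes cleaning idempotent on clean tags while still
  discarding genuine failed-ligation reads (full read length).
* Low quality: >10% of bases below Q20. Poly-A: post-trim A fraction
  ≥80% or an A-run ≥10.
* Known matching: full-length, equal-length, ungapped Hamming distance
  ≤2; ambiguous tags go to the lexicographically smallest id and the tie
  is logged.
* Coordinates are 0-based half-open internally and 1-based closed in GFF
  output; duplex rule arithmetic is 1-based from the miRNA 5′ end.
* All randomness flows from a single integer seed; every output
  (including gzipped FASTQ) is byte-identical across reruns.

# Phenotype utilities

Total chlorophyll is the stated linear form C_T = 20.29·A645 + 8.05·A663
(mg/g fresh weight). qRT-PCR relative expression is 2^(−ΔΔCt) with
triplicates averaged on the Ct scale and amplification efficiency fixed at
2; the ΔΔCt form is a documented stand-in, since only the reference genes
(miR5059 for miRNAs, β-actin for genes) are stated in the source design.

# Known limitations

* The flat hairpin score threshold is length-dependent in its specificity
  (see above); candidate lists on deep data contain plausible-looking
  false hairpins.
* The exact binomial DE test ignores biological replicate variance;
  pooled replicates make it anti-conservative for genuinely dispersed
  data. That is faithful to the re-implemented procedure, not a
  recommendation.
* Target scanning is ungapped; bulged sites are invisible.
* The QC "Remove Adapter%" vs "Insert Null%" split follows this package's
  own labeling convention (no-adapter-evidence vs adapter-at-position-1);
  the source table does not define these columns.
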