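---
title: "Methods: TAD-based interpretation of structural variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TAD-based interpretation of structural variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadsv)
```

## The analysis unit: TADs and resolved regions

Topologically associated domains are self-interacting genomic intervals;
regulatory interactions (enhancer–promoter contacts, chromatin loops)
occur mostly within a TAD, and a structural-variant breakpoint that falls
inside one can rewire those contacts. `tadsv` therefore resolves every SV
to a set of regions anchored on TADs: the TAD containing each breakpoint
(brTAD), optionally up to five flanking TADs per side in coordinate order
(offsets −5…+5; flanks are genomic, not transcriptional, because genome
structure is strand-free), and — for CNVs — the interior of the span not
covered by the two end brTADs, kept as a separate "remaining" region. An
explicit genomic-region mode bypasses TADs entirely.

Three deliberate choices in this module:

* **Internal coordinates are 0-based half-open; user-facing coordinates
  are 1-based inclusive.** Interval arithmetic (containment, overlap,
  adjacency) is unambiguous in the half-open convention; clinical strings
  (ISCN) and browser links are printed 1-based. Conversion happens only
  at the I/O boundary, and a property test over random intervals checks
  `display(start) = start + 1` throughout.
* **Breakpoints in inter-TAD gaps resolve to the gap interval itself**,
  flagged `boundary/gap`, rather than being assigned to the nearer TAD.
  TAD boundaries restrict regulatory interactions and there is no
  principled rule for which side should win; surfacing the gap keeps the
  ambiguity visible to the analyst.
* **Chromosomes without called TADs** (chromosome Y in common
  references) fall back to a tiling of fixed-size windows, the window
  size being the reference's average TAD size (e.g. 815 kb for a
  lymphoblastoid reference). Windows tile the chromosome exactly:
  `[floor(pos/w)*w, floor(pos/w)*w + w)`.

Insertions are modeled as up to three independent breakpoints (acceptor
site, donor-span start, donor-span end), each resolved on its own, since
no insertion-specific TAD rule exists. Deletions and duplications must be
larger than 1 kb; smaller events are rejected at construction.

## Element retrieval and disruption flags

At a breakpoint TAD every overlapping annotated element is retrieved;
from the remaining regions, flanking TADs and explicit regions only
protein-coding genes, lincRNAs, lncRNAs and other elements with a tissue
expression pattern are kept. (Whether flanking TADs should use the
breakpoint-style or filtered retrieval is genuinely open; this package
applies the permissive rule only to the brTAD itself, on the view that
flanks are scanned for *candidate* genes, for which the filtered set is
the relevant one.) The filter is monotone by construction: the
breakpoint-rule element set is always a superset of the filtered set,
and a property test asserts this on the synthetic genome.

Three flags summarise breakpoint impact, each with a conservative
boundary convention:

* a gene is **disrupted** only when the breakpoint is strictly interior
  to its span — a breakpoint at an exact gene boundary flanks, not
  disrupts;
* a chromatin **loop is broken** when the breakpoint lies strictly
  between its two anchors (`end_a <= pos < start_b`); breakpoints inside
  an anchor are ambiguous and not counted;
* a regulatory-interaction **cluster is severed** when the breakpoint
  falls within the cluster hull *and* at least one element lies entirely
  on each side — the break must actually separate a regulator from its
  target.

## Phenotype similarity

Each ontology term's information content is `IC(t) = -ln(|ann(t)|/N)`,
where `ann(t)` is the set of diseases annotated to `t` or any descendant
and `N` the number of annotated diseases; the root has IC 0 and IC is
anti-monotone along `is_a` edges because annotations propagate upward.
The natural-log base is a convention; only ratios of scores matter for
interpretation. Pairwise term similarity is the IC of the most
informative common ancestor (each term counts among its own ancestors,
so `sim(t,t) = IC(t)` and `sim(a,b) <= min(IC(a), IC(b))`).

Two term sets are compared with the **symmetric best-match average**:
for each term the best pairwise similarity against the other set, the
maxima averaged within each direction and the two directions averaged.
The package deliberately does *not* use the all-pairs mean, although the
phrase "mean of the pairwise comparisons" could be read that way: the
defining property of MaxSSc — that a set compared with itself scores the
mean IC of its terms — holds for best-match (the best partner of a term
in its own set is itself, by the `sim <= min(IC)` bound) and fails for
the all-pairs mean. Best-match is the reading that makes the two
definitions consistent, and it is asserted by both a unit test and a
property test.

**PhenSSc** is the query–disorder list similarity; **MaxSSc** the
query's self-similarity, its ceiling. The permutation *p*-value draws
`n` (default 100) random term sets of the query's size and reports the
fraction of simulated scores `>=` the observed one — ties count against
significance, exactly as the estimator is defined, so p-values live on
the grid `0, 1/n, …, 1` and an observed score of 0 yields `p = 1`. A
`1e-9` float guard makes arithmetic ties robust to round-off. The
sampling pool is the set of *directly* disease-annotated terms: those
are the vocabulary actually used to describe disorders, which is what a
random patient description would draw from, and on the bundled toy
ontology this makes the estimator agree with exhaustive enumeration over
all same-size subsets (the test checks agreement within three binomial
standard errors at `n = 10{,}000`). Sampling from the propagated
(ancestor-closed) pool would mix specific and near-root terms and change
the null. Per-disorder random streams are derived deterministically from
one user seed and the disorder id, so whole report tables reproduce
byte-for-byte.

## CNV database matching

The mutual (reciprocal) overlap of a query and a database record is
`min(100*ov/len(query), 100*ov/len(record))`; requiring `mutual >= 70`
is equivalent to requiring both coverages to pass 70%. Candidates must
match in dosage direction (loss vs gain). The best hit per database
maximises mutual overlap, with ties broken by higher record coverage and
then lexicographic record id — purely to make output deterministic.
Frequencies are echoed from the source, never imputed. Symmetry, scale
invariance, threshold monotonicity and agreement with a full linear scan
are property-tested.

## Automated ACMG dosage scoring

Only machine-determinable criteria are automated; everything needing
literature, inheritance or de-novo information enters as manual
adjustment points (`final_score(ev, manual = ...)`). The loss rubric:
gene content (1A, 0.00 / 1B, −0.60), an established haploinsufficient
gene fully contained or disrupted (2A, +1.00), complete containment
within a curated benign region (2F, −1.00), a 100%-mutual-overlap
benign or likely-benign best hit when 2F does not apply (−0.90), and
protein-coding gene-count bins 0–24 / 25–34 / ≥ 35 mapping to 0.00 /
+0.45 / +0.90. Gains mirror this with triplosensitive genes and bins
0–34 / 35–49 / ≥ 50. The −0.90 point for the curated benign overlap is
pinned inside the guideline's allowed range as the value that reproduces
the worked clinical case bundled as a fixture. Scores are summed at
two-decimal precision and banded with inclusive hundredth-precision
edges (≥ 0.99 pathogenic; 0.90–0.98; −0.89–0.89; −0.98 – −0.90;
≤ −0.99); banding is computed on integer hundredths to avoid float-edge
surprises, and a grid test asserts the bands form a monotone total
partition.

## Rule engine for balanced SVs

Rules are evaluated in fixed precedence — pathogenic, likely pathogenic,
likely benign, benign, else VUS — so conflicts resolve toward the more
severe call (clinical conservatism). "Near a candidate gene" is
operationalised as *within the brTAD or a requested flanking TAD*;
"predicted to impact long-range regulatory interactions" as *cluster
severed or at least one loop broken* — exactly the signals the
annotation module computes. "Significant phenotype overlap" defaults to
`PhenSSc/MaxSSc >= 0.5` and `p <= 0.05`; both are configurable, and a
`force_phenotype_overlap` override exists because qualitative expert
judgement sometimes accepts a candidate whose p-value is weak (small
annotated-term pools make small p-values unreachable; on the bundled
four-term ontology the smallest possible p is 1/6). Tightening either
threshold can only clear the flag, never raise it (tested).

The consensus merge of three evaluators' calls takes the majority when
two agree and otherwise the median on the ordered five-level scale; it
is permutation-invariant and checked against a sort-based oracle on all
125 call triples.

## The synthetic universe, and what passing tests show

`make_toy_genome()` emits a deterministic miniature genome: chr1 with
six 100-kb TADs, chr2 with four, eighteen genes (planted archetypes for
every rule plus seeded filler), a regulatory cluster and loop set
straddling a planted breakpoint, tiling cytobands, three CNV source
databases (five planted records plus ~40 seeded random ones), and a
12-term ontology with four diseases annotated to four leaf terms. Sizes
were chosen so every hand-worked number is reachable in closed form:
leaf ICs of ln 2 and ln 4, a branch IC of ln(4/3), a self-similarity of
(ln 2 + ln 4)/2 ≈ 1.0397, a cross-branch best-match score of ≈ 0.4185,
and an exact permutation p of 1/6. Planted truths (brTAD indices, the
worked-case ACMG score of −0.90, loop and cluster disruption counts) are
re-derived by independent brute-force code inside the generator before
any file is written. `make_random_suite()` adds randomized SVs whose
expected brTADs, best hits and categories are derived by straight-line
scans and stored as an oracle file.

The generator emulates nested ordered TADs, dosage and disease
annotations, frequency-bearing CNV databases and a DAG ontology, but
not: realistic TAD or gene size distributions, overlapping or nested
genes, ontology scale (tens of thousands of terms), multi-parent
annotation noise, or segmental-duplication artefacts in CNV databases.
Passing tests therefore demonstrate correctness of the interval
arithmetic, scoring formulas and rule logic — not calibration of the
thresholds on real cohorts.

Test problem sizes: 1,000 random breakpoints and 1,000 random CNV
queries for the oracle suites, 10,000 sampled edges for IC
anti-monotonicity on a 200-term random ontology, 10,000 permutations
for the exact-p comparison, and 12–40 SVs for batch determinism — small
enough to run in seconds while exercising every code path.

## Known limitations

* Output is TSV only; report tables are deterministic and
  byte-reproducible, but no spreadsheet writer is bundled.
* Complex SVs must be decomposed into simple SVs by the user; one
  variant is analysed at a time.
* The tissue/cell line for TAD and loop definitions is a user choice;
  TAD boundaries vary across tissues and no automatic selection is
  attempted.
* The rule engine sees inheritance only through per-gene disorder
  links; it does not integrate SNV findings, segregation or de-novo
  status.
* Ontology ingestion accepts a single-rooted `is_a` DAG; other
  relationship types (part-of, etc.) are ignored by design.
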