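---
title: "Detecting and tracking ecDNA in Barrett's oesophagus cohorts"
author: "ecamplicon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and tracking ecDNA in Barrett's oesophagus cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecamplicon)
```

## The scientific problem

Extrachromosomal DNA (ecDNA) elements are circular, acentric DNA particles
that carry amplified oncogenes. Because they lack centromeres they are
inherited non-Mendelianly at cell division, which accelerates copy-number
evolution and intratumoral heterogeneity. A central question in
oesophageal pre-cancer biology is whether ecDNA arises only in established
adenocarcinoma (EAC) or already in the dysplastic stages of Barrett's
oesophagus — and whether pre-cancer ecDNA is maintained, amplified and
structurally remodelled as lesions transform.

`ecamplicon` implements the computational side of that analysis as a
tested pipeline over the standard file artefacts of whole-genome
breakpoint-graph reconstruction:

1. **Seed detection** — filter copy-number segments into candidate
   focal-amplification regions using cohort-specific thresholds.
2. **Classification** — assign each reconstructed amplicon (breakpoint
   graph + cycle decomposition) one of four classes: ecDNA, BFB
   (breakage–fusion–bridge), complex non-cyclic, or linear.
3. **Similarity / clonality** — score pairs of amplicons on a 0–1 scale
   and test significance against an empirical null, to decide whether
   ecDNAs seen in different biopsies of one patient share a common origin.
4. **Complexity** — quantify structural diversity of an amplicon's cycle
   decomposition.
5. **Gene annotation** — call genes (oncogenes, immunomodulatory genes)
   carried at amplified copy number with an intact 5' end.
6. **Cohort statistics** — pair sequencing biopsies with histology records
   and compute the association statistics (one-sided Fisher tests,
   Haldane-corrected odds ratios, Mann–Whitney, Levene).

Because the cohorts this design emulates are access-controlled, the
package ships a first-class synthetic-cohort generator; every claim the
test suite makes is a claim about recovery of planted truth or about exact
statistics on printed contingency tables.

## Data model and file dialects

An amplicon is represented by two objects. The **breakpoint graph**
(`amplicon_graph`) holds oriented sequence segments with estimated copy
counts plus junction edges; a junction endpoint is a `(chromosome,
position, side)` triple where `side = head` is the 3' boundary of a
segment and `tail` the 5' boundary. Edges are unordered: an edge equals
its endpoint-swapped form, which the constructor canonicalizes. The
**cycle decomposition** (`decomposition`) is a weighted list of cyclic and
linear walks over a segment table; a linear walk is marked in the file
dialect by the sentinel segment id `0` at its ends.

Coordinates are 1-based inclusive throughout, matching the graph/cycles
file dialects; BED output converts to 0-based half-open at the writer
boundary only. Both writers emit deterministic ordering (segments by
coordinate, walks by descending weight), so write–read–write round trips
are byte-identical. Unknown record types are skipped with a warning
rather than failing, because the dialect has drifted across producer
versions. Discordant-edge endpoints must sit on a segment boundary within
1 bp — these files come from a graph builder, not raw variant calls.

## Seed detection

Seeds are called per sample in three steps, in this order: keep segments
with total copy number **strictly greater** than `cn_min`; merge kept
segments on the same chromosome separated by at most `merge_gap`; drop
merged intervals with length at most `size_min`. The strict inequalities
matter: a segment at exactly the threshold is dropped, and the boundary
tests assert this. Four presets ship with the package:

| preset        | cn_min | size_min | intended cohort                  |
|---------------|--------|----------|----------------------------------|
| `cambridge`   | 4.5    | 10 kbp   | cross-sectional surveillance     |
| `fhcc_tumour` | 4.3    | 50 kbp   | longitudinal case–control, tumour|
| `fhcc_normal` | 4.0    | 10 kbp   | longitudinal case–control, normal|
| `tcga`        | 4.5    | 50 kbp   | external EAC tumours             |

The merge gap (default 300 kbp) is this package's choice: the source
protocol merges and refines seeds without publishing a gap value, a finite
gap is required, and the value is configurable. The size filter applies to
*merged* intervals, mirroring the identify–merge–refine order.

## The classification cascade

The published classifier's internal heuristics are not described in the
protocol this package follows, so the cascade below is this package's
documented operationalization, validated against synthetic truth (it is
not claimed to reproduce the upstream tool's labels on real data):

1. **ecDNA** — there is a cyclic walk with weight ≥ `cn_min` whose
   footprint covers at least `ecdna_cycle_weight_min` (default 0.5) of the
   amplified bases, *or* the total weight of cyclic walks touching the
   amplified region reaches `cn_min`. A circular structure at amplified
   copy number is the operative definition of ecDNA.
2. **BFB** — not ecDNA, and at least two foldback junctions (inverted
   orientation, endpoints within `foldback_dist_max` = 25 kbp on one
   chromosome) carrying ≥ `foldback_frac_min` (default 0.25) of the
   discordant copy-count weight. Foldbacks are the junction signature of
   breakage–fusion–bridge cycles.
3. **complex non-cyclic** — neither, with ≥ `complex_edge_min` (default 3)
   discordant edges touching the amplified intervals.
4. **linear** — everything else that passed seeding.

Distinct ecDNA *species* within one amplicon are counted as connected
clusters of qualifying cyclic walks whose genomic footprints are disjoint
between clusters. Overlapping amplicons within a sample are deduplicated
by class rank (ecDNA < BFB < complex < linear), then by largest amplified
footprint, then lexicographically — the dedup is idempotent and
order-invariant, and tests assert both.

## Amplicon similarity and the clonality call

The similarity score for amplicons $a, b$ combines two Jaccard indices:

$$ J_\mathrm{gen}(a,b) = \frac{|A \cap B|}{|A \cup B|}, \qquad
   J_\mathrm{bp}(a,b) = \frac{m}{|E_a| + |E_b| - m}, $$

where $A, B$ are the amplified base sets, $E_a, E_b$ the discordant
junction sets, and $m$ the size of a greedy one-to-one junction matching
(endpoints agree within `tol` = 100 bp — short-read junction coordinates
jitter by tens of base pairs — with matching sides, allowing the
whole-edge endpoint swap). The score is the mean of the two when both
amplicons carry junctions, otherwise the genomic Jaccard alone. The exact
combination is deliberately isolated behind one function so asymmetric
(containment-style) variants can be swapped in; scores from this package
are comparable only to scores computed the same way. On small instances
the greedy matching is asserted equal to the exhaustive maximum bipartite
matching.

Significance is empirical: null scores are computed on `n_null` pairs of
amplicons drawn from *different* patients (which cannot be clonal), and

$$ p = \frac{1 + \#\{s_\mathrm{null} \ge s_\mathrm{obs}\}}{n_\mathrm{null} + 1}. $$

When fewer than `n_null` distinct cross-patient pairs exist, the null
falls back to random placement: each amplicon's per-chromosome footprint
(junctions riding along) is relocated uniformly on the genome and
re-scored. At the default cohort size the cross-patient pool is a few
hundred pairs, so the random-placement null is the one actually exercised
end-to-end; the empirical-pair route is unit-tested separately. Raw
per-pair p-values are reported without multiple-testing correction,
matching how such pairs are conventionally reported; a
Benjamini–Hochberg flag would be a one-line addition to
`find_clonal_pairs()` output.

A **clonal pair** is a within-patient pair of ecDNA amplicons from
different sequencing biopsies with positive genomic overlap and $p <
\alpha$ (default 0.05). Pairs are oriented so the first member carries the
less severe windowed histology; `cn_delta` is then the copy-number change
along disease progression.

## Complexity

Amplicon complexity is the Shannon entropy (base 2) of the normalized
decomposition weights: $H = -\sum_i f_i \log_2 f_i$ with $f_i = w_i /
\sum_j w_j$ over positive-weight walks. $H$ is zero for a single walk,
bounded by $\log_2 k$ for $k$ walks, permutation- and scale-invariant.
The published score additionally involves decomposition residuals, which
are not reconstructible from the cycles files alone; this package's
values are in bits and comparable only within analyses using this
definition. That caveat is why the cohort-level claim tested here is
ordinal (EAC-grade structures are more complex than pre-cancer ones,
one-sided Mann–Whitney), not numeric.

## Gene calls

A gene is called on an amplicon when its length-weighted mean copy number
over the gene body is ≥ 4.5 (uncovered bases count as diploid, CN 2 — a
conservative default for partial overlap) and its 5' end is intact. "5'
intact" is operationalized as: the 5'-most base lies in an amplified
interval and no discordant junction falls strictly within the first
kilobase downstream of the 5' end (window configurable; the source
criterion names no operational window). Whether the source used
length-weighted or segment-mean averaging is unstated; length weighting is
the natural choice for per-base copy number and is what the per-base
brute-force oracle in the tests checks.

## Statistics

All 2×2 analyses use the one-sided Fisher's exact test (upper-tail
hypergeometric probability of enrichment in cell *a*, computed in log
space to well over 12 significant digits and asserted equal to full
margin-constrained enumeration). Odds ratios apply the Haldane
correction — 0.5 added to **every** cell if **any** cell is zero — and
Woolf (log-normal) confidence intervals over the possibly-corrected
cells; the Woolf interval reproduces the printed 1.0–4.7 interval for the
printed late-vs-early table, which is why it is the default, with the
exact conditional interval available behind `method = "conditional"`.
Mann–Whitney uses exact enumeration of all rank assignments when the
pooled sample has at most 12 observations (valid under ties) and the
tie-corrected normal approximation with continuity correction otherwise.
Levene's test is the one-way ANOVA F on absolute deviations from group
means. Test direction is fixed by table construction: the more-advanced
group is row 1 and ecDNA-positive is column 1 (or row 1 in the per-sample
tables), so "greater" always means enrichment of ecDNA with advancing
disease.

`build_cohort_tables()` reconstructs the study's tables from per-sample
status: patient-level ecDNA by histology group, patient-level ecDNA by
outcome arm, and the two cancer-outcome per-sample tables (time point 1
on-level high-grade dysplasia; time point 2 on-level EAC). A patient is
positive when any sample is. Histology pairing assigns on-level records
(identical oesophageal level, in cm above the gastro-oesophageal
junction) and windowed records (within ±1 cm, inclusive); among multiple
qualifying records the most severe grade wins, over the order NDBE < LGD
< HGD < EAC.

## What the synthetic cohorts emulate — and what they do not

The `fhcc` design emulates a longitudinal case–control study: 40
cancer-outcome (CO) and 40 non-cancer-outcome (NCO) patients, two
sequencing biopsies (upper/lower levels, 2 cm apart) at each of two time
points, histology collected independently at, near, or away from the
sequencing levels. The planted conditions are the study's design rates:
13/40 CO and 1/40 NCO patients ecDNA-positive (0.325 and 0.025
patient-level prevalence); at time point 1 every on-level-matched
ecDNA-positive sample sits in high-grade dysplasia (6 on-level positives,
one windowed-only) against 21/46 HGD among on-level negatives; at time
point 2, 9 of 11 on-level positives sit in adenocarcinoma. Positivity and
histology category counts are planted deterministically — randomness
drives structure coordinates, copy numbers, satellite-cycle weights and
clone noise, never the counts — because the cohort-level contingency
tables are the quantities the pipeline must reproduce exactly. Planted
counts equal `round(prevalence × n)`, so they also sit inside the exact
binomial interval of the design prevalences.

Eight clonal ecDNA lineages span two samples each: five cross-time-point
lineages whose second occurrence is grade-advanced (HGD → EAC), and three
same-grade within-time-point lineages — mirroring the mix of same- and
advanced-histology pairs such a study observes. Clonal propagation
multiplies copy number by `cn_escalation_factor` (default 1.5) per grade
advance with bounded multiplicative noise U(0.9, 1.1); the bound
guarantees every grade-advanced pair escalates, which is the planted
condition the recovery test asserts. Grade also drives structural
complexity through `rearrangement_steps_by_grade` (extra satellite cycles:
0 for NDBE/LGD, 1 for HGD, 3 for EAC) and ecDNA segment count (three
extra segments at EAC grade).

The `cambridge` design is cross-sectional: 42 NDBE/LGD, 25 HGD, 51
early-stage and 88 late-stage EAC patients, one biopsy each, with ecDNA in
0, 1, 13 and 38 patients respectively.

Copy numbers are log-normal with median 15 for ecDNA and 8 for other
focal amplifications (SD 0.25 on the log scale) — chosen so ecDNA-borne
genes are stochastically higher-copy than genes on other amplifications
at cohort scale, an ordinal property the tests assert. The toy genome is
4 chromosomes × 10 Mb with 60 fixed-position genes (12 flagged oncogenes,
6 immunomodulatory), small enough that per-base brute-force oracles are
feasible in the test suite.

What the generator does **not** emulate: read-level data (no
FASTQ/BAM/sequence content), biopsy purity and ploidy variation (a purity
dilution knob is deliberately unimplemented), germline CNV background,
mutational signatures, and real breakpoint-graph inference noise. Passing
tests therefore demonstrate that the pipeline's logic is correct and
internally consistent under the study's design conditions — not that the
classifier reproduces the upstream tool's labels on real sequencing data.

## Numerical and design choices

* **Determinism.** All randomness flows through per-unit RNG streams
  seeded by a stable hash of `(master seed, unit label)`, so generation is
  order-independent and byte-reproducible; emitted files use fixed numeric
  formats. Two pipeline runs with one seed produce byte-identical trees.
* **Interval arithmetic.** Module-surface merging (amplified intervals,
  seed calling, writers) uses GenomicRanges. The inner-loop interval
  queries (intersection/union lengths, point membership) use base-R
  sort-and-scan routines asserted equivalent to the GenomicRanges route by
  a randomized property test; this keeps the empirical-null loop fast on
  one CPU.
* **Degenerate inputs.** Empty cohorts, all-zero tables, zero-weight
  decompositions, empty amplified intervals and degenerate Levene inputs
  all raise explicit errors or produce well-defined empty outputs, each
  covered by a test.
* **Problem sizes.** The shipped test suite and acceptance script run the
  full 80-patient longitudinal design, the 206-patient cross-sectional
  design, 300 structure-recovery draws and 1000-draw similarity nulls —
  sizes chosen to match the emulated studies while keeping a full run in
  minutes on a single CPU.
* **Interfaces.** This is an analysis package used from R: the exported
  stage functions, `simulate_cohort()`/`run_pipeline()`, and
  `scripts/acceptance.R` are the operational surface; no shell CLI is
  shipped.

## Known limitations

* The classification cascade and the similarity-score combination are
  documented stand-ins for unpublished upstream definitions; both are
  isolated behind single functions for substitution.
* Complexity omits decomposition residuals (not present in cycles files).
* The similarity null treats amplicons as rigid per-chromosome blocks
  under random placement; it does not model genome-wide amplification
  hotspots.
* Gene calls assume the toy annotation's gene models; overlapping
  isoforms and partial 5' UTR structures are out of scope.
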