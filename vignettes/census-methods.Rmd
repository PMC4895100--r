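---
title: "Methods: census statistics for full-length SSU rRNA collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: census statistics for full-length SSU rRNA collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssucensus)
```

## The problem

A molecular census of bacteria and archaea asks how thoroughly we have
sampled microbial diversity, using full-length 16S rRNA gene sequences as
the unit of observation and operational taxonomic units (OTUs) as the
proxy for taxa. `ssucensus` implements the whole accounting pipeline:
curating an aligned sequence export and its metadata, computing pairwise
distances, clustering into OTUs by average-neighbor linkage at the
conventional 0/3/5/10/20% thresholds, and deriving the census statistics
— coverage, rarefaction, habitat tables, temporal trends, taxonomic rate
ratios, the cultured census, and cross-method OTU overlap.

Two coverage statistics carry the headline conclusions. With $n_1$ the
number of singleton OTUs, $N_t$ total sequences, and $S_t$ total OTUs:

$$C_{\mathrm{Sequence}} = 1 - \frac{n_1}{N_t} \qquad
  C_{\mathrm{OTU}} = 1 - \frac{n_1}{S_t}$$

$C_{\mathrm{Sequence}}$ is Good's coverage — the probability that the
next sequence sampled falls in an already-observed OTU. $C_{\mathrm{OTU}}$
extends the same idea to the OTU level: the probability that a newly
formed OTU matches an existing one. Because $S_t \le N_t$, OTU coverage
never exceeds Good's coverage; a census can look nearly complete by the
first measure (most sequencing revisits abundant organisms) while the
second reveals that most OTUs have been seen exactly once.

## Curation conventions

**Ambiguity screen.** Sequences with more than `max_ambiguous` (default
2) ambiguous base calls are removed. Anything outside A/C/G/T/U and the
gap characters counts — N and all other IUPAC codes alike.

**Trimming and coverage characters.** Census collections are trimmed to
a window of alignment columns that every retained sequence fully
overlaps. Windows are taken as 1-based alignment columns; published
windows stated in unaligned reference positions (e.g. *E. coli*
113–1350) convert via `ref_positions_to_columns()`, which decouples the
tool from any particular alignment. Spanning is judged by the alignment
convention of the source databases: `.` marks missing data (the
unsequenced terminal stretch) while `-` marks a deletion inside the
sequenced region and therefore counts as coverage. A sequence is kept
when its non-`.` span covers both window bounds and its slice contains
at least one base. This makes trimming idempotent — re-trimming a
trimmed collection is the identity — which would not hold if edge
deletions were mistaken for missing data.

**Habitat labels.** The judgment inside isolation-source curation is
externalized to a user-editable mapping file (pattern → coarse/fine
category), matched exactly after lower-casing and whitespace
normalization. Records with no isolation source are `NoSource`; present
but unmapped sources fall to the coarse `Other` category. The two are
deliberately distinct rows in census tables. The coarse/fine hierarchy
itself is fixed (`environment_hierarchy()`).

**Cultured flags.** A record counts as cultured when its strain or
isolate field carries data and its database name does not contain
`"Unc"` (case-sensitive), the database convention for sequences from
uncultured organisms.

## Distances

`pairwise_distance()` is the uncorrected distance: differences over
compared positions, walking shared alignment columns. Columns gapped in
both sequences are skipped; a maximal run of columns gapped in one and
the same sequence counts as a single difference and a single compared
position (gap-open, not gap-extend); U equals T; ambiguity codes
mismatch everything, including themselves — conservative and
deterministic after the two-ambiguity screen. Terminal gap runs are
skipped by default; `penalize_terminal_gaps = TRUE` scores them like
internal runs. Whether the original census penalized terminal gaps is
not documented; the default of `FALSE` is this package's choice, and the
toggle keeps the convention testable. Distances are never rounded before
clustering; rounding belongs to the reporting layer only.

## Average-neighbor clustering

Agglomerative clustering where the distance between clusters is the
arithmetic mean of all cross-cluster pairwise distances. The
implementation uses the size-weighted (Lance–Williams) update, which
keeps the working matrix exactly equal to the recomputed mean at every
step; tests verify equivalence against a brute-force implementation
that recomputes every mean from the original matrix, and against
`hclust(method = "average")` on tie-free matrices.

Numerical choices:

* **Cut rule.** Thresholds are exact cut heights; a merge at a distance
  exactly equal to the threshold is included (`<=`). One clustering run
  serves all requested thresholds, so partitions at increasing
  thresholds are nested coarsenings by construction (merge heights are
  non-decreasing for average linkage; a running maximum guards against
  floating-point dips).
* **Tie-break.** When several candidate merges share the minimum
  distance, the pair whose lexicographically smallest member id is least
  (then the second id) merges first. Results are therefore independent
  of storage order.
* **Sparse stores.** A store built with a cutoff omits pairs beyond it.
  Clustering refuses thresholds above the cutoff rather than
  approximating, and scores an absent cross-pair as 1.0 — an upper
  bound on the true distance, so a merge mean computed this way can only
  defer merges, never invent them. Production OTU tools make sparse
  approximations at the million-sequence scale; this package defines
  exact behavior instead and accepts the divergence risk knowingly.
* **Labels.** `OTU` plus the zero-padded rank by descending abundance,
  ties by smallest member id — stable across runs.

## Coverage and rarefaction

Per-category census rows need a singleton definition. An OTU that is a
singleton *within a category* may be abundant globally; the package
counts singletons on category-scoped abundances, the only reading under
which a per-row coverage is computable from that row alone. A
consequence worth knowing: OTU columns count distinct OTUs touched by a
category, and because an OTU can span categories those columns need not
sum to the global OTU count (sequence columns always do).

Rarefaction is the exact hypergeometric expectation
$E[S_n] = \sum_i \left(1 - \binom{N - N_i}{n}\middle/\binom{N}{n}\right)$,
evaluated with log-gamma binomials so totals beyond $10^6$ sequences do
not overflow. It is deterministic — no seed sensitivity in reported
curves — and `rarefy_resample()` provides the Monte-Carlo cross-check
mode used by the tests (agreement within three standard errors, and
exact agreement with exhaustive enumeration for pools of up to 12
sequences).

Reports round coverages to one-decimal percentages; all underlying
computation keeps full precision.

## Temporal and taxonomic analyses

* **Discovery year of an OTU** is the minimum deposition year among its
  members; OTUs whose members all lack years are tallied separately.
* **Submission concentration** is the minimal number of submissions
  whose largest members hold at least half of a year's sequences
  (largest first, ties by submission id); tests check minimality.
* **Rate ratios** split records at a pivot year. "Before and after
  2006" is implemented as deposited ≤ 2006 versus > 2006 — the boundary
  year's side is not documented in the census literature, so the
  comparator is configurable. Shares are within-domain; phyla absent
  before the pivot get a flagged undefined fold rather than silent
  exclusion, and a minimum-sequence filter (default 1,000) marks which
  phyla are reportable without dropping the rest.
* **Cultured census** reports, per phylum, the percentage of sequences
  from cultured organisms and the percentage of the phylum's OTUs with
  at least one cultured member.
* **Method overlap** reports, for methods A and B, the percentage of
  A's OTUs also containing a B-recovered sequence; the diagonal is the
  percentage of A's OTUs found by no other method.

## The synthetic-community generator

Every stage is testable without downloads because `community_spec()` /
`sample_community()` emulate the statistical structure the analyses
assume: true OTU centers with a skewed (default lognormal) abundance
profile; per-read divergence capped at `within_divergence`; centers
rejection-sampled to pairwise distances of at least
`min_center_divergence`; deposition years growing exponentially to a
plateau; submission sizes drawn from a Dirichlet with concentration
below 1 (a few submissions dominate each year, submissions being
year-scoped so per-year concentration statistics are well-posed);
habitat categories with configurable weights; per-phylum cultured
probabilities and recovery-method mixes; and an optional per-phylum
multiplier on post-pivot deposition odds so rate-ratio analyses have a
programmed enrichment to recover (`expected_rate_ratio()` gives the
closed-form truth; phyla ride on centers, so expectations are
conditioned on the realized abundance-weighted mixture).

Two deliberate simplifications. Mutations substitute uniformly among
A/C/G/T at up to `floor(within_divergence * length)` positions — no
indels beyond the fixed shared gap columns — so within-OTU divergence is
controlled exactly and clustering correctness is isolated from
gap-convention effects (gap handling has its own tests in the distance
module). And the constraint `within_divergence < min_center_divergence/2`
is enforced at spec construction: with reads at most 0.01 from their
center and centers at least 0.08 apart, within-OTU pairs are ≤ 0.02 and
cross-OTU pairs ≥ 0.06, so clustering at 0.03 must recover the truth
exactly; the tests check that recovery across 20 seeds.

Default sizes — 25 centers, 150 sequences, 140 columns (10% shared gap
columns) — are chosen so a complete simulate–curate–cluster–census pass
is a seconds-scale operation suitable for routine testing; the analysis
scripts use a richer 40-center, 300-sequence community. What the
generator does *not* emulate: chimeras, sequencing-error models with
quality scores, phylogenetically realistic evolution, or indel
variation. Passing tests therefore demonstrate correctness of the
census arithmetic and the clustering on cleanly separated communities,
not robustness to alignment artifacts in real databases.

## Reference data and known discrepancies

The package ships the published per-habitat census summary of the SILVA
SSU Ref v.123 full-length collection (`silva123_habitat_census()`) and
the 2009–2012 deposition-concentration window
(`silva123_deposition_window()`) as plain-text reference inputs. Two
source-data caveats are preserved rather than patched: the archaeal
fine rows sum to 53,471 sequences against a printed total of 53,546
(difference 75), so aggregation checks target the coarse row sums and
the bacterial grand total; and the cultured analysis of the original
census used a slightly larger OTU universe (including single-cell and
assembly-derived sequences) than its habitat table, which is why
`cultured_summary()` and `method_overlap()` take whatever
partition/metadata scope the caller selects instead of hard-wiring one.

Recomputing the published coverage percentages (94.5%/29.2% bacterial,
38.5% archaeal OTU coverage) requires the deposited ~1.4M-row
per-sequence OTU-assignment tables; `read_figshare_census()` consumes
tables of that shape and the relevant test runs the recomputation when
the downloaded tables are present locally.

## Limitations

* Exact average-neighbor clustering is $O(n^2)$ memory and roughly
  $O(n^3)$ time in this implementation — appropriate for the tested
  scales (hundreds to low thousands), not for millions of sequences.
* The isolation-source mapping reproduces whatever judgment it encodes;
  the package validates structure, not semantics.
* Distances are uncorrected; no evolutionary-model correction or k-mer
  approximation is offered.
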