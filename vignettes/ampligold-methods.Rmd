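---
title: "ampligold: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ampligold: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampligold)
```

## The problem

16S rRNA amplicon sequencing estimates the composition of a microbial
community, but every stage of the computational pipeline — OTU clustering,
taxonomic classification, diversity estimation — introduces error, and with
real samples there is no ground truth to measure that error against.
ampligold builds fully synthetic communities in which the true source
organism of every read is known, and scores any pipeline's output against
that gold standard. The package generates the data (references, defined
communities, in-silico PCR amplicons, optional sequencing error) and
evaluates three pipeline products: OTU assignments, taxonomic calls, and
alpha/beta-diversity estimates.

## The synthetic-data generator

### Fixture references

`make_fixture()` builds a reference pool with no downloads. Each genus
receives an independent, uniformly random ancestor sequence; species are
derived from their genus ancestor by i.i.d. point substitutions (default
rate 0.02 per base), so within-genus k-mer distance is far below
between-genus distance — the separation real 16S genera show, in idealized
form. Every reference embeds exact binding sites for two nested primer
systems laid out like a real 16S gene: a V3–V5 style system (357F/926R,
~554 bp product) enclosing a V4 system (U515F/806R, ~289 bp product).
Primer-site positions are masked from mutation, so in-silico PCR succeeds
on every fixture reference by construction. Taxonomies follow the
canonical seven-rank ladder with genera nested pairwise into families,
orders, classes and phyla, and an ultrametric tree (species split at depth
0.02 from the leaves, genera at the root) is emitted as the "true"
phylogeny for the distance evaluators.

What the fixtures do **not** emulate: conserved/variable region structure
within the gene, compositional bias of real 16S alphabets, chimeras,
intra-genomic 16S copy variation, and the ragged, non-ultrametric
phylogenies of real databases. Tests passing on fixtures therefore verify
the *bookkeeping and the statistics* — primer matching, slicing, read
accounting, scoring algebra — not robustness to real-database pathologies.

### Curation

`curate_references()` applies the standard reference filters: length
strictly greater than 1000 bp and no ambiguity codes.
`drop_species_outliers()` removes likely mis-annotated records: within
each species group of at least 3 sequences it computes pairwise distances
as 1 − cosine similarity of 8-mer count profiles, takes the medoid as the
group centroid, and drops records strictly beyond the group's
90th-percentile distance to the medoid. The alignment-free k-mer/medoid
construction is this package's own choice of metric; it is deterministic,
O(n²) on small groups, and preserves the percentile semantics. Groups
smaller than 3 pass through, since a percentile over fewer than 3
distances is degenerate. Both the percentile and k are parameters.

### Community design

A community is specified per genus by a target mean and standard deviation
of fractional abundance plus a species-count rule — either a Gaussian count
or the log rule *n = a·log(f) + b*, where *f* is the genus's drawn
fraction. Two conventions were open and are fixed here:

* **Log base.** The rule's base is unstated in common usage; we use base
  10 (fractional abundances are decade-scaled in microbiome practice) and
  expose it as `log_base`.
* **Within-genus apportionment.** How a genus's fraction is divided among
  its selected species is a free choice; we use a symmetric Dirichlet(1)
  draw (uniform on the simplex) as the maximally non-informative option.
* **Negative draws.** A Gaussian fraction draw ≤ 0 omits the genus from
  that community, mirroring how genera come and go between real stool
  samples.
* **Scarcity.** If the rule requests more species than the reference pool
  holds for that genus, the draw is capped at availability with a warning.

Member fractions are renormalized to sum to exactly 1. When the spec
means themselves sum to 1 and sds are 0, renormalization is a no-op and
the fractions are exact. `estimate_genus_specs()` recovers mean/sd specs
from a samples × genera abundance table using the sample (n−1) standard
deviation convention.

## In-silico PCR

Primer annealing is tested by ungapped sliding of the IUPAC primer along
the plus strand: a site requires at most `max_mismatch` (default 2)
degenerate mismatches overall **and** zero mismatches in the 3'-terminal
`anchor_len` (default 3) bases, since polymerase extension needs a matched
3' end. The thresholds quantify "sufficient similarity with 3' annealing"
and are exposed as parameters, not facts about any particular chemistry.
The reverse primer is searched as its reverse complement downstream of the
forward site (its 3' end is then the leftmost base of the pattern), and
the amplicon is the inclusive slice across both binding sites; a flag
trims primers instead. Positions are 1-based, the R convention.

Read replication multiplies each member's fraction by the read depth and
rounds half-to-even; members rounding below one read, and members whose
reference yields no product, are recorded as *designed drop-outs* so that
evaluators can distinguish simulation loss from pipeline loss. Read IDs
are globally unique and the mapping file carries exactly one row per read
— the gold standard every evaluator joins against.

The error model is deliberately simple: i.i.d. per-base substitutions at
`sub_rate`, and deletions/insertions each at `indel_rate/2` so the
expected length change is zero. It produces calibrated marginal error
rates (verified against binomial standard errors in the tests) but no
platform-specific structure — no homopolymer effects, no cycle-dependent
quality decay, no paired ends.

## Evaluators

### OTU generation: pair counting

Over the reads of one community present in both the mapping and the OTU
table, every pair is truly same-source or not, and clustered together or
not. With the source × OTU contingency table \(n_{ij}\):

* true match \(= \sum_{ij} \binom{n_{ij}}{2}\)
* false split \(= \sum_i \binom{n_{i\cdot}}{2} -\) true match
* false match \(= \sum_j \binom{n_{\cdot j}}{2} -\) true match
* true split \(= \binom{N}{2} -\) the other three.

Sensitivity = TM/(TM+FS); specificity = TS/(TS+FM). Reads missing from
the OTU table are excluded from pair counting and reported separately as
a dropped fraction, because loss is a distinct failure mode from bad
clustering. Pair counting is per community (distributions across
communities are summarized as quartiles); the `weight` column plays no
role in pair counting. The contingency formulas are verified against
brute-force enumeration of all pairs in the test suite.

### Classification: six outcomes with ranks off

Each read's called lineage is compared positionally (by taxon name, not
rank label — reference ladders differ in depth) against the truth
truncated at the target rank (species or genus): correct, undercalled
(strict ancestor), overcalled (extends beyond the *full* truth lineage on
its path — overconfidence is judged against the truth's own resolution,
so a species-depth call scored at genus level is correct, not
overcalled), sibling miscall (right parent, wrong target leaf, 1 rank
off), miscalled (ranks off = target depth minus the depth of the last
common ancestor), or dropped. Ranks off counts every lineage field, which
is why deep reference ladders can produce large distances.

Reads are grouped into source organisms (one accession within one
community). How discordant reads of one source collapse into one outcome
is not uniquely determined, so three strategies are offered and bracket
the possibilities: `plurality` (default; modal category of the non-dropped
reads, ties broken toward the more severe category), `worst_case`, and a
read-fraction summary (`summarize_read_fractions()`). A source is "lost"
only when all its reads are dropped; read-level loss is visible in the
read outcomes. Per-clade aggregation (`aggregate_by_clade()`) groups
sources by a named rank (default order) and reports per-clade percentages
and mean ranks off; lineages that do not reach the rank fall under
`unresolved`.

### Diversity

Alpha diversity uses the Hill family \({}^qD = (\sum_i p_i^q)^{1/(1-q)}\)
with the \(q = 1\) limit \(\exp(-\sum p_i \ln p_i)\); profiles are
evaluated on the grid \(q = -1\) to \(5\) in steps of \(0.5\), with mean
curves across communities and percentile bootstrap confidence bands from
5000 resamplings of communities with replacement. Richness is \(q = 0\)
exactly; Shannon is reported both on its own and through the \(q = 1\)
limit.

Beta diversity offers both raw weighted UniFrac
\(\sum_b \ell_b\,|A_b - B_b|\) (with \(A_b\) the abundance mass of
community *a* descending through branch *b*) and the normalized variant
(divided by \(\sum_b \ell_b (A_b + B_b)\), range [0, 1]); reports state
which was used. DPCoA is computed operationally: square roots of
patristic distances, classical metric scaling, communities placed at
abundance-weighted centroids, Euclidean distances between centroids.
Eigenvalues below \(-10^{-8}\) times the leading eigenvalue trigger a
warning and are truncated at zero; because the embedding is Euclidean the
distances satisfy the triangle inequality. The implementation agrees with
an independent branch-enumeration oracle and with the phyloseq
implementation on random trees (test suite).

Because diversity estimates are used as comparators, accuracy is measured
as *monotonicity*: Spearman rank correlation (average ranks on ties)
between true and estimated values, with percentile bootstrap confidence
intervals (1000 iterations, resampling index pairs). Both \(\rho\) and
\(\rho^2\) are reported, since either may be the quantity of interest.

## Reproducibility

Every stochastic function takes a seed and restores the caller's RNG
state. The CLI derives a per-module substream from one global seed, so
adding a pipeline stage never perturbs the stream of an earlier one, and
writes a manifest (subcommand, parameters, seed, timestamp) before
outputs. Re-running any subcommand with its manifest's parameters
reproduces the outputs byte for byte.

## Problem sizes

The test suite and the acceptance script run on fixture pools of 2–10
genera with 2–5 species each (1500 bp references), communities of 20–100,
read depths of 500–50,000, 10-leaf random trees for the beta-diversity
oracles, and 120,000+ simulated bases for error-model calibration. These
sizes were chosen so that the brute-force oracles (all-pairs enumeration,
branch enumeration) remain exact cross-checks while the whole suite runs
on a single CPU in minutes.

## Known limitations

* The error model is marginal, not platform-faithful; it cannot test
  quality-aware preprocessing.
* No chimera simulation, no paired-end reads, no novel (out-of-reference)
  organisms — the benchmark is an idealized setting in which every read
  has an in-pool source.
* Classification scoring assumes the pipeline's taxonomy strings share
  the reference's ladder vocabulary; it compares names positionally and
  does not reconcile synonyms across databases.
* DPCoA and UniFrac require every taxon in the abundance vectors to be a
  tip of the supplied tree; evaluating a real pipeline's OTUs against the
  true phylogeny therefore requires the pipeline's OTU IDs to be mapped
  to reference accessions first.
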