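# ampligold

Synthetic 16S rRNA amplicon datasets with a known gold standard, and
evaluators that score amplicon-pipeline output against it.

Microbiome pipelines cluster 16S reads into OTUs, classify them
taxonomically, and estimate alpha/beta diversity — but with real samples
there is no ground truth to measure any of those steps against. ampligold
generates communities in which the true source organism of **every read**
is known: it designs defined communities from per-genus abundance
specifications, performs in-silico PCR with degenerate primers against
reference 16S sequences, optionally corrupts reads with a calibrated
substitution/indel model, and emits a per-read mapping file (read →
accession, organism, taxonomy, community). Any pipeline's output,
converted to a common per-read OTU table
(`seq,community,otu_id,ncbi_rank,name,ncbi_tax_id,taxonomy_string,weight`),
can then be scored.

The evaluators compute:

* **OTU generation** — pair counting over reads: with the source × OTU
  contingency table *n<sub>ij</sub>*, true match = Σ C(n<sub>ij</sub>, 2),
  false split = Σ C(n<sub>i·</sub>, 2) − TM, false match =
  Σ C(n<sub>·j</sub>, 2) − TM, true split = C(N, 2) − rest;
  sensitivity = TM/(TM+FS), specificity = TS/(TS+FM), with dropped reads
  reported separately.
* **Classification** — six outcome categories per source organism
  (correct, undercalled, overcalled, sibling miscall, miscalled, dropped)
  with "ranks off" distances, plus per-clade breakdowns.
* **Diversity** — Hill profiles *<sup>q</sup>D = (Σ p<sub>i</sub><sup>q</sup>)<sup>1/(1−q)</sup>*
  (q = −1…5, bootstrap bands), Shannon, weighted UniFrac (raw and
  normalized) and DPCoA on a true phylogeny, and Spearman monotonicity of
  estimates against truth with bootstrap CIs.

A fixture generator (`make_fixture()`) builds reference pools with
coherent taxonomies, embedded primer sites for the 357F/926R (V3–V5) and
U515F/806R (V4) pairs, and a matching ultrametric tree, so everything is
testable without downloading any database.

## Worked example

```r
library(ampligold)

fx <- make_fixture(n_genera = 4, species_per_genus = 3, seq_len = 1500, seed = 1)
specs <- do.call(rbind, Map(genus_spec,
  genus = sprintf("Genus%02d", 1:4),
  mean_frac = c(0.4, 0.3, 0.2, 0.1), sd_frac = c(0.1, 0.07, 0.05, 0.02),
  rule_type = "gaussian", p1 = 2, p2 = 0))
targets <- design_communities(specs, fx$refs, n = 6, seed = 7)
res <- generate_reads(targets, fx$refs, primers_emp(), depth = 5000)

# score a perfect identity "pipeline" (one OTU per source, truth as call)
otu <- otu_table_from_mapping(res$mapping)
rep <- per_community_report(otu, res$mapping)
rep$summary
#>             metric min q1 median q3 max
#> 1      sensitivity   1  1      1  1   1
#> 2      specificity   1  1      1  1   1
#> 3 dropped_fraction   0  0      0  0   0

summarize_outcomes(evaluate_classification(otu, res$mapping, "species"))$percent
#>           correct       undercalled        overcalled miscalled_sibling
#>               100                 0                 0                 0
#>         miscalled           dropped
#>                 0                 0

monotonicity_report(shannon_from_targets(targets),
                    shannon_from_otu(otu), seed = 7)$rho
#> [1] 1
```

Sensitivity and specificity of 1 mean no truly-same-source pair was split
and no different-source pair was lumped; 100% correct classification and
Spearman ρ = 1 for Shannon are the expected ceiling for an error-free
pipeline — real pipelines land below these values, and the gap is the
measurement. The same steps are available from a shell via the bundled
CLI (`inst/scripts/ampligold`): `make-fixture`, `design-communities`,
`amplify`, `add-errors`, `eval-otu`, `eval-classification`,
`eval-diversity`, `eval-distance`, each writing a reproducibility
manifest.

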