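# ighrep

Age-resolved analysis of human immunoglobulin heavy-chain (IgH)
repertoires from AIRR-format rearrangement tables.

The B-cell receptor repertoire matures through childhood: somatic
hypermutation (SHM) load rises steeply in the first decade of life, V1
family and J6 gene usage decline, downstream constant-region genes (IgG2,
IgA2) gain ground, clonal lineages grow longer trunks, and germline-encoded
self-reactive VH4-34 antibodies (the AVY patch in FWR1, the NHS sequon in
CDR2) are progressively mutated away. `ighrep` implements the full analysis
chain needed to quantify these signals in a cohort, for immunologists and
computational biologists working with bulk AIRR-seq data:

* **UMI collapsing** — reads with identical 14-nt UMIs collapse to a
  majority consensus; identical sequences under one constant primer merge
  (`collapseReads`).
* **Annotation** — V-gene mutation counting with replacement/silent (R/S)
  classification per region against the IMGT-style germline alignment
  (`countVMutations`, `annotateMutations`), and subset assignment: IgD/IgM
  with ≤ 2 mutations are naive, ≥ 3 are memory, class-switched sequences
  are antigen-experienced regardless (`classifySubset`).
* **Clonal analysis** — clones share V gene, J gene and CDR3 length with
  CDR3 hamming distance ≤ ⌊L/15⌋, single linkage (`clusterClones`);
  lineage trees rooted at the germline give the trunk length (germline →
  MRCA distance, a maturity proxy) and the Gini index of copy counts
  (`buildLineage`, `cloneMetrics`), with depth-normalising subsampling
  (`subsampleRepertoire`).
* **Selection** — a focused binomial test comparing the observed CDR
  replacement fraction CDR_R/(CDR_R+CDR_S) to an expected-mutability
  baseline enumerated from the germline, with selection strength
  σ = log[(CDR_R+½)/(CDR_S+½)] − log[p/(1−p)] and the zero-silent R/S rule
  (`expectedMutability`, `selectionTest`, `aggregateSelection`).
* **Motifs** — VH4-34 AVY/NHS scoring at the amino-acid level with
  four-category tabulation (`scoreVH434Motifs`, `motifCategoryProportions`).
* **Cohort synthesis** — cross-individual cluster sharing spectra,
  per-subject feature matrices, Wilcoxon/Kruskal-Wallis age-group tests,
  logarithmic trend fits `y = a + b·log(age)`, and PCA stratification with
  age-group convex hulls (`sharingSpectrum`, `buildFeatureMatrix`,
  `compareAgeGroups`, `fitLogTrend`, `pcaStratify`).
* **Synthetic cohorts** — a deterministic generator
  (`simulationConfig`, `simulateRepertoire`) produces AIRR tables across
  six age bands (0-3, 4-8, 9-16, 17-25, 26-39, 40+ years) with ground-truth
  clone membership, mutation events and trunk lengths, so the whole chain
  is testable without sequencing data.

Tables are plain data.frames with AIRR column names (`sequence_alignment`,
`germline_alignment`, `v_call`, `junction`, `c_call`, ...); the germline
reference and lineage trees are S4 objects (`GermlineDatabase`,
`LineageTree`).

## Worked example

```r
library(ighrep)

db  <- buildToyGermlineDb()
db
#> GermlineDatabase with 17 genes ( D:3, J:6, V:8 )

cfg <- simulationConfig(nSubjects = 6L, ages = c(2, 6, 12, 20, 32, 45),
                        seed = 7L, cloneCount = 40)
sim <- simulateRepertoire(cfg, db)
tab <- annotateSubsets(annotateMutations(filterProductive(sim$airr), db))
tab <- clusterClones(tab)

# memory (mutated) fraction of IgD/IgM rises with age
igdm <- tab[tab$subset %in% c("naive_IgDM", "memory_IgDM"), ]
round(sapply(split(igdm$subset, igdm$subject_id),
             function(x) mean(x == "memory_IgDM")), 2)
#>  S01  S02  S03  S04  S05  S06
#> 0.11 0.08 0.14 0.11 0.17 0.36

# mean lineage trunk length grows logarithmically with age
m <- cloneMetrics(tab)
trunk <- sapply(split(m$trunk_length, m$subject_id), mean)
round(trunk, 2)
#>  S01  S02  S03  S04  S05  S06
#> 2.28 2.52 4.64 4.40 4.95 8.03
fit <- fitLogTrend(cfg@ages, trunk)
sprintf("trunk ~ %.2f + %.2f log(age), R2 = %.2f", fit$a, fit$b,
        fit$r_squared)
#> "trunk ~ 0.49 + 1.57 log(age), R2 = 0.76"

# clone-level antigen-driven selection statistics
sel <- aggregateSelection(tab, db, level = "clone")
round(mean(sel$rs_cdr, na.rm = TRUE), 2)
#> 1.33
```

The subjects aged 2-45 years show the expected maturation gradient: the
mutated IgD/IgM fraction climbs from ~0.1 to ~0.4, and mean trunk length
roughly triples, following a saturating `a + b·log(age)` curve.
`runPipeline(cfg, "out/")` chains every stage and writes all result TSVs
(annotated AIRR table, clone metrics, selection, motif categories, sharing
spectrum, features, PCA scores); `inst/scripts/ighrep` exposes the same
stages as shell subcommands (`simulate`, `collapse`, `annotate`, `cluster`,
`lineage`, `selection`, `motifs`, `pipeline`).

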