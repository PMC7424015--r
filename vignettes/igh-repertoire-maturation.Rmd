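---
title: "Models and methods: age-resolved IgH repertoire analysis"
author: "ighrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: age-resolved IgH repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighrep)
```

# Scope

`ighrep` implements an analysis chain for immunoglobulin heavy-chain (IgH)
repertoires aimed at quantifying how B-cell repertoires mature with age:
from UMI-tagged reads, through mutation and subset annotation, clonal
clustering and lineage metrics, antigen-driven-selection statistics and
VH4-34 self-reactivity motif scoring, to cohort-level synthesis (sharing,
age-group tests, trend fits, PCA). Because real AIRR-seq cohorts are large
and access-controlled, the package ships a synthetic repertoire generator
with full ground truth; every stage is validated against that truth or an
independent oracle. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic validation does
and does not establish about real data.

# The synthetic cohort generator

## Germline reference

`buildToyGermlineDb()` deterministically constructs a self-contained,
IMGT-like reference: eight V genes across families V1-V4, three D genes and
six J genes. Each V gene is 96 codons of FWR1 (25) / CDR1 (8) / FWR2 (17) /
CDR2 (8) / FWR3 (38), followed by the conserved Cys-104 codon and a short
trimmable 3' tail; J genes are a trimmable 5' region, the conserved Trp-118
codon and an in-frame FR4. The VH4-34-like gene carries the two
self-reactivity motifs of the real VH4-34 germline: the Ala-Val-Tyr (AVY)
hydrophobic patch in FWR1 and the Asn-His-Ser (NHS) N-glycosylation sequon
in CDR2. The J6-like gene is the longest J, mirroring the association of J6
rearrangements with long junctions. The genes are synthetic: no licensed
database content is embedded, and coordinates are exact by construction,
which is what makes codon-level oracles possible.

## Generative model

`simulationConfig()` holds the cohort conditions; `simulateRepertoire()`
draws, per subject:

* **Age structure** — six age bands (0-3, 4-8, 9-16, 17-25, 26-39, 40+
  years). The default cohort has 18 subjects, three per band, spanning
  0.5-50 years.
* **Gene usage** — categorical V/J weights per band. V1-family usage falls
  from 0.36 to 0.20 and J6 usage from 0.30 to 0.17 across bands; the
  VH4-34-like gene is held at 0.08 in all bands (its usage is
  age-independent; only its mutation status changes).
* **Junction model** — junction length is drawn per rearrangement from a
  normal model conditional on the J gene (means 45-51 nt, J6-like 63 nt;
  SD 4.5 nt), rounded to a codon multiple with a 21-nt floor. V/D/J ends
  are trimmed and untemplated N nucleotides inserted to hit the target;
  draws producing a stop codon are rejection-resampled (cap 100, then an
  error signals an infeasible length model).
* **Somatic hypermutation** — a lineage's expected V-gene mutation load is
  the saturating curve `mu(age) = a + b*log(1 + age)` per compartment
  (defaults: IgD/IgM `4 + 2 log(1+age)`, IgG `2 + 5 log(1+age)`, IgA
  `3 + 5 log(1+age)`), reproducing the steep rise in the first decade and
  the later plateau. A fraction (0.55) of the load is placed on the clone's
  trunk; branches add Poisson(1.5) mutations each. Substitution positions
  are uniform over the V segment with no back mutation (each position
  mutates at most once per lineage); WRC/GYW hotspot weighting is available
  for the expected-mutability baseline but is off in the generator, so that
  the selection null is exactly uniform.
* **Naive fraction** — the probability that an IgD/IgM lineage stays
  unmutated falls from 0.90 (0-3 y) to 0.62 (40+ y), so the memory
  (mutated) fraction of IgD/IgM rises from ~0.1 to ~0.4.
* **Subclasses** — per-band weights over IgM, IgD, IgG1-3, IgA1-2, with
  IgG2 (0.03 to 0.13) and IgA2 (0.04 to 0.13) shares rising with age. The
  compartment is drawn per clone; the subclass is assigned per sequence
  within the compartment (class-switch histories within a tree are not
  modelled).
* **Clone sizes and copies** — clone sizes follow a truncated power law
  `P(k) ~ k^-2.5`, k at most 20; per-sequence copy counts are geometric
  (p = 0.4) + 1, chosen to produce non-degenerate Gini indices. Neither law
  is calibrated to a published distribution (none is available for healthy
  repertoires at this resolution); they are sized for test power.

Every sequence carries a truth record: true clone id, the list of mutation
events (position, bases, region, R/S), the true trunk length and the
intended subset. Subjects receive independent RNG streams derived from the
master seed, so repertoires are byte-identical given a configuration and
changing one subject does not perturb the others.

## What the generator does not emulate

No sequencing-quality profiles, paired-end structure, chimeras or primer
artifacts; no indels (mutations are substitutions only); no convergent
("public") rearrangements — junctions are drawn independently per subject,
so cross-individual sharing is structurally absent and the sharing analysis
can only be validated on planted designs; no within-tree class-switch
events; and SHM placement is uniform rather than hotspot-biased. Passing
tests therefore establish algorithmic correctness (counting, clustering,
tree metrics, test calibration), not that real repertoires satisfy the
generative assumptions.

# Annotation

`countVMutations()` compares `sequence_alignment` to `germline_alignment`
within the V segment (FWR1 through FWR3; CDR3 is excluded, as V-gene
mutation counts conventionally stop at the 3' V boundary). A mismatch is
replacement (R) if the mutated codon translates differently from the
germline codon, where the codon context applies **all** observed mutations
of that codon; this convention is deterministic, matches event-level
counting, and is what the simulator records, so truth comparisons are
exact. Positions with `N` or gaps on either side are skipped — indels and
ambiguous bases are not counted as mutations.

Subset assignment follows the isotype-plus-mutation rule: IgD/IgM with at
most 2 V-gene mutations are naive (the allowance absorbs allelic variation
and residual error), IgD/IgM with 3+ are IgD/IgM memory, and all
class-switched sequences are antigen-experienced regardless of mutation
count; IgE and IgG4 are excluded. For ambiguous comma-separated V calls the
first listed gene is used.

# UMI collapsing

`collapseReads()` implements two-stage collapsing: reads sharing a UMI are
one mRNA molecule and collapse to a per-position majority consensus (groups
of discordant read lengths are split by length first; 2-vs-2 ties resolve
to the alphabetically first base, a determinism choice); records with
identical full-length sequence and identical constant primer but different
UMIs then merge, summing molecule counts. Output rows equal the distinct
(consensus sequence, constant primer) pairs. UMI collisions between
distinct molecules are treated as one molecule — an accepted limitation.

# Clonal clustering and lineages

Clones require identical V gene, J gene (gene level, alleles ignored — D is
not used) and CDR3 length, and CDR3 hamming distance within 1 mismatch per
15 nt: threshold `floor(L/15)` for CDR3 length L, so short CDR3s are
strict. Clustering is single-linkage over the threshold graph — the natural
reading of a chain criterion, and checkable against a brute-force
connected-components oracle.

`buildLineage()` merges identical sequences (summing copies), joins unique
sequences by a minimum spanning tree under hamming distance on the aligned
V segment plus CDR3, and roots the tree at the clone's germline
reconstruction, whose junction-internal N region is masked and excluded
from distances (junctional nucleotides are undefined in the germline;
counting them would inflate trunk lengths with non-SHM differences). The
MRCA is inferred by position-wise consensus: every unmasked position where
all members carry the same non-germline base is a trunk mutation;
`trunkLength` is the root-MRCA distance over unmasked positions. When the
MRCA is observed this is exact; when intermediates are hidden the estimate
errs only if all surviving branches share a coincidental mutation (mean
absolute error stays within 1 nt in validation). This distance-based
construction is deliberately not maximum parsimony with inferred internal
states: it is deterministic, fast, and exact whenever intermediates are
observed, which is what the truth-recovery tests require. The Gini index
over member copy counts is `sum_ij |x_i - x_j| / (2 n sum x)`.
`subsampleRepertoire()` (default depth 25,609 unique sequences) normalises
read depth before lineage metrics.

# Selection statistics

The expected-mutability baseline enumerates all `3L` single-nucleotide
substitutions of a germline V segment and classifies each as
(CDR/FWR, R/S); `p_focused = p_cdr_r / (p_cdr_r + p_cdr_s)` is the null
probability that a CDR mutation is a replacement (~0.75-0.81 for the toy
genes). Under no selection, a unit's CDR replacement count is
`Binomial(CDR_R + CDR_S, p_focused)`; `selectionTest()` reports the exact
two-sided binomial p-value and the selection strength
`sigma = log((CDR_R + 1/2)/(CDR_S + 1/2)) - log(p/(1-p))` with
Haldane-Anscombe corrections. This is a closed-form focused test rather
than a full Bayesian posterior with cross-sequence convolution: the focused
statistic is the quantity of interest, the exact test is deterministic and
oracle-checkable, and its null calibration can be verified by simulation
(the calibration run uses 200 substitution events per replicate, for which
the exact test size is 0.039; sizes from 60 to 200 events all lie within
0.03-0.07, so the choice is not delicate). R/S ratios apply the zero-silent
rule — S is set to 1 when a unit has replacements but no silent mutations —
and are undefined (excluded from means) when both counts are zero. Because
sequences within a clone are not independent, clone-level analysis reduces
each clone to a majority-consensus representative and recomputes its
profile; subject-subset pooling sums representative counts and uses an
n-weighted mean of the per-gene baselines.

Note that with a ~0.07 shift in the replacement fraction (a 1.5-fold odds
enrichment), the exact test needs on the order of 300-400 CDR mutations for
80% power; per-sequence counts are far below that, which is why powered
claims are made at the pooled level.

# Motif scoring

For VH4-34(-like) sequences, the AVY and NHS codons are located by
translated-pattern search in the germline FWR1 and CDR2. Motif status is
judged at the amino-acid level (mutating a motif is a protein-level event;
synonymous changes leave it intact). The AVY patch is mutated on any
amino-acid difference; the NHS sequon follows the canonical N-x-S rule — it
is destroyed only if the first residue stops being Asn, the third stops
being Ser, or the middle residue becomes Pro. Codons overlapping `N` or
gaps are unscored and excluded from category proportions.

# Cohort synthesis

Sharing uses the same clustering criterion applied to the pooled cohort
(single linkage across subjects); a subject's sharing spectrum is the
fraction of its clusters with each subject-multiplicity. Feature matrices
have one row per subject and subset family (mutated IgD/IgM, IgG, IgA) with
the age-sensitive features (mean mutation count, mean CDR R/S, mean
junction length, V1 and J6 frequencies, proportion mutated, IgG2-of-IgG or
IgA1-of-IgA proportion, mean trunk length and Gini); absent families are
absent rows, never zeros. Group comparisons are Wilcoxon rank-sum against
the 0-3 y reference plus a Kruskal-Wallis omnibus at the 0.05 level, with
no multiple-testing correction by default (raw p-values are reported; a
Benjamini-Hochberg adjustment can be applied by the caller via
`p.adjust`). Age trends are least-squares fits of `y = a + b log(age)`; the
reported goodness p-value is the model F test (a replicate-based
lack-of-fit chi-square is not identifiable from one observation per
subject, so the F test is reported instead; a constant response returns
`b = 0`, `R^2 = 0`, `p = 1`). PCA standardises complete-case rows (no
imputation — the cohorts are small and imputation would invent structure),
drops zero-variance columns with a warning, and reports the first two
components with per-age-group convex hulls and hull centres.

# Validation design and problem sizes

The test suite validates each stage at sizes chosen to finish in minutes on
one CPU while leaving sampling error well below the tested effects:
clustering against a brute-force oracle on 50 repertoires of up to ~250
sequences; mutation-count fidelity on a 10,000-sequence cohort (exact
equality with the truth sidecar); selection-test calibration on 2,000 null
replicates; trunk recovery on 100 lineages; and trend/stratification checks
on a 24-subject cohort (four per band). The motif-trend check restricts the
cohort's V usage to the VH4-34-like gene: scoring only concerns VH4-34
sequences, and at mixed usage the per-band counts leave the flat older
bands within sampling noise of each other, which a six-point rank
correlation cannot tolerate; with the restricted cohort every sequence
contributes and the decline resolves across all bands. Generator defaults
are unchanged by any of this — cohort sizes are test-power choices, stated
here once.

# Known limitations

* Clustering bins by exact CDR3 length; indel-bearing junction variants of
  one clone are split.
* Trunk lengths are method-consistent (MST + consensus MRCA), not
  tool-identical to parsimony-based reconstructions; on real data with
  unobserved intermediates they are estimates.
* The expected-mutability baseline defaults to uniform targeting; a 5-mer
  hotspot table can be supplied, but no published targeting model is
  bundled.
* Cross-individual sharing on synthetic cohorts is degenerate (all clusters
  private) because the generator has no convergent recombination; sharing
  code is validated on planted designs instead.
* The R/S ratio with the zero-silent rule is bounded by the number of CDR
  mutations, so its per-clone mean on lightly mutated repertoires sits well
  below its asymptotic (heavily mutated) value.
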