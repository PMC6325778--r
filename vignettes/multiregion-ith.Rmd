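---
title: "Quantifying intratumor heterogeneity from multi-region variant calls"
author: "mrith package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intratumor heterogeneity from multi-region variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrith)
```

## The problem

When several spatially separated regions of the same tumor are sequenced,
somatic alterations split into two compartments. A **trunk** mutation is
present in every sampled region: it was acquired before the most recent
common ancestor of the sampled tumor cells and is clonal. A **branch**
mutation is missing from at least one region: it marks subclonal
diversification. The balance between the two compartments is the tumor's
intratumor heterogeneity (ITH), and it matters clinically — a targeted
drug aimed at a branch mutation can only debulk part of the tumor, and
liquid-biopsy assays see subclonal alterations far less reliably than
clonal ones.

`mrith` implements this analysis for cohorts of non-small-cell lung
cancer (NSCLC) patients profiled by multi-region panel sequencing with
matched plasma (ctDNA): trunk/branch classification, an ITH index,
per-patient phylogenies, driver/passenger composition of the two
compartments, a driver-dominance score, and trunk-versus-branch ctDNA
detection concordance. A clonal-evolution simulator with complete ground
truth stands in for patient data, so every stage is testable end to end.

## Data model and identity of a mutation

Inputs are pre-called variants — one TSV row per observation of a variant
in one region — not reads; alignment and variant calling are upstream of
this package. A mutation's identity across regions and in plasma is its
canonical key: `chrom:pos:ref:alt` for SNVs and indels (1-based,
VCF-style coordinates), and `gene:class:event` for CNVs and fusions,
which have no meaningful single coordinate. Coordinate-level identity is
the strictest reproducible matching rule; gene-level keys for the
non-positional classes are a package convention. Panel BED files keep
their native 0-based half-open convention, converted only inside
`filter_to_panel()`.

CNV and fusion records participate in trunk/branch classification and the
ITH index exactly like SNVs: the cohort-level variant counts in this kind
of study pool all somatic alteration classes. They carry no read-count
requirement.

**Presence rule.** A variant is present in a region if it has an
observation there with at least one supporting read (`min_alt_reads = 1`
by default); rows without read counts (CNV/fusion) count by existence.
The calls are assumed already quality-filtered upstream, so the package
deliberately does not re-threshold them — changing the presence rule
silently changes trunk/branch labels, which is why it is a single
explicit parameter rather than a hidden filter.

## The ITH index

For a patient with $n_t$ trunk and $n_b$ branch mutations,

$$\mathrm{ITHi} = \frac{n_b}{n_t + n_b} \in [0, 1],$$

the branch fraction: 0 for a fully clonal tumor and 1 when nothing is
shared by all regions. Published descriptions of this index pin down only
its direction (higher when the tumor has fewer trunk mutations); the
branch fraction is the simplest bounded statistic with that
monotonicity, and `compute_ithi(formula = "branch_trunk_ratio")` provides
the unbounded ratio alternative for sensitivity analyses.

Patients with a single sampled region carry no ITH information (every
mutation is trivially "shared by all regions"); they are retained in
per-patient tables but excluded from between-subtype comparisons.
Subtype contrasts use the two-sided Mann-Whitney U test: the exact
no-tie null when the pooled sample size is at most 20 and values are
tie-free (cohorts of ~30 patients sit below this), the normal
approximation with tie correction otherwise. Raw p-values are reported
without multiplicity correction, matching how such single-contrast
analyses are typically presented.

## Phylogeny reconstruction

Each patient's binary mutation-by-region matrix is turned into a rooted
tree with the germline (zero somatic mutations) as outgroup, under
maximum parsimony with binary characters:

* **Search.** All rooted leaf-labeled topologies are scored for up to 6
  distinct region profiles ($(2n-3)!!$ of them); for 7–10, stepwise leaf
  insertion with branch-and-bound, pruning on the monotone Fitch bound.
  The search is exact in both regimes. More than 10 regions is refused
  rather than approximated. Regions with identical mutation profiles are
  collapsed first and re-attached as zero-length cherries, which also
  removes most tie-heavy degenerate searches.
* **Scoring.** Fitch counting, vectorized over unique mutation rows with
  multiplicities.
* **Edge assignment.** A two-state minimum-change dynamic program
  (Sankoff) with the root forced to the germline state. Traceback ties
  are resolved toward the parent state, i.e. changes are deferred away
  from the root. This choice makes the trunk edge carry exactly the
  clonal (all-regions) mutations whenever a minimum-change labeling
  allows it; the alternative (accelerating changes rootward) can place a
  gain of a *subclonal* mutation on the trunk when homoplasy is present,
  which would break the correspondence between the trunk edge and the
  trunk compartment. Somatic point mutations are treated as effectively
  irreversible: loss (back-mutation) edges arise only for characters
  incompatible with the tree — calling noise, in practice — and they
  count toward the parsimony score and edge lengths.
* **Determinism.** Among equally parsimonious topologies the one with
  the lexicographically smallest canonical (label-sorted) Newick string
  is returned, so results are reproducible to the byte.

Branch lengths are mutation counts, so the sum of edge lengths equals
the parsimony score, and on a homoplasy-free matrix the trunk fraction
of the tree equals $1 - \mathrm{ITHi}$. Trees are serialized as Newick
with the root labeled `germline`; the writer is in-package because the
output requires a labeled root and supports single-region (single-leaf)
trees.

The **evolution pattern** is read from the matrix, not the tree: if the
distinct subclonal presence patterns are pairwise nested the subclones
form one chain (`LINEAR`); any non-nested pair means divergence
(`BRANCHED`). A tumor with no branch mutations is `LINEAR`. This
definition is algorithm-independent and stable even when the optimal
topology is not unique.

```{r example-tree}
mat <- matrix(0L, 10, 3,
              dimnames = list(paste0("m", 1:10), c("R1", "R2", "R3")))
mat[1:5, ] <- 1L          # clonal
mat[6:8, c(1, 2)] <- 1L   # shared by R1, R2
mat[9:10, 3] <- 1L        # private to R3
build_phylogenetic_tree(mat, patient_id = "example")
```

## Driver composition and dominance

Driver status comes from a user-supplied catalog of genes with
oncogene/TSG roles (genes absent from the catalog are passengers by
definition — there is no de novo driver discovery). Within each patient
group and compartment, the driver-versus-passenger and (among drivers)
oncogene-versus-TSG dichotomies are each tested with an exact two-sided
binomial test against an even split, which matches the one-proportion
style in which such compositions are reported.

The **driver-dominance score** of gene $g$ measures self-sufficiency:
with $D_i$ the number of distinct mutated driver genes in carrier $i$,

$$\mathrm{score}(g) = \frac{1}{|C_g|} \sum_{i \in C_g} \frac{1}{D_i},$$

over the carriers $C_g$ (patients with any mutation in $g$). It is 1
exactly when $g$ is the sole mutated driver in every carrier and decays
with co-drivers. Counting *distinct genes* rather than mutations makes
"co-driver" a gene-level notion; trunk and branch mutations both count,
since a co-driver constrains therapy regardless of clonality. No
canonical formula for this score is published; this one realizes the
stated semantics and is deliberately isolated behind
`compute_dominance()` so alternatives can be swapped in.

## ctDNA concordance

Every tissue-confirmed mutation of a patient with a plasma sample is
looked up in the ctDNA table by its canonical key; it is **detected**
when it has at least one high-quality mutant read (`detect_threshold =
1`; read counts are post-quality-filter by contract). Tissue mutations
without an explicit plasma row count as assayed-but-undetected when the
patient has a plasma sample — deep targeted plasma panels cover their
design space, so absence of a row is evidence of absence; a flag
(`missing_as_undetected = FALSE`) switches to excluding them, since
published analyses are often ambiguous on this point. Plasma-only
variants are out of scope and dropped with a message.

Detection rates are pooled over mutations within each stratum (overall
and per subtype, split by clonality) rather than averaged over patients,
which is the construction implied when a study reports a single
mutation-count table with stratum percentages. The trunk-versus-branch
contrast is a two-sided Fisher exact test on the 2×2
detected/undetected table (exact at these counts; a chi-square variant
is available). A patient is ctDNA-positive when at least one
tumor-derived mutation is detected.

## The simulator

`simulate_cohort()` draws, per patient: a region count (uniform on 3–7),
a random rooted bifurcating region tree, a Poisson mutation count (mean
14), and per-mutation clonality — trunk with subtype-specific
probability $\theta$, otherwise placed uniformly on a non-root edge and
present in exactly the regions below it. Presence is therefore
perfect-phylogeny compatible by construction, so the pipeline's
parsimony score must equal the mutation count on every simulated
patient — a strong end-to-end invariant. An optional per-cell dropout
rate deletes presence calls to create homoplasy and exercise the
incompatible-matrix code path.

Defaults emulate a 32-patient NSCLC cohort: 9 EGFR-mutant LUAD, 6
KRAS-mutant LUAD, 11 EGFR&KRAS-wild-type LUAD, 5 LUSC, 1 LELC; the
lowest trunk fraction in EGFR-mutant LUAD ($\theta = 0.30$ vs 0.55–0.60
elsewhere); a burden of 14 ≈ 437 variants / 32 patients; variant classes
at 92/4/3/1% (SNV/indel/CNV/fusion, ≈ 421:13:3); and per-subtype ctDNA
detection probabilities taken from the published stratum table where
printed (trunk: LUSC 0.81, wild-type LUAD 0.53, EGFR-mutant 0.30,
KRAS-mutant 0.22; branch rates inside the reported 13–25% band; the
unreported LELC trunk rate set to 0.45). Oncogene shares per subtype
(EGFR-mutant oncogene-heavy at 0.75, LUSC TSG-heavy at 0.30) mirror the
reported trunk-composition contrasts. The canonical driver (EGFR or
KRAS) is forced as a trunk oncogene SNV in its subtype — so
$\theta$-limit experiments use the wild-type subtype, where nothing is
forced and $\theta = 0$ yields ITHi exactly 1.

Two modelling details are deliberate:

* **ctDNA calibration.** A mutation in stratum with target detection
  probability $p$ gets mutant reads $\sim \mathrm{Binomial}(d, q)$ at
  plasma depth $d = 1000$ with $q = 1 - (1-p)^{1/d}$, so that
  $P(\ge 1\ \text{read}) = p$ exactly. Stratum detection rates are thus
  directly controllable generative parameters, and recovery can be
  judged against binomial sampling error.
* **Region coverage.** A region with zero somatic calls cannot be
  represented in a per-observation variant table, so the generator
  redraws mutation placement until every sampled region carries at
  least one mutation (enlarging the burden in the rare infeasible
  case). Without this, low-$\theta$ cohorts would silently lose regions
  and bias the branch fraction downward.

What the simulator does **not** model: sequencing reads, purity and
ploidy, VAF-driven clonal deconvolution (tissue VAFs are decorative
draws — higher for trunk than branch — with read counts kept consistent),
copy-number segments, or plasma-private variants. Passing tests
therefore demonstrate correctness of the analysis logic under clean
presence/absence data and calibrated detection, not robustness to
caller noise beyond the dropout switch.

## Numerical and degenerate-input choices

* Zero mutations make the ITH index undefined: an error, not an NA.
* Patients whose variants are all dropped by the presence rule are
  excluded from the ITH table with a warning.
* Exact tests are used wherever the null can be enumerated
  (`binom.test`, `fisher.test`, exact `wilcox.test`); the test suite
  checks each against independent enumeration oracles rather than
  trusting shared code paths.
* Empty strata (e.g. a subtype with no branch mutations in plasma) are
  omitted from summary tables rather than reported as 0/0.
* All output tables are UTF-8, LF, tab-separated with headers; reruns
  on identical inputs are byte-identical.

## Problem sizes used in validation

The shipped tests reconstruct trees for cohorts at the default 32-patient
scale, verify the parsimony search against brute-force Fitch enumeration
on matrices with up to 5 regions, recover $\theta = 0.3$ from 200
simulated patients, and check detection-rate calibration at roughly 2000
mutations per replicate across 100 seeded replicates — sizes chosen so
the full suite documents the method's statistical behavior while running
in about a minute.

## Known limitations

* The exact search is capped at 10 regions (and is exponential in the
  number of *distinct* region profiles); larger designs need
  heuristic tree search, which is out of scope.
* Branch topology for matrices with heavy homoplasy is not unique;
  only the parsimony score, the trunk compartment, and the
  deterministic tie-break are guaranteed stable.
* The ITH index ignores VAFs entirely: presence/absence ITH is the
  target quantity, not cancer-cell-fraction subclone structure.
* The dominance score and the ITH index formula are package conventions
  for quantities whose published definitions are underspecified; both
  are isolated behind single functions and flagged as configurable.
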