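# mrith — multi-region intratumor heterogeneity and ctDNA concordance

`mrith` analyzes multi-region somatic variant calls from non-small-cell
lung cancer (NSCLC) cohorts. When several regions of one tumor are
sequenced, each alteration is either a **trunk** mutation (present in
every region — clonal) or a **branch** mutation (missing from at least
one — subclonal). From that split the package computes, per patient and
cohort:

- the **ITH index**, the branch fraction
  `ITHi = n_branch / (n_trunk + n_branch) ∈ [0, 1]`, higher when fewer
  mutations are clonal, compared between subtypes (EGFR-mutant LUAD,
  KRAS-mutant LUAD, EGFR&KRAS-wild-type LUAD, LUSC, LELC) with exact
  Mann-Whitney tests;
- an exact **maximum-parsimony phylogeny** over the tumor regions with a
  germline outgroup root, mutation-count branch lengths (Fitch scoring,
  exhaustive topology search ≤ 6 distinct region profiles,
  branch-and-bound for 7–10), and a linear/branched evolution-pattern
  call;
- **driver/passenger and oncogene/TSG composition** of the trunk and
  branch compartments (exact binomial tests against an even split) and a
  per-gene **driver-dominance score** — the mean over carriers of
  `1 / (# distinct mutated driver genes)`, 1 for a fully self-sufficient
  driver;
- **ctDNA concordance**: which tumor-derived mutations are detected in
  matched plasma (≥ 1 high-quality mutant read), with pooled
  trunk-vs-branch detection rates and Fisher exact contrasts, overall
  and by subtype;
- a **clonal-evolution + ctDNA simulator** with complete ground truth
  (subtype-specific trunk fractions, driver mixtures, calibrated
  detection probabilities), so the whole pipeline is testable without
  patient data.

Inputs are plain TSV tables of pre-called variants (tissue and plasma),
a two-column driver catalog, and optionally a panel BED; outputs are TSV
tables and Newick trees. See the vignette
(`vignettes/multiregion-ith.Rmd`) for the model, parameter meanings and
design decisions.

## Worked example

Simulate a 32-patient cohort at the default study conditions and run the
full pipeline:

```r
library(mrith)

sim <- simulate_cohort(simulation_config(seed = 42))
dir <- tempfile(); write_simulated_cohort(sim, dir)
res <- run_pipeline(file.path(dir, "tissue.tsv"), file.path(dir, "out"),
                    ctdna   = file.path(dir, "ctdna.tsv"),
                    drivers = file.path(dir, "drivers.tsv"))

res$cohort
#> mrith_cohort: 32 patients, 155 regions, 465 distinct variants, 1517 observations
#>   subtypes: EGFR_LUAD=9, KRAS_LUAD=6, LELC=1, LUSC=5, WT_LUAD=11

head(res$ithi, 3)
#>   patient_id   subtype n_regions n_trunk n_branch      ithi
#> 1       P001 EGFR_LUAD         3       8       10 0.5555556
#> 2       P002 EGFR_LUAD         6       4       10 0.7142857
#> 3       P003 EGFR_LUAD         6       4       13 0.7647059

compare_ithi_by_subtype(res$ithi, "EGFR_LUAD", c("KRAS_LUAD", "WT_LUAD"))[
  c("median1", "median2", "p.value")]
#> $median1            $median2            $p.value
#> [1] 0.7142857       [1] 0.4090909       [1] 0.0002998672

res$trees[["P001"]]
#> mrith_tree [P001]: 3 regions, parsimony score 18, trunk 8, BRANCHED
#>   (((P001_R1:1,P001_R2:2):5,P001_R3:2):8)germline;
```

P001's tree reads: 8 clonal mutations on the trunk from germline, then a
subclone shared by regions R1+R2 (5 mutations) diverging from R3; branch
lengths are mutation counts and their sum (18) is the parsimony score.
The EGFR-mutant subtype shows the highest ITH index (median 0.71 vs 0.41
in the combined KRAS-mutant/wild-type group, Mann-Whitney p = 3.0e-4),
and the aggregate report (`res$report`, written as `report.tsv`) shows
the trunk compartment enriched for drivers (57.7% driver, binomial
p = 0.020) and plasma detecting trunk mutations far better than branch
mutations (46.9% vs 19.0%, Fisher p = 1.9e-10) — the qualitative
structure the simulator is parameterized to emulate.

A thin CLI wrapper is included:

```sh
Rscript inst/cli/mrith.R simulate --seed 17 --out simdir
Rscript inst/cli/mrith.R run-all --tissue simdir/tissue.tsv \
    --ctdna simdir/ctdna.tsv --drivers simdir/drivers.tsv --out results_dir
```

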