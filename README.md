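# breedpanel

Population-genetic analysis of multi-breed SNP genotype data, ending in the
selection of a reduced panel of breed-informative markers. The package is
aimed at livestock geneticists who have a few hundred individuals from a
handful of breeds genotyped at a SNP panel and want the standard workup:

* **QC** — SNP/sample call-rate filters, pooled-MAF floor, identity-by-state
  pruning of near-duplicate samples (PLINK text and VCF input).
* **Within-breed diversity** — allele frequencies, observed/expected
  heterozygosity, fixation index F_IS = 1 − H_O/H_E, and Hill-number
  diversity profiles qD = (Σ p_i^q)^(1/(1−q)) for q = 0, 1, 2.
* **Exact Hardy–Weinberg tests** — conditional enumeration of heterozygote
  counts per locus and breed, with mid-p option and de Finetti (ternary)
  plot coordinates.
* **Between-breed differentiation** — Weir–Cockerham θ from the (a, b, c)
  variance components, Nei's G_ST = (H_T − H_S)/H_T, Euclidean distance on
  allele-frequency vectors, and an F_ST-outlier scan that fits a trimmed
  chi-square model to the empirical neutral distribution.
* **DAPC panel selection** — PCA + linear discriminant analysis with
  a-score choice of the number of PCs, per-SNP contribution scores,
  threshold selection of breed-informative SNPs, and Gaussian membership
  posteriors comparing breed-assignment accuracy of the full versus the
  reduced panel.
* **Simulator** — Balding–Nichols multi-breed genotypes with controllable
  F_ST, F_IS (including heterozygote excess), MAF spectrum and
  missingness, so the whole pipeline runs without any external data.

See `vignettes/breedpanel-methods.Rmd` for the estimators, defaults and
their rationale.

## Worked example

Simulate a three-breed study (3 × 100 individuals, 300 SNPs, between-breed
F_ST 0.04, mild heterozygote excess F_IS = −0.03, high-diversity MAF
spectrum), QC it, and run the main analyses:

```r
library(breedpanel)

sim <- simulate_genotypes(sim_config(seed = 42, anc_maf_range = c(0.3, 0.5)))
tab <- apply_qc(sim$table)$table
tab
#> genotype_table: 300 samples x 300 loci, 3 population(s) [pop1, pop2, pop3], 0.00% missing

round(pairwise_fst(tab), 3)
#>       pop1  pop2  pop3
#> pop1 0.000 0.036 0.038
#> pop2 0.036 0.000 0.037
#> pop3 0.038 0.037 0.000

fis(tab, by_population = TRUE)$overall
#>       population        F_IS
#> 1           pop1 -0.03309945
#> 2           pop2 -0.02409969
#> 3           pop3 -0.03062624
#> 4 within_overall -0.02926908

hill_profile(tab)$summary
#>   population q  mean_qD
#> 1     pooled 0 2.000000
#> 2     pooled 1 1.931049
#> 3     pooled 2 1.877920

hwe_scan(tab)$n_deviating
#> [1] 31

outflank_scan(tab)
#> outlier_scan: 300 loci included (H_E >= 0.10), df = 1.67, mean F_ST = 0.0448, 5 outlier(s) at alpha = 0.05

compare_panels(tab, threshold = 0.01, seed = 42)
#> panel_comparison: 2 PCs retained; full 99.7% vs reduced (46 SNPs) 96.3% correct
```

Reading the output: the pairwise Weir–Cockerham F_ST estimates recover the
simulated differentiation (0.036–0.038 around the target 0.04); the
multilocus within-breed F_IS is negative (≈ −0.029), the heterozygote
excess that also drives 31 loci past the exact Hardy–Weinberg test in at
least one breed; the Hill profile (2, 1.93, 1.88) says every locus is
polymorphic with diversity close to the biallelic maximum; the outlier scan
flags about α = 5% of loci, i.e. no evidence of selection beyond the
neutral tail; and thresholding DAPC contributions at 0.01 selects a 46-SNP
panel that still assigns 96.3% of animals to their true breed, against
99.7% with all 300 SNPs.

`run_pipeline(run_config(table = tab, seed = 42, outdir = "results/run"))`
executes all stages in order and writes TSV/JSON outputs (`diversity.tsv`,
`hwe.tsv`, `distances_*.tsv`, `outliers.tsv`, `panel.tsv`,
`assignment.json`, `run_report.json`); identical config and seed give
byte-identical files. A thin command-line wrapper over the simulator and
pipeline is in `inst/scripts/breedpanel.R`.

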