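---
title: "Methods: diversity, differentiation and breed-informative SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, differentiation and breed-informative SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedpanel)
```

`breedpanel` implements the standard population-genetic workup applied to a
multi-breed SNP panel — for example three commercial pig breeds genotyped at
a few hundred coding SNPs — ending in the selection of a reduced panel of
breed-informative markers and a comparison of breed-assignment accuracy with
the full panel. This vignette explains the statistical machinery, the
defaults and their rationale, the numerical choices, and what the bundled
simulator can and cannot tell you about real data.

## The genotype container and quality control

All functions operate on a `genotype_table`: an individuals-by-loci matrix
of alternate-allele dosages (0/1/2, `NA` missing) plus sample and locus
metadata. Readers are provided for PLINK text (`.ped`/`.map`) and VCF. When
reading PLINK text the alternate allele is defined as the pooled minor
allele (tie broken to the lexicographically later allele) and recorded in
the locus metadata, so downstream frequencies are reproducible from the
files alone. Every statistic in the package is invariant to which allele is
called "alternate" (heterozygosity, F-statistics, IBS, distances, DAPC),
so this orientation is a bookkeeping convention, not a modelling choice.

QC applies four filters in a fixed, documented order — SNP call rate
(default ≥ 0.99), pooled MAF (≥ 0.05), sample call rate (≥ 0.99), and
identity-by-state pruning (IBS > 0.95 removes the lower-call-rate member of
the pair, ties to the later index). A single pass is used rather than
iterating to a fixed point; `apply_qc` is idempotent, so a second pass
removes nothing. Sex-discrepancy checks are out of scope (no sex-chromosome
model).

## Within-population diversity

Per locus and population the package reports the alternate-allele frequency
$p$, observed heterozygosity $H_O$ (proportion of dosage-1 genotypes among
typed individuals), Nei's gene diversity $H_E = 2p(1-p)$ (a
$2n/(2n-1)$ small-sample factor is available but off by default, matching
the plug-in convention), and the fixation index

$$F_{IS} = 1 - H_O / H_E .$$

The multilocus $F_{IS}$ is the ratio of sums $1 - \sum_l H_{O,l} / \sum_l
H_{E,l}$, the usual multilocus estimator; it is stable when many loci have
small $H_E$, unlike the mean of per-locus ratios (also available). Negative
values indicate heterozygote excess. Monomorphic loci ($H_E = 0$) drop out
of both sums.

Diversity profiles use Hill numbers
$^qD = (\sum_i p_i^q)^{1/(1-q)}$ over the alleles present: $q=0$ is
allelic richness, $q=1$ the exponential of Shannon information (taken as
the analytic limit), and $q=2$ the inverse Simpson concentration, which at
a biallelic locus satisfies the identity $^2D = 1/(1 - H_E)$ — a relation
the tests verify per locus. $^qD$ is non-increasing in $q$, with equality
only at $p = 0.5$ or fixation. Profile means are arithmetic means of
per-locus values; because real studies sometimes report pooled and
sometimes per-population profiles, both are emitted.

## Exact Hardy–Weinberg tests

`hwe_exact` is the conditional exact test: given the allele counts, every
heterozygote count $h$ of the same parity as the rarer-allele count is
enumerated, with conditional probability proportional to
$2^h / (n_{AA}(h)!\, h!\, n_{BB}(h)!)$. The enumeration uses the ratio
recurrence $P(h{+}2)/P(h) = 4\,n_{AA}(h)\,n_{BB}(h) / ((h{+}1)(h{+}2))$ in
log space, so counts in the hundreds are no problem. The p-value sums all
outcomes no more probable than the observed one (ties included with a
$1+10^{-12}$ relative guard); the mid-p variant subtracts half the observed
outcome's probability — for a monomorphic locus, where a single outcome
carries all mass, mid-p is therefore 0.5 while the standard p is 1.

Two numerical facts matter for interpretation. First, the exact test is
conservative by discreteness: its true type-I rate at $\alpha = 0.05$ is
about 0.034 at $n = 100$ and 0.040 at $n = 300$ (computable directly from
the null distribution). Calibration checks in the test suite therefore run
at the pooled study scale ($n = 300$, 1000 loci), where the realized rate
sits comfortably inside the binomial band around the nominal level; the
mid-p variant is closer to nominal at small $n$ if that is a concern.
Second, testing is per population by default — Hardy–Weinberg proportions
are only expected within a panmictic unit, and pooling differentiated
populations produces spurious heterozygote deficits (Wahlund effect). A
locus counts as "deviating" when significant in at least one population;
raw exact p-values are the default (Bonferroni/BH optional).

For visualization, `ternary_coordinates` maps genotype frequency triples
into the de Finetti triangle ($x = f_{BB} + f_{AB}/2$,
$y = f_{AB}\sqrt{3}/2$) and `hwe_parabola` traces the curve of equilibrium
points $y = \sqrt{3}\,x(1-x)$; the coordinates are the contract, rendering
is left to the user.

## Differentiation and the outlier scan

Pairwise differentiation uses three metrics, all computed from the same
table:

* **Weir–Cockerham $\theta$** from the 1984 variance components $a$
  (among populations), $b$ (among individuals within populations) and $c$
  (within individuals), with $\theta = a/(a+b+c)$. Multilocus estimates
  combine loci as a ratio of sums $\sum_l a_l / \sum_l (a_l+b_l+c_l)$
  (mean-of-ratios optional). The estimator is unbiased, so identical
  populations give slightly negative values — that is a property, not a
  bug.
* **Nei's $G_{ST}$** per pair: $H_S$ is the unweighted mean of the two
  within-population gene diversities, $H_T = 2\bar p(1-\bar p)$ at the
  unweighted mean frequency, combined over loci as
  $\sum(H_T - H_S)/\sum H_T$. No sample-size weighting is applied — the
  pair is treated symmetrically.
* **Euclidean distance** between the populations' alternate-allele
  frequency vectors on the 0–1 scale, one coordinate per locus. Other
  codings (per-allele columns, percent scale) change the value by a
  constant factor; the 0–1 single-column convention is the default and the
  one the tests pin down (e.g. $\Delta p = 0.1$ at 300 loci gives
  $\sqrt{3}$).

The outlier scan follows the trimmed chi-square approach: per-locus
*uncorrected* $\theta$ values (finite-sample correction terms dropped, so
the statistic is non-negative in expectation under drift) are computed
across all populations; loci with pooled $H_E < 0.1$ are excluded
(low-diversity loci have unstable $\theta$); the lowest and highest 5% are
trimmed; and the model $\theta\,\mathrm{df}/\bar F_{ST} \sim
\chi^2_{\mathrm{df}}$, truncated to the kept range, is fitted by maximum
likelihood. Because the truncated likelihood has no closed-form profile for
$\bar F_{ST}$, both parameters are optimized jointly on the log scale — a
coarse grid over df seeds a Nelder–Mead refinement (relative tolerance
$10^{-8}$); divergence of df (near-constant $\theta$ across loci) and
non-convergence raise errors with diagnostics rather than returning a
silent fit. Right-tail p-values from the fitted distribution flag
selection candidates at $\alpha = 0.05$. On neutral simulations the
flagged fraction is close to $\alpha$ and loci spiked to $F\approx0.5$ on
an $F = 0.03$ background are detected with high power (both are exercised
in the test suite).

## DAPC and panel selection

The discriminant analysis of principal components proceeds in the standard
two stages. PCA of the dosage matrix (mean-imputed missing values,
centered, unscaled by default — dosages share a scale, so unit-variance
scaling mostly amplifies rare-allele noise) gives sample scores; linear
discriminant analysis on the first `n_pca` scores solves the generalized
eigenproblem of between- versus pooled within-group covariance and keeps
$K-1$ axes (fewer if `n_pca` < $K-1$), each normalized to unit pooled
within-group variance. With all PCs retained this reproduces plain LDA of
the genotype matrix exactly — the test suite checks posterior agreement
with an independent LDA implementation to $10^{-8}$.

The number of retained PCs is chosen by the a-score: observed training
reassignment minus its permutation expectation (10 seeded label
permutations per candidate by default, grid $1..\min(100, n-K)$). The
permutation baseline absorbs training-set optimism, which grows roughly
like $n_{pca}/n$; this is exactly why raw reassignment cannot be used to
pick `n_pca`.

Membership probabilities are Gaussian in discriminant space: posterior of
group $k$ proportional to $\exp(-\tfrac12 \sum_j (y_j - c_{kj})^2 /
\sigma^2_j)$ with axis-wise pooled within-group variance and equal priors.
This is the single biggest driver of assignment-rate numbers; a different
posterior model (e.g. class-proportional priors or full covariance) will
move per-breed percentages by a few points. "Assignment accuracy" is
reported both as the proportion of individuals reassigned to their true
breed and as the mean posterior of the true breed, since published phrases
like "average assignment probability" are ambiguous between the two.

Per-SNP contributions to axis $j$ are squared composite loadings
$(\sum_{pc} v_{snp,pc}\, \beta_{pc,j})^2$, normalized to sum to one per
axis. The informative panel keeps SNPs whose contribution exceeds a
threshold (default 0.01) under a configurable axis policy — maximum over
axes by default; published analyses rarely state the axis rule, and "axis
1" or eigenvalue-weighted versions are provided. `compare_panels` then
*refits* the whole DAPC on the reduced panel (rather than re-projecting
through the full-panel model) and reports both assignments; refitting is
the honest comparison, since a deployed reduced panel would be used alone.
Reduced panels lose information by construction, so their accuracy is at
most that of the full panel on average — a property the acceptance tests
check over seeds — while `threshold = 0` returns the full panel and
reproduces the full report exactly.

## The simulator: what it emulates and what it does not

`simulate_genotypes` draws a Balding–Nichols dataset: ancestral frequencies
$p \sim U(\text{anc\_maf\_range})$, population frequencies $p_k \sim
\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ so that $E[p_k] = p$ and
$\mathrm{Var}[p_k] = F p(1-p)$, and genotypes from the
inbreeding-adjusted frequencies $P(\text{het}) = 2p_k(1-p_k)(1-F_{IS})$,
homozygotes $p_k^2 + p_k(1-p_k)F_{IS}$ and symmetric. Negative $F_{IS}$
(heterozygote excess) is sampled directly from these probabilities, not by
rejection. When drift pushes $p_k$ close to fixation the requested excess
can become infeasible (a homozygote probability would go negative); by
default $F_{IS}$ is clamped at such cells to the feasibility bound
$-\min(p_k, 1-p_k)/\max(p_k, 1-p_k)$, which leaves the realized multilocus
$F_{IS}$ essentially unchanged because those cells carry near-zero $H_E$
(set `clamp_fis = FALSE` to error instead). `fst_target` may be a
per-locus vector, which is how the tests spike a handful of
high-differentiation loci onto a neutral background.

Defaults emulate a three-breed design: $K = 3$, $n = 100$ per breed,
$L = 300$ loci, $F = 0.04$ (typical of closely related commercial breeds,
pairwise $F_{ST}$ 0.03–0.05), $F_{IS} = -0.03$ (the mild heterozygote
excess seen in managed populations that avoid close matings), ancestral
MAF uniform on (0.05, 0.5) so simulated panels respect the QC MAF floor.
For study-scale checks that target a high-diversity genotyping panel —
where average allele proportions sit near 0.5 and mean Hill numbers are
around $(2, 1.95, 1.91)$ — the ancestral range is narrowed to (0.3, 0.5);
by closed-form integration $E[^1\!D] \approx 1.95$ and
$E[^2\!D] \approx 1.90$ there, matching that regime. The acceptance script
and the parameter-recovery tests use this range; problem sizes throughout
(up to 20 replicate seeds of the 3×100×300 design, 1000-locus calibration
runs) keep every check within desk-scale runtimes.

The simulator deliberately omits linkage disequilibrium, admixture and
migration, selection (other than per-locus $F$ spikes), ascertainment bias
of SNP chips, and family structure. Passing tests on simulated data
therefore demonstrate estimator correctness and calibration under the
stated model — not robustness to LD between panel SNPs or to pedigree
structure in real breeding populations, which typically widen the spread
of per-locus statistics and can inflate outlier-scan false positives.

## Degenerate inputs and tie-breaks, in one place

* Loci with no typed samples: frequencies `NA`, flagged with a warning.
* Monomorphic loci: $H_E = 0$, per-locus $F_{IS}$ undefined and excluded
  from multilocus sums; exact HWE p = 1; Weir–Cockerham components all
  zero with $\theta$ flagged `NA`.
* Sample pairs with no shared typed loci: IBS `NA` plus warning.
* IBS pruning tie (equal call rates): the later sample index is removed.
* PLINK allele-count tie: the lexicographically later allele becomes alt.
* a-score tie: the smaller number of PCs wins.
* Singular within-group covariance in DAPC: ridge of $10^{-8}$ times the
  mean diagonal is added, with a warning.
* All per-locus $\theta$ identical, or fewer than 20 usable loci: the
  outlier scan refuses to fit.

## Reproducibility

Every stochastic step (simulation, a-score permutations) is driven by an
explicit integer seed, and `run_pipeline` re-emits byte-identical TSV/JSON
outputs for identical config and seed. The pipeline writes its seed into
each JSON output so downstream consumers can trace provenance.
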