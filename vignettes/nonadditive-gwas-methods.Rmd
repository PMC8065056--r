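---
title: "Methods: multi-panel imputation combination and non-additive association testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-panel imputation combination and non-additive association testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasmodels)
```

## What this package models

Standard genome-wide association studies test one hypothesis per variant:
that disease risk rises linearly (on the log-odds scale) with the count of
an effect allele. Variants acting recessively — where only effect-allele
homozygotes carry the risk — are systematically under-powered under that
additive test, especially at low allele frequency, because the signal is
concentrated in a tiny homozygote class that the additive coding dilutes.
`gwasmodels` implements the full analysis stack needed to look for such
signals in imputed case-control data:

1. **Genotype-probability data handling** (Oxford GEN/SAMPLE, VCF GP/DS
   fields, summary-statistics TSVs).
2. **Combination of imputation results from several reference panels**,
   keeping for each variant the panel with the best info score.
3. **Marker QC** (missingness, exact Hardy-Weinberg, MAF, info score) plus
   the post-association filters specific to recessive/genotypic tests.
4. **Five-inheritance-model logistic association** — additive, dominant,
   recessive, heterodominant (overdominant), genotypic (2-df) — on
   expected-dosage encodings, with covariates, non-PAR X-chromosome
   support under full X inactivation, and a dominance-deviation test.
5. **Locus collapsing and inheritance classification**, plus a
   cross-phenotype matrix.
6. **Wakefield approximate-Bayes-factor 99% credible sets.**
7. **Fixed-effect meta-analysis** (inverse-variance and sample-size/z-score).
8. **Power and required-sample-size calculation per inheritance model.**
9. A **synthetic cohort generator** that gives every stage a test substrate
   with the statistical structure the analysis assumes.

## The association model

For a variant with imputed probability triple $(p_0, p_1, p_2)$ of carrying
0/1/2 copies of the effect allele, each inheritance model contributes the
expected value of its genotype coding as the design column:

| model          | coding of genotype $g$ | expected encoding   |
|----------------|------------------------|---------------------|
| additive       | $g$                    | $p_1 + 2p_2$        |
| dominant       | $1\{g \ge 1\}$         | $p_1 + p_2$         |
| recessive      | $1\{g = 2\}$           | $p_2$               |
| heterodominant | $1\{g = 1\}$           | $p_1$               |
| genotypic      | $(1\{g=1\},\,1\{g=2\})$| $(p_1,\,p_2)$       |

The fit is a maximum-likelihood logistic regression of case status on the
encoding plus covariates, by iteratively reweighted least squares
(tolerance $10^{-8}$ on the coefficient change, at most 25 iterations).
Imputation uncertainty enters through the expected encodings (the
"expected" dosage method); this is deterministic and, for hard-called
genotypes, identical to a fit on integer dosages. Single-column models are
tested with a 1-df Wald statistic; the genotypic model with a 2-df
likelihood-ratio test against the covariate-only fit. Quasi-complete
separation is detected as non-convergence or any genotype coefficient
beyond $|\beta| > 15$ and reported as a non-converged record with missing
statistics rather than as a fabricated estimate. Covariates are
standardised internally for numerical stability; genotype effects are
reported on their original scale.

**X chromosome.** Analysis is restricted to non-pseudoautosomal variants
(hg19 PAR boundaries 2,699,520 and 154,931,044). Under full X inactivation
a hemizygous male is biologically equivalent to a homozygous female, so
male genotypes are stored homozygote-coded ($(p_0, 0, p_2)$): the autosomal
encodings then automatically produce the required male codings (additive
$2p(B)$, dominant/recessive $p(B)$, heterodominant 0). Samples with missing
sex are dropped for X variants. The default "stratified" fit adds a sex
main effect (separate male/female baselines) with a shared genotype
effect; with single-sex data it falls back to the pooled fit with a
warning. Hardy-Weinberg tables on X use females only, since male
hemizygote coding would otherwise register as extreme homozygote excess.

**Dominance deviation.** A logistic fit of status on the additive dosage
*plus* an expected-heterozygote indicator ($p_1$) and covariates; the Wald
p of the heterozygote coefficient measures departure from additivity. For
additive signals this p is uniform; recessive, dominant or overdominant
signals push it small. It is the referee that decides whether a locus
significant under both additive and non-additive models is genuinely
non-additive.

## QC thresholds and their defaults

| parameter | default | role |
|---|---|---|
| `max_missingness` | 0.05 | remove variants missing in $\ge$ 5% of samples |
| `hwe_all_p_floor` | $10^{-20}$ | whole-cohort exact HWE floor (hard calls) |
| `min_maf` | 0.001 | MAF floor from expected dosages (boundary kept) |
| `min_info` | 0.7 | imputation info gate |
| `hwe_controls_p_floor` | $10^{-6}$ | post-association control-HWE filter |
| `min_alt_hom_cases` | 3 | recessive/genotypic homozygote-case floor |
| `hard_call_threshold` | 0.9 | probability needed to call a genotype |

The info score is the standard ratio of observed to Hardy-Weinberg-expected
dosage variance: with $e_i = p_1 + 2p_2$, $f_i = p_1 + 4p_2$ and
$\theta = \sum e_i / 2N$,
$\mathrm{info} = 1 - \sum_i (f_i - e_i^2) / (2N\theta(1-\theta))$, defined
as 1 when $\theta \in \{0, 1\}$. Anti-informative triples can drive it
negative; such values are reported as-is and fail the 0.7 gate naturally.
The Hardy-Weinberg test is the exact conditional test on hard-call counts
(two-sided: the sum of probabilities of heterozygote counts no more
probable than the observed one). Probability triples summing below 0.98
are treated as missing — imputation software emits deflated triples for
uncertain genotypes and keeping them biases expected dosages; triples
between 0.98 and 1 are renormalised.

The post-association filter removes records with control-HWE
$p < 10^{-6}$ (all models) and recessive/genotypic records with fewer than
three hard-called effect-allele homozygote cases; these are the
configurations that drive genomic inflation and deflation specific to the
recessive and genotypic tests. The homozygote count is deliberately an
integer hard-call count, not an expected dosage.

## Panel combination

Variants are matched across panels by (chromosome, position, unordered
allele pair); panels are assumed pre-harmonised to one strand. The
combined set is the union of variants, each taken from the covering panel
with the highest info score, ties broken by a configurable panel priority
(the choice is arbitrary but must be deterministic). Genotypes are never
blended across panels. Imputation accuracy is evaluated by masking a
truth set down to an "in-silico array", re-imputing, and computing the
allelic dosage $R^2$ (squared Pearson correlation between imputed and true
dosages), summarised as the percentage of info-passing variants with
$R^2 \ge 0.5$ per MAF bin (default edges 0.001, 0.005, 0.01, 0.05, 0.1,
0.2, 0.5).

## Loci and classification

Genome-wide significant variants ($p < 5\times10^{-8}$) are collapsed per
chromosome by transitive single-linkage within 500 kb (the IRanges
`reduce` idiom); the lead is the smallest p across models, ties broken by
position. The experiment-wide threshold divides the genome-wide level by
2.5 effective tests ($2\times10^{-8}$), reflecting the correlation among
the five model tests. Classification: additive-only significance is
"additive"; significance under both additive and non-additive models is
non-additive only when the dominance-deviation p is below 0.05, otherwise
"additive"; non-additive-only significance without deviation support is
"undetermined". The non-additive subtype is the model with the smallest p.
X-chromosome loci are classified on significance alone (the deviation test
is run on autosomes), so ambiguous X patterns are "undetermined".

## Credible sets

For a fine-mapped region the package keeps variants in LD with the lead
(dosage $r^2 > 0.1$; the lead always stays), computes Wakefield's
approximate Bayes factor
$\mathrm{ABF} = \sqrt{1-r}\, e^{r z^2/2}$ with $z = \beta/\mathrm{SE}$ and
shrinkage $r = W/(\mathrm{SE}^2 + W)$ under a Gaussian effect prior of
variance $W = 0.04$, normalises the ABFs to posterior probabilities, ranks
by ABF (ties by position), and includes variants until the cumulative
posterior first exceeds 0.99, inclusive of the crossing variant. Note the
minimum attainable ABF is $\sqrt{1-r}$ (at $z = 0$), which matters when
constructing synthetic examples.

## Meta-analysis

Inverse-variance weighting is the default: $w_i = 1/\mathrm{SE}_i^2$,
pooled $\beta = \sum w_i\beta_i/\sum w_i$, pooled
$\mathrm{SE} = 1/\sqrt{\sum w_i}$. When a study's $\beta$ is unreliable
(e.g. inflated rare-homozygote estimates) the sample-size method converts
each study's two-sided p and direction into a signed z-score and pools
with $\sqrt{N}$ weights. Heterogeneity is Cochran's
$Q = \sum w_i(\beta_i - \bar\beta)^2$ with $I^2 = \max(0, (Q - df)/Q)$.
For case-control studies an effective N, $4/(1/n_\text{cases} +
1/n_\text{controls})$, is available; plain total N is the default since
the upstream tools' default behaviour is total N.

## Power and required sample size

This module reproduces published calculator-style figures, and its
conventions deserve explicit statement because the underlying tools leave
them implicit.

**Recessive and dominant tests** are treated as a binary-exposure
two-proportion problem. Under Hardy-Weinberg equilibrium the exposure
prevalence is $f = q^2$ (recessive) or $1-(1-q)^2$ (dominant). Controls
carry the population exposure $p_0 = f$ (the rare-disease convention used
by case-control sample-size calculators) and cases the odds-shifted
$p_1 = \mathrm{OR}\cdot f/(1-f)\,/\,(1 + \mathrm{OR}\cdot f/(1-f))$.

**The additive test** is a Cochran-Armitage trend contrast. Penetrances
rise multiplicatively with allele count on the *risk* scale
($f_g = f_0\cdot\mathrm{OR}^g$, the genetic-power-calculator convention —
not odds-multiplicative, which gives materially different numbers at
appreciable prevalence), with $f_0$ solved so the population case fraction
equals the study case fraction; case and control genotype distributions
follow by Bayes' rule.

**The normal deviate.** Writing $\Delta$ for the case-control contrast and
$V_p$, $V_u$ for its pooled-null and unpooled-alternative variances at the
study's case:control allocation, power at total size $N$ is
$\Phi(|\Delta|\sqrt{N/\bar V} - z_{\alpha/2}) +
\Phi(-|\Delta|\sqrt{N/\bar V} - z_{\alpha/2})$ with the symmetrised
variance $\bar V = (V_p + V_u)/2$. The two-proportion literature variously
uses $V_p$, $V_u$ or a mixed form, and the choice moves required sample
sizes by a factor of up to ~2.8 at these extreme significance levels; the
symmetrised form is the convention that reconstructs the sample sizes
printed by the epidemiological calculators this module mirrors, and both
tails are included so that $\mathrm{OR} = 1$ returns exactly $\alpha$.
Required N is found by bisection at fixed case fraction (rounded up);
"population sample size" throughout means total cohort size at the
study's observed case fraction.

Two caveats are deliberate and documented rather than hidden. First, the
planning deviate is *conservative* relative to the realized power of a
logistic Wald test on data actually drawn from the assumed two-binomial
design: a Wald test at the planned N typically exceeds the target power.
The package therefore ships a Monte-Carlo arbiter
(`mc_power_contrast()`) that simulates the design the formula assumes and
applies the same contrast statistic; the analytic power agrees with it to
well within 0.03. Second, under *prospective* (population) sampling — the
synthetic-data module's generative model, where the cohort-wide MAF is the
population MAF — the information about a rare recessive effect is lower
still, because the retrospective parametrisation implicitly enriches
homozygotes beyond what a population cohort contains. Planned sizes are a
design convention, not a guarantee about any particular sampling scheme.

```{r power-example}
sp <- power_spec("recessive", maf = 0.036, or = 4.32,
                 n_cases = 6967, n_controls = 49670)
sample_size_for_power(sp)
power_case_control(sp, 67611)
```

## The synthetic cohort generator

The generator emulates a large age-related-disease cohort: independent
variants drawn at Hardy-Weinberg genotype frequencies at specified MAFs
(X males as 0/1 hemizygotes, stored homozygote-coded); binary disease from
a prospective logistic model whose linear predictor applies each variant's
$\ln \mathrm{OR}$ on its declared inheritance coding, the intercept solved
by root-finding so the expected case fraction hits its target; sex
Bernoulli(0.5), age uniform 40-90, optional standard-normal PCs. One
generative mechanism serves association testing, calibration checks and
power checks alike. Per-panel imputation noise draws each sample's triple
from a Dirichlet with concentration $1 + \kappa$ on the true genotype and
0.5 elsewhere — a smooth interpolation from uninformative ($\kappa = 0$)
to hard calls ($\kappa \to \infty$; capped at $10^6$) — and panel coverage
predicates remove variants a panel does not impute (e.g. indels). A single
seed fixes all randomness; sex is drawn off the genotype stream so the two
are independent.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: linkage disequilibrium between variants,
population structure and relatedness, genotyping batch effects,
phenotype misclassification, and imputation error that is correlated
across samples (Dirichlet noise is independent per sample, so info scores
are optimistic about structured error).

## Numerical choices and test problem sizes

Degenerate inputs are handled explicitly: monomorphic variants are
dropped before fitting; constant dosage vectors give missing $R^2$/LD;
all-missing triples give a missing info score; empty MAF bins report a
missing percentage with a zero count; ABF requires a positive SE; the
sample-size search errors above a $10^9$ cap. Ties are always broken
deterministically (panel priority, genomic position, model order).

The test suite runs the statistical property checks at reduced but
adequately powered sizes chosen for a desktop run: type-I calibration
over 5,000 simulated null variants of 2,000 samples; effect-size recovery
over 60 replicates of 8,000 samples per model; recessive-vs-additive
detection over 12 replicates of 57,000 samples at the type-2-diabetes
locus configuration; credible-set coverage over 40 replicates of 8,000
samples with six LD proxies; panel-combination dominance over ~10
replicates of 3-panel cohorts. The acceptance script's sample-size
figures are analytic and deterministic.

## Known limitations

* Variants are treated as independent everywhere except the explicit LD
  computation in fine-mapping; there is no haplotype model.
* The association engine is plain logistic regression — no mixed models
  or saddle-point correction for extreme case-control imbalance.
* Only biallelic variants are supported; multiallelic VCF records are
  skipped.
* The power module covers additive, dominant and recessive designs; the
  heterodominant and genotypic models have no closed-form planning
  convention here.
* BGEN binary input is not implemented; GEN/SAMPLE and VCF GP/DS are.
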