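---
title: "Methods: the reanalysis engine, its metrics, and the synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the reanalysis engine, its metrics, and the synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reanalyzr)
```

## The diagnostic model

`reanalyzr` scores every disease in a curated knowledge base against two
streams of evidence: the patient's clinical findings and the gene
zygosities deduced from a trio variant table. The model is deliberately a
naive-Bayes posterior,

$$P(d \mid E) \;\propto\; I_d \prod_{f} L(f \mid d) \prod_{z} L(z \mid d),$$

with the disease incidence $I_d$ as prior. Conditional independence of
findings given the disease is the strongest assumption here; it is the
minimal model that supports every behavior the engine needs — pertinent
negatives that *lower* a disease, onset information, incidence priors, and
cheap leave-one-out recomputation. Findings in real diseases co-occur
(a syndrome's facial features are not independent), so the posterior is
best read as a well-calibrated *ranking* rather than a calibrated
probability.

Likelihood terms:

* **Associated finding**, frequency $f$ in affected individuals: $f$ when
  present, $1-f$ when absent. A present finding whose onset falls outside
  the association's onset window is multiplied by `epsilon_onset`
  (default 0.1). Onset is a single `[earliest, latest]` window in decimal
  years — the minimal testable representation of "frequency **and onset**
  are curated".
* **Unassociated finding**: the finding's population `background_rate`
  when present, its complement when absent. Requiring a background rate
  per finding is what lets a pertinent negative discriminate: absence of a
  hallmark finding costs a disease $1-f$ while costing every other disease
  only $1-\text{background}$.
* **Gene zygosity**: if the disease links the gene *with the same
  inheritance class*, the likelihood is
  $\lambda_{\min} + (\lambda_{\max}-\lambda_{\min})(s/5)\pi$ with severity
  $s \in [0,5]$ and penetrance $\pi$; otherwise the constant false-positive
  rate $\varphi$. $\varphi$ (default 0.01) encodes that healthy exomes
  carry incidentally damaged genes; because it is the *same* for every
  non-linked disease, a zygosity in an unlinked gene shifts nothing and
  earns zero pertinence.

Accumulation is in log space with a max-subtraction guard; no disease is
ever truncated from the differential, however small its posterior, so
leave-one-out distances are always over the identical disease set. Ties in
every ranking break lexicographically (disease, item or test identifier)
for deterministic output.

### Tunable constants

| constant | default | meaning |
|---|---|---|
| `lambda_min`, `lambda_max` | 0.05, 0.95 | zygosity-likelihood calibration range at severity 0 and 5 |
| `phi` | 0.01 | likelihood of an incidental damaged-gene zygosity |
| `epsilon_onset` | 0.1 | out-of-window onset down-weight |
| `af_multiplier` | 1 | slack on the incidence-derived allele-frequency threshold |
| `min_depth` | 10 reads | below this, a zygosity is flagged `low_depth` |
| severity table | lof 5, damaging missense 3, benign missense 1, synonymous / noncoding 0.5, other 1 | consequence-class base scores |

The severity base scores are a package choice: only the 0–5 scale itself
is externally fixed. `known_pathogenic` annotations force severity 5. For
monoallelic and X-linked calls the gene severity is the maximum allele
score; for biallelic calls it is the mean of the top two allele scores
(a homozygote contributes its score twice), reflecting that a recessive
mechanism needs both alleles damaged.

## The two ranking metrics

**Pertinence** of an ascertained item (finding *or* zygosity — they are
normalized jointly) is the total variation distance between the full
differential and the differential recomputed without that item, expressed
as a percent of the maximum over all items. Total variation was chosen as
the distance because it is bounded in $[0,1]$, symmetric, and makes the
100%-normalization well behaved; the distance function is an argument of
the internals, so rank-based alternatives can be substituted for
sensitivity studies. When every raw distance is zero (a completely flat
effect) all percents are defined as 0 — no division by zero.

**Usefulness** of a candidate test $t$ is
$\sum_o P(o \mid \text{current}) \cdot
\mathrm{TV}(\text{current}, \text{updated with } o)$ over the test's
outcomes: present/absent for findings, and for gene tests a binary
"matching-class zygosity found at severity 5 / not found". The binary gene
outcome is the smallest outcome space that reproduces the key clinical
behavior: when the phenotype strongly supports a disease whose gene has
*no* variants in the table, that gene tops the recommendation list —
which is how a deletion or non-coding variant invisible to the exome
pipeline gets flagged for targeted follow-up.

The implementation computes leave-one-out posteriors by subtracting the
item's log-likelihood column from the accumulated log posterior; the test
suite holds it to agreement within $10^{-12}$ with a brute-force oracle
that rebuilds the inputs and recomputes the differential from scratch for
every left-out item.

## Zygosity calling rules

Per gene, from proband/mother/father alt-allele dosages:

* single autosomal het: monoallelic; de novo iff both parents are
  genotyped reference, `unknown` if a needed parent is missing;
* homozygous alt: biallelic; neither genotyped parent carrying yields flag
  `biallelic_without_carrier_parents` (the signature of a false-positive
  call cluster), exactly one carrier among two genotyped parents yields
  `transmission_inconsistent`;
* two hets with distinct parental origins: biallelic in trans; both from
  the same parent: presumed cis, called monoallelic with flag
  `possible_cis_pair`; origins unresolvable (missing parent, both parents
  carriers): biallelic with `phase_unknown`;
* chrX in a male proband: X-linked hemizygous, de novo status from the
  mother alone. Female chrX variants follow the autosomal classes, so an
  `x_linked` gene link matches hemizygous males — the configuration the
  inheritance mode describes;
* read depth below `min_depth` in any supporting genotype: `low_depth`.

Ambiguities always become flags, never silent drops: the clinician, not
the caller, dismisses a flagged zygosity. The full rule set is pinned by
an exhaustively enumerated truth-table oracle over all trio dosage
combinations, both chromosome types, both sexes, and missing-parent
patterns.

The frequency filter retains a variant iff its population allele frequency
is missing or $\le$ `af_multiplier` $\times \max_d \hat q(d)$ over the
diseases linked to its gene, with Hardy–Weinberg expectations
$\hat q = I$ (monoallelic, X-linked male incidence) or $\sqrt I$
(biallelic). With full penetrance these are upper bounds on a pathogenic
allele's frequency; the multiplier absorbs reduced penetrance and
prevalence/incidence slack. Genes without knowledge-base links are never
filtered (no expectation exists), and the boundary value is retained —
only variants *exceeding* the expectation are ignored.

## The synthetic cohorts

The simulator generates trio cases with known ground truth at the regimes
reported for clinical pipelines: spurious de novo calls per trio are
Poisson with mean 3.2 (BAM-aware joint calling), 71 (separate calling with
BAM access) or 406 (single-sample VCFs only); incidental damaged-gene
zygosities in disease-linked genes default to Poisson mean 18.6. Further
choices, each made once on field-plausibility grounds:

* A spurious de novo call lands in a disease-linked gene with probability
  0.25 — roughly the fraction of genes with a convincing disease
  association among all exome genes — so de novo noise creates *real*
  competing zygosities and recovery genuinely degrades as the noise mean
  rises.
* Incidental zygosities are class-matching compound heterozygotes 30% of
  the time (carrier couples exist), otherwise single inherited carrier
  alleles; noise consequences are weighted toward low severity.
* Phenotypes are Bernoulli draws from the true disease's association
  frequencies, thinned by `finding_dropout`; at least one positive is
  always kept, because a patient is ascertained when something presents.
  Pertinent negatives are sampled preferentially from findings frequent in
  competitor diseases, emulating how a clinician records discriminating
  negatives.
* The **causal-free arm** (`include_causal = FALSE`) models unsolved
  cases: the phenotype is still drawn from a real disease but that
  disease's gene is withheld from the variant table entirely. This is both
  the "unsolved" contrast arm and the fixture for the absent-gene
  recommendation scenario.
* Single-parent cases (default rate 0.1) lack the father; de novo status
  becomes `unknown` where his genotype is needed, and the de novo count
  summary averages full trios only.
* Fixture knowledge bases are generated programmatically (log-uniform
  incidences $10^{-6}$–$10^{-4}$, beta-distributed association
  frequencies, 5–12 associations per disease, 85% of diseases monogenic
  across the three inheritance modes). They emulate the *shape* of a
  curated diagnostic database at desk scale — they contain no real
  disease content.

What passing on these cohorts does **not** show: performance against a
real curated knowledge base (orders of magnitude larger, with correlated
findings and a curated finding hierarchy), robustness to phenotype noise
beyond independent dropout (no wrong findings, no granularity mismatches),
or behavior on CNVs and non-coding variants, which the table format here
does not carry. The simulator's unsolved arm idealizes undiagnosed
patients as "true disease not representable in the table"; real
undiagnosed cohorts also contain atypical presentations of representable
diseases.

## Problem sizes and determinism

The shipped checks run 30-disease/40-finding knowledge bases with cohorts
of 40–100 cases (oracle-equivalence checks use 100 randomized
10-disease/15-finding instances), sizes chosen so the whole suite
completes in minutes on a single core while keeping the noise regimes at
their full means (up to ~420 variants per case at the 406 regime). All
randomness flows from explicit integer seeds through R's default RNG;
per-case seeds are derived arithmetically from the cohort seed, so cohorts
are reproducible case-by-case and independent of iteration order.

## Known limitations

* Naive Bayes ignores finding correlations and can over-concentrate the
  posterior; pertinence percents inherit that sharpness.
* Penetrance is carried on gene links but defaults to 1; no mosaicism
  model (a mosaic parent will look like `transmission_inconsistent` or a
  false de novo).
* One zygosity per gene: when monoallelic and biallelic readings are both
  plausible the engine emits the single most severe consistent call and
  flags the ambiguity, rather than scoring both.
* Finding granularity is flat: a specific finding bundled under a broader
  one in the knowledge base dilutes specificity, and nothing in the engine
  can recover it.
* The gene-test outcome model for usefulness is binary; a graded outcome
  space (severity, zygosity class) would refine the expected-change
  estimate for recessive diseases in particular.
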