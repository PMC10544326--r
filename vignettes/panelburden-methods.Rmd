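---
title: "Methods: rare-variant burden, Firth association, and cumulative risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant burden, Firth association, and cumulative risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelburden)
```

panelburden implements the analysis chain of a panel-sequencing case-control
study of breast cancer susceptibility: variant classification, carrier-burden
tabulation, penalized-likelihood association testing, and absolute-risk
estimation. This vignette documents the models, the tunable parameters, the
numerical choices, and the limits of what the synthetic-data tests can show.

## Variant classification

Each row of an annotated variant table (one row per subject x variant,
ANNOVAR-style consequence vocabulary) is mapped to one of three categories by
an ordered rule list:

1. **Excluded gene.** Genes analysed but removed from association work; the
   default is PPM1D, whose truncating variants arise largely as somatic
   mosaicism and therefore do not reflect germline risk.
2. **Out-of-scope consequence.** In-frame insertions/deletions, intronic,
   UTR, and synonymous rows are never analysed.
3. **Protein-truncating variants (PTVs).** Frameshift indels, nonsense
   (stop-gain) variants, and canonical +/-2 splice variants. Three
   refinements: variants in a transcript's *last exon* are excluded (the
   truncated product usually escapes nonsense-mediated decay); *splice
   variants in the penultimate exon* are excluded except in genes where the
   truncated protein is still expected to be pathogenic (default exception
   set ATM, BARD1, BRCA1, RAD51C, RAD51D, PALB2 — the published exception
   list prints RAD51C twice, which we read as RAD51C and RAD51D; the set is
   configurable); and a named list of splice variants of uncertain clinical
   significance (six canonical BRCA1 splice variants under ENIGMA
   classification) is excluded explicitly.
4. **Rare missense.** Missense rows are kept when the gnomAD non-Finnish
   European allele frequency is below 0.001 and the clinical classification
   is not benign or likely benign. Rows with *unknown* allele frequency are
   kept — absence from gnomAD implies rarity — but flagged (`af_unknown`)
   for audit. Rare missense variants classified pathogenic remain in the
   scan set (none occurred in the emulated study) and can be filtered by the
   caller.

Splice +/-2 membership is taken from the upstream annotator's consequence
term; the package deliberately does not re-derive splice distances from
genomic coordinates, which are out of scope. Classification of a row depends
only on that row and the configuration, so results are order-independent; the
test suite checks every row of a randomized fixture against an independently
coded rule oracle.

Retained missense variants are annotated with the functional protein domain
(UniProt-style residue intervals, 1-based inclusive, validated for
non-overlap within a gene) containing their residue, enabling domain-level
burden scans.

## Carrier burden and stratification

Classified variants collapse to a subjects x units binary carrier matrix
(units are genes, or gene:domain pairs for missense). A subject carrying any
number of qualifying variants in a unit scores 1; heterozygous and homozygous
carriers are not distinguished, matching the emulated study's analysis.
Prevalence tables report per-unit and gene-set carrier counts and
percentages (100 x carriers / group size); the "established" set aggregates
ATM, BARD1, BRCA1, BRCA2, CHEK2, PALB2, RAD51C, RAD51D and TP53, counting
each subject once. Percentages are stored at full precision and rounded only
for presentation. Because the published table's total row counts variant
observations while its text counts carrier subjects, `tabulate_prevalence()`
reports both per-unit rows and an `any_unit` subject-level row, exposing
rather than resolving such discrepancies.

Stratification helpers partition subjects by first-degree family history, by
an age cut (default 50 years; the boundary is assigned to the upper stratum
by default, `< 50` vs `>= 50`, and is configurable because the emulated study
did not define the boundary side), and by tumour receptor subtype. The
triple-negative subset is defined only for cases with all three of ER, PR
and HER2 observed. Subjects missing a stratifier are dropped and reported.
Group-location comparisons wrap the two-sided Wilcoxon rank-sum and two-sample
t tests; proportion comparisons default to Fisher's exact test (the emulated
study did not name its test; we report the method used).

## Firth penalized-likelihood logistic regression

Carrier counts in rare-variant studies are small, and zero cells (e.g. no
carrier controls) make ordinary maximum likelihood diverge (separation). The
association engine therefore maximizes the Jeffreys-prior-penalized
log-likelihood

$$\ell^*(\beta) = \ell(\beta) + \tfrac12 \log \det I(\beta), \qquad
I(\beta) = X^\top W X,\; W = \mathrm{diag}\{\pi_i(1-\pi_i)\},$$

by Newton-Raphson on the modified score

$$U^*_r(\beta) = \sum_i \left( y_i - \pi_i + h_i(\tfrac12 - \pi_i) \right) x_{ir},$$

with $h_i$ the hat diagonal of the weighted least-squares representation.
This penalty guarantees finite estimates on any full-rank design, including
fully separated data.

Numerical choices (the published analysis specifies none):

* convergence when $\max_r |U^*_r| <$ `tol` (default `1e-6`), with up to 100
  iterations and 25 step-halvings whenever a step fails to increase
  $\ell^*$;
* a secondary stopping rule declares convergence when a full Newton step
  changes no coefficient by more than `xtol` (default `1e-6`): on designs
  with thousands of rows and covariates of magnitude ~50 (age in years),
  rounding noise floors the score sum near `2e-6` and the iteration
  otherwise oscillates at amplitude ~`1e-7` around the optimum without
  formally meeting `tol`. Since the step is still taken, the remaining error
  is far below reporting precision. The solver is verified against direct
  numerical maximization of $\ell^*$ (gradient-free BFGS plus Newton
  polishing on numerical derivatives) to `1e-6` per coordinate on random
  small designs;
* the covariance is the inverse penalized information at the optimum, and
  inference is Wald: $\mathrm{OR} = e^{\beta_j}$ with
  $e^{\beta_j \pm 1.96\,SE_j}$ intervals and two-sided normal p values. The
  published intervals are log-symmetric around the odds ratio (e.g. 9.75
  with 1.81–52.69), which is consistent with Wald rather than
  profile-penalized-likelihood intervals; profile intervals are not
  implemented.

Association scans fit one model per unit and outcome: case status on carrier
status, adjusted by default for age (continuous, in years — the published
analysis does not state whether age was banded, and continuous adjustment is
the parsimonious reading) and first-degree family history. Subtype-specific
outcomes (ER-positive, ER-negative, triple-negative) compare subtype cases
against the full control group. Subjects missing an adjustment covariate or
a required marker are dropped listwise per fit, and per-fit carrier counts
and convergence diagnostics are echoed. No multiple-testing correction is
applied, matching the emulated study's fixed 0.05 threshold; scans return
raw Wald p values and callers can `p.adjust()` as desired.

The age trend of the odds ratio is modelled by adding a carrier x age
interaction with age centred at a reference (default 50 years):
$\mathrm{OR}(t) = \exp(\beta_c + \beta_{int}(t - t_{ref}))$. The per-year
multiplier $e^{\beta_{int}}$ is invariant to the reference choice; only the
carrier main effect re-anchors.

## Cumulative (absolute) risk

Carrier cumulative risk combines the age-specific odds ratio with a
population incidence table (piecewise-constant rates on 5-year bands,
contiguous from age 0) under the rare-disease approximation RR ≈ OR. The
constrained-incidence recursion maintains disease-free survivor fractions
$S_1$ (carriers) and $S_0$ (non-carriers), both 1 at age 0, and in each band
solves for the non-carrier hazard that makes the survivor-weighted mixture
reproduce the population rate:

$$\lambda_0(t) = \lambda_{pop}(t)\,
\frac{f S_1(t) + (1-f) S_0(t)}{f S_1(t)\,RR(t) + (1-f) S_0(t)},
\qquad \lambda_1(t) = RR(t)\,\lambda_0(t),$$

followed by $S \leftarrow S\, e^{-\lambda \Delta t}$. Cumulative risk is
$F(T) = 1 - \exp(-\sum_{t<T} \lambda(t)\Delta t)$. The mixture identity holds
to machine precision in every band and the recursion is validated against a
discrete-time population simulation. Competing mortality is ignored ("risk in
the absence of other events"), and a validity note is emitted when band
incidence x RR x width exceeds 0.1, where RR ≈ OR is strained. Confidence
bands re-run the whole recursion at the odds ratio's interval bounds
(plug-in propagation — the construction achievable from reported intervals;
no resampling). The carrier frequency at birth `f` defaults, in the
pipeline, to the control carrier frequency of the unit. The published
recursion is cited "as previously described" without restatement; the scheme
above is the standard constrained-incidence recursion with survivor-fraction
feedback and is flagged as such.

The threshold report labels each curve against the 30%-by-age-80
surveillance threshold used by NICE guidance.

## The synthetic cohort generator

No individual-level data from the emulated study are distributable, so the
generator emulates its design: a source population receives per-gene carrier
indicators and disease status from a logistic model, and fixed numbers of
cases and controls are sampled (retrospective design, making the logistic
odds ratio the estimand). Defaults reproduce the study's marginals: 990
cases and 1,094 controls; family history 16.2% vs 8.0% with the study's
missingness; banded age distributions per group; receptor status for cases
only, ER drawn first and PR/HER2 conditionally on ER with rates chosen to
approximate the reported marginal positivities (75.8% / 61.6% / 16.1%) and
triple-negative fraction (~11.5%); per-gene carrier frequencies and odds
ratios following the per-gene carrier counts and estimates, including a
BRCA2 founder variant carried by ~55% of BRCA2 carriers.

Design choices worth recording:

* **Configured frequencies are control frequencies.** Because carriers are
  depleted among the non-diseased when OR > 1, the generator converts the
  configured control carrier frequency to the implied source-population
  frequency ($\mathrm{odds}_{pop} = \mathrm{odds}_{ctrl}(1 + o_0
  \mathrm{OR})/(1 + o_0)$ with $o_0$ the baseline disease odds) so realized
  control frequencies match the configuration.
* **Two age modes.** In the default `"table"` mode, ages are re-drawn per
  group from the banded distributions after sampling, reproducing the
  study's age structure exactly in expectation; this is valid because
  carriers are independent of age when no interaction is configured. The
  `"model"` mode draws age in the source population and enters it (and any
  carrier x age interaction) in the disease model; it is required for
  age-trend simulations and enforced when `log_or_age` is non-zero.
* **One RNG stream per table**, derived from the master seed, so adding one
  output does not perturb the others; identical configuration and seed give
  byte-identical tables.
* **Decoy rows** exercise every exclusion rule (last-exon PTVs, penultimate
  splice variants with and without the exception, the six named BRCA1 splice
  variants, common and benign missense, in-frame/UTR/intronic/synonymous
  rows, PPM1D) without ever altering qualifying carrier status.
* The `bc_like` incidence preset is an age-increasing rate vector whose
  cumulative population risk to 80 is ~8%, within the 5–15% range typical of
  female breast cancer; the incidence table the emulated study used is not
  distributable, so absolute risk figures are comparable only qualitatively.

What the generator does **not** emulate: linkage between variants, within-
family correlation, genotyping or calling error, the age-matching algorithm
of the original sampling frame (only marginal band frequencies are matched),
and correlation between family history and carrier status (family history is
drawn independently of carriers, so covariate adjustment shifts estimates
only through sampling noise). Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to those real-data features.

## Calibration study conditions

The test suite's simulation studies use these problem sizes, chosen to
balance Monte-Carlo precision against a default test run of a few minutes:

* type-I error of the Wald test: 1,000 replicates at study scale with a null
  gene at control carrier frequency 0.05 (~100 carriers) — the regime where
  the Wald normal approximation applies. At sparse counts (frequency 0.01,
  ~20 carriers) the test is **conservative** (empirical size ~0.02 at
  nominal 0.05); a dedicated test asserts it never exceeds nominal there.
* confidence-interval coverage and estimate distribution: 500 replicates of
  a founder-like gene (control frequency 9e-4, OR 9.75). Coverage sits near
  0.95. The *median* estimated OR at these counts (~8.5 case and ~1 control
  carriers expected) is ~7.6: the Firth penalty reduces the mean bias of the
  log-odds coefficient, not the median bias of the odds ratio, and at such
  counts its median shrinkage is substantial. Consistency is demonstrated
  separately: a single large cohort (10^6 subjects) recovers the generating
  odds ratio closely.
* age-trend recovery: one cohort of 50,000 subjects with a generated
  per-year multiplier of 0.94, and 200 null replicates at study scale for
  interval coverage of 1.0.
* risk recursion: cross-checked against binomial-count population
  simulations of 10^6–10^7 individuals (equivalent to individual-level
  simulation, band by band).

## Known limitations

* Domain-level scans require the domain map to cover the residues of
  interest; unmapped residues are reported with no domain and excluded from
  domain units.
* Exact reproduction of the emulated study's *adjusted* odds ratios is
  impossible from published tables (individual covariates unavailable);
  only unadjusted 2x2 penalized estimates are exactly checkable from
  printed counts, and the package's parameter-recovery suites substitute
  for the rest.
* Profile-penalized-likelihood intervals, mixed models, polygenic scores and
  meta-analysis are out of scope.
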