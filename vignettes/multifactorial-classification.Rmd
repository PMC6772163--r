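---
title: "Multifactorial likelihood classification of BRCA1/2 variants: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifactorial likelihood classification of BRCA1/2 variants: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfclass)
```

## The model and its assumptions

`mfclass` implements the quantitative framework used by expert panels to
classify rare *BRCA1*/*BRCA2* variants. Each clinical evidence type —
co-segregation with disease, breast tumour pathology, co-occurrence in
trans with a known pathogenic variant, reported family history, and
case-control carrier counts — is summarised as a likelihood ratio (LR)
comparing a *pathogenic* hypothesis (the variant behaves like a classical
high-risk allele) with a *neutral* one. The core assumption is conditional
independence of evidence types given pathogenicity status, so LRs multiply,
and the combined LR updates a bioinformatic prior in odds form:

$$\mathrm{posterior} = \frac{p \cdot \mathrm{LR}}{p \cdot \mathrm{LR} + (1-p)}.$$

Two framing consequences are worth keeping in mind. First, the model is
calibrated for *high-risk* alleles: a moderate-risk variant can sit
persistently near the middle of the scale and no amount of data will move
it cleanly to either end. Second, because the prior comes from bioinformatic
prediction of protein/splicing effect, mechanisms invisible to those
predictors (e.g. exonic splice-enhancer loss) can produce confidently wrong
priors; the quantitative machinery cannot rescue a mis-specified prior.

### Gate, classes and boundary policy

Combined LRs strictly inside (0.5, 2) are treated as insufficient data: no
posterior is computed (`is_informative()`). The interval is **open** —
values of exactly 0.5 or 2 are informative — because reference datasets
contain classified variants with combined LRs barely above 2.

Posterior cut-offs follow the IARC five-tier scheme. The published wording
("Class 3: 0.05–0.949") leaves 0.949–0.95 undefined; we close every band
below: C5 $(0.99, 1]$, C4 $[0.95, 0.99]$, C3 $[0.05, 0.95)$, C2
$[0.001, 0.05)$, C1 $[0, 0.001)$. Whether any real variant ever lands in
0.949–0.95 is unknowable from the published record; the policy is flagged
here rather than hidden.

### Prior assignment

`assign_prior()` takes the maximum of the available protein-level and
splicing priors. In-frame deletions, which substitution-based predictors do
not score, take the highest per-deleted-base prior in place of the
protein-level one.

## Co-segregation Bayes factor

`family_segregation_lr()` computes, per family,
$P(\text{data} \mid \text{causal}) / P(\text{data} \mid \text{neutral})$
with untyped genotypes marginalised by Elston–Stewart style peeling
(variable elimination in reverse topological order, which on loop-free
pedigrees peels nuclear-family cliques; a test-suite oracle checks it
against exhaustive enumeration to $10^{-10}$).

**Genotype model.** Rare autosomal dominant, two states per person
(noncarrier / heterozygous carrier). Founders are carriers with probability
$2f$ ($f$ = variant allele frequency, config); a carrier parent transmits
with probability 1/2; homozygotes are ignored as negligible for rare
variants. Consanguineous matings are rejected with a clear error; other
marriage-structure loops are handled exactly by the elimination.

**Penetrance.** Piecewise-constant per-year hazards over seven age brackets
(<30, 30–39, …, 70–79, 80+, the last capped at 105 years), per cancer type
(female breast, ovarian, optionally male breast), multiplied by per-bracket
hazard ratios for carriers. An unaffected member censored at age $c$
contributes $\exp(-H_{\text{all}}(c))$. A member affected with type $t$ at
an age in bracket $b$ contributes the exact competing-risks probability

$$S_{\text{all}}(\text{start}_b)\cdot
  \frac{h_t}{h_{\text{tot}}}\bigl(1 - e^{-h_{\text{tot}} w_b}\bigr),$$

which reduces to the familiar "survive earlier brackets, event in bracket"
form when only one type has positive hazard. We use the competing-risks
form because the synthetic-data generator draws independent event times per
type and takes the minimum; making the likelihood the exact sampling
probability of the generated (bracket-coarsened) data is what lets the
neutral-hypothesis martingale test demand mean LR = 1 *exactly* rather than
approximately.

**Conventions.** Ovarian cancers diagnosed before 30 use the 30–39 bracket
hazard (the youngest ovarian penetrance class is too sparse to estimate);
affected members without a diagnosis age fall back to 45 (midpoint of the
40–49 bracket); non-breast/ovarian cancers censor at their diagnosis age;
male breast cancers censor at diagnosis when no male hazard is configured;
unaffected members without any usable age contribute likelihood 1 with a
warning. Unaffected members are censored at the earliest of last-observed
age and prophylactic-surgery age, with the genotyping-test date standing in
when no last-observed age was recorded.

**Ascertainment.** Families reach a classification programme through an
affected carrier index case, so both hypothesis likelihoods are divided by
the marginal probability of the proband's own genotype-and-phenotype data
(the proband's factors cancel). This single-ascertainment correction is the
main under-specified choice in the published pipelines; it is isolated in
one internal function (`hypothesis_likelihood`) so alternative schemes can
be swapped in. Eligibility requires at least two genotyped members
including a carrier proband.

**Penetrance numbers.** Published penetrance and hazard-ratio estimates are
not redistributed here. `inst/extdata/penetrance_placeholder.tsv` carries
order-of-magnitude values (e.g. female breast baseline rising from
5×10⁻⁵/yr before 30 to 3×10⁻³/yr after 70; carrier hazard ratios 20 down
to 3 with age; ovarian hazard ratios peaking at 30 in mid-life; allele
frequency 5×10⁻⁴) chosen once to resemble a high-risk breast/ovarian
predisposition gene. Every test and simulation is relative to this config;
users must substitute published estimates for real classification.

## Other evidence components

- **Pathology** (`pathology_lr`): the first-diagnosed tumour with any
  informative marker gets exactly one LR, keyed by the richest information
  level with table entries (ER+grade, ER only, grade only), the marker
  pattern, and an age band (<50 / ≥50). The shipped table is a placeholder
  for published estimates.
- **Co-occurrence** (`cooccurrence_lr`): binomial LR
  $((1-\theta_P)/(1-\theta_N))^{n-k} (\theta_P/\theta_N)^k$ for $k$
  observed in-trans co-occurrences among $n$ tested carriers; with
  $\theta_P \ll \theta_N$, absence of co-occurrence mildly supports
  pathogenicity. This is a documented reconstruction of the form used in
  the cited prior literature; both probabilities are config.
- **Family history** (`family_history_lr`): a pass-through lookup of
  externally calibrated category LRs; `"none_supplied"` omits the
  component.
- **Case-control** (`case_control_lr`): a profile likelihood ratio. Under
  the pathogenic hypothesis the case carrier frequency is the rare-disease
  enrichment $q' = rr\,q/(rr\,q + 1 - q)$ of the population frequency $q$
  at the gene's assumed relative risk; $q$ is maximised out under each
  hypothesis. The construction is finite for degenerate counts (no
  carriers anywhere gives exactly 1) and identically 1 at $rr = 1$.
  Ethnic strata are computed separately and multiplied.
- **Population frequency** (`frequency_category`): categories from the
  highest minor allele frequency across five outbred reference populations
  (exome+genome tranches summed): not observed / single observation (one
  allele total) / (0, 10⁻⁴) / [10⁻⁴, 0.01). Variants absent from the
  outbred sets but present in the Finnish or Ashkenazi founder sets are
  excluded from frequency-LR work (any founder allele count ≥ 1 — the
  published rule mentions only a single observation and we generalise).
  MAF > 0.01 in any outbred population is stand-alone benign evidence
  (`baseline_common_class1`, strict inequality).

## Calibration of qualitative evidence

`crosstab_lr()` turns a cross-tab of (Likely) Benign vs (Likely) Pathogenic
reference variants per evidence category into an LR towards pathogenicity,
$(a/n_1)/(c/n_2)$, with a 95% log-scale Wald interval
$\exp(\ln LR \pm 1.96\,\mathrm{SE})$,
$\mathrm{SE} = \sqrt{1/a - 1/n_1 + 1/c - 1/n_2}$. The CI formula is not
stated in the published tables; the log-Wald form was adopted because it
reproduces every published interval from the published counts.

Zero cells are conservatively replaced by a single observation, in both the
proportion and the SE (flagged in the output). In a **two-category** table
the borrowed observation is taken from the complementary cell of the same
arm in the point estimate only, so within-arm proportions still sum to one
(this is what the published two-category splicing table does: 48/49 =
97.96%), while the SE keeps the raw complementary count. Multi-category
tables are not renormalised. Two display conventions mirror the published
reports: values print at two decimals, and a strictly positive bound that
would print as 0.00 prints as 0.01.

`acmg_strength()` maps LRs to ACMG/AMP code strengths: supporting
[2.08, 4.3), moderate [4.3, 18.7), strong [18.7, 350), very strong ≥ 350,
with benign bins at the reciprocals, mirrored so that $x \to 1/x$ flips the
direction and preserves the strength; LRs in (1/2.08, 2.08) are
uninformative. `inverse_lr()` restates an estimate in the benign direction
(reciprocal point estimate, swapped reciprocal bounds). Note one printed
artifact in the published record: the benign-direction interval quoted in
the text was formed from *rounded* direct bounds (1/0.32 = 3.12); full
precision inversion gives 3.13 and the package reports full precision.

`concordance_table()` tabulates internal class groups (LB = C1∪C2, VUS =
C3, LP = C4∪C5) against external assertion lists with at-least-one
semantics, counting externally absent variants separately.

## Synthetic data: what it emulates, what it does not

`simulate_pedigree()` emulates clinic families: three generations, sibship
sizes 1 + Poisson(2), founder genotypes at carrier frequency $2f$,
Mendelian transmission, phenotypes from the bracket-hazard model (carrier
hazard ratios applied only under the causal hypothesis), relatives
genotyped with configured probability.

Ascertainment is **exact-conditional** rather than literal
rejection-resampling: a proband position is fixed (uniformly among the
females), her genotype is clamped to carrier with ancestor genotypes drawn
from their exact Bayes conditional, and her diagnosis is drawn conditional
on preceding her current age. This is distributionally equivalent to
resampling the family until the chosen member is an affected carrier, but
costs O(1) draws even at realistic allele frequencies (where a literal
rejection loop would need ~10⁵ draws per family), and it makes the rest of
the family exactly model-conditional given the proband's data — which is
why the test suite can demand that the mean neutral-hypothesis family LR
equal 1 to within Monte-Carlo error (a martingale property), not merely
hover near it. Choosing the proband *after* seeing who is affected (the
literal reading) weights families by one over the number of affected
carriers and would bias that mean.

`simulate_evidence_cohort()` draws variants with true classes, assigns
evidence categories from class-conditional probability tables (so a
category's generating LR is known by construction), and attaches a single
lognormal component LR per variant whose class-separation is controlled by
an accuracy parameter. `simulate_population_frequencies()` constructs
allele-count tables realising each frequency category.

What a green test does **not** establish: the generators draw marker-free
phenotypes (no tumour pathology correlations), independent family
structures (no shared environment or polygenic background), no
mutation-spectrum realism, and no linkage disequilibrium. They validate the
statistical machinery, not the clinical calibration of any particular
penetrance table.

All generators take a mandatory seed and run in an isolated RNG scope (the
caller's RNG state is untouched).

## Numerical choices

- Peeling uses exact variable elimination over 2-state genotype variables;
  no loop-cutting (consanguineous pedigrees are rejected). Likelihood
  magnitudes in clinic-sized families stay far from double-precision
  underflow.
- The case-control profile maximisation uses `optimize()` on the nuisance
  frequency with the crude pooled MLE checked as a fallback start; a grid
  oracle in the tests agrees to 10⁻³.
- Reference-table reproduction is checked by interval arithmetic: published
  component LRs are rounded to two decimals, so the product's half-ulp
  interval is required to intersect the printed combined LR's half-ulp
  interval. A fixed relative tolerance (e.g. 0.1%) is provably wrong for
  rows with small components (a component of 0.18 carries ±2.8% print
  uncertainty on its own).
- The 80+ hazard bracket is capped at 105 years for event probabilities.

## Known limitations

- The ascertainment correction conditions on a single proband; families
  ascertained through multiple probands need a different correction.
- Male phenotypes beyond optional male breast cancer (prostate, pancreatic)
  are not modelled.
- No HGVS validation or genome coordinates: variant identifiers are opaque
  strings.
- Exact (Clopper–Pearson) intervals are deliberately out of scope; the
  Wald form is what the published calibration used.
- Duplicate submissions of the same family must be deduplicated upstream;
  the model assumes independent families.
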