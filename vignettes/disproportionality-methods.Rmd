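---
title: "Disproportionality methods for spontaneous-report signal detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods for spontaneous-report signal detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aesignal)
```

## The data and what can be asked of it

A spontaneous reporting system collects unsolicited case reports of
suspected adverse drug reactions. Each report names one or more drugs with
a role code (primary suspect `PS`, secondary suspect `SS`, concomitant `C`,
interacting `I`), a set of MedDRA preferred terms (PTs) describing the
reaction, demographics, and outcome codes. There is no denominator — nobody
knows how many patients took the drug without filing a report — so absolute
risks are not estimable. What is estimable is *disproportionality*: whether
a drug–event pair is reported more often than the rest of the database
would predict. That is a statistical screen, not a causal claim; every
positive signal needs clinical and epidemiological follow-up.

`aesignal` implements this screen end to end for OpenVigil/FAERS-style
tabular extracts, with the incretin-based antidiabetic classes (GLP-1
receptor agonists and DPP-4 inhibitors) versus biliary disorders as the
motivating application.

## Cleaning: versions of a case are not independent reports

FAERS cases are resubmitted as follow-ups under the same case identifier.
Counting versions as reports inflates every cell of every table, so
`deduplicate_reports()` keeps exactly one entry per case: the one with the
most recent FDA acceptance date, with date ties broken by the higher
per-entry identifier. The tie-break field is the per-entry identifier
(the `primaryid` analogue), not the case identifier: equality of the case
identifier is the rule's precondition, so the discriminating field must be
a different one. Identifier comparison is numeric when every identifier is
an all-digit string and lexicographic otherwise, which makes the operation
deterministic on any input; it is also idempotent, and both properties are
tested.

Window filtering (`filter_window()`, default `2013Q1`–`2024Q1`) keys on the
FDA acceptance date — the only date the extract schema carries — with both
boundary quarters included. Ingestion (`read_ae_reports()`) quarantines
malformed rows (unparseable dates, ages outside [0, 130], empty reaction
sets, duplicated entry identifiers, unknown codes) with a reason rather
than dropping them; quarantined rows travel with the collection and are
written out by the pipeline.

A report naming study drugs of both classes as primary suspect is retained
in both class cohorts; the pipeline logs how many such reports it saw.
Whether a case that names several study drugs should count once per drug or
once globally is a genuine ambiguity of report-level counting; the default
is per-case-global (a case contributes once to any table it enters), which
matches report-level cohort totals.

## The SMQ catalog

Standardized MedDRA queries group PTs for one medical condition area and
may nest. The biliary-disorder analysis uses a depth-2 tree: one root with
nine sub-queries (malignant tumours; benign neoplasms; investigations,
signs and symptoms; tract disorders; tumours of unspecified malignancy;
congenital disorders; gallbladder related; gallstone related; infectious).
A node's *effective* term set is the union of its own terms and all
descendants' terms, so membership rolls up monotonically: a report matching
a child matches every ancestor, and matches at most once per node however
many of its PTs are in the set.

MedDRA term lists are licensed and cannot be redistributed, so the package
bundles a synthetic catalog (`example_smq_path()`, marked `synthetic` in
its filename) with the study topology and invented-but-plausible PT lists;
the same plain-CSV schema accepts user-supplied real lists. Each term
carries a narrow/broad scope tag; because the scope used by the source
extraction tool is generally not recorded in study methods, the default
includes all terms and the choice is written into the run metadata.
Matching is exact string equality on case-folded, trimmed PT text — no
fuzzy matching, since PTs are a controlled vocabulary.

## The four statistics

All four summarise the same fourfold table, built by `contingency_table()`
with the report as the counting unit and exposure defined by the
primary-suspect role.

**ROR.** `(a/b)/(c/d)` with the Woolf interval
`exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`. With any zero cell the estimate or
interval is undefined; the default policy returns `NA` with a
`ror_defined = FALSE` flag (an undefined bound *fails* the signal
criterion), and a Haldane–Anscombe +0.5 correction is available as an
explicit option. The policy used is recorded in the output.

**PRR and χ².** `[a/(a+b)]/[c/(c+d)]` with its log-scale interval, and the
Pearson statistic `N(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)]` without continuity
correction by default — whether historical analyses applied Yates'
correction is usually unstated, so it is a flag rather than a default.

**BCPNN information component.** The posterior of the joint and marginal
reporting probabilities is taken as independent Beta distributions with
prior pseudo-counts `alpha1 = beta1 = gamma11 = 1`, `alpha = beta = 2`, and
the joint prior count tied to the margins so the prior IC is zero. The
closed forms are

$$E(IC) = \log_2 \frac{(n+\gamma_{11})(N+\alpha)(N+\beta)}
  {(N+\gamma)(n_{1.}+\alpha_1)(n_{.1}+\beta_1)}, \qquad
  \gamma = \gamma_{11}\frac{(N+\alpha)(N+\beta)}
  {(n_{1.}+\alpha_1)(n_{.1}+\beta_1)},$$

with the delta-method variance summing the three Beta variance terms, and
`IC025 = E(IC) − 1.96·√V(IC)`. Two points deserve honesty. First, $E(IC)$
is the log of a ratio of posterior *means*, not the posterior mean of the
log; the two differ by $O(1/a)$, which is negligible at database scale but
visible for small cells. Second, the variance is a first-order
approximation. The package therefore also provides a Monte-Carlo mode
(`bcpnn_ic(..., method = "mc")`) that samples the three Beta posteriors
directly; the validation suite checks the closed form against stratified
Monte-Carlo sampling at database-scale tables (joint cells in the hundreds
to thousands, margins in the tens of thousands), the regime where the
approximations are in their element and where the statistic is actually
used.

**MGPS / EBGM.** Each cell's count is modelled as
$n \sim \text{Poisson}(\lambda E)$ with expected count
$E = n_{drug} \cdot n_{term} / N$ from the unstratified report-level
margins (a stratification key is supported but off by default). The
reporting-rate ratio $\lambda$ has a two-component gamma-mixture prior
whose five hyperparameters are fitted by maximising the summed log marginal
likelihood (a negative-binomial mixture) over all drug–term cells of the
dataset. Numerics: parameters are optimised on the log/logit scale with
`nlminb` from the fixed start `(0.2, 0.1, 2, 4, 1/3)`, the two component
log-likelihoods are combined by log-sum-exp, and box constraints (shapes
and rates in $[10^{-6}, 10^{6}]$) keep the optimiser away from numerically
degenerate point masses. The fit is deterministic given the data, records
its evaluation trace, and errors on fewer than two cells.

Scoring a cell updates each component to `Gamma(shape + n, rate + E)` with
posterior weights proportional to the marginal likelihoods; the EBGM is the
posterior geometric mean $\exp(E[\ln\lambda])$ via the digamma identity,
and EBGM05 solves the posterior mixture CDF = 0.05 by bisection to relative
tolerance $10^{-8}$. The name EBGM05 denotes the 5th posterior percentile
(the MGPS convention), even though analyses sometimes gloss it as a "lower
95% CI bound"; the quantile is configurable (`ebgm_quantile = 0.025` gives
the two-sided-style bound) and the choice is written into the run metadata.

**Joint rule.** `evaluate_signals()` declares a positive signal only when
all four method-specific criteria hold (`n ≥ 3` and ROR lower bound > 1;
χ² ≥ 4 and PRR lower bound > 1; IC025 > 0; EBGM05 > 2). The conjunction is
pure: flipping any single criterion flips the decision, and an undefined
(`NA`) quantity fails its criterion.

## Descriptive layer

Percentages in distribution tables are rounded half-up to two decimals,
matching how such tables are conventionally typeset (base R's
round-half-even would differ on exact .005 boundaries). Age bands are
`<19`, `19–45`, `46–65`, `>65` with inclusive boundaries as written —
membership of the 45/46 boundary is a presentation choice the package makes
explicitly. Median ages are computed over known ages only, and an all-unknown
cohort reports the median as unavailable rather than a number.

The serious-outcome rule defaults to death, life-threatening,
hospitalization, disability, congenital anomaly, *plus* required
intervention: published class-level serious counts in this area equal the
five-code sums plus the required-intervention row, so the six-code rule
reproduces printed rates; the strict five-code variant is one argument
away. Rates across drugs are compared with the standard r×2 Pearson
chi-square (`chisq.test`, no continuity correction), df = r − 1.

Subgroup disproportionality crosses male/female with the four known age
bands; unknown sex or age is excluded from strata but retained in cohort
totals. Each stratum restricts *both* the exposed and the comparator
reports before rebuilding the table, so a stratum's comparator is its own
peers. Strata with no exposed-and-event report are returned as explicit
no-data rows. The MGPS prior is fitted once on the full dataset and reused
across strata (stratum-specific refits would be unstable at stratum sizes).

## The synthetic generator

`simulate_reports()` generates the study conditions: one primary-suspect
drug per report drawn from a weighted menu (ten study drugs at weights
echoing the two classes' report volumes and within-class shares, plus four
high-volume background drugs supplying the comparator mass); per-PT
independent Bernoulli reactions at menu baselines, multiplied by a spiked
rate ratio ρ for chosen (drug, PT) pairs; demographics from a sex table, a
two-component normal age mixture (means 55 and 72, clamped to [0, 120],
40% missing) and a US-heavy country table; outcomes via a latent
serious/non-serious class; acceptance dates uniform over the study window;
and a configured fraction of cases cloned as duplicate versions (same case
identifier, fresh entry identifier, later in-window date). The ground truth
(per-pair ρ, duplicate links, case count) is returned alongside, and
`expected_ror()` gives the closed-form odds ratio the configuration
implies, so recovery can be tested without circularity.

What the generator deliberately does *not* emulate: co-reporting
correlation between PTs (reactions are independent given the drug),
drug co-medication structure (exactly one suspect drug), reporting-rate
drift over calendar time, and country-specific reporting styles. Two
consequences matter for interpreting green tests. First, passing recovery
tests show the statistics work under clean independence, not that they
overcome confounding or stimulated reporting in real data. Second, the
generator's null cells are *exactly* multinomial-Poisson — real databases
are overdispersed — and an empirical-Bayes prior fitted to dispersion-free
data concentrates on the few reporting ratios actually present (in a
one-spike simulation, effectively a two-point prior at 1 and at ρ). That is
correct maximum-likelihood behaviour, not a defect; the engine-level
validation therefore fits priors on mildly overdispersed cells, the regime
real extracts occupy.

## Validation design and problem sizes

The suite validates each engine against an independent oracle: ROR/PRR/χ²
against textbook scalar formulas and `chisq.test` on 1000 random tables
(agreement to $10^{-10}$ relative); the closed-form IC against stratified
Monte-Carlo sampling of its Beta posterior ($10^5$ draws, 20
database-scale tables, 3 standard errors, with the moment functional
compared like for like as discussed above); EBGM and EBGM05 against
numerical quadrature of the posterior mixture (50 cells, 4 significant
digits); and the MGPS fit against simulation from a known single gamma
prior (5000 cells). On that last check: a two-component mixture fitted to
single-component truth is unidentifiable — the two components can split
the truth between them in many ways, and across seeds the dominant weight
wanders while the *fitted prior mean* stays within a few percent of the
truth. The recovery assertion therefore targets the prior mean, the
identifiable quantity.

End-to-end recovery runs the full pipeline (deduplicate → SMQ mapping →
statistics → joint decision) on ten simulated extracts of 200,000 reports
with one pair spiked at ρ = 4 on a baseline-0.005 PT and a 10% duplicate
rate, requiring the spiked pair flagged in every run, at most 5% of null
pairs flagged (observed: none), and the deduplicated count equal to the
ground-truth case count exactly. These sizes keep the whole suite in the
low minutes while leaving the spiked cell large enough (~100 reports) for
all four thresholds to bind.

## Limitations

The screen inherits every limitation of spontaneous data: no denominator,
reporting biases, confounding by indication, duplicate detection only
within the case-identifier mechanism. The comparator universe is whatever
was loaded — class-level RORs against a full-database background are
reproduced only when the full extract is supplied. The BCPNN closed form is
an approximation that should not be read to three decimals for cells under
a few dozen reports; the Monte-Carlo mode exists for exactly that case.
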