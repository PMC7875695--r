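---
title: "Screening prescriptions for unsubstantiated medications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening prescriptions for unsubstantiated medications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoprx)
```

## The model

The screen rests on one statistic. For two codes $a$ and $b$ (a
diagnosis and a medication, or two medications), the *Q value* is the
lift of the pair over prescriptions:

$$Q(a,b) \;=\; \frac{P(a,b)}{P(a)\,P(b)},$$

estimated by plug-in frequencies within a training corpus,
$\hat Q = n_{ab}\,n /(n_a n_b)$. $Q = 1$ is the independence point:
pairs that co-occur more often than chance have $Q > 1$. An association
is *positive* when $Q > \alpha$, with $\alpha = 1$ by default —
the natural independence cutoff for a lift statistic. Because
prescribing differs by demography, Q values are computed separately
within each stratum (sex × 5-year age band, half-open bands
$[5k, 5k+5)$ indexed $k = \lfloor \mathrm{age}/5\rfloor$), with a pooled
stratum always computed as well.

A medication on a prescription is *explained* when some co-listed
diagnosis (D-M) or some co-listed medication (M-M) has a positive
association with it; a prescription is *substantiated* when every
medication is explained, otherwise *unsubstantiated*, and the
unexplained medications are the flagged alert targets. The unit of
analysis is the prescription throughout — probabilities are
per-prescription frequencies, not per-patient, and repeat visits are
treated as independent prescriptions.

Key semantic choices, all configurable through `classifier_params()`:

* **Rule.** The default rule is `dm_or_mm`: a disease *or* a
  co-medication may explain a medication. The stricter `dm_and_mm`
  (both channels must be positive) is also provided because both
  definitions circulate for this family of models; under it,
  single-medication prescriptions satisfy the M-M clause vacuously by
  default, since otherwise every monotherapy would be auto-flagged.
* **Threshold.** Strictly greater than $\alpha$ counts as positive;
  $Q = \alpha$ exactly is negative. The boundary case is unlikely in
  continuous data but must be deterministic.
* **Absence.** A pair with no record (never co-occurred, or below the
  support floor) is negative evidence. No smoothing is applied: absent
  is absent, not $Q = 0$.
* **Fallback.** When the patient's stratum has no record for a pair,
  the lookup falls back to the pooled stratum (`fallback = "pooled"`);
  `"none"` disables this. Sparse strata make the fallback essential at
  desk scale (below).

### Pseudo-associations and pruning

Comorbidity induces spurious positive lifts: if hypertension and type 2
diabetes are frequent comorbidities, insulin acquires $Q > 1$ with
hypertension even though hypertension never indicates insulin. Two
mitigations are implemented. At classification time the D-M evidence
for a medication is the *maximum-Q* diagnosis on the prescription
(equivalent to the existential test at a strict threshold). As an
optional mining-time mode, `prune_global_top1()` keeps, per stratum and
medication, only the single highest-Q D-M record and discards the rest
— so a pseudo-associated diagnosis can no longer explain the medication
when the true indication is absent from the prescription. Ties break
towards the lexicographically smaller diagnosis code, for determinism.
Pruning is off by default; it trades a little specificity (an
occasionally mis-ranked top diagnosis) for sensitivity against
comorbidity-driven misses, and `analytic_lift()` on the default
generator quantifies the effect (the insulin–hypertension lift sits
strictly between 1 and the direct diabetes–insulin lift).

### Federated merging

Two models mined from different corpora are combined one-shot with
`merge_models()`: for a (stratum, pair) key present in both, the record
whose training corpus co-occurrence count `n_joint` is larger is copied
unchanged into the hybrid; `n_joint` is the only co-occurrence
frequency the models store, which fixes the reading of "higher
frequency of co-occurrence". Ties prefer the first (original) model,
which is typically the one with the larger corpus. Pairs present in
only one model are included by default (`unshared = "union"`);
`"intersection"` is available because the choice is genuinely open and
materially changes the hybrid's specificity profile. Every hybrid
record carries a provenance column and is byte-identical to its source
record.

## The synthetic world

The generator (`generator_truth()`, `generate_corpus()`) emulates the
kind of outpatient corpus the screen is trained on, with a fully known
ground truth:

* **Demographics.** Two presets: `"local"` (age mean 53.4, SD 19.8
  years, 36% male) mirroring a US academic-center cohort, and
  `"original"` (mean 46.6, SD 23.3, 45% male) mirroring a national
  claims population — so original/local/hybrid experiments run on
  genuinely different demographic mixes. Ages are truncated-normal
  integers in [18, 100).
* **Diagnoses.** In the default `"visit"` mode the number of diagnoses
  is drawn from a pmf (defaults 0.30/0.30/0.25/0.15 for 1–4) and
  diseases are sampled without replacement with weights tilted by age
  band and sex, and multiplied for comorbid partners already drawn
  (hypertension–diabetes ×2.5 is the planted pseudo-association
  source). Themed visits make unrelated disease pairs negatively
  correlated, as in real per-visit coding. The `"bernoulli"` mode draws
  each disease independently instead; it exists because exact pairwise
  independence is what a lift-calibration oracle needs.
* **Medications.** Each disease prescribes its indicated medications
  independently with the catalog probabilities; companion rules add
  co-medications (folic acid with methotrexate, probability 0.85 — the
  planted M-M structure). A prescription whose indicated draws all fail
  receives a health-maintenance filler (a `Z00.0` encounter code plus a
  vitamin supplement) rather than being redrawn — rejection would
  couple otherwise-independent pairs, whereas the filler keeps them
  exactly independent and is itself explainable by its own encounter
  code.
* **Errors.** With probability `error_rate` (default 0.1) one
  medication is injected, drawn uniformly from the medications neither
  indicated by the visit's diagnoses nor reachable as companions — so
  the injected set is disjoint from anything legitimately drawable and
  the labels are exact: a prescription is unsubstantiated if and only
  if it carries an injected medication. Injection is independent of the
  indicated draw, so the unsubstantiated fraction is binomial at
  `error_rate`. Each injected error gets a severity label drawn from
  `severity_mix` (defaults 0 / 27/232 / 205/232 for
  life-threatening / serious / significant, the mix observed in the
  motivating chart review).

`analytic_lift()` computes the exact population lift of any D-M or M-M
pair under a truth object, by enumerating the disease-subset
distribution per stratum (ordered-tuple recursion in visit mode,
$2^n$ products in Bernoulli mode) and combining it with closed-form
conditional medication probabilities, error channel included. It
reduces to $1/P(D)$ for a medication prescribed only with disease $D$,
which the tests verify, and it is the oracle the miner is calibrated
against (mined $\hat Q$ within 10% at a 200,000-prescription corpus;
independent pairs within [0.8, 1.2]).

What the generator does *not* emulate: longitudinal patient histories
(every prescription is an independent visit), dosing, free-text
diagnoses, coding noise, and errors subtler than a wholly unindicated
medication (e.g. wrong dose, or a plausible-but-wrong drug in class).
Passing tests therefore show that the implementation recovers the
structure it was pointed at — not that the screen would reach the same
operating point on real EHR data.

## Evaluation protocol

Because unsubstantiated prescriptions are rare (~1–2% in practice,
10% under the default generator), evaluation uses an *enriched* test
set: the trained model classifies a held-out validation set, and the
same number of prescriptions (300 by default, i.e. a 600-prescription
test set) is sampled from each predicted class. Reviewer behaviour is
emulated by `simulate_reviews()` (configurable label/severity noise and
a 6-point confidence scale); prescriptions with any rating below 4 are
excluded, disagreements go to a tie-breaking third label
(`adjudicate()`), and inter-rater agreement is summarised with Cohen's
$\kappa$ using the large-sample standard error
$\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}$. Severity agreement is computed on the
3-level scale restricted to prescriptions both raters called
unsubstantiated. Confusion metrics take *unsubstantiated* as the
positive class; zero-denominator metrics are reported as `NA`, never 0,
and rounding to two decimals happens only in the formatted report
(`format_sweep_table()`), which mirrors the conventional
Sen/Spe/PPV/NPV/Accu layout per model across the
$\alpha \in [0.5, 1.5]$ grid.

One caveat is inherited from the protocol itself: enrichment balances
the *predicted* classes, so false negatives are diluted among the many
predicted-negatives and the measured sensitivity is higher than the
population sensitivity. This is a property of the protocol, reported
as such.

## Scale, sparsity, and practical guidance

The reference deployments of this model family train on corpora in the
$10^8$–$10^9$ range, where every stratum is dense. The package's
experiments run at desk scale — 100,000 original-profile plus 60,000
local-profile training prescriptions and a 5,000–8,000-prescription
test pool in the shipped experiments — chosen so the full suite runs in
minutes while planted lifts ($\geq 5$ for the rare-disease indications)
remain comfortably estimable. At this scale the 34 sex × age strata
hold only a few thousand prescriptions each, and a rare pair observed
once in a stratum gets an enormous noise Q. Consequences worth knowing:

* `min_support` defaults to 1 (every observed pair is a record, the
  most literal reading of the mining step), but with desk-scale corpora
  a support floor of 5–20, or pooled-only mining
  (`stratified = FALSE`), markedly stabilises per-medication evidence.
* The pooled fallback only applies when a stratum record is *absent*; a
  present-but-noisy stratum record wins. That is the documented lookup
  semantics, so the support floor is the right tool for suppressing
  noisy records.
* `prune_global_top1()` recovers most comorbidity-driven misses at a
  small specificity cost, and is worth enabling when the corpus is
  large enough that the top-ranked diagnosis per medication is stable.

## Numerical and degenerate-input choices

* Model files are plain text with a versioned header; Q values are
  written with 17 significant digits so save/load round-trips are
  bit-exact. Corrupt or truncated files fail loudly.
* All randomness flows through explicit integer seeds
  (`withr::with_seed`); identical seeds reproduce corpora, samples and
  reviews bit for bit.
* Empty corpora are an error for mining; empty files read as empty
  corpora; invalid rows are counted and reported (skip-and-log by
  default, abort on request).
* A t test between zero-variance equal-mean groups reports statistic 0
  and $p = 1$ rather than erroring; a single-level sex table yields
  `NA` for the chi-square contrast; $\kappa$ with degenerate marginals
  ($p_e = 1$) is an explicit error.
* In `merge_models()` the hybrid's records carry an added `source`
  column; merging a model with itself reproduces it record-for-record
  once that column is dropped.

## Known limitations

The screen only sees age, sex, diagnosis codes and medication codes:
no laboratory values, chief complaints, doses or temporal context, so
dose-dependent errors and clinically nuanced misprescribing are out of
scope by construction. The mapping from source coding systems to ATC is
a pluggable table (`read_code_map()`, `map_codes()`); no licensed
dictionaries are bundled. Severity labels are generator metadata
standing in for reviewer judgment, not a clinical grading. And the
hybrid-model experiments share one disease catalog across demographic
presets; truly different prescribing cultures would differ in the
catalog itself, which the merge rule can represent but the generator
does not currently produce.
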