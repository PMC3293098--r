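---
title: "A decision-tree cost-of-illness model of induced abortion in Uganda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree cost-of-illness model of induced abortion in Uganda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcost)
```

## The problem and the model

Where abortion is legally restricted, procedures are pushed into hidden
clinics and self-induction, complications are frequent, and the resulting
healthcare use and mortality carry real economic weight that rarely appears
in health accounts. `abcost` estimates that burden for Uganda with a
single-cohort decision tree: a chance-node tree splits abortion seekers by
provider training, provider type, procedure failure, complications, care
setting, access, and survival; each terminal carries an itemized cost
bundle; the expected cost per case is the probability-weighted sum of leaf
costs, computed both bottom-up (`rollback()`) and by exhaustive path
enumeration (`enumerate_paths()`), which serve as mutual oracles and agree
to 1e-9 on every tree we generate.

The cohort flow encoded by `build_study_tree()`:

* **Provider**: trained (doctor, clinical officer, nurse/midwife) vs.
  untrained (dispenser, lay practitioner, self-induction), with conditional
  provider shares within each group.
* **Failure**: rare for trained providers (0.0005) and common for untrained
  ones (0.17). After an untrained failure the woman retries once with a
  trained provider (paying both fees); a failure with a trained provider —
  including a failed retry — means the pregnancy continues.
* **Complications** (probability depends on the provider) split into
  hospital-level vs. out-patient-level need; each needs *access* (0.67).
  Women needing hospital care without access either die in the community
  (0.05) or worsen and present late, facing the in-hospital mortality split
  (0.02); women without out-patient access self-medicate and recover.
* **Continued pregnancy** ends in birth (0.87; facility 0.393 vs. home, each
  with maternal and perinatal mortality), a treated mid-pregnancy
  miscarriage (0.03, routed through the complication subtree), or an early
  miscarriage.

Every chance node designates one branch as the *complement* of its
siblings (`1 − Σ p_sibling`), so branch probabilities stay normalized
whatever values are sampled. Probabilities printed alongside their
complements in the source tables (untrained 0.44, out-patient 0.56, early
miscarriage 0.10) are stored as printed for reference but are not used by
the tree; their tornado spread is exactly zero, which doubles as a test of
the unused-parameter invariant.

## Costing rules

Costs live in per-terminal bundles (`build_cost_bundles()`), each item
tagged with an economic category (direct medical, direct non-medical,
indirect) and, for healthcare items, a payer (patient, government, or an
`unallocated` residual, unused by default). The identity
`direct_medical + direct_non_medical + indirect = societal` holds item-wise,
hence for every Monte Carlo draw, not just in summaries.

The compositions the published tables leave implicit are resolved as
follows (these are the package's own reconstructions and the main source of
reproduction error; the acceptance tolerances on category means reflect
that):

* **All abortion seekers** pay the provider's procedure fee, a per-attempt
  procurement productivity loss ($1.14), and one procurement transport
  ($2.49) + upkeep ($11.59) episode. Procurement is always patient-paid:
  the government does not provide illegal abortions.
* **Treated complications** add the setting's personnel/supplies/drugs/
  diagnostics (government, direct medical), overhead and capital
  (government, direct non-medical), the out-of-pocket payment ($1.48,
  patient — applied in both settings by default, configurable via
  `study_options()`), a second transport + upkeep episode (patient), and
  the setting's productivity loss.
* **Self-medication** (no out-patient access) has no itemized row; we price
  it at the out-patient drugs cost ($1.20, configurable) plus the
  out-patient productivity loss.
* **Retry paths** carry both procedure fees and two procurement
  productivity episodes, but only one transport/upkeep episode per seeker.
* **Births** add antenatal care weighted by the 94% attendance rate, and
  facility deliveries add the hospital delivery cost ($116.63, treated as
  already adjusted for cesarean and obstetric-complication rates);
  pregnancy care is government-paid.
* **Every maternal death** — in hospital, in the community, or at delivery —
  adds the human-capital mortality cost. Perinatal-death branches are
  represented in the topology but carry no extra cost by default
  (`perinatal_extra_cost`), since the source tables price none.

Mortality is valued as `w (1 − (1+r)^−L)/r` with `w = $474.27` (GDP per
capita), `r = 3%`/year and `L = 40` years of remaining life expectancy at
the mean age at death of 28. `L` is configurable; 40 years is our reading
of period life tables for Ugandan women at that age, and the value the
model's indirect-cost level supports. Economic constants are fixed, never
sampled.

## Uncertainty analysis

Each (low, high) range is read as a 95% interval, so `se = (high − low)/4`
(`derive_se()`). `fit_distributions()` assigns beta distributions to
probabilities by the method of moments and normal distributions to costs;
`se = 0` yields a point mass. If a probability's range is so wide that
`se² ≥ m(1 − m)` the sd is clamped to `0.99 √(m(1−m))` with a warning —
clamping preserves the mean, which is what drives expected costs.

`run_psa()` draws all parameters independently (no correlation structure is
published), truncates normal cost draws at zero (at the published se/mean
ratios this shifts means negligibly), and re-evaluates the tree per
iteration. The engine is vectorized: leaf probabilities accumulate
parent-to-child over the draw matrix and leaf costs factor into one matrix
product per category, so 10,000 iterations take about a second. Draws come
from a single seeded generator in parameter-table order, making runs
bit-reproducible for a fixed seed. The 95% credibility range is the
empirical 2.5th–97.5th percentile band (linear interpolation); the
reported minimum/maximum are observed Monte Carlo extremes and are
therefore seed-dependent.

`run_tornado()` sweeps each parameter to its published low and high bounds
(not distribution percentiles), all others at base case, and ranks by the
absolute societal-cost spread, ties broken by table order.

```{r, eval = FALSE}
study <- uganda_study()
psa <- run_psa(study, iterations = 10000, seed = 1)
tidy(psa)
autoplot(run_tornado(study))
```

## The synthetic-study generator

`generate_study()` emulates the *statistical structure* of the study inputs
— chance-node probabilities whose ranges bracket the mean, nonnegative
costs with proportional ranges, a complement branch per node — on random
topologies (depth ≤ 6, branching ≤ 4), and stores the analytic expected
cost computed at generation time by an independent exhaustive enumeration.
Probability means are normalized per node; ranges are
`mean ± U(0.2, 1)·min(m, 1−m)`, which keeps the beta fits well-posed, while
a small fraction (5%) get a full `[0, 1]` range around a small mean to
exercise the clamping path deliberately. Cost means are log-uniform on
`[1, 500]` to span the magnitudes of the real unit-cost table; all values
are rounded to 6 significant digits so parameter files round-trip exactly
through the CSV reader. `recovery_experiment()` checks that PSA means
recover the stored ground truth within `3·sd/√n`.

What passing these tests shows is that the *engine* — tree evaluation,
distribution fitting, sampling, summarization — is correct; it says nothing
about whether the Uganda parameter values themselves are right, and the
generator deliberately makes no attempt at epidemiological realism.

## Problem sizes and numerical choices

The packaged tree has 558 nodes (288 terminals). The default analyses use
10,000 Monte Carlo iterations; the test suite uses 100–10,000 depending on
what a test demonstrates, and the engine-property tests run 200 random
synthetic trees at depths 1–4. Chance-node sums are verified to 1e-9 at
every evaluation; oracle-equivalence checks use 1e-9 absolute tolerance;
beta fits reproduce (mean, se) to (1e-9, 1e-6). Degenerate inputs are
first-class: zero-width ranges give point masses and a zero-variance PSA,
zero-probability branches leave the tree valid, and a single-terminal tree
evaluates to its own cost.

## Known limitations

* The per-terminal cost compositions are reconstructed from narrative
  costing rules, not from a published per-leaf table; category means
  (especially direct non-medical) inherit that uncertainty.
* The patient/government payer split allocates all patient-side items to
  patients, so the patient share comes out near the top of the plausible
  range; published accounts suggest a residual payer (mission/NGO
  facilities) that the `unallocated` tag can represent but which defaults
  to zero.
* Single-cohort expected values only: no time cycles, no cost-effectiveness
  denominator, no intangible costs, no friction-cost alternative to the
  human-capital approach.
* Parameters are sampled independently; any real correlation (e.g. between
  complication probabilities across providers) is ignored.
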