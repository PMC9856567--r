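---
title: "Penetrance-based risk projection for Lynch syndrome: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penetrance-based risk projection for Lynch syndrome: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lynchRisk)
```

# The model

Lynch syndrome (LS) is an autosomal-dominant cancer predisposition caused by
a pathogenic variant (PV) in one of five mismatch-repair-associated genes
(*MLH1*, *MSH2*, *MSH6*, *PMS2*, *EPCAM*). Carriers face sharply elevated
risks for nine cancer sites, but the size of that elevation depends on the
gene, the sex, and the site — which is why a personalized projection, rather
than a single quoted "Lynch risk", is clinically useful.

The engine's primitive is the **age-specific conditional penetrance (ACP)**:
the probability that a person with genotype $g$, sex $s$, race $r$ and
ethnicity $e$ has a first onset of cancer $c$ at exactly (discrete) age $a$,

$$p_c(a) = P(T_c = a \mid G = g, S = s, R = r, E = e),
  \qquad a = 1, \dots, 85.$$

Curves are stored dense over integer ages 1..85; age 85 is the lifetime
horizon. Each curve satisfies $0 \le p_c(a) \le 1$ and
$\sum_a p_c(a) \le 1$ (the remainder is the probability of never developing
that cancer). Cancers are modeled independently — there is no competing-risk
or multi-site joint model, matching the per-site conditioning of the risk
formula below.

**Future risk.** For a user who is free of cancer $c$ at current age
$a_\mathrm{cur}$, the projected risk through a horizon $a_\mathrm{fut}$ is
the conditional probability over the half-open interval
$(a_\mathrm{cur}, a_\mathrm{fut}]$:

$$P(a_\mathrm{cur} < T_c \le a_\mathrm{fut} \mid T_c > a_\mathrm{cur})
 = \frac{\sum_{a = a_\mathrm{cur}+1}^{a_\mathrm{fut}} p_c(a)}
        {S_c(a_\mathrm{cur})},
 \qquad S_c(a_\mathrm{cur}) = 1 - \sum_{a=1}^{a_\mathrm{cur}} p_c(a).$$

`futureRisk()` and `makeRiskSeries()` implement this; a `RiskSeries` holds
the value at every horizon from $a_\mathrm{cur}$ (where it is 0) to 85 and
is validated to be nondecreasing.

# Intervention calculus

Published intervention effects arrive in three currencies — relative risks
(RR), odds ratios (OR) and hazard ratios (HR) — and each acts on the curve
differently.

- **RR** (`applyRR`): direct elementwise multiplication,
  $p_1(a) = \mathrm{RR} \cdot p_0(a)$.
- **OR** (`applyOR`): converted age by age to an RR against that age's
  baseline probability,
  $\mathrm{RR}(a) = \mathrm{OR} / [(1 - p_0(a)) + \mathrm{OR} \cdot p_0(a)]$,
  then multiplied. As $p_0 \to 0$ the conversion approaches the OR itself.
- **HR** (`applyHrSchedule`, `applyConstantHR`): the curve is converted to
  discrete hazards
  $\lambda_0(a) = p_0(a) / \bigl(1 - \sum_{t<a} p_0(t)\bigr)$
  (`acpToHazard`), the hazards are multiplied by the HR, and the result is
  converted back by the forward recursion
  $p_1(a) = \lambda_1(a)\bigl(1 - \sum_{t<a} p_1(t)\bigr)$
  (`hazardToAcp`).

The back-conversion deserves a note: we implement it as the exact algebraic
inverse of the hazard definition, which guarantees that
`hazardToAcp(acpToHazard(x))` is the identity to machine precision (a
property the test suite checks on thousands of random curves) and that a
constant HR on a single-age curve reduces to plain RR multiplication. An
alternative reading that normalizes by the running sum of *hazards* rather
than reconstructed penetrances would break both properties, so it was
rejected. After HR multiplication hazards are clamped at 1, which preserves
probability semantics for adversarial inputs and never triggers for
realistic effect sizes.

**Continuous exposures** (`continuousEffect`). Weight and BMI effects are
reported per exposure step and compounded geometrically:

$$\mathrm{OR} \text{ or } \mathrm{HR} =
  (1 + \sigma v_k)^{|\Delta v_k|},$$

with $\sigma = +1$ for risk-increasing changes, $-1$ for decreasing, $v_k$
the per-step effect (0.20 per 5 kg for endometrial OR; 0.07 per BMI point
for colorectal HR) and $|\Delta v_k|$ the magnitude in step units, fractions
allowed. The published model is deliberately asymmetric —
$(1+v)^d (1-v)^d \ne 1$ — and the implementation preserves that asymmetry
rather than "correcting" it.

**Time-varying schedules** (`evalHrSchedule`). The aspirin HR is reported at
follow-up knots (2 y, 0.56), (5 y, 0.63), (10 y, 0.65). Between knots the
schedule interpolates linearly; beyond the last knot the final value is held
constant for life. Before the first knot, no effect estimate exists, so we
anchor the interpolation at (0, 1.0) — no effect at initiation — as the
conservative choice. Interventions are assumed to start at the user's
current age, so the schedule is indexed by $a - a_\mathrm{cur}$;
retrospective start ages are not modeled because the profile collects no
such input.

# Baseline adjustment

**Colonoscopy deconvolution** (`deconvolveMixture`). The colorectal
literature baselines were estimated on cohorts that mixed screened and
unscreened subjects. With adherence proportion $p = 0.818$ and screening RR
$= 0.44$, the observed curve is the mixture
$m(a) = (1-p)\,u(a) + p \cdot \mathrm{RR} \cdot u(a)$, so the unscreened
baseline is recovered exactly as $u(a) = m(a) / [(1-p) + p\,\mathrm{RR}]$.
Re-mixing reproduces the input to machine precision. The single $(p,
\mathrm{RR})$ pair is applied at all ages, sexes and genes — the screening
effect is generalized to all five LS genes by stated assumption.

**Lifetime cap** (`capLifetime`). Deconvolution inflates the curve (divide
by 0.542), and the result can exceed a plausible lifetime risk; curves whose
lifetime sum exceeds 0.90 are rescaled proportionally so the sum equals
0.90 exactly. The rescale is shape-preserving; truncating late ages instead
would distort the onset-age distribution, so it was not used. In the
colorectal pipeline the order is fixed as *deconvolve → cap → BMI
personalization → interventions*: the cap is applied to the quantity that
was described as capped (the adjusted, unscreened baseline), before
user-specific personalization.

**BMI personalization** (`personalizeBmi`). Baselines for colorectal and
endometrial cancer are sex-averaged at reference mean BMIs of 27.1 kg/m²
(male) and 26.0 kg/m² (female). The user's BMI is clamped to [25, 30] —
below the overweight threshold and above the obesity reference the baseline
is not extrapolated further — and the difference from the reference mean is
converted into a constant measure via the continuous model: the HR path for
colorectal (0.07 per BMI point), the OR path for endometrial, where the BMI
difference is first converted to weight through
$\Delta\mathrm{kg} = \Delta\mathrm{BMI} \times \mathrm{height}^2$ and
compounded in 5-kg steps (fractional steps as fractional exponents). The OR
is converted per age rather than at a single representative baseline
probability — the faithful reading of the conversion's age index.
Colorectal BMI personalization is applied only to *MLH1* carriers: that is
the gene the source effect was estimated in, and unlike colonoscopy and
aspirin no generalization assumption was stated for it. The raw (unclamped)
BMI is retained for the weight-loss menu.

**Race/ethnicity stratification** (`stratifyFromRelative`). Where carrier
risks are published relative to the general population, a
race/ethnicity-conditioned carrier curve is derived from the matching
general-population curve by applying the relative measure through the
appropriate pathway (RR directly, OR per age, HR on the hazard scale).

# The per-profile engine

`profileRisks()` assembles, for every cancer associated with the user's
gene and sex (per the supported gene–cancer association matrix,
`geneCancerAssociations()`) and not in their prior-cancer history: the
adjusted baseline series, one series per selected intervention
(`postInterventionCurve`), the additively composed series, and the matched
general-population series. Prior cancers remove the site entirely —
recurrence risk is a different quantity this engine does not estimate. A
prior hysterectomy or oophorectomy zeroes the corresponding organ's
baseline instead of removing it, so the display can still show the zero.

**Composition** (`composeSeries`). Studies of intervention combinations are
lacking, so joint effects are assumed additive. Additivity is implemented
on the cumulative-risk scale: at each horizon the reductions
$(\text{baseline} - \text{single}_k)$ are summed, subtracted from the
baseline, and floored at zero (over-subtraction is possible when several
strong effects stack; the floor at zero rather than at the largest single
reduction is the simpler reading and is what the tests pin down). A surgery
series is identically zero, so it drives any composition to zero. A running
maximum restores monotonicity where the floor binds.

**Menu** (`buildMenu`). Colonoscopy and aspirin are offered whenever
colorectal cancer is associated with the user's gene; surgeries to females
without the corresponding prior surgery when the organ's association
exists. Weight-loss options run in whole pounds from 0 to
$\lfloor \min(5, \mathrm{BMI} - 25) \times \mathrm{height}^2 \times
2.20462 \rfloor$: no positive option at or below BMI 25 (users in the
normal range should not be nudged to lose weight), and at most five BMI
points for very obese users so the modeled benefit is not overstated. The
weight-loss magnitude is measured from the raw BMI but applied on the
clamped, personalized baseline; the interaction is an approximation we
accept for the same reason the clamp exists.

# Risk conveyance

All rounding lives in the reporting layer; everything upstream is full
precision. Three display styles are quantized from the same series:

- **line**: yearly cumulative percents from the current age to 85, rounded
  to the nearest 1 %;
- **bar**: two snapshots — within five years ($a_\mathrm{cur}+5$, truncated
  at 85) and by age 85 — rounded to the nearest 1 %;
- **personograph**: the same two snapshots as shaded icons out of 20, i.e.
  5 % granularity (`personographCounts(risk) = roundHalfUp(20 · risk)`).

Rounding is half-up (no published tie rule; half-up matches how the
percentages read). The lifetime table reports absolute user and
general-population percents plus their ratio to one decimal, ordered by
descending user risk; a zero general-population lifetime risk makes the
ratio undefined and is rendered as a dash, never as infinity.
`renderReport()` emits a deterministic JSON payload plus Markdown text with
the intervention caveats carried verbatim from the registry (3-year
colonoscopy interval, 600 mg aspirin dose); PDF typography is a delivery
concern outside this package.

# The synthetic generator

Real penetrance tables are curated from literature and registry data and
are not shipped. `simulateAcpDatabase()` generates structurally identical
databases: each stratum's curve is a discretized Beta density over ages
1..85 scaled so its lifetime sum equals the stratum's target exactly, with
the integer argmax at the requested onset mode by construction. The seed
draws only the Beta concentration (uniform on 8–16, a mild shape jitter),
so generation is fully deterministic given the seed. The default
specification (`syntheticStrataSpec()`) covers every admissible gene–
cancer–sex stratum with lifetime targets echoing the broad published
pattern — colorectal/endometrial carrier risks of tens of percent with
onset modes in the 50s–60s, rarer sites at a few percent, general-population
targets an order of magnitude lower, and a mild gene gradient
(MLH1/MSH2 > MSH6 > EPCAM/PMS2).

What the generator does *not* emulate: real curves' estimation noise and
age-range censoring, race/ethnicity heterogeneity (defaults are generated
at the unknown-race level only), correlated multi-site risks, and secular
screening trends. Tests passing on synthetic data therefore validate the
*calculus* — conversions, pipelines, quantization — not the clinical
accuracy of any particular risk number.

# Numerical choices and limitations

- Curve validation tolerates `1e-9` slack on the $\sum \le 1$ constraint;
  hazard round-trips are tested at `1e-12`.
- The deconvolved unscreened curve is an intermediate whose sum may exceed
  1; it is exempt from the sum constraint and always capped next.
- Pounds↔kg uses 2.20462; BMI = kg/m².
- Problem sizes in the test suite (curve counts in the hundreds to
  thousands, 200,000-draw microsimulations for the future-risk oracle) were
  chosen so Monte-Carlo error is far below the tolerances being checked.
- Out of scope: carriers of PVs in two LS genes, uncertainty intervals on
  the projections, cancers with insufficient LS-specific data
  (hepatobiliary, sebaceous, kidney/ureter), recurrence risk, and any
  estimation of the registry constants from data — they are inputs, fixed
  from their sources.
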