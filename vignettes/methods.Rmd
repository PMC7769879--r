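---
title: "Methods: balance accounting, pathway decomposition and CV analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: balance accounting, pathway decomposition and CV analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electroferm)
```

## The accounting model

A cathodic electrofermentation cell receives reducing power from two
sources: the substrates fed (lactate, optionally butyrate) and the charge
delivered to the cathode. The package tracks both currencies — carbon and
electron equivalents — through a batch run.

Electron equivalents use the **degree of reduction**: γ = 4C + H − 2O mol
e⁻ per mol, the electrons released by complete oxidation to CO₂ and H₂O.
γ is evaluated on the **neutral acid form** (C₃H₆O₃ for lactate, not the
anion): this reproduces the per-compound e⁻:C ratios used in published
ledgers (lactate 4, acetate 4, propionate 14/3, butyrate 5) and avoids
any charge bookkeeping for dissociation. CO₂ is the zero reference; H₂
carries 2. The registry is a packaged table
(`inst/extdata/compounds.csv`) and user-extensible, because HPLC methods
for these broths typically monitor valerate, caproate and alcohols even
when they stay below detection.

The **electron balance** divides the electron content recovered at the
outlet (residual substrates, soluble products in both chambers and in
withdrawn samples, H₂ in the headspace) by the electrons fed plus the
delivered charge ∫|i| dt / F. The **carbon balance** is the analogous
carbon ratio (CO₂ counts at the outlet; H₂ does not carry carbon). The
**electrofermentation coefficient** η_EF divides the delivered charge by
the electron content of the *soluble products formed*:

* gases are excluded (soluble products only), and
* any compound fed as substrate in that cell is excluded — its outlet
  entries are unconsumed substrate, not product. In butyrate-fed cells
  butyrate is excluded from the denominator; in lactate-only cells the
  butyrate formed by chain elongation counts. This exclusion rule is the
  only convention that reproduces all five published coefficient values
  carried in `worked_example_table()`.

Balances are computed per cell over all cycles by default
(`experiment_ledger()`), with a per-cycle mode (`cycle_index =`). For
non-electrochemical controls the delivered charge is zero and η_EF is
reported as not applicable (0 from `ef_coefficient()`, `NA` in reports).

Other conventions, chosen once:

* Time is kept in hours; a day is exactly 24 h for mM d⁻¹ rates.
* Interpolation between samples is linear — no kinetic model is assumed
  for between-sample values.
* Sample-withdrawal corrections use the concentration *at* the
  withdrawal time by default; a cycle-average alternative is selectable
  (`withdrawn_moles(method = "cycle_average")`). Published work rarely
  states which convention it uses; at sampling fractions below 5 % of the
  working volume the difference is immaterial.
* An addition recorded at the exact cycle-start instant is part of the
  initial sampled inventory (the start-of-cycle sample is drawn after
  feeding); only later re-additions enter the "added" term. This keeps
  ledgers, yields and the simulator mutually consistent.
* Average current for the specific-energy figure excludes the startup
  segment run at a more negative applied potential; the charge integral
  for the electron balance includes it.
* Missing gas readings enter balances as zero outlet (not-detected
  semantics); concentrations below HPLC detection are entered as 0.
* Report rounding: balances to 1 decimal, η_EF to 2.

### Specific energy consumption

E_C = I_avg · V_cell · t / Σmᵢ, in kWh per kg of product formed. The
result is very sensitive to the mass basis Σmᵢ (which products count,
whether anolyte-migrated and withdrawn product is included, per cycle or
cumulative): with a plausible single-cycle product basis for a 150 mM
lactate run (≈1.25 g across propionic, acetic and butyric acid at 2.18 mA
and 3 V for 381.6 h) the figure evaluates to ≈2 kWh kg⁻¹. Published
headline values near or below 1 kWh kg⁻¹ imply a broader mass basis than
the equation's literal per-cycle reading; the package always reports the
literal computation and leaves the basis to the caller.

## Pathway extent decomposition

`builtin_network()` carries four reactions over
{lactate, propionate, acetate, butyrate, H₂, CO₂, cathode e⁻}:
fermentation (3 lactate → 2 propionate + acetate + CO₂),
homoacetogenesis (4 H₂ + 2 CO₂ → acetate), chain elongation
(lactate + acetate → butyrate + CO₂) and hydrogen evolution
(2 e⁻ → H₂). HCO₃⁻ consumed by acetogens is accounted as CO₂ — the
carbon ledger does not distinguish speciation. The chain-elongation
stoichiometry is the unique 1:1:1 form that balances both carbon
(3 + 2 = 4 + 1) and electrons (12 + 8 = 20): reports of this pathway name
lactate and acetate as the inputs without coefficients, and any other
integer combination breaks one of the two balances.

`decompose_extents()` is the algebraic attribution, **not** a
least-squares fit: Δbutyrate fixes chain elongation, Δpropionate/2 fixes
fermentation, and Δacetate − ξ_ferm + ξ_ce fixes acetogenesis. Three data
enter and three extents leave, so propionate and butyrate residuals are
zero by construction; the **lactate residual** is the informative one —
it exposes substrate consumed by unmodelled fates (biomass, aerobic loss)
without attributing it biologically. If acetate falls short of what
fermentation alone implies, the acetogenic extent is floored at zero and
the shortfall reported as a (negative) acetate residual. The implied
demands follow from the network: 4ξ_acet mmol H₂, twice that in mmol e⁻
of cathodic charge, and net CO₂ = ξ_ferm − 2ξ_acet + ξ_ce.
`co2_recycled()` caps the "recycled from fermentation" figure at the CO₂
actually produced internally and flags any excess as externally sourced.

Windows matter: the attribution assumes non-negative product deltas, so
callers select production-phase windows, and windows may deliberately
exclude the late chain-elongation phase when studying the
propionate:acetate correlation. The predicted ratio
2ξ_ferm / (ξ_ferm + ξ_acet − ξ_ce) is 2 for fermentation alone and 4/3
under full CO₂ recycling.

## Cyclic voltammetry

Scans are processed per branch (cathodic = sweep toward negative
potentials) on a uniform 1 mV grid — a 1 mV s⁻¹ scan rate implies ≈1 mV
native spacing — with centered Savitzky–Golay smoothing. Defaults:
**25 mV window, polynomial order 2**, chosen to resolve couples separated
by ~50 mV (the scale of interest for cytochrome-type surface couples)
without splitting noise into spurious extrema.

Peak *positions* are local extrema of the raw smoothed branch current,
confirmed by the derivative sign change, with topographic prominence
against the chosen threshold. Extrema are deliberately not located on a
baseline-subtracted signal: subtracting a fitted line moves every
extremum to where dI/dE equals the fitted slope, and the hydrogen
evolution tail — large, monotone, confined to the negative end — skews
any least-squares line. The tail being monotone, it contributes no
extremum of its own. Peak *magnitudes* are reported after subtracting a
per-branch linear baseline fit by Huber robust regression (robust to the
tail); a `baseline = "none"` mode is available. Reduction current is
negative by convention; magnitudes are absolute.

Couples are paired greedily by nearest potential across branches within
0.10 V (configurable; generous enough for a 50 mV couple with margin).
The onset shift between begin and end scans is the displacement of the
most positive potential at which the cathodic current magnitude first
crosses a threshold; a positive value (end − begin) means reduced
overpotential, the signature of electroactive biofilm development. The
threshold must be set above the capacitive envelope — the package errors
if it is never reached rather than guessing.

## The simulator

`simulate_batch()` emulates the batch protocol of a 150 mL two-chamber
cell: lactate restored to a target concentration at each cycle start
(butyrate optionally co-fed in cycle 1), cycles of ~6 days, daily 1 mL
analytical samples, a cathodic potential program of −1.2 V for the first
24 h then −1.0 V, and a headspace gas bag.

* **Cumulative reaction extents follow logistic curves** (3 parameters
  per reaction: total, midpoint, steepness). No rate law is asserted for
  these communities; the logistic is the simplest shape that reproduces
  the sigmoidal concentration profiles seen in such reactors, and the
  ground truth stays closed-form.
* **Butyrate migration** across the proton-exchange membrane is zero
  order at 0.35 mM d⁻¹ — the rate abiotic controls show — active when
  butyrate is present; mass is moved to the anolyte series, not lost.
* **Withdrawals** remove moles at the sampled concentration with the
  volume replaced by blank medium, so the constant-volume assumption of
  the analysis layer holds exactly; the recorded sample is the
  pre-withdrawal concentration (the material actually analysed).
  Consecutive cycles are separated by a 0.1 h feeding gap so the
  pre-feed and post-feed samples are distinct time points.
* **Gases**: CO₂ and surplus H₂ (evolution beyond the acetogenic demand)
  are stripped to the headspace and captured at a configurable fraction
  (1 by default).
* **The current trace** is the baseline (side/capacitive) current plus
  the faradaic H₂-evolution demand, emitted as a staircase whose
  trapezoidal integral reproduces the cumulative HER electron demand to
  rounding error. With zero baseline and full gas capture, noiseless runs
  therefore close both balances to better than 10⁻⁶ % — the conservation
  property the test suite asserts.
* **Noise** is additive Gaussian on recorded concentrations, truncated at
  zero (an HPLC measurement-error model); the underlying mass bookkeeping
  is exact. Defaults: 0.2 mM noise, 20 mM lactate, extents 0.7 mmol
  fermentation + 0.35 mmol acetogenesis (full CO₂ recycling) + matching
  H₂ evolution.

Zero-truncation has one estimator consequence worth knowing: in a window
that starts from product-free medium, the initial product samples are
censored upward by E[max(N(0, σ), 0)] ≈ 0.4 σ, so recovered extents read
slightly low. The test suite therefore asserts *exact* recovery on
noiseless first cycles and *unbiasedness* (50 seeds, 0.5 mM noise, within
2 standard errors) on second cycles, where initial products sit well
above the censoring region. Real analyses hit the same issue whenever
initial concentrations are at the detection limit.

What the simulator does **not** emulate — and hence what passing tests do
not establish about real reactors: pH dynamics and their metabolic
feedback, biomass growth and its carbon sink, oxygen intrusion chemistry,
community composition, electrode potentials, or kinetic rate laws. It
establishes that the *accounting* is exact and the *inference* recovers
known ground truth under the stated noise model.

`simulate_cv()` builds voltammograms as capacitive offsets of opposite
sign per branch, Gaussian faradaic peaks, an exponential HER tail below a
configurable onset, and seeded Gaussian noise — the morphology needed to
exercise smoothing, peak detection, pairing and onset logic.

## Numerical choices and degenerate inputs

* Faraday constant 96 485 C mol⁻¹; ideal-gas conversion for bag
  fractions; molar masses fixed at standard values (lactic 90.08, acetic
  60.05, propionic 74.08, butyric 88.11, caproic 116.16, H₂ 2.016, CO₂
  44.01 g mol⁻¹).
* Charge integration is trapezoidal on the current magnitude; empty
  windows, extrapolation beyond a series span, zero inlets, zero product
  electrons with nonzero charge, and thresholds never reached are all
  errors, not silent zeros.
* Balances above 100 % are reported with a warning (inconsistent
  inputs), never clipped.
* The golden-row tests against the packaged published ledgers account
  for the ±0.05 rounding of every printed 1-d.p. entry by interval
  arithmetic rather than a single ad-hoc tolerance; with small inlets the
  propagated envelope exceeds ±0.3 percentage points for a few carbon
  balances, which is a property of the printed precision, not of the
  arithmetic.

Problem sizes used by the shipped tests: single- and two-cycle
simulations at daily sampling (≈6–12 samples per series), 50-seed
recovery ensembles, 100-seed voltammogram ensembles at 1 mV resolution —
all chosen to exercise the estimators' statistical claims at sizes a
desk-scale re-analysis would use.

## Known limitations

* No speciation/pKa chemistry: equivalents are computed on neutral acid
  forms and HCO₃⁻ is treated as CO₂.
* The extent decomposition is exactly identified (three products, three
  extents): it cannot detect model misfit beyond the lactate residual,
  and competing pathways producing the same products are not separable.
* Membrane transport is modelled only as the zero-order butyrate term;
  other carboxylates are assumed not to migrate appreciably.
* The energy figure's product-mass basis is caller-defined (see above).
* CV analysis assumes a locally linear non-faradaic baseline per branch;
  strongly curved capacitive envelopes would need a different baseline
  model (`baseline = "none"` plus external correction).
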