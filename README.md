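# electroferm

Quantitative accounting for **cathodic electrofermentation** of lactate in
two-chamber bioelectrochemical cells. Electrofermentation steers a mixed
fermentative culture with a polarized electrode: at a cathode poised near
−1 V vs. Ag/AgCl, lactate is fermented to propionate and acetate while
electrochemically evolved H₂ lets homoacetogens recycle the fermentation
CO₂ back into acetate. Deciding whether that is actually happening in a
reactor — and how well — is a bookkeeping problem over carbon, electrons
and charge. This package does that bookkeeping, for experimentalists
running bioelectrochemical batch reactors and for anyone auditing
published carbon/charge ledgers.

## What it computes

**Carbon and electron balances.** Every compound is assigned its degree of
reduction γ = 4C + H − 2O (mol e⁻ per mol; CO₂ is the zero reference, H₂
carries 2). For a batch cell the electron balance is

    EB (%) = 100 · Σᵢ Q_i^out / ( Σⱼ Q_j^in + ∫ i dt / F )

where Q are the electron contents of substrates fed and of residual
substrates, soluble products and H₂ recovered, and ∫i dt/F is the charge
delivered to the cathode (Faraday constant F = 96 485 C mol⁻¹). The
electrofermentation coefficient

    η_EF = ( ∫ i dt / F ) / Σᵢ Q_i^out,products

compares delivered charge with the electron content of the *soluble
products formed* (compounds fed as substrate, and gases, are excluded).

**Pathway extent decomposition.** Measured concentration changes are
attributed algebraically to four carbon- and electron-balanced reactions:

| reaction | stoichiometry |
|---|---|
| lactate fermentation | 3 lactate → 2 propionate + acetate + CO₂ |
| homoacetogenesis | 4 H₂ + 2 CO₂ → acetate |
| chain elongation | lactate + acetate → butyrate + CO₂ |
| hydrogen evolution | 2 e⁻ → H₂ |

Butyrate fixes the chain-elongation extent, propionate fixes
fermentation, and acetate in excess of fermentation fixes acetogenesis;
the H₂ and cathodic-charge demand and the net CO₂ follow. Coupling
fermentation to full CO₂ recycling predicts 0.67 mol propionate and
0.50 mol acetate per mol lactate — a propionate:acetate ratio of 1.33,
against 2.0 for fermentation alone.

**Rates, yields, energy.** Interval production rates between consecutive
samples (mM d⁻¹ and g L⁻¹ d⁻¹), per-cycle molar yields corrected for
sample withdrawal and membrane migration, and specific energy consumption
E_C = I_avg·V·t / Σmᵢ (kWh per kg product).

**Cyclic voltammetry.** Savitzky–Golay smoothing and first-derivative
analysis on a 1 mV grid, faradaic peak detection with topographic
prominence, redox-couple pairing by nearest potential, and onset-potential
shifts between begin/end scans (the signature of an electroactive
biofilm).

**Simulator.** `simulate_batch()` generates complete synthetic cell
experiments (logistic reaction-extent curves, zero-order butyrate
migration across the membrane, daily sampling with volume withdrawal,
truncated-Gaussian HPLC noise, a current trace consistent with the H₂
electron demand) with known ground truth, so the whole pipeline is
testable end to end; `simulate_cv()` does the same for voltammograms.

## Worked example

Re-audit a published ledger (cell LB1: 20 mM lactate + 20 mM butyrate,
four batch cycles, −1 V applied):

```r
library(electroferm)
led <- worked_example_ledger("LB1")
led
#> balance_ledger LB1
#>   inlet: 46.5 mmol C, 196 mmol e-; charge: 123.8 mmol e-
#>   outlet: 32.9 mmol C, 217.1 mmol e-
#>   carbon balance: 70.8 %; electron balance: 67.9 %
round(ef_coefficient(led), 2)
#> [1] 1.36
```

67.9 % of the electrons fed as substrates plus delivered charge were
recovered in residual substrates, soluble products and H₂; η_EF = 1.36
means 1.36 electron equivalents of charge were invested per electron
equivalent of soluble product formed (values > 1 indicate charge lost to
H₂ escape or side reactions).

Simulate a 20 mM lactate cycle with fermentation coupled to full CO₂
recycling, then recover the pathway activity from the "measured" series:

```r
sim <- simulate_batch(sim_params(seed = 42, noise_sd = 0.2))
report_extents(sim$experiment)
#>   cell batch xi_ferm xi_acet xi_ce xi_her h2_demand charge_demand co2_net
#> 1  SIM     1   0.696   0.344     0   1.38      1.38          2.75 0.00847
#>   co2_recycled co2_external residual_lactate ratio
#> 1        0.688            0         -0.00694  1.34
```

The decomposition recovers the configured extents (0.7 mmol fermentation,
0.35 mmol acetogenesis) to within the injected measurement noise; the
predicted propionate:acetate ratio 1.34 sits at the theoretical 4/3 of
the fully CO₂-recycling regime, and 0.69 mmol CO₂ were fixed back into
acetate.

A thin command-line wrapper over the same functions lives at
`inst/cli/electroferm.R` (subcommands `balance`, `rates`, `stoich`, `cv`,
`simulate`, `report`, driven by one YAML config).

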