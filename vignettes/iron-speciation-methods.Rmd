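---
title: "Methods: equilibrium iron speciation in transferrin/chelator media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equilibrium iron speciation in transferrin/chelator media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferrispec)
```

## Scope and model

`ferrispec` models the extracellular iron chemistry of erythroid
differentiation medium as a closed thermodynamic system: total pools of
transferrin protein, iron and chelator ligand, all Fe³⁺, at fixed pH and
bicarbonate. The central assumption is that association/dissociation
kinetics of Fe³⁺ with both transferrin and the chelator are fast
relative to the net cellular uptake rate, so the medium is always at
equilibrium ("quasi-static"). Iron moves between carriers only by
release into the free Fe³⁺ pool and re-binding — no direct
carrier-to-carrier transfer, no ternary transferrin–iron–chelator
intermediates, no redox chemistry (Fe²⁺), and no intracellular
trafficking are modelled.

Species and mass-action laws, writing $f = [\mathrm{Fe^{3+}}]$ and
$L$ for free ligand:

$$\mathrm{tf_1} = K_1 f\,\mathrm{tf_0},\qquad
  \mathrm{tf_2} = K_2 f\,\mathrm{tf_1},\qquad
  [\mathrm{FeL}_i] = \beta_i' \, f \, L^i \;(i = 1..n).$$

The two monoferric transferrin forms (N- vs C-lobe) are lumped into a
single pool `tf1`: the model uses only the two macroscopic sequential
constants, and no lobe-specific constants enter anywhere, so resolving
the lobes would add state without information.

### Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `k1`, `k2` | 7.0e22, 3.6e21 | L/mol | sequential conditional Tf association constants, valid at pH 7.4 / 3.5 mmol/L HCO₃⁻; no pH dependence of transferrin binding is modelled |
| `log_beta` (deferiprone) | 15.01, 27.30, 37.43 | log₁₀ (L/mol)ⁱ | cumulative constants for FeL, FeL₂, FeL₃, referenced to deprotonated ligand |
| `pka` (deferiprone) | 3.68, 9.77 | — | ligand protonation; drives the side-reaction coefficient |
| `molar_mass_equivalence` | 76,900 | g/mol | µg/mL ↔ mol/L conversion of transferrin recipes |
| `molar_mass_budget` | 80,000 | g/mol | per-cell and per-unit protein mass budgets |
| `rate` | 1.7e-7 | mol Fe³⁺/(L·h) | constant net cellular iron uptake |
| `rtol` | 1e-10 | relative | solver tolerance on both component balances |

Two deliberate conventions deserve comment.

**Protonation correction is on by default.** At pH 7.4 deferiprone is
almost entirely in its neutral HL form ($\alpha \approx 4.25\times
10^{-3}$), so the raw β values overstate its effective affinity by
$\alpha^{-i}$. With raw constants the model predicts deferiprone would
*strip* transferrin (pFe³⁺ ≈ 28, above transferrin's ≈ 23.8), which
contradicts both the observed gel-shift re-loading of apotransferrin
and the culture rescue itself; with the corrected constants
(conditional log β₃′ = 30.31, pFe³⁺ ≈ 20.85) the model reproduces the
qualitative chemistry: deferiprone stabilises Fe³⁺ in medium yet yields
it to transferrin. `correct_protonation = FALSE` disables the
correction everywhere for sensitivity analysis.

**Two transferrin molar masses.** Published medium recipes equate
1000 µg/mL holotransferrin with 26 µmol/L of chelated iron, which
back-solves to 76,900 g/mol; published mass budgets use the nominal
"~80 kDa". The two differ by ~4%. The package keeps both as named
constants — `molar_mass_equivalence` for concentration conversions,
`molar_mass_budget` for mass budgets — rather than silently averaging,
so each published worked number is reproduced exactly by the calculator
that owns it.

Similarly, the residual-dose calculator defaults to a cell volume of
200 fL. The femtolitre scale is the physically plausible one for a
reticulocyte, and it is the value under which 21.7 mg/L medium
deferiprone maps to 0.14 mg/kg per transfused unit for a 62 kg adult;
"200 pL", which is sometimes seen in print, is dimensionally
inconsistent with that dose by three orders of magnitude.

**pFe³⁺ conventions.** pFe³⁺ is −log₁₀ free Fe³⁺ at 1 µmol/L total
iron, 10 µmol/L total ligand, pH 7.4. For transferrin, "10 µmol/L total
ligand" is interpreted as 10 µmol/L protein molecules (20 µmol/L
sites), the convention under which literature transferrin pFe values
are quoted. Note that pFe values computed from the constants above are
self-consistent within this package but need not equal literature pFe
values to the decimal, which were produced from other constant sets;
only the ordering (deferiprone < transferrin < siderophore-class
chelators) is meaningful across sources.

## Numerical method

In log concentration variables $x = \ln f$, $y = \ln L$, the iron and
ligand balance residuals are smooth and strictly monotone in their own
variable (the system is the stationarity condition of a convex
Gibbs-type potential). The solver:

1. builds a deterministic starting point from the composition alone
   (solve the 1-D iron balance with all ligand free, then the ligand
   balance at that iron level);
2. runs damped Newton with a forward-difference Jacobian, step clamp of
   5 log units and residual-halving backtracking, to a relative balance
   tolerance of 1e-10 (cap 200 iterations);
3. falls back to nested interval bisection on the two monotone balances
   (guaranteed to converge) plus a short Newton polish, and raises a
   typed solver error with the achieved residual if even that fails.

Compositions with a zero pool use a concentration floor of 1e-30 mol/L
only to keep logarithms finite; zero-iron media are returned exactly
without solving. Degenerate inputs (negative pools, ligand without a
chelator definition, fractions of an empty transferrin pool) raise
typed validation errors rather than NaN.

Because the starting point depends only on the current totals, two
solves of the same composition are bit-identical, and a time course
evaluated on different grids agrees *exactly* at shared times. This is
why the time-course simulator deliberately re-solves each grid point
from scratch instead of warm-starting from the previous time step: a
warm-started iterate stops somewhere inside the tolerance ball that
depends on the path taken, which would break exact grid-refinement
agreement for at most a few milliseconds of saved work.

## Time course

`simulate_timecourse()` depletes total iron linearly,
$Fe(t) = Fe(0) - r\,t$, clamped at zero (with the clamp time recorded
and a warning issued); transferrin and ligand pools are conserved since
cells internalise iron and recycle apotransferrin and free ligand. The
default horizon is 96 h — the window in which most hemoglobin is
synthesised — at 0.1 h resolution (961 equilibrium solves, well under a
second each scenario). The default rate 1.7e-7 mol/(L·h) is the
conventional figure for 10⁷ hemoglobinized cells per mL in 4 days;
recomputing it from that basis with `uptake_rate_from_basis()` gives
2.08e-7 (the conventional figure is ~20% lower than its own stated
basis), and both are available so either convention can be simulated.

Uptake is applied to *total* iron regardless of speciation, matching
the "net average uptake" phrasing under which the rate is defined; no
saturable uptake law is modelled because none is specified at this
level of description.

## Curve fitting

The iron/hemoglobin dose–response is fitted by Levenberg–Marquardt
least squares (via `minpack.lm`) to
$Hb = Hb_{max}\,c/(EC_{50}+c)$ on the untransformed scale (the response
is measured and displayed untransformed), with deterministic starts:
$Hb_{max}$ at the largest observed response, $EC_{50}$ at the positive
concentration whose response is nearest half of it. Oxygen-saturation
curves are fitted with the Hill model
$S = pO_2^{\,n}/(P_{50}^{\,n}+pO_2^{\,n})$; the Hill form is a modelling
choice — P₅₀ is defined operationally as the pressure at half
saturation — so a model-free P₅₀ by linear interpolation at the 0.5
crossing is always reported alongside, and curves that do not span 0.5
are rejected.

## Synthetic data

The generators emulate the *statistical structure* the fitting stages
assume: hyperbolic mean response at the culture design concentrations
(0, 1.3, 2.6, 5.2, 13, 26, 52 µmol/L; 24 points) with additive Gaussian
noise of sd 5% of $Hb_{max}$ truncated at zero; Hill-curve saturations
with sd 0.01 clipped to [0, 1]; and additive noise on simulated
transferrin fractions, renormalised to sum to one. Ground-truth
defaults ($Hb_{max} = 30$ pg/cell, $EC_{50} = 5$ µmol/L,
$P_{50} = 26.8$ mmHg, $n = 2.7$) sit at physiologically plausible
magnitudes. Every generated table carries a manifest (seed, truth,
generator config) and regenerates bit-identically from it; generators
restore the caller's RNG state.

What passing recovery tests on these data shows is that the estimators
are correct and well-conditioned *under the assumed error model*. Real
dose–response data add donor-to-donor heterogeneity, possibly
non-Gaussian and heteroscedastic error, and batch structure, none of
which the generators emulate — recovery rates here are not a claim
about biological replicates.

## A known tension: "re-loading most apotransferrin"

Equilibrating 13 µmol/L apotransferrin with 52 µmol/L Def₃·Fe³⁺ under
the default corrected constants gives (see the worked example, and
`scripts/acceptance.R`):

```{r reload}
r <- medium_from_recipe(atf_ug_per_ml = 1000, complex_umol_per_l = 52)
st <- solve_equilibrium(r$medium, chelator = r$chelator)
round(c(apo = st$frac_apo, mono = st$frac_mono, holo = st$frac_holo,
        sites = st$tf_site_saturation), 3)
```

94% of transferrin ends up carrying iron and 63% of sites are occupied
— "most apotransferrin is re-loaded" — but the strictly *diferric*
fraction is 32%, not a majority: at this composition the ligand pool is
stoichiometrically tight (156 µmol/L ligand for 52 µmol/L iron), and
free iron settles near $1.4\times10^{-22}$ mol/L where transferrin's
first site ($K_1 f \approx 10$) loads readily but the second
($K_2 f \approx 0.5$) only partially. The result is sensitive to the
assumed pKa: raising the hydroxyl pKa by ~0.25 units would tip the
equilibrium to majority-diferric. The package reports the fractions as
solved and leaves the interpretation explicit rather than tuning
constants to a gel image.

## Limitations

* Equilibrium only: exchange kinetics, medium refreshment schedules and
  cell-population dynamics are out of scope.
* Conditional constants are valid only at the stated pH/bicarbonate;
  transferrin binding carries no modelled pH dependence.
* Only deferiprone ships with stability constants; deferoxamine,
  deferasirox and hinokitiol are stoichiometry-only entries requiring
  user-supplied log β.
* The dose–response and Hill fits are unweighted least squares; no
  between-donor variance model is provided.
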