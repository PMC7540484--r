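# sorbfe

Free-energy and structural analysis of small-molecule sorption in
condensed-phase soil-organic-matter (SOM) models.

Sorption to soil organic matter — here represented by multi-molecule,
periodic Leonardite humic acid (LHA) boxes at two hydration levels —
controls the environmental fate of nutrients and pollutants. `sorbfe`
implements the post-processing side of a physics-based route to sorption
propensities: it turns the raw outputs of perturbation molecular-dynamics
simulations (non-equilibrium work values, λ-schedule derivatives,
coordinate trajectories) into sorption free energies with honest
uncertainties and into the microscopic descriptors that explain them. No
experimental sorption data are needed for calibration; experimental values
enter only for validation, as relative free energies known up to an
additive constant.

The package is aimed at molecular-simulation practitioners. It does not run
MD; a synthetic-data module generates inputs with known ground truth
(Crooks-consistent work distributions, polynomial λ-curves, ideal and
micro-segregated particle boxes, planted hydrogen-bond geometries) so the
whole pipeline is testable at desk scale.

## What it computes

**Free energies from non-equilibrium work.** A sorbate is decoupled from its
surroundings along a coupling parameter λ; each finite-time switching
simulation yields a work value W = ∫₀¹ (∂H/∂λ) dλ. From bidirectional work
sets the decoupling free energy is estimated by

- *Crooks Gaussian intersection (CGI)*: ΔG is the crossing point of the
  Gaussian fitted to the forward works and the Gaussian fitted to the
  negated reverse works (the crossing between the means; with equal widths,
  their midpoint). The Crooks fluctuation relation guarantees the true
  crossing sits at ΔG.
- *Jarzynski equality*: ΔG = −RT ln⟨exp(−W/RT)⟩, evaluated through a
  shifted log-sum-exp.
- Uncertainties by resampling each direction 1,000 times
  (`bootstrap_estimate`), plus convergence profiles over data fractions.

**Thermodynamic integration.** ΔG = ∫₀¹ ⟨∂H/∂λ⟩ dλ by trapezoidal
quadrature on 21 equally spaced λ points, one integral per independent run,
standard error over runs.

**Thermodynamic cycles.** ΔG_sorb = ΔG_vac − ΔG_LHA and
ΔG_hyd = ΔG_vac − ΔG_water, errors in quadrature; relative sorption
ΔΔG = ΔG_sorb(hydrated) − ΔG_sorb(dry); water activity
a_w = exp(ΔG_water→LHA/RT); −RT ln K conversion and non-positive anchoring
for experimental scales.

**Structural descriptors.** Radial distribution functions under the
minimum-image convention; Kirkwood–Buff integrals
G = ∫₀ᴿ 4πr²(g−1) dr at boundaries 0.3/0.4/0.5/1.5 nm (starred variant
multiplied by molar fractions); preferential solvation
δ_B = x_B(G_AB − Σ_α x_α G_Aα)/(V_corr + Σ_α x_α G_Aα) with a 1.5-nm
correlation sphere and heavy-atom molar fractions; geometric hydrogen bonds
(H···A ≤ 0.25 nm and D–H···A angle ≥ 135°); Shrake–Rupley-style SASA with
carbon/heteroatom surface fractions; pairwise Lennard-Jones +
reaction-field electrostatic energies (ε_rf = 61, 1.4-nm cutoff).

**Correlation ledger.** Pearson coefficients, OLS and fixed-slope-1 fits
linking descriptors to sorption free energies, with strength classes for
reporting.

An embedded benchmark (`table1_fixture()`) carries 18 diverse compounds
with calculated dry/hydrated sorption free energies and relative
experimental values for both hydration states.

## Worked example

Estimate a sorption free energy from synthetic, Crooks-consistent work
distributions with a planted truth of 1.5 − (−21.0) = 22.5 kJ/mol:

```r
library(sorbfe)

ws_vac <- crooks_gaussian_workset(dG_true = 1.5,  sigma = 1.5, temperature = 300,
                                  n_per_direction = 75, seed = 11)
ws_lha <- crooks_gaussian_workset(dG_true = -21.0, sigma = 5,  temperature = 300,
                                  n_per_direction = 75, seed = 12)
dG_vac <- bootstrap_estimate(ws_vac, "cgi", n_boot = 1000, seed = 13)
dG_lha <- bootstrap_estimate(ws_lha, "cgi", n_boot = 1000, seed = 14)
sorption_free_energy(dG_vac, dG_lha)
#> Free-energy estimate: 22.31 +/- 0.43 kJ/mol [derived]
```

The estimate recovers the planted 22.5 kJ/mol well within its propagated
bootstrap uncertainty. The same calls accept measured work tables via
`read_work_table()`.

Validation against the embedded benchmark:

```r
t1 <- table1_fixture()
round(pearson(t1$ddG_exp_dry, t1$dG_dry), 2)
#> [1] 0.75
correlation_table(data.frame(dG_sorb = t1$dG_hyd, exp_rel = t1$ddG_exp_hyd))
#> Correlation ledger (1 properties)
#>  property    r    slope intercept    offset strength flag
#>   exp_rel 0.76 1.530561  1.522454 -4.316667   strong
```

Calculated and experimental sorption free energies correlate at r = 0.75
(dry) and 0.76 (hydrated); the regression of calculated on experimental
values is steeper than the identity line, and the slope-1 offset absorbs
the unknown additive constant of the experimental scale.

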