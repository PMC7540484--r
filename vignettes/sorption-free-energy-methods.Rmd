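---
title: "Methods: free energies and structural descriptors of sorption in SOM models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free energies and structural descriptors of sorption in SOM models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorbfe)
```

# The model and its assumptions

Sorption of a small organic molecule into a condensed-phase soil-organic-
matter (SOM) matrix is quantified through a thermodynamic cycle. The
sorbate's interactions with its surroundings are scaled by a coupling
parameter λ from fully interacting (λ = 0) to a non-interacting dummy
(λ = 1). The free energy of decoupling is computed once in vacuum and once
in the environment of interest, and the sorption (or hydration) free energy
is their difference:

ΔG_sorb = ΔG_vac − ΔG_env.

Because the sum of free-energy changes around a closed cycle vanishes, the
composition is exact; all approximation lives in the individual decoupling
estimates. `sorbfe` starts where the molecular-dynamics engine stops: its
inputs are work values, λ-derivatives and coordinates, not force-field
trajectories.

## Non-equilibrium work estimators

Each finite-time switching simulation yields a work value
W = ∫₀¹ (∂H/∂λ) dλ. The sign convention is fixed throughout: *forward*
means removing the sorbate (λ 0 → 1) and *reverse* means growing it
(λ 1 → 0). Reverse works are negated before any fitting so that both
distributions live on the same free-energy axis.

**Crooks Gaussian intersection (CGI).** If the forward and negated-reverse
work distributions are Gaussian, the Crooks fluctuation relation forces
their densities to cross exactly at ΔG. We fit both by sample moments
(mean, n−1 standard deviation — at the production sample size of 75 values
per direction the difference from a maximum-likelihood fit is negligible,
and moments are testable in closed form) and solve the density-equality
quadratic. Of its two roots we take the one between the two means, the
physically meaningful crossing. Two degenerate situations are handled
explicitly:

- (near-)equal fitted widths: the crossing degenerates to the midpoint of
  the means, which is returned directly;
- unequal sample widths but means so close that no root lies between them
  (common in bootstrap resamples at low dissipation): the equal-width
  limit — the midpoint — is returned and the estimate is flagged
  `degenerate_crossing`. A hard failure is reserved for a negative
  discriminant.

When the two means are separated by more than four pooled standard
deviations the overlap of the distributions is too poor for the
intersection to be trustworthy and the estimate carries a `poor_overlap`
flag.

**Jarzynski equality.** ΔG = −RT ln⟨exp(−W/RT)⟩ for forward work (sign
flipped for reverse). The exponential average is evaluated through a
shifted log-sum-exp so arbitrarily large work values cannot overflow. The
estimator is biased from above (Jensen) at finite n and its variance is
dominated by rare low-work tails once σ/RT exceeds ~1; this is exactly the
regime in which CGI's use of both directions pays off, and the convergence
comparison in the test suite asserts that behaviour.

**Bootstrap.** Uncertainties come from resampling the work distributions
1,000 times (the default `n_boot`). Each direction is resampled
independently, with replacement, at its own sample size; the resampling
unit is the individual work value, with the 25 runs × 3 replicate models
per direction pooled into one distribution (per-model labels are retained
in `work_set` for optional stratified analyses). The reported value and
uncertainty are the mean and standard deviation over the resampled
estimates; a fixed seed makes the procedure bit-reproducible.

**Convergence profiles.** `convergence_profile()` re-estimates on nested
fractions of the data. Subsampling is *without* replacement by default
(with-replacement offered via `replace = TRUE`); each fraction derives its
own subsampling stream from the seed, and fraction 1.0 skips subsampling
entirely so it reproduces `bootstrap_estimate()` on the same seed path.

## Thermodynamic integration

⟨∂H/∂λ⟩ curves on 21 equally spaced λ points (the standard protocol) are
integrated per run by the composite trapezoidal rule; the estimate is the
mean over the (default five) independent runs. The uncertainty is the
standard error over runs — sd/√n — chosen because the runs are independent
repetitions of the same protocol; a single run yields uncertainty 0 with a
`single_run` warning flag. Integration per run followed by averaging is
numerically identical to averaging curves first, but the run-level
integrals are what define the error model.

The trapezoid on 21 points is exact for linear integrands and carries the
classical h²/12 · [f′(1) − f′(0)] error otherwise: 6.25 × 10⁻⁴ for a pure
cubic, which the tests assert as an exact quantity rather than an opaque
tolerance.

## Thermodynamic cycles and experimental scales

Cycle composition propagates errors in quadrature. Experimental
sorption free energies derive from humic-acid/air partition coefficients as
−RT ln K + c with c an unknown additive constant; the package never
estimates c. All calculated-vs-experimental comparisons use statistics that
are invariant to additive shifts: Pearson correlation, OLS slope, and the
slope-1 offset mean(y − x). `anchor_nonpositive()` reproduces the
convention of shifting an experimental set so its maximum is zero; note
that the embedded benchmark's experimental columns were anchored on the
larger source compound set, so their maximum is −1.8 rather than 0 — the
operation anchors whatever set it is given, and downstream statistics do
not depend on the choice.

Report rounding is one decimal in kJ/mol (two decimals for correlation
coefficients); internal arithmetic is never rounded.

## Structural descriptors

All coordinates are in nm in rectangular periodic boxes; distances use the
minimum-image convention.

- **RDF**: shell counts between two selections, normalised per frame by the
  ideal-gas expectation (pair density × exact shell volume), averaged over
  frames. `r_max` may not exceed half the smallest box edge.
- **Kirkwood–Buff integrals**: trapezoid of 4πr²(g−1) on bin centres,
  anchored at r = 0 with g = 0 (the empty innermost shell contributes
  g − 1 = −1), with linear interpolation at an upper boundary that falls
  between centres. Boundaries of 0.3/0.4/0.5 nm probe the first
  coordination environment; 1.5 nm is the full correlation range. The
  starred variant multiplies by x_A·x_B and measures contacts.
- **Preferential solvation**: δ_B = x_B(G_AB − S)/(V_corr + S) with
  S = Σ_α x_α G_Aα, V_corr the volume of a 1.5-nm sphere, and molar
  fractions computed as normalised heavy-atom counts over the whole system.
  RDFs entering the KB integrals use heavy atoms only, consistent with the
  fractions; the sorbate's own selection is its heavy atoms, so the
  correlation volume is effectively centred on the sorbate's geometry.
- **Hydrogen bonds**: a D–H···A triple counts when |H···A| ≤ 0.25 nm and
  the angle at the hydrogen between H→D and H→A is ≥ 135°, both boundaries
  inclusive. The angle is evaluated at the hydrogen (180° = linear); an
  acceptor identical to the donor atom is skipped. An H-centred convention
  is the only one implemented; donors must be supplied with their attached
  hydrogens, which keeps the operation agnostic to topology formats.
- **SASA**: numeric sphere sampling with a deterministic golden-spiral
  lattice (default 960 points — 1% accuracy on an isolated sphere), probe
  radius 0.14 nm (water-sized). Hydrogen-class particles are merged with
  their heavy atoms (united-atom convention) and excluded from the sphere
  set; occlusion is evaluated within the selected atom set. Per-atom areas
  are attributed to carbon vs heteroatom classes and reported as fractions.
- **Pair interaction energies**: sum over unique cross-group pairs within a
  single 1.4-nm cutoff; Lennard-Jones C12/r¹² − C6/r⁶ with geometric
  combination of per-particle parameters, and Coulomb with a reaction-field
  correction for a continuum of ε_rf = 61 beyond the cutoff at zero ionic
  strength. The triple-range pair list used by MD engines is an efficiency
  device only; a single analysis cutoff differs negligibly for these
  descriptors.

## Key parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| temperature | 300 | K | simulation condition of the production systems |
| R | 8.314 × 10⁻³ | kJ mol⁻¹ K⁻¹ | gas constant |
| `n_boot` | 1000 | — | resampling depth for uncertainties |
| λ grid | 21 points | — | standard equally spaced TI schedule |
| TI runs | 5 | — | independent repetitions defining the standard error |
| KB boundaries | 0.3/0.4/0.5/1.5 | nm | local environment / full correlation range |
| H-bond criterion | 0.25 nm, 135° | | geometric definition, boundaries inclusive |
| SASA probe, points | 0.14 nm, 960 | | water-sized probe; 1% sphere accuracy |
| pair cutoff, ε_rf | 1.4 nm, 61 | | reaction-field electrostatics convention |

# The synthetic-data generators

The generators supply inputs with the statistical structure the estimators
assume, plus planted ground truth:

- `crooks_gaussian_workset()` draws forward works from
  N(ΔG + σ²/2RT, σ) and reverse works from N(−ΔG + σ²/2RT, σ) — the unique
  Gaussian pair satisfying the Crooks relation for the planted ΔG. The gap
  between the forward and negated-reverse means is the dissipated work
  σ²/RT. The Gaussian model is chosen because CGI itself assumes it;
  heavier-tailed stress variants can be built by composing work sets.
- `polynomial_lambda_curve()` adds iid Gaussian noise to a polynomial
  λ-curve and stores the analytic integral.
- `ideal_gas_box()` is the structural null: uniform positions, deterministic
  largest-remainder composition, so g → 1, G → 0 and δ → 0.
- `clustered_mixture_box()` splits the box into water-rich and matrix-rich
  halves; each species falls into its preferred half with probability
  0.5 + 0.5·s/(1+s) (s = association strength; s = 0 recovers the ideal
  box), and a compact six-atom sorbate cluster is planted at the centre of
  the requested region. Defaults (400 LHA, 300 water, 20 calcium heavy
  atoms in a 6-nm box, s = 4) give unambiguous planted δ signs while
  staying desk-sized. Geometric regions, not an energy model, are enough to
  plant the signs the analysis must recover.
- `planted_hbond_frame()` places ideal D–H···A triples (0.18–0.24 nm,
  150–180°) and decoys violating exactly one criterion each on a sparse
  grid, so the true count is exact.

Every generator requires a seed and is bit-reproducible.

**What passing tests show — and what they do not.** The synthetic suites
verify the estimators and descriptors against constructions that satisfy
their assumptions exactly (Gaussian work, uniform or two-region mixing,
isolated H-bond geometries). Real trajectories violate these assumptions in
ways the generators do not emulate: anharmonic work tails, slow matrix
relaxation that biases the removing direction, genuine solvation structure
in g(r), force-field energetics. Passing therefore demonstrates
correctness of the computation, not accuracy of an MD workflow; absolute
sorption free energies of the 18-compound benchmark are carried as a fixed
reference table, not recomputed.

# Numerical choices and degenerate inputs

- Sample sizes in the test suite: work sets of 75 values per direction
  (the production budget) up to 10⁴ for convergence checks; ideal-gas boxes
  of 2,000 particles over 3–4 independent frames, which gives shell
  statistics adequate for the ±0.05 RDF flatness band; 500 regenerations
  for repeated-generation oracles.
- Bootstrap failure policy: an estimator error on a resample is recorded,
  not fatal; the estimate fails only if more than half the resamples fail.
- `convergence_profile` seeds: per-fraction subsampling streams are derived
  as seed + 7919·i so fractions are independent yet reproducible.
- KB integration uses bin centres with the r = 0 anchor described above;
  this makes g ≡ 1 integrate to exactly 0 apart from the empty anchor bin.
- RDF chunking bounds memory at ~2 × 10⁶ pair distances per block, so
  large single frames stream rather than allocate.
- GRO positions are written at 3-decimal nm precision; round-tripping a
  written file is exact with respect to the written (quantised) values.
- Pipeline reports embed the seed and an FNV-1a hash of the deparsed
  configuration; identical inputs yield byte-identical JSON.

# Known limitations

- CGI inherits the Gaussian assumption; strongly bimodal work
  distributions are flagged at best (`poor_overlap`), not modelled.
- Only rectangular boxes; no triclinic minimum image.
- The pair-energy descriptor covers nonbonded terms only — no bonded
  contributions, constraints or virial, and no intra-group energies.
- SASA radii must be supplied per particle; no built-in radii table is
  claimed beyond the 0.15-nm default placeholder.
- The correlation ledger reports raw coefficients without multiplicity
  correction, matching its exploratory role.
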