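Package: sorbfe
Title: Sorption Free Energies and Microscopic Descriptors for Soil Organic Matter Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates solvation and sorption free energies of small organic
    molecules in condensed-phase soil-organic-matter (humic acid) models from
    non-equilibrium work distributions (Crooks Gaussian intersection and
    Jarzynski estimators with bootstrap uncertainties) and from thermodynamic
    integration over a lambda schedule, composes them through thermodynamic
    cycles into sorption, hydration and relative free energies with propagated
    errors, and computes structural descriptors of sorbate-matrix association
    from periodic particle configurations: radial distribution functions,
    Kirkwood-Buff integrals, preferential solvation coefficients, geometric
    hydrogen bonds, solvent-accessible surface area with element-class
    fractions, and pairwise reaction-field/Lennard-Jones interaction energies.
    A correlation ledger links the descriptors to sorption propensity, and a
    synthetic-data module generates work sets, lambda curves and particle
    boxes with known ground truth so the full pipeline is testable without a
    molecular dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
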