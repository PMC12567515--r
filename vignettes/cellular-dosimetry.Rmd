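---
title: "Cellular-scale dosimetry for boron-based binary radiotherapies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular-scale dosimetry for boron-based binary radiotherapies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldose)
```

## The problem

Two binary radiotherapies exploit boron chemistry to concentrate dose inside
tumour cells. Boron neutron capture therapy (BNCT) relies on
$^{10}\mathrm{B}(n,\alpha)^{7}\mathrm{Li}$: a thermal neutron captured on
boron-10 releases an α particle and a lithium recoil whose combined range is
below one cell diameter, so the dose is deposited where the boron sits.
Proton–boron fusion therapy (PBFT) relies on
$p + {}^{11}\mathrm{B} \rightarrow 3\alpha$ (Q = 8.7 MeV), resonant near a
proton energy of 675 keV with a cross section of about 1 barn, proposed as an
in-situ enhancer of proton therapy.

`celldose` implements the cellular-scale dosimetry for both modalities
around a boron-rich small molecule — the ferrabis(dicarbollide) anion
[3,3′-Fe(1,2-C₂B₉H₁₁)₂]⁻, 18 boron atoms and one iron atom per anion —
together with the assay analyses (uptake, viability, clonogenic survival,
proliferation, ROS kinetics) used to interpret irradiation experiments on
breast cancer cell lines, and synthetic generators for every input so the
whole pipeline is testable without measured data.

## Reaction kinematics

A capture at rest shares its kinetic release $Q$ between two products by
momentum conservation, $E_a = Q\, m_b/(m_a+m_b)$. The two capture channels
are:

* 94%: $Q = 2.31$ MeV → α 1.47 MeV + ⁷Li 0.84 MeV, followed by a 0.48 MeV
  de-excitation photon;
* 6% (ground state): $Q = 2.79$ MeV → α 1.78 MeV + ⁷Li 1.01 MeV.

```{r kinematics}
solve_two_body(2.31, 4, 7)
solve_two_body(2.79, 4, 7)
ch <- bnct_channels()
channel_photon_energy(ch$ground, ch$excited)
```

Kinematics are nonrelativistic with integer mass numbers: at these energies
the relativistic correction is parts in 10⁴, far below the two-decimal
precision at which the product energies are conventionally quoted.

## Stopping power and ranges

All charged-particle transport rests on one stopping model: the first-order
Bethe formula with a material-level mean excitation energy (water
$I = 75$ eV by convention, Mylar 78.7 eV, air 85.7 eV, boron 76 eV) and a
Barkas effective charge for helium ions. Below the formula's validity limit
(0.5 MeV for protons; the velocity-equivalent ≈2 MeV for α particles) a
power law matched in value and log-slope at the junction continues the curve
smoothly to the 1 keV transport cutoff. No shell, Barkas-correction or
density-effect terms are included; against published tabulations this
parameterization is accurate to roughly 2–4% over 0.5–20 MeV, which is
adequate here because every reproduced quantity is either exact arithmetic
or a ratio of doses computed with the same model.

CSDA ranges are the quadrature $R(E) = \int_0^E dE'/S(E')$ (relative
tolerance $10^{-8}$); the integrand vanishes at zero energy under the
power-law continuation, so the integral is proper.

```{r stopping}
let_keV_um(c(0.675, 2), "proton")   # resonance protons ionize more densely
csda_range(c(0.675, 2), "proton")[, c("energy_MeV", "range_um")]
```

A 675 keV proton ranges out after about 12.5 µm of water — half a cell
diameter. This matters for the enhancement study below: resonance-energy
protons stop inside the cell, so the nanoshell doses are dominated by
stopping tracks.

## Geometry

The cell is the standard concentric-sphere idealization used in cellular
dosimetry: cytoplasm of radius 12.5 µm, nucleus of radius 5 µm, and — for
the fusion study — a 1.5 µm boron sphere at the nucleus centre wrapped in
ten contiguous 10 nm water scoring shells (1-based outward). Coordinates are
Cartesian µm with the beam along +z; boundary ties belong to the inner
region, deterministically. Ray tracing solves sphere intersections exactly
and the region volumes close to the cell volume to $10^{-9}$ relative.

The upstream degrader (air path plus Mylar foils) is tuned by bisection on
the free air path so that the transported mean energy at the cell entrance
hits a target within ±10 keV; Bohr straggling accumulated across the stack
sets the Gaussian entrance-energy spread (≈23 keV sigma for 2 MeV → 675
keV), which the cell-level simulation inherits.

```{r degrader}
st <- tune_degrader(2.0, 675)
c(mean_keV = attr(st, "mean_MeV") * 1e3, sigma_keV = attr(st, "sigma_MeV") * 1e3)
```

## Monte Carlo transport

Transport is condensed-history CSDA on straight tracks: no multiple Coulomb
scattering and no nuclear elastic interactions, a deliberate simplification
defensible over sub-30 µm paths where lateral displacement is small compared
with every scoring dimension. Numerical choices:

* step length = min(distance to the next sphere boundary, length giving 1%
  fractional energy loss), with a midpoint-corrected mean loss per step;
* particles are killed below 1 keV and deposit the residual locally;
* boundary-crossing deposits are attributed by stepping exactly to the
  boundary (the step never straddles two regions);
* Bohr straggling is a per-step Gaussian, off by default inside the cell and
  applied analytically in the degrader;
* batch $b$ of a run is seeded `seed + b`, making every tally
  bit-reproducible; each batch is a full-fluence estimate and the batch
  spread gives the relative standard error.

The kernel conserves energy exactly (deposits plus escapes equal the
injected energy to rounding) and its track lengths reproduce the quadrature
CSDA range to better than 0.5%; a broad beam on a thin water sphere
reproduces the analytic thin-target dose $\Phi\, S(E)/\rho$ within 1%.

```{r run, eval = FALSE}
cell <- cell_model()
run_mc(beam_spec(2.0, "broad"), cell, n_histories = 3e4, seed = 1)
```

### Beam fields and the reported dose

The spot size of the modelled microbeam (70 × 70 µm²) and the total of
2 × 10⁸ protons fix the fluence, but a cellular absorbed dose also depends
on how that field overlaps a given cell — a quantity the available
description leaves open. The package therefore exposes the field as
configuration (`square`, `broad`, `point`), importance-samples square fields
over the cell's cross-section disk, and always reports dose per unit
fluence, so any field assumption can be scaled without re-running. For the
same reason the average LET over a well depends on an unstated averaging
convention; `let_keV_um()` gives the track LET at any energy and the tallies
give the energy-weighted picture.

## The two-step fusion enhancement procedure

Evaluated cross-section data for $p+{}^{11}\mathrm{B}\rightarrow 3\alpha$ in
the resonance region are not available to general-purpose transport codes,
so the enhancement is computed in two decoupled steps:

1. transport the degraded proton beam and score the shell doses $D_p(k)$;
2. replace the boron sphere by an isotropic, mono-energetic 3 MeV α emitter
   (the mean energy of the 3α final state) and score $D_\alpha(k)$, weighting
   the source so its total statistical weight equals the expected α count.

The expected count comes from the thin-target yield $Y_{3\alpha} = \sigma_R
\times n_B$ with $\sigma_R = 1$ barn, multiplied by the fluence through the
boron sphere and by three α per reaction. For $n_B$ the package implements
two readings:

* **solid sphere** (default): the mean chord $4r/3 = 2$ µm of the 1.5 µm
  sphere times the ¹¹B atom density of elemental boron (2.37 g/cm³, 80.1%
  ¹¹B), giving $n_B = 2.11\times10^{-5}$ atoms/barn and ≈18 α for 2 × 10⁸
  protons in the 70 × 70 µm² field;
* **dissolved**: a stated concentration (µg/g) along a stated path (e.g.
  the 25 µm cell chord), which at realistic cellular loadings yields orders
  of magnitude fewer α.

Only the first reading reproduces the ≈18 α worked value, so it is the
default; both are kept because the provenance of $n_B$ in the original
yield evaluation is not stated.

```{r alpha-count}
expected_alpha_count(pbft_config())
```

α emission points are uniform over the sphere volume (the natural reading of
treating the sphere as the emitter) and the α weighting uses the expected
count rather than a Poisson draw, so shell tallies are deterministic given
the seed. Enhancement per shell is $(D_p + D_\alpha)/D_p$, and its quoted
uncertainty is the combined statistical resolution
$\sqrt{\sigma_p^2+\sigma_\alpha^2}/D_p$ of comparing the enhanced against
the unenhanced dose: "indistinguishable from 1" means the α contribution
lies below what tallies at the stated precision could resolve. At the study
conditions the α contribution is a few parts in 10⁵ of the proton shell
dose — the enhancement from the fusion reaction alone is negligible, which
is exactly the conclusion the dosimetry supports, and shifts the burden of
explaining the observed radiosensitization to chemistry (ROS production).

Run sizes: the shipped defaults (10⁵ proton histories, 2 × 10⁴ α histories,
10 batches) hold the nucleus and cytoplasm doses below 1% relative error and
all ten shell doses below 10%, mirroring the uncertainty targets of the
modelled study; a default run takes seconds to a couple of minutes on one
core.

### Internal consistency of the modelled setup

One tension is worth recording: a 675 keV proton cannot cross 25 µm of water
(its range is ~12.5 µm), so a mean energy of 675 keV *inside* the cell and a
mean of ~600 keV at the far side cannot both hold for a water sphere of this
size. The package models the entrance energy as the tuned quantity
and lets resonance protons stop inside the cell; users who prefer a
crossing-beam configuration can raise the entrance energy in the config.

## Thermal-neutron dose components

For in-vitro neutron irradiation the dose decomposes into a boron component,
an endogenous-element component and field terms. `component_doses()` uses
the kerma approximation — fluence × atom density × thermal (2200 m/s) cross
section × locally deposited energy — with σ(¹⁰B(n,α)) = 3837 b and
σ(¹⁴N(n,p)) = 1.83 b (0.626 MeV proton). The boron energy per capture is
branch-weighted, 0.94 × 2.31 + 0.06 × 2.79 MeV, with a flag to use the
dominant channel only. Two deliberate exclusions:

* the 478 keV boron-capture photon is excluded from local dose: a sub-mm
  in-vitro sample is far from photon equilibrium, and the diagnostic
  `boron_photon_dose()` confirms the excluded term stays under 1% of the
  boron component for thicknesses up to 1 mm;
* by the same argument the 2.22 MeV hydrogen-capture photons are not
  transported; the ¹H term enters as a configured field dose instead.

The table across a ¹⁰B grid keeps the structure such results are reported
in: absolute Gy and percentage per component, non-boron rows constant,
boron strictly increasing and linear through the origin, percentages
summing to 100.

```{r bnct}
field <- neutron_field(1e12, background_gamma_Gy = 0.05, hydrogen_dose_Gy = 0.1)
build_table(field, tissue_composition(), c(0, 1, 5, 10))[, 1:5]
```

The thermal fluence is a free parameter because the fluence delivered by a
reactor thermal column in a given irradiation is facility calibration data;
1 × 10¹² n/cm² is a representative default. Cellular uptake converts to
tissue ppm via `ppm_from_uptake()`: ng of boron per 10⁶ cells, a packing
density of 10⁸ cells/cm³ (typical for epithelial tumours), and the 19.9%
¹⁰B fraction of natural boron.

## Assay analyses and their generators

The analysis stages are deliberately plain and each is paired with a
generator whose ground truth it must recover:

* `fold_change()` — ratio of compartment means, reported to 2 significant
  figures rounded half away from zero (the convention behind quoting
  "1.7-fold"/"2.2-fold");
* `b_fe_ratio()` — measured B:Fe mass ratio per compartment against the
  stoichiometric 18 × 10.811/55.845 = 3.484 (the molar ratio 18 is also
  reported, since a "ratio of about three" is only meaningful as a mass
  ratio);
* `growth_rate()` — $(N(t_i)-N(t_0))/N(t_0) \times 100$ with any
  cell-number proxy (total protein), hence scale-invariant;
* `survival_fraction()` — colonies/(seeded × control plating efficiency),
  the standard clonogenic definition;
* `ros_fold()` — pointwise ratio of mean fluorescence against the
  non-irradiated treated reference, delta-method SD;
* `fit_ic50()` — four-parameter logistic by Levenberg–Marquardt least
  squares with IC50 on the log scale and the top left free (plates rarely
  normalize perfectly); Wald 95% CI on log(IC50). A response that increases
  with dose is flagged, never silently summarized as an IC50.

Generator noise families are fixed: lognormal (mean-parameterized) for
concentrations and fluorescence, Poisson for colony counts, Gaussian for
pixel maps, lognormal inter-animal scatter around mono-exponential organ
kinetics for biodistribution. Defaults use the magnitudes of the modelled
study (IC50 83.5 and 103 µM, elemental-map levels 250/430 µg/g vs 150/200
µg/g, 7.5 mg B/kg) so demonstration output looks like real data. What the
generators do *not* emulate: plate-position effects, heteroscedastic
detector noise, correlated replicates, non-exponential pharmacokinetics and
real image texture — so passing round-trip tests validates the estimators'
arithmetic and statistical behaviour, not robustness to real-world artefact
structure.

Verified statistical behaviour at the shipped settings: the IC50 Wald
interval covers the truth in well over 90% of generator replicates; the
clonogenic estimator is unbiased to ±0.05 at three wells; the B:Fe ratio
converges to 3.484 (law of large numbers, checked at n = 10⁴); organ
kinetics are recovered within 5% by log-linear regression.

## Known limitations

* No multiple scattering, nuclear elastics, secondary electrons or photon
  transport: absolute doses carry the few-percent stopping-model bias and
  nanoshell doses exclude δ-ray redistribution.
* The 3α final state is a mono-energetic 3 MeV surrogate, not a sampled
  three-body spectrum; an energy-spectrum hook exists but defaults off.
* The kerma treatment of neutron components assumes charged products deposit
  locally, valid for cell-scale targets but not for photon-dominated terms —
  which is why those enter as configuration.
* Single spherical cell; no monolayer flattening, no cell-to-cell boron
  heterogeneity.
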