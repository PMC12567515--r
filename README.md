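# celldose

Cellular-scale dosimetry and assay analysis for boron-based binary
radiotherapies: boron neutron capture therapy (BNCT) and proton–boron fusion
therapy (PBFT), built around a boron-rich small-molecule radio enhancer (the
ferrabis(dicarbollide) anion, 18 B : 1 Fe) in breast cancer cells. It is
aimed at radiation biophysicists and medical-physics researchers who want
desk-scale, reproducible estimates of the doses a single cell receives under
proton or thermal-neutron irradiation, and at experimentalists analysing the
accompanying uptake/viability/survival/ROS assays.

## What it computes

**Capture kinematics.** The ¹⁰B(n,α)⁷Li reaction shares each channel's
kinetic release *Q* between the products by momentum conservation,
*E*ₐ = *Q·m*ᵦ/(*m*ₐ+*m*ᵦ): the 94% channel (*Q* = 2.31 MeV) gives a
1.47 MeV α and a 0.84 MeV ⁷Li plus a 0.48 MeV photon; the 6% ground-state
channel (*Q* = 2.79 MeV) gives 1.78 and 1.01 MeV.

**Monte Carlo cell dosimetry.** A condensed-history CSDA transport kernel
(Bethe stopping with a matched low-energy continuation, Rcpp inner loop)
moves protons and α particles through a concentric-sphere MIRD cell —
cytoplasm radius 12.5 µm, nucleus 5 µm, optional 1.5 µm boron sphere wrapped
in ten 10 nm scoring shells — behind an air/Mylar degrader tuned to the
675 keV p+¹¹B resonance. Tallies give per-region dose in Gy with batch
statistics and dose per unit fluence.

**Two-step fusion enhancement.** With no evaluated resonance cross sections
available to transport codes, the fusion contribution is estimated by (1)
scoring shell doses under the proton beam, then (2) re-emitting from the
boron sphere as an isotropic 3 MeV α source weighted by the thin-target
yield *Y*₃α = σ_R·*n*_B (σ_R = 1 barn; *n*_B from the sphere's mean chord
4r/3), about 18 α for 2×10⁸ protons in a 70×70 µm² field.

**Thermal-neutron dose components.** A kerma-style calculator decomposes
the in-vitro neutron dose into ¹⁰B, ¹⁴N, ¹H and background-gamma components
across a grid of ¹⁰B loadings (ppm), with the 478 keV capture photon
excluded under the thin-sample non-equilibrium argument.

**Assay analysis + synthetic data.** Fold changes, B:Fe stoichiometry
(mass ratio 3.484), growth rate, clonogenic survival, ROS fold-change
kinetics and 4PL IC50 fitting — each paired with a seeded generator that
emits known ground truth.

## Worked example

```r
library(celldose)

solve_two_body(2.31, 4, 7)
#>  E_a  E_b
#> 1.47 0.84

expected_alpha_count(pbft_config())
#> [1] 18.30558

rep <- run_two_step(pbft_config(seed = 42))   # ~15 s; full defaults
head(as.data.frame(rep), 3)
#>   shell dose_p_Gy rel_err_p dose_a_Gy rel_err_a enhancement enhancement_se
#> 1     1    351089    0.0462      18.8   0.00200           1         0.0462
#> 2     2    346486    0.0486      18.2   0.00189           1         0.0486
#> 3     3    355515    0.0830      17.7   0.00181           1         0.0830
```

The two-body solve reproduces the printed capture product energies exactly.
The yield reconstruction gives ≈18 expected α particles. In the two-step
report, each shell's proton dose is a few 10⁵ Gy (2×10⁸ protons concentrated
into nanogram shells) while the 18 fusion α contribute ~16–19 Gy — an
enhancement of a few parts in 10⁵, far below the tallies' statistical
resolution (`enhancement_se`): the fusion reaction alone does not measurably
raise the nanoshell dose.

```r
build_table(neutron_field(1e12, 0.05, 0.1), tissue_composition(),
            c(0, 1, 5, 10))[, c("ppm_10B", "boron_Gy", "boron_pct", "total_Gy")]
#>   ppm_10B boron_Gy boron_pct total_Gy
#> 1       0   0.0000       0.0    0.426
#> 2       1   0.0865      16.9    0.513
#> 3       5   0.4324      50.4    0.859
#> 4      10   0.8647      67.0    1.291
```

At 10¹² n/cm² each ppm of ¹⁰B adds 0.086 Gy of locally deposited
capture-product dose; the non-boron components stay fixed while the boron
share of the total climbs with loading.

```r
fit_ic50(gen_dose_response(ic50 = 83.5, seed = 7))
#> 4PL dose-response fit: IC50 = 82.8 (95% CI 70.4-97.5)
#>   top 1.03, bottom 0.0608, hill 1.64

fold_change(250, 150)$reported   # cytoplasm Fe, treated vs control
#> [1] 1.7
```

## Documentation

The methods vignette (`vignettes/cellular-dosimetry.Rmd`) describes the
stopping-power model and its accuracy, the transport and scoring choices,
both readings of the yield formula's areal density, the kerma exclusions,
and what the synthetic generators do and do not emulate.
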