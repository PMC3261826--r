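# neutronplan

A voxel Monte Carlo dose engine for first-steps **fast-neutron therapy
planning** at a reactor-based beamline. Clinical dose estimation at such
facilities traditionally relies on water-phantom depth-dose tables; moving to
patient-specific planning needs an engine that can transport the mixed
neutron/photon beam through a voxelised anatomy and produce the standard
planning outputs. `neutronplan` implements that pipeline end to end, in R with
a compiled transport kernel, for physicists prototyping planning studies and
for teaching the anatomy of such an engine.

What it does:

* samples primaries from binned energy spectra by inverse CDF
  (a synthetic fission-beam generator stands in for the measured spectrum:
  Watt shape, a = 0.988 MeV, b = 2.249 MeV⁻¹, plus a 300 K thermal tail),
* transports neutrons (isotropic-CM elastic scattering with free-gas thermal
  motion below 4 eV, 1/v radiative capture with the 2.2246 MeV hydrogen
  capture gamma) and photons (Klein–Nishina Compton, parametric
  photoelectric and pair production) through a solid-box water phantom with a
  40-chamber scoring array, a 10.6-million-voxel water phantom, an optional
  concrete treatment room, and a synthetic anthropomorphic head phantom with
  six salivary-gland ROIs,
* scores absorbed dose per particle type under the kerma approximation with
  history-by-history statistical errors: per region the engine keeps
  per-history sums Σx and Σx², so the dose per unit primary fluence is
  D = (Σx/n)/m · A_beam (Gy cm²) with standard error
  √((Σx²/n − (Σx/n)²)/(n−1))/m · A_beam,
* derives depth-dose curves, lateral profiles, cumulative DVHs
  V(D) = fraction of organ volume with dose ≥ D, RBE-weighted doses
  (D_w = Σ_tag w_tag D_tag, clinical w = 3 for the neutron lineage),
  least-squares photon renormalisation, and spline + marching-squares isodose
  contours.

## Worked example

A 9 × 9 cm² parallel neutron beam (total fluence rate 3.2·10⁸ cm⁻²s⁻¹) on the
solid-box water phantom:

```r
library(neutronplan)

spectrum <- synthetic_medapp_spectrum("neutron", total_rate = 3.2e8)
beam     <- beam_config(9, 9, center = c(-100, 0, 0))
run      <- run_simulation(solid_box_phantom(), beam, spectrum,
                           transport_config(2e5, seed = 1))
run
#> <mc_run> neutron beam, 200000 histories, chamber geometry, 1.9 s
#>   energy balance: max per-history imbalance 1.28e-15
#>   deposited fraction of available energy: 0.894

dd <- depth_dose(run)
head(scale_depth_dose(dd, fluence_rate = 3.2e8), 3)
#>   depth_cm        dose           se
#> 1      0.5 0.007383940 0.0005828847
#> 2      1.5 0.008306286 0.0007569180
#> 3      2.5 0.006587435 0.0006485123
```

The chamber at 0.5 cm depth sees ≈ 7.4 mGy/s (± 8%, one standard deviation of
the history-by-history estimate): a 3-minute irradiation delivers ≈ 1.3 Gy at
the surface, and the dose falls off with an attenuation length of a few
centimeters — the depth-dose curve the facility's calibration tables are
built on. `depth_dose()` on a voxelised run pools 4 × 2 voxels (0.16 cm³)
around the beam axis; `cumulative_dvh()`, `apply_rbe()` and
`isodose_contours()` take it from a head-phantom dose grid to the planning
outputs.

## What to read next

The methods vignette (`vignettes/methods.Rmd`) documents the interaction
model and its assumptions, the free-gas substitution for thermal scattering,
the kerma approximation, the RNG design, what the synthetic spectrum and head
phantom do and do not emulate, and the engine's known limitations.
`inst/extdata/PROVENANCE.md` records where every packaged physical constant
comes from.
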