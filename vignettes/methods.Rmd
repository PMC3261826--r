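---
title: "Methods: the neutronplan Monte Carlo dose engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the neutronplan Monte Carlo dose engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`neutronplan` is a self-contained Monte Carlo engine for first-steps
treatment-planning studies at a reactor-based fast-neutron therapy beamline.
It transports neutrons and photons sampled from binned source spectra through
a water calibration phantom (as a solid box with a scoring-chamber array, or
fully voxelised) and through a voxelised anthropomorphic head phantom, scores
absorbed dose per particle type with per-history statistical errors, and
derives the standard planning outputs: depth-dose curves, lateral profiles,
cumulative dose-volume histograms (DVHs), RBE-weighted doses and isodose
contours.

This vignette explains the physical model, its assumptions and the numerical
choices, so that results can be interpreted — and mistrusted — correctly.

## Transport model

### Neutrons

Two interaction channels are modelled per element:

* **Elastic scattering**, isotropic in the centre-of-mass frame. With target
  mass number $A$ and $\alpha = ((A-1)/(A+1))^2$, the outgoing energy for a
  stationary target is $E' = E\,[(1+\alpha) + (1-\alpha)\mu_{cm}]/2$, so
  $E'/E$ is uniform on $[\alpha, 1]$ and the mean lethargy gain on hydrogen
  is 1. Below 4 eV the target is given free-gas Maxwellian motion at 300 K
  (target velocities sampled with the standard relative-speed rejection), so
  the neutron population equilibrates near thermal energies instead of
  cooling indefinitely. This free-gas model **replaces** molecular
  thermal-scattering laws such as S($\alpha$,$\beta$); bound-atom effects in
  water (an enhanced effective cross section and inelastic energy transfer
  below ~1 eV) are not reproduced, which biases the thermalised part of the
  spectrum at depth. The bias mostly affects where thermal captures happen,
  not the fast-neutron (hydrogen-recoil) dose that dominates the therapeutic
  signal.
* **Radiative capture**, with $1/v$ cross sections anchored at 2200 m/s
  values. Hydrogen emits its single 2.2246 MeV capture gamma isotropically;
  for all other elements the capture Q-value is deposited locally — their
  capture-gamma transport is a second-order effect in tissue, where hydrogen
  dominates absorption. Nitrogen's (n,p) channel is out of scope; this biases
  the thermal-neutron dose in nitrogen-bearing tissue low by design.

Cross sections come from packaged smooth log-log anchor tables (resonances
omitted; see `inst/extdata/PROVENANCE.md`). Inelastic channels and charged
particle production reactions are not modelled, so doses above ~10 MeV
incident energy are underestimated; the fission-spectrum beam carries little
fluence there.

### Photons

Compton scattering (Klein-Nishina, sampled by rejection on $E'/E$),
photoelectric absorption (parametric $\sigma \propto Z^{4.5}/E^{3}$ anchored
to water at 10 keV) and pair production (parametric $\propto Z^2$, zero below
1.022 MeV, with both annihilation photons tracked). Rayleigh scattering and
bremsstrahlung are omitted. In water between 0.1 and 8 MeV the total
attenuation agrees with reference values at the few-percent level, which is
adequate for the relative depth-dose behaviour the engine targets.

### Kerma approximation and particle tagging

Charged particles are **not** transported: recoil protons, Compton/photo
electrons and pair electrons deposit their kinetic energy at the interaction
site. At the relevant energies their ranges (a recoil proton of 1 MeV:
~25 um; a 1 MeV electron: ~4 mm) are comparable to or smaller than a voxel,
so this kerma approximation distorts dose only at material interfaces and
field edges over an electron-range scale. Every deposit carries a tag:

* `proton` — neutron elastic recoil on hydrogen,
* `neutron` — recoil on heavier nuclei, sub-cutoff termination, capture
  deposits,
* `electron_n` / `electron_p` — electron-mediated deposits whose primary
  lineage is a neutron (capture gammas) or a photon.

"Photon dose" is therefore reported through its electron progeny, and the
lineage grouping lets DVHs be weighted per primary kind: for a single-kind
run the neutron-lineage dose is exactly the run total, so no covariance
bookkeeping is needed when RBE weights are applied after the fact.

## Random numbers and reproducibility

Each history gets its own counter-based stream: a splitmix64 hash of
`(seed, history index)` seeds xoshiro256++. Runs are bit-reproducible under
`(seed, n_histories, config)` and independent of execution order. Two runs
with the same seed are correlated history-by-history; the room-influence
study exploits this by comparing the phantom inside the concrete room against
the identical room with vacuum walls, so the difference isolates the
wall-scattered component instead of drowning it in independent-run noise.
Single-sample helpers exposed to R (`elastic_scatter()`, `compton_sample()`)
draw their default seeds from R's RNG so `set.seed()` behaves as expected.

## Tallies

Dose tallies accumulate per-history sums and sums of squares per region and
tag (history-by-history statistics keep correlated secondaries honest); the
standard error of the mean is $\sqrt{(\overline{x^2}-\bar{x}^2)/(n-1)}$.
Doses are reported per unit primary planar fluence (Gy cm$^2$, the
per-history dose divided by $1/A_{beam}$); multiplying by the beam's total
fluence rate (cm$^{-2}$s$^{-1}$) and the irradiation time gives dose rate and
absolute dose. The cell-fluence tally accumulates track lengths in 58
log-spaced energy bins between $10^{-3}$ eV and 20 MeV (the bin count is a
fixed design target; the edges are this engine's choice).

## Geometry

* **Solid-box water phantom**: 63.5 x 63.5 x 52 cm$^3$ Perspex container,
  2 cm walls, 12 x 34 cm$^2$ entrance window sealed by two 1.5 mm aluminum
  plates; 40 water-equivalent tube chambers (r = 0.38 cm, h = 1.21 cm, first
  at 0.5 cm depth, 1 cm pitch) score without perturbing transport (they are
  water inside water, < 0.1% of the volume). Coordinates: origin at the
  centre of the beam-entry water face, beam along +x.
* **Voxelised water phantom**: the box is enlarged to 64 x 64 x 52 cm$^3$ so
  that 0.2 x 0.2 x 0.5 cm$^3$ voxels divide it exactly (10,649,600 voxels);
  walls and window are painted into the grid by voxel-centre membership.
  Voxel-centre assignment makes the aluminum window one voxel (2 mm) thick
  instead of 3 mm; the resulting bias is far below Monte Carlo resolution.
* **Treatment room** (optional): six concrete slabs around an air cavity —
  83 cm walls, 50 cm beam-entry wall with a 20 x 30 cm$^2$ window, floor and
  ceiling 145 cm from the beam axis; lateral and longitudinal cavity
  distances are schematic choices (2.0 m and 1.0/1.5 m).
* **Voxel phantoms**: integer organ-ID grids (x fastest, half-open voxel
  intervals), an organ-to-material map onto the packaged 30-tissue table, and
  vacuum outside the body.

Transport through voxel grids uses exact Amanatides-Woo face crossings;
through the solid geometry, plane-by-plane surface tracking. Free flights
sample one optical depth per flight and accumulate it across media, so
piecewise-constant media are sampled exactly. For voxel grids, Woodcock
(delta) tracking with a grid-wide majorant is available as an option
(`tracking = "woodcock"`); surface tracking remains the reference and the
test suite checks the two agree statistically. Cutoffs: neutrons 0.01 eV
(remaining energy deposited as neutron dose), photons 10 keV (deposited as
electron dose); both are engine choices placed where the remaining range or
energy is sub-voxel.

## The synthetic sources and phantom

The measured converter-plate beam spectrum and the reference female voxel
phantom used in the clinical context are not publicly available, so the
package generates stand-ins and labels them as such:

* `synthetic_medapp_spectrum()` — neutrons: a Watt fission shape
  (a = 0.988 MeV, b = 2.249 MeV$^{-1}$, mean ~2.03 MeV) carrying 95% of the
  fluence plus a 300 K thermal Maxwellian tail carrying 5% (a filtered
  fission beam retains a small thermal component; the exact fraction is a
  generator choice), normalised to a requested total fluence rate — the
  study values are 3.2e8 cm$^{-2}$s$^{-1}$ for neutrons and 2.9e8 for
  photons. Photons: a broad fission-gamma-like exponential
  ($e^{-E/1.5\,\mathrm{MeV}}$ with a soft roll-off below 0.2 MeV) on
  0.1-8 MeV. Relative depth-dose shapes are comparable to a real filtered
  beam; absolute magnitudes and spectral fine structure are not.
* `synthetic_head_phantom()` — a layered ellipsoidal head and neck on the
  1.775 x 1.775 x 4.84 mm voxel convention, 87 slices: skin shell (thicker
  than the largest voxel dimension so the body surface is always skin),
  subcutaneous adipose, muscle, cortical-bone skull/mandible/spine with
  spongiosa and cord, air trachea, eyes, brain, and six salivary glands
  (parotid, submandibular, sublingual; right/left) as disjoint labelled ROI
  masks. Gland positions are fixed anatomy-book choices jittered up to 2 mm
  by the seed. It emulates the material heterogeneity that shapes head-case
  dose distributions (bone's low hydrogen content, air cavities), not any
  individual's anatomy — passing tests on it says the machinery is correct,
  not that a real patient's DVH would look the same.

## Planning analytics

Depth-dose curves pool voxel doses mass-weighted over a 4 x 2 voxel block
(0.16 cm$^3$) around the beam axis at every depth; pooled errors combine
per-voxel errors in quadrature (adjacent-voxel correlations make this a mild
overestimate). DVHs are survival curves over equal-volume voxels,
anchored at $V(0)=1$. RBE weighting is an explicit post-processing step
(default: 3 for the neutron lineage — a clinical scalar, since an
energy-dependent RBE is not established — and 1 for photons). The
primary-photon renormalisation is a least-squares scale over a 0-10 cm depth
window, $s = \sum P(R-S) / \sum P^2$, chosen because "match over the first
10 cm" needs a definite criterion; $s$ is invariant to common rescaling of
all three curves. Isodose contours spline-upsample the slice four-fold
(separable cubic splines) and run marching squares at percentages of the
prescribed dose; levels outside the data range yield empty contour sets
rather than errors.

## Test and verification scale

The test suite verifies the engine against closed-form oracles (exponential
attenuation, isotropic-CM moments, Thomson limit, piecewise-exponential
first-collision depths, brute-force DVHs) and against itself (solid vs
voxelised water phantom within combined statistical errors, seeded
bit-reproducibility, per-history energy conservation to $10^{-6}$ relative).
Monte Carlo checks run at $2\times 10^4$ to $5\times 10^5$ histories — sizes
chosen so statistical assertions have comfortable power while the suite stays
interactive; the acceptance script uses $8\times 10^6$ histories per
room-influence run, a size chosen so the seed-correlated difference between
the two arms is resolved fine relative to the 2% scale of interest. The secondary capture-gamma dose fraction in the first centimeters
of water is reported (not gated): with the synthetic stand-in spectra it
falls below the ~10-15% band quoted for the measured beam, chiefly because
the synthetic primary-photon spectrum is harder than the beam-tube reality.

## Known limitations

* No inelastic neutron channels, no (n,p)/(n,alpha), no S($\alpha$,$\beta$)
  molecular binding: thermal-depth dose and nitrogen dose are biased.
* Kerma approximation: no electron/proton transport, so interface and
  penumbra dose on sub-voxel scales is idealised.
* Parallel rectangular beam with sharp edges; divergence and penumbra are
  deliberately excluded.
* Packaged cross sections are smooth fits; resonance self-shielding effects
  are absent.
* Absolute doses from the synthetic spectra are stand-ins; only relative
  behaviour should be compared against measured beams.
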