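# Provenance of packaged physical data

All data files in this directory are plain-text, user-replaceable tables. They
are *simplified stand-ins* for evaluated nuclear-data libraries and reference
anatomical phantoms, adequate for a first-steps planning engine but not for
clinical dosimetry.

## elements.tsv
CODATA/IUPAC standard atomic weights, 5 significant digits. The mass number A
used in elastic-scattering kinematics is taken as `round(A_r)`.

## xs_elastic.tsv
Smooth log-log anchor tables for the neutron elastic cross section per element
(barns), linearly interpolated in log-log between anchors. Anchors follow the
well-known smooth trend of the evaluated data (e.g. hydrogen ~20.4 b at thermal
energies falling to ~4.2 b at 1 MeV and ~0.94 b at 10 MeV); **resonance
structure is deliberately omitted**. Minor elements (Na...I) use coarse
two-to-five point tables because they contribute little to dose in tissue,
water, Perspex or concrete.

## xs_capture.tsv
Radiative-capture cross sections at 0.0253 eV (2200 m/s) per element, barns,
extended to all energies by the 1/v law. `E_gamma_MeV` is the single capture
gamma emitted (hydrogen only: the 2.2246 MeV deuteron binding energy);
all other elements deposit their capture Q-value locally — a documented
simplification. Nitrogen keeps only radiative capture: the larger 14N(n,p)14C
channel (~1.83 b thermal) is out of scope of this engine, which biases the
thermal-neutron dose in nitrogen-bearing tissue low.

## materials.tsv
Structural materials: water, Perspex (PMMA, C5O2H8, 1.19 g/cm3, specified by
atom ratio), aluminum, ordinary concrete (NIST-style composition), dry air.
Tissue materials (ids 11-40, exactly 30 of them, mirroring the projection of
141 organ IDs onto 30 materials in the reference anthropomorphic phantom):
ICRU-44 / ICRP-89-style elemental mass fractions and densities. They reproduce
the published spot values this engine is checked against:

- adipose tissue (id 28): H mass fraction 0.114 -> hydrogen atom fraction 62.5 %
- cortical bone (id 13): H mass fraction 0.035 exactly
- skin id 19, muscle id 21, adipose id 28 (the ids quoted for the head case)

Note: a quoted "31.2 % element abundance" of hydrogen in hard bone cannot be
reproduced from any composition with H mass fraction 0.035 (which yields
~39.6 % atomic); the packaged table keeps the mass-fraction statement, which is
the physically binding one for neutron dose, and records the discrepancy here.

Compositions are otherwise an implementer choice; each row sums to 1 within
1e-9 and is validated at load time.
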