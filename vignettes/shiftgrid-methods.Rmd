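---
title: "shiftgrid: model, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{shiftgrid: model, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftgrid)
```

## The model

`shiftgrid` predicts the isotropic chemical shielding of protein
backbone atoms and Cβ as an additive sum of grid-interpolated terms,
then maps shielding to the measured chemical shift by a per-atom-type
linear calibration δ = b − aσ. The additivity assumption — that the
backbone/side-chain conformational term, the two neighbour side-chain
corrections, the hydrogen-bond corrections, the ring current and the
water term combine linearly — is the model's central approximation. It
is what makes a lookup-table predictor possible at all: each term is
parameterised once on a small model system (a capped Ala–X–Ala
tripeptide for the backbone terms; bimolecular amide/alpha
hydrogen-bond complexes for the H-bond terms) and composed at prediction
time. The price is that cooperative effects (bifurcated hydrogen bonds,
simultaneous side-chain contacts, charge–charge polarisation) are
invisible; they surface as outliers rather than being absorbed into fit
parameters, which is exactly why the calibration stage carries a GESD
outlier diagnostic rather than a robust-regression fallback.

### Term bookkeeping across the peptide bond

The amide group of residue *i* (N–H) is chemically bonded to the
carbonyl of residue *i−1* (C′=O). Every term is attributed to the
residue that *owns the atom*:

* the primary amide hydrogen-bond term (HB1) for atoms Hᴺ, N, Hα of
  residue *i* uses residue *i*'s own amide proton; for the carbonyl
  carbon it would use the amide proton of residue *i+1* (the proton
  actually across its C′=O), but the default mask excludes HB1 for C′
  anyway;
* the secondary (acceptor-centred) terms for atoms Cα, Hα, C′ anchor on
  residue *i*'s own carbonyl oxygen, while for N and Hᴺ they anchor on
  the carbonyl oxygen of residue *i−1* — the oxygen of the amide group
  those atoms belong to.

### Hydrogen-bond geometry

A bond is described by (r, θ, ρ): the H···O distance, the angle at the
acceptor oxygen measured along O=C (sp² acceptors) or O–C (hydroxyl),
and a dihedral fixing the azimuth (H···O=C–N for amide carbonyls,
H···O=C–C for carboxylates, H···O–C–Hᴼ to the hydroxyl proton for
Ser/Thr/Tyr — the hydroxyl reference is genuinely ambiguous in the
source parameterisation, so bundles declare their choice in the
manifest, along with the sign convention for ρ; bundles declaring the
opposite convention are converted on load). Scan windows are 1.5–3.0 Å
for amide donors and 1.8–4.0 Å for alpha donors with θ ∈ [90°, 180°];
distances below the scanned minimum clamp to the boundary (the
steric-clash region was discarded at parameterisation, so extrapolating
into it would be meaningless), and distances beyond the window
contribute exactly zero.

Backbone carbonyl acceptors of residues i−1, i, i+1 are excluded from
residue *i*'s donor search — the tripeptide backbone term already
contains those groups — and each term keeps only the single nearest
in-range partner per donor kind (the parameterisation model systems
contain one partner; bifurcated geometries are not parameterised). A
config switch (`secondary_mode = "sum"`) sums over simultaneous
secondary donors instead, for users who want to probe that choice.

### Ring current and water terms

The ring current is a point dipole, i·B·(1 − 3cos²θ)/r³, summed over
Phe/Tyr six-rings, the His five-ring and both Trp rings, cut off
sharply at 8 Å, and applied to protons only. The intensity factors i
(relative to benzene) and the constant B are *configuration data* with
literature-typical magnitudes (B = 30.42 ppm·Å³; PHE 1.00, TYR 0.84,
HIS 0.90, TRP5 1.04, TRP6 1.02): the source method inherits them from
external work without printing values, so hard-coding any particular
set into formulas would overstate their provenance. Amide protons with
no protein partner receive the water correction, magnitude 2.07 ppm,
applied as a *decrease* in shielding (hydrogen bonding deshields amide
protons); the magnitude is parameterised data, the sign a documented
package choice, and both live in the bundle manifest.

## Interpolation

Backbone surfaces are periodic in every dihedral axis. Interpolation is
separable Catmull–Rom cubic convolution: exact on nodes, C¹-continuous,
wrapped across the ±180° seam on periodic axes and edge-clamped on
bounded axes (r, θ). Residues with two or more side-chain torsions use
nearest-neighbour lookup instead (their source data were sampled too
sparsely for stable cubic fits), with midpoint ties broken toward the
smaller node coordinate — a deterministic rule that makes
`nearest_node()` testable against exhaustive argmin. Whether the
original tables wrap cubically at the seam is not documented; this
package mandates periodic wrapping and records it in the bundle
manifest, because a seam discontinuity would be a numerical artifact
with no physical meaning.

Grid bundles are directories of `manifest.json` plus one raw
little-endian float64 array per surface (C order, axes as listed).
The layout is deliberately boring: byte-exact round trips
(save → load → save is byte-identical, asserted in the suite), lazy
loading of individual arrays, and a plain-text TSV exchange format for
hand-written test grids.

## Calibration

Per atom type and per protein, δ is regressed on σ by ordinary least
squares and reported in the δ = b − aσ sign convention; RMSD is the
root mean square of regression residuals and the correlation is
reported as |r|. Random-coil subtraction is applied identically to
predicted and experimental shifts, so it cancels in the residuals and
leaves the reported RMSD unchanged exactly (refitting on corrected
pairs preserves RMSD exactly only at unit slope — both facts are
asserted in the test suite). GESD (α = 0.05, up to k = 5) *flags*
outliers; it removes nothing unless a refit is explicitly requested,
mirroring how single-outlier cases are reported rather than silently
dropped.

Ensembles are handled by averaging shieldings over models first, then
regressing once. Since both operations are linear the order would not
change the fitted parameters, but the documented order (average σ →
regress → subtract random coil for reporting) is fixed so reports are
reproducible to the last bit.

## The synthetic world

`make_library()` builds complete bundles from closed-form surfaces:
`cosine_mix` (sums of cosine products with integer frequencies —
360°-periodic by construction) for backbone grids, `radial_decay`
(vanishing at the r-axis maximum) for hydrogen-bond surfaces, and
`constant` for null-library identity tests. Baselines and amplitudes
mimic realistic shielding ranges (≈120 ppm baseline and a few ppm of
conformational range for Cα, ≈25 ppm and sub-ppm range for Hᴺ) — this
is cosmetic realism only; the surfaces are explicitly non-physical.
Every surface's specification is stored in the manifest, so
interpolation accuracy is always tested against the re-evaluated
analytic form, never against frozen numbers. The σ^A reference
constants are computed from the generator's own Ala effect grids at
(−120°, 140°), making the neighbour-term zero identity hold by
construction; the loader re-checks it at 1e-9 on every bundle.

One deviation from the interface sketch: the reference constants are
stored per side (previous-neighbour vs next-neighbour effect) rather
than as a single per-atom set, because the two effect surfaces are
independent grids and a single constant cannot zero both identities on
a general bundle.

`make_toy_structure()` builds chains with ideal bond lengths and angles
whose torsions round-trip through `torsions()` to below 1e-4°, covering
all twenty residue types including full aromatic ring geometry, and can
place a ghost acceptor group at an exact prescribed (r, θ, ρ) for
hydrogen-bond tests. `make_observations()` inverts the calibration as a
generator (δ = b − aσ + ε, seeded).

What a green test does **not** establish: agreement with any quantum
reference (the shipped surfaces are synthetic), behaviour on real PDB
pathologies beyond those modelled (altLoc resolution, chain breaks,
missing hydrogens are covered; crystal symmetry, insertion codes and
mmCIF are not — insertion codes are a hard error), or predictive
accuracy for side-chain atoms beyond Cβ, which are out of scope.

## Degenerate inputs and tie-breaks

* Terminal residues (φ or ψ undefined) produce *no* prediction rather
  than a zero-filled one; absent neighbours contribute exactly 0 with
  "absent" provenance.
* Glycine has no Cβ entry; its Hα is reported as the mean over the two
  alpha protons (position-dependent terms evaluated per proton, then
  averaged), mirroring the methyl-averaging convention of the
  parameterisation models. Proline has no amide proton, hence no Hᴺ
  prediction and no water term.
* Missing side-chain torsions required by a grid are an error in strict
  mode (default); permissive mode substitutes −60°, the most common
  rotamer. This is a deliberate, visible fallback rather than silent
  nearest-node snapping.
* Zero variance in σ or constant δ aborts the calibration with a
  degenerate-fit error; a zero residual SD stops GESD cleanly.
* Disulfide-bonded cysteines are modelled as free Cys with a warning;
  protonation states are taken as supplied in the input structure and
  never reassigned.

## Performance notes

Everything is plain R. A 100-grid synthetic bundle builds in about a
second; predicting a 640-model ensemble of a short peptide (the largest
ensemble size exercised in the acceptance suite) completes in seconds.
The lookup design means prediction cost is dominated by the
hydrogen-bond candidate scan, which is quadratic in residue count with
a small constant — adequate for the package's testing-first scope, and
the honest place to optimise first if large proteins become a use case.
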