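# shiftgrid

Grid-based additive prediction of protein backbone (and Cβ) NMR chemical
shifts from three-dimensional structure.

## What it does, and for whom

NMR chemical shifts carry structural information, and predictors that map
a coordinate model to expected shifts are the workhorse of shift-guided
structure validation and refinement. `shiftgrid` implements the
quantum-parameterised, table-lookup flavour of such predictors: the
isotropic chemical shielding σ of each backbone atom (Cα, Cβ, C′, Hα,
H^N, N) is assembled as an additive sum of physically interpretable
terms, each interpolated from a precomputed hypersurface:

    σᵢ = σ_BB(φᵢ, ψᵢ, χ₁…)            backbone/side-chain (tripeptide) term
       + Δσ_BB(i−1) + Δσ_BB(i+1)      neighbour side-chain corrections
       + Δσ_HB                        amide hydrogen-bond terms (1° + 2°)
       + Δσ_HαB                       alpha-hydrogen-bond terms (1° + 2°)
       + Δσ_RC                        aromatic ring current (protons only)
       + Δσ_w                         water term for exposed amide protons

and converted to an observable shift by linear calibration against
experiment,

    δᵢ = b − a·σᵢ ,

with a, b fitted per atom type by ordinary least squares, RMSD and |r|
reported after regression, optional sequence-corrected random-coil
subtraction, and Rosner's generalized extreme studentized deviate (GESD)
test flagging outliers. Multi-model NMR ensembles are handled by
averaging shieldings over models *first* and regressing once.

The neighbour corrections are referenced to an alanine tripeptide at
standard angles (φ_std, ψ_std) = (−120°, 140°), so an alanine neighbour
sitting exactly there contributes zero by construction. Exposed amide
protons that find no protein hydrogen-bond partner receive a water
correction of magnitude 2.07 ppm; the ring-current term is a point
dipole, i·B·(1 − 3 cos²θ)/r³, cut off at 8 Å.

The quantum-derived lookup tables themselves are treated as replaceable
data: a *grid bundle* (a directory of `manifest.json` plus raw
little-endian float64 arrays) declares every surface's axes,
interpolation mode (periodic cubic for ≤1 side-chain torsion,
nearest-neighbour for 2–4) and reference constants. A synthetic-surface
generator (`make_library()`, `make_toy_structure()`,
`make_observations()`) produces fully self-consistent bundles,
ideal-geometry structures and noisy observations, so the entire pipeline
is testable with no external downloads.

## Worked example

Generate a seeded synthetic fixture set (grid bundle, 24-residue toy
structure, noisy shifts with generator truth a = 0.95, b = 185,
noise 1 ppm), predict, then calibrate:

```r
library(shiftgrid)
d <- tempfile(); dir.create(d)
cmd_make_fixtures(list(out_dir = d, seed = 1, residues = "A,G,S"))
cmd_predict(list(structure = file.path(d, "toy.pdb"),
                 bundle = file.path(d, "bundle"),
                 out = file.path(d, "rep.tsv")))
head(read_report(file.path(d, "rep.tsv"))[,
     c("seq_index","res_type","atom_type","BB","BB_prev","W","sigma_total")])
```

```
  seq_index res_type atom_type      BB   BB_prev     W sigma_total
1         2      GLY        CA 118.702  0.000000    NA     118.687
2         2      GLY         C  64.096  0.000000    NA      63.701
3         2      GLY        HA  27.060  0.000000    NA      27.055
4         2      GLY        HN  25.007  0.000000 -2.07     22.931
5         2      GLY         N 122.112  0.000000    NA     122.708
6         3      SER        CA 119.924 -0.819887    NA     119.344
```

Each row is one atom's term breakdown in ppm of *shielding*: residue 2's
amide proton finds no hydrogen-bond partner in this extended toy strand,
so it carries the −2.07 ppm water correction; `NA` cells are terms
masked out for that atom type (e.g. no water term for Cα), and
`BB_prev = 0` for residue 2 because residue 1 is a terminus with no
defined φ. Calibration against the generated observations:

```r
cmd_calibrate(list(structure = file.path(d, "toy.pdb"),
                   bundle = file.path(d, "bundle"),
                   shifts = file.path(d, "shifts.tsv"),
                   out = file.path(d, "cal.tsv")))
```

```
atom_type   a       b        n  rmsd   pearson_r
CA        1.164  211.144    22  1.098  0.613
CB        1.551  272.547    14  0.696  0.683
C         0.987  187.092    22  0.863  0.611
HA       -2.511   91.525    22  1.190  0.184
HN        1.636  200.698    22  1.331  0.492
N         0.908  179.748    22  0.981  0.644
```

Heavy atoms recover the generator's slope to within the fit's standard
error at this sample size; the proton rows illustrate an honest failure
mode — synthetic proton surfaces span well under 1 ppm, so 1 ppm of
observation noise swamps the slope. (The test suite's recovery checks
therefore use 50+ pairs and SE-scaled bounds.)

The same pipeline runs from the shell via the installed wrapper:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "shiftgrid.R", package = "shiftgrid"))')
Rscript "$CLI" make-fixtures --out-dir /tmp/fx --seed 1
Rscript "$CLI" predict --structure /tmp/fx/toy.pdb --bundle /tmp/fx/bundle --out /tmp/fx/rep.tsv
Rscript "$CLI" calibrate --structure /tmp/fx/toy.pdb --bundle /tmp/fx/bundle \
        --shifts /tmp/fx/shifts.tsv --out /tmp/fx/cal.tsv
```

Exit codes: 0 report written, 2 validation failure, 3 too few matched
pairs to calibrate.

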