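---
title: "Methods: copper-site binding energetics and inhibition kinetics"
author: "cuprobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copper-site binding energetics and inhibition kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuprobind)
```

# The system

Lytic polysaccharide monooxygenases (LPMOs) carry a solvent-exposed
mononuclear Cu(II) site coordinated by the "histidine brace": the
imidazole and terminal-amine nitrogens of a (methylated) N-terminal
histidine plus the imidazole of a second histidine, with an axial
tyrosine oxygen. Two exchangeable positions — one equatorial, one axial —
are occupied by water in the resting enzyme. Small carboxylic acids and
amino acids (oxalate, citrate, histidine, ...) can chelate the copper by
displacing those two waters, which competes with reduction of the site
and inhibits turnover. `cuprobind` implements the quantitative pipeline
around that hypothesis: complexation energetics from quantum-chemical
species energies, activity and IC50 reduction from photometric and
turbidimetric assays, hydration and coordination analysis of the site,
and the correlation that ties computed stability to measured potency.

# The binding-energy ledger

Binding energetics are assembled from *tabulated* total electronic
energies; no electronic-structure calculation is run here. For a ligand
L binding the active-site model A:

$$\Delta E_\mathrm{bind} = E(\mathrm{AL}_\mathrm{DEE})
  - E(\mathrm{A}_\mathrm{DEE}) - E(\mathrm{L}_\mathrm{H_2O})
  + \Delta E_\mathrm{BSSE}$$

The complex and the bare site are evaluated in a diethyl-ether (DEE)
continuum (dielectric 4.2, a standard stand-in for a protein interior),
the free ligand in water; the difference in the ligand's reference state
is what makes dehydration an explicit cost. The same total splits into
physical steps:

$$\Delta E_\mathrm{bind} = \Delta E_\mathrm{int}
  + \Delta E_\mathrm{def}(A) + \Delta E_\mathrm{def}(L)
  + \Delta E_\mathrm{dehydr}(L) + \Delta E_\mathrm{BSSE}$$

with the interaction energy taken between fragments frozen at the dimer
geometry, deformation energies the strain of reaching that geometry, and
dehydration the water-to-DEE transfer of the ligand. The two routes are
algebraically identical; `decompose()` and `binding_energy()` compute
them independently and the test suite asserts agreement to $10^{-9}$
relative on randomized tables.

The counterpoise correction is computed from ghost-basis evaluations,
$\Delta E_\mathrm{BSSE}(X) = E_{AL}(X) - E_X(X)$, exactly in this
direction by default. Note that this sign *deepens* the binding energy
(the dimer basis lowers each monomer), which is opposite to the usual
counterpoise convention; because source tabulations in this field are
found with either convention, `bsse_sign = "conventional"` negates both
components. The ghost-basis monomer references $E_X(X)$ are taken at the
dimer geometry (standard counterpoise practice); the energy table schema
carries geometry and basis as separate fields, so the alternative
(native-geometry) convention is representable as data if a tabulation
requires it.

Thermal corrections, when supplied, enter as
$\Delta G_\mathrm{bind,corr} = \Delta G_\mathrm{corr}(AL) -
\Delta G_\mathrm{corr}(A) - \Delta G_\mathrm{corr}(L)$ and
$\Delta G_\mathrm{bind} = \Delta E_\mathrm{bind} +
\Delta G_\mathrm{bind,corr}$ (rigid-rotor/harmonic-oscillator values at
298.15 K, configurable). Absent corrections leave the $\Delta G$ fields
`NA` rather than silently zero: ranking and correlation run on
$\Delta E_\mathrm{bind}$ alone in that case.

Units: the ingest default is hartree (the universal quantum-chemistry
output unit), converted with 1 Eh = 2625.4996394799 kJ/mol; a CSV may
override per file with a `unit` column.

# Assay reduction and IC50

Photometric activities follow Beer–Lambert bookkeeping: the blank rate
is subtracted from the enzyme rate *before* unit conversion, the slope
is converted to molar product formation via the coerulignone absorption
coefficient ($\varepsilon_{469}$ = 53,200 M$^{-1}$cm$^{-1}$), scaled by
reaction volume to µmol/min (1 U) and divided by enzyme mass. Residual
activity is the plain percentage against the uninhibited reference and
is scale-invariant. Turbidimetric rates are least-squares slopes of
light intensity over a stated time window (the default analysis window
in the packaged examples is 40–200 s at 10 Hz), reported as magnitude
plus direction because depolymerization *reduces* optical density.

Dose–response series are fitted with a single-exponential decay,
$A(c) = A_0 e^{-kc}$, by unweighted nonlinear least squares, and
$\mathrm{IC}_{50} = \ln 2 / k$ — the concentration where the fitted
curve crosses $A_0/2$. This is the simplest model consistent with
"concentration at half activity" reporting; start values come from a
log-linear regression of the positive activities, which is exact for
noiseless data (so clean data are recovered to $10^{-6}$ regardless of
the concentration grid, and Gauss–Newton refinement is skipped when the
start already reproduces the data). A model-free estimate — log-linear
interpolation between the two observed points bracketing half the
zero-dose activity — is always reported alongside (`ic50_interp`) as a
sanity check against model misfit. The fit is deliberately unweighted
(per-point uncertainties are rarely available) and works equally on
activities or residual percentages, which differ only by $A_0$. The
IC50 standard error is delta-method propagated,
$\delta_{\mathrm{IC}_{50}} = \ln 2 \cdot \delta_k / k^2$.
Non-decaying or constant series raise a "no inhibition detected" error
rather than returning a spurious constant.

Inhibition constants: for competitive inhibition,
$K_i = \mathrm{IC}_{50} / (1 + [S]/K_M)$ (Cheng–Prusoff); $K_M$ must be
supplied by the user — the packaged assays do not determine it, and a
default would be an invention. The equilibrium bridge from computed
energies is $K_D = e^{-\Delta G_\mathrm{bind}/RT}$ with
$K_i \approx 1/K_D$, implemented exactly in this form. Note the
bookkeeping here behaves like an *association* constant (stronger
binding, i.e. more negative $\Delta G$, gives larger $K_D$ and smaller
$K_i$); the package follows the thermodynamic-cycle convention as used
rather than "correcting" it, and tests pin the identities
$\ln K_i = \Delta G/RT$ and $K_i \cdot K_D = 1$.

The bridge to experiment is the working linear relation
$\ln \mathrm{IC}_{50} \approx a + b\,\Delta G_\mathrm{bind}$ (an
analytic derivation is not available for a mechanism with several
similarly inhibited steps), estimated by ordinary least squares of
$\ln \mathrm{IC}_{50}$ on the energy with closed-form $R^2$ and
coefficient errors.

# Hydration analysis

The radial distribution function around the copper is the ratio of the
observed water-oxygen density at distance $r$ to the bulk density:
distances are histogrammed per frame under the minimum-image convention
(orthorhombic boxes only; triclinic input is rejected explicitly) and
normalized by $4\pi r^2 \Delta r \rho$ with $\rho = N/V$ by default.
Water *oxygens* are the target selection; hydrogens are never counted.
For non-periodic fixtures a user-supplied bulk density replaces $N/V$.
Defaults $\Delta r = 0.02$ Å and $r_\mathrm{max} = 8$ Å resolve the
2.5/3.2 Å shell structure comfortably while staying below half the box.

Coordination numbers integrate $4\pi\rho\, g(r) r^2$ by trapezoid over
the binned profile, with the exact integration bounds appended to the
grid (holding $g$ at the nearest-bin value) so that no half-bin mass is
lost at the edges; on homogeneous fixtures the full-sphere integral
conserves the particle count to well within 2%.

Shell location smooths $g(r)$ with a centered moving average (default 5
bins; window ends are padded with the nearest defined value so the
window edge cannot fabricate a rise). Local maxima closer than one
window are merged, and two maxima separated by a dip shallower than 20%
of the lower one are treated as sampling noise on a single feature —
this also absorbs noise bumps on the bulk plateau. Reported peak radii
are refined to sub-bin precision by a quadratic vertex through the three
bins around each maximum. The first minimum is the lowest smoothed point
between the two peaks; the second minimum is the first trough after the
second peak (not the global minimum of the bulk tail). Per-shell
coordination numbers integrate up to the first minimum and between the
two minima respectively.

One subtlety is encoded in the generator's ground truth: when a shell is
generated with radius $\sim \mathcal{N}(\mu, \sigma)$, the *maximum of
g(r)* does not sit at $\mu$ but at
$(\mu + \sqrt{\mu^2 - 8\sigma^2})/2$, slightly inside it, because of the
$1/r^2$ normalization. For $\mu = 2.5$ Å, $\sigma = 0.1$ Å this is
2.492 Å. Parameter-recovery tests compare the detected peak against this
derived mode, at one-bin tolerance.

# Superposition and clustering

Pairwise frame RMSDs use least-squares rigid-body superposition
(Kabsch): SVD of the centered covariance matrix with the determinant
sign corrected so reflections are excluded; collinear selections are
rejected. The test suite checks this route against an independent
quaternion (Horn) implementation and against an established structural
bioinformatics package.

Conformational clustering is the greedy neighbor-count (GROMOS-style)
algorithm, the de-facto standard for "clustering with an RMSD cutoff":
the frame with the most neighbors within the cutoff (default 2.5 Å)
becomes a centroid, it and its neighbors are removed, and the procedure
repeats; ties resolve to the lowest frame index, and clusters are
numbered by decreasing size. The default atom selection is all
non-hydrogen atoms; the selection is exposed as a parameter because the
appropriate choice (whole protein vs. active site) depends on the
question being asked. The output is always a partition, asserted on
every run.

# Coordination geometry

`cu_distances()` reports Euclidean Cu–donor distances to 0.001 Å in a
fixed six-role order (brace nitrogens, tyrosine oxygen, equatorial and
axial exchangeable positions); unoccupied roles are flagged rather than
erroring, and a π-coordinated position (e.g. a phenylalanine ring) is
reported as the mean distance to explicitly tagged ring carbons — π
coordination is never inferred automatically.

Axial/equatorial classification fits the plane of the three brace
nitrogens and measures each remaining donor's angle to that plane: more
than 45° off-plane is axial, with the exact-45° tie resolving to
equatorial (a documented, deterministic boundary choice; the underlying
structures are classified by inspection in the literature, so the
threshold is this package's convention).

Denticity counts tagged ligand donor atoms within a bond cutoff of
2.6 Å. That default covers observed Cu–donor coordinate bonds up to
~2.53 Å while excluding the 2.80/3.01/3.36 Å distances reported for
dissociated or unoccupied positions; the cutoff is configurable and the
test suite sweeps it across the tabulated distances to verify the count
changes only at those values. Hydrogen bonds are reported as all polar-H
to O/N acceptor pairs within 2.2 Å, excluding each hydrogen's covalent
partner.

# Synthetic data: what it does and does not emulate

All fixtures are generated in code from a single integer seed. A
named-stream splitter derives an independent substream per generator, so
adding a generator never perturbs another's output and every fixture is
bit-reproducible.

* `gen_energy_table()` draws the *components* (interaction, deformation,
  dehydration, counterpoise, thermal) from uniform ranges — or accepts
  them verbatim — and constructs species energies consistent with both
  assembly routes by construction. It emulates the bookkeeping structure
  of a quantum-chemistry tabulation, not its physics: recovering the
  components proves the ledger algebra, not any electronic-structure
  result.
* `gen_site_trajectory()` places shell waters at
  $\mathcal{N}(\mu,\sigma)$ radii with uniform directions over a uniform
  bulk, with an excluded-volume radius (default 2 Å) around the copper.
  It reproduces the two-shell radial structure and bulk normalization of
  a solvated site but none of water's orientational or
  hydrogen-bond-network structure; RDF tests on it validate estimator
  correctness, not simulation realism.
* `gen_site_geometry()` realizes tabulated Cu–donor distances on
  idealized octahedral axes. Bond *angles* are idealized and are never
  asserted; only distances are meaningful.
* `gen_dose_response()` applies multiplicative Gaussian noise to the
  exponential decay; `gen_correlation()` draws energies uniformly and
  adds Gaussian scatter to $\ln \mathrm{IC}_{50}$.

The synthetic ligand panel (`ligand_panel_fixture()`) realizes the two
published electronic binding-energy totals (citric acid −267, oxalic
acid −255 kJ/mol) with an invented component split and invented weaker
ligands; it exists for ranking and format tests only.

# Problem sizes and numerical choices

The packaged checks use: 100 single-ligand synthetic tables for the
route-consistency identity; 200 noisy dose–response series (5%
multiplicative noise, 8 concentrations) for median-IC50 recovery within
5%; 500 replicate 11-point regressions ($\sigma = 0.3$) for slope
recovery within two standard errors of the mean; 500 homogeneous frames
(200 waters) for RDF flatness at $1 \pm 0.05$ and particle-count
conservation within 2%; 5000 two-shell frames (50 bulk waters, 17 Å box)
for peak recovery at one-bin tolerance — chosen so a one-water shell at
$\sigma = 0.1$ Å is sampled well past the estimator's jitter; exhaustive
clustering-oracle comparison on all set sizes up to 10 frames; and 50
random superposition pairs against the quaternion route at $10^{-8}$ Å.

Degenerate inputs are handled explicitly: zero-range generator
specifications produce exactly zero energetics; constant dose–response
series raise rather than fit; collinear atom sets are rejected in
superposition and plane fitting; inverted shell bounds and out-of-range
windows are errors.

# Limitations

* The quantum-chemical and molecular-dynamics numbers themselves are
  inputs here. Published appendix-level quantities (the full
  binding-energy table, the $R^2$ = 0.968/0.764/0.815 correlations over
  it, optimized geometries) cannot be recomputed without the external
  engines and are represented only by synthetic fixtures.
* Triclinic boxes and errors-in-variables regression are out of scope.
* The exponential IC50 model is phenomenological; mechanism-based
  kinetic fitting ($K_M$, $k_{cat}$) is deliberately not provided.
* The $K_D$/$K_i$ bridge is a rough single-step approximation for a
  multi-step mechanism and is exposed as printed, sign convention
  included.
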