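# cuprobind

Analysis of small-molecule inhibition of the copper active site of lytic
polysaccharide monooxygenases (LPMOs), for enzymologists and modellers
working on these enzymes. LPMOs oxidatively cleave cellulose at a
solvent-exposed Cu(II) site held by the histidine brace; small chelators
(oxalate, citrate, histidine, ...) displace the two copper-bound waters
and inhibit turnover. `cuprobind` turns the raw artifacts of such a study
— tabulated quantum-chemical species energies, photometric and
turbidimetric assay traces, solvated-site trajectories and site
structures — into the quantities that test the chelation hypothesis.

The core model is a thermodynamic cycle for ligand binding,

    ΔE_bind = E(AL_DEE) − E(A_DEE) − E(L_H2O) + ΔE_BSSE
            = ΔE_int + ΔE_def(A) + ΔE_def(L) + ΔE_dehydr(L) + ΔE_BSSE

with counterpoise (Boys–Bernardi) correction ΔE_BSSE(X) = E_AL(X) −
E_X(X), thermal corrections ΔG_bind = ΔE_bind + ΔG_bind,corr, and the
kinetic bridge

    IC50 = ln 2 / k  (from A(c) = A0 e^{−kc}),
    K_i = IC50 / (1 + [S]/K_M),   K_D = e^{−ΔG_bind/RT},
    ln(IC50) ≈ a + b·ΔG_bind.

Around it sit the hydration analysis (copper–water radial distribution
function, shell coordination numbers N = 4πρ ∫ g(r) r² dr, GROMOS-style
RMSD-cutoff clustering with Kabsch superposition) and Cu(II)
coordination geometry (donor distances, axial/equatorial roles,
denticity, hydrogen-bond contacts). Seeded generators produce every
synthetic fixture; curated reference measurements (activities, IC50s,
Cu–donor bond lengths) ship as plain-text CSV.

## Worked example

Rank a ligand panel by binding energy and correlate with measured IC50s
(the panel fixture realizes the two published totals, −267 and −255
kJ/mol for citric and oxalic acid, with a synthetic component split):

```r
library(cuprobind)

fx <- ligand_panel_fixture(seed = 1)
ranked <- rank_ligands(decompose_ligands(fx$records, fx$thermal))
ranked[, c("rank", "ligand_id", "dE_int", "dE_dehydr_L", "dE_bind")]
#>   rank      ligand_id dE_int dE_dehydr_L dE_bind
#> 1    1    citric acid   -367          90    -267
#> 2    2    oxalic acid   -345          80    -255
#> 3    3      histidine   -300          60    -230
#> ...

ic <- lpmo_ic50_table()
hc <- ic[ic$assay == "hydrocoerulignone", ]
m  <- merge(hc, ranked, by.x = "inhibitor", by.y = "ligand_id")
correlate_ic50_dg(m$ic50_mM, m$dE_bind)
#> ln(IC50) = 5.409 + 0.01992 * E;  R^2 = 0.812 (n = 9)
```

Stronger (more negative) binding predicts lower IC50: the slope is
positive and the log-potencies of nine ligands fall on the line with
R² ≈ 0.81 (the measured IC50s against the fixture's energy scale).

Fit an IC50 from a noisy dose–response series and convert it:

```r
dr <- gen_dose_response(11, noise = 0.05)    # truth: IC50 = 1 mM
f  <- fit_ic50(dr$concentration_mM, dr$activity)
f
#> IC50 = 0.9498 mM (SE 0.02); A0 = 101.6, k = 0.7298 /mM; n = 8
cheng_prusoff_ki(f$ic50, S = 0.5, K_M = 1.0)
#> [1] 0.633188
```

Hydration shells around the copper from a trajectory:

```r
tr <- gen_site_trajectory(1, n_frames = 5000, n_bulk = 50, box = c(17, 17, 17))
p  <- radial_distribution(tr, dr = 0.02, r_max = 8)
find_shells(p, window = 7)
#> shells: peak1 2.49 A (min 2.85, n = 1.66), peak2 3.20 A (min 3.61, n = 2.05) [ok]
```

The two peaks recover the generated 2.5/3.2 Å shells (the g(r) maximum
of a Normal-radius shell sits slightly inside its mean; see the methods
vignette), matching the picture of one equatorial water closer to the
copper than the axial one.

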