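# mdunfold

Order parameters, free-energy landscapes and unfolding analysis for
protein molecular-dynamics trajectories.

`mdunfold` is for structural bioinformaticians who have a fixed-topology
protein trajectory (for example, a thermal-unfolding run saved as a
multi-model PDB) and want the standard unfolding-analysis battery without
bespoke scripts:

- **Per-frame order parameters** — Cα RMSD by optimal (Kabsch)
  superposition, radius of gyration *R*g, fraction of native contacts
  *N*c, Shrake–Rupley solvent-accessible surface area (SASA), and
  intraprotein backbone hydrogen-bond counts.
- **Per-residue RMSF** about an iteratively refined mean structure.
- **2-D free-energy landscapes** by Boltzmann inversion,
  *F* = −*RT* ln *P*, of the joint histogram of any two order parameters,
  with grid-local basin detection and basin ΔF.
- **Dynamic cross-correlation matrices** (DCCM) of residue motion over
  configurable trajectory windows.
- **Per-frame secondary structure** with a simplified Kabsch–Sander
  scheme (electrostatic H-bond model, helix/bridge/turn/bend patterns).
- **A synthetic multi-state trajectory generator** — an idealised
  helix + β-hairpin mini-protein whose conformers (native, partially
  unfolded intermediate, fully unfolded) interconvert by a Markov switch
  with Gaussian coordinate jitter — so every analysis stage can be
  validated against known state populations.

The core definitions: a native contact is a heavy-atom pair from residues
at least 3 apart in sequence within 4 Å in the reference structure, and
*N*c is the fraction of those pairs still within 4 Å in a frame; the
landscape is *F* = −*RT* ln *P* in kcal/mol
(R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹) with unvisited bins masked and the
minimum shifted to zero; DCCM entries are
C_ij = ⟨Δx_i·Δx_j⟩ / √(⟨|Δx_i|²⟩⟨|Δx_j|²⟩) over a window.

## Worked example

Simulate a five-temperature synthetic unfolding ladder (300–500 K) and
run the whole pipeline:

```r
library(mdunfold)

toy <- make_toy_protein(30)
toy$model
#> structure_model: 153 atoms (153 heavy), 30 residues
paste(assign_frame(md_trajectory(toy$model, toy$native)), collapse = "")
#> "CHHHHHHHHHSCCEEEEEEETTEEEEEEEC"   # helix + antiparallel hairpin

res <- run_unfolding_analysis(run_config(n_frames = 500, sasa_stride = 10,
                                         ss_stride = 10, seed = 42,
                                         out_dir = "ladder_run"))
print(res$summary, digits = 3)
#>   temperature_K rmsd_nm_mean rmsd_nm_sd rg_nm_mean rg_nm_sd nc_mean  nc_sd
#> 1           300       0.0622      0.101       1.33   0.0875  0.8749 0.0463
#> 2           350       0.2314      0.374       1.47   0.3230  0.8020 0.1605
#> 3           400       0.6229      0.676       1.81   0.5719  0.6392 0.2757
#> 4           450       1.3580      0.785       2.42   0.6521  0.3433 0.3073
#> 5           500       2.0956      0.435       3.04   0.3585  0.0573 0.1672
#>   sasa_nm2_mean sasa_nm2_sd
#> 1          20.4        0.56
#> ...
```

Mean *N*c falls and mean *R*g rises monotonically with temperature: the
ladder unfolds. The free-energy landscape of *N*c against RMSD at 450 K
resolves the three populated states as separate basins:

```r
g <- res$fel_grids[["fel_nc_rmsd_450K"]]
find_minima(g)
#>   ix iy       x      y     F
#> 1  1 60 0.00761 22.479 0.000     # unfolded (global minimum at 450 K)
#> 2 34 24 0.50997  9.140 0.819     # intermediate, +0.82 kcal/mol
#> 3 58  1 0.87533  0.618 1.956     # native-like, +1.96 kcal/mol
```

All outputs (series CSVs in nm / nm², the summary table, FEL grids, DCCM
matrices, secondary-structure timelines, hidden-state ground truth and a
run log) land in `out_dir`, and a rerun with the same config and seed is
byte-identical.

A thin command-line front end with `analyze`, `simulate`, `fel` and
`report` verbs is installed at `inst/scripts/mdunfold`.

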