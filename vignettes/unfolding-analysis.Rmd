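---
title: "Methods: order parameters, free-energy landscapes and synthetic unfolding trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: order parameters, free-energy landscapes and synthetic unfolding trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdunfold)
```

`mdunfold` characterises protein unfolding from fixed-topology
trajectories. This vignette documents the models behind each stage, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical and design choices that were
genuinely open.

## Trajectory model and units

A trajectory is a `structure_model` (atoms with element, residue
assignment, backbone/side-chain flags, van der Waals radius, mass) plus
an `n_atoms × 3 × n_frames` coordinate array. Coordinates are Ångström
internally everywhere; the pipeline converts to nm (RMSD, *R*g) and nm²
(total SASA) only at reporting, the convention in which unfolding studies
tabulate these quantities. Multi-model PDB is the on-disk format: the
first `MODEL` defines the topology and later models must match it atom
for atom — a mismatch is a hard error naming the offending model, because
silently re-mapping atoms would corrupt every downstream analysis.

Van der Waals radii come from a single per-element table
(C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Å; 1.70 Å for anything
else). Residue numbering from the file is preserved for reporting while
internal indices are renumbered 1..n contiguously. Tagged or auxiliary
N-terminal residues are ordinary residues here; excluding them is a
selection choice, not a hard-coded rule.

## Order parameters

**RMSD.** Each frame is superposed onto the reference over the chosen
selection (default Cα) with the Kabsch algorithm: SVD of the weighted
covariance matrix with a determinant correction so a reflection is never
returned. For degenerate (e.g. collinear) point sets the optimal rotation
is not unique; the RMSD still is, and the fit is flagged. The test suite
checks the implementation against an independent quaternion (Horn)
oracle to 10⁻⁸ on random point sets.

**Radius of gyration.** √( Σ mₖ|xₖ−x̄|² / Σ mₖ ) over the selection
(default: all heavy atoms, mass-weighted). No superposition — *R*g is
rigid-motion invariant by construction.

**RMSF.** Fluctuation of each Cα about its mean position. By default
frames are superposed onto the mean structure, which is refined
iteratively (align, re-average; 2 passes) because the mean of unaligned
frames mixes internal motion with global tumbling; frame-1 reference is
selectable. For pure isotropic jitter of per-coordinate SD σ the RMSF is
σ√3, which the suite verifies.

**Native contacts.** The contact set is every heavy-atom pair from
residues ≥ 3 apart in sequence within 4.0 Å in the reference frame, and
*N*c per frame is the fraction of those pairs still within the cutoff,
strictly re-evaluated (tolerance factor 1.0) so the reference frame
scores exactly 1. The 4 Å heavy-atom rule over distinct residues is the
standard definition; the minimum sequence separation of 3 is this
package's default (exposed in the API) — without it, trivially permanent
|Δres| ≤ 2 contacts would put a high floor under *N*c and compress the
unfolding signal. A soft/switching *Q*-style variant is deliberately out
of scope.

**SASA.** Shrake–Rupley quadrature with a 1.4 Å water probe: test points
on each atom's solvent-expanded sphere, a point being exposed when
outside every neighbour's expanded sphere; the per-atom area is the
exposed fraction times 4π(r+probe)². Points are placed by a deterministic
golden-spiral rule, so results are reproducible without a seed. The
default of 240 points per atom keeps whole-trajectory series affordable;
the quadrature error falls with the point count (the suite checks 960
against 10 000 points within 0.5%, and the isolated-atom analytic area
within 1%). SASA is computed over heavy atoms only. Side-chain SASA of a
tracked residue (the generator's tryptophan-like residue; W80 in the
motivating use case) is summed over that residue's side-chain heavy atoms
in the context of the whole structure, and reported in Å² — reports of
side-chain SASA per residue in the tens of nm² are physically implausible
(a single side chain exposes on the order of 1–3 nm² at most), so this
package does not adopt that unit at the residue level.

**Hydrogen bonds.** Counted between backbone N–H donors and C=O
acceptors of residues ≥ 2 apart: N···O ≤ 3.5 Å **and** D–H···A angle
≥ 120°. When the structure carries no amide hydrogens, H is
reconstructed geometrically (1.01 Å from N, anti to the preceding
carbonyl). The angle test is applied in both cases: on an ideal α-helix
the N···O distances for i→i+2 (3.37 Å) and i→i+3 (3.21 Å) also fall
under 3.5 Å, so a distance-only criterion triples the count with
contacts that are not hydrogen bonds; the angle term (i→i+3 angles sit
near 90°) leaves exactly the i→i+4 ladder, 8 bonds on a 12-residue
helix.

## Free-energy landscapes

`fel_2d` bins two order-parameter series on an equal-width 2-D grid
spanning their data range and Boltzmann-inverts the joint probabilities:
F = −RT ln P in kcal/mol with R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹, shifted so
the minimum visited bin is 0. Unvisited bins are **masked**, not given a
large sentinel: −RT ln 0 is undefined, and a sentinel would corrupt basin
searches and ΔF values. Exponentiating −F/RT and renormalising over
unmasked bins reproduces the empirical histogram exactly (to 10⁻¹² in the
suite), so no information is lost in the inversion. Trajectories are
treated as equilibrium samples at their own temperature; no reweighting.

Defaults: 60 × 60 bins (no established convention exists; exposed in the
config), and a basin `depth_threshold` of 2 kcal/mol — published
landscape analyses report basin counts qualitatively from contour maps
without stating a threshold, so the default here is an explicit package
choice. Basins are grid-local minima (a visited bin not exceeded by any
visited 8-neighbour, at or below the threshold), with tied plateaus
merged to the first bin in row-major order; watershed segmentation of
basins of attraction is a non-goal. ΔF between basins is antisymmetric
and invariant to the global shift.

For **occupancy recovery** tests the two states are far apart in the
(Nc, Rg) plane while jitter keeps each state's cloud much narrower than
a bin, so a coarse 5 × 5 grid puts each state in a single bin and basin
ΔF estimates −RT ln(p₂/p₁) directly; with fine grids the basin bin holds
only each state's modal mass and the identity no longer holds exactly.

## Dynamic cross-correlation

C_ij = ⟨Δx_i·Δx_j⟩ / √(⟨|Δx_i|²⟩⟨|Δx_j|²⟩) over a frame window, with
Δx taken about the window mean after superposing each frame onto the
(iteratively refined) window-mean structure. Superposition defaults to
on — otherwise global rotation dominates the correlations — and is
selectable since conventions differ. Atoms immobile within a window get
zero off-diagonal entries with a warning rather than 0/0. Default
windows are the first and last 10% of frames ("start" and "end" of the
run); window lengths are an explicit package choice. The matrix is
exactly symmetric with unit diagonal and entries in [−1, 1]; frame order
within a window is irrelevant (moment-based definition).

## Secondary structure

A simplified Kabsch–Sander assigner: backbone H-bonds are scored with
the classic electrostatic model
E = 27.888·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol (distances
clamped below 0.5 Å; bond when E < −0.5 kcal/mol), amide H
reconstructed when absent. n-turns (CO(i)←NH(i+n), n = 3,4,5) give
G/H/I helices from two consecutive turns; parallel/antiparallel bridge
patterns give E (ladders) and B (isolated bridges); remaining turn
interiors give T; a Cα(i−2)–Cα(i)–Cα(i+2) direction change above 70°
gives S; otherwise C, with priority H > G > I > E > B > T > S > C.
Simplifications relative to full DSSP: no β-bulge special cases and no
chirality-based 3₁₀/π disambiguation beyond the bond patterns — the
downstream use is coarse content classes (helix, strand, turn/bend,
coil). Fewer than 5 residues with complete backbone falls back to
all-coil with a warning; chain termini are never assigned H or E. On
ideal helix and hairpin fixtures the suite requires ≥ 90% residue-frame
agreement with the `mdtraj` DSSP implementation (observed differences
are confined to segment termini).

## The synthetic generator

The generator stands in for undeposited MD trajectories. It emulates the
one property the analyses actually assume: a fixed-topology ensemble
mixing a native-like state, a partially unfolded intermediate and an
expanded unfolded state with known populations. It is **not** physics —
no solvent, no force field, no kinetics calibrated to real temperatures
(temperature labels are labels), and its frames jump between templates
instantaneously rather than diffusing. Passing recovery tests therefore
demonstrates correctness of the analysis stack, not realism of the
ensemble.

The toy protein (12–80 residues; default 30) is built from ideal peptide
internal coordinates: an α-helix (φ,ψ = −57°,−47°), a loop, and a
two-stranded antiparallel β-hairpin whose turn (φ,ψ = 27°,38° / 140°,−38°)
and strand (−93°,107°) torsions were refined once, by direct minimisation
of the Kabsch–Sander energies of the intended cross-strand register, so
the hairpin genuinely hydrogen-bonds and is assigned E by secondary
structure. Consecutive Cα–Cα distances are 3.8 ± 0.1 Å. With side chains,
helix/strand residues carry a Cβ, loop/turn residues are glycine, and one
strand residue is a 10-heavy-atom tryptophan-like side chain for SASA
tracking.

Templates: the unfolded conformer is the chain rebuilt with extended
torsions (−150°,150°), which breaks every native contact with a margin
exceeding the cutoff plus 6 jitter SDs; the intermediate unwinds a
contiguous N-terminal prefix (helix first, then loop, then the outer
first strand) until its retained contact fraction best matches the
target (default 0.5) — helix-only unwinding cannot reach 0.5 because the
hairpin carries most of the fold's contacts. Rg orders
native < intermediate < unfolded by construction.

Trajectories follow a Markov chain with transition probability
p_j/dwell to state j ≠ i, which has the configured occupancies as its
stationary distribution and satisfies detailed balance; each frame adds
i.i.d. Gaussian jitter (default σ = 0.3 Å per coordinate, small against
the 4 Å cutoff so state identity dominates *N*c). One master seed drives
all randomness; the caller's RNG state is left untouched; the hidden
state path is exported as ground truth so recovery tests never re-infer
it from coordinates. The default thermal schedule moves occupancy mass
native → intermediate → unfolded across 300/350/400/450/500 K.

Default problem sizes — 1500 frames per temperature, dwell 5, with SASA
and secondary structure evaluated every 5th frame — were chosen so the
mean-occupancy standard error (inflated by Markov autocorrelation,
roughly √((1+ρ)/(1−ρ)) with ρ the stay probability) is several times
smaller than the smallest between-temperature gap in expected *N*c,
making the recovered monotone trends stable across seeds while keeping a
full ladder analysis interactive.

## Pipeline conventions

The native reference for *N*c and RMSD is, for synthetic runs, the
generator's noise-free native template (the analogue of using the
deposited native structure); for file inputs it is frame 1 of the
coldest trajectory, overridable. Summary statistics use the sample
(n−1) SD and by default discard no equilibration (the fraction is a
config knob, since published tables rarely state their discard). Every
defaulted parameter is logged at WARN once per run so silent divergences
from a paper's (often unstated) settings are visible; a `COMPLETE`
marker is written only when every stage succeeded, and identical
config + seed reruns are byte-identical.

## Known limitations

- Multi-model PDB is the only trajectory format; binary formats (XTC,
  DCD) would need an external converter.
- The FEL basin detector reports grid-local minima; rugged landscapes at
  fine binning can yield more minima than metastable states.
- The secondary-structure assigner is a simplified Kabsch–Sander scheme;
  byte-for-byte agreement with any particular DSSP release is a
  non-goal.
- The generator's intermediate is a single rigid template; real
  intermediates are heterogeneous ensembles.
- No per-residue relative accessibility normalisation for SASA, and no
  H-bond energies in the order-parameter module (energetic H-bonds live
  in the secondary-structure module).
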