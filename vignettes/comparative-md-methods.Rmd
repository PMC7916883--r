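---
title: "Methods: comparative trajectory analysis with tidytraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative trajectory analysis with tidytraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidytraj)
```

tidytraj compares the conformational dynamics of two homologous protein
systems from their molecular-dynamics trajectories. This vignette is the
package's own account of the methods: the quantities it computes, the
conventions and numerical choices behind them, what the synthetic
generators do and do not emulate, and the limits of what a passing test
suite demonstrates.

## Data model and units

A structure is a tibble of PDB atoms with author residue numbering
preserved verbatim; coordinates are Angstrom at the PDB boundary. A
trajectory is an `n_frames x n_atoms x 3` array in **nanometres** with
strictly increasing frame times in picoseconds; the Å↔nm conversion is
confined to I/O. Fluctuation quantities (RMSD, RMSF, eigenvalues, TMSF)
are therefore in nm and nm²; SASA and the radius of gyration are
reported in Å² and Å, the units in which such structural parameters are
conventionally tabulated.

The required trajectory interchange dialect is multi-model PDB with a
frame-time sidecar TSV. It is text-exact and language-neutral; binary
engine formats can be converted to it by any standard tool. A
consequence worth knowing: PDB stores coordinates at 0.001 Å, so a write
→ read round trip is exact only to 1e-4 nm.

## Superposition and fluctuation metrics

Superposition uses the Kabsch algorithm: the proper rotation (via SVD of
the weighted cross-covariance, with the determinant sign correction that
excludes reflections) and translation minimizing weighted RMSD. Inputs
with fewer than three atoms or a collinear reference are rejected, since
the rotation is then not identifiable.

A `fit_spec` separates the atoms used *to fit* from the atoms *measured
over*. Self-fitting a monomer (fit = measure = that monomer's Cα set)
isolates its internal fluctuation; non-self-fitting (fit on monomer A,
measure monomer B) additionally picks up the relative displacement of
the monomers, so the difference between the two series reads out
inter-monomer mobility. RMSD is computed against the starting structure.
RMSF is computed about the time-average position after fitting —
the reference for the average-position convention is a deliberate
choice, documented here because engines differ; with
`build_covariance(..., two_pass = FALSE)` the covariance trace equals
`sum(RMSF^2)` exactly, which the tests exploit as a cross-check between
two independently coded routes.

Region statistics (active-site floor, inner/outer walls, roof, PLP and
folate sites, shipped as `shmt_regions()` in the mesophilic enzyme's
numbering) report the arithmetic mean and the **population** (1/n) SD
over member residues. The population convention was chosen because the
region is the entire population of interest, not a sample from a larger
one; the per-replica RMSD SDs fed to the Welch test use the sample
(n−1) SD, as those do estimate dispersion from finite sampling.

Cα-only selections are unweighted (equal masses cancel); the all-atom
radius of gyration is mass-weighted with standard atomic masses.

## Geometric interaction criteria

All cutoffs are strict inequalities and purely geometric:

| parameter | default | unit | role |
|---|---|---|---|
| probe radius | 1.4 | Å | water-sized SASA probe |
| contact cutoff | 6 | Å | close inter-atomic contact, `d < cutoff` |
| H-bond distance | 3.5 | Å | donor–acceptor heavy atoms, `d < cutoff` |
| H-bond angle | 120 | ° | donor–hydrogen–acceptor, `angle > cutoff` |
| sphere points | 960 | — | SASA sampling density per atom |

SASA uses deterministic Shrake–Rupley sampling: one fixed golden-spiral
point set shared by every atom, so results are bit-reproducible and the
total is exactly the sum of per-atom areas. 960 points give ≤0.5% error
on an isolated sphere (the tests verify this against the closed form,
and against the analytic two-intersecting-spheres formula). van der
Waals radii follow the Bondi compilation.

Contacts apply **no** bonded or same-residue exclusions — the criterion
is distance alone. Engine tools differ here (most exclude 1–2/1–3
neighbours and scale 1–4), which shifts absolute intra-molecular contact
counts by a large, convention-dependent amount; comparisons should
therefore be made within one convention, and the package declares its
convention rather than imitating any engine's.

Hydrogen-bond donors are N/O atoms with a covalently bound hydrogen
(hydrogens are attached geometrically to the nearest heavy atom within
1.25 Å); acceptors are all N/O; water oxygens act as both. A donor whose
hydrogens are absent from the model is skipped with a message rather
than guessed. Counts are unique donor–acceptor pairs per frame.

## Essential dynamics

The Cα covariance is built from fitted frames about their ensemble mean,
by default in two passes (fit to the starting conformation, average,
re-fit to that average) so the mean and the fit reference are mutually
consistent. Eigenpairs are sorted by decreasing eigenvalue; each
eigenvector's sign is fixed so its largest-magnitude component is
positive, removing the arbitrary sign from projections, porcupine output
and tests. Ties are left in the (stable) order the symmetric eigensolver
returns. For a rigidly fitted ensemble at least six eigenvalues vanish
to numerical precision — the rigid-body degrees of freedom — and the
tests assert this.

Projections dot the fitted, mean-centred frames with an eigenvector;
their variance equals the eigenvalue *by construction* (population
normalisation, same fitted frames), which the tests assert numerically
rather than trusting. The cosine content of projection *i* against the
*i*-th half-period cosine,
\(c_i = \frac{2}{T}\left(\int_0^T \cos(i\pi t/T)\,p(t)\,dt\right)^2 / \int_0^T p(t)^2\,dt\),
is evaluated with trapezoid integrals on the actual frame-time grid, so
unevenly spaced or concatenated time axes are handled; after replica
concatenation the time axis is re-indexed to a continuous grid for
exactly this reason. Values near 1 mean the largest-amplitude motion is
statistically indistinguishable from random diffusion (the seeded
random-walk generator reproduces this, median c₁ ≈ 0.97 over 50
walkers), values near 0 indicate converged sampling.

Porcupine extraction takes the conformations at the minimum and maximum
of a projection series and emits per-atom vectors
`(proj_max − proj_min) × eigenvector`, written as a two-model PDB plus a
vector table for visualisation tools.

## Free-energy landscapes

The 2-D landscape over eigenvectors 1 and 2 is Boltzmann inversion of
the binned density, \(F_i = -k_B T \ln(N_i/N_{max})\) with
\(k_B = 0.0083144621\) kJ·mol⁻¹·K⁻¹ and T = 300 K by default. The most
populated bin anchors F = 0 and every occupied bin has F ≥ 0; empty bins
are undefined (+∞). Published landscape figures often show negative
absolute values, which correspond to an engine-specific constant offset;
since basin structure is invariant under a constant shift applied to the
energies and the level together (a property the tests check), basin
counts and gaps carry over between conventions while absolute colourbar
values do not.

Bins default to 32×32 (configurable); edges span the sampled range,
right-open except the last bin so extreme frames are counted. Basins are
connected components of bins with finite F below a level, under
8-neighbour connectivity — chosen so that contours touching diagonally
count as one basin, matching how basins are counted visually on a
contour plot. The flood fill is verified against an exhaustive labeling
oracle on random lattices up to 64×64.

Two-state recovery sets the practical accuracy: with 10⁵ frames and
32×32 bins, the basin free-energy gap of a mixture with populations
(p, 1−p) lands within 0.3 kJ/mol of −k_BT ln((1−p)/p). The residual bias
is binning: a state's density peak need not align with a bin centre, so
modal-bin counts understate or overstate populations by up to roughly a
bin's density variation.

## Replicate statistics and the two-system comparison

Each replica is trimmed to the equilibration window (default 10–100 ns —
the usual protocol for 100-ns production runs where equilibration
completes within the first few ns) and its RMSD mean and SD recorded.
The two systems' sets of per-replica SDs are compared with a one-sided
**Welch** (unequal-variance) t test; the pooled-variance variant is
available by flag. Welch is the default because there is no reason to
assume the two systems fluctuate with equal between-replica variance —
the quantity under test is precisely a difference in variability. The
phrase "SDs of the RMSD means" admits two readings (per-replica SDs of
the series vs the SD across replicas of per-replica means); the package
adopts the per-replica-SD reading, which yields one set of n values per
system as the test requires.

`analyze_system()` chains the stages (trim → concatenate → RMSF/regions
→ covariance/projections → cosine contents → landscape → geometry) and
`build_comparison_report()` aligns two systems side by side, mapping
system-B residue numbers onto system-A numbering through a pairwise
alignment (`pairwise_align()`: global Needleman–Wunsch, BLOSUM62, gap
open 10, extend 0.5). Percent identity counts identical columns over
columns with residues on both sides; gap columns are excluded from the
denominator. That denominator is a documented convention — published
identity figures rarely state theirs, and including end gaps can move
the figure by several points.

## Synthetic generators: what they emulate, and what they do not

Every generator is a pure function of its arguments (seeded locally; the
global RNG is never touched) and records its ground truth as an
attribute:

- `gaussian_ensemble()` — i.i.d. frames with a prescribed (diagonal or
  full) 3N×3N covariance: ground truth for eigenvalue recovery and RMSF
  (σ√3 for isotropic noise).
- `diffusion_trajectory()` — independent Gaussian random walks: the
  canonical unconverged-sampling fixture with cosine content near 1.
- `two_state_ensemble()` — a two-conformation mixture with prescribed
  populations and jitter, with true state labels recorded: ground truth
  for landscape gaps.
- `hinge_dimer_trajectory()` — rigid rotation of one chain about an
  interface axis: ground truth for the self/non-self fitting contrast.
- `toy_dimer()` / `add_point_solvent()` — small dimers with valid PDB
  naming whose backbone geometry creates an N–H···O=C ladder across the
  interface, plus random three-point waters: fixtures for the
  donor/acceptor typing and the strict geometric criteria.

These ensembles are statistically controlled but physically naive: no
bonded structure, no excluded volume, no solvent physics, no correlated
collective motions beyond what is prescribed, i.i.d. frames instead of
autocorrelated dynamics. Passing tests therefore demonstrate that the
*estimators* are correct at known ground truth and stated problem sizes
— they do not demonstrate that 10 replicas of 100 ns suffice to converge
any particular real protein's essential subspace, which is exactly what
the cosine-content diagnostic is for on real data.

Default generator scales were fixed once at values typical for stable
folded proteins at 300 K — per-coordinate jitter 0.02–0.05 nm (Cα RMSF
of well-ordered regions), state separations of a few tenths of a nm
(loop/hinge rearrangements), hinge angles up to 30° — and the test
problem sizes (200 atoms × 5000 frames for RMSF recovery, 10⁴ frames for
spectra, 10⁵ for landscape gaps, 50 × 200-step walkers) are the smallest
at which the stated tolerances are statistically comfortable.

## Degenerate inputs and error policy

Fewer than 3 fit atoms, collinear references, single-frame RMSF, empty
trimming windows, all-zero projection series, zero-frame landscapes,
mismatched replica topologies, unknown elements in SASA, unknown config
keys and region residues missing from a structure all raise immediate,
named errors — never silent coercion. Two deliberate conventions:
both-groups-constant-and-equal in the t test returns p = 0.5 with a
message (the test is uninformative, not an error), and altloc records
resolve to the highest-occupancy conformer with ties broken by the first
altloc letter.

## Known limitations

- Force-field energetics (inter-monomer van der Waals/electrostatic
  decompositions) are out of scope; the geometric criteria are the
  interaction surface.
- Missing-residue reconstruction is not performed; incomplete models are
  accepted and their gaps reported.
- Absolute contact counts are convention-dependent (no exclusions here);
  compare within one convention only.
- The landscape is limited to two reaction coordinates and reports
  relative free energies only; no kinetics.
- Structure-derived checks against the two reference crystal structures
  require the user to supply the PDB files (see
  `inst/extdata/accessions/README.md`); they are not redistributed.
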