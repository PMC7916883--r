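# tidytraj

Comparative analysis of protein molecular-dynamics trajectories in R,
organised around the workflow used to contrast homologous enzymes — for
example a cold-adapted (psychrophilic) enzyme against its mesophilic
counterpart, where the scientific question is *how much more, and where,
does one structure fluctuate than the other*. The package implements the
full chain of trajectory-derived quantities such comparisons rest on:

- **Superposition metrics** — least-squares (Kabsch) superposition; Cα
  RMSD time series against the starting structure, including *self-* and
  *non-self-fitting* of the monomers of a dimer (fit on one monomer,
  measure the other) to separate internal fluctuation from inter-monomer
  displacement; per-residue RMSF profiles,
  `RMSF_i = sqrt(<|r_i − <r_i>|²>)`, with mean ± SD statistics over named
  functional regions (active-site floor/walls/roof, cofactor sites).
- **Geometric interaction statistics** — solvent accessible surface area
  (deterministic Shrake–Rupley sphere sampling, 1.4 Å probe), close
  inter-atomic contacts (strict `d < 6 Å`), hydrogen bonds (strict
  `d(D,A) < 3.5 Å` and D–H–A angle `> 120°`), mass-weighted radius of
  gyration, and their trajectory means ± SDs.
- **Essential dynamics** — the 3N×3N Cα positional covariance matrix and
  its eigendecomposition; eigenvalue spectra, total mean-square
  fluctuation (TMSF = trace), cumulative mode contributions, trajectory
  projections, cosine-content convergence diagnostics
  (`c_i = (2/T)(∫ cos(iπt/T) p(t) dt)² / ∫ p(t)² dt`), and porcupine-mode
  extraction (extreme conformations plus per-atom displacement vectors).
- **Free-energy landscapes** — 2-D Boltzmann inversion over the first two
  eigenvector projections, `F_i = −k_B T ln(N_i / N_max)` (so the most
  probable bin sits at `F = 0`), with flood-fill basin enumeration at
  chosen energy levels.
- **Replicate statistics** — equilibration trimming (default 10–100 ns),
  multi-replica concatenation with provenance, per-replica RMSD mean/SD,
  and a one-sided Welch *t* test on the two systems' sets of per-replica
  SDs.
- **Synthetic generators** — seeded, ground-truth-carrying ensembles
  (prescribed covariance, random diffusion, two-state mixtures, hinge
  dimers, toy dimers with donors/acceptors) that make every stage
  verifiable without MD engine output.

Structures and trajectories are exchanged as (multi-model) PDB text with
a frame-time sidecar TSV; results come back as tibbles that compose with
the pipe, with `autoplot()`/`plot_*()` figures and `tidy()`/`glance()`
methods for fitted objects.

## Worked example

A miniature two-system comparison on synthetic replicas (system B built
with 2.5× the coordinate noise of system A):

```r
library(tidytraj)

make_system <- function(noise_nm, seed) {
  lapply(1:5, function(r) {
    g <- gaussian_ensemble(helix_reference(12), noise_nm^2, 180, seed = seed + r)
    md_trajectory(g$coords, times_ps = (0:179) * 500,
                  atoms = tibble::tibble(eleno = 1:12, elety = "CA", resid = "ALA",
                                         chain = "A", resno = 1:12,
                                         element = "C", type = "ATOM"))
  })
}
sys_a <- analyze_system(make_system(0.02, 300), "reference_system",
                        start_ns = 10, end_ns = 90, geometry = FALSE, fel_bins = 16)
sys_b <- analyze_system(make_system(0.05, 400), "flexible_system",
                        start_ns = 10, end_ns = 90, geometry = FALSE, fel_bins = 16)
report <- build_comparison_report(sys_a, sys_b)
report
#> <md_comparison> reference_system vs flexible_system
#>   one-sided test on per-replica RMSD SDs (flexible_system > reference_system): t = 35.187, p = 8.086e-07
report$ed
#> # A tibble: 2 × 7
#>   system           n_calpha tmsf_nm2 top2_pct top10_pct cosine1  cosine2
#>   <chr>               <int>    <dbl>    <dbl>     <dbl>   <dbl>    <dbl>
#> 1 reference_system       12   0.0120     8.94      40.6 0.00172 0.000292
#> 2 flexible_system        12   0.0740     8.85      40.8 0.00162 0.000254
```

Read: the "flexible" system's TMSF is ~6× the reference (the prescribed
noise-variance ratio 2.5² = 6.25), its per-replica RMSD SDs are
significantly larger (one-sided Welch test), and both systems' low
cosine contents say the synthetic sampling is converged, so the
comparison reflects the ensembles rather than a sampling artefact.
`autoplot(sys_b$fel)` draws the corresponding free-energy landscape;
`plot_rmsf(sys_b$rmsf)` the per-residue flexibility profile.

The same pipeline runs from the shell via the bundled wrapper:

```sh
inst/cli/tidytraj simulate --config run.cfg --outdir sim
inst/cli/tidytraj compare  --config run.cfg --outdir out
```

where `run.cfg` is a flat `key = value` file; every cutoff and the
10–100 ns window default to the standard choices, so a minimal config
names only the trajectory paths.

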