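# serialboot

Resampling tools for appraising conformational changes in time-resolved
serial crystallography.

Time-resolved serial crystallography merges partial reflection intensities
recorded one microcrystal at a time. Interpreting the result — is this
density feature a real conformational change, and how well determined are the
refined coordinates? — rests on tools whose uncertainties are rarely
quantified. Because a serial dataset is a large collection of exchangeable
frames, those uncertainties can be estimated by **bootstrap resampling**:
draw fixed-size subsets of frames with replacement, re-run the analysis on
each subset, and read errors off the spread of the results.

serialboot implements that workflow for structural biologists and methods
developers:

* **Resampling & merging** — fixed-size bootstrap plans over frames
  (`bootstrap_plan()`, `expected_multiplicity()`), Monte-Carlo merging with
  with-replacement multiplicities (`merge_frames()`), clip-at-zero amplitude
  conversion, and half-set R-split figures of merit.
* **Difference Fourier & omit maps** — isomorphous
  FT[(F_obs(activated) − F_obs(reference)) · exp(iΦ(reference))] maps
  (`difference_map()`), σ-scaling, Polder-style omit maps with a flat-solvent
  exclusion zone (`omit_map()`).
* **Extrapolation** — F_ext = (1/f)·F_obs(activated) + (1 − 1/f)·F_obs(reference)
  with non-positive-amplitude rejection bookkeeping (`extrapolate()`,
  `remix()`).
* **SVD denoising** — stacks of resampled difference maps decomposed as
  A = USVᵀ; the principal component is a consensus map with replicate noise
  (including phase noise) suppressed (`svd_decompose()`, `principal_map()`);
  pedestal-thresholded sphere integration with resampling error bars
  (`integrate_sphere()`, `quantify_series()`).
* **Two-state refinement & occupancy scans** — reciprocal-space least-squares
  refinement of a free activated conformer against a frozen reference at
  occupancy f (`refine()`), occupancy scans exposing the linear 1/f
  displacement law and a Pearson-correlation occupancy estimate
  (`occupancy_scan()`).
* **Coordinate errors** — bootstrap coordinate spreads
  (`coordinate_spread()`), the closed-form estimate
  σ_free² = 0.65·(N_a/N_o)·R_free²·d_min²·C^e (`sigma_free()`), the B-factor
  displacement scale u = √(B/8π²) (`b_to_u()`), and a quantitative comparison
  of partial-occupancy versus extrapolated-data refinement
  (`compare_approaches()`).
* **Synthetic serial diffraction** — a seeded generator of per-frame partial
  intensities (frame scale × partiality × additive noise) and a full study
  simulator (resting state + 13 log-spaced delays) so everything runs without
  external data (`simulate_frames()`, `simulate_study()`, `run_pipeline()`).

I/O covers a minimal CrystFEL-style stream-chunk dialect (real chunks parse;
extra columns are ignored), columnar reflection tables, fixed-column PDB with
altloc conformers, and a portable text map container.

## Worked example

Estimate activated-state coordinate errors for a toy two-state crystal by
bootstrap resampling:

```r
library(serialboot)

sys <- toy_two_state(seed = 11, n_atoms = 8, displacement = 0.15)
f_true <- 0.27
study <- two_state_frameset(sys$dark, sys$light, f_true, d_min = 2.0,
                            n_frames = 400, seed = 21)

plan <- bootstrap_plan(n_frames = 400, sample_size = 400, n_resamples = 10,
                       seed = 31)
expected_multiplicity(400, 400, 10)
#> [1] 10

models <- lapply(plan$indices, function(ix) {
  merged <- merge_frames(study$light, ix)
  F_obs <- intensities_to_amplitudes(merged, d_min = 2.0)
  fit <- refine(F_obs, two_state_model(sys$dark, sys$dark, f_true),
                refine_options(mode = "partial_occupancy", f = f_true))
  activated_model(fit)
})

spread <- coordinate_spread(models)
round(attr(spread, "mean_all"), 4)
#> [1] 0.0146
round(attr(rmsd_profile(sys$dark, models[[1]]), "mean"), 3)
#> [1] 0.084
round(attr(rmsd_profile(sys$dark, sys$light), "mean"), 3)
#> [1] 0.075
```

Reading: each bootstrap replicate remerges 400 resampled frames and refines
the activated conformer from a resting-state start. The refined mean
displacement from the resting structure (0.084 Å for the first replicate) is
close to the generating truth (0.075 Å), and the atom positions scatter by
0.0146 Å rms across replicates — the bootstrap coordinate error, the number a
displacement must exceed before it deserves a structural interpretation. For
scale, a B-factor of 41 Å² corresponds to `b_to_u(41)` ≈ 0.72 Å of thermal
motion: fluctuation amplitude and the precision of a refined mean position are
very different quantities.

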