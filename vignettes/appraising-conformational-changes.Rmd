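---
title: "Appraising conformational changes by resampling serial crystallography data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Appraising conformational changes by resampling serial crystallography data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialboot)
```

## The problem

Time-resolved serial crystallography merges partial reflection intensities
recorded one diffraction pattern (one microcrystal) at a time, for a resting
state and a series of pump-probe time delays. Structural interpretation then
rests on a chain of tools — isomorphous difference Fourier maps, occupancy
estimation, partial-occupancy or extrapolated-data refinement — each of which
carries assumptions that are rarely stress-tested. Because a serial dataset is
a large collection of exchangeable frames, it invites *resampling*: drawing
fixed-size bootstrap subsets of frames with replacement, re-running the whole
analysis on each subset, and reading uncertainties off the spread of the
results. serialboot implements that workflow end to end, together with a
synthetic serial-diffraction generator so every tool can be exercised and
tested without external data.

## Models and conventions

**Crystal model.** Toy systems live in a triclinic P1 cell. Atoms carry an
element, an electron count, fractional coordinates, an isotropic B-factor and
an occupancy; a two-state crystal is one atom table with conformer tags "A"
(reference, occupancy $1-f$) and "B" (activated, occupancy $f$), where $f$ is
the crystallographic occupancy — the fraction of molecules on the activated
trajectory. Structure factors are computed by direct summation,

$$F(hkl)=\sum_j occ_j\, z_j\, e^{-B_j s^2/4}\, e^{2\pi i\, h\cdot x_j},
\qquad s = 1/d(hkl),$$

with a constant per-element electron count rather than Cromer–Mann form
factors: amplitudes stay reproducible in closed form, and every appraisal
operation downstream is insensitive to the radial shape of the atomic form
factor. Phases are stored in radians and printed in degrees; the Friedel
half-sphere is fixed as $h>0$, or $h=0 \wedge k>0$, or $h=k=0 \wedge l>0$.
Space-group symmetry beyond P1 is out of scope — every appraisal operation
acts on merged data, where symmetry has already been applied.

**Difference maps.** The isomorphous difference Fourier map is the synthesis
of $(F_{obs}^{act}-F_{obs}^{ref})\,e^{i\Phi_{ref}}$ with reference-state
phases. Positive features mark density gained on activation, negative features
density lost. No figure-of-merit weighting is applied. $F(000)$ is excluded
from all syntheses, so maps have zero mean by construction, and the map
"sigma" used for contour levels and pedestals is the root mean square voxel
value. Grids default to a spacing of $d_{min}/3$ with even dimensions, always
large enough to hold every coefficient without aliasing.

**Extrapolation.** A hypothetical full-occupancy activated dataset is
approximated on amplitudes by
$F_{ext} = \tfrac1f F_{obs}^{act} + (1-\tfrac1f) F_{obs}^{ref}$.
Amplification by $1/f$ amplifies errors too; non-positive extrapolated
amplitudes are rejected and logged (the single implemented policy), and sigmas
propagate as $\sqrt{(\sigma_l/f)^2+((1-1/f)\sigma_d)^2}$ under an independence
assumption. `remix()` is the exact algebraic inverse and is used as a
round-trip self-test.

## The synthetic generator

`simulate_frames()` draws, per frame, a Bernoulli subset of reflections and
reports $I_p = s\,p\,I_{true} + \epsilon$ with a lognormal frame scale $s$
(shot-to-shot beam and crystal-size fluctuations), a uniform partiality $p$,
and additive Gaussian noise $\epsilon$ whose sd is a fraction of the median
truth intensity. Defaults — scale sigma 0.3, partiality in $[0.2, 1]$,
observation fraction 0.7, noise 5% of the median intensity — are desk-scale
choices representative of well-behaved serial data; the generator makes no
claim to detector realism (no geometry, profiles, or indexing ambiguity).
Negative observed intensities are kept, deliberately, to exercise the
intensity-to-amplitude policy. Every frame derives its own seed from the
master seed through a counter-based rule (`derive_seed()`), so any subset of
frames is reproducible in isolation.

Two design choices of the two-state toy generator deserve emphasis:

* **Zero net translation.** In P1, translating *all* scattering matter leaves
  every amplitude unchanged — it is a pure gauge mode of amplitude-only data —
  and in a real crystal lattice contacts pin the molecule. The generated
  displacement field is therefore centered (the displacements of moved atoms
  sum to zero), and the refinement engine carries the matching soft restraint
  anchoring the free-atom centroid to its starting value. Without the pair of
  choices, refinements at high modeled occupancy drift along the near-null
  translation direction and displacement profiles become meaningless.
* **Small displacements.** Moved atoms are displaced by 0.15–0.35 Å. This is
  the regime in which the difference-Fourier "same phase" approximation and
  the linear $1/f$ response hold; it mirrors the sub-Ångström backbone
  displacements the appraisal literature targets. The toy is *not* evidence
  about large conformational changes, where extrapolation and difference maps
  are known to degrade.

What passing tests on this generator show, and what they do not: they validate
the algebra and statistics of the appraisal chain (merging converges to the
truth scaled by the analytic gain $E[s]E[p]$, bootstrap spreads scale as
$N^{-1/2}$, SVD denoising beats individual replicates, both refinement modes
recover a known truth). They do not probe indexing errors, non-isomorphism,
radiation damage, anisotropic disorder or scaling-model bias, all of which are
present in real serial data.

## Resampling and merging

`bootstrap_plan()` draws fixed-size multisets of frame indices with
replacement — the resampling unit is always the frame, never the individual
observation. With $m$ replicates of $n_s$ draws from $N$ frames, each frame is
selected $m\,n_s/N$ times on average (`expected_multiplicity()`), e.g. four
times for 100 replicates of 10 000 patterns from 250 000; replicates are
"separate but not independent". Merging is a plain unweighted Monte-Carlo mean
per reflection (a frame drawn $k$ times counts $k$-fold, and the multiplicity
reports draws); per-frame scaling refinement is deliberately out of scope, so
partiality and scale fluctuations are averaged, not modeled. Amplitudes come
from a clip-at-zero square root, $F=\sqrt{\max(I,0)}$, with
$\sigma_F = sem/2F$ for positive amplitudes; a French–Wilson treatment would
slot in behind the same interface. The default multiplicity cutoff is 3
measurements, and dropped-reflection counts are always reported.

## Two-state refinement and the occupancy scan

`refine()` minimizes $\sum_{hkl} (F_{obs} - k\,|F_{calc}|)^2$ over the
coordinates and B-factors of the free atoms with a bounded quasi-Newton method
and analytic gradients, refitting the overall scale
$k=\sum F_{obs}|F_{calc}| / \sum |F_{calc}|^2$ in closed form at every
evaluation. In partial-occupancy mode $F_{calc}$ is the coherent sum of the
frozen conformer A at occupancy $1-f$ and the free conformer B at occupancy
$f$; in extrapolated mode a single free conformer at full occupancy is refined
against the extrapolated amplitudes. There are no geometric restraints — toy
models are sparse, and the engine is an appraisal instrument, not a
macromolecular refinement program. A deterministic 5% reflection subset (seeded
hash) is held out for R-free. Numerical details that matter: B-factors are
bounded to $[0.01, 500]$ Å²; the target trace is monitored per macro-cycle
(default 5 cycles) with a relative-decrease stopping rule; the free-atom
centroid restraint has weight $10^{-2}\sum F_{obs}^2$ per Å², negligible along
data-determined directions but decisive along the translation gauge mode.

`occupancy_scan()` repeats the partial-occupancy refinement over an occupancy
grid and reports (i) the mean displacement versus $1/f$ with a least-squares
line over a configured domain (default $f \ge 0.25$, where the response is
linear), and (ii) the Pearson correlation of each per-atom displacement
profile against the grid-mean profile — an amplitude-independent signature
whose maximum serves as an occupancy estimate. Ties within $10^{-3}$ are
reported as a range, smallest-$f$ first. On noise-free data the correlation is
1 everywhere by construction; the selection is only informative on noisy data.

## Uncertainty estimation

Three complementary error estimates:

* `coordinate_spread()` — per-atom rms deviation from the mean position over
  replicate refinements against bootstrap-resampled data; this is the
  empirical, model-free estimate, and it scales as $N_{frames}^{-1/2}$.
* `sigma_free()` — the closed-form diffraction-precision-index style estimate
  $\sigma_{free}^2 = 0.65\,(N_a/N_o)\,R_{free}^2\,d_{min}^2\,C^{e}$, valid at
  full occupancy. The completeness exponent $e$ defaults to $-3/2$ and is
  config-exposed: printed renderings of the formula are typographically
  ambiguous about the sign, and a positive exponent would make the error
  shrink as completeness falls, which is unphysical.
* `b_to_u()` — $\langle u\rangle=\sqrt{B/8\pi^2}$, the thermal-motion scale.
  The gap between $\langle u\rangle$ and the refined-coordinate spread (about
  a factor of five on the reference study's numbers) separates physical
  fluctuation amplitude from the precision of a refined mean position.

`compare_approaches()` quantifies whether partial-occupancy and
extrapolated-data refinements tell the same story: per-atom separation of the
two mean coordinate sets against the summed bootstrap error bars, plus the
Pearson correlation of the two displacement profiles.

## SVD of resampled difference maps

Stacking $m$ replicate difference maps as columns of a voxels-by-maps matrix
$A$ and decomposing $A=USV^T$, the first left singular vector is a consensus
map in which noise uncorrelated across replicates is suppressed — including
the phase noise introduced by using each replicate's slightly different
reference phases, which is how the resampling probes phase bias. The component
is scaled by $S_1/\sqrt m$ so its magnitude matches an individual map, and its
sign (arbitrary in any SVD) is fixed by positive correlation with the
voxel-wise stack mean. SVD is applied within one delay's replicate set;
analysis of right singular vectors across delays is out of scope.

`integrate_sphere()` quantifies a feature by summing voxel values within a
radius of a site (0.8 Å by convention for waters) after zeroing voxels below a
pedestal of the map's own sigma — 2.0σ for difference maps, 0.1σ for omit
maps, both config-exposed. Sphere membership is by voxel-center inclusion; the
estimate converges with grid refinement and is accurate to a few percent at
spacings of a quarter radius for generic (off-lattice) centers.
`quantify_series()` repeats this over replicates and delays; the replicate
standard deviation is the resampling error bar on the feature amplitude.

Omit maps compute $F_{calc}$ with the selected atoms removed, fit $k$ by least
squares, and synthesize $(F_{obs}-k|F_{calc}|)e^{i\Phi_{calc}}$. The optional
flat solvent places a constant density beyond a probe radius of every
remaining atom; the Polder-style exclusion keeps a sphere around the omitted
atoms solvent-free so weak density is not swamped. Parity is with this stated
definition, not with any particular production implementation's solvent mask.

## The pipeline and its study layout

`simulate_study()` + `run_pipeline()` wire everything into the study layout
the toolkit targets: one resting dataset plus 13 logarithmically spaced delays
(16 ns–1.725 ms), 100 bootstrap replicates each — 1400 resampled datasets —
with occupancy ramping to 27% and a transient water ordered only at
intermediate delays. Per delay the pipeline merges every replicate, computes
replicate difference maps against matched resampled dark data, extracts the
principal SVD component, and quantifies the water site with resampling error
bars; a replicate subset (configurable, default 10) is carried through both
refinement modes for coordinate spreads and the approach comparison. Problem
sizes in the default config (8 atoms, 12 Å cell, 2 Å resolution, 300 frames
per dataset) are chosen so the full pipeline runs in about two minutes on one
CPU; every stage scales to larger configs through the same fields. One master
seed fans out to all stages via `derive_seed()`, and each run writes a
machine-readable manifest.

## Numerical and I/O choices

* Stream text output uses `%.6g`; the reflection table uses `%.10g` because
  its round-trip is specified lossless. Maps round-trip through a documented
  plain-text grid to better than $10^{-6}$.
* `read_stream()` parses the public stream-chunk layout (begin/end markers,
  reflection block with `h k l I sigma(I)` plus ignored extra columns),
  renumbers frames densely from 0 and keeps original serial numbers; parsers
  never drop chunks silently — parsed/ignored counts are returned.
* Degenerate inputs fail loudly: zero-reflection resolution cutoffs, all-zero
  maps under sigma-scaling or SVD, empty omit selections, spheres containing
  no voxel center, missing seeds.

## Known limitations

The scattering model is a point-electron approximation; amplitudes are not
comparable to Cromer–Mann calculations. Merging has no scaling model, so
systematic per-frame effects beyond a global scale are treated as noise.
Refinement is unrestrained and reciprocal-space only, so it is unsuitable for
real macromolecules. The extrapolated-data route inherits the known
error-amplification of the $1/f$ formula; its R-factors are expected to be
worse than partial-occupancy ones on the same data. All validation evidence is
synthetic; conclusions about real-beamline systematics are out of scope.
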