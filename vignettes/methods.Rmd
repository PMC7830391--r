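---
title: "Few-view CT reconstruction and ant-colony hyperparameter tuning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-view CT reconstruction and ant-colony hyperparameter tuning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Reconstructing an attenuation image $x$ from X-ray projections $b = Ax$
becomes badly ill-posed when only a few dozen view angles are measured.
Total-variation (TV) regularised iterative solvers handle this regime
well, but their behaviour hinges on a handful of hyperparameters that
are data-specific and tedious to tune by hand.  `acotomo` implements

* the AwPCSD solver — adaptive-weighted projection-controlled steepest
  descent: alternating SART data-fidelity sweeps, a non-negativity
  projection, and normalised steepest descent on an edge-preserving
  adaptive-weighted TV (AwTV) norm;
* an ant-colony-optimisation (ACO) tuner that selects the solver's
  data-inconsistency tolerance $\varepsilon$ and TV sub-iteration count
  $n_g$ automatically, using one-iteration reconstructions scored by
  correlation against a reference image;
* baselines (CGLS, leave-one-angle-out cross-validation, a fixed
  "arbitrary" setting), image-quality metrics (CC, UQI, relative
  error, RMSE), a synthetic thorax-like phantom with a mixed
  Poisson–Gaussian noise model, and a desk-scale experiment harness.

# Geometry and projectors

The system operator $A$ is never materialised.  Forward and back
projection share one Siddon-style traversal that accumulates exact
ray–voxel intersection lengths, so the pair is an exact adjoint
($\langle Ax, y\rangle = \langle x, A^{\mathsf T}y\rangle$ to rounding) —
a property the suite verifies directly and against an independently
assembled dense intersection-length matrix on small grids.  Voxel
membership along a ray is decided at segment midpoints, and an axis the
ray is exactly parallel to uses a half-open convention, so
boundary-riding rays deposit into exactly one voxel row.  Parallel- and
fan-beam 2D modes are the primary surface; `cone3d` runs the same
traversal in 3D.  The detector is flat with one central ray per pixel;
realism comes from the noise model, not detector sub-sampling.

# The noise model

A line integral $p$ corresponds to expected counts $I = I_0 e^{-p}$.
The detector records $\mathrm{Poisson}(I)$ plus additive Gaussian
electronic noise (the mixed Poisson–Gaussian detector model), and the
noisy integral is $p' = \log(I_0 / \max(\text{counts}, 1))$.  The
reference acquisition uses $I_0 = 60000$ counts and Gaussian mean 0,
sd 0.5 counts; three stress levels (30000/1, 20000/3, 10000/5) are
predefined in the experiment plan.  Two numerical choices are ours: the
Gaussian component is added in the *count* domain (sd 0.5 counts would
be negligible if added to line integrals, which would make the stated
parameter meaningless), and counts are clipped at 1 before the
logarithm (photon starvation guard; threshold configurable).  Poisson
draws switch to a normal approximation above mean $10^7$, where `rpois`
would overflow and the relative skew is below $4\times10^{-4}$.

# The AwPCSD solver

Each outer iteration $w$:

1. record $dd = \lVert Ax - b\rVert_2$;
2. if $dd^2 > \varepsilon$, run one SART sweep over all angles with
   relaxation $\beta$ (per-angle normalisation $V_a^{-1} A_a^{\mathsf T} W_a$);
3. project $x \leftarrow \max(0, x)$ (POCS);
4. decay $\beta \leftarrow \beta\,\beta_{red}$;
5. set the TV step *control* $\eta = k\,dd(w)/dd(1)$ ($\eta = 1$ on the
   first iteration, clamped to $(0, 10]$);
6. run $n_g$ steepest-descent sub-iterations on the smoothed AwTV norm,
   each moving the image by $\eta \cdot \lVert \Delta_{data}\rVert_2$ in
   L2 norm, where $\Delta_{data}$ is the iteration's data-update step.

Stopping: $\beta < 0.005$; or $c < -0.99$ together with
$dd \le \varepsilon$, where $c$ is the cosine between the data-update
and TV-update steps of the iteration (0 if either vanishes); or the
outer-iteration cap.

Two design choices deserve emphasis:

* **SART normalisation is per angle.**  Normalising each angular
  sub-update by column sums over *all* angles scales every update down
  by the number of views; measured on the 64×64 world this leaves SART
  at ~17% relative error after 50 sweeps versus ~8.6% with the standard
  per-angle normalisation.  `os_sart` generalises this per subset, so
  one subset per angle reproduces `sart_sweep` and a single subset is a
  SIRT-like full-data update.
* **The TV step is scaled by the data-step norm.**  A literal unit-L2
  TV step of size $\eta$ is dimensionally untethered to the image: on a
  desk-scale phantom whose whole L2 norm is ~0.4, unit steps flatten
  the image and the $dd$-ratio feedback then amplifies $\eta$ to its
  clamp (measured divergence).  Scaling each TV sub-step by the norm of
  the iteration's data-update step — the convention of the
  ASD-POCS family this solver descends from — keeps the two phases
  commensurate at any scale while preserving the projection-controlled
  decay of $\eta$.  A corollary: when the SART phase is gated off
  ($dd^2 \le \varepsilon$) the data step is zero and the iteration is a
  no-op.  We deliberately do *not* carry a previous step norm into
  gated iterations: doing so lets the TV phase keep polishing an image
  whose data fit someone else paid for, which in the tuner rewards
  large-$\varepsilon$ "free-rider" ants riding on the warm-start image
  (measured: the tuner then systematically selects configurations whose
  from-scratch reconstructions are poor), and in full runs lets mid-
  $\varepsilon$ configurations smooth away structure long after data
  fitting has stopped.

The AwTV norm is
$\sum_v \sqrt{\sum_a w_a \Delta_a^2}$ with backward differences
$\Delta_a$ (zero outside the grid) and weights
$w_a = e^{-(\Delta_a/\delta)^2}$; as $\delta \to \infty$ it reduces to
isotropic TV.  Its gradient freezes the weights at the current image
(lagged diffusivity) and smooths each square root to
$\sqrt{\cdot + \mu^2}$ with $\mu = 10^{-8}\max(\max|x|, 1)$ by default;
the gradient is checked against central finite differences of exactly
that frozen objective.  The scale factor $\delta$ defaults to the 90th
percentile of a short OS-SART probe reconstruction (20 passes,
$\beta = 1$, half the angles per subset), floored at $10^{-8}$.

The solver is resumable: `awpcsd(..., n_outer = k)` returns a `$state`
whose continuation is bit-identical to an uninterrupted run.  The tuner
relies on this warm-start contract, swapping $(\varepsilon, n_g)$
between one-iteration resumptions.

The pseudo-code leaves ambiguous whether the SART phase runs one sweep
or several per outer iteration; one sweep is implemented.  $\varepsilon$
is compared against the *squared* residual in the SART gate and against
the unsquared residual in the stopping rule, each exactly as written in
its source line.

# The ACO tuner

Pheromones $\tau_i$ live on candidate *values* per dimension (10 for
$\varepsilon$, 15 for $n_g$), all initialised to 1.  Ants sample a
configuration per dimension with $P_i = \tau_i/\sum_q \tau_q$, run one
AwPCSD outer iteration from the previous-iteration-best image, and are
scored by CC against the reference.  After a generation, each chosen
value's pheromone is updated with
$\tau_i \leftarrow (1-\sigma)\tau_i + \bar s_i$ ($\bar s_i$ = mean
score of the ants choosing value $i$) and each dimension is normalised
by its maximum.  Values no ant chose carry no new evidence and keep
their pheromone: evaporating them too would, at the reference
evaporation $\sigma = 1$, permanently extinguish any value missed in a
single generation — measured on a rigged deterministic objective this
capped argmax recovery at 18/20 runs, versus 40/40 with the
no-evidence-no-update rule.

Control flow: a generation that improves on the previous one advances
an *iteration* (the winning image becomes the new warm-start base and
$\beta$ decays once); a non-improving generation launches another
generation; exhausting the per-iteration generation budget also
advances an iteration.  Once the iteration cap is reached the colony
keeps sampling generations at the fixed base until the generation
budget is exhausted — a terminal phase that concentrates evidence for
the final selection.  The run ends there, or earlier if an ant's
reconstruction meets the solver's own stopping criteria.  Running to
the caps — rather than stopping at the first non-improving streak — is
the only reading consistent with the reference training run's
wall-clock arithmetic (about an order of magnitude more generations
than a single streak allows).

Every ant's score accumulates into its configuration's cell; the final
answer is the cell with the highest accumulated score, ties broken by
lowest candidate indices.  The entire run is reproducible under the
colony seed, ants are evaluated sequentially, and the caller's RNG
state is restored afterwards.

A known limitation, visible at desk scale: once the warm-start
trajectory is nearly converged, ants whose large $\varepsilon$ gates
the SART phase off return the base image unchanged and score almost as
well as data-fitting ants, although their configuration reconstructs
poorly from scratch.  One-iteration scoring is informative while the
trajectory is still converging — on the 64² world, roughly the first
three to four iterations — so the desk-scale experiment plan caps the
iteration budget there (default 3) and spends the generation budget in
the terminal sampling phase, instead of using the reference 50
iterations that suit a far larger, slower-converging volume.

# Search-space calibration

$\varepsilon$ bounds a squared projection residual, so its useful range
scales with $\lVert b\rVert_2^2$: the reference grid's values
(0 … $5\times10^5$) are "very wide" *for the data they were chosen
for*.  `default_search_space()` reproduces that literal grid;
`scaled_search_space()` keeps its shape (10 $\varepsilon$ values
including 0, the same 15 $n_g$ values 2…30) but spans $\varepsilon$
logarithmically over $[\lVert b\rVert^2/10^5, \lVert b\rVert^2]$, which
is what the experiment harness uses.  Pinned values follow the
reference setup: $\beta = 1$, $\beta_{red} = 0.99$, $\delta$ from the
OS-SART percentile probe.

# The synthetic phantom

A piecewise-constant ellipse phantom stands in for a licensed
anthropomorphic thorax: body outline, two low-attenuation lungs, a
heart-like blob, spine and rib features.  Attenuation values are
physically based for a ~70 keV beam — soft tissue 0.019 mm⁻¹, inflated
lung 0.005, heart 0.022, bone capped at 0.025 — because the noise level
in the projection domain is set jointly by $I_0$ and the attenuation
line integrals; at the stated $I_0 = 60000$ this yields a few hundred
counts behind the mediastinum, matching the few-view low-dose regime
the method targets.  `male`/`female` variants deterministically perturb
element sizes and intensities to emulate differently parametrised
samples.  The phantom reproduces the piecewise-constant, sharp-edged,
low-contrast character of anthropomorphic data but none of its anatomy,
beam-hardening, scatter or motion; a green comparison on it shows the
pipeline ranks methods as expected in this idealised world, not that it
reproduces any clinical figure.

The default desk geometry mirrors the reference proportions: as many
detector pixels as image columns (64 for a 64² grid), pitch covering
the field of view at the detector, 50 views over 360° — a genuinely
few-view, slightly underdetermined system (3200 rays vs 4096 unknowns).
Voxels are 5 mm, giving a ~320 mm thorax-like field of view.

# Numerical choices and degenerate inputs

* Zero row/column sums in SART contribute zero update; all-zero
  pheromone dimensions are reset to uniform; negative pheromones
  (possible only from negative scores) clamp to 0.
* A failed ant reconstruction scores −1 and is logged, not fatal.
* CGLS stops early when the projection residual norm increases (the
  usual semi-convergence guard on noisy data) or when the
  normal-equations gradient vanishes.
* `estimate_delta` falls back to $10^{-8}$ on non-positive percentiles.
* Metrics are computed over the full volume in double precision with no
  masking; CC/UQI error out on zero-variance input rather than
  returning NaN.

# Scaling of the shipped tests

The test suite and acceptance checks run the full pipeline at 64² with
the desk-scale colony (50 ants, 3-iteration horizon, 12-generation
terminal phase) and exercise cross-validation on tiny worlds (full
strided CV at 64² takes hours), keeping the whole suite inside CI
budgets; the reference-scale colony (50 ants × 10 generations × 50
iterations) is exercised on the rigged deterministic objective where
ant evaluation is free.  The comparison pattern (tuned AwPCSD beating
CGLS and an arbitrary TV setting, errors growing with noise) is the
desk-scale analogue of the reference experiments, not a numerical
reproduction of them — the anthropomorphic phantom those numbers depend
on is licensed and deliberately not modelled.
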