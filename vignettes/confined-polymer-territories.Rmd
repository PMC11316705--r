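---
title: "Confined polymer models of chromosome territories: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confined polymer models of chromosome territories: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

Interphase chromosomes occupy distinct chromosome territories (CTs) whose
shapes range from near-spherical to strongly elongated. `ctpoly` asks a
simple physical question about that geometry: *how does the shape of a rigid
confinement, at fixed monomer density, change the internal contact
statistics of the polymer inside it?* The observable of interest is the
contact probability `p_c(l)` between monomers at scaled contour separation
`l`, whose power-law decay `p_c(l) ~ l^(-alpha)` is the standard diagnostic
of chromosome folding state: `alpha ~ 2.18` for a swollen self-avoiding coil,
`alpha ~ 1` for a crumpled (fractal) globule, and `alpha -> 0` in the
surface-dominated plateau of a compact equilibrium globule.

The package implements both directions of the analysis:

* **Direct modelling** — a Kremer–Grest bead-spring chain inside rigid
  spheroids of aspect ratio `beta = c/a` (oblate `beta < 1`, sphere
  `beta = 1`, prolate `beta > 1`) at reduced densities
  `rho sigma^3 = N/V`, with `alpha` measured from the trajectory.
* **Inverse modelling** — given ensembles of per-chromosome 3D structures
  (bead coordinate files, as produced by Hi-C-based structure modelling
  tools), fit a spheroid per structure by PCA, compute sphericity
  `Phi = pi^(1/3) (6V)^(2/3) / S`, classify shapes, and compare
  length-rescaled, doubly normalized contact-probability curves across
  chromosomes.

# The chain model

The chain is the canonical Kremer–Grest bead-spring polymer in reduced
Lennard-Jones units (`sigma = eps = tau = m = 1`):

* **FENE bonds**, `U(r) = -0.5 k R0^2 log(1 - (r/R0)^2)`, with the community
  standard `k = 30 eps/sigma^2`, `R0 = 1.5 sigma`. These values are stated
  defaults of `force_field()` and can be overridden.
* **WCA excluded volume** between all bead pairs (including bonded
  neighbours), `U(r) = 4 eps [(sigma/r)^12 - (sigma/r)^6] + eps` truncated
  at `2^(1/6) sigma`.
* **Fully flexible by default.** No bending potential is applied
  (`k_bend = 0`); an angular term `U = k_bend (1 - cos theta)` is available
  for semiflexible variants and is covered by the energy-conservation
  tests, but all shipped analyses use the flexible chain.

The combined bond potential has its minimum near `0.97 sigma`, which is the
mean bond length observed in production runs.

# The confinement

`axes_from_density(N, rho, beta)` returns the target cavity: `b = a`,
`c = beta a`, `V = (4/3) pi a^2 c = N / rho`. Two shapes at the same
`(N, rho)` always enclose the same volume, so `beta` isolates the pure
shape effect.

The wall itself is repulsive, in two interchangeable modes:

* `shell_beads` (default): WCA monomers tiled quasi-uniformly over the
  surface by a Fibonacci-sphere lattice at spacing `0.25 sigma`
  (`fibonacci_shell()`), mirroring a confinement shell built from beads.
* `analytic`: the laterally integrated force of the same tiling treated as
  a continuous sheet of WCA sites at density `n_A = 1/spacing^2`. For a
  bead at depth `d` below the surface the sheet force is
  `F(d) = 2 pi n_A d U_WCA(d)` (obtained by integrating the pair force over
  the sheet plane), applied along the inward level-set gradient. At the
  default spacing the two modes agree in direction and to better than ~10%
  in magnitude half a monomer diameter from the wall; the analytic mode is
  cheaper and is what the simulator uses while a confinement is being
  compressed (below).

**Density correction (Gibbs offset).** A WCA wall is soft: it excludes the
chain from a layer of roughly one monomer diameter, so a shell placed
exactly on the target cavity surface would realize a substantially higher
density than `N/V` (at `rho sigma^3 = 0.25` the error approaches a factor
of two). The simulator therefore places the shell *outward* of the target
cavity by the Gibbs dividing surface of the planar wall potential,
`delta = integral (1 - exp(-Phi(z)/kT)) dz ~ 1.05 sigma` at defaults
(`wall_offset()`), so that the accessible volume for bead centers matches
the nominal cavity. Trajectories record both surfaces: `$geom` (the wall)
and `$cavity` (the nominal, density-defining spheroid).

# Chain preparation: compressed swollen coils

`run_simulation()` prepares the chain (default `init = "compressed_saw"`)
in three phases within one seeded run:

1. **Swelling** — an unconfined chain relaxes from a random walk into a
   swollen self-avoiding coil (`n_steps_prep`, default `2 N^2` steps).
2. **Compression** — the confinement starts with every bead at least
   `2 sigma` inside a scaled-up spheroid and shrinks linearly to the target
   over `n_steps_compress` (default `4 N^2`) steps, slowly enough that the
   wall never overtakes the thermal motion of the beads.
3. **Equilibration and production** — `n_steps_equil` discarded steps, then
   `n_steps_prod` steps sampled every `sample_every`.

This mirrors the physical situation the model addresses: an interphase
chromosome is a long self-avoiding chain packed into a territory, and its
large-scale state is territorial/crumpled rather than a fully equilibrated
compact globule (whose contact decay would be much flatter, approaching the
plateau `alpha -> 0` well inside the fit window at the highest density).
Observables are averaged over the trailing 10% of saved frames
(`last_fraction = 0.1`), by which point the radius of gyration is
stationary (`equilibration_diagnostics()`); the slow topological
reorganization of the crumpled state is intentionally retained, not
averaged away. The alternative `init = "random_walk"` prepares a locally
equilibrated but non-territorial state and is the fast choice when only
cavity-filling matters (e.g. shape-recovery checks).

# Integrator and numerics

* Langevin dynamics by BAOAB splitting, `dt = 0.01 tau`,
  `gamma = 1/tau`, `kT = 1`; `gamma = 0` reduces to velocity Verlet
  (energy drift below `1e-3 eps` per bead per `1e4` steps at
  `dt = 0.005`). Kinetic energy is measured at the O-step midpoint, where
  the OU update leaves the Maxwell distribution exact.
* Pair interactions use a Verlet neighbour list (skin `0.4 sigma`,
  rebuilt when any bead has moved half a skin); shell beads are looked up
  through a static cell grid. Forces and trajectories are bitwise
  deterministic for a given seed and platform (own xoshiro256++ /
  polar-method normal generator).
* A fresh random-walk start is relaxed by an overdamped push-off with a
  geometrically ramped force cap before dynamics begin; production aborts
  (rather than clamps) on any FENE bond reaching `R0`.
* The analytic wall clamps its depth argument at `0.7 sigma`, bounding the
  inward force for the rare bead found at or beyond the surface while the
  confinement is compressing; the clamp is irrelevant in equilibrium, where
  the unclamped Boltzmann weight of that depth is `exp(-200)`-level.

# Observables and conventions

* **Scaled separation** `l = k / N`: contour separation in beads over chain
  length, so chains of different `N` share the axis (`l = 0.07` is
  `k = 10` on `N = 150`).
* **Contact**: center distance *strictly* below `r_cutoff = 2 sigma`.
  Bonded pairs (`k = 1`) are always in contact at that cutoff and are
  excluded by default (`min_separation = 2`).
* **`<R^2(l)>`** averages over all pairs at each `k` and the trailing 10%
  of frames; `contact_probability()` enumerates the identical pairs.
* **Scaling fit**: unweighted OLS of `log p_c` on `log l` on the raw grid
  over `0.07 < l < 0.2` (strict), the decade where shape effects are
  visible but the plateau has not set in; `alpha` is minus the slope.
  Optional logarithmic binning (`log_bins`) averages points per bin before
  fitting, for noisy large-`l` tails; the shipped analyses fit the raw
  grid.
* **Replicas**: seeds are pooled by summing contact counts, then fitting
  (`replica_scaling()`), which also reports per-seed exponents and their
  t-interval; both pooling orders are thereby available.
* **Distance distribution**: histogram of
  `x = sqrt(R^2(k)) / sqrt(<R^2(k)>)` (unit mean square by construction),
  the shape diagnostic distinguishing confinement geometries at fixed `l`.

# Inverse modelling choices

* **Spheroid fit**: semi-axes from PCA second moments with the
  uniform-ellipsoid factor `sqrt(5)` (`axis = sqrt(5 lambda)`), the robust
  default; a least-squares surface refinement of the outer quartile of
  points is available (`method = "surface"`).
* **Classes**: with sorted axes `a <= b <= c`, *sphere* if
  `c/a <= 1 + tol` (default `tol = 0.15`); otherwise *prolate* when the
  long-axis gap dominates (`c - b >= b - a`), else *oblate*. The reported
  aspect ratio is `c / mean(a, b)` for prolate and `a / mean(b, c)` for
  oblate fits.
* **Sphericity** uses exact spheroid surface formulas when two fitted axes
  agree to `1e-8` (relative) and the Thomsen `p = 1.6075` approximation
  (error < 1.1%) for triaxial fits; `Phi` is invariant under rotation and
  uniform scaling of the cloud.
* **Cross-chromosome curves**: each chromosome's `p_c` is mapped to the
  shared rescaled grid by linear interpolation, *masked* (never
  extrapolated) outside its support; then (1) divided pointwise by the
  cross-chromosome mean curve and (2) scaled to unit trapezoidal area —
  in that order, removing first the generic distance decay and then the
  total-contact differences.

# Synthetic data

`generate_confined_ensemble()` stands in for an ensemble of Hi-C-derived
per-chromosome structures: short confined simulations with known
ground-truth `beta`, one final conformation per replica, full
parameterization and seed recorded so any ensemble regenerates
bit-identically. It emulates the geometry and confinement of such
ensembles, not their data-driven features: no locus-specific interactions,
no compartments or TADs, no inter-chromosomal contacts, and no experimental
noise. Passing tests on these ensembles therefore validates the machinery
(fitting, classification, normalization) and the physics of homopolymer
confinement — not biological accuracy on real nuclei.

`generate_free_chain("ideal")` provides the closed-form oracle ensemble
(`<R^2(k)> = k b^2`; Gaussian radial end-to-end law; contact decay
`k^(-3/2)` at small cutoff); `"saw"` is the unconfined Kremer–Grest
reference whose measured exponent at the `N = 150` fit window lies near,
but below, the asymptotic `2.18` (finite-size effect).
`generate_toy_profiles()` builds exact power-law curve sets for the
normalization and fitting machinery.

# Problem sizes used in the test-suite and acceptance runs

The shipped tests and the acceptance script run the full 5-shape x
3-density grid at `N = 150`: 5 seeds per cell with per-run phase lengths
`prep = 4.5e4`, `compress = 9e4`, `equil = 1e5`, `production = 4e5` steps
(800 frames, trailing 80 analysed) for the lowest- and highest-density
rows, and reduced statistics (3 seeds, `2e5` production) for the
middle-density row, which only enters the density-monotonicity check where
the exponent separation is large. The unconfined self-avoiding-walk
control pools 8 seeds at `3e5 + 3e5` steps. These sizes were chosen as
the smallest at which the radius-of-gyration diagnostic passes and pooled
exponents stabilize; per-seed exponents still scatter by roughly
`+/- 0.1-0.2`, which is why pooled counts over multiple seeds are the
reported quantity. The equilibration default in `sim_config()`
(`200 N^2` steps) is deliberately more conservative than these desk-scale
figures.

# Known limitations

* A single homopolymer chain per cavity: no multi-chain territories, no
  entanglement-driven slow dynamics at these lengths, no hydrodynamics.
* The crumpled state obtained by compression relaxes slowly; exponents at
  the highest density depend mildly on how long the state is aged before
  sampling (documented above), which is inherent to modelling territorial
  chromosomes with equilibrium-seeking dynamics.
* The analytic wall is the integrated-sheet approximation of the bead
  shell; curvature corrections of order `sigma / a` are ignored.
* Spheroid fits assume a convex, roughly ellipsoidal cloud; strongly bent
  or fragmented structures will be summarized poorly by any single
  spheroid.
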