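---
title: "Coarse-grained simulation of multi-component colloidal gel networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained simulation of multi-component colloidal gel networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`gelsim` simulates physical hydrogels as networks of colloidal-scale
building blocks. A "particle" is not a monomer but a micron-scale blob of
self-assembled material (a fiber segment or bundle cross-section); `d`,
the particle size, and `eps`, the sticking energy between blobs, define
the reduced units. Because `eps` is of order 100 k_B T, a network formed
once does not remodel thermally: the gels are athermal and all rheology is
run at zero temperature.

Particles interact through

* a **two-body 18-16 potential**
  `E2(r) = A eps [(d2/r)^18 - (d2/r)^16] H(r_cut - r)`
  with a steep core below its minimum at `r_min = sqrt(9/8) d2 ~ 0.98 d`
  (for the reference `d2 = 0.922 d`) and a short attractive tail, cut off
  sharply at `r_cut = 2 d`. The depth is `-0.0433 A eps`, so `A` sets the
  bond strength; the residual at the cutoff (~`3e-6 A eps`) is negligible
  for all `A` used.
* a **three-body angular term**, purely repulsive,
  `E3 = B eps L(r_ij) L(r_ik) exp(-[(cos t_ijk - cos t_bar)/w]^2)`, with
  `L(r) = (d3/r)^10 [1 - (r/r_cut)^10]^2 H(r_cut - r)`. Together with the
  pair attraction it selects bond angles near `cos t_bar`, which is what
  turns a particle fluid into a branched fibrous network instead of
  droplets. `B` sets the angular stiffness and `cos t_bar` the local fiber
  geometry (smaller values give straighter, stiffer fibers).

Per species only `A`, `B` and `cos t_bar` are varied; the geometry
constants (`w = 0.3`, `d2 = 0.922 d`, `d3 = 1.1 d`, `r_cut = 2 d`) are
shared by all species and cross interactions. A triplet's `(B, cos t_bar)`
is resolved by the *set* of species it contains; in particular the
PIC-UPy cross row uses `B = 0`, which removes the angular repulsion
between unlike strands and lets the two networks wrap around each other
(the interpenetrating-network morphology). The shipped parameter sets are

```{r}
library(gelsim)
preset_interaction_table(c("PIC", "UPy"))
gel_cross("PIC", "BTA")$order
```

Forces are analytic gradients; the stress tensor is assembled from
per-interaction relative coordinates (`sigma_ab = -V^-1 sum r_ij,a f_j,b`
for pairs, and the analogous two-bond form for triplets), which is exact
under periodic boundaries and reduces to the familiar single-sum virial in
an open system. The zx component equals `dE/dgamma / V` under affine
shear — the tests verify this identity numerically, along with
force-gradient consistency and brute-force energy resummation.

## Units

With `d ~ 1 um`, `eps ~ 100 k_B T` (300 K) and Stokes drag of a micron
sphere in water, the stress unit `eps/d^3` is ~0.4 Pa and the time unit
`tau = zeta d^2/eps` is ~2e-2 s; `unit_system()` and `to_physical()`
expose this mapping. Internally `d = eps = m = zeta = 1`: the physical
picture fixes the drag scale but leaves the particle mass and the drag
coefficient without separate reference values, so both are set to one,
making the reduced time unit coincide with `tau`.

# Dynamics and preparation

Three integrators share a velocity-Verlet core (default `dt = 0.005 tau`,
validated by the dt^2 energy-drift test):

* **Nose-Hoover** (single chain, relaxation `100 dt`) for thermalized
  stages. Only the sampled temperature matters downstream, not thermostat
  internals.
* **Damped zero-temperature** dynamics (viscous force `-zeta v`, inertia
  retained) to drain kinetic energy. A run ends when the kinetic
  temperature `2 KE/(3 N k_B)` falls below a threshold; at the default
  `1e-10 eps/k_B` the structure is an inherent structure (residual forces
  are tiny). An important practical fact: the approach to the threshold is
  dominated by a handful of very soft network modes, so the last decades
  of temperature decay slowly. For large preparations a threshold of
  `1e-7`-`1e-8` gives structurally indistinguishable networks at a
  fraction of the cost, and the size-reduced studies below use that.
* **Conservative** mode, used only to validate energy conservation.

Gels are prepared in three stages: particles on a simple-cubic lattice are
randomized at `T_hot = 0.5 eps/k_B`, quenched and relaxed at
`T_quench = 0.05 eps/k_B` (both under the thermostat; the quench is
instantaneous by default, a linear ramp is available via `ramp = TRUE`),
then drained to zero temperature. Stage durations default to `1e3 tau`
each — appropriate for production-scale networks; the package's tests use
much shorter stages at small N, which still produce percolating networks.
The volume fraction (spheres of radius `0.5 d`) defaults to
`phi = 0.05` *per species*, realized as
`N = round(phi L^3 / ((4/3) pi r^3))`.

Two-component mixtures support two orders, mirroring how the physical
gels form:

* **simultaneous**: species A is randomized hot, species B is inserted at
  random overlap-free positions (rejection at `r < d`, bounded retries),
  and the joint system is quenched and drained together;
* **sequential**: species A is gelled completely first, then every A
  particle is anchored by a harmonic tether (`1.0 eps/d^2`) while B is
  inserted and quenched inside the frozen host; the tethers are removed
  for the final drain. At `T_quench = 0.05` the equipartition scale
  `sqrt(k_B T/k) ~ 0.22 d` bounds the host's excursions well below a
  particle size, which the tests assert.

The sequential route exists because a fast-forming network (PIC) is
confined by a slow-forming one (BTA) if both are quenched together, which
would distort the host morphology; the PIC-BTA preset therefore carries
`order = "sequential"`.

# Rheology

**Linear spectra.** The optimally windowed chirp drives the box under
Lees-Edwards boundaries (flow = x, gradient = z, fixed package-wide) with
an exponentially swept strain, amplitude `gamma0 = 0.01` (linear regime),
enclosed in a symmetric raised-cosine taper over 10% of each end. The
exact taper shape and sweep range are tunable parameters; correctness is
established against closed-form oracles rather than a particular window
optimality argument. Strain is applied as per-step affine increments; the
particles then relax by damped zero-temperature dynamics, so the drag
acts on non-affine motion. Stress (zx virial) and strain are Fourier
transformed and `G* = sigma~/gamma~` is read off on a log-spaced
subsample of bins, without smoothing. Spectra are reported up to the
crossover `omega_c` where G'' first crosses G' (located by log-log
interpolation); beyond it lies the inertial resonance of the particles,
which experiments do not access. The rheometer reproduces the closed-form
response of a single bead tethered to a fixed anchor (spring k with
dashpot zeta in the stress path: G'' = zeta omega z0^2/V at low
frequency, G' -> k z0^2/V at high frequency, exact finite-inertia form in
between) to better than 5% over two decades.

A caveat discovered while validating at small sizes: a floppy
`phi = 0.05` network has a plateau modulus of order `1e-4 eps/d^3` but an
effective viscosity of order `1e-2 eps tau/d^3`, so its crossover sits at
`omega_c ~ 1e-3/tau` — far below what a short chirp can reach. The
package therefore also provides `plateau_modulus()`, which measures the
zero-frequency plateau directly as the symmetric stress response to
`+/-gamma` strain steps relaxed to the inherent-structure criterion. On a
denser network whose crossover falls inside the chirp band the two
estimates agree (tests demand 20%), which justifies using
`plateau_modulus()` for size-reduced comparisons.

**Nonlinear response.** `startup_shear()` alternates strain steps
`delta_gamma = 0.01` with damped relaxations of `delta_t` (default
`1e3 tau`, the published choice satisfying
`delta_gamma/delta_t < gamma0 omega_c` for all parameterized systems) and
differentiates the post-relaxation stresses centrally:
`K(sigma_n) = (sigma_{n+1} - sigma_{n-1})/(2 delta_gamma)`. `K` at low
stress matches the plateau modulus, and is insensitive to doubling
`delta_t` once the relaxation is complete.

# Porosity

Both estimators start from the same clearance field on an `N_g^3` grid
(origin at the box corner, nodes at `(L/N_g)(i,j,k)`, periodic
distances): each node carries the radius of the largest sphere centred
there that avoids all particles (radius `r_colloid = 0.5 d`), zero inside
a particle.

* `pore_size_probe()` (probe-weighted): uniform random probes are
  assigned the largest clearance sphere containing them; probes
  overlapping a particle or covered by no sphere are rejected and
  resampled until `N_r` (default `5e4`) are accepted, with rejection
  counts reported. Each pore is thereby weighted by the volume assigned
  to it. The survival curve `P(r > R)` is accumulated on a fine radius
  grid and the mean pore size is its area (trapezoidal rule), which
  equals the direct mean of per-probe radii.
* `pore_size_census()` (grid census): grid nodes replace random probes,
  each identified pore — identified by the node carrying its maximal
  sphere, distinct maximal nodes counting as distinct pores — is counted
  once, pores at or below the niche cutoff `r_c = 0.25 d` are discarded,
  and the average is unweighted. This weights large and small pores
  equally, closer to how imaging experiments report pore sizes, and on
  mixed-pore systems it sits below the probe-weighted mean.

Defaults `N_g = 25`, `N_r = 5e4` follow the published analysis; `N_g >=
15` already gives consistent means (tests demand 10%). Species filtering
(`species =`) analyses one network of a mixture, e.g. the host pores of a
two-component gel, and equals running on the stripped configuration. The
fast local-optimization refinement described in the porosity literature
is deliberately not implemented; the exhaustive grid forms are.

# Numerical choices and degenerate inputs

* Minimum image uses the standard Lees-Edwards convention (wrap gradient,
  shift flow, wrap flow/vorticity); it equals the strict sheared-image
  minimum within `L/2`, and configurations must satisfy `r_cut <= L/2`.
* Neighbour search is a Verlet list with a `0.3 d` skin rebuilt from an
  `O(N^2)` sweep when accumulated displacement (including strain motion)
  exceeds half the skin; at the `N <= O(10^3)` sizes this package targets
  the simple sweep costs the same as cell lists and is easier to audit.
  Trajectories are independent of the rebuild frequency to tight
  tolerance (tested).
* The pair cutoff is applied as printed (a sharp Heaviside step); the
  ~`3e-6 A eps` energy discontinuity at `r_cut` is part of the model.
* Equal clearance maxima in the census tie-break to the lowest node
  index; the probe method needs no tie-break since only the radius value
  enters.
* Empty boxes, unknown species labels, non-positive separations, boxes
  smaller than `2 r_cut`, insertion failures, non-converging drains, and
  survival curves that are not non-increasing all raise errors rather
  than returning silently wrong numbers.
* All stochastic stages (velocity draws, insertions, probe placement)
  consume named substreams derived from a single scenario seed, so each
  stage is independently reproducible and identical seeds give
  bit-identical trajectories.

# What the tests do and do not show

The synthetic fixtures (lattices, straight fibers, corner-cube and
two-cavity phantoms, random clusters) exercise every operator against
independent oracles: brute-force resummation, finite differences,
closed-form spectra, exhaustive fine-grid porosity references, and
equipartition. The size-reduced studies (~100-350 particles, stage
durations of tens to hundreds of tau) reproduce the *direction and
rough magnitude* of the published observations — percolating single-species
networks, a strongly enhanced two-component plateau (the mixture/PIC
plateau ratio lands in the tens at these sizes), colocalization and
host-pore opening under cross-attraction, sequential-vs-simultaneous
structural differences. They do not reproduce cluster-scale quantities
that need large boxes and long anneals: the precise ~30x plateau ratio
and the smallest crossover `omega_c ~ 1/(134 tau)` belong to full-scale
runs, and finite-size effects (a box only ~6 pore diameters wide, seeds
mattering at the factor-2 level for floppy moduli) are visible in the
reduced numbers. Real gels additionally contain polydispersity,
hydrodynamics and solvent-mediated interactions that the model abstracts
away.

# A worked example

```{r, eval = FALSE}
library(gelsim)
prot <- prep_protocol(t_hot = 40, t_quench = 100, stop_T = 1e-8, seed = 1)
gel <- prepare_single_gel("PIC", prot, L = 12)
mix <- prepare_mixture("PIC", "UPy", protocol = prot, L = 12)
G_pic <- plateau_modulus(gel, preset_interaction_table("PIC"))
G_mix <- plateau_modulus(mix, preset_interaction_table(c("PIC", "UPy")))
G_mix / G_pic   # enhancement of the two-component network

pores <- pore_size_probe(mix, species = "PIC", seed = 1)
mean_pore_size(pores)
```
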