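---
title: "Multipolar coarse-graining of rigid molecules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multipolar coarse-graining of rigid molecules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgrb)
```

# The model

`cgrb` treats a molecule as a *rigid blob*: a fixed set of interaction
sites ("united atoms") at body-frame positions $\rho_\alpha$ about the
center of mass. Two blobs $A$ and $B$ with center separation
$\mathbf{R} = \mathbf{R}_A - \mathbf{R}_B$ interact through a sum of
identical site–site pair potentials,

$$E(\mathbf R,\Omega) \approx V(\mathbf R,\Omega)
  = \sum_{\alpha=1}^{N_A}\sum_{\beta=1}^{N_B} U(r_{\alpha\beta}),
  \qquad r_{\alpha\beta} = |\mathbf R + \rho_{\alpha\beta}|,\;
  \rho_{\alpha\beta} = \rho_\alpha - \rho_\beta .$$

Expanding each $U(r_{\alpha\beta})$ about $R = |\mathbf R|$ (valid for
$R > \rho_{\alpha\beta}$) and truncating at fourth order turns the double
sum into a short series of radial coefficients times orientation-dependent
angular parts,

$$V(R,\Omega) = \sum_{(m,n)} V^{(mn)}(R)\,\Theta^{(mn)}(\Omega),
\qquad
V^{(mn)} = \frac{1}{n!\,(m-n)!!}\,
           R^{n}\Big(\frac{1}{R}\frac{d}{dR}\Big)^{(m+n)/2} U(R),$$

$$\Theta^{(mn)} = \sum_{\alpha\beta}
   (\hat{\mathbf R}\cdot\rho_{\alpha\beta})^{\,n}\,
   \rho_{\alpha\beta}^{\,m-n},$$

with $(m,n)$ restricted so that $m+n$ and $m-n$ are both even
($n = m, m-2, \dots, 0$ or $1$): nine terms through $m \le 4$. The point
of the method is that every $\Theta^{(mn)}$ is expressible **without atom
loops** through a handful of *interaction moment tensors* of each blob,

$$\Gamma^{(m)} = \sum_\alpha \underbrace{\rho_\alpha\otimes\cdots\otimes
\rho_\alpha}_{m}, \qquad m = 0,\dots,4,$$

plus their trace contractions
$\mathrm{Tr}^{(2)}\Gamma^{(2)} = \sum\rho^2$,
$\mathrm{Tr}^{(2)}\Gamma^{(3)} = \sum\rho^2\rho$,
$\mathrm{Tr}^{(2)}\Gamma^{(4)} = \sum\rho^2\rho\rho$ and
$\mathrm{Tr}^{(4)}\Gamma^{(4)} = \sum\rho^4$. `angular_part_tensor()`
implements the nine $(m,n)$ cases as explicitly expanded scalar
invariants, obtained by binomial expansion of
$(\hat R\cdot\rho_\alpha - \hat R\cdot\rho_\beta)^n
 (\rho_\alpha^2 - 2\rho_\alpha\!\cdot\!\rho_\beta + \rho_\beta^2)^{(m-n)/2}$.
The general compact formula for these contractions is hard to transcribe
reliably, so the package takes the *definition* as ground truth:
`angular_part_direct()` performs the $O(N_A N_B)$ double sum, and a
property test demands agreement with the tensor route to $10^{-9}$
relative error on hundreds of random blob pairs. The same expansion,
differentiated analytically term by term (including the rotational
gradients of every invariant), supplies forces and torques; symmetric
finite differences of the energy are kept as an independent oracle, never
as the production path.

Symmetric tensors are stored flat: ranks $0\ldots4$ contiguously, each
rank enumerated row-major over sorted index tuples
($\binom{N+m-1}{m}$ components per rank, i.e. 1/3/6/10/15 for $N=3$,
35 slots in total). `sym_index()` maps an index tuple to its slot;
published tensor tables in this layout load directly with
`read_tensor_table()`.

## Convergence caveat for exponential potentials

For a Morse potential the $k$-th radial derivative scales as $\alpha^k U$,
so the *relative* weight of higher series terms is governed by
$\alpha\rho$ and does not shrink as the blobs separate. For C60
($\alpha = 1.3\,\text{Å}^{-1}$, cage radius 3.55 Å) $\alpha\rho \approx
4.6$, and the truncated series recovers the all-atom well only partially
at any order $\le 4$; the truncation error decreases monotonically with
order (tested) but stays a sizable fraction of the interaction. This is
why the C60 workflow below *fits* the single-site potential rather than
using the raw truncated series as an MD energy.

# The C60 system

`build_c60()` constructs the truncated icosahedron from a regular
icosahedron by dividing each directed edge at parameter $t$; pentagon
edges (C–C single bonds) have length $t\,a$ and hexagon–hexagon edges
(C=C double bonds) $(1-2t)\,a$, so the two requested bond lengths fix
$t$ and the scale exactly. With bonds 1.450/1.386 Å the circumradius
comes out 3.536 Å. Icosahedral symmetry makes the odd-rank moment
tensors vanish and $\Gamma^{(2)}$ nearly isotropic.

## Parameterizing the coarse-grained potential

The atomic carbon–carbon interaction is a Morse potential
($D_e = 0.074$ kcal/mol, $\alpha = 1.3$ Å$^{-1}$, $R_0 = 4.1$ Å). The
coarse-grained single-site model is an effective Morse with energy scale
$N_A N_B = 3600$ and $\alpha$ held at 1.3. `cg_parameterize()`:

1. scans the exact 60×60 all-atom energy for the three face-to-face
   configurations (hexagon–hexagon, hexagon–pentagon, pentagon–pentagon)
   and averages them with equal weights — the three curves coincide
   within a few percent of the well depth on the outer attractive branch,
   while their depths spread by about 10% (7.45/7.07/6.70 kcal/mol);
2. least-squares fits the scaled Morse over a window
   $[0.9, 1.6]\times R_{\min}$ around the curve minimum (unweighted;
   the window keeps the steep repulsive wall from dominating);
3. at order $>0$, includes the moment-tensor correction terms of the
   *trial* Morse in the fitted model (self-consistent fit).

Choices here that were genuinely open: the reference curve (we fit to the
discrete all-atom sum; an external reference curve can be supplied as a
two-column file instead), equal-weight orientation averaging, and the
window. Our zeroth-order fit lands at $R_0 = 9.89$ Å with
$3600\,D_e = 7.0$ kcal/mol — essentially the minimum of the reference
curve, as any least-squares Morse fit must (no window choice moves it by
more than ~0.15 Å, because the true inner wall is *softer* than the
Morse wall, pushing fits outward, not inward). Published values for this
system (9.5 Å at order 0, 9.65 Å at order 3, from an unstated fit
protocol) sit a few percent inside the all-atom minimum and could not be
reproduced by any least-squares reading we tried; the package reports
what its stated protocol computes.

## What the MD engine evaluates for the CG C60 runs

The liquid-state C60 results use the coarse-grained model in its
*parameterized single-site* form: each molecule is one site carrying the
fitted Morse (order-3 parameters $R_0 = 9.65$ Å, $D_e = 0.00177$
kcal/mol, $\alpha = 1.3$; energy $3600\,U(R)$ through the leading series
term), evaluated once per pair per step. The multipolar series is the
*parameterization* machinery. Three pieces of evidence force this
reading of the original study: its reported RDF first peaks sit exactly
at the fitted $R_0$ of each model (9.5/9.65 Å) rather than at the
minimum the tensor-corrected series would have (≈10.7 Å, 11.6 kcal/mol
deep — which would also invert the reported diffusion ordering between
the CG and all-atom models); its diffusion coefficients order as
CG-0th > CG-3rd > all-atom, exactly as the well depths
6.12 < 6.37 < 7.1 kcal/mol; and its own description of the CG model is a
single point at the center of mass evaluated once per step. The full
tensor-series engines (`cg3`, `cg4`) remain available and exact against
finite differences for blobs where the expansion converges.

# Molecular dynamics

Rigid-body NVT dynamics in a cubic periodic box with minimum-image
convention:

* **Translation** — velocity-Verlet (leapfrog-equivalent) integration.
* **Rotation** — body-frame Euler equations including the gyroscopic
  $\omega\times I\omega$ term, with the orientation quaternion advanced
  by the exact rotation $\exp(\tfrac{1}{2}\,\omega\,dt)$ and renormalized
  each step; the second half-kick solves the implicit Euler update by
  three fixed-point iterations. Quaternions solve the same equations as
  Euler angles without gimbal singularities.
* **Thermostat** — velocity rescaling at fixed intervals.
  Translational and rotational subsystems are rescaled *separately*:
  under a central CG potential the torques vanish, rotational kinetic
  energy never rethermalizes dynamically, and a single common factor
  would drag the translational temperature far off target (we measured
  2200 K translational at a nominal 1529 K before separating the
  factors). `thermostat_rescale()` at the R level implements the plain
  6-DOF rescale for a single configuration.
* **Cutoff** — center-of-mass distance cutoff, default $3\sigma^*$ with
  $\sigma^*$ the potential's equilibrium length ($R_0$ for Morse,
  $\sigma$ for LJ), clamped below half the box edge. The leading
  $(0,0)$ term is energy-shifted to zero at the cutoff; for a Morse
  potential at $3\sigma^*$ the neglected higher-order shift terms are
  $O(e^{-2\alpha\sigma^*})$ of the well and immaterial. The all-atom
  engine applies the same center-of-mass cutoff without a shift.
* **Neighbor search** — the paper-scale system (256 molecules, box
  63 Å, cutoff 29 Å) has box/cutoff ≈ 2.2, so a full $O(N^2)$
  minimum-image pair loop is used; at these sizes it is not the
  bottleneck.

Internal units are Å, ps, amu and kcal/mol
(1 kcal/mol = 418.4 amu Å²/ps²). Default timestep 5 fs for the CG
single-site liquid (vibrational period ≈ 200 fs) and 2 fs for all-atom
rigid-body runs. Energy conservation in NVE is ~$10^{-6}$ of the well
depth over $10^4$ steps at 2 fs for both engines, and drift scales as
$dt^2$.

## Initial conditions (the synthetic-data generator)

`fcc_configuration()` defines the study conditions: $N = 4k^3$ molecular
centers on an FCC lattice in a cubic box whose edge follows from the
target mass density ($V = nM/(N_{\mathrm{Av}}\rho)$; 256 molecules of
C60 at 1.219 g/cm³ give a 63.1 Å box), orientations uniform over
rotations (Shoemake quaternions), linear and angular velocities
Maxwell–Boltzmann at the target temperature with net linear momentum
zeroed. All randomness is seeded; trajectories are bit-reproducible from
(seed, config). What this generator does *not* emulate: pre-equilibrated
liquid structure (runs must melt the lattice — we discard 30 ps before
production), polydispersity, flexible intramolecular modes, and
electrostatics. Passing tests on these inputs therefore validate the
series algebra, the integrator and the estimators — not the Morse model's
fidelity to real fullerene melts.

## Observables and run lengths

* `rdf()` — center-of-mass pair histogram (default bin 0.1 Å),
  normalized by ideal-gas shell counts; `first_peak()` refines the first
  maximum by parabolic interpolation through three bins (the published
  peak positions imply sub-bin resolution).
* `vaf()` — molecule- and origin-averaged normalized velocity
  autocorrelation; velocities are stored every 2–5 steps. Default lag
  window 0.5 ps (the range in which the liquid's VAF structure lives).
* `green_kubo_D()` — $D = \tfrac{1}{3}\langle v^2\rangle\int C_v\,dt$
  by trapezoid, converted to $10^{-9}$ m²/s (×10 from Å²/ps). The
  integral requires a decayed tail ($|C_v| < 0.05$) or an explicit
  override; at the liquid state points studied here the tail decays
  slowly and the integral converges only by ≈3 ps, which is the window
  the reproduction runs use (at 0.5 ps roughly 10% of the integral is
  still missing). `msd_diffusion()` provides the Einstein-relation
  cross-check; the two agree within a few percent on converged runs.

Reproduction runs use 256 molecules, 30 ps equilibration + 100 ps
production at 5 fs — sizes chosen so the full liquid-state suite
reproduces the published peaks within ~1% while remaining desk-scale.
Seed-to-seed spread of the first-peak height is ≈0.05 and of $D$
≈0.15×10⁻⁹ m²/s at these lengths.

# Known limitations

* Ranks above 4, spatial dimensions other than 3, and multi-species
  mixtures are out of scope.
* The series engines (`cg3`/`cg4`) are exact implementations of the
  truncated expansion but, per the convergence caveat above, are poor
  energy models for exponential site potentials at C60-like
  $\alpha\rho$; they are the right tool for compact blobs or power-law
  potentials.
* No Ewald/long-range electrostatics, no barostat, no bonded
  intramolecular dynamics (blobs are rigid by construction; for C60 the
  neglected internal entropy is ≈0.2% of the free energy).
* The velocity-rescaling thermostat does not generate a rigorous
  canonical ensemble; it matches the original study's choice.
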