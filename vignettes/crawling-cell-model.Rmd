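---
title: "A mechanochemical subcellular-element model of cell crawling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanochemical subcellular-element model of cell crawling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(subcell)
```

## The model

`subcell` simulates a single cell crawling on a flat substrate as a network
of *subcellular elements*: coarse-grained particles connected by
Kelvin–Voigt bonds (spring and dashpot in parallel) augmented with a linear
actuator that shifts the free length of each bond. Because a cell is an
inertialess active body, the physics is a per-element overdamped force
balance,

$$
\zeta_i(t)\,\mathbf v_i
  + \sum_{j\in\Omega_i}\xi\,\ell_{ij}\,(\mathbf v_i-\mathbf v_j)
  = \sum_{j\in\Omega_i}\frac{\kappa}{\ell_{ij}}\,\hat{\mathbf r}_{ij}
    \bigl(r_{ij}-\ell_{ij}-\ell^{\mathrm{act}}_{ij}(t)\bigr)
  + \mathbf f^{\mathrm{area}}_i ,
$$

where $\zeta_i$ is the substrate friction coefficient of element $i$
(adhesion strength), $\xi$ the intracellular dissipation rate, $\kappa$ the
bond elastic modulus, $\ell_{ij}$ the bond rest length, and
$\ell^{\mathrm{act}}_{ij}\ge 0$ the actuator elongation modeling
protrusive cytoskeletal force. The spring constant is strain-normalized
($\kappa/\ell_{ij}$), so the actuator force on a bond is
$-\kappa\,\ell^{\mathrm{act}}_{ij}\hat{\mathbf r}_{ij}/\ell_{ij}$ and a bond
stretched by a fixed *fraction* of its rest length feels the same force at
any mesh resolution. $\mathbf f^{\mathrm{area}} = -\partial U^{\mathrm{area}}
/\partial\mathbf r$, with $U^{\mathrm{area}} = \sum_{\langle ijk\rangle}
\sigma/S_{ijk}^2$ over oriented mesh triangles, is a soft barrier that
prevents the network from collapsing; with the default $\sigma = 10^{-6}$
it is negligible except near degenerate triangles (it pre-stresses the rest
mesh by about 3% of the cell size, which the test suite equilibrates away
before asserting exact-zero invariants).

All internal forces appear in action–reaction pairs, so the model is
*force-free* and *torque-free*: $\sum_i \mathbf f^{\rm int}_i = 0$ exactly,
and net migration is impossible unless the substrate friction $\zeta_i$ is
spatially inhomogeneous. This is the central constraint the package is
built around, and the invariants are monitored at every snapshot.

Lengths are scaled by $L_0 = 10\,\mu\mathrm{m}$, times by $T_0 =
1\,\mathrm{min}$, forces by $F_0 = 10\,\mathrm{nN}$ (`model_units()`
converts). The standard cells are a 5-ring hexagonal patch ($N = 91$
elements, 240 bonds, diameter $L_{\rm cell} = 1$) and a 7-ring patch
($N = 169$, 462 bonds, $L_{\rm cell} = 1.4$); `build_circular_cell()`
provides a disc-shaped variant assembled from concentric rings stitched by
a structured annulus triangulation (chosen over a Delaunay construction
because it cannot produce crossing edges and keeps all triangle areas
positive by construction; the achieved element count is within ±10% of the
request).

## Intracellular chemistry

Protrusion is driven by an excitable two-variable reaction–diffusion system
for the membrane phosphoinositides PIP2 ($U$) and PIP3 ($V$):

$$
\partial_t U = D_U \nabla^2 U + G_U(U, V), \qquad
\partial_t V = D_V \nabla^2 V + G_V(U, V),
$$

with Gray–Scott-type kinetics in which the phosphorylation and
dephosphorylation exchange terms carry global couplings $\langle U\rangle$
and $\langle V^2\rangle$ (population mean and mean square), a constant PIP2
source $S$, and linear degradation ($\gamma U$, $\mu V$). The rest state
$(U, V) = (S/\gamma, 0) = (5, 0)$ is stable; a localized stimulus
$(\delta U, \delta V) = (-I, +I)$ with $I = 0.75$ on the activator element
launches a single wave of $V$ that traverses the cell and relaxes, while a
ten-times-smaller stimulus dies out (`rd_phase_plane()` tabulates the
nullclines and flow field).

The Laplacian on the moving particle cloud uses the meshfree MPS kernel
with weight $w(r) = r_e/r - 1$ below the cutoff $r_e = 4\ell_0$,
symmetrized particle densities $n_{ij}$, and normalization
$\lambda = r_e^2/6$. Two properties matter in practice:

* the exchange terms are exactly pairwise antisymmetric, so the kernel
  conserves a constant field to machine precision;
* on the perfect hexagonal rest lattice the kernel's lattice constant is
  5.496 for a field with continuum Laplacian 4 (verified in the tests
  against an independent neighbor-shell sum), i.e. the *effective*
  diffusion coefficient is about $1.37 D$. This is a property of the
  discretization itself at this $r_e/\ell_0$, not an implementation choice,
  and it is shared by any simulation built on the same kernel and lattice.

Neighbor lists are rebuilt every `neighbor_every` steps (default 50; the
elements move by $\sim 10^{-4}\ell_0$ per step so the list is effectively
exact), while the weights $w(r_{ij})$ are recomputed from current positions
every step. $r_e$ is pinned to the rest-mesh $\ell_0$ rather than rescaled
as the cell deforms; deformations are $O(10\%)$ and a time-constant
operator keeps the scheme simple.

## Mechanochemical coupling

Chemistry drives mechanics through two channels:

* **Actuator**: $\ell^{\rm act}_{ij} = \ell_V \tanh(a V_{ij})$ with
  $V_{ij}$ the bond-averaged PIP3, $a = \pi$, $\ell_V = \ell_{ij}$. The
  $\tanh$ saturation bounds the protrusion even for strong excitations.
* **Adhesion**: the friction coefficient relaxes with delay $\tau_\zeta$
  under $\tau_\zeta\,\dot\zeta_i = h_\zeta(\zeta_i) - A_v h_v(v_i) -
  (1-A_v) h_V(V_i)$. $h_\zeta$ is a double-wall function that pins
  $\zeta$ near $\zeta_{\rm slip}$ or $\zeta_{\rm stick}$ (transition width
  $\epsilon_\zeta = \zeta_{\rm slip}/2$); $h_v$ de-adheres elements moving
  faster than $v^* = 1$; $h_V$ de-adheres (for $\sigma_V > 0$) or adheres
  (for $\sigma_V < 0$) elements with PIP3 above $V^* = 0.5$. $A_v \in
  [0, 1]$ mixes mechanical and chemical control.

$\zeta$ is initialized at $\zeta_{\rm stick}$ — a resting cell adheres —
and this is exposed through `coupling_params(zeta_init=)`. A numerical
guard clamps $\zeta$ to $[\zeta_{\rm slip}/2,\, 2\zeta_{\rm stick}]$; the
wall functions keep it inside $[\zeta_{\rm slip}, \zeta_{\rm stick}]$ up to
the transition width, and the clamp is never active in practice.

A prescribed sinusoidal wave driver replaces the chemistry for controlled
experiments: $c_i = c_0(1 - \cos\phi_i)$ with phase
$\phi_i = \omega t + q_w (x_i - x^*)$ and a two-state friction that is
slip for $(\phi_i - \psi_\zeta) \bmod 2\pi \in (0, \pi]$ and stick
otherwise. Two conventions needed deciding:

* **Sign of the phase.** The package's default makes the crest travel from
  the rightmost (activator) element toward the left, which is the
  configuration all directional results refer to;
  `wave_driver_params(literal_sign = TRUE)` flips the propagation
  direction for comparison.
* **Wave origin $x^*$.** The phase is evaluated against the activator's
  *current* $x$ position, keeping the wave pattern attached to the cell.
  A static origin would let the accumulated migration (a third of a cell
  length per cycle) shift the effective $\psi_\zeta$ between relaxation
  and measurement cycles, corrupting the phase-shift map.

## Integration

Explicit Euler throughout, $\delta t = 10^{-5}$ for coupled
reaction–diffusion runs and $10^{-4}$ for prescribed-wave runs (the
reaction–diffusion stability bound $\delta t < \ell_0^2 / 8\max(D_U,D_V)
\approx 2.9\times10^{-3}$ and the spring relaxation rate
$\kappa/\ell_0/\zeta \sim 10^4$ both leave ample margin). The velocity
system $[\mathrm{diag}(\zeta_i) + \xi W]\,\mathbf v = \mathbf F$ (with $W$
the bond-graph Laplacian weighted by $\ell_{ij}$) is symmetric positive
definite and is solved *exactly* rather than with lagged velocities,
because the force-free identity $\sum_i \zeta_i \mathbf v_i = \sum_i
\mathbf F_i$ — and with it the vanishing traction monopole — holds only
for the exact solution. Inside the compiled time loop the solver is a
Jacobi-preconditioned conjugate gradient warm-started by linear
extrapolation from the two previous steps (relative residual $10^{-12}$,
dense-solve fallback); at snapshot times the state is re-solved with a
dense direct factorization so recorded trajectories carry the force-free
and torque-free identities at machine precision. The R-level
`solve_velocities()` is a plain dense solve.

Residual bookkeeping: at each snapshot the engine records
$\bigl\lVert\sum_i \zeta_i\mathbf v_i\bigr\rVert$ (traction monopole),
$\lvert\sum_i \mathbf r_i\times \zeta_i\mathbf v_i\rvert$ (torque about the
center of mass), and their natural scales $\sum_i\lVert\zeta_i\mathbf
v_i\rVert$ and $\sum_i\lVert\mathbf r_i\rVert\,\lVert\zeta_i\mathbf
v_i\rVert$. Relative residuals are meaningful only while the cell exerts
measurable traction; between waves the cell relaxes to numerical
equilibrium and both numerator and denominator sit at the roundoff floor,
so summary metrics take the maximum over snapshots whose traction scale
exceeds $10^{-6}$ of the run maximum. Simulations abort (returning all
snapshots so far) on non-finite state or on a triangle area below
$10^{-8}$.

## Observables

`displacement_per_cycle()` measures the signed center-of-mass
$x$-displacement over one driving period after discarding five relaxation
cycles (the stick–slip transients die out after one to two). `msd_vac()`
computes the time-averaged mean-square displacement and the
autocorrelation of the velocity *direction* on a log-spaced lag grid; the
ballistic-to-diffusive crossover is the first lag at which the centered
log–log slope of the MSD falls below 1.5 (halfway between the slopes of
the two regimes).

Traction multipoles are evaluated in the velocity-aligned comoving frame
(origin at the center of mass, first axis along $\mathbf V_{\rm cm}$
estimated by centered differences of the sampled trajectory; frames with
$\lvert\mathbf V_{\rm cm}\rvert < 10^{-6}$ are flagged undefined and reuse
the last valid orientation). Positions enter relative to the center of
mass, which makes the dipole translation-invariant. The dipole eigenvalue
$\lambda_1$ is the one whose eigenvector axis is closer to the velocity
angle modulo $\pi$ (axes, not directions, reported in
$(-\pi/2, \pi/2]$). The torque is the antisymmetric dipole part
$M^{(2)}_{12} - M^{(2)}_{21}$, a frame-rotation invariant.

## What the drivers and fixtures emulate — and what they do not

The simulation *is* the data generator: all tests run on cells built and
driven in code, under the standard parameter set (Tables of defaults in
`mech_params()`, `rd_params()`, `coupling_params()`). The model emulates
the coordination of protrusion and stick–slip adhesion by a single
excitable chemical wave. It does not emulate: cell polarity (no memory of
direction beyond the refractory tail of the previous wave, so migration
persistence is short), bond remodeling (the network is permanent),
contractile actuation ($\ell^{\rm act}\ge 0$), adhesion-molecule transport,
or three-dimensional mechanics. Passing tests therefore certify the
mechanochemical mechanism and its invariants, not quantitative agreement
with any particular real cell type.

## Problem sizes and measured behavior

The test suite and the acceptance script run at sizes chosen to exercise
the full mechanism at workstation scale: the 5-ring cell for all dynamic
runs; prescribed-wave scans over a $5\times12$ $(q_w, \psi_\zeta)$ grid at
three to four cycles per point; coupled runs of 4–6 cycles; and a 5-seed
ensemble of 15–20 time-unit random-excitation runs. With these choices the
suite reproduces, from scratch: rightward crawling at $\psi_\zeta = 5\pi/9$
and leftward at $14\pi/9$, a reciprocating phase shift between them,
retrograde-wave crawling for $\sigma_V = +2\pi$ and direct-wave crawling
for $\sigma_V = -2\pi$, and a one-cycle migration distance $\Delta
R/L_{\rm cell} \approx 0.37$ at $A_v = 0.6$, $\tau_\zeta = 0.01$ —
a maximum in $A_v$, i.e. mixed mechanochemical adhesion control beats
either pure control.

Two measured results deserve caveats. The wavenumber dependence of
$\lvert\Delta R\rvert$ has a shallow maximum: $q_w = \pi$ edges out
$q_w = 4\pi/5$ by under 2%, so "the optimal wavenumber" is only defined up
to the scan resolution. And the MSD of the randomly excited cell crosses
from ballistic to diffusive at $t \approx 0.45$–$0.48$ (robust across
seeds and run lengths), with the velocity direction decorrelating on the
same sub-unit timescale — the persistence generated by wave-origin memory
alone is weak, consistent with the absence of an explicit polarity
mechanism.

## Known limitations

* The hexagonal-lattice MPS kernel overestimates the continuum Laplacian
  by the lattice factor 1.37 (above); treat physical diffusivities
  accordingly.
* The area barrier is a soft $1/S^2$ penalty with no regularization at
  $S \to 0$; a sufficiently violent parameter choice can still collapse a
  triangle, which aborts the run rather than silently continuing.
* The circular-cell builder targets the element count only approximately,
  and its bond count depends on the ring stitching; treat circular-cell
  bond statistics as construction-specific.
* Explicit Euler is first-order: halving $\delta t$ changes the
  prescribed-wave $\Delta R$ per cycle by under $10^{-4}$ relative in our
  checks; all defaults keep at least a 20-fold margin below the relevant
  stability bounds.
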