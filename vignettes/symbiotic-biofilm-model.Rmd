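---
title: "A continuum model of a cross-feeding dual-species biofilm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A continuum model of a cross-feeding dual-species biofilm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(symbiofilm)
```

## The model

`symbiofilm` simulates the growth of a two-species oral biofilm — an
early colonizer of the *Streptococcus* type (species 1) and a
late colonizer of the *Veillonella* type (species 2) — as a continuum
free-boundary problem on a rectangular domain with bulk fluid above
the film. The species interact mutualistically through a lactic-acid
intermediate:

* both species consume a common nutrient (saliva) that diffuses in
  from the top boundary;
* species 1 grows on saliva and secretes lactic acid; the acid
  inhibits its own growth through a factor $k_l/(k_l+s_2)$;
* species 2 cannot use the saliva carbon source directly: its growth
  requires the acid ($s_2/(k_{22}+s_2)$ Monod factor) and consumes it,
  which in turn relieves the inhibition of species 1.

The state consists of two biomass volume fractions $\vartheta_1,
\vartheta_2$ (summing to one inside the biofilm), the saliva and acid
concentrations $s_1, s_2$, and a growth potential $\Phi$. The five
governing equations are

* biomass: $\partial_t \vartheta_i + \nabla\cdot(\mathbf u\,
  \vartheta_i) = g_i/\rho_i$ with no-flow boundaries, where
  $g_1 = \vartheta_1 \rho_s \mu_1 \frac{s_1}{k_{11}+s_1}
  \frac{k_l}{k_l+s_2}$ and
  $g_2 = \vartheta_2 \rho_v \mu_2 \frac{s_1}{k_{21}+s_1}
  \frac{s_2}{k_{22}+s_2}$;
* saliva (quasi-steady, transport is much faster than growth):
  $-D_1 \nabla^2 s_1 = -g_1/Y_{s1} - g_2/Y_{v1}$, fixed value
  $\bar s_1$ on the top edge, no flux elsewhere;
* acid (time-dependent; in a batch system it accumulates):
  $\partial_t s_2 + \nabla\cdot(\mathbf u s_2) - D_2\nabla^2 s_2 =
  \lambda g_1 - g_2/Y_{v2}$, no-flow everywhere, or optionally
  $s_2 = 0$ on the top edge (instant removal, a flow-cell idealization);
* growth flow: $\nabla\cdot\mathbf u = \nabla^2\Phi = g_1/\rho_s +
  g_2/\rho_v$ inside the biofilm, $\Phi = 0$ on the biofilm–fluid
  interface, no flux where the film touches the domain boundary, and
  $\mathbf u = 0$ in the fluid.

The solver works entirely in dimensionless variables: lengths scaled
by the domain height $H$, time by one day $t_d$, concentrations by
$\bar s_1$, the potential by $H^2/t_d$. The resulting groups (run
`nondimensionalize(biofilm_params())`) are, for the default parameter
set: $\Psi_1 = \mu_1 t_d = 2.592$, $\Psi_2 = 6.912$,
$\Theta_{11}^2 = 5.94$, $\Theta_{12}^2 = 15.84$,
$\Theta_{21}^2 = 142.56$, $\Theta_{22}^2 = 7603.2$, $D_2^* = 960$,
$K_{11} = K_{21} = 0.0878$, $K_{22} = 0.00878$, $K_L = 0.1$.

The competitive ablation variant (`variant = "competitive"`) removes
the acid factors from both growth laws and sets the acid sink to zero
while keeping acid production and transport, so the acid accumulates
without feeding back. Comparing the two variants isolates what the
cross-feeding contributes to the dynamics.

## Numerical scheme

The discretization is a cell-centered finite-volume scheme on a fixed
structured grid over the unit square (default $200\times200$; the
studies in this vignette and the acceptance script use $100\times100$
with $\Delta T = 1/100$ to keep runtimes at desk scale — the shipped
default configuration keeps the reference $200\times200$,
$\Delta T = 1/200$). Design choices, in the order they matter:

* **Interface representation.** The biofilm domain is the set of
  cells whose total volume fraction reaches $1/2$; the interface is
  the sub-cell $\vartheta_{\rm tot} = 1/2$ contour. The advected
  fractions already carry the interface, so no separate level-set
  equation is solved and no reinitialization is needed.
* **Saliva.** Five-point Laplacian, Dirichlet top edge imposed at the
  boundary face by a ghost value. The Monod nonlinearity is resolved
  by Picard iteration with the saturation denominators frozen per
  sweep; each sweep is then linear with a nonnegative uptake
  coefficient, so the discrete maximum principle ($0 \le S_1 \le 1$)
  holds at every iterate. Convergence is declared at a relative
  update below $10^{-8}$ (`picard_tol`).
* **Potential.** The Poisson problem is assembled on biofilm cells
  only; at a face between a biofilm and a fluid cell the interface
  condition $\chi = 0$ is imposed at the face center (embedded
  Dirichlet, first-order locally). Face-normal velocities are the
  discrete gradient of $\chi$ through each face, which makes the
  discrete divergence of the velocity equal the growth source cell by
  cell — this is what closes the mass ledger below exactly.
* **Biomass transport.** Conservative first-order upwind fluxes with
  explicit growth sources. Within each time step the
  saliva/potential/advection/mask sequence is subcycled so every
  sub-step satisfies a CFL bound of $1/2$; refreshing the velocity
  field and the mask inside the step matters, because a cell just
  ahead of the front has no outflow faces until it joins the biofilm,
  and without the refresh it overfills. After each sub-step the
  fractions are clipped to $[0,1]$ and, inside the biofilm, rescaled
  to sum at most one; the applied correction is logged in the step
  balance (it sits at rounding level, $\sim10^{-14}$, in the baseline
  runs) and a correction above $10^{-3}$ in a cell away from the
  interface band aborts the run as an advection overshoot.
* **Acid.** Backward-Euler diffusion (the acid diffusion number
  $D_2^* = 960$ rules out an explicit treatment), explicit upwind
  advection, explicit production. The consumption sink is linearized
  in the new concentration with frozen saturation denominator: the
  linearized sink coefficient reaches $\sim 2\times10^{5}$/day, so an
  explicit sink would be unstable (and negative) at any practical
  step; the semi-implicit form keeps the system an M-matrix and the
  concentration nonnegative unconditionally.
* **Linear algebra.** All systems are solved by direct sparse
  Cholesky factorizations (deterministic at these sizes); the
  symbolic factorization is cached per sparsity pattern.
* **Splitting order.** Saliva before potential (the growth sources
  need $S_1$), acid last (it feeds back only at the next step). The
  splitting is first order: a Richardson probe on the total biomass
  shows differences shrinking by a factor of two per halving of
  $\Delta T$.

When the film reaches the top of the domain the fluid layer — and
with it the free boundary the model is built on — ceases to exist;
`run_simulation()` then ends the run cleanly and flags the trajectory
(`$terminated`) rather than erroring, so partial results remain
usable.

## The default parameter set, and what it implies

The defaults of `biofilm_params()` describe a 300 µm square domain
fed with saliva at 10 kg/m³, maximum growth rates $\mu_1 = 3\times
10^{-5}$/s and $\mu_2 = 8\times10^{-5}$/s, equal biomass densities
1100 kg/m³, yields of 0.1, acid production coefficient $\lambda =
0.5$, and Monod constants $k_{11} = k_{21} = 0.878$, $k_{22} =
0.0878$, $k_l = 1$ kg/m³. Several of these are order-of-magnitude
estimates; all are configurable.

Two closed-form consequences of this parameter set are worth stating,
because they determine everything the simulations below show:

1. **The acid is pinned near zero while species 2 is present.** The
   consumption capacity $\Theta_{22}^2\vartheta_2$ exceeds the
   production $\Theta_{21}^2\vartheta_1$ by a factor of
   $\sim 53\,\vartheta_2/\vartheta_1$, so the acid settles at the
   quasi-equilibrium where consumption equals production,
   $S_2^* \approx K_{22}\,\Theta_{21}^2\vartheta_1 /
   (\Theta_{22}^2\vartheta_2) \sim 2\times10^{-4}$ — three orders of
   magnitude below the inhibition scale $K_L = 0.1$. Species 2 is
   strictly rationed by the acid supply: its mass gain is
   $Y_{v2}\lambda = 0.05$ of the species-1 gain, and at
   quasi-equilibrium the net acid release to the fluid is exactly
   zero. Two consequences follow: the acid boundary condition can
   barely influence growth (the measured thickness reduction in the
   comparison below is $\approx 0$), and the local composition drifts
   everywhere toward the same species-1-dominated attractor, so no
   depth stratification develops.
2. **Growth is near-exponential at $\approx 2.4$/day.** With
   $\bar s_1 \gg k_{11}$ the saliva Monod factor stays near 0.92 and
   inhibition never engages, so the film thickens
   near-exponentially and reaches the top of the unit domain at
   $T \approx 1.7$ from $h_0 = 0.1$; runs started from the thicker
   slab and patch scenarios likewise terminate before their nominal
   end times. Runs requested beyond that point end early as described
   above.

These are properties of the stated parameter values, not of the
discretization: both follow from arithmetic on the dimensionless
groups and are reproduced by an independent ODE integration of the
well-mixed (0-D) reaction network in the test suite. Published
descriptions of this system show a slower-growing, stratifying film
with appreciable acid levels, which would require a substantially
weaker acid sink than these constants give; we implement the
equations and constants as stated and report what they yield, and the
package exposes every constant so other regimes can be explored (for
instance, lowering `Y_v2` or `mu2` strengthens acid accumulation and
with it the inhibition feedback).

## What the generators emulate

* `init_mixed()` — the reference scenario: a 50/50 mixture under the
  sinusoidal interface $Z = 0.1 + 0.05\sin(4\pi X + \pi/2)$, no acid,
  saliva at its boundary value. With `amplitude = 0` it is the flat
  reference of the homogenization study.
* `init_random_field()` — a flat slab ($Z < 0.2$) whose composition
  is a stationary Gaussian random field with squared-exponential
  covariance $\exp(-r^2/\ell^2)$, synthesized spectrally on a
  periodic grid, mapped into $[0,1]$ by the normal-CDF transform and
  affinely rescaled to a spatial mean of exactly $1/2$. The exact
  mean makes the initial mass of each species identical across
  correlation lengths ($\ell \in \{2,4,8\}\Delta x$ with $\Delta x =
  1/200$ in the study), which the homogenization comparison requires.
  The rank-preserving transform distorts the correlation structure
  somewhat; the realized e-folding length stays within a factor of
  two of $\ell$ (checked against a sample-autocorrelation oracle).
* `init_patches()` — four pure species-2 clusters, numbered left to
  right, carved by rotated superquadrics $|\xi/a|^p + |\zeta/b|^p
  \le 1$ inside a pure species-1 film. The exact shapes in published
  imagery are not recoverable; the default set is a documented
  synthetic stand-in (semi-axes 0.04–0.08, exponents 2–4, fixed
  angles), and `patches = "random"` draws new geometries from the
  documented ranges. The non-flat interface variant uses
  $Z = 0.25 + 0.05\sin(2\pi X + \pi/2)$, which clears every default
  patch.

What the generators do *not* emulate: single-cell attachment
("corn-cob" architecture), EPS, pH chemistry beyond the acid proxy,
and colony merging — the model's free-boundary construction assumes a
simply connected film, which is why runs stop when the film meets the
top boundary.

## A short worked run

A coarse, fast version of the baseline scenario:

```{r demo}
grid <- build_grid(50)
traj <- run_simulation(init_mixed(grid), grid = grid,
                       settings = solver_settings(dT = 1/50, T_end = 0.5),
                       cadence = 0.25)
summary(traj)
```

```{r demo-plot}
plot(traj, "mass")
```

The per-step series carries the diagnostics used by the tests: the
advective CFL number, the Picard sweep count, and the logged
clip/rescale magnitude:

```{r demo-tail}
tail(traj$series, 3)
```

## Verification

The test suite checks, among others:

* all dimensionless groups against hand arithmetic to $10^{-12}$,
  and dimensional vs dimensionless kinetics to $10^{-12}$;
* the acid half-suppression identity $g_1(s_2 = k_l) =
  \tfrac12 g_1(s_2 = 0)$;
* the quasi-steady saliva solver against the cosh profile
  (linear-uptake regime) and the parabolic deficit (zeroth-order
  regime) on a 200-cell column, both within 1%;
* the potential solver against the 1D column closed form
  $\chi = G(Z^2-h^2)/2$, $u = GZ$, within 1%;
* passive advection against exact translation (centroid within one
  cell after 20 steps);
* per-step discrete mass ledgers for both species and the acid
  (closed to $10^{-6}$, with the logged correction accounted);
* maximum principles ($S_1 \in [0,1]$, $S_2 \ge 0$, $\vartheta_i \in
  [0,1]$) along full runs;
* mirror symmetry about $X = 1/2$ preserved to $10^{-8}$ over the
  whole baseline run;
* the well-mixed reaction network against an independent `deSolve`
  integration.

The desk-scale studies (the acceptance checks) run the paired
boundary-condition comparison, the homogenization study (one mixed
reference plus three correlation lengths times five seeds) and the
symbiotic/competitive ablation at $100\times100$, $\Delta T = 1/100$.
Under the default constants the film reaches the top of the domain
before the nominal end times of these studies (see the closed-form
consequences above), so the checks pinned to late times report
against the terminated trajectories; the early-time checks (the
homogenization ordering at $T = 0.25$, the competitive dominance of
the faster grower) are unaffected. Passing tests demonstrate internal
consistency of the solver at desk scale; they do not by themselves
validate the biological parameter estimates, and real biofilms
violate several model assumptions (no EPS phase, no detachment, no
fluid flow above the film).

## Known limitations

* First-order accuracy in time and space; front positions carry
  $O(\Delta x)$ error and the splitting error is $O(\Delta T)$.
* The embedded interface condition for the potential is imposed at
  face centers, not at the sub-cell contour, which is consistent but
  locally first-order.
* The model cannot continue past complete occupation of the domain,
  and cannot represent merging colonies or detachment.
* The acid quasi-equilibrium makes the default regime numerically
  easy but biologically extreme (see above); regimes with strong acid
  accumulation exercise the inhibition pathway more heavily and may
  need smaller `dT` for accuracy (stability is unconditional).
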