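---
title: "An energy-derived model of collectively aligning elliptical cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An energy-derived model of collectively aligning elliptical cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(cellalign)
```

## The model

`cellalign` simulates populations of actively crawling cells — fibroblasts
are the motivating example — as constant-area ellipses in a periodic square
box. Each cell $i$ carries a centroid $X_i \in [0, L)^2$, an orientation
$\alpha_i \in [0, 2\pi)$ and an aspect ratio $r_i = a_i/b_i \ge 1$. Working
in units of the reference length $\sqrt{A/\pi}$ (so each cell has area
$\pi$ and $a_i b_i = 1$) and of the overlap-relaxation time, the
overdamped, friction-dominated dynamics are a gradient flow of a total
energy with three kinds of contributions:

* **Self-propulsion.** Each cell moves with constant non-dimensional speed
  $\nu$ along its orientation vector $e(\alpha) = (\cos\alpha, \sin\alpha)$.
  $\nu$ compares the propulsion speed with the strength of overlap
  avoidance: it is the single control parameter of the base model.
* **Overlap avoidance.** Crawling cells tend not to move on top of each
  other. The model penalises the *area* of pairwise overlap with a flat
  potential, which makes all overlap forces expressible through the 2 or 4
  boundary intersection points $Y^{ij}_k$ of each overlapping ellipse pair
  — ordered anticlockwise around cell $i$ and paired so that the arc from
  $Y_{2k-1}$ to $Y_{2k}$ lies inside cell $j$:
  $$\dot X_i = -\sum_{j}\sum_{k} (Y^{ij}_{2k-1} - Y^{ij}_{2k})^\perp
    + \nu e(\alpha_i), \qquad
  \dot\alpha_i = \frac{2r}{r^2+1}\sum_{j}\sum_{k}
    \left(|X_i - Y^{ij}_{2k}|^2 - |X_i - Y^{ij}_{2k-1}|^2\right),$$
  with $\perp$ the left turn $(x,y) \mapsto (-y,x)$. The force pushes the
  cell along the normal of the chord connecting the intersection points;
  the torque turns it from the shorter towards the longer of the two
  centre-to-intersection segments. Both are exact negative gradients of
  the overlap area, which the test suite verifies against central finite
  differences of an independent polygon-clipping area routine. (In these
  units the translation term equals $-\nabla_{X}|A\cap B|$ and the torque
  $-\tfrac{4r}{r^2+1}\,\partial_\alpha |A\cap B|$; the mobility prefactors
  follow from the elliptic geometry of the friction integral.)
* **Shape relaxation** (optional, strength $\gamma$). The aspect ratio
  becomes dynamic at fixed area,
  $$\dot r_i = \frac{4r^2}{r^2+1}\sum_{j,k}
    \left[\sin 2\theta^{ij}_{2k-1} - \sin 2\theta^{ij}_{2k}\right]
    + 16\gamma\,\frac{1 + \bar r r^3}{1 + r^2}\Bigl(1 - \frac{r}{\bar r}\Bigr),$$
  where $\theta^{ij}_k$ are the boundary coordinates of the contact points
  on cell $i$. Flank contacts shorten the cell, tip contacts lengthen it,
  and the second term relaxes $r$ towards the preferred ratio
  $\bar r = 2$.
* **Cell-cell junctions and supracellular actin** (optional; strengths
  $\kappa$, $\mu$, range $\lambda$). Junctions are deterministic
  zero-rest-length springs between front/back endpoints
  $X^\pm = X \pm a\,e(\alpha)$: one is active for every endpoint pair
  closer than $\lambda$, and breaks as soon as it stretches beyond
  $\lambda$ (the active set is stateless). Front-back pairs carry a
  polar-aligning actin torque $-\mu\frac{r}{r^2+1}\sin(\alpha_i-\alpha_j)$
  and like-ended pairs the anti-polar $+\sin$ counterpart — the negative
  gradient of the bending energy $\tfrac{m}{4a}|e(\alpha_i) \mp
  e(\alpha_j)|^2$ of a three-point discretised inextensible rod spanning
  the junction. Junction pulls also rotate the cells through the lever
  term $\tfrac{4\kappa r^{3/2}}{r^2+1}\,(X^\mp_j - X^\pm_i)\cdot
  (\pm e^\perp(\alpha_i))$.

Because the junction module assumes a fixed aspect ratio, combining it
with shape dynamics is refused unless an explicit experimental flag is
set.

## Parameters

| field | meaning | default |
|---|---|---|
| `nu` | self-propulsion vs overlap avoidance | 0.5 |
| `gamma` | shape-restoring strength (0 = rigid) | 0 |
| `rbar` | preferred aspect ratio | 2 |
| `kappa` | junction spring strength | 0 |
| `mu` | actin bending strength | 0 |
| `lam` | junction range (non-dim length) | 0 |
| `n_cells`, `box_l` | population size, periodic box side | 125, 20 |
| `dt`, `t_end`, `save_every` | Euler step, horizon, frame stride | 0.01, 400, 100 |
| `seed` | reproducibility seed | 1 |

All lengths are in cell-radius units ($\sqrt{A/\pi}$): a cell of aspect
ratio 2 is $2\sqrt 2 \approx 2.8$ long, so `lam = 0.2` is about 7% of a
cell length (`junction_range_pct()`). The default `n_cells`/`box_l` pair
gives an area density $N\pi/L^2 \approx 0.98$: a confluent layer.

## What the generator emulates — and what it does not

Initial conditions place cells uniformly at random with uniform random
orientations (`init_population()`), the isotropic state from which all
reference experiments start. The model deliberately omits: cell division,
orientational noise (available as an extension flag `noise_sd`, off by
default), biochemical signalling, substrate interactions, and any shape
freedom beyond the aspect ratio. Conclusions from passing tests therefore
concern the mechanistic interplay of propulsion, overlap avoidance,
deformability and junction mechanics — not the full variability of real
fibroblast cultures, whose shapes, protrusions and adhesion kinetics are
far richer.

## Numerical choices

* **Ellipse-ellipse intersection.** In cell $i$'s frame the partner's
  implicit quadratic restricted to the boundary of $i$ is a trigonometric
  quadratic; the tangent half-angle substitution turns it into a quartic,
  solved in closed form (Ferrari with a resolvent cubic) and polished with
  Newton steps on the boundary residual to $10^{-13}$ of the coefficient
  scale; a 16-point sign-scan safety net catches roots lost to
  cancellation. Roots closer than $10^{-8}$ in the boundary coordinate are
  merged; configurations reduced to a single (tangential) point count as
  no overlap, so point counts are always 0, 2 or 4.
* **Degeneracies.** Exactly coincident ellipses raise an error from the
  geometry layer; the engine resolves them by a seeded $10^{-6}$ jitter
  and logs the event. Containment (one boundary strictly inside the
  other) produces zero contact points and hence zero force from the
  formulas; the engine instead pushes the contained cell out along the
  centre difference at speed equal to the container's semi-minor axis and
  logs the event. At unit area ratios containment cannot occur
  geometrically, so this fallback only guards numerical corner cases.
* **Overlap-area oracle.** `overlap_area()` rasterises nothing and trusts
  no intersection points: it clips two 4096-gon approximations of the
  boundaries (Sutherland–Hodgman) and is accurate to better than
  $10^{-6}$ relative. It exists to verify the forces, not to drive them.
* **Integration.** Explicit Euler with `dt = 0.01`, all derivatives
  evaluated at the pre-step state. Positions wrap into $[0,L)$,
  orientations into $[0,2\pi)$; with shape dynamics on, $r$ is clamped to
  $[1, 16]$ (values below 1 would swap the axes' roles mid-step; the
  upper clamp is a numerical guard that reference runs never hit — clamp
  events are counted and reported).
* **Neighbour search.** Bounding-circle broad phase over all pairs
  ($a_i + a_j$ radius test); at the reference sizes ($N \le 125$) this is
  already cheap, and a property test checks it is a superset of the true
  overlap set.
* **Periodicity.** All pair geometry uses the minimum-image convention,
  components mapped into $(-L/2, L/2]$.

## Observables

The global **nematic alignment** is the modulus of the mean double-angle
phasor $S = |\langle e^{2i\alpha}\rangle|$ — the standard 2D nematic order
parameter, chosen here as the package's alignment definition; every
downstream use (trend tests, argmax locations) is robust to any standard
nematic definition. **Packing fraction** is the raster-estimated area of
the union of all cells over $L^2$: at fixed $N$ and $L$ it increases
exactly when mutual overlap decreases. **Contact statistics** sample a
trajectory window (default $t \in [0, 10]$ at interval 0.1) and count
distinct interaction partners and maximal-run interaction durations.
The **alignment length scale** fits $C(d) = e^{-d/\ell}$ to the binned
nematic pair correlation (bin width 0.5, capped at $L$) — an exponential
correlation length, again a standard choice made here as a design
decision. The **junction graph** treats cells as nodes and junctioned
pairs as simple edges; the fraction of degree-2 cells tracks the linear
chains associated with long-ranged alignment, and
`degree_alignment_correlation()` quantifies this across an ensemble.

Equilibrated observables average the final 10% of recorded frames of a
fixed-horizon run; no adaptive stationarity detection is attempted.

## Problem sizes

The package ships two scales. The `"paper"` presets use $N = 125$,
$L = 20$ and horizons $T = 400$–800 with ensembles of tens of replicates.
The `"reduced"` scale — used throughout the test suite and the
acceptance script as this package's reference experiment size — keeps the
same area density with $N = 50$, $L = 12.6$, $T = 200$ and 10 replicates
per condition, which preserves the non-dimensional physics while keeping
a full parameter sweep in the minutes range on one core. Replicates share
seeds across grid values, so sweep comparisons are paired.

## A short example

```{r example, eval = FALSE}
p <- preset_params("junction", scale = "reduced", seed = 1)
traj <- simulate_cells(p)
glance(traj)
autoplot(traj)

sw <- run_sweep(sweep_spec("kappa", c(0, 0.5, 1, 1.5, 2, 2.5),
                           reps = 10, base = p))
tidy(sw)
autoplot(sw)
```

## Known limitations

* Explicit Euler is first-order; `dt` is configurable for convergence
  checks but no higher-order integrator is provided.
* The overlap force saturates for deeply interpenetrating pairs (the
  chord between intersection points shrinks again), a property of the
  flat overlap potential itself; at the reference densities and
  $\sigma$-dominated regimes such states are not visited.
* Ensemble findings at the reduced scale are subject to finite-size
  effects — in a 12.6-wide box an aligned chain of five cells already
  spans the torus — and optimum *locations* over coarse parameter grids
  are correspondingly less sharp than value trends; see the acceptance
  notes in the README.
* Junction formation is deterministic and instantaneous; stochastic
  formation/breakage kinetics, side junctions and intracellular bundle
  mechanics are out of scope.
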