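---
title: "A hybrid model of arterial-patch-induced angiogenesis"
author: "angiopatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid model of arterial-patch-induced angiogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiopatch)
```

## The biological setting

Suturing a small arterial graft (a "patch") into the wall of a vein induces
vigorous angiogenesis: new vessels sprout from a pre-existing artery a few
millimetres away and grow toward the patch, eventually forming an
arteriovenous fistula. Two observations make this system unusual for a
chemotaxis model. First, the measured VEGFA concentration is *lowest* at the
patch and highest near the pre-existing artery, so the sprouts migrate *down*
the VEGFA gradient — classical gradient chemotaxis cannot explain the
direction of growth. Second, VEGFA at the sprouting site oscillates while
attenuating, approximately as a damped sinusoid, and the vessels' growth
speed oscillates with it: fast early, nearly stalled over days 2–6, regrowing
after day 7, and reaching the patch periphery around day 10.

`angiopatch` implements the hybrid continuum–discrete model built on these
observations: sprout tips are biased random walkers whose drift responds to
the spatial gradient of the *temporal change* of VEGFA rather than to the
VEGFA gradient itself.

## The VEGFA field

The concentration is prescribed in closed form on the unit square, with the
patch a disk of radius $R = 0.1$ centred at $(0, 1/2)$ on the left boundary:

$$
c(\mathbf{x}, t) =
\begin{cases}
a\,\bigl\{b + \sin(2\pi\sigma t)\,e^{-\gamma t}\bigr\}
\Bigl\{1 - \dfrac{(r_0 - r_p)^2}{\epsilon^2}\Bigr\}, & r_p > R,\\[4pt]
0, & r_p \le R,
\end{cases}
$$

where $r_p$ is the distance to the patch centre. The kinetic factor is the
damped sinusoid fitted to the ELISA series; the quadratic spatial factor
makes $c$ increase with distance from the patch, encoding "high near the
pre-existing artery, low at the patch". One dimensionless time unit is one
day.

The printed formula contains the literal constant 3; the package exposes it
as the parameter `r0` because its role only becomes visible together with
$\epsilon$: with the defaults $\epsilon = 2.9 = r_0 - R$ the spatial factor
vanishes *exactly* on the patch boundary, so the two branches of the formula
join continuously. `vegf_params()` keeps that coupling explicit and the test
suite asserts the continuity.

Simulation defaults (dimensionless): $a = 1$, $b = 0.39$,
$\sigma = 0.23/2$ per day, $\gamma = 0.15$ per day, $\epsilon = 2.9$,
$r_0 = 3$. With these, the kinetic factor stays strictly positive over the
14-day window, so $c \ge 0$ everywhere.

Because $\partial c/\partial t$ factorizes into a time factor times the
(nonnegative) spatial factor, its sign is spatially uniform: time splits
into *growth periods* ($\partial c/\partial t > 0$) and *rest periods*
($\partial c/\partial t \le 0$) at the roots of
$\tan(2\pi\sigma t) = 2\pi\sigma/\gamma$. `period_boundaries()` returns them
in closed form; with the defaults the first three are near days 1.89, 6.24
and 10.59, so the window [0, 14] is growth–rest–growth–rest. This is the
clock that makes the growth curves oscillate.

## Chemotactic velocity from temporal VEGFA change

The chemotactic potential is
$$
f = \begin{cases}-\beta\, c_t, & c_t > 0,\\ 0, & c_t \le 0,\end{cases}
\qquad \mathbf{v}_m = \nabla f ,
$$
with $\beta = 1$ by default. During growth periods $c_t$ is *smaller* near
the patch, so $f$ is less negative there and $\nabla f$ points patch-ward:
rising VEGFA far from the patch pushes tips toward the patch. During rest
periods $f \equiv 0$ and migration is pure random motility.

Two numerical points. $c_t$ is evaluated analytically (the field is closed
form), never by differencing $c$ in time. And the printed lattice formula
for $\mathbf{v}_m$ carries a factor $-\beta/2$ in front of averaged
difference quotients of $f$, while $f$ itself already contains $-\beta$;
applying both would square $\beta$ and flip the drift away from the patch,
contradicting every reported simulation picture. The package therefore lets
$\beta$ enter exactly once, inside $f$, and uses the plain averaged
difference quotient as the gradient operator, so that
$\mathbf{v}_m = \nabla f$ is the governing definition. With the published
$\beta = 1$ the magnitude is identical under either reading; for
$\beta \ne 1$ users should be aware the package follows the
$\mathbf{v}_m = \nabla f$ convention.

## The dual-lattice upwind scheme

The sprout-tip density $n$ obeys
$n_t = -\nabla\cdot(-d\,\nabla n + n \mathbf{v}_m)$ with zero-flux walls,
$d = 1.728\times 10^{-4}$. It is discretized on a dual lattice
(`dual_lattice()`): cell centres $((i-\tfrac12)h, (j-\tfrac12)h)$ carry $n$
and $\mathbf{v}_m$; cell corners $(ih, jh)$ carry $f$ and the fluxes,
$h = 1/N$. The advective flux is assembled upwind
(`upwind_split()`, `advective_flux()`), diffusion is the standard difference
quotient, and every boundary face carries exactly zero flux
(`total_flux()`).

Rewriting the update as a five-point stencil gives, per site, nonnegative
weights summing to one — stay, left, right, down, up
(`transition_probabilities()`):
$$
P^{stay} = 1 - \frac{4 d \tau}{h^2} - \frac{\tau}{h}\sum v^{\pm},
\qquad
P^{move} = \frac{d\tau}{h^2} + \frac{\tau}{h}v^{(\mathrm{dir})},
$$
valid whenever the adaptive step obeys
$\tau \le h^2 / \{4 (d + h \hat v)\}$ with $\hat v$ the largest split
component (`stable_timestep()`). The same weights drive both the continuum
solver (`density_step()`) — which conserves mass and positivity exactly —
and the discrete tips. The flux form (`density_step_flux()`) and the
probability form are maintained as two independent code paths and the test
suite checks they agree to $10^{-12}$ on random instances, which pins down
every index convention in the stencil.

Numerical choices made here, where the formulation left them open:

* **Grid size.** $N$ is not stated in the source material; the default is
  $N = 100$ ($h = 0.01$), making the patch radius ten cells. $N$ is
  configurable and results do depend on the grid step (the arrival
  tolerance below scales with $h$).
* **Safety factor.** $\tau$ is 0.9 of the stability bound, keeping the stay
  probability strictly positive everywhere rather than allowing it to hit
  zero at the bound.
* **Boundary closure.** At wall-adjacent sites the wall-facing move weight
  (diffusive and advective parts alike) is folded into the stay weight —
  the exact probabilistic counterpart of the zero-flux condition, and the
  choice that keeps the tuples normalized at edges.

## The discrete tip layer

Twenty tips start on the right boundary column $i = N$ (the pre-existing
vessel), at rows drawn uniformly *without replacement* — shared starting
sites would trigger anastomosis at birth, which is surely not intended.
Each adaptive step, every active tip samples stay/left/right/down/up from
the transition tuple at its site.

**Anastomosis.** The occupancy network maps each site to the first tip that
claimed it, and claims are never released. A tip that steps onto a site
claimed by *any other* tip — including its parent or a sibling branch —
fuses there and terminates; the junction site is recorded in its trajectory.
Stays, and re-visits to sites the tip claimed itself, are exempt. When two
tips propose the same empty site in one step, ascending id admits the
first; the second anastomoses. This fixed ordering (moves and anastomosis
resolved tip by tip in ascending id against the continuously updated
occupancy, then arrival checks, then branching) is required for bit-exact
determinism; the model description itself is silent on ordering.

**Arrival.** A tip whose site centre is within $R + h$ of the patch centre
has reached the patch periphery: it stops and its arrival time is recorded.
The one-cell tolerance makes "reaching the periphery" robust to the grid
step.

**Branching.** A tip older than `t_branching` may spawn one daughter per
step at its own site, with probability given by the piecewise table in the
local dimensionless concentration (0 below 0.25, then 0.3 / 0.4 / 0.5, and
1 at $c \ge 0.7$) — but only while the local VEGFA is rising. Daughters
inherit only position: age restarts at zero. The branching decision is
gated on the field at the step's start time $t_k$ and the daughter's birth
time is $t_k$, which makes "no branching during rest periods" an exact
invariant rather than one blurred by the step width. `t_branching` has no
published value; the default 0.5 days is chosen to sit well inside the
first growth period (length $\approx 1.89$ days), so early branching is
possible at all.

**Trajectories.** A tip's logged trajectory records site *changes* only;
stay steps append nothing. This loses no metric information (stays
contribute zero path length and cannot change a running maximum) and keeps
a 14-day run's log compact.

## Vessel measurement

The in vivo protocol measures from the outer circumference of the arteriole
to the farthest point of the new blood vessel. The package mirrors it at
the lineage level: a *vessel* is an initial sprout plus all its descendants,
and its extent is the straight-line distance from the root's origin on the
right boundary to the farthest site any member ever visited
(`final_vessel_lengths()`, `growth_curve()`), converted at 3 mm per domain
unit (the mean in vivo patch-to-artery distance of 0.3 ± 0.2 cm; the scale
is configurable and linear in all outputs). Counting each branch as its own
vessel instead would flood the statistic with hundreds of one- or two-cell
stubs that an histology slide would never register as vessels. Path length
(trajectory arc length) is reported alongside extent, with
extent ≤ path always.

Because the extent is a running maximum, per-vessel growth curves never
retreat; the per-day mean over the 20 lineages is the package's growth
curve, and ensemble runs average it across seeds
(`run_ensemble()`, `ensemble_growth_curve()`).

A note on arrival-time summaries: not every seeded run produces an arrival
within 14 days (rest periods consume roughly half the window, and
anastomosis removes most walkers). The ensemble summary therefore reports
the median first-arrival time over the runs in which vascularization
occurred, alongside the count of such runs.

## Fitting the kinetic factor to measured series

`fit_vegf_params()` fits $a\{b + \sin(2\pi\sigma t)e^{-\gamma t}\}$ to a
concentration series measured at a fixed location (the spatial factor is
absorbed into $a$, which then carries pg/mL). Sinusoid least squares is
multimodal in $\sigma$, so the fit multi-starts over a $\sigma$ grid
spanning 0.05–0.5 cycles/day crossed with a small $\gamma$ grid; each start
profiles the conditionally linear pair $(ab, a)$ by ordinary least squares
before Levenberg–Marquardt refinement, and the best converged start by RSS
wins. A constant series is flagged degenerate (only $ab$ is identifiable).
At least 8 distinct time points are required for the 4 free parameters.

`generate_fixture_series()` emulates the in vivo sampling design — times
1, 3, 6, 12, 18 h and days 1–7, three replicates per point, multiplicative
Gaussian noise — around the in-vivo-fitted values
$(a, b, \sigma, \gamma) = (46.2525, 0.2131, 0.1548, 0.3485)$. It emulates
the *design*, not the tissue: real series carry assay noise that need not
be multiplicative or Gaussian, replicate animals are not exchangeable
repeats of one animal, and the true kinetics need not be an exact damped
sinusoid. Recovery tests on these fixtures therefore demonstrate that the
optimizer finds the right basin and propagates noise sanely — not that the
model is correct for rabbit tissue.

## What the tests do and do not show

The suite checks, among others: exactness of the analytic rate against
finite differences; continuity of the field at the patch rim; probability
normalization, nonnegativity, mass conservation and positivity of the
scheme; the flux-form/probability-form equivalence; zero drift during rest
periods and patch-ward drift during growth; determinism of full runs; and
the headline reproduction numbers under the default study conditions —
a 50-seed ensemble for arrival statistics and pooled vessel lengths, and a
100-trial Monte Carlo for fit recovery at 5% noise. These problem sizes
(50 runs, $N = 100$, 14 days; 100 fit trials) are the package's chosen
desk-scale experiment; single runs take well under a second.

Passing them shows the implementation is a faithful, conservative,
reproducible realization of the model. It does not validate the model
against tissue: the VEGFA field is prescribed rather than solved, there is
no endothelial proliferation, no blood flow or perfusion coupling, no
haptotaxis, and the domain is a 2-D unit square. One reported in vivo
comparison is intrinsically loose: "at most two sprouts reach the patch"
summarizes a handful of simulation runs, and across larger seeded ensembles
the arrival count occasionally reaches three — the distribution's mode and
typical range match the published statement, its seeded maximum need not.

## Session info

```{r}
sessionInfo()
```
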