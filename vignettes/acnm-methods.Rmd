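---
title: "The active contour neighbourhood model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The active contour neighbourhood model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements: the
assumptions behind it, what every tunable means and why its default is what
it is, the numerical scheme, the design choices that were genuinely open,
and what the synthetic phantom does and does not establish about real data.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The model

A brain contour is represented implicitly as the zero level of a scalar
field $\varphi$ over one slice, positive inside.  Instead of evolving
$\varphi$ over the whole slice, evolution is confined to the **active
contour neighbourhood (ACN)**: the belt obtained by dilating the current
contour's border pixels with a disc.  After the field has settled inside
one belt, the contour is re-extracted and a fresh belt is built around it;
this outer replacement repeats until two successive contours agree.  The
confinement is what makes the model robust: the true brain boundary is
assumed to lie inside the belt of a reasonable initial contour, so the
evolution never has the opportunity to converge to a remote minimum.

The speed law is

$$\varphi_t \;=\; D(I)\,\lvert\nabla\varphi\rvert \;+\;
  \beta\,\mathrm{div}\!\left(g(I_r)\,\nabla\varphi\right)$$

with a data term driven by two belt statistics: $\mu$, the mean intensity
over the whole belt, and $I_m$, the bright bound of the brain tissue on the
brain side of the belt.  Writing $r = |I-\mu| / ((I_m-\mu)\,t)$,

$$D(I) = \begin{cases}
 -e^{-r} & I < \mu \\[2pt]
 \;e^{-r} - \exp\!\left(-\dfrac{2(I_m-\mu) - |I-\mu|}{(I_m-\mu)\,t}\right) & I \ge \mu .
\end{cases}$$

$D$ is negative on $[0,\mu)$, positive on $(\mu, I_m)$, zero exactly at
$I_m$, and negative again on $(I_m, 1]$.  The belt mean $\mu$ works as the
dark bound of brain tissue because the belt straddles the boundary: its
outside half samples CSF and skull gap, dragging the mean below the
gray-matter level.  The zero at $I_m$ with contraction beyond is the
model's distinctive feature — tissue brighter than the brain's bright
bound (the eyeball is the canonical case) is expelled rather than engulfed.
$D$ jumps at $I=\mu$ (left limit $-1$, right limit $1 - e^{-2/t}$); the
discontinuity is part of the law as stated, and only the branch values,
never continuity, are asserted in tests.  For extreme statistics with
$|I-\mu| > 2(I_m-\mu)$ the second branch can fall below $-1$; within the
normalized intensity range and realistic belts it stays in $(-1,1)$.

The smoothing term is an edge-stopped curvature flow, expanded in geodesic
form as $g\,\kappa\,\lvert\nabla\varphi\rvert + \nabla g \cdot
\nabla\varphi$.  Its edge indicator is not the image gradient but the
**regional value**

$$I_r = \tfrac{1}{2}\left[(I_{\max} - I_{\min}) + |I_{\mathrm{mean}} - I|\right],$$

built from windowed statistics ($I_{\max}$ over an $N_1 \times N_1$ window,
$I_{\min}$ and $I_{\mathrm{mean}}$ over $N_2 \times N_2$; windows clipped
at the image border).  $I_r$ is zero in homogeneous tissue and large near
boundaries *including weak boundaries with no usable gradient* — the
failure case of gradient-based edge stops.  The printed form of the
regional value in the source material is typographically ambiguous; the
form above is fixed by two requirements: it must vanish in homogeneous
regions and grow with both the local range and the deviation from the
local mean.

A linear baseline data term $D = \varepsilon - |I - T_0|$ is kept for
comparison.  Its defaults are derived from the same belt statistics,
$T_0 = I_m$ and $\varepsilon = I_m - \mu$, so that it expands over the same
brain band $[\mu, I_m]$ — but, being symmetric about its target, it then
necessarily also expands on $(I_m, I_m + \varepsilon)$.  A symmetric linear
profile cannot cover the brain band and exclude brighter tissue at the
same time; that is precisely the defect the nonlinear law removes, and the
leakage comparison in the test suite measures it directly.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `beta` | 1.2 | weight of the edge-stopped curvature term (dimensionless) |
| `t` | 6 | speed parameter: larger `t` speeds contraction below `mu` and slows expansion inside `(mu, I_m)` |
| `r_acn` | 5 px | belt radius ("slight" dilation of the border) |
| `r_prop` | 1 px | contraction/expansion radius of slice-to-slice propagation |
| `n1`, `n2` | 40, 20 px | window side lengths of the regional-value statistics |
| `sigma_g` | 0.1 | scale of the edge stop `g = 1/(1 + (I_r/sigma_g)^2)` on the normalized intensity scale |
| `inner_max` | 120 | PDE steps per belt |
| `reinit_every` | 20 | steps between reinitializations |
| `outer_max` | 10 | belt replacements per slice |
| `converge_tol` | 0.995 | Dice between successive contours that ends the outer loop |
| `min_area` | 30 px | smallest surviving component per slice |
| `min_brain_area` | 50 px | slice area below which a propagation direction stops |

`beta` and `t` are the two parameters a user is expected to set; the fixed
pair (1.2, 6) is the reference protocol.  `r_acn = 5` matters doubly: the
belt must reach far enough outside the contour that its mean samples dark
non-brain tissue, and it must *not* be so large that it bridges the
CSF/skull gap and pulls scalp into the expansion band — at much smaller
image scales it should be scaled down with the image.  `r_prop = 1` (not
larger) is deliberate: a deeper contraction of the propagated contour
biases the next slice's first belt toward the brain interior; if the belt
mean then lands above the gray-matter intensity, gray matter falls into
the contraction range and the contour strands at a second stable
equilibrium, the WM/GM interface.  The same consideration sets the
surrogate initializer's safety margin to 1 px.

Two statistics choices deserve mention because they deviate from the most
literal reading of "belt mean and belt maximum".  First, $I_m$ is taken
over the *brain side* of the belt (belt ∩ current region): bright
non-brain tissue entering the belt from outside must not raise the very
bound that is meant to exclude it — with a whole-belt maximum, the moment
the belt touches the eyeball, $I_m$ jumps to the eye intensity and the
exclusion mechanism deletes itself.  Second, $I_m$ is a 99.5th percentile
rather than a strict maximum: a strict maximum ratchets — a handful of
bright rim pixels straying into the region at the end of one belt pass
drags $I_m$ up irreversibly — whereas a high quantile ignores isolated
outliers while following any genuine shift of the brain's bright bound.

## Intensity normalization

All statistics assume intensities on $[0,1]$.  `normalize_intensity`
rescales the robust percentile span (defaults 2/98) onto $[0,1]$ and
clips; it uses order-statistic quantiles, which makes it exactly
idempotent.  The *pipeline*, however, normalizes with `p_high = 100`: any
upper-tail clipping maps the brightest white matter and the eyeball to the
same value 1.0 and empties the exclusion interval $[I_m, 1]$ that the
speed law needs.  The lower tail keeps the robust 2% cut.

## Numerics

- $\varphi$ is initialized per belt pass as the exact signed Euclidean
  distance of the current region (positive inside, zero level between the
  pixel grid).
- The advection term uses the Godunov upwind gradient; the curvature term
  uses central differences; the time step is the stability bound
  $0.45 / (\max|D| + 4\beta\max g)$ recomputed per belt.
- Reinitialization integrates $\varphi_\tau = S(\varphi_0)(1 -
  \lvert\nabla\varphi\rvert)$ with a smoothed sign and the sub-cell
  interface fix: cells adjacent to the zero crossing relax toward their
  distance interpolated from the incoming field.  The fix is essential
  here, not cosmetic: rebuilding the distance from the binarized region
  instead quantizes the front to the pixel grid every `reinit_every`
  steps, which freezes any front moving slower than about half a pixel
  per window — slow fronts are exactly what the leakage comparison has to
  resolve.
- Inner-loop convergence is measured per reinitialization window (zero-set
  movement below 10% of the boundary length), not per step: CFL-limited
  speeds are of order 0.01 px/step, so a creeping front flips pixels in
  rare synchronized bursts that a per-step test would mistake for
  convergence.
- The outer loop stops at Dice 0.995 between successive contours.  Under
  the phantom's nominal noise the equilibrium contour dithers at Dice
  0.997–0.998 between belt replacements, so a tighter threshold (e.g.
  0.999) is never reached and merely exhausts the iteration budget.
- Degenerate belts ($I_m \le \mu + 10^{-6}$, e.g. over constant intensity)
  raise a typed error rather than dividing by almost zero.  Components
  below `min_area` are discarded at contour extraction; several disjoint
  components may survive (cerebrum and cerebellum can be disjoint within a
  slice).

## Slice-to-slice propagation

The middle slice — where the brain cross-section is simplest — is
initialized by a threshold surrogate: Otsu level floored at 0.2, largest
connected component (rejected if it touches the image border, since a head
is surrounded by background), hole filling, morphological closing, 1 px
safety erosion.  A circle variant (same centroid, 0.83 × the surrogate's
area) is provided to demonstrate tolerance to a coarse start; it recovers
less of the gray matter than the surrogate on the phantom because the
circle sits entirely inside the brain where belt means are high, and the
reference protocol likewise ranks it weakest.

For every other slice, the previous result is contracted or expanded by
`r_prop` according to a discriminant: partition the image into R1 (current
slice brighter than the next) and R2 (the rest); if the current mask
covers R1 at least as much as R2, the brain is receding and the contour is
contracted, otherwise expanded.  Coverage compares absolute pixel counts
(the plain reading).  Ties contract — the safer error, since the level set
can re-expand inside its belt while outward leakage is the failure mode
the model exists to prevent.  The discriminant presumes noise: on ideal
noise-free tissue every unchanged pixel falls on one side of the
partition and swamps the count, while noise splits unchanged tissue evenly
and leaves the systematic boundary-band difference to tip the balance.
Each direction of the sweep stops when the contour empties or falls below
`min_brain_area`; slices are otherwise evolved independently, so small
inter-slice artifacts in the assembled 3D mask are expected and no 3D
regularization is applied.

## The synthetic phantom

The generator emulates what a T1 head presents to a brain extractor:
bright white matter (0.75), mid gray matter (0.45) in a shell, dark CSF
(0.15) in a gap between brain and scalp ring (0.55), ventricular CSF
inside the brain (part of the ground truth, as internal CSF is), a
sinusoidal "gyri" perturbation of the brain radius
($r(\theta) = r_0(1 + 0.07\sin 9\theta)$) that the smoothing term must not
erase, an ellipsoidal slice profile making per-slice areas unimodal, a
bright eyeball (0.95, above white matter) joined to the brain by a
low-contrast corridor (0.40) — the weak-boundary scenario — additive
Gaussian noise (sd 0.02) and a separable low-order cosine bias field
(±10%).  Ground truth is white + gray matter and interior CSF; scalp,
skull gap, eye and background are excluded.  Default geometry is
96 × 128 × 128 voxels; generation is deterministic given the seed.

What passing on the phantom does show: the speed law's sign structure
translates into the intended contour behaviour on tissue with realistic
contrast ordering, noise and smooth inhomogeneity; the slice-to-slice
machinery tracks a smoothly varying cross-section; the eye-exclusion
mechanism works where a linear speed law demonstrably leaks.  What it does
not show: performance on real anatomy (partial-volume voxels, dura and
vessels, true gyral geometry, acquisition artifacts), robustness to
registration or orientation differences, or behaviour at tissue contrasts
other than T1.  The phantom is also geometrically forgiving below its
default scale only up to a point: at in-plane sizes near 64 px the
gray-matter shell (~3 px) is thinner than any useful belt, which is a
property of the method's operating regime, not of the implementation.

## Known limitations

- Basin sensitivity: the belt mean must land below the gray-matter level
  for the contour to hold the true boundary; belts confined to the brain
  interior converge to the WM/GM interface instead.  Good initialization
  (the point of the propagation scheme) is load-bearing.
- The corridor tissue of the weak-boundary scenario (intensity 0.40,
  inside the expansion band once the belt straddles the true boundary) is
  annexed by the nonlinear law up to the eye surface; the eye itself is
  excluded.  On real data the analogous behaviour is retaining small
  bright-adjacent non-brain tissue near the surface while excluding the
  bright structure.
- At `t = 6` the contraction beyond $I_m$ is mild (the branch difference
  shrinks as both exponents approach 1), so exclusion of bright tissue is
  slower than exclusion of dark tissue; decreasing `t` strengthens it at
  the cost of faster expansion elsewhere.
- Runtime is dominated by the explicit PDE loop; a 96 × 128 × 128 volume
  takes on the order of a minute.
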