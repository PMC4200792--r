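---
title: "Mechanics and statistics of repressor-anchored DNA loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics and statistics of repressor-anchored DNA loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopfactor)
```

## The model and its assumptions

`loopfactor` treats double-helical DNA as a chain of rigid base pairs.
Each pair carries a right-handed orthonormal frame (short axis, long
axis, normal); successive pairs are related by six rigid-body step
parameters — tilt, roll and twist (degrees) and shift, slide and rise
(Å) — composed in the mid-step (dimeric-frame) convention of the
3DNA/CEHS standard, so that the translational components do not depend
on the direction in which the chain is read.  Internally the step
rotation is factored as
$T = R_z(\omega/2)\,\exp([(\tau,\rho,0)\times])\,R_z(\omega/2)$,
which makes both composition and its exact inverse (`params_from_frames`,
a ZYZ Euler decomposition) numerically robust; round-trip error on random
steps is below $10^{-12}$.

The energetic model is an *ideal, inextensible, naturally straight*
helix.  Only the three step angles fluctuate; shift and slide are pinned
at 0 and rise at 3.4 Å.  The deformation energy is quadratic and
diagonal,

$$E \;=\; \sum_i \tfrac12\!\left[
  \frac{\tau_i^2}{\sigma_t^2} + \frac{\rho_i^2}{\sigma_r^2} +
  \frac{(\omega_i-\omega_0)^2}{\sigma_w^2}\right] \; (k_BT),$$

with defaults $\sigma_t=\sigma_r=4.84^\circ$, $\sigma_w=4.09^\circ$ and
$\omega_0 = 360^\circ/10.5$.  Three consequences pin these numbers
together and are verified by tests:

* the persistence length $P = 2\,h/(\sigma_t^2+\sigma_r^2)$ (radians,
  $h=3.4$ Å) equals 476 Å, i.e. "nearly 500 Å" — this requires reading
  ±4.84° as the rms of *each* bending component, not of the net bend;
* the stiffness ratio $(\sigma_t/\sigma_w)^2 = 1.40$ — twisting 1.4
  times more restricted than bending;
* equipartition: a sampled step carries $3/2\,k_BT$ on average.

Softened steps (e.g. pyrimidine–purine steps of promoter elements)
multiply *both* bending and twisting rms values by a common factor,
default 1.5.  Whether the twist component shares the bending factor is
not decidable from the sources; we apply it uniformly and expose the
factor as a parameter.  Protein-occupied steps (HU footprints) are rigid
and contribute no elastic energy.

## Loop closure and the J factor

A loop anchor fixes the frames of the base pairs at the free ends of the
two repressor-bound operators and the *closing step*: the phantom step
that, applied to the last base pair, lands exactly on the first base
pair in the reference complex.  For a sampled chain the phantom pair
misses, and the residual is summarized by the end-to-end displacement
$|\mathbf r|$, the global bend $\Gamma$ (angle between the first and
phantom normals) and the net twist $\omega$ (the twist of the ZYZ
decomposition of the residual rotation, i.e. rotation about the mean
normal).  A configuration is looped when $|\mathbf r|\le 15$ Å and both
angles are within $11.5^\circ$; we implement the angular test as
$\cos\Gamma \ge 0.98$ — the direction that agrees with "fluctuations of
11.5° or less".

The J factor converts the looped fraction into an effective molar
concentration:

$$J = \frac{\text{hits}/\text{samples}}
          {N_A\,\tfrac{4\pi}{3}r_{\max}^3 \cdot
           \tfrac{1-\cos\gamma_{\max}}{2} \cdot
           \tfrac{\omega_{\max}}{180^\circ}} \;[\mathrm{M}],$$

the denominator being the probability that a uniformly placed and
oriented end falls inside the capture window at 1 M; it equals
$5.460\times10^{-3}$ at the default window.  This
position-and-orientation density normalization is our own documented
choice: the published normalization behind numbers like
$J\sim10^{-14}$ M at $5\times10^{-15}$ hit fraction cannot be
reconstructed from the text, and with our constant the same fraction
gives $\sim 10^{-12}$ M.  Comparisons *between* conditions (HU levels,
anchor variants) are unaffected by the constant.  Standard errors follow
binomial counting statistics; zero hits are reported with a rule-of-three
95% upper bound.

Sampling uses direct Gaussian Monte Carlo over step angles and, for
efficiency, the half-chain pairwise combination: $m$ half-chains from
each side give $m^2$ effective full chains.  The combination is exact
(a 1×1 combination reproduces the full-chain build bit-for-bit) and
unbiased (tested against naive sampling at 2 SE on a toy loop); the
binomial standard error neglects the pair-reuse correlation of the
$m^2$ samples and is therefore an approximation, adequate at the hit
counts we report.  With HU, footprints are placed within each half
independently, so junction-spanning placements are excluded; the naive
full-chain sampler remains the unbiased reference for that bias.

## HU decoration

Bound HU replaces the 14 steps of its site with the fixed parameters of
a bent footprint.  The four shipped footprints are *synthetic* two-kink
fixtures (net bends 107–130°, mild untwisting) standing in for
crystallographic parameter sets that are not printed in any source we
ship; real sets can be supplied as `.par` files.  Binding levels are
specified as one dimer per `mean_spacing` bp of free linear DNA.  The
placement process — sites visited once in random order, a free window
accepted with probability $p$ — maps exactly onto classical random
sequential adsorption of 14-mers observed at time $-\log(1-p)$ (uniform
visit marks become exponential arrival times, and only a site's first
attempt can ever succeed).  The per-site density of placed footprints
is then the closed-form integral implemented in `rsa_density()`, and
`calibrate_site_probability()` inverts it.  Edge effects on finite
chains are $O(14/L)$ and neglected; simulated occupancy on 15-kb chains
matches the 1/150 and 1/1000 targets within 3 SE.

## Anchors: a parametric, synthetic V

The absolute geometry of the repressor assembly is not available to this
package, so anchors are built from a parametric V: two arms in a plane
separated by the virtual valence angle α, each carrying a 14-step
operator whose center sits `arm_length` Å from the vertex, with the
anchor frames placed 7 rigid helical steps from the operator centers
(loop lengths are counted between operator centers; a 92-step loop has
78 configurable steps).  Each operator may point toward the inside or
the outside of the V, generating the two antiparallel (A1, A2) and two
parallel (P1, P2) loop types.  Opening the repressor by Δα rotates one
arm rigidly about the axis perpendicular to both arms through the
vertex.

The defaults (α = 60°, arm length 80 Å) were chosen once so that the
dominant antiparallel 92-bp loop describes a gradual U-turn with a lower
bending penalty than either parallel loop, reproducing the expected
qualitative ordering.  Two limitations follow from the fixture's
simplicity and should temper interpretation: flipping an operator moves
the attachment point to the other end of the operator, so the secondary
antiparallel form (A2) attaches close to the vertex and is penalized
more strongly than in the real assembly, where A1 and A2 are nearly
degenerate; and all energies tied to this geometry are qualitative —
the package makes no claim to reproduce published absolute loop energies
or J factors, which depend on unavailable structural detail and on
sampling budgets (~10¹⁷ chains) far beyond a desk run.  Ensembles of
operator-end variants (standing in for solution-structure ensembles) are
generated by Gaussian jitter of the end frames and expanded as
left×right cross-products.

## Constrained optimization

Minimum-energy loops fix both terminal frames — six scalar constraints
(three positional, three orientational).  We minimize over the
$3(n-1)$ step angles with an augmented Lagrangian: inner L-BFGS solves
with an exact adjoint (reverse-accumulation) gradient, outer multiplier
updates, and a penalty weight that grows only when the residual stalls.
Convergence is declared at residuals below $10^{-6}$ Å and $10^{-6}$
degrees.  The rotational constraint uses the skew part of the residual
rotation, which vanishes exactly at alignment and keeps the gradient
linear in the frame entries.  We chose this scheme over an elimination
of the last step's six parameters because elimination would have to let
that step translate freely, breaking strict inextensibility and treating
one step asymmetrically; the two formulations share their constrained
minima, and a fixed-weight penalty minimization is kept as an
independent equivalence check in the tests.  Correctness anchors:

* the analytic gradient matches central finite differences to better
  than $10^{-6}$ relative error;
* a torsionally relaxed ring (147 steps = 14 exact helical turns)
  reproduces the continuum elastic-rod energy $2\pi^2 P/L$ to $10^{-8}$
  relative — the discrete circle's energy equals the continuum value
  identically under this parameterization;
* at isotropic minima the twist deviation is uniform along the chain
  (spread $<10^{-4\circ}$), the behavior expected of an ideal rod.

Initialization bends the rest-state helix along a circular arc toward
the target ("arc"); a straight "rest" start, a user chain, or a previous
optimum (warm start, used by the Δα scan) are alternatives.  Multi-start
with seeded 1° perturbations is available (`n_starts`); the default is a
single deterministic start, which we prefer for reproducibility — every
start is reported and the lowest converged minimum returned, so
tie-breaking among near-degenerate minima is left visible to the caller.

## Loop geometry and topology

Bending is reported as the angle γ between successive base-pair normals
and twist as the *twist of supercoiling* θ: the rotation of the
base-pair short axes about a discrete ribbon erected on the polygonal
axis through the base-pair origins, with the pathway closed by the
straight segment joining the terminal origins.  The reference vector is
parallel-transported through every polygon vertex (rotation about the
local binormal), including the final vertex that closes the reference
onto the first material vector — without that closure term White's
theorem fails by visible fractions of a turn at sharp closure
junctions.  Writhe is the exact Gauss double sum over segment pairs,
evaluated with the Van Oosterom–Strackee arctangent form for the
spherical quadrilateral of each pair; the common arcsine form
mis-branches for long or close segment pairs and was rejected after
cross-checking against dense numerical integration.  With both choices,
$Tw + Wr$ matches an independently computed axis–edge linking number to
machine precision, far inside the $10^{-3}$-turn acceptance band, and is
invariant under deformations that avoid strand passage.

## Numerical choices and degenerate inputs

Angles are degrees at every interface and radians internally.  Twist is
wrapped to $(-180^\circ,180^\circ]$; wrapping flips the sign of the
recovered bend magnitude (same bend phase), which the inverse map
handles explicitly.  Rotation-vector derivatives use the closed form of
Gallego & Yezzi with a series fallback below $10^{-7}$ radians.
Zero-length closure segments (exactly closed rings) fall back to the
bisector tangent for the ribbon; material vectors parallel to a segment
axis raise an error rather than return a silent 0.  The RSA integral is
evaluated with `integrate` at $10^{-10}$ relative tolerance, and
infeasible binding densities (beyond the 14-mer jamming limit) are
rejected.  Anchor files store full 3×3 triads, validated to $10^{-10}$
orthonormality on load, to avoid Euler-convention drift.

## What the synthetic data do and do not show

The generators emulate the *statistical* structure of the problem:
Gaussian step fluctuations, rigid bent footprints placed by RSA,
parametric anchor variability.  They do not emulate sequence-specific
force constants, anisotropic bending, intrinsic curvature, protein
sterics or excluded volume, electrostatics, or the true repressor
coordinates.  Tests passing on these fixtures therefore validate the
machinery (frame algebra, estimators, optimizer, topology) and the
qualitative physics (helical-phase oscillation of J, HU filling the
closure valleys, antiparallel loops bending less, softening lowering
energies with localized bending bursts, overtwisting reshaping loops),
not quantitative agreement with any particular published system.

## Problem sizes

Default desk-scale runs: persistence-length fits use $10^5$ chains of
300 steps (about 15 s); toy J-factor comparisons use ensembles of
450–3000 half-chains with inflated fluctuation scales so that closure
is observable; profile scans use 2000 half-chains per length; 92-bp
optimizations (78 free steps, 231 variables) converge in roughly
500–1500 L-BFGS iterations.  All stochastic entry points accept a seed
and are bit-reproducible under it.
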