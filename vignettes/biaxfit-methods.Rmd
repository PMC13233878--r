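---
title: "Methods: forward models, surrogate, and inverse calibration in biaxfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward models, surrogate, and inverse calibration in biaxfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biaxfit)
```

## The problem

Soft airway tissue (trachea, left and right primary bronchus) is strongly
anisotropic: collagen fibers aligned with the airway axis stiffen the
axial response well before the circumferential one. `biaxfit` implements
an end-to-end pipeline for identifying the four parameters of the
Holzapfel--Gasser--Ogden (HGO) hyperelastic model from planar
equi-biaxial tensile tests in which a square sample is gripped by
multi-tine rakes: forward simulation of the test, a neural-network
surrogate of the forward map, and weighted bounded nonlinear
least-squares inverse calibration. Because raw human tissue records are
not publicly deposited, the package ships a synthetic-data generator
that emulates the experimental protocol, so every stage is exercised
end-to-end without downloads.

## Constitutive model

The strain-energy density is

$$U = C_{10}(\bar I_1 - 3) +
      \frac{k_1}{2k_2}\left[e^{k_2 E^2} - 1\right],
  \qquad E = \kappa(\bar I_1 - 3) + (1 - 3\kappa)(\bar I_4 - 1),$$

with matrix stiffness $C_{10}$ (kPa), fiber stiffness $k_1$ (kPa),
exponential nonlinearity $k_2$ (--), and fiber dispersion
$\kappa \in [0, 1/3]$ ($0$ = perfectly aligned, $1/3$ = isotropic).
$\bar I_1$ and $\bar I_4$ are the first and fourth invariants of the
deviatoric right Cauchy--Green tensor; the mean fiber direction is the
axial axis by default. Two forms of the exponent are implemented:

* `form = "standard"` (default): the GOH/ABAQUS convention above, with
  the whole bracket squared. This is what general-purpose FE codes
  evaluate, so it is what parameters calibrated through such codes mean.
* `form = "squared-i4"`: a variant that squares only $(\bar I_4 - 1)$
  inside the exponent, provided for comparison with reports that write
  the energy that way.

The fiber term is tension-only ($E > 0$); under the equi-biaxial tension
protocol this switch never activates, but it is defined for
completeness. The tissue is treated as fully incompressible ($J = 1$),
so deviatoric and total invariants coincide; there is no volumetric
parameter.

**Plane stress.** Samples are thin membranes: the through-thickness
stretch follows kinematically from incompressibility,
$\lambda_3 = 1/(\lambda_1\lambda_2)$, and the out-of-plane Cauchy stress
is zero after analytic pressure elimination. The in-plane first
Piola--Kirchhoff stress is then simply the derivative of the condensed
energy $\hat U(\lambda_1, \lambda_2)$; `numerical_stress_oracle()`
verifies the closed-form stresses by central differencing exactly this
reduction, and the test suite holds the two routes to $10^{-6}$
relative agreement on random states.

## Loading protocol

The test ramps both axes simultaneously to 50% engineering strain at a
nominal 2.5%/s, where strain is rake displacement divided by the
initial inter-rake gauge length ($\mathrm{side} - 2\cdot\mathrm{apron}
= 3.2$ mm by default). The recorded curve is defined as 25 force
samples per direction at equally spaced strain levels from 0 to the
maximum inclusive, 50 values in total -- this $n = 50$ contract is what
the calibration objective consumes. Time stamps follow from the nominal
rate and are metadata only: all downstream computations are functions
of the sampled strains.

## Forward models

**Homogeneous model** (`homogeneous_forward()`). If the gauge region
deforms homogeneously, the force per direction at strain $\varepsilon$
is $P(1+\varepsilon)\, t\, w_0$ with $t$ the thickness and $w_0$ the
effective width. We take $w_0 = \mathrm{side} - 2\cdot\mathrm{apron}$,
the rake-spanned strip, on the grounds that the rakes load only that
strip; it is configurable. Stresses in kPa with lengths in mm give
forces in mN directly. This analytic map is the default forward model
for surrogate training: it preserves the structure of the pipeline
while replacing a multi-day FE campaign with a map that evaluates in
microseconds.

**Finite element model** (`fe_forward()`). A quarter-symmetry
total-Lagrangian membrane model resolves the actual rake boundary
conditions. Design choices:

* *Elements and quadrature.* 6-node quadratic triangles with a 3-point
  Gauss rule; incompressibility and plane stress are condensed
  analytically at each quadrature point, so the unknowns are the
  in-plane displacements only.
* *Mesh.* A graded tensor grid, refined near the rake lines and tine
  positions (fine spacing never above $\approx r/2.4$, $r$ the tine
  radius, so every hole boundary is resolved at the coarsest level),
  with triangles inside a tine circle removed and nearby nodes
  projected radially onto the circle. Refinement levels shrink both
  spacings by 0.8 per level; element count grows strictly.
* *Rakes.* Each tine is a hole whose boundary nodes are rigidly tied to
  the tine's reference point (kinematic coupling); the reference points
  are driven in the pulling direction and held transversely, which
  reduces to Dirichlet conditions on the hole-boundary nodes. Reaction
  forces are summed over the driven nodes and doubled for quarter
  symmetry.
* *Solver.* Displacement-controlled incremental Newton with a
  backtracking line search on the residual norm, factorization reuse
  between iterations (refactoring when contraction stalls), and
  adaptive load-step bisection; divergence is reported with the failing
  load factor. The residual tolerance is $10^{-6}$ mN in the 2-norm.
* *Tangent.* Central differencing of the analytic stress with respect
  to the deformation gradient at each Gauss point ($h = 10^{-6}$),
  assembled with precomputed shape-gradient products. The residual
  itself is always the analytic stress; only the tangent is
  differenced, which affects the iteration path, not the solution.

On a hole-free square with uniform edge displacements the exact
solution is the homogeneous deformation; the solver reproduces it to
$\sim 10^{-6}$ relative, and this oracle equivalence is asserted in the
acceptance tests at all 50 protocol points. The rake model is markedly
more compliant than the uniform-edge idealization -- the tissue between
tines and the free apron edges sheds load -- which is why boundary
conditions matter for calibration and why the comparison is asserted
qualitatively in the tests. At the coarsest refinement the discrete
rake problem can converge to a slightly direction-asymmetric
equilibrium (in-plane membrane compression near the apron admits
near-buckling states); from level 2 upward the isotropic response is
direction-symmetric to $10^{-4}$.

`mesh_convergence()` reports peak force against element count across
refinement levels and declares convergence below 1% relative change.
Hole-boundary resolution improves along with the far field, so
convergence of the rake model is slower than textbook $h$-refinement on
smooth problems; the study reports the measured sequence rather than
assuming a rate.

## Synthetic data

`synthesize_experiment()` writes a dense CSV record: 10 preconditioning
cycles (triangular ramps at 95% amplitude -- present so cycle
extraction sees realistic input; no Mullins-type softening is modeled)
followed by the measurement ramp, which carries the protocol's sampling
strains exactly so that noiseless resampling is an identity. Noise is
additive Gaussian with standard deviation
$\sigma(F) = \sigma_0 + c\,|F|$, default $\sigma_0 = 5$ mN and
$c = 0.01$: readings below 30 mN are then noise-dominated while large
forces stay proportionally accurate, matching the reliability tiers of
the weighting scheme. A JSON sidecar stores the generating parameters,
thickness, true cycle boundaries and the noiseless 50-point curve.

`generate_cohort()` draws per-region parameters from truncated normal
distributions with the airway cohort's means and standard deviations
(trachea $C_{10}$ 0.53 ± 0.25 kPa, $k_1$ 0.17 ± 0.30 kPa, $k_2$ 6.1 ±
2.0, $\kappa$ 0.08 ± 0.01; analogous values for the bronchi), truncated
to the surrogate training space so that every sample is calibratable
there, with thickness uniform in 1.24--2.84 mm. Truncation shifts the
realized means away from the nominal ones (most visibly for $k_1$,
whose nominal distribution puts roughly a third of its mass below the
space); the tests therefore check empirical means against the
closed-form truncated-normal mean.

What the generator does *not* emulate: viscoelastic rate effects,
preconditioning softening, rake tearing at high strain, heterogeneity
within a sample, and any mismatch between the homogeneous forward map
and the true rake mechanics. Passing recovery tests therefore
demonstrate the correctness and conditioning of the pipeline, not the
fidelity of the homogeneous idealization to real rake-mounted tissue.

## Surrogate model

The surrogate maps $(C_{10}, k_1, k_2, \kappa, t)$ to the 50 sampled
forces with a 5--128--64--50 feedforward network, tanh-sigmoid hidden
layers and linear output.

* *Input scaling:* the strictly positive parameters ($C_{10}$, $k_1$,
  $t$) enter through their logarithms, then all five inputs are min--max
  scaled to $[-1, 1]$ over the (warped) space bounds ($C_{10}$ 0.01--2
  kPa, $k_1$ 0.005--1 kPa, $k_2$ 1--10, $\kappa$ 0--0.10, $t$ 1.24--2.84
  mm). The log warp matters: the transformed force surface behaves like
  $\log k_1 + \log t$ plus smooth terms, so in raw coordinates the
  gradient with respect to $k_1$ blows up like $1/k_1$ at the lower edge
  of the space and the network generalizes poorly there; in log
  coordinates the dominant dependence is linear. $\kappa$ may be zero
  and $k_2$ acts nearly linearly in the exponent, so both stay
  untransformed.
* *Output transform:* forces span about seven decades across this space
  (the exponential fiber term dominates at its stiff corner), so raw
  standardization leaves the loss blind to the large-force designs that
  dominate the pooled validation NRMSE. Outputs are passed through
  $\operatorname{asinh}$ (logarithmic for large forces, linear through
  zero, so the zero-displacement samples need no special casing) and
  standardized per output index; the least-squares residuals are then
  weighted back to force scale with fixed delta-method factors
  $\cosh(z)\,\mathrm{sd}_j / \|F\|$, so the training loss approximates
  the squared pooled relative error that validation measures.
* *Training:* full-batch L-BFGS on the weighted least-squares loss with
  a small fixed $L_2$ weight penalty ($10^{-10}$). One optimizer
  iteration is one epoch. True evidence-based Bayesian regularization
  is not implemented; the model metadata records
  `regularization = "l2"` so the fallback is explicit. Training stops
  at an MSE target ($10^{-7}$ in the normalized space), a
  loss-gradient max-norm floor ($10^{-4}$), or the epoch cap, and the
  stop reason plus the per-chunk MSE history are stored. Weight
  initialization is seeded, and full-batch training makes the result
  bit-reproducible.
* *Validation:* pooled NRMSE in percent,
  $\sqrt{\sum_j (F^{NN}_j - F^{ref}_j)^2 / \sum_j (F^{ref}_j)^2}\times
  100$, over all $m = n_{test}\times 50$ force values, computed on
  designs disjoint from training.

The acceptance experiment trains on 2,000 Latin-hypercube designs and
validates on 200 fresh ones ($m = 10{,}000$), with an 8,000-epoch
budget: a quasi-Newton first-order trainer needs more, cheaper epochs
than a Levenberg--Marquardt trainer to reach the same loss, and the
epoch cap is a budget, not a property of the data (the acceptance
configuration also lowers the gradient floor to `1e-6`, since on the
summed-squared-residual scale the published floor can trigger while the
loss is still descending). Latin hypercube sampling uses one sample per
equal-probability stratum per dimension and is seeded; the default
variant is the maximin LHS, whose inter-point distance maximization
keeps the stiff corner of the space covered -- with a plain random
Latin hypercube the pooled validation error varies several-fold between
draws because that corner dominates the pooled metric. Failed forward
evaluations (none occur with the analytic
map, but the contract covers FE-backed training) are replaced by fresh
draws and logged, aborting if more than 10% fail.

## Inverse calibration

The objective is the weighted sum of squared force differences

$$\varphi(\theta) = \sum_{i=1}^{n}
  \left[W(F^{exp}_i)\,(F^{exp}_i - F^{num}_i(\theta))\right]^2,
  \qquad
  W(F) = \begin{cases} 2 & F \ge 100\text{ mN}\\
                       1 & 30 \le F < 100\text{ mN}\\
                       0 & \text{otherwise,}\end{cases}$$

pooling both directions ($n = 50$), with weights computed from the
experimental forces only. The residual vector $W_i (F^{exp}_i -
F^{num}_i)$ is passed to a bounded Levenberg--Marquardt trust-region
solver (`minpack.lm::nls.lm`) under the calibration bounds ($C_{10}$
0.01--10 kPa starting at 1.0, $k_1$ 0--10 kPa at 0.1, $k_2$ 0--10 at
1.0, $\kappa$ 0--0.33 at 0); with a surrogate predictor the bounds are
intersected with the training space. Multistart uses the fixed initial
guess plus uniformly drawn in-bound points (3 starts by default,
seeded); the best converged start wins, ties going to the lowest index.
Function and step tolerances are $10^{-8}$ with 200 iterations per
start. Predictor failures return a large penalty residual so the
optimizer survives excursions into non-evaluable regions.

Two numerical points matter in practice:

* *Analytic Jacobians.* At stiff corners of the space the matrix term
  contributes $\sim 10^{-5}$ of the total force; a finite-difference
  Jacobian loses that sensitivity to cancellation and the solver stalls
  with $C_{10}$ railed at a bound. The homogeneous forward map and the
  surrogate both provide closed-form parameter Jacobians (direct
  differentiation and backpropagation respectively), which restores
  exact recovery on noiseless data across the whole space.
* *Multistart width.* On a small fraction of synthetic samples the
  3-start default lands every start in the same local valley; the
  cohort studies in the test suite use 8 starts. The default stays 3,
  matching the standard protocol.

**Identifiability.** The weighting scheme zeroes every force below
30 mN -- which for soft airway parameters is precisely the
matrix-dominated regime. With the default noise model, $k_2$ (and
$\kappa$, $k_1$) are recovered tightly in the Monte-Carlo study, while
$C_{10}$ is statistically ill-determined: its contribution to the
weighted points is of the order of the noise floor, and the sandwich
covariance of the weighted least-squares estimator predicts
median relative errors near 100% across cohort-like draws -- the
Monte-Carlo results in the test suite match that prediction. This is a
property of the objective under the stated noise, not of the optimizer;
it parallels the wide cohort dispersion reported for $C_{10}$ and the
known non-uniqueness caveats of exponential constitutive fits. Users
who need tight matrix-stiffness estimates should either lower the
weighting threshold (the package exposes the weights) or add
low-force-resolving instrumentation.

**Fit metrics.** Each calibration reports the residual norm (the
objective at the optimum), $R^2 = 1 - \sum(F^{exp}-F^{num})^2 /
\sum(F^{exp}-\bar F^{exp})^2$, per-start diagnostics and wall time.

## Bilinear moduli

Tissue stress--strain curves are routinely summarized by an initial and
an ultimate modulus from linear fits with $R^2 > 0.9$. A "longest
window with $R^2 \ge 0.9$" rule is not sufficient to pin those slopes:
for an exactly bilinear curve the full-curve fit can itself reach
$R^2 \approx 0.93$, so the longest admissible window swallows the knee
and biases the terminal slope by tens of percent. `bilinear_moduli()`
instead fits a least-squares change point: every admissible break
splits the curve into two shared-endpoint windows (each at least 5
points), the break maximizing the *worse* of the two per-window $R^2$
values is selected (a scale-free criterion -- raw SSE would be dominated
by the large terminal stresses), and each modulus is reported only if
its window reaches the $R^2$ threshold, otherwise flagged. This
recovers exact bilinear curves to machine precision, returns equal
moduli for straight lines, and honestly flags strongly exponential
curves that have no linear terminal regime.

## Problem sizes and runtimes

The test suite runs the material core on thousands of random states,
the FE oracle on a 6x6-cell quarter square at all 50 protocol points,
the rake FE model at moderate strain and coarse-to-medium refinement
(the full-strain, fine-mesh rake solve is a minutes-long computation
and is exercised at reduced strain in routine testing), the full
2,000/200 surrogate experiment, and 20-seed Monte-Carlo recovery
studies. The acceptance script repeats the surrogate experiment from
scratch at the full size; everything runs on a single CPU core in
well under half an hour.

## Known limitations

* The FE membrane model is 2D plane stress; thickness-direction effects
  in thick samples are not represented.
* Tine--tissue interaction is idealized as rigid kinematic coupling of
  hole boundaries: no contact, slip, or local tearing.
* The surrogate is only as good as its training forward map; training
  against the FE model is supported through the forward-model handle
  but is a long computation.
* Viscoelasticity and preconditioning mechanics are out of scope; the
  generator's preconditioning cycles are purely structural.
* True Bayesian regularization (evidence-based penalty updates) is not
  implemented; a fixed weight decay stands in and is labeled in the
  model metadata.
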