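---
title: "Methods: forward modelling, phantom simulation and reconstruction in eitgwo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward modelling, phantom simulation and reconstruction in eitgwo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`eitgwo` is a desk-scale electrical impedance tomography (EIT) toolkit for a
16-electrode circular sensor. It simulates boundary-voltage data for random
circular-inclusion phantoms and reconstructs conductivity images with three
methods — Landweber iteration, a radial basis function neural network
(RBFNN), and the same network with its output weights searched by a grey
wolf optimiser (GWO-RBFNN) — and scores them with RMSE and the image
correlation coefficient (ICC). This vignette is the package's account of the
underlying science: the models, the tunable parameters, the numerical
choices, and — importantly — what the simulation study can and cannot show.

## The forward problem

Within the sensor field $\Omega$ (a disc of radius 47.5 mm) the electric
potential $\varphi$ under low-frequency current injection obeys the
conductivity equation

$$\nabla \cdot \big[\sigma(x,y)\, \nabla \varphi(x,y)\big] = 0,$$

with the injected current entering through the boundary condition
$\sigma\, \partial\varphi/\partial n = -j$ on $\partial\Omega$ and the
insulating remainder of the boundary carrying $j = 0$. The excitation is a
0.5 mA current at 50 kHz; the model is real-valued (conductivity only, no
permittivity), so the frequency is carried as metadata.

**Discretisation.** `build_mesh()` triangulates the disc with linear (P1)
elements on concentric rings and solves the weak form with a sparse Cholesky
factorisation (`Matrix`). Conductivity is piecewise constant per element.
Three numerical choices matter:

* *Electrode model.* Electrodes are modelled with the shunt/gap model: each
  10 mm electrode is a set of boundary nodes that receive the injected
  current with arc-length (trapezoid) weights, and electrode voltage is the
  same weighted average of nodal potentials. Contact impedance is taken as
  zero; the solver interface (node sets + weights) leaves room for a
  complete-electrode upgrade. Because injection and measurement use
  identical functionals and the stiffness matrix is symmetric, reciprocity
  holds on the discrete system to solver precision — the test suite checks
  1e-8.
* *Refinement-invariant electrodes.* Boundary nodes are placed at exactly
  the electrode edges (and cosine-graded inside the electrode, where the
  shunt model's current density is singular) at every refinement level, so
  refining the mesh never changes the discrete electrode geometry. Ring
  radii blend uniform spacing with a sine profile: near-uniform at the
  centre, so a 10 mm inclusion always covers several element centroids, with
  a thin boundary layer under the electrodes. With this layout the
  homogeneous-disc frame changes by &lt;1% between the production resolution
  (`n_refine = 1`, 1536 elements) and the next level, which is the
  convergence criterion the default was chosen to meet.
* *Grounding.* The potential is fixed to zero at one node of electrode 1.
  All reported quantities are voltage *differences*, so the reference is
  unobservable.

**Protocol.** `adjacent_protocol()` implements adjacent drive / adjacent
measurement: current through each neighbouring pair $(k, k+1)$ in turn,
voltage across every neighbouring pair not touching the drive — 13
measurements per drive, 208 per frame, in a fixed drive-major order that is
part of the package contract.

**Sensitivity.** `compute_sensitivity()` uses the adjoint-field identity:
the derivative of measurement $m$ under drive $d$ with respect to element
conductivity $\sigma_e$ is $-A_e\, \nabla u_m \cdot \nabla u_d$ on the
element, where $u_m$ is the field driven by the measurement functional. One
factorisation and $2 \times 16$ solves give the whole 208-column-per-element
matrix; the suite verifies it element-wise against central finite
differences (1e-3 relative on entries above 1e-3 of the per-element column
scale — below that, finite-difference truncation error, which scales with
the perturbation squared, dominates any relative comparison).

## Phantoms and the simulated dataset

`sample_phantom()` draws 1–3 non-overlapping circular inclusions of
diameter 10 mm, background 5.5e-4 S/m and targets 5.5e-8 S/m (contrast
1e4 — effectively perfect insulators, which makes the forward map strongly
nonlinear in the inclusion region). `generate_dataset()` forward-solves
1700 phantoms (equal thirds of 1/2/3 targets, 567/567/566), rasterises each
truth image on a fixed 24×24 pixel grid masked to the disc (≈450 active
pixels), and splits 1500/200 into disjoint train/test sets.

Design choices made where the design was genuinely open:

* *Placement.* The study configuration places inclusion centres uniformly
  in the annulus between 30 mm and the admissible 42.5 mm — the outer band
  of the field. Two reasons: the adjacent protocol's sensitivity
  concentrates near the boundary, which is the regime the sensor geometry
  is designed for; and near-boundary targets are the stated operating
  condition of the study this package reproduces. `sample_phantom()` itself
  defaults to uniform placement over the whole admissible disc
  (`inner_radius_mm = 0`); the annular mode is one argument away in either
  direction.
* *Image scale.* Truth images are binary on $[0,1]$ (background 0, target
  1), i.e. per-pixel conductivity affinely rescaled. All metrics operate on
  this scale, which is what makes RMSE values of order 0.1 comparable
  across methods.
* *Network input.* Voltage frames enter the networks raw (not
  background-subtracted) and are standardised per channel with
  training-set statistics. Standardisation is what makes Euclidean
  distances — the currency of K-means and Gaussian activations —
  meaningful across channels whose absolute scale spans an order of
  magnitude.
* *Noise.* `add_noise()` adds zero-mean Gaussian noise per frame with
  $\mathrm{SNR(dB)} = 10\log_{10}(P_{\mathrm{signal}}/P_{\mathrm{noise}})$
  computed over the frame's 208 channels. Noise is applied to test frames
  only (train-time noise is a config flag). Calibration is tested to
  ±0.5 dB over 1000 frames.

What the generator emulates: geometry, protocol, conductivities, sample
sizes and noise levels of a 16-electrode simulation study. What it does not:
3D current spreading (the tank is modelled at its mid-plane), electrode
contact impedance, instrumentation noise correlated across channels, and
any real-tank artefacts (electrode misplacement, drift). Passing tests
therefore validate the algorithms under idealised simulation, not hardware
performance.

## Reconstruction methods

**Landweber (baseline).** Difference imaging: the data are
$\delta v = v - v_{\mathrm{ref}}$ with $v_{\mathrm{ref}}$ the homogeneous
background frame, and the operator is the background sensitivity matrix
aggregated onto the pixel grid and scaled by the conductivity contrast
(`landweber_operator()`), so a $[0,1]$ image $x$ predicts
$\delta v = A x$. The iteration
$x_{k+1} = x_k + \lambda A^{\top}(\delta v - A x_k)$ runs 200 iterations at
$\lambda = 1/\sigma_{\max}(A)^2$ by default (a warning is raised beyond the
$2/\sigma_{\max}^2$ divergence bound); values are clipped to $[0,1]$ only
after the last iteration so the linear analysis stays exact. The suite
checks monotone residual decrease and convergence to the pseudo-inverse
solution on consistent systems.

**RBFNN.** A single hidden layer of $h$ Gaussian units maps a standardised
frame $x$ to the image $\hat y$:
$$\hat y = W^{\top} \phi(x), \qquad
  \phi_i(x) = \exp\!\big(-\lVert x - c_i \rVert^2 / (2 b_i^2)\big).$$
Training follows the classical three-step recipe:

1. *Centres* by online competitive K-means (`fit_centers()`): one sample at
   a time in a seeded shuffled order, only the winning centre moves,
   $c \leftarrow c + \eta (x - c)$, $\eta = 0.1$; ties break toward the
   lowest centre index; stop when the largest per-epoch displacement drops
   below 1e-6 or after 200 epochs (with a constant step the displacement
   plateaus, so the epoch cap is usually what stops it).
2. *Widths* by the maximum-distance rule (`compute_widths()`):
   $b_i = c_{\max}/\sqrt{2h}$, all equal, with $c_{\max}$ the largest
   inter-centre distance. The literal alternative $c_{\max}/(2h)$ is
   selectable (`rule = "linear"`) for sensitivity analysis.
3. *Output weights* by least squares (`fit_weights_lsm()`): a
   rank-revealing SVD solve returning the minimum-norm solution when the
   activation matrix is rank-deficient (singular values below
   $\max(N,h)\,\varepsilon\, s_1$ are truncated). An optional ridge penalty
   exists but is off by default.

The default $h = 64$ keeps the hidden layer far below the 1500 training
samples and the weight space ($h \times 450 \approx 29{,}000$ dimensions)
within reach of the optimiser.

**GWO-RBFNN.** The grey wolf optimiser treats the flattened weight matrix
as a wolf position and the training RMSE
$S = \sqrt{\tfrac{1}{n}\sum_i (D_i - Y_i)^2}$ (over all training samples
and pixels) as fitness. Each iteration the three best-so-far solutions
$\alpha, \beta, \delta$ guide every wolf through the encircling equations
$$D = |C \cdot X_p - X|, \qquad X^{t+1} = X_p - A \cdot D,$$
with $A = 2 a r_1 - a$, $C = 2 r_2$, and the convergence factor $a$
decreasing linearly from 2 to 0; a wolf's new position is the average of
the three leader-guided candidates, clamped to the bounds. $r_1, r_2$ are
drawn independently per wolf, per leader, per dimension, per iteration.
Leaders are replaced only by strictly better solutions, so the best-so-far
trace is non-increasing by construction, and at the final iteration
($a = 0$) the update is a pure contraction onto the leaders.

Defaults: 30 wolves, 300 iterations, fitness on the full training set each
iteration. Because the weight space is large, the pack is seeded at the
least-squares solution: one wolf exactly at $W_{\mathrm{LSM}}$, the rest
perturbed by seeded Gaussian noise of scale
$0.1\lVert W_{\mathrm{LSM}}\rVert/\sqrt{D}$, with per-dimension bounds
$W_{\mathrm{LSM}} \pm 3\sigma$. Pure random initialisation over the same
box is available (`init = "random"`). For speed, fitness inside the
optimiser is evaluated through precomputed Gram matrices
($\lVert \Phi W - Y\rVert_F^2 = \langle W, \Phi^{\top}\Phi W\rangle -
2\langle W, \Phi^{\top}Y\rangle + \lVert Y\rVert^2$), which is
algebraically exact and is tested against the reference implementation.

**A structural consequence worth stating plainly.** The least-squares
solution is the *global minimiser* of the GWO's own fitness. A search
seeded at that optimum can tie it but never strictly improve on it, and
since leaders are replaced only on strict improvement the returned weights
equal $W_{\mathrm{LSM}}$ exactly: with these (deliberately faithful)
choices, GWO-RBFNN and RBFNN are the *same network*, and every test-set
metric of the two methods coincides. The optimiser can only add value over
least squares when the fitness differs from the solved objective —
regularised, clipped, noise-injected, or subsampled — or when the seeding
is abandoned (in which case a metaheuristic over 29,000 dimensions reliably
*underperforms* the closed-form solve; the suite asserts both directions).
The package keeps the faithful construction and documents the tie rather
than quietly changing the objective.

## Quality metrics

`image_rmse()` is the root mean square pixel error; `image_icc()` is the
Pearson correlation between estimated and true pixel vectors. Both operate
on the $[0,1]$ image scale after clipping. A zero-variance estimate (e.g.
an all-zero difference image) has no defined correlation; it is reported as
ICC 0 and flagged (`icc_defined`), with a strict-error mode available.
Zero-variance truth images cannot occur because every phantom contains at
least one target. `evaluate_reconstructions()` and `summarize_report()`
produce per-sample rows and their plain means — every summary number is
recomputable from the per-sample report, with no hidden aggregation.

## The study driver and reproducibility

`run_study()` executes the full experiment: dataset, RBFNN, GWO-RBFNN,
Landweber operator, evaluation at no-noise/50/40/30 dB, and (optionally)
artifacts — the dataset container, model containers, per-sample report,
summary table, the GWO fitness trace and a truth-vs-reconstruction gallery
with a fixed $[0,1]$ colour scale. All randomness flows from one master
seed, expanded per stage by hashing the stage name (`derive_seed()`), so a
single stage can be re-run reproducibly; the same config and seed give
bit-identical summaries. Problem sizes used by the bundled checks: the
statistical blocks run the full 1700-sample study at three seeds; unit
tests use a 640-element mesh and 60–150-sample datasets.

## What the simulation study shows — and what it cannot

Two findings from running the pipeline at its study scale deserve emphasis
(the acceptance script recomputes both from scratch):

* The *RMSE* ordering of the three methods reproduces: the networks beat
  Landweber (≈0.133 vs ≈0.154 at no noise, seed 1). The *ICC* ordering does
  not: Landweber's smooth blob correlates better (≈0.59) with the sparse
  binary truth than the 64-unit network regression (≈0.54).
* Absolute ICC values near 0.95 are not reachable by *any* generic
  voltage-to-image regressor trained on 1500 samples under these
  conditions. The reason is coverage, not optimisation: a binary 10 mm
  target on a 24×24 grid lights up only ~5 pixels, so the Pearson ICC
  demands position accuracy of a few millimetres, while 1500 samples spread
  over the 4–6-dimensional configuration space of 2–3 targets leave
  nearest-neighbour distances of the order of a centimetre. A
  nearest-training-image oracle — an upper proxy for kernel-style
  regression — stays far below such values on multi-target samples, and no
  setting of $h$, widths, or optimiser budget changes that. Reported
  reference values of that magnitude imply either much denser (or
  lower-dimensional, e.g. single-target-dominated) training coverage or a
  smoother image representation than the binary rasterisation used here.

Known limitations, beyond those already noted: the same FEM family (at the
same resolution) generates the data and the Landweber operator, so the
baseline enjoys a mild inverse-crime advantage; the K-means step with a
constant learning rate does not converge to a fixed point (the epoch cap is
the effective stopping rule); and the GWO search, however configured,
cannot repair a data-coverage deficit.
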