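---
title: "Low-rank network models of decision dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-rank network models of decision dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentloop)
```

## The model

`latentloop` models a population of N cortical neurons during a
delayed-response decision task as a recurrent rate network

$$\tau \dot r_i = -r_i + \phi_i\Big(\sum_j J_{ij} r_j + I_i(t)\Big),
\qquad \phi_i(x) = \tfrac{r^{max}_i}{2}\,(\tanh x + 1),$$

with time constant $\tau = 40$ ms and per-neuron saturation $r^{max}_i$
(spikes/s, trainable). The connectivity is constrained to rank
$P \ll N$,

$$J = U A U^\top,$$

where the columns of the orthonormal basis $U \in \mathbb R^{N\times P}$
split into $C = 3$ *coding* dimensions — aligned during training with the
sample, choice and response axes extracted from data by discriminant
analysis — and $R = P - C$ *residual* dimensions, learned freely. The
$P \times P$ interaction matrix $A$ couples the latent coordinates
$m_l(t) = \sum_i u_i^l r_i(t)$, which obey the closed P-dimensional
equation $\tau \dot m = -m + U^\top \phi(UAm + I(t))$; the package
integrates either form (they agree exactly on the shared grid, which the
test suite asserts).

Task inputs follow the trial structure: three 150 ms tone pulses at
$[-1.85,-1.7)$, $[-1.6,-1.45)$, $[-1.35,-1.2)$ s relative to the go cue
(low vs high tone = left vs right trial), a go pulse at $[0, 0.1)$ s, and a
proprioceptive lick input (per-choice vector times the recorded lick rate)
active only after the cue. Tone and go inputs are rank-P
($U\,\vec\imath$); all windows are half-open.

## Fitting

Training minimises, by Adam (learning rate $5\times10^{-4}$, global
gradient-norm clipping at 1),

$$\lambda_{recon}\,\mathcal L_{recon} + \lambda_{align}\,\mathcal L_{align}
 + \lambda_{orth}\,\mathcal L_{orth},$$

with $\lambda = (0.7,\ 0.5,\ 500)$: summed squared error against the
condition-averaged rates of correct trials; a cosine penalty
$4 - \cos(u_1, v_{sample}) - 2\cos(u_2, v_{choice}) - \cos(u_3,
v_{response})$ tying the first three columns of $U$ to the data axes (the
choice term doubled — it is the readout of the upcoming decision); and
$\|I - U^\top U\|_F^2$ keeping the basis near-orthonormal. Trainable
parameters: $U$ ($N\times P$), $A$ ($P^2$), the three latent task-input
vectors, two lick vectors, and $r^{max}$ (optimised on a log scale so it
stays positive). Gradients are exact reverse-mode derivatives through the
forward-Euler recursion, implemented in compiled code and verified against
central finite differences (relative error $\sim 10^{-8}$) in the test
suite.

Numerical choices worth knowing:

* **Integrator.** Forward Euler, default `dt = 5` ms ($\tau/8$); RK4 is
  available behind `method = "rk4"`. Fitting and evaluation always use the
  data grid. `dt` must satisfy `dt <= tau/4`.
* **Initial condition.** The zero-input baseline $\phi(0) = r^{max}/2$.
* **Initialisation.** Data-driven: $U$ = the coding axes completed with
  the leading principal components of the condition averages outside the
  coding subspace; $A$ and the latent input vectors from a least-squares
  fit of the latent dynamics linearised around the baseline gain
  $\bar G = U^\top \mathrm{diag}(r^{max}/2)\, U$; lick vectors by
  regressing the post-go off-subspace residual on the lick rate;
  $r^{max}_i$ = twice the neuron's mean rate (floored at 0.5 spikes/s).
  This warm start typically lands within a few percent of the final
  explained variance and cuts the iteration budget by an order of
  magnitude relative to a random start.
* **Learning-rate schedule.** On top of the constant reference rate, the
  package applies a step decay ($\times 0.2$ at 60% and 85% of the
  iteration budget). Desk-scale fits run for thousands rather than
  hundreds of thousands of iterations, and the annealing lets the jagged
  late-phase landscape (gradients through near-bistable trajectories are
  large and sign-alternating) settle.
* **Soft orthonormality.** With the reference penalty weight, desk-scale
  budgets leave $\|I - U^\top U\|_F \sim 0.1$–$0.4$ (column norms within a
  few percent of 1, modest cross-correlations); the deviation shrinks
  slowly with further training. Downstream analyses treat $U$ as
  approximately orthonormal; the constructor's tolerance is configurable
  for exactly this reason.
* **Observation filter.** Recorded rates are spikes smoothed with a causal
  50 ms exponential kernel. The package therefore passes the model's
  predicted rates through the *same* filter inside every data-facing loss
  and prediction (`measurement_filter = TRUE`, the default), treating the
  smoothing as part of the observation model rather than asking the
  network to mimic a filtered version of itself. Gradients flow through
  the filter's adjoint. Disable it when fitting unfiltered rates.
* **Stationary starts.** If the gradient norm is numerically negligible
  (a warm start at a joint optimum), optimisation stops immediately —
  Adam would otherwise rescale a zero gradient into full-size steps.

Cross-validation splits trials 80/20 per condition (stratified,
seeded), refits on the training averages, and reports held-out MSE plus
the mean cosine between fitted coding columns and the training-set
discriminant axes, over a grid of latent dimensionalities.

## Coding axes

The sample, choice and response directions are extracted from
condition-averaged trajectories with a two-class discriminant
$S_w(\gamma)^{-1}(\mu_R - \mu_L)$ over the windows: first 600 ms of the
sample period, the 600 ms before the go cue, and the 350 ms after it;
then orthogonalised by Gram–Schmidt in that order, with the choice axis
oriented so the right-condition delay average projects positively.

The shrinkage $\gamma$ interpolates between classical LDA
($\gamma = 0$) and the normalised mean-difference direction
($\gamma = 1$). For *time-bin* observations on condition-averaged
trajectories the package defaults to $\gamma = 1$: the within-window
scatter is deterministic ramping, not exchangeable noise, and whitening
by it makes the axes unstable under resampling (we verified that
intermediate $\gamma$ produces axes that fail to converge to the
noiseless-data axes as trial counts grow). For per-trial observations,
where $S_w$ estimates genuine trial noise, intermediate shrinkage is
appropriate and the closed-form LDA oracle in the tests uses
$\gamma = 0$.

## What the synthetic generator emulates — and what it does not

`make_ground_truth()` builds networks whose latent couplings are set in
gain-normalised units (divided by the mean baseline gain
$\bar g = \overline{r^{max}}/2$), so the designed dynamics are
independent of the firing-rate scale:

* a **sample** latent integrating the tone pulses (leaky, $-0.6$);
* a **choice** latent with weakly supracritical self-excitation
  ($+1.15$): the sample input tips it into one of two saturating basins,
  producing selective delay ramping and two condition-specific attractors
  that persist when the go cue is withheld;
* a **response** latent driven by the go cue and by the choice state;
* **residual** latents that are active but weakly selective — a slow
  condition-independent ramp and a fast, mildly selective transient —
  feeding the choice latent through asymmetric couplings. This matters
  twice over: it makes $A$ non-normal (the non-normality analyses have
  something to find), and it makes the residual subspace shape the
  condition averages (so cross-validated dimensionality recovery is
  informative; with silent residual dimensions a $P = 3$ model would fit
  $P_{true} = 5$ data perfectly).
* **lick inputs** distinct per choice after the go cue, so the response
  epoch carries selectivity that is not a linear shadow of the delay
  choice signal (without them the response axis is a noise-dominated
  Gram–Schmidt residual).

$U$ is drawn orthogonal to the $r^{max}$ vector, making the baseline
$r = r^{max}/2$ an exact zero-input fixed point with zero latent
projection — the bistability then develops symmetrically.

Recordings add, per trial: a constant latent input bias following an
AR(1) process across trials (correlation $e^{-1/20}$ per trial, scale
0.08 input units — slow state drift), Gaussian observation noise
(3 spikes/s) clipped at zero, and the 50 ms causal smoothing. Default
`dt` is 5 ms. Because a constant bias is a persistent drive, the slow and
unstable latent modes amplify it from the start of the trial: large
biases occasionally commit the choice mode to the wrong basin before or
despite the stimulus. The generator therefore labels each trial's
outcome by the basin its late-delay choice projection lands in, which
yields realistic miss rates of roughly 10–25% at the default bias scale
and supplies genuine error trials to the error-axis analyses. Averaging
and training use hit trials only (matching the fitting protocol); note
also that the across-trial AR(1) correlation divides the effective
sample count of any trial average by roughly twice the drift timescale,
so condition averages converge more slowly than $1/\sqrt{K}$ in the
bias-driven directions. The `true_coding_basis` stored with a ground truth is the
discriminant basis of the generator's own noiseless smoothed averages —
the recoverable target of the estimation pipeline — rather than raw
columns of $U$: the choice latent saturates already during the sample
epoch, so the discriminant directions mix latent coordinates and raw
columns are not an attainable reference.

Not emulated: spiking statistics (a Poisson observation model is out of
scope; the noise is Gaussian on rates), session-level behavioural
structure, electrode drift, and any realistic diversity of single-neuron
temporal tuning beyond what the low-rank dynamics produce. Passing tests
on this generator shows the estimators are correct and well-conditioned
under the stated noise model — not that real recordings satisfy that
model.

## Perturbation experiments

Pulse perturbations ($I_{pert} = g\,u_l$, 100 ms, default 12 onsets
spanning the delay, magnitudes on a 31-point grid over $[-15, 15]$) run
with the go cue withheld and the simulation extended 0.9 s past the
nominal go time. Choice flips are counted with the symmetric margin
$\epsilon = 0.25\,(x_R - x_L)$ on the endpoints of the choice
projection. Random control directions are drawn in the orthogonal
complement of $U$ (via full QR). Neuron-targeted perturbations give the
top-K neurons of a loading ranking input $\alpha/K$ each during the first
100 ms of the delay; the summed input is $\alpha$ for every K (the
per-neuron formula is authoritative; note its Euclidean norm is
$\alpha/\sqrt K$, not constant). A protocol variant with 150 ms pulses
and 11 windows is reachable through the function arguments.

## Non-normality diagnostics

The Henrici index $\sqrt{\|A\|_F^2 - \sum_i |\lambda_i|^2}\,/\,\|A\|_F$
is 0 exactly for normal matrices and 1 for nilpotent ones. The
pseudospectrum evaluates $\|(zI-A)^{-1}\|_2 = 1/\sigma_{min}(zI-A)$ on a
lattice (default $201^2$ over a box 1.5× the spectral radius), together
with the residual-subspace alignment $\|R^\top v_1(z)\|$ of the most
amplified input direction.

`schur_modes()` returns the *quasi-lower-triangular* real Schur form
$A = QTQ^\top$ with the negative-real eigenvalue block leading. The
ordering is implemented by rotating $A$ into block form on the invariant
subspace of the negative-real group (computed from the eigendecomposition)
and Schur-factorising each diagonal block; only the negative/nonnegative
partition is contractual — within blocks the usual rotational freedom of
the Schur form remains. Mode projections use $s = Q^\top m$ (columns of
$Q$ are Schur vectors); the transform is orthogonal, so $\|s\| = \|m\|$
whichever orientation convention one expects. `feedforward_energy()`
measures the non-normal content of $T$: strictly-lower entries outside
the $2\times2$ blocks plus, per complex-pair block
$[[a, b], [c, a]]$, the non-normal part $(b + c)^2$ (the skew part is the
rotation encoding the imaginary eigenvalue pair and is normal); this
quantity equals $\|A\|_F^2 - \sum |\lambda_i|^2$ identically.

## Attractors

`find_fixed_point()` integrates with the go cue withheld to 1.05 s past
the nominal go time and reports the normalised flow residual
(RMS of $-r + \phi(Jr)$ divided by the mean $r^{max}$; tolerance
$10^{-6}$), with optional Newton polish. Stability is read from the
Jacobian $M = -I + DJ$, $D_{ii} = \phi_i'(h_i)$: stable below
$-10^{-4}$, marginal within $\pm10^{-4}$. Although $M$ is $N \times N$,
its spectrum is $\{-1\}$ plus at most $P$ nontrivial eigenvalues, so
dense eigensolves are cheap at desk scale.

## Single-trial variability

Trial-to-trial variability is modelled as a constant, trial-specific
input $I^{(k)} = U\,T_{\cdot k}$ — a P-dimensional shift of the operating
point, not a change of connectivity. Joint training adds to the
condition-averaged objective: an epoch-averaged loss (pre-sample, sample,
delay, response; the pre-sample epoch is included although the loss can
be configured with any epoch set), a projection loss matching model and
data trajectories along the coding axes, and a bias-magnitude penalty,
with weights $(0.65, 0.1666, 0.02, 0.5, 500, 0.1)$. The
epoch/projection terms activate only once the trial-averaged loss falls
below 10% of its initial value (threshold fraction configurable) — the
reference procedure states the gating but not the threshold. Trial start
times are re-drawn each iteration from $\mathcal U(-4.35, -2.35)$ s so
the network cannot time-lock a bias-driven response and must integrate
the stimulus.

At test time `fit_test_trial_biases()` freezes every network parameter
and fits only the biases of held-out trials against their single-trial
rates (per-trial squared error plus the magnitude penalty; the reference
text does not spell out the test-time objective, and per-trial
reconstruction is the natural choice). Recovery of planted biases is
assessed as the cosine between planted and recovered *input vectors in
neural space* ($U_{true}T_{true}$ vs $U_{fit}T_{fit}$), which is
invariant to rotations of the residual basis.

Error axes are per-side no-intercept logistic decoders (ridge penalty,
default 1; the reference fixes only "no intercept") on the P-dimensional
biases, with an 80/20 stratified split — drawn independently of the
model's train/test trial split — and bootstrap SDs. A no-intercept
decoder's boundary passes through the origin; bias sets in which one
class surrounds the origin are intrinsically at-chance for it, which is
worth remembering when interpreting accuracies. The
coding/residual interpolation
$I(\alpha) = I_{err} - \alpha I_{coding} + \alpha I_{residual}$
(normalised) spans pure coding ($\alpha = -1$) to pure residual
($\alpha = +1$); the split uses the canonical latent coordinates
$1..C$ vs $C+1..P$.

## Two-area model

The thalamocortical extension couples the recurrent cortical network to a
non-recurrent thalamus ($\tau_{th} = \tau/3$) through rank-limited
bottlenecks $J^{ct} = U^{ALM} J^{ct,post} B^{ct} J^{ct,pre}
(U^{th})^\top$ (and symmetrically for cortex→thalamus), with the sample
stimulus routed to cortex and the go cue to thalamus. The simulator
evaluates all couplings in factored form; tests verify it against a
dense block-matrix oracle to $10^{-8}$ and exact decoupling when the
bottlenecks are zeroed. `disconnect()` reports delay-period
activity-reduction ratios; `thalamic_perturbation_sweep()` compares
choice-axis against random residual-direction inputs (defaults: 40
magnitudes in $[1,6]$, 120 unit-norm directions). The module stops at
the simulation/perturbation interface: a joint two-area trainer is not
part of the package's surface, and two-area ground truths for testing
are constructed directly.

## Problem sizes and reproducibility

All randomness is seed-controlled; identical seeds give bit-identical
generators, splits and fits. The packaged experiments use desk-scale
problems chosen to keep each analysis in minutes on one core: recovery
experiments at $N = 100$, $P_{true} = 5$, 200 trials per condition,
`dt = 10` ms, iteration budgets of $10^3$–$10^4$ (the reference protocol
allows $4\times10^5$); bias-recovery sessions at $N = 60$, $P = 8$. At
these budgets the condition-averaged fit reaches the ceiling set by
held-out-average noise to within one to two points of explained
variance. Known limitations: Adam with sign-scaled steps makes relative
loss weights matter less than their magnitudes suggest (the
orthogonality deviation equilibrates rather than vanishing); Euler
integration at `dt` near $\tau/4$ trades accuracy for speed (halve `dt`
to check any marginal result); and the discriminant axes of richly
coupled networks are only as stable as the window means that define
them.
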