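---
title: "Enhancing multi-focal HIE lesions with rough-set neural networks and anti-homomorphic filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancing multi-focal HIE lesions with rough-set neural networks and anti-homomorphic filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roughmri)
```

## The problem

Hypoxic-ischemic encephalopathy (HIE) in term neonates produces brain
lesions that are hard to see on MR slices for three compounding reasons:
the lesions are *multi-focal* (many small foci dispersed through tissue
rather than one mass), *small* (a few pixels across), and *low-contrast*
(an intensity bump of ~0.1–0.2 on a normalised scale).  On top of that,
neonatal imaging carries three characteristic artifact families that
further blur lesion boundaries:

* **partial-volume** mixing — a voxel at a tissue interface averages the
  signals of both tissues, modelled here as an isotropic Gaussian
  low-pass;
* **chemical shift** — the fat resonance is offset from water, so the
  fat compartment is imaged displaced by a few pixels along the readout
  axis, producing a bright band on one interface and a dark band on the
  other;
* **motion ghosting** — quasi-periodic subject motion modulates every
  *k*-th phase-encode line of k-space, creating displaced replicas of
  bright structures at a spacing of `height / interval` rows.

This package implements a complete enhancement-and-staging chain for
such slices: a frequency-domain *anti-homomorphic* filter, rough-set
attribute reduction over pixel descriptors, a neural network with
interval ("rough") weights, metaheuristic weight tuning, artifact-voxel
suppression, and stage classification with three dedicated training
functions.  Because real neonatal data cannot ship with a package, a
seeded phantom generator reproduces the salient statistical features of
the target data and provides exact ground truth.

## The anti-homomorphic filter

The classical homomorphic filter treats an image as a product of
illumination and reflectance, $f(x,y) = i(x,y)\,r(x,y)$.  A logarithm
turns the product into a sum, a radial gain $H(u,v)$ applied in the
centered frequency domain rebalances the two components, and an
exponential maps back:

$$ g = \exp\!\big(\mathcal{F}^{-1}\!\left[H \cdot \mathcal{F}(\ln(f+\varepsilon))\right]\big) - \varepsilon. $$

Its **anti-homomorphic** dual runs the pipeline the other way around:
the exponential first *expands* the dynamic range to linear-domain
intensities, linear filtering is applied with the *inverted* gain $1/H$,
and the logarithm *compresses* the range back:

$$ g = \ln\!\big(\max(\mathcal{F}^{-1}\!\left[H^{-1} \cdot \mathcal{F}(e^{f})\right], \varepsilon)\big). $$

For unit gain both reduce to the identity, which the tests assert to
$10^{-6}$; on 8×8–16×16 grids both pipelines are checked pixel-for-pixel
against a brute-force $O(N^4)$ DFT re-implementation.

The gain itself is a Gaussian high-frequency-emphasis surface

$$ H(u,v) = (\gamma_H-\gamma_L)\big(1-e^{-c\,D^2/d_0^2}\big) + \gamma_L $$

with $D$ the centered radial frequency in cycles/pixel.  The source
material names only "a low-frequency gain and a high-frequency gain"
without an algebraic form, so this standard homomorphic-practice surface
is a design choice; defaults are $\gamma_L = 0.5$, $\gamma_H = 2$,
$c = 1$, $d_0 = 0.1$ (a fifth of the Nyquist radius), and
$\varepsilon = 10^{-6}$ guards the logarithm.  Every filter output is
min–max normalised to $[0,1]$ by default (disable with
`normalize = FALSE`) so different filters are directly comparable.

## Rough sets and the two reducers

Pixel descriptors are organised as a decision system $S = (U, A, V, f)$:
objects, conditional attributes, and one decision column.  Equivalence
classes under exact value equality give lower/upper approximations of
each decision class; the union of lower approximations is the *positive
region* and $\gamma = |POS|/|U|$ the dependency degree.

**LRSM** (local-redundancy stability measure) performs greedy forward
selection driven by the *relative significance*

$$ RSIG(a, B, D) = \frac{|POS_B(D)| - |POS_{B\setminus a}(D)|}{|U/B| - |U/(B\setminus a)|}, $$

which rewards positive-region gain but divides by the number of extra
equivalence classes the attribute creates — a guard against
overfitting-style splits.  A zero denominator (the attribute refines
nothing) gives RSIG 0.  Two structural facts speed the loop up and shape
its semantics:

* positive regions grow monotonically with the attribute set, so objects
  already decided by the selected attributes — and, crucially, objects
  *undecidable even under the full attribute set* — can be removed from
  the working universe;
* an attribute can only matter on its *active region*, the objects whose
  equivalence classes it actually refines.

The second removal above is the "local" in the name, and it is what
reproduces the source's worked example: on the 8-object table the two
inconsistent objects are dropped from the working universe, after which
either attribute alone decides everything that is decidable, both carry
RSIG 1, and the reduct has a single attribute.  The cost is that on
*inconsistent* systems the returned reduct preserves dependency on the
decidable objects rather than on the full universe (on the worked
example $\gamma(\{a\}) = 5/8 < 6/8 = \gamma(\{a,b\})$ — no single
attribute can preserve global dependency there, so the single-attribute
worked-example outcome and global preservation are mutually exclusive;
we follow the worked example).  On consistent systems the algorithm is
exactly the standard dependency-preserving greedy, and the test suite
verifies $\gamma$-preservation against exhaustive subset search on that
domain.  Mutually redundant candidates are pruned one at a time (latest
declared first) — dropping two attributes that are only redundant given
each other would silently lose dependency.

**NBD-RS** generalises indiscernibility to continuous data through
$\delta$-neighborhoods under a metric (euclidean, manhattan, or
chebyshev; euclidean on min–max-normalised columns by default, with
$\delta = 0.15$ so one radius is meaningful across attributes).  The
driving quantity is the neighborhood conditional information entropy

$$ H(D \mid B) = -\frac{1}{|U|}\sum_{x\in U} \log_2
   \frac{|N_B(x)\cap [x]_D|}{|N_B(x)|}, $$

finite and non-negative because $x$ belongs to both sets.  The reducer
computes $H(D\mid C)$ for the full attribute set first and then greedily
adds the attribute of maximal importance
$H(D\mid B) - H(D\mid B\cup\{a\})$ until the reduct is within
$\varepsilon$ of the full-set entropy.  Anchoring the stop to the
full-set value (rather than to the individual importances) matters:
neighborhood entropy is *not monotone* in the attribute set — shrinking
a neighborhood can remove same-class neighbours — so an
importance-threshold greedy can stall strictly above $H(D\mid C)$ (we
measured ~1.5% of random 6-object tables).  The full-set anchor makes
entropy preservation unconditional.

## The rough network

Each rough neuron is a pair of conventional sigmoid neurons sharing
inputs — one fires from the lower-bound weights, one from the
upper-bound weights — and emits the ordered interval
$(\min, \max)$ of the two responses, so $o_{low} \le o_{up}$ holds by
construction for arbitrary weights (property-tested over 1000 seeded
draws).  Three de-intervalisation decisions make the network trainable:

* **between hidden layers** the interval collapses to its midpoint —
  hidden layers stay rough while the trainers get a single
  differentiable path (the single largest interpretive choice in the
  package);
* **at the output layer** the class logits are the midpoint of the
  *pre-activation* interval, which is exactly the centre-weight
  response (the interval terms cancel under averaging), softmax-
  normalised.  A softmax over sigmoid-bounded activations would cap the
  attainable confidence (cross-entropy floor ≈ 0.55 for three classes)
  and in practice trained to chance-level pixel classifiers;
* **weight intervals** are initialised from the rough-set reduction:
  centres from a seeded uniform $(-1/\sqrt{fan},\,1/\sqrt{fan})$, and
  interval half-width $h\cdot|BND(reduct)|/|U|$ with $h = 0.5$ — the
  more undecidable the reduct leaves the training table, the wider the
  intervals.  A consistent table (empty boundary region) degenerates to
  a conventional network exactly, which the tests assert bit-for-bit.

Classifying stages and suppressing artifact voxels are two different
jobs that the source conflates; we separate them into two heads sharing
the descriptor trunk: a pixel-level 3-class head
(`lesion` / `voxel-artifact` / `background`) used for enhancement, and
an image-level 3-stage head (`mild` / `moderate` / `severe`) used for
staging.  Enhancement multiplies each intensity by
$1 - \kappa\, s_{artifact}$ ($\kappa = 0.8$ by default): pixels the
network attributes to artifact structure are darkened, lesions and
tissue pass through.  The rule is a reconstruction — the source states
only the purpose ("remove voxels") — and is validated by the
MCC-improvement property, not by any printed number.

## Optimizers and trainers

The three metaheuristics (particle swarm with constriction-equivalent
coefficients $w=0.729$, $c_1=c_2=1.49445$; pelican; hippopotamus) share
one contract: box bounds enforced by clamping, greedy incumbents, one
seeded generator per run with draws in fixed agent-major order, and
bit-reproducibility under a fixed seed.  The pelican and hippopotamus
update equations follow the canonical published formulations; the source
names only the behavioural phases.  Weight tuning flattens every layer's
(centre, half-width) pairs into the decision vector, scores candidates
by training cross-entropy plus an interval-width penalty
$\lambda_w \cdot \overline{|h|}$ with $\lambda_w = 0.01$ (discouraging
vacuous intervals), and rebuilds the network with half-widths through an
absolute value so $w_{low} \le w_{up}$ holds by construction.

The trainers optimise the centre weights with half-widths frozen,
differentiating through the genuine rough forward pass:

* **CG** — the textbook conjugate-gradient recurrence for symmetric
  non-negative-definite systems, with the residual identity and
  A-conjugacy of directions unit-tested.  Since CG is a linear solver,
  it trains the classifier as Gauss–Newton steps on the *output layer
  only* (earlier layers frozen), each normal-equations solve done by
  `cg_solve()`.  Finite termination in at most $n$ steps is an
  exact-arithmetic property, so the convergence tests use moderately
  conditioned random SPD systems where it is observable in doubles.
* **LM** — damped least squares on the per-sample
  $\sqrt{\text{cross-entropy}}$ residuals: solve
  $(J^\top J + \lambda I)\,\delta = J^\top r$, divide $\lambda$ by the
  factor (default 10) on accepted steps, multiply on rejections and
  retry; $\lambda_0 = 10^{-3}$.  With vanishing damping on a linear
  model it reproduces ordinary least squares (oracle-tested).
* **RMLM** — the reduced-memory variant: search directions from the
  limited-memory two-loop recursion over at most $m$ stored
  (parameter-change, gradient-change) pairs (default $m=5$, curvature-
  guarded), Armijo backtracking with $c = 10^{-4}$, oldest pair evicted
  beyond capacity.  On quadratics it reaches the closed-form minimum to
  $10^{-8}$ and, at full memory, tracks a BFGS reference.

## The phantom generator

Defaults emulate the target data: 256×256 grayscale slices, an
elliptical head (semi-axes 0.44/0.38 of the extents) with a grey-matter
rim at intensity 0.45 and white-matter interior at 0.62 on a 0.05
background, 0–20 non-overlapping lesion disks of radius 2–6 px at
contrast +0.18 rejection-sampled uniformly inside white matter, then the
three artifacts in order: Gaussian partial-volume blur
($\sigma = 1$ px), chemical shift of the scalp-fat rim (3 px along the
readout axis), and motion ghosting (every 8th k-space row scaled by
1.25; the row holding the DC bin is spared, since modulating it is a
global brightness change rather than ghosting).  The stage label is a
deterministic function of the lesion-area fraction of the head region —
below 0.5% mild, 0.5–2% moderate, above 2% severe — which yields
roughly balanced stages at the default spec (14/25/21 over the 60
default seeds).  The lesion-size and contrast choices are engineering
choices, not claims about any real dataset.

Augmentation draws integer translations (±10% of each extent), nearest-
neighbour scaling in [0.9, 1.1], and horizontal/vertical flips uniformly
under the run seed, applies the identical transform to image and masks,
and recomputes the stage from the transformed masks.

What the phantoms do *not* emulate: real anatomy (no atlas, no
gyrification), Rician noise statistics, coil inhomogeneity, 3-D partial
volume, or lesion texture.  Passing tests therefore demonstrate that the
pipeline's machinery is correct and that enhancement helps under the
modelled artifact families — not clinical performance.

## The pipeline and its evaluation

`run_pipeline()` chains: phantoms → anti-homomorphic filter → pixel
descriptors (local mean/variance, gradient magnitude, local range as a
boundary surrogate, Laplacian response over a 5-px window, each
min–max-normalised) → reduction (features quantised to 8 equal-width
levels for the equivalence-class operators; the neighborhood reducer
takes them raw) → interval initialisation → metaheuristic tuning of the
pixel suppressor → suppression of every slice → stage training →
metrics.  Two sizing decisions keep the metaheuristic honest: pixel
training rows are sampled at a 2:1:1
background:lesion:artifact mix (balanced sampling trains the classifier
too far from the test-time prior; pure prior sampling starves the
minority classes), and the suppressor is a *single* rough layer —
softmax regression over five descriptors, 36 decision variables —
because the population optimizers tune that reliably within their
iteration budget, while a 16-neuron hidden layer (~300 variables) is
beyond them.  The stage head keeps the 16-neuron hidden layer and is
trained by gradient methods.

Pixel-level evaluation thresholds each slice with a two-level Otsu
(head vs background, then lesion candidates within the bright
compartment) and accumulates confusion counts over the held-out third
of slices; the headline comparison is full-pipeline MCC versus the
filter-only branch on identical thresholds.  Stage features are
aggregates of the enhanced slice and of the suppressor's score maps
(lesion-score area fraction, mean lesion score, artifact-score area,
global mean, 99th percentile, gradient energy), min–max-normalised on
the training split.  The default run uses 60 phantoms with a 40/20
split, PSO at 20 agents × 60 iterations, and RMLM at 150 iterations —
about half a minute on one core; these sizes are the package's chosen
study conditions and are also what `tests/testthat/test-acceptance.R`
exercises.

All metric formulas are the standard closed forms; they reproduce, at
printed rounding, every cell of the published reference column from its
confusion counts (and the neighbouring column as a cross-check), which
is how the formula reconstruction was validated.  Zero denominators map
to 0 by convention; the reference counts never exercise that branch.

## Numerical choices and degenerate inputs

* Exact equality defines equivalence classes; continuous features must
  be quantised upstream (the pipeline uses 8 equal-width bins).
* Neighborhood membership uses `<= delta + 1e-12` to absorb float noise
  at radius boundaries.
* Smoothing kernels are normalised and use replicate padding, so
  constant images are exact fixed points of every blur.
* Ties: max-RSIG and max-importance selections break toward the
  earliest declared attribute; stage argmax breaks toward the less
  severe stage.
* `min–max` normalisation of a constant image returns it unchanged.
* The spectrum layout places the zero-frequency bin at
  `floor(n/2) + 1` along each axis; radial gains are literal distance
  functions of that layout.

## Known limitations

* The interval semantics are not propagated through training: trainers
  and tuners treat half-widths as frozen or penalised, never as
  first-class uncertainty estimates.
* CG training touches only the output layer; it is a linear solver and
  this is documented behaviour, not an approximation of full
  backpropagation.
* On inconsistent decision systems LRSM preserves dependency locally
  (see above); use NBD-RS when global entropy preservation on noisy
  continuous data is the priority.
* Phantom realism is deliberately limited; no claim about clinical
  data follows from the shipped experiments.
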