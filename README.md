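# roughmri

Enhancement and staging of multi-focal hypoxic-ischemic-encephalopathy
(HIE) lesions in 2-D neonatal brain MR slices.  HIE lesions are small,
dispersed, and low-contrast, and neonatal imaging adds partial-volume
blur, chemical-shift bands, and motion ghosting on top — so the
package combines a frequency-domain filter that targets those artifact
families with a rough-set-driven neural network that suppresses
artifact voxels and classifies lesion stage.  It is aimed at medical
image-analysis researchers who want a fully seeded, testable
implementation of the whole chain on synthetic phantoms with exact
ground truth.

## What is inside

* **Anti-homomorphic filter.**  The homomorphic filter computes
  `exp(IFT(H · FT(ln(f + ε))))` with a radial high-frequency-emphasis
  gain `H(u,v) = (γ_H − γ_L)(1 − exp(−c·D²/d₀²)) + γ_L`.  Its
  anti-homomorphic dual expands the dynamic range first and compresses
  last, with the inverted gain: `ln(max(IFT(H⁻¹ · FT(exp(f))), ε))`.
  Both are verified against a brute-force O(N⁴) DFT oracle.  Laplacian
  (4/8-neighbour), Gaussian, and bilateral baselines are included.
* **Rough-set attribute reduction.**  Classical machinery (partitions,
  approximations, positive/boundary regions, dependency γ, active
  regions) plus two reducers: LRSM, a greedy driven by the relative
  significance `RSIG(a,B,D) = Δ|POS| / Δ|U/B|` with local-redundancy
  pruning, and NBD-RS, a δ-neighborhood reducer driven by conditional
  information entropy `H(D|B) = −mean log₂(|N(x)∩[x]_D| / |N(x)|)`.
* **Rough neural network.**  Paired lower/upper-bound neurons emitting
  ordered sigmoid intervals, interval half-widths initialised from the
  boundary-region fraction of a reduct, midpoint de-intervalisation
  between layers, and a softmax head on the centre logits.
* **Optimizers and trainers.**  Particle swarm, pelican, and
  hippopotamus metaheuristics under one seeded, bounds-clamped, greedy
  contract for weight tuning; conjugate gradients,
  Levenberg–Marquardt, and reduced-memory LM (limited-memory two-loop
  recursion + Armijo) for classifier training.
* **Phantom generator and evaluation.**  Seeded 256×256 neonatal-brain
  phantoms with multi-focal lesions, ground-truth masks, stage labels,
  the three artifact families, and translate/scale/flip augmentation;
  confusion counts, the full enhancement-metric suite (accuracy,
  precision, recall, FP rate, F, Jaccard, MCC), stage reports, and a
  one-call pipeline.

## Worked example

```r
library(roughmri)

# a seeded phantom with ground truth
sample <- generate_phantom(phantom_spec(seed = 7))
sum(sample$lesion_mask)   # 584 lesion pixels
sample$stage              # "moderate"

# anti-homomorphic enhancement
gain <- make_emphasis_gain(dim(sample$image))
enhanced <- anti_homomorphic_filter(sample$image, gain)

# the 8-object reference decision system: both attributes carry
# relative significance 1 and the reduct is a single attribute
ds <- read_decision_system(system.file("extdata",
        "worked_example_decision_system.csv", package = "roughmri"))
rsig(ds, "a", c("a", "b"))   # 1
rsig(ds, "b", c("a", "b"))   # 1
lrsm_reduce(ds)              # "a"

# enhancement metrics from a confusion-count table
metrics_from_counts(list(TP = 610218, TN = 272386, FP = 232, FN = 61164))
#> accuracy 0.9350, precision 0.9996, recall 0.9089, f_value 0.9521,
#> jaccard 0.9086, mcc 0.8609, fp_rate 0.000851

# the full chain on 60 phantoms (~30 s on one core)
report <- run_pipeline(pipeline_config(n_images = 60, seed = 1))
report$pixel_metrics$mcc         # 0.1355  (full pipeline)
report$ahf_metrics$mcc           # 0.1281  (filter-only branch)
report$stage$overall_accuracy    # 0.85    (held-out stage accuracy)
```

The pixel-level numbers compare two-level-Otsu lesion candidates on the
held-out slices against the ground-truth masks: the suppression stage
raises the Matthews correlation over the filter-only branch, and the
stage head recovers mild/moderate/severe labels well above the 1/3
chance level.

A thin command-line front end lives at `inst/cli/roughmri.R`
(`phantom`, `filter`, `reduce`, `enhance`, `eval`, `pipeline` verbs).

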