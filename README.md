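# ssqeeg

Patient-specific seizure prediction from multichannel scalp EEG, built
around synchrosqueezed wavelet time-frequency images and a
multi-level-feature convolutional neural network (MLF-CNN), with
segment-based evaluation.

**For whom:** researchers working on EEG-based seizure prediction who want
a self-contained, fully testable R implementation of the
preictal-vs-interictal classification chain — from EDF recordings and
seizure annotations to cross-validated per-patient metrics — without any
Python/deep-learning-framework dependency.

## The method

1. **Staging.** For each seizure with onset $t_0$ and offset $t_1$:
   preictal $= [t_0 - 15\,\mathrm{min},\, t_0)$, ictal $= [t_0, t_1)$,
   interictal = everything at least 4 h from every onset and offset
   (enforced across record boundaries); the rest, including postictal, is
   excluded. Windows of 1 s or 3 s tile the usable periods; interictal
   windows are subsampled to a 1:1 class ratio.
2. **Transform.** Per channel, the continuous wavelet transform
   $W_x(a,b) = \int x(t)\, a^{-1/2}\overline{\psi((t-b)/a)}\,dt$ with an
   analytic Morlet wavelet on a log scale grid (8 voices/octave,
   0.5–50 Hz); the phase transform
   $\omega_x(a,b) = \Re[\partial_b W_x / (i2\pi W_x)]$; and
   synchrosqueezing
   $T_x(\xi,b) = \sum_k W_x(a_k,b)\,\Delta a_k/a_k$ over scales whose
   $\omega$ falls in the bin of $\xi$ — energy is reassigned onto sharp
   ridges on a linear 128-bin frequency grid. Per-column reassignment
   mass is conserved exactly.
3. **Images.** Magnitude maps are band-limited to 50 Hz, bilinearly
   resized to 128 × 128, min-max normalized per channel, and stacked in
   montage order (e.g. 128 × 128 × 18 for the bundled CHB-MIT bipolar
   montage).
4. **Classifier.** A VGG16-derived CNN: five conv blocks (3×3, stride 1,
   2×2 max-pool; fewer convs in blocks 4–5), a 1×1 projection after every
   block, transposed-convolution upsampling of the five projected maps to
   one fusion size, channel concatenation, two FC + dropout layers and a
   softmax. Implemented in RcppArmadillo with exact backprop (verified
   against finite differences) and deterministic seeded training.
5. **Evaluation.** Stratified 5-fold cross-validation per patient;
   accuracy, sensitivity, specificity and false predictions per
   interictal hour (FPR/h); unweighted per-patient averages.

A synthetic-EEG module generates annotated multichannel records ($1/f$
background, elevated 3 Hz preictal rhythm, ictal bursts) written as real
EDF files, so the entire chain is exercisable offline.

## Worked example

```r
library(ssqeeg)

fx <- tempfile("fixtures")
ds <- generate_dataset(fx, n_patients = 2, seed = 1, n_channels = 3)

cfg <- pipeline_config(
  data_dir = fx, annotations = ds$annotations, montage = ds$montage,
  out_dir = tempfile("results"), segment_seconds = 3, transform = "swt",
  model = model_config(input_shape = c(128, 128, 3), profile = "reduced"))

res <- run_pipeline(cfg)
print(res$summary[, c("patient", "accuracy", "sensitivity",
                      "specificity", "fpr_per_hour")], digits = 4)
```

Output from this exact run:

```
  patient accuracy sensitivity specificity fpr_per_hour
1   pat01      100         100         100            0
2   pat02      100         100         100            0
3 Average      100         100         100            0
```

Each patient row pools the five held-out folds of that patient's own
model: accuracy/sensitivity/specificity are percentages over held-out
segments (positive class = preictal) and `fpr_per_hour` is false alarms
per evaluated interictal hour. The synthetic preictal signature is strong
by construction (amplitude ratio 4), so a correct implementation should
classify it essentially perfectly — the scrambled-label control in the
acceptance suite verifies that this is learning, not leakage. `Average`
is the unweighted mean over patients. `results.csv`, `summary.csv` and a
reproducibility `manifest.json` are written to `out_dir`.

A command-line front end wraps the same pipeline:

```sh
Rscript -e 'ssqeeg::ssqeeg_cli()' fixtures --out_dir=fx --n_patients=3
Rscript -e 'ssqeeg::ssqeeg_cli()' run-all  --data_dir=fx --out_dir=results
```

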