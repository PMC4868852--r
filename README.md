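# neurofuse

Discriminative classification of neurodegenerative disease from paired
neuroimaging volumes — a gray-matter density map (structural MRI) and an
FDG-PET intensity map per subject — for binary diagnostic tasks: AD vs NC,
MCI vs NC, and MCI-C vs MCI-NC (conversion prediction).

The pipeline turns each volume into a bag-of-features representation and
fuses the two modalities in a canonical space:

* **dense descriptors** — gradient-orientation histograms on a regular patch
  grid over 2D slices (dense-SIFT style, D = 128), pooled per volume;
* **spatial pyramid** — per-cell encoding over an undivided layer plus a 2×2
  subdivision, stacked;
* **encoding** — K-means visual vocabulary with BoVW occurrence histograms
  and VLAD residual vectors `v_k = Σ_{NN(x_m)=μ_k} (x_m − μ_k)`;
* **normalization** — signed square root `x ← sign(x)|x|^ρ` (ρ = 0.5), then
  inter/intra-subject L2AL2W (l2 per feature dimension across training
  subjects, then l2 per subject);
* **CCA fusion** — regularized canonical correlation analysis
  `(B¹, B²) = argmax corr(B¹ᵀX¹, B²ᵀX²)` and the augmented representation
  `F = [X¹; X²; Z¹; Z²]` combining individual and shared features;
* **explicit kernel maps** — Hellinger (exact), chi-square and
  Jensen–Shannon (sampled approximate maps), so a linear SVM emulates the
  nonlinear kernels;
* **classification** — linear SVMs with hybrid score fusion
  `S = α·S_BoVW + (1−α)·S_VLAD` (α chosen on an inner split), evaluated by
  repeated stratified 10-fold cross-validation with ACC, SEN, SPEC, BAC,
  PPV, NPV and AUC reported as mean ± SD over folds.

Real paired MRI/PET cohorts are access-restricted, so the package includes a
synthetic-cohort generator: both modalities of a subject are driven by one
shared latent vector carrying a disease-severity shift, rendered as textured
volumes with modality-specific structure and noise. See the methods
vignette (`vignettes/neurofuse-methods.Rmd`) for the generative model and
all design decisions.

## Worked example

```r
library(neurofuse)

spec <- cohort_spec(n_per_class = 10, volume_shape = c(32, 32, 32),
                    shared_effect = 1, modality_noise = 0.2, seed = 42)
records <- generate_paired_volumes(spec)

cfg <- experiment_config(
  data = list(cohort = spec),
  tasks = "AD_vs_NC",
  representations = c("MRI", "MRIPET", "MRIPETHF"),
  K = list(bovw = 32, vlad = 8),
  cv = list(k = 5, repeats = 2),
  seed = 42)

report <- run_repeated_cv(records, "AD_vs_NC", cfg)
print(report)
```

```
Repeated stratified CV report: task AD_vs_NC, 2 x 5-fold, seed 42
  MRI       ACC=0.57±0.31 SEN=0.55±0.44 SPEC=0.60±0.39 BAC=0.57±0.31 PPV=0.57±0.39 NPV=0.61±0.34 AUC=0.53±0.36
  MRIPET    ACC=0.57±0.24 SEN=0.50±0.41 SPEC=0.65±0.34 BAC=0.57±0.24 PPV=0.58±0.33 NPV=0.60±0.33 AUC=0.68±0.26
  MRIPETHF  ACC=0.80±0.20 SEN=0.75±0.26 SPEC=0.85±0.24 BAC=0.80±0.20 PPV=0.87±0.22 NPV=0.80±0.22 AUC=0.88±0.18
```

On this deliberately small cohort (10 subjects per class), one modality
alone is near chance, plain concatenation helps a little, and the hybrid
CCA-augmented representation with BoVW/VLAD score fusion reaches 0.80
accuracy — the fusion gradient the method is built around. Every number is
a mean ± SD over the 2 × 5 cross-validation folds; within each training
fold the codebooks, CCA bases, normalization statistics, SVM cost and
fusion weight are refit from scratch.

`run_experiment()` drives the same computation from a single declarative
config (or YAML file), writes `report.csv` / `report.json` / `summary.txt`
plus a config snapshot and log, and `inst/cli/neurofuse` wraps it for the
shell (`synth`, `run`, `report` subcommands).

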