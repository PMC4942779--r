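# ibdquant

Histological grading of inflammatory bowel disease (IBD) from label-free
multimodal nonlinear microscopy, in R.

## What it does, and for whom

Gastroenterology pathologists grade IBD tissue sections with three
histological indices: **architecture** (crypt distortion; level 0 or 2),
**chronicity** (lymphocyte/plasma-cell infiltration; 0 or 2) and
**activity** (neutrophil presence and epithelial damage; 0 or 1).
Multimodal nonlinear microscopy acquires five co-registered, stain-free
channels of the same section — CARS at 2850 and 2930 cm⁻¹ (lipid- and
protein-weighted), two-photon autofluorescence at 458 and 525 nm
(NAD(P)H- and flavin-weighted), and second-harmonic generation (fibrillar
collagen). `ibdquant` is for image-analysis researchers who want to
quantify such acquisitions and predict the pathologist's indices from
them.

The pipeline:

1. **Preprocess** each mosaic: median filter → ×4 block-mean downsampling
   → per-tile flat-field (vignette) correction → percentile contrast
   stretch to [0, 1].
2. **Extract 87 features** per sample: 15 crypt-geometry features (mean/SD
   of area, perimeter, equivalent diameter `√(4A/π)`, radius,
   eccentricity, solidity; crypt density; nearest-neighbour distance
   statistics) plus first-order histogram statistics (mean, σ, smoothness
   `1 − 1/(1+σ²)`, third moment, uniformity `Σp²`, entropy `−Σp log₂p`)
   of every channel and Michelson contrasts `(m_a−m_b)/(m_a+m_b)` of
   channel pairs, each over two ROIs: all crypts, and the mucosa without
   crypts.
3. **Rank features** by Fisher's discriminant ratio
   `FDR = (μ₁−μ₂)²/(s₁²+s₂²)` for each index.
4. **Classify** with a two-class LDA per index
   (`w = S_w⁻¹(μ_alt−μ₀)`, midpoint threshold on the LD value), using
   leave-one-out cross-validation and greedy forward feature selection.

Patient images of this kind are not publicly deposited, so the package
includes a first-class synthetic generator (`generate_cohort()`) that
renders five-channel mosaics of healthy vs inflamed mucosa — distorted,
branched, sparser crypts; elevated TPEF background; lymphocyte-like
spots; SHG fibrosis patches; per-tile vignetting; Poisson + Gaussian
noise — with exact ground-truth masks and labels.

## A worked example

```r
library(ibdquant)

spec   <- cohort_spec(n_samples = 20, seed = 1)   # 10 healthy, 10 diseased
cohort <- generate_cohort(spec)
pp     <- lapply(cohort, function(it)
            preprocess_sample(it$sample, it$roi, preprocess_config()))
features <- extract_feature_table(pp)
labels   <- setNames(lapply(cohort, `[[`, "labels"),
                     vapply(cohort, function(it) it$sample$sample_id, ""))

head(as.data.frame(rank_features(features, labels, "architecture"))[, 1:6], 3)
#>   rank           feature      fdr infinite   family    roi
#> 1    1     crypt_density      Inf     TRUE geometry crypts
#> 2    2 eccentricity_mean 88.23274    FALSE geometry crypts
#> 3    3   SHG_mean_crypts 86.42176    FALSE      irp crypts

sel <- select_features(features, labels, "architecture")
sel$loo_accuracy
#> [1] 1
sel$selected_features
#> [1] "crypt_density"
```

With the default presets the classes are strongly separated. Crypt
density tops the ranking — at this cohort size its within-class variance
is zero (each class realises a fixed lattice count), so its FDR is
reported as +Inf and flagged; crypt eccentricity and the SHG crypt mean
(fibrosis) follow. A single feature suffices for a perfect leave-one-out
accuracy, so the greedy search stops there. The same run as a
reproducible artifact set:

```r
run_pipeline(run_config(cohort = spec), "run1")
# run1/features.csv, run1/ranking_*.csv, run1/models/model_*.json,
# run1/ld_values.csv, run1/report.md
```

A thin command-line front end with `simulate / preprocess / extract /
rank / train / predict / run / report` subcommands is installed at
`inst/scripts/ibdquant.R`.

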