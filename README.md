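# mosae

Multi-omics supervised autoencoders for binary clinical endpoint prediction.

Cancer cohorts profile each patient on several molecular layers at once —
DNA methylation, miRNA-Seq, RNA-Seq, protein expression (RPPA) — and record
binarized clinical outcome endpoints (OS, DSS, PFI, DFI). These layers are
related (same tumour) but heterogeneous: widths span two orders of magnitude
and scales differ entirely. `mosae` is for analysts who want to fuse such
layers into one predictive representation without letting the widest layer
drown the rest, with a leakage-safe cross-validation harness around it.

## The model

One supervised autoencoder per omics, shaped by that omics' width, fused by
averaging. For omics *i* with data *X*⁽ⁱ⁾ ∈ ℝ^(N×p⁽ⁱ⁾):

* an omics-specific first layer **compresses** high-dimensional layers
  (p⁽ⁱ⁾ > 1000 by default) or **expands** low-dimensional ones, then an
  encoder maps to a latent code *H*⁽ⁱ⁾ ∈ ℝ^(N×k) with a shared width *k*;
* a linear decoder reconstructs *X̃*⁽ⁱ⁾; an affine+sigmoid head predicts
  *Ỹ*⁽ⁱ⁾ from *H*⁽ⁱ⁾;
* the fused code is the element-wise average
  *H*⁽ᶠ⁾ = (1/M) Σᵢ *H*⁽ⁱ⁾, and a fused head produces the prediction of
  record *Y*⁽ᶠ⁾.

Everything trains jointly on the composite objective

    J = Σᵢ ‖X⁽ⁱ⁾ − X̃⁽ⁱ⁾‖²_F + α Σᵢ L(Y, Ỹ⁽ⁱ⁾) + β L(Y, Y⁽ᶠ⁾),   α = β = 1,

with L binary cross-entropy (or squared error). The package also ships the
ablation grid around the model (multi-omics vs. concatenated input, average
vs. concatenation fusion, supervision on/off, specific layers on/off, AE
vs. NN backbone), a stratified k-fold CV harness reporting ROC AUC
mean ± sd, quantile-based feature filtering fitted on training folds only,
a synthetic multi-omics generator with a Monte-Carlo Bayes-AUC ceiling, and
a command-line interface. The dense-network core (forward, backprop, Adam)
is implemented in the package on BLAS matrix operations and is verified
against finite differences in the test suite.

## Worked example

Generate a four-layer synthetic cohort whose predictive signal is split
evenly across the layers, then compare fused and single-layer models:

```r
library(mosae)

params <- synthetic_params(n_samples = 300, omics_dims = c(800L, 200L, 900L, 60L),
                           latent_dim = 5, seed = 42)
ds <- generate_multiomics(params)
ds
#> <multi_omics_dataset> 300 samples, 4 omics, endpoint OS (89 positive)
#>   methylation      800 features
#>   mirna            200 features
#>   rnaseq           900 features
#>   rppa             60 features

bayes_auc_estimate(params)   # ceiling no classifier can beat
#> 0.867

cfg <- mosae_config(latent_dim = 32L, high_width = 48L, low_width = 300L,
                    dim_threshold = 500L, epochs = 40L, learning_rate = 2e-3,
                    lr_decay = 0.99)
cross_validate(ds, mosae_variant(), cfg, n_folds = 5, seed = 1)
#> <cv_result> MOSAE on OS: AUC 0.7862(±0.0405) over 5 folds

cross_validate(select_omics(ds, "rnaseq"), mosae_variant(), cfg,
               n_folds = 5, seed = 1)
#> <cv_result> MOSAE on OS: AUC 0.6587(±0.0588) over 5 folds
```

The fused model (0.786) clearly beats the best single layer (0.659) and
approaches the 0.867 ceiling: each omics carries only a quarter of the
signal, and averaging the supervised latent codes recovers the rest. On real
cohorts use the reference-scale defaults (`mosae_config()`: latent 400,
compression 100, expansion 1000) and read matrices with
`read_omics_matrix()` / `align_samples()`.

The same workflow is scriptable: `inst/cli/mosae.R` exposes `simulate`,
`preprocess`, `train`, `cv` and `ablation` subcommands driven by a YAML
config; every run writes a `manifest.json` with the fully resolved
configuration and seed.

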