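# glcsa: global-local channel-spatial attention for prostate zonal segmentation

`glcsa` is an R implementation of a pseudo-3D attention mechanism for
segmenting the prostate's transition zone (TZ) and peripheral zone (PZ) in
T2-weighted MRI. A volume is processed as a stack of 2D slices whose batch
axis carries depth semantics; a **GLCSA block** sits between the encoder and
decoder of a U-Net and refines the skip connections with four attention
maps plus a cross-slice interaction module:

- **global channel attention** `Ygc = softmax(Q K' / sqrt(C_c))` - a
  row-stochastic channel-similarity map over the channel-concatenated
  multiscale tokens;
- **global spatial attention** `Ygs` - multi-head (default 4) scaled
  dot-product attention over token positions, `d_k = C_c / H_c`;
- **local channel attention** `Ylc = sigmoid(DWConv1D(GAP(F), k))` - an
  efficient-channel-attention gate, `F_c^l = F * Ylc + F`;
- **local spatial attention** `Yls` - an inception-style tower of dilated
  convolutions (3x3/d1, 5x5/d2, 7x7/d3) reduced to one channel,
  `F_s^l = F * Yls`;
- **slice interaction (SIM)** - per-position multi-head attention across
  slices (no positional encoding, hence permutation-equivariant in depth);
- **fusion** `Fgl = wlo*Fl + wgo*Fg + wt*F` with softmax-normalized
  learnable weights, followed by LayerNorm, GeLU and per-stage upsampling
  back to the skip resolutions.

Because no deep-learning framework exists in the target environment, the
package ships its own tape-based reverse-mode autograd over base R arrays
with RcppArmadillo/BLAS kernels, a minimal NIfTI-1 reader/writer, a
prostate phantom generator for fully self-contained testing, Dice/IoU/mean-
surface-distance evaluation, and a paired Wilcoxon signed-rank comparison.

## Worked example

Generate a small phantom dataset, train a GLCSA-UNet briefly, and evaluate:

```r
library(glcsa)

dir <- tempfile("synth")
generate_dataset(6, dir, phantom_spec(shape = c(8, 32, 32), seed = 1))
train <- load_dataset(dir, "train")   # 5 subjects
test  <- load_dataset(dir, "test")    # 1 subject

net <- with_seed(2, attach_glcsa(
  build_unet(network_spec(stages = 2, base_channels = 8, input_hw = c(32, 32))),
  glcsa_config(Ps = 8)))
fit <- train_network(net, train, train_config(lr = 3e-3, epochs = 10, seed = 3))
tail(fit$history, 3)
#>    epoch      loss        dsc        iou
#> 8      8 0.4126469 0.29560081 0.21008670
#> 9      9 0.3620160 0.36386278 0.28714520
#> 10    10 0.3297999 0.39180295 0.32599246
ev <- evaluate_network(fit$net, test)
ev$records
#>   subject_id class       dsc       iou        msd            flags
#> 1    sub-003    TZ 0.9281768 0.8659794 0.09453263
#> 2    sub-003    PZ 0.0000000 0.0000000        NaN empty-prediction
```

Ten toy epochs already segment the bright transition zone well (held-out
DSC 0.93; MSD is the symmetric mean surface distance in voxels) while the
thin peripheral shell is still empty and flagged - exactly the asymmetry
that motivates the attention block. At the acceptance scale - 30 phantoms
of shape (20, 64, 64), base-16-channel networks, Adam 1e-4, 20 epochs - the
pipeline reaches held-out mean DSC of 0.950 (TZ) and 0.959 (PZ) for the
GLCSA-UNet, with the matched plain U-Net at 0.939 (TZ) / 0.954 (PZ); the
attention block adds ~2% parameters on the default base-64 backbone (the
source architecture reports ~1.27% at paper scale). The run producing those
numbers is `tests/testthat/test-acceptance.R`, criterion 7.

## Command line

```sh
Rscript inst/cli/glcsa synth --out data/ --n 30 --seed 7 --noise 25
Rscript inst/cli/glcsa train --config run.yaml [--ablate no_glsa|no_glca]
Rscript inst/cli/glcsa eval --ckpt run/checkpoint.rds --data data/ --out metrics.csv
Rscript inst/cli/glcsa compare --a metrics_a.csv --b metrics_b.csv --out report.json
```

`run.yaml` carries the seed, data source (directory or synthetic spec),
network/GLCSA/training configuration; unknown keys are rejected by name.
Every command is reproducible from (config, seed) and refuses to overwrite
outputs without `--force`.

## Ablation switches

`glcsa_config()` exposes the studied design axes: channel-only /
spatial-only attention (`enable_glca` / `enable_glsa`), attention order
(`glca_first` / `glsa_first`), path fusion (`sequential` / `sum` /
`parallel`), patch vs global token embedding, LA1 vs LA2 local attention,
SIM on/off, patch size, head counts, and the local-gate kernel.

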