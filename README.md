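# gcaseg

Boundary-aware grid-attention segmentation of tumor MRI, in R.

Osteosarcoma MRI slices are hard to segment for three recurring reasons: the
tumor-tissue boundary is often blurred and low-contrast, transverse-section
lesions can be very small (so a slight spatial shift of the prediction ruins
the overlap), and lesion outlines can be complex with thin background gaps
that naive models paint over. `gcaseg` implements a segmentation network
built around three blocks that target exactly these failure modes, plus the
loss, metrics, data handling and a synthetic-data generator that together
make the whole pipeline testable end to end on a laptop CPU — no dataset
download, no GPU, no external deep-learning framework (the package ships its
own small reverse-mode autodiff core with compiled convolution kernels).

## The model

A dilated-residual backbone (DRN-D-22 layout, output stride 8, layer norm in
place of batch norm) feeds three components:

* **Grid contextual attention (GCA).** The feature map `X ∈ R^{C×H×W}` is
  split into `P_h × P_w` patches. Each patch is average-pooled along the
  height and width directions; the pooled profiles are multiplied
  element-wise by global directional attention
  `Â^h = Excit(Avg_w X)`, `Â^w = Excit(Avg_h X)` (with
  `Excit = Conv ∘ Sigmoid ∘ Conv ∘ ReLU`), passed through a shared
  compression conv and per-direction sigmoid expansions, and recombined per
  patch as the outer product `A^m_{i,j} = Ã^h_{i,j} × Ã^w_{i,j}`, which
  reweights the patch. A replicate-pad / crop pair makes any patch size fit
  any map. A residual skip is on by default.

* **Statistical texture learning block (STLB).** Low-level features are
  summarized by quantization-counting operators: each pixel's cosine
  similarity to the map's mean feature is quantized against `N` levels
  `L_n = (n/N)(max S − min S) + min S`, softly encoded
  (`E_{i,n} = 1 − |L_n − S_i|` inside a half-open bin of width `1/N`), and
  counted into a normalized histogram (1d-QCO) or an `N × N` co-occurrence
  map over width-adjacent pixel pairs (2d-QCO). A texture enhancement module
  reconstructs the level statistics through a graph adjacency
  `G = Softmax(Conv(P)^T Conv(P))` and decodes `O = Reshape(L′ × E)`; a
  pyramid texture module applies the 2d operator at several spatial scales
  and averages level-wise. The result is fused back as extra channels for
  the head.

* **Spatial transformer block (STB).** A localization branch regresses a
  2×3 affine matrix `M_affine` from the fused features (zero initial weights,
  bias `[1,0,0,0,1,0]`, so the untrained block is exactly the identity); the
  initial prediction `pred = Softmax(Conv_{1×1}(X))` is resampled through
  `(x^s, y^s) = M_affine (x^t, y^t, 1)^T` with bilinear interpolation and
  zero out-of-bounds padding, correcting small spatial shifts of the
  prediction map.

Training uses the compound loss

    Loss = FL_seg + β · FL_boundary,   β = 0.2

where both terms are class-weighted focal losses
`FL = −α y (1−p)^γ log p − (1−α)(1−y) p^γ log(1−p)` with `γ = 1.25` and `α`
taken from the batch's background-pixel ratio. The boundary term compares a
differentiable Sobel surrogate of the predicted tumor probability against
the Canny boundary of the ground truth, sharpened at 0.5. Optimization is
Adam at base learning rate 1e-4 with polynomial decay
`(1 − epoch/total)^0.9` over 200 epochs (all defaults; the worked example
below uses a scaled-down configuration).

Evaluation reports accuracy, precision, recall, F1, Dice (DSC) and IOU from
the pixel confusion matrix; for binary masks F1 ≡ DSC and
IOU = DSC/(2−DSC).

## Worked example

Train the reduced-width network on eight synthetic "easy" lesions (64×64)
for 60 optimizer steps and inspect the result:

```r
library(gcaseg)

samples <- generate_samples(8, "easy", size = 64, seed = 42)
cfg <- train_config(epochs = 30, base_lr = 1e-3, batch_size = 4, seed = 1,
                    model = model_config_small())
fit <- train_model(samples, cfg)

tail(fit$history[, c("epoch", "lr", "loss", "seg", "boundary", "dsc")], 3)
#>  epoch           lr        loss         seg    boundary       dsc
#>     27 1.258925e-04 0.005104989 0.004076139 0.005144246 0.9335960
#>     28 8.740129e-05 0.005077017 0.004051820 0.005125988 0.9337219
#>     29 4.683719e-05 0.005057542 0.004032461 0.005125405 0.9337219

seg_evaluate(model_forward(fit$model, samples[[1]]$image)$mask,
             samples[[1]]$mask)
#> seg_evaluation: acc=0.9839 pre=0.8821 rec=1.0000 f1=0.9374 dsc=0.9374 iou=0.8821
```

The `loss` column is the compound objective; `seg` and `boundary` are its
two focal components (the boundary term enters with weight 0.2); `dsc` is
the running train Dice. Thirty epochs of two minibatches each are 60 steps —
enough to reach Dice ≈ 0.93 on this easy set; the acceptance run below
trains for the full 200 steps and passes 0.95. The default full-width model
builds with

```r
count_parameters(build_model(model_config(), seed = 1))$total
#> [1] 22205928
```

about 22 M trainable parameters.

A command-line wrapper for synthesis, training, evaluation and prediction is
installed at `inst/cli/gcaseg`:

```sh
inst/cli/gcaseg synth --n 20 --mode mix --seed 1 --out data/
inst/cli/gcaseg train --config train.yaml
inst/cli/gcaseg eval --checkpoint model.rds --manifest data/manifest.csv
inst/cli/gcaseg predict --checkpoint model.rds --image img.png --out mask.png --boundary
```

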