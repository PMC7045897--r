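# ddunet

Fully automatic tumor segmentation on dual-sequence (T1-weighted +
T2-weighted) MRI with a dense dual-path encoder-decoder network, in pure
R (convolution kernels in Rcpp).

Nasopharyngeal carcinoma is hard to delineate from either MRI sequence
alone: part of the lesion is hypointense (contrast-free) on T1W, while on
T2W some normal tissue is as bright as tumor. `ddunet` implements the
complete pipeline for fusing both sequences:

* **phantom** — a synthetic dual-sequence study generator (head ellipsoid,
  lesions bright on T2W and partially hypointense on T1W, T2W-only
  confuser blobs, differing in-plane resolutions, misregistration, noise)
  so everything below is testable with no patient data;
* **preprocess** — rigid co-registration of T1W onto T2W by
  mutual information with a (1+1) evolutionary optimizer (initial radius
  0.004, 300 iterations), 50% in-plane downsampling, per-volume min-max
  normalization, zero-pad / centered-crop to the network input;
* **model** — the dual-path network: per-sequence encoder blocks, a
  DenseNet-style fusion block (micro-blocks
  GN-LReLU-conv1x1-GN-LReLU-conv3x3, growth rate K, width `in + mK`, then
  a 1x1-compression + 2x2-average-pooling transition), further encoder
  stages, and one decoder block per downsampling (3x3 transposed
  convolution, skip concatenation, two conv-GN-LReLU refinements) ending
  in a 1x1 convolution with pixel-wise sigmoid — plus the single-sequence
  ablation variant. Group norm (8 groups), leaky ReLU (slope 0.1).
  Layers, reverse-mode autodiff and Adam are implemented in the package;
  gradients are verified against finite differences in the tests;
* **training** — soft Dice loss `1 - (2Σpg + s)/(Σp + Σg + s)`, Adam
  (default lr 1e-4), batch size 1, per-epoch flip/rescale augmentation;
* **postprocess** — thresholding, 3D connected components, and removal of
  components confined to a single axial slice (the typical false
  positives of a 2D network);
* **evaluate** — per-patient Dice `2TP/(2TP+FP+FN)`, sensitivity
  `TP/(TP+FN)`, precision `TP/(TP+FP)`, patient-level k-fold
  cross-validation, and a Mann-Whitney U comparison of dual- versus
  single-sequence models under identical folds.

## Worked example

Generate a small cohort, preprocess it, and run the dual-versus-single
comparison with tiny networks (a couple of minutes on one CPU):

```r
library(ddunet)

pc <- phantomConfig(gridShape = c(64L, 64L, 10L),
                    spacingCh1 = c(2, 2, 4), spacingCh2 = c(1, 1, 4),
                    lesionRadiusRange = c(7, 11), t1HypoFraction = 0.5,
                    confuserCount = 3L, confuserRadiusRange = c(4, 7),
                    misregOffset = c(1, 0.5, 0), noiseSd = 0.03)
studies <- generateCohort(12, pc, seed = 101)
pre <- lapply(studies, preprocessStudy,
              regOpts = registrationOptions(seed = 101),
              targetSize = c(32L, 32L))

res <- runInputComparison(
  pre, k = 2, seed = 101,
  netCfg = segNetConfig(inputSize = 32L, channelsPerStage = c(8L, 16L),
                        growthRate = 8L, denseMicroBlocks = 2L,
                        bottleneckFactor = 2L, gnGroups = 4L),
  trainCfg = trainConfig(epochs = 14L, learningRate = 5e-4))
res$table1[, c("input", "dsc_mean", "sensitivity_mean", "precision_mean")]
```

```
  input  dsc_mean sensitivity_mean precision_mean
1  dual 0.8925375        0.8410243      0.9687456
2    t1 0.5383008        0.7360566      0.5139316
3    t2 0.8333744        0.8834249      0.7964609
```

Per-patient metrics are in `res$perPatient`, per-fold means in
`res$perFold`, and `res$tests` holds the Mann-Whitney comparisons of
per-fold Dice against the dual model. The directional pattern mirrors the
clinical motivation: the T1W-only model misses the hypointense part of
each lesion, the T2W-only model is fooled by the bright confusers, and
the dual model — which sees that the confusers are absent on T1W and the
full lesion extent on T2W — outperforms both.

Single pieces work standalone, e.g. registration:

```r
st  <- generateStudy(phantomConfig(misregOffset = c(3, 2, 0), noiseSd = 0))
reg <- registerVolumes(t1w(st), t2w(st))
reg$transform$translation
#> [1] -3.0008564 -2.0277924  0.2306991
```

A thin CLI over the same functions lives at `inst/cli/ddunet.R`
(`pipeline`, `phantom`, `evaluate` subcommands).

## Documentation

The methods vignette (`vignettes/dual-sequence-segmentation.Rmd`) gives
the full account: model and assumptions, parameter semantics and
defaults, numerical safeguards (gradient clipping, classifier bias
initialization, the registration overlap floor), what the phantom does
and does not emulate, and the problem sizes the tests run at.
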