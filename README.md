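# vqheal

Unsupervised, geometry-invariant lesion detection in 3D volumes.

`vqheal` is for researchers who want to detect focal anomalies (e.g. bright
tumours in PET-like scans) *without lesion labels*, on data whose voxel
sizes, fields of view (FOV) and orientations vary between scans. It trains
generative models on healthy volumes only and scores deviations from
normality at test time.

## The method

1. **Whole-body coordinates.** Each anatomical axis is identified with
   `[0, 1]`. A volume carries a frame giving, per axis, the sub-interval
   `[lo, hi]` it covers plus a signed axis permutation for rotated scans.
   CoordConv-style channels (values evenly spaced from `lo` to `hi`) are
   concatenated to the image and, pooled by the downsampling factor, to the
   decoder's latent input — so the networks always know where in the body,
   and at what scale, they are looking. Cropping a volume contracts its
   frame so that the crop's channels equal the parent's sub-block exactly.

2. **VQ-VAE.** A convolutional encoder compresses the volume by a factor
   `F` per axis and snaps each latent vector to the nearest of `K` codebook
   vectors, giving a grid of discrete tokens `Z_iq`. Trained with L1
   reconstruction + commitment loss, straight-through gradients and an EMA
   codebook. A second, smaller codec encodes the co-registered auxiliary
   (CT-like) modality.

3. **Autoregressive transformer.** The token grid is raster-flattened into
   a sequence `s` and modelled as `p(s_i | s_<i, c)` by a causal
   transformer. The conditioning `c` enters via cross-attention and is the
   position-wise sum of two embeddings: the auxiliary-modality tokens and
   quantized *spatial tokens* `sp = b_i + b_j·B + b_k·B²` formed by binning
   the pooled coordinates into `B = 20` bins of 0.05 — telling the model
   where in the body each token sits, whatever the crop or resolution.

4. **Healing + KDE scoring.** At inference, tokens with likelihood below a
   threshold `t` are resampled from the model (`S` healed sequences), each
   decoded `Ddec` times with decoder dropout — `S · Ddec` "healed"
   reconstructions (300 at the reference defaults 60 × 5). A Gaussian KDE
   fitted per voxel across the ensemble, evaluated at the observed
   intensity `x`, gives the anomaly score `−log(f(x) + ε)`: intensities the
   healthy model cannot explain score high.

5. **Evaluation.** Best-achievable DICE (exact sweep over observed score
   values) and AUPRC (step-wise, tie-aware) against binary lesion masks.

A seeded phantom generator provides paired two-modality, body-shaped
volumes with bright focal lesions, two voxel-size presets, random-crop FOVs
and 90° rotations, so the whole pipeline is exercisable end-to-end on
synthetic data at desk scale.

## Worked example

Train a small detector on healthy phantoms and score a lesioned case:

```r
library(vqheal)

# healthy training corpus, two voxel-size presets
corp <- lapply(1:8, function(i) {
  pre <- phantom_preset(if (i %% 2 == 0) "fine" else "coarse")
  generate_phantom(phantom_spec(spacing = pre$spacing, frame = pre$frame,
                                seed = derive_seed(11, paste0("tr", i))))
})
codec <- train_codec(codec_init(codec_config(), seed = 1),
                     lapply(corp, `[[`, "primary"), steps = 250, seed = 2)
auxc  <- train_codec(codec_init(codec_config(n_z = 16L, width = 24L), seed = 3),
                     lapply(corp, `[[`, "auxiliary"), steps = 150, seed = 4)
ds <- tokenize_corpus(lapply(corp, function(p)
        list(primary = p$primary, auxiliary = p$auxiliary)),
      codec, auxc, crops_per_volume = 2, seed = 5)
model <- train_seqmodel(seq_init(seq_config(K = 64L, K_aux = 64L), seed = 6),
                        ds, steps = 150, seed = 7)

# a lesioned test phantom
ph <- generate_phantom(phantom_spec(n_lesions = 2L, seed = 777))
sc <- score_volume(ph$primary, ph$auxiliary, codec, auxc, model,
                   anomaly_config(S = 6L, Ddec = 2L, bw_floor = 0.02), seed = 8)
les <- ph$lesion_mask > 0
median(sc$score[les]); median(sc$score[!les])
auprc(sc$score, ph$lesion_mask)
best_dice(sc$score, ph$lesion_mask)$dice
```

On this 2-minute run the printed numbers are

```
[1] 27.63102        # median anomaly score inside lesions
[1] -2.654693       # median score in background
[1] 0.9864869       # AUPRC at ~0.9 % lesion prevalence
[1] 0.9932432       # best-achievable DICE
```

— lesion voxels score orders of magnitude above background, and the score
map segments the lesions almost perfectly on this synthetic case. The same
`score_volume()` call accepts cropped (`crop_volume()`) and rotated
(`rotate_frame()`) inputs unchanged.

The pipeline can also be driven from a YAML config, in R via
`run_pipeline()` or from a shell via the CLI:

```sh
inst/cli/vqheal run-all --config run.yaml --seed 7
```

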