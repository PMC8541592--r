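# countda

Semi-supervised domain adaptation for **holistic counting**: transferring
an image→count regression model from a labelled *source* image domain to
a *target* domain that differs both in appearance (**covariate shift**)
and in count range (**label gap**). Typical users are people counting
cells in microscopy, leaves in phenotyping rigs, or pedestrians in CCTV,
who have labels for one imaging setup and want a model that works on the
next one after annotating only a handful of its images.

## Method

With source labels $Y_S = [a,b]$ and target labels $Y_T = [a',b']$, the
pipeline runs three stages:

1. **Pretrain** — feature extractor $\phi_S$ + regressor $R$ are trained
   on the source with MSE against min–max normalised labels
   $y \mapsto (y-a)/(b-a) \in [0,1]$. Normalising removes the source
   scale, which is what later lets a different target range be restored
   without touching the extractor.
2. **Adversarial alignment** — a target extractor $\phi_T$ (initialised
   from $\phi_S$; $\phi_S$ and $R$ frozen) is trained so a discriminator
   $D$ cannot tell $\phi_T(t)$ from $\phi_S(s)$, alternating

   $\min_\Psi\; \mathbb{E}_s[-\log D(\phi_S(s))] + \mathbb{E}_t[-\log(1-D(\phi_T(t)))]$
   and
   $\min_{\Theta_T}\; \mathbb{E}_t[-\log D(\phi_T(t))] - \lambda\,\sigma^2(R(\phi_T(t)))$,

   where the output-variance term (population variance, weight
   $\lambda$) prevents *posterior collapse* — all target predictions
   clashing to one value. This stage is unsupervised, so it stops on a
   joint patience rule over two unsupervised monitors: the kernel
   **MMD²** between held-out source/target features and the GAN
   global-optimality deviation **GGO** $= |\mathbb{E}[D(z)] - 1/2|$;
   training ends when neither has improved for 10 epochs, restoring the
   best-MMD snapshot.
3. **Fine-tune** — $R$ alone is retrained on $k$ labelled target images
   (10–50) against raw counts, which maps predictions into $[a',b']$.

Evaluation uses the counting metrics with
$\epsilon_i = y_i - \mathrm{round}(\hat y_i)$: |DiC|, DiC, MSE and
percentage agreement, and brackets the method between the no-adaptation
transfer (**UB**) and fully-supervised target training (**LB**).

A parameterised synthetic cell-scene renderer (`scene_spec()`,
`render_scene()`, `generate_dataset()`, `make_shifted_pair()`) builds
shifted source/target dataset pairs so the whole pipeline is testable at
desk scale; the generator guarantees that connected components of its
noise-free mask equal the stored count.

## Worked example

```r
library(countda)

# source: blue blobs, counts 3-8; target: red smaller halo'd blobs, 6-12
pair <- make_shifted_pair(
  scene_spec(image_size = 64, count_range = c(3, 8),
             blob_radius_range = c(3, 5),
             blob_color = c(0.25, 0.35, 0.90), seed = 11),
  appearance_shift = list(blob_color = c(0.90, 0.25, 0.20), halo = TRUE),
  label_gap_shift  = list(count_range = c(6, 12),
                          blob_radius_range = c(2, 3.5)))
tgt <- pair$target; tgt$seed <- 12L
generate_dataset(pair$source, 300, out_dir = "data/source")
generate_dataset(tgt, 300, out_dir = "data/target", domain = "target")

res <- run_experiment(
  "data/source", "data/target",
  model_config = list(feature_dim = 128, image_size = 64, seed = 0),
  cfg_pretrain = stage_config(lr_head = 1e-3, lr_fe = 1e-3,
                              max_epochs = 30, patience = 8, seed = 0),
  cfg_adapt    = stage_config(lr_head = 1e-3, lr_phi = 1e-5,
                              max_epochs = 25, lambda = 0.1, seed = 0),
  cfg_finetune = stage_config(lr_head = 1e-2, max_epochs = 200,
                              augment = FALSE, seed = 0),
  k = 50)
res$bounds$table
#>   condition abs_dic_mean abs_dic_std   dic_mean  dic_std      mse pct_agree  n
#> 1        UB    1.8266667   1.3601307  1.7733333 1.428970 5.186667  18.66667 75
#> 2      Ours    1.1600000   0.8491564  0.3066667 1.404501 2.066667  21.33333 75
#> 3        LB    0.9866667   0.8405289 -0.1333333 1.289272 1.680000  30.66667 75
```

Reading the table: raw transfer of the pretrained model (UB) is ~1.8
cells off on average (MSE 5.19) because its outputs live on the source
scale; after adversarial alignment plus a 50-image fine-tune the adapted
model (Ours) is ~1.2 cells off (MSE 2.07), close to the fully-supervised
ceiling (LB, MSE 1.68). `res$adaptation$trace` holds the per-epoch
`mmd2`/`ggo` monitor values and patience counters behind the stopping
decision.

A shell-level interface wraps the same functions
(`exec/countda generate|run|sweep`), driven by YAML configs; see
`inst/extdata/toy_t3.yaml` for a bundled scene description.

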