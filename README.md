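# fundusadapt

Joint optic-disc (OD) and optic-cup (OC) segmentation in fundus photographs
with **unsupervised domain adaptation**, for glaucoma screening research.
The package is for people who need OD/OC masks and vertical cup-to-disc
ratios (CDR) on images from a camera for which no labels exist, given
labels from another camera.

## Method

A segmentation network `G` is trained on a labeled source domain `X_S` and
an unlabeled target domain `X_T`:

1. a convolutional autoencoder, pretrained to reconstruct source images and
   then frozen, maps each `x_s` to an enhanced `x_s+` sharing its label;
   the union `X_U = X_S ∪ X_S+` (the *new source domain*) doubles the
   labeled set with structurally faithful but blurred variants;
2. the network — an ASPP encoder–decoder with a boundary-regression branch
   and a boundary-conditioned mask branch — minimizes
   `L = L_m + L_b + λ_adv (L_adv_m + L_adv_b + L_adv_b+)`,
   where `L_m` is multi-label cross-entropy on masks, `L_b` mean-squared
   error on soft boundary maps, and the adversarial terms fool three patch
   discriminators;
3. the discriminators (five 4×4 stride-2 convolutions, 94-px receptive
   field, one real/fake probability per 32×32 cell) separate
   source vs enhanced boundaries (`D_b+`), new-source vs target boundaries
   (`D_b`) and new-source vs target masks (`D_m`), so target-domain
   predictions are dragged toward source statistics without target labels.

Evaluation: Dice `DSC = 2TP/(2TP+FP+FN)` per structure, vertical
`CDR = d(OC)/d(OD)`, its error `δ = |CDR_p − CDR_g|`, ROC/AUC of predicted
CDR for screening, and the weighted-rank challenge score
`R = 0.35·R_cup + 0.25·R_disc + 0.4·R_δ`.

A seeded synthetic fundus generator (elliptical disc/cup phantoms, Bézier
vessels, controllable source→target brightness/contrast/vessel shift)
makes the whole pipeline runnable and testable on one CPU; real datasets in
the REFUGE mask convention (PNG, 0 = cup, 128 = disc rim, 255 = background)
can be dropped in via the same directory layout.

## Worked example

```r
library(fundusadapt)

src <- generate_domain(domain_spec(40, seed = 101))                   # labeled
tgt <- generate_domain(domain_spec(40, shift = target_shift(), seed = 202))
tst <- generate_domain(domain_spec(20, shift = target_shift(), seed = 303))

cae <- pretrain_cae(build_cae(seed = 1),
                    lapply(src, `[[`, "image"), epochs = 15, seed = 1)$cae

cfg <- train_config(seg_lr = 1e-3, epochs = 30, seed = 1)   # full CAE-BMAL
fit <- train_segmentation(cfg, src, tgt, cae = cae)

preds <- predict_masks(fit$checkpoint$segnet, lapply(tst, `[[`, "image"))
ev <- evaluate_predictions(lapply(preds, `[[`, "mask"),
                           lapply(tst, `[[`, "mask"))
ev$summary
#>     metric      mean         sd
#> 1 dsc_disc 0.8977507 0.02638939
#> 2  dsc_cup 0.7232785 0.12707690
#> 3    delta 0.0741067 0.04995140
```

Read: on 20 held-out *target*-domain images the adapted model overlaps the
reference disc at Dice 0.90 and the cup at 0.72, and its vertical
cup-to-disc ratio is off by 0.074 on average.  The same data trained with
`use_cae = FALSE, use_bmal = FALSE, use_db_plus = FALSE` (supervised
source-only baseline) collapses on this shifted target —
`dsc_disc 0.363, dsc_cup 0.0` — while scoring `dsc_disc 0.955` on
source-domain test images: the adversarial alignment recovers most of the
cross-domain loss without ever seeing a target label.
`run_adaptation_experiment()` repeats this comparison over the whole
ablation ladder (baseline → +CAE → +CAE+BMAL → full) across seeds.

A command-line wrapper covers the pipeline end to end:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fundusadapt.R", package = "fundusadapt"))')
Rscript $CLI simulate --out data/src --domain source --n 40 --seed 1 --size 128
Rscript $CLI simulate --out data/tgt --domain target --n 40 --seed 2 --size 128
Rscript $CLI pretrain-cae --source data/src --out runs/cae --epochs 15 --seed 1
Rscript $CLI augment --source data/src --weights runs/cae/cae.rds --out data/enh --seed 1
Rscript $CLI train --source data/src --target data/tgt --weights runs/cae/cae.rds \
        --out runs/full --seg_lr 1e-3 --epochs 30 --seed 1
Rscript $CLI predict --checkpoint runs/full/checkpoint.rds --input data/tst --out runs/pred
Rscript $CLI evaluate --pred runs/pred/masks --gt data/tst/masks --out report.json
```

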