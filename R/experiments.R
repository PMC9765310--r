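# Scaled-down adaptation experiment: trains the ablation ladder
# (baseline -> +CAE -> +CAE+BMAL -> full) on synthetic source/target
# domains across several seeds and evaluates every run on a held-out
# target test set.  This reproduces the qualitative shape of the published
# ablation at desk scale.

ablation_toggles <- function(name) {
  switch(name,
    baseline = list(use_cae = FALSE, use_bmal = FALSE, use_db_plus = FALSE),
    cae = list(use_cae = TRUE, use_bmal = FALSE, use_db_plus = FALSE),
    bmal = list(use_cae = FALSE, use_bmal = TRUE, use_db_plus = FALSE),
    cae_bmal = list(use_cae = TRUE, use_bmal = TRUE, use_db_plus = FALSE),
    full = list(use_cae = TRUE, use_bmal = TRUE, use_db_plus = TRUE),
    stop("unknown ablation config '", name, "'", call. = FALSE)
  )
}

#' Run the desk-scale domain-adaptation experiment
#'
#' For each seed: generates a labeled synthetic source domain, an unlabeled
#' shifted target domain and a held-out target test set; pretrains one
#' autoencoder on the source images; trains the segmentation network under
#' each requested ablation configuration; and evaluates disc/cup Dice and
#' the CDR error on the target test set.
#'
#' The segmentation learning rate defaults to `1e-3` here (standard Adam
#' magnitude for training small networks from random initialization); all
#' other optimization settings follow [train_config()].
#'
#' @param n_source,n_target training images per domain.
#' @param n_test held-out target test images.
#' @param image_size image side in pixels (multiple of 16).
#' @param epochs training epochs per run.
#' @param seeds integer vector of experiment seeds.
#' @param configs subset of `baseline`, `cae`, `bmal`, `cae_bmal`, `full`.
#' @param seg_lr segmentation learning rate.
#' @param cae_epochs autoencoder pretraining epochs.
#' @param verbose print per-run progress.
#' @return data frame with one row per (config, seed): mean target-test
#'   `dsc_disc`, `dsc_cup`, `delta`.
#' @export
run_adaptation_experiment <- function(n_source = 40L, n_target = 40L,
                                      n_test = 20L, image_size = 128L,
                                      epochs = 30L, seeds = 1:3,
                                      configs = c("baseline", "cae",
                                                  "cae_bmal", "full"),
                                      seg_lr = 1e-3, cae_epochs = 15L,
                                      verbose = FALSE) {
  rows <- list()
  for (seed in seeds) {
    src <- generate_domain(domain_spec(n_source, seed = derive_seed(seed, "src"),
                                       image_size = image_size))
    tgt <- generate_domain(domain_spec(n_target, shift = target_shift(),
                                       seed = derive_seed(seed, "tgt"),
                                       image_size = image_size))
    tst <- generate_domain(domain_spec(n_test, shift = target_shift(),
                                       seed = derive_seed(seed, "tst"),
                                       image_size = image_size))
    cae <- build_cae(seed = derive_seed(seed, "cae-init"))
    cae <- pretrain_cae(cae, lapply(src, `[[`, "image"),
                        epochs = cae_epochs,
                        seed = derive_seed(seed, "cae-pre"))$cae
    for (cfg_name in configs) {
      tg <- ablation_toggles(cfg_name)
      cfg <- train_config(seg_lr = seg_lr, epochs = epochs, seed = seed,
                          use_cae = tg$use_cae, use_bmal = tg$use_bmal,
                          use_db_plus = tg$use_db_plus)
      fit <- train_segmentation(cfg, src, target = tgt,
                                cae = if (tg$use_cae) cae else NULL)
      preds <- predict_masks(fit$checkpoint$segnet,
                             lapply(tst, `[[`, "image"))
      ev <- evaluate_predictions(lapply(preds, `[[`, "mask"),
                                 lapply(tst, `[[`, "mask"))
      s <- ev$summary
      row <- data.frame(config = cfg_name, seed = seed,
                        dsc_disc = s$mean[s$metric == "dsc_disc"],
                        dsc_cup = s$mean[s$metric == "dsc_cup"],
                        delta = s$mean[s$metric == "delta"])
      if (verbose) {
        message(sprintf("seed %d %-9s dsc_disc %.3f dsc_cup %.3f delta %.3f",
                        seed, cfg_name, row$dsc_disc, row$dsc_cup,
                        row$delta))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
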