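# Reproducible desk-scale studies: a full train-and-score benchmark on
# synthetic phantoms, and the paired coordinate-channel codec ablation.
# These are the package's own scaled-down analogues of whole-body
# experiments: 32^3 grids, downsampling factor 4, a 64-code codebook and a
# 4-layer sequence model, sized so each study runs on one CPU in minutes.

#' Desk-scale end-to-end anomaly-detection study
#'
#' Generates a healthy training corpus with mixed voxel-size presets, trains
#' the primary and auxiliary codecs and two sequence models (with and
#' without spatial-token conditioning, identical seeds), then scores
#' lesioned test phantoms across full-FOV, cropped and rotated variants and
#' evaluates best-DICE/AUPRC per case.
#'
#' The KDE bandwidth floor defaults to the phantom acquisition-noise scale
#' (0.02): a floor below the noise SD makes the negative-log-density score
#' diverge on plain measurement noise.
#'
#' @param seed global seed; every stage derives its own.
#' @param n_train healthy training phantoms.
#' @param n_test lesioned test phantoms (variants cycle full-coarse,
#'   cropped, full-fine, rotated).
#' @param codec_steps,aux_steps,seq_steps training lengths.
#' @param S,Ddec healed samples and dropout decodings per case.
#' @param bw_floor KDE bandwidth floor on the intensity scale.
#' @param crops_per_volume random crops per volume when tokenizing.
#' @param verbose print stage progress.
#' @return list with `cases` (per-case data.frame: variant, lesion/background
#'   median scores, AUPRC, best-DICE, prevalence), `psnr_holdout`,
#'   `auprc_cropped_spatial`, `auprc_cropped_nospatial`, `nll_trace_spatial`,
#'   `nll_trace_nospatial`, `ensemble_n` and the trained models.
#' @export
desk_study <- function(seed = 1L, n_train = 64L, n_test = 8L,
                       codec_steps = 320L, aux_steps = 180L,
                       seq_steps = 400L, S = 6L, Ddec = 2L, bw_floor = 0.02,
                       crops_per_volume = 2L, verbose = TRUE) {
  log <- function(...) if (verbose) message(sprintf(...))
  shape <- c(32L, 32L, 32L)
  t0 <- Sys.time()

  train <- lapply(seq_len(n_train), function(i) {
    pre <- phantom_preset(if (i %% 2L == 0L) "fine" else "coarse", shape)
    generate_phantom(phantom_spec(shape = shape, spacing = pre$spacing,
                                  frame = pre$frame,
                                  seed = derive_seed(seed, paste0("train", i))))
  })
  holdout <- lapply(1:2, function(i) {
    pre <- phantom_preset(if (i %% 2L == 0L) "fine" else "coarse", shape)
    generate_phantom(phantom_spec(shape = shape, spacing = pre$spacing,
                                  frame = pre$frame,
                                  seed = derive_seed(seed, paste0("hold", i))))
  })
  variants <- rep(c("full_coarse", "cropped", "full_fine", "rotated",
                    "cropped", "full_coarse", "cropped", "rotated"),
                  length.out = n_test)
  tests <- lapply(seq_len(n_test), function(i) {
    variant <- variants[i]
    cseed <- derive_seed(seed, paste0("test", i))
    pre <- phantom_preset(if (variant %in% c("full_fine", "rotated")) "fine"
                          else "coarse", shape)
    ph <- generate_phantom(phantom_spec(shape = shape, spacing = pre$spacing,
                                        frame = pre$frame, n_lesions = 2L,
                                        lesion_radius_vox = c(2, 3.5),
                                        seed = cseed))
    mask <- ph$lesion_mask
    if (variant == "cropped") {
      cb <- with_seed(derive_seed(cseed, "box"),
                      lesion_crop_box(mask, c(24L, 28L), shape))
      ph$primary <- crop_volume(ph$primary, cb)
      ph$auxiliary <- crop_volume(ph$auxiliary, cb)
      mask <- mask[(cb[1, 1] + 1L):cb[1, 2], (cb[2, 1] + 1L):cb[2, 2],
                   (cb[3, 1] + 1L):cb[3, 2], drop = FALSE]
    } else if (variant == "rotated") {
      syms <- axis_symmetries(proper_only = TRUE)
      syms <- Filter(function(s) !(identical(s$perm, 1:3) && !any(s$flip)), syms)
      sym <- with_seed(derive_seed(cseed, "rot"),
                       syms[[sample.int(length(syms), 1L)]])
      ph$primary <- rotate_frame(ph$primary, sym)
      ph$auxiliary <- rotate_frame(ph$auxiliary, sym)
      mask <- apply_symmetry(mask, sym)
    }
    list(id = sprintf("test_%02d", i), variant = variant,
         primary = ph$primary, auxiliary = ph$auxiliary, mask = mask)
  })
  log("[study] corpus ready (%.1f s)", as.numeric(Sys.time() - t0, units = "secs"))

  codec <- train_codec(codec_init(codec_config(), derive_seed(seed, "codec_init")),
                       lapply(train, `[[`, "primary"), steps = codec_steps,
                       seed = derive_seed(seed, "codec_train"))
  auxc <- train_codec(codec_init(codec_config(n_z = 16L, width = 24L),
                                 derive_seed(seed, "aux_init")),
                      lapply(train, `[[`, "auxiliary"), steps = aux_steps,
                      seed = derive_seed(seed, "aux_train"))
  psnr_holdout <- mean(vapply(holdout, function(ph)
    psnr(ph$primary$data, codec_reconstruct(codec, ph$primary)$data),
    numeric(1)))
  log("[study] codecs trained; holdout PSNR %.1f dB (%.1f min)",
      psnr_holdout, as.numeric(Sys.time() - t0, units = "mins"))

  cases_tok <- lapply(train, function(ph)
    list(primary = ph$primary, auxiliary = ph$auxiliary))
  ds <- tokenize_corpus(cases_tok, codec, auxc,
                        crops_per_volume = crops_per_volume,
                        seed = derive_seed(seed, "tokenize"))
  mk_model <- function(use_spatial) {
    train_seqmodel(seq_init(seq_config(K = codec$cfg$K, K_aux = auxc$cfg$K,
                                       use_spatial = use_spatial),
                            derive_seed(seed, "seq_init")),
                   ds, steps = seq_steps, seed = derive_seed(seed, "seq_train"))
  }
  model_sp <- mk_model(TRUE)
  log("[study] spatial model trained, final NLL %.3f (%.1f min)",
      mean(utils::tail(attr(model_sp, "nll_trace"), 25)),
      as.numeric(Sys.time() - t0, units = "mins"))
  model_ns <- mk_model(FALSE)
  log("[study] unconditioned-spatial model trained, final NLL %.3f (%.1f min)",
      mean(utils::tail(attr(model_ns, "nll_trace"), 25)),
      as.numeric(Sys.time() - t0, units = "mins"))

  acfg <- anomaly_config(S = S, Ddec = Ddec, bw_floor = bw_floor)
  score_case <- function(cs, model) {
    sc <- score_volume(cs$primary, cs$auxiliary, codec, auxc, model, acfg,
                       seed = derive_seed(seed, paste0("score_", cs$id)))
    les <- cs$mask > 0
    list(auprc = auprc(sc$score, cs$mask),
         dice = best_dice(sc$score, cs$mask)$dice,
         med_lesion = stats::median(sc$score[les]),
         med_background = stats::median(sc$score[!les]),
         prevalence = mean(les), n = sc$n, flagged = sum(sc$mask))
  }
  rows <- lapply(tests, function(cs) {
    r <- score_case(cs, model_sp)
    data.frame(id = cs$id, variant = cs$variant, prevalence = r$prevalence,
               med_lesion = r$med_lesion, med_background = r$med_background,
               auprc = r$auprc, best_dice = r$dice, flagged = r$flagged,
               stringsAsFactors = FALSE)
  })
  cases <- do.call(rbind, rows)
  log("[study] scored %d cases with spatial conditioning (%.1f min)",
      nrow(cases), as.numeric(Sys.time() - t0, units = "mins"))
  cropped <- Filter(function(cs) cs$variant == "cropped", tests)
  auprc_ns <- vapply(cropped, function(cs) score_case(cs, model_ns)$auprc,
                     numeric(1))
  out <- list(cases = cases, psnr_holdout = psnr_holdout,
              auprc_cropped_spatial = cases$auprc[cases$variant == "cropped"],
              auprc_cropped_nospatial = auprc_ns,
              nll_trace_spatial = attr(model_sp, "nll_trace"),
              nll_trace_nospatial = attr(model_ns, "nll_trace"),
              ensemble_n = S * Ddec,
              runtime_min = as.numeric(Sys.time() - t0, units = "mins"),
              codec = codec, aux_codec = auxc,
              model_spatial = model_sp, model_nospatial = model_ns)
  log("[study] done in %.1f min", out$runtime_min)
  out
}

#' Paired coordinate-channel codec ablation on mixed geometries
#'
#' Trains two codecs that differ only in whether CoordConv channels are
#' injected (identical initialization and data-order seeds) on a
#' mixed-resolution healthy corpus, and compares held-out reconstruction
#' error.
#'
#' @param seed global seed.
#' @param n_train,n_holdout corpus sizes (both mix the coarse and fine
#'   presets).
#' @param steps training steps per codec.
#' @return list with per-volume `mae_with` / `mae_without`, their means,
#'   and mean PSNRs.
#' @export
coord_ablation_study <- function(seed = 1L, n_train = 16L, n_holdout = 6L,
                                 steps = 300L) {
  shape <- c(32L, 32L, 32L)
  gen <- function(tag, i) {
    pre <- phantom_preset(if (i %% 2L == 0L) "fine" else "coarse", shape)
    generate_phantom(phantom_spec(shape = shape, spacing = pre$spacing,
                                  frame = pre$frame,
                                  seed = derive_seed(seed, paste0(tag, i))))$primary
  }
  corp <- lapply(seq_len(n_train), gen, tag = "abl_tr")
  hold <- lapply(seq_len(n_holdout), gen, tag = "abl_ho")
  fit <- function(use_coords) {
    train_codec(codec_init(codec_config(use_coords = use_coords),
                           derive_seed(seed, "abl_init")),
                corp, steps = steps, seed = derive_seed(seed, "abl_train"))
  }
  c_with <- fit(TRUE)
  c_without <- fit(FALSE)
  mae <- function(codec) vapply(hold, function(v)
    mean(abs(codec_reconstruct(codec, v)$data - v$data)), numeric(1))
  mw <- mae(c_with); mo <- mae(c_without)
  list(mae_with = mw, mae_without = mo,
       mean_mae_with = mean(mw), mean_mae_without = mean(mo),
       psnr_with = mean(vapply(hold, function(v)
         psnr(v$data, codec_reconstruct(c_with, v)$data), numeric(1))),
       psnr_without = mean(vapply(hold, function(v)
         psnr(v$data, codec_reconstruct(c_without, v)$data), numeric(1))))
}
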