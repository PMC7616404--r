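# Orchestration: a single config drives corpus generation, codec training,
# sequence-model training, anomaly scoring and evaluation, with derived
# seeds per stage and artifact-based stage skipping.

.config_schema <- list(
  paths = c("root"),
  seed = NULL, verbose = NULL,
  corpus = c("n_cases", "shape", "n_lesions", "lesion_radius_vox", "lesion_contrast",
             "noise_sd", "crop_sizes"),
  codec = c("K", "n_z", "width", "n_down", "n_res", "steps", "lr",
            "crop_sizes", "aux_n_z", "aux_width", "aux_steps"),
  seqmodel = c("n_layers", "n_heads", "d", "steps", "lr", "B",
               "use_spatial", "use_aux", "max_len", "crops_per_volume"),
  anomaly = c("t", "S", "Ddec"))

#' Build a run configuration
#'
#' @param root working directory for all artifacts (corpus/, ckpt/, out/).
#' @param seed global seed; every stage derives its own via [derive_seed()].
#' @param corpus,codec,seqmodel,anomaly per-stage option lists (see
#'   `vqheal:::.config_schema` for the recognized fields).
#' @param verbose logical.
#' @return a validated `run_config`.
#' @export
run_config <- function(root, seed = 1L, corpus = list(), codec = list(),
                       seqmodel = list(), anomaly = list(), verbose = TRUE) {
  cfg <- list(paths = list(root = root), seed = as.integer(seed),
              verbose = isTRUE(verbose),
              corpus = utils::modifyList(
                list(n_cases = 16L, shape = c(32L, 32L, 32L), n_lesions = 1L,
                     lesion_radius_vox = c(2, 4), lesion_contrast = 2.5,
                     noise_sd = 0.02, crop_sizes = c(20L, 24L)), corpus),
              codec = utils::modifyList(
                list(K = 64L, n_z = 32L, width = 32L, n_down = 2L, n_res = 1L,
                     steps = 200L, lr = 2e-3, crop_sizes = c(16L, 20L, 24L, 28L),
                     aux_n_z = 16L, aux_width = 24L, aux_steps = 150L), codec),
              seqmodel = utils::modifyList(
                list(n_layers = 4L, n_heads = 4L, d = 64L, steps = 200L,
                     lr = 3e-3, B = 20L, use_spatial = TRUE, use_aux = TRUE,
                     max_len = 560L, crops_per_volume = 2L), seqmodel),
              anomaly = utils::modifyList(
                list(S = 4L, Ddec = 2L), anomaly))
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  for (sec in names(cfg)) {
    if (!sec %in% names(.config_schema))
      stop("unknown config section: '", sec, "'")
    allowed <- .config_schema[[sec]]
    if (!is.null(allowed) && is.list(cfg[[sec]]) && sec != "paths")
      for (fld in names(cfg[[sec]]))
        if (!fld %in% allowed)
          stop("unknown config field: '", sec, ".", fld, "'")
  }
  invisible(TRUE)
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @param cfg a `run_config`.
#' @return `read_run_config` returns the `run_config` (round-trips
#'   losslessly); `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, c(list(root = y$paths$root, seed = y$seed %||% 1L,
                             verbose = y$verbose %||% TRUE),
                        y[intersect(names(y), c("corpus", "codec", "seqmodel",
                                                "anomaly"))]))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

stage_paths <- function(cfg) {
  root <- cfg$paths$root
  list(corpus = file.path(root, "corpus"),
       manifest = file.path(root, "corpus", "manifest.csv"),
       codec = file.path(root, "ckpt", "codec.rds"),
       aux_codec = file.path(root, "ckpt", "codec_aux.rds"),
       seqmodel = file.path(root, "ckpt", "seqmodel.rds"),
       maps = file.path(root, "out", "maps"),
       eval_csv = file.path(root, "out", "evaluation.csv"))
}

#' Run the pipeline
#'
#' Stages: `phantoms` (corpus generation), `codec` (primary + auxiliary
#' VQ-VAE training), `seqmodel` (transformer training), `score` (anomaly
#' maps for the test split) and `eval` (metrics CSV). A completed stage
#' whose artifacts exist is skipped unless `force = TRUE`; a missing
#' dependency raises an error naming the stage to run first.
#'
#' @param cfg a [run_config()].
#' @param stages subset of `c("phantoms","codec","seqmodel","score","eval")`.
#' @param force re-run stages whose artifacts already exist.
#' @return run report: per-stage status plus headline metrics.
#' @export
run_pipeline <- function(cfg, stages = c("phantoms", "codec", "seqmodel",
                                         "score", "eval"), force = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  sp <- stage_paths(cfg)
  log <- function(...) if (cfg$verbose) message(sprintf(...))
  report <- list()
  if ("phantoms" %in% stages) {
    if (file.exists(sp$manifest) && !force) {
      log("[phantoms] corpus exists, skipping"); report$phantoms <- "skipped"
    } else {
      tpl <- phantom_spec(shape = cfg$corpus$shape,
                          n_lesions = cfg$corpus$n_lesions,
                          lesion_radius_vox = cfg$corpus$lesion_radius_vox,
                          lesion_contrast = cfg$corpus$lesion_contrast,
                          noise_sd = cfg$corpus$noise_sd)
      make_corpus(cfg$corpus$n_cases, tpl, corpus_aug(cfg$corpus$crop_sizes),
                  seed = derive_seed(cfg$seed, "corpus"), dir = sp$corpus)
      log("[phantoms] wrote corpus (%d cases) to %s", cfg$corpus$n_cases, sp$corpus)
      report$phantoms <- "done"
    }
  }
  load_split <- function(split) {
    if (!file.exists(sp$manifest))
      stop("corpus not found; run the 'phantoms' stage first")
    mf <- utils::read.csv(sp$manifest, stringsAsFactors = FALSE)
    mf <- mf[mf$split == split, , drop = FALSE]
    lapply(seq_len(nrow(mf)), function(i) {
      list(id = mf$id[i], variant = mf$variant[i],
           primary = read_volume(mf$primary_path[i], "primary"),
           auxiliary = read_volume(mf$aux_path[i], "auxiliary"),
           mask = read_volume(mf$mask_path[i])$data)
    })
  }
  if ("codec" %in% stages) {
    if (file.exists(sp$codec) && !force) {
      log("[codec] checkpoint exists, skipping"); report$codec <- "skipped"
    } else {
      train <- load_split("train")
      dir.create(dirname(sp$codec), recursive = TRUE, showWarnings = FALSE)
      cc <- cfg$codec
      codec <- codec_init(codec_config(K = cc$K, n_z = cc$n_z, width = cc$width,
                                       n_down = cc$n_down, n_res = cc$n_res),
                          seed = derive_seed(cfg$seed, "codec_init"))
      codec <- train_codec(codec, lapply(train, `[[`, "primary"),
                           steps = cc$steps, lr = cc$lr,
                           crop_sizes = cc$crop_sizes,
                           seed = derive_seed(cfg$seed, "codec_train"),
                           verbose = cfg$verbose)
      save_codec(codec, sp$codec)
      auxc <- codec_init(codec_config(K = cc$K, n_z = cc$aux_n_z,
                                      width = cc$aux_width, n_down = cc$n_down,
                                      n_res = cc$n_res),
                         seed = derive_seed(cfg$seed, "aux_init"))
      auxc <- train_codec(auxc, lapply(train, `[[`, "auxiliary"),
                          steps = cc$aux_steps, lr = cc$lr,
                          crop_sizes = cc$crop_sizes,
                          seed = derive_seed(cfg$seed, "aux_train"),
                          verbose = cfg$verbose)
      save_codec(auxc, sp$aux_codec)
      log("[codec] trained primary (final loss %.4f) and auxiliary codecs",
          utils::tail(attr(codec, "loss_trace"), 1))
      report$codec <- "done"
    }
  }
  if ("seqmodel" %in% stages) {
    if (file.exists(sp$seqmodel) && !force) {
      log("[seqmodel] checkpoint exists, skipping"); report$seqmodel <- "skipped"
    } else {
      if (!file.exists(sp$codec))
        stop("codec checkpoint not found; run the 'codec' stage first")
      codec <- load_codec(sp$codec); auxc <- load_codec(sp$aux_codec)
      train <- load_split("train")
      sm <- cfg$seqmodel
      ds <- tokenize_corpus(train, codec, auxc, B = sm$B,
                            crops_per_volume = sm$crops_per_volume,
                            crop_sizes = cfg$codec$crop_sizes,
                            seed = derive_seed(cfg$seed, "tokenize"))
      model <- seq_init(seq_config(K = codec$cfg$K, K_aux = auxc$cfg$K,
                                   B = sm$B, n_layers = sm$n_layers,
                                   n_heads = sm$n_heads, d = sm$d,
                                   max_len = sm$max_len,
                                   use_aux = sm$use_aux,
                                   use_spatial = sm$use_spatial),
                        seed = derive_seed(cfg$seed, "seq_init"))
      model <- train_seqmodel(model, ds, steps = sm$steps, lr = sm$lr,
                              seed = derive_seed(cfg$seed, "seq_train"),
                              verbose = cfg$verbose)
      save_seqmodel(model, sp$seqmodel)
      tr <- attr(model, "nll_trace")
      log("[seqmodel] trained: nll %.3f -> %.3f", tr[1], utils::tail(tr, 1))
      report$seqmodel <- "done"
    }
  }
  if ("score" %in% stages) {
    if (!file.exists(sp$seqmodel))
      stop("sequence-model checkpoint not found; run the 'seqmodel' stage first")
    codec <- load_codec(sp$codec); auxc <- load_codec(sp$aux_codec)
    model <- load_seqmodel(sp$seqmodel)
    test <- load_split("test")
    dir.create(sp$maps, recursive = TRUE, showWarnings = FALSE)
    acfg <- anomaly_config(t = cfg$anomaly$t, S = cfg$anomaly$S,
                           Ddec = cfg$anomaly$Ddec)
    for (cs in test) {
      out <- file.path(sp$maps, paste0(cs$id, "_score.nii"))
      if (file.exists(out) && !force) next
      sc <- score_volume(cs$primary, cs$auxiliary, codec, auxc, model,
                         acfg, seed = derive_seed(cfg$seed, paste0("score_", cs$id)))
      write_volume(volume(sc$score, cs$primary$spacing, cs$primary$frame), out)
      jsonlite::write_json(list(id = cs$id, t = sc$t, S = acfg$S,
                                Ddec = acfg$Ddec, n_recon = sc$n,
                                n_flagged = sum(sc$mask),
                                seed = cfg$seed),
                           file.path(sp$maps, paste0(cs$id, "_report.json")),
                           auto_unbox = TRUE)
      log("[score] %s: %d/%d tokens flagged", cs$id, sum(sc$mask),
          length(sc$mask))
    }
    report$score <- "done"
  }
  if ("eval" %in% stages) {
    test <- load_split("test")
    ev_cases <- list()
    for (cs in test) {
      mp <- file.path(sp$maps, paste0(cs$id, "_score.nii"))
      if (!file.exists(mp))
        stop("score map for ", cs$id, " not found; run the 'score' stage first")
      ev_cases[[cs$id]] <- list(score = read_volume(mp)$data, truth = cs$mask)
    }
    dir.create(dirname(sp$eval_csv), recursive = TRUE, showWarnings = FALSE)
    df <- evaluate_corpus(ev_cases, csv = sp$eval_csv)
    log("[eval] mean best-DICE %.3f, mean AUPRC %.3f",
        attr(df, "mean_dice"), attr(df, "mean_auprc"))
    report$eval <- list(mean_dice = attr(df, "mean_dice"),
                        mean_auprc = attr(df, "mean_auprc"),
                        csv = sp$eval_csv)
  }
  report
}

#' Tokenize a corpus for sequence-model training
#'
#' For each volume, emits the full-FOV token sequence plus `crops_per_volume`
#' random cube crops (varying FOV -> varying sequence lengths), each with its
#' auxiliary-token and spatial-token conditioning.
#'
#' @param cases list of corpus cases (`primary`, `auxiliary` volumes).
#' @param codec,aux_codec trained codecs.
#' @param B spatial bin count.
#' @param crops_per_volume random crops added per volume.
#' @param crop_sizes candidate cube sizes.
#' @param seed RNG seed.
#' @return list of `list(s=, cond=)` training examples.
#' @export
tokenize_corpus <- function(cases, codec, aux_codec, B = 20L,
                            crops_per_volume = 2L,
                            crop_sizes = c(16L, 20L, 24L, 28L), seed = 1L) {
  ds <- list()
  with_seed(seed, {
    for (cs in cases) {
      vols <- list(list(p = cs$primary, a = cs$auxiliary))
      d <- dim(cs$primary$data)
      sizes <- crop_sizes[crop_sizes <= min(d)]
      for (k in seq_len(crops_per_volume)) {
        if (!length(sizes)) break
        sz <- sizes[sample.int(length(sizes), 1L)]
        st <- vapply(d, function(n) sample.int(n - sz + 1L, 1L) - 1L, integer(1))
        cb <- cbind(st, st + sz)
        vols[[length(vols) + 1L]] <- list(p = crop_volume(cs$primary, cb),
                                          a = crop_volume(cs$auxiliary, cb))
      }
      for (v in vols) {
        ds[[length(ds) + 1L]] <- tokenize_example(v$p, v$a, codec, aux_codec, B)
      }
    }
  })
  ds
}

tokenize_example <- function(pvol, avol, codec, aux_codec, B = 20L) {
  enc <- codec_encode_volume(codec, pvol)
  s <- raster_flatten(enc$idx)
  aux <- if (!is.null(avol) && !is.null(aux_codec))
    raster_flatten(codec_encode_volume(aux_codec, avol)$idx) else NULL
  spg <- quantize_spatial_tokens(pool_coords_to_latent(enc$channels, codec$cfg$F), B)
  sp <- raster_flatten(spg$sp)
  list(s = s, cond = conditioning(aux = aux, sp = sp, length_hint = length(sp)))
}
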