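# Inference-side anomaly scorer: flag low-likelihood latent tokens, resample
# "healed" token sequences from the autoregressive model, decode a dropout
# ensemble of reconstructions, and turn the ensemble into a per-voxel
# kernel-density anomaly map scored at the observed intensity.

#' Anomaly-scoring configuration
#'
#' @param t resampling threshold in `(0, 1]`: tokens with realized
#'   likelihood `p(s_i) < t` are flagged and resampled. The default `NULL`
#'   resolves to `1/K` (chance level) at scoring time; [sweep_threshold()]
#'   selects it from a validation set instead.
#' @param S healed token sequences sampled per case (default 60).
#' @param Ddec dropout decodings per healed sequence (default 5); the
#'   ensemble holds `N = S * Ddec` reconstructions (300 at the defaults).
#' @param bw_floor lower bound on the per-voxel KDE bandwidth, on the
#'   intensity scale.
#' @param eps density floor inside the `-log` score transform.
#' @param restrict_to_normal if `TRUE`, resampling renormalizes over tokens
#'   with `p >= t` only (off by default: draws use the full categorical).
#' @return an `anomaly_config` list.
#' @export
anomaly_config <- function(t = NULL, S = 60L, Ddec = 5L, bw_floor = 1e-3,
                           eps = 1e-12, restrict_to_normal = FALSE) {
  if (!is.null(t) && (t <= 0 || t > 1)) stop("threshold t must lie in (0, 1]")
  structure(list(t = t, S = as.integer(S), Ddec = as.integer(Ddec),
                 bw_floor = bw_floor, eps = eps,
                 restrict_to_normal = isTRUE(restrict_to_normal)),
            class = "anomaly_config")
}

#' Flag anomalous tokens by likelihood threshold
#' @param profile a [token_likelihoods()] result (or a numeric vector of
#'   realized likelihoods).
#' @param t threshold in `(0, 1]`; strict comparison `p < t`.
#' @return logical mask over positions.
#' @export
flag_anomalous_tokens <- function(profile, t) {
  if (t <= 0 || t > 1) stop("threshold t must lie in (0, 1]")
  p <- if (is.list(profile)) profile$p else profile
  p < t
}

#' Resample healed token sequences
#'
#' Proceeds through the sequence in raster order with a KV-cached
#' incremental pass. At each flagged position the token is redrawn from the
#' model's categorical distribution given the already-healed prefix and the
#' conditioning; unmasked positions are copied verbatim. The `S` draws are
#' independent under per-sample derived seeds.
#'
#' @param s observed token sequence (0-based).
#' @param mask logical vector flagging anomalous positions.
#' @param cond a [conditioning()] bundle.
#' @param model trained [seq_init()] model.
#' @param S number of healed sequences.
#' @param seed base seed; sample `j` uses `derive_seed(seed, paste0("heal", j))`.
#' @param cfg an [anomaly_config()] (for `restrict_to_normal` and `t`).
#' @return integer matrix `S x L` of healed sequences.
#' @export
resample_healed_sequences <- function(s, mask, cond, model, S = 60L, seed = 1L,
                                      cfg = anomaly_config()) {
  L <- length(s)
  stopifnot(length(mask) == L)
  healed <- matrix(rep(as.integer(s), each = S), nrow = S)
  if (!any(mask)) return(healed)
  K <- model$cfg$K
  for (j in seq_len(S)) {
    with_seed(derive_seed(seed, paste0("heal", j)), {
      st <- seq_infer_init(model, cond)
      hj <- as.integer(s)
      prev_id <- K + 1L                       # BOS
      for (i in seq_len(L)) {
        stp <- seq_infer_step(st, prev_id)
        st <- stp$state
        if (mask[i]) {
          pr <- stp$probs
          if (cfg$restrict_to_normal && !is.null(cfg$t)) {
            keep <- pr >= cfg$t
            if (any(keep)) pr <- pr * keep
          }
          hj[i] <- sample.int(K, 1L, prob = pr) - 1L
        }
        prev_id <- hj[i] + 1L
      }
      healed[j, ] <- hj
    })
  }
  healed
}

#' Decode a healed-sequence ensemble with decoder dropout
#'
#' Every healed sequence is decoded `Ddec` times with dropout active under
#' distinct derived sub-seeds, yielding `N = S * Ddec` reconstructions
#' shaped exactly like the source volume.
#'
#' @param healed integer matrix `S x L` from [resample_healed_sequences()].
#' @param lat_coords latent-resolution coordinate matrix.
#' @param lat_shape integer(3) latent shape.
#' @param codec trained codec.
#' @param out_shape unpadded output shape.
#' @param Ddec dropout decodings per sequence (>= 1); with `Ddec = 1` and
#'   `dropout = FALSE` the decode is deterministic.
#' @param seed base seed for dropout masks.
#' @param dropout enable decoder dropout.
#' @return list with `recons` (matrix `N x prod(out_shape)`) and `n`.
#' @export
decode_ensemble <- function(healed, lat_coords, lat_shape, codec, out_shape,
                            Ddec = 5L, seed = 1L, dropout = TRUE) {
  S <- nrow(healed)
  n_vox <- prod(out_shape)
  recons <- matrix(0, S * Ddec, n_vox)
  r <- 0L
  for (j in seq_len(S)) {
    grid <- raster_unflatten(healed[j, ], lat_shape)
    for (dd in seq_len(Ddec)) {
      r <- r + 1L
      xr <- codec_decode(codec, idx = grid, lat_coords = lat_coords,
                         lat_shape = lat_shape, out_shape = out_shape,
                         dropout = dropout,
                         seed = derive_seed(seed, paste0("dec", j, "_", dd)))
      recons[r, ] <- as.numeric(xr)
    }
  }
  list(recons = recons, n = S * Ddec)
}

#' Voxel-wise KDE anomaly map
#'
#' Fits a Gaussian KDE independently at every voxel across the ensemble of
#' healed reconstructions and evaluates the density at the observed
#' intensity. Bandwidth per voxel follows Scott's rule
#' `h = sd * N^(-1/5)` with a floor; the anomaly score is `-log(f + eps)`
#' so that low density (an intensity the healed distribution cannot
#' explain) maps to a high score.
#'
#' @param observed 3D array (or vector) of observed intensities.
#' @param ensemble a [decode_ensemble()] result (or an `N x V` matrix).
#' @param config an [anomaly_config()].
#' @return list with arrays `density` and `score` shaped like `observed`,
#'   plus the per-voxel `bandwidth`.
#' @export
kde_score_map <- function(observed, ensemble, config = anomaly_config()) {
  E <- if (is.list(ensemble)) ensemble$recons else ensemble
  obs <- as.numeric(observed)
  if (ncol(E) != length(obs)) stop("ensemble / observed shape mismatch")
  N <- nrow(E)
  mu <- colMeans(E)
  sd_v <- sqrt(pmax(colMeans(E * E) - mu^2, 0) * N / max(N - 1, 1))
  h <- pmax(sd_v * N^(-1/5), config$bw_floor)
  zs <- sweep(E, 2, obs, `-`)
  zs <- sweep(zs, 2, h, `/`)
  dens <- colMeans(stats::dnorm(zs))
  dens <- dens / h
  score <- -log(dens + config$eps)
  shp <- if (!is.null(dim(observed))) dim(observed) else length(obs)
  list(density = array(dens, shp), score = array(score, shp),
       bandwidth = array(h, shp))
}

#' Score a volume end-to-end
#'
#' Encodes the volume, computes token likelihoods under the sequence model,
#' flags tokens below the threshold, resamples healed sequences, decodes a
#' dropout ensemble and returns the voxel-wise KDE anomaly map.
#'
#' @param vol primary-modality [volume()].
#' @param aux_vol co-registered auxiliary volume (or `NULL` for empty
#'   auxiliary conditioning).
#' @param codec,aux_codec trained codecs for the two modalities.
#' @param model trained sequence model.
#' @param config an [anomaly_config()]; a `NULL` threshold resolves to
#'   `1/K`.
#' @param seed seed driving resampling and dropout.
#' @return list: `score` and `density` arrays, the token `mask`, the
#'   likelihood `profile`, ensemble size `n` and the threshold `t` used.
#' @export
score_volume <- function(vol, aux_vol, codec, aux_codec, model,
                         config = anomaly_config(), seed = 1L) {
  enc <- codec_encode_volume(codec, vol)
  s <- raster_flatten(enc$idx)
  aux_tok <- NULL
  if (!is.null(aux_vol) && !is.null(aux_codec)) {
    enca <- codec_encode_volume(aux_codec, aux_vol)
    aux_tok <- raster_flatten(enca$idx)
  }
  spg <- quantize_spatial_tokens(
    pool_coords_to_latent(enc$channels, codec$cfg$F), model$cfg$B)
  sp_tok <- raster_flatten(spg$sp)
  cond <- conditioning(aux = aux_tok, sp = sp_tok,
                       length_hint = length(sp_tok))
  profile <- token_likelihoods(s, cond, model)
  t_use <- config$t %||% (1 / model$cfg$K)
  mask <- flag_anomalous_tokens(profile, t_use)
  healed <- resample_healed_sequences(s, mask, cond, model, S = config$S,
                                      seed = derive_seed(seed, "resample"),
                                      cfg = config)
  ens <- decode_ensemble(healed, enc$lat_coords, enc$lat_shape, codec,
                         out_shape = dim(vol$data), Ddec = config$Ddec,
                         seed = derive_seed(seed, "dropout"))
  km <- kde_score_map(vol$data, ens, config)
  list(score = km$score, density = km$density, mask = mask,
       profile = profile, n = ens$n, t = t_use, healed = healed)
}

#' Select the resampling threshold on a validation set
#'
#' Sweeps a log-spaced grid of thresholds and returns the one maximizing
#' the mean best-achievable DICE of the resulting anomaly maps.
#'
#' @param cases list of validation cases, each
#'   `list(vol=, aux=, truth=)` with `truth` a binary lesion mask.
#' @param codec,aux_codec,model trained models.
#' @param grid thresholds to try (default log-spaced `1e-4 ... 0.5`).
#' @param config base [anomaly_config()].
#' @param seed scoring seed.
#' @return list with `t` (selected threshold) and the sweep table.
#' @export
sweep_threshold <- function(cases, codec, aux_codec, model,
                            grid = 10^seq(-4, log10(0.5), length.out = 8),
                            config = anomaly_config(), seed = 1L) {
  res <- data.frame(t = grid, mean_dice = NA_real_)
  for (gi in seq_along(grid)) {
    cfg_t <- config; cfg_t$t <- grid[gi]
    dices <- vapply(cases, function(cs) {
      sc <- score_volume(cs$vol, cs$aux, codec, aux_codec, model, cfg_t, seed)
      best_dice(sc$score, cs$truth)$dice
    }, numeric(1))
    res$mean_dice[gi] <- mean(dices, na.rm = TRUE)
  }
  list(t = res$t[which.max(res$mean_dice)], sweep = res)
}
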