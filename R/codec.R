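# Vector-quantized autoencoder over 3D volumes with CoordConv conditioning:
# coordinate channels are concatenated to the input image once, and again at
# the decoder's latent entry (pooled to latent resolution). Training uses the
# straight-through estimator with an EMA codebook and an L1 reconstruction
# objective plus a commitment term.

#' Codec configuration
#'
#' @param K codebook vocabulary size (paper scale 256; desk default 64).
#' @param n_z latent embedding dimension (paper 128 primary / 64 auxiliary).
#' @param width convolutional channel width (paper scale 128; desk 32).
#' @param n_down number of stride-2 downsampling layers; the downsampling
#'   factor is `F = 2^n_down` (paper scale 3 -> F=8; desk 2 -> F=4).
#' @param n_res residual blocks at the latent resolution.
#' @param dropout_p dropout probability before the last upsampling layer.
#' @param use_coords concatenate CoordConv channels (set `FALSE` for the
#'   channel-free ablation; input layout is unchanged, the channels are
#'   zeroed).
#' @param beta commitment-loss weight.
#' @param ema_decay EMA decay for codebook updates.
#' @return a `codec_config` list.
#' @export
codec_config <- function(K = 64L, n_z = 32L, width = 32L, n_down = 2L,
                         n_res = 1L, dropout_p = 0.05, use_coords = TRUE,
                         beta = 0.25, ema_decay = 0.99) {
  stopifnot(K >= 2L, n_z >= 1L, n_down >= 1L)
  structure(list(K = as.integer(K), n_z = as.integer(n_z),
                 width = as.integer(width), n_down = as.integer(n_down),
                 n_res = as.integer(n_res), dropout_p = dropout_p,
                 use_coords = isTRUE(use_coords), beta = beta,
                 ema_decay = ema_decay, F = as.integer(2^n_down)),
            class = "codec_config")
}

#' Initialize a codec (untrained)
#' @param cfg a [codec_config()].
#' @param seed integer seed for parameter initialization.
#' @return a `codec` object (parameters, codebook, intensity scale).
#' @export
codec_init <- function(cfg, seed = 1L) {
  with_seed(seed, {
    w <- cfg$width; nz <- cfg$n_z
    p <- list()
    cin <- 4L  # intensity + 3 coordinate channels
    for (l in seq_len(cfg$n_down)) {
      ci <- if (l == 1L) cin else w
      p[[paste0("enc_down", l, "_W")]] <- param_init(64L * ci, w)
      p[[paste0("enc_down", l, "_b")]] <- numeric(w)
    }
    for (r in seq_len(cfg$n_res)) {
      p[[paste0("enc_res", r, "_W1")]] <- param_init(27L * w, w)
      p[[paste0("enc_res", r, "_b1")]] <- numeric(w)
      p[[paste0("enc_res", r, "_W2")]] <- param_init(w, w)
      p[[paste0("enc_res", r, "_b2")]] <- numeric(w)
    }
    p[["enc_out_W"]] <- param_init(w, nz)
    p[["enc_out_b"]] <- numeric(nz)
    p[["dec_in_W"]] <- param_init(nz + 3L, w)
    p[["dec_in_b"]] <- numeric(w)
    for (r in seq_len(cfg$n_res)) {
      p[[paste0("dec_res", r, "_W1")]] <- param_init(27L * w, w)
      p[[paste0("dec_res", r, "_b1")]] <- numeric(w)
      p[[paste0("dec_res", r, "_W2")]] <- param_init(w, w)
      p[[paste0("dec_res", r, "_b2")]] <- numeric(w)
    }
    for (l in seq_len(cfg$n_down)) {
      co <- if (l == cfg$n_down) 1L else w
      p[[paste0("dec_up", l, "_W")]] <- param_init(64L * co, w)
      p[[paste0("dec_up", l, "_b")]] <- numeric(co)
    }
    codebook <- list(E = matrix(stats::rnorm(cfg$K * nz, sd = 0.3), cfg$K, nz),
                     cluster_size = rep(1e-2, cfg$K),
                     cluster_sum = matrix(0, cfg$K, nz))
    codebook$cluster_sum <- codebook$E * codebook$cluster_size
    structure(list(cfg = cfg, params = p, codebook = codebook,
                   norm = c(0, 1)), class = "codec")
  })
}

# ---- forward / backward ----------------------------------------------------

res_block_fwd <- function(x, shape, p, prefix) {
  c1 <- conv3d_fwd(x, shape, p[[paste0(prefix, "_W1")]], p[[paste0(prefix, "_b1")]],
                   k = 3L, stride = 1L, pad = 1L)
  r1 <- relu_fwd(c1$y)
  h2 <- sweep(r1$y %*% p[[paste0(prefix, "_W2")]], 2, p[[paste0(prefix, "_b2")]], `+`)
  r2 <- relu_fwd(h2)
  list(y = x + r2$y, c1 = c1, r1 = r1, r2 = r2)
}

res_block_bwd <- function(dy, cache, p, prefix) {
  dr2 <- relu_bwd(dy, cache$r2)
  dW2 <- crossprod(cache$r1$y, dr2)
  db2 <- colSums(dr2)
  dr1 <- relu_bwd(dr2 %*% t(p[[paste0(prefix, "_W2")]]), cache$r1)
  cb <- conv3d_bwd(dr1, cache$c1, p[[paste0(prefix, "_W1")]])
  grads <- stats::setNames(list(cb$dW, cb$db, dW2, db2),
                           paste0(prefix, c("_W1", "_b1", "_W2", "_b2")))
  list(dx = dy + cb$dx, grads = grads)
}

encoder_fwd <- function(codec, x, in_shape) {
  cfg <- codec$cfg; p <- codec$params
  caches <- list(); shape <- in_shape
  h <- x
  for (l in seq_len(cfg$n_down)) {
    cv <- conv3d_fwd(h, shape, p[[paste0("enc_down", l, "_W")]],
                     p[[paste0("enc_down", l, "_b")]], k = 4L, stride = 2L, pad = 1L)
    rl <- relu_fwd(cv$y)
    caches[[paste0("down", l)]] <- list(cv = cv, rl = rl)
    h <- rl$y; shape <- cv$plan$out_shape
  }
  for (r in seq_len(cfg$n_res)) {
    rb <- res_block_fwd(h, shape, p, paste0("enc_res", r))
    caches[[paste0("res", r)]] <- rb
    h <- rb$y
  }
  caches$pre_out <- h
  z <- sweep(h %*% p$enc_out_W, 2, p$enc_out_b, `+`)
  list(z = z, lat_shape = shape, caches = caches)
}

encoder_bwd <- function(codec, dz, fw) {
  cfg <- codec$cfg; p <- codec$params
  grads <- list()
  grads$enc_out_W <- crossprod(fw$caches$pre_out, dz)
  grads$enc_out_b <- colSums(dz)
  dh <- dz %*% t(p$enc_out_W)
  for (r in rev(seq_len(cfg$n_res))) {
    rb <- res_block_bwd(dh, fw$caches[[paste0("res", r)]], p, paste0("enc_res", r))
    grads <- c(grads, rb$grads)
    dh <- rb$dx
  }
  for (l in rev(seq_len(cfg$n_down))) {
    cc <- fw$caches[[paste0("down", l)]]
    dcv <- relu_bwd(dh, cc$rl)
    cb <- conv3d_bwd(dcv, cc$cv, p[[paste0("enc_down", l, "_W")]])
    grads[[paste0("enc_down", l, "_W")]] <- cb$dW
    grads[[paste0("enc_down", l, "_b")]] <- cb$db
    dh <- cb$dx
  }
  grads
}

decoder_fwd <- function(codec, zq, lat_coords_mat, lat_shape, dropout_active = FALSE) {
  cfg <- codec$cfg; p <- codec$params
  caches <- list(lat_shape = lat_shape)
  h <- cbind(zq, lat_coords_mat)
  caches$input <- h
  h <- sweep(h %*% p$dec_in_W, 2, p$dec_in_b, `+`)
  r0 <- relu_fwd(h); caches$r0 <- r0
  h <- r0$y
  shape <- lat_shape
  for (r in seq_len(cfg$n_res)) {
    rb <- res_block_fwd(h, shape, p, paste0("dec_res", r))
    caches[[paste0("res", r)]] <- rb
    h <- rb$y
  }
  for (l in seq_len(cfg$n_down)) {
    if (l == cfg$n_down) {
      dp <- dropout_fwd(h, cfg$dropout_p, dropout_active)
      caches$dropout <- dp
      h <- dp$y
    }
    out_shape <- shape * 2L
    ct <- convtrans3d_fwd(h, out_shape, p[[paste0("dec_up", l, "_W")]],
                          p[[paste0("dec_up", l, "_b")]], k = 4L, stride = 2L, pad = 1L)
    caches[[paste0("up", l)]] <- list(ct = ct)
    h <- ct$y; shape <- out_shape
    if (l < cfg$n_down) {
      rl <- relu_fwd(h)
      caches[[paste0("uprelu", l)]] <- rl
      h <- rl$y
    }
  }
  list(xhat = h, out_shape = shape, caches = caches)
}

decoder_bwd <- function(codec, dxhat, fw) {
  cfg <- codec$cfg; p <- codec$params
  grads <- list()
  dh <- dxhat
  for (l in rev(seq_len(cfg$n_down))) {
    if (l < cfg$n_down) dh <- relu_bwd(dh, fw$caches[[paste0("uprelu", l)]])
    cb <- convtrans3d_bwd(dh, fw$caches[[paste0("up", l)]]$ct,
                          p[[paste0("dec_up", l, "_W")]])
    grads[[paste0("dec_up", l, "_W")]] <- cb$dW
    grads[[paste0("dec_up", l, "_b")]] <- cb$db
    dh <- cb$dx
    if (l == cfg$n_down) dh <- dropout_bwd(dh, fw$caches$dropout)
  }
  for (r in rev(seq_len(cfg$n_res))) {
    rb <- res_block_bwd(dh, fw$caches[[paste0("res", r)]], p, paste0("dec_res", r))
    grads <- c(grads, rb$grads)
    dh <- rb$dx
  }
  dh <- relu_bwd(dh, fw$caches$r0)
  grads$dec_in_W <- crossprod(fw$caches$input, dh)
  grads$dec_in_b <- colSums(dh)
  din <- dh %*% t(p$dec_in_W)
  list(dzq = din[, seq_len(cfg$n_z), drop = FALSE], grads = grads)
}

# ---- quantization ----------------------------------------------------------

#' Nearest-codebook quantization
#'
#' Replaces each latent feature vector by the codebook vector minimizing
#' squared Euclidean distance; ties break toward the lowest index.
#'
#' @param z numeric matrix (positions x n_z) of continuous latents.
#' @param codebook a codec codebook (list with matrix `E`), or a matrix.
#' @return list with `zq` (quantized matrix) and `idx` (0-based integer
#'   codebook indices per position).
#' @export
quantize <- function(z, codebook) {
  E <- if (is.list(codebook)) codebook$E else codebook
  if (is.null(E) || nrow(E) < 1L) stop("empty codebook")
  if (ncol(z) != ncol(E)) stop("latent feature dimension does not match codebook")
  d2 <- outer(rowSums(z * z), rowSums(E * E), `+`) - 2 * tcrossprod(z, E)
  idx <- max.col(-d2, ties.method = "first")
  # the expansion form can misorder near-ties by a rounding ulp; recompute
  # exact squared distances for rows whose margin is within tolerance
  mins <- d2[cbind(seq_len(nrow(z)), idx)]
  tol <- 1e-9 * (1 + abs(mins))
  close <- which(rowSums(d2 <= mins + tol) > 1L)
  for (i in close) {
    dd <- colSums((t(E) - z[i, ])^2)
    idx[i] <- which(dd == min(dd))[1]
  }
  list(zq = E[idx, , drop = FALSE], idx = idx - 1L)
}

# ---- user-facing encode / decode ------------------------------------------

normalize_intensity <- function(x, norm) (x - norm[1]) / max(norm[2] - norm[1], 1e-8)
denormalize_intensity <- function(x, norm) x * max(norm[2] - norm[1], 1e-8) + norm[1]

codec_input_matrix <- function(codec, data, channels) {
  x <- normalize_intensity(as.numeric(data), codec$norm)
  if (codec$cfg$use_coords)
    cbind(x, as.numeric(channels[[1]]), as.numeric(channels[[2]]),
          as.numeric(channels[[3]]))
  else
    cbind(x, 0, 0, 0)
}

lat_coords_matrix <- function(codec, channels, factor) {
  lat <- pool_coords_to_latent(channels, factor)
  m <- cbind(as.numeric(lat[[1]]), as.numeric(lat[[2]]), as.numeric(lat[[3]]))
  if (!codec$cfg$use_coords) m[] <- 0
  list(mat = m, channels = lat)
}

#' Encode a volume to its latent token grid
#'
#' Pads the volume to the codec's downsampling factor, synthesizes the
#' coordinate channels, runs the encoder and quantizes against the codebook.
#'
#' @param codec a trained [codec_init()] object.
#' @param vol a [volume()].
#' @return list with `idx` (integer array at latent shape, 0-based), `zq`,
#'   `z`, `lat_shape`, `lat_coords` (pooled channels), `pad` record and the
#'   padded shape.
#' @export
codec_encode_volume <- function(codec, vol) {
  pd <- pad_to_factor(vol, codec$cfg$F)
  channels <- padded_coord_channels(vol, pd$pad)
  shape <- dim(pd$volume$data)
  x <- codec_input_matrix(codec, pd$volume$data, channels)
  fw <- encoder_fwd(codec, x, shape)
  q <- quantize(fw$z, codec$codebook)
  lc <- lat_coords_matrix(codec, channels, codec$cfg$F)
  list(idx = array(q$idx, fw$lat_shape), zq = q$zq, z = fw$z,
       lat_shape = fw$lat_shape, lat_coords = lc$mat, pad = pd$pad,
       padded_shape = shape, channels = channels)
}

#' Decode a latent grid back to a volume
#'
#' @param codec a codec.
#' @param idx integer array (0-based codebook indices) at latent shape, or a
#'   quantized matrix via `zq=`.
#' @param lat_coords latent-resolution coordinate matrix (positions x 3), as
#'   produced by [codec_encode_volume()].
#' @param lat_shape integer(3) latent grid shape.
#' @param out_shape integer(3) target (unpadded) output shape.
#' @param dropout enable decoder dropout (stochastic under `seed`).
#' @param seed RNG seed used when `dropout = TRUE`.
#' @return 3D array of reconstructed intensities (denormalized).
#' @export
codec_decode <- function(codec, idx = NULL, lat_coords, lat_shape,
                         out_shape = NULL, zq = NULL, dropout = FALSE,
                         seed = 1L) {
  if (is.null(zq)) zq <- codec$codebook$E[as.integer(idx) + 1L, , drop = FALSE]
  run <- function() decoder_fwd(codec, zq, lat_coords, lat_shape,
                                dropout_active = dropout)
  fw <- if (dropout) with_seed(seed, run()) else run()
  full <- lat_shape * codec$cfg$F
  xr <- array(fw$xhat[, 1], full)
  if (!is.null(out_shape))
    xr <- xr[seq_len(out_shape[1]), seq_len(out_shape[2]), seq_len(out_shape[3]),
             drop = FALSE]
  array(denormalize_intensity(xr, codec$norm), dim(xr))
}

#' Reconstruct a volume through encode -> quantize -> decode
#' @param codec a trained codec.
#' @param vol a [volume()].
#' @param dropout,seed decoder dropout switches (see [codec_decode()]).
#' @return a `volume` with identical shape, spacing and frame to `vol`.
#' @export
codec_reconstruct <- function(codec, vol, dropout = FALSE, seed = 1L) {
  enc <- codec_encode_volume(codec, vol)
  xr <- codec_decode(codec, idx = enc$idx, lat_coords = enc$lat_coords,
                     lat_shape = enc$lat_shape, out_shape = dim(vol$data),
                     dropout = dropout, seed = seed)
  volume(xr, spacing = vol$spacing, frame = vol$frame, modality = vol$modality)
}

# ---- training --------------------------------------------------------------

#' Train the codec on a corpus of volumes with random-crop FOV augmentation
#'
#' Each step draws a volume, takes a random cube crop (sizes from
#' `crop_sizes`, all multiples of the downsampling factor), synthesizes the
#' crop's coordinate channels via [crop_frame()], and performs one Adam step
#' on the L1 reconstruction + commitment objective with a straight-through
#' gradient and EMA codebook updates.
#'
#' @param codec an initialized codec.
#' @param corpus list of [volume()] objects (healthy training set).
#' @param steps number of optimization steps.
#' @param lr Adam learning rate.
#' @param crop_sizes candidate cube crop sizes in voxels (include the full
#'   extent to train on whole volumes too).
#' @param crop_prob probability that a step uses a crop rather than the full
#'   volume.
#' @param seed RNG seed controlling crop sampling, dropout and ordering.
#' @param verbose print loss every 50 steps.
#' @return the trained codec, with the per-step loss trace in
#'   `attr(, "loss_trace")`.
#' @export
train_codec <- function(codec, corpus, steps = 300L, lr = 2e-3,
                        crop_sizes = c(16L, 20L, 24L, 28L), crop_prob = 0.5,
                        seed = 1L, verbose = FALSE) {
  stopifnot(length(corpus) >= 1L)
  cfg <- codec$cfg
  rng <- range(unlist(lapply(corpus, function(v) range(v$data))))
  codec$norm <- rng
  opt <- adam_init(codec$params)
  trace <- numeric(steps)
  with_seed(seed, {
    for (step in seq_len(steps)) {
      vol <- corpus[[sample.int(length(corpus), 1L)]]
      d <- dim(vol$data)
      cs <- crop_sizes[crop_sizes <= min(d)]
      if (length(cs) && stats::runif(1) < crop_prob) {
        sz <- cs[sample.int(length(cs), 1L)]
        st <- vapply(d, function(n) sample.int(n - sz + 1L, 1L) - 1L, integer(1))
        vol <- crop_volume(vol, cbind(st, st + sz))
      }
      shape <- dim(vol$data)
      channels <- make_coord_channels(shape, vol$frame)
      x <- codec_input_matrix(codec, vol$data, channels)
      fe <- encoder_fwd(codec, x, shape)
      q <- quantize(fe$z, codec$codebook)
      lc <- lat_coords_matrix(codec, channels, cfg$F)
      fd <- decoder_fwd(codec, q$zq, lc$mat, fe$lat_shape, dropout_active = TRUE)
      target <- x[, 1]
      resid <- fd$xhat[, 1] - target
      loss_rec <- mean(abs(resid))
      loss_commit <- cfg$beta * mean((fe$z - q$zq)^2)
      loss <- loss_rec + loss_commit
      if (!is.finite(loss)) stop("NaN/Inf loss at step ", step, " - aborting codec training")
      trace[step] <- loss
      dxhat <- matrix(sign(resid) / length(resid), ncol = 1L)
      bd <- decoder_bwd(codec, dxhat, fd)
      # straight-through: decoder gradient passes through the quantizer,
      # plus the commitment pull of z toward its (stopped) code
      dz <- bd$dzq + 2 * cfg$beta * (fe$z - q$zq) / length(fe$z)
      ge <- encoder_bwd(codec, dz, fe)
      grads <- c(bd$grads, ge)
      upd <- adam_step(codec$params, grads[names(codec$params)], opt, lr = lr)
      codec$params <- upd$params; opt <- upd$state
      codec$codebook <- ema_codebook_update(codec$codebook, fe$z, q$idx, cfg)
      if (verbose && step %% 50L == 0L)
        message(sprintf("codec step %d: loss %.5f (rec %.5f)", step, loss, loss_rec))
    }
  })
  attr(codec, "loss_trace") <- trace
  codec
}

ema_codebook_update <- function(cb, z, idx0, cfg) {
  K <- cfg$K; dec <- cfg$ema_decay
  counts <- tabulate(idx0 + 1L, nbins = K)
  sums <- matrix(0, K, cfg$n_z)
  rs <- rowsum(z, group = idx0 + 1L)
  sums[as.integer(rownames(rs)), ] <- rs
  cb$cluster_size <- dec * cb$cluster_size + (1 - dec) * counts
  cb$cluster_sum <- dec * cb$cluster_sum + (1 - dec) * sums
  n <- sum(cb$cluster_size)
  smoothed <- (cb$cluster_size + 1e-5) / (n + K * 1e-5) * n
  cb$E <- cb$cluster_sum / smoothed
  # restart dead codes at random encoder outputs to keep the book in use
  dead <- which(cb$cluster_size < 1e-3)
  if (length(dead) && nrow(z) > 0L) {
    pick <- sample.int(nrow(z), length(dead), replace = TRUE)
    cb$E[dead, ] <- z[pick, , drop = FALSE]
    cb$cluster_sum[dead, ] <- cb$E[dead, , drop = FALSE] * cb$cluster_size[dead]
  }
  cb
}

#' Save / load a codec checkpoint
#' @param codec a codec. @param path file path (`.rds`).
#' @return `save_codec` returns `path` invisibly; `load_codec` the codec.
#' @export
save_codec <- function(codec, path) { saveRDS(codec, path); invisible(path) }
#' @rdname save_codec
#' @export
load_codec <- function(path) readRDS(path)
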