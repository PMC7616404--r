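# Raster tokenization of the latent index grid and an autoregressive
# categorical transformer over token sequences. Conditioning (auxiliary-
# modality tokens + quantized spatial tokens, embedded and summed position-
# wise) enters exclusively via cross-attention; the main sequence carries
# learned positional embeddings over the raster index. A begin-of-sequence
# token (index K) prefixes the input so p(s_0) is defined.

#' Raster-flatten a 3D integer grid into a token sequence
#'
#' Fixed order: last axis fastest, first axis slowest. The same order is
#' used for image tokens and spatial tokens so the two sequences stay
#' positionally aligned.
#'
#' @param grid 3D integer array.
#' @return integer vector of length `prod(dim(grid))`.
#' @export
raster_flatten <- function(grid) {
  as.integer(as.vector(aperm(grid, c(3L, 2L, 1L))))
}

#' @rdname raster_flatten
#' @param s integer token sequence.
#' @param shape integer(3) target grid shape.
#' @export
raster_unflatten <- function(s, shape) {
  shape <- as.integer(shape)
  if (length(s) != prod(shape)) stop("sequence length does not match shape")
  aperm(array(as.integer(s), rev(shape)), c(3L, 2L, 1L))
}

#' Sequence-model configuration
#'
#' @param K image-token vocabulary size (codec codebook size).
#' @param K_aux auxiliary-token vocabulary size.
#' @param B spatial-token bin count; the spatial vocabulary is `B^3 + 1`
#'   (one padding token).
#' @param n_layers,n_heads,d transformer depth, heads and embedding
#'   dimension (paper scale 14/8/256; desk default 4/4/64).
#' @param d_ff feed-forward width (default `4 * d`).
#' @param max_len maximum sequence length accepted.
#' @param use_aux,use_spatial enable the auxiliary / spatial parts of the
#'   conditioning sum (disabling both gives the unconditional ablation).
#' @return a `seq_config` list.
#' @export
seq_config <- function(K = 64L, K_aux = 64L, B = 20L, n_layers = 4L,
                       n_heads = 4L, d = 64L, d_ff = NULL, max_len = 520L,
                       use_aux = TRUE, use_spatial = TRUE) {
  stopifnot(d %% n_heads == 0L)
  structure(list(K = as.integer(K), K_aux = as.integer(K_aux), B = as.integer(B),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 d = as.integer(d), d_ff = as.integer(d_ff %||% (4L * d)),
                 max_len = as.integer(max_len), use_aux = isTRUE(use_aux),
                 use_spatial = isTRUE(use_spatial)),
            class = "seq_config")
}

#' Initialize a sequence model (untrained)
#' @param cfg a [seq_config()].
#' @param seed RNG seed for initialization.
#' @return a `seq_model` object.
#' @export
seq_init <- function(cfg, seed = 1L) {
  with_seed(seed, {
    d <- cfg$d; sc <- 0.02
    p <- list(tok_emb = matrix(stats::rnorm((cfg$K + 1L) * d, sd = sc), cfg$K + 1L, d),
              pos_emb = matrix(stats::rnorm(cfg$max_len * d, sd = sc), cfg$max_len, d),
              aux_emb = matrix(stats::rnorm(cfg$K_aux * d, sd = sc), cfg$K_aux, d),
              sp_emb = matrix(stats::rnorm((cfg$B^3 + 1L) * d, sd = sc), cfg$B^3 + 1L, d),
              mem_ln_g = rep(1, d), mem_ln_b = numeric(d))
    for (i in seq_len(cfg$n_layers)) {
      pre <- paste0("l", i, "_")
      p[[paste0(pre, "ln1_g")]] <- rep(1, d); p[[paste0(pre, "ln1_b")]] <- numeric(d)
      for (nm in c("Wq", "Wk", "Wv", "Wo"))
        p[[paste0(pre, nm)]] <- param_init(d, d, scale = sc)
      p[[paste0(pre, "bo")]] <- numeric(d)
      p[[paste0(pre, "lnc_g")]] <- rep(1, d); p[[paste0(pre, "lnc_b")]] <- numeric(d)
      for (nm in c("Wcq", "Wck", "Wcv", "Wco"))
        p[[paste0(pre, nm)]] <- param_init(d, d, scale = sc)
      p[[paste0(pre, "bco")]] <- numeric(d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d); p[[paste0(pre, "ln2_b")]] <- numeric(d)
      p[[paste0(pre, "W1")]] <- param_init(d, cfg$d_ff, scale = sc)
      p[[paste0(pre, "b1")]] <- numeric(cfg$d_ff)
      p[[paste0(pre, "W2")]] <- param_init(cfg$d_ff, d, scale = sc)
      p[[paste0(pre, "b2")]] <- numeric(d)
    }
    p$lnf_g <- rep(1, d); p$lnf_b <- numeric(d)
    p$head_W <- param_init(d, cfg$K, scale = sc)
    p$head_b <- numeric(cfg$K)
    structure(list(cfg = cfg, params = p), class = "seq_model")
  })
}

#' Bundle conditioning sequences
#'
#' The auxiliary and spatial token sequences must have equal length; they
#' are embedded and summed position-wise inside the model.
#'
#' @param aux integer vector of auxiliary-codec token indices (0-based), or
#'   `NULL` for empty (zero) auxiliary conditioning.
#' @param sp integer vector of spatial tokens (0-based), or `NULL`.
#' @param length_hint conditioning length when both parts are `NULL`.
#' @return a `conditioning` object.
#' @export
conditioning <- function(aux = NULL, sp = NULL, length_hint = 1L) {
  if (!is.null(aux) && !is.null(sp) && length(aux) != length(sp))
    stop("auxiliary and spatial sequences must have equal length")
  structure(list(aux = aux, sp = sp,
                 len = length(aux %||% sp %||% numeric(length_hint))),
            class = "conditioning")
}

# Build the (LN-normalized) cross-attention memory; returns cache for backward.
build_memory <- function(model, cond) {
  cfg <- model$cfg; p <- model$params
  Lc <- cond$len
  m <- matrix(0, Lc, cfg$d)
  if (cfg$use_aux && !is.null(cond$aux)) m <- m + p$aux_emb[cond$aux + 1L, , drop = FALSE]
  if (cfg$use_spatial && !is.null(cond$sp)) m <- m + p$sp_emb[cond$sp + 1L, , drop = FALSE]
  ln <- layernorm_fwd(m, p$mem_ln_g, p$mem_ln_b)
  list(mem = ln$y, ln = ln, raw = m)
}

seq_forward <- function(model, s, cond, want_cache = FALSE) {
  cfg <- model$cfg; p <- model$params
  L <- length(s)
  if (L > cfg$max_len)
    stop("sequence length ", L, " exceeds maximum context ", cfg$max_len)
  if (any(s < 0L) || any(s >= cfg$K)) stop("token out of vocabulary [0, K)")
  ids <- c(cfg$K + 1L, s[seq_len(L - 1L)] + 1L)   # BOS then shifted tokens
  x <- p$tok_emb[ids, , drop = FALSE] + p$pos_emb[seq_len(L), , drop = FALSE]
  memf <- build_memory(model, cond)
  caches <- list(ids = ids, L = L, memf = memf, layers = vector("list", cfg$n_layers))
  for (i in seq_len(cfg$n_layers)) {
    pre <- paste0("l", i, "_")
    lc <- list()
    ln1 <- layernorm_fwd(x, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    q <- ln1$y %*% p[[paste0(pre, "Wq")]]
    k <- ln1$y %*% p[[paste0(pre, "Wk")]]
    v <- ln1$y %*% p[[paste0(pre, "Wv")]]
    att <- mha_fwd(q, k, v, cfg$n_heads, causal = TRUE)
    proj <- sweep(att$y %*% p[[paste0(pre, "Wo")]], 2, p[[paste0(pre, "bo")]], `+`)
    x1 <- x + proj
    lnc <- layernorm_fwd(x1, p[[paste0(pre, "lnc_g")]], p[[paste0(pre, "lnc_b")]])
    q2 <- lnc$y %*% p[[paste0(pre, "Wcq")]]
    k2 <- memf$mem %*% p[[paste0(pre, "Wck")]]
    v2 <- memf$mem %*% p[[paste0(pre, "Wcv")]]
    att2 <- mha_fwd(q2, k2, v2, cfg$n_heads, causal = FALSE)
    proj2 <- sweep(att2$y %*% p[[paste0(pre, "Wco")]], 2, p[[paste0(pre, "bco")]], `+`)
    x2 <- x1 + proj2
    ln2 <- layernorm_fwd(x2, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    h <- gelu_fwd(sweep(ln2$y %*% p[[paste0(pre, "W1")]], 2, p[[paste0(pre, "b1")]], `+`))
    ff <- sweep(h$y %*% p[[paste0(pre, "W2")]], 2, p[[paste0(pre, "b2")]], `+`)
    x3 <- x2 + ff
    if (want_cache)
      caches$layers[[i]] <- list(ln1 = ln1, att = att, x = x, x1 = x1, lnc = lnc,
                                 att2 = att2, ln2 = ln2, h = h, x2 = x2)
    x <- x3
  }
  lnf <- layernorm_fwd(x, p$lnf_g, p$lnf_b)
  logits <- sweep(lnf$y %*% p$head_W, 2, p$head_b, `+`)
  probs <- softmax_rows(logits)
  caches$lnf <- lnf
  list(probs = probs, logits = logits, caches = caches)
}

seq_backward <- function(model, fw, dlogits) {
  cfg <- model$cfg; p <- model$params
  ca <- fw$caches
  g <- list()
  g$head_W <- crossprod(ca$lnf$y, dlogits)
  g$head_b <- colSums(dlogits)
  lb <- layernorm_bwd(dlogits %*% t(p$head_W), ca$lnf)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dx <- lb$dx
  dmem <- matrix(0, nrow(ca$memf$mem), cfg$d)
  for (i in rev(seq_len(cfg$n_layers))) {
    pre <- paste0("l", i, "_"); lc <- ca$layers[[i]]
    # feed-forward
    dff <- dx
    g[[paste0(pre, "W2")]] <- crossprod(lc$h$y, dff)
    g[[paste0(pre, "b2")]] <- colSums(dff)
    dh <- gelu_bwd(dff %*% t(p[[paste0(pre, "W2")]]), lc$h)
    g[[paste0(pre, "W1")]] <- crossprod(lc$ln2$y, dh)
    g[[paste0(pre, "b1")]] <- colSums(dh)
    lb2 <- layernorm_bwd(dh %*% t(p[[paste0(pre, "W1")]]), lc$ln2)
    g[[paste0(pre, "ln2_g")]] <- lb2$dg; g[[paste0(pre, "ln2_b")]] <- lb2$db
    dx2 <- dx + lb2$dx
    # cross-attention
    dproj2 <- dx2
    g[[paste0(pre, "Wco")]] <- crossprod(lc$att2$y, dproj2)
    g[[paste0(pre, "bco")]] <- colSums(dproj2)
    datt2 <- dproj2 %*% t(p[[paste0(pre, "Wco")]])
    mb2 <- mha_bwd(datt2, lc$att2)
    g[[paste0(pre, "Wcq")]] <- crossprod(lc$lnc$y, mb2$dq)
    g[[paste0(pre, "Wck")]] <- crossprod(ca$memf$mem, mb2$dk)
    g[[paste0(pre, "Wcv")]] <- crossprod(ca$memf$mem, mb2$dv)
    dmem <- dmem + mb2$dk %*% t(p[[paste0(pre, "Wck")]]) +
                   mb2$dv %*% t(p[[paste0(pre, "Wcv")]])
    lbc <- layernorm_bwd(mb2$dq %*% t(p[[paste0(pre, "Wcq")]]), lc$lnc)
    g[[paste0(pre, "lnc_g")]] <- lbc$dg; g[[paste0(pre, "lnc_b")]] <- lbc$db
    dx1 <- dx2 + lbc$dx
    # self-attention
    dproj <- dx1
    g[[paste0(pre, "Wo")]] <- crossprod(lc$att$y, dproj)
    g[[paste0(pre, "bo")]] <- colSums(dproj)
    datt <- dproj %*% t(p[[paste0(pre, "Wo")]])
    mb <- mha_bwd(datt, lc$att)
    g[[paste0(pre, "Wq")]] <- crossprod(lc$ln1$y, mb$dq)
    g[[paste0(pre, "Wk")]] <- crossprod(lc$ln1$y, mb$dk)
    g[[paste0(pre, "Wv")]] <- crossprod(lc$ln1$y, mb$dv)
    dln1 <- mb$dq %*% t(p[[paste0(pre, "Wq")]]) +
            mb$dk %*% t(p[[paste0(pre, "Wk")]]) +
            mb$dv %*% t(p[[paste0(pre, "Wv")]])
    lb1 <- layernorm_bwd(dln1, lc$ln1)
    g[[paste0(pre, "ln1_g")]] <- lb1$dg; g[[paste0(pre, "ln1_b")]] <- lb1$db
    dx <- dx1 + lb1$dx
  }
  # embeddings
  g$tok_emb <- embed_grad(cfg$K + 1L, ca$ids, dx)
  g$pos_emb <- matrix(0, cfg$max_len, cfg$d)
  g$pos_emb[seq_len(ca$L), ] <- dx
  # memory layernorm and embedding tables
  lbm <- layernorm_bwd(dmem, ca$memf$ln)
  g$mem_ln_g <- lbm$dg; g$mem_ln_b <- lbm$db
  g$aux_emb <- matrix(0, cfg$K_aux, cfg$d)
  g$sp_emb <- matrix(0, cfg$B^3 + 1L, cfg$d)
  if (cfg$use_aux && !is.null(ca$aux_idx))
    g$aux_emb <- embed_grad(cfg$K_aux, ca$aux_idx, lbm$dx)
  if (cfg$use_spatial && !is.null(ca$sp_idx))
    g$sp_emb <- embed_grad(cfg$B^3 + 1L, ca$sp_idx, lbm$dx)
  g
}

#' Per-position categorical likelihoods of a token sequence
#'
#' Runs the autoregressive model once and extracts, for every position, the
#' full categorical distribution over the vocabulary and the realized
#' likelihood `p(s_i | s_<i, c)` of the observed token.
#'
#' @param s integer token sequence (0-based values in `[0, K)`).
#' @param cond a [conditioning()] bundle.
#' @param model a trained [seq_init()] model.
#' @return list with `probs` (L x K matrix), `p` (realized likelihoods) and
#'   `nll` (mean negative log-likelihood).
#' @export
token_likelihoods <- function(s, cond, model) {
  fw <- seq_forward(model, s, cond)
  L <- length(s)
  pr <- fw$probs[cbind(seq_len(L), s + 1L)]
  list(probs = fw$probs, p = pr, nll = -mean(log(pmax(pr, 1e-12))))
}

#' Train the sequence model on tokenized examples
#'
#' Examples may have varying sequence lengths (crops and rotations produce
#' different latent grids); each step optimizes the mean NLL of one example.
#'
#' @param model an initialized [seq_init()] model.
#' @param dataset list of examples, each `list(s=, cond=)` with `s` a
#'   0-based token sequence and `cond` a [conditioning()].
#' @param steps optimization steps.
#' @param lr Adam learning rate (with 20-step linear warmup).
#' @param seed RNG seed for example order.
#' @param verbose print NLL every 50 steps.
#' @return the trained model with `attr(, "nll_trace")`.
#' @export
train_seqmodel <- function(model, dataset, steps = 200L, lr = 3e-3, seed = 1L,
                           verbose = FALSE) {
  stopifnot(length(dataset) >= 1L)
  opt <- adam_init(model$params)
  trace <- numeric(steps)
  with_seed(seed, {
    for (step in seq_len(steps)) {
      ex <- dataset[[sample.int(length(dataset), 1L)]]
      fw <- seq_forward(model, ex$s, ex$cond, want_cache = TRUE)
      fw$caches$aux_idx <- if (!is.null(ex$cond$aux)) ex$cond$aux + 1L
      fw$caches$sp_idx <- if (!is.null(ex$cond$sp)) ex$cond$sp + 1L
      L <- length(ex$s)
      pr <- fw$probs[cbind(seq_len(L), ex$s + 1L)]
      nll <- -mean(log(pmax(pr, 1e-12)))
      if (!is.finite(nll)) stop("NaN/Inf NLL at step ", step)
      trace[step] <- nll
      dlogits <- fw$probs
      dlogits[cbind(seq_len(L), ex$s + 1L)] <-
        dlogits[cbind(seq_len(L), ex$s + 1L)] - 1
      dlogits <- dlogits / L
      g <- seq_backward(model, fw, dlogits)
      step_lr <- lr * min(1, step / 20)
      upd <- adam_step(model$params, g[names(model$params)], opt, lr = step_lr)
      model$params <- upd$params; opt <- upd$state
      if (verbose && step %% 50L == 0L)
        message(sprintf("seq step %d: nll %.4f", step, nll))
    }
  })
  attr(model, "nll_trace") <- trace
  model
}

# ---- incremental (KV-cached) inference -------------------------------------

# Precompute everything position-independent: LN'd memory and per-layer
# cross-attention keys/values.
seq_infer_init <- function(model, cond) {
  cfg <- model$cfg; p <- model$params
  memf <- build_memory(model, cond)
  layers <- lapply(seq_len(cfg$n_layers), function(i) {
    pre <- paste0("l", i, "_")
    list(k2 = memf$mem %*% p[[paste0(pre, "Wck")]],
         v2 = memf$mem %*% p[[paste0(pre, "Wcv")]],
         kself = NULL, vself = NULL)
  })
  list(model = model, layers = layers, t = 0L)
}

ln_vec <- function(x, g, b, eps = 1e-5) {
  mu <- mean(x); xc <- x - mu
  xc / sqrt(mean(xc * xc) + eps) * g + b
}

# Advance one position: feed the *input* token id (1-based row of tok_emb;
# BOS = K+1) at the next position; returns the categorical distribution for
# the token at that position.
seq_infer_step <- function(state, input_id) {
  model <- state$model; cfg <- model$cfg; p <- model$params
  t <- state$t + 1L
  if (t > cfg$max_len) stop("sequence length exceeds maximum context ", cfg$max_len)
  x <- p$tok_emb[input_id, ] + p$pos_emb[t, ]
  nh <- cfg$n_heads; dh <- cfg$d %/% nh
  for (i in seq_len(cfg$n_layers)) {
    pre <- paste0("l", i, "_"); st <- state$layers[[i]]
    h1 <- ln_vec(x, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    q <- h1 %*% p[[paste0(pre, "Wq")]]
    k <- h1 %*% p[[paste0(pre, "Wk")]]
    v <- h1 %*% p[[paste0(pre, "Wv")]]
    st$kself <- rbind(st$kself, k)
    st$vself <- rbind(st$vself, v)
    att <- numeric(cfg$d)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      sc <- (st$kself[, cols, drop = FALSE] %*% q[1, cols]) / sqrt(dh)
      w <- exp(sc - max(sc)); w <- w / sum(w)
      att[cols] <- crossprod(st$vself[, cols, drop = FALSE], w)
    }
    x <- x + as.numeric(att %*% p[[paste0(pre, "Wo")]]) + p[[paste0(pre, "bo")]]
    h2 <- ln_vec(x, p[[paste0(pre, "lnc_g")]], p[[paste0(pre, "lnc_b")]])
    q2 <- h2 %*% p[[paste0(pre, "Wcq")]]
    att2 <- numeric(cfg$d)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      sc <- (st$k2[, cols, drop = FALSE] %*% q2[1, cols]) / sqrt(dh)
      w <- exp(sc - max(sc)); w <- w / sum(w)
      att2[cols] <- crossprod(st$v2[, cols, drop = FALSE], w)
    }
    x <- x + as.numeric(att2 %*% p[[paste0(pre, "Wco")]]) + p[[paste0(pre, "bco")]]
    h3 <- ln_vec(x, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    a1 <- as.numeric(h3 %*% p[[paste0(pre, "W1")]]) + p[[paste0(pre, "b1")]]
    x <- x + as.numeric((a1 * stats::pnorm(a1)) %*% p[[paste0(pre, "W2")]]) +
         p[[paste0(pre, "b2")]]
    state$layers[[i]] <- st
  }
  hf <- ln_vec(x, p$lnf_g, p$lnf_b)
  logits <- as.numeric(hf %*% p$head_W) + p$head_b
  e <- exp(logits - max(logits))
  state$t <- t
  list(probs = e / sum(e), state = state)
}

#' Save / load a sequence-model checkpoint
#' @param model a `seq_model`. @param path file path (`.rds`).
#' @export
save_seqmodel <- function(model, path) { saveRDS(model, path); invisible(path) }
#' @rdname save_seqmodel
#' @export
load_seqmodel <- function(path) readRDS(path)
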