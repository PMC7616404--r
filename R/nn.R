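# Minimal neural-network kernels in base R matrix ops.
#
# Feature maps are stored as (Npos x C) matrices with voxel positions in R
# array order (first axis fastest). 3D convolutions run as im2col gathers
# followed by one GEMM; transposed convolutions and the convolution input
# gradient reuse a cached sparse scatter matrix. Plans (gather indices +
# scatter matrix) are cached per input shape, so repeated crops of the same
# size pay the indexing cost once.

.plan_cache <- new.env(parent = emptyenv())

conv_plan <- function(in_shape, k, stride, pad) {
  key <- paste(c(in_shape, k, stride, pad), collapse = "_")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  pd <- in_shape + 2L * pad
  od <- (in_shape + 2L * pad - k) %/% stride + 1L
  n_out <- prod(od); n_pad <- prod(pd); k3 <- k^3
  # output position coordinates (1-based), first axis fastest
  ox <- arrayInd(seq_len(n_out), od)
  # kernel offsets, dx fastest
  offs <- arrayInd(seq_len(k3), c(k, k, k))
  base <- (ox - 1L) * stride            # n_out x 3, 0-based window starts
  gi <- matrix(0L, n_out, k3)
  for (kk in seq_len(k3)) {
    x <- base[, 1] + offs[kk, 1]
    y <- base[, 2] + offs[kk, 2]
    z <- base[, 3] + offs[kk, 3]
    gi[, kk] <- x + (y - 1L) * pd[1] + (z - 1L) * pd[1] * pd[2]
  }
  # linear indices of the unpadded interior inside the padded block
  ix <- arrayInd(seq_len(prod(in_shape)), in_shape)
  ii <- (ix[, 1] + pad) + (ix[, 2] + pad - 1L) * pd[1] + (ix[, 3] + pad - 1L) * pd[1] * pd[2]
  scatter <- Matrix::sparseMatrix(i = as.vector(gi), j = seq_len(n_out * k3),
                                  x = 1, dims = c(n_pad, n_out * k3))
  plan <- list(in_shape = in_shape, out_shape = od, k3 = k3, n_pad = n_pad,
               gi = as.vector(gi), ii = ii, scatter = scatter)
  if (length(ls(.plan_cache)) > 60L) rm(list = ls(.plan_cache)[1], envir = .plan_cache)
  .plan_cache[[key]] <- plan
  plan
}

conv3d_fwd <- function(x, in_shape, W, b, k, stride, pad) {
  plan <- conv_plan(in_shape, k, stride, pad)
  cin <- ncol(x)
  xp <- matrix(0, plan$n_pad, cin)
  xp[plan$ii, ] <- x
  A <- xp[plan$gi, , drop = FALSE]
  dim(A) <- c(length(plan$gi) %/% plan$k3, plan$k3 * cin)
  y <- A %*% W
  y <- sweep(y, 2, b, `+`)
  list(y = y, A = A, plan = plan, cin = cin)
}

conv3d_bwd <- function(dy, cache, W) {
  dW <- crossprod(cache$A, dy)
  db <- colSums(dy)
  dP <- dy %*% t(W)
  dim(dP) <- c(nrow(dP) * cache$plan$k3, cache$cin)
  dxp <- as.matrix(cache$plan$scatter %*% dP)
  dx <- dxp[cache$plan$ii, , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# Transposed conv: maps latent shape `in_shape` up to `out_shape`; uses the
# plan of the adjoint convolution (built on out_shape). W: (k^3*Cout) x Cin.
convtrans3d_fwd <- function(x, out_shape, W, b, k, stride, pad) {
  plan <- conv_plan(out_shape, k, stride, pad)
  cout <- nrow(W) %/% plan$k3
  C <- x %*% t(W)                      # Ns x (k3*Cout)
  dim(C) <- c(nrow(x) * plan$k3, cout)
  yp <- as.matrix(plan$scatter %*% C)
  y <- yp[plan$ii, , drop = FALSE]
  y <- sweep(y, 2, b, `+`)
  list(y = y, x = x, plan = plan, cout = cout)
}

convtrans3d_bwd <- function(dy, cache, W) {
  plan <- cache$plan
  dyp <- matrix(0, plan$n_pad, cache$cout)
  dyp[plan$ii, ] <- dy
  A <- dyp[plan$gi, , drop = FALSE]
  dim(A) <- c(length(plan$gi) %/% plan$k3, plan$k3 * cache$cout)
  dx <- A %*% W
  dW <- crossprod(A, cache$x)
  db <- colSums(dy)
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) {
  y <- x; y[y < 0] <- 0
  list(y = y, mask = x > 0)
}
relu_bwd <- function(dy, cache) dy * cache$mask

gelu_fwd <- function(x) list(y = x * stats::pnorm(x), x = x)
gelu_bwd <- function(dy, cache) {
  x <- cache$x
  dy * (stats::pnorm(x) + x * stats::dnorm(x))
}

# Inverted dropout; draws from the current RNG stream.
dropout_fwd <- function(x, p, active) {
  if (!active || p <= 0) return(list(y = x, mask = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(y = x * mask, mask = mask)
}
dropout_bwd <- function(dy, cache) if (is.null(cache$mask)) dy else dy * cache$mask

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2, g, `*`)
  y <- sweep(y, 2, b, `+`)
  list(y = y, xhat = xhat, inv = inv, g = g)
}
layernorm_bwd <- function(dy, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  dxh <- sweep(dy, 2, cache$g, `*`)
  dx <- inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# Multi-head scaled dot-product attention. q: Lq x d, k/v: Lk x d (already
# projected). `causal` masks keys j > i (valid when Lq == Lk).
mha_fwd <- function(q, k, v, n_heads, causal = FALSE) {
  d <- ncol(q); dh <- d %/% n_heads
  Lq <- nrow(q); Lk <- nrow(k)
  out <- matrix(0, Lq, d)
  caches <- vector("list", n_heads)
  neg <- -1e30
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    qs <- q[, cols, drop = FALSE]; ks <- k[, cols, drop = FALSE]
    vs <- v[, cols, drop = FALSE]
    s <- tcrossprod(qs, ks) / sqrt(dh)
    if (causal && Lq > 1) s[upper.tri(s)] <- neg
    a <- softmax_rows(s)
    out[, cols] <- a %*% vs
    caches[[h]] <- list(a = a, qs = qs, ks = ks, vs = vs, cols = cols, dh = dh)
  }
  list(y = out, caches = caches, causal = causal)
}

mha_bwd <- function(dy, cache) {
  ch <- cache$caches
  d <- ncol(dy)
  dq <- matrix(0, nrow(dy), d)
  dk <- matrix(0, nrow(ch[[1]]$ks), d)
  dv <- matrix(0, nrow(ch[[1]]$vs), d)
  for (h in seq_along(ch)) {
    cc <- ch[[h]]; cols <- cc$cols
    dout <- dy[, cols, drop = FALSE]
    da <- tcrossprod(dout, cc$vs)
    dv[, cols] <- crossprod(cc$a, dout)
    ds <- cc$a * (da - rowSums(da * cc$a))
    dq[, cols] <- (ds %*% cc$ks) / sqrt(cc$dh)
    dk[, cols] <- crossprod(ds, cc$qs) / sqrt(cc$dh)
  }
  list(dq = dq, dk = dk, dv = dv)
}

# ---- parameter containers and Adam -----------------------------------------

param_init <- function(nrow, ncol, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (nrow + ncol))
  matrix(stats::rnorm(nrow * ncol, sd = scale), nrow, ncol)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 5) {
  state$t <- state$t + 1L
  # global gradient-norm clipping for stability
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  sc <- if (is.finite(gn) && gn > clip) clip / gn else 1
  for (nm in names(params)) {
    g <- grads[[nm]] * sc
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Accumulate gradients into an embedding table from row indices.
embed_grad <- function(n_rows, idx, dy) {
  g <- rowsum(dy, group = idx)
  out <- matrix(0, n_rows, ncol(dy))
  out[as.integer(rownames(g)), ] <- g
  out
}
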