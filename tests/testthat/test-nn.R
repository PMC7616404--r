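# Numerical kernels: convolution oracles and gradient checks. These guard
# the hand-written backprop the codec and transformer rely on.

naive_conv3d <- function(x4, W, b, k, stride, pad) {
  d <- dim(x4)[1:3]; cin <- dim(x4)[4]; cout <- length(b)
  pd <- d + 2 * pad
  xp <- array(0, c(pd, cin))
  xp[pad + (1:d[1]), pad + (1:d[2]), pad + (1:d[3]), ] <- x4
  od <- (pd - k) %/% stride + 1
  y <- array(0, c(od, cout))
  Wa <- array(W, c(k, k, k, cin, cout))
  for (ox in 1:od[1]) for (oy in 1:od[2]) for (oz in 1:od[3]) {
    patch <- xp[(ox - 1) * stride + (1:k), (oy - 1) * stride + (1:k),
                (oz - 1) * stride + (1:k), , drop = FALSE]
    dim(patch) <- c(k, k, k, cin)
    for (co in 1:cout)
      y[ox, oy, oz, co] <- sum(patch * Wa[, , , , co]) + b[co]
  }
  y
}

test_that("the strided conv3d matches a naive sliding-window oracle", {
  withr::with_seed(81, {
    d <- c(6L, 8L, 4L); cin <- 3L; cout <- 5L; k <- 4L
    x <- array(rnorm(prod(d) * cin), c(d, cin))
    W <- matrix(rnorm(k^3 * cin * cout), k^3 * cin, cout)
    b <- rnorm(cout)
    fw <- vqheal:::conv3d_fwd(matrix(x, prod(d), cin), d, W, b, k, 2L, 1L)
    yn <- naive_conv3d(x, W, b, k, 2, 1)
    expect_equal(array(fw$y, dim(yn)), yn, tolerance = 1e-12)
  })
})

test_that("conv and transposed-conv gradients match finite differences", {
  withr::with_seed(82, {
    d <- c(4L, 6L, 4L); cin <- 2L; cout <- 3L
    x <- matrix(rnorm(prod(d) * cin), prod(d), cin)
    W <- matrix(rnorm(64 * cin * cout), 64 * cin, cout)
    b <- rnorm(cout)
    fw <- vqheal:::conv3d_fwd(x, d, W, b, 4L, 2L, 1L)
    dy <- matrix(rnorm(length(fw$y)), nrow(fw$y))
    bw <- vqheal:::conv3d_bwd(dy, fw, W)
    eps <- 1e-6
    dirx <- matrix(rnorm(length(x)), nrow(x))
    num <- (sum(vqheal:::conv3d_fwd(x + eps * dirx, d, W, b, 4L, 2L, 1L)$y * dy) -
            sum(vqheal:::conv3d_fwd(x - eps * dirx, d, W, b, 4L, 2L, 1L)$y * dy)) / (2 * eps)
    expect_equal(sum(bw$dx * dirx), num, tolerance = 1e-5)

    ls <- c(2L, 3L, 2L)
    xt <- matrix(rnorm(prod(ls) * cout), prod(ls), cout)
    Wt <- matrix(rnorm(64 * cin * cout), 64 * cin, cout)
    ft <- vqheal:::convtrans3d_fwd(xt, ls * 2L, Wt, rnorm(cin), 4L, 2L, 1L)
    expect_identical(nrow(ft$y), as.integer(prod(ls * 2L)))
    dyt <- matrix(rnorm(length(ft$y)), nrow(ft$y))
    bt <- vqheal:::convtrans3d_bwd(dyt, ft, Wt)
    dirw <- matrix(rnorm(length(Wt)), nrow(Wt))
    numw <- (sum(vqheal:::convtrans3d_fwd(xt, ls * 2L, Wt + eps * dirw, rnorm(cin) * 0, 4L, 2L, 1L)$y * dyt) -
             sum(vqheal:::convtrans3d_fwd(xt, ls * 2L, Wt - eps * dirw, rnorm(cin) * 0, 4L, 2L, 1L)$y * dyt)) / (2 * eps)
    expect_equal(sum(bt$dW * dirw), numw, tolerance = 1e-5)
  })
})

test_that("transformer gradients match finite differences", {
  cfg <- seq_config(K = 6L, K_aux = 5L, B = 3L, n_layers = 2L, n_heads = 2L,
                    d = 8L, max_len = 12L)
  m <- seq_init(cfg, seed = 7L)
  s <- c(0L, 3L, 5L, 2L, 1L, 4L)
  cond <- conditioning(aux = c(1L, 0L, 4L, 2L, 3L, 1L),
                       sp = c(0L, 5L, 9L, 26L, 3L, 7L))
  lossm <- function(m) {
    fw <- vqheal:::seq_forward(m, s, cond)
    -mean(log(fw$probs[cbind(seq_along(s), s + 1L)]))
  }
  fw <- vqheal:::seq_forward(m, s, cond, want_cache = TRUE)
  fw$caches$aux_idx <- cond$aux + 1L
  fw$caches$sp_idx <- cond$sp + 1L
  L <- length(s)
  dlog <- fw$probs
  dlog[cbind(1:L, s + 1L)] <- dlog[cbind(1:L, s + 1L)] - 1
  g <- vqheal:::seq_backward(m, fw, dlog / L)
  eps <- 1e-6
  withr::with_seed(83, {
    for (nm in c("tok_emb", "aux_emb", "sp_emb", "l1_Wq", "l1_Wck", "l2_W1",
                 "head_W", "lnf_g")) {
      i <- sample(length(g[[nm]]), 1)
      m2 <- m; m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
      m3 <- m; m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
      num <- (lossm(m2) - lossm(m3)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4)
    }
  })
})

test_that("incremental KV-cached inference matches the full forward pass", {
  fx <- fixture_memorized()
  fw <- vqheal:::seq_forward(fx$model, fx$s, fx$cond)
  st <- vqheal:::seq_infer_init(fx$model, fx$cond)
  prev <- fx$cfg$K + 1L
  for (i in seq_along(fx$s)) {
    stp <- vqheal:::seq_infer_step(st, prev)
    st <- stp$state
    expect_equal(stp$probs, fw$probs[i, ], tolerance = 1e-12)
    prev <- fx$s[i] + 1L
  }
})
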