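# Raster tokenization and the autoregressive transformer.

test_that("raster flatten/unflatten are inverse with last axis fastest", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      shape <- sample(2:5, 3, replace = TRUE)
      g <- array(sample.int(100, prod(shape), replace = TRUE), shape)
      expect_identical(raster_unflatten(raster_flatten(g), shape), g)
    }
  })
  # documented order: last axis fastest, first axis slowest
  g <- array(0L, c(2L, 2L, 2L))
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    g[i, j, k] <- (i - 1L) * 4L + (j - 1L) * 2L + (k - 1L)
  expect_identical(raster_flatten(g), 0:7)
  expect_error(raster_unflatten(0:6, c(2L, 2L, 2L)), "length")
})

test_that("image and spatial token grids flatten in the same order", {
  v <- fixture_volume(c(8L, 8L, 8L), seed = 42L)
  ch <- make_coord_channels(dim(v$data), v$frame)
  lat <- pool_coords_to_latent(ch, 2L)
  g <- quantize_spatial_tokens(lat, 20L)
  s <- raster_flatten(g$sp)
  # position p of the flattened sequence corresponds to grid entry
  # unflatten(seq)[p'] for the same raster convention
  expect_identical(raster_unflatten(s, dim(g$sp)), g$sp)
})

test_that("positional distributions are normalized and causal", {
  fx <- fixture_memorized()
  fw <- token_likelihoods(fx$s, fx$cond, fx$model)
  expect_true(all(abs(rowSums(fw$probs) - 1) < 1e-5))
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))
  # exhaustive causality: perturbing s at positions >= i leaves the
  # distribution at i unchanged
  withr::with_seed(43, {
    for (i in seq_along(fx$s)) {
      s2 <- fx$s
      tail_idx <- i:length(fx$s)
      s2[tail_idx] <- sample(0:(fx$cfg$K - 1L), length(tail_idx), replace = TRUE)
      fw2 <- token_likelihoods(s2, fx$cond, fx$model)
      expect_equal(fw2$probs[seq_len(i), ], fw$probs[seq_len(i), ],
                   tolerance = 1e-12)
    }
  })
})

test_that("a memorized sequence gets realized likelihood > 0.99 everywhere", {
  fx <- fixture_memorized()
  p <- token_likelihoods(fx$s, fx$cond, fx$model)$p
  expect_true(all(p > 0.99))
})

test_that("per-sequence likelihoods do not depend on other sequences", {
  fx <- fixture_memorized()
  alone <- token_likelihoods(fx$s, fx$cond, fx$model)$p
  withr::with_seed(44, {
    others <- lapply(1:3, function(i)
      sample(0:(fx$cfg$K - 1L), length(fx$s), replace = TRUE))
  })
  batch <- lapply(c(others[1:2], list(fx$s), others[3]), function(s)
    token_likelihoods(s, fx$cond, fx$model)$p)
  expect_equal(batch[[3]], alone, tolerance = 1e-5)
})

test_that("vocabulary and context-length violations raise clear errors", {
  fx <- fixture_memorized()
  bad <- fx$s; bad[2] <- fx$cfg$K
  expect_error(token_likelihoods(bad, fx$cond, fx$model), "vocabulary")
  long_s <- rep(0L, fx$cfg$max_len + 1L)
  expect_error(token_likelihoods(long_s, conditioning(length_hint = 4L), fx$model),
               as.character(fx$cfg$max_len))
})

test_that("empty auxiliary conditioning still trains and infers", {
  cfg <- seq_config(K = 5L, K_aux = 4L, B = 2L, n_layers = 1L, n_heads = 2L,
                    d = 8L, max_len = 10L)
  s <- c(1L, 4L, 0L, 2L)
  cond <- conditioning(length_hint = 4L)     # zero memory
  m <- train_seqmodel(seq_init(cfg, seed = 1L), list(list(s = s, cond = cond)),
                      steps = 20L, seed = 2L)
  fw <- token_likelihoods(s, cond, m)
  expect_true(all(is.finite(fw$probs)))
  expect_true(all(abs(rowSums(fw$probs) - 1) < 1e-5))
})

test_that("training reduces the NLL on a small varied-length corpus", {
  withr::with_seed(45, {
    # structured sequences: repeated motifs of different lengths
    ds <- lapply(1:6, function(i) {
      L <- sample(c(24L, 36L, 48L), 1L)
      motif <- sample(0:7, 6, replace = TRUE)
      list(s = as.integer(rep(motif, length.out = L)),
           cond = conditioning(sp = as.integer(seq_len(L) %% 8),
                               length_hint = L))
    })
  })
  cfg <- seq_config(K = 8L, K_aux = 4L, B = 2L, n_layers = 2L, n_heads = 2L,
                    d = 16L, max_len = 64L)
  m <- train_seqmodel(seq_init(cfg, seed = 3L), ds, steps = 150L, seed = 4L)
  tr <- attr(m, "nll_trace")
  expect_lt(mean(utils::tail(tr, 20)), 0.7 * mean(utils::head(tr, 20)))
})

test_that("spatial conditioning discriminates correct from wrong frames", {
  # isolate the mechanism: each training example is a "crop" whose content
  # tokens are a fixed random table of its location, with spatial tokens
  # broadcasting that location - so the conditioning is the only source of
  # information about the first token
  cfg <- seq_config(K = 8L, K_aux = 4L, B = 2L, n_layers = 2L, n_heads = 2L,
                    d = 16L, max_len = 8L)
  tab <- c(3L, 7L, 1L, 5L, 0L, 6L, 2L, 4L)
  withr::with_seed(46, {
    ds <- lapply(1:40, function(i) {
      o <- sample(0:7, 1)
      s <- c(tab[o + 1], (tab[o + 1] + 1L) %% 8L, tab[o + 1])
      list(s = as.integer(s), cond = conditioning(sp = rep(o, 3), length_hint = 3))
    })
  })
  m <- train_seqmodel(seq_init(cfg, seed = 2L), ds, steps = 250L, lr = 1e-2,
                      seed = 3L)
  nll <- sapply(0:7, function(o) {
    s <- as.integer(c(tab[o + 1], (tab[o + 1] + 1L) %% 8L, tab[o + 1]))
    c(ok = token_likelihoods(s, conditioning(sp = rep(o, 3), length_hint = 3), m)$nll,
      wrong = token_likelihoods(s, conditioning(sp = rep((o + 3L) %% 8L, 3),
                                                length_hint = 3), m)$nll)
  })
  # paired comparison over every location: the true tokens are far more
  # likely under the correct spatial tokens than under a wrong frame
  expect_lt(mean(nll["ok", ]), mean(nll["wrong", ]))
})

test_that("conditioning requires aligned lengths", {
  expect_error(conditioning(aux = c(0L, 1L), sp = c(0L, 1L, 2L)), "equal length")
})
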