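# Token flagging, healing, ensemble decoding, KDE maps.

test_that("flagging compares strictly against the threshold", {
  expect_identical(flag_anomalous_tokens(c(0.9, 0.02, 0.5), 0.1),
                   c(FALSE, TRUE, FALSE))
  expect_identical(flag_anomalous_tokens(c(0.9, 0.02, 0.5), 1e-12),
                   rep(FALSE, 3))
  expect_identical(flag_anomalous_tokens(c(0.999, 1.0), 1),
                   c(TRUE, FALSE))
  expect_error(flag_anomalous_tokens(c(0.5), 0), "\\(0, 1\\]")
  expect_error(flag_anomalous_tokens(c(0.5), 1.5), "\\(0, 1\\]")
})

test_that("healing copies unmasked positions and is seed-reproducible", {
  fx <- fixture_memorized()
  mask <- rep(FALSE, length(fx$s))
  h0 <- resample_healed_sequences(fx$s, mask, fx$cond, fx$model, S = 3L, seed = 1L)
  expect_true(all(apply(h0, 1, identical, y = fx$s)))
  mask[4] <- TRUE
  h1 <- resample_healed_sequences(fx$s, mask, fx$cond, fx$model, S = 4L, seed = 1L)
  h2 <- resample_healed_sequences(fx$s, mask, fx$cond, fx$model, S = 4L, seed = 1L)
  expect_identical(h1, h2)
  expect_true(all(h1[, -4] == rep(fx$s[-4], each = 4L)))
  # with a near-uniform (untrained) model, different seeds give different draws
  m0 <- seq_init(fx$cfg, seed = 99L)
  g1 <- resample_healed_sequences(fx$s, mask, fx$cond, m0, S = 8L, seed = 1L)
  g2 <- resample_healed_sequences(fx$s, mask, fx$cond, m0, S = 8L, seed = 2L)
  expect_false(identical(g1, g2))
})

test_that("near-one-hot distributions heal to their argmax", {
  # the memorized model's distribution at every position is > 0.99 on the
  # true token, so redraws almost surely return it
  fx <- fixture_memorized()
  mask <- rep(FALSE, length(fx$s)); mask[5] <- TRUE
  h <- resample_healed_sequences(fx$s, mask, fx$cond, fx$model, S = 100L, seed = 7L)
  expect_gte(mean(h[, 5] == fx$s[5]), 0.99)
})

test_that("the ensemble holds S x Ddec reconstructions of the source shape", {
  fx <- fixture_codec()
  v <- fixture_volume(c(16L, 16L, 16L), seed = 51L)
  enc <- codec_encode_volume(fx$codec, v)
  s <- raster_flatten(enc$idx)
  healed <- matrix(rep(s, 6), nrow = 6, byrow = TRUE)
  ens <- decode_ensemble(healed, enc$lat_coords, enc$lat_shape, fx$codec,
                         out_shape = dim(v$data), Ddec = 3L, seed = 1L)
  expect_identical(ens$n, 18L)
  expect_identical(dim(ens$recons), c(18L, as.integer(prod(dim(v$data)))))
  # S = 1, Ddec = 1, no dropout: single deterministic reconstruction
  one <- decode_ensemble(healed[1, , drop = FALSE], enc$lat_coords,
                         enc$lat_shape, fx$codec, out_shape = dim(v$data),
                         Ddec = 1L, seed = 1L, dropout = FALSE)
  two <- decode_ensemble(healed[1, , drop = FALSE], enc$lat_coords,
                         enc$lat_shape, fx$codec, out_shape = dim(v$data),
                         Ddec = 1L, seed = 99L, dropout = FALSE)
  expect_identical(one$recons, two$recons)
})

test_that("KDE density matches the closed-form kernel sum", {
  # samples {0,0,1,1}: Scott bandwidth = sd * 4^(-1/5)
  E <- matrix(c(0, 0, 1, 1), 4, 1)
  obs <- 0.5
  km <- kde_score_map(array(obs, c(1, 1, 1)), E, anomaly_config())
  h <- stats::sd(c(0, 0, 1, 1)) * 4^(-1/5)
  direct <- mean(stats::dnorm((c(0, 0, 1, 1) - obs) / h)) / h
  expect_equal(as.numeric(km$density), direct, tolerance = 1e-10)
  expect_equal(as.numeric(km$score), -log(direct + 1e-12), tolerance = 1e-10)
})

test_that("KDE map matches a brute-force per-voxel oracle on 4^3 fixtures", {
  withr::with_seed(52, {
    for (rep in 1:3) {
      N <- 7L
      obs <- array(runif(64), c(4L, 4L, 4L))
      E <- matrix(runif(N * 64), N, 64)
      km <- kde_score_map(obs, E, anomaly_config())
      for (vx in sample(64, 12)) {
        xs <- E[, vx]
        h <- max(stats::sd(xs) * N^(-1/5), 1e-3)
        f <- mean(stats::dnorm((xs - as.numeric(obs)[vx]) / h)) / h
        expect_equal(as.numeric(km$density)[vx], f, tolerance = 1e-8)
      }
    }
  })
})

test_that("KDE obeys the scaling law and score is anti-monotone in density", {
  withr::with_seed(53, {
    obs <- array(runif(8), c(2L, 2L, 2L))
    E <- matrix(runif(5 * 8, 0.3, 0.9), 5, 8)
    k1 <- kde_score_map(obs, E, anomaly_config(bw_floor = 0))
    cc <- 3.7
    k2 <- kde_score_map(obs * cc, E * cc, anomaly_config(bw_floor = 0))
    expect_equal(as.numeric(k2$density), as.numeric(k1$density) / cc,
                 tolerance = 1e-10)
    o <- order(as.numeric(k1$density))
    expect_true(all(diff(as.numeric(k1$score)[o]) <= 0))
    expect_true(all(as.numeric(k1$density) >= 0))
    expect_true(all(is.finite(as.numeric(k1$score))))
  })
})

test_that("an exactly reproduced voxel scores lower than a distant one", {
  # all reconstructions equal the observation at voxel 1; voxel 2 observed
  # far (>5 bandwidths) from every sample
  E <- cbind(rep(0.4, 6), rep(0.4, 6))
  obs <- array(c(0.4, 0.9), c(2, 1, 1))
  km <- kde_score_map(obs, E, anomaly_config())   # bw floor 1e-3 (sd = 0)
  expect_lt(km$score[1, 1, 1], km$score[2, 1, 1])
})

test_that("anomaly config validates and composes the ensemble size", {
  expect_error(anomaly_config(t = 0), "\\(0, 1\\]")
  cfg <- anomaly_config()
  expect_identical(cfg$S * cfg$Ddec, 300L)
})
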