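# Coordinate frames, channels, crops, rotations, pooling, spatial tokens.

test_that("coordinate channels span the frame endpoints with even spacing", {
  f <- whole_body_frame()
  ch <- make_coord_channels(c(2L, 1L, 1L), f)
  expect_identical(as.vector(ch[[1]]), c(0, 1))
  ch5 <- make_coord_channels(c(5L, 1L, 1L), f)
  expect_identical(as.vector(ch5[[1]]), c(0, 0.25, 0.5, 0.75, 1))
  # length-1 axes collapse to lo
  expect_identical(as.vector(ch5[[2]]), rep(0, 5))
  # a frame contracted to [0.2, 0.7] runs 0.2 at the first slice to 0.7 at
  # the last
  f2 <- coord_frame(rbind(c(0.2, 0.7), c(0, 1), c(0, 1)))
  ch2 <- make_coord_channels(c(6L, 2L, 2L), f2)
  expect_equal(range(ch2[[1]]), c(0.2, 0.7))
  expect_true(all(diff(ch2[[1]][, 1, 1]) > 0))
  # channel t varies only along its own axis
  expect_equal(ch2[[1]][3, 1, 1], ch2[[1]][3, 2, 2])
})

test_that("invalid frames are rejected", {
  expect_error(coord_frame(rbind(c(-0.2, 0.5), c(0, 1), c(0, 1))), "bounds")
  expect_error(coord_frame(rbind(c(0.8, 0.5), c(0, 1), c(0, 1))), "lo <= hi")
  expect_error(coord_frame(perm = c(1L, 1L, 3L)), "permutation")
})

test_that("crop_frame reproduces the parent channel sub-block exactly", {
  f <- whole_body_frame()
  shape <- c(101L, 33L, 17L)
  ch <- make_coord_channels(shape, f)
  cf <- crop_frame(f, shape, rbind(c(20L, 71L), c(5L, 30L), c(0L, 17L)))
  expect_identical(cf$bounds[1, ], c(0.2, 0.7))
  ch2 <- make_coord_channels(c(51L, 25L, 17L), cf)
  for (t in 1:3)
    expect_identical(ch2[[t]], ch[[t]][21:71, 6:30, 1:17])
  # full-extent crop leaves bounds unchanged
  idf <- crop_frame(f, shape, cbind(c(0L, 0L, 0L), shape))
  expect_identical(idf$bounds, f$bounds)
})

test_that("nested crops compose exactly (random boxes)", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      shape <- sample(10:60, 3, replace = TRUE)
      f0 <- coord_frame(cbind(runif(3, 0, 0.3), runif(3, 0.6, 1)))
      st1 <- vapply(shape, function(n) sample.int(n - 4L, 1L) - 1L, integer(1))
      en1 <- st1 + vapply(shape - st1, function(m) sample.int(m - 1L, 1L) + 1L, integer(1))
      f1 <- crop_frame(f0, shape, cbind(st1, en1))
      s1 <- en1 - st1
      st2 <- vapply(s1, function(n) sample.int(max(n - 2L, 1L), 1L) - 1L, integer(1))
      en2 <- st2 + vapply(s1 - st2, function(m) max(sample.int(m, 1L), 1L), integer(1))
      f2 <- crop_frame(f1, s1, cbind(st2, en2))
      f12 <- crop_frame(f0, shape, cbind(st1 + st2, st1 + en2))
      ch_a <- make_coord_channels(en2 - st2, f2)
      ch_b <- make_coord_channels(en2 - st2, f12)
      for (t in 1:3) expect_identical(ch_a[[t]], ch_b[[t]])
    }
  })
})

test_that("crop boxes must be non-empty and in bounds", {
  f <- whole_body_frame()
  expect_error(crop_frame(f, c(10L, 10L, 10L), rbind(c(4L, 4L), c(0L, 10L), c(0L, 10L))),
               "empty")
  expect_error(crop_frame(f, c(10L, 10L, 10L), rbind(c(0L, 11L), c(0L, 10L), c(0L, 10L))),
               "bounds")
})

test_that("rotation and channel synthesis commute for all 48 symmetries", {
  v <- fixture_volume(c(8L, 10L, 12L), seed = 7L)
  ch0 <- make_coord_channels(dim(v$data), v$frame)
  for (sym in axis_symmetries()) {
    rv <- rotate_frame(v, sym)
    cha <- make_coord_channels(dim(rv$data), rv$frame)
    for (t in 1:3)
      expect_identical(cha[[t]], apply_symmetry(ch0[[t]], sym))
  }
})

test_that("rotations compose and preserve anatomy", {
  v <- fixture_volume(c(6L, 6L, 6L), seed = 3L)
  id <- list(perm = 1:3, flip = c(FALSE, FALSE, FALSE))
  expect_identical(rotate_frame(v, id)$data, v$data)
  # two 90-degree rotations about one axis equal one 180-degree rotation
  r90 <- list(perm = c(2L, 1L, 3L), flip = c(TRUE, FALSE, FALSE))
  r180 <- compose_symmetry(r90, r90)
  v2 <- rotate_frame(rotate_frame(v, r90), r90)
  v3 <- rotate_frame(v, r180)
  expect_identical(v2$data, v3$data)
  expect_identical(v2$frame$perm, v3$frame$perm)
  expect_identical(v2$frame$sign, v3$frame$sign)
  # the anatomical channel follows the axis its anatomy was mapped to
  rv <- rotate_frame(v, list(perm = c(3L, 1L, 2L), flip = c(FALSE, TRUE, FALSE)))
  ch <- make_coord_channels(dim(rv$data), rv$frame)
  t1 <- rv$frame$perm[1]
  expect_gt(stats::sd(ch[[t1]][, 1, 1]), 0)   # varies along image axis 1
  expect_equal(stats::sd(ch[[t1]][1, , 1]), 0)
  expect_error(rotate_frame(v, list(perm = c(1L, 1L, 2L), flip = rep(FALSE, 3))),
               "orthogonal")
})

test_that("average pooling to latent resolution matches block means", {
  f <- whole_body_frame()
  ch <- make_coord_channels(c(8L, 8L, 8L), f)
  p <- pool_coords_to_latent(ch, 8L)
  expect_equal(unlist(lapply(p, as.numeric)), rep(0.5, 3), ignore_attr = TRUE)
  expect_identical(pool_coords_to_latent(ch, 1L), ch)
  withr::with_seed(5, {
    r <- array(runif(6 * 4 * 8), c(6L, 4L, 8L))
    rc <- structure(list(r, sqrt(r), r^2), class = "coord_channels")
    pm <- pool_coords_to_latent(rc, 2L)
    brute <- function(a, fct) {
      o <- array(0, dim(a) %/% fct)
      for (i in seq_len(dim(o)[1])) for (j in seq_len(dim(o)[2]))
        for (k in seq_len(dim(o)[3]))
          o[i, j, k] <- mean(a[((i - 1) * fct + 1):(i * fct),
                               ((j - 1) * fct + 1):(j * fct),
                               ((k - 1) * fct + 1):(k * fct)])
      o
    }
    expect_equal(pm[[1]], brute(r, 2), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(pm[[3]], brute(r^2, 2), tolerance = 1e-12, ignore_attr = TRUE)
  })
  expect_error(pool_coords_to_latent(ch, 3L), "divisible")
})

test_that("spatial tokens follow the base-B composition with top-bin clamp", {
  mk <- function(v1, v2, v3)
    structure(list(array(v1, c(1, 1, 1)), array(v2, c(1, 1, 1)),
                   array(v3, c(1, 1, 1))), class = "coord_channels")
  expect_identical(as.vector(quantize_spatial_tokens(mk(0, 0, 0), 20L)$sp), 0L)
  g <- quantize_spatial_tokens(mk(0.15, 0.26, 0.11), 20L)   # bins (3, 5, 2)
  expect_identical(as.vector(g$sp), 3L + 5L * 20L + 2L * 400L)
  top <- quantize_spatial_tokens(mk(1, 1, 1), 20L)
  expect_identical(as.vector(top$sp), 7999L)
  expect_identical(vapply(top$bins, as.integer, integer(1)), rep(19L, 3))
  expect_error(quantize_spatial_tokens(mk(1.2, 0, 0), 20L), "outside")
  # default bin width 0.05: value just below a boundary stays in its bin
  expect_identical(as.vector(quantize_spatial_tokens(mk(0.049999, 0, 0), 20L)$bins[[1]]), 0L)
  expect_identical(as.vector(quantize_spatial_tokens(mk(0.05, 0, 0), 20L)$bins[[1]]), 1L)
})

test_that("spatial token binning matches a brute-force oracle and inverts", {
  withr::with_seed(11, {
    for (B in c(2L, 7L, 20L)) {
      n <- 400L
      v <- lapply(1:3, function(i) array(runif(n), c(n, 1, 1)))
      g <- quantize_spatial_tokens(structure(v, class = "coord_channels"), B)
      brute <- vapply(seq_len(n), function(i) {
        b <- vapply(1:3, function(t) {
          bb <- 0L
          while (bb < B - 1L && v[[t]][i] >= (bb + 1) / B) bb <- bb + 1L
          bb
        }, integer(1))
        b[1] + b[2] * B + b[3] * B * B
      }, integer(1))
      expect_identical(as.vector(g$sp), brute)
    }
  })
  # exhaustive decode round-trip over all bin triples at B = 20
  B <- 20L
  bi <- rep(0:(B - 1), times = B * B)
  bj <- rep(rep(0:(B - 1), each = B), times = B)
  bk <- rep(0:(B - 1), each = B * B)
  sp <- bi + bj * B + bk * B * B
  expect_identical(sort(sp), 0:(B^3 - 1))          # bijection onto the range
  dec <- spatial_tokens_to_bins(sp, B)
  expect_identical(dec$b_i, bi)
  expect_identical(dec$b_j, bj)
  expect_identical(dec$b_k, bk)
})

test_that("frame sidecars round-trip including rotation and crop metadata", {
  v <- fixture_volume(c(9L, 7L, 5L), seed = 13L)
  rv <- rotate_frame(v, list(perm = c(2L, 3L, 1L), flip = c(TRUE, FALSE, TRUE)))
  path <- tempfile(fileext = ".frame.json")
  write_frame_sidecar(rv$frame, path)
  f2 <- read_frame_sidecar(path)
  ch_a <- make_coord_channels(dim(rv$data), rv$frame)
  ch_b <- make_coord_channels(dim(rv$data), f2)
  for (t in 1:3) expect_identical(ch_a[[t]], ch_b[[t]])
})
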