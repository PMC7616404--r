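# Coordinate frames, CoordConv-style channel synthesis, crop/rotation
# propagation, pooling to latent resolution, and quantized spatial tokens.
#
# A frame anchors a volume inside a whole-body [0,1] reference per anatomical
# axis. Random crops contract the per-axis range; 90-degree rotations permute
# and/or flip the image axes while the anatomical coordinates of every voxel
# are preserved. Crops additionally carry an exact reference-grid descriptor
# so that regenerating channels for a crop reproduces the parent's values
# bitwise (the property the whole geometry-invariant pipeline rests on).

#' Construct a coordinate frame
#'
#' @param bounds 3x2 numeric matrix (or list of pairs), row t holding the
#'   `(lo, hi)` sub-interval of the whole-body `[0,1]` reference covered by
#'   anatomical axis t. The whole-body frame is `((0,1),(0,1),(0,1))`.
#' @param perm integer(3); image axis `a` displays anatomical axis `perm[a]`.
#' @param sign integer(3) of +/-1; -1 means image axis `a` traverses its
#'   anatomical axis in descending coordinate order (a flip).
#' @param ref internal exact-grid descriptors (set by [crop_frame()]); one
#'   entry per image axis or `NULL`.
#' @return an object of class `coord_frame`.
#' @export
coord_frame <- function(bounds = cbind(c(0, 0, 0), c(1, 1, 1)),
                        perm = 1:3, sign = c(1L, 1L, 1L), ref = NULL) {
  if (is.list(bounds)) bounds <- do.call(rbind, bounds)
  bounds <- matrix(as.numeric(bounds), nrow = 3, ncol = 2)
  f <- structure(list(bounds = bounds, perm = as.integer(perm),
                      sign = as.integer(sign),
                      ref = ref %||% vector("list", 3L)),
                 class = "coord_frame")
  validate_frame(f)
  f
}

#' @export
print.coord_frame <- function(x, ...) {
  cat("<coord_frame>\n")
  for (t in 1:3)
    cat(sprintf("  anat axis %d: [%.6g, %.6g]\n", t, x$bounds[t, 1], x$bounds[t, 2]))
  if (!identical(x$perm, 1:3) || any(x$sign < 0))
    cat("  perm:", x$perm * x$sign, "\n")
  invisible(x)
}

#' Whole-body identity frame
#' @return a `coord_frame` spanning `[0,1]` on every axis.
#' @export
whole_body_frame <- function() coord_frame()

validate_frame <- function(f) {
  if (!inherits(f, "coord_frame")) stop("not a coord_frame")
  b <- f$bounds
  if (any(!is.finite(b)) || any(b < -1e-12) || any(b > 1 + 1e-12))
    stop("frame bounds must lie in [0, 1]")
  if (any(b[, 1] > b[, 2])) stop("frame bounds must satisfy lo <= hi")
  if (!identical(sort(f$perm), 1:3)) stop("frame perm must be a permutation of 1:3")
  if (!all(f$sign %in% c(-1L, 1L))) stop("frame sign entries must be +/-1")
  invisible(TRUE)
}

# Canonical ascending coordinate values along image axis `a` of length n.
# With an exact-grid descriptor the value at index r is computed by the
# *same* floating-point expression the parent grid used at its own index
# off + r, which is what makes crop sub-blocks reproduce bitwise.
axis_values <- function(frame, a, n) {
  t <- frame$perm[a]
  r <- frame$ref[[a]]
  if (is.null(r)) {
    lo <- frame$bounds[t, 1]; hi <- frame$bounds[t, 2]
    if (n == 1L) return(lo)
    lo + (hi - lo) * ((0:(n - 1)) / (n - 1))
  } else {
    idx <- r$off + 0:(n - 1)
    if (r$n0 == 1L) return(rep(r$lo0, n))
    r$lo0 + (r$hi0 - r$lo0) * (idx / (r$n0 - 1))
  }
}

#' Synthesize CoordConv coordinate channels for a volume shape
#'
#' Produces three scalar grids holding, at every voxel, the voxel's
#' whole-body coordinate along each anatomical axis, evenly spaced from the
#' frame's `lo` to `hi` inclusive (a length-1 axis yields `lo`). Channel t
#' varies only along the image axis that displays anatomical axis t.
#'
#' @param shape integer(3) of positive grid dimensions.
#' @param frame a [coord_frame()].
#' @return list of three arrays of dim `shape`, indexed by anatomical axis;
#'   class `coord_channels`.
#' @export
make_coord_channels <- function(shape, frame) {
  validate_frame(frame)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive integers")
  ch <- vector("list", 3L)
  for (a in 1:3) {
    t <- frame$perm[a]
    v <- axis_values(frame, a, shape[a])
    if (frame$sign[a] < 0L) v <- rev(v)
    idx <- slice.index(array(0L, shape), a)
    ch[[t]] <- array(v[idx], shape)
  }
  structure(ch, class = "coord_channels", shape = shape)
}

#' Contract a coordinate frame to a crop
#'
#' Index intervals are half-open `[start, stop)` and 0-based, in array index
#' order. The returned frame's per-axis bounds equal the parent coordinate
#' values at the first and last retained index, so channels regenerated for
#' the crop equal the parent's sub-block exactly.
#'
#' @param parent_frame a [coord_frame()].
#' @param parent_shape integer(3) parent grid dimensions.
#' @param crop_box 3x2 integer matrix of `(start, stop)` per image axis.
#' @return the cropped `coord_frame`.
#' @export
crop_frame <- function(parent_frame, parent_shape, crop_box) {
  validate_frame(parent_frame)
  parent_shape <- as.integer(parent_shape)
  crop_box <- matrix(as.integer(crop_box), nrow = 3, ncol = 2)
  st <- crop_box[, 1]; en <- crop_box[, 2]
  if (any(st < 0L) || any(en > parent_shape) || any(en <= st))
    stop("crop box out of bounds or empty")
  bounds <- parent_frame$bounds
  ref <- vector("list", 3L)
  for (a in 1:3) {
    n <- parent_shape[a]; m <- en[a] - st[a]; t <- parent_frame$perm[a]
    # canonical (ascending) offset of the retained block
    off <- if (parent_frame$sign[a] < 0L) n - en[a] else st[a]
    pr <- parent_frame$ref[[a]]
    ref[[a]] <- if (is.null(pr)) {
      list(lo0 = bounds[t, 1], hi0 = bounds[t, 2], n0 = n, off = off)
    } else {
      list(lo0 = pr$lo0, hi0 = pr$hi0, n0 = pr$n0, off = pr$off + off)
    }
  }
  child <- structure(list(bounds = bounds, perm = parent_frame$perm,
                          sign = parent_frame$sign, ref = ref),
                     class = "coord_frame")
  for (a in 1:3) {
    t <- child$perm[a]; m <- en[a] - st[a]
    v <- axis_values(child, a, m)
    child$bounds[t, ] <- c(v[1], v[m])
  }
  child
}

# ---- axis-aligned orthogonal symmetries ------------------------------------

#' Enumerate the 48 axis-aligned orthogonal symmetries
#'
#' Each symmetry is a signed axis permutation: output axis `a` draws from
#' input axis `perm[a]`, reversed when `flip[a]` is `TRUE`. The 24 with
#' positive determinant are the 90-degree rotation group; the full set of 48
#' includes reflections.
#'
#' @param proper_only if `TRUE`, return only the 24 proper rotations.
#' @return list of `list(perm=, flip=)` descriptors.
#' @export
axis_symmetries <- function(proper_only = FALSE) {
  perms <- list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))
  out <- list()
  for (p in perms) {
    sgn_p <- if (identical(p, c(1L,2L,3L)) || identical(p, c(2L,3L,1L)) ||
                 identical(p, c(3L,1L,2L))) 1 else -1
    for (m in 0:7) {
      fl <- c(bitwAnd(m, 1L) > 0L, bitwAnd(m, 2L) > 0L, bitwAnd(m, 4L) > 0L)
      det <- sgn_p * prod(ifelse(fl, -1, 1))
      if (proper_only && det < 0) next
      out[[length(out) + 1L]] <- list(perm = p, flip = fl)
    }
  }
  out
}

#' Apply a signed axis permutation to a 3D array
#' @param arr 3D array.
#' @param sym a symmetry descriptor from [axis_symmetries()].
#' @return the transformed array.
#' @export
apply_symmetry <- function(arr, sym) {
  check_symmetry(sym)
  y <- aperm(arr, sym$perm)
  d <- dim(y)
  if (sym$flip[1]) y <- y[d[1]:1, , , drop = FALSE]
  if (sym$flip[2]) y <- y[, d[2]:1, , drop = FALSE]
  if (sym$flip[3]) y <- y[, , d[3]:1, drop = FALSE]
  y
}

check_symmetry <- function(sym) {
  if (!is.list(sym) || !identical(sort(as.integer(sym$perm)), 1:3) ||
      length(sym$flip) != 3L || !is.logical(sym$flip))
    stop("unsupported transform: only axis-aligned orthogonal symmetries are implemented")
  invisible(TRUE)
}

#' Compose two symmetries (apply `s1` first, then `s2`)
#' @param s2,s1 symmetry descriptors.
#' @return the composed descriptor.
#' @export
compose_symmetry <- function(s2, s1) {
  perm <- s1$perm[s2$perm]
  flip <- xor(s2$flip, s1$flip[s2$perm])
  list(perm = as.integer(perm), flip = flip)
}

#' Rotate a volume by an axis-aligned orthogonal symmetry
#'
#' Voxel data, spacing and the coordinate frame are transformed together, so
#' the anatomical coordinate of every voxel is preserved: channels generated
#' from the rotated frame equal the rotated channels of the source.
#'
#' @param volume a [volume()].
#' @param rotation a symmetry descriptor from [axis_symmetries()].
#' @return the rotated `volume`.
#' @export
rotate_frame <- function(volume, rotation) {
  check_symmetry(rotation)
  p <- rotation$perm; fl <- rotation$flip
  f <- volume$frame
  nf <- structure(list(bounds = f$bounds,
                       perm = f$perm[p],
                       sign = as.integer(f$sign[p] * ifelse(fl, -1L, 1L)),
                       ref = f$ref[p]),
                  class = "coord_frame")
  volume$data <- apply_symmetry(volume$data, rotation)
  volume$spacing <- volume$spacing[p]
  volume$frame <- nf
  volume
}

#' Average-pool coordinate channels to latent resolution
#'
#' Each channel is pooled independently with kernel size and stride equal to
#' the codec's downsampling factor, mirroring how the encoder collapses
#' voxels into latent positions.
#'
#' @param channels a `coord_channels` object.
#' @param factor positive integer pooling factor.
#' @return pooled `coord_channels` at latent resolution.
#' @export
pool_coords_to_latent <- function(channels, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(channels)
  shp <- dim(channels[[1]])
  if (any(shp %% factor != 0L))
    stop("shape not divisible by pooling factor; pad the volume first")
  out <- lapply(channels, function(ch) block_mean(ch, factor))
  structure(out, class = "coord_channels", shape = shp %/% factor)
}

# Mean over non-overlapping factor^3 blocks, one axis at a time.
block_mean <- function(a, f) {
  for (ax in 1:3) {
    d <- dim(a)
    a <- aperm(a, c(ax, setdiff(1:3, ax)))
    da <- dim(a)
    dim(a) <- c(f, da[1] %/% f, da[2], da[3])
    a <- colMeans(a)                      # drops the block dimension
    a <- aperm(a, order(c(ax, setdiff(1:3, ax))))
  }
  a
}

# ---- quantized spatial tokens ----------------------------------------------

#' Quantize latent-resolution coordinates into spatial tokens
#'
#' Bins each pooled coordinate channel into `B` equal bins of width `1/B`
#' (value 1.0 clamps into the top bin) and composes the per-voxel bin triple
#' by base-B positional notation: `sp = b_i + b_j * B + b_k * B^2`.
#'
#' @param latent_coords pooled `coord_channels` (values in `[0,1]`).
#' @param B positive integer bin count (default 20, bins of 0.05).
#' @return a `spatial_token_grid`: list with integer array `sp`, bin arrays
#'   `bins` and the bin count `B`.
#' @export
quantize_spatial_tokens <- function(latent_coords, B = 20L) {
  B <- as.integer(B)
  if (B < 1L) stop("B must be a positive integer")
  vals <- lapply(latent_coords, as.numeric)
  rng <- range(unlist(vals))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("coordinate values outside [0, 1]")
  bins <- lapply(latent_coords, function(ch) {
    v <- pmin(pmax(ch, 0), 1)
    b <- pmin(as.integer(floor(v * B)), B - 1L)
    array(b, dim(ch))
  })
  sp <- bins[[1]] + bins[[2]] * B + bins[[3]] * (B * B)
  structure(list(sp = sp, bins = bins, B = B), class = "spatial_token_grid")
}

#' Decode spatial tokens back into bin triples
#' @param sp integer array (or vector) of spatial tokens.
#' @param B bin count used to compose them.
#' @return list of three integer arrays `(b_i, b_j, b_k)`.
#' @export
spatial_tokens_to_bins <- function(sp, B) {
  B <- as.integer(B)
  list(b_i = sp %% B, b_j = (sp %/% B) %% B, b_k = sp %/% (B * B))
}

# ---- frame sidecar serialization -------------------------------------------

#' Write / read a coordinate-frame JSON sidecar
#'
#' The sidecar stores the per-axis `[lo, hi]` bounds and the signed axis
#' permutation, plus (when present) the exact crop reference grid so that
#' round-tripping preserves bitwise channel reproduction.
#'
#' @param frame a `coord_frame`.
#' @param path file path of the sidecar (conventionally `<image>.frame.json`).
#' @return `write_frame_sidecar` returns `path` invisibly;
#'   `read_frame_sidecar` returns the `coord_frame`.
#' @export
write_frame_sidecar <- function(frame, path) {
  validate_frame(frame)
  obj <- list(frame = lapply(1:3, function(t) frame$bounds[t, ]),
              perm = frame$perm * frame$sign)
  if (any(!vapply(frame$ref, is.null, logical(1)))) obj$ref <- frame$ref
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frame_sidecar
#' @export
read_frame_sidecar <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  sperm <- as.integer(unlist(obj$perm))
  ref <- NULL
  if (!is.null(obj$ref)) {
    ref <- lapply(obj$ref, function(r) {
      if (is.null(r) || length(r) == 0) NULL
      else list(lo0 = as.numeric(r$lo0), hi0 = as.numeric(r$hi0),
                n0 = as.integer(r$n0), off = as.integer(r$off))
    })
  }
  coord_frame(bounds = matrix(as.numeric(unlist(obj$frame)), nrow = 3, byrow = TRUE),
              perm = abs(sperm), sign = sign(sperm), ref = ref)
}
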