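# Seeded synthetic phantoms: paired two-modality 3D volumes with a shared
# body-shaped support, anatomically placed "organ" blobs, optional bright
# focal lesions in the primary modality, plus the geometric variation the
# pipeline is built for - two voxel-size presets, random-crop FOVs and
# 90-degree rotations. The anatomy is a continuous function of whole-body
# coordinates, so a fine-resolution (smaller-FOV) scan samples the same body
# at a different geometry and the coordinate channels genuinely carry
# information.

# Anatomical organ template: whole-body coordinates, radii (whole-body
# units), and per-modality contrasts. Fixed across phantoms (jittered per
# case) so that intensity is predictable from position.
.organ_template <- data.frame(
  u1 = c(0.36, 0.62, 0.42, 0.60, 0.50, 0.50),
  u2 = c(0.44, 0.50, 0.56, 0.48, 0.44, 0.58),
  u3 = c(0.72, 0.60, 0.44, 0.30, 0.86, 0.18),
  r  = c(0.10, 0.16, 0.12, 0.11, 0.12, 0.09),
  c_primary = c(0.32, 0.18, -0.08, 0.12, 0.36, 0.22),
  c_aux     = c(0.12, 0.30, 0.22, -0.10, 0.26, 0.08)
)

#' Phantom specification
#'
#' @param shape integer(3) grid shape.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param frame [coord_frame()] placing the grid in the whole-body reference.
#' @param body_axes ellipsoid semi-axes as fractions of the reference.
#' @param organ_jitter SD of the per-case jitter on organ centres.
#' @param n_lesions number of bright focal lesions (0 for healthy phantoms).
#' @param lesion_radius_vox lesion radius range in voxels.
#' @param lesion_contrast lesion-to-local-background intensity multiplier
#'   (>= 2).
#' @param noise_sd additive Gaussian noise SD (post-normalization scale).
#' @param seed integer; fully determines the phantom.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 32L), spacing = c(3.6, 3.6, 3),
                         frame = whole_body_frame(),
                         body_axes = c(0.42, 0.38, 0.46),
                         organ_jitter = 0.02, n_lesions = 0L,
                         lesion_radius_vox = c(2, 4), lesion_contrast = 2.5,
                         noise_sd = 0.02, seed = 1L) {
  if (lesion_contrast < 2 && n_lesions > 0L)
    warning("lesion contrast below 2 gives weakly separable lesions")
  structure(list(shape = as.integer(shape), spacing = spacing, frame = frame,
                 body_axes = body_axes, organ_jitter = organ_jitter,
                 n_lesions = as.integer(n_lesions),
                 lesion_radius_vox = lesion_radius_vox,
                 lesion_contrast = lesion_contrast, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "phantom_spec")
}

#' Resolution presets
#'
#' `"coarse"` is a whole-body grid at 3.6x3.6x3 mm; `"fine"` samples a
#' central sub-FOV of the same body at 2.036x2.036x3 mm (spacing ratio
#' ~1.77), so the two presets share one anatomical template at different
#' geometries.
#'
#' @param preset `"coarse"` or `"fine"`.
#' @param shape grid shape (default 32^3).
#' @return list `(spacing, frame)` to splice into [phantom_spec()].
#' @export
phantom_preset <- function(preset = c("coarse", "fine"), shape = c(32L, 32L, 32L)) {
  preset <- match.arg(preset)
  if (preset == "coarse")
    return(list(spacing = c(3.6, 3.6, 3), frame = whole_body_frame()))
  ratio <- 2.036 / 3.6
  lo <- (1 - ratio) / 2
  b <- rbind(c(lo, lo + ratio), c(lo, lo + ratio), c(0.15, 0.85))
  list(spacing = c(2.036, 2.036, 3), frame = coord_frame(bounds = b))
}

#' Generate a paired two-modality phantom
#'
#' The primary volume emulates a PET-like scan (body + organ uptake + hot
#' lesions + noise); the auxiliary volume shares the anatomy with its own
#' contrasts and no lesions (CT-like). Lesions are uniform bright balls set
#' to `1.2 * lesion_contrast` times the mean intensity of their surrounding
#' shell, so the contrast invariant holds under the configured noise.
#'
#' @param spec a [phantom_spec()].
#' @return list `primary`, `auxiliary` ([volume()]s), `lesion_mask`
#'   (integer array), `frame`.
#' @export
generate_phantom <- function(spec) {
  ch <- make_coord_channels(spec$shape, spec$frame)
  u1 <- ch[[1]]; u2 <- ch[[2]]; u3 <- ch[[3]]
  ax <- spec$body_axes
  e <- ((u1 - 0.5) / ax[1])^2 + ((u2 - 0.5) / ax[2])^2 + ((u3 - 0.5) / ax[3])^2
  body <- 1 / (1 + exp((e - 1) / 0.08))
  with_seed(spec$seed, {
    # background uptake/attenuation trend smoothly along the body axes,
    # emulating the position-dependent baseline of real acquisitions
    primary <- (0.12 + 0.14 * u3) * body
    aux <- (0.28 + 0.12 * u1) * body
    tmpl <- .organ_template
    for (i in seq_len(nrow(tmpl))) {
      cen <- c(tmpl$u1[i], tmpl$u2[i], tmpl$u3[i]) +
        stats::rnorm(3, sd = spec$organ_jitter)
      rad <- tmpl$r[i] * stats::runif(1, 0.9, 1.1)
      g <- exp(-(((u1 - cen[1])^2 + (u2 - cen[2])^2 + (u3 - cen[3])^2) /
                   (2 * (rad / 2)^2)))
      primary <- primary + tmpl$c_primary[i] * g * body
      aux <- aux + tmpl$c_aux[i] * g * body
    }
    mask <- array(0L, spec$shape)
    if (spec$n_lesions > 0L) {
      step <- if (spec$shape[1] > 1L)
        (spec$frame$bounds[1, 2] - spec$frame$bounds[1, 1]) / (spec$shape[1] - 1L)
        else 0.03
      for (l in seq_len(spec$n_lesions)) {
        placed <- FALSE
        for (attempt in 1:50) {
          cen <- 0.5 + (stats::runif(3) - 0.5) * 1.2 * ax
          ec <- sum(((cen - 0.5) / ax)^2)
          if (ec > 0.5) next
          # skip centres outside this volume's FOV
          in_fov <- cen[1] >= min(u1) && cen[1] <= max(u1) &&
                    cen[2] >= min(u2) && cen[2] <= max(u2) &&
                    cen[3] >= min(u3) && cen[3] <= max(u3)
          if (!in_fov) next
          r_vox <- stats::runif(1, spec$lesion_radius_vox[1], spec$lesion_radius_vox[2])
          r_u <- r_vox * step
          d2 <- (u1 - cen[1])^2 + (u2 - cen[2])^2 + (u3 - cen[3])^2
          m <- d2 <= r_u^2 & body > 0.5
          if (sum(m) < 4L) next
          shell <- d2 > r_u^2 & d2 <= (2 * r_u)^2 & body > 0.5 & mask == 0L
          bg <- if (sum(shell) > 0L) mean(primary[shell]) else mean(primary[body > 0.5])
          primary[m] <- 1.2 * spec$lesion_contrast * bg
          mask[m] <- 1L
          placed <- TRUE
          break
        }
        if (!placed) stop("could not place a lesion inside the body support")
      }
    }
    primary <- pmax(primary + stats::rnorm(length(primary), sd = spec$noise_sd), 0)
    aux <- pmax(aux + stats::rnorm(length(aux), sd = spec$noise_sd * 0.5), 0)
  })
  dim(primary) <- spec$shape; dim(aux) <- spec$shape
  list(primary = volume(primary, spec$spacing, spec$frame, "primary"),
       auxiliary = volume(aux, spec$spacing, spec$frame, "auxiliary"),
       lesion_mask = mask, frame = spec$frame)
}

#' Corpus augmentation configuration
#' @param crop_sizes cube sizes (voxels, multiples of the codec factor)
#'   used for the cropped test variant.
#' @param proper_rotations use only the 24 proper rotations for the rotated
#'   test variant.
#' @return a list.
#' @export
corpus_aug <- function(crop_sizes = c(20L, 24L), proper_rotations = TRUE) {
  list(crop_sizes = as.integer(crop_sizes),
       proper_rotations = isTRUE(proper_rotations))
}

#' Generate a train/val/test phantom corpus
#'
#' Training phantoms are healthy (the unsupervised premise); validation and
#' test phantoms carry lesions. Test cases cycle through four variants:
#' full-FOV coarse, full-FOV fine, cropped (crop box guaranteed to contain
#' a lesion) and rotated (random 90-degree symmetry). Training cases
#' alternate between the coarse and fine presets.
#'
#' @param n total number of cases; split 60/15/25 into train/val/test.
#' @param template a [phantom_spec()] supplying everything but geometry,
#'   lesions and seed.
#' @param aug a [corpus_aug()].
#' @param seed global corpus seed; each case derives its own.
#' @param dir optional directory: writes NIfTI volumes, frame sidecars,
#'   lesion masks and a `manifest.csv`.
#' @return list `manifest` (data.frame) and `cases` (in-memory case list:
#'   `id, split, variant, primary, auxiliary, mask`).
#' @export
make_corpus <- function(n, template = phantom_spec(), aug = corpus_aug(),
                        seed = 1L, dir = NULL) {
  stopifnot(n >= 3L)
  n_train <- max(1L, round(0.6 * n))
  n_val <- max(1L, round(0.15 * n))
  n_test <- n - n_train - n_val
  if (n_test < 1L) { n_train <- n_train - (1L - n_test); n_test <- 1L }
  variants <- c("full_coarse", "full_fine", "cropped", "rotated")
  syms <- axis_symmetries(proper_only = aug$proper_rotations)
  syms <- Filter(function(s) !(identical(s$perm, 1:3) && !any(s$flip)), syms)
  cases <- list(); rows <- list()
  idx <- 0L
  add_case <- function(id, split, variant, ph, mask) {
    cases[[id]] <<- list(id = id, split = split, variant = variant,
                         primary = ph$primary, auxiliary = ph$auxiliary,
                         mask = mask)
    rows[[id]] <<- data.frame(id = id, split = split, variant = variant,
                              n_lesion_vox = sum(mask),
                              spacing = paste(signif(ph$primary$spacing, 4),
                                              collapse = "x"),
                              stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_train)) {
    idx <- idx + 1L
    pre <- phantom_preset(if (i %% 2L == 0L) "fine" else "coarse", template$shape)
    sp <- template
    sp$spacing <- pre$spacing; sp$frame <- pre$frame
    sp$n_lesions <- 0L; sp$seed <- derive_seed(seed, paste0("case", idx))
    ph <- generate_phantom(sp)
    add_case(sprintf("train_%03d", i), "train", "healthy", ph,
             array(0L, template$shape))
  }
  lesioned_spec <- function(preset, case_seed) {
    pre <- phantom_preset(preset, template$shape)
    sp <- template
    sp$spacing <- pre$spacing; sp$frame <- pre$frame
    sp$n_lesions <- max(1L, template$n_lesions)
    sp$seed <- case_seed
    sp
  }
  for (i in seq_len(n_val)) {
    idx <- idx + 1L
    ph <- generate_phantom(lesioned_spec("coarse", derive_seed(seed, paste0("case", idx))))
    add_case(sprintf("val_%03d", i), "val", "full_coarse", ph, attr_mask(ph))
  }
  for (i in seq_len(n_test)) {
    idx <- idx + 1L
    variant <- variants[(i - 1L) %% length(variants) + 1L]
    cseed <- derive_seed(seed, paste0("case", idx))
    if (variant %in% c("full_coarse", "cropped")) {
      ph <- generate_phantom(lesioned_spec("coarse", cseed))
    } else {
      ph <- generate_phantom(lesioned_spec("fine", cseed))
    }
    mask <- attr_mask(ph)
    if (variant == "cropped") {
      cb <- with_seed(derive_seed(cseed, "cropbox"),
                      lesion_crop_box(mask, aug$crop_sizes, template$shape))
      ph$primary <- crop_volume(ph$primary, cb)
      ph$auxiliary <- crop_volume(ph$auxiliary, cb)
      mask <- mask[(cb[1, 1] + 1L):cb[1, 2], (cb[2, 1] + 1L):cb[2, 2],
                   (cb[3, 1] + 1L):cb[3, 2], drop = FALSE]
    } else if (variant == "rotated") {
      sym <- with_seed(derive_seed(cseed, "rot"),
                       syms[[sample.int(length(syms), 1L)]])
      ph$primary <- rotate_frame(ph$primary, sym)
      ph$auxiliary <- rotate_frame(ph$auxiliary, sym)
      mask <- apply_symmetry(mask, sym)
    }
    add_case(sprintf("test_%03d", i), "test", variant, ph, mask)
  }
  manifest <- do.call(rbind, rows[names(cases)])
  rownames(manifest) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$primary_path <- manifest$aux_path <- manifest$mask_path <- NA_character_
    for (j in seq_len(nrow(manifest))) {
      cs <- cases[[manifest$id[j]]]
      pp <- file.path(dir, paste0(cs$id, "_primary.nii"))
      pa <- file.path(dir, paste0(cs$id, "_aux.nii"))
      pm <- file.path(dir, paste0(cs$id, "_mask.nii"))
      write_volume(cs$primary, pp)
      write_volume(cs$auxiliary, pa)
      write_volume(volume(cs$mask + 0, cs$primary$spacing, cs$primary$frame), pm)
      manifest$primary_path[j] <- pp; manifest$aux_path[j] <- pa
      manifest$mask_path[j] <- pm
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(manifest = manifest, cases = cases)
}

attr_mask <- function(ph) ph$lesion_mask

# Pick a cube crop box (0-based, half-open) guaranteed to contain a lesion
# voxel; assumes the mask is non-empty.
lesion_crop_box <- function(mask, sizes, shape) {
  w <- which(mask > 0L, arr.ind = TRUE)
  anchor <- w[sample.int(nrow(w), 1L), ]        # 1-based voxel index
  sz <- sizes[sizes <= min(shape)]
  sz <- sz[sample.int(length(sz), 1L)]
  st <- integer(3)
  for (a in 1:3) {
    lo_min <- max(0L, anchor[a] - sz)           # keep anchor inside [st, st+sz)
    lo_max <- min(shape[a] - sz, anchor[a] - 1L)
    if (lo_max < lo_min) lo_max <- lo_min
    st[a] <- lo_min + sample.int(lo_max - lo_min + 1L, 1L) - 1L
  }
  cbind(st, st + sz)
}
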