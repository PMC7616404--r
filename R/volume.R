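# Volume container: a 3D scalar grid with voxel spacing, a coordinate frame
# and a modality tag; NIfTI round-trip with a JSON frame sidecar.

#' Construct a volume
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric(3) voxel spacing in mm (all > 0).
#' @param frame a [coord_frame()] anchoring the volume in the whole-body
#'   reference; defaults to the whole-body frame.
#' @param modality `"primary"` (e.g. PET-like) or `"auxiliary"` (CT-like).
#' @return an object of class `volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), frame = whole_body_frame(),
                   modality = c("primary", "auxiliary")) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (any(!is.finite(data))) stop("volume data must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  validate_frame(frame)
  structure(list(data = data, spacing = spacing, frame = frame,
                 modality = modality), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume %s> %dx%dx%d, spacing %.3gx%.3gx%.3g mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Crop a volume and contract its frame
#'
#' @param vol a [volume()].
#' @param crop_box 3x2 integer matrix of half-open, 0-based `(start, stop)`
#'   index intervals per image axis.
#' @return the cropped `volume` with frame updated via [crop_frame()].
#' @export
crop_volume <- function(vol, crop_box) {
  crop_box <- matrix(as.integer(crop_box), 3, 2)
  nf <- crop_frame(vol$frame, dim(vol$data), crop_box)
  st <- crop_box[, 1] + 1L; en <- crop_box[, 2]
  vol$data <- vol$data[st[1]:en[1], st[2]:en[2], st[3]:en[3], drop = FALSE]
  vol$frame <- nf
  vol
}

#' Pad a volume so each dimension is a multiple of the downsampling factor
#'
#' Pads at the high end with edge values. The padding record allows exact
#' un-padding; coordinate channels for the padded extent are synthesized by
#' [padded_coord_channels()] via linear extrapolation clamped to `[0,1]`.
#'
#' @param vol a [volume()].
#' @param F downsampling factor (>= 1).
#' @return list `(volume = padded volume, pad = integer(3) of voxels added)`.
#' @export
pad_to_factor <- function(vol, F) {
  F <- as.integer(F)
  if (F < 1L) stop("F must be >= 1")
  d <- dim(vol$data)
  pad <- (F - d %% F) %% F
  if (all(pad == 0L)) return(list(volume = vol, pad = pad))
  nd <- d + pad
  x <- array(0, nd)
  x[1:d[1], 1:d[2], 1:d[3]] <- vol$data
  if (pad[1] > 0L) x[(d[1] + 1L):nd[1], , ] <- x[rep(d[1], pad[1]), , ]
  if (pad[2] > 0L) x[, (d[2] + 1L):nd[2], ] <- x[, rep(d[2], pad[2]), ]
  if (pad[3] > 0L) x[, , (d[3] + 1L):nd[3]] <- x[, , rep(d[3], pad[3])]
  vol$data <- x
  list(volume = vol, pad = pad)
}

#' Undo [pad_to_factor()]
#' @param vol the padded volume.
#' @param pad the padding record.
#' @return the original-extent volume.
#' @export
unpad_volume <- function(vol, pad) {
  d <- dim(vol$data) - pad
  vol$data <- vol$data[1:d[1], 1:d[2], 1:d[3], drop = FALSE]
  vol
}

#' Coordinate channels for a padded extent
#'
#' The true frame describes the unpadded grid; padded voxels get coordinates
#' extrapolated at the parent grid step, clamped to `[0,1]`, so the encoder
#' sees a smooth coordinate field over the whole padded block.
#'
#' @param vol the *unpadded* volume.
#' @param pad integer(3) padding record from [pad_to_factor()].
#' @return `coord_channels` of the padded shape.
#' @export
padded_coord_channels <- function(vol, pad) {
  d <- dim(vol$data)
  ch <- make_coord_channels(d, vol$frame)
  if (all(pad == 0L)) return(ch)
  nd <- d + pad
  out <- lapply(1:3, function(t) {
    a <- array(0, nd)
    a[1:d[1], 1:d[2], 1:d[3]] <- ch[[t]]
    a
  })
  for (ax in 1:3) {
    if (pad[ax] == 0L) next
    # per-axis linear extrapolation using the last grid step along ax
    for (t in 1:3) {
      last <- extract_slice(out[[t]], ax, d[ax])
      prev <- if (d[ax] >= 2L) extract_slice(out[[t]], ax, d[ax] - 1L) else last
      delta <- last - prev
      for (p in seq_len(pad[ax])) {
        val <- pmin(pmax(last + p * delta, 0), 1)
        out[[t]] <- assign_slice(out[[t]], ax, d[ax] + p, val)
      }
    }
  }
  structure(out, class = "coord_channels", shape = nd)
}

extract_slice <- function(a, ax, i) {
  switch(ax, a[i, , , drop = TRUE], a[, i, , drop = TRUE], a[, , i, drop = TRUE])
}
assign_slice <- function(a, ax, i, val) {
  switch(ax,
         { a[i, , ] <- val; a },
         { a[, i, ] <- val; a },
         { a[, , i] <- val; a })
}
#' Write / read a volume as NIfTI with a frame sidecar
#'
#' Spacing goes into the NIfTI pixdim; the coordinate frame is stored in a
#' `<path>.frame.json` sidecar (see [write_frame_sidecar()]).
#'
#' @param vol a [volume()].
#' @param path NIfTI file path (`.nii` / `.nii.gz`).
#' @param modality modality tag restored on read.
#' @return `write_volume` returns `path` invisibly; `read_volume` the `volume`.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  write_frame_sidecar(vol$frame, sidecar_path(path))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, modality = "primary") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  frame <- if (file.exists(sidecar_path(path))) read_frame_sidecar(sidecar_path(path))
           else whole_body_frame()
  volume(array(as.numeric(img), dim(img)[1:3]), spacing = sp, frame = frame,
         modality = modality)
}

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".frame.json")
}
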