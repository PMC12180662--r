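# Volume container and NIfTI I/O plus the array-level preprocessing steps:
# center crop, min-max intensity rescaling, isotropic resize-and-pad.
# Data layout is (D, H, W): the axial slice index runs along the first axis.

# Canonical affine: voxel axis 1 (slice axis) -> world z, axis 2 -> y,
# axis 3 -> x.
.canonical_affine <- function() {
  a <- matrix(0, 4, 4)
  a[1, 3] <- 1; a[2, 2] <- 1; a[3, 1] <- 1; a[4, 4] <- 1
  a
}

#' Construct a volume object
#'
#' @param data Numeric 3D array laid out `(D, H, W)` with the axial slice
#'   index along the first axis.
#' @param affine 4x4 voxel-to-world transform; defaults to a canonical affine
#'   mapping the slice axis to world z.
#' @param meta Optional list of provenance fields.
#' @return An object of class `volume`.
#' @export
as_volume <- function(data, affine = NULL, meta = list()) {
  if (inherits(data, "volume")) return(data)
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (is.null(affine)) affine <- .canonical_affine()
  structure(list(data = data, affine = affine, meta = meta), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s  range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Write a volume as NIfTI-1
#'
#' @param vol A [as_volume()] object or 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type, `"float"` for intensities or
#'   `"uint8"` for masks.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path, datatype = "float") {
  vol <- as_volume(vol)
  img <- RNifti::asNifti(vol$data, datatype = datatype)
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  ok <- tryCatch({
    RNifti::writeNifti(img, path)
    TRUE
  }, error = function(e) {
    stop("failed to write NIfTI volume to '", path, "': ",
         conditionMessage(e))
  })
  invisible(path)
}

#' Read a NIfTI volume, canonicalizing the slice axis
#'
#' Reads a 3D NIfTI file and permutes the voxel axes so that axis 1 is the
#' axis most closely aligned with the world z (inferior--superior) direction,
#' i.e. the axial stacking axis.
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return A [as_volume()] object.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) != 3L) {
    stop("expected a 3D volume but '", path, "' has ", length(d),
         " dimensions; 4D/time-series inputs are not supported")
  }
  aff <- unclass(RNifti::xform(path))
  data <- array(as.numeric(img), dim = d)
  # Which voxel axis is dominantly aligned with world z?
  dom <- apply(abs(aff[1:3, 1:3]), 2, which.max)
  zaxis <- which(dom == 3L)
  perm <- seq_len(3L)
  if (length(zaxis) == 1L && zaxis != 1L) {
    perm <- c(zaxis, setdiff(1:3, zaxis))
    data <- aperm(data, perm)
    aff4 <- aff
    aff4[, 1:3] <- aff[, perm]
    aff <- aff4
  }
  as_volume(data, affine = aff,
            meta = list(path = path, original_shape = d, axis_perm = perm))
}

.apply_to_data <- function(vol, f) {
  if (inherits(vol, "volume")) {
    vol$data <- f(vol$data)
    vol
  } else {
    f(vol)
  }
}

#' Center-crop a volume
#'
#' Crops a centered window; when a remainder is odd the extra voxel is
#' dropped from the high-index side.  Cropping never pads.
#'
#' @param vol A volume or 3D array.
#' @param target Integer vector `(D, H, W)`, each `<=` the source dimension.
#' @return Cropped volume of shape `target`, same type as the input.
#' @export
center_crop <- function(vol, target) {
  f <- function(data) {
    src <- dim(data)
    if (length(target) != length(src)) stop("target rank mismatch")
    if (any(target > src)) {
      bad <- which(target > src)[1]
      stop("center_crop target exceeds source along dimension ", bad,
           " (", target[bad], " > ", src[bad], "); cropping never pads")
    }
    start <- floor((src - target) / 2) + 1L
    data[start[1]:(start[1] + target[1] - 1L),
         start[2]:(start[2] + target[2] - 1L),
         start[3]:(start[3] + target[3] - 1L), drop = FALSE]
  }
  .apply_to_data(vol, f)
}

#' Min-max rescale intensities to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant volume maps to all zeros.
#'
#' @param vol A volume or 3D array with finite values.
#' @return Rescaled volume, same type as the input.
#' @export
rescale_intensity <- function(vol) {
  f <- function(data) {
    if (any(!is.finite(data))) stop("rescale_intensity: non-finite values present")
    rng <- range(data)
    if (rng[1] == rng[2]) return(array(0, dim(data)))
    (data - rng[1]) / (rng[2] - rng[1])
  }
  .apply_to_data(vol, f)
}

#' Isotropically resize then zero-pad to an exact target shape
#'
#' The volume is scaled by a single factor so it fits within `target`
#' (trilinear interpolation), then symmetrically zero-padded to exactly
#' `target` (any odd padding remainder goes to the high-index side).
#'
#' @param vol A volume or 3D array.
#' @param target Positive integer vector `(D, H, W)`.
#' @return Volume of shape `target`, same type as the input.
#' @export
resize_pad <- function(vol, target) {
  if (any(target <= 0)) stop("resize_pad target must be positive")
  f <- function(data) {
    src <- dim(data)
    s <- min(target / src)
    newshape <- pmax(1L, pmin(as.integer(round(src * s)), target))
    resized <- resize_linear(data, newshape)
    out <- array(0, dim = target)
    pre <- floor((target - newshape) / 2)
    out[pre[1] + seq_len(newshape[1]),
        pre[2] + seq_len(newshape[2]),
        pre[3] + seq_len(newshape[3])] <- resized
    out
  }
  .apply_to_data(vol, f)
}
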