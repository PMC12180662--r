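# Synthetic phantom volumes: smooth ellipsoidal "brain" with per-subject
# structural variation, plus compact ellipsoidal lesions with known masks.
# These emulate preprocessed axial brain volumes (intensities in [0,1],
# slice axis first) so the whole pipeline is testable without external data.

# RNG stream tags; one substream per (component, volume index) so a dataset
# can be extended without reshuffling earlier volumes.
.STREAM_STRUCT <- 11L
.STREAM_NOISE  <- 12L
.STREAM_LESION <- 13L

#' Phantom dataset specification
#'
#' Describes a family of synthetic 3D volumes: a smooth ellipsoidal head with
#' per-subject warping and texture, voxel noise, and (for anomalous members)
#' 1--3 compact ellipsoidal lesions with an additive intensity offset and a
#' Gaussian-smoothed border.
#'
#' @param shape Integer vector `(D, H, W)`: axial slice count first.
#' @param n_normal,n_anomalous Number of normal / anomalous volumes.
#' @param lesion_radius_range Length-2 vector, lesion semi-axis range in voxels.
#' @param lesion_contrast Additive intensity offset in `[-1, 1]`; positive
#'   gives hyperintense lesions.
#' @param n_lesion_range Length-2 integer vector, lesions per anomalous volume.
#' @param deformation_scale Magnitude (voxels) of the smooth per-subject warp;
#'   `0` switches off all subject-to-subject structural variation.
#' @param noise_sd Standard deviation of additive voxel noise.
#' @param seed Integer base seed; every volume derives its own substream.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 64L, 64L),
                         n_normal = 10L, n_anomalous = 10L,
                         lesion_radius_range = c(3, 7),
                         lesion_contrast = 0.4,
                         n_lesion_range = c(1L, 3L),
                         deformation_scale = 1.5,
                         noise_sd = 0.02,
                         seed = 1L) {
  if (length(shape) != 3L || any(shape < 8L)) {
    bad <- which(shape < 8L)
    stop("phantom shape must be 3 dims each >= 8; offending dimension(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(lesion_radius_range <= 0)) stop("lesion_radius_range must be positive")
  if (abs(lesion_contrast) > 1) stop("lesion_contrast must lie in [-1, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(shape = as.integer(shape),
                 n_normal = as.integer(n_normal),
                 n_anomalous = as.integer(n_anomalous),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 lesion_contrast = as.numeric(lesion_contrast),
                 n_lesion_range = as.integer(n_lesion_range),
                 deformation_scale = as.numeric(deformation_scale),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Normalized coordinate grids in [-1, 1] for a (D,H,W) shape.
.phantom_coords <- function(shape) {
  ax <- lapply(shape, function(n) seq(-1, 1, length.out = n))
  list(z = array(rep(ax[[1]], times = shape[2] * shape[3]), dim = shape),
       y = array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]),
                 dim = shape),
       x = array(rep(ax[[3]], each = shape[1] * shape[2]), dim = shape))
}

# Noiseless, unclipped structural image for one subject.
.phantom_structure <- function(spec, index) {
  shape <- spec$shape
  co <- .phantom_coords(shape)
  dz <- dy <- dx <- 0
  tex <- 0
  if (spec$deformation_scale > 0) {
    set.seed(mix_seed(spec$seed, .STREAM_STRUCT, index))
    smooth_unit <- function() {
      f <- gauss_smooth(array(stats::rnorm(prod(shape)), dim = shape), 3)
      f / max(stats::sd(f), 1e-12)
    }
    # displacement in normalized units: voxels * 2 / extent
    dz <- smooth_unit() * spec$deformation_scale * 2 / shape[1]
    dy <- smooth_unit() * spec$deformation_scale * 2 / shape[2]
    dx <- smooth_unit() * spec$deformation_scale * 2 / shape[3]
    tex <- smooth_unit() * 0.08
  }
  r2 <- ((co$z + dz) / 0.70)^2 + ((co$y + dy) / 0.80)^2 +
    ((co$x + dx) / 0.80)^2
  edge <- 1 / (1 + exp((r2 - 1) / 0.08))
  (0.55 + tex) * edge
}

.phantom_noise <- function(spec, index) {
  if (spec$noise_sd == 0) return(0)
  set.seed(mix_seed(spec$seed, .STREAM_NOISE, index))
  array(stats::rnorm(prod(spec$shape), sd = spec$noise_sd), dim = spec$shape)
}

#' Generate one normal phantom volume
#'
#' Deterministic given `(spec$seed, index)`.  The volume is a smooth
#' ellipsoidal head with per-subject smooth deformation and low-frequency
#' texture, additive voxel noise, clipped to `[0, 1]`; background is ~0.
#'
#' @param spec A [phantom_spec()].
#' @param index 1-based volume index selecting the RNG substream.
#' @return A `(D, H, W)` array of intensities in `[0, 1]`.
#' @export
generate_normal_volume <- function(spec, index) {
  stopifnot(inherits(spec, "phantom_spec"))
  clip01(.phantom_structure(spec, index) + .phantom_noise(spec, index))
}

#' Generate one anomalous phantom volume with its ground-truth mask
#'
#' Inserts 1--3 ellipsoidal lesions (additive contrast, Gaussian-smoothed
#' border, sigma = 1 voxel) into the normal counterpart of the same index.
#' The mask marks voxels whose intensity was modified by more than half the
#' contrast, so `lesion_contrast = 0` yields an all-zero mask.
#'
#' @inheritParams generate_normal_volume
#' @return A list with `volume` (intensities in `[0, 1]`), `mask` (integer
#'   0/1 array) and `lesion_fraction` (fraction of masked voxels).
#' @export
generate_anomalous_volume <- function(spec, index) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  if (2 * max(spec$lesion_radius_range) >= min(shape)) {
    stop("lesion (diameter up to ", 2 * max(spec$lesion_radius_range),
         " voxels) does not fit inside the volume (min dim ", min(shape), ")")
  }
  base <- .phantom_structure(spec, index)
  set.seed(mix_seed(spec$seed, .STREAM_LESION, index))
  n_les <- if (spec$n_lesion_range[1] == spec$n_lesion_range[2]) {
    spec$n_lesion_range[1]
  } else {
    sample(spec$n_lesion_range[1]:spec$n_lesion_range[2], 1L)
  }
  co <- .phantom_coords(shape)
  ind <- array(0, dim = shape)
  for (k in seq_len(n_les)) {
    centre <- stats::runif(3, -0.35, 0.35)          # normalized, inside head
    radii <- stats::runif(3, spec$lesion_radius_range[1],
                          spec$lesion_radius_range[2])
    rn <- radii * 2 / shape                          # voxels -> normalized
    d2 <- ((co$z - centre[1]) / rn[1])^2 + ((co$y - centre[2]) / rn[2])^2 +
      ((co$x - centre[3]) / rn[3])^2
    ind <- pmax(ind, as.numeric(d2 <= 1))
  }
  field <- spec$lesion_contrast * gauss_smooth(ind, 1)
  mask <- array(as.integer(abs(field) > abs(spec$lesion_contrast) / 2),
                dim = shape)
  vol <- clip01(base + field + .phantom_noise(spec, index))
  list(volume = vol, mask = mask, lesion_fraction = mean(mask))
}

#' Write a phantom dataset to disk
#'
#' Writes every volume (and, for anomalous volumes, its mask) as compressed
#' NIfTI with consistent affines, plus a CSV manifest.
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame with columns
#'   `path`, `label`, `mask_path`, `seed`.
#' @export
write_phantom_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- list()
  for (i in seq_len(spec$n_normal)) {
    v <- generate_normal_volume(spec, i)
    p <- file.path(out_dir, sprintf("normal_%03d.nii.gz", i))
    write_volume(as_volume(v), p)
    rows[[length(rows) + 1L]] <- data.frame(path = p, label = "normal",
                                            mask_path = "", seed = spec$seed,
                                            stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$n_anomalous)) {
    idx <- spec$n_normal + i
    av <- generate_anomalous_volume(spec, idx)
    p <- file.path(out_dir, sprintf("anomalous_%03d.nii.gz", i))
    pm <- file.path(out_dir, sprintf("anomalous_%03d_mask.nii.gz", i))
    write_volume(as_volume(av$volume), p)
    write_volume(as_volume(av$mask), pm, datatype = "uint8")
    rows[[length(rows) + 1L]] <- data.frame(path = p, label = "anomalous",
                                            mask_path = pm, seed = spec$seed,
                                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
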