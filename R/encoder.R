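# Slice encoder: backbone taps -> neighborhood aggregation -> multi-layer
# fusion at the first tap's resolution -> channel reduction to the target
# embedding dimension.  A slice feature map is an (H0, W0, C) array.

#' Encoder configuration
#'
#' @param p Odd neighborhood patch size for local feature aggregation.
#' @param target_dim Embedding dimension after channel reduction.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(p = 3L, target_dim = 512L) {
  if (p %% 2L == 0L || p < 1L) stop("patch size p must be odd and >= 1")
  if (target_dim < 1L) stop("target_dim must be >= 1")
  structure(list(p = as.integer(p), target_dim = as.integer(target_dim)),
            class = "encoder_config")
}

#' Neighborhood mean aggregation of a feature grid
#'
#' Replaces each location by the mean over its `p` x `p` spatial
#' neighborhood (stride 1, replicate-padded borders).  The mean filter is
#' separable, so the pass is done per axis.
#'
#' @param grid `(H, W, C)` array (a 2D matrix is treated as one channel).
#' @param p Odd patch size; `p = 1` is the identity.
#' @return Array of the same shape.
#' @export
patch_aggregate <- function(grid, p) {
  if (p %% 2L == 0L) stop("patch size p must be odd")
  if (p == 1L) return(grid)
  was_mat <- is.matrix(grid)
  if (was_mat) grid <- array(grid, c(dim(grid), 1L))
  r <- (p - 1L) %/% 2L
  for (ax in 1:2) {
    n <- dim(grid)[ax]
    acc <- array(0, dim(grid))
    for (off in -r:r) {
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      acc <- acc + take_along(grid, idx, ax)
    }
    grid <- acc / p
  }
  if (was_mat) grid <- grid[, , 1]
  grid
}

#' Fuse multi-layer feature grids at a common resolution
#'
#' Bilinearly upscales every grid to `fuse_resolution` (by default the
#' spatial size of the first grid) and concatenates along the channel axis
#' in layer order.
#'
#' @param grids Non-empty list of `(H_l, W_l, C_l)` arrays.
#' @param fuse_resolution Target `(H0, W0)`; defaults to the first grid's.
#' @return `(H0, W0, sum(C_l))` array.
#' @export
fuse_layers <- function(grids, fuse_resolution = NULL) {
  if (length(grids) == 0L) stop("fuse_layers needs at least one feature grid")
  if (is.null(fuse_resolution)) fuse_resolution <- dim(grids[[1]])[1:2]
  up <- lapply(grids, function(g) {
    resize_linear(g, c(fuse_resolution, dim(g)[3]))
  })
  ctot <- sum(vapply(up, function(g) dim(g)[3], integer(1)))
  out <- array(0, c(fuse_resolution, ctot))
  at <- 0L
  for (g in up) {
    cg <- dim(g)[3]
    out[, , at + seq_len(cg)] <- g
    at <- at + cg
  }
  out
}

#' Reduce the channel dimension by adaptive mean pooling
#'
#' Per spatial location, averages contiguous channel windows down to
#' `target_dim` channels (the window boundaries follow adaptive average
#' pooling: output channel `i` covers input channels
#' `floor((i-1)C/t)+1 .. ceil(iC/t)`).  Spatial layout is untouched; there
#' is no up-projection.
#'
#' @param fused `(H, W, C)` array.
#' @param target_dim Output channel count, `<= C`.
#' @return `(H, W, target_dim)` array.
#' @export
reduce_channels <- function(fused, target_dim) {
  C <- dim(fused)[3]
  if (target_dim > C) {
    stop("target_dim (", target_dim, ") exceeds fused channel count (", C,
         "); channel reduction never up-projects")
  }
  if (target_dim == C) return(fused)
  out <- array(0, c(dim(fused)[1:2], target_dim))
  for (i in seq_len(target_dim)) {
    lo <- floor((i - 1) * C / target_dim) + 1L
    hi <- ceiling(i * C / target_dim)
    block <- matrix(fused[, , lo:hi], ncol = hi - lo + 1L)
    out[, , i] <- rowMeans(block)
  }
  out
}

#' Encode one axial slice into a fused low-resolution feature map
#'
#' Pipeline: backbone taps -> per-layer neighborhood aggregation -> bilinear
#' fusion at the first tap's resolution -> channel reduction to
#' `config$target_dim`.  A pure function of (slice, backbone weights,
#' config).
#'
#' @param slice_img 2D matrix (grayscale slice) or `(H, W, C)` array.
#' @param backbone A `backbone_adapter`.
#' @param config An [encoder_config()].
#' @return `(H0, W0, target_dim)` array of class `slice_feature_map` with
#'   attributes `layers` (tap provenance) and `p`.
#' @export
encode_slice <- function(slice_img, backbone, config = encoder_config()) {
  taps <- extract_layer_features(slice_img, backbone)
  agg <- lapply(taps, patch_aggregate, p = config$p)
  fused <- fuse_layers(agg)
  red <- reduce_channels(fused, config$target_dim)
  structure(red, class = c("slice_feature_map", class(red)),
            layers = names(taps), p = config$p)
}
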