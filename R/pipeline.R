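# Volume-level pipeline: encode each axial slice, aggregate features along
# depth with a sliding window mean, score every voxel of the low-resolution
# grid with the conditional flow, and upscale the anomaly map back to the
# input resolution.

#' Encode every axial slice of a volume
#'
#' @param volume A `volume` or `(D, H, W)` array.
#' @param backbone A `backbone_adapter`.
#' @param config An [encoder_config()].
#' @return `(D, H0, W0, C)` array of per-slice feature maps.
#' @export
encode_volume <- function(volume, backbone, config = encoder_config()) {
  data <- if (inherits(volume, "volume")) volume$data else volume
  D <- dim(data)[1]
  first <- encode_slice(data[1, , ], backbone, config)
  out <- array(0, c(D, dim(first)))
  out[1, , , ] <- first
  if (D > 1L) {
    for (j in 2:D) out[j, , , ] <- encode_slice(data[j, , ], backbone, config)
  }
  out
}

#' Depth-wise aggregation of slice feature maps
#'
#' Per voxel of the low-resolution grid, the feature vector is replaced by
#' the mean over a window of `w` slices centered at its slice (replicated
#' at the volume ends).  The mean is permutation-invariant within the
#' window; `w = 1` reproduces the stacked per-slice features exactly.
#'
#' @param slice_maps `(D, H0, W0, C)` array or list of `(H0, W0, C)` arrays
#'   with identical shapes.
#' @param w Odd window width.
#' @return `(D, H0, W0, C)` array.
#' @export
aggregate_volume <- function(slice_maps, w = 3L) {
  if (is.list(slice_maps)) {
    shapes <- vapply(slice_maps, function(m) paste(dim(m), collapse = "x"),
                     character(1))
    if (length(unique(shapes)) != 1L) {
      stop("slice feature maps disagree in shape: ",
           paste(unique(shapes), collapse = " vs "))
    }
    arr <- array(0, c(length(slice_maps), dim(slice_maps[[1]])))
    for (j in seq_along(slice_maps)) arr[j, , , ] <- slice_maps[[j]]
    slice_maps <- arr
  }
  if (w %% 2L != 1L) stop("aggregation window w must be odd")
  if (w == 1L) return(slice_maps)
  D <- dim(slice_maps)[1]
  r <- (w - 1L) %/% 2L
  acc <- array(0, dim(slice_maps))
  for (off in -r:r) {
    idx <- pmin(pmax(seq_len(D) + off, 1L), D)
    acc <- acc + take_along(slice_maps, idx, 1L)
  }
  acc / w
}

#' Convert log-likelihood to anomaly score
#'
#' `s = 1 - exp(logp)`: strictly decreasing in `logp`, range `(-Inf, 1]`.
#'
#' @param logp Finite log-likelihood value(s).
#' @return Anomaly score(s), same shape.
#' @export
anomaly_score <- function(logp) {
  if (any(is.na(logp))) stop("anomaly_score: NaN/NA log-likelihood")
  1 - exp(logp)
}

#' Score a volume voxel-wise with a trained flow
#'
#' Encodes each axial slice, aggregates along depth, evaluates the
#' per-voxel log-likelihood under the flow conditioned on the voxel's
#' `(h, w)` positional code, converts to anomaly scores, and bilinearly
#' upscales each slice's score grid to the input resolution (the depth axis
#' is already at slice resolution).
#'
#' @param volume A `volume` or `(D, H, W)` array, preprocessed.
#' @param backbone A `backbone_adapter`.
#' @param flow A trained [flow_model()].
#' @param config An [encoder_config()] (its `target_dim` must equal the
#'   flow's `d`).
#' @param w Odd depth aggregation window.
#' @param allow_untrained Permit scoring with an untrained flow (used for
#'   closed-form oracles); by default an untrained flow is an error.
#' @param stabilize Numerically stabilize the score transform by shifting
#'   log-likelihoods by their per-volume maximum and scaling by `1/d`
#'   before exponentiating.  This is a strictly increasing
#'   reparameterization of the raw score `1 - exp(logp)` (which underflows
#'   to a constant for high-dimensional features), so every rank-based or
#'   min-max-normalized quantity downstream is unchanged.
#' @param slice_features Optional precomputed [encode_volume()] output for
#'   this volume (skips re-encoding).
#' @return An object of class `anomaly_map` with fields `scores`
#'   (`D x H x W`), `lowres` (`D x H0 x W0`), `logp`, and normalization
#'   state `"raw"`.
#' @export
score_volume <- function(volume, backbone, flow, config = encoder_config(),
                         w = 3L, allow_untrained = FALSE, stabilize = TRUE,
                         slice_features = NULL) {
  stopifnot(inherits(flow, "flow_model"))
  if (!isTRUE(flow$trained) && !allow_untrained) {
    stop("flow is untrained; train it or load a checkpoint before scoring")
  }
  data <- if (inherits(volume, "volume")) volume$data else volume
  feats <- if (is.null(slice_features)) {
    encode_volume(data, backbone, config)
  } else {
    slice_features
  }
  feats <- aggregate_volume(feats, w)
  D <- dim(feats)[1]; H0 <- dim(feats)[2]; W0 <- dim(feats)[3]
  C <- dim(feats)[4]
  X <- matrix(feats, ncol = C)             # rows: d fastest, then h, then w
  if (!is.null(flow$feature_center)) {
    X <- sweep(X, 2, flow$feature_center, `-`)
    X <- sweep(X, 2, flow$feature_scale, `/`)
  }
  cond_grid <- positional_condition(H0, W0, flow$cond_dim)
  cond <- cond_grid[rep(seq_len(H0 * W0), each = D), , drop = FALSE]
  logp <- log_likelihood(flow, X, cond)
  sc <- if (stabilize) {
    anomaly_score((logp - max(logp)) / flow$d)
  } else {
    anomaly_score(logp)
  }
  lowres <- array(sc, c(D, H0, W0))
  scores <- array(0, dim(data))
  for (j in seq_len(D)) {
    scores[j, , ] <- resize_linear(lowres[j, , ], dim(data)[2:3])
  }
  structure(list(scores = scores, lowres = lowres,
                 logp = array(logp, c(D, H0, W0)),
                 normalization = "raw",
                 affine = if (inherits(volume, "volume")) volume$affine else
                   NULL),
            class = "anomaly_map")
}

#' @export
print.anomaly_map <- function(x, ...) {
  cat(sprintf("<anomaly_map> %s (%s), score range [%.4g, %.4g]\n",
              paste(dim(x$scores), collapse = "x"), x$normalization,
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Per-slice image-level anomaly scores
#'
#' The image-level score of an axial slice is the maximum voxel anomaly
#' score within the slice.
#'
#' @param map An `anomaly_map`.
#' @return Numeric vector, one score per axial slice.
#' @export
image_level_scores <- function(map) {
  stopifnot(inherits(map, "anomaly_map"))
  if (length(map$scores) == 0L) stop("empty anomaly map")
  apply(map$scores, 1, max)
}

#' Min-max normalize anomaly maps
#'
#' `per_volume`: each map is min-max scaled to `[0, 1]` within its own
#' volume (the protocol for pixel-level metrics).  `dataset`: a single
#' min-max over all maps jointly (the protocol for image-level metrics).
#' A constant map normalizes to all zeros.  Both modes preserve the rank
#' order of voxels within a volume.
#'
#' @param maps An `anomaly_map` or list of them.
#' @param mode `"per_volume"` or `"dataset"`.
#' @return List of normalized `anomaly_map`s (or a single map if a single
#'   map was given).
#' @export
normalize_scores <- function(maps, mode = c("per_volume", "dataset")) {
  mode <- match.arg(mode)
  single <- inherits(maps, "anomaly_map")
  if (single) maps <- list(maps)
  if (length(maps) == 0L) stop("normalize_scores: no maps given")
  scale_map <- function(m, lo, hi) {
    if (hi == lo) {
      m$scores[] <- 0
      m$lowres[] <- 0
    } else {
      m$scores <- (m$scores - lo) / (hi - lo)
      m$lowres <- (m$lowres - lo) / (hi - lo)
    }
    m$normalization <- mode
    m
  }
  if (mode == "per_volume") {
    maps <- lapply(maps, function(m) {
      scale_map(m, min(m$scores), max(m$scores))
    })
  } else {
    lo <- min(vapply(maps, function(m) min(m$scores), numeric(1)))
    hi <- max(vapply(maps, function(m) max(m$scores), numeric(1)))
    maps <- lapply(maps, scale_map, lo = lo, hi = hi)
  }
  if (single) maps[[1]] else maps
}

#' Fit the anomaly localization model on normal volumes
#'
#' Encodes every training volume slice-by-slice, aggregates along depth,
#' standardizes the pooled feature channels, and trains the conditional
#' flow with the configured contrastive loss.  One volume's feature vectors
#' form one optimization batch.
#'
#' @param volumes List of normal `volume`s or `(D, H, W)` arrays.
#' @param backbone A `backbone_adapter`.
#' @param config An [encoder_config()].
#' @param loss_cfg A [loss_config()].
#' @param w Odd depth aggregation window.
#' @param n_coupling,hidden,cond_dim,clamp Flow architecture settings.
#' @param epochs Training epochs over the volume list.
#' @param lr Adam learning rate.
#' @param seed Seed for flow initialization.
#' @param slice_features Optional list of precomputed [encode_volume()]
#'   outputs, parallel to `volumes` (skips re-encoding).
#' @return List of class `anomaly_fit` with the trained `flow`, `backbone`,
#'   `config`, `w` and the training `loss_log`.
#' @export
fit_anomaly_model <- function(volumes, backbone, config = encoder_config(),
                              loss_cfg = loss_config(), w = 3L,
                              n_coupling = 8L, hidden = 64L, cond_dim = 32L,
                              clamp = 1.9, epochs = 2L, lr = 0.001,
                              seed = 1L, slice_features = NULL) {
  if (is.null(slice_features)) {
    stopifnot(length(volumes) >= 1L)
    slice_features <- lapply(volumes, encode_volume, backbone = backbone,
                             config = config)
  }
  feats <- lapply(slice_features, aggregate_volume, w = w)
  dims <- dim(feats[[1]])
  D <- dims[1]; H0 <- dims[2]; W0 <- dims[3]; C <- dims[4]
  batches <- lapply(feats, function(f) matrix(f, ncol = C))
  pooled <- do.call(rbind, batches)
  center <- colMeans(pooled)
  scale <- pmax(apply(pooled, 2, stats::sd), 1e-6)
  batches <- lapply(batches, function(b) {
    sweep(sweep(b, 2, center, `-`), 2, scale, `/`)
  })
  cond_grid <- positional_condition(H0, W0, cond_dim)
  cond <- cond_grid[rep(seq_len(H0 * W0), each = D), , drop = FALSE]
  flow <- flow_model(C, n_coupling = n_coupling, hidden = hidden,
                     cond_dim = cond_dim, clamp = clamp, seed = seed)
  flow$feature_center <- center
  flow$feature_scale <- scale
  flow <- train_flow(flow, batches, conds = cond, loss_cfg = loss_cfg,
                     epochs = epochs, lr = lr)
  structure(list(flow = flow, backbone = backbone, config = config, w = w,
                 loss_log = flow$loss_log),
            class = "anomaly_fit")
}
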