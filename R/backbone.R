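# Slice feature backbones.
#
# Two adapters stand behind the pluggable backbone interface:
#   * tiny_cnn_backbone(): a small fixed random-weight CNN, usable on CPU.
#     Random convolutional features are a standard lightweight stand-in for
#     pretrained features in feature-embedding anomaly detection.
#   * wide_resnet50_table(): the architecture table of the wide 50-layer
#     bottleneck residual network (width factor 2), used to account for the
#     backbone's parameter budget without loading weights.
#
# Feature grids are stored (H, W, C) throughout.

# ---- minimal conv2d with im2col -------------------------------------------

# Lower a padded image into the patch matrix: rows index output locations
# (row-major within a column-major (Hout, Wout) grid), columns index
# (dy, dx, channel) in that nesting order.
im2col <- function(x, k, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  P <- array(0, c(Hp, Wp, C))
  P[pad + seq_len(H), pad + seq_len(W), ] <- x
  Hout <- (Hp - k) %/% stride + 1L
  Wout <- (Wp - k) %/% stride + 1L
  ys <- seq(1L, by = stride, length.out = Hout)
  xs <- seq(1L, by = stride, length.out = Wout)
  M <- matrix(0, Hout * Wout, k * k * C)
  col <- 1L
  for (c in seq_len(C)) {
    for (dx in 0:(k - 1L)) {
      for (dy in 0:(k - 1L)) {
        M[, col] <- as.vector(P[ys + dy, xs + dx, c])
        col <- col + 1L
      }
    }
  }
  attr(M, "geom") <- list(H = H, W = W, C = C, Hout = Hout, Wout = Wout,
                          k = k, stride = stride, pad = pad)
  M
}

# Scatter-add the patch-matrix gradient back onto the input image.
col2im <- function(gM, geom) {
  Hp <- geom$H + 2L * geom$pad; Wp <- geom$W + 2L * geom$pad
  gP <- array(0, c(Hp, Wp, geom$C))
  ys <- seq(1L, by = geom$stride, length.out = geom$Hout)
  xs <- seq(1L, by = geom$stride, length.out = geom$Wout)
  col <- 1L
  for (c in seq_len(geom$C)) {
    for (dx in 0:(geom$k - 1L)) {
      for (dy in 0:(geom$k - 1L)) {
        gP[ys + dy, xs + dx, c] <- gP[ys + dy, xs + dx, c] +
          matrix(gM[, col], geom$Hout, geom$Wout)
        col <- col + 1L
      }
    }
  }
  gP[geom$pad + seq_len(geom$H), geom$pad + seq_len(geom$W), , drop = FALSE]
}

conv2d_forward <- function(x, layer) {
  M <- im2col(x, layer$k, layer$stride, layer$pad)
  geom <- attr(M, "geom")
  out <- M %*% layer$W
  out <- sweep(out, 2, layer$b, `+`)
  pre <- array(out, c(geom$Hout, geom$Wout, ncol(layer$W)))
  act <- if (isTRUE(layer$relu)) pmax(pre, 0) else pre
  list(out = act, cache = list(M = M, geom = geom, pre = pre))
}

conv2d_backward <- function(gout, layer, cache) {
  if (isTRUE(layer$relu)) gout <- gout * (cache$pre > 0)
  gmat <- matrix(gout, nrow(cache$M), ncol(layer$W))
  gW <- crossprod(cache$M, gmat)
  gb <- colSums(gmat)
  gx <- col2im(gmat %*% t(layer$W), cache$geom)
  list(gW = gW, gb = gb, gx = gx)
}

new_conv_layer <- function(cin, cout, k = 3L, stride = 1L, pad = 1L,
                           relu = TRUE, init_sd = NULL) {
  if (is.null(init_sd)) init_sd <- sqrt(2 / (k * k * cin))  # He init
  list(W = matrix(stats::rnorm(k * k * cin * cout, sd = init_sd),
                  k * k * cin, cout),
       b = rep(0, cout), k = k, stride = stride, pad = pad, relu = relu)
}

# ---- backbone adapter interface -------------------------------------------

#' Small random-weight CNN backbone adapter
#'
#' Three stride-2 convolutional stages with fixed, seeded random weights.
#' Stages 2 and 3 are tapped by default, at spatial strides 4 and 8, with
#' strictly decreasing resolution.  The forward pass is deterministic; the
#' adapter is frozen unless fine-tuned via [finetune_backbone()].
#'
#' @param seed Integer seed for weight initialization.
#' @param channels Channel counts of the three stages.
#' @param tap_layers Which stages to expose as feature taps.
#' @return An object of class `backbone_adapter`.
#' @export
tiny_cnn_backbone <- function(seed = 1L, channels = c(16L, 32L, 64L),
                              tap_layers = c(2L, 3L)) {
  stopifnot(length(channels) == 3L, all(tap_layers %in% 1:3))
  set.seed(mix_seed(seed, 97L))
  stages <- list(
    new_conv_layer(3L, channels[1], stride = 2L),
    new_conv_layer(channels[1], channels[2], stride = 2L),
    new_conv_layer(channels[2], channels[3], stride = 2L))
  structure(list(name = "tiny_cnn", tap_layers = sort(as.integer(tap_layers)),
                 stages = stages, channels = channels,
                 strides = c(2L, 4L, 8L), input_channels = 3L,
                 frozen = TRUE, seed = as.integer(seed)),
            class = "backbone_adapter")
}

#' Extract tapped intermediate feature grids for one slice
#'
#' Runs the backbone forward in evaluation mode and returns the feature grid
#' of every tapped stage.  Grayscale input is replicated to the backbone's
#' expected channel count.
#'
#' @param slice_img 2D matrix, or `(H, W, C)` array.
#' @param backbone A `backbone_adapter`.
#' @param keep_cache Keep forward intermediates (needed for fine-tuning).
#' @return Named list of `(H_l, W_l, C_l)` arrays, one per tapped layer.
#' @export
extract_layer_features <- function(slice_img, backbone, keep_cache = FALSE) {
  stopifnot(inherits(backbone, "backbone_adapter"))
  x <- slice_img
  if (is.matrix(x)) x <- array(rep(x, backbone$input_channels),
                               c(dim(x), backbone$input_channels))
  min_size <- 2^length(backbone$stages)
  if (any(dim(x)[1:2] < min_size)) {
    stop("input spatial size ", paste(dim(x)[1:2], collapse = "x"),
         " too small for the deepest tap; minimum is ",
         min_size, "x", min_size)
  }
  taps <- list(); caches <- list()
  for (s in seq_along(backbone$stages)) {
    fw <- conv2d_forward(x, backbone$stages[[s]])
    if (keep_cache) caches[[s]] <- fw$cache
    x <- fw$out
    if (s %in% backbone$tap_layers) taps[[as.character(s)]] <- x
  }
  if (keep_cache) attr(taps, "cache") <- caches
  taps
}

# ---- wide residual network parameter accounting ---------------------------

#' Architecture table of a bottleneck ResNet-50 style backbone
#'
#' Enumerates every parameterized layer (convolutions, batch-norm
#' scale/shift, final fully connected layer) of a 50-layer bottleneck
#' residual network with a configurable per-group width.  `width_per_group =
#' 128` gives the wide (x2) variant used as the slice feature backbone;
#' `64` gives the standard ResNet-50.
#'
#' @param width_per_group Bottleneck width for 64 input planes.
#' @return Data frame with columns `layer`, `kind`, `params`.
#' @export
wide_resnet50_table <- function(width_per_group = 128L) {
  rows <- list()
  add <- function(layer, kind, params) {
    rows[[length(rows) + 1L]] <<- data.frame(layer = layer, kind = kind,
                                             params = params,
                                             stringsAsFactors = FALSE)
  }
  add("stem.conv", "conv7x7", 3 * 64 * 49)
  add("stem.bn", "bn", 2 * 64)
  blocks <- c(3L, 4L, 6L, 3L); planes <- c(64L, 128L, 256L, 512L)
  inch <- 64L
  for (s in seq_len(4L)) {
    p <- planes[s]; w <- p * width_per_group %/% 64L; out <- 4L * p
    for (b in seq_len(blocks[s])) {
      tag <- sprintf("layer%d.block%d", s, b)
      add(paste0(tag, ".conv1"), "conv1x1", inch * w)
      add(paste0(tag, ".bn1"), "bn", 2 * w)
      add(paste0(tag, ".conv2"), "conv3x3", 9 * w * w)
      add(paste0(tag, ".bn2"), "bn", 2 * w)
      add(paste0(tag, ".conv3"), "conv1x1", w * out)
      add(paste0(tag, ".bn3"), "bn", 2 * out)
      if (b == 1L) {
        add(paste0(tag, ".downsample.conv"), "conv1x1", inch * out)
        add(paste0(tag, ".downsample.bn"), "bn", 2 * out)
      }
      inch <- out
    }
  }
  add("fc", "linear", 2048 * 1000 + 1000)
  do.call(rbind, rows)
}

#' Total parameter count of a backbone architecture table
#'
#' @param table A data frame as returned by [wide_resnet50_table()].
#' @return Total number of parameters (numeric scalar).
#' @export
count_backbone_params <- function(table = wide_resnet50_table()) {
  sum(table$params)
}
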