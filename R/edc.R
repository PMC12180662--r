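# Encoder-decoder contrast (EDC) pre-training: fine-tune the slice backbone
# on an independent 2D image set by training a mirrored decoder to
# reconstruct the tapped encoder feature maps under a stop-gradient global
# cosine loss.  The encoder branch of the loss is treated as constant;
# encoder weights receive gradient only through the decoder's input
# (bottleneck) path.  The loss is used only at this stage - the returned
# encoder is frozen for anomaly localization training.

nearest_up2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  x[rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), , drop = FALSE]
}

nearest_up2_backward <- function(g) {
  H <- dim(g)[1] %/% 2L; W <- dim(g)[2] %/% 2L
  out <- array(0, c(H, W, dim(g)[3]))
  for (dy in 1:2) for (dx in 1:2) {
    out <- out + g[seq(dy, by = 2L, length.out = H),
                   seq(dx, by = 2L, length.out = W), , drop = FALSE]
  }
  out
}

#' Build an encoder-decoder pair for fine-tuning
#'
#' The decoder mirrors only the tapped encoder stages: a bottleneck
#' convolution on the deepest tap, a convolution producing the
#' reconstruction of the deepest tapped feature map, and a nearest-upsample
#' + convolution producing the shallower one.
#'
#' @param backbone A `backbone_adapter` with taps at stages 2 and 3.
#' @param seed Seed for decoder weight initialization.
#' @return An object of class `encoder_decoder_pair`.
#' @export
encoder_decoder_pair <- function(backbone, seed = 1L) {
  stopifnot(inherits(backbone, "backbone_adapter"))
  if (!identical(backbone$tap_layers, c(2L, 3L))) {
    stop("encoder_decoder_pair expects taps at stages 2 and 3")
  }
  c2 <- backbone$channels[2]; c3 <- backbone$channels[3]
  set.seed(mix_seed(seed, 71L))
  decoder <- list(
    bottleneck = new_conv_layer(c3, c3, stride = 1L, relu = TRUE),
    dec3 = new_conv_layer(c3, c3, stride = 1L, relu = FALSE),
    dec2 = new_conv_layer(c3, c2, stride = 1L, relu = FALSE))
  structure(list(encoder = backbone, decoder = decoder,
                 seed = as.integer(seed)),
            class = "encoder_decoder_pair")
}

# Decoder forward from the deepest encoder tap; returns f_D^2, f_D^3.
.decoder_forward <- function(decoder, fE3) {
  bn <- conv2d_forward(fE3, decoder$bottleneck)
  d3 <- conv2d_forward(bn$out, decoder$dec3)
  up <- nearest_up2(d3$out)
  d2 <- conv2d_forward(up, decoder$dec2)
  list(feats = list(`2` = d2$out, `3` = d3$out),
       caches = list(bn = bn$cache, d3 = d3$cache, d2 = d2$cache))
}

#' Global cosine distance loss with stop-gradient
#'
#' `sum_l [1 - cos(flatten(fE_l), flatten(fD_l))]` where each feature grid
#' is flattened to a single vector and the encoder branch is treated as a
#' constant: gradients (when requested) are taken only with respect to the
#' decoder features.
#'
#' @param enc_feats,dec_feats Lists of feature grids with matching shapes.
#' @param grad Also return gradients with respect to each decoder grid.
#' @return Scalar loss in `[0, 2 * n_layers]`, or a list `(value, gdec)`.
#' @export
global_cosine_loss <- function(enc_feats, dec_feats, grad = FALSE) {
  if (length(enc_feats) != length(dec_feats)) {
    stop("encoder and decoder feature lists differ in length")
  }
  value <- 0
  gdec <- vector("list", length(enc_feats))
  for (l in seq_along(enc_feats)) {
    a <- as.numeric(enc_feats[[l]])            # stop-gradient branch
    b <- as.numeric(dec_feats[[l]])
    if (!identical(dim(enc_feats[[l]]), dim(dec_feats[[l]]))) {
      stop("feature shape mismatch at layer ",
           names(enc_feats)[l] %||% l)
    }
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) {
      value <- value + 1                       # cosine undefined -> distance 1
      if (grad) gdec[[l]] <- array(0, dim(dec_feats[[l]]))
      next
    }
    cs <- sum(a * b) / (na * nb)
    value <- value + 1 - cs
    if (grad) {
      g <- -(a / (na * nb) - cs * b / nb^2)
      gdec[[l]] <- array(g, dim(dec_feats[[l]]))
    }
  }
  if (grad) list(value = value, gdec = gdec) else value
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Full loss gradients for one image: decoder parameter grads, encoder
# parameter grads (via the bottleneck path only), and the loss value.
.edc_gradients <- function(pair, img, detach_bottleneck = FALSE) {
  enc <- pair$encoder
  taps <- extract_layer_features(img, enc, keep_cache = TRUE)
  caches <- attr(taps, "cache")
  dec <- .decoder_forward(pair$decoder, taps[["3"]])
  gc <- global_cosine_loss(taps[c("2", "3")], dec$feats, grad = TRUE)
  # decoder backward
  bd2 <- conv2d_backward(gc$gdec[[1]], pair$decoder$dec2, dec$caches$d2)
  g_d3 <- gc$gdec[[2]] + nearest_up2_backward(bd2$gx)
  bd3 <- conv2d_backward(g_d3, pair$decoder$dec3, dec$caches$d3)
  bbn <- conv2d_backward(bd3$gx, pair$decoder$bottleneck, dec$caches$bn)
  dec_grads <- list(bottleneck = bbn[c("gW", "gb")],
                    dec3 = bd3[c("gW", "gb")],
                    dec2 = bd2[c("gW", "gb")])
  # encoder backward through the bottleneck input (the only non-sg path)
  enc_grads <- lapply(enc$stages, function(st)
    list(gW = st$W * 0, gb = st$b * 0))
  if (!detach_bottleneck) {
    gx <- bbn$gx
    for (s in rev(seq_along(enc$stages))) {
      bs <- conv2d_backward(gx, enc$stages[[s]], caches[[s]])
      enc_grads[[s]] <- bs[c("gW", "gb")]
      gx <- bs$gx
    }
  }
  list(value = gc$value, dec_grads = dec_grads, enc_grads = enc_grads)
}

#' Fine-tune the backbone with encoder-decoder contrast
#'
#' Adam on both the decoder and (through the bottleneck path) the encoder,
#' minimizing the stop-gradient global cosine loss over an independent set
#' of 2D images.  With `epochs = 0` the weights are returned unchanged.
#'
#' @param images List of 2D matrices (grayscale, spatial dims divisible
#'   by 8), or a 3D array sliced along the first axis.
#' @param pair An [encoder_decoder_pair()].
#' @param epochs Number of passes over the images.
#' @param lr Adam learning rate.
#' @return List with the fine-tuned frozen `backbone`, the `decoder`, and a
#'   per-step `loss_trace`.
#' @export
finetune_backbone <- function(images, pair, epochs = 1L, lr = 1e-3) {
  stopifnot(inherits(pair, "encoder_decoder_pair"))
  if (is.array(images) && length(dim(images)) == 3L) {
    images <- lapply(seq_len(dim(images)[1]), function(j) images[j, , ])
  }
  if (length(images) == 0L) stop("finetune_backbone: empty image set")
  enc <- pair$encoder
  dec <- pair$decoder
  adam <- list()
  gkey <- function(...) paste(..., sep = ".")
  st_get <- function(key, p) adam[[key]] %||% list(m = p * 0, v = p * 0)
  t <- 0L
  trace <- numeric(0)
  for (ep in seq_len(epochs)) {
    for (img in images) {
      t <- t + 1L
      pair$encoder <- enc
      pair$decoder <- dec
      g <- .edc_gradients(pair, img)
      trace <- c(trace, g$value)
      upd <- function(p, gr, key) {
        s <- st_get(key, p)
        s$m <- 0.9 * s$m + 0.1 * gr
        s$v <- 0.999 * s$v + 0.001 * gr^2
        adam[[key]] <<- s
        p - lr * (s$m / (1 - 0.9^t)) / (sqrt(s$v / (1 - 0.999^t)) + 1e-8)
      }
      for (nm in names(dec)) {
        dec[[nm]]$W <- upd(dec[[nm]]$W, g$dec_grads[[nm]]$gW, gkey("d", nm, "W"))
        dec[[nm]]$b <- upd(dec[[nm]]$b, g$dec_grads[[nm]]$gb, gkey("d", nm, "b"))
      }
      for (s in seq_along(enc$stages)) {
        enc$stages[[s]]$W <- upd(enc$stages[[s]]$W, g$enc_grads[[s]]$gW,
                                 gkey("e", s, "W"))
        enc$stages[[s]]$b <- upd(enc$stages[[s]]$b, g$enc_grads[[s]]$gb,
                                 gkey("e", s, "b"))
      }
    }
  }
  enc$frozen <- TRUE
  list(backbone = enc, decoder = dec, loss_trace = trace)
}
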