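# Shared fixtures: tiny specs, hand-built backbones/flows, brute-force
# oracles used across test files.

tiny_spec <- function(seed = 1L, ...) {
  phantom_spec(shape = c(8L, 16L, 16L), lesion_radius_range = c(2, 3),
               n_lesion_range = c(1L, 1L), seed = seed, ...)
}

# Flow with randomized (non-identity) coupling subnets.
perturbed_flow <- function(d, n_coupling = 4L, hidden = 16L, cond_dim = 4L,
                           seed = 1L, sd = 0.3) {
  m <- flow_model(d, n_coupling = n_coupling, hidden = hidden,
                  cond_dim = cond_dim, seed = seed)
  set.seed(seed + 1000L)
  for (k in seq_along(m$layers)) {
    m$layers[[k]]$W2 <- matrix(stats::rnorm(length(m$layers[[k]]$W2), sd = sd),
                               nrow(m$layers[[k]]$W2))
    m$layers[[k]]$b2 <- stats::rnorm(length(m$layers[[k]]$b2), sd = sd / 3)
  }
  m
}

# Brute-force AUROC: concordant-pair fraction with ties counted half.
pairwise_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Brute-force best F1 by looping over every distinct threshold.
bruteforce_best_f1 <- function(scores, labels) {
  best <- 0
  for (t in sort(unique(scores))) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    best <- max(best, f1)
  }
  best
}

# Brute-force replicate-padded p x p mean filter on a matrix.
bruteforce_patch_mean <- function(m, p) {
  r <- (p - 1) / 2
  out <- m
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      ii <- pmin(pmax((i - r):(i + r), 1), nrow(m))
      jj <- pmin(pmax((j - r):(j + r), 1), ncol(m))
      out[i, j] <- mean(m[ii, jj])
    }
  }
  out
}

# Plain direct 2D convolution oracle (stride, zero padding, single channel
# in/out), weights indexed w[dy, dx].
direct_conv2d <- function(img, w, stride = 1, pad = 1) {
  k <- nrow(w)
  H <- nrow(img); W <- ncol(img)
  P <- matrix(0, H + 2 * pad, W + 2 * pad)
  P[pad + seq_len(H), pad + seq_len(W)] <- img
  Hout <- (H + 2 * pad - k) %/% stride + 1
  Wout <- (W + 2 * pad - k) %/% stride + 1
  out <- matrix(0, Hout, Wout)
  for (i in seq_len(Hout)) {
    for (j in seq_len(Wout)) {
      y <- (i - 1) * stride
      x <- (j - 1) * stride
      out[i, j] <- sum(P[y + seq_len(k), x + seq_len(k)] * w)
    }
  }
  out
}
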