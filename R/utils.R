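#' @keywords internal
"_PACKAGE"

# Deterministic substream seeds: a Lehmer-style mix of a base seed with one or
# more stream/index integers.  All arithmetic stays below 2^53 so the result
# is exact in doubles and identical across platforms.
mix_seed <- function(seed, ...) {
  m <- 2147483629
  s <- (abs(as.numeric(seed)) %% m) + 1
  for (x in as.numeric(c(...))) {
    s <- (s * 48271 + (abs(x) + 1) * 16807) %% m
  }
  as.integer(s)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Index an array along one axis with an arbitrary (possibly clamped or
# repeated) index vector, keeping the other axes intact.
take_along <- function(arr, idx, axis) {
  args <- lapply(dim(arr), seq_len)
  args[[axis]] <- idx
  do.call(`[`, c(list(arr), args, list(drop = FALSE)))
}

# Separable Gaussian smoothing with replicate-padded borders.
gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

smooth_axis <- function(arr, sigma, axis) {
  if (sigma <= 0) return(arr)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  n <- dim(arr)[axis]
  out <- array(0, dim(arr))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + k[j] * take_along(arr, idx, axis)
  }
  out
}

gauss_smooth <- function(arr, sigma) {
  for (ax in seq_along(dim(arr))) arr <- smooth_axis(arr, sigma, ax)
  arr
}

# Linear resampling along one axis (centre-aligned sampling grid); applying it
# along every axis gives exact bi-/trilinear interpolation.
resize_axis <- function(arr, m, axis) {
  n <- dim(arr)[axis]
  if (m == n) return(arr)
  xi <- (seq_len(m) - 0.5) * n / m + 0.5
  xi <- pmin(pmax(xi, 1), n)
  lo <- pmin(floor(xi), n - 1L)
  if (n == 1L) lo <- rep(1, m)
  w <- xi - lo
  hi <- pmin(lo + 1L, n)
  a <- take_along(arr, lo, axis)
  b <- take_along(arr, hi, axis)
  wshape <- rep(1L, length(dim(arr)))
  wshape[axis] <- m
  wb <- array(rep(w, each = prod(dim(arr)[seq_len(axis - 1L)])),
              dim = dim(a))
  a * (1 - wb) + b * wb
}

resize_linear <- function(arr, target) {
  stopifnot(length(target) == length(dim(arr)))
  for (ax in seq_along(target)) arr <- resize_axis(arr, target[ax], ax)
  arr
}

# FNV-1a over a deparsed object; used to fingerprint configurations so that a
# flow checkpoint can refuse to score features from a different encoder setup.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
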