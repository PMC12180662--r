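# Conditional normalizing flow over feature vectors.
#
# RealNVP-style affine coupling layers with a fixed random channel
# permutation per layer.  Each coupling subnet is two linear maps with one
# ReLU in between; the subnet sees the untransformed half of the vector
# concatenated with a sinusoidal 2D positional code.  Scales are
# soft-clamped (s <- a * tanh(s / a)) so the log-determinant stays bounded.
# The last linear map is zero-initialized, so a fresh flow is exactly the
# identity and its likelihood is the standard Gaussian closed form.
#
# Gradients are derived by hand (reverse-mode through the coupling algebra)
# and optimized with Adam; there is no autodiff runtime behind this.

#' Sinusoidal 2D positional condition grid
#'
#' Fixed code: the first half of the channels encodes the row index, the
#' second half the column index, each with an interleaved sine/cosine
#' geometric frequency ladder.  Values lie in `[-1, 1]` and depend only on
#' `(h, w, H0, W0)`.
#'
#' @param H0,W0 Spatial grid size.
#' @param condition_dim Even total width of the code.
#' @return `(H0 * W0) x condition_dim` matrix; row `h + (w-1) * H0`
#'   corresponds to location `(h, w)` (column-major flattening).
#' @export
positional_condition <- function(H0, W0, condition_dim = 32L) {
  if (H0 < 1L || W0 < 1L) stop("grid dimensions must be positive")
  if (condition_dim %% 2L != 0L) stop("condition_dim must be even")
  half <- condition_dim %/% 2L
  code1d <- function(pos, width) {
    out <- matrix(0, length(pos), width)
    for (i in seq_len(width)) {
      freq <- 1 / 10000^((2 * ((i - 1) %/% 2)) / width)
      ang <- pos * freq
      out[, i] <- if (i %% 2L == 1L) sin(ang) else cos(ang)
    }
    out
  }
  pos_h <- rep(0:(H0 - 1L), times = W0)
  pos_w <- rep(0:(W0 - 1L), each = H0)
  cbind(code1d(pos_h, half), code1d(pos_w, half))
}

#' Construct a conditional normalizing flow
#'
#' @param d Feature dimension.
#' @param n_coupling Number of affine coupling layers.
#' @param hidden Hidden width of each two-linear+ReLU coupling subnet.
#' @param cond_dim Width of the positional condition appended to every
#'   subnet input.
#' @param clamp Soft-clamp bound `a` for log-scales.
#' @param seed Seed for permutations and subnet initialization.
#' @return An object of class `flow_model`, identity-initialized (the last
#'   linear map of every subnet is zero).
#' @export
flow_model <- function(d, n_coupling = 8L, hidden = 512L, cond_dim = 32L,
                       clamp = 1.9, seed = 1L) {
  stopifnot(d >= 2L, n_coupling >= 1L, hidden >= 1L)
  set.seed(mix_seed(seed, 41L))
  da <- ceiling(d / 2); db <- d - da
  layers <- vector("list", n_coupling)
  for (k in seq_len(n_coupling)) {
    perm <- sample.int(d)
    inw <- da + cond_dim
    layers[[k]] <- list(
      perm = perm, invperm = order(perm),
      W1 = matrix(stats::rnorm(inw * hidden, sd = sqrt(2 / inw)), inw, hidden),
      b1 = rep(0, hidden),
      W2 = matrix(0, hidden, 2L * db),  # zero init => identity transform
      b2 = rep(0, 2L * db))
  }
  structure(list(d = as.integer(d), da = as.integer(da), db = as.integer(db),
                 n_coupling = as.integer(n_coupling),
                 hidden = as.integer(hidden), cond_dim = as.integer(cond_dim),
                 clamp = clamp, layers = layers, seed = as.integer(seed),
                 trained = FALSE, feature_center = NULL, feature_scale = NULL,
                 config_hash = NULL),
            class = "flow_model")
}

.check_flow_input <- function(model, x, cond) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$d) {
    stop("feature dimension mismatch: got ", ncol(x), ", flow expects ",
         model$d)
  }
  if (is.null(cond)) cond <- matrix(0, nrow(x), model$cond_dim)
  if (!is.matrix(cond)) cond <- matrix(cond, nrow = 1)
  if (nrow(cond) == 1L && nrow(x) > 1L) {
    cond <- cond[rep(1L, nrow(x)), , drop = FALSE]
  }
  if (ncol(cond) != model$cond_dim || nrow(cond) != nrow(x)) {
    stop("condition dimension mismatch: got ", nrow(cond), "x", ncol(cond),
         ", expected ", nrow(x), "x", model$cond_dim)
  }
  list(x = x, cond = cond)
}

.subnet_forward <- function(layer, xa, cond, clamp, db) {
  u <- cbind(xa, cond)
  pre <- sweep(u %*% layer$W1, 2, layer$b1, `+`)
  h <- pmax(pre, 0)
  out <- sweep(h %*% layer$W2, 2, layer$b2, `+`)
  s_raw <- out[, seq_len(db), drop = FALSE]
  t <- out[, db + seq_len(db), drop = FALSE]
  s <- clamp * tanh(s_raw / clamp)
  list(u = u, pre = pre, h = h, s_raw = s_raw, s = s, t = t)
}

#' Flow forward transform
#'
#' @param model A [flow_model()].
#' @param x `n x d` matrix of feature vectors (finite).
#' @param cond `n x cond_dim` condition matrix (a single row is recycled);
#'   `NULL` for a zero condition.
#' @param keep_cache Keep per-layer intermediates for backpropagation.
#' @return List with `z` (`n x d`), `logdet` (length-`n` vector) and,
#'   optionally, `cache`.
#' @export
flow_forward <- function(model, x, cond = NULL, keep_cache = FALSE) {
  ck <- .check_flow_input(model, x, cond)
  x <- ck$x; cond <- ck$cond
  if (any(!is.finite(x))) stop("flow_forward: non-finite input")
  n <- nrow(x); da <- model$da; db <- model$db
  logdet <- rep(0, n)
  cache <- if (keep_cache) vector("list", model$n_coupling) else NULL
  for (k in seq_len(model$n_coupling)) {
    ly <- model$layers[[k]]
    xp <- x[, ly$perm, drop = FALSE]
    xa <- xp[, seq_len(da), drop = FALSE]
    xb <- xp[, da + seq_len(db), drop = FALSE]
    sn <- .subnet_forward(ly, xa, cond, model$clamp, db)
    yb <- xb * exp(sn$s) + sn$t
    logdet <- logdet + rowSums(sn$s)
    if (keep_cache) cache[[k]] <- c(sn, list(xb = xb))
    x <- cbind(xa, yb)[, ly$invperm, drop = FALSE]
  }
  out <- list(z = x, logdet = logdet)
  if (keep_cache) out$cache <- cache
  out
}

#' Flow inverse transform
#'
#' Exact algebraic inverse of [flow_forward()].
#'
#' @inheritParams flow_forward
#' @param z `n x d` matrix in latent space.
#' @return `n x d` matrix `x` with `flow_forward(model, x, cond)$z == z`
#'   up to float rounding.
#' @export
flow_inverse <- function(model, z, cond = NULL) {
  ck <- .check_flow_input(model, z, cond)
  z <- ck$x; cond <- ck$cond
  da <- model$da; db <- model$db
  for (k in rev(seq_len(model$n_coupling))) {
    ly <- model$layers[[k]]
    zp <- z[, ly$perm, drop = FALSE]
    ya <- zp[, seq_len(da), drop = FALSE]
    yb <- zp[, da + seq_len(db), drop = FALSE]
    sn <- .subnet_forward(ly, ya, cond, model$clamp, db)
    xb <- (yb - sn$t) * exp(-sn$s)
    z <- cbind(ya, xb)[, ly$invperm, drop = FALSE]
  }
  z
}

#' Per-vector log-likelihood under the flow
#'
#' Change of variables with a standard multivariate Gaussian base:
#' `log p(x) = -d/2 log(2 pi) - ||phi(x)||^2 / 2 + log|det(d phi/d x)|`.
#'
#' @inheritParams flow_forward
#' @return Length-`n` vector of log-likelihoods.
#' @export
log_likelihood <- function(model, x, cond = NULL) {
  fw <- flow_forward(model, x, cond)
  -model$d / 2 * log(2 * pi) - 0.5 * rowSums(fw$z^2) + fw$logdet
}

#' Mean negative log-likelihood training objective
#'
#' @inheritParams flow_forward
#' @return Scalar: mean over the batch of
#'   `d/2 log(2 pi) + ||phi(x)||^2 / 2 - log|det|`.
#' @export
nll_objective <- function(model, x, cond = NULL) {
  if (is.null(x) || length(x) == 0L || (is.matrix(x) && nrow(x) == 0L)) {
    stop("nll_objective: empty batch")
  }
  -mean(log_likelihood(model, x, cond))
}

# Reverse-mode gradients of sum_i g_logp[i] * logp_i with respect to all
# subnet parameters.  `fw` must come from flow_forward(..., keep_cache=TRUE).
flow_backward <- function(model, fw, g_logp) {
  da <- model$da; db <- model$db
  gy <- -fw$z * g_logp                 # d logp / dz = -z, row-scaled
  glogdet <- g_logp                    # d logp / d logdet = 1
  grads <- vector("list", model$n_coupling)
  for (k in rev(seq_len(model$n_coupling))) {
    ly <- model$layers[[k]]
    cc <- fw$cache[[k]]
    gyp <- gy[, ly$perm, drop = FALSE]
    gya <- gyp[, seq_len(da), drop = FALSE]
    gyb <- gyp[, da + seq_len(db), drop = FALSE]
    es <- exp(cc$s)
    gs <- gyb * cc$xb * es + glogdet   # logdet adds g_logp to every s column
    gt <- gyb
    gs_raw <- gs * (1 - (cc$s / model$clamp)^2)
    gout <- cbind(gs_raw, gt)
    gW2 <- crossprod(cc$h, gout)
    gb2 <- colSums(gout)
    gh <- gout %*% t(ly$W2)
    gpre <- gh * (cc$pre > 0)
    gW1 <- crossprod(cc$u, gpre)
    gb1 <- colSums(gpre)
    gu <- gpre %*% t(ly$W1)
    gxa <- gya + gu[, seq_len(da), drop = FALSE]
    gxb <- gyb * es
    gxp <- cbind(gxa, gxb)
    gy <- gxp[, ly$invperm, drop = FALSE]
    grads[[k]] <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  }
  grads
}

# Extract / restore trainable parameters of the flow as a nested list.
flow_params <- function(model) {
  lapply(model$layers, function(ly) ly[c("W1", "b1", "W2", "b2")])
}

flow_set_params <- function(model, params) {
  for (k in seq_along(params)) {
    model$layers[[k]][c("W1", "b1", "W2", "b2")] <- params[[k]]
  }
  model
}

#' Train a flow on batches of normal feature vectors
#'
#' One optimization step per batch (a batch is all feature vectors from one
#' volume's slices).  Each step draws noise-synthesized anomalous features,
#' evaluates the flow negative log-likelihood of the normal features plus
#' the selected contrastive boundary loss, and applies one Adam update.
#'
#' @param model A [flow_model()].
#' @param batches List of `n_b x d` feature matrices.
#' @param conds Single condition matrix shared by all batches, or list
#'   parallel to `batches`.
#' @param loss_cfg A [loss_config()].
#' @param epochs Passes over `batches`.
#' @param lr Adam learning rate.
#' @return The trained model, with a `loss_log` data frame attached
#'   (`epoch`, `batch`, `nll`, `contrastive`).
#' @export
train_flow <- function(model, batches, conds = NULL,
                       loss_cfg = loss_config(), epochs = 1L, lr = 0.001) {
  stopifnot(inherits(model, "flow_model"), length(batches) >= 1L)
  params <- flow_params(model)
  state <- lapply(params, function(ly) lapply(ly, function(p)
    list(m = p * 0, v = p * 0)))
  t <- 0L
  log <- list()
  for (ep in seq_len(epochs)) {
    for (b in seq_along(batches)) {
      t <- t + 1L
      x <- batches[[b]]
      cond <- if (is.list(conds)) conds[[b]] else conds
      model <- flow_set_params(model, params)
      fwp <- flow_forward(model, x, cond, keep_cache = TRUE)
      const <- -model$d / 2 * log(2 * pi)
      logp <- const - 0.5 * rowSums(fwp$z^2) + fwp$logdet
      if (loss_cfg$variant != "none") {
        # Noise synthesis happens in the raw embedding space.  When the
        # trainer receives standardized features, an i.i.d. sigma in raw
        # space is a per-channel sigma / scale_c in standardized space.
        if (is.null(model$feature_scale)) {
          xq <- synthesize_anomalies(x, loss_cfg$sigma,
                                     seed = mix_seed(loss_cfg$seed, 53L, t))
        } else {
          set.seed(mix_seed(loss_cfg$seed, 53L, t))
          eps <- matrix(stats::rnorm(length(x), sd = loss_cfg$sigma),
                        nrow(x), ncol(x))
          xq <- x + sweep(eps, 2, model$feature_scale, `/`)
        }
        fwq <- flow_forward(model, xq, cond, keep_cache = TRUE)
        logq <- const - 0.5 * rowSums(fwq$z^2) + fwq$logdet
      } else {
        logq <- numeric(0)
      }
      n <- length(logp)
      gp <- rep(-1 / n, n)              # d(mean NLL)/d logp_i
      gq <- rep(0, length(logq))
      closs <- 0
      if (loss_cfg$variant != "none") {
        # The contrastive terms act on per-dimension-scaled log-likelihoods
        # (bits-per-dim style): raw log-likelihoods grow linearly with d,
        # which would let the squared/hinge terms drown the density fit.
        # The loss ops themselves stay defined on the raw scalars.
        cl <- contrastive_loss(logp / model$d, logq / model$d, loss_cfg,
                               seed = mix_seed(loss_cfg$seed, 59L, t),
                               grad = TRUE)
        closs <- cl$value
        # batch-mean scaling keeps the contrastive term commensurate with
        # the mean NLL regardless of batch size
        sc <- if (loss_cfg$variant == "triplet") 1 else 1 / n
        gp <- gp + sc * cl$gp / model$d
        gq <- gq + sc * cl$gq / model$d
      }
      gradp <- flow_backward(model, fwp, gp)
      grads <- gradp
      if (any(gq != 0)) {
        gradq <- flow_backward(model, fwq, gq)
        for (k in seq_along(grads)) {
          for (nm in names(grads[[k]])) {
            grads[[k]][[nm]] <- grads[[k]][[nm]] + gradq[[k]][[nm]]
          }
        }
      }
      for (k in seq_along(params)) {
        for (nm in names(params[[k]])) {
          g <- grads[[k]][[nm]]
          s <- state[[k]][[nm]]
          s$m <- 0.9 * s$m + 0.1 * g
          s$v <- 0.999 * s$v + 0.001 * g^2
          mhat <- s$m / (1 - 0.9^t)
          vhat <- s$v / (1 - 0.999^t)
          params[[k]][[nm]] <- params[[k]][[nm]] -
            lr * mhat / (sqrt(vhat) + 1e-8)
          state[[k]][[nm]] <- s
        }
      }
      log[[t]] <- data.frame(epoch = ep, batch = b, nll = -mean(logp),
                             contrastive = closs)
    }
  }
  model <- flow_set_params(model, params)
  model$trained <- TRUE
  model$loss_log <- do.call(rbind, log)
  model
}

#' Save / load a flow checkpoint
#'
#' The checkpoint carries a configuration fingerprint; [load_flow()] can
#' verify it against an expected hash to prevent scoring features produced
#' by a different encoder setup.
#'
#' @param model A `flow_model`.
#' @param path Checkpoint path.
#' @param config Optional configuration object to fingerprint.
#' @return `save_flow` returns `path` invisibly; `load_flow` the model.
#' @export
save_flow <- function(model, path, config = NULL) {
  if (!is.null(config)) model$config_hash <- config_hash(config)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_flow
#' @param expected_hash If non-`NULL`, a config hash that must match.
#' @export
load_flow <- function(path, expected_hash = NULL) {
  if (!file.exists(path)) stop("no flow checkpoint at ", path)
  model <- readRDS(path)
  if (!is.null(expected_hash) && !identical(model$config_hash, expected_hash)) {
    stop("flow checkpoint config hash (", model$config_hash,
         ") does not match the current configuration (", expected_hash, ")")
  }
  model
}
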