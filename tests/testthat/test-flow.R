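test_that("positional codes are bounded, distinct and input-free", {
  pc <- positional_condition(8, 8, 16)
  expect_identical(dim(pc), c(64L, 16L))
  expect_true(all(pc >= -1 & pc <= 1))
  expect_identical(anyDuplicated(as.data.frame(pc)), 0L)
  expect_identical(pc, positional_condition(8, 8, 16))
  expect_error(positional_condition(8, 8, 15), "even")
  expect_error(positional_condition(0, 8, 16), "positive")
})

test_that("a fresh flow is the identity with zero log-determinant", {
  m <- flow_model(d = 6, n_coupling = 4, hidden = 8, cond_dim = 4, seed = 2)
  x <- matrix(rnorm(30), 5, 6)
  cond <- matrix(runif(5 * 4, -1, 1), 5, 4)
  fw <- flow_forward(m, x, cond)
  expect_identical(fw$z, x)
  expect_identical(fw$logdet, rep(0, 5))
  expect_equal(flow_inverse(m, x, cond), x)
})

test_that("identity-flow likelihoods match the standard Gaussian closed form", {
  m <- flow_model(d = 2, n_coupling = 2, hidden = 4, cond_dim = 2, seed = 1)
  expect_equal(log_likelihood(m, matrix(0, 1, 2)), -log(2 * pi),
               tolerance = 1e-9)
  expect_equal(log_likelihood(m, matrix(c(1, 0), 1, 2)),
               -log(2 * pi) - 0.5, tolerance = 1e-9)
  expect_equal(nll_objective(m, matrix(0, 3, 2)), log(2 * pi),
               tolerance = 1e-9)
  expect_error(nll_objective(m, matrix(0, 0, 2)), "empty")
})

test_that("forward and inverse are mutual inverses", {
  m <- perturbed_flow(d = 8, seed = 5)
  x <- matrix(rnorm(50 * 8), 50, 8)
  cond <- matrix(runif(50 * 4, -1, 1), 50, 4)
  fw <- flow_forward(m, x, cond)
  expect_lt(max(abs(flow_inverse(m, fw$z, cond) - x)), 1e-10)
  z <- matrix(rnorm(50 * 8), 50, 8)
  expect_lt(max(abs(flow_forward(m, flow_inverse(m, z, cond), cond)$z - z)),
            1e-10)
})

test_that("a hand-built single coupling inverts by dividing out the scale", {
  m <- flow_model(d = 2, n_coupling = 1, hidden = 2, cond_dim = 2, seed = 3)
  m$layers[[1]]$perm <- 1:2
  m$layers[[1]]$invperm <- 1:2
  s0 <- 0.4; t0 <- -0.7
  m$layers[[1]]$b2 <- c(s0, t0)      # W2 stays zero: constant subnet output
  s_eff <- m$clamp * tanh(s0 / m$clamp)
  x <- matrix(c(1.5, 2.0), 1, 2)
  fw <- flow_forward(m, x, matrix(0, 1, 2))
  expect_equal(fw$z[1, 2], 2.0 * exp(s_eff) + t0, tolerance = 1e-12)
  expect_equal(fw$logdet, s_eff, tolerance = 1e-12)
  z <- matrix(c(1.5, 0.9), 1, 2)
  inv <- flow_inverse(m, z, matrix(0, 1, 2))
  expect_equal(inv[1, 2], (0.9 - t0) / exp(s_eff), tolerance = 1e-12)
})

test_that("the log-determinant matches a finite-difference Jacobian", {
  for (d in c(3, 4)) {
    m <- perturbed_flow(d = d, n_coupling = 3, hidden = 8, cond_dim = 2,
                        seed = d)
    x0 <- rnorm(d)
    c0 <- matrix(c(0.3, -0.2), 1)
    J <- matrix(0, d, d)
    h <- 1e-5
    for (j in seq_len(d)) {
      e <- rep(0, d); e[j] <- h
      J[, j] <- (flow_forward(m, matrix(x0 + e, 1), c0)$z -
                   flow_forward(m, matrix(x0 - e, 1), c0)$z) / (2 * h)
    }
    expect_equal(flow_forward(m, matrix(x0, 1), c0)$logdet,
                 log(abs(det(J))), tolerance = 1e-3)
  }
})

test_that("change-of-variables consistency holds for any flow", {
  m <- perturbed_flow(d = 6, seed = 9)
  x <- matrix(rnorm(20 * 6), 20, 6)
  cond <- matrix(runif(20 * 4, -1, 1), 20, 4)
  fw <- flow_forward(m, x, cond)
  base <- rowSums(matrix(dnorm(fw$z, log = TRUE), nrow(fw$z)))
  expect_equal(log_likelihood(m, x, cond), base + fw$logdet,
               tolerance = 1e-10)
  expect_equal(nll_objective(m, x, cond), -mean(log_likelihood(m, x, cond)),
               tolerance = 1e-12)
})

test_that("dimension mismatches and non-finite inputs are rejected", {
  m <- flow_model(d = 4, n_coupling = 2, hidden = 4, cond_dim = 2, seed = 1)
  expect_error(flow_forward(m, matrix(0, 2, 3)), "dimension mismatch")
  expect_error(flow_forward(m, matrix(0, 2, 4), matrix(0, 2, 5)),
               "condition dimension")
  expect_error(flow_forward(m, matrix(c(NaN, 0, 0, 0), 1, 4)), "non-finite")
})

test_that("parameter gradients match finite differences", {
  m <- perturbed_flow(d = 4, n_coupling = 2, hidden = 6, cond_dim = 2,
                      seed = 11)
  set.seed(1)
  n <- 6
  x <- matrix(rnorm(n * 4), n, 4)
  cond <- matrix(runif(n * 2, -1, 1), n, 2)
  fw <- flow_forward(m, x, cond, keep_cache = TRUE)
  gr <- voxelflow:::flow_backward(m, fw, rep(-1 / n, n))
  h <- 1e-6
  for (k in 1:2) {
    for (nm in c("W1", "b1", "W2", "b2")) {
      i <- sample(length(m$layers[[k]][[nm]]), 1)
      mp <- m; mp$layers[[k]][[nm]][i] <- mp$layers[[k]][[nm]][i] + h
      mm <- m; mm$layers[[k]][[nm]][i] <- mm$layers[[k]][[nm]][i] - h
      num <- (nll_objective(mp, x, cond) - nll_objective(mm, x, cond)) / (2 * h)
      expect_equal(gr[[k]][[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training approaches the entropy of the generating Gaussian", {
  S <- matrix(c(1, 0.6, 0.6, 1), 2)
  L <- chol(S)
  mu <- c(1, -0.5)
  set.seed(42)
  gen <- function(n) matrix(rnorm(n * 2), n, 2) %*% L +
    matrix(mu, n, 2, byrow = TRUE)
  m <- flow_model(d = 2, n_coupling = 4, hidden = 32, cond_dim = 2, seed = 5)
  batches <- lapply(1:20, function(i) gen(200))
  m <- train_flow(m, batches, conds = matrix(0, 1, 2),
                  loss_cfg = loss_config(variant = "none"),
                  epochs = 10, lr = 0.01)   # 200 steps
  entropy <- 0.5 * log((2 * pi * exp(1))^2 * det(S))
  expect_lt(abs(tail(m$loss_log$nll, 1) - entropy), 0.1)
  # held-out normal data is likelier than far outliers
  held <- gen(500)
  far <- held + 8
  expect_gt(mean(log_likelihood(m, held, matrix(0, 1, 2))),
            mean(log_likelihood(m, far, matrix(0, 1, 2))))
})

test_that("checkpoints round-trip and reject mismatched config hashes", {
  m <- perturbed_flow(d = 4, seed = 2)
  m$trained <- TRUE
  p <- tempfile(fileext = ".rds")
  cfg <- list(flow = list(n_coupling = 4), encoder = list(target_dim = 4))
  save_flow(m, p, config = cfg)
  m2 <- load_flow(p, expected_hash = voxelflow:::config_hash(cfg))
  expect_equal(m2$layers, m$layers)
  cfg$encoder$target_dim <- 8
  expect_error(load_flow(p, expected_hash = voxelflow:::config_hash(cfg)),
               "hash")
  unlink(p)
})
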