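test_that("anomaly synthesis is exact at sigma 0 and seeded", {
  f <- matrix(rnorm(20), 4, 5)
  expect_identical(synthesize_anomalies(f, 0), f)
  a1 <- synthesize_anomalies(f, 0.1, seed = 3)
  a2 <- synthesize_anomalies(f, 0.1, seed = 3)
  a3 <- synthesize_anomalies(f, 0.1, seed = 4)
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))
  expect_error(synthesize_anomalies(f, -0.1), ">= 0")
})

test_that("noise variance matches sigma^2 at scale", {
  f <- matrix(0, 1, 1e5)
  d <- synthesize_anomalies(f, 0.06, seed = 1) - f
  expect_lt(abs(var(as.numeric(d)) - 0.0036) / 0.0036, 0.05)
})

test_that("triplet loss reproduces its margin cases", {
  # n = 2: the derangement always swaps
  # margin satisfied: |lp_i - lq_i| well beyond |lp_i - lp_j| + tau
  expect_equal(triplet_loss(c(0, 0), c(-2, -2), tau = 1), 0)
  # degenerate collapse: every term equals tau
  expect_equal(triplet_loss(c(1, 1), c(1, 1), tau = 1), 1)
  # direct evaluation: term1 = max(0, 1 - 0.25 + 1) = 1.75, term2 = 0
  l <- triplet_loss(c(0, 1), c(-0.5, 1 - sqrt(2)), tau = 1)
  expect_equal(l, mean(c(1.75, 0)))
  expect_error(triplet_loss(1, 1), "at least 2")
})

test_that("triplet gradients match finite differences", {
  set.seed(7)
  lp <- rnorm(6); lq <- rnorm(6)
  g <- triplet_loss(lp, lq, tau = 1, seed = 2, grad = TRUE)
  h <- 1e-7
  for (i in c(1, 4)) {
    ep <- rep(0, 6); ep[i] <- h
    expect_equal(g$gp[i],
                 (triplet_loss(lp + ep, lq, tau = 1, seed = 2) -
                    triplet_loss(lp - ep, lq, tau = 1, seed = 2)) / (2 * h),
                 tolerance = 1e-5)
    expect_equal(g$gq[i],
                 (triplet_loss(lp, lq + ep, tau = 1, seed = 2) -
                    triplet_loss(lp, lq - ep, tau = 1, seed = 2)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("bgspp loss follows the boundary hinge arithmetic", {
  # percentile boundary of 0:10 at beta = 10 is exactly 1
  lp <- as.numeric(0:10)
  expect_equal(as.numeric(quantile(lp, 0.1)), 1)
  # single normal below the boundary by 1, no anomalies
  expect_equal(bgspp_loss(lp, numeric(0), beta = 10, tau = 1), 1)
  # an anomaly exactly at the boundary contributes tau
  expect_equal(bgspp_loss(lp, logq = 1, beta = 10, tau = 1), 1 + 1)
  # both hinges inactive
  expect_equal(bgspp_loss(rep(5, 10), logq = c(-5, -8), beta = 10, tau = 1), 0)
  expect_error(bgspp_loss(numeric(0)), "non-empty")
})

test_that("pairwise ranking loss evaluates its hinges", {
  expect_equal(prl_loss(c(5, 6), c(0, 1), tau = 1), 0)
  expect_equal(prl_loss(0.3, 0.3, tau = 1), 1)
  expect_equal(prl_loss(0.5, 0.2, tau = 1), 0.7)
  # full cross-product mode vs a double-loop oracle
  set.seed(1)
  lp <- rnorm(4); lq <- rnorm(3)
  want <- 0
  for (i in 1:4) for (j in 1:3) want <- want + max(0, 1 - (lp[i] - lq[j]))
  expect_equal(prl_loss(lp, lq, tau = 1, pairs = "full"), want)
  expect_error(prl_loss(numeric(0), numeric(0)), "non-empty")
})

test_that("all contrastive losses are shift-invariant and monotone in logq", {
  set.seed(3)
  lp <- rnorm(8); lq <- rnorm(8)
  c <- 3.7
  expect_equal(triplet_loss(lp + c, lq + c, seed = 5),
               triplet_loss(lp, lq, seed = 5))
  expect_equal(bgspp_loss(lp + c, lq + c), bgspp_loss(lp, lq))
  expect_equal(prl_loss(lp + c, lq + c), prl_loss(lp, lq))
  # raising any logq never decreases bgspp or prl
  for (i in c(2, 5)) {
    lq2 <- lq; lq2[i] <- lq2[i] + 0.8
    expect_gte(bgspp_loss(lp, lq2), bgspp_loss(lp, lq))
    expect_gte(prl_loss(lp, lq2), prl_loss(lp, lq))
  }
  # non-negativity
  expect_gte(triplet_loss(lp, lq, seed = 5), 0)
  expect_gte(bgspp_loss(lp, lq), 0)
  expect_gte(prl_loss(lp, lq), 0)
})

test_that("total_loss adds the selected term", {
  expect_equal(total_loss(2.0, 1.75, "triplet"), 3.75)
  expect_equal(total_loss(2.0, 0, "triplet"), 2.0)
  expect_equal(total_loss(2.0, 99, "none"), 2.0)
  expect_error(total_loss(Inf, 0, "none"), "finite")
})

test_that("loss_config validates its domain", {
  expect_error(loss_config(sigma = -1), "sigma")
  expect_error(loss_config(beta = 0), "beta")
  expect_error(loss_config(variant = "nope"))
})
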