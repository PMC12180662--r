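test_that("AUROC equals the brute-force concordant-pair fraction", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  set.seed(4)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    scores <- round(rnorm(n), 1)           # induce ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(auroc(scores, labels), pairwise_auroc(scores, labels))
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  expect_error(auroc(1:3, c(0, 1, 2)), "0/1")
})

test_that("random scores on balanced classes give AUROC near one half", {
  set.seed(9)
  n <- 20000
  expect_equal(auroc(rnorm(n), rep(c(0, 1), n / 2)), 0.5, tolerance = 0.02)
})

test_that("AUPRC matches a hand-swept precision-recall integration", {
  expect_equal(auprc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(auprc(c(0.3, 0.6), c(1, 1)), 1)        # all-positive labels
  # 6-point hand example: scores desc 6,5,4,3,2,1 labels 1,0,1,1,0,0
  # thresholds: R = 1/3, 1/3, 2/3, 1, 1, 1 ; P = 1, 1/2, 2/3, 3/4, 3/5, 1/2
  want <- (1 / 3) * 1 + 0 + (1 / 3) * (2 / 3) + (1 / 3) * (3 / 4) + 0 + 0
  expect_equal(auprc(6:1, c(1, 0, 1, 1, 0, 0)), want)
})

test_that("the F1 sweep finds the optimum with the stated tie rule", {
  b <- best_f1_threshold(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(b$f1, 1)
  expect_equal(b$threshold, 0.8)            # smallest optimal threshold
  # all scores equal: the only prediction is all-positive
  f <- 0.25
  b2 <- best_f1_threshold(rep(0.5, 8), c(1, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(b2$f1, 2 * f / (1 + f))
  expect_error(best_f1_threshold(1:3, c(0, 0, 0)), "positive")
})

test_that("max-Dice equals max-F1 on random draws", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(50:500, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, runif(1, 0.05, 0.6))
    if (sum(labels) == 0) labels[1] <- 1
    bf <- best_f1_threshold(scores, labels)
    expect_identical(max_dice(scores, labels), bf$f1)
  }
  # and both equal the brute-force sweep on a few cases
  set.seed(12)
  for (i in 1:5) {
    scores <- round(runif(30), 1)
    labels <- rbinom(30, 1, 0.3); labels[1] <- 1
    expect_equal(max_dice(scores, labels), bruteforce_best_f1(scores, labels))
  }
})

test_that("threshold metrics follow the confusion-matrix arithmetic", {
  expect_warning(p <- threshold_metrics(c(1, 1, 1, 1), c(1, 1, 1, 1), 0.5),
                 "specificity")
  expect_equal(unlist(p[c("accuracy", "precision", "f1")]),
               c(accuracy = 1, precision = 1, f1 = 1))
  # TP=3 FP=1 FN=1 TN=5
  scores <- c(0.9, 0.9, 0.9, 0.9, rep(0.1, 6))
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- threshold_metrics(scores, labels, 0.5)
  expect_equal(m$precision, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.75)
  # all-negative prediction: precision 0 with a warning, specificity 1
  expect_warning(m2 <- threshold_metrics(c(0.1, 0.2), c(1, 0), 0.9),
                 "precision")
  expect_equal(m2$precision, 0)
  expect_equal(m2$specificity, 1)
  expect_error(threshold_metrics(1:2, c(1, 2), 0.5), "0/1")
  expect_error(threshold_metrics(1:2, c(1, 0), NA), "finite")
})

test_that("connected component labeling separates face-connected regions", {
  mk <- array(0L, c(3, 4, 4))
  mk[1, 1:2, 1] <- 1L
  mk[3, 4, 4] <- 1L
  lab <- voxelflow:::label_components(mk)
  expect_equal(max(lab), 2)
  expect_equal(sum(lab == lab[1, 1, 1]), 2)
  # diagonal voxels are separate regions (face connectivity)
  mk2 <- matrix(0L, 3, 3); mk2[1, 1] <- 1L; mk2[2, 2] <- 1L
  expect_equal(max(voxelflow:::label_components(mk2)), 2)
})

test_that("PRO matches an exhaustive sweep oracle on a toy map", {
  mask <- matrix(0L, 6, 6)
  mask[2:3, 2:3] <- 1L       # region A
  mask[5, 5:6] <- 1L         # region B
  set.seed(3)
  sc <- matrix(runif(36, 0, 0.4), 6, 6)
  sc[2:3, 2:3] <- c(0.9, 0.85, 0.8, 0.95)
  sc[5, 5:6] <- c(0.05, 0.1)  # region B scores below every negative
  got <- pro_score(sc, mask, fpr_cap = 0.3)
  # oracle: independent threshold sweep with trapezoidal integration
  thr <- sort(unique(as.numeric(sc)), decreasing = TRUE)
  neg <- sc[mask == 0]
  regions <- list(sc[2:3, 2:3], sc[5, 5:6])
  fpr <- sapply(thr, function(t) mean(neg >= t))
  pro <- sapply(thr, function(t)
    mean(sapply(regions, function(r) mean(r >= t))))
  fpr <- c(0, fpr); pro <- c(0, pro)
  i <- which(fpr > 0.3)[1]
  w <- (0.3 - fpr[i - 1]) / (fpr[i] - fpr[i - 1])
  fpr2 <- c(fpr[1:(i - 1)], 0.3)
  pro2 <- c(pro[1:(i - 1)], pro[i - 1] + w * (pro[i] - pro[i - 1]))
  want <- sum(diff(fpr2) * (pro2[-1] + pro2[-length(pro2)]) / 2) / 0.3
  expect_equal(got, want)
  # with one region fully detected and one missed below the cap, the
  # per-region mean sits at 0.5 for all sub-cap thresholds
  expect_equal(want, 0.5, tolerance = 0.05)
  # perfect map
  expect_equal(pro_score(mask + 0, mask), 1)
  expect_error(pro_score(sc, matrix(0L, 6, 6)), "no anomalous region")
})

test_that("rank metrics are invariant to strictly monotone transforms", {
  set.seed(6)
  scores <- rnorm(400)
  labels <- rbinom(400, 1, 0.2); labels[1] <- 1; labels[2] <- 0
  trans <- function(x) exp(2 * x) + 1
  expect_equal(auroc(trans(scores), labels), auroc(scores, labels))
  expect_equal(auprc(trans(scores), labels), auprc(scores, labels))
  expect_equal(max_dice(trans(scores), labels), max_dice(scores, labels))
  mask <- matrix(labels[1:100], 10, 10)
  if (sum(mask) > 0) {
    s2 <- matrix(scores[1:100], 10, 10)
    expect_equal(pro_score(trans(s2), mask), pro_score(s2, mask),
                 tolerance = 1e-10)
  }
})

mk_map <- function(vals, d) {
  structure(list(scores = array(vals, d), lowres = array(vals, d),
                 normalization = "raw"), class = "anomaly_map")
}

test_that("pixel-level report averages per-volume metrics", {
  set.seed(8)
  d <- c(2, 5, 5)
  m1 <- mk_map(runif(50), d); k1 <- array(rbinom(50, 1, 0.3), d)
  m2 <- mk_map(runif(50), d); k2 <- array(rbinom(50, 1, 0.3), d)
  r_single <- evaluate_pixel_level(list(m1), list(k1))
  r_dup <- evaluate_pixel_level(list(m1, m1), list(k1, k1))
  expect_equal(r_dup$metrics, r_single$metrics)
  # mean of per-volume AUROCs, computed by hand volume-by-volume
  r12 <- evaluate_pixel_level(list(m1, m2), list(k1, k2))
  a1 <- auroc(as.numeric(m1$scores), as.numeric(k1))
  a2 <- auroc(as.numeric(m2$scores), as.numeric(k2))
  expect_equal(r12$metrics$auroc, mean(c(a1, a2)))
  # perfectly separating map on one volume, chance-free check of the mean
  mp <- mk_map(as.numeric(k1), d)
  rp <- evaluate_pixel_level(list(mp, m1), list(k1, k1))
  expect_equal(rp$metrics$auroc,
               mean(c(1, auroc(as.numeric(m1$scores), as.numeric(k1)))))
  # empty-mask volumes are excluded with a message
  expect_message(
    re <- evaluate_pixel_level(list(m1, m2), list(k1, array(0L, d))),
    "excluded")
  expect_equal(re$metrics$auroc, a1)
  expect_equal(re$n_excluded, 1L)
  expect_error(evaluate_pixel_level(list(m1), list(array(0L, c(3, 5, 5)))),
               "mismatch")
})

test_that("image-level report pools slices after dataset normalization", {
  d <- c(4, 3, 3)
  set.seed(10)
  maps <- lapply(1:3, function(i) mk_map(runif(36, 0, i), d))
  masks <- lapply(1:3, function(i) {
    m <- array(0L, d)
    if (i > 1) m[i, 1, 1] <- 1L
    m
  })
  r <- evaluate_image_level(maps, masks = masks)
  # oracle: pooled slice maxima with dataset-level min-max (rank-preserving)
  sc <- unlist(lapply(maps, function(m) apply(m$scores, 1, max)))
  lab <- unlist(lapply(masks, function(m) apply(m, 1, function(s) any(s != 0))))
  expect_equal(r$metrics$auroc, auroc(sc, as.numeric(lab)))
  expect_equal(r$metrics$auprc, auprc(sc, as.numeric(lab)))
  expect_equal(r$n_slices, 12)
  # anomalous slices outscoring all normal slices give AUROC 1
  perfect <- lapply(masks, function(m) mk_map(as.numeric(m), d))
  rp <- evaluate_image_level(perfect, masks = masks)
  expect_equal(rp$metrics$auroc, 1)
  expect_error(evaluate_image_level(maps, labels = c(1, 0)), "label count")
})
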