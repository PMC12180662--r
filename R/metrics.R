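# Evaluation metrics for anomaly segmentation and detection: threshold-free
# (AUROC, AUPRC, PRO, maximum Dice / F1) and confusion-matrix metrics at the
# F1-optimal threshold.  Pixel-level reports normalize per volume, compute
# metrics per volume and average; image-level reports normalize across the
# dataset and pool all slices.

.check_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  as.integer(labels)
}

#' Area under the ROC curve (rank formulation)
#'
#' Mann--Whitney statistic: the probability that a random positive outranks
#' a random negative, with ties counted half.
#'
#' @param scores Numeric scores (higher = more anomalous).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- .check_labels(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("AUROC needs both classes present (got ", npos, " positives, ",
         nneg, " negatives)")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve (step-wise integration)
#'
#' Thresholds sweep the distinct score values in decreasing order;
#' `AP = sum_k (R_k - R_{k-1}) P_k`.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`; all-positive labels give 1.
#' @export
auprc <- function(scores, labels) {
  labels <- .check_labels(labels)
  npos <- sum(labels == 1L)
  if (npos == 0L) stop("AUPRC needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tied block
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' F1-optimal threshold
#'
#' Exhaustive sweep over the distinct score values (the precision-recall
#' curve thresholds) with the `score >= threshold` binarization rule; ties
#' in F1 break toward the smallest threshold.
#'
#' @inheritParams auroc
#' @return List with `threshold` and `f1`.
#' @export
best_f1_threshold <- function(scores, labels) {
  labels <- .check_labels(labels)
  npos <- sum(labels == 1L)
  if (npos == 0L) stop("best_f1_threshold needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  thr <- s[keep]; tp <- tp[keep]; fp <- fp[keep]
  f1 <- 2 * tp / (2 * tp + fp + (npos - tp))
  best <- max(f1)
  # ties toward the smallest threshold: last index among the maxima
  idx <- max(which(f1 == best))
  list(threshold = thr[idx], f1 = best)
}

#' Maximum Dice coefficient over all thresholds
#'
#' Independently coded sweep (ascending order, complement counting) of
#' `Dice = 2 TP / (pred_pos + npos)`; mathematically identical to the
#' maximum F1 score.
#'
#' @inheritParams auroc
#' @return Maximum Dice in `[0, 1]`.
#' @export
max_dice <- function(scores, labels) {
  labels <- .check_labels(labels)
  npos <- sum(labels == 1L)
  if (npos == 0L) stop("max_dice needs at least one positive")
  o <- order(scores)                      # ascending
  s <- scores[o]; y <- labels[o]
  first <- !duplicated(s)                 # first index of each distinct value
  # predicting score >= s[i]: everything from i on is positive
  n <- length(s)
  pos_below <- cumsum(y) - y              # positives strictly before i
  count_below <- seq_len(n) - 1L
  tp <- npos - pos_below[first]
  predpos <- n - count_below[first]
  max(2 * tp / (predpos + npos))
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' Binarizes at `score >= threshold`.  Zero-division cases (e.g. no
#' predicted positives) return 0 with a warning.
#'
#' @inheritParams auroc
#' @param threshold Finite score threshold.
#' @return List with `specificity`, `accuracy`, `precision`, `f1`.
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  labels <- .check_labels(labels)
  if (!is.finite(threshold)) stop("threshold must be finite")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, ": zero denominator, reporting 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  list(specificity = safe(tn, tn + fp, "specificity"),
       accuracy = (tp + tn) / length(labels),
       precision = safe(tp, tp + fp, "precision"),
       f1 = safe(2 * tp, 2 * tp + fp + fn, "F1"))
}

# Connected components with face (4/6) connectivity; plain BFS flood fill.
label_components <- function(mask) {
  d <- dim(mask)
  if (is.null(d)) d <- length(mask)
  nd <- length(d)
  lab <- array(0L, d)
  idx_all <- which(mask != 0)
  if (length(idx_all) == 0L) return(lab)
  coords <- arrayInd(idx_all, d)
  inmask <- array(FALSE, d); inmask[idx_all] <- TRUE
  strides <- cumprod(c(1, d[-nd]))
  cur <- 0L
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1]]; queue <- queue[-1]
      vi <- arrayInd(v, d)
      for (ax in seq_len(nd)) {
        for (dd in c(-1L, 1L)) {
          ni <- vi
          ni[ax] <- ni[ax] + dd
          if (ni[ax] < 1L || ni[ax] > d[ax]) next
          nb <- v + dd * strides[ax]
          if (inmask[nb] && lab[nb] == 0L) {
            lab[nb] <- cur
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  lab
}

#' Per-region overlap (PRO) score
#'
#' Thresholds sweep the score range; at each threshold the mean recall over
#' the connected ground-truth regions is paired with the pooled
#' false-positive rate.  The per-region-overlap curve is integrated
#' (trapezoid) over FPR in `[0, fpr_cap]` and normalized by the cap.
#'
#' @param maps Score array or list of score arrays.
#' @param masks 0/1 mask array or list, aligned with `maps`; must contain at
#'   least one connected anomalous region in total.
#' @param fpr_cap Upper false-positive-rate integration limit.
#' @param max_thresholds Cap on the number of distinct thresholds swept
#'   (quantile-subsampled above this).
#' @return PRO in `[0, 1]`.
#' @export
pro_score <- function(maps, masks, fpr_cap = 0.3, max_thresholds = 200L) {
  if (!is.list(maps)) maps <- list(maps)
  if (!is.list(masks)) masks <- list(masks)
  stopifnot(length(maps) == length(masks))
  regions <- list()
  all_scores <- numeric(0)
  neg_scores <- numeric(0)
  for (v in seq_along(maps)) {
    sc <- as.array(maps[[v]]); mk <- as.array(masks[[v]])
    if (!identical(dim(sc), dim(mk))) stop("map/mask shape mismatch at ", v)
    lab <- label_components(mk)
    nreg <- max(lab)
    for (r in seq_len(nreg)) {
      regions[[length(regions) + 1L]] <- sc[lab == r]
    }
    neg_scores <- c(neg_scores, sc[mk == 0])
    all_scores <- c(all_scores, as.numeric(sc))
  }
  if (length(regions) == 0L) stop("pro_score: masks contain no anomalous region")
  thr <- sort(unique(all_scores), decreasing = TRUE)
  if (length(thr) > max_thresholds) {
    thr <- unique(stats::quantile(all_scores,
                                  probs = seq(1, 0, length.out = max_thresholds),
                                  names = FALSE, type = 1))
    thr <- sort(thr, decreasing = TRUE)
  }
  nneg <- length(neg_scores)
  fpr <- vapply(thr, function(t) sum(neg_scores >= t) / nneg, numeric(1))
  pro <- vapply(thr, function(t) {
    mean(vapply(regions, function(r) mean(r >= t), numeric(1)))
  }, numeric(1))
  fpr <- c(0, fpr); pro <- c(0, pro)
  o <- order(fpr)
  fpr <- fpr[o]; pro <- pro[o]
  if (max(fpr) < fpr_cap) {
    fpr <- c(fpr, fpr_cap)
    pro <- c(pro, pro[length(pro)])
  } else if (!any(fpr == fpr_cap)) {
    i <- which(fpr > fpr_cap)[1]
    w <- (fpr_cap - fpr[i - 1]) / (fpr[i] - fpr[i - 1])
    pcap <- pro[i - 1] + w * (pro[i] - pro[i - 1])
    fpr <- c(fpr[seq_len(i - 1)], fpr_cap)
    pro <- c(pro[seq_len(i - 1)], pcap)
  } else {
    keep <- fpr <= fpr_cap
    fpr <- fpr[keep]; pro <- pro[keep]
  }
  sum(diff(fpr) * (pro[-1] + pro[-length(pro)]) / 2) / fpr_cap
}

.metric_bundle <- function(scores, labels, with_pro = FALSE, maps = NULL,
                           masks = NULL) {
  bf <- best_f1_threshold(scores, labels)
  md <- max_dice(scores, labels)
  if (abs(md - bf$f1) > 1e-12) {
    stop("internal inconsistency: max-Dice (", md, ") != max-F1 (", bf$f1, ")")
  }
  tm <- threshold_metrics(scores, labels, bf$threshold)
  out <- list(auroc = auroc(scores, labels),
              auprc = auprc(scores, labels),
              max_dice = md,
              f1_threshold = bf$threshold,
              specificity = tm$specificity,
              accuracy = tm$accuracy,
              precision = tm$precision)
  if (with_pro) out$pro <- pro_score(maps, masks)
  out
}

#' Pixel-level evaluation report
#'
#' Protocol: per-volume min-max normalization, metrics per volume, then the
#' unweighted mean across volumes.  Volumes with empty masks are excluded
#' from the averaging (their count is reported and messaged).
#'
#' @param maps List of `anomaly_map`s (or raw score arrays).
#' @param masks List of 0/1 mask arrays aligned with `maps`.
#' @return An object of class `eval_report` (level `"pixel"`) with the mean
#'   metrics, the per-volume breakdown, and the number of excluded volumes.
#' @export
evaluate_pixel_level <- function(maps, masks) {
  stopifnot(length(maps) == length(masks))
  maps <- lapply(maps, function(m) {
    if (inherits(m, "anomaly_map")) m else
      structure(list(scores = as.array(m), lowres = as.array(m),
                     normalization = "raw"), class = "anomaly_map")
  })
  for (v in seq_along(maps)) {
    if (!identical(dim(maps[[v]]$scores), dim(as.array(masks[[v]])))) {
      stop("map/mask shape mismatch for volume ", v)
    }
  }
  maps <- normalize_scores(maps, "per_volume")
  rows <- list()
  excluded <- 0L
  for (v in seq_along(maps)) {
    mask <- as.array(masks[[v]])
    if (sum(mask) == 0L) {
      excluded <- excluded + 1L
      next
    }
    b <- .metric_bundle(as.numeric(maps[[v]]$scores), as.numeric(mask != 0),
                        with_pro = TRUE, maps = maps[[v]]$scores,
                        masks = mask)
    rows[[length(rows) + 1L]] <- as.data.frame(c(list(volume = v), b))
  }
  if (excluded > 0L) {
    message(excluded, " volume(s) with empty masks excluded from pixel-level",
            " averaging")
  }
  if (length(rows) == 0L) stop("no volume with a non-empty mask to evaluate")
  per_volume <- do.call(rbind, rows)
  metrics <- colMeans(per_volume[, setdiff(names(per_volume), "volume")])
  structure(list(level = "pixel", metrics = as.list(metrics),
                 per_volume = per_volume, n_excluded = excluded),
            class = "eval_report")
}

#' Image (slice)-level evaluation report
#'
#' Protocol: dataset-level min-max normalization over all volumes, one
#' score per axial slice (the slice's maximum voxel score), metrics pooled
#' over all slices of all volumes.  A slice is anomalous iff its mask
#' contains at least one positive voxel.
#'
#' @param maps List of `anomaly_map`s.
#' @param masks List of mask arrays (used to derive slice labels), or
#'   `NULL` if `labels` is given.
#' @param labels Optional list/vector of per-slice 0/1 labels, one entry
#'   per slice of each volume in order.
#' @return An object of class `eval_report` (level `"image"`).
#' @export
evaluate_image_level <- function(maps, masks = NULL, labels = NULL) {
  stopifnot(inherits(maps[[1]], "anomaly_map"))
  maps <- normalize_scores(maps, "dataset")
  scores <- unlist(lapply(maps, image_level_scores))
  if (is.null(labels)) {
    if (is.null(masks)) stop("provide masks or labels")
    labels <- unlist(lapply(masks, function(m) {
      as.integer(apply(as.array(m), 1, function(s) any(s != 0)))
    }))
  } else {
    labels <- unlist(labels)
  }
  if (length(labels) != length(scores)) {
    stop("label count (", length(labels), ") does not match slice count (",
         length(scores), ")")
  }
  b <- .metric_bundle(scores, labels, with_pro = FALSE)
  structure(list(level = "image", metrics = b,
                 n_slices = length(scores)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$level, "level\n")
  m <- x$metrics
  for (nm in names(m)) cat(sprintf("  %-12s %.4f\n", nm, m[[nm]]))
  invisible(x)
}
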