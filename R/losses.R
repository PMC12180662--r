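# Feature-space anomaly synthesis and contrastive boundary losses.
#
# Anomalous features are synthesized by adding i.i.d. Gaussian noise to the
# final embedding vectors.  The contrastive losses act on the scalar
# per-vector log-likelihoods of normal (logp) and perturbed (logq)
# features, softly pulling normals together and pushing perturbed features
# below a margin.

#' Loss configuration
#'
#' @param variant One of `"triplet"`, `"bgspp"`, `"prl"`, `"none"`.
#' @param sigma Noise standard deviation for anomaly synthesis.
#' @param tau Margin of the contrastive losses.
#' @param beta Percentile (0--100) defining the normal boundary `b_n`
#'   (boundary-guided semi-push-pull only).
#' @param prl_pairs `"aligned"` pairs `(i, i)` or `"full"` cross-product
#'   pairing for the pairwise ranking loss.
#' @param seed Seed for noise and triplet partner assignment.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(variant = c("triplet", "bgspp", "prl", "none"),
                        sigma = 0.06, tau = 1.0, beta = 10,
                        prl_pairs = c("aligned", "full"), seed = 1L) {
  variant <- match.arg(variant)
  prl_pairs <- match.arg(prl_pairs)
  if (sigma < 0) stop("sigma must be >= 0")
  if (tau < 0) stop("tau must be >= 0")
  if (beta <= 0 || beta >= 100) stop("beta must lie in (0, 100)")
  structure(list(variant = variant, sigma = sigma, tau = tau, beta = beta,
                 prl_pairs = prl_pairs, seed = as.integer(seed)),
            class = "loss_config")
}

#' Synthesize anomalous features by Gaussian perturbation
#'
#' `f~ = f + e`, `e ~ N(0, sigma^2)` i.i.d. per element, reproducible under
#' `seed`.  Applied to the final embedding vectors.
#'
#' @param features Numeric matrix or array.
#' @param sigma Noise standard deviation (`0` returns the input exactly).
#' @param seed Integer seed.
#' @return Perturbed features, same shape as the input.
#' @export
synthesize_anomalies <- function(features, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(features)
  set.seed(mix_seed(seed, 31L))
  features + stats::rnorm(length(features), sd = sigma)
}

# Seeded random derangement: shuffle, then pair each element with its cyclic
# successor in shuffled order.  No element maps to itself for n >= 2.
.derangement <- function(n, seed) {
  set.seed(mix_seed(seed, 37L))
  ord <- sample.int(n)
  j <- integer(n)
  j[ord] <- ord[c(2:n, 1L)]
  j
}

#' Triplet loss on scalar log-likelihoods
#'
#' `mean_i max(0, (logp_i - logp_j)^2 - (logp_i - logq_i)^2 + tau)`, where
#' the positive partner `j` is a seeded random derangement of the batch.
#' Pulls normal log-likelihoods pairwise together and pushes each perturbed
#' feature's log-likelihood away from its normal counterpart by the margin.
#'
#' @param logp,logq Equal-length numeric vectors of normal / perturbed
#'   log-likelihoods (`length >= 2` normals).
#' @param tau Margin.
#' @param seed Seed for the partner derangement.
#' @param grad Also return gradients with respect to `logp` and `logq`.
#' @return Scalar loss, or a list `(value, gp, gq)` when `grad = TRUE`.
#' @export
triplet_loss <- function(logp, logq, tau = 1.0, seed = 1L, grad = FALSE) {
  n <- length(logp)
  if (n < 2L) stop("triplet loss needs at least 2 normal entries")
  if (length(logq) != n) stop("logq must pair with logp")
  j <- .derangement(n, seed)
  dpp <- logp - logp[j]
  dpq <- logp - logq
  term <- dpp^2 - dpq^2 + tau
  active <- term > 0
  value <- mean(pmax(term, 0))
  if (!grad) return(value)
  gp <- numeric(n); gq <- numeric(n)
  a <- which(active)
  gp[a] <- gp[a] + 2 * dpp[a] - 2 * dpq[a]
  for (i in a) gp[j[i]] <- gp[j[i]] - 2 * dpp[i]
  gq[a] <- 2 * dpq[a]
  list(value = value, gp = gp / n, gq = gq / n)
}

#' Boundary-guided semi-push-pull loss
#'
#' With `b_n` the `beta`-th percentile of the normal log-likelihoods:
#' `sum_i |min(logp_i - b_n, 0)| + sum_j |max(logq_j - b_n + tau, 0)|`.
#' Normals below the boundary are pulled up; perturbed features are pushed
#' below `b_n - tau`.  The boundary is treated as a constant of the batch.
#'
#' @param logp Non-empty vector of normal log-likelihoods.
#' @param logq Vector of perturbed log-likelihoods (may be empty).
#' @param beta Percentile in (0, 100).
#' @param tau Margin.
#' @param grad Also return gradients.
#' @return Scalar loss, or a list `(value, gp, gq)`.
#' @export
bgspp_loss <- function(logp, logq = numeric(0), beta = 10, tau = 1.0,
                       grad = FALSE) {
  if (length(logp) == 0L) stop("bgspp loss needs a non-empty normal batch")
  bn <- as.numeric(stats::quantile(logp, beta / 100))
  pull <- pmin(logp - bn, 0)
  push <- pmax(logq - bn + tau, 0)
  value <- sum(abs(pull)) + sum(abs(push))
  if (!grad) return(value)
  list(value = value,
       gp = -as.numeric(logp < bn),
       gq = as.numeric(logq - bn + tau > 0))
}

#' Pairwise ranking loss
#'
#' `sum max(0, tau - (logp_i - logq_j))` over aligned pairs `(i, i)`
#' (default) or the full `i x j` cross-product.
#'
#' @inheritParams bgspp_loss
#' @param pairs `"aligned"` or `"full"`.
#' @return Scalar loss, or a list `(value, gp, gq)`.
#' @export
prl_loss <- function(logp, logq, tau = 1.0, pairs = c("aligned", "full"),
                     grad = FALSE) {
  pairs <- match.arg(pairs)
  if (length(logp) == 0L || length(logq) == 0L) {
    stop("prl loss needs non-empty logp and logq")
  }
  if (pairs == "aligned") {
    if (length(logp) != length(logq)) stop("aligned pairing needs equal lengths")
    h <- pmax(0, tau - (logp - logq))
    value <- sum(h)
    if (!grad) return(value)
    act <- as.numeric(h > 0)
    return(list(value = value, gp = -act, gq = act))
  }
  diffs <- outer(logp, logq, `-`)
  h <- pmax(0, tau - diffs)
  value <- sum(h)
  if (!grad) return(value)
  act <- h > 0
  list(value = value, gp = -rowSums(act), gq = colSums(act))
}

# Dispatch on the configured variant; returns (value, gp, gq) when grad=TRUE.
contrastive_loss <- function(logp, logq, cfg, seed = cfg$seed, grad = FALSE) {
  switch(cfg$variant,
         triplet = triplet_loss(logp, logq, tau = cfg$tau, seed = seed,
                                grad = grad),
         bgspp = bgspp_loss(logp, logq, beta = cfg$beta, tau = cfg$tau,
                            grad = grad),
         prl = prl_loss(logp, logq, tau = cfg$tau, pairs = cfg$prl_pairs,
                        grad = grad),
         none = if (grad) {
           list(value = 0, gp = numeric(length(logp)),
                gq = numeric(length(logq)))
         } else 0)
}

#' Combine the flow objective with a contrastive term
#'
#' Unweighted sum; variant `"none"` returns the flow objective alone.
#'
#' @param flow_nll Scalar flow negative log-likelihood objective.
#' @param contrastive Scalar contrastive loss.
#' @param variant Loss variant name.
#' @return Scalar total loss.
#' @export
total_loss <- function(flow_nll, contrastive, variant = "triplet") {
  if (!is.finite(flow_nll)) stop("flow objective must be finite")
  if (variant == "none") return(flow_nll)
  if (!is.finite(contrastive)) stop("contrastive loss must be finite")
  flow_nll + contrastive
}
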