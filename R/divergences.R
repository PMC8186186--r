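#' @name divergences
#' @title MMD and Kullback-Leibler divergence estimators
#'
#' @description
#' The generalized objective penalizes two divergences: a maximum mean
#' discrepancy (MMD) between latent samples drawn through the encoder and
#' samples from the latent prior, and a Kullback-Leibler (KL) term between
#' the per-cell mixture posterior and the learnable Gaussian-mixture prior.
#' The MMD uses a Gaussian RBF kernel with bandwidth `sigma^2 = L` (the
#' latent dimension), the usual InfoVAE-lineage convention, and the biased
#' V-statistic estimator, which is non-negative by construction.
NULL

#' Gaussian RBF kernel
#'
#' `k(a, b) = exp(-||a - b||^2 / (2 sigma^2))`, a characteristic kernel on
#' the latent space; symmetric, with values in (0, 1].
#'
#' @param a,b numeric vectors of equal length.
#' @param bandwidth kernel bandwidth `sigma^2 > 0`.
#' @export
rbf_kernel <- function(a, b, bandwidth) {
  if (length(a) != length(b)) stop("kernel arguments must have equal length")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  exp(-sum((a - b)^2) / (2 * bandwidth))
}

# squared Euclidean cross-distance matrix between row sets
.cross_sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Maximum mean discrepancy (biased V-statistic)
#'
#' `MMD^2 = mean k(p, p') + mean k(q, q') - 2 mean k(p, q)` over all pairs
#' including self-pairs. Non-negative for a characteristic kernel; zero when
#' the two sample sets coincide.
#'
#' @param samples_p n x L matrix of samples from the first distribution.
#' @param samples_q m x L matrix of samples from the second distribution.
#' @param bandwidth RBF bandwidth `sigma^2`; defaults to the latent dimension
#'   `L`.
#' @export
mmd_vstat <- function(samples_p, samples_q, bandwidth = ncol(samples_p)) {
  samples_p <- as.matrix(samples_p)
  samples_q <- as.matrix(samples_q)
  if (ncol(samples_p) != ncol(samples_q)) {
    stop("sample sets must share the latent dimension")
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")
  kpp <- exp(-.cross_sqdist(samples_p, samples_p) / (2 * bandwidth))
  kqq <- exp(-.cross_sqdist(samples_q, samples_q) / (2 * bandwidth))
  kpq <- exp(-.cross_sqdist(samples_p, samples_q) / (2 * bandwidth))
  max(mean(kpp) + mean(kqq) - 2 * mean(kpq), 0)
}

#' Diagonal Gaussian parameters
#'
#' @param mean numeric vector of length L.
#' @param log_variance numeric vector of length L; the variance is
#'   `exp(log_variance)`, positive by construction.
#' @export
gaussian_params <- function(mean, log_variance) {
  if (length(mean) != length(log_variance)) {
    stop("mean and log_variance must have equal length")
  }
  if (any(!is.finite(mean)) || any(!is.finite(log_variance))) {
    stop("Gaussian parameters must be finite")
  }
  structure(list(mean = as.numeric(mean),
                 log_variance = as.numeric(log_variance)),
            class = "gaussian_params")
}

#' KL divergence between two diagonal Gaussians
#'
#' Closed form, summed over dimensions:
#' `log(sigma_q / sigma_p) + (sigma_p^2 + (mu_p - mu_q)^2) / (2 sigma_q^2) - 1/2`.
#'
#' @param p,q [gaussian_params()] objects of equal dimension.
#' @export
gaussian_kl_pair <- function(p, q) {
  stopifnot(inherits(p, "gaussian_params"), inherits(q, "gaussian_params"))
  if (length(p$mean) != length(q$mean)) stop("dimension mismatch")
  vp <- exp(p$log_variance)
  vq <- exp(q$log_variance)
  sum(0.5 * (q$log_variance - p$log_variance) +
        (vp + (p$mean - q$mean)^2) / (2 * vq) - 0.5)
}

#' KL divergence between two categorical distributions
#'
#' `sum q_i log(q_i / p_i)` with the convention `0 log 0 = 0`. A zero prior
#' probability where the posterior carries mass makes the divergence
#' infinite and is reported as an error (in training the prior weights come
#' through a softmax, so this cannot occur).
#'
#' @param q,p probability vectors of equal length, each summing to 1.
#' @export
categorical_kl <- function(q, p) {
  if (length(q) != length(p)) stop("length mismatch")
  if (abs(sum(q) - 1) > 1e-6 || abs(sum(p) - 1) > 1e-6) {
    stop("arguments must be probability vectors summing to 1")
  }
  if (any(p == 0 & q > 0)) stop("infinite divergence: prior has zero mass where posterior is positive")
  pos <- q > 0
  sum(q[pos] * (log(q[pos]) - log(p[pos])))
}

#' Learnable Gaussian-mixture prior
#'
#' The prior over the latent space is a K-component mixture of diagonal
#' Gaussians whose weights, means and variances are all trainable.
#'
#' @param weights probability vector over the K components (sums to 1).
#' @param means K x L matrix of component means.
#' @param log_variances K x L matrix of component log-variances.
#' @export
mixture_prior <- function(weights, means, log_variances) {
  means <- as.matrix(means)
  log_variances <- as.matrix(log_variances)
  if (abs(sum(weights) - 1) > 1e-6) stop("mixture weights must sum to 1")
  if (any(weights < 0)) stop("mixture weights must be non-negative")
  K <- length(weights)
  if (nrow(means) != K || nrow(log_variances) != K) {
    stop("one row of means/log_variances per component required")
  }
  if (!all(dim(means) == dim(log_variances))) stop("dimension mismatch")
  structure(list(weights = as.numeric(weights), means = means,
                 log_variances = log_variances, K = K, L = ncol(means)),
            class = "mixture_prior")
}

#' Per-cell mixture posterior
#'
#' Encoder output for a batch of cells: categorical responsibilities
#' `q(y | x)` over the K components and per-component diagonal-Gaussian
#' parameters `q(z | x, y)`.
#'
#' @param responsibilities n x K matrix, rows on the simplex.
#' @param means,log_variances lists of K matrices, each n x L.
#' @export
mixture_posterior <- function(responsibilities, means, log_variances) {
  responsibilities <- as.matrix(responsibilities)
  if (any(abs(rowSums(responsibilities) - 1) > 1e-6)) {
    stop("responsibility rows must sum to 1")
  }
  K <- ncol(responsibilities)
  if (length(means) != K || length(log_variances) != K) {
    stop("one mean/log-variance matrix per component required")
  }
  structure(list(responsibilities = responsibilities,
                 means = lapply(means, as.matrix),
                 log_variances = lapply(log_variances, as.matrix),
                 K = K, L = ncol(as.matrix(means[[1]]))),
            class = "mixture_posterior")
}

#' Joint KL between the mixture posterior and the mixture prior
#'
#' Per cell,
#' `sum_y q(y|x) KL(q(z|x,y) || prior_y) + KL(q(y|x) || prior weights)`,
#' the analytic KL of the joint `(z, y)` factorization; reduced by the
#' empirical mean over cells.
#'
#' @param posterior a [mixture_posterior()].
#' @param prior a [mixture_prior()] with matching K and L.
#' @param reduce if `TRUE` (default) return the mean over cells, otherwise
#'   the per-cell vector.
#' @export
mixture_joint_kl <- function(posterior, prior, reduce = TRUE) {
  stopifnot(inherits(posterior, "mixture_posterior"),
            inherits(prior, "mixture_prior"))
  if (posterior$K != prior$K) stop("component count K mismatch")
  if (posterior$L != prior$L) stop("latent dimension mismatch")
  n <- nrow(posterior$responsibilities)
  K <- prior$K
  gauss <- matrix(0, n, K)
  for (k in seq_len(K)) {
    M <- posterior$means[[k]]
    V <- posterior$log_variances[[k]]
    pm <- matrix(prior$means[k, ], n, prior$L, byrow = TRUE)
    plv <- matrix(prior$log_variances[k, ], n, prior$L, byrow = TRUE)
    gauss[, k] <- rowSums(0.5 * (plv - V) +
                            (exp(V) + (M - pm)^2) / (2 * exp(plv)) - 0.5)
  }
  R <- posterior$responsibilities
  logw <- matrix(log(pmax(prior$weights, 1e-12)), n, K, byrow = TRUE)
  cat_term <- rowSums(ifelse(R > 0, R * (log(R) - logw), 0))
  per_cell <- rowSums(R * gauss) + cat_term
  if (reduce) mean(per_cell) else per_cell
}

#' Draw samples from a mixture prior
#'
#' For each draw, a component is sampled from the mixture weights and a
#' latent point from that component's diagonal Gaussian.
#'
#' @param prior a [mixture_prior()].
#' @param n number of samples.
#' @return list with `z` (n x L) and `component` (integer vector).
#' @export
sample_mixture_prior <- function(prior, n) {
  stopifnot(inherits(prior, "mixture_prior"))
  y <- sample.int(prior$K, n, replace = TRUE, prob = prior$weights)
  eps <- matrix(stats::rnorm(n * prior$L), n, prior$L)
  z <- prior$means[y, , drop = FALSE] +
    exp(prior$log_variances[y, , drop = FALSE] / 2) * eps
  list(z = z, component = y, eps = eps)
}
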