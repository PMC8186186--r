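#' @name autoencoder_models
#' @title Encoder/decoder networks for the generalized objective
#'
#' @description
#' One hidden layer on each side, sigmoid activations. The encoder maps raw
#' counts to a K-component mixture posterior: per-component latent means and
#' log-variances plus a K-way responsibility head (softmax). One latent point
#' per cell is drawn by Gaussian reparameterization within each component and
#' combined by responsibility weighting; the decoder maps it back to the
#' parameters of the chosen count likelihood (a softmax simplex over genes
#' for the library-size-constrained losses, an exponential link otherwise,
#' a logistic link for zero-inflation probabilities, and a free per-gene
#' inverse-dispersion).
#'
#' Gradients of the full objective (reconstruction NLL + weighted KL +
#' weighted MMD) are computed analytically; optimisation is plain Adam.
#' With a fixed seed and single-threaded BLAS, training is reproducible.
NULL

#' Network specification
#'
#' @param hidden_units number of neurons H in the (single) hidden layer of
#'   encoder and decoder; default 256.
#' @param latent_units latent dimension L; default 32. Must satisfy
#'   `L <= H` and `L <=` number of genes.
#' @param loss_name one of the nine reconstruction losses (see
#'   [count_likelihoods]).
#' @param elbo an [elbo_config()] (or architecture name resolved via
#'   [resolve_architecture()]).
#' @param seed integer seed controlling weight initialisation.
#' @export
network_spec <- function(hidden_units = 256L, latent_units = 32L,
                         loss_name = "nb", elbo = resolve_architecture("VAE"),
                         seed = 0L) {
  hidden_units <- as.integer(hidden_units)
  latent_units <- as.integer(latent_units)
  if (hidden_units < 1L || latent_units < 1L) stop("H and L must be positive")
  if (latent_units > hidden_units) stop("latent_units must not exceed hidden_units")
  loss_spec(loss_name)  # validates the name
  stopifnot(inherits(elbo, "elbo_config"))
  structure(list(hidden_units = hidden_units, latent_units = latent_units,
                 loss_name = loss_name, elbo = elbo, seed = as.integer(seed)),
            class = "network_spec")
}

#' Training configuration
#'
#' Defaults follow the package's standard protocol: 100 epochs, minibatches
#' of 100 cells, Adam with learning rate 0.001.
#'
#' @param epochs number of passes over the data (>= 1).
#' @param batch_size cells per minibatch (>= 1).
#' @param learning_rate Adam step size.
#' @param shuffle_seed seed for minibatch shuffling and all stochastic
#'   elements of training (reparameterization noise, prior draws).
#' @export
training_config <- function(epochs = 100L, batch_size = 100L,
                            learning_rate = 0.001, shuffle_seed = 0L) {
  epochs <- as.integer(epochs)
  batch_size <- as.integer(batch_size)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate,
                 shuffle_seed = as.integer(shuffle_seed)),
            class = "training_config")
}

.glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

.V_CLAMP <- 10    # |log-variance| bound
.ETA_CLAMP <- 15  # |log-mean| bound for the exponential link

#' Build an untrained autoencoder
#'
#' Allocates and seeds all parameters. For K = 1 the latent prior is the
#' standard normal (fixed, the classic VAE choice); for K > 1 the prior is a
#' learnable Gaussian mixture whose weights, means and variances are trained
#' jointly with the network.
#'
#' @param spec a [network_spec()].
#' @param n_genes number of input genes; must be >= `latent_units`.
#' @return an object of class `scmixae_model`.
#' @export
build_autoencoder <- function(spec, n_genes) {
  stopifnot(inherits(spec, "network_spec"))
  n_genes <- as.integer(n_genes)
  if (spec$latent_units > n_genes) {
    stop("latent dimension exceeds the number of genes")
  }
  ls <- loss_spec(spec$loss_name)
  H <- spec$hidden_units; L <- spec$latent_units
  K <- spec$elbo$n_components
  set.seed(spec$seed)
  par <- list(W1 = .glorot(n_genes, H), b1 = numeric(H))
  for (k in seq_len(K)) {
    par[[paste0("Wm", k)]] <- .glorot(H, L)
    par[[paste0("bm", k)]] <- numeric(L)
    par[[paste0("Wv", k)]] <- .glorot(H, L)
    par[[paste0("bv", k)]] <- numeric(L)
  }
  if (K > 1L) {
    par$Wr <- .glorot(H, K)
    par$br <- numeric(K)
    # learnable mixture prior: uniform weights, dispersed means, unit variances
    par$prior_u <- numeric(K)
    par$prior_m <- matrix(stats::rnorm(K * L), K, L)
    par$prior_lv <- matrix(0, K, L)
  }
  par$W2 <- .glorot(L, H)
  par$b2 <- numeric(H)
  par$Wo <- .glorot(H, n_genes)
  par$bo <- numeric(n_genes)
  if (ls$zero_inflated) {
    par$Wp <- .glorot(H, n_genes)
    par$bp <- numeric(n_genes)
  }
  if (ls$needs_dispersion) par$log_r <- numeric(n_genes)
  structure(list(params = par, spec = spec, n_genes = n_genes,
                 gene_ids = NULL, trained = FALSE, history = NULL,
                 train_library_sizes = NULL),
            class = "scmixae_model")
}

#' @export
print.scmixae_model <- function(x, ...) {
  cf <- elbo_coefficients(x$spec$elbo)
  cat(sprintf("scmixae_model: H=%d L=%d K=%d loss=%s (MMD coef %g, KL coef %g), %s\n",
              x$spec$hidden_units, x$spec$latent_units,
              x$spec$elbo$n_components, x$spec$loss_name,
              cf[["mmd"]], cf[["kl"]],
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.row_softmax <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

.prior_parts <- function(par, K, L) {
  if (K > 1L) {
    u <- par$prior_u
    w <- exp(u - max(u)); w <- w / sum(w)
    list(w = w, m = par$prior_m, lv = par$prior_lv, trainable = TRUE)
  } else {
    list(w = 1, m = matrix(0, 1, L), lv = matrix(0, 1, L), trainable = FALSE)
  }
}

# Forward + analytic backward pass over one minibatch.
# X: n x G raw counts. noise: list(eps = list of K n x L matrices,
# prior_eps = n x L, prior_y = integer n). Returns loss terms and, when
# want_grads, a gradient list parallel to par.
.ae_step <- function(par, X, spec, want_grads = TRUE, noise = NULL) {
  ls <- loss_spec(spec$loss_name)
  H <- spec$hidden_units; L <- spec$latent_units
  K <- spec$elbo$n_components
  cf <- elbo_coefficients(spec$elbo)
  n <- nrow(X); G <- ncol(X)
  lib <- rowSums(X)

  ## ---- encoder ----
  A1 <- sweep(X %*% par$W1, 2, par$b1, "+")
  h <- .sigmoid(A1)
  M <- V <- Vmask <- vector("list", K)
  for (k in seq_len(K)) {
    M[[k]] <- sweep(h %*% par[[paste0("Wm", k)]], 2, par[[paste0("bm", k)]], "+")
    Vraw <- sweep(h %*% par[[paste0("Wv", k)]], 2, par[[paste0("bv", k)]], "+")
    Vmask[[k]] <- abs(Vraw) < .V_CLAMP
    V[[k]] <- pmin(pmax(Vraw, -.V_CLAMP), .V_CLAMP)
  }
  if (K > 1L) {
    Rlog <- sweep(h %*% par$Wr, 2, par$br, "+")
    Q <- .row_softmax(Rlog)
  } else {
    Q <- matrix(1, n, 1)
  }

  ## ---- latent sample ----
  if (is.null(noise)) {
    noise <- list(eps = lapply(seq_len(K), function(k) matrix(stats::rnorm(n * L), n, L)))
  }
  Zk <- vector("list", K)
  Z <- matrix(0, n, L)
  for (k in seq_len(K)) {
    Zk[[k]] <- M[[k]] + exp(V[[k]] / 2) * noise$eps[[k]]
    Z <- Z + Q[, k] * Zk[[k]]
  }

  ## ---- decoder ----
  A2 <- sweep(Z %*% par$W2, 2, par$b2, "+")
  hd <- .sigmoid(A2)
  Tlog <- sweep(hd %*% par$Wo, 2, par$bo, "+")
  EtaMask <- NULL
  if (ls$family == "mse") {
    Mu <- Tlog
  } else if (ls$constrained) {
    S <- .row_softmax(Tlog)
    Mu <- lib * S
  } else {
    EtaMask <- abs(Tlog) < .ETA_CLAMP
    Eta <- pmin(pmax(Tlog, -.ETA_CLAMP), .ETA_CLAMP)
    Mu <- exp(Eta)
  }
  if (ls$zero_inflated) {
    Pg <- sweep(hd %*% par$Wp, 2, par$bp, "+")
    Pi <- .sigmoid(Pg)
  }
  if (ls$needs_dispersion) {
    r <- matrix(exp(par$log_r), n, G, byrow = TRUE)
  }

  ## ---- reconstruction NLL (sum over genes, mean over cells) ----
  logMu <- if (ls$family != "mse") log(pmax(Mu, 1e-10))
  if (ls$family == "mse") {
    recon <- mean(rowSums((X - Mu)^2))
  } else if (ls$family == "poisson") {
    nll_el <- Mu - X * logMu + lgamma(X + 1)
    recon <- mean(rowSums(nll_el))
  } else if (ls$family == "nb") {
    nll_el <- lgamma(r) + lgamma(X + 1) - lgamma(X + r) -
      r * log(r) + (r + X) * log(r + Mu) - X * logMu
    recon <- mean(rowSums(nll_el))
  } else if (ls$family == "zip") {
    base <- Mu - X * logMu + lgamma(X + 1)
    P <- (1 - Pi) * exp(-base)
    is0 <- X == 0
    P[is0] <- P[is0] + Pi[is0]
    P <- pmax(P, 1e-10)
    recon <- mean(rowSums(-log(P)))
  } else if (ls$family == "zinb") {
    base <- lgamma(r) + lgamma(X + 1) - lgamma(X + r) -
      r * log(r) + (r + X) * log(r + Mu) - X * logMu
    P <- (1 - Pi) * exp(-base)
    is0 <- X == 0
    P[is0] <- P[is0] + Pi[is0]
    P <- pmax(P, 1e-10)
    recon <- mean(rowSums(-log(P)))
  }

  ## ---- KL term (analytic, always computed: cheap bookkeeping) ----
  pri <- .prior_parts(par, K, L)
  KLg <- matrix(0, n, K)
  for (k in seq_len(K)) {
    pm <- matrix(pri$m[k, ], n, L, byrow = TRUE)
    plv <- matrix(pri$lv[k, ], n, L, byrow = TRUE)
    KLg[, k] <- rowSums(0.5 * (plv - V[[k]]) +
                          (exp(V[[k]]) + (M[[k]] - pm)^2) / (2 * exp(plv)) - 0.5)
  }
  logw <- matrix(log(pmax(pri$w, 1e-12)), n, K, byrow = TRUE)
  Qs <- pmax(Q, 1e-12)
  kl_cells <- rowSums(Q * KLg) + rowSums(Q * (log(Qs) - logw))
  kl <- mean(kl_cells)

  ## ---- MMD term (skipped entirely when its coefficient is 0) ----
  mmd <- NA_real_
  use_mmd <- cf[["mmd"]] != 0
  if (use_mmd) {
    if (is.null(noise$prior_y)) {
      y <- sample.int(K, n, replace = TRUE,
                      prob = if (K > 1L) pri$w else NULL)
      prior_eps <- matrix(stats::rnorm(n * L), n, L)
    } else {
      y <- noise$prior_y
      prior_eps <- noise$prior_eps
    }
    Sz <- pri$m[y, , drop = FALSE] + exp(pri$lv[y, , drop = FALSE] / 2) * prior_eps
    bw <- L
    Kpp <- exp(-.cross_sqdist(Z, Z) / (2 * bw))
    Kss <- exp(-.cross_sqdist(Sz, Sz) / (2 * bw))
    Kps <- exp(-.cross_sqdist(Z, Sz) / (2 * bw))
    mmd <- mean(Kpp) + mean(Kss) - 2 * mean(Kps)
  }

  total <- recon + cf[["kl"]] * kl + (if (use_mmd) cf[["mmd"]] * mmd else 0)
  terms <- list(recon = recon, kl = kl, mmd = mmd, total = total)
  if (!want_grads) return(list(terms = terms, Z = Z, Q = Q, M = M))

  ## ================= backward =================
  g <- list()

  ## ---- reconstruction head gradients ----
  if (ls$family == "mse") {
    DelO <- (2 / n) * (Mu - X)
    Del_head <- DelO
  } else {
    # dLoss/dMu elementwise (already includes the 1/n reduction)
    if (ls$family == "poisson") {
      DelMu <- (1 - X / pmax(Mu, 1e-10)) / n
    } else if (ls$family == "nb") {
      DelMu <- ((r + X) / (r + Mu) - X / pmax(Mu, 1e-10)) / n
    } else if (ls$family == "zip") {
      f0 <- exp(-Mu)
      DelMu <- (1 - X / pmax(Mu, 1e-10)) / n
      DelMu[is0] <- ((1 - Pi[is0]) * f0[is0] / P[is0]) / n
      DelPi <- (Pi / n)                        # x > 0: d(-log(1-pi))/dPg
      DelPi[is0] <- (-(1 - f0[is0]) / P[is0]) * Pi[is0] * (1 - Pi[is0]) / n
    } else if (ls$family == "zinb") {
      f0 <- exp(r * (log(r) - log(r + Mu)))
      DelMu <- ((r + X) / (r + Mu) - X / pmax(Mu, 1e-10)) / n
      DelMu[is0] <- ((1 - Pi[is0]) * f0[is0] * r[is0] / ((r[is0] + Mu[is0]) * P[is0])) / n
      DelPi <- (Pi / n)
      DelPi[is0] <- (-(1 - f0[is0]) / P[is0]) * Pi[is0] * (1 - Pi[is0]) / n
    }
    if (ls$constrained) {
      dS <- lib * DelMu
      Del_head <- S * (dS - rowSums(dS * S))
    } else {
      Del_head <- Mu * DelMu
      Del_head[!EtaMask] <- 0
    }
  }
  g$Wo <- crossprod(hd, Del_head)
  g$bo <- colSums(Del_head)
  Del_hd <- tcrossprod(Del_head, par$Wo)
  if (ls$zero_inflated) {
    g$Wp <- crossprod(hd, DelPi)
    g$bp <- colSums(DelPi)
    Del_hd <- Del_hd + tcrossprod(DelPi, par$Wp)
  }
  if (ls$needs_dispersion) {
    if (ls$family == "nb") {
      dnr <- digamma(r) - digamma(X + r) - log(r) - 1 +
        log(r + Mu) + (r + X) / (r + Mu)
    } else { # zinb
      dnr <- digamma(r) - digamma(X + r) - log(r) - 1 +
        log(r + Mu) + (r + X) / (r + Mu)
      df0 <- f0 * (log(r) - log(r + Mu) + Mu / (r + Mu))
      dnr[is0] <- -(1 - Pi[is0]) * df0[is0] / P[is0]
    }
    g$log_r <- exp(par$log_r) * colSums(dnr) / n
  }

  ## ---- decoder hidden layer ----
  Del_A2 <- Del_hd * hd * (1 - hd)
  g$W2 <- crossprod(Z, Del_A2)
  g$b2 <- colSums(Del_A2)
  dZ <- tcrossprod(Del_A2, par$W2)

  ## ---- MMD gradient into Z and the prior ----
  if (use_mmd) {
    c_mmd <- cf[["mmd"]]
    rsKpp <- rowSums(Kpp); rsKps <- rowSums(Kps)
    csKps <- colSums(Kps); rsKss <- rowSums(Kss)
    dP <- (-2 / (n^2 * bw)) * (rsKpp * Z - Kpp %*% Z) +
      (2 / (n * n * bw)) * (rsKps * Z - Kps %*% Sz)
    dZ <- dZ + c_mmd * dP
    if (pri$trainable) {
      dSz <- (-2 / (n^2 * bw)) * (rsKss * Sz - Kss %*% Sz) +
        (2 / (n * n * bw)) * (csKps * Sz - crossprod(Kps, Z))
      g$prior_m <- matrix(0, K, L)
      g$prior_lv <- matrix(0, K, L)
      half_sd <- 0.5 * exp(pri$lv[y, , drop = FALSE] / 2) * prior_eps
      for (k in seq_len(K)) {
        idx <- y == k
        if (any(idx)) {
          g$prior_m[k, ] <- c_mmd * colSums(dSz[idx, , drop = FALSE])
          g$prior_lv[k, ] <- c_mmd *
            colSums(dSz[idx, , drop = FALSE] * half_sd[idx, , drop = FALSE])
        }
      }
    }
  }

  ## ---- latent combination ----
  dM <- dV <- vector("list", K)
  dQ <- matrix(0, n, K)
  for (k in seq_len(K)) {
    dZk <- dZ * Q[, k]
    dM[[k]] <- dZk
    dV[[k]] <- dZk * 0.5 * exp(V[[k]] / 2) * noise$eps[[k]]
    dQ[, k] <- rowSums(dZ * Zk[[k]])
  }

  ## ---- KL gradients ----
  c_kl <- cf[["kl"]]
  if (c_kl != 0) {
    if (pri$trainable) {
      if (is.null(g$prior_m)) { g$prior_m <- matrix(0, K, L); g$prior_lv <- matrix(0, K, L) }
      g$prior_u <- c_kl * (pri$w - colMeans(Q))
    }
    for (k in seq_len(K)) {
      pm <- matrix(pri$m[k, ], n, L, byrow = TRUE)
      plv <- matrix(pri$lv[k, ], n, L, byrow = TRUE)
      iv <- exp(-plv)
      dM[[k]] <- dM[[k]] + (c_kl / n) * Q[, k] * (M[[k]] - pm) * iv
      dV[[k]] <- dV[[k]] + (c_kl / n) * Q[, k] * 0.5 * (exp(V[[k]]) * iv - 1)
      dQ[, k] <- dQ[, k] + (c_kl / n) * (KLg[, k] + log(Qs[, k]) + 1 - logw[, k])
      if (pri$trainable) {
        g$prior_m[k, ] <- g$prior_m[k, ] +
          (c_kl / n) * colSums(Q[, k] * (pm - M[[k]]) * iv)
        g$prior_lv[k, ] <- g$prior_lv[k, ] +
          (c_kl / n) * colSums(Q[, k] * 0.5 *
                                 (1 - (exp(V[[k]]) + (M[[k]] - pm)^2) * iv))
      }
    }
  }

  ## ---- encoder heads ----
  dh <- matrix(0, n, H)
  for (k in seq_len(K)) {
    dV[[k]][!Vmask[[k]]] <- 0  # clamp mask on the log-variance head
    g[[paste0("Wm", k)]] <- crossprod(h, dM[[k]])
    g[[paste0("bm", k)]] <- colSums(dM[[k]])
    g[[paste0("Wv", k)]] <- crossprod(h, dV[[k]])
    g[[paste0("bv", k)]] <- colSums(dV[[k]])
    dh <- dh + tcrossprod(dM[[k]], par[[paste0("Wm", k)]]) +
      tcrossprod(dV[[k]], par[[paste0("Wv", k)]])
  }
  if (K > 1L) {
    Del_R <- Q * (dQ - rowSums(dQ * Q))
    g$Wr <- crossprod(h, Del_R)
    g$br <- colSums(Del_R)
    dh <- dh + tcrossprod(Del_R, par$Wr)
  }

  ## ---- encoder hidden layer ----
  Del_A1 <- dh * h * (1 - h)
  g$W1 <- crossprod(X, Del_A1)
  g$b1 <- colSums(Del_A1)

  list(terms = terms, grads = g)
}

#' Train an autoencoder on a count matrix
#'
#' Minimises the negated generalized ELBO by minibatch Adam. Per-epoch means
#' of the reconstruction NLL, the KL term, the MMD term (NA when its
#' coefficient is zero and the term is skipped) and the total loss are
#' recorded in `history`.
#'
#' @param model an untrained model from [build_autoencoder()].
#' @param counts a [count_matrix()] whose gene count matches the model.
#' @param tc a [training_config()].
#' @return the trained `scmixae_model` with `history` filled in.
#' @export
train <- function(model, counts, tc = training_config()) {
  stopifnot(inherits(model, "scmixae_model"), inherits(counts, "count_matrix"),
            inherits(tc, "training_config"))
  X <- counts$values
  if (nrow(X) == 0L) stop("empty count matrix")
  if (ncol(X) != model$n_genes) {
    stop(sprintf("model expects %d genes, counts have %d",
                 model$n_genes, ncol(X)))
  }
  par <- model$params
  spec <- model$spec
  adam_m <- lapply(par, function(p) p * 0)
  adam_v <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- tc$learning_rate
  t_step <- 0L
  nm_upd <- names(par)

  n <- nrow(X)
  hist <- data.frame(epoch = seq_len(tc$epochs), recon = NA_real_,
                     kl = NA_real_, mmd = NA_real_, total = NA_real_)
  set.seed(tc$shuffle_seed)
  for (ep in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = tc$batch_size)
    acc <- c(recon = 0, kl = 0, mmd = 0, total = 0)
    mmd_seen <- FALSE
    for (s in starts) {
      idx <- ord[s:min(s + tc$batch_size - 1L, n)]
      step <- .ae_step(par, X[idx, , drop = FALSE], spec, want_grads = TRUE)
      tm <- step$terms
      if (!is.finite(tm$total)) {
        bad <- names(which(!vapply(tm, is.finite, logical(1))))
        stop("non-finite loss during training (term: ",
             paste(bad, collapse = ", "), ") at epoch ", ep)
      }
      acc["recon"] <- acc["recon"] + tm$recon
      acc["kl"] <- acc["kl"] + tm$kl
      acc["total"] <- acc["total"] + tm$total
      if (is.finite(tm$mmd)) { acc["mmd"] <- acc["mmd"] + tm$mmd; mmd_seen <- TRUE }
      t_step <- t_step + 1L
      corr <- lr * sqrt(1 - b2^t_step) / (1 - b1^t_step)
      for (nmp in names(step$grads)) {
        gr <- step$grads[[nmp]]
        adam_m[[nmp]] <- b1 * adam_m[[nmp]] + (1 - b1) * gr
        adam_v[[nmp]] <- b2 * adam_v[[nmp]] + (1 - b2) * gr^2
        par[[nmp]] <- par[[nmp]] - corr * adam_m[[nmp]] / (sqrt(adam_v[[nmp]]) + eps)
      }
    }
    nb <- length(starts)
    hist$recon[ep] <- acc["recon"] / nb
    hist$kl[ep] <- acc["kl"] / nb
    hist$mmd[ep] <- if (mmd_seen) acc["mmd"] / nb else NA_real_
    hist$total[ep] <- acc["total"] / nb
  }
  model$params <- par
  model$trained <- TRUE
  model$history <- hist
  model$gene_ids <- counts$gene_ids
  model$train_library_sizes <- rowSums(X)
  model
}

#' Encode cells into the latent space
#'
#' Deterministic point estimate: the responsibility-weighted posterior mean
#' `sum_y q(y|x) mu_y(x)` (no sampling), so identical cells map to identical
#' latent rows.
#'
#' @param model a trained `scmixae_model`.
#' @param counts a [count_matrix()] over the training genes (same order).
#' @return a [latent_matrix()], cells x L.
#' @export
encode <- function(model, counts) {
  stopifnot(inherits(model, "scmixae_model"), inherits(counts, "count_matrix"))
  if (!is.null(model$gene_ids) &&
      !identical(counts$gene_ids, model$gene_ids)) {
    stop("gene ids/order of counts do not match the training genes")
  }
  if (ncol(counts$values) != model$n_genes) stop("gene count mismatch")
  par <- model$params
  spec <- model$spec
  K <- spec$elbo$n_components
  h <- .sigmoid(sweep(counts$values %*% par$W1, 2, par$b1, "+"))
  if (K > 1L) {
    Q <- .row_softmax(sweep(h %*% par$Wr, 2, par$br, "+"))
  } else {
    Q <- matrix(1, nrow(h), 1)
  }
  Z <- matrix(0, nrow(h), spec$latent_units)
  for (k in seq_len(K)) {
    Mk <- sweep(h %*% par[[paste0("Wm", k)]], 2, par[[paste0("bm", k)]], "+")
    Z <- Z + Q[, k] * Mk
  }
  latent_matrix(Z, counts$cell_ids)
}

#' Generate synthetic cells from a trained model
#'
#' Samples a component from the prior weights, a latent point from that
#' component, decodes it to likelihood parameters, and draws integer counts
#' from the configured count law. Library sizes for the constrained losses
#' are resampled from the training cells' observed totals.
#'
#' @param model a trained `scmixae_model` (count losses only; MSE models have
#'   no sampling law — use the decoded means instead).
#' @param n number of cells to generate.
#' @param seed RNG seed.
#' @return a [count_matrix()] with the training gene ids.
#' @export
generate_cells <- function(model, n, seed = 0L) {
  stopifnot(inherits(model, "scmixae_model"))
  if (!model$trained) stop("model must be trained first")
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  ls <- loss_spec(model$spec$loss_name)
  if (ls$family == "mse") {
    stop("MSE models define no count sampling law; decode means instead")
  }
  par <- model$params
  spec <- model$spec
  K <- spec$elbo$n_components; L <- spec$latent_units; G <- model$n_genes
  pri <- .prior_parts(par, K, L)
  set.seed(seed)
  y <- if (K > 1L) sample.int(K, n, replace = TRUE, prob = pri$w) else rep(1L, n)
  Z <- pri$m[y, , drop = FALSE] +
    exp(pri$lv[y, , drop = FALSE] / 2) * matrix(stats::rnorm(n * L), n, L)
  hd <- .sigmoid(sweep(Z %*% par$W2, 2, par$b2, "+"))
  Tlog <- sweep(hd %*% par$Wo, 2, par$bo, "+")
  if (ls$constrained) {
    S <- .row_softmax(Tlog)
    lib <- sample(model$train_library_sizes, n, replace = TRUE)
    Mu <- lib * S
  } else {
    Mu <- exp(pmin(pmax(Tlog, -.ETA_CLAMP), .ETA_CLAMP))
  }
  counts <- if (ls$needs_dispersion) {
    r <- matrix(exp(par$log_r), n, G, byrow = TRUE)
    matrix(stats::rnbinom(n * G, mu = Mu, size = r), n, G)
  } else {
    matrix(stats::rpois(n * G, lambda = Mu), n, G)
  }
  if (ls$zero_inflated) {
    Pi <- .sigmoid(sweep(hd %*% par$Wp, 2, par$bp, "+"))
    counts[matrix(stats::runif(n * G), n, G) < Pi] <- 0
  }
  count_matrix(counts, gene_ids = model$gene_ids %||% paste0("g", seq_len(G)),
               cell_ids = paste0("synthetic_cell_", seq_len(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
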