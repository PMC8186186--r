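#' @name generalized_elbo
#' @title The generalized evidence lower bound
#'
#' @description
#' Every architecture in the package maximises one objective,
#'
#' \deqn{ELBO = E[\log d(x|z,y)] - (\alpha+\lambda-1)\,MMD(p_e(z)\,\|\,q(z))
#'   - (1-\alpha)\,E[KL(p_e(z,y|x)\,\|\,q(z,y))],}
#'
#' so a single pair of user-set coefficients \eqn{(\alpha, \lambda)} plus the
#' number of mixture components K selects among VAE, MMDAE, MMDVAE, GMVAE,
#' GMMMD and GMMMDVAE. Training minimises the negated ELBO.
NULL

#' ELBO configuration
#'
#' Holds `(alpha, lambda, K)`. The derived coefficients — `alpha + lambda - 1`
#' on the MMD term and `1 - alpha` on the KL term — are recomputed on demand
#' by [elbo_coefficients()], never stored.
#'
#' @param alpha,lambda_ real coefficients of the generalized objective.
#' @param n_components integer K >= 1, the number of mixture components of
#'   the latent prior and posterior.
#' @export
elbo_config <- function(alpha, lambda_, n_components = 1L) {
  if (!is.finite(alpha) || !is.finite(lambda_)) {
    stop("alpha and lambda must be finite")
  }
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("K must be >= 1")
  structure(list(alpha = alpha, lambda_ = lambda_,
                 n_components = n_components),
            class = "elbo_config")
}

#' @export
print.elbo_config <- function(x, ...) {
  cf <- elbo_coefficients(x)
  cat(sprintf("elbo_config: alpha = %g, lambda = %g, K = %d (MMD coef %g, KL coef %g)\n",
              x$alpha, x$lambda_, x$n_components, cf[["mmd"]], cf[["kl"]]))
  invisible(x)
}

.ARCHITECTURES <- list(
  VAE      = list(alpha = 0, lambda_ = 1, mixture = FALSE),
  MMDAE    = list(alpha = 1, lambda_ = 1, mixture = FALSE),
  MMDVAE   = list(alpha = 0, lambda_ = 2, mixture = FALSE),
  GMVAE    = list(alpha = 0, lambda_ = 1, mixture = TRUE),
  GMMMD    = list(alpha = 1, lambda_ = 1, mixture = TRUE),
  GMMMDVAE = list(alpha = 0, lambda_ = 2, mixture = TRUE)
)

#' Resolve a named architecture to its ELBO configuration
#'
#' Maps the six architecture names to their `(alpha, lambda)` settings:
#' VAE (0, 1), MMDAE (1, 1), MMDVAE (0, 2) with K = 1, and their
#' Gaussian-mixture counterparts GMVAE (0, 1), GMMMD (1, 1),
#' GMMMDVAE (0, 2) with K > 1 (typically the number of datasets being
#' integrated, or the expected number of cell populations).
#'
#' @param name one of `"VAE"`, `"MMDAE"`, `"MMDVAE"`, `"GMVAE"`, `"GMMMD"`,
#'   `"GMMMDVAE"`.
#' @param n_components K; must be 1 for the single-Gaussian family and > 1
#'   for the GM family.
#' @return an [elbo_config()].
#' @export
resolve_architecture <- function(name, n_components = 1L) {
  if (!name %in% names(.ARCHITECTURES)) {
    stop("unknown architecture '", name, "'; choose one of: ",
         paste(names(.ARCHITECTURES), collapse = ", "))
  }
  a <- .ARCHITECTURES[[name]]
  n_components <- as.integer(n_components)
  if (a$mixture && n_components <= 1L) {
    stop(name, " requires K > 1 mixture components")
  }
  if (!a$mixture && n_components != 1L) {
    stop(name, " requires K = 1")
  }
  elbo_config(a$alpha, a$lambda_, n_components)
}

#' Coefficients of the divergence terms
#'
#' @param config an [elbo_config()].
#' @return named numeric vector `c(mmd = alpha + lambda - 1, kl = 1 - alpha)`.
#' @export
elbo_coefficients <- function(config) {
  stopifnot(inherits(config, "elbo_config"))
  c(mmd = config$alpha + config$lambda_ - 1, kl = 1 - config$alpha)
}

#' Assemble the generalized ELBO from its three terms
#'
#' @param reconstruction_ll expected reconstruction log-likelihood
#'   `E[log d(x|z,y)]` (a log-likelihood: the negation of the reconstruction
#'   NLL).
#' @param mmd MMD estimate between encoded and prior latent samples.
#' @param kl joint KL estimate between posterior and prior.
#' @param config an [elbo_config()].
#' @return the scalar ELBO; training minimises its negation.
#' @export
compute_elbo <- function(reconstruction_ll, mmd, kl, config) {
  if (!all(is.finite(c(reconstruction_ll, mmd, kl)))) {
    stop("ELBO terms must be finite")
  }
  cf <- elbo_coefficients(config)
  reconstruction_ll - cf[["mmd"]] * mmd - cf[["kl"]] * kl
}
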