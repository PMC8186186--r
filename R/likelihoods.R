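#' @name count_likelihoods
#' @title Reconstruction negative log-likelihoods for raw counts
#'
#' @description
#' The reconstruction term of the autoencoder objective is the log-likelihood
#' of the observed raw counts under a count distribution whose parameters the
#' decoder emits. Nine losses are supported: `mse`, `poisson`, `nb`, `zip`,
#' `zinb`, and the library-size-`constrained_*` variants of the four count
#' laws (see [constrain_means()]).
#'
#' All `*_nll` functions accept vectors or cells x genes matrices and return
#' the elementwise negative log-likelihood when `reduce = FALSE`, or the
#' scalar reduction "sum over genes, mean over cells" when `reduce = TRUE`
#' (the default; this makes the loss magnitude independent of batch size).
#' A bare vector is treated as a single cell.
#'
#' Numerical conventions: log-gamma is used throughout; probabilities are
#' floored at 1e-10 before taking logs; entries with `x = 0` and `mean = 0`
#' contribute exactly 0.
NULL

.as_cell_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1)
}

.reduce_nll <- function(nll, reduce) {
  if (!reduce) return(nll)
  mean(rowSums(nll))
}

.check_counts <- function(x) {
  if (any(x < 0)) stop("counts must be non-negative")
  if (any(abs(x - round(x)) > 1e-8)) stop("counts must be integral")
}

.PROB_FLOOR <- 1e-10

#' Poisson negative log-likelihood
#'
#' `NLL = mean - x * log(mean) + lgamma(x + 1)` elementwise.
#'
#' @param x non-negative integer counts (vector or cells x genes matrix).
#' @param mean Poisson means, same shape (or recycled); must be positive
#'   except where `x = 0`, where `mean = 0` contributes 0.
#' @param reduce if `TRUE` return sum over genes, mean over cells.
#' @return scalar (reduced) or elementwise NLL matrix.
#' @export
poisson_nll <- function(x, mean, reduce = TRUE) {
  x <- .as_cell_matrix(x); .check_counts(x)
  mu <- .as_cell_matrix(mean + 0 * x)
  if (any(mu < 0)) stop("mean must be non-negative")
  if (any(mu == 0 & x > 0)) stop("mean = 0 requires x = 0")
  xlogmu <- ifelse(x > 0, x * log(pmax(mu, .PROB_FLOOR)), 0)
  .reduce_nll(mu - xlogmu + lgamma(x + 1), reduce)
}

#' Negative binomial negative log-likelihood
#'
#' Mean / inverse-dispersion parameterization: with `r = dispersion`,
#' `P(x) = Gamma(x+r) / (Gamma(r) x!) * (r/(r+mu))^r * (mu/(r+mu))^x`,
#' variance `mu + mu^2 / r`.
#'
#' @inheritParams poisson_nll
#' @param dispersion inverse-dispersion `r > 0`; scalar, per-gene vector, or
#'   full matrix.
#' @export
nb_nll <- function(x, mean, dispersion, reduce = TRUE) {
  x <- .as_cell_matrix(x); .check_counts(x)
  mu <- .as_cell_matrix(mean + 0 * x)
  if (any(mu < 0)) stop("mean must be non-negative")
  if (any(mu == 0 & x > 0)) stop("mean = 0 requires x = 0")
  if (any(dispersion <= 0)) stop("dispersion must be positive")
  r <- if (is.matrix(dispersion)) {
    dispersion
  } else if (length(dispersion) == 1L) {
    matrix(dispersion, nrow(x), ncol(x))
  } else if (length(dispersion) == ncol(x)) {
    matrix(dispersion, nrow(x), ncol(x), byrow = TRUE)  # per-gene
  } else {
    stop("dispersion must be scalar, per-gene, or a full matrix")
  }
  xlogmu <- ifelse(x > 0, x * log(pmax(mu, .PROB_FLOOR)), 0)
  nll <- lgamma(r) + lgamma(x + 1) - lgamma(x + r) -
    r * log(r) + (r + x) * log(r + mu) - xlogmu
  nll[x == 0 & mu == 0] <- 0
  .reduce_nll(nll, reduce)
}

#' Zero-inflated Poisson negative log-likelihood
#'
#' `P(x) = pi * 1[x = 0] + (1 - pi) * Poisson(x | mu)`.
#'
#' @inheritParams poisson_nll
#' @param zero_inflation zero-inflation probabilities `pi` in \[0, 1\].
#' @export
zip_nll <- function(x, mean, zero_inflation, reduce = TRUE) {
  x <- .as_cell_matrix(x); .check_counts(x)
  mu <- .as_cell_matrix(mean + 0 * x)
  pi0 <- .as_cell_matrix(zero_inflation + 0 * x)
  if (any(pi0 < 0 | pi0 > 1)) stop("zero_inflation must lie in [0, 1]")
  if (any(mu < 0)) stop("mean must be non-negative")
  if (any(mu == 0 & x > 0)) stop("mean = 0 requires x = 0")
  .reduce_nll(.zi_nll(x, pi0, poisson_nll(x, mu, reduce = FALSE)), reduce)
}

# zero-inflate a base count NLL: exact in log space for x > 0 (so deep
# tails are not clipped), with the probability floor only guarding the
# genuinely degenerate pi = 1, x > 0 case
.zi_nll <- function(x, pi0, base) {
  nll <- base - log(pmax(1 - pi0, .PROB_FLOOR))
  exact <- pi0 == 0
  nll[exact] <- base[exact]
  is0 <- x == 0
  nll[is0] <- -log(pmax(pi0[is0] + (1 - pi0[is0]) * exp(-base[is0]),
                        .PROB_FLOOR))
  nll[is0 & exact] <- base[is0 & exact]
  nll
}

#' Zero-inflated negative binomial negative log-likelihood
#'
#' `P(x) = pi * 1[x = 0] + (1 - pi) * NB(x | mu, r)`.
#'
#' @inheritParams nb_nll
#' @param zero_inflation zero-inflation probabilities `pi` in \[0, 1\].
#' @export
zinb_nll <- function(x, mean, dispersion, zero_inflation, reduce = TRUE) {
  x <- .as_cell_matrix(x); .check_counts(x)
  mu <- .as_cell_matrix(mean + 0 * x)
  pi0 <- .as_cell_matrix(zero_inflation + 0 * x)
  if (any(pi0 < 0 | pi0 > 1)) stop("zero_inflation must lie in [0, 1]")
  .reduce_nll(.zi_nll(x, pi0, nb_nll(x, mu, dispersion, reduce = FALSE)),
              reduce)
}

#' Mean squared error reconstruction loss
#'
#' Mean over cells of the per-cell sum of squared differences; the fallback
#' loss for data where no count law applies.
#'
#' @param x observed values (vector or cells x genes matrix).
#' @param mean reconstructed values, same shape.
#' @export
mse_loss <- function(x, mean) {
  x <- .as_cell_matrix(x)
  m <- .as_cell_matrix(mean)
  if (!all(dim(x) == dim(m))) stop("shape mismatch between x and mean")
  mean(rowSums((x - m)^2))
}

#' Scale per-cell simplexes to library-size-conserving means
#'
#' The "constrained" losses require the decoder to emit, per cell, a
#' probability simplex over genes; the reconstruction mean is that simplex
#' multiplied by the cell's observed total count (library size), so each
#' reconstructed expression profile conserves the cell's total counts.
#'
#' @param simplex cells x genes matrix; every row must sum to 1 within 1e-6.
#' @param library_sizes positive per-cell totals.
#' @return mean matrix whose row `i` sums to `library_sizes[i]`.
#' @export
constrain_means <- function(simplex, library_sizes) {
  simplex <- .as_cell_matrix(simplex)
  if (length(library_sizes) != nrow(simplex)) {
    stop("one library size per cell required")
  }
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  rs <- rowSums(simplex)
  if (any(abs(rs - 1) > 1e-6)) stop("simplex rows must sum to 1 within 1e-6")
  simplex * library_sizes
}

# Loss registry: family and parameter requirements, keyed by loss name.
.LOSS_NAMES <- c("mse", "poisson", "constrained_poisson", "nb",
                 "constrained_nb", "zip", "constrained_zip", "zinb",
                 "constrained_zinb")

loss_spec <- function(name) {
  if (!name %in% .LOSS_NAMES) {
    stop("unknown loss '", name, "'; choose one of: ",
         paste(.LOSS_NAMES, collapse = ", "))
  }
  family <- sub("^constrained_", "", name)
  list(name = name,
       family = family,
       constrained = grepl("^constrained_", name),
       needs_dispersion = family %in% c("nb", "zinb"),
       zero_inflated = family %in% c("zip", "zinb"))
}
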