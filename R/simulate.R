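#' @name synthetic_data
#' @title Multi-batch negative-binomial count simulator
#'
#' @description
#' Generates cells x genes raw-count matrices with known cell-type labels and
#' batch structure, emulating the statistical assumptions of the package's
#' count likelihoods: gene-wise baseline means from a log-normal, per-type
#' multiplicative effects on a random gene subset, per-batch gene-wise
#' multiplicative factors (technical batch effect), negative-binomial
#' sampling, and optional independent Bernoulli dropout (extra zeros,
#' matching the zero-inflated likelihood family).
NULL

#' Simulation specification
#'
#' @param n_types number of cell types.
#' @param cells_per_type integer vector (recycled) of cells per type *per
#'   batch*.
#' @param n_genes number of genes.
#' @param n_batches number of batches; each batch contains every type.
#' @param type_effect_scale log-space SD of per-type multiplicative gene
#'   effects (applied to a random `affected_fraction` of genes per type).
#' @param affected_fraction fraction of genes carrying each type's effect.
#' @param batch_effect_scale log-space SD of per-batch gene-wise
#'   multiplicative factors; 0 disables batch effects.
#' @param dispersion NB inverse-dispersion r (variance `mu + mu^2 / r`).
#' @param dropout_prob extra zero probability in \[0, 1\].
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   gene baseline means.
#' @param seed RNG seed.
#' @export
simulation_spec <- function(n_types = 3L, cells_per_type = 200L,
                            n_genes = 200L, n_batches = 1L,
                            type_effect_scale = 1.0, affected_fraction = 0.3,
                            batch_effect_scale = 0, dispersion = 2,
                            dropout_prob = 0, baseline_meanlog = log(2),
                            baseline_sdlog = 1, seed = 0L) {
  if (n_types < 1L || n_genes < 1L || n_batches < 1L) {
    stop("n_types, n_genes and n_batches must be positive")
  }
  if (any(cells_per_type < 1L)) stop("cells_per_type must be positive")
  if (dropout_prob < 0 || dropout_prob > 1) stop("dropout_prob must lie in [0, 1]")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (type_effect_scale < 0 || batch_effect_scale < 0) {
    stop("effect scales must be non-negative")
  }
  if (affected_fraction <= 0 || affected_fraction > 1) {
    stop("affected_fraction must lie in (0, 1]")
  }
  structure(list(n_types = as.integer(n_types),
                 cells_per_type = rep_len(as.integer(cells_per_type), n_types),
                 n_genes = as.integer(n_genes),
                 n_batches = as.integer(n_batches),
                 type_effect_scale = type_effect_scale,
                 affected_fraction = affected_fraction,
                 batch_effect_scale = batch_effect_scale,
                 dispersion = dispersion, dropout_prob = dropout_prob,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a multi-batch, multi-type count dataset
#'
#' @param spec a [simulation_spec()].
#' @return list with `counts` (a [count_matrix()] carrying batch labels when
#'   `n_batches > 1`) and `type_labels` (integer ground-truth cell types).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes
  baseline <- stats::rlnorm(G, spec$baseline_meanlog, spec$baseline_sdlog)
  # per-type multiplicative effects on a random gene subset
  type_factor <- matrix(1, spec$n_types, G)
  n_aff <- max(1L, round(spec$affected_fraction * G))
  for (t in seq_len(spec$n_types)) {
    idx <- sample.int(G, n_aff)
    type_factor[t, idx] <- stats::rlnorm(n_aff, 0, spec$type_effect_scale)
  }
  batch_factor <- matrix(1, spec$n_batches, G)
  if (spec$batch_effect_scale > 0) {
    for (b in seq_len(spec$n_batches)) {
      batch_factor[b, ] <- stats::rlnorm(G, 0, spec$batch_effect_scale)
    }
  }
  blocks <- list(); types <- integer(0); batches <- character(0)
  for (b in seq_len(spec$n_batches)) {
    for (t in seq_len(spec$n_types)) {
      nc <- spec$cells_per_type[t]
      mu <- baseline * type_factor[t, ] * batch_factor[b, ]
      cnt <- matrix(stats::rnbinom(nc * G, mu = rep(mu, each = nc),
                                   size = spec$dispersion), nc, G)
      if (spec$dropout_prob > 0) {
        cnt[matrix(stats::runif(nc * G), nc, G) < spec$dropout_prob] <- 0
      }
      blocks[[length(blocks) + 1L]] <- cnt
      types <- c(types, rep(t, nc))
      batches <- c(batches, rep(paste0("batch", b), nc))
    }
  }
  values <- do.call(rbind, blocks)
  counts <- count_matrix(values,
                         gene_ids = paste0("gene", seq_len(G)),
                         cell_ids = paste0("cell", seq_len(nrow(values))),
                         batch_labels = if (spec$n_batches > 1L) batches else NULL)
  list(counts = counts, type_labels = types)
}

#' Canonical test fixtures
#'
#' Three fixed-seed datasets used throughout the test suite:
#' \describe{
#'   \item{F1 "well-separated"}{3 types x 200 cells, 200 genes, one batch, no
#'     batch effect — cell types are recoverable by any sensible embedding.}
#'   \item{F2 "two-batch"}{the F1 design duplicated across 2 batches with a
#'     moderate batch effect (log-SD 0.4).}
#'   \item{F3 "strong-batch"}{2 batches with a strong batch effect
#'     (log-SD 0.8) on top of realistic noise (weaker type effects,
#'     overdispersion r = 0.5, 30% dropout), so the batch effect confounds
#'     uncorrected clustering without collapsing the data into noiseless,
#'     mutually unreachable islands.}
#' }
#'
#' @return named list of `list(counts, type_labels)` entries `F1`, `F2`, `F3`.
#' @export
make_standard_fixtures <- function() {
  list(
    F1 = simulate_dataset(simulation_spec(
      n_types = 3, cells_per_type = 200, n_genes = 200, n_batches = 1,
      batch_effect_scale = 0, seed = 101)),
    F2 = simulate_dataset(simulation_spec(
      n_types = 3, cells_per_type = 100, n_genes = 200, n_batches = 2,
      batch_effect_scale = 0.4, seed = 102)),
    F3 = simulate_dataset(simulation_spec(
      n_types = 3, cells_per_type = 100, n_genes = 200, n_batches = 2,
      type_effect_scale = 0.7, batch_effect_scale = 0.8, dispersion = 0.5,
      dropout_prob = 0.3, seed = 103))
  )
}
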