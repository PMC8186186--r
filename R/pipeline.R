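#' @name integration_pipeline
#' @title Batch-aware integration and clustering workflow
#'
#' @description
#' The end-to-end workflow: merge per-sample matrices, select highly variable
#' genes (HVGs) within each batch and merge the rankings (avoiding
#' batch-specific genes), train an autoencoder on the raw counts of the HVG
#' subset, embed cells in the latent space, optionally apply a
#' batch-correction hook, build a kNN neighbourhood graph, cluster with the
#' Leiden algorithm at a target cluster count, score against reference
#' labels when available, and rank marker genes per cluster with the
#' Mann-Whitney U test.
NULL

#' Batch-aware highly-variable-gene selection
#'
#' Within each batch: counts are normalised per cell to the median library
#' size, log1p-transformed, and genes are ranked by their dispersion
#' (variance/mean) z-scored within 20 equal-frequency mean bins. Rankings
#' are merged across batches by the number of batches in which a gene falls
#' in that batch's top `k`, with the mean within-batch normalised dispersion
#' as tie-break, so genes variable in only one batch rank below genes
#' variable everywhere.
#'
#' @param counts a [count_matrix()].
#' @param batch_labels per-cell batch labels; defaults to the matrix's own
#'   `batch_labels`, or a single batch when absent.
#' @param k number of genes to select.
#' @return character vector of `k` gene ids, ranked.
#' @export
select_hvgs <- function(counts, batch_labels = NULL, k = 1000L) {
  stopifnot(inherits(counts, "count_matrix"))
  k <- as.integer(k)
  G <- ncol(counts$values)
  if (k > G) stop("k exceeds the number of genes")
  if (is.null(batch_labels)) batch_labels <- counts$batch_labels
  if (is.null(batch_labels)) batch_labels <- rep("all", nrow(counts$values))
  batches <- unique(batch_labels)
  n_top <- matrix(0, length(batches), G)
  disp_z <- matrix(NA_real_, length(batches), G)
  for (bi in seq_along(batches)) {
    Xb <- counts$values[batch_labels == batches[bi], , drop = FALSE]
    if (nrow(Xb) < 2L) stop("batch '", batches[bi], "' has fewer than 2 cells")
    lib <- rowSums(Xb)
    lib[lib == 0] <- 1
    Xn <- log1p(Xb / lib * stats::median(lib))
    mu <- colMeans(Xn)
    v <- apply(Xn, 2, stats::var)
    disp <- ifelse(mu > 0, v / mu, 0)
    # z-score dispersion within equal-frequency mean bins; keep >= ~10
    # genes per bin so the bin statistics are meaningful on small panels
    nb <- min(20L, max(1L, floor(G / 10)))
    bins <- cut(rank(mu, ties.method = "first"), breaks = nb, labels = FALSE)
    z <- disp
    for (b in unique(bins)) {
      sel <- bins == b
      # median/MAD so hyper-variable genes cannot corrupt their own bin's
      # scale; fall back to mean/sd for near-constant bins
      ctr <- stats::median(disp[sel])
      s <- stats::mad(disp[sel])
      if (!is.finite(s) || s == 0) {
        ctr <- mean(disp[sel])
        s <- stats::sd(disp[sel])
      }
      z[sel] <- if (!is.finite(s) || s == 0) 0 else (disp[sel] - ctr) / s
    }
    disp_z[bi, ] <- z
    n_top[bi, order(z, decreasing = TRUE)[seq_len(k)]] <- 1
  }
  n_batches_top <- colSums(n_top)
  mean_z <- colMeans(disp_z)
  ord <- order(n_batches_top, mean_z, decreasing = TRUE)
  counts$gene_ids[ord[seq_len(k)]]
}

#' k-nearest-neighbour graph over the latent space
#'
#' Euclidean kNN, symmetrised by edge union. Edge weights are a Gaussian
#' connectivity `exp(-d^2 / (s_i s_j))` with per-node bandwidth `s_i` equal
#' to the distance to the node's k-th neighbour, so weights lie in (0, 1]
#' and decrease with distance.
#'
#' @param latent a [latent_matrix()] (or bare matrix).
#' @param k neighbours per node; must be < number of cells.
#' @return object of class `neighborhood_graph`: sparse symmetric adjacency
#'   plus the parameters used.
#' @export
knn_graph <- function(latent, k = 15L) {
  Zm <- if (inherits(latent, "latent_matrix")) latent$values else as.matrix(latent)
  n <- nrow(Zm)
  k <- as.integer(k)
  if (k >= n) stop("k must be smaller than the number of cells")
  D <- as.matrix(stats::dist(Zm))
  adj <- matrix(0, n, n)
  kth <- numeric(n)
  nn_idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])
    nbrs <- setdiff(ord, i)[seq_len(k)]
    nn_idx[i, ] <- nbrs
    kth[i] <- D[i, nbrs[k]]
  }
  kth[kth == 0] <- min(kth[kth > 0], 1)  # duplicated points: avoid 0 bandwidth
  for (i in seq_len(n)) {
    for (j in nn_idx[i, ]) {
      w <- exp(-D[i, j]^2 / (kth[i] * kth[j]))
      adj[i, j] <- max(adj[i, j], w)
      adj[j, i] <- adj[i, j]
    }
  }
  diag(adj) <- 0
  dimnames(adj) <- list(rownames(Zm), rownames(Zm))
  structure(list(adjacency = Matrix::Matrix(adj, sparse = TRUE),
                 k = k, metric = "euclidean"),
            class = "neighborhood_graph")
}

#' @export
print.neighborhood_graph <- function(x, ...) {
  cat(sprintf("neighborhood_graph: %d cells, k = %d (%s), %d edges\n",
              nrow(x$adjacency), x$k, x$metric,
              Matrix::nnzero(x$adjacency) / 2))
  invisible(x)
}

.graph_to_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Leiden clustering at a target number of clusters
#'
#' Runs the Leiden algorithm (via igraph) under a monotone search over the
#' resolution parameter — bracketing by geometric expansion from
#' \[0.01, 5\], then bisection, at most 50 Leiden evaluations — and returns
#' the partition whose cluster count matches `target`. When the exact count
#' is unattainable the achievable partition closest in cluster count is
#' returned with `attr(labels, "warning_flag") = TRUE`.
#'
#' @param graph a `neighborhood_graph` from [knn_graph()] (or an igraph).
#' @param target desired number of clusters (>= 2).
#' @param seed RNG seed fixed before every Leiden call.
#' @return integer label vector (1-based).
#' @export
leiden_at_target <- function(graph, target, seed = 0L) {
  target <- as.integer(target)
  if (target < 2L) stop("target number of clusters must be >= 2")
  g <- if (inherits(graph, "neighborhood_graph")) .graph_to_igraph(graph) else graph
  ncomp <- igraph::count_components(g)
  if (ncomp > target) {
    stop("graph has ", ncomp, " connected components, more than the ",
         target, " requested clusters")
  }
  run <- function(res) {
    set.seed(seed)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = res, n_iterations = 5)
    igraph::membership(cl)
  }
  lo <- 0.01; hi <- 5
  m_lo <- run(lo); m_hi <- run(hi)
  evals <- 2L
  best <- m_lo; best_gap <- abs(max(m_lo) - target)
  note <- function(m) {
    gap <- abs(max(m) - target)
    if (gap < best_gap) { best <<- m; best_gap <<- gap }
  }
  note(m_hi)
  while (max(m_hi) < target && hi < 1e4 && evals < 50L) {
    hi <- hi * 2; m_hi <- run(hi); evals <- evals + 1L; note(m_hi)
  }
  while (max(m_lo) > target && lo > 1e-6 && evals < 50L) {
    lo <- lo / 2; m_lo <- run(lo); evals <- evals + 1L; note(m_lo)
  }
  while (evals < 50L && best_gap > 0) {
    mid <- sqrt(lo * hi)
    m <- run(mid); evals <- evals + 1L; note(m)
    if (max(m) < target) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-9) break
  }
  labels <- as.integer(best)
  if (best_gap > 0) {
    warning("exact cluster count ", target, " unattainable; returning ",
            max(labels), " clusters")
    attr(labels, "warning_flag") <- TRUE
  }
  labels
}

#' Mann-Whitney marker-gene ranking
#'
#' For every cluster, a one-vs-rest two-sided Mann-Whitney U test per gene
#' (tie-corrected normal approximation) with Benjamini-Hochberg adjustment
#' within the cluster. Genes are ordered by ascending p-value, then by
#' descending effect (U above its null mean first).
#'
#' @param counts a [count_matrix()] (raw counts; the test is rank-based so
#'   any monotone per-gene transform gives identical results).
#' @param labels per-cell cluster labels.
#' @return data.frame with columns `cluster`, `gene`, `U`, `p_value`,
#'   `p_adjusted`, `rank`.
#' @export
mann_whitney_markers <- function(counts, labels) {
  stopifnot(inherits(counts, "count_matrix"))
  X <- counts$values
  if (length(labels) != nrow(X)) stop("one label per cell required")
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) stop("need at least 2 clusters")
  sizes <- table(labels)
  if (any(sizes < 2L)) stop("every cluster needs at least 2 cells")
  n <- nrow(X)
  out <- list()
  for (cl in clusters) {
    in_cl <- labels == cl
    n1 <- sum(in_cl); n2 <- n - n1
    U <- p <- numeric(ncol(X))
    for (gi in seq_len(ncol(X))) {
      v <- X[, gi]
      rk <- rank(v)
      U[gi] <- sum(rk[in_cl]) - n1 * (n1 + 1) / 2
      tie <- table(v)
      tie_term <- sum(tie^3 - tie) / (n * (n - 1))
      var_u <- n1 * n2 / 12 * ((n + 1) - tie_term)
      if (var_u <= 0) { p[gi] <- 1; next }
      z <- (U[gi] - n1 * n2 / 2) / sqrt(var_u)
      p[gi] <- 2 * stats::pnorm(-abs(z))
    }
    p <- pmin(p, 1)
    padj <- stats::p.adjust(p, method = "BH")
    effect <- U - n1 * n2 / 2
    ord <- order(p, -effect)
    out[[length(out) + 1L]] <- data.frame(
      cluster = cl, gene = counts$gene_ids[ord], U = U[ord],
      p_value = p[ord], p_adjusted = padj[ord],
      rank = seq_along(ord), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Reference batch-correction hook: per-batch latent centering
#'
#' A latent-corrector plug-in (signature `function(latent, batch_labels)`)
#' that subtracts each batch's latent centroid and restores the global
#' centroid — the simplest location-only integration, provided for testing
#' the hook mechanism and as a baseline. Harmony-style tools can be plugged
#' in through the same signature.
#'
#' @param latent a [latent_matrix()].
#' @param batch_labels per-cell batch labels.
#' @return corrected [latent_matrix()].
#' @export
center_batches_hook <- function(latent, batch_labels) {
  stopifnot(inherits(latent, "latent_matrix"))
  Zm <- latent$values
  if (length(batch_labels) != nrow(Zm)) stop("one batch label per cell required")
  global <- colMeans(Zm)
  for (b in unique(batch_labels)) {
    sel <- batch_labels == b
    Zm[sel, ] <- sweep(Zm[sel, , drop = FALSE], 2,
                       colMeans(Zm[sel, , drop = FALSE]) - global)
  }
  latent_matrix(Zm, latent$cell_ids)
}

#' Pipeline configuration
#'
#' @param target_n_clusters desired cluster count for [leiden_at_target()].
#' @param n_hvgs HVGs to select (default 1000, capped at the gene count).
#' @param knn_k neighbours for the kNN graph (default 15).
#' @param network a [network_spec()] (architecture, sizes, loss, ELBO).
#' @param training a [training_config()].
#' @param correction_hook optional plug-in: either a latent-corrector
#'   `function(latent, batch_labels) -> latent_matrix` or a graph-builder
#'   `function(latent, batch_labels) -> neighborhood_graph` (set
#'   `hook_type = "graph"`).
#' @param hook_type `"latent"` or `"graph"`.
#' @param seed master seed for clustering.
#' @export
pipeline_config <- function(target_n_clusters, n_hvgs = 1000L, knn_k = 15L,
                            network = network_spec(),
                            training = training_config(),
                            correction_hook = NULL,
                            hook_type = c("latent", "graph"), seed = 0L) {
  target_n_clusters <- as.integer(target_n_clusters)
  if (target_n_clusters < 2L) stop("target_n_clusters must be >= 2")
  if (n_hvgs < 1L) stop("n_hvgs must be >= 1")
  hook_type <- match.arg(hook_type)
  stopifnot(inherits(network, "network_spec"),
            inherits(training, "training_config"))
  structure(list(target_n_clusters = target_n_clusters,
                 n_hvgs = as.integer(n_hvgs), knn_k = as.integer(knn_k),
                 network = network, training = training,
                 correction_hook = correction_hook, hook_type = hook_type,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full integration pipeline
#'
#' merge (if a sample list) -> batch-aware HVG selection -> subset to HVGs
#' -> train autoencoder on raw counts -> encode -> optional correction hook
#' -> kNN graph -> Leiden at the target cluster count -> agreement metrics
#' (when reference labels are given) -> Mann-Whitney markers. Cell order is
#' preserved throughout; every stage is seeded.
#'
#' @param counts a [count_matrix()] or a list of them (merged with
#'   `sample_names`).
#' @param config a [pipeline_config()].
#' @param sample_names names for the samples when `counts` is a list.
#' @param labels_true optional reference labels for the metric report.
#' @param out_dir optional directory; when given, `hvgs.txt`, `latent.csv`,
#'   `labels.csv`, `metrics.json` and `markers.tsv` are written there.
#' @return list with `hvgs`, `latent`, `corrected_latent`, `graph`,
#'   `labels`, `metrics` (or NULL), `markers`, `model`.
#' @export
run_pipeline <- function(counts, config, sample_names = NULL,
                         labels_true = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.list(counts) && !inherits(counts, "count_matrix")) {
    if (is.null(sample_names)) sample_names <- paste0("sample", seq_along(counts))
    counts <- merge_samples(counts, sample_names)
  }
  stopifnot(inherits(counts, "count_matrix"))
  if (config$target_n_clusters > nrow(counts$values)) {
    stop("pipeline stage 'clustering': target cluster count exceeds the number of cells")
  }
  k_hvg <- min(config$n_hvgs, ncol(counts$values))
  hvgs <- select_hvgs(counts, k = k_hvg)
  sub <- count_matrix(counts$values[, hvgs, drop = FALSE], gene_ids = hvgs,
                      cell_ids = counts$cell_ids,
                      batch_labels = counts$batch_labels)
  model <- build_autoencoder(config$network, n_genes = length(hvgs))
  model <- train(model, sub, config$training)
  latent <- encode(model, sub)
  corrected <- NULL
  graph_input <- latent
  graph <- NULL
  if (!is.null(config$correction_hook)) {
    if (is.null(counts$batch_labels)) {
      stop("pipeline stage 'correction': a correction hook requires batch labels")
    }
    if (config$hook_type == "latent") {
      corrected <- config$correction_hook(latent, counts$batch_labels)
      stopifnot(inherits(corrected, "latent_matrix"))
      graph_input <- corrected
    } else {
      graph <- config$correction_hook(latent, counts$batch_labels)
      stopifnot(inherits(graph, "neighborhood_graph"))
    }
  }
  if (is.null(graph)) graph <- knn_graph(graph_input, k = config$knn_k)
  labels <- leiden_at_target(graph, config$target_n_clusters,
                             seed = config$seed)
  metrics <- if (!is.null(labels_true)) clustering_report(labels_true, labels)
  markers <- mann_whitney_markers(sub, labels)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(hvgs, file.path(out_dir, "hvgs.txt"))
    save_latent(latent, file.path(out_dir, "latent.csv"))
    save_labels(labels, counts$cell_ids, file.path(out_dir, "labels.csv"))
    if (!is.null(metrics)) save_metrics(metrics, file.path(out_dir, "metrics.json"))
    utils::write.table(markers, file.path(out_dir, "markers.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(hvgs = hvgs, latent = latent, corrected_latent = corrected,
       graph = graph, labels = labels, metrics = metrics, markers = markers,
       model = model)
}
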