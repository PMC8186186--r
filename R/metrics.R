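#' @name clustering_metrics
#' @title External clustering-agreement metrics
#'
#' @description
#' Six metrics comparing a predicted clustering with a reference labelling
#' (typically manually annotated cell types): the chance-adjusted Rand index
#' (ARI), adjusted mutual information (AMI, arithmetic-mean normalisation),
#' Fowlkes-Mallows index (FMI), homogeneity (HS), completeness (CS), and
#' their harmonic mean, the V-measure (VM). All are computed from the
#' contingency table of the two labellings and are invariant to relabelling
#' on either side. Natural logarithms are used in all entropy computations.
NULL

.check_labels <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  if (length(a) < 2L) stop("need at least 2 items")
}

#' Contingency table of two labellings
#'
#' @param a,b label vectors (integer, character or factor) of equal length.
#' @return count matrix with one row per class of `a`, one column per class
#'   of `b`; entries sum to `length(a)`.
#' @export
contingency <- function(a, b) {
  .check_labels(a, b)
  unclass(table(a, b, dnn = NULL))
}

# pair counts from a contingency table: number of co-clustered pairs
.choose2 <- function(x) x * (x - 1) / 2

#' Adjusted Rand index
#'
#' The Rand index (fraction of item pairs on which two clusterings agree),
#' adjusted so that its expected value under random labelling with fixed
#' cluster sizes is 0; 1 means identical partitions.
#'
#' @param a,b label vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  ct <- contingency(a, b)
  n <- sum(ct)
  sum_ij <- sum(.choose2(ct))
  sum_a <- sum(.choose2(rowSums(ct)))
  sum_b <- sum(.choose2(colSums(ct)))
  npairs <- .choose2(n)
  expected <- sum_a * sum_b / npairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

.entropy_counts <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

.mutual_information <- function(ct) {
  n <- sum(ct)
  ra <- rowSums(ct); cb <- colSums(ct)
  mi <- 0
  for (i in seq_len(nrow(ct))) {
    for (j in seq_len(ncol(ct))) {
      nij <- ct[i, j]
      if (nij > 0) mi <- mi + nij / n * log(nij * n / (ra[[i]] * cb[[j]]))
    }
  }
  mi
}

# Expected mutual information under the permutation (hypergeometric) model,
# following Vinh, Epps & Bailey (2010).
.expected_mi <- function(ct) {
  n <- sum(ct)
  ra <- rowSums(ct); cb <- colSums(ct)
  emi <- 0
  for (ai in ra) {
    for (bj in cb) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (lo > hi) next
      for (nij in lo:hi) {
        term <- nij / n * log(n * nij / (ai * bj))
        lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
          lgamma(n - bj + 1) - lgamma(n + 1) - lgamma(nij + 1) -
          lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
          lgamma(n - ai - bj + nij + 1)
        emi <- emi + term * exp(lp)
      }
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' Mutual information adjusted for chance under the permutation model,
#' normalised by the arithmetic mean of the two label entropies:
#' `(MI - E[MI]) / (mean(H(a), H(b)) - E[MI])`. Two single-class labellings
#' give 1 by convention; tiny negative floating-point results are clipped.
#'
#' @param a,b label vectors of equal length.
#' @return scalar, at most 1 (about 0 for unrelated labellings).
#' @export
adjusted_mutual_information <- function(a, b) {
  ct <- contingency(a, b)
  ha <- .entropy_counts(rowSums(ct))
  hb <- .entropy_counts(colSums(ct))
  if (ha == 0 && hb == 0) return(1)
  mi <- .mutual_information(ct)
  emi <- .expected_mi(ct)
  denom <- (ha + hb) / 2 - emi
  # the adjustment degenerates when E[MI] reaches the entropy bound (tiny
  # partitions where every labelling is equivalent under permutation); the
  # ratio is then 0/0 and defined to be 0
  if (abs(denom) < 1e-12) return(0)
  ami <- (mi - emi) / denom
  if (ami > -1e-12 && ami < 0) ami <- 0
  ami
}

#' Fowlkes-Mallows index
#'
#' Geometric mean of pairwise precision and recall:
#' `TP / sqrt((TP + FP) (TP + FN))` over item pairs, where TP counts pairs
#' co-clustered in both labellings. 0 by convention when either side has no
#' co-clustered pairs.
#'
#' @param a,b label vectors of equal length.
#' @return scalar in \[0, 1\].
#' @export
fowlkes_mallows <- function(a, b) {
  ct <- contingency(a, b)
  tp <- sum(.choose2(ct))
  pa <- sum(.choose2(rowSums(ct)))   # TP + FN (pairs together in a)
  pb <- sum(.choose2(colSums(ct)))   # TP + FP (pairs together in b)
  if (pa == 0 || pb == 0) return(0)
  tp / sqrt(pa * pb)
}

#' Homogeneity, completeness and V-measure
#'
#' Homogeneity is 1 when every predicted cluster contains members of a
#' single true class (`1 - H(true|pred) / H(true)`, with 1 when
#' `H(true) = 0`); completeness is the same quantity with the roles of true
#' and predicted labels exchanged; the V-measure is their harmonic mean
#' (0 when both are 0).
#'
#' @param labels_true reference label vector.
#' @param labels_pred predicted label vector of equal length.
#' @return scalar in \[0, 1\].
#' @export
homogeneity <- function(labels_true, labels_pred) {
  ct <- contingency(labels_true, labels_pred)
  h_true <- .entropy_counts(rowSums(ct))
  if (h_true == 0) return(1)
  # H(true | pred) = H(joint) - H(pred)
  h_cond <- .entropy_counts(ct) - .entropy_counts(colSums(ct))
  1 - h_cond / h_true
}

#' @rdname homogeneity
#' @export
completeness <- function(labels_true, labels_pred) {
  homogeneity(labels_pred, labels_true)
}

#' @rdname homogeneity
#' @export
v_measure <- function(labels_true, labels_pred) {
  hs <- homogeneity(labels_true, labels_pred)
  cs <- completeness(labels_true, labels_pred)
  if (hs + cs == 0) return(0)
  2 * hs * cs / (hs + cs)
}

#' Full clustering-agreement report
#'
#' @param labels_true reference labels.
#' @param labels_pred predicted labels.
#' @return named list with `ari`, `ami`, `fmi`, `homogeneity`,
#'   `completeness`, `v_measure` — ready for [save_metrics()].
#' @export
clustering_report <- function(labels_true, labels_pred) {
  list(ari = adjusted_rand_index(labels_true, labels_pred),
       ami = adjusted_mutual_information(labels_true, labels_pred),
       fmi = fowlkes_mallows(labels_true, labels_pred),
       homogeneity = homogeneity(labels_true, labels_pred),
       completeness = completeness(labels_true, labels_pred),
       v_measure = v_measure(labels_true, labels_pred))
}
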