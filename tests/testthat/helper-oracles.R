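# Brute-force, definition-level oracles for the clustering metrics, written
# independently of the package's contingency-table implementations: pair
# enumeration for the pair-counting indices, direct probability sums for the
# entropies, and R's dhyper for the expected mutual information.

# pair counts by enumerating all item pairs
oracle_pair_counts <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa) n10 <- n10 + 1
      else if (sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
}

oracle_ari <- function(a, b) {
  pc <- oracle_pair_counts(a, b)
  tp <- pc["n11"]; sum_a <- pc["n11"] + pc["n10"]; sum_b <- pc["n11"] + pc["n01"]
  npairs <- sum(pc)
  expected <- sum_a * sum_b / npairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  unname((tp - expected) / (max_index - expected))
}

oracle_fmi <- function(a, b) {
  pc <- oracle_pair_counts(a, b)
  tp <- pc["n11"]
  pa <- pc["n11"] + pc["n10"]; pb <- pc["n11"] + pc["n01"]
  if (pa == 0 || pb == 0) return(0)
  unname(tp / sqrt(pa * pb))
}

oracle_entropy <- function(labels) {
  p <- as.numeric(prop.table(table(labels)))
  -sum(ifelse(p > 0, p * log(p), 0))
}

oracle_mi <- function(a, b) {
  oracle_entropy(a) + oracle_entropy(b) - oracle_entropy(paste(a, b, sep = "\r"))
}

# conditional entropy H(a | b) by direct summation over the classes of b
oracle_cond_entropy <- function(a, b) {
  h <- 0
  for (cls in unique(b)) {
    sel <- b == cls
    h <- h + sum(sel) / length(b) * oracle_entropy(a[sel])
  }
  h
}

oracle_homogeneity <- function(a, b) {
  ha <- oracle_entropy(a)
  if (ha == 0) return(1)
  1 - oracle_cond_entropy(a, b) / ha
}

oracle_v_measure <- function(a, b) {
  hs <- oracle_homogeneity(a, b)
  cs <- oracle_homogeneity(b, a)
  if (hs + cs == 0) return(0)
  2 * hs * cs / (hs + cs)
}

# E[MI] under the permutation model; hypergeometric pmf via stats::dhyper
oracle_emi <- function(a, b) {
  n <- length(a)
  ra <- as.numeric(table(a)); cb <- as.numeric(table(b))
  emi <- 0
  for (ai in ra) {
    for (bj in cb) {
      for (nij in max(1, ai + bj - n):min(ai, bj)) {
        if (nij < 1) next
        pr <- stats::dhyper(nij, bj, n - bj, ai)
        emi <- emi + pr * nij / n * log(n * nij / (ai * bj))
      }
    }
  }
  emi
}

oracle_ami <- function(a, b) {
  ha <- oracle_entropy(a); hb <- oracle_entropy(b)
  if (ha == 0 && hb == 0) return(1)
  emi <- oracle_emi(a, b)
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < 1e-12) return(0)  # degenerate adjustment, same convention
  res <- (oracle_mi(a, b) - emi) / denom
  if (res > -1e-12 && res < 0) res <- 0
  res
}

# all set partitions of n items into at most kmax blocks, as canonical
# (restricted-growth) label vectors
all_partitions <- function(n, kmax = 3L) {
  out <- list()
  grow <- function(labels) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    top <- max(labels)
    for (next_lab in seq_len(min(top + 1L, kmax))) grow(c(labels, next_lab))
  }
  grow(1L)
  out
}

# random label pairs for property-style loops
random_label_pair <- function(n, kmax = 5L) {
  list(a = sample.int(kmax, n, replace = TRUE),
       b = sample.int(kmax, n, replace = TRUE))
}
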