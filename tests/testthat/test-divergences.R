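test_that("rbf_kernel is a symmetric kernel with the stated closed form", {
  expect_equal(rbf_kernel(1:3, 1:3, 2), 1)
  a <- c(0, 0); b <- c(2, 0)  # ||a-b||^2 = 4 = 2 sigma^2 with sigma^2 = 2
  expect_equal(rbf_kernel(a, b, 2), exp(-1), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:5) {
    u <- rnorm(4); v <- rnorm(4)
    expect_equal(rbf_kernel(u, v, 1.7), rbf_kernel(v, u, 1.7))
  }
  expect_error(rbf_kernel(1:2, 1:3, 1), "equal length")
  expect_error(rbf_kernel(1:2, 1:2, 0), "positive")
})

test_that("mmd_vstat vanishes on identical samples and expands for singletons", {
  set.seed(2)
  A <- matrix(rnorm(40), 10, 4)
  expect_lt(mmd_vstat(A, A), 1e-12)
  a <- matrix(c(0, 0), 1); b <- matrix(c(1, 1), 1)
  expect_equal(mmd_vstat(a, b, bandwidth = 2),
               2 * (1 - rbf_kernel(c(0, 0), c(1, 1), 2)), tolerance = 1e-12)
  expect_error(mmd_vstat(matrix(0, 2, 2), matrix(0, 2, 3)), "dimension")
})

test_that("mmd_vstat separates distant clouds and is permutation-invariant", {
  set.seed(42)
  p <- matrix(rnorm(400), 200, 2)
  q_near <- matrix(rnorm(400), 200, 2)
  q_far <- matrix(rnorm(400, mean = 5), 200, 2)
  expect_gt(mmd_vstat(p, q_far), mmd_vstat(p, q_near))
  perm <- sample(200)
  expect_equal(mmd_vstat(p[perm, ], q_far), mmd_vstat(p, q_far),
               tolerance = 1e-12)
})

test_that("gaussian_kl_pair matches its closed form", {
  p <- gaussian_params(c(0, 0), c(0, 0))
  expect_equal(gaussian_kl_pair(p, p), 0)
  expect_equal(gaussian_kl_pair(gaussian_params(0, 0), gaussian_params(1, 0)),
               0.5, tolerance = 1e-12)
  expect_equal(gaussian_kl_pair(gaussian_params(0, 0),
                                gaussian_params(0, log(2))),
               0.5 * log(2) - 0.25, tolerance = 1e-12)
  expect_error(gaussian_kl_pair(p, gaussian_params(0, 0)), "dimension")
})

test_that("categorical_kl matches direct evaluation and flags zero support", {
  expect_equal(categorical_kl(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(categorical_kl(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_equal(categorical_kl(c(0.75, 0.25), c(0.5, 0.5)),
               0.75 * log(1.5) + 0.25 * log(0.5), tolerance = 1e-12)
  expect_error(categorical_kl(c(0.5, 0.5), c(1, 0)), "zero mass")
  expect_error(categorical_kl(c(0.5, 0.4), c(0.5, 0.5)), "summing to 1")
})

test_that("divergences are non-negative on random instances", {
  set.seed(5)
  for (i in 1:20) {
    p <- gaussian_params(rnorm(3), rnorm(3))
    q <- gaussian_params(rnorm(3), rnorm(3))
    expect_gte(gaussian_kl_pair(p, q), 0)
    qv <- rgamma(4, 1); qv <- qv / sum(qv)
    pv <- rgamma(4, 1) + 0.01; pv <- pv / sum(pv)
    expect_gte(categorical_kl(qv, pv), 0)
  }
})

test_that("mixture_joint_kl reduces correctly for K = 1 and at the prior", {
  set.seed(6)
  n <- 4; L <- 3
  M <- matrix(rnorm(n * L), n, L); V <- matrix(rnorm(n * L, sd = 0.3), n, L)
  post <- mixture_posterior(matrix(1, n, 1), list(M), list(V))
  pri <- mixture_prior(1, matrix(0, 1, L), matrix(0, 1, L))
  per_cell <- mixture_joint_kl(post, pri, reduce = FALSE)
  for (i in seq_len(n)) {
    expect_equal(per_cell[i],
                 gaussian_kl_pair(gaussian_params(M[i, ], V[i, ]),
                                  gaussian_params(rep(0, L), rep(0, L))),
                 tolerance = 1e-12)
  }
  # posterior identical to prior: zero divergence
  K <- 3
  pm <- matrix(rnorm(K * L), K, L); plv <- matrix(rnorm(K * L, sd = 0.2), K, L)
  w <- c(0.2, 0.3, 0.5)
  post2 <- mixture_posterior(
    matrix(w, n, K, byrow = TRUE),
    lapply(seq_len(K), function(k) matrix(pm[k, ], n, L, byrow = TRUE)),
    lapply(seq_len(K), function(k) matrix(plv[k, ], n, L, byrow = TRUE)))
  pri2 <- mixture_prior(w, pm, plv)
  expect_lt(abs(mixture_joint_kl(post2, pri2)), 1e-10)
})

test_that("mixture_joint_kl agrees with a Monte-Carlo estimate of the joint KL", {
  set.seed(11)
  n <- 3; L <- 2; K <- 2
  R <- matrix(rgamma(n * K, 1), n, K); R <- R / rowSums(R)
  M <- lapply(1:K, function(k) matrix(rnorm(n * L), n, L))
  V <- lapply(1:K, function(k) matrix(rnorm(n * L, sd = 0.4), n, L))
  w <- c(0.4, 0.6)
  pm <- matrix(rnorm(K * L), K, L); plv <- matrix(rnorm(K * L, sd = 0.4), K, L)
  post <- mixture_posterior(R, M, V)
  pri <- mixture_prior(w, pm, plv)
  analytic <- mixture_joint_kl(post, pri, reduce = FALSE)
  nmc <- 1e5
  for (i in seq_len(n)) {
    y <- sample.int(K, nmc, replace = TRUE, prob = R[i, ])
    mu <- t(vapply(y, function(k) M[[k]][i, ], numeric(L)))
    sd_ <- t(vapply(y, function(k) exp(V[[k]][i, ] / 2), numeric(L)))
    z <- mu + sd_ * matrix(rnorm(nmc * L), nmc, L)
    log_q <- log(R[i, ][y]) +
      rowSums(dnorm(z, mu, sd_, log = TRUE))
    log_p <- log(w[y]) +
      rowSums(dnorm(z, pm[y, , drop = FALSE],
                    exp(plv[y, , drop = FALSE] / 2), log = TRUE))
    draws <- log_q - log_p
    se <- sd(draws) / sqrt(nmc)
    expect_lt(abs(mean(draws) - analytic[i]), 3 * se + 1e-8)
  }
})
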