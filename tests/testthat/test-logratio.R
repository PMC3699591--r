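test_that("the centred log-ratio transform matches hand-worked values", {
  z <- clr_transform(c(1 / 2, 1 / 4, 1 / 4), log_base = 2)
  expect_equal(z, c(2 / 3, -1 / 3, -1 / 3))
  expect_equal(sum(z), 0)
  # scale invariance: any positive multiple is experimentally equivalent
  for (c in c(0.001, 7, 1e6)) {
    expect_equal(clr_transform(c * c(1 / 2, 1 / 4, 1 / 4)), z)
  }
  expect_equal(clr_transform(rep(1 / 5, 5)), rep(0, 5))
  expect_error(clr_transform(c(0.5, 0, 0.5)), "strictly positive")
  expect_error(clr_transform(3), "D >= 2")
})

test_that("every transformed posterior draw sums to zero", {
  p <- sample_posterior(posterior_alpha(c(0, 2, 50, 3)), 200, seed = 5)
  z <- clr_transform(p)
  expect_equal(dim(z), dim(p))
  expect_true(all(abs(colSums(z)) < 1e-9 * nrow(z)))
})

test_that("digamma identities give the documented log-proportion means", {
  # natural-log scale: E[ln q_i] = psi(alpha_i) - psi(alpha0)
  m11 <- clr_moments(posterior_alpha(c(0, 0), prior_mass = 1), log_base = exp(1))
  expect_equal(digamma(1) - digamma(2), -1)
  expect_equal(m11$mean, c(0, 0))
  expect_equal(m11$cov[1, 1], trigamma(1) / 2)
  expect_equal(m11$cov[1, 1], pi^2 / 12, tolerance = 1e-12)

  expect_equal(digamma(1) - digamma(3), -1.5)
  m12 <- clr_moments(posterior_alpha(c(0, 1), prior_mass = 1), log_base = exp(1))
  # centred mean of component 1: (psi(1)-psi(3)) - mean of the two log-means
  raw <- digamma(c(1, 2)) - digamma(3)
  expect_equal(m12$mean, raw - mean(raw))
})

test_that("analytic moments carry the sum-zero structure and base conversion", {
  params <- posterior_alpha(c(3, 0, 17, 2))
  m2 <- clr_moments(params, log_base = 2)
  me <- clr_moments(params, log_base = exp(1))
  expect_equal(sum(m2$mean), 0)
  expect_equal(unname(rowSums(m2$cov)), rep(0, 4), tolerance = 1e-12)
  expect_equal(m2$cov, t(m2$cov))
  expect_true(all(eigen(m2$cov, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  expect_equal(m2$mean, me$mean / log(2))
  expect_equal(m2$cov, me$cov / log(2)^2)
})

test_that("Monte-Carlo moments agree with the closed forms within 4 SE", {
  # the derived matrix forms checked against a brute-force oracle
  withr::with_seed(99, {
    for (D in c(2, 5, 20)) {
      alpha <- runif(D, 0.5, 30)
      params <- structure(list(alpha = alpha, alpha0 = sum(alpha)),
                          class = "dirichlet_params")
      ana <- clr_moments(params, log_base = 2)
      n <- 50000
      z <- clr_transform(sample_posterior(params, n, seed = D), log_base = 2)
      emp_mean <- rowMeans(z)
      emp_var <- apply(z, 1, var)
      se_mean <- sqrt(diag(ana$cov) / n)
      expect_true(all(abs(emp_mean - ana$mean) < 4 * se_mean))
      m4 <- rowMeans((z - emp_mean)^4)
      se_var <- sqrt(pmax(m4 - emp_var^2, 0) / n)
      expect_true(all(abs(emp_var - diag(ana$cov)) < 4 * se_var))
      # a sampled off-diagonal entry
      cv <- stats::cov(z[1, ], z[2, ])
      expect_lt(abs(cv - ana$cov[1, 2]), 6 * sqrt((1 + 2) * ana$cov[1, 1] * ana$cov[2, 2] / n))
    }
  })
})

test_that("induced covariance decays as the number of genes grows", {
  base_counts <- c(5, 20, 0, 50, 9)
  max_off <- vapply(c(10, 100, 1000), function(D) {
    counts <- rep_len(base_counts, D)
    cv <- clr_moments(posterior_alpha(counts))$cov
    max(abs(cv[upper.tri(cv)]))
  }, numeric(1))
  expect_true(all(diff(max_off) < 0))
})

test_that("the sum-zero basis projection is an isometry", {
  V <- ilr_basis(6)
  expect_equal(crossprod(V), diag(5), tolerance = 1e-12)
  expect_equal(unname(colSums(V)), rep(0, 5), tolerance = 1e-12)
  p <- sample_posterior(posterior_alpha(c(4, 0, 9, 1, 30, 2)), 50, seed = 8)
  z <- clr_transform(p)
  y <- ilr_transform(p)
  expect_equal(dim(y), c(5, 50))
  expect_equal(as.vector(dist(t(y))), as.vector(dist(t(z))), tolerance = 1e-9)
})

test_that("identical replicates show no observed difference beyond MC error", {
  counts <- c(gA = 100L, gB = 1000L, gC = 10L, gD = 0L, gE = 250L)
  env <- sampling_variance_envelope(counts, counts, n_mc = 4000, seed = 21)
  expect_equal(env$gene, names(counts))
  expect_true(all(abs(env$observed) < 0.35))
  expect_true(all(env$inside))
  expect_true(all(env$lo < env$hi))
})

test_that("the envelope narrows with read count", {
  D <- 40
  c1 <- c(rep(500L, D - 2L), 0L, 1000L)
  env <- sampling_variance_envelope(c1, c1, n_mc = 3000, seed = 31)
  width <- env$hi - env$lo
  expect_gt(width[D - 1L], width[D])  # zero-count gene wider than count-1000 gene
  expect_error(sampling_variance_envelope(c1, c1[-1]), "equal length")
})
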