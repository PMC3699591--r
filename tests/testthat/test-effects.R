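test_that("the within-condition mixture pools replicates with equal weight", {
  n <- 10000
  mix <- within_mixture(list(const_draws(1, n_mc = n), const_draws(3, n_mc = n)), seed = 1)
  expect_lt(abs(mean(mix) - 2), 4 * 1 / sqrt(n))  # Bernoulli spread sd = 1

  mix3 <- within_mixture(list(const_draws(0, n_mc = 3 * n), const_draws(0, n_mc = 3 * n),
                              const_draws(3, n_mc = 3 * n)), seed = 2)
  se3 <- sqrt(2) / sqrt(3 * n)  # mixture var = 2
  expect_lt(abs(mean(mix3) - 1), 4 * se3)

  same <- within_mixture(list(const_draws(7, n_mc = 50), const_draws(7, n_mc = 50)), seed = 3)
  expect_equal(same, const_draws(7, n_mc = 50))

  expect_error(within_mixture(list(const_draws(1))), ">= 2 replicate")
  expect_error(within_mixture(list(const_draws(1, n_mc = 10), const_draws(1, n_mc = 20))),
               "same n_mc")
})

test_that("between-condition differences subtract per MC index", {
  expect_equal(between_difference(const_draws(2, n_mc = 10), const_draws(5, n_mc = 10)),
               const_draws(-3, n_mc = 10))
  z <- matrix(rnorm(50), 5)
  expect_equal(between_difference(z, z), matrix(0, 5, 10))
  expect_error(between_difference(z, z[, 1:5]), "identical dimensions")
})

test_that("the within-condition difference takes the largest magnitude across conditions", {
  n <- 200
  dw <- within_difference(list(const_draws(0, n_mc = n), const_draws(1, n_mc = n)),
                          list(const_draws(0, n_mc = n), const_draws(4, n_mc = n)), seed = 4)
  expect_equal(unclass(dw)[1, ], rep(4, n), ignore_attr = TRUE)
  expect_false(any(attr(dw, "degenerate")))

  dw1 <- within_difference(list(const_draws(0, n_mc = n), const_draws(1, n_mc = n)),
                           list(const_draws(0, n_mc = n), const_draws(1, n_mc = n)), seed = 5)
  expect_true(all(dw1 == 1))

  # constant identical replicates: the zero is re-drawn, persists, and flags the gene
  dg <- within_difference(list(const_draws(2, n_mc = n), const_draws(2, n_mc = n)),
                          list(const_draws(5, n_mc = n), const_draws(5, n_mc = n)), seed = 6)
  expect_true(all(attr(dg, "degenerate")))
})

test_that("the effect size is a paired ratio, never a ratio of summaries", {
  expect_equal(effect_ratio(const_draws(-3, n_mc = 5), const_draws(4, n_mc = 5)),
               const_draws(-0.75, n_mc = 5))
  dr <- effect_ratio(c(2, 4), c(1, 8))
  expect_equal(dr, c(2, 0.5))
  expect_equal(median(dr), 1.25)
  expect_false(isTRUE(all.equal(median(dr), median(c(2, 4)) / median(c(1, 8)))))
  expect_error(effect_ratio(c(1, 2, 3), c(1, 2)), "paired")
})

test_that("zeta is the symmetric quantile of zero", {
  expect_equal(zeta_stat(c(1, 2, 3, 4)), 0)
  expect_equal(zeta_stat(c(-1, -2, 1, 2)), 0.5)
  draws <- c(rep(-1, 3), rep(1, 97))
  expect_equal(zeta_stat(draws), 0.03)
  m <- rbind(c(1, 2, 3, 4), c(-1, -2, 1, 2))
  expect_equal(zeta_stat(m), c(0, 0.5))
  # always bounded by one half
  withr::with_seed(10, {
    for (i in 1:20) {
      x <- rnorm(97, mean = runif(1, -3, 3))
      expect_true(zeta_stat(x) >= 0 && zeta_stat(x) <= 0.5)
    }
  })
})

test_that("the decision rule needs both a large effect and a small zeta", {
  row <- tibble::tibble(E = 1.8, zeta = 0.0001)
  expect_true(call_differential(row, 1.5, 0.01))
  expect_false(call_differential(tibble::tibble(E = 1.8, zeta = 0.035), 1.5, 0.01))
  expect_false(call_differential(tibble::tibble(E = 0.2, zeta = 0), 1.5, 0.01))
  expect_true(call_differential(tibble::tibble(E = -1.8, zeta = 0.0001), 1.5, 0.01))
  expect_error(call_differential(row, -1, 0.01), "positive")
  expect_error(call_differential(row, 1.5, 0), "positive")
})

test_that("swapping the two conditions negates M and E and fixes zeta, W, A", {
  cts <- tiny_counts()
  d <- tiny_design()
  swapped <- d[c(3, 4, 1, 2), ]
  f1 <- ddex(cts, d, n_mc = 64, seed = 17)
  f2 <- ddex(cts, swapped, n_mc = 64, seed = 17)
  expect_identical(f1$results$M, -f2$results$M)
  expect_identical(f1$results$E, -f2$results$E)
  expect_identical(f1$results$zeta, f2$results$zeta)
  expect_identical(f1$results$W, f2$results$W)
  expect_identical(f1$results$A, f2$results$A)
  expect_identical(f1$results$called, f2$results$called)
})

test_that("results are invariant to gene-row and sample-column permutations", {
  cts <- tiny_counts()
  d <- tiny_design()
  f <- ddex(cts, d, n_mc = 64, seed = 23)
  perm <- c(2, 3, 1)
  fp <- ddex(cts[perm, ], d, n_mc = 64, seed = 23)
  expect_identical(fp$results$gene, f$results$gene[perm])
  expect_identical(fp$results$M, f$results$M[perm])
  fc <- ddex(cts[, c("gene", "s4", "s2", "s1", "s3")], d, n_mc = 64, seed = 23)
  expect_identical(fc$results, f$results)
})

test_that("a deeper library with the same composition changes M only within MC error", {
  withr::with_seed(41, {
    counts <- tibble::tibble(
      gene = sprintf("g%03d", 1:150),
      s1 = as.integer(rmultinom(1, 6e4, rlnorm(150, 3, 1.2))),
      s2 = as.integer(rmultinom(1, 6e4, rlnorm(150, 3, 1.2))),
      s3 = as.integer(rmultinom(1, 6e4, rlnorm(150, 3, 1.2))),
      s4 = as.integer(rmultinom(1, 6e4, rlnorm(150, 3, 1.2)))
    )
  })
  d <- tiny_design()
  f1 <- ddex(counts, d, n_mc = 1000, seed = 2)
  deeper <- dplyr::mutate(counts, s1 = s1 * 10L)
  f2 <- ddex(deeper, d, n_mc = 1000, seed = 2)
  # M spread per gene is order W; its median's MC error is ~ W * sqrt(pi/2/n)
  mc_se <- f1$results$W * sqrt(pi / 2 / 1000)
  expect_true(median(abs(f1$results$M - f2$results$M) / mc_se) < 1)
  expect_true(mean(abs(f1$results$M - f2$results$M) < 4 * mc_se) > 0.95)
})

test_that("a label-symmetric null with identical columns calls nothing", {
  withr::with_seed(31, {
    base <- as.integer(rmultinom(1, 2e5, rlnorm(400, 2, 1.5)))
  })
  cts <- tibble::tibble(gene = sprintf("g%03d", 1:400),
                        s1 = base, s2 = base, s3 = base, s4 = base)
  f <- ddex(cts, tiny_design(), n_mc = 128, seed = 13)
  expect_equal(sum(f$results$called), 0)
  expect_true(all(f$results$zeta >= 0 & f$results$zeta <= 0.5))
  expect_true(all(f$results$W > 0))
})

test_that("growing separation raises |E| and shrinks zeta", {
  # two-condition spike at increasing fold, fixed within-condition noise
  withr::with_seed(77, {
    bb <- as.integer(rmultinom(1, 1e5, rlnorm(300, 2, 1.5)))
  })
  stats <- purrr::map_dfr(c(1, 2, 8), function(fold) {
    spiked <- c(bb, 200L)
    boosted <- c(bb, as.integer(200 * fold))
    cts <- tibble::tibble(gene = sprintf("g%03d", seq_along(spiked)),
                          s1 = technical_replicate(boosted, method = "dirichlet", seed = 1),
                          s2 = technical_replicate(boosted, method = "dirichlet", seed = 2),
                          s3 = technical_replicate(spiked, method = "dirichlet", seed = 3),
                          s4 = technical_replicate(spiked, method = "dirichlet", seed = 4))
    f <- ddex(cts, tiny_design(), n_mc = 256, seed = 5)
    tail(f$results, 1)[, c("E", "zeta")]
  })
  expect_true(all(diff(abs(stats$E)) > 0))
  expect_true(all(diff(stats$zeta) <= 0))
})

test_that("zero-count genes are retained and flagged, or dropped on request", {
  cts <- tiny_counts()  # gB is all-zero
  f <- ddex(cts, tiny_design(), n_mc = 32, seed = 1)
  expect_equal(f$results$all_zero, c(FALSE, TRUE, FALSE))
  expect_false(f$results$called[2])
  fd <- ddex(cts, tiny_design(), n_mc = 32, seed = 1, drop_zero_genes = TRUE)
  expect_equal(fd$results$gene, c("gA", "gC"))
})

test_that("the conservative preset tightens the effect cutoff to 2", {
  f <- ddex(tiny_counts(), tiny_design(), n_mc = 32, seed = 1, conservative = TRUE)
  expect_equal(f$config$effect_cutoff, 2)
  expect_true(all(f$results$called == (abs(f$results$E) >= 2 & f$results$zeta <= 0.01)))
})

test_that("tidy and glance expose the fit tables", {
  f <- ddex(tiny_counts(), tiny_design(), n_mc = 32, seed = 1)
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("gene", "A", "M", "E", "W", "zeta", "called",
                    "med_s1", "med_A", "M_q01", "E_q99") %in% names(td)))
  g <- glance(f)
  expect_equal(g$n_genes, 3)
  expect_equal(g$seed, 1)
  expect_output(print(f), "called differential")
})

test_that("the row-median kernel agrees with stats::median", {
  withr::with_seed(55, {
    for (n in c(3, 4, 101, 1000)) {
      m <- matrix(rnorm(17 * n), nrow = 17)
      expect_equal(ddex:::row_medians(m), apply(m, 1, median))
    }
  })
})

test_that("conditions with more than two replicates fit end to end", {
  withr::with_seed(61, {
    lam <- rlnorm(80, 2, 1.5)
    cols <- lapply(1:6, function(i) as.integer(rmultinom(1, 3e4, lam)))
  })
  cts <- tibble::tibble(gene = sprintf("g%02d", 1:80))
  for (i in 1:6) cts[[paste0("s", i)]] <- cols[[i]]
  d <- tibble::tibble(sample = paste0("s", 1:6),
                      condition = rep(c("A", "B"), each = 3))
  f <- ddex(cts, d, n_mc = 96, seed = 8)
  expect_equal(nrow(f$results), 80)
  expect_true(all(f$results$W > 0))
  expect_true(all(f$results$zeta <= 0.5))
  # null design: nothing should be called
  expect_lte(sum(f$results$called), 1)
})
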