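test_that("kNN radius is the distance to the ks-th nearest other sample", {
  x <- matrix(c(0, 1, 2), ncol = 1)
  expect_equal(knn_radius(x, 2L, 2L), 1)        # both neighbours at distance 1
  y <- matrix(c(0, 1, 5), ncol = 1)
  expect_equal(knn_radius(y, 1L, 1L), 1)
  expect_equal(knn_radius(y, 1L, 2L), 5)
  dup <- matrix(c(0, 0, 3), ncol = 1)
  expect_equal(knn_radius(dup, 1L, 1L), 0)       # duplicate -> zero radius
  expect_error(knn_radius(y, 1L, 3L), "ks")
})

test_that("bandwidth formula: closed form, monotonicity, floor", {
  p <- rvkde_params(alpha = 1, beta = 1, ks = 1L, kt = 1L)
  # m = 1: sigma = R * Gamma(3/2) / sqrt(pi) = R / 2
  expect_equal(rvkde_bandwidth(2, 1L, p), 1)
  expect_equal(rvkde_bandwidth(0, 1L, p, sigma_floor = 1e-9), 1e-9)
  p2 <- rvkde_params(beta = 2, ks = 1L)
  expect_equal(rvkde_bandwidth(3, 4L, p2),
               2 * rvkde_bandwidth(3, 4L, rvkde_params(beta = 1, ks = 1L)))
  # decreasing in alpha, increasing in R
  lo_a <- rvkde_bandwidth(1, 2L, rvkde_params(alpha = 0.5, ks = 5L))
  hi_a <- rvkde_bandwidth(1, 2L, rvkde_params(alpha = 2, ks = 5L))
  expect_gt(lo_a, hi_a)
  expect_error(rvkde_params(alpha = -1), "alpha")
})

test_that("fitting is deterministic, with positive finite bandwidths and floored duplicates", {
  withr::with_seed(17, {
    rel <- matrix(rnorm(40, mean = 0), ncol = 2)
    unr <- matrix(rnorm(40, mean = 6), ncol = 2)
  })
  m1 <- rvkde_fit(rel, unr, rvkde_params(ks = 3L))
  m2 <- rvkde_fit(rel, unr, rvkde_params(ks = 3L))
  expect_identical(m1$classes$related$sigma, m2$classes$related$sigma)
  expect_true(all(is.finite(m1$classes$related$sigma)))
  expect_true(all(m1$classes$related$sigma > 0))

  same <- matrix(1, nrow = 5, ncol = 2)
  mdup <- rvkde_fit(same, unr, rvkde_params(ks = 2L))
  sig <- mdup$classes$related$sigma
  expect_true(all(sig > 0))
  expect_equal(length(unique(sig)), 1L)  # every radius 0 -> all at the floor

  expect_error(rvkde_fit(rel[1:3, ], unr, rvkde_params(ks = 5L)), "samples")
  expect_error(rvkde_fit(rel, unr[, 1, drop = FALSE], rvkde_params(ks = 3L)),
               "dimension")
})

test_that("class density matches the Gaussian closed form and a brute-force KDE oracle", {
  # single training point, sigma = 1, m = 1: peak is 1/sqrt(2*pi)
  model <- structure(list(
    classes = list(related = list(x = matrix(2, 1, 1), sigma = 1, n = 1L),
                   unrelated = list(x = matrix(9, 1, 1), sigma = 1, n = 1L)),
    m = 1L, params = rvkde_params(kt = 5L), n = 2L), class = "rvkde")
  expect_equal(class_density(model, "related", 2), 1 / sqrt(2 * pi))
  expect_lt(class_density(model, "related", 60), 1e-300)

  # kt >= n_j equals the independent double-loop KDE to 1e-12
  withr::with_seed(23, {
    rel <- matrix(rnorm(100), ncol = 2)          # 50 random 2-D points
    unr <- matrix(rnorm(60, mean = 4), ncol = 2)
    fit <- rvkde_fit(rel, unr, rvkde_params(ks = 4L, kt = 50L))
    for (i in 1:10) {
      v <- rnorm(2, mean = 1)
      expect_equal(class_density(fit, "related", v),
                   oracle_kde(fit$classes$related$x,
                              fit$classes$related$sigma, v),
                   tolerance = 1e-12)
    }
  })
})

test_that("kt-truncation error is one-sided: truncated density never exceeds the full sum", {
  withr::with_seed(29, {
    rel <- matrix(rnorm(80), ncol = 2)
    unr <- matrix(rnorm(80, mean = 3), ncol = 2)
    full <- rvkde_fit(rel, unr, rvkde_params(ks = 4L, kt = 40L))
    trunc <- rvkde_fit(rel, unr, rvkde_params(ks = 4L, kt = 5L))
    for (i in 1:20) {
      v <- rnorm(2, sd = 2)
      expect_lte(class_density(trunc, "related", v),
                 class_density(full, "related", v) + 1e-15)
    }
  })
})

test_that("the full-sum density integrates to 1 on a 1-D grid", {
  withr::with_seed(37, {
    rel <- matrix(rnorm(60), ncol = 1)
    unr <- matrix(rnorm(60, mean = 10), ncol = 1)
  })
  fit <- rvkde_fit(rel, unr, rvkde_params(beta = 1.3, ks = 5L, kt = 60L))
  grid <- seq(-12, 12, length.out = 4001)
  dens <- exp(pplink:::rvkde_log_density(fit, matrix(grid, ncol = 1),
                                         "related"))
  integral <- sum((dens[-1] + dens[-length(dens)]) / 2) * diff(grid[1:2])
  expect_equal(integral, 1, tolerance = 1e-3)
})

test_that("the estimator is consistent for a 1-D standard normal", {
  withr::with_seed(43, {
    x <- matrix(rnorm(2000), ncol = 1)
    other <- matrix(rnorm(2000, mean = 50), ncol = 1)
  })
  # the (alpha*ks)^(1/m) divisor makes sigma ~ beta * (per-point spacing),
  # so beta carries the absolute smoothing scale; 50 puts sigma near the
  # usual n^(-1/5) bandwidth for n = 2000
  fit <- rvkde_fit(x, other, rvkde_params(alpha = 1, beta = 50, ks = 20L,
                                          kt = 2000L))
  grid <- seq(-2, 2, length.out = 81)
  est <- exp(pplink:::rvkde_log_density(fit, matrix(grid, ncol = 1),
                                        "related"))
  expect_lt(mean(abs(est - dnorm(grid))), 0.05)
})

test_that("likelihoods weight densities by class priors; scores and ties behave", {
  withr::with_seed(47, {
    rel <- matrix(rnorm(60, mean = 0), ncol = 2)
    unr <- matrix(rnorm(200, mean = 5), ncol = 2)
  })
  fit <- rvkde_fit(rel, unr, rvkde_params(ks = 4L, kt = 100L))
  L0 <- likelihoods(fit, c(0, 0))
  expect_gt(L0[["related"]], L0[["unrelated"]])
  expect_equal(rvkde_classify(fit, c(0, 0)), "related")
  expect_equal(rvkde_classify(fit, c(5, 5)), "unrelated")
  # prior weighting: L_j = (n_j / n) * f_j
  expect_equal(L0[["related"]],
               (60 / 260) * class_density(fit, "related", c(0, 0)))

  # score is monotone in the related likelihood; remote-but-finite queries
  # keep a defined log-space ratio, and the no-evidence case (both class
  # densities exactly zero) scores 0 and falls to "unrelated"
  s_near <- rvkde_score(fit, c(0, 0))
  s_far <- rvkde_score(fit, c(2.5, 2.5))
  expect_gt(s_near, s_far)
  expect_equal(class_density(fit, "related", c(Inf, Inf)), 0)
  expect_equal(rvkde_score(fit, c(Inf, Inf)), 0)
  expect_equal(rvkde_classify(fit, c(Inf, Inf)), "unrelated")
})

test_that("F-measure handles perfect, empty and balanced cases", {
  expect_equal(f_measure(10, 0, 0), 1)
  expect_equal(f_measure(0, 5, 7), 0)
  expect_equal(f_measure(5, 5, 5), 0.5)   # precision = recall = 0.5
  expect_error(f_measure(-1, 0, 0), ">= 0")
})

test_that("grid-search CV is deterministic, respects ties, and recovers separable classes", {
  withr::with_seed(53, {
    rel <- matrix(rnorm(80, mean = 0), ncol = 2)
    unr <- matrix(rnorm(80, mean = 4), ncol = 2)
  })
  one <- data.frame(alpha = 1, beta = 2, ks = 3L, kt = 10L)
  p1 <- grid_search_cv(rel, unr, grid = one, seed = 9L)
  expect_equal(p1$beta, 2)

  grid <- expand.grid(alpha = 1, beta = c(0.5, 1), ks = c(3L, 5L), kt = 20L)
  a <- grid_search_cv(rel, unr, grid = grid, seed = 9L)
  b <- grid_search_cv(rel, unr, grid = grid, seed = 9L)
  expect_identical(unclass(a), unclass(b))
  expect_s3_class(a, "rvkde_params")
  cv <- attr(a, "cv_results")
  expect_equal(nrow(cv), nrow(grid))

  # separable data: the selected parameters classify well in CV
  expect_gt(max(cv$mean_f, na.rm = TRUE), 0.9)
  expect_error(grid_search_cv(rel, unr, grid = grid[0, ]), "empty")
})

test_that("model serialization round-trips predictions exactly", {
  withr::with_seed(59, {
    rel <- matrix(rnorm(40), ncol = 2)
    unr <- matrix(rnorm(40, mean = 3), ncol = 2)
    q <- matrix(rnorm(20), ncol = 2)
  })
  fit <- rvkde_fit(rel, unr, rvkde_params(ks = 3L, kt = 10L))
  path <- withr::local_tempfile(fileext = ".json")
  write_rvkde(fit, path)
  back <- read_rvkde(path)
  expect_equal(predict(back, q, type = "score"),
               predict(fit, q, type = "score"))
})
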