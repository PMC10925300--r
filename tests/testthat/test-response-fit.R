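test_that("linear fit reproduces exact and hand-solved coefficients", {
  x <- c(-1, 0, 1, 2, 3)
  expect_equal(fit_linear(x, 2 * x)$slope, 2, tolerance = 1e-12)
  expect_equal(fit_linear(x, 2 * x)$rss, 0, tolerance = 1e-12)
  ## toy points vs normal equations solved by hand
  y <- c(0.2, -0.1, 0.4, 0.8, 1.1)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  f <- fit_linear(x, y)
  expect_equal(c(f$intercept, f$slope), as.vector(beta), tolerance = 1e-10)
  expect_equal(f$rss, sum((y - X %*% beta)^2), tolerance = 1e-10)
  ## translation invariance of the slope
  expect_equal(fit_linear(x + 5, y)$slope, f$slope, tolerance = 1e-10)
  expect_error(fit_linear(rep(1, 5), y), "spread")
})

test_that("sigmoid fit recovers known parameters", {
  set.seed(101)
  x <- runif(30, -1.8, 0.8)
  y <- sigmoid4(x, 0, 4, -1, 1) + rnorm(30, 0, 0.02)
  f <- fit_sigmoid(x, y, n_starts = 10, seed = 1)
  expect_true(f$converged)
  expect_lt(abs(f$params$a - 0), 0.1)
  expect_lt(abs(f$params$b - 4), 1.0)
  expect_lt(abs(f$params$c - (-1)), 0.1)
  expect_lt(abs(f$params$d - 1), 0.1)
  expect_equal(f$slope_at_inflection, f$params$b * (f$params$d - f$params$c) / 4)
})

test_that("constant data degenerates to the constant model", {
  x <- seq(-1, 1, length.out = 12)
  f <- fit_sigmoid(x, rep(0.4, 12))
  expect_equal(f$params$c, 0.4, tolerance = 1e-6)
  expect_equal(f$params$d, 0.4, tolerance = 1e-6)
  expect_equal(f$rss, 0, tolerance = 1e-10)
})

test_that("mirroring x negates a and b after canonicalisation", {
  set.seed(7)
  x <- runif(40, -1.5, 1.5)
  y <- sigmoid4(x, 0.3, 3, -0.5, 0.8) + rnorm(40, 0, 0.01)
  f1 <- fit_sigmoid(x, y, seed = 2)
  f2 <- fit_sigmoid(-x, y, seed = 2)
  expect_lt(abs(f2$params$a - (-f1$params$a)), 0.05)
  expect_lt(abs(f2$params$b - (-f1$params$b)), 0.3)
  expect_lt(abs(f2$params$c - f1$params$c), 0.05)
  expect_lt(abs(f2$params$d - f1$params$d), 0.05)
})

test_that("canonical form is unique: c <= d with orientation in sign(b)", {
  p1 <- list(a = 0.2, b = -2, c = -1, d = 1)
  p2 <- list(a = 0.2, b = 2, c = 1, d = -1)  # same curve, flipped encoding
  can <- canon <- scdose:::canonicalize_sigmoid(p2)
  expect_equal(can, p1)
  xs <- seq(-2, 2, length.out = 9)
  expect_equal(sigmoid4(xs, can$a, can$b, can$c, can$d),
               sigmoid4(xs, p2$a, p2$b, p2$c, p2$d), tolerance = 1e-12)
})

test_that("loess fit matches analytic curves and respects its window rules", {
  x <- seq(-2, 2, length.out = 40)
  y <- x^2
  f <- fit_loess(x, y, span = 0.5)
  interior <- seq(-1.5, 1.5, length.out = 11)
  expect_lt(max(abs(f$fitted_fun(interior) - interior^2)), 1e-3)
  ## span 1 on linear data reproduces OLS on interior points
  yl <- 0.7 * x + 0.1
  fl <- fit_loess(x, yl, span = 1)
  ols <- fit_linear(x, yl)
  expect_lt(max(abs(fl$fitted_fun(interior) - ols$fitted_fun(interior))), 1e-6)
  ## evaluation clamps outside the observed range (no extrapolation)
  expect_equal(f$fitted_fun(5), f$fitted_fun(2), tolerance = 1e-9)
  expect_error(fit_loess(x[1:9], y[1:9], span = 0.05), "span")
})

test_that("loess derivative changes sign exactly once on rise-fall truth", {
  x <- seq(-1.8, 0.8, length.out = 30)
  y <- eval_response(response_truth("nonmonotonic", peak_x = -0.5,
                                    peak_height = 1, width = 0.5), x)
  f <- fit_loess(x, y, span = 0.75)
  gx <- seq(-1.7, 0.7, length.out = 200)
  dy <- diff(f$fitted_fun(gx))
  flips <- sum(diff(sign(dy[abs(dy) > 1e-8])) != 0)
  expect_equal(flips, 1)
})

test_that("AIC follows the least-squares Gaussian convention", {
  expect_equal(compute_aic(5, 20, 3), 20 * log(0.25) + 6, tolerance = 1e-12)
  ## halving rss lowers aic by n log 2
  expect_equal(compute_aic(5, 20, 3) - compute_aic(2.5, 20, 3),
               20 * log(2), tolerance = 1e-12)
  ## equal rss, k differing by 2: delta is exactly -4
  expect_equal(compute_aic(3, 15, 5) - compute_aic(3, 15, 3), 4)
  expect_equal(compute_aic(0, 10, 3), -Inf)
  expect_error(compute_aic(1, 3, 5))
})

test_that("delta AIC stored in fits is recomputable from rss, n and k", {
  set.seed(11)
  x <- runif(25, -1.8, 0.8)
  y <- sigmoid4(x, -0.2, 5, -0.8, 0.4) + rnorm(25, 0, 0.05)
  f <- fit_dose_response(x, y, min_q = 0.01, check_nonmono = FALSE)
  expect_equal(f$delta_aic,
               compute_aic(f$rss_linear, f$n_points, 3) -
                 compute_aic(f$rss_sigmoid, f$n_points, 5),
               tolerance = 1e-9)
})

test_that("cross-validation is near-perfect on noise-free sigmoid data", {
  set.seed(13)
  x <- runif(30, -1.8, 0.8)
  y <- sigmoid4(x, 0, 4, -1, 1)
  cv <- crossvalidate(x, y, "sigmoid", folds = 10, seed = 3)
  expect_gt(cv$cv_r, 0.999)
})

test_that("cross-validation stays low on pure noise", {
  set.seed(17)
  rs <- replicate(50, {
    x <- runif(30, -1.8, 0.8)
    y <- rnorm(30, 0, 1)
    crossvalidate(x, y, "linear", folds = 10, seed = 1)$cv_r
  })
  expect_lt(abs(median(rs)), 0.3)
})

test_that("fewer points than folds falls back to leave-one-out with warning", {
  x <- seq(-1, 1, length.out = 7); y <- 0.5 * x
  expect_warning(cv <- crossvalidate(x, y, "linear", folds = 10, seed = 1),
                 "leave-one-out")
  expect_equal(cv$folds, 7)
})

test_that("one-copy restriction keeps the closed interval [-1, log2(1.5)]", {
  x <- c(-1.83, -1.0, -0.5, 0, 0.51, log2(1.5), 0.6)
  r <- restrict_copy_range(x, x)
  expect_false(-1.83 %in% r$x)  # beyond one-copy loss: excluded
  expect_true(-1.0 %in% r$x)    # boundary included
  expect_true(0 %in% r$x)
  expect_true(any(abs(r$x - log2(1.5)) < 1e-9))  # upper boundary included
  expect_false(0.6 %in% r$x)
})

test_that("classifier recovers linear and sigmoid truths at high rate", {
  set.seed(19)
  n_rep <- 30
  lin_ok <- sig_ok <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    x <- runif(30, -1.8, 0.8)
    yl <- 0.5 * x + rnorm(30, 0, 0.05)
    ys <- sigmoid4(x, 0, 4, -1, 1) + rnorm(30, 0, 0.05)
    lin_ok[i] <- fit_dose_response(x, yl, min_q = 0.01, n_starts = 5,
                                   check_nonmono = FALSE)$response_class == "linear"
    sig_ok[i] <- fit_dose_response(x, ys, min_q = 0.01, n_starts = 5,
                                   check_nonmono = FALSE)$response_class == "nonlinear"
  }
  expect_gte(mean(lin_ok), 0.9)
  expect_gte(mean(sig_ok), 0.9)
})

test_that("flat truth is classified unresponsive when tests are null", {
  set.seed(23)
  x <- runif(30, -1.8, 0.8)
  y <- rnorm(30, 0, 0.02)
  f <- fit_dose_response(x, y, min_q = 0.6, check_nonmono = FALSE)
  expect_equal(f$response_class, "unresponsive")
})

test_that("restricted one-copy fits still detect a sigmoid with interior inflection", {
  set.seed(29)
  hits <- replicate(10, {
    x <- runif(40, -1.8, 0.8)
    y <- sigmoid4(x, -0.3, 6, -1, 0.6) + rnorm(40, 0, 0.05)
    r <- restrict_copy_range(x, y)
    ## fewer retained points than folds: the leave-one-out fallback warns
    f <- suppressWarnings(fit_dose_response(r$x, r$y, min_q = 0.01,
                                            n_starts = 6,
                                            check_nonmono = FALSE))
    identical(f$response_class, "nonlinear")
  })
  expect_gte(mean(hits), 0.7)
})

test_that("line-generated data keeps median delta AIC below 2 (nesting sanity)", {
  set.seed(31)
  daics <- replicate(25, {
    x <- runif(30, -1.8, 0.8)
    y <- 0.4 * x + rnorm(30, 0, 0.05)
    fit_dose_response(x, y, min_q = 0.01, n_starts = 5,
                      check_nonmono = FALSE)$delta_aic
  })
  expect_lt(median(daics), 2)
})

test_that("sigmoid parameter recovery is unbiased over replicates", {
  set.seed(37)
  est <- t(replicate(30, {
    x <- runif(30, -1.8, 0.8)
    y <- sigmoid4(x, 0, 4, -1, 1) + rnorm(30, 0, 0.05)
    unlist(fit_sigmoid(x, y, n_starts = 6, seed = sample.int(1e6, 1))$params)
  }))
  bias <- colMeans(est) - c(a = 0, b = 4, c = -1, d = 1)
  expect_lt(abs(bias[["a"]]), 0.1)
  expect_lt(abs(bias[["b"]]), 1.0)
  expect_lt(abs(bias[["c"]]), 0.1)
  expect_lt(abs(bias[["d"]]), 0.1)
})

test_that("grid predictions match the closed form and flag extrapolation", {
  set.seed(41)
  x <- runif(25, -1.2, 0.5)
  fcs <- data.frame(
    guide_id = sprintf("g%d", 1:25), line = "CRISPRi",
    gene_id = rep("CIS", 25), log2fc = x, se = 0.05, p_value = 0.001,
    family = "cis")
  trans_fc <- fcs
  trans_fc$gene_id <- "T1"
  trans_fc$log2fc <- sigmoid4(x, -0.3, 4, -1, 0.5) + rnorm(25, 0, 0.02)
  trans_fc$family <- "trans"
  fc_table <- rbind(fcs, trans_fc)
  lib <- data.frame(guide_id = sprintf("g%d", 1:25), target_gene = "CIS",
                    guide_class = "tiling", effector = "CRISPRi")
  fits <- fit_dose_responses(fc_table, lib, "CIS", "T1",
                             check_nonmono = FALSE, seed = 2)
  grid <- predict_grid(fits)
  expect_equal(grid$grid[1], -1.83)
  expect_equal(grid$grid[length(grid$grid)], 0.51)
  ## sigmoid predictions are monotone along the grid
  dd <- diff(grid$predictions[1, ])
  expect_true(all(dd >= -1e-9) || all(dd <= 1e-9))
  ## spot-check five grid points against the analytic curve
  f <- attr(fits, "fits")[["CIS|T1"]]
  pts <- c(1, 25, 50, 75, 100)
  expect_equal(grid$predictions[1, pts],
               sigmoid4(grid$grid[pts], f$params$a, f$params$b,
                        f$params$c, f$params$d), tolerance = 1e-9)
  ## extrapolation flagged outside the observed dosage range
  expect_true(any(grid$extrapolated[1, grid$grid < min(x)]))
  expect_false(any(grid$extrapolated[1, grid$grid > min(x) + 0.01 &
                                          grid$grid < max(x) - 0.01]))
})
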