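## Dose-response modelling: each trans gene's pseudo-bulk log2FC as a
## function of the cis gene's log2FC across guides. Linear vs four-parameter
## sigmoid compared by AIC; loess for non-monotonic shapes; 10-fold
## cross-validation over guides; classification into
## unresponsive / linear / nonlinear / nonmonotonic; prediction on a common
## dosage grid.

#' Ordinary least-squares linear dose-response fit
#'
#' @param x Cis dosages (log2FC) per guide.
#' @param y Trans log2FCs per guide.
#' @param w Optional weights (e.g. inverse squared SE); default unweighted.
#' @return list(intercept, slope, rss, fitted_fun)
#' @export
fit_linear <- function(x, y, w = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("no dosage spread: all x identical")
  fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  slope_p <- suppressWarnings(stats::coef(summary(fit))["x", "Pr(>|t|)"])
  list(intercept = unname(cf[1]), slope = unname(cf[2]),
       rss = sum(stats::residuals(fit)^2), slope_p = slope_p,
       fitted_fun = function(newx) unname(cf[1] + cf[2] * newx))
}

## Canonical form: c <= d, orientation carried by the sign of b.
## (a, b, c, d) and (a, -b, d, c) describe the same curve.
canonicalize_sigmoid <- function(p) {
  if (p[["c"]] > p[["d"]]) {
    p <- list(a = p[["a"]], b = -p[["b"]], c = p[["d"]], d = p[["c"]])
  }
  p
}

## heuristic start: asymptotes from y extremes, a at the steepest local
## change, b from range over spread
.sigmoid_start <- function(x, y) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  dx <- diff(xs); dy <- diff(ys)
  slope <- ifelse(dx > 0, dy / dx, 0)
  k <- which.max(abs(slope))
  a0 <- mean(xs[k + 0:1])
  iqr <- max(stats::IQR(x), 0.1)
  b0 <- sign(sum(slope)) * diff(range(y)) / iqr
  if (b0 == 0) b0 <- 1
  list(a = a0, b = b0, c = min(y), d = max(y))
}

#' Fit a four-parameter sigmoid dose-response curve
#'
#' Least-squares fit of `f(x) = c + (d - c) / (1 + exp(-b (x - a)))` by
#' damped (Levenberg-Marquardt) nonlinear least squares with one heuristic
#' start plus `n_starts - 1` seeded random starts within bounds; the
#' best-RSS converged solution is returned in canonical form (`c <= d`,
#' orientation in the sign of `b`). If no start converges the best evaluated
#' start is returned with `converged = FALSE`.
#'
#' Bounds: `|a| <= 2 * range(x)`, `|b| <= 50`, `c` and `d` within the y
#' range extended by 50% on either side.
#'
#' @param x,y Dosages and trans log2FCs (>= 6 points, positive x spread).
#' @param w Optional weights.
#' @param n_starts Total number of starts (default 10).
#' @param seed Seed for the random starts.
#' @return list(params = list(a, b, c, d), rss, converged,
#'   slope_at_inflection = b (d - c) / 4, fitted_fun)
#' @export
fit_sigmoid <- function(x, y, w = NULL, n_starts = 10L, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 6)
  if (stats::sd(x) == 0) stop("no dosage spread: all x identical")
  xr <- diff(range(x))
  yr <- diff(range(y))
  if (yr == 0) yr <- 1e-3
  lower <- c(a = min(x) - 2 * xr, b = -50, c = min(y) - 0.5 * yr, d = min(y) - 0.5 * yr)
  upper <- c(a = max(x) + 2 * xr, b = 50, c = max(y) + 0.5 * yr, d = max(y) + 0.5 * yr)
  clamp <- function(s) pmin(pmax(unlist(s), lower), upper)

  starts <- with_local_seed(seed, {
    s <- list(clamp(.sigmoid_start(x, y)))
    for (i in seq_len(max(n_starts - 1L, 0L))) {
      s[[i + 1L]] <- stats::setNames(
        lower + stats::runif(4) * (upper - lower), names(lower))
    }
    s
  })
  weights <- w %||% rep(1, length(x))
  best <- NULL
  best_rss <- Inf
  best_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ c + (d - c) / (1 + exp(-b * (x - a))),
        start = as.list(s), lower = lower, upper = upper,
        weights = weights,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) {
      rss <- sum(weights * (y - sigmoid4(x, s[["a"]], s[["b"]], s[["c"]], s[["d"]]))^2)
      if (rss < best_rss && !best_conv) {
        best_rss <- rss
        best <- as.list(s)
      }
      next
    }
    cf <- as.list(stats::coef(fit))
    rss <- sum(weights * stats::residuals(fit)^2)
    if (!best_conv || rss < best_rss) {
      best <- cf
      best_rss <- rss
      best_conv <- TRUE
    }
  }
  p <- canonicalize_sigmoid(best)
  rss <- sum(weights * (y - sigmoid4(x, p$a, p$b, p$c, p$d))^2)
  ## a sigmoid nests the constant model; never report a worse RSS than it
  const_rss <- sum(weights * (y - stats::weighted.mean(y, weights))^2)
  if (rss > const_rss + 1e-12) {
    p <- list(a = mean(x), b = 0, c = stats::weighted.mean(y, weights),
              d = stats::weighted.mean(y, weights))
    rss <- const_rss
  }
  list(params = p, rss = rss, converged = best_conv,
       slope_at_inflection = p$b * (p$d - p$c) / 4,
       fitted_fun = function(newx) sigmoid4(newx, p$a, p$b, p$c, p$d))
}

#' Loess dose-response fit with clamped evaluation
#'
#' Locally weighted quadratic regression (tricube weights). Evaluation at
#' new dosages clamps to the observed x range: loess is never extrapolated.
#'
#' @param x,y Dosages and responses (>= 8 points).
#' @param span Loess span (default 0.75).
#' @return list(model, rss, fitted_fun, x_range)
#' @export
fit_loess <- function(x, y, span = 0.75) {
  stopifnot(length(x) == length(y), length(x) >= 8)
  if (span * length(x) < 4) stop("span too small: local windows below 4 points")
  fit <- suppressWarnings(
    stats::loess(y ~ x, span = span, degree = 2,
                 family = "gaussian",
                 control = stats::loess.control(surface = "direct")))
  rng <- range(x)
  fitted_fun <- function(newx) {
    as.numeric(suppressWarnings(
      stats::predict(fit, data.frame(x = pmin(pmax(newx, rng[1]), rng[2])))))
  }
  list(model = fit, rss = sum(stats::residuals(fit)^2),
       fitted_fun = fitted_fun, x_range = rng)
}

#' Akaike information criterion for a least-squares fit
#'
#' Gaussian-error least-squares convention: `AIC = n log(rss / n) + 2 k`,
#' where `k` counts the mean-function parameters plus one for the error
#' variance (linear k = 3, four-parameter sigmoid k = 5). An exact fit
#' (rss = 0) returns `-Inf`.
#'
#' @param rss Residual sum of squares.
#' @param n_points Number of observations.
#' @param k_params Parameter count including the error variance.
#' @return AIC value.
#' @export
compute_aic <- function(rss, n_points, k_params) {
  stopifnot(n_points > k_params, rss >= 0)
  if (rss == 0) return(-Inf)
  n_points * log(rss / n_points) + 2 * k_params
}

#' Cross-validate a dose-response model over guides
#'
#' Points (guides) are partitioned into `folds` random folds (seeded); the
#' model is refitted on each training set and predictions on the held-out
#' guides are pooled. Reported is the Pearson correlation between pooled
#' held-out predictions and observations.
#'
#' @param x,y Data.
#' @param model `"linear"`, `"sigmoid"` or `"loess"`.
#' @param folds Number of folds (default 10); reduced to `length(x)`
#'   (leave-one-out, with a warning) when there are fewer points.
#' @param seed Seed for the fold partition and sigmoid starts.
#' @param span,n_starts Passed through to the fitters.
#' @return list(cv_r, predictions, observations, folds)
#' @export
crossvalidate <- function(x, y, model = c("sigmoid", "linear", "loess"),
                          folds = 10L, seed = 1L, span = 0.75,
                          n_starts = 10L) {
  model <- match.arg(model)
  n <- length(x)
  if (n < folds) {
    warning("fewer points than folds; using leave-one-out")
    folds <- n
  }
  fold_id <- with_local_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  pred <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fitted_fun <- switch(model,
      linear = fit_linear(x[!test], y[!test])$fitted_fun,
      sigmoid = fit_sigmoid(x[!test], y[!test], n_starts = n_starts,
                            seed = seed + f)$fitted_fun,
      loess = fit_loess(x[!test], y[!test], span = span)$fitted_fun)
    pred[test] <- fitted_fun(x[test])
  }
  cv_r <- if (stats::sd(pred) == 0 || stats::sd(y) == 0) NA_real_
          else stats::cor(pred, y)
  list(cv_r = cv_r, predictions = pred, observations = y, folds = folds)
}

#' Restrict dose-response points to a one-copy loss/gain window
#'
#' Retains points whose cis dosage lies in the closed interval
#' `[-1, log2(1.5)]` — a hypothetical single copy loss (0.5x) to single copy
#' gain (1.5x) of the cis gene.
#'
#' @param x,y Data.
#' @return list(x, y, kept) — `kept` is the logical retention mask.
#' @export
restrict_copy_range <- function(x, y) {
  kept <- x >= -1 & x <= log2(1.5)
  list(x = x[kept], y = y[kept], kept = kept)
}

## leave-one-out mean squared prediction error for the non-monotonicity rule
.loo_mse <- function(x, y, refit) {
  pred <- vapply(seq_along(x), function(i) {
    f <- tryCatch(refit(x[-i], y[-i]), error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    f(x[i])
  }, numeric(1))
  mean((pred - y)^2, na.rm = TRUE)
}

## derivative sign changes of a fitted curve on a fine grid; returns the
## number of sign flips and the amplitude of the largest internal extremum
## relative to the curve endpoints
.curve_turning <- function(fitted_fun, rng, n = 101L) {
  gx <- seq(rng[1], rng[2], length.out = n)
  gy <- fitted_fun(gx)
  dy <- diff(gy)
  s <- sign(dy[abs(dy) > 1e-10])
  flips <- sum(diff(s) != 0)
  amp <- 0
  if (flips > 0) {
    interior <- gy[2:(n - 1)]
    amp <- max(abs(c(max(interior) - max(gy[c(1, n)]),
                     min(gy[c(1, n)]) - min(interior))))
  }
  list(flips = flips, amplitude = amp)
}

#' Fit and classify one trans gene's dose response to one cis gene
#'
#' Runs the linear and sigmoid fits, computes AICs and
#' `delta_aic = aic_linear - aic_sigmoid` (positive favours the sigmoid),
#' cross-validates the sigmoid fit, applies the non-monotonicity rule, and
#' classifies the response:
#' * `unresponsive` — no guide test on this gene significant at
#'   `unresponsive_fdr` (BH within the pair's own guide tests) AND no
#'   dose-effect evidence: the AIC-selected model's response span over the
#'   observed dosage window (`effective_range`: the linear fit's
#'   `|slope| * range(x)` when `delta_aic <= daic_threshold`, the sigmoid's
#'   `d - c` otherwise) is below `range_min`, or the linear slope is
#'   statistically indistinguishable from zero (p > 0.05);
#' * `nonmonotonic` — the loess leave-one-out error beats the sigmoid's by
#'   more than 5% and the loess curve has an internal extremum with
#'   amplitude above twice the sigmoid residual SD;
#' * `nonlinear` — `delta_aic > daic_threshold` (default 2; the enrichment
#'   analyses also use 0);
#' * `linear` otherwise.
#'
#' @param x,y Dosages and trans log2FCs across guides.
#' @param w Optional weights.
#' @param min_q Smallest within-pair BH-adjusted q-value over this gene's
#'   guide tests (`NA` to skip the significance arm of the unresponsive
#'   rule).
#' @param daic_threshold ΔAIC cutoff for `nonlinear` (default 2).
#' @param range_min Minimum dynamic range (log2 units) to count as
#'   responsive (default 0.1).
#' @param unresponsive_fdr FDR level of the significance arm (default 0.05).
#' @param span Loess span.
#' @param folds,n_starts,seed Fitting/CV controls.
#' @param check_nonmono Set `FALSE` to skip the (costlier) non-monotonicity
#'   rule.
#' @return A `dose_fit` list: params, rss/aic per model, `delta_aic`,
#'   `cv_r`, `dynamic_range`, `response_class`, `slope_at_inflection`,
#'   fitted functions, and bookkeeping (`n_points`, `x_range`).
#' @export
fit_dose_response <- function(x, y, w = NULL, min_q = NA_real_,
                              daic_threshold = 2, range_min = 0.1,
                              unresponsive_fdr = 0.05, span = 0.75,
                              folds = 10L, n_starts = 10L, seed = 1L,
                              check_nonmono = TRUE) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!is.null(w)) w <- w[ok]
  if (length(x) < 6) {
    return(structure(list(response_class = NA_character_,
                          reason = "too_few_points", n_points = length(x)),
                     class = "dose_fit"))
  }
  lin <- fit_linear(x, y, w)
  sig <- fit_sigmoid(x, y, w, n_starts = n_starts, seed = seed)
  n <- length(x)
  aic_linear <- compute_aic(lin$rss, n, 3)
  aic_sigmoid <- compute_aic(sig$rss, n, 5)
  delta_aic <- aic_linear - aic_sigmoid
  cv <- crossvalidate(x, y, "sigmoid", folds = folds, seed = seed,
                      n_starts = n_starts)
  dynamic_range <- sig$params$d - sig$params$c

  nonmono <- FALSE
  lo <- NULL
  if (check_nonmono && length(x) >= 8) {
    lo <- tryCatch(fit_loess(x, y, span = span), error = function(e) NULL)
    if (!is.null(lo)) {
      turn <- .curve_turning(lo$fitted_fun, range(x))
      resid_sd <- sqrt(sig$rss / max(n - 4, 1))
      if (turn$flips >= 1 && turn$amplitude > 2 * resid_sd) {
        mse_sig <- .loo_mse(x, y, function(xt, yt) {
          fit_sigmoid(xt, yt, n_starts = max(3L, n_starts %/% 3L),
                      seed = seed)$fitted_fun
        })
        mse_lo <- .loo_mse(x, y, function(xt, yt) {
          fit_loess(xt, yt, span = span)$fitted_fun
        })
        nonmono <- is.finite(mse_lo) && is.finite(mse_sig) &&
          mse_lo < 0.95 * mse_sig
      }
    }
  }

  significant <- if (is.na(min_q)) TRUE else min_q <= unresponsive_fdr
  ## response span of the AIC-selected model over the observed window: the
  ## sigmoid's asymptote difference overstates the range when the linear
  ## model is the better description
  effective_range <- if (delta_aic > daic_threshold) dynamic_range
                     else abs(lin$slope) * diff(range(x))
  ## no dose-effect evidence: small span, or a span carried by a slope that
  ## is statistically indistinguishable from zero
  no_effect <- effective_range < range_min ||
    (is.finite(lin$slope_p) && lin$slope_p > 0.05)
  response_class <-
    if (!significant && no_effect) "unresponsive"
    else if (nonmono) "nonmonotonic"
    else if (delta_aic > daic_threshold) "nonlinear"
    else "linear"

  structure(list(
    params = sig$params,
    linear = list(intercept = lin$intercept, slope = lin$slope),
    rss_linear = lin$rss, rss_sigmoid = sig$rss,
    aic_linear = aic_linear, aic_sigmoid = aic_sigmoid,
    delta_aic = delta_aic, cv_r = cv$cv_r,
    dynamic_range = dynamic_range,
    effective_range = effective_range,
    slope_at_inflection = sig$slope_at_inflection,
    response_class = response_class,
    converged = sig$converged,
    loess = lo,
    sigmoid_fun = sig$fitted_fun,
    linear_fun = lin$fitted_fun,
    n_points = n, x_range = range(x),
    reason = NA_character_), class = "dose_fit")
}

#' Fit dose responses for every (cis gene, trans gene) pair
#'
#' Builds, for each cis gene, the per-guide dose-response data: x = the
#' guide's estimated log2FC on the cis gene, y = its log2FC on the trans
#' gene, over all guides targeting that cis gene plus the NTC guides as
#' anchors near zero dosage; then runs [fit_dose_response()] per trans gene.
#'
#' @param fc_table [fold_change_table()] output.
#' @param guide_library Guide table.
#' @param cis_genes Cis genes to analyse.
#' @param trans_genes Trans genes to analyse.
#' @param restrict_one_copy If `TRUE`, fits are restricted to the one-copy
#'   window via [restrict_copy_range()].
#' @param weights_from_se Use inverse squared SEs as weights.
#' @param ... Passed to [fit_dose_response()].
#' @return data.frame (one row per pair) with the fit summaries, plus the
#'   full `dose_fit` objects in `attr(, "fits")` keyed `"cis|trans"`.
#' @export
fit_dose_responses <- function(fc_table, guide_library, cis_genes,
                               trans_genes, restrict_one_copy = FALSE,
                               weights_from_se = FALSE, ...) {
  fits <- list()
  rows <- list()
  for (cg in cis_genes) {
    lib <- guide_library
    use_guides <- lib$guide_id[(!is.na(lib$target_gene) & lib$target_gene == cg) |
                                 lib$guide_class == "NTC"]
    sub <- fc_table[fc_table$guide_id %in% use_guides & !is.na(fc_table$log2fc), ]
    cis_fc <- sub[sub$gene_id == cg, c("guide_id", "line", "log2fc")]
    names(cis_fc)[3] <- "x"
    for (tg in trans_genes) {
      tr <- sub[sub$gene_id == tg,
                c("guide_id", "line", "log2fc", "se", "p_value")]
      m <- merge(cis_fc, tr, by = c("guide_id", "line"))
      x <- m$x; y <- m$log2fc
      if (restrict_one_copy) {
        r <- restrict_copy_range(x, y)
        keep <- r$kept
      } else keep <- rep(TRUE, length(x))
      w <- if (weights_from_se) 1 / pmax(m$se, 1e-3)^2 else NULL
      ## pair-level significance: BH within this pair's own guide tests
      pv <- m$p_value[!is.na(m$p_value)]
      min_q <- if (length(pv)) min(adjust_fdr(pv)) else NA_real_
      f <- if (sum(keep) >= 6) {
        fit_dose_response(x[keep], y[keep], w = if (is.null(w)) NULL else w[keep],
                          min_q = min_q, ...)
      } else {
        structure(list(response_class = NA_character_,
                       reason = "too_few_points_after_restriction",
                       n_points = sum(keep)), class = "dose_fit")
      }
      fits[[paste(cg, tg, sep = "|")]] <- f
      rows[[length(rows) + 1L]] <- data.frame(
        cis_gene = cg, trans_gene = tg,
        a = f$params$a %||% NA_real_, b = f$params$b %||% NA_real_,
        c = f$params$c %||% NA_real_, d = f$params$d %||% NA_real_,
        slope_at_inflection = f$slope_at_inflection %||% NA_real_,
        rss_linear = f$rss_linear %||% NA_real_,
        rss_sigmoid = f$rss_sigmoid %||% NA_real_,
        aic_linear = f$aic_linear %||% NA_real_,
        aic_sigmoid = f$aic_sigmoid %||% NA_real_,
        delta_aic = f$delta_aic %||% NA_real_,
        cv_r = f$cv_r %||% NA_real_,
        dynamic_range = f$dynamic_range %||% NA_real_,
        effective_range = f$effective_range %||% NA_real_,
        response_class = f$response_class %||% NA_character_,
        n_points = f$n_points %||% NA_integer_,
        reason = f$reason %||% NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Predict trans responses on a uniform cis-dosage grid
#'
#' Evaluates each pair's selected model on a shared dosage grid (default 100
#' points on `[-1.83, 0.51]` log2FC, the empirically observed range of the
#' titration): sigmoid/linear fits analytically, non-monotonic genes via the
#' clamped loess. An `extrapolated` mask marks grid points outside the cis
#' gene's own observed dosage range.
#'
#' @param dosefits Result of [fit_dose_responses()] (with its `fits`
#'   attribute).
#' @param grid_min,grid_max,grid_n Grid specification.
#' @return A `response_grid` list: `grid` (dosage values), `predictions`
#'   (matrix pairs x grid), `extrapolated` (same shape), `pairs`
#'   (data.frame cis_gene/trans_gene/response_class).
#' @export
predict_grid <- function(dosefits, grid_min = -1.83, grid_max = 0.51,
                         grid_n = 100L) {
  grid <- seq(grid_min, grid_max, length.out = grid_n)
  fits <- attr(dosefits, "fits")
  keep <- !is.na(dosefits$response_class)
  pairs <- dosefits[keep, c("cis_gene", "trans_gene", "response_class")]
  pred <- matrix(NA_real_, nrow = nrow(pairs), ncol = grid_n)
  extra <- matrix(FALSE, nrow = nrow(pairs), ncol = grid_n)
  for (i in seq_len(nrow(pairs))) {
    key <- paste(pairs$cis_gene[i], pairs$trans_gene[i], sep = "|")
    f <- fits[[key]]
    fun <- if (identical(f$response_class, "nonmonotonic") && !is.null(f$loess))
      f$loess$fitted_fun else f$sigmoid_fun
    pred[i, ] <- fun(grid)
    extra[i, ] <- grid < f$x_range[1] | grid > f$x_range[2]
  }
  rn <- paste(pairs$cis_gene, pairs$trans_gene, sep = "|")
  dimnames(pred) <- list(rn, NULL)
  dimnames(extra) <- list(rn, NULL)
  structure(list(grid = grid, predictions = pred, extrapolated = extra,
                 pairs = pairs), class = "response_grid")
}
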