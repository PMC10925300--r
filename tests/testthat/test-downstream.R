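## minimal response_grid construction for clustering tests
toy_grid <- function(curves_by_cis, grid_n = 50) {
  ## curves_by_cis: list cis -> matrix trans x grid_n
  pairs <- do.call(rbind, lapply(names(curves_by_cis), function(cg) {
    data.frame(cis_gene = cg, trans_gene = rownames(curves_by_cis[[cg]]),
               response_class = "linear")
  }))
  pred <- do.call(rbind, lapply(curves_by_cis, identity))
  rownames(pred) <- paste(pairs$cis_gene, pairs$trans_gene, sep = "|")
  structure(list(grid = seq(-1.83, 0.51, length.out = grid_n),
                 predictions = pred,
                 extrapolated = matrix(FALSE, nrow(pred), grid_n),
                 pairs = pairs), class = "response_grid")
}

test_that("identical curves land in the same cluster and order does not matter", {
  g <- seq(-1.83, 0.51, length.out = 50)
  base <- rbind(A1 = g, A2 = g, B1 = -g, B2 = -g, C1 = g * 0, C2 = g * 0)
  grid <- toy_grid(list(CIS = base))
  cl <- cluster_responses(grid, k = 3)
  expect_equal(cl$clusters[["A1"]], cl$clusters[["A2"]])
  expect_equal(cl$clusters[["B1"]], cl$clusters[["B2"]])
  expect_equal(cl$clusters[["C1"]], cl$clusters[["C2"]])
  expect_equal(length(unique(cl$clusters)), 3)
  ## permutation invariance of the induced partition
  perm <- sample(nrow(base))
  grid2 <- toy_grid(list(CIS = base[perm, ]))
  cl2 <- cluster_responses(grid2, k = 3)
  same1 <- outer(cl$clusters[rownames(base)], cl$clusters[rownames(base)], "==")
  same2 <- outer(cl2$clusters[rownames(base)], cl2$clusters[rownames(base)], "==")
  expect_equal(same1, same2)
})

test_that("planted archetypes are recovered with high adjusted Rand index", {
  skip_if_not_installed("mclust")
  set.seed(55)
  g <- seq(-1.83, 0.51, length.out = 50)
  n_per <- 15
  curves <- list()
  truth <- c()
  for (i in seq_len(3 * n_per)) {
    arch <- c("up", "down", "flat")[ceiling(i / n_per)]
    base <- switch(arch, up = 0.8 * g, down = -0.8 * g, flat = 0 * g)
    curves[[sprintf("T%02d", i)]] <- base + rnorm(50, 0, 0.05)
    truth[sprintf("T%02d", i)] <- arch
  }
  grid <- toy_grid(list(CIS = do.call(rbind, curves)))
  cl <- cluster_responses(grid, k = 3)
  ari <- mclust::adjustedRandIndex(cl$clusters, truth[names(cl$clusters)])
  expect_gte(ari, 0.9)
})

test_that("genes with a missing curve are excluded with reason", {
  g <- seq(-1.83, 0.51, length.out = 50)
  grid <- toy_grid(list(C1 = rbind(A = g, B = -g, C = 0 * g),
                        C2 = rbind(A = g, B = -g)))  # C missing for C2
  cl <- cluster_responses(grid, k = 2)
  expect_equal(cl$excluded, "C")
  expect_false("C" %in% names(cl$clusters))
})

test_that("parameter-metric correlations behave at the identity and the null", {
  df <- data.frame(cis_gene = "CIS", trans_gene = sprintf("T%d", 1:40),
                   a = rnorm(40), b = rnorm(40), c = rnorm(40), d = rnorm(40),
                   dynamic_range = runif(40, 0, 2))
  ann <- data.frame(gene_id = df$trans_gene,
                    self = df$dynamic_range,
                    noise = rnorm(40),
                    const = 1)
  res <- correlate_parameters(df, ann)
  self_row <- res[res$parameter == "dynamic_range" & res$metric == "self", ]
  expect_equal(self_row$r, 1, tolerance = 1e-12)
  ## zero-variance metric is reported missing with reason
  const_rows <- res[res$metric == "const", ]
  expect_true(all(is.na(const_rows$r)))
  expect_true(all(const_rows$reason == "zero_variance"))
  ## independent metrics: small correlations
  noise_rows <- res[res$metric == "noise", ]
  expect_lt(median(abs(noise_rows$r)), 0.25)
})

test_that("group comparisons detect planted shifts and pass the identity null", {
  set.seed(77)
  base <- rnorm(80)
  df <- data.frame(cis_gene = "CIS", trans_gene = sprintf("T%d", 1:80),
                   a = 0, b = 0, c = 0, d = 0,
                   dynamic_range = base + rep(c(1, 0), each = 40))
  ann <- data.frame(gene_id = df$trans_gene,
                    flagged = rep(c(TRUE, FALSE), each = 40),
                    balanced = rep(c(TRUE, FALSE), 40))
  res <- compare_groups(df, ann, parameters = "dynamic_range")
  expect_lt(res$p_value[res$flag == "flagged"], 0.05)
  expect_gt(res$p_value[res$flag == "balanced"], 0.05)
  ## identical groups: p = 1
  df2 <- df; df2$dynamic_range <- 1
  res2 <- compare_groups(df2, ann, parameters = "dynamic_range")
  expect_equal(res2$p_value, c(1, 1))
})

test_that("planted dynamic-range shifts reach significance in most replicates", {
  set.seed(79)
  hits <- replicate(25, {
    vals <- c(rnorm(40, 1, 1), rnorm(40, 0, 1))
    df <- data.frame(cis_gene = "CIS", trans_gene = sprintf("T%d", 1:80),
                     a = 0, b = 0, c = 0, d = 0, dynamic_range = vals)
    ann <- data.frame(gene_id = df$trans_gene,
                      flagged = rep(c(TRUE, FALSE), each = 40))
    compare_groups(df, ann, parameters = "dynamic_range")$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("Fisher enrichment matches the exhaustive hypergeometric oracle", {
  ## balanced table: OR 1, p 1
  df <- data.frame(cis_gene = "CIS", trans_gene = sprintf("T%d", 1:40),
                   delta_aic = rep(c(3, -1), each = 20),
                   response_class = "linear")
  sets <- list(S = sprintf("T%d", c(1:10, 21:30)))
  res <- enrich_nonlinear(df, sets, daic_cut = 0)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_value, 1)
  expect_equal(unlist(res[, c("n11", "n12", "n21", "n22")], use.names = FALSE),
               c(10, 10, 10, 10))
  ## planted enrichment: OR 16 with brute-force hypergeometric p
  df2 <- data.frame(cis_gene = "CIS", trans_gene = sprintf("T%d", 1:50),
                    delta_aic = c(rep(3, 25), rep(-1, 25)),
                    response_class = "linear")
  sets2 <- list(S = sprintf("T%d", c(1:20, 26:30)))
  res2 <- enrich_nonlinear(df2, sets2, daic_cut = 0)
  expect_equal(res2$odds_ratio, (20 * 20) / (5 * 5))
  tab <- matrix(c(20, 5, 5, 20), 2, byrow = TRUE)
  expect_equal(res2$p_value, fisher_brute(tab), tolerance = 1e-9)
  ## the unresponsive x set variant uses response_class as the row variable
  df3 <- df2
  df3$response_class <- c(rep("unresponsive", 25), rep("linear", 25))
  res3 <- enrich_nonlinear(df3, sets2, row_variable = "unresponsive")
  expect_equal(res3$n11, 20)
})

test_that("degenerate enrichment margins get the Haldane correction", {
  df <- data.frame(cis_gene = "CIS", trans_gene = sprintf("T%d", 1:20),
                   delta_aic = rep(3, 20), response_class = "linear")
  res <- enrich_nonlinear(df, list(S = sprintf("T%d", 1:5)), daic_cut = 0)
  expect_true(res$haldane)
  expect_true(is.finite(res$odds_ratio))
})

test_that("cell-type correlations recover a self profile and planted gradients", {
  set.seed(91)
  genes <- sprintf("T%d", 1:30)
  fc <- expand.grid(guide_id = sprintf("g%d", 1:6), gene_id = genes,
                    stringsAsFactors = FALSE)
  fc$line <- "CRISPRi"
  dos <- seq(-1.5, 0.5, length.out = 6)
  load <- rnorm(30)
  ## per-guide FC = gene loading x dosage + noise, so the correlation with a
  ## loading-proportional profile strengthens monotonically with |dosage|
  resp <- outer(load, dos) + matrix(rnorm(30 * 6, 0, 0.5), 30)
  fc$log2fc <- resp[cbind(match(fc$gene_id, genes),
                          match(fc$guide_id, sprintf("g%d", 1:6)))]
  prof <- cbind(mature = load, other = rnorm(30))
  rownames(prof) <- genes
  res <- celltype_correlation(fc, prof, genes, already_scaled = TRUE)
  r_mature <- res$r[paste0(sprintf("g%d", 1:6), "|CRISPRi"), "mature"]
  ## correlation tracks the dosage gradient monotonically
  expect_gt(abs(cor(r_mature, dos, method = "spearman")), 0.9)
  expect_equal(unname(which.max(abs(r_mature))), 1L)
  expect_error(celltype_correlation(fc, prof[1:5, , drop = FALSE], genes),
               "overlap")
})

test_that("null cell-type correlations are significant at about the nominal FDR", {
  set.seed(93)
  genes <- sprintf("T%d", 1:40)
  hits <- replicate(40, {
    fc <- expand.grid(guide_id = sprintf("g%d", 1:5), gene_id = genes,
                      stringsAsFactors = FALSE)
    fc$line <- "CRISPRi"
    fc$log2fc <- rnorm(nrow(fc))
    prof <- matrix(rnorm(40 * 4), 40, dimnames = list(genes, letters[1:4]))
    res <- celltype_correlation(fc, prof, genes)
    mean(res$q <= 0.10, na.rm = TRUE)
  })
  expect_lte(mean(hits), 0.10)
})

test_that("PCA diagnostics satisfy variance conservation and find planted factors", {
  set.seed(95)
  genes <- sprintf("T%d", 1:30)
  dos <- seq(-1.8, 0.6, length.out = 12)
  load <- rnorm(30)
  fc <- expand.grid(guide_id = sprintf("g%02d", 1:12), gene_id = genes,
                    stringsAsFactors = FALSE)
  fc$line <- "CRISPRi"
  fc$log2fc <- load[match(fc$gene_id, genes)] *
    dos[match(fc$guide_id, sprintf("g%02d", 1:12))]
  res <- pca_foldchanges(fc, genes)
  expect_gt(res$var_explained[1], 0.99)  # rank-1 structure
  expect_equal(sum(res$var_explained), 1, tolerance = 1e-12)
  pc1 <- res$scores[paste0(sprintf("g%02d", 1:12), "|CRISPRi"), 1]
  expect_gt(abs(cor(pc1, dos)), 0.9)
  ## noisy variant still satisfies conservation
  fc$log2fc <- fc$log2fc + rnorm(nrow(fc), 0, 0.1)
  res2 <- pca_foldchanges(fc, genes)
  expect_equal(sum(res2$var_explained), 1, tolerance = 1e-12)
})
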