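test_that("normalisation scales to median depth and preserves zeros and composition", {
  set.seed(2)
  mat <- matrix(rpois(100 * 20, 5), nrow = 100,
                dimnames = list(sprintf("g%d", 1:100), sprintf("c%d", 1:20)))
  assay <- counts_assay(mat, rownames(mat), colnames(mat), "cdna")
  norm <- normalize_cells(assay)
  ## brute-force recomputation of the median-depth property
  tot <- colSums(mat)
  med <- median(tot)
  expect_equal(norm, sweep(mat, 2, med / tot, "*"), tolerance = 1e-12)
  expect_true(all((norm == 0) == (mat == 0)))
  ## doubling one cell's counts leaves its normalised composition unchanged
  mat2 <- mat; mat2[, 3] <- mat2[, 3] * 2L
  norm2 <- normalize_cells(counts_assay(mat2, rownames(mat), colnames(mat), "cdna"))
  expect_equal(norm2[, 3] / sum(norm2[, 3]), norm[, 3] / sum(norm[, 3]),
               tolerance = 1e-12)
  ## equal depths: identity up to one global constant
  mat3 <- matrix(3L, nrow = 4, ncol = 5,
                 dimnames = list(sprintf("g%d", 1:4), sprintf("c%d", 1:5)))
  norm3 <- normalize_cells(counts_assay(mat3, rownames(mat3), colnames(mat3), "cdna"))
  expect_equal(unique(as.vector(norm3 / mat3)), 1)
})

test_that("zero-depth cells are excluded with a warning", {
  mat <- cbind(c(1, 2), c(0, 0))
  assay <- counts_assay(mat, c("g1", "g2"), c("c1", "c2"), "cdna")
  expect_warning(norm <- normalize_cells(assay), "zero-depth")
  expect_equal(ncol(norm), 1)
})

test_that("NTC self-comparison gives near-zero fold change and truth is recovered", {
  ## moderate-noise regime: this checks estimator bias, not sampling noise
  cfg <- small_sim_config(n_cells_per_guide = 200, seed = 23,
                          dispersion = 100, dropout_logit_scale = 0)
  d <- simulate_experiment(cfg)
  fc <- fold_change_table(d$cdna, truth_annotation(d), d$guide_library,
                          compute_se = FALSE)
  ## NTC guides against the pooled NTC reference: |log2FC| < 0.05 on the cis gene
  ntc <- fc[fc$guide_id %in% sprintf("NTC_%d", 1:3) & fc$gene_id == "CIS_A", ]
  expect_true(all(abs(ntc$log2fc) < 0.05))
  ## a guide with true cis effect -1.0ish estimated within 0.1
  lib <- d$guide_library
  tgt <- lib[!is.na(lib$target_gene), ]
  for (i in seq_len(nrow(tgt))) {
    est <- fc$log2fc[fc$guide_id == tgt$guide_id[i] & fc$gene_id == "CIS_A"]
    expect_lt(abs(est - tgt$cis_log2fc[i]), 0.12)
  }
})

test_that("pseudo-bulk estimator is invariant to per-cell depth rescaling", {
  set.seed(4)
  mat <- matrix(rpois(30 * 60, 8), nrow = 30,
                dimnames = list(sprintf("g%d", 1:30), sprintf("c%d", 1:60)))
  grp <- sprintf("c%d", 1:25); ref <- sprintf("c%d", 26:60)
  r1 <- pseudobulk_log2fc(mat, grp, ref, "g5", n_boot = 10, seed = 1)
  ## rescale each cell's counts by an integer factor (keeps counts integral)
  fac <- sample(1:5, 60, replace = TRUE)
  mat2 <- sweep(mat, 2, fac, "*")
  r2 <- pseudobulk_log2fc(mat2, grp, ref, "g5", n_boot = 10, seed = 1)
  ## fractions change only via the pooled totals; estimator stays close
  expect_lt(abs(r1$log2fc - r2$log2fc), 0.15)
  ## groups below min_cells produce a reason, not a number
  r3 <- pseudobulk_log2fc(mat, grp[1:3], ref, "g5")
  expect_true(is.na(r3$log2fc))
  expect_equal(r3$reason, "too_few_cells")
})

test_that("bootstrap SE shrinks roughly as 1/sqrt(n_cells)", {
  set.seed(6)
  n_big <- 800
  n_ref <- 4000  # large reference so the group term dominates the SE
  mat <- matrix(rpois(20 * (n_big + n_ref), 10), nrow = 20)
  dimnames(mat) <- list(sprintf("g%d", 1:20), sprintf("c%d", seq_len(ncol(mat))))
  ref <- sprintf("c%d", (n_big + 1):(n_big + n_ref))
  se_at <- function(n) {
    pseudobulk_log2fc(mat, sprintf("c%d", 1:n), ref, "g3",
                      n_boot = 400, seed = 9)$se
  }
  se50 <- se_at(50); se200 <- se_at(200); se800 <- se_at(800)
  ## reference group fixed, so ratios track sqrt(4) = 2 within 25%
  expect_lt(abs(se50 / se200 - 2), 0.5)
  expect_lt(abs(se200 / se800 - 2), 0.5)
})

test_that("Wilcoxon test handles degenerate and ordinary inputs", {
  expect_equal(test_perturbation_significance(rep(1, 10), rep(1, 12)), 1)
  set.seed(3)
  p <- test_perturbation_significance(rnorm(50, 2), rnorm(50, 0))
  expect_lt(p, 1e-6)
})

test_that("BH adjustment matches the hand computation and brute force", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_fdr(p), rep(0.04, 4))
  set.seed(12)
  for (n in c(1, 7, 40, 100)) {
    pv <- runif(n)^1.5
    expect_equal(adjust_fdr(pv), bh_brute(pv), tolerance = 1e-12)
  }
  ## q >= p and monotone in p-rank
  pv <- runif(60)
  q <- adjust_fdr(pv)
  expect_true(all(q >= pv))
  expect_true(all(diff(q[order(pv)]) >= -1e-12))
})

test_that("direction concordance counts sign agreement among significant cis tests", {
  ## constructed table: 50 significant guides, one sign-flipped
  fc <- data.frame(guide_id = sprintf("g%d", 1:50), gene_id = "CIS",
                   line = rep(c("CRISPRi", "CRISPRa"), 25),
                   log2fc = rep(c(-1, 1), 25), family = "cis",
                   q_value = 0.001)
  lib <- data.frame(guide_id = fc$guide_id, target_gene = "CIS",
                    guide_class = "TSS", effector = fc$line)
  expect_equal(direction_concordance(fc, lib)$concordance, 1.0)
  fc$log2fc[1] <- 1  # CRISPRi guide with a positive fold change
  expect_equal(direction_concordance(fc, lib)$concordance, 0.98)
  fc$q_value <- 0.5
  expect_true(is.na(direction_concordance(fc, lib)$concordance))
})

test_that("on/off split yields concordant trans effects under graded truth", {
  cfg <- small_sim_config(n_cells_per_guide = 400, seed = 29)
  d <- simulate_experiment(cfg)
  ann <- truth_annotation(d)
  trans <- d$gene_table$gene_id[d$gene_table$role == "trans"]
  ## strongest knock-down guide: many cis-zero cells
  res <- onoff_split_check(d$cdna, ann, d$guide_library, "gA01", "CIS_A",
                           trans, min_cells = 10)
  expect_true(is.na(res$reason))
  expect_gte(res$correlation, 0.8)
})

test_that("on/off split flags the adversarial binary-effect simulation", {
  cfg <- small_sim_config(n_cells_per_guide = 250, seed = 33,
                          onoff_mode = TRUE)
  d <- simulate_experiment(cfg)
  ann <- truth_annotation(d)
  trans <- d$gene_table$gene_id[d$gene_table$role == "trans"]
  res <- onoff_split_check(d$cdna, ann, d$guide_library, "gA03", "CIS_A",
                           trans, min_cells = 10)
  ## trans effects live only in the silenced subset: concordance collapses
  expect_lt(res$correlation, 0.5)
})

test_that("mean absolute trans response tracks cis dosage magnitude", {
  cfg <- small_sim_config(n_cells_per_guide = 120, seed = 37)
  d <- simulate_experiment(cfg)
  fc <- fold_change_table(d$cdna, truth_annotation(d), d$guide_library,
                          compute_se = FALSE)
  trans <- d$gene_table$gene_id[d$gene_table$role == "trans"]
  mar <- mean_abs_trans_response(fc, d$guide_library, "CIS_A", trans)
  ## NTC anchors present near zero dosage
  expect_true(any(grepl("NTC", mar$guide_id)))
  expect_true(all(abs(mar$cis_log2fc[grepl("NTC", mar$guide_id)]) < 0.15))
  ## monotone truth: |cis fc| and mean |trans fc| positively associated
  expect_gt(cor(abs(mar$cis_log2fc), mar$mean_abs_trans_fc,
                method = "spearman"), 0)
})
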