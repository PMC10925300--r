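## Small in-code fixtures shared across tests.

## compact screen: a few guides per cis gene, small trans panel
small_sim_config <- function(n_cells_per_guide = 40, seed = 42,
                             n_trans = 12, ...) {
  guides <- rbind(
    data.frame(guide_id = sprintf("gA%02d", 1:6), target_gene = "CIS_A",
               guide_class = "tiling",
               tss_offset_bp = seq(-500L, 500L, length.out = 6),
               cis_log2fc = seq(-1.8, -0.3, length.out = 6),
               effector = "CRISPRi"),
    data.frame(guide_id = sprintf("gB%02d", 1:4), target_gene = "CIS_A",
               guide_class = "tiling",
               tss_offset_bp = seq(-400L, 400L, length.out = 4),
               cis_log2fc = seq(0.2, 0.8, length.out = 4),
               effector = "CRISPRa"),
    data.frame(guide_id = sprintf("NTC_%d", 1:3), target_gene = NA_character_,
               guide_class = "NTC", tss_offset_bp = NA_integer_,
               cis_log2fc = 0, effector = NA_character_))
  trans_ids <- sprintf("T%02d", seq_len(n_trans))
  genes <- rbind(
    data.frame(gene_id = "CIS_A", role = "cis", baseline_mean = 60),
    data.frame(gene_id = trans_ids, role = "trans",
               baseline_mean = seq(10, 60, length.out = n_trans)),
    data.frame(gene_id = "CTRL_HIGH", role = "control_high",
               baseline_mean = 300),
    data.frame(gene_id = c("EFF_KRAB", "EFF_VPR"), role = "effector_transcript",
               baseline_mean = 8))
  genes$effector_line <- c(NA, rep(NA, n_trans), NA, "CRISPRi", "CRISPRa")
  genes$tss_pos <- c(50000L, rep(NA_integer_, n_trans + 3))
  genes$chrom <- c("chrS", rep(NA_character_, n_trans + 3))
  ## balanced responders like the real panel: a quarter follow the cis gene
  ## down, a quarter mirror it up, the rest stay flat
  responses <- list()
  for (i in seq_len(n_trans %/% 4)) {
    responses[[trans_ids[i]]] <- list(
      CIS_A = response_truth("sigmoid", a = -0.5, b = 3, c = -1, d = 0.4))
  }
  for (i in seq(n_trans %/% 4 + 1, n_trans %/% 2)) {
    responses[[trans_ids[i]]] <- list(
      CIS_A = response_truth("sigmoid", a = -0.4, b = -3, c = -0.4, d = 0.8))
  }
  sim_config(guides = guides, genes = genes, responses = responses,
             n_cells_per_guide = n_cells_per_guide, seed = seed, ...)
}

## all-flat null configuration: no guide has any effect
flat_sim_config <- function(n_cells_per_guide = 200, seed = 7,
                            n_guides = 24, n_trans = 40, ...) {
  n_tgt <- n_guides - 5
  guides <- rbind(
    data.frame(guide_id = sprintf("g%02d", seq_len(n_tgt)),
               target_gene = "CIS_A", guide_class = "tiling",
               tss_offset_bp = seq(-900L, 900L, length.out = n_tgt),
               cis_log2fc = 0,
               effector = rep(c("CRISPRi", "CRISPRa"), length.out = n_tgt)),
    data.frame(guide_id = sprintf("NTC_%d", 1:5), target_gene = NA_character_,
               guide_class = "NTC", tss_offset_bp = NA_integer_,
               cis_log2fc = 0, effector = NA_character_))
  trans_ids <- sprintf("T%02d", seq_len(n_trans))
  genes <- rbind(
    data.frame(gene_id = "CIS_A", role = "cis", baseline_mean = 50),
    data.frame(gene_id = trans_ids, role = "trans",
               baseline_mean = exp(seq(log(5), log(70), length.out = n_trans))),
    data.frame(gene_id = c("EFF_KRAB", "EFF_VPR"), role = "effector_transcript",
               baseline_mean = 8))
  genes$effector_line <- c(NA, rep(NA, n_trans), "CRISPRi", "CRISPRa")
  sim_config(guides = guides, genes = genes, responses = list(),
             n_cells_per_guide = n_cells_per_guide, seed = seed, ...)
}

## annotation straight from simulation truth (bypasses demux/assignment)
truth_annotation <- function(dataset) {
  tc <- dataset$truth$cells
  data.frame(barcode = tc$barcode, line = tc$line,
             assigned_guide = tc$guide_id, n_guides_positive = 1L,
             qc_pass = TRUE, stringsAsFactors = FALSE)
}

## independent brute-force BH, straight from the step-up definition
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- rep(NA_real_, n)
  prev <- 1
  for (i in seq(n, 1)) {
    val <- min(p[o[i]] * n / i, prev)
    q[o[i]] <- val
    prev <- val
  }
  q
}

## exhaustive hypergeometric two-sided Fisher p for a 2x2 table
fisher_brute <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) {
    exp(lchoose(c1, a) + lchoose(n - c1, r1 - a) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
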