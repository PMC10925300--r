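## Pseudo-bulk fold-change estimation against matched non-targeting
## controls, per-cell normalisation, significance testing and the
## robustness checks used on the cis estimates.

#' Normalise per-cell expression
#'
#' Two per-cell scalings are provided, both keeping zeros at exactly zero:
#' * `"depth"` (the default) scales each cell's counts to the median total
#'   panel depth — the conventional library-size normalisation;
#' * `"median_ratio"` divides each cell by a DESeq-style size factor, the
#'   median across well-expressed genes of the cell's count over that gene's
#'   mean — robust to composition: on a small targeted panel, strong
#'   perturbations change the panel total itself, which total-depth scaling
#'   folds back into every unchanged gene.
#'
#' @param cdna [counts_assay()] of gene counts.
#' @param method `"depth"` or `"median_ratio"`.
#' @param min_ref For `"median_ratio"`: genes with mean count below this are
#'   not used for the size factor (default 5).
#' @return A dense matrix (genes x cells) of normalised expression. Cells
#'   with zero total counts are dropped with a warning.
#' @export
normalize_cells <- function(cdna, method = c("depth", "median_ratio"),
                            min_ref = 5) {
  stopifnot(inherits(cdna, "counts_assay"))
  method <- match.arg(method)
  tot <- Matrix::colSums(cdna$counts)
  keep <- tot > 0
  if (any(!keep)) {
    warning(sum(!keep), " zero-depth cell(s) excluded from normalisation")
  }
  m <- cdna$counts[, keep, drop = FALSE]
  if (method == "depth") {
    sf <- tot[keep] / stats::median(tot[keep])
  } else {
    ref <- Matrix::rowMeans(m)
    use <- which(ref >= min_ref)
    if (length(use) < 3) use <- order(ref, decreasing = TRUE)[seq_len(min(3, nrow(m)))]
    ratios <- as.matrix(m[use, , drop = FALSE]) / ref[use]
    sf <- apply(ratios, 2, stats::median)
    ## degenerate cells (median ratio 0): fall back to depth scaling
    zero_sf <- sf <= 0
    if (any(zero_sf)) sf[zero_sf] <- tot[keep][zero_sf] / stats::median(tot[keep])
    sf <- sf / stats::median(sf)
  }
  out <- as.matrix(m %*% Matrix::Diagonal(x = 1 / sf, names = FALSE))
  dimnames(out) <- list(rownames(m), colnames(m))
  out
}

## count fraction of one gene over the panel total within a cell group,
## with a pseudocount in UMI-equivalents
.group_fraction <- function(gene_sums, total_sums, eps = 0.5) {
  (gene_sums + eps) / (total_sums + eps)
}

#' Pseudo-bulk log2 fold change of one cell group against a reference
#'
#' The estimator is the log2 ratio of within-group count fractions: gene
#' UMIs summed over the group's cells divided by total panel UMIs in those
#' cells (pseudocount `eps` UMI-equivalents), compared to the same fraction
#' in the reference (NTC) cells. Being fraction-based it is invariant to
#' per-cell depth rescaling. The standard error is a seeded nonparametric
#' bootstrap over cells of both groups.
#'
#' @param counts Sparse or dense gene x cell count matrix.
#' @param group_cells,ref_cells Column indices (or barcode names) of the
#'   guide group and the NTC reference group.
#' @param gene Gene id (row name) or row index.
#' @param eps Pseudocount, UMI-equivalents (default 0.5).
#' @param n_boot Bootstrap replicates for the SE (default 200).
#' @param min_cells Minimum cells in each group (default 10); below it the
#'   estimate is `NA` with a reason.
#' @param seed Integer seed for the bootstrap.
#' @return list(log2fc, se, n_cells, reason)
#' @export
pseudobulk_log2fc <- function(counts, group_cells, ref_cells, gene,
                              eps = 0.5, n_boot = 200L, min_cells = 10L,
                              seed = 1L) {
  if (length(group_cells) < min_cells || length(ref_cells) < min_cells) {
    return(list(log2fc = NA_real_, se = NA_real_,
                n_cells = length(group_cells), reason = "too_few_cells"))
  }
  g <- counts[, group_cells, drop = FALSE]
  r <- counts[, ref_cells, drop = FALSE]
  est <- log2(.group_fraction(sum(g[gene, ]), sum(g), eps) /
                .group_fraction(sum(r[gene, ]), sum(r), eps))
  gg <- as.numeric(g[gene, ]); gt <- Matrix::colSums(g)
  rg <- as.numeric(r[gene, ]); rt <- Matrix::colSums(r)
  boots <- with_local_seed(seed, vapply(seq_len(n_boot), function(b) {
    bi <- sample.int(length(gg), replace = TRUE)
    ri <- sample.int(length(rg), replace = TRUE)
    log2(.group_fraction(sum(gg[bi]), sum(gt[bi]), eps) /
           .group_fraction(sum(rg[ri]), sum(rt[ri]), eps))
  }, numeric(1)))
  list(log2fc = est, se = stats::sd(boots),
       n_cells = length(group_cells), reason = NA_character_)
}

#' Wilcoxon rank-sum test of a perturbation against the NTC reference
#'
#' Two-sided rank-sum test on per-cell normalised expression of one gene,
#' guide cells vs NTC cells of the same line. The normal approximation with
#' tie correction is used without the continuity correction: cell groups
#' here are large (tens to thousands) and on heavily tied count data the
#' continuity correction makes the null p-values visibly conservative.
#' Constant values in both groups give p = 1.
#'
#' @param group_values,ref_values Numeric vectors of per-cell normalised
#'   expression.
#' @return p-value in \[0, 1\].
#' @export
test_perturbation_significance <- function(group_values, ref_values) {
  stopifnot(length(group_values) > 0, length(ref_values) > 0)
  if (length(unique(c(group_values, ref_values))) == 1L) return(1)
  suppressWarnings(
    stats::wilcox.test(group_values, ref_values, exact = FALSE,
                       correct = FALSE)$p.value)
}

#' Per-guide pseudo-bulk fold changes for all genes vs matched NTC
#'
#' For every assigned guide group, computes the pseudo-bulk log2 fold change
#' of every panel gene against the pooled NTC cells of the same effector
#' line, with bootstrap standard errors and Wilcoxon p-values on per-cell
#' normalised expression. BH q-values are computed in two families: cis
#' tests (guides against their own target genes; judged at 10% FDR) and
#' trans tests (all other guide x gene pairs; judged at 5% FDR).
#'
#' @param cdna [counts_assay()] of gene counts.
#' @param annotation Cell annotation from [cell_annotation()] (or the truth
#'   table of a simulation): `barcode`, `line`, `assigned_guide`.
#' @param guide_library Guide table (`guide_id`, `target_gene`,
#'   `guide_class`, `effector`).
#' @param genes Optional character vector of genes to analyse (default: all
#'   assay features).
#' @param eps,n_boot,min_cells,seed See [pseudobulk_log2fc()].
#' @param compute_se Set `FALSE` to skip the bootstrap (fast paths).
#' @param norm_method Per-cell normalisation used for the Wilcoxon tests
#'   (see [normalize_cells()]); default `"median_ratio"`.
#' @param composition_correct If `TRUE` (default) the pseudo-bulk log2
#'   ratios are recentred by their median across the analysed panel
#'   (median-of-ratios correction): this removes both the depth imbalance
#'   between guide and reference pools and the compositional shift that
#'   strong perturbations of a small targeted panel induce in unchanged
#'   genes. `FALSE` gives the plain count-fraction estimator.
#' @return A `FoldChangeTable` data.frame keyed by (`guide_id`, `gene_id`,
#'   `line`): `log2fc`, `se`, `n_cells`, `p_value`, `q_value`, `family`.
#' @export
fold_change_table <- function(cdna, annotation, guide_library,
                              genes = NULL, eps = 0.5, n_boot = 200L,
                              min_cells = 10L, seed = 1L,
                              compute_se = TRUE,
                              norm_method = "median_ratio",
                              composition_correct = TRUE) {
  stopifnot(inherits(cdna, "counts_assay"))
  genes <- genes %||% feature_ids(cdna)
  ann <- annotation[!is.na(annotation$assigned_guide), , drop = FALSE]
  ann <- ann[ann$barcode %in% cdna$barcodes, , drop = FALSE]
  counts <- cdna$counts[, ann$barcode, drop = FALSE]
  norm <- normalize_cells(counts_assay(counts, rownames(counts),
                                       colnames(counts), "cdna"),
                          method = norm_method)

  ntc_ids <- guide_library$guide_id[guide_library$guide_class == "NTC"]
  tgt_of <- stats::setNames(guide_library$target_gene, guide_library$guide_id)

  rows <- list()
  with_local_seed(seed, for (line in unique(ann$line)) {
    in_line <- ann$line == line
    ref_cells <- ann$barcode[in_line & ann$assigned_guide %in% ntc_ids]
    if (length(ref_cells) == 0) next
    ref_tot <- Matrix::colSums(counts[, ref_cells, drop = FALSE])
    guides_here <- unique(ann$assigned_guide[in_line])
    ## precompute bootstrap index draws shared across genes per group
    for (gid in guides_here) {
      grp_cells <- ann$barcode[in_line & ann$assigned_guide == gid]
      ref_use <- if (gid %in% ntc_ids) setdiff(ref_cells, grp_cells) else ref_cells
      n_grp <- length(grp_cells)
      if (n_grp < min_cells || length(ref_use) < min_cells) {
        rows[[length(rows) + 1L]] <- data.frame(
          guide_id = gid, gene_id = genes, line = line,
          log2fc = NA_real_, se = NA_real_, n_cells = n_grp,
          p_value = NA_real_, reason = "too_few_cells")
        next
      }
      gmat <- counts[, grp_cells, drop = FALSE]
      rmat <- counts[, ref_use, drop = FALSE]
      g_tot <- Matrix::colSums(gmat); r_tot <- Matrix::colSums(rmat)
      g_sum <- Matrix::rowSums(gmat); r_sum <- Matrix::rowSums(rmat)
      est_of <- function(gs, gt, rs, rt) {
        if (composition_correct) {
          l <- log2((gs + eps) / (rs + eps))
          l - stats::median(l)
        } else {
          log2(.group_fraction(gs, gt, eps) / .group_fraction(rs, rt, eps))
        }
      }
      est <- est_of(g_sum[genes], sum(g_tot), r_sum[genes], sum(r_tot))
      se <- rep(NA_real_, length(genes))
      if (compute_se) {
        gdense <- as.matrix(gmat[genes, , drop = FALSE])
        rdense <- as.matrix(rmat[genes, , drop = FALSE])
        bmat <- matrix(NA_real_, nrow = length(genes), ncol = n_boot)
        for (b in seq_len(n_boot)) {
          bi <- sample.int(ncol(gdense), replace = TRUE)
          ri <- sample.int(ncol(rdense), replace = TRUE)
          bmat[, b] <- est_of(rowSums(gdense[, bi, drop = FALSE]), sum(g_tot[bi]),
                              rowSums(rdense[, ri, drop = FALSE]), sum(r_tot[ri]))
        }
        se <- apply(bmat, 1, stats::sd)
      }
      nm <- norm[genes, , drop = FALSE]
      grp_n <- intersect(grp_cells, colnames(nm))
      ref_n <- intersect(ref_use, colnames(nm))
      pv <- vapply(genes, function(gene) {
        test_perturbation_significance(nm[gene, grp_n], nm[gene, ref_n])
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        guide_id = gid, gene_id = genes, line = line,
        log2fc = unname(est), se = unname(se), n_cells = n_grp,
        p_value = unname(pv), reason = NA_character_)
    }
  })
  fc <- do.call(rbind, rows)
  rownames(fc) <- NULL
  ## FDR families: cis tests (guide vs own target) at 10%, trans tests at 5%
  fc$family <- ifelse(!is.na(tgt_of[fc$guide_id]) &
                        fc$gene_id == tgt_of[fc$guide_id], "cis", "trans")
  fc$q_value <- NA_real_
  for (fam in c("cis", "trans")) {
    idx <- which(fc$family == fam & !is.na(fc$p_value))
    fc$q_value[idx] <- adjust_fdr(fc$p_value[idx])
  }
  fc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Direction concordance of significant cis perturbations
#'
#' Fraction of significant cis perturbations (q <= `fdr` in the cis family)
#' whose fold-change sign matches the effector line's expected direction:
#' negative for CRISPRi, positive for CRISPRa.
#'
#' @param fc_table [fold_change_table()] output.
#' @param guide_library Guide table.
#' @param fdr Significance cutoff on the cis-family q-values (default 0.10).
#' @return list(concordance, n_significant); concordance is `NA` when no
#'   perturbation is significant.
#' @export
direction_concordance <- function(fc_table, guide_library, fdr = 0.10) {
  cis <- fc_table[fc_table$family == "cis" & !is.na(fc_table$q_value) &
                    fc_table$q_value <= fdr, , drop = FALSE]
  if (nrow(cis) == 0) return(list(concordance = NA_real_, n_significant = 0L))
  expected <- ifelse(cis$line == "CRISPRi", -1, 1)
  ok <- sign(cis$log2fc) == expected
  list(concordance = mean(ok), n_significant = nrow(cis))
}

#' On/off split robustness check
#'
#' Splits the cells of one guide by whether the cis gene's normalised
#' expression is zero or positive, recomputes trans log2 fold changes in
#' each subset against the same NTC reference, and reports their Pearson
#' correlation across trans genes. High concordance indicates the guide's
#' pseudo-bulk dosage effect is a graded shift rather than a changing
#' mixture of fully-silenced and untouched cells.
#'
#' @param cdna [counts_assay()].
#' @param annotation Cell annotation.
#' @param guide_library Guide table.
#' @param guide_id Guide to check.
#' @param cis_gene Its target (cis) gene.
#' @param trans_genes Character vector of trans genes to correlate over.
#' @param min_cells Minimum cells per subset (default 10).
#' @param eps Pseudocount.
#' @return list(correlation, n_zero, n_positive, reason)
#' @export
onoff_split_check <- function(cdna, annotation, guide_library, guide_id,
                              cis_gene, trans_genes, min_cells = 10L,
                              eps = 0.5) {
  ann <- annotation[!is.na(annotation$assigned_guide), , drop = FALSE]
  grp <- ann[ann$assigned_guide == guide_id, , drop = FALSE]
  if (nrow(grp) == 0) return(list(correlation = NA_real_, reason = "no_cells"))
  line <- grp$line[1]
  ntc_ids <- guide_library$guide_id[guide_library$guide_class == "NTC"]
  ref_cells <- ann$barcode[ann$line == line & ann$assigned_guide %in% ntc_ids]
  counts <- cdna$counts
  norm <- normalize_cells(subset_cells(cdna, c(grp$barcode, ref_cells)))
  zero <- grp$barcode[norm[cis_gene, grp$barcode] == 0]
  pos <- setdiff(grp$barcode, zero)
  if (length(zero) < min_cells || length(pos) < min_cells) {
    return(list(correlation = NA_real_, n_zero = length(zero),
                n_positive = length(pos), reason = "subset_below_min_cells"))
  }
  fc_of <- function(cellset) {
    g <- counts[, cellset, drop = FALSE]
    r <- counts[, ref_cells, drop = FALSE]
    log2(.group_fraction(Matrix::rowSums(g)[trans_genes], sum(g), eps) /
           .group_fraction(Matrix::rowSums(r)[trans_genes], sum(r), eps))
  }
  list(correlation = stats::cor(fc_of(zero), fc_of(pos)),
       n_zero = length(zero), n_positive = length(pos),
       reason = NA_character_)
}

#' Mean absolute trans response per guide, paired with cis dosage
#'
#' One row per (guide, line): the guide's estimated cis log2FC on its target
#' gene and the mean |log2FC| over trans genes. NTC guides are included as
#' anchor points at cis dosage ~ 0 (their cis value is the mean over the cis
#' genes' NTC rows).
#'
#' @param fc_table [fold_change_table()] output.
#' @param guide_library Guide table.
#' @param cis_gene Cis gene whose guides to report.
#' @param trans_genes Trans genes averaged over.
#' @return data.frame(guide_id, line, cis_log2fc, mean_abs_trans_fc)
#' @export
mean_abs_trans_response <- function(fc_table, guide_library, cis_gene,
                                    trans_genes) {
  lib <- guide_library
  keep_guides <- lib$guide_id[(!is.na(lib$target_gene) & lib$target_gene == cis_gene) |
                                lib$guide_class == "NTC"]
  sub <- fc_table[fc_table$guide_id %in% keep_guides, , drop = FALSE]
  out <- list()
  for (key in unique(paste(sub$guide_id, sub$line))) {
    s <- sub[paste(sub$guide_id, sub$line) == key, , drop = FALSE]
    cisv <- s$log2fc[s$gene_id == cis_gene]
    out[[key]] <- data.frame(
      guide_id = s$guide_id[1], line = s$line[1],
      cis_log2fc = if (length(cisv)) cisv else NA_real_,
      mean_abs_trans_fc = mean(abs(s$log2fc[s$gene_id %in% trans_genes]),
                               na.rm = TRUE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
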