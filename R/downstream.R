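## Downstream analyses on fitted responses: clustering of predicted curves,
## annotation correlations and group tests, gene-set enrichment of
## nonlinearity, cell-type correlation "phenotypes", and a PCA diagnostic.

#' Hierarchically cluster trans genes by their predicted response curves
#'
#' Each trans gene is described by its predicted log2FC curves concatenated
#' across cis genes (shared dosage grid); genes missing any curve are
#' excluded. Euclidean distance, Ward linkage (`ward.D2`), tree cut at `k`.
#' Curves are used on their raw log2FC scale by default so that dynamic
#' range contributes to cluster identity; set `scale_rows = TRUE` for the
#' z-scaled variant.
#'
#' @param grid A `response_grid` from [predict_grid()].
#' @param k Number of clusters (default 6).
#' @param scale_rows Z-scale each gene's concatenated curve first.
#' @return list(clusters = named integer vector per trans gene, hclust,
#'   curves = the feature matrix, excluded = genes dropped for missing
#'   curves)
#' @export
cluster_responses <- function(grid, k = 6L, scale_rows = FALSE) {
  stopifnot(inherits(grid, "response_grid"))
  pairs <- grid$pairs
  cis_genes <- sort(unique(pairs$cis_gene))
  trans_genes <- sort(unique(pairs$trans_gene))
  n_grid <- length(grid$grid)
  curves <- matrix(NA_real_, nrow = length(trans_genes),
                   ncol = n_grid * length(cis_genes),
                   dimnames = list(trans_genes, NULL))
  for (j in seq_along(cis_genes)) {
    sel <- which(pairs$cis_gene == cis_genes[j])
    rows <- match(pairs$trans_gene[sel], trans_genes)
    curves[rows, (j - 1) * n_grid + seq_len(n_grid)] <-
      grid$predictions[sel, , drop = FALSE]
  }
  complete <- stats::complete.cases(curves)
  excluded <- trans_genes[!complete]
  m <- curves[complete, , drop = FALSE]
  if (scale_rows) m <- t(scale(t(m)))
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  clusters <- stats::cutree(hc, k = k)
  list(clusters = clusters, hclust = hc, curves = m, excluded = excluded)
}

#' Correlate sigmoid fit parameters with quantitative gene metrics
#'
#' Pairwise-complete Pearson correlations of each fit parameter
#' (`a`, `b`, `c`, `d`, `dynamic_range`) with each numeric metric, per cis
#' gene, BH-adjusted within each cis gene's family.
#'
#' @param dosefits [fit_dose_responses()] table.
#' @param annotations data.frame keyed by `gene_id` with numeric metric
#'   columns.
#' @param parameters Parameters to correlate (default all five).
#' @param min_pairs Minimum complete pairs (default 5).
#' @return data.frame(cis_gene, parameter, metric, r, n, p_value, q_value,
#'   reason)
#' @export
correlate_parameters <- function(dosefits, annotations,
                                 parameters = c("a", "b", "c", "d",
                                                "dynamic_range"),
                                 min_pairs = 5L) {
  metrics <- setdiff(names(annotations)[vapply(annotations, is.numeric, TRUE)],
                     "gene_id")
  rows <- list()
  for (cg in unique(dosefits$cis_gene)) {
    sub <- dosefits[dosefits$cis_gene == cg, , drop = FALSE]
    idx <- match(sub$trans_gene, annotations$gene_id)
    for (par in parameters) {
      for (met in metrics) {
        xv <- sub[[par]]
        yv <- annotations[[met]][idx]
        ok <- is.finite(xv) & is.finite(yv)
        if (sum(ok) < min_pairs) {
          rows[[length(rows) + 1L]] <- data.frame(
            cis_gene = cg, parameter = par, metric = met, r = NA_real_,
            n = sum(ok), p_value = NA_real_, reason = "too_few_pairs")
          next
        }
        if (stats::sd(xv[ok]) == 0 || stats::sd(yv[ok]) == 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            cis_gene = cg, parameter = par, metric = met, r = NA_real_,
            n = sum(ok), p_value = NA_real_, reason = "zero_variance")
          next
        }
        ct <- stats::cor.test(xv[ok], yv[ok], method = "pearson")
        rows[[length(rows) + 1L]] <- data.frame(
          cis_gene = cg, parameter = par, metric = met,
          r = unname(ct$estimate), n = sum(ok), p_value = ct$p.value,
          reason = NA_character_)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  for (cg in unique(out$cis_gene)) {
    idx <- which(out$cis_gene == cg & !is.na(out$p_value))
    out$q_value[idx] <- adjust_fdr(out$p_value[idx])
  }
  rownames(out) <- NULL
  out
}

#' Compare fit parameters between flagged and unflagged genes
#'
#' Two-sided Wilcoxon rank-sum tests of each parameter between genes inside
#' and outside each binary annotation, per cis gene.
#'
#' @param dosefits [fit_dose_responses()] table.
#' @param annotations data.frame keyed by `gene_id` with logical flag
#'   columns.
#' @param parameters Parameters to test.
#' @param min_group Minimum genes per group (default 3).
#' @return data.frame(cis_gene, parameter, flag, n_yes, n_no, median_yes,
#'   median_no, p_value, reason)
#' @export
compare_groups <- function(dosefits, annotations,
                           parameters = c("a", "b", "c", "d",
                                          "dynamic_range"),
                           min_group = 3L) {
  flags <- setdiff(names(annotations)[vapply(annotations, is.logical, TRUE)],
                   "gene_id")
  rows <- list()
  for (cg in unique(dosefits$cis_gene)) {
    sub <- dosefits[dosefits$cis_gene == cg, , drop = FALSE]
    idx <- match(sub$trans_gene, annotations$gene_id)
    for (par in parameters) {
      for (fl in flags) {
        v <- sub[[par]]
        f <- annotations[[fl]][idx]
        ok <- is.finite(v) & !is.na(f)
        yes <- v[ok & f]; no <- v[ok & !f]
        if (length(yes) < min_group || length(no) < min_group) {
          rows[[length(rows) + 1L]] <- data.frame(
            cis_gene = cg, parameter = par, flag = fl,
            n_yes = length(yes), n_no = length(no),
            median_yes = NA_real_, median_no = NA_real_,
            p_value = NA_real_, reason = "group_too_small")
          next
        }
        p <- if (length(unique(c(yes, no))) == 1L) 1 else
          suppressWarnings(stats::wilcox.test(yes, no, exact = FALSE)$p.value)
        rows[[length(rows) + 1L]] <- data.frame(
          cis_gene = cg, parameter = par, flag = fl,
          n_yes = length(yes), n_no = length(no),
          median_yes = stats::median(yes), median_no = stats::median(no),
          p_value = p, reason = NA_character_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## odds ratio straight from the 2x2 table, with Haldane 0.5 correction on
## degenerate margins
.table_or <- function(tab) {
  haldane <- any(tab == 0)
  t2 <- if (haldane) tab + 0.5 else tab
  list(odds_ratio = (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1]),
       haldane = haldane)
}

#' Enrichment of nonlinear responses in gene sets
#'
#' Per cis gene and gene set, a 2x2 Fisher exact test of
#' `{delta_aic > daic_cut}` x `{gene in set}` over the analysed trans genes,
#' BH-corrected across sets within each cis gene. Setting
#' `row_variable = "unresponsive"` instead tests membership of the
#' unresponsive class (the housekeeping enrichment variant).
#'
#' @param dosefits [fit_dose_responses()] table.
#' @param gene_sets Named list of character vectors, or a two-column
#'   data.frame (set, gene).
#' @param daic_cut ΔAIC cutoff defining "nonlinear" (0 or 2 are the working
#'   presets; default 0).
#' @param row_variable `"nonlinear"` (ΔAIC rule) or `"unresponsive"`
#'   (response-class rule).
#' @return data.frame(cis_gene, gene_set, odds_ratio, log_odds, p_value,
#'   q_value, haldane, and the 2x2 counts n11..n22) where n11 = responsive
#'   genes in the set.
#' @export
enrich_nonlinear <- function(dosefits, gene_sets, daic_cut = 0,
                             row_variable = c("nonlinear", "unresponsive")) {
  row_variable <- match.arg(row_variable)
  if (is.data.frame(gene_sets)) {
    gene_sets <- split(as.character(gene_sets[[2]]), gene_sets[[1]])
  }
  rows <- list()
  for (cg in unique(dosefits$cis_gene)) {
    sub <- dosefits[dosefits$cis_gene == cg & !is.na(dosefits$response_class), ]
    flag <- if (row_variable == "nonlinear") sub$delta_aic > daic_cut
            else sub$response_class == "unresponsive"
    for (gs in names(gene_sets)) {
      inset <- sub$trans_gene %in% gene_sets[[gs]]
      tab <- matrix(c(sum(flag & inset), sum(flag & !inset),
                      sum(!flag & inset), sum(!flag & !inset)),
                    nrow = 2, byrow = TRUE)
      p <- stats::fisher.test(tab)$p.value
      or <- .table_or(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        cis_gene = cg, gene_set = gs,
        odds_ratio = or$odds_ratio, log_odds = log(or$odds_ratio),
        p_value = p, haldane = or$haldane,
        n11 = tab[1, 1], n12 = tab[1, 2], n21 = tab[2, 1], n22 = tab[2, 2])
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  for (cg in unique(out$cis_gene)) {
    idx <- which(out$cis_gene == cg)
    out$q_value[idx] <- adjust_fdr(out$p_value[idx])
  }
  rownames(out) <- NULL
  out
}

#' Cell-type correlation "phenotypes" of each perturbation
#'
#' Correlates each perturbation's trans log2FC vector with each cell type's
#' expression profile (z-scored per gene across cell types beforehand),
#' giving an interpretable similarity between the induced transcriptional
#' state and each cell-type state. BH across the whole matrix at 10% FDR.
#'
#' @param fc_table [fold_change_table()] output (trans rows used).
#' @param celltype_profiles Numeric matrix genes x cell types (mean
#'   expression; z-scaled per gene here unless `already_scaled`).
#' @param trans_genes Genes to use.
#' @param already_scaled Skip the per-gene z-scaling.
#' @param min_overlap Minimum genes shared between panel and profiles
#'   (default 10).
#' @return list(r = matrix perturbation x cell type, p, q)
#' @export
celltype_correlation <- function(fc_table, celltype_profiles, trans_genes,
                                 already_scaled = FALSE, min_overlap = 10L) {
  prof <- as.matrix(celltype_profiles)
  genes <- intersect(trans_genes, rownames(prof))
  if (length(genes) < min_overlap) {
    stop("only ", length(genes), " genes overlap the cell-type profiles (need >= ",
         min_overlap, ")")
  }
  prof <- prof[genes, , drop = FALSE]
  if (!already_scaled) prof <- t(scale(t(prof)))
  sub <- fc_table[fc_table$gene_id %in% genes & !is.na(fc_table$log2fc), ]
  sub$pert <- paste(sub$guide_id, sub$line, sep = "|")
  perts <- unique(sub$pert)
  r <- matrix(NA_real_, length(perts), ncol(prof),
              dimnames = list(perts, colnames(prof)))
  p <- r
  for (i in seq_along(perts)) {
    s <- sub[sub$pert == perts[i], ]
    v <- stats::setNames(s$log2fc, s$gene_id)[genes]
    for (j in seq_len(ncol(prof))) {
      ok <- is.finite(v) & is.finite(prof[, j])
      if (sum(ok) < min_overlap) next
      ct <- stats::cor.test(v[ok], prof[ok, j])
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  q <- p
  q[] <- adjust_fdr(as.vector(p))
  list(r = r, p = p, q = q)
}

#' PCA of the perturbation x trans gene fold-change matrix
#'
#' Diagnostic: with dosage as the dominant signal, the first components
#' should order perturbations along cis dosage.
#'
#' @param fc_table [fold_change_table()] output.
#' @param trans_genes Genes forming the columns.
#' @return list(scores, sdev, var_explained, prcomp)
#' @export
pca_foldchanges <- function(fc_table, trans_genes) {
  sub <- fc_table[fc_table$gene_id %in% trans_genes & !is.na(fc_table$log2fc), ]
  sub$pert <- paste(sub$guide_id, sub$line, sep = "|")
  m <- stats::xtabs(log2fc ~ pert + gene_id, data = sub)
  m <- as.matrix(m[, trans_genes[trans_genes %in% colnames(m)], drop = FALSE])
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  list(scores = pc$x, sdev = pc$sdev,
       var_explained = pc$sdev^2 / sum(pc$sdev^2), prcomp = pc)
}
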