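## Cell calling: effector-line demultiplexing from hashtags + effector
## transcripts, per-guide Gaussian-mixture sgRNA assignment, and QC.

#' Demultiplex cells into effector lines
#'
#' Combines two pieces of evidence per cell: the dominant hashtag after
#' centred log-ratio (CLR) transformation across hash features, and the
#' dominant effector transcript (e.g. the KRAB-dCas9 cDNA vs the dCas9-VPR
#' cDNA). A cell is labelled with a line only when both calls are made and
#' agree; otherwise it is `ambiguous`. The hash call requires the top CLR
#' value to exceed the runner-up by `clr_margin`; the effector call requires
#' a strict count majority.
#'
#' @param hashes A [counts_assay()] of hashtag counts whose feature ids are
#'   named by `hash_map`.
#' @param effector_counts Matrix or data.frame of per-cell counts of the two
#'   effector transcripts: rows = lines (named as in `hash_map`), columns =
#'   cells (same order as `hashes` barcodes).
#' @param hash_map Named character vector mapping line label to hash feature
#'   id. Default `c(CRISPRi = "HTO_CRISPRi", CRISPRa = "HTO_CRISPRa")`.
#' @param clr_margin Required CLR margin between top and runner-up hash
#'   (default 1.0).
#' @return data.frame with `barcode` and `line`
#'   (`"CRISPRi"`, `"CRISPRa"`, or `"ambiguous"`).
#' @export
demux_cell_lines <- function(hashes, effector_counts,
                             hash_map = c(CRISPRi = "HTO_CRISPRi",
                                          CRISPRa = "HTO_CRISPRa"),
                             clr_margin = 1.0) {
  stopifnot(inherits(hashes, "counts_assay"))
  missing_h <- setdiff(unname(hash_map), feature_ids(hashes))
  if (length(missing_h)) {
    stop("hash assay lacks expected features: ", paste(missing_h, collapse = ", "))
  }
  h <- as.matrix(hashes$counts[unname(hash_map), , drop = FALSE])
  rownames(h) <- names(hash_map)
  ## CLR across hash features within each cell
  lh <- log1p(h)
  clr <- sweep(lh, 2, colMeans(lh))
  top <- apply(clr, 2, which.max)
  margin <- apply(clr, 2, function(v) {
    s <- sort(v, decreasing = TRUE)
    s[1] - s[2]
  })
  hash_call <- ifelse(margin >= clr_margin, rownames(clr)[top], NA_character_)

  e <- as.matrix(effector_counts)
  stopifnot(nrow(e) == length(hash_map), ncol(e) == ncol(h))
  if (is.null(rownames(e))) rownames(e) <- names(hash_map)
  e <- e[names(hash_map), , drop = FALSE]
  e_top <- apply(e, 2, which.max)
  e_tie <- apply(e, 2, function(v) max(v) == sort(v, decreasing = TRUE)[2])
  eff_call <- ifelse(e_tie, NA_character_, rownames(e)[e_top])

  line <- ifelse(!is.na(hash_call) & !is.na(eff_call) & hash_call == eff_call,
                 hash_call, "ambiguous")
  data.frame(barcode = hashes$barcodes, line = line, stringsAsFactors = FALSE)
}

## Two-component 1-D Gaussian EM on a numeric vector.
## Deterministic initialisation by a 2-quantile (median) split; iterates at
## most `max_iter` times or until the log-likelihood moves < tol.
fit_gmm_1d <- function(v, max_iter = 100L, tol = 1e-6) {
  stopifnot(length(v) >= 4)
  med <- stats::median(v)
  lo <- v[v <= med]; hi <- v[v > med]
  if (!length(hi)) { hi <- max(v); lo <- v[v < max(v)] }
  mu <- c(mean(lo), mean(hi))
  s2 <- pmax(c(stats::var(lo), stats::var(hi)), 1e-4)
  s2[is.na(s2)] <- 1e-4
  w <- c(length(lo), length(hi)) / length(v)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- cbind(w[1] * stats::dnorm(v, mu[1], sqrt(s2[1])),
                  w[2] * stats::dnorm(v, mu[2], sqrt(s2[2])))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    resp <- dens / tot
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-8)
    mu <- colSums(resp * v) / nk
    s2 <- pmax(colSums(resp * (outer(v, mu, "-"))^2) / nk, 1e-6)
    w <- nk / length(v)
  }
  ## order components low < high
  o <- order(mu)
  list(means = mu[o], variances = s2[o], weights = w[o],
       loglik = ll_old, converged = converged)
}

#' Assign each cell to a single sgRNA via per-guide Gaussian mixtures
#'
#' For every guide, a 2-component Gaussian mixture is fitted to
#' `log10(count + 1)` over cells with at least one UMI of that guide,
#' separating ambient background from true delivery. A cell is positive for
#' a guide when its posterior probability of the high component exceeds
#' `posterior_threshold` and its raw count is at least `min_count`. Cells
#' positive for exactly one guide receive that assignment; cells positive
#' for zero or several guides remain unassigned.
#'
#' Guides with fewer than `min_fit_cells` nonzero cells, or whose fitted
#' components collapse (mean gap < 0.1 on the log10 scale), fall back to the
#' fixed-count rule `count >= min_count` with a warning.
#'
#' @param guide_assay [counts_assay()] of sgRNA capture counts.
#' @param min_count Minimum raw UMI count for a positive call (default 3).
#' @param posterior_threshold Posterior required for the high component
#'   (default 0.5).
#' @param min_fit_cells Minimum nonzero cells to attempt a mixture fit
#'   (default 20).
#' @param seed Integer seed (kept for interface stability; the EM
#'   initialisation is deterministic).
#' @return list with `assignments` (data.frame: `barcode`, `assigned_guide`,
#'   `n_guides_positive`, `total_guide_umis`), `positives` (logical matrix
#'   guides x cells) and `fits` (per-guide mixture summaries).
#' @export
assign_guides_gmm <- function(guide_assay, min_count = 3L,
                              posterior_threshold = 0.5,
                              min_fit_cells = 20L, seed = 1L) {
  stopifnot(inherits(guide_assay, "counts_assay"))
  counts <- guide_assay$counts
  gids <- feature_ids(guide_assay)
  ncell <- ncol(counts)
  positives <- matrix(FALSE, nrow = length(gids), ncol = ncell,
                      dimnames = list(gids, colnames(counts)))
  fits <- vector("list", length(gids))
  names(fits) <- gids
  for (g in seq_along(gids)) {
    row <- counts[g, ]
    nz <- which(row >= 1)
    if (length(nz) == 0) next
    v <- log10(row[nz] + 1)
    use_fallback <- length(nz) < min_fit_cells || length(unique(v)) < 3
    fit <- NULL
    if (!use_fallback) {
      fit <- fit_gmm_1d(v)
      if (diff(fit$means) < 0.1) {
        warning("degenerate mixture for guide ", gids[g],
                "; falling back to count threshold")
        use_fallback <- TRUE
      }
    }
    if (use_fallback) {
      pos_nz <- row[nz] >= min_count
      fits[[g]] <- list(guide_id = gids[g], fallback = TRUE)
    } else {
      d1 <- fit$weights[1] * stats::dnorm(v, fit$means[1], sqrt(fit$variances[1]))
      d2 <- fit$weights[2] * stats::dnorm(v, fit$means[2], sqrt(fit$variances[2]))
      post_hi <- d2 / pmax(d1 + d2, .Machine$double.xmin)
      pos_nz <- post_hi > posterior_threshold & row[nz] >= min_count
      fits[[g]] <- list(guide_id = gids[g], fallback = FALSE,
                        means = fit$means, variances = fit$variances,
                        weights = fit$weights,
                        threshold_posterior = posterior_threshold,
                        converged = fit$converged)
    }
    positives[g, nz[pos_nz]] <- TRUE
  }
  npos <- colSums(positives)
  assigned <- rep(NA_character_, ncell)
  one <- npos == 1
  if (any(one)) {
    assigned[one] <- gids[apply(positives[, one, drop = FALSE], 2, which.max)]
  }
  assignments <- data.frame(
    barcode = guide_assay$barcodes,
    assigned_guide = assigned,
    n_guides_positive = as.integer(npos),
    total_guide_umis = as.integer(Matrix::colSums(counts)),
    stringsAsFactors = FALSE)
  list(assignments = assignments, positives = positives, fits = fits)
}

#' Flag cells passing standard QC
#'
#' Monotone threshold filter on total UMIs and detected genes: relaxing any
#' threshold never removes a passing cell.
#'
#' @param cdna [counts_assay()] of gene expression counts.
#' @param min_total_umis,max_total_umis Bounds on per-cell total panel UMIs.
#' @param min_genes_detected Minimum number of genes with nonzero counts.
#' @return data.frame with `barcode`, `total_umis`, `genes_detected`,
#'   `qc_pass`.
#' @export
qc_filter <- function(cdna, min_total_umis = 0, max_total_umis = Inf,
                      min_genes_detected = 0) {
  stopifnot(inherits(cdna, "counts_assay"),
            min_total_umis >= 0, min_genes_detected >= 0)
  tot <- Matrix::colSums(cdna$counts)
  ngene <- Matrix::colSums(cdna$counts > 0)
  data.frame(barcode = cdna$barcodes,
             total_umis = as.integer(tot),
             genes_detected = as.integer(ngene),
             qc_pass = tot >= min_total_umis & tot <= max_total_umis &
               ngene >= min_genes_detected,
             stringsAsFactors = FALSE)
}

#' Build the cell annotation table from demux, assignment and QC
#'
#' A cell's `assigned_guide` is retained only when it passed QC, was
#' positive for exactly one guide, and has an unambiguous line call.
#'
#' @param lines Result of [demux_cell_lines()].
#' @param assignments `assignments` element of [assign_guides_gmm()].
#' @param qc Result of [qc_filter()].
#' @return data.frame keyed by barcode with `line`, `assigned_guide`,
#'   `n_guides_positive`, `qc_pass`.
#' @export
cell_annotation <- function(lines, assignments, qc) {
  stopifnot(identical(lines$barcode, assignments$barcode),
            identical(lines$barcode, qc$barcode))
  out <- data.frame(barcode = lines$barcode,
                    line = lines$line,
                    assigned_guide = assignments$assigned_guide,
                    n_guides_positive = assignments$n_guides_positive,
                    qc_pass = qc$qc_pass,
                    stringsAsFactors = FALSE)
  drop <- !out$qc_pass | out$n_guides_positive != 1L | out$line == "ambiguous"
  out$assigned_guide[drop] <- NA_character_
  out
}
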