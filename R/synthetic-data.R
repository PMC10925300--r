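## Synthetic targeted multimodal CRISPRi/a titration datasets with known
## ground truth: guide identities, cis effects, and per-(cis, trans) response
## functions. The generator emulates the screen design itself (two pooled
## effector lines, ~96 guides with 5 NTCs, a ~90-gene targeted panel), not
## read-level sequencing.

#' Describe the true dose-response of one trans gene to one cis gene
#'
#' The response maps cis-gene dosage `x` (log2 fold change vs baseline) to the
#' expected trans-gene log2 fold change. All forms are anchored so that the
#' expected trans log2FC at `x = 0` is exactly 0.
#'
#' @param form One of `"flat"`, `"linear"`, `"sigmoid"`, `"nonmonotonic"`.
#' @param slope Linear form: trans log2FC per unit cis log2FC.
#' @param a,b,c,d Sigmoid form: inflection location (`a`, cis log2FC units),
#'   steepness (`b`; its sign carries orientation), lower and upper asymptote
#'   (`c`, `d`, trans log2FC units). Requires `c <= d`.
#' @param peak_x,peak_height,width Non-monotonic form: a Gaussian bump centred
#'   at `peak_x` with the given height and standard-deviation width.
#' @return A `response_truth` object.
#' @export
response_truth <- function(form = c("flat", "linear", "sigmoid", "nonmonotonic"),
                           slope = NULL, a = NULL, b = NULL, c = NULL, d = NULL,
                           peak_x = NULL, peak_height = NULL, width = 0.45) {
  form <- match.arg(form)
  params <- switch(form,
    flat = list(),
    linear = {
      stopifnot(is.numeric(slope), length(slope) == 1L)
      list(slope = slope)
    },
    sigmoid = {
      stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
      if (c > d) {
        stop("ambiguous sigmoid truth: c > d; encode orientation in the sign of b")
      }
      list(a = a, b = b, c = c, d = d)
    },
    nonmonotonic = {
      stopifnot(is.numeric(peak_x), is.numeric(peak_height), width > 0)
      list(peak_x = peak_x, peak_height = peak_height, width = width)
    })
  structure(list(form = form, params = params), class = "response_truth")
}

#' Four-parameter sigmoid
#'
#' `f(x) = c + (d - c) / (1 + exp(-b * (x - a)))`. Used both as simulation
#' truth and as the model fitted by [fit_sigmoid()].
#'
#' @param x Numeric vector of cis dosages (log2FC units).
#' @param a,b,c,d Sigmoid parameters (see [response_truth()]).
#' @return Numeric vector of the same length as `x`.
#' @export
sigmoid4 <- function(x, a, b, c, d) {
  c + (d - c) / (1 + exp(-b * (x - a)))
}

#' Evaluate a response truth at given cis dosages
#'
#' @param truth A [response_truth()] object.
#' @param x Numeric vector of cis log2 fold changes.
#' @return Expected trans log2 fold changes (0 at `x = 0` by construction).
#' @export
eval_response <- function(truth, x) {
  stopifnot(inherits(truth, "response_truth"))
  p <- truth$params
  f <- switch(truth$form,
    flat = function(x) rep(0, length(x)),
    linear = function(x) p$slope * x,
    sigmoid = function(x) sigmoid4(x, p$a, p$b, p$c, p$d),
    nonmonotonic = function(x) p$peak_height * exp(-(x - p$peak_x)^2 / (2 * p$width^2)))
  f(x) - f(0)
}

## Planted response class implied by a truth object; the label the pipeline
## classifier is expected to recover.
truth_class <- function(truth) {
  switch(truth$form,
    flat = "unresponsive",
    linear = "linear",
    sigmoid = "nonlinear",
    nonmonotonic = "nonmonotonic")
}

#' Build a simulation configuration
#'
#' @param guides data.frame with columns `guide_id`, `target_gene` (NA for
#'   NTCs), `guide_class` (`TSS`, `tiling`, `CRE`, `attenuated`, `NTC`),
#'   `tss_offset_bp`, `cis_log2fc` (true effect in the matched effector line;
#'   0 for NTC) and `effector` (`CRISPRi`/`CRISPRa`; NA for NTC, which are
#'   simulated in both lines).
#' @param genes data.frame with columns `gene_id`, `role` (`cis`, `trans`,
#'   `control_high`, `control_low`, `effector_transcript`), `baseline_mean`
#'   (expected UMIs per cell at dosage 0) and optionally `effector_line`
#'   (for effector transcripts) and `tss_pos`/`chrom` (cis genes, used to
#'   anchor guide genomic positions).
#' @param responses Nested named list: `responses[[trans_gene]][[cis_gene]]`
#'   is a [response_truth()]. Missing entries are treated as flat.
#' @param n_cells_per_guide Cells simulated per guide and line.
#' @param dispersion Negative-binomial size; counts have
#'   `var = mu + mu^2 / dispersion`. `Inf` gives Poisson counts.
#' @param dropout_logit_scale Slope `s` of the extra-zero (dropout) model,
#'   `P(drop) = plogis(-s * log(mu))`, logistic in log mean with midpoint at
#'   `mu = 1`. `0` disables dropout.
#' @param ambient_guide_rate Expected background UMIs per non-delivered guide
#'   per cell (Poisson).
#' @param guide_capture_mean Mean UMIs of the delivered guide.
#' @param hash_depth Mean total hashtag UMIs per cell.
#' @param hash_error_rate Probability a hash read is assigned to the wrong
#'   hashtag.
#' @param effector_mean Mean UMIs of the matched effector transcript (used
#'   when the gene table carries no explicit baseline for it).
#' @param multiplet_rate Fraction of cells carrying a second delivered guide.
#' @param onoff_mode If `TRUE`, CRISPRi knock-down is simulated as a binary
#'   on/off mixture: each perturbed cell is fully silenced with probability
#'   `1 - 2^cis_log2fc` (so the pseudo-bulk mean matches the nominal effect)
#'   and unperturbed otherwise, with trans responses following the cell state.
#'   Exercises the on/off-split robustness check.
#' @param propagate_dosage_noise If `TRUE`, each cell's dosage is jittered by
#'   `N(0, dosage_noise_sd)` before evaluating trans responses.
#' @param dosage_noise_sd Cell-level dosage jitter used by the propagate mode.
#' @param seed Integer seed; identical configs give bit-identical datasets.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(guides, genes, responses = list(),
                       n_cells_per_guide = 150,
                       dispersion = 10,
                       dropout_logit_scale = 1,
                       ambient_guide_rate = 0.2,
                       guide_capture_mean = 30,
                       hash_depth = 50,
                       hash_error_rate = 0.05,
                       effector_mean = 8,
                       multiplet_rate = 0,
                       onoff_mode = FALSE,
                       propagate_dosage_noise = FALSE,
                       dosage_noise_sd = 0.2,
                       seed = 1L) {
  stopifnot(is.data.frame(guides), is.data.frame(genes))
  need_g <- c("guide_id", "target_gene", "guide_class", "tss_offset_bp",
              "cis_log2fc", "effector")
  if (!all(need_g %in% names(guides))) {
    stop("guides table missing columns: ",
         paste(setdiff(need_g, names(guides)), collapse = ", "))
  }
  if (!all(c("gene_id", "role", "baseline_mean") %in% names(genes))) {
    stop("genes table needs gene_id, role, baseline_mean")
  }
  is_ntc <- guides$guide_class == "NTC"
  if (any(guides$cis_log2fc[is_ntc] != 0) || any(!is.na(guides$target_gene[is_ntc]))) {
    stop("NTC guides must have cis_log2fc = 0 and no target gene")
  }
  if (any(!is.na(guides$target_gene) &
          !guides$target_gene %in% genes$gene_id[genes$role == "cis"])) {
    stop("guide target_gene not among cis genes")
  }
  stopifnot(n_cells_per_guide >= 1, dispersion > 0,
            ambient_guide_rate >= 0, hash_error_rate >= 0, hash_error_rate <= 1,
            multiplet_rate >= 0, multiplet_rate <= 1)
  for (tg in names(responses)) {
    for (cg in names(responses[[tg]])) {
      if (!inherits(responses[[tg]][[cg]], "response_truth")) {
        stop("responses[['", tg, "']][['", cg, "']] is not a response_truth")
      }
    }
  }
  structure(list(guides = guides, genes = genes, responses = responses,
                 n_cells_per_guide = as.integer(n_cells_per_guide),
                 dispersion = dispersion,
                 dropout_logit_scale = dropout_logit_scale,
                 ambient_guide_rate = ambient_guide_rate,
                 guide_capture_mean = guide_capture_mean,
                 hash_depth = hash_depth, hash_error_rate = hash_error_rate,
                 effector_mean = effector_mean,
                 multiplet_rate = multiplet_rate,
                 onoff_mode = isTRUE(onoff_mode),
                 propagate_dosage_noise = isTRUE(propagate_dosage_noise),
                 dosage_noise_sd = dosage_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Per-gene magnitude of the cis effect as a function of TSS offset: a
## Gaussian efficacy profile peaked downstream of the TSS for CRISPRi
## (+238 bp) and just upstream for CRISPRa (-99 bp), mirroring where the two
## effector domains act most strongly.
.efficacy <- function(offset, effector, sd = 350) {
  peak <- ifelse(effector == "CRISPRi", 238, -99)
  exp(-(offset - peak)^2 / (2 * sd^2))
}

#' Default screen-scale simulation configuration
#'
#' Emulates the study design: 96 guides (5 non-targeting controls; TSS,
#' tiling, CRE and attenuated designs across both effector lines) targeting
#' 4 cis genes, a targeted panel of the 4 cis genes plus 80 trans genes, one
#' highly expressed housekeeping control, one silent control, and the two
#' effector transcripts. Three of the cis genes drive trans networks; the
#' fourth is an unrelated control with flat trans responses. The 80 trans
#' genes are planted in three response archetypes — "activated" (sigmoid up
#' on cis gene 1, linear down on cis gene 3; four members additionally
#' non-monotonic on cis gene 2), "repressed" (the mirror image) and
#' "buffered" (flat everywhere) — so both per-pair response classes and the
#' archetype partition are known ground truth.
#'
#' @param n_cells_per_guide Cells per guide per line (default 150).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
default_sim_config <- function(n_cells_per_guide = 150, seed = 1L, ...) {
  cis <- data.frame(
    gene_id = c("CISG1", "CISG2", "CISG3", "CISG4"),
    depth_i = c(1.84, 1.20, 1.40, 1.00),   # max CRISPRi knock-down (|log2FC|)
    depth_a = c(0.51, 0.45, 0.18, 0.40),   # max CRISPRa activation
    tss_pos = c(100000L, 300000L, 500000L, 700000L))

  guide_rows <- list()
  for (g in seq_len(nrow(cis))) {
    gene <- cis$gene_id[g]
    mk <- function(class, offset, effector, rel) {
      depth <- if (effector == "CRISPRi") -cis$depth_i[g] else cis$depth_a[g]
      data.frame(target_gene = gene, guide_class = class,
                 tss_offset_bp = as.integer(offset), effector = effector,
                 cis_log2fc = depth * rel)
    }
    rows <- list(
      mk("TSS", -50, "CRISPRi", 1.00),
      mk("TSS", 25, "CRISPRa", 1.00))
    for (off in seq(-1000L, 1000L, by = 250L)) {
      rows <- c(rows, list(mk("tiling", off, "CRISPRi", .efficacy(off, "CRISPRi"))))
    }
    for (off in seq(-900L, 900L, by = 300L)) {
      rows <- c(rows, list(mk("tiling", off, "CRISPRa", .efficacy(off, "CRISPRa"))))
    }
    rows <- c(rows, list(
      mk("CRE", -5200, "CRISPRi", 0.45),
      mk("CRE", 4800, "CRISPRa", 0.55),
      mk("attenuated", -30, "CRISPRi", 0.30),
      mk("attenuated", -30, "CRISPRa", 0.35)))
    ## extra attenuated-series guides on the widest-range gene (96 total)
    if (g == 1L) {
      rows <- c(rows, list(
        mk("attenuated", -30, "CRISPRi", 0.60),
        mk("attenuated", -30, "CRISPRi", 0.80),
        mk("attenuated", -30, "CRISPRa", 0.65)))
    }
    guide_rows[[g]] <- do.call(rbind, rows)
  }
  guides <- do.call(rbind, guide_rows)
  ntc <- data.frame(target_gene = NA_character_, guide_class = "NTC",
                    tss_offset_bp = NA_integer_, effector = NA_character_,
                    cis_log2fc = 0)
  guides <- rbind(guides, ntc[rep(1, 5), ])
  guides$guide_id <- c(sprintf("g%02d_%s", stats::ave(seq_len(nrow(guides) - 5),
                                                      guides$target_gene[seq_len(nrow(guides) - 5)],
                                                      FUN = seq_along),
                               guides$target_gene[seq_len(nrow(guides) - 5)]),
                       sprintf("NTC_%d", 1:5))
  rownames(guides) <- NULL
  guides <- guides[, c("guide_id", "target_gene", "guide_class",
                       "tss_offset_bp", "cis_log2fc", "effector")]

  n_trans <- 80
  trans_ids <- sprintf("TRANS%02d", seq_len(n_trans))
  archetype <- rep(c("activated", "repressed", "buffered"),
                   times = c(27, 27, 26))
  ## deterministic spread of baseline expression, 5..80 mean UMIs
  trans_base <- round(exp(seq(log(5), log(80), length.out = n_trans)), 2)

  genes <- rbind(
    data.frame(gene_id = cis$gene_id, role = "cis",
               baseline_mean = c(60, 80, 50, 40)),
    data.frame(gene_id = trans_ids, role = "trans", baseline_mean = trans_base),
    data.frame(gene_id = "CTRL_HIGH", role = "control_high", baseline_mean = 400),
    data.frame(gene_id = "CTRL_LOW", role = "control_low", baseline_mean = 0.05),
    data.frame(gene_id = c("EFF_KRAB", "EFF_VPR"), role = "effector_transcript",
               baseline_mean = 8))
  genes$effector_line <- NA_character_
  genes$effector_line[genes$gene_id == "EFF_KRAB"] <- "CRISPRi"
  genes$effector_line[genes$gene_id == "EFF_VPR"] <- "CRISPRa"
  genes$tss_pos <- NA_integer_
  genes$tss_pos[match(cis$gene_id, genes$gene_id)] <- cis$tss_pos
  genes$chrom <- ifelse(is.na(genes$tss_pos), NA_character_, "chrS")

  act_sig <- response_truth("sigmoid", a = -0.5, b = 3, c = -1.2, d = 0.4)
  rep_sig <- response_truth("sigmoid", a = -0.4, b = -3, c = -0.5, d = 0.9)
  nonmono <- response_truth("nonmonotonic", peak_x = -0.8, peak_height = 0.9,
                            width = 0.45)
  responses <- list()
  nonmono_members <- trans_ids[archetype == "activated"][1:4]
  for (i in seq_len(n_trans)) {
    tg <- trans_ids[i]
    r <- list()
    if (archetype[i] == "activated") {
      r$CISG1 <- act_sig
      r$CISG3 <- response_truth("linear", slope = -0.5)
      if (tg %in% nonmono_members) r$CISG2 <- nonmono
    } else if (archetype[i] == "repressed") {
      r$CISG1 <- rep_sig
      r$CISG3 <- response_truth("linear", slope = 0.4)
    }
    responses[[tg]] <- r
  }

  cfg <- sim_config(guides = guides, genes = genes, responses = responses,
                    n_cells_per_guide = n_cells_per_guide, seed = seed, ...)
  cfg$archetypes <- data.frame(gene_id = trans_ids, archetype = archetype)
  cfg
}

## negative binomial draws, Poisson in the infinite-dispersion limit,
## with the optional extra-zero dropout layer
.draw_counts <- function(mu, dispersion, dropout_logit_scale) {
  n <- length(mu)
  x <- if (is.infinite(dispersion)) stats::rpois(n, mu)
       else stats::rnbinom(n, mu = mu, size = dispersion)
  s <- dropout_logit_scale
  if (s > 0) {
    keep <- rep(1L, n)
    pos <- mu > 0
    p_drop <- stats::plogis(-s * log(mu[pos]))
    keep[pos] <- stats::rbinom(sum(pos), 1L, 1 - p_drop)
    x <- x * keep
  }
  x
}

#' Simulate a targeted multimodal titration experiment
#'
#' Draws one dataset from a [sim_config()]: cells carry exactly one delivered
#' guide (plus ambient background over all guides), cDNA counts are negative
#' binomial with per-gene means `baseline_mean * 2^E`, where `E` is the
#' expected log2FC implied by the cell's guide (the cis gene is shifted by
#' the guide's `cis_log2fc` directly; trans genes by their
#' [response_truth()] evaluated at that dosage), hashtag counts follow the
#' cell's line with cross-contamination, and effector transcripts are present
#' only in the matched line. NTC guides are simulated in both lines.
#'
#' @param config A `sim_config`.
#' @return A list with `cdna`, `guides`, `hashes` ([counts_assay()] objects
#'   sharing barcodes), `guide_library` (the guide table), and `truth`
#'   (list: `cells` with each cell's delivered guide/line/dosage,
#'   `expected_log2fc` per (guide, gene), `response_class` per
#'   (cis gene, trans gene), and `archetypes` when the config carries them).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  guides <- config$guides
  genes <- config$genes
  cis_ids <- genes$gene_id[genes$role == "cis"]

  with_local_seed(config$seed, {
    ## --- cell table -----------------------------------------------------
    cell_rows <- list()
    for (i in seq_len(nrow(guides))) {
      lines <- if (guides$guide_class[i] == "NTC") c("CRISPRi", "CRISPRa")
               else guides$effector[i]
      for (ln in lines) {
        cell_rows[[length(cell_rows) + 1L]] <-
          data.frame(guide_id = guides$guide_id[i], line = ln,
                     n = config$n_cells_per_guide)
      }
    }
    groups <- do.call(rbind, cell_rows)
    n_total <- sum(groups$n)
    cells <- data.frame(
      barcode = sprintf("BC%06d-1", seq_len(n_total)),
      guide_id = rep(groups$guide_id, groups$n),
      line = rep(groups$line, groups$n),
      stringsAsFactors = FALSE)
    gi <- match(cells$guide_id, guides$guide_id)
    cells$dosage <- guides$cis_log2fc[gi]
    cells$target_gene <- guides$target_gene[gi]

    ## per-cell multiplet second guide
    cells$guide2 <- NA_character_
    if (config$multiplet_rate > 0) {
      is_mult <- stats::runif(n_total) < config$multiplet_rate
      cells$guide2[is_mult] <- sample(guides$guide_id, sum(is_mult), replace = TRUE)
    }

    ## on/off mixture: fully silenced with prob 1 - 2^fc (CRISPRi, fc < 0)
    cells$off_state <- FALSE
    if (config$onoff_mode) {
      idx <- which(cells$line == "CRISPRi" & !is.na(cells$target_gene) &
                     cells$dosage < 0)
      p_off <- pmin(pmax(1 - 2^cells$dosage[idx], 0), 1)
      cells$off_state[idx] <- stats::rbinom(length(idx), 1L, p_off) == 1L
    }

    ## --- expected log2FC per (guide, gene), matched line ----------------
    fc_genes <- genes$gene_id[genes$role %in%
                                c("cis", "trans", "control_high", "control_low")]
    exp_fc <- expand.grid(guide_id = guides$guide_id, gene_id = fc_genes,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    exp_fc$expected_log2fc <- 0
    for (i in seq_len(nrow(guides))) {
      tgt <- guides$target_gene[i]
      if (is.na(tgt)) next
      x <- guides$cis_log2fc[i]
      sel_cis <- exp_fc$guide_id == guides$guide_id[i] & exp_fc$gene_id == tgt
      exp_fc$expected_log2fc[sel_cis] <- x
      for (tg in names(config$responses)) {
        tr <- config$responses[[tg]][[tgt]]
        if (is.null(tr)) next
        sel <- exp_fc$guide_id == guides$guide_id[i] & exp_fc$gene_id == tg
        exp_fc$expected_log2fc[sel] <- eval_response(tr, x)
      }
    }

    ## --- cDNA counts ----------------------------------------------------
    panel <- genes
    n_genes <- nrow(panel)
    mu <- matrix(rep(panel$baseline_mean, n_total), nrow = n_genes)
    rownames(mu) <- panel$gene_id

    ## effector transcripts: matched line only
    for (k in which(panel$role == "effector_transcript")) {
      base <- panel$baseline_mean[k]
      if (is.na(base) || base <= 0) base <- config$effector_mean
      mu[k, ] <- ifelse(cells$line == panel$effector_line[k], base, 0)
    }

    ## apply expected fold changes per guide group (vectorised over cells)
    eff_dosage <- cells$dosage
    if (config$propagate_dosage_noise) {
      has_t <- !is.na(cells$target_gene)
      eff_dosage[has_t] <- eff_dosage[has_t] +
        stats::rnorm(sum(has_t), 0, config$dosage_noise_sd)
    }
    for (i in seq_len(nrow(guides))) {
      tgt <- guides$target_gene[i]
      if (is.na(tgt)) next
      cols <- which(cells$guide_id == guides$guide_id[i])
      if (!length(cols)) next
      x <- eff_dosage[cols]
      off <- cells$off_state[cols]
      ## binary on/off mode: cells are either fully silenced or untouched
      ## (the graded pseudo-bulk mean emerges from the mixture); graded
      ## mode shifts every cell by the guide's dosage
      onoff_here <- config$onoff_mode &&
        identical(guides$effector[i], "CRISPRi") && guides$cis_log2fc[i] < 0
      x_cell <- if (onoff_here) ifelse(off, -5, 0) else x
      cis_mult <- if (onoff_here) ifelse(off, 0, 1) else 2^x
      mu[tgt, cols] <- panel$baseline_mean[panel$gene_id == tgt] * cis_mult
      ## trans genes responding to this cis gene
      for (tg in names(config$responses)) {
        tr <- config$responses[[tg]][[tgt]]
        if (is.null(tr)) next
        mu[tg, cols] <- panel$baseline_mean[panel$gene_id == tg] *
          2^eval_response(tr, x_cell)
      }
    }

    cdna_counts <- matrix(
      .draw_counts(as.vector(mu), config$dispersion, config$dropout_logit_scale),
      nrow = n_genes, dimnames = list(panel$gene_id, cells$barcode))

    ## --- guide capture counts -------------------------------------------
    n_guides <- nrow(guides)
    g_counts <- matrix(stats::rpois(n_guides * n_total, config$ambient_guide_rate),
                       nrow = n_guides,
                       dimnames = list(guides$guide_id, cells$barcode))
    delivered_idx <- cbind(match(cells$guide_id, guides$guide_id), seq_len(n_total))
    g_counts[delivered_idx] <- g_counts[delivered_idx] +
      stats::rnbinom(n_total, mu = config$guide_capture_mean, size = config$dispersion)
    second <- which(!is.na(cells$guide2))
    if (length(second)) {
      idx2 <- cbind(match(cells$guide2[second], guides$guide_id), second)
      g_counts[idx2] <- g_counts[idx2] +
        stats::rnbinom(length(second), mu = config$guide_capture_mean,
                       size = config$dispersion)
    }

    ## --- hashtag counts ---------------------------------------------------
    hash_ids <- c(CRISPRi = "HTO_CRISPRi", CRISPRa = "HTO_CRISPRa")
    tot_hash <- stats::rnbinom(n_total, mu = config$hash_depth,
                               size = config$dispersion)
    own <- stats::rbinom(n_total, tot_hash, 1 - config$hash_error_rate)
    h_counts <- matrix(0L, nrow = 2, ncol = n_total,
                       dimnames = list(unname(hash_ids), cells$barcode))
    own_row <- ifelse(cells$line == "CRISPRi", 1L, 2L)
    h_counts[cbind(own_row, seq_len(n_total))] <- own
    h_counts[cbind(3L - own_row, seq_len(n_total))] <- tot_hash - own

    truth <- list(
      cells = cells[, c("barcode", "guide_id", "line", "dosage",
                        "target_gene", "guide2", "off_state")],
      expected_log2fc = exp_fc,
      response_class = {
        rc <- expand.grid(cis_gene = cis_ids,
                          gene_id = genes$gene_id[genes$role == "trans"],
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        rc$class <- "unresponsive"
        for (tg in names(config$responses)) {
          for (cg in names(config$responses[[tg]])) {
            rc$class[rc$cis_gene == cg & rc$gene_id == tg] <-
              truth_class(config$responses[[tg]][[cg]])
          }
        }
        rc
      })
    if (!is.null(config$archetypes)) truth$archetypes <- config$archetypes

    list(
      cdna = counts_assay(cdna_counts, panel$gene_id, cells$barcode, "cdna"),
      guides = counts_assay(g_counts, guides$guide_id, cells$barcode, "guide"),
      hashes = counts_assay(h_counts, unname(hash_ids), cells$barcode, "hash"),
      guide_library = guides,
      gene_table = genes,
      truth = truth)
  })
}

#' Write a simulated dataset to disk as plain-text fixtures
#'
#' Each modality is written as a MatrixMarket triplet matrix plus
#' `features.tsv` and `barcodes.tsv`; the guide library, gene table and truth
#' tables are written as TSV. Files round-trip losslessly through
#' [read_counts()].
#'
#' @param dataset Result of [simulate_experiment()].
#' @param directory Output directory.
#' @param force Overwrite an existing directory (default `FALSE`: refuse).
#' @return Invisibly, the directory path.
#' @export
write_fixture <- function(dataset, directory, force = FALSE) {
  if (dir.exists(directory) && !force) {
    stop("directory exists (use force = TRUE to overwrite): ", directory)
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (mod in c("cdna", "guides", "hashes")) {
    sub <- file.path(directory, mod)
    dir.create(sub, showWarnings = FALSE)
    a <- dataset[[mod]]
    Matrix::writeMM(a$counts, file.path(sub, "matrix.mtx"))
    utils::write.table(a$features, file.path(sub, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(a$barcodes, file.path(sub, "barcodes.tsv"))
  }
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(directory, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(dataset$guide_library, "guide_library.tsv")
  write_tsv(dataset$gene_table, "gene_table.tsv")
  write_tsv(dataset$truth$cells, "truth_cells.tsv")
  write_tsv(dataset$truth$expected_log2fc, "truth_expected_log2fc.tsv")
  write_tsv(dataset$truth$response_class, "truth_response_class.tsv")
  if (!is.null(dataset$truth$archetypes)) {
    write_tsv(dataset$truth$archetypes, "truth_archetypes.tsv")
  }
  invisible(directory)
}
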