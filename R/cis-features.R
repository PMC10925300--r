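## Cis determinants of dosage strength: effect size vs distance from the
## TSS, and chromatin-peak overlap tests.

#' Smoothed cis-effect profile over distance from the TSS
#'
#' Gaussian-kernel smoothed mean of per-guide cis log2 fold changes (signed
#' and absolute) as a function of the guide's TSS offset, per effector line.
#' Only TSS and tiling guides are used by default (attenuated guides sit at
#' fixed offsets with artificially weakened activity and NTCs have no
#' position; CRE guides are distal). The reported `argmax_offset` is the
#' offset maximising the smoothed |log2FC|.
#'
#' @param fc_table [fold_change_table()] output (cis rows used).
#' @param guide_library Guide table with `tss_offset_bp`.
#' @param effector `"CRISPRi"` or `"CRISPRa"`.
#' @param bandwidth Gaussian kernel SD in bp (default 150; the tiling
#'   interval is ~100 bp, so this pools neighbouring guides without
#'   oversmoothing).
#' @param classes Guide classes included (default TSS + tiling).
#' @param grid_n Evaluation grid resolution.
#' @return list(offsets, smoothed_abs, smoothed_signed, argmax_offset,
#'   guides = the per-guide table used)
#' @export
distance_profile <- function(fc_table, guide_library, effector,
                             bandwidth = 150, classes = c("TSS", "tiling"),
                             grid_n = 401L) {
  lib <- guide_library[guide_library$guide_class %in% classes &
                         !is.na(guide_library$tss_offset_bp), , drop = FALSE]
  cis <- fc_table[fc_table$family == "cis" & fc_table$line == effector &
                    !is.na(fc_table$log2fc), , drop = FALSE]
  m <- merge(lib[, c("guide_id", "tss_offset_bp")],
             cis[, c("guide_id", "log2fc")], by = "guide_id")
  if (nrow(m) < 5) stop("need >= 5 positioned guides with fold changes; have ",
                        nrow(m))
  grid <- seq(min(m$tss_offset_bp), max(m$tss_offset_bp), length.out = grid_n)
  smooth_at <- function(values) {
    vapply(grid, function(g) {
      w <- stats::dnorm(m$tss_offset_bp - g, sd = bandwidth)
      sum(w * values) / sum(w)
    }, numeric(1))
  }
  sm_abs <- smooth_at(abs(m$log2fc))
  sm_signed <- smooth_at(m$log2fc)
  list(offsets = grid, smoothed_abs = sm_abs, smoothed_signed = sm_signed,
       argmax_offset = grid[which.max(sm_abs)], guides = m)
}

#' Read a BED file of chromatin peaks
#'
#' @param path BED file (0-based half-open intervals).
#' @param mark_name Label for the peak set (default: file stem).
#' @return A `peak_set` list: `mark_name` and a `GRanges` of intervals.
#' @export
read_peaks <- function(path, mark_name = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- GenomicRanges::sort(gr)
  structure(list(mark_name = mark_name %||% sub("\\.bed$", "", basename(path)),
                 intervals = gr),
            class = "peak_set")
}

#' Guide genomic positions from TSS anchors
#'
#' Maps each positioned guide onto its cis gene's TSS anchor:
#' `pos = tss_pos + tss_offset_bp` (offsets are signed in transcription
#' direction).
#'
#' @param guide_library Guide table.
#' @param gene_table Gene table with `tss_pos` and `chrom` for cis genes.
#' @return data.frame(guide_id, chrom, pos) for guides with positions.
#' @export
guide_positions <- function(guide_library, gene_table) {
  lib <- guide_library[!is.na(guide_library$target_gene) &
                         !is.na(guide_library$tss_offset_bp), , drop = FALSE]
  gi <- match(lib$target_gene, gene_table$gene_id)
  out <- data.frame(guide_id = lib$guide_id,
                    chrom = gene_table$chrom[gi],
                    pos = gene_table$tss_pos[gi] + lib$tss_offset_bp)
  out[!is.na(out$pos) & !is.na(out$chrom), , drop = FALSE]
}

#' Which guides fall inside a peak set
#'
#' Point-in-interval overlap under the BED convention: a guide at 0-based
#' position `p` overlaps a 0-based half-open interval `[start, end)` iff
#' `start <= p < end`.
#'
#' @param positions [guide_positions()] output.
#' @param peaks A `peak_set`.
#' @return Logical vector along `positions` rows.
#' @export
guides_in_peaks <- function(positions, peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  pts <- GenomicRanges::GRanges(positions$chrom,
                                IRanges::IRanges(positions$pos + 1L, width = 1L))
  IRanges::overlapsAny(pts, peaks$intervals)
}

#' Test cis effect size against chromatin-peak overlap
#'
#' For each peak set, a two-sided Wilcoxon rank-sum test comparing the
#' |log2FC| of guides overlapping the mark vs guides outside it, with the
#' overlap counts reported.
#'
#' @param guide_library,gene_table For [guide_positions()].
#' @param peak_sets List of `peak_set` objects.
#' @param fc_table [fold_change_table()] output (cis rows).
#' @param effector Optional line restriction.
#' @return data.frame(mark, n_overlap, n_outside, median_abs_in,
#'   median_abs_out, p_value, reason)
#' @export
peak_overlap_test <- function(guide_library, gene_table, peak_sets, fc_table,
                              effector = NULL) {
  pos <- guide_positions(guide_library, gene_table)
  cis <- fc_table[fc_table$family == "cis" & !is.na(fc_table$log2fc), ]
  if (!is.null(effector)) cis <- cis[cis$line == effector, ]
  m <- merge(pos, cis[, c("guide_id", "log2fc")], by = "guide_id")
  rows <- list()
  for (ps in peak_sets) {
    ov <- guides_in_peaks(m, ps)
    if (!any(ov)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mark = ps$mark_name, n_overlap = 0L, n_outside = sum(!ov),
        median_abs_in = NA_real_, median_abs_out = NA_real_,
        p_value = NA_real_, reason = "no_overlapping_guides")
      next
    }
    a <- abs(m$log2fc[ov]); b <- abs(m$log2fc[!ov])
    p <- if (length(b) == 0) NA_real_ else
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    rows[[length(rows) + 1L]] <- data.frame(
      mark = ps$mark_name, n_overlap = length(a), n_outside = length(b),
      median_abs_in = stats::median(a), median_abs_out = stats::median(b),
      p_value = p, reason = NA_character_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
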