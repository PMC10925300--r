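## On-disk formats and the pipeline orchestrator. Fixtures are MatrixMarket
## triplets + features.tsv + barcodes.tsv per modality, TSV tables for
## everything else, and a YAML configuration whose defaults equal the
## package's documented defaults.

#' Read a sparse counts matrix with features and barcodes
#'
#' @param matrix_path MatrixMarket triplet file; duplicate (i, j) entries
#'   are summed.
#' @param features_path TSV whose first column is the feature id.
#' @param barcodes_path One barcode per line.
#' @param modality Passed to [counts_assay()].
#' @return A [counts_assay()].
#' @export
read_counts <- function(matrix_path, features_path, barcodes_path,
                        modality = "cdna") {
  for (p in c(matrix_path, features_path, barcodes_path)) {
    if (!file.exists(p)) stop("missing file: ", p)
  }
  m <- Matrix::readMM(matrix_path)
  ## triplet duplicates are summed by the conversion to column-compressed form
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  features <- utils::read.delim(features_path, header = TRUE,
                                stringsAsFactors = FALSE)
  barcodes <- readLines(barcodes_path)
  if (nrow(features) != nrow(m)) {
    stop("dimension mismatch: ", features_path, " has ", nrow(features),
         " features but matrix has ", nrow(m), " rows")
  }
  if (length(barcodes) != ncol(m)) {
    stop("dimension mismatch: ", barcodes_path, " has ", length(barcodes),
         " barcodes but matrix has ", ncol(m), " columns")
  }
  counts_assay(m, features, barcodes, modality)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param directory Fixture directory.
#' @return The same structure [simulate_experiment()] returns (truth tables
#'   included when present).
#' @export
read_fixture <- function(directory) {
  rd <- function(mod, modality) {
    read_counts(file.path(directory, mod, "matrix.mtx"),
                file.path(directory, mod, "features.tsv"),
                file.path(directory, mod, "barcodes.tsv"), modality)
  }
  tsv <- function(name) {
    p <- file.path(directory, name)
    if (file.exists(p)) utils::read.delim(p, stringsAsFactors = FALSE) else NULL
  }
  truth <- list(cells = tsv("truth_cells.tsv"),
                expected_log2fc = tsv("truth_expected_log2fc.tsv"),
                response_class = tsv("truth_response_class.tsv"),
                archetypes = tsv("truth_archetypes.tsv"))
  list(cdna = rd("cdna", "cdna"), guides = rd("guides", "guide"),
       hashes = rd("hashes", "hash"),
       guide_library = tsv("guide_library.tsv"),
       gene_table = tsv("gene_table.tsv"),
       truth = truth[!vapply(truth, is.null, TRUE)])
}

#' Default pipeline configuration
#'
#' All parameters default to the package's documented values; the config
#' round-trips through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param input_dir Fixture directory (`NULL` to simulate in-memory).
#' @param output_dir Result directory.
#' @param seed Master seed; every stage derives its randomness from it.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = "scdose_results",
                            seed = 1L) {
  structure(list(
    paths = list(input_dir = input_dir, output_dir = output_dir),
    seed = as.integer(seed),
    simulate = list(enabled = is.null(input_dir), n_cells_per_guide = 150L),
    assign = list(min_count = 3L, posterior_threshold = 0.5,
                  min_fit_cells = 20L, clr_margin = 1.0),
    qc = list(min_total_umis = 0L, max_total_umis = Inf,
              min_genes_detected = 0L),
    dosage = list(eps = 0.5, n_boot = 200L, min_cells = 10L,
                  cis_fdr = 0.10, trans_fdr = 0.05),
    response = list(daic_threshold = 2, range_min = 0.1, span = 0.75,
                    folds = 10L, n_starts = 10L,
                    grid_min = -1.83, grid_max = 0.51, grid_n = 100L,
                    restrict_one_copy = FALSE),
    downstream = list(k_clusters = 6L, daic_cuts = c(0, 2))),
    class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$qc$max_total_umis <- if (is.infinite(cfg$qc$max_total_umis)) ".inf"
                           else cfg$qc$max_total_umis
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (identical(cfg$qc$max_total_umis, ".inf")) cfg$qc$max_total_umis <- Inf
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (optional) -> demultiplex + assign + QC -> pseudo-bulk
#' fold changes -> dose-response fits + grid prediction -> downstream
#' clustering. Each stage logs the number of cells/guides/genes surviving
#' its filters; all result tables are written as TSV to the configured
#' output directory along with a manifest (seed, parameter hash, versions).
#' Rerunning with an identical config reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results (`dataset`,
#'   `annotation`, `fc_table`, `dosefits`, `grid`, `clusters`, paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$paths$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dataset <- run_stage("simulate", {
    if (isTRUE(config$simulate$enabled)) {
      .log_stage("simulate", "generating default synthetic dataset (seed %d)",
                 config$seed)
      simulate_experiment(default_sim_config(
        n_cells_per_guide = config$simulate$n_cells_per_guide,
        seed = config$seed))
    } else {
      .log_stage("simulate", "loading fixture from %s", config$paths$input_dir)
      read_fixture(config$paths$input_dir)
    }
  })

  annotation <- run_stage("assign", {
    eff_map <- c(CRISPRi = "EFF_KRAB", CRISPRa = "EFF_VPR")
    eff_rows <- intersect(unname(eff_map), feature_ids(dataset$cdna))
    eff <- as.matrix(dataset$cdna$counts[eff_rows, , drop = FALSE])
    rownames(eff) <- names(eff_map)[match(eff_rows, unname(eff_map))]
    lines <- demux_cell_lines(dataset$hashes, eff,
                              clr_margin = config$assign$clr_margin)
    asg <- assign_guides_gmm(dataset$guides,
                             min_count = config$assign$min_count,
                             posterior_threshold = config$assign$posterior_threshold,
                             min_fit_cells = config$assign$min_fit_cells,
                             seed = config$seed)
    qc <- qc_filter(dataset$cdna,
                    min_total_umis = config$qc$min_total_umis,
                    max_total_umis = config$qc$max_total_umis,
                    min_genes_detected = config$qc$min_genes_detected)
    ann <- cell_annotation(lines, asg$assignments, qc)
    .log_stage("assign", "%d cells; %d line-called; %d single-guide assigned",
               nrow(ann), sum(ann$line != "ambiguous"),
               sum(!is.na(ann$assigned_guide)))
    ann
  })
  .write_tsv(annotation, file.path(out_dir, "cell_annotation.tsv"))

  gene_table <- dataset$gene_table
  cis_genes <- gene_table$gene_id[gene_table$role == "cis"]
  trans_genes <- gene_table$gene_id[gene_table$role == "trans"]

  fc_table <- run_stage("dosage", {
    fc <- fold_change_table(dataset$cdna, annotation, dataset$guide_library,
                            genes = c(cis_genes, trans_genes,
                                      gene_table$gene_id[gene_table$role %in%
                                        c("control_high", "control_low")]),
                            eps = config$dosage$eps,
                            n_boot = config$dosage$n_boot,
                            min_cells = config$dosage$min_cells,
                            seed = config$seed)
    .log_stage("dosage", "%d (guide, gene) fold changes; %d cis-significant at %g FDR",
               nrow(fc), sum(fc$family == "cis" &
                               fc$q_value <= config$dosage$cis_fdr, na.rm = TRUE),
               config$dosage$cis_fdr)
    fc
  })
  .write_tsv(fc_table, file.path(out_dir, "fold_changes.tsv"))

  dosefits <- run_stage("response", {
    df <- fit_dose_responses(
      fc_table, dataset$guide_library, cis_genes, trans_genes,
      restrict_one_copy = config$response$restrict_one_copy,
      daic_threshold = config$response$daic_threshold,
      range_min = config$response$range_min,
      unresponsive_fdr = config$dosage$trans_fdr,
      span = config$response$span, folds = config$response$folds,
      n_starts = config$response$n_starts, seed = config$seed)
    .log_stage("response", "%d pairs fitted; classes: %s",
               sum(!is.na(df$response_class)),
               paste(names(table(df$response_class)),
                     table(df$response_class), collapse = ", "))
    df
  })
  .write_tsv(dosefits, file.path(out_dir, "dose_fits.tsv"))

  grid <- run_stage("response_grid", {
    predict_grid(dosefits, grid_min = config$response$grid_min,
                 grid_max = config$response$grid_max,
                 grid_n = config$response$grid_n)
  })
  pred_df <- as.data.frame(grid$predictions)
  names(pred_df) <- sprintf("x%03d", seq_along(grid$grid))
  grid_df <- data.frame(grid$pairs, pred_df, row.names = NULL)
  .write_tsv(grid_df, file.path(out_dir, "response_grid.tsv"))

  clusters <- run_stage("downstream", {
    cl <- cluster_responses(grid, k = config$downstream$k_clusters)
    .log_stage("downstream", "%d trans genes clustered into %d clusters (%d excluded)",
               length(cl$clusters), config$downstream$k_clusters,
               length(cl$excluded))
    cl
  })
  .write_tsv(data.frame(gene_id = names(clusters$clusters),
                        cluster = unname(clusters$clusters)),
             file.path(out_dir, "response_clusters.tsv"))

  manifest <- c(
    sprintf("scdose_version: %s",
            as.character(utils::packageVersion("scdose"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("seed: %d", config$seed),
    sprintf("config_hash: %s", config_hash(config)),
    sprintf("n_cells: %d", n_cells(dataset$cdna)),
    sprintf("n_guides: %d", nrow(dataset$guide_library)),
    sprintf("n_genes: %d", nrow(gene_table)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(dataset = dataset, annotation = annotation,
                 fc_table = fc_table, dosefits = dosefits, grid = grid,
                 clusters = clusters, output_dir = out_dir))
}

#' Stable hash of a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @return Hex md5 string of the serialised parameter list.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config), tmp, version = 2)
  unname(tools::md5sum(tmp))
}
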