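#' Construct a counts assay
#'
#' A `counts_assay` holds the sparse UMI count matrix for one capture
#' modality (cDNA, sgRNA, or hashtag) together with feature and barcode
#' identities. Features are rows, cells are columns, following the usual
#' droplet-data convention (matrix.mtx + features.tsv + barcodes.tsv).
#'
#' @param counts A matrix or sparse Matrix of non-negative UMI counts,
#'   features x cells.
#' @param features Character vector of feature ids (length `nrow(counts)`),
#'   or a data.frame whose first column is the feature id.
#' @param barcodes Character vector of cell barcodes (length `ncol(counts)`).
#' @param modality One of `"cdna"`, `"guide"`, `"hash"`.
#' @return An object of class `counts_assay` with elements `counts`
#'   (a `dgCMatrix`), `features` (data.frame), `barcodes` (character) and
#'   `modality`.
#' @export
counts_assay <- function(counts, features, barcodes, modality = c("cdna", "guide", "hash")) {
  modality <- match.arg(modality)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
                        "CsparseMatrix")
  if (is.character(features)) features <- data.frame(feature_id = features)
  stopifnot(is.data.frame(features), nrow(features) == nrow(counts))
  barcodes <- as.character(barcodes)
  stopifnot(length(barcodes) == ncol(counts))
  if (anyDuplicated(barcodes)) stop("duplicate cell barcodes")
  if (anyDuplicated(features[[1]])) stop("duplicate feature ids")
  dimnames(counts) <- list(as.character(features[[1]]), barcodes)
  structure(list(counts = counts, features = features, barcodes = barcodes,
                 modality = modality),
            class = "counts_assay")
}

#' @export
print.counts_assay <- function(x, ...) {
  cat(sprintf("<counts_assay:%s> %d features x %d cells, %d nonzero\n",
              x$modality, nrow(x$counts), ncol(x$counts),
              length(x$counts@x)))
  invisible(x)
}

#' @export
dim.counts_assay <- function(x) dim(x$counts)

n_cells <- function(assay) ncol(assay$counts)

## run code under a given seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}

feature_ids <- function(assay) rownames(assay$counts)

## subset an assay to a barcode set (order preserved as given)
subset_cells <- function(assay, barcodes) {
  counts_assay(assay$counts[, barcodes, drop = FALSE],
               assay$features, barcodes, assay$modality)
}

#' Benjamini-Hochberg adjustment within one declared test family
#'
#' Thin wrapper around [stats::p.adjust()] kept so that the family structure
#' (which p-values are corrected together) is explicit at call sites: the cis
#' tests form one family (judged at 10% FDR) and the trans tests another
#' (judged at 5% FDR).
#'
#' @param p Numeric vector of p-values constituting one family.
#' @return Numeric vector of BH q-values, same length and order as `p`.
#' @export
adjust_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}
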