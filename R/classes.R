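#' Construct a raw spatial transcriptomics dataset
#'
#' Bundles a spot-by-gene count matrix with per-spot spatial coordinates.
#' This is the entry object of the pipeline: counts are raw (non-negative
#' integers, typically UMIs), coordinates are continuous floats in the
#' chip's native units, and an optional in-tissue mask marks spots to keep.
#'
#' @param counts spot x gene matrix (base matrix or [Matrix::sparseMatrix])
#'   of non-negative counts.
#' @param coords spot x 2 numeric matrix (columns x, y).
#' @param gene_names character vector, one per gene column. Defaults to
#'   `colnames(counts)`.
#' @param spot_ids character vector of unique spot identifiers. Defaults to
#'   `rownames(counts)`.
#' @param in_tissue optional logical vector; `FALSE` spots are dropped by
#'   [filter_spots()].
#' @param section optional integer vector of section indices (1-based,
#'   ordered along the stacking axis) for multi-section 3D data.
#' @return An object of class `raw_dataset`.
#' @seealso [filter_spots()], [lognormalize()], [generate_spatial_data()]
#' @export
raw_dataset <- function(counts, coords, gene_names = colnames(counts),
                        spot_ids = rownames(counts), in_tissue = NULL,
                        section = NULL) {
  counts <- as_count_matrix(counts)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(counts)
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(counts)))
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(n))
  if (nrow(coords) != n)
    stop("coords has ", nrow(coords), " rows but counts has ", n, " spots")
  if (ncol(coords) < 2) stop("coords must have at least 2 columns (x, y)")
  if (ncol(coords) >= 3 && is.null(section)) {
    section <- as.integer(coords[, 3])
    coords <- coords[, 1:2, drop = FALSE]
  }
  coords <- coords[, 1:2, drop = FALSE]
  colnames(coords) <- c("x", "y")
  if (anyDuplicated(spot_ids)) stop("spot_ids must be unique")
  if (length(gene_names) != ncol(counts))
    stop("gene_names length does not match gene count")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (!is.null(in_tissue)) {
    in_tissue <- as.logical(in_tissue)
    stopifnot(length(in_tissue) == n)
  }
  if (!is.null(section)) {
    section <- as.integer(section)
    stopifnot(length(section) == n)
  }
  structure(list(counts = counts, coords = coords,
                 gene_names = as.character(gene_names),
                 spot_ids = as.character(spot_ids),
                 in_tissue = in_tissue, section = section),
            class = "raw_dataset")
}

as_count_matrix <- function(counts) {
  if (inherits(counts, "sparseMatrix")) {
    methods::as(counts, "CsparseMatrix")
  } else {
    methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE), "CsparseMatrix")
  }
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat("raw_dataset:", nrow(x$counts), "spots x", ncol(x$counts), "genes\n")
  if (!is.null(x$section))
    cat("  sections:", length(unique(x$section)), "\n")
  if (!is.null(x$in_tissue))
    cat("  in tissue:", sum(x$in_tissue), "/", length(x$in_tissue), "\n")
  invisible(x)
}

#' Construct a normalized expression matrix
#'
#' Holds the spot x gene matrix of normalized log expression that the
#' auto-encoder consumes (and that its decoder reconstructs).
#'
#' @param values dense numeric spot x gene matrix.
#' @param gene_names,spot_ids identifiers; default to dimnames.
#' @param denoised logical flag marking decoder output (see
#'   [denoised_expression()]).
#' @return An object of class `expression_matrix` with elements `values`,
#'   `gene_names`, `spot_ids`.
#' @export
expression_matrix <- function(values, gene_names = colnames(values),
                              spot_ids = rownames(values), denoised = FALSE) {
  values <- as.matrix(values)
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(values)))
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(values)))
  if (!all(is.finite(values))) stop("expression values must be finite")
  dimnames(values) <- list(spot_ids, gene_names)
  structure(list(values = values, gene_names = as.character(gene_names),
                 spot_ids = as.character(spot_ids), denoised = denoised),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "spots x", ncol(x$values),
      "genes", if (isTRUE(x$denoised)) "(denoised)" else "", "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
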