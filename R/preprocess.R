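#' Drop spots outside the tissue area
#'
#' Removes the spots whose `in_tissue` flag is `FALSE`, keeping counts,
#' coordinates, section labels and spot ids in lockstep. A dataset without
#' a mask is returned unchanged.
#'
#' @param raw a [raw_dataset()].
#' @return A `raw_dataset` restricted to in-tissue spots (mask cleared).
#' @export
filter_spots <- function(raw) {
  stopifnot(inherits(raw, "raw_dataset"))
  if (is.null(raw$in_tissue)) return(raw)
  keep <- which(raw$in_tissue)
  if (length(keep) == 0L) stop("no spots remain after tissue filtering")
  raw_dataset(raw$counts[keep, , drop = FALSE],
              raw$coords[keep, , drop = FALSE],
              gene_names = raw$gene_names,
              spot_ids = raw$spot_ids[keep],
              section = raw$section[keep])
}

#' Library-size normalization and log transform
#'
#' Scales each spot so its total count equals `target_sum`, then applies
#' `log(1 + x)`. With `target_sum = "median"` (default) the common scale is
#' the median library size across spots, which leaves typical spots almost
#' untouched.
#'
#' @param raw a [raw_dataset()].
#' @param target_sum positive scalar, or `"median"`.
#' @return An [expression_matrix()] of normalized log expression.
#' @export
lognormalize <- function(raw, target_sum = "median") {
  stopifnot(inherits(raw, "raw_dataset"))
  lib <- Matrix::rowSums(raw$counts)
  if (any(lib == 0)) {
    bad <- raw$spot_ids[which(lib == 0)[1]]
    stop("spot '", bad, "' has zero total count; remove it before normalizing")
  }
  if (identical(target_sum, "median")) target_sum <- stats::median(lib)
  stopifnot(is.numeric(target_sum), target_sum > 0)
  x <- as.matrix(raw$counts) * (target_sum / lib)
  expression_matrix(log1p(x), gene_names = raw$gene_names,
                    spot_ids = raw$spot_ids)
}

#' Select highly variable genes
#'
#' Ranks genes by mean-binned normalized dispersion (dispersion =
#' variance / mean, z-scored within bins of comparable mean expression —
#' the long-standing single-cell default) and keeps the top `n_top`.
#' Zero-variance genes have undefined dispersion and are never selected.
#' Returned columns keep the original gene order.
#'
#' @param expr an [expression_matrix()] of log-normalized values.
#' @param n_top number of genes to keep (default 3000); if fewer variable
#'   genes exist, all are kept.
#' @param n_bins number of mean-expression bins for dispersion
#'   normalization.
#' @return An `expression_matrix` restricted to the selected genes.
#' @export
select_hvg <- function(expr, n_top = 3000, n_bins = 20) {
  stopifnot(inherits(expr, "expression_matrix"), n_top >= 1)
  x <- expr$values
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  ok <- which(v > 0 & mu > 0)
  if (length(ok) <= n_top) {
    keep <- seq_len(ncol(x))  # nothing to rank away: identity
  } else {
    disp <- v[ok] / mu[ok]
    bins <- cut(rank(mu[ok], ties.method = "first"),
                breaks = min(n_bins, length(ok)), labels = FALSE)
    z <- disp
    for (b in unique(bins)) {
      idx <- bins == b
      m <- mean(disp[idx]); s <- stats::sd(disp[idx])
      z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
    }
    ord <- ok[order(z, decreasing = TRUE)]
    keep <- sort(ord[seq_len(n_top)])
  }
  expression_matrix(x[, keep, drop = FALSE],
                    gene_names = expr$gene_names[keep],
                    spot_ids = expr$spot_ids)
}
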