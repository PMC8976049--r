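#' @title Spatial neighbor networks
#' @description Internal constructor: wraps a binary symmetric adjacency
#'   with self-loops into an `snn` object.
#' @noRd
new_snn <- function(adjacency, spot_ids, mode, param) {
  adjacency <- methods::as(adjacency, "CsparseMatrix")
  adjacency@x[] <- 1
  structure(list(adjacency = Matrix::drop0(adjacency),
                 spot_ids = as.character(spot_ids),
                 mode = mode, param = param),
            class = "snn")
}

#' @export
print.snn <- function(x, ...) {
  n <- nrow(x$adjacency)
  stats <- snn_neighbor_stats(x)
  cat("snn (", x$mode, "): ", n, " spots, mean ",
      round(stats$mean_neighbors, 2), " neighbors/spot\n", sep = "")
  invisible(x)
}

#' Neighbor-count statistics of a spatial neighbor network
#'
#' Off-diagonal degree summary; useful for checking the radius rule's
#' recommendation of 6-15 neighbors per spot on average.
#'
#' @param snn an `snn` object.
#' @return list with `mean_neighbors`, `min_neighbors`, `max_neighbors`.
#' @export
snn_neighbor_stats <- function(snn) {
  deg <- Matrix::rowSums(snn$adjacency) - 1  # exclude self-loop
  list(mean_neighbors = mean(deg), min_neighbors = min(deg),
       max_neighbors = max(deg))
}

check_coords <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (anyNA(coords) || !all(is.finite(coords))) stop("coordinates contain NaN/NA")
  coords
}

#' Build a radius-based spatial neighbor network
#'
#' Connects two spots when their Euclidean distance is strictly below `r`
#' (boundary ties at exactly `r` are excluded); self-loops are always
#' present. For non-lattice platforms choose `r` so the mean neighbor
#' count lands around 6-15 (see [snn_neighbor_stats()]).
#'
#' @param coords spot x 2 numeric matrix.
#' @param r positive radius in coordinate units.
#' @param spot_ids optional spot identifiers.
#' @return An `snn` object.
#' @export
build_radius_snn <- function(coords, r, spot_ids = rownames(coords)) {
  coords <- check_coords(coords)
  stopifnot(r > 0, nrow(coords) >= 1)
  n <- nrow(coords)
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(n))
  # blocked pairwise distances: O(N^2) memory in blocks of ~2e7 entries
  block <- max(1L, floor(2e7 / n))
  ii <- jj <- list(); b <- 1L
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(rowSums(coords[rows, , drop = FALSE]^2), rowSums(coords^2), "+") -
      2 * coords[rows, , drop = FALSE] %*% t(coords)
    hit <- which(d2 < r^2, arr.ind = TRUE)
    ii[[b]] <- rows[hit[, 1]]; jj[[b]] <- hit[, 2]; b <- b + 1L
  }
  i <- unlist(ii); j <- unlist(jj)
  adj <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  Matrix::diag(adj) <- 1
  new_snn(adj, spot_ids, mode = "radius", param = r)
}

#' Build a k-nearest-neighbor spatial network
#'
#' Each spot selects its `k` nearest neighbors (Euclidean); the directed
#' relation is symmetrized by union, so an edge survives if either
#' endpoint selected the other. Self-loops are added. `k = 6` is the
#' default for Visium's hexagonal lattice, where each interior spot has
#' exactly six equidistant neighbors. Distance ties at the k-th position
#' are broken by spot index for determinism.
#'
#' @param coords spot x 2 numeric matrix.
#' @param k neighbors per spot (default 6); must be `< N`.
#' @param spot_ids optional spot identifiers.
#' @return An `snn` object.
#' @export
build_knn_snn <- function(coords, k = 6, spot_ids = rownames(coords)) {
  coords <- check_coords(coords)
  n <- nrow(coords)
  stopifnot(k >= 1)
  if (k >= n) stop("k (", k, ") must be smaller than the number of spots (", n, ")")
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(n))
  sq <- rowSums(coords^2)
  block <- max(1L, floor(2e7 / n))
  ii <- jj <- list(); b <- 1L
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * coords[rows, , drop = FALSE] %*% t(coords)
    for (ri in seq_along(rows)) {
      i0 <- rows[ri]
      d <- d2[ri, ]; d[i0] <- Inf
      nb <- order(d)[seq_len(k)]  # order() breaks ties by index
      ii[[b]] <- rep.int(i0, k); jj[[b]] <- nb; b <- b + 1L
    }
  }
  i <- unlist(ii); j <- unlist(jj)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  Matrix::diag(adj) <- 1
  new_snn(adj, spot_ids, mode = "knn", param = k)
}

#' Pre-cluster expression for the cell type-aware network
#'
#' Louvain community detection at low resolution (default 0.2) on a
#' k-nearest-neighbor graph of the top principal components of the
#' expression matrix. The coarse labels are used by
#' [prune_to_aware_snn()] to cut spatial edges that straddle distinct
#' expression programs. Recommended only for low-resolution platforms
#' (multi-cell spots); at cellular resolution the pre-clustering is noise
#' driven and pruning hurts.
#'
#' @param expr an [expression_matrix()].
#' @param resolution Louvain resolution (default 0.2, intentionally coarse).
#' @param n_pcs number of principal components (default 50, capped by dim).
#' @param k_graph kNN graph degree (default 15).
#' @param seed RNG seed for the community search.
#' @return list with `labels` (integer per spot, from 1) and `resolution`,
#'   class `precluster_labels`.
#' @export
precluster <- function(expr, resolution = 0.2, n_pcs = 50, k_graph = 15,
                       seed = 0) {
  stopifnot(inherits(expr, "expression_matrix"))
  x <- expr$values
  n <- nrow(x)
  if (n == 1L) {
    return(structure(list(labels = 1L, resolution = resolution),
                     class = "precluster_labels"))
  }
  n_pcs <- min(n_pcs, ncol(x), n - 1L)
  pcs <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  labels <- louvain_on_embedding(pcs, resolution = resolution,
                                 k_graph = min(k_graph, n - 1L), seed = seed)
  structure(list(labels = labels, resolution = resolution),
            class = "precluster_labels")
}

# Louvain on a union-symmetrized kNN graph of an embedding; shared by
# precluster() and cluster_louvain().
louvain_on_embedding <- function(emb, resolution, k_graph, seed) {
  n <- nrow(emb)
  sq <- rowSums(emb^2)
  d2 <- outer(sq, sq, "+") - 2 * emb %*% t(emb)
  diag(d2) <- Inf
  nb <- t(apply(d2, 1, function(d) order(d)[seq_len(k_graph)]))
  el <- cbind(rep(seq_len(n), each = k_graph), as.vector(t(nb)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(comm))
}

#' Prune a spatial network to expression pre-clusters
#'
#' Removes every edge whose endpoints carry different pre-cluster labels;
#' self-loops are always kept. The result's edge set is a subset of the
#' input's, so downstream attention on the pruned network can only
#' restrict, never add, information flow.
#'
#' @param snn an `snn` object.
#' @param labels a `precluster_labels` object (or integer vector, one per
#'   spot).
#' @return An `snn` object with `mode = "aware"`.
#' @export
prune_to_aware_snn <- function(snn, labels) {
  stopifnot(inherits(snn, "snn"))
  if (inherits(labels, "precluster_labels")) labels <- labels$labels
  n <- nrow(snn$adjacency)
  if (length(labels) != n) stop("labels must cover all ", n, " spots")
  tr <- Matrix::summary(snn$adjacency)
  keep <- labels[tr$i] == labels[tr$j] | tr$i == tr$j
  adj <- Matrix::sparseMatrix(i = tr$i[keep], j = tr$j[keep], x = 1,
                              dims = c(n, n))
  new_snn(adj, snn$spot_ids, mode = "aware", param = snn$param)
}

#' Build a 3D spatial network across aligned consecutive sections
#'
#' Combines the per-section 2D networks (block diagonal) with
#' inter-section edges: spots in *adjacent* sections are connected when
#' their in-plane (x, y) distance is below `inter_section_radius`
#' (coordinates must already be aligned across sections). Non-adjacent
#' sections are never connected. The inter-section edges let the
#' auto-encoder smooth over per-section batch effects while the
#' section-internal structure is preserved.
#'
#' @param per_section_snns list of `snn` objects, one per section, in
#'   stacking order.
#' @param coords list of per-section coordinate matrices (aligned), same
#'   order and row counts as the networks.
#' @param inter_section_radius positive radius for in-plane matching
#'   between adjacent sections.
#' @return An `snn` object over the concatenated spots.
#' @export
build_3d_snn <- function(per_section_snns, coords, inter_section_radius) {
  stopifnot(is.list(per_section_snns), length(per_section_snns) >= 1,
            length(coords) == length(per_section_snns),
            inter_section_radius > 0)
  ns <- length(per_section_snns)
  if (ns == 1L) return(per_section_snns[[1]])
  sizes <- vapply(per_section_snns, function(s) nrow(s$adjacency), 0L)
  offsets <- cumsum(c(0L, sizes[-ns]))
  n <- sum(sizes)
  blocks <- lapply(per_section_snns, function(s) s$adjacency)
  adj <- Matrix::bdiag(blocks)
  extra_i <- extra_j <- list()
  for (s in seq_len(ns - 1L)) {
    a <- check_coords(coords[[s]])[, 1:2, drop = FALSE]
    b <- check_coords(coords[[s + 1L]])[, 1:2, drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    hit <- which(d2 < inter_section_radius^2, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      extra_i[[s]] <- offsets[s] + hit[, 1]
      extra_j[[s]] <- offsets[s + 1L] + hit[, 2]
    }
  }
  i <- unlist(extra_i); j <- unlist(extra_j)
  if (length(i) > 0) {
    adj <- adj + Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                                      dims = c(n, n))
  }
  ids <- unlist(lapply(per_section_snns, function(s) s$spot_ids))
  if (anyDuplicated(ids)) {
    ids <- unlist(lapply(seq_len(ns), function(s)
      paste0("s", s, "_", per_section_snns[[s]]$spot_ids)))
  }
  new_snn(adj, ids, mode = "3d", param = inter_section_radius)
}

#' Edge list of a spatial neighbor network
#'
#' @param snn an `snn` object.
#' @param upper_only return each undirected edge once (i <= j)?
#' @param self_loops include the diagonal?
#' @return data.frame with integer columns `i`, `j`.
#' @export
snn_edges <- function(snn, upper_only = FALSE, self_loops = TRUE) {
  tr <- Matrix::summary(snn$adjacency)
  df <- data.frame(i = tr$i, j = tr$j)
  if (!self_loops) df <- df[df$i != df$j, , drop = FALSE]
  if (upper_only) df <- df[df$i <= df$j, , drop = FALSE]
  df[order(df$i, df$j), , drop = FALSE]
}
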