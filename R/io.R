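#' Write a dataset to plain-text files
#'
#' Writes either MatrixMarket sparse format (`counts.mtx` +
#' `genes.tsv` + `barcodes.tsv`) or a dense CSV (`counts.csv`), plus a
#' coordinate table `coords.csv` with columns `spot_id, x, y[, section]`.
#'
#' @param raw a [raw_dataset()].
#' @param dir output directory (created if missing).
#' @param format `"mtx+csv"` (default) or `"csv"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(raw, dir, format = c("mtx+csv", "csv")) {
  stopifnot(inherits(raw, "raw_dataset"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx+csv") {
    Matrix::writeMM(raw$counts, file.path(dir, "counts.mtx"))
    writeLines(raw$gene_names, file.path(dir, "genes.tsv"))
    writeLines(raw$spot_ids, file.path(dir, "barcodes.tsv"))
  } else {
    m <- as.matrix(raw$counts)
    dimnames(m) <- list(raw$spot_ids, raw$gene_names)
    utils::write.csv(m, file.path(dir, "counts.csv"))
  }
  cdf <- data.frame(spot_id = raw$spot_ids, x = raw$coords[, 1],
                    y = raw$coords[, 2])
  if (!is.null(raw$section)) cdf$section <- raw$section
  utils::write.csv(cdf, file.path(dir, "coords.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset from plain-text files
#'
#' Counterpart of [write_dataset()]. Spot order follows the coordinate
#' file; matrix and coordinate spot counts must agree.
#'
#' @param dir directory holding the files.
#' @param format `"mtx+csv"` or `"csv"`.
#' @return a [raw_dataset()].
#' @export
read_dataset <- function(dir, format = c("mtx+csv", "csv")) {
  format <- match.arg(format)
  coords_path <- file.path(dir, "coords.csv")
  if (!file.exists(coords_path)) stop("missing ", coords_path)
  cdf <- utils::read.csv(coords_path)
  if (format == "mtx+csv") {
    counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")),
                          "CsparseMatrix")
    genes <- readLines(file.path(dir, "genes.tsv"))
    barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  } else {
    m <- utils::read.csv(file.path(dir, "counts.csv"), row.names = 1,
                         check.names = FALSE)
    counts <- as_count_matrix(as.matrix(m))
    genes <- colnames(m)
    barcodes <- rownames(m)
  }
  if (nrow(counts) != nrow(cdf))
    stop("matrix has ", nrow(counts), " spots but coordinate file has ",
         nrow(cdf), " rows")
  ord <- match(cdf$spot_id, barcodes)
  if (anyNA(ord)) stop("coordinate spot_ids do not match matrix barcodes")
  raw_dataset(counts[ord, , drop = FALSE],
              as.matrix(cdf[, c("x", "y")]),
              gene_names = genes, spot_ids = cdf$spot_id,
              section = if ("section" %in% names(cdf)) cdf$section else NULL)
}

#' Export a spatial network as an edge-list TSV
#'
#' One undirected edge per line (`spot_id_a`, `spot_id_b`), self-loops
#' omitted (they are implicit and always present).
#'
#' @param snn an `snn` object.
#' @param path output TSV path.
#' @export
write_snn_edges <- function(snn, path) {
  ed <- snn_edges(snn, upper_only = TRUE, self_loops = FALSE)
  df <- data.frame(spot_id_a = snn$spot_ids[ed$i],
                   spot_id_b = snn$spot_ids[ed$j])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a spatial network from an edge-list TSV
#'
#' @param path TSV written by [write_snn_edges()].
#' @param spot_ids full spot id vector fixing node order (isolated spots
#'   keep only their self-loop).
#' @return an `snn` object.
#' @export
read_snn_edges <- function(path, spot_ids) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  i <- match(df$spot_id_a, spot_ids)
  j <- match(df$spot_id_b, spot_ids)
  if (anyNA(i) || anyNA(j)) stop("edge list contains unknown spot ids")
  n <- length(spot_ids)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  Matrix::diag(adj) <- 1
  new_snn(adj, spot_ids, mode = "imported", param = NA_real_)
}

#' End-to-end pipeline configuration
#'
#' Collects every stage parameter with the method's standard defaults:
#' median-library normalization, 3000 HVGs, kNN graph with k = 6
#' (Visium-style) or a radius rule, optional cell type-aware pruning at
#' pre-cluster resolution 0.2, 512-30 auto-encoder trained 500 (or 1000)
#' iterations at learning rate 1e-4 and weight decay 1e-4, then
#' GMM (k known) or Louvain clustering and Wilcoxon markers at 1% FDR.
#'
#' @param graph_mode `"knn"` or `"radius"`.
#' @param k,radius neighbor rule parameters (k defaults to 6).
#' @param aware use the cell type-aware module?
#' @param precluster_resolution Louvain resolution for the pre-clustering.
#' @param n_hvg HVG count (default 3000).
#' @param target_sum library-size target, or `"median"`.
#' @param n_domains number of domains for GMM clustering; `NULL` uses
#'   Louvain at `cluster_resolution`.
#' @param cluster_resolution Louvain resolution for domain calling.
#' @param inter_section_radius 3D mode inter-section radius; `NULL`
#'   reuses `radius` (or the lattice kNN scale).
#' @param fdr marker significance threshold.
#' @param seed global seed.
#' @param ... passed to [stagate_config()] (e.g. `n_iterations`,
#'   `hidden_dims`, `learning_rate`).
#' @return list of class `run_config`.
#' @export
run_config <- function(graph_mode = "knn", k = 6, radius = NULL,
                       aware = FALSE, precluster_resolution = 0.2,
                       n_hvg = 3000, target_sum = "median",
                       n_domains = NULL, cluster_resolution = 1,
                       inter_section_radius = NULL, fdr = 0.01,
                       seed = 0, ...) {
  graph_mode <- match.arg(graph_mode, c("knn", "radius"))
  model <- stagate_config(seed = seed, ...)
  structure(list(graph_mode = graph_mode, k = k, radius = radius,
                 aware = aware, precluster_resolution = precluster_resolution,
                 n_hvg = n_hvg, target_sum = target_sum,
                 n_domains = n_domains, cluster_resolution = cluster_resolution,
                 inter_section_radius = inter_section_radius, fdr = fdr,
                 seed = seed, model = model),
            class = "run_config")
}

build_graph_for <- function(raw, config) {
  if (is.null(raw$section) || length(unique(raw$section)) == 1L) {
    if (config$graph_mode == "knn") {
      build_knn_snn(raw$coords, k = config$k, spot_ids = raw$spot_ids)
    } else {
      if (is.null(config$radius)) stop("radius mode requires a radius")
      build_radius_snn(raw$coords, r = config$radius,
                       spot_ids = raw$spot_ids)
    }
  } else {
    secs <- sort(unique(raw$section))
    snns <- list(); coords <- list()
    for (s in seq_along(secs)) {
      rows <- which(raw$section == secs[s])
      coords[[s]] <- raw$coords[rows, , drop = FALSE]
      snns[[s]] <- if (config$graph_mode == "knn") {
        build_knn_snn(coords[[s]], k = config$k,
                      spot_ids = raw$spot_ids[rows])
      } else {
        build_radius_snn(coords[[s]], r = config$radius,
                         spot_ids = raw$spot_ids[rows])
      }
    }
    isr <- config$inter_section_radius
    if (is.null(isr)) isr <- if (!is.null(config$radius)) config$radius else 1.01
    build_3d_snn(snns, coords, inter_section_radius = isr)
  }
}

#' Run the full pipeline and write artifacts
#'
#' Preprocess (tissue filter, log-normalize, HVG) -> spatial graph
#' (2D or 3D by section labels; optional aware pruning) -> auto-encoder
#' training -> clustering -> marker ranking. Results are written as
#' plain-text tables plus a provenance JSON capturing the configuration
#' and seed.
#'
#' @param raw a [raw_dataset()] (spots in coordinate order), or a
#'   directory path readable by [read_dataset()].
#' @param outdir output directory.
#' @param config a [run_config()].
#' @param format input format when `raw` is a path.
#' @return invisible list with the in-memory results (`expr`, `snn`,
#'   `fit`, `domains`, `markers`).
#' @export
run_pipeline <- function(raw, outdir, config = run_config(),
                         format = "mtx+csv") {
  if (is.character(raw)) raw <- read_dataset(raw, format = format)
  stopifnot(inherits(raw, "raw_dataset"), inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, f) tryCatch(f(), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  raw <- stage("filter", function() filter_spots(raw))
  expr <- stage("normalize", function()
    lognormalize(raw, target_sum = config$target_sum))
  expr <- stage("hvg", function() select_hvg(expr, n_top = config$n_hvg))
  snn <- stage("graph", function() build_graph_for(raw, config))
  aware_snn <- NULL
  if (isTRUE(config$aware)) {
    aware_snn <- stage("aware-graph", function() {
      pl <- precluster(expr, resolution = config$precluster_resolution,
                       seed = config$seed)
      prune_to_aware_snn(snn, pl)
    })
  }
  fit <- stage("train", function()
    stagate_train(expr, snn, aware_snn = aware_snn, config = config$model))
  domains <- stage("cluster", function() {
    if (!is.null(config$n_domains)) {
      cluster_gmm(fit$embeddings, k = config$n_domains, seed = config$seed)
    } else {
      cluster_louvain(fit$embeddings, resolution = config$cluster_resolution,
                      seed = config$seed)
    }
  })
  markers <- NULL
  if (length(unique(domains$labels)) >= 2) {
    markers <- stage("markers", function()
      rank_markers(expr, domains, fdr = config$fdr))
  }
  # artifacts
  emb <- data.frame(spot_id = expr$spot_ids, fit$embeddings,
                    check.names = FALSE)
  utils::write.csv(emb, file.path(outdir, "embeddings.csv"), row.names = FALSE)
  den <- data.frame(spot_id = expr$spot_ids, fit$reconstruction$values,
                    check.names = FALSE)
  utils::write.csv(den, file.path(outdir, "denoised.csv"), row.names = FALSE)
  utils::write.csv(data.frame(spot_id = expr$spot_ids,
                              domain = domains$labels),
                   file.path(outdir, "labels.csv"), row.names = FALSE)
  if (!is.null(markers))
    utils::write.csv(markers, file.path(outdir, "markers.csv"),
                     row.names = FALSE)
  utils::write.table(fit$attention, file.path(outdir, "attention_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(iteration = seq_along(fit$loss_history),
                              loss = fit$loss_history),
                   file.path(outdir, "loss_history.csv"), row.names = FALSE)
  cfg <- config
  cfg$model <- unclass(cfg$model)
  prov <- list(config = unclass(cfg), seed = config$seed,
               config_hash = config_hash(config),
               package_version = as.character(utils::packageVersion("stagate")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(expr = expr, snn = snn, fit = fit, domains = domains,
                 markers = markers))
}

config_hash <- function(config) {
  cfg <- config
  cfg$model <- unclass(cfg$model)
  ser <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(as.character(ser))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
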