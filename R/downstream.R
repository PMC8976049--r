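#' Gaussian-mixture clustering of spot embeddings
#'
#' Model-based clustering with `mclust` for the case where the number of
#' spatial domains is known a priori (e.g. annotated cortical layers).
#' Uses the equal-covariance Gaussian mixture (`modelNames = "EEE"`),
#' whose deterministic hierarchical initialization makes results
#' reproducible for a fixed seed.
#'
#' @param emb spot x d embedding matrix (e.g. `fit$embeddings`).
#' @param k number of mixture components (domains).
#' @param seed RNG seed.
#' @param model_name mclust covariance model (default `"EEE"`).
#' @return list of class `domain_assignment` with `labels` (integer from
#'   1), `method`, `k`.
#' @export
cluster_gmm <- function(emb, k, seed = 0, model_name = "EEE") {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  stopifnot(k >= 1)
  if (k > n) stop("k (", k, ") exceeds the number of spots (", n, ")")
  set.seed(seed)
  if (k == 1L) {
    labels <- rep(1L, n)
  } else if (k == n) {
    labels <- seq_len(n)
  } else {
    mclustBIC <- mclust::mclustBIC  # Mclust() resolves this in the caller
    fit <- mclust::Mclust(emb, G = k, modelNames = model_name,
                          verbose = FALSE)
    if (is.null(fit)) fit <- mclust::Mclust(emb, G = k, verbose = FALSE)
    if (is.null(fit)) stop("mclust failed to fit ", k, " components")
    labels <- as.integer(fit$classification)
  }
  structure(list(labels = labels, method = "gmm", k = k, seed = seed),
            class = "domain_assignment")
}

#' Louvain clustering of spot embeddings
#'
#' Community detection on a union-symmetrized kNN graph of the
#' embeddings, for the case where the number of domains is unknown. The
#' resolution steers the granularity and is chosen by the analyst.
#'
#' @param emb spot x d embedding matrix.
#' @param resolution Louvain resolution (> 0).
#' @param k_graph kNN graph degree (default 15).
#' @param seed RNG seed (community search).
#' @return a `domain_assignment` (labels from 1).
#' @export
cluster_louvain <- function(emb, resolution = 1, k_graph = 15, seed = 0) {
  emb <- as.matrix(emb)
  stopifnot(resolution > 0)
  labels <- louvain_on_embedding(emb, resolution = resolution,
                                 k_graph = min(k_graph, nrow(emb) - 1L),
                                 seed = seed)
  structure(list(labels = labels, method = "louvain",
                 resolution = resolution, seed = seed),
            class = "domain_assignment")
}

#' @export
print.domain_assignment <- function(x, ...) {
  cat("domain_assignment (", x$method, "): ", length(x$labels), " spots, ",
      length(unique(x$labels)), " domains\n", sep = "")
  invisible(x)
}

# one-vs-rest Wilcoxon rank-sum z statistic and p-value per gene
# (normal approximation with tie correction), vectorized over genes
wilcoxon_genes <- function(x, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  p <- ncol(x)
  stat <- pval <- numeric(p)
  for (g in seq_len(p)) {
    rk <- rank(x[, g])
    w <- sum(rk[in_group])                 # rank-sum of the group
    mu <- n1 * (n + 1) / 2
    ties <- table(x[, g])
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sig2 <= 0) { stat[g] <- 0; pval[g] <- 1; next }
    z <- (w - mu) / sqrt(sig2)
    stat[g] <- z
    pval[g] <- 2 * stats::pnorm(-abs(z))
  }
  list(stat = stat, pval = pval)
}

#' Rank marker genes per spatial domain
#'
#' One-vs-rest Wilcoxon rank-sum test for every gene and domain (normal
#' approximation with tie correction), with Benjamini-Hochberg adjustment
#' applied within each domain's gene list. Genes with adjusted p below
#' `fdr` (default 1%) are flagged significant. Positive statistics mean
#' higher expression inside the domain.
#'
#' @param expr [expression_matrix()] (typically the normalized input or
#'   the denoised reconstruction).
#' @param domains a `domain_assignment` (or integer label vector).
#' @param fdr significance threshold on BH-adjusted p (default 0.01).
#' @return data.frame with columns `domain`, `gene`, `stat` (signed z),
#'   `p_value`, `p_adjusted`, `significant`, ordered by domain then
#'   adjusted p.
#' @export
rank_markers <- function(expr, domains, fdr = 0.01) {
  stopifnot(inherits(expr, "expression_matrix"))
  labels <- if (inherits(domains, "domain_assignment")) domains$labels else
    as.integer(domains)
  if (length(labels) != nrow(expr$values))
    stop("domain labels do not cover all spots")
  doms <- sort(unique(labels))
  if (length(doms) < 2) stop("need at least two domains to rank markers")
  out <- list()
  for (d in doms) {
    in_g <- labels == d
    if (sum(in_g) < 2 || sum(!in_g) < 2) {
      warning("domain ", d, " has fewer than 2 spots; skipped")
      next
    }
    wt <- wilcoxon_genes(expr$values, in_g)
    padj <- stats::p.adjust(wt$pval, method = "BH")
    df <- data.frame(domain = d, gene = expr$gene_names,
                     stat = wt$stat, p_value = wt$pval, p_adjusted = padj,
                     significant = padj < fdr)
    out[[as.character(d)]] <- df[order(df$p_adjusted, -df$stat), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Moran's I spatial autocorrelation
#'
#' Classic Moran's I of a per-spot variable with the SNN adjacency
#' (self-loops removed) as binary spatial weights:
#' `I = N / W * sum_ij w_ij (v_i - vbar)(v_j - vbar) / sum_i (v_i - vbar)^2`.
#' Positive values indicate spatially coherent (smooth) patterns.
#'
#' @param values numeric vector, one value per spot (nonzero variance).
#' @param snn an `snn` over the same spots.
#' @return scalar Moran's I.
#' @export
morans_i <- function(values, snn) {
  stopifnot(inherits(snn, "snn"))
  v <- as.numeric(values)
  n <- length(v)
  if (n != nrow(snn$adjacency)) stop("values do not cover all spots")
  if (stats::var(v) == 0) stop("values have zero variance; Moran's I undefined")
  w <- snn$adjacency
  Matrix::diag(w) <- 0
  w <- Matrix::drop0(w)
  z <- v - mean(v)
  s0 <- sum(w)
  num <- as.numeric(z %*% (w %*% z))
  (n / s0) * num / sum(z^2)
}

#' Extract the denoised expression matrix from a fit
#'
#' The decoder's reconstruction of the normalized expression, repackaged
#' with the original gene and spot names and flagged as denoised. Shape
#' and spot order always equal the training input.
#'
#' @param fit a `stagate_fit`.
#' @return an [expression_matrix()] with `denoised = TRUE`.
#' @export
denoised_expression <- function(fit) {
  stopifnot(inherits(fit, "stagate_fit"))
  fit$reconstruction
}

#' External clustering-agreement metrics
#'
#' Adjusted Rand index (via `mclust`), normalized mutual information
#' (arithmetic normalization) and homogeneity score of a predicted
#' labeling against ground truth.
#'
#' @param labels,truth integer/factor label vectors of equal length.
#' @return list with `ari`, `nmi`, `homogeneity`.
#' @export
cluster_metrics <- function(labels, truth) {
  if (inherits(labels, "domain_assignment")) labels <- labels$labels
  if (inherits(truth, "domain_assignment")) truth <- truth$labels
  stopifnot(length(labels) == length(truth))
  tab <- table(labels, truth)
  n <- sum(tab)
  pj <- colSums(tab) / n; pi_ <- rowSums(tab) / n
  pij <- tab / n
  mi <- sum(ifelse(pij > 0, pij * log(pij / (pi_ %o% pj)), 0))
  h_true <- -sum(ifelse(pj > 0, pj * log(pj), 0))
  h_pred <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  nmi <- if (mi == 0) 0 else mi / ((h_true + h_pred) / 2)
  # homogeneity = 1 - H(truth | pred) / H(truth), with H(truth|pred) = H(truth) - MI
  homogeneity <- if (h_true == 0) 1 else 1 - (h_true - mi) / h_true
  list(ari = mclust::adjustedRandIndex(labels, truth),
       nmi = nmi, homogeneity = homogeneity)
}
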