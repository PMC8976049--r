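# Graph attention auto-encoder.
#
# Architecture (two-layer encoder, mirrored decoder, tied weights):
#   z_i      = W1 x_i
#   e_ij     = sigmoid(v_s' z_i + v_r' z_j)            on SNN edges (i,j)
#   att_ij   = softmax over j in S_i of e_ij           (rows sum to 1)
#   h1_i     = elu( sum_j att_ij z_j )
#   h2_i     = elu( W2 h1_i )                          <- embedding
#   d1_i     = elu( sum_j att_ij (W2' h2_j) )          decoder, tied W2'
#   xhat_i   = elu( W1' d1_i )                         tied W1', no attention
# Loss: sum_i ||x_i - xhat_i||^2 (default) or the un-squared 2-norm.
# The decoder has no parameters of its own: weights are transposes of the
# encoder's and its attention is the encoder's attention object.

elu <- function(x) {
  if (is.matrix(x)) return(.elu_cpp(x))
  neg <- x < 0
  x[neg] <- expm1(x[neg])
  x
}
# derivative of elu at pre-activation x: 1 for x > 0, exp(x) otherwise
elu_grad <- function(x) {
  if (is.matrix(x)) return(.elu_grad_cpp(x))
  exp(pmin(x, 0))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# per-edge dot products row_i(A) . row_j(B); C++ kernel avoids E x d temporaries
edge_rowdot <- function(A, B, ei, ej) {
  .edge_rowdot_cpp(A, B, as.integer(ei), as.integer(ej))
}

#' Initialize model parameters
#'
#' Glorot-uniform initialization of the encoder weight matrices and the
#' attention weight vectors; the decoder reuses these (tied transposes),
#' so no decoder parameters exist.
#'
#' @param n_genes input dimension (number of genes after HVG selection).
#' @param hidden_dims encoder layer widths, default `c(512, 30)`; the last
#'   entry is the embedding dimension.
#' @param seed RNG seed.
#' @return list of class `stagate_params`: `W` (list of out x in
#'   matrices), `v_s`, `v_r` (attention vectors, length `hidden_dims[1]`),
#'   `dims`.
#' @export
stagate_params <- function(n_genes, hidden_dims = c(512, 30), seed = 0) {
  stopifnot(n_genes >= 1, length(hidden_dims) >= 1, all(hidden_dims >= 1))
  set.seed(seed)
  dims <- c(n_genes, hidden_dims)
  glorot <- function(nout, nin) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
  }
  W <- lapply(seq_along(hidden_dims),
              function(k) glorot(dims[k + 1], dims[k]))
  d1 <- hidden_dims[1]
  lim_v <- sqrt(6 / (d1 + 1))
  structure(list(W = W,
                 v_s = stats::runif(d1, -lim_v, lim_v),
                 v_r = stats::runif(d1, -lim_v, lim_v),
                 dims = dims),
            class = "stagate_params")
}

#' Materialize the (tied) decoder weights
#'
#' The decoder weight of layer k is the exact transpose of the encoder's
#' `W[[k]]` — returned here as concrete matrices for inspection; they are
#' never free parameters.
#'
#' @param params a `stagate_params` object.
#' @return list of matrices, `t(params$W[[k]])` per layer.
#' @export
get_decoder_weights <- function(params) lapply(params$W, t)

# Edge index of an SNN in canonical order (by receiving spot i, then j).
# Self-loops guarantee every i in 1..N appears, which rowsum() relies on.
snn_edge_index <- function(snn) {
  tr <- Matrix::summary(snn$adjacency)
  ord <- order(tr$i, tr$j)
  list(ei = tr$i[ord], ej = tr$j[ord], n = nrow(snn$adjacency))
}

#' Raw attention scores on the edges of a spatial network
#'
#' For every edge (i, j) of the network (self-loops included) computes
#' `sigmoid(v_s' (W h_i) + v_r' (W h_j))`, the unnormalized attention of
#' receiving spot i on neighbor j. Values lie in (0, 1).
#'
#' @param h spot x dim input features (the layer's input embedding).
#' @param W out x in weight matrix of the layer.
#' @param v_s,v_r attention vectors (length out).
#' @param snn an `snn` object.
#' @return numeric vector of scores, one per edge in [snn_edges()] order
#'   (sorted by i then j).
#' @export
attention_scores <- function(h, W, v_s, v_r, snn) {
  h <- as.matrix(h)
  if (ncol(h) != ncol(W)) stop("feature dimension ", ncol(h),
                               " does not match W input dimension ", ncol(W))
  if (length(v_s) != nrow(W) || length(v_r) != nrow(W))
    stop("attention vector length does not match W output dimension")
  idx <- snn_edge_index(snn)
  z <- h %*% t(W)
  s <- drop(z %*% v_s)
  r <- drop(z %*% v_r)
  sigmoid(s[idx$ei] + r[idx$ej])
}

# softmax of per-edge values over the receiving spot's neighbor set
softmax_edges <- function(e, ei) {
  ex <- exp(e)
  den <- rowsum(ex, ei)[, 1]
  unname(ex / den[ei])
}

#' Normalize attention scores per receiving spot
#'
#' Softmax of the raw edge scores over each spot's neighbor set
#' (self-loop included), so every spot's incoming weights sum to one.
#'
#' @param e raw scores from [attention_scores()], in edge order.
#' @param snn the `snn` the scores were computed on.
#' @return numeric vector of normalized weights per edge.
#' @export
normalize_attention <- function(e, snn) {
  idx <- snn_edge_index(snn)
  if (length(e) != length(idx$ei))
    stop("score vector length does not match SNN edge count")
  softmax_edges(e, idx$ei)
}

#' Attention map as a sparse row-stochastic matrix
#'
#' @param att per-edge weights in [snn_edges()] order.
#' @param snn the underlying `snn`.
#' @return a sparse N x N matrix whose rows sum to 1.
#' @export
attention_matrix <- function(att, snn) {
  idx <- snn_edge_index(snn)
  Matrix::sparseMatrix(i = idx$ei, j = idx$ej, x = att, dims = c(idx$n, idx$n))
}

#' Blend spatial and cell type-aware attention
#'
#' Linear combination `(1 - alpha) * spatial + alpha * aware`. The aware
#' map lives on a pruned subset of the spatial edge set and contributes 0
#' on pruned-away edges, so each row of the blend still sums to 1.
#'
#' @param att_spatial,att_aware sparse attention matrices (see
#'   [attention_matrix()]); the aware support must be a subset of the
#'   spatial support.
#' @param alpha weight of the aware component in `[0, 1]` (default 0.5).
#' @return sparse blended attention matrix.
#' @export
blend_attention <- function(att_spatial, att_aware, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  (1 - alpha) * att_spatial + alpha * att_aware
}

#' Encode expression into spot embeddings
#'
#' Applies the attention-weighted aggregation layers followed by the
#' final attention-free linear layer (all ELU-activated). With the
#' default two-layer architecture: one graph attention layer to the
#' hidden width, then a plain layer to the embedding width.
#'
#' @param x [expression_matrix()] or spot x gene matrix.
#' @param params `stagate_params`.
#' @param att attention: a sparse row-stochastic matrix (single attention
#'   layer) or a list of one per attention-bearing layer.
#' @return spot x d embedding matrix.
#' @export
encode <- function(x, params, att) {
  h <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  L <- length(params$W)
  if (!is.list(att)) att <- rep(list(att), max(L - 1L, 0L))
  if (L > 1L) {
    for (k in seq_len(L - 1L)) {
      h <- elu(as.matrix(att[[k]] %*% (h %*% t(params$W[[k]]))))
      if (anyNA(h)) stop("non-finite values in encoder layer ", k)
    }
  }
  h <- elu(h %*% t(params$W[[L]]))
  if (anyNA(h)) stop("non-finite values in final encoder layer")
  h
}

#' Decode embeddings back to expression (tied weights)
#'
#' Mirror of [encode()]: the first decoder layer aggregates neighbors
#' with the *encoder's* attention and the transpose of the last encoder
#' weight; the final decoder layer is attention-free and uses the
#' transpose of the first encoder weight.
#'
#' @param h spot x d embedding matrix (encoder output).
#' @inheritParams encode
#' @return spot x gene reconstructed matrix.
#' @export
decode <- function(h, params, att) {
  h <- as.matrix(h)
  L <- length(params$W)
  if (!is.list(att)) att <- rep(list(att), max(L - 1L, 0L))
  if (L > 1L) {
    for (k in seq(L, 2L)) {
      h <- elu(as.matrix(att[[k - 1L]] %*% (h %*% params$W[[k]])))
      if (anyNA(h)) stop("non-finite values in decoder layer ", k)
    }
  }
  xhat <- elu(h %*% params$W[[1L]])
  if (anyNA(xhat)) stop("non-finite values in final decoder layer")
  xhat
}

#' Reconstruction loss
#'
#' Sum over spots of the squared Euclidean distance between input and
#' reconstruction (default), or of the plain 2-norm (`mode = "norm"`).
#' The squared form is the optimization default (smooth at zero); both
#' share the perfect-reconstruction optimum.
#'
#' @param x,x_hat matrices (or [expression_matrix()]) of equal shape.
#' @param mode `"squared"` or `"norm"`.
#' @return scalar loss.
#' @export
reconstruction_loss <- function(x, x_hat, mode = c("squared", "norm")) {
  mode <- match.arg(mode)
  x <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  x_hat <- if (inherits(x_hat, "expression_matrix")) x_hat$values else as.matrix(x_hat)
  if (!all(dim(x) == dim(x_hat)))
    stop("shape mismatch: ", paste(dim(x), collapse = "x"), " vs ",
         paste(dim(x_hat), collapse = "x"))
  rsq <- rowSums((x - x_hat)^2)
  if (mode == "squared") sum(rsq) else sum(sqrt(rsq))
}

#' Training configuration
#'
#' Defaults follow the method's standard settings: two-layer 512-30
#' encoder, Adam at learning rate 1e-4 with weight decay 1e-4, ELU
#' activations, 500 iterations (1000 when the cell type-aware module is
#' active), aware-blend weight `alpha = 0.5`.
#'
#' @param hidden_dims encoder widths (hidden, embedding).
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient added to gradients.
#' @param n_iterations full-batch iterations; `NULL` picks 500, or 1000
#'   when an aware network is supplied.
#' @param alpha aware-attention blend weight in `[0, 1]`.
#' @param loss `"squared"` (default) or `"norm"` reconstruction loss.
#' @param seed RNG seed for parameter initialization.
#' @param verbose print loss every 50 iterations?
#' @return list of class `stagate_config`.
#' @export
stagate_config <- function(hidden_dims = c(512, 30), learning_rate = 1e-4,
                           weight_decay = 1e-4, n_iterations = NULL,
                           alpha = 0.5, loss = "squared", seed = 0,
                           verbose = FALSE) {
  stopifnot(learning_rate > 0, weight_decay >= 0,
            is.null(n_iterations) || n_iterations >= 1,
            length(hidden_dims) == 2)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  structure(list(hidden_dims = hidden_dims, learning_rate = learning_rate,
                 weight_decay = weight_decay, n_iterations = n_iterations,
                 alpha = alpha, loss = match.arg(loss, c("squared", "norm")),
                 seed = seed, verbose = verbose),
            class = "stagate_config")
}

# forward pass; returns all intermediates needed by the backward pass
stagate_forward <- function(P, X, idx, aware_idx = NULL, alpha = 0.5,
                            loss_mode = "squared") {
  W1 <- P$W[[1]]; W2 <- P$W[[2]]
  Z <- X %*% t(W1)
  s <- drop(Z %*% P$v_s); r <- drop(Z %*% P$v_r)
  e <- sigmoid(s[idx$ei] + r[idx$ej])
  att_sp <- softmax_edges(e, idx$ei)
  if (!is.null(aware_idx)) {
    aw <- aware_idx$mask
    att_aw <- softmax_edges(e[aw], idx$ei[aw])
    att <- (1 - alpha) * att_sp
    att[aw] <- att[aw] + alpha * att_aw
  } else {
    att_aw <- NULL
    att <- att_sp
  }
  A <- Matrix::sparseMatrix(i = idx$ei, j = idx$ej, x = att,
                            dims = c(idx$n, idx$n))
  H1p <- as.matrix(A %*% Z);  H1 <- elu(H1p)
  H2p <- H1 %*% t(W2);        H2 <- elu(H2p)
  M   <- H2 %*% W2
  D1p <- as.matrix(A %*% M);  D1 <- elu(D1p)
  Xhp <- D1 %*% W1;           Xh <- elu(Xhp)
  rsq <- .rowSums((X - Xh)^2, nrow(X), ncol(X))
  loss <- if (loss_mode == "squared") sum(rsq) else sum(sqrt(rsq))
  list(Z = Z, e = e, att_sp = att_sp, att_aw = att_aw, att = att, A = A,
       H1p = H1p, H1 = H1, H2p = H2p, H2 = H2, M = M, D1p = D1p, D1 = D1,
       Xhp = Xhp, Xh = Xh, loss = loss, rsq = rsq)
}

# analytic gradients of the reconstruction loss w.r.t. W1, W2, v_s, v_r
stagate_backward <- function(P, X, idx, fw, aware_idx = NULL, alpha = 0.5,
                             loss_mode = "squared") {
  W1 <- P$W[[1]]; W2 <- P$W[[2]]
  ei <- idx$ei; ej <- idx$ej
  if (loss_mode == "squared") {
    dXh <- -2 * (X - fw$Xh)
  } else {
    nrm <- sqrt(pmax(fw$rsq, 1e-12))
    dXh <- (fw$Xh - X) / nrm
  }
  G_Xhp <- dXh * elu_grad(fw$Xhp)
  gW1 <- crossprod(fw$D1, G_Xhp)                        # d1 x G
  G_D1p <- (G_Xhp %*% t(W1)) * elu_grad(fw$D1p)
  gA_dec <- edge_rowdot(G_D1p, fw$M, ei, ej)
  G_M <- as.matrix(Matrix::crossprod(fw$A, G_D1p))
  gW2 <- crossprod(fw$H2, G_M)                          # d2 x d1
  G_H2p <- (G_M %*% t(W2)) * elu_grad(fw$H2p)
  gW2 <- gW2 + crossprod(G_H2p, fw$H1)
  G_H1p <- (G_H2p %*% W2) * elu_grad(fw$H1p)
  gA_enc <- edge_rowdot(G_H1p, fw$Z, ei, ej)
  G_Z <- as.matrix(Matrix::crossprod(fw$A, G_H1p))
  gA <- gA_dec + gA_enc                                  # dL/datt per edge
  # attention -> raw scores, through the per-spot softmax Jacobian
  if (!is.null(aware_idx)) {
    aw <- aware_idx$mask
    d_sp <- (1 - alpha) * gA
    de <- fw$att_sp * (d_sp - rowsum(d_sp * fw$att_sp, ei)[, 1][ei])
    d_aw <- alpha * gA[aw]
    ei_aw <- ei[aw]
    de_aw <- fw$att_aw * (d_aw - rowsum(d_aw * fw$att_aw, ei_aw)[, 1][ei_aw])
    de[aw] <- de[aw] + de_aw
  } else {
    de <- fw$att * (gA - rowsum(gA * fw$att, ei)[, 1][ei])
  }
  du <- de * fw$e * (1 - fw$e)
  ds <- rowsum(du, ei)[, 1]
  dr <- numeric(idx$n)
  dr_part <- rowsum(du, ej)
  dr[as.integer(rownames(dr_part))] <- dr_part[, 1]
  gvs <- drop(crossprod(fw$Z, ds))
  gvr <- drop(crossprod(fw$Z, dr))
  G_Z <- G_Z + tcrossprod(ds, P$v_s) + tcrossprod(dr, P$v_r)
  gW1 <- gW1 + crossprod(G_Z, X)
  list(W1 = gW1, W2 = gW2, v_s = gvs, v_r = gvr)
}

#' Train the graph attention auto-encoder
#'
#' Full-batch Adam training on the whole spot graph. Attention is part of
#' the computation graph: the per-edge weights are recomputed from the
#' current parameters at every iteration and gradients flow through the
#' softmax and sigmoid. When `aware_snn` is given, raw scores are shared
#' but normalized separately over the full and pruned neighbor sets, then
#' blended with weight `alpha`.
#'
#' @param expr [expression_matrix()] (normalized log expression).
#' @param snn spatial neighbor network over the same spots.
#' @param aware_snn optional cell type-aware network from
#'   [prune_to_aware_snn()]; activates the blended-attention mode and the
#'   1000-iteration default.
#' @param config a [stagate_config()].
#' @return `stagate_fit`: `embeddings` (spot x d), `reconstruction`
#'   (spot x gene [expression_matrix()], flagged denoised), `params`,
#'   `attention` (edge data.frame with blended and component weights),
#'   `loss_history`, `diagnostics` (max deviation of attention row sums
#'   from 1 over all iterations), `config`.
#' @export
stagate_train <- function(expr, snn, aware_snn = NULL,
                          config = stagate_config()) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(snn, "snn"))
  X <- expr$values
  n <- nrow(X)
  if (nrow(snn$adjacency) != n)
    stop("SNN has ", nrow(snn$adjacency), " spots but expression has ", n)
  idx <- snn_edge_index(snn)
  aware_idx <- NULL
  if (!is.null(aware_snn)) {
    stopifnot(inherits(aware_snn, "snn"), nrow(aware_snn$adjacency) == n)
    key_all <- idx$ei * (n + 1) + idx$ej
    aidx <- snn_edge_index(aware_snn)
    key_aw <- aidx$ei * (n + 1) + aidx$ej
    if (!all(key_aw %in% key_all))
      stop("aware SNN edges are not a subset of the SNN edges")
    aware_idx <- list(mask = key_all %in% key_aw)
  }
  n_iter <- config$n_iterations
  if (is.null(n_iter)) n_iter <- if (is.null(aware_snn)) 500L else 1000L
  P <- stagate_params(ncol(X), config$hidden_dims, seed = config$seed)
  # Adam state
  mom <- lapply(list(P$W[[1]], P$W[[2]], P$v_s, P$v_r), function(p) p * 0)
  vel <- mom
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate; wd <- config$weight_decay
  loss_hist <- numeric(n_iter)
  max_dev <- 0
  fw <- NULL
  for (it in seq_len(n_iter)) {
    fw <- stagate_forward(P, X, idx, aware_idx, config$alpha, config$loss)
    if (!is.finite(fw$loss))
      stop("training diverged at iteration ", it, " (non-finite loss)")
    loss_hist[it] <- fw$loss
    max_dev <- max(max_dev, max(abs(rowsum(fw$att, idx$ei)[, 1] - 1)))
    g <- stagate_backward(P, X, idx, fw, aware_idx, config$alpha, config$loss)
    plist <- list(P$W[[1]], P$W[[2]], P$v_s, P$v_r)
    glist <- list(g$W1, g$W2, g$v_s, g$v_r)
    for (p in seq_along(plist)) {
      gr <- glist[[p]] + wd * plist[[p]]
      mom[[p]] <- b1 * mom[[p]] + (1 - b1) * gr
      vel[[p]] <- b2 * vel[[p]] + (1 - b2) * gr^2
      mhat <- mom[[p]] / (1 - b1^it)
      vhat <- vel[[p]] / (1 - b2^it)
      plist[[p]] <- plist[[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
    P$W[[1]] <- plist[[1]]; P$W[[2]] <- plist[[2]]
    P$v_s <- plist[[3]]; P$v_r <- plist[[4]]
    if (config$verbose && (it %% 50 == 0 || it == 1))
      message(sprintf("iter %4d  loss %.4f", it, fw$loss))
  }
  # final states under the trained parameters
  fw <- stagate_forward(P, X, idx, aware_idx, config$alpha, config$loss)
  emb <- fw$H2
  rownames(emb) <- expr$spot_ids
  colnames(emb) <- paste0("dim", seq_len(ncol(emb)))
  recon <- expression_matrix(fw$Xh, gene_names = expr$gene_names,
                             spot_ids = expr$spot_ids, denoised = TRUE)
  att_df <- data.frame(i = idx$ei, j = idx$ej,
                       spot_i = expr$spot_ids[idx$ei],
                       spot_j = expr$spot_ids[idx$ej],
                       att = fw$att, att_spatial = fw$att_sp)
  if (!is.null(aware_idx)) {
    att_df$att_aware <- 0
    att_df$att_aware[aware_idx$mask] <- fw$att_aw
  }
  structure(list(embeddings = emb, reconstruction = recon, params = P,
                 attention = att_df, loss_history = loss_hist,
                 diagnostics = list(max_attention_rowsum_dev = max_dev),
                 config = config, n_iterations = n_iter,
                 alpha = if (is.null(aware_snn)) NA_real_ else config$alpha),
            class = "stagate_fit")
}

#' @export
print.stagate_fit <- function(x, ...) {
  cat("stagate_fit:", nrow(x$embeddings), "spots,",
      ncol(x$embeddings), "embedding dims;",
      x$n_iterations, "iterations, final loss",
      format(utils::tail(x$loss_history, 1), digits = 6), "\n")
  invisible(x)
}
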