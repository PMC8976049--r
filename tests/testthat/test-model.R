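test_that("attention scores follow the sigmoid of the two projections", {
  coords <- cbind(c(0, 1), 0)
  snn <- build_radius_snn(coords, r = 1.5)       # fully connected pair
  h <- matrix(c(1, 2), 2, 1)
  # zero attention vectors: every score is sigmoid(0) = 0.5
  e0 <- attention_scores(h, matrix(1, 1, 1), 0, 0, snn)
  expect_equal(e0, rep(0.5, 4))  # 2 self-loops + 2 directed edges
  # scalar case: W = 1, v_s = 0.5, v_r = 0.25, h_i = 1, h_j = 2
  e <- attention_scores(h, matrix(1, 1, 1), 0.5, 0.25, snn)
  ed <- snn_edges(snn)
  score_12 <- e[ed$i == 1 & ed$j == 2]
  expect_equal(score_12, 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_true(all(e > 0 & e < 1))
  # v_s == v_r makes scores symmetric in (i, j)
  es <- attention_scores(h, matrix(1, 1, 1), 0.4, 0.4, snn)
  expect_equal(es[ed$i == 1 & ed$j == 2], es[ed$i == 2 & ed$j == 1])
  expect_error(attention_scores(matrix(1, 2, 3), matrix(1, 1, 1), 0, 0, snn),
               "dimension")
})

test_that("normalized attention is a softmax over each neighbor set", {
  # isolated spot: self-loop gets weight 1
  iso <- build_radius_snn(cbind(c(0, 10), 0), r = 1)
  att <- normalize_attention(c(0.3, 0.9), iso)
  expect_equal(att, c(1, 1))
  # uniform scores over 3 neighbors: 1/3 each
  tri <- build_radius_snn(cbind(c(0, 1, 0.5), c(0, 0, 0.8)), r = 1.2)
  e_tri <- rep(0.7, nrow(snn_edges(tri)))
  att_tri <- normalize_attention(e_tri, tri)
  expect_equal(att_tri, rep(1 / 3, 9))
  # closed form: two elements with e = 0 and ln 2 give 1/3 and 2/3
  pair <- build_radius_snn(cbind(c(0, 1), 0), r = 1.5)
  ed <- snn_edges(pair)
  e <- numeric(4)
  e[ed$i == 1 & ed$j == 1] <- 0
  e[ed$i == 1 & ed$j == 2] <- log(2)
  att <- normalize_attention(e, pair)
  expect_equal(att[ed$i == 1 & ed$j == 1], 1 / 3)
  expect_equal(att[ed$i == 1 & ed$j == 2], 2 / 3)
  # row sums are always 1
  expect_equal(unname(rowsum(att, ed$i)[, 1]), c(1, 1))
})

test_that("attention blending interpolates and validates alpha", {
  coords <- cbind(0:2, 0)
  snn <- build_radius_snn(coords, r = 1.5)
  aw <- prune_to_aware_snn(snn, c(1, 2, 2))
  e <- attention_scores(matrix(rnorm(3), 3, 1), matrix(1, 1, 1), 0.2, -0.1, snn)
  S <- attention_matrix(normalize_attention(e, snn), snn)
  idx_aw <- stagate:::snn_edge_index(aw)
  e_aw <- attention_scores(matrix(rnorm(3), 3, 1), matrix(1, 1, 1), 0.2, -0.1, aw)
  Aw <- attention_matrix(normalize_attention(e_aw, aw), aw)
  expect_equal(as.matrix(blend_attention(S, Aw, 0)), as.matrix(S))
  expect_equal(as.matrix(blend_attention(S, Aw, 1)),
               as.matrix(Aw) + 0 * as.matrix(S))
  half <- blend_attention(S, Aw, 0.5)
  expect_equal(unname(Matrix::rowSums(half)), rep(1, 3))
  expect_error(blend_attention(S, Aw, 1.2), "alpha")
  expect_equal(eval(formals(blend_attention)$alpha), 0.5)
})

test_that("encode/decode reduce to identity maps in the self-attention case", {
  # attention mass all on self-loops + identity weights + non-negative input
  # (ELU is identity on [0, Inf)) => encode is the identity
  n <- 4; G <- 3
  X <- matrix(runif(n * G), n, G)
  P <- stagate_params(G, hidden_dims = c(G, G), seed = 1)
  P$W[[1]] <- diag(G); P$W[[2]] <- diag(G)
  I_att <- Matrix::sparseMatrix(i = 1:n, j = 1:n, x = 1)
  expect_equal(encode(X, P, I_att), X, ignore_attr = TRUE)
  expect_equal(decode(encode(X, P, I_att), P, I_att), X, ignore_attr = TRUE)
  # zero input propagates to zero embedding
  expect_equal(encode(matrix(0, n, G), P, I_att), matrix(0, n, G),
               ignore_attr = TRUE)
})

test_that("decoder weights are exact transposes of encoder weights", {
  P <- stagate_params(7, hidden_dims = c(5, 2), seed = 3)
  dec <- get_decoder_weights(P)
  expect_identical(dec[[1]], t(P$W[[1]]))
  expect_identical(dec[[2]], t(P$W[[2]]))
})

test_that("sparse encoder/decoder matches the dense-matrix oracle", {
  set.seed(40)
  for (rep in 1:5) {
    n <- sample(4:12, 1); G <- sample(2:6, 1)
    X <- matrix(rnorm(n * G), n, G)
    coords <- cbind(runif(n, 0, 3), runif(n, 0, 3))
    snn <- build_radius_snn(coords, r = runif(1, 1, 2.5))
    P <- stagate_params(G, hidden_dims = c(4, 2), seed = rep)
    e <- attention_scores(X, P$W[[1]], P$v_s, P$v_r, snn)
    att <- normalize_attention(e, snn)
    A <- attention_matrix(att, snn)
    H2 <- encode(X, P, A)
    Xh <- decode(H2, P, A)
    ref <- dense_forward(X, P$W[[1]], P$W[[2]], as.matrix(A))
    expect_equal(H2, ref$H2, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(Xh, ref$Xh, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("reconstruction loss: zero at identity, hand values, shape guard", {
  x <- rbind(c(1, 0), c(3, 4))
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(rbind(c(1, 0)), rbind(c(0, 0))), 1)
  expect_equal(reconstruction_loss(rbind(c(1, 0)), rbind(c(0, 0)), "norm"), 1)
  expect_equal(reconstruction_loss(rbind(c(3, 4)), rbind(c(0, 0))), 25)
  expect_equal(reconstruction_loss(rbind(c(3, 4)), rbind(c(0, 0)), "norm"), 5)
  expect_error(reconstruction_loss(x, x[, 1, drop = FALSE]), "shape")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(41)
  n <- 6; G <- 4
  X <- matrix(rnorm(n * G), n, G)
  snn <- build_radius_snn(cbind(runif(n, 0, 3), runif(n, 0, 3)), r = 1.8)
  idx <- stagate:::snn_edge_index(snn)
  aw <- prune_to_aware_snn(snn, rep(1:2, each = 3))
  aidx <- local({
    key <- idx$ei * (n + 1) + idx$ej
    a <- stagate:::snn_edge_index(aw)
    list(mask = key %in% (a$ei * (n + 1) + a$ej))
  })
  for (case in list(list(aware = NULL, mode = "squared"),
                    list(aware = aidx, mode = "squared"),
                    list(aware = NULL, mode = "norm"))) {
    P <- stagate_params(G, hidden_dims = c(5, 2), seed = 2)
    fw <- stagate:::stagate_forward(P, X, idx, case$aware, 0.5, case$mode)
    g <- stagate:::stagate_backward(P, X, idx, fw, case$aware, 0.5, case$mode)
    num <- function(get, set) {
      p0 <- get(); gn <- p0 * 0; eps <- 1e-6
      for (i in seq_along(p0)) {
        p <- p0; p[i] <- p0[i] + eps; set(p)
        lp <- stagate:::stagate_forward(P, X, idx, case$aware, 0.5, case$mode)$loss
        p[i] <- p0[i] - eps; set(p)
        lm <- stagate:::stagate_forward(P, X, idx, case$aware, 0.5, case$mode)$loss
        gn[i] <- (lp - lm) / (2 * eps); set(p0)
      }
      gn
    }
    gn_W1 <- num(function() P$W[[1]], function(p) P$W[[1]] <<- p)
    gn_vs <- num(function() P$v_s, function(p) P$v_s <<- p)
    gn_vr <- num(function() P$v_r, function(p) P$v_r <<- p)
    expect_lt(max(abs(g$W1 - gn_W1)) / max(abs(gn_W1)), 1e-6)
    expect_lt(max(abs(g$v_s - gn_vs)) / max(abs(gn_vs) + 1e-9), 1e-5)
    expect_lt(max(abs(g$v_r - gn_vr)) / max(abs(gn_vr) + 1e-9), 1e-5)
  }
})

test_that("training reduces the loss and keeps attention normalized", {
  d <- generate_spatial_data(synthetic_spec(n_spots = 80, n_genes = 20,
                                            n_markers_per_domain = 5, seed = 7))
  expr <- lognormalize(d$raw)
  snn <- build_knn_snn(d$raw$coords, k = 6)
  fit <- stagate_train(expr, snn, config = stagate_config(
    hidden_dims = c(16, 4), n_iterations = 60, seed = 1))
  expect_lt(tail(fit$loss_history, 1), fit$loss_history[1])
  expect_lt(fit$diagnostics$max_attention_rowsum_dev, 1e-6)
  expect_equal(dim(fit$reconstruction$values), dim(expr$values))
  expect_identical(fit$reconstruction$spot_ids, expr$spot_ids)
})

test_that("training is equivariant to spot permutation", {
  # uniform-random coordinates: no lattice distance ties, so the kNN graph
  # is permutation-stable and training must be exactly equivariant
  d <- generate_spatial_data(synthetic_spec(lattice = "uniform", n_spots = 40,
                                            n_genes = 10,
                                            n_markers_per_domain = 3, seed = 8))
  expr <- lognormalize(d$raw)
  snn <- build_knn_snn(d$raw$coords, k = 4)
  cfg <- stagate_config(hidden_dims = c(8, 3), n_iterations = 30, seed = 5)
  fit <- stagate_train(expr, snn, config = cfg)
  set.seed(99)
  perm <- sample(40)
  expr_p <- expression_matrix(expr$values[perm, ],
                              gene_names = expr$gene_names,
                              spot_ids = expr$spot_ids[perm])
  snn_p <- build_knn_snn(d$raw$coords[perm, ], k = 4)
  fit_p <- stagate_train(expr_p, snn_p, config = cfg)
  expect_equal(fit_p$embeddings, fit$embeddings[perm, ],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit_p$reconstruction$values, fit$reconstruction$values[perm, ],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("information never flows between non-neighbors in layer 1", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(6:25, 1); G <- sample(2:5, 1)
    X <- matrix(rnorm(n * G), n, G)
    snn <- build_radius_snn(cbind(runif(n, 0, 4), runif(n, 0, 4)),
                            r = runif(1, 0.8, 2))
    P <- stagate_params(G, hidden_dims = c(4, 2), seed = rep)
    A <- as.matrix(snn$adjacency)
    nonadj <- which(A == 0, arr.ind = TRUE)
    if (nrow(nonadj) == 0) next
    pick <- nonadj[sample(nrow(nonadj), 1), ]
    i <- pick[1]; j <- pick[2]
    h_before <- layer1_output(P, X, snn)
    Xp <- X
    Xp[j, ] <- Xp[j, ] + rnorm(G, sd = 3)
    h_after <- layer1_output(P, Xp, snn)
    expect_equal(h_after[i, ], h_before[i, ], tolerance = 1e-12)
  }
})

test_that("reconstruction tracks signal rather than noise on rank-1 data", {
  set.seed(43)
  n <- 100; G <- 15
  signal <- outer(rep(1, n), seq(0.5, 3, length.out = G))
  noise <- matrix(rnorm(n * G, sd = 0.05), n, G)
  noisy <- pmax(signal + noise, 0)
  expr <- expression_matrix(noisy)
  snn <- build_knn_snn(cbind(runif(n, 0, 10), runif(n, 0, 10)), k = 6)
  fit <- stagate_train(expr, snn, config = stagate_config(
    hidden_dims = c(8, 2), n_iterations = 300, seed = 1,
    learning_rate = 1e-3))
  cor_signal <- cor(as.vector(fit$reconstruction$values), as.vector(signal))
  cor_noise <- cor(as.vector(fit$reconstruction$values), as.vector(noisy))
  expect_gt(cor_signal, cor_noise)
})

test_that("training configuration defaults match the standard settings", {
  cfg <- stagate_config()
  expect_equal(cfg$hidden_dims, c(512, 30))
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$weight_decay, 1e-4)
  expect_equal(cfg$alpha, 0.5)
  expect_error(stagate_config(alpha = 2), "alpha")
  # 500 iterations by default, 1000 with the aware module
  d <- generate_spatial_data(synthetic_spec(n_spots = 20, n_genes = 6,
                                            n_markers_per_domain = 0, seed = 1))
  expr <- lognormalize(d$raw)
  snn <- build_knn_snn(d$raw$coords, k = 3)
  cfg2 <- stagate_config(hidden_dims = c(4, 2), n_iterations = 2)
  fit <- stagate_train(expr, snn, config = cfg2)
  expect_equal(fit$n_iterations, 2)
})
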