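# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use naive dense / loop implementations so they share
# no code path with the package internals they check.

make_small_raw <- function(n = 8, G = 5, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n * G, lambda = 5) + 1, n, G)  # +1: no zero spots
  coords <- cbind(runif(n, 0, 4), runif(n, 0, 4))
  raw_dataset(counts, coords)
}

# brute-force O(N^2) radius graph: dense loops, strict inequality
brute_radius_adj <- function(coords, r) {
  n <- nrow(coords)
  A <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sqrt(sum((coords[i, ] - coords[j, ])^2)) < r) A[i, j] <- 1
  }
  A
}

# brute-force kNN with union symmetrization, index-order tie break
brute_knn_adj <- function(coords, k) {
  n <- nrow(coords)
  A <- diag(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]
    A[i, nb] <- 1
  }
  pmax(A, t(A))
}

# dense-matrix forward pass of the auto-encoder: explicit per-spot sums over
# a full N x N attention matrix (no sparse ops, no shared helpers)
dense_forward <- function(X, W1, W2, Adense) {
  n <- nrow(X)
  elu_ref <- function(v) ifelse(v > 0, v, exp(v) - 1)
  H1 <- matrix(0, n, nrow(W1))
  for (i in seq_len(n)) {
    acc <- numeric(nrow(W1))
    for (j in seq_len(n)) {
      if (Adense[i, j] != 0) acc <- acc + Adense[i, j] * as.numeric(W1 %*% X[j, ])
    }
    H1[i, ] <- elu_ref(acc)
  }
  H2 <- t(apply(H1, 1, function(h) elu_ref(as.numeric(W2 %*% h))))
  D1 <- matrix(0, n, nrow(W1))
  for (i in seq_len(n)) {
    acc <- numeric(nrow(W1))
    for (j in seq_len(n)) {
      if (Adense[i, j] != 0)
        acc <- acc + Adense[i, j] * as.numeric(t(W2) %*% H2[j, ])
    }
    D1[i, ] <- elu_ref(acc)
  }
  Xh <- t(apply(D1, 1, function(h) elu_ref(as.numeric(t(W1) %*% h))))
  list(H2 = H2, Xh = Xh)
}

# Moran's I by the literal double sum over a dense weight matrix
morans_i_brute <- function(values, Wdense) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + Wdense[i, j] * z[i] * z[j]
  (n / sum(Wdense)) * num / sum(z^2)
}

# first graph-attention layer output assembled from the exported operations
layer1_output <- function(P, X, snn) {
  e <- attention_scores(X, P$W[[1]], P$v_s, P$v_r, snn)
  att <- normalize_attention(e, snn)
  A <- attention_matrix(att, snn)
  stagate:::elu(as.matrix(A %*% (X %*% t(P$W[[1]]))))
}
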