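# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no data files.

# small omics matrix with reproducible values
toy_omics <- function(n = 6, d = 4, modality = "rna", seed = 1) {
  set.seed(seed)
  omics_matrix(matrix(rpois(n * d, 5), n, d),
               spot_ids = sprintf("s%02d", seq_len(n)),
               feature_names = sprintf("f%02d", seq_len(d)),
               modality = modality)
}

# a graph object with an arbitrary operator, for hand-built model tests
manual_graph <- function(adjacency, normalized_form = NULL) {
  structure(list(adjacency = methods::as(Matrix::Matrix(adjacency, sparse = TRUE),
                                         "generalMatrix"),
                 k = 1L, kind = "spatial", symmetrized = TRUE,
                 normalized_form = if (!is.null(normalized_form))
                   methods::as(Matrix::Matrix(normalized_form, sparse = TRUE),
                               "generalMatrix")),
            class = "nbr_graph")
}

# random symmetrized kNN graph for oracle tests
random_graph <- function(n, k = 2, seed = 1) {
  set.seed(seed)
  build_spatial_graph(matrix(runif(n * 2), n, 2), k1 = min(k, n - 1))
}

# identity-weight parameter block for a square gcn stack (d = hidden = latent)
identity_block <- function(d) list(W0 = diag(d), W1 = diag(d), W2 = diag(d))

# dense step-by-step oracle for the three-layer graph-convolution stack:
# layers 1-2 rectified, layer 3 linear (independent of the package's tape)
dense_gcn_oracle <- function(x, A, W0, W1, W2) {
  A <- as.matrix(A)
  h1 <- pmax(A %*% (x %*% W0), 0)
  h2 <- pmax(A %*% (h1 %*% W1), 0)
  A %*% (h2 %*% W2)
}

# model data bundle on a small lattice, for training tests
toy_model_data <- function(n_side = 6, d_f = 8, d1 = 5, d2 = 5, seed = 3) {
  set.seed(seed)
  n <- n_side^2
  coords <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side)))
  g_s <- build_spatial_graph(coords, k1 = 3)
  emb_f <- matrix(rnorm(n * d_f), n, d_f)
  emb1 <- matrix(rnorm(n * d1), n, d1)
  emb2 <- matrix(rnorm(n * d2), n, d2)
  g_f <- build_embedding_graph(emb_f, k2 = 4)
  g_1 <- build_embedding_graph(emb1, k2 = 4)
  g_2 <- build_embedding_graph(emb2, k2 = 4)
  list(emb_f = emb_f, emb1 = emb1, emb2 = emb2,
       A_s = g_s$normalized_form, A_f = g_f$normalized_form,
       A_1 = g_1$normalized_form, A_2 = g_2$normalized_form)
}
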