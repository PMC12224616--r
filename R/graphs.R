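#' Spot neighbourhood graphs
#'
#' Spots are connected either by physical proximity (the spatial graph: each
#' spot keeps its k1 nearest neighbours by Euclidean distance) or by
#' similarity of their low-dimensional profiles (the embedding graph: each
#' spot keeps the k2 spots with the highest Pearson correlation of
#' embeddings). Directed kNN selections are symmetrized by logical OR, and a
#' self-loop-augmented symmetric normalization D^{-1/2}(A+I)D^{-1/2} is
#' attached for use in graph convolutions.
#'
#' Ties (equal distances or correlations) are broken towards the lowest spot
#' index so graphs are reproducible.
#'
#' @name nbr_graph
NULL

new_nbr_graph <- function(adjacency, k, kind, normalized_form = NULL) {
  structure(list(adjacency = adjacency, k = as.integer(k), kind = kind,
                 symmetrized = TRUE, normalized_form = normalized_form),
            class = "nbr_graph")
}

#' @export
print.nbr_graph <- function(x, ...) {
  cat(sprintf("<nbr_graph> %s, %d spots, k = %d, %d undirected edges%s\n",
              x$kind, nrow(x$adjacency), x$k,
              Matrix::nnzero(x$adjacency) / 2,
              if (is.null(x$normalized_form)) "" else ", normalized"))
  invisible(x)
}

# rows of `score`: for each i pick k columns with smallest score (self given
# Inf by caller). Stable order() breaks ties by lowest index.
knn_select <- function(score, k) {
  n <- nrow(score)
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) idx[i, ] <- order(score[i, ])[seq_len(k)]
  idx
}

knn_adjacency <- function(idx) {
  n <- nrow(idx)
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(idx)), j = as.vector(idx),
                            x = 1, dims = c(n, n))
  sym <- a + Matrix::t(a)
  sym@x[] <- 1
  methods::as(sym, "generalMatrix")
}

#' Build the spatial k-nearest-neighbour graph
#'
#' @param p A [spot_coords()] (or numeric spot-by-2 matrix).
#' @param k1 Neighbours per spot before symmetrization (default 3).
#' @param normalize Attach the symmetric normalized form (default `TRUE`).
#' @return A `nbr_graph` with `kind = "spatial"`.
#' @export
build_spatial_graph <- function(p, k1 = 3L, normalize = TRUE) {
  coords <- if (inherits(p, "spot_coords")) p$coords else as.matrix(p)
  n <- nrow(coords)
  if (n < 2L) stop_validation("need at least 2 spots to build a graph")
  k1 <- assert_scalar_count(k1, "k1")
  if (k1 >= n) {
    warning("k1 >= N; clamped to N - 1 = ", n - 1L)
    k1 <- n - 1L
  }
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  g <- new_nbr_graph(knn_adjacency(knn_select(d, k1)), k1, "spatial")
  if (normalize) g <- normalize_adjacency(g) else g
}

#' Pearson correlation between spot embeddings
#'
#' Pairwise Pearson correlation of the rows of an embedding matrix. Rows of
#' zero variance get correlation 0 against everything (with a warning); the
#' diagonal is 1 for non-constant rows.
#'
#' @param e An [embedding_matrix()] (or numeric matrix) with at least 2
#'   columns.
#' @return A symmetric spot-by-spot matrix with entries in \[-1, 1\].
#' @export
pearson_matrix <- function(e) {
  x <- if (inherits(e, "embedding_matrix")) e$values else as.matrix(e)
  if (ncol(x) < 2L)
    stop_validation("row-wise correlation needs embedding dim >= 2")
  sds <- apply(x, 1L, stats::sd)
  const <- sds == 0
  r <- suppressWarnings(cor(t(x)))
  if (any(const)) {
    warning(sum(const), " constant embedding row(s); their correlations set to 0")
    r[const, ] <- 0
    r[, const] <- 0
  }
  r[is.na(r)] <- 0
  pmin(pmax(r, -1), 1)
}

#' Build the embedding (correlation) k-nearest-neighbour graph
#'
#' @param e An [embedding_matrix()] (or numeric matrix).
#' @param k2 Neighbours per spot by highest Pearson correlation (default 20).
#' @param normalize Attach the symmetric normalized form (default `TRUE`).
#' @return A `nbr_graph` with `kind = "embedding"`.
#' @export
build_embedding_graph <- function(e, k2 = 20L, normalize = TRUE) {
  r <- pearson_matrix(e)
  n <- nrow(r)
  if (n < 2L) stop_validation("need at least 2 spots to build a graph")
  k2 <- assert_scalar_count(k2, "k2")
  if (k2 >= n) {
    warning("k2 >= N; clamped to N - 1 = ", n - 1L)
    k2 <- n - 1L
  }
  score <- -r
  diag(score) <- Inf
  g <- new_nbr_graph(knn_adjacency(knn_select(score, k2)), k2, "embedding")
  if (normalize) g <- normalize_adjacency(g) else g
}

#' Symmetric self-loop normalization of an adjacency matrix
#'
#' Computes D^{-1/2} (A + I) D^{-1/2}, where D is the degree matrix of
#' A + I, and stores it in the graph's `normalized_form`. This is the
#' operator used by the graph-convolution layers.
#'
#' @param g A `nbr_graph`.
#' @return The graph with `normalized_form` filled in.
#' @export
normalize_adjacency <- function(g) {
  stopifnot(inherits(g, "nbr_graph"))
  a <- g$adjacency
  ahat <- a + Matrix::Diagonal(nrow(a))
  dinv <- 1 / sqrt(Matrix::rowSums(ahat))
  dm <- Matrix::Diagonal(x = dinv)
  g$normalized_form <- methods::as(dm %*% ahat %*% dm, "generalMatrix")
  g
}

# operator a graph contributes to the model: normalized if available
graph_operator <- function(g, raw_adjacency = FALSE) {
  if (raw_adjacency || is.null(g$normalized_form)) g$adjacency else g$normalized_form
}

#' Export a graph as an edge list
#'
#' Writes one `i<TAB>j` pair per undirected edge (0-based indices, i < j).
#'
#' @param g A `nbr_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_edgelist <- function(g, path) {
  stopifnot(inherits(g, "nbr_graph"))
  t3 <- methods::as(g$adjacency, "TsparseMatrix")
  ij <- cbind(i = t3@i, j = t3@j)         # already 0-based
  ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  write.table(ij, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("i", "j"))
  invisible(path)
}
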