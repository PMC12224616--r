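#' Fit the spatial multi-omics domain model
#'
#' End-to-end pipeline: align the two modalities and coordinates on shared
#' spots, normalize each modality (library-size + log1p for RNA/ATAC,
#' centered log-ratio for ADT), reduce both to PCA embeddings, obtain the
#' per-spot language-model embedding from a provider (or a supplied matrix),
#' build the spatial and correlation kNN graphs, train the six-branch graph
#' autoencoder with hierarchical attention fusion, and cluster the final
#' latent representation into spatial domains with a shared-covariance
#' Gaussian mixture.
#'
#' @param rna [omics_matrix()] of the RNA modality (raw counts or
#'   pre-normalized).
#' @param mod2 [omics_matrix()] of the second modality (ATAC or ADT).
#' @param coords [spot_coords()].
#' @param n_domains Number of spatial domains for the final clustering; set
#'   `NULL` to skip clustering.
#' @param embedding Optional precomputed per-spot [embedding_matrix()] (e.g.
#'   language-model output, spots in any order containing the aligned IDs) —
#'   overrides `provider`.
#' @param provider An [embedding_provider()]; default is the
#'   `pca_fallback` provider (width 64), which needs no external weights.
#'   Use `embedding_provider("zero")` for the zero-embedding ablation.
#' @param k1 Spatial-graph neighbours (default 3).
#' @param k2 Embedding-graph neighbours (default 20).
#' @param pca_dim PCA width for the two omics embeddings (default 50,
#'   clamped to the rank bound).
#' @param latent_dim Latent width entering attention (default 64).
#' @param hidden_dim Hidden layer width (default 256).
#' @param epochs Training epochs (default 200).
#' @param learning_rate Adam step size (default 1e-3).
#' @param loss_weights Named weights over `rec_1`, `rec_2`, `rec_fs`,
#'   `rec_fe`, `cor_1`, `cor_2` (all default 1).
#' @param normalize_rna,normalize_mod2 Normalization methods passed to
#'   [normalize_modality()]; `NULL` picks the modality default. Matrices
#'   already flagged normalized are left untouched.
#' @param raw_adjacency Use raw binary adjacencies in the graph convolutions
#'   instead of the symmetric normalized operator.
#' @param seed Seed governing initialization and clustering restarts.
#' @param verbose Progress messages.
#' @return An object of class `spafuse`; see [print.spafuse()],
#'   [summary.spafuse()], [plot.spafuse()]. Key fields: `latent` (final
#'   N x latent embedding), `latents` (all branch latents), `attention`
#'   (per-view weight matrices), `history` (per-epoch loss terms),
#'   `domains` (a `domain_assignment`, if clustered), `params` (trained
#'   weights).
#' @examples
#' \donttest{
#' sim <- simulate_spatial_multiomics(rows = 8, cols = 8, n_domains = 2,
#'                                    seed = 1)
#' fit <- spafuse(sim$rna, sim$mod2, sim$coords, n_domains = 2,
#'                epochs = 20, seed = 1)
#' compute_metrics(fit$domains, sim$truth)
#' }
#' @export
spafuse <- function(rna, mod2, coords, n_domains = NULL,
                    embedding = NULL, provider = NULL,
                    k1 = 3L, k2 = 20L, pca_dim = 50L,
                    latent_dim = 64L, hidden_dim = 256L,
                    epochs = 200L, learning_rate = 1e-3,
                    loss_weights = default_loss_weights(),
                    normalize_rna = NULL, normalize_mod2 = NULL,
                    raw_adjacency = FALSE, seed = 0L, verbose = FALSE) {
  cl <- match.call()
  al <- align_spots(rna, mod2, coords)
  n <- length(al$coords$spot_ids)
  say <- function(...) if (verbose) message(...)

  rna_n <- if (al$m1$normalized) al$m1 else
    normalize_modality(al$m1, normalize_rna)
  mod2_n <- if (al$m2$normalized) al$m2 else
    normalize_modality(al$m2, normalize_mod2)

  pd <- min(pca_dim, nrow(rna_n$values), ncol(rna_n$values),
            ncol(mod2_n$values))
  if (pd < pca_dim)
    say("pca_dim clamped to ", pd, " by the data dimensions")
  emb1 <- pca_embed(rna_n, pd, seed = seed)
  emb2 <- pca_embed(mod2_n, pd, seed = seed)

  if (!is.null(embedding)) {
    if (!inherits(embedding, "embedding_matrix"))
      embedding <- embedding_matrix(as.matrix(embedding), source = "llm")
    if (nrow(embedding$values) != n) {
      if (all(al$coords$spot_ids %in% embedding$spot_ids)) {
        embedding <- embedding_matrix(
          embedding$values[al$coords$spot_ids, , drop = FALSE],
          source = embedding$source)
      } else {
        stop_validation("embedding has ", nrow(embedding$values),
                        " rows but ", n, " aligned spots")
      }
    }
    emb_f <- embedding
  } else {
    if (is.null(provider))
      provider <- embedding_provider("pca_fallback", dim = 64L, seed = seed)
    emb_f <- embed_spots(provider, rna_n)
  }
  say("embedding source: ", emb_f$source, " (width ", emb_f$dim, ")")

  g_s <- build_spatial_graph(al$coords, k1 = k1)
  g_1 <- build_embedding_graph(emb1, k2 = k2)
  g_2 <- build_embedding_graph(emb2, k2 = k2)
  g_f <- if (emb_f$source == "zero") g_1 else build_embedding_graph(emb_f, k2 = k2)
  # an all-zero embedding has no correlation structure; its embedding-graph
  # branch falls back to the modality-1 graph so the ablation runs unchanged

  data <- list(emb_f = emb_f$values, emb1 = emb1$values, emb2 = emb2$values,
               A_s = graph_operator(g_s, raw_adjacency),
               A_f = graph_operator(g_f, raw_adjacency),
               A_1 = graph_operator(g_1, raw_adjacency),
               A_2 = graph_operator(g_2, raw_adjacency))
  say("training ", epochs, " epochs on ", n, " spots")
  tr <- train_model(data, loss_weights = loss_weights, epochs = epochs,
                    learning_rate = learning_rate, hidden = hidden_dim,
                    latent = latent_dim, seed = seed, verbose = verbose)

  latent <- tr$latent$Emb
  rownames(latent) <- al$coords$spot_ids
  domains <- NULL
  if (!is.null(n_domains)) {
    say("clustering into ", n_domains, " domains")
    domains <- cluster_embedding(latent, n_domains, seed = seed)
  }
  structure(list(
    call = cl, spot_ids = al$coords$spot_ids, coords = al$coords,
    latent = latent,
    latents = tr$latent[c("R_fs", "R_fe", "R_os1", "R_oe1", "R_os2", "R_oe2",
                          "EA_s", "EA_e", "EA_1", "EA_2")],
    attention = tr$latent$weights,
    history = tr$history, params = tr$params, data = data,
    loss_weights = tr$loss_weights, domains = domains,
    embedding_source = emb_f$source,
    graphs = list(spatial = g_s, emb1 = g_1, emb2 = g_2, emb_f = g_f),
    config = list(k1 = k1, k2 = k2, pca_dim = pd, latent_dim = latent_dim,
                  hidden_dim = hidden_dim, epochs = epochs,
                  learning_rate = learning_rate, seed = seed,
                  n_domains = n_domains, raw_adjacency = raw_adjacency)
  ), class = "spafuse")
}

#' @export
print.spafuse <- function(x, ...) {
  cat("Spatial multi-omics domain model\n")
  cat(sprintf("  %d spots, latent width %d, embedding source: %s\n",
              length(x$spot_ids), ncol(x$latent), x$embedding_source))
  if (nrow(x$history))
    cat(sprintf("  trained %d epochs, final total loss %.5g\n",
                max(x$history$epoch), x$history$total[nrow(x$history)]))
  if (!is.null(x$domains))
    cat(sprintf("  %d spatial domains (sizes: %s)\n", x$domains$n_domains,
                paste(table(x$domains$labels), collapse = ", ")))
  invisible(x)
}

#' @export
summary.spafuse <- function(object, ...) {
  x <- object
  print(x)
  if (nrow(x$history)) {
    cat("\nfinal loss terms:\n")
    last <- x$history[nrow(x$history), -1]
    for (nm in names(last)) cat(sprintf("  %-6s %.5g\n", nm, last[[nm]]))
  }
  cat("\nmean attention weight per view:\n")
  modal <- attention_view_modalities()
  for (v in names(x$attention)) {
    m <- colMeans(x$attention[[v]])
    mods <- modal[[v]]
    cat(sprintf("  view %-5s %s\n", v,
                paste(sprintf("%s=%.3f", mods, m), collapse = "  ")))
  }
  invisible(x)
}

#' Extract mean attention weights
#'
#' The per-view mean attention weights — the model's interpretable
#' "coefficients" saying how much each input contributes to each fusion.
#'
#' @param object A [spafuse()] fit.
#' @param ... Unused.
#' @return Named numeric vector `view.modality` -> mean weight.
#' @export
coef.spafuse <- function(object, ...) {
  modal <- attention_view_modalities()
  out <- c()
  for (v in names(object$attention)) {
    m <- colMeans(object$attention[[v]])
    names(m) <- paste(v, modal[[v]], sep = ".")
    out <- c(out, m)
  }
  out
}

#' @export
fitted.spafuse <- function(object, ...) object$latent

#' Reconstruction residuals
#'
#' Differences between each omics embedding and its decode from the final
#' latent representation (through the spatial graph), one matrix per
#' modality.
#'
#' @param object A [spafuse()] fit.
#' @param ... Unused.
#' @return List with `emb1` and `emb2` residual matrices.
#' @export
residuals.spafuse <- function(object, ...) {
  g <- list(normalized_form = object$data$A_s, adjacency = object$data$A_s)
  class(g) <- "nbr_graph"
  list(emb1 = object$data$emb1 -
         decoder_forward(object$latent, g, object$params$dec_o1),
       emb2 = object$data$emb2 -
         decoder_forward(object$latent, g, object$params$dec_o2))
}

#' @export
logLik.spafuse <- function(object, ...) {
  if (is.null(object$domains))
    stop_validation("fit has no clustering; refit with n_domains set")
  ll <- object$domains$loglik
  attr(ll, "df") <- NA_integer_
  class(ll) <- "logLik"
  ll
}

#' Plot a fitted domain model
#'
#' `type = "domains"` draws the spot lattice colored by assigned domain;
#' `"loss"` draws the training total loss; `"attention"` draws per-view
#' mean weights.
#'
#' @param x A [spafuse()] fit.
#' @param type Plot type.
#' @param ... Passed to the underlying base-graphics call.
#' @export
plot.spafuse <- function(x, type = c("domains", "loss", "attention"), ...) {
  type <- match.arg(type)
  if (type == "domains") {
    if (is.null(x$domains)) stop_validation("fit has no clustering")
    graphics::plot(x$coords$coords, col = x$domains$labels, pch = 15,
                   asp = 1, xlab = "x", ylab = "y",
                   main = "Spatial domains", ...)
  } else if (type == "loss") {
    graphics::plot(x$history$epoch, x$history$total, type = "l",
                   xlab = "epoch", ylab = "total loss",
                   main = "Training loss", ...)
  } else {
    w <- coef(x)
    graphics::barplot(w, las = 2, cex.names = 0.7,
                      ylab = "mean attention weight", ...)
  }
  invisible(x)
}
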