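# Domain clustering, supervised evaluation metrics, attention summaries.

# Shared-covariance (EEE family) Gaussian-mixture EM with seeded kmeans
# restarts. Free mixing proportions and means; one pooled full covariance.
gmm_eee <- function(x, n_components, seed = 0L, n_start = 5L,
                    max_iter = 200L, tol = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x); k <- n_components
  best <- NULL
  for (r in seq_len(n_start)) {
    km <- with_seed(seed + 1000L * r,
                    kmeans(x, centers = k, nstart = 1L, iter.max = 50L))
    z <- matrix(0, n, k)
    z[cbind(seq_len(n), km$cluster)] <- 1
    ll_trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      nk <- colSums(z)
      nk <- pmax(nk, 1e-10)
      pi_k <- nk / n
      mu <- crossprod(z, x) / nk                 # k x d
      sigma <- matrix(0, d, d)
      for (j in seq_len(k)) {
        xc <- sweep(x, 2L, mu[j, ], `-`)
        sigma <- sigma + crossprod(xc * z[, j], xc)
      }
      sigma <- sigma / n
      ch <- tryCatch(chol(sigma), error = function(e) NULL)
      if (is.null(ch)) {
        warning("singular pooled covariance; adding diagonal jitter")
        sigma <- sigma + diag(1e-6 * (mean(diag(sigma)) + 1e-12), d)
        ch <- chol(sigma)
      }
      logdet <- 2 * sum(log(diag(ch)))
      logd <- matrix(0, n, k)
      for (j in seq_len(k)) {
        xc <- sweep(x, 2L, mu[j, ], `-`)
        q <- backsolve(ch, t(xc), transpose = TRUE)  # d x n
        logd[, j] <- log(pi_k[j]) -
          0.5 * (d * log(2 * pi) + logdet + colSums(q * q))
      }
      mx <- apply(logd, 1L, max)
      lse <- mx + log(rowSums(exp(logd - mx)))
      ll <- sum(lse)
      ll_trace <- c(ll_trace, ll)
      z <- exp(logd - lse)
      if (is.finite(ll_old) && ll - ll_old < tol * abs(ll_old)) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$loglik) {
      best <- list(labels = max.col(z, ties.method = "first"),
                   loglik = ll, loglik_trace = ll_trace,
                   means = mu, covariance = sigma, proportions = pi_k,
                   restart = r)
    }
  }
  best
}

#' Cluster the latent embedding into spatial domains
#'
#' Model-based clustering of the spot embedding with a Gaussian mixture
#' whose components share one full covariance matrix (the EEE covariance
#' family of mclust), fitted by EM from several seeded k-means starts; the
#' restart with the highest log-likelihood wins. Deterministic under a
#' fixed seed.
#'
#' @param e Spot-by-latent numeric matrix (or [embedding_matrix()]).
#' @param n_domains Number of domains (>= 2, <= N).
#' @param seed RNG seed for the restarts.
#' @param n_start Number of k-means restarts (default 5).
#' @param method `"em"` (native EM, default) or `"mclust"` (requires the
#'   mclust package; model `"EEE"`).
#' @return List of class `domain_assignment`: `labels` (1-based integer
#'   domains), `n_domains`, `method`, `loglik`, and for `"em"` the
#'   `loglik_trace` across EM iterations of the winning restart.
#' @export
cluster_embedding <- function(e, n_domains, seed = 0L, n_start = 5L,
                              method = c("em", "mclust")) {
  method <- match.arg(method)
  x <- if (inherits(e, "embedding_matrix")) e$values else as.matrix(e)
  n_domains <- assert_scalar_count(n_domains, "n_domains")
  if (n_domains < 2L) stop_validation("n_domains must be at least 2")
  if (n_domains > nrow(x))
    stop_validation("n_domains (", n_domains, ") exceeds spot count (", nrow(x), ")")
  if (method == "mclust") {
    if (!requireNamespace("mclust", quietly = TRUE))
      stop_validation("method = 'mclust' requires the mclust package")
    mclustBIC <- mclust::mclustBIC  # Mclust() resolves this in the caller
    fit <- with_seed(seed, mclust::Mclust(x, G = n_domains, modelNames = "EEE",
                                          verbose = FALSE))
    return(structure(list(labels = as.integer(fit$classification),
                          n_domains = n_domains, method = "mclust",
                          loglik = fit$loglik, loglik_trace = NULL),
                     class = "domain_assignment"))
  }
  fit <- gmm_eee(x, n_domains, seed = seed, n_start = n_start)
  structure(list(labels = as.integer(fit$labels), n_domains = n_domains,
                 method = "em", loglik = fit$loglik,
                 loglik_trace = fit$loglik_trace, means = fit$means,
                 covariance = fit$covariance, proportions = fit$proportions),
            class = "domain_assignment")
}

#' @export
print.domain_assignment <- function(x, ...) {
  cat(sprintf("<domain_assignment> %d spots, %d domains (%s)\n",
              length(x$labels), x$n_domains, x$method))
  print(table(domain = x$labels))
  invisible(x)
}

entropy_nat <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# expected mutual information under the hypergeometric null (Vinh et al.)
expected_mi <- function(a, b, n) {
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1L, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      nij <- lo:hi
      log_p <- lgamma(a[i] + 1) + lgamma(b[j] + 1) + lgamma(n - a[i] + 1) +
        lgamma(n - b[j] + 1) - lgamma(n + 1) - lgamma(nij + 1) -
        lgamma(a[i] - nij + 1) - lgamma(b[j] - nij + 1) -
        lgamma(n - a[i] - b[j] + nij + 1)
      emi <- emi + sum(nij / n * log(n * nij / (a[i] * b[j])) * exp(log_p))
    }
  }
  emi
}

#' Supervised clustering agreement metrics
#'
#' Homogeneity, V-measure, adjusted mutual information (AMI), normalized
#' mutual information (NMI), and the adjusted Rand index (ARI) between a
#' predicted partition and a ground-truth annotation. Entropies use natural
#' logarithms; NMI is normalized by the arithmetic mean of the two
#' entropies; AMI uses the max-entropy denominator with the exact
#' hypergeometric expected mutual information. All metrics are invariant to
#' label renaming.
#'
#' @param pred,truth Label vectors of equal length (integers, factors or a
#'   `domain_assignment`).
#' @return List of class `metric_report` with elements `homogeneity`,
#'   `v_measure`, `ami`, `nmi`, `ari`.
#' @examples
#' compute_metrics(c(1, 1, 2, 2), c(1, 1, 2, 2))
#' @export
compute_metrics <- function(pred, truth) {
  lab <- function(x) if (inherits(x, "domain_assignment")) x$labels else x
  pred <- lab(pred); truth <- lab(truth)
  if (length(pred) != length(truth))
    stop_validation("pred has length ", length(pred), " but truth has ",
                    length(truth))
  n <- length(pred)
  tab <- table(truth, pred)
  a <- rowSums(tab); b <- colSums(tab)
  h_t <- entropy_nat(a); h_p <- entropy_nat(b)
  nz <- tab > 0
  mi <- sum((tab[nz] / n) * log(n * tab[nz] / (a[row(tab)][nz] * b[col(tab)][nz])))
  mi <- max(mi, 0)
  # conditional entropies
  h_t_given_p <- h_t - mi
  h_p_given_t <- h_p - mi
  homogeneity <- if (h_t == 0) 1 else 1 - h_t_given_p / h_t
  completeness <- if (h_p == 0) 1 else 1 - h_p_given_t / h_p
  v <- if (homogeneity + completeness == 0) 0 else
    2 * homogeneity * completeness / (homogeneity + completeness)
  nmi <- if (h_t == 0 && h_p == 0) 1 else if (mi == 0) 0 else
    mi / ((h_t + h_p) / 2)
  emi <- expected_mi(a, b, n)
  denom <- max(h_t, h_p) - emi
  ami <- if (abs(denom) < 1e-15) 1 else (mi - emi) / denom
  # adjusted Rand index
  comb2 <- function(x) sum(x * (x - 1) / 2)
  sij <- comb2(as.vector(tab)); sa <- comb2(a); sb <- comb2(b)
  stot <- comb2(n)
  expected <- sa * sb / stot
  maxind <- (sa + sb) / 2
  ari <- if (abs(maxind - expected) < 1e-15) 1 else
    (sij - expected) / (maxind - expected)
  structure(list(homogeneity = homogeneity, v_measure = v, ami = ami,
                 nmi = nmi, ari = ari),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-12s %.4f\n", nm, x[[nm]]))
  invisible(x)
}

attention_view_modalities <- function() {
  list(s = c("llm", "omics1"), e = c("llm", "omics1"),
       `1` = c("spatial", "feature"), `2` = c("spatial", "feature"),
       final = c("omics1", "omics2"))
}

#' Per-domain attention-weight summary
#'
#' Long-format table of attention weights suitable for violin plots, plus
#' per-domain mean weights, for one or more fusion views. Views: `"s"` (LLM
#' vs omics-1, spatial graph), `"e"` (LLM vs omics-1, embedding graph),
#' `"1"` (spatial vs feature, modality 1 branch), `"2"` (same for
#' modality 2), `"final"` (omics-1 vs omics-2 branch).
#'
#' @param weights Named list of spot-by-M attention weight matrices (a fit's
#'   `$attention`), or a [spafuse()] fit.
#' @param labels Per-spot domain labels (defaults to the fit's domains).
#' @param views Views to include (default all present).
#' @return List with `table` (columns spot, cluster, view, modality, weight)
#'   and `means` (per cluster x view x modality mean weight).
#' @export
summarize_attention <- function(weights, labels = NULL, views = NULL) {
  if (inherits(weights, "spafuse")) {
    if (is.null(labels)) labels <- weights$domains$labels
    weights <- weights$attention
  }
  if (is.null(labels)) stop_validation("per-spot labels are required")
  if (is.null(views)) views <- names(weights)
  unknown <- setdiff(views, names(weights))
  if (length(unknown))
    stop_validation("unknown view(s): ", paste(unknown, collapse = ", "),
                    "; valid views: ", paste(names(weights), collapse = ", "))
  modal <- attention_view_modalities()
  rows <- list()
  for (v in views) {
    w <- weights[[v]]
    if (length(labels) != nrow(w))
      stop_validation("labels length does not match weight rows for view ", v)
    mods <- modal[[v]]
    if (is.null(mods)) mods <- paste0("input", seq_len(ncol(w)))
    for (k in seq_len(ncol(w)))
      rows[[length(rows) + 1L]] <- data.frame(
        spot = seq_len(nrow(w)), cluster = labels, view = v,
        modality = mods[k], weight = w[, k])
  }
  long <- do.call(rbind, rows)
  means <- stats::aggregate(weight ~ cluster + view + modality, long, mean)
  list(table = long, means = means)
}

#' Two-dimensional layout of the latent embedding
#'
#' Classical metric multidimensional scaling (principal coordinates) of the
#' Euclidean distances between spot latents, for plotting. Deterministic;
#' axis signs are fixed so the largest-magnitude coordinate on each axis is
#' positive.
#'
#' @param e Spot-by-latent matrix (or [embedding_matrix()]), N >= 10.
#' @param seed Kept for interface stability; the layout is deterministic.
#' @return N x 2 matrix with columns `dim1`, `dim2`.
#' @export
project_2d <- function(e, seed = 0L) {
  x <- if (inherits(e, "embedding_matrix")) e$values else as.matrix(e)
  if (nrow(x) < 10L) stop_validation("2-D layout needs at least 10 spots")
  y <- cmdscale(dist(x), k = 2L)
  for (j in 1:2) {
    s <- sign(y[which.max(abs(y[, j])), j])
    if (s < 0) y[, j] <- -y[, j]
  }
  colnames(y) <- c("dim1", "dim2")
  rownames(y) <- rownames(x)
  y
}
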