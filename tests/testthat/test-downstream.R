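blobs <- function(n_per = 30, centers = rbind(c(0, 0), c(10, 0), c(0, 10)),
                  sd = 1, seed = 0) {
  set.seed(seed)
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(j)
    cbind(rnorm(n_per, centers[j, 1], sd), rnorm(n_per, centers[j, 2], sd))))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

test_that("the shared-covariance GMM recovers separated blobs deterministically", {
  b <- blobs(seed = 0)
  d <- cluster_embedding(b$x, 3, seed = 0)
  expect_equal(compute_metrics(d, b$labels)$ari, 1)
  # log-likelihood non-decreasing over EM iterations of the winning restart
  expect_true(all(diff(d$loglik_trace) > -1e-6))
  # determinism
  d2 <- cluster_embedding(b$x, 3, seed = 0)
  expect_identical(d$labels, d2$labels)

  # duplicate rows always co-cluster
  x <- b$x
  x[2, ] <- x[1, ]
  dd <- cluster_embedding(x, 3, seed = 1)
  expect_equal(dd$labels[1], dd$labels[2])

  expect_error(cluster_embedding(b$x, 1), "at least 2",
               class = "spafuse_validation_error")
  expect_error(cluster_embedding(b$x[1:3, ], 5), "exceeds",
               class = "spafuse_validation_error")
})

test_that("the native EM agrees with mclust's EEE model on separable data", {
  skip_if_not_installed("mclust")
  b <- blobs(seed = 3)
  own <- cluster_embedding(b$x, 3, seed = 0, method = "em")
  ref <- cluster_embedding(b$x, 3, seed = 0, method = "mclust")
  expect_equal(compute_metrics(own, ref)$ari, 1)
  # near-identical mixture log-likelihoods at the optimum
  expect_equal(own$loglik, ref$loglik, tolerance = 1e-3)
})

test_that("supervised metrics hit their closed-form values and invariances", {
  # perfect agreement and label-permutation invariance
  t0 <- c(1, 1, 2, 2, 3, 3)
  expect_equal(unlist(compute_metrics(t0, t0)), rep(1, 5), ignore_attr = TRUE)
  expect_equal(unlist(compute_metrics(c(7, 7, 5, 5, 1, 1), t0)), rep(1, 5),
               ignore_attr = TRUE)

  # contingency table [[2,1],[1,2]] over 6 items, against an independent
  # from-scratch evaluation of the published formulas
  truth <- c(1, 1, 1, 2, 2, 2)
  pred  <- c(1, 1, 2, 1, 2, 2)
  m <- compute_metrics(pred, truth)
  tab <- table(truth, pred); n <- 6
  a <- rowSums(tab); b <- colSums(tab)
  H <- function(cnt) { p <- cnt / sum(cnt); -sum(p * log(p)) }
  mi <- 0
  for (i in 1:2) for (j in 1:2)
    mi <- mi + tab[i, j] / n * log(n * tab[i, j] / (a[i] * b[j]))
  h <- 1 - (H(a) - mi) / H(a)
  c_ <- 1 - (H(b) - mi) / H(b)
  emi <- 0
  for (i in 1:2) for (j in 1:2) for (nij in max(1, a[i] + b[j] - n):min(a[i], b[j]))
    emi <- emi + nij / n * log(n * nij / (a[i] * b[j])) *
      exp(lfactorial(a[i]) + lfactorial(b[j]) + lfactorial(n - a[i]) +
            lfactorial(n - b[j]) - lfactorial(n) - lfactorial(nij) -
            lfactorial(a[i] - nij) - lfactorial(b[j] - nij) -
            lfactorial(n - a[i] - b[j] + nij))
  comb2 <- function(x) sum(choose(x, 2))
  ari_hand <- (comb2(tab) - comb2(a) * comb2(b) / comb2(n)) /
    ((comb2(a) + comb2(b)) / 2 - comb2(a) * comb2(b) / comb2(n))
  expect_equal(m$homogeneity, h, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m$v_measure, 2 * h * c_ / (h + c_), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(m$nmi, mi / ((H(a) + H(b)) / 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(m$ami, (mi - emi) / (max(H(a), H(b)) - emi), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(m$ari, ari_hand, tolerance = 1e-9, ignore_attr = TRUE)
  # frozen reference values (independent implementation, same normalizations)
  expect_equal(m$homogeneity, 0.08170416594551, tolerance = 1e-10)
  expect_equal(m$ami, -0.11111111111111, tolerance = 1e-10)
  expect_equal(m$ari, -1 / 9, tolerance = 1e-12)

  expect_error(compute_metrics(1:3, 1:4), "length",
               class = "spafuse_validation_error")
})

test_that("ARI of random labelings is centered on zero", {
  truth <- rep(1:4, each = 25)
  set.seed(123)
  aris <- replicate(200, compute_metrics(sample(1:4, 100, TRUE), truth)$ari)
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("attention summaries aggregate weights per domain correctly", {
  n <- 12
  labels <- rep(1:2, each = 6)
  w_uniform <- matrix(0.5, n, 2)
  # planted dominance: domain 1 prefers the first input, domain 2 is flat
  w_dom <- rbind(matrix(c(0.9, 0.1), 6, 2, byrow = TRUE),
                 matrix(0.5, 6, 2))
  weights <- list(s = w_dom, e = w_uniform, `1` = w_uniform, `2` = w_uniform,
                  final = w_uniform)

  out <- summarize_attention(weights, labels)
  expect_named(out$table, c("spot", "cluster", "view", "modality", "weight"))
  means_s <- out$means[out$means$view == "s", ]
  llm_d1 <- means_s$weight[means_s$cluster == 1 & means_s$modality == "llm"]
  om_d1 <- means_s$weight[means_s$cluster == 1 & means_s$modality == "omics1"]
  expect_gt(llm_d1, om_d1)
  expect_equal(means_s$weight[means_s$cluster == 2], c(0.5, 0.5),
               tolerance = 1e-12, ignore_attr = TRUE)

  # identical inputs at a fusion site: every cluster's mean is 1/M
  means_e <- out$means[out$means$view == "e", ]
  expect_true(all(abs(means_e$weight - 0.5) < 1e-12))

  # one cluster covering all spots: per-cluster means equal global means
  out1 <- summarize_attention(weights["s"], rep(1, n), views = "s")
  gl <- colMeans(w_dom)
  expect_equal(sort(out1$means$weight), sort(unname(gl)), tolerance = 1e-12)

  expect_error(summarize_attention(weights, labels, views = "nope"),
               "valid views", class = "spafuse_validation_error")
})

test_that("the 2-D layout is deterministic and separation-preserving", {
  b <- blobs(n_per = 20, centers = rbind(c(0, 0, 0), c(50, 0, 0)), seed = 1)
  set.seed(1)
  x <- cbind(b$x[1:40, ], matrix(rnorm(40 * 3), 40, 3))
  x[1:20, 1] <- 0; x[21:40, 1] <- 50
  y <- project_2d(x, seed = 0)
  expect_equal(dim(y), c(40L, 2L))
  expect_identical(y, project_2d(x, seed = 0))
  inter <- as.matrix(dist(y[, 1:2]))[1:20, 21:40]
  intra <- as.matrix(dist(y[1:20, 1:2]))
  expect_gt(mean(inter), mean(intra))
  expect_error(project_2d(x[1:5, ]), "at least 10",
               class = "spafuse_validation_error")
})
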