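test_that("encoder and decoder match the dense layer-by-layer oracle", {
  set.seed(21)
  for (case in 1:10) {
    n <- sample(4:20, 1)
    d_in <- sample(3:6, 1); hidden <- sample(4:8, 1); latent <- sample(2:5, 1)
    g <- random_graph(n, k = sample(1:3, 1), seed = case)
    x <- matrix(rnorm(n * d_in), n, d_in)
    enc <- list(W0 = matrix(rnorm(d_in * hidden), d_in, hidden),
                W1 = matrix(rnorm(hidden * latent), hidden, latent),
                W2 = matrix(rnorm(latent * latent), latent, latent))
    expect_equal(encoder_forward(x, g, enc),
                 dense_gcn_oracle(x, g$normalized_form,
                                  enc$W0, enc$W1, enc$W2),
                 tolerance = 1e-9, ignore_attr = TRUE)
    dec <- list(W0 = matrix(rnorm(latent * latent), latent, latent),
                W1 = matrix(rnorm(latent * hidden), latent, hidden),
                W2 = matrix(rnorm(hidden * d_in), hidden, d_in))
    z <- matrix(rnorm(n * latent), n, latent)
    expect_equal(decoder_forward(z, g, dec),
                 dense_gcn_oracle(z, g$normalized_form,
                                  dec$W0, dec$W1, dec$W2),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("bias-free stacks are zero-preserving and identity under identity weights", {
  g <- random_graph(6, k = 2, seed = 5)
  enc <- identity_block(3)
  expect_true(all(encoder_forward(matrix(0, 6, 3), g, enc) == 0))
  expect_true(all(decoder_forward(matrix(0, 6, 3), g, enc) == 0))

  # single node with (normalized) self-loop operator = 1: identity chain
  g1 <- manual_graph(matrix(0, 1, 1), normalized_form = matrix(1, 1, 1))
  x <- matrix(c(0.3, 1.7, 0), 1, 3)
  expect_equal(encoder_forward(x, g1, identity_block(3)), x,
               ignore_attr = TRUE)
  expect_equal(decoder_forward(x, g1, identity_block(3)), x,
               ignore_attr = TRUE)

  expect_error(encoder_forward(matrix(0, 6, 4), g, enc), "width",
               class = "spafuse_validation_error")
  expect_error(encoder_forward(matrix(0, 5, 3), g, enc), "rows",
               class = "spafuse_validation_error")
})

test_that("attention weights are normalized, symmetric for identical inputs, and match hand arithmetic", {
  set.seed(9)
  params <- list(W = matrix(rnorm(9), 3, 3), mu = matrix(rnorm(3), 3, 1))
  r <- matrix(rnorm(15), 5, 3)

  # identical inputs: uniform weights, fused equals the input
  for (m in 2:3) {
    res <- attention_fuse(rep(list(r), m), params)
    expect_equal(res$weights, matrix(1 / m, 5, m), tolerance = 1e-12)
    expect_equal(res$fused, r, tolerance = 1e-12)
  }

  # hand evaluation, N = 2, latent = 2, M = 2
  W <- matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2)
  mu <- matrix(c(1, -1), 2, 1)
  r1 <- matrix(c(1, 0, 0, 1), 2, 2)
  r2 <- matrix(c(0.2, 0.4, -0.1, 0.3), 2, 2)
  res2 <- attention_fuse(list(r1, r2), list(W = W, mu = mu))
  for (i in 1:2) {
    s1 <- drop(tanh(r1[i, , drop = FALSE] %*% W) %*% mu)
    s2 <- drop(tanh(r2[i, , drop = FALSE] %*% W) %*% mu)
    a <- exp(c(s1, s2)) / sum(exp(c(s1, s2)))
    expect_equal(res2$weights[i, ], a, tolerance = 1e-12)
    expect_equal(res2$fused[i, ], a[1] * r1[i, ] + a[2] * r2[i, ],
                 tolerance = 1e-12)
  }

  # rows always sum to one; epsilon never changes the weights
  expect_equal(rowSums(res2$weights), c(1, 1), tolerance = 1e-12)
  res_lo <- attention_fuse(list(r1, r2), list(W = W, mu = mu), epsilon = 1e-10)
  res_hi <- attention_fuse(list(r1, r2), list(W = W, mu = mu), epsilon = 1e-2)
  expect_equal(res_lo$weights, res_hi$weights, tolerance = 1e-12)

  expect_error(attention_fuse(list(r1), list(W = W, mu = mu)), "at least 2")
  expect_error(attention_fuse(list(r1, matrix(0, 3, 2)), list(W = W, mu = mu)),
               "mismatch")
})

test_that("forward_pass wires the six branches and five fusion views", {
  data <- toy_model_data(n_side = 4, d_f = 6, d1 = 4, d2 = 4, seed = 1)
  params <- init_params(6, 4, 4, hidden = 8, latent = 5, seed = 1)
  fwd <- forward_pass(data, params)
  for (nm in c("R_fs", "R_fe", "R_os1", "R_oe1", "R_os2", "R_oe2",
               "EA_s", "EA_e", "EA_1", "EA_2", "Emb"))
    expect_equal(dim(fwd[[nm]]), c(16L, 5L), label = nm)
  expect_named(fwd$weights, c("s", "e", "1", "2", "final"))
  for (w in fwd$weights) expect_equal(rowSums(w), rep(1, 16), tolerance = 1e-6)

  # zero language-model embedding: its branches are exactly zero, the rest live
  data0 <- data
  data0$emb_f <- data$emb_f * 0
  fwd0 <- forward_pass(data0, params)
  expect_true(all(fwd0$R_fs == 0))
  expect_true(all(fwd0$R_fe == 0))
  expect_true(all(is.finite(fwd0$Emb)))

  # identical omics modalities with identical graphs and shared params give
  # identical branch latents; any difference enters via the LLM branch only
  data_eq <- data
  data_eq$emb2 <- data_eq$emb1
  data_eq$A_2 <- data_eq$A_1
  params_eq <- params
  params_eq$enc_o2 <- params_eq$enc_o1
  params_eq$att_2 <- params_eq$att_s
  fwd_eq <- forward_pass(data_eq, params_eq)
  expect_equal(fwd_eq$R_os2, fwd_eq$R_os1, tolerance = 1e-12)
  expect_equal(fwd_eq$R_oe2, fwd_eq$R_oe1, tolerance = 1e-12)
})

test_that("loss terms follow the stated MSE and weighted-sum accounting", {
  # direct mean-squared Frobenius row norm: x=(1,0) vs 0, N=1 -> 1
  tape <- spafuse:::ad_tape()
  l <- spafuse:::ad_mse(tape, spafuse:::ad_const(tape, matrix(c(1, 0), 1, 2)),
                        spafuse:::ad_const(tape, matrix(0, 1, 2)))
  expect_identical(l$value, 1)

  # contrived identity setup: every reconstruction and correspondence loss is 0
  n <- 4; d <- 3
  gI <- manual_graph(matrix(0, n, n), normalized_form = diag(n))
  x <- matrix(abs(rnorm(n * d)), n, d)
  params <- list(enc_f = identity_block(d), enc_o1 = identity_block(d),
                 enc_o2 = identity_block(d), dec_f = identity_block(d),
                 dec_o1 = identity_block(d), dec_o2 = identity_block(d),
                 att_s = list(W = diag(d), mu = matrix(1, d, 1)),
                 att_e = list(W = diag(d), mu = matrix(1, d, 1)),
                 att_1 = list(W = diag(d), mu = matrix(1, d, 1)),
                 att_2 = list(W = diag(d), mu = matrix(1, d, 1)),
                 att_final = list(W = diag(d), mu = matrix(1, d, 1)))
  data <- list(emb_f = x, emb1 = x, emb2 = x,
               A_s = gI$normalized_form, A_f = gI$normalized_form,
               A_1 = gI$normalized_form, A_2 = gI$normalized_form)
  rep0 <- compute_losses(data, params)
  for (nm in c("rec_1", "rec_2", "rec_fs", "rec_fe", "cor_1", "cor_2"))
    expect_equal(rep0[[nm]], 0, tolerance = 1e-12, label = nm)
  expect_equal(rep0$total, 0, tolerance = 1e-12)

  # weighted-sum contract on a non-trivial instance
  data2 <- toy_model_data(n_side = 3, d_f = 4, d1 = 3, d2 = 3, seed = 2)
  p2 <- init_params(4, 3, 3, hidden = 5, latent = 3, seed = 2)
  w <- c(rec_1 = 2, rec_2 = 0, rec_fs = 0, rec_fe = 0, cor_1 = 0, cor_2 = 0)
  rep2 <- compute_losses(data2, p2, w)
  expect_equal(rep2$total, 2 * rep2$rec_1, tolerance = 1e-12)
  expect_error(compute_losses(data2, p2, c(bogus = 1)), "unknown")
  expect_error(compute_losses(data2, p2, rep(0, 6)), "at least one")
})

test_that("training descends, is seed-deterministic, and reports consistent totals", {
  data <- toy_model_data(n_side = 5, d_f = 6, d1 = 4, d2 = 4, seed = 4)
  tr <- train_model(data, epochs = 50, hidden = 8, latent = 6, seed = 4)
  expect_lt(tr$history$total[50], tr$history$total[1])
  # every epoch's total equals the weighted sum of its terms
  terms <- as.matrix(tr$history[, c("rec_1", "rec_2", "rec_fs", "rec_fe",
                                    "cor_1", "cor_2")])
  expect_equal(tr$history$total, drop(terms %*% tr$loss_weights),
               tolerance = 1e-9)
  expect_true(all(terms >= 0))

  tr2 <- train_model(data, epochs = 50, hidden = 8, latent = 6, seed = 4)
  expect_equal(tr2$history$total[50], tr$history$total[50], tolerance = 1e-6)

  tr0 <- train_model(data, epochs = 0, hidden = 8, latent = 6, seed = 4)
  expect_equal(nrow(tr0$history), 0L)
  expect_equal(tr0$params$enc_f$W0,
               init_params(6, 4, 4, hidden = 8, latent = 6, seed = 4)$enc_f$W0)

  # zero embedding trains to a finite latent (ablation path health)
  data0 <- data
  data0$emb_f <- data$emb_f * 0
  tr_z <- train_model(data0, epochs = 10, hidden = 8, latent = 6, seed = 4)
  expect_true(all(is.finite(tr_z$latent$Emb)))
})
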