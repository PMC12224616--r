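# Six-branch graph autoencoder with hierarchical multi-view attention.
#
# Three encoders (Enc_f for the language-model embedding, Enc_o1/Enc_o2 for
# the two omics embeddings) are each applied with two graphs (spatial +
# matching embedding graph), giving six latents. Five attention sites fuse
# them pairwise into the final embedding. Three mirrored decoders provide
# reconstruction targets; two decode-then-re-encode cycles across modalities
# give the correspondence losses.

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

enc_shapes <- function(d_in, hidden, latent)
  list(W0 = c(d_in, hidden), W1 = c(hidden, latent), W2 = c(latent, latent))

dec_shapes <- function(d_out, hidden, latent)
  list(W0 = c(latent, latent), W1 = c(latent, hidden), W2 = c(hidden, d_out))

init_block <- function(shapes, bias) {
  p <- lapply(shapes, function(s) glorot(s[1], s[2]))
  if (bias) for (nm in names(shapes))
    p[[paste0("b", substring(nm, 2))]] <- matrix(0, 1L, shapes[[nm]][2])
  p
}

#' Initialize model parameters
#'
#' Glorot-uniform weights for the three encoders, three decoders, and the
#' five attention sites, drawn under a fixed seed.
#'
#' @param d_f,d1,d2 Input widths of the language-model embedding and the two
#'   omics embeddings.
#' @param hidden Hidden layer width (default 256).
#' @param latent Latent width entering attention (default 64).
#' @param seed RNG seed.
#' @param bias Add bias vectors to graph-convolution layers (default
#'   `FALSE`: layers are pure adjacency/weight products).
#' @return Nested list of parameter matrices.
#' @export
init_params <- function(d_f, d1, d2, hidden = 256L, latent = 64L, seed = 0L,
                        bias = FALSE) {
  with_seed(seed, {
    att <- function() list(W = glorot(latent, latent), mu = glorot(latent, 1L))
    list(
      enc_f  = init_block(enc_shapes(d_f, hidden, latent), bias),
      enc_o1 = init_block(enc_shapes(d1, hidden, latent), bias),
      enc_o2 = init_block(enc_shapes(d2, hidden, latent), bias),
      dec_f  = init_block(dec_shapes(d_f, hidden, latent), bias),
      dec_o1 = init_block(dec_shapes(d1, hidden, latent), bias),
      dec_o2 = init_block(dec_shapes(d2, hidden, latent), bias),
      att_s = att(), att_e = att(), att_1 = att(), att_2 = att(),
      att_final = att(),
      dims = list(d_f = d_f, d1 = d1, d2 = d2, hidden = hidden,
                  latent = latent, bias = bias)
    )
  })
}

# one graph-convolution stack: layers 1-2 rectified, layer 3 linear
gcn_stack_ad <- function(tape, x, A, p) {
  lay <- function(h, W, b, act) {
    h <- ad_spmm(tape, A, ad_mm(tape, h, W))
    if (!is.null(b)) h <- ad_add_bias(tape, h, b)
    if (act) ad_relu(tape, h) else h
  }
  h <- lay(x, p$W0, p$b0, TRUE)
  h <- lay(h, p$W1, p$b1, TRUE)
  lay(h, p$W2, p$b2, FALSE)
}

wrap_block <- function(tape, p, as_param = FALSE) {
  wrap <- if (as_param) ad_param else ad_const
  out <- lapply(p[names(p) %in% c("W0", "W1", "W2", "b0", "b1", "b2", "W", "mu")],
                function(m) wrap(tape, m))
  # ensure absent biases read as NULL
  for (nm in c("b0", "b1", "b2")) if (is.null(out[[nm]])) out[nm] <- list(NULL)
  out
}

#' Encoder forward pass
#'
#' Three graph-convolution layers: the first two apply the (normalized)
#' adjacency product, the weight product and a rectifier; the third is
#' linear. With `bias = FALSE` (default) the map is positively homogeneous,
#' so zero input gives zero output.
#'
#' @param x Numeric spot-by-dim input matrix (or [embedding_matrix()]).
#' @param g A [nbr_graph][build_spatial_graph] whose operator multiplies each
#'   layer.
#' @param params One encoder block from [init_params()] (fields `W0`, `W1`,
#'   `W2`, optional biases).
#' @param raw_adjacency Use the raw binary adjacency instead of the
#'   normalized operator.
#' @return Spot-by-latent numeric matrix.
#' @export
encoder_forward <- function(x, g, params, raw_adjacency = FALSE) {
  x <- if (inherits(x, "embedding_matrix")) x$values else as.matrix(x)
  A <- graph_operator(g, raw_adjacency)
  if (nrow(x) != nrow(A))
    stop_validation("input has ", nrow(x), " rows but graph has ", nrow(A), " spots")
  if (ncol(x) != nrow(params$W0))
    stop_validation("input width ", ncol(x), " does not match W0 rows ",
                    nrow(params$W0))
  tape <- ad_tape()
  gcn_stack_ad(tape, ad_const(tape, x), A, wrap_block(tape, params))$value
}

#' Decoder forward pass
#'
#' Mirror image of [encoder_forward()]: latent -> latent -> hidden -> output
#' widths, final layer linear.
#'
#' @param z Spot-by-latent numeric matrix.
#' @inheritParams encoder_forward
#' @return Spot-by-output numeric matrix.
#' @export
decoder_forward <- function(z, g, params, raw_adjacency = FALSE) {
  z <- as.matrix(z)
  A <- graph_operator(g, raw_adjacency)
  if (ncol(z) != nrow(params$W0))
    stop_validation("latent width ", ncol(z), " does not match decoder input ",
                    nrow(params$W0))
  tape <- ad_tape()
  gcn_stack_ad(tape, ad_const(tape, z), A, wrap_block(tape, params))$value
}

attention_ad <- function(tape, inputs, W, mu, epsilon) {
  scores <- lapply(inputs, function(Rk)
    ad_mm(tape, ad_tanh(tape, ad_mm(tape, Rk, W)), mu))
  alpha <- ad_softmax_rows(tape, ad_cbind(tape, scores), shift = epsilon)
  fused <- ad_sum_list(tape, lapply(seq_along(inputs), function(k)
    ad_rowscale(tape, inputs[[k]], ad_col(tape, alpha, k))))
  list(fused = fused, weights = alpha)
}

#' Attention fusion of aligned latent representations
#'
#' Per spot i and view k, score_k(i) = tanh(R_k[i,] W) . mu; the weights are
#' a softmax over views of (score + epsilon) and the fused output is the
#' weight-averaged combination. Because epsilon shifts every score equally,
#' the weights do not depend on it (softmax shift invariance); it is kept as
#' a numerical-stability constant.
#'
#' @param inputs List of M >= 2 spot-by-latent matrices of identical shape.
#' @param params List with `W` (latent x latent) and `mu` (latent x 1).
#' @param epsilon Scalar added to every score (default 1e-8).
#' @return List with `fused` (spot x latent) and `weights` (spot x M, rows
#'   summing to 1).
#' @export
attention_fuse <- function(inputs, params, epsilon = 1e-8) {
  if (length(inputs) < 2L) stop_validation("attention needs at least 2 inputs")
  inputs <- lapply(inputs, as.matrix)
  dims <- vapply(inputs, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop_validation("attention inputs have mismatched shapes: ",
                    paste(apply(dims, 2, paste, collapse = "x"), collapse = " vs "))
  tape <- ad_tape()
  res <- attention_ad(tape, lapply(inputs, ad_const, tape = tape),
                      ad_const(tape, params$W), ad_const(tape, params$mu),
                      epsilon)
  list(fused = res$fused$value, weights = res$weights$value)
}

# Full forward pass on the tape. `data` holds emb_f/emb1/emb2 matrices and
# sparse operators A_s, A_f, A_1, A_2; `pn` holds wrapped parameter nodes.
forward_ad <- function(tape, data, pn, epsilon = 1e-8) {
  xf <- ad_const(tape, data$emb_f)
  x1 <- ad_const(tape, data$emb1)
  x2 <- ad_const(tape, data$emb2)
  R_fs  <- gcn_stack_ad(tape, xf, data$A_s, pn$enc_f)
  R_fe  <- gcn_stack_ad(tape, xf, data$A_f, pn$enc_f)
  R_os1 <- gcn_stack_ad(tape, x1, data$A_s, pn$enc_o1)
  R_oe1 <- gcn_stack_ad(tape, x1, data$A_1, pn$enc_o1)
  R_os2 <- gcn_stack_ad(tape, x2, data$A_s, pn$enc_o2)
  R_oe2 <- gcn_stack_ad(tape, x2, data$A_2, pn$enc_o2)
  f_s <- attention_ad(tape, list(R_fs, R_os1), pn$att_s$W, pn$att_s$mu, epsilon)
  f_e <- attention_ad(tape, list(R_fe, R_oe1), pn$att_e$W, pn$att_e$mu, epsilon)
  f_1 <- attention_ad(tape, list(f_s$fused, f_e$fused), pn$att_1$W, pn$att_1$mu, epsilon)
  f_2 <- attention_ad(tape, list(R_os2, R_oe2), pn$att_2$W, pn$att_2$mu, epsilon)
  f_final <- attention_ad(tape, list(f_1$fused, f_2$fused),
                          pn$att_final$W, pn$att_final$mu, epsilon)
  list(R_fs = R_fs, R_fe = R_fe, R_os1 = R_os1, R_oe1 = R_oe1,
       R_os2 = R_os2, R_oe2 = R_oe2,
       EA_s = f_s$fused, EA_e = f_e$fused, EA_1 = f_1$fused,
       EA_2 = f_2$fused, Emb = f_final$fused,
       weights = list(s = f_s$weights, e = f_e$weights, `1` = f_1$weights,
                      `2` = f_2$weights, final = f_final$weights))
}

losses_ad <- function(tape, fwd, data, pn) {
  xf <- ad_const(tape, data$emb_f)
  x1 <- ad_const(tape, data$emb1)
  x2 <- ad_const(tape, data$emb2)
  list(
    rec_1  = ad_mse(tape, x1, gcn_stack_ad(tape, fwd$Emb, data$A_s, pn$dec_o1)),
    rec_2  = ad_mse(tape, x2, gcn_stack_ad(tape, fwd$Emb, data$A_s, pn$dec_o2)),
    rec_fs = ad_mse(tape, xf, gcn_stack_ad(tape, fwd$R_fs, data$A_s, pn$dec_f)),
    rec_fe = ad_mse(tape, xf, gcn_stack_ad(tape, fwd$R_fe, data$A_f, pn$dec_f)),
    cor_1  = ad_mse(tape, fwd$EA_1,
                    gcn_stack_ad(tape,
                                 gcn_stack_ad(tape, fwd$EA_1, data$A_s, pn$dec_o2),
                                 data$A_s, pn$enc_o2)),
    cor_2  = ad_mse(tape, fwd$EA_2,
                    gcn_stack_ad(tape,
                                 gcn_stack_ad(tape, fwd$EA_2, data$A_s, pn$dec_o1),
                                 data$A_s, pn$enc_o1))
  )
}

wrap_params <- function(tape, params, as_param) {
  pn <- list()
  for (blk in c("enc_f", "enc_o1", "enc_o2", "dec_f", "dec_o1", "dec_o2"))
    pn[[blk]] <- wrap_block(tape, params[[blk]], as_param)
  for (blk in c("att_s", "att_e", "att_1", "att_2", "att_final")) {
    wrap <- if (as_param) ad_param else ad_const
    pn[[blk]] <- list(W = wrap(tape, params[[blk]]$W),
                      mu = wrap(tape, params[[blk]]$mu))
  }
  pn
}

default_loss_weights <- function()
  c(rec_1 = 1, rec_2 = 1, rec_fs = 1, rec_fe = 1, cor_1 = 1, cor_2 = 1)

check_loss_weights <- function(w) {
  nm <- names(default_loss_weights())
  if (is.null(names(w))) names(w) <- nm[seq_along(w)]
  full <- default_loss_weights()
  unknown <- setdiff(names(w), nm)
  if (length(unknown))
    stop_validation("unknown loss weight(s): ", paste(unknown, collapse = ", "))
  full[names(w)] <- w
  if (any(full < 0)) stop_validation("loss weights must be nonnegative")
  if (all(full == 0)) stop_validation("at least one loss weight must be > 0")
  full
}

#' Run the full forward pass without training
#'
#' @param data List with embeddings `emb_f`, `emb1`, `emb2` (spot-by-dim
#'   matrices) and graph operators `A_s`, `A_f`, `A_1`, `A_2` (sparse,
#'   typically the normalized forms).
#' @param params From [init_params()] (or a trained fit's `$params`).
#' @param epsilon Attention stability constant.
#' @return List of the six encoder latents (`R_fs`, `R_fe`, `R_os1`,
#'   `R_oe1`, `R_os2`, `R_oe2`), the fusion products `EA_s`, `EA_e`, `EA_1`,
#'   `EA_2`, the final embedding `Emb`, and per-view attention `weights`.
#' @export
forward_pass <- function(data, params, epsilon = 1e-8) {
  tape <- ad_tape()
  fwd <- forward_ad(tape, data, wrap_params(tape, params, FALSE), epsilon)
  out <- lapply(fwd[setdiff(names(fwd), "weights")], function(n) n$value)
  out$weights <- lapply(fwd$weights, function(n) n$value)
  out
}

#' Evaluate the six loss terms and their weighted total
#'
#' Reconstruction losses compare each branch's decode against its input
#' embedding; correspondence losses decode one modality's fused latent with
#' the *other* modality's decoder, re-encode it, and compare with the
#' original latent. Every term is the mean over spots of the squared row
#' norm of the difference.
#'
#' @inheritParams forward_pass
#' @param loss_weights Named nonnegative vector over `rec_1`, `rec_2`,
#'   `rec_fs`, `rec_fe`, `cor_1`, `cor_2`.
#' @return List of class `loss_report` with the six terms and `total`.
#' @export
compute_losses <- function(data, params, loss_weights = default_loss_weights(),
                           epsilon = 1e-8) {
  loss_weights <- check_loss_weights(loss_weights)
  tape <- ad_tape()
  pn <- wrap_params(tape, params, FALSE)
  fwd <- forward_ad(tape, data, pn, epsilon)
  terms <- lapply(losses_ad(tape, fwd, data, pn), function(n) n$value)
  terms$total <- sum(unlist(terms) * loss_weights)
  structure(terms, class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat("loss terms:\n")
  for (nm in setdiff(names(x), "total"))
    cat(sprintf("  %-6s %.6g\n", nm, x[[nm]]))
  cat(sprintf("  total  %.6g\n", x$total))
  invisible(x)
}

adam_state <- function(flat) lapply(flat, function(m) list(m = m * 0, v = m * 0))

# paths to every parameter matrix in the nested params list
param_paths <- function(params) {
  out <- list()
  for (blk in setdiff(names(params), "dims"))
    for (nm in names(params[[blk]]))
      out[[length(out) + 1L]] <- c(blk, nm)
  out
}

#' Train the model
#'
#' Full-graph gradient training of all encoder, decoder and attention
#' parameters with Adam, minimizing the weighted loss. Deterministic under a
#' fixed seed and single-threaded BLAS.
#'
#' @inheritParams compute_losses
#' @param params Initial parameters; `NULL` initializes via [init_params()]
#'   from the data dimensions.
#' @param epochs Number of epochs (default 200).
#' @param learning_rate Adam step size (default 1e-3).
#' @param hidden,latent Layer widths used when `params` is `NULL`.
#' @param seed Seed for initialization.
#' @param verbose Print the total loss every 50 epochs.
#' @return List with `params` (trained), `latent` (the forward pass at the
#'   trained parameters), and `history` (data frame of per-epoch loss terms).
#' @export
train_model <- function(data, params = NULL,
                        loss_weights = default_loss_weights(),
                        epochs = 200L, learning_rate = 1e-3,
                        hidden = 256L, latent = 64L, seed = 0L,
                        epsilon = 1e-8, verbose = FALSE) {
  loss_weights <- check_loss_weights(loss_weights)
  epochs <- max(0L, as.integer(epochs))
  if (is.null(params))
    params <- init_params(ncol(data$emb_f), ncol(data$emb1), ncol(data$emb2),
                          hidden = hidden, latent = latent, seed = seed)
  paths <- param_paths(params)
  get_p <- function(path) params[[path[1]]][[path[2]]]
  state <- lapply(paths, function(p) {
    m <- get_p(p); list(m = m * 0, v = m * 0)
  })
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    tape <- ad_tape()
    pn <- wrap_params(tape, params, TRUE)
    fwd <- forward_ad(tape, data, pn, epsilon)
    terms <- losses_ad(tape, fwd, data, pn)
    total <- ad_wsum(tape, terms, loss_weights)
    if (!is.finite(total$value)) {
      bad <- names(terms)[!vapply(terms, function(n) is.finite(n$value), TRUE)]
      stop_training("non-finite loss at epoch ", ep,
                    if (length(bad)) paste0(" (term: ", bad[1], ")"),
                    "; try a lower learning rate")
    }
    ad_backward(tape, total)
    for (k in seq_along(paths)) {
      path <- paths[[k]]
      node <- pn[[path[1]]][[path[2]]]
      g <- node$grad
      if (is.null(g)) next
      st <- state[[k]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g * g
      state[[k]] <- st
      mhat <- st$m / (1 - b1^ep)
      vhat <- st$v / (1 - b2^ep)
      params[[path[1]]][[path[2]]] <-
        params[[path[1]]][[path[2]]] - learning_rate * mhat / (sqrt(vhat) + eps)
    }
    rep_ <- lapply(terms, function(n) n$value)
    rep_$total <- total$value
    history[[ep]] <- rep_
    if (verbose && (ep %% 50 == 0 || ep == 1))
      message(sprintf("epoch %d: total loss %.5f", ep, total$value))
  }
  hist_df <- if (epochs > 0)
    do.call(rbind, lapply(seq_len(epochs), function(ep)
      data.frame(epoch = ep, as.data.frame(history[[ep]]), check.names = FALSE)))
  else
    data.frame(epoch = integer(), rec_1 = numeric(), rec_2 = numeric(),
               rec_fs = numeric(), rec_fe = numeric(), cor_1 = numeric(),
               cor_2 = numeric(), total = numeric())
  list(params = params, latent = forward_pass(data, params, epsilon),
       history = hist_df, loss_weights = loss_weights)
}
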