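# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A tape records nodes in creation order; each non-leaf node carries a
# backward closure that pushes its upstream gradient into its parents.
# Because nodes are only created from already-existing nodes, reverse
# creation order is a valid topological order for backpropagation. Sparse
# graph operators enter only as constants (ad_spmm), so gradients stay dense.

ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

new_ad <- function(tape, value, backward = NULL, requires = TRUE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$backward <- if (requires) backward else NULL
  node$requires <- requires
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- node
  node
}

ad_param <- function(tape, value) new_ad(tape, value, requires = TRUE)
ad_const <- function(tape, value) new_ad(tape, value, requires = FALSE)

ad_accum <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

ad_requires <- function(...) any(vapply(list(...), function(n) n$requires, TRUE))

# dense matrix product
ad_mm <- function(tape, a, b) {
  val <- a$value %*% b$value
  new_ad(tape, val, requires = ad_requires(a, b), backward = function(g) {
    if (a$requires) ad_accum(a, g %*% t(b$value))
    if (b$requires) ad_accum(b, crossprod(a$value, g))
  })
}

# constant sparse operator times dense node
ad_spmm <- function(tape, A, b) {
  val <- as.matrix(A %*% b$value)
  new_ad(tape, val, requires = b$requires, backward = function(g) {
    ad_accum(b, as.matrix(Matrix::crossprod(A, g)))
  })
}

ad_relu <- function(tape, x) {
  mask <- x$value > 0
  new_ad(tape, x$value * mask, requires = x$requires,
         backward = function(g) ad_accum(x, g * mask))
}

ad_tanh <- function(tape, x) {
  val <- tanh(x$value)
  new_ad(tape, val, requires = x$requires,
         backward = function(g) ad_accum(x, g * (1 - val * val)))
}

ad_add <- function(tape, a, b) {
  new_ad(tape, a$value + b$value, requires = ad_requires(a, b),
         backward = function(g) { ad_accum(a, g); ad_accum(b, g) })
}

# add a row vector node (1 x d) to every row — bias term
ad_add_bias <- function(tape, x, b) {
  new_ad(tape, sweep(x$value, 2L, as.vector(b$value), `+`),
         requires = ad_requires(x, b), backward = function(g) {
           ad_accum(x, g)
           ad_accum(b, matrix(colSums(g), 1L))
         })
}

ad_cbind <- function(tape, cols) {
  val <- do.call(cbind, lapply(cols, function(n) n$value))
  new_ad(tape, val, requires = any(vapply(cols, function(n) n$requires, TRUE)),
         backward = function(g) {
           for (k in seq_along(cols))
             ad_accum(cols[[k]], g[, k, drop = FALSE])
         })
}

# row-wise softmax of an N x M score matrix (plus scalar constant shift)
ad_softmax_rows <- function(tape, x, shift = 0) {
  s <- x$value + shift
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  p <- e / rowSums(e)
  new_ad(tape, p, requires = x$requires, backward = function(g) {
    ad_accum(x, p * (g - rowSums(g * p)))
  })
}

ad_col <- function(tape, x, k) {
  n <- nrow(x$value)
  new_ad(tape, x$value[, k, drop = FALSE], requires = x$requires,
         backward = function(g) {
           full <- matrix(0, n, ncol(x$value))
           full[, k] <- g
           ad_accum(x, full)
         })
}

# scale rows of x (N x d) by weight column w (N x 1)
ad_rowscale <- function(tape, x, w) {
  wv <- as.vector(w$value)
  new_ad(tape, x$value * wv, requires = ad_requires(x, w),
         backward = function(g) {
           if (x$requires) ad_accum(x, g * wv)
           if (w$requires) ad_accum(w, matrix(rowSums(g * x$value), ncol = 1L))
         })
}

ad_sum_list <- function(tape, nodes) {
  val <- Reduce(`+`, lapply(nodes, function(n) n$value))
  new_ad(tape, val, requires = any(vapply(nodes, function(n) n$requires, TRUE)),
         backward = function(g) for (n in nodes) ad_accum(n, g))
}

# mean over rows of squared row norms: sum((a - b)^2) / nrow
ad_mse <- function(tape, a, b) {
  diff <- a$value - b$value
  n <- nrow(diff)
  new_ad(tape, sum(diff * diff) / n, requires = ad_requires(a, b),
         backward = function(g) {
           d <- (2 * as.numeric(g) / n) * diff
           if (a$requires) ad_accum(a, d)
           if (b$requires) ad_accum(b, -d)
         })
}

# weighted sum of scalar nodes
ad_wsum <- function(tape, nodes, weights) {
  val <- sum(vapply(nodes, function(n) n$value, 0) * weights)
  new_ad(tape, val, requires = any(vapply(nodes, function(n) n$requires, TRUE)),
         backward = function(g) {
           for (k in seq_along(nodes))
             ad_accum(nodes[[k]], as.numeric(g) * weights[k])
         })
}

ad_backward <- function(tape, node) {
  node$grad <- matrix(1, 1L, 1L)[1, 1]
  for (k in rev(seq_len(tape$n))) {
    n <- tape$nodes[[k]]
    if (!is.null(n$grad) && !is.null(n$backward)) n$backward(n$grad)
  }
  invisible(NULL)
}
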