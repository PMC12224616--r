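#' @importFrom stats cor kmeans prcomp rnorm runif rbinom rnbinom
#'   cmdscale dist plogis coef fitted residuals logLik
#' @importFrom utils read.table write.table modifyList
#' @importFrom graphics barplot
#' @importFrom methods as is
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("spafuse_validation_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("spafuse_format_error", "error")))
}

stop_training <- function(...) {
  stop(errorCondition(paste0(...), class = c("spafuse_training_error", "error")))
}

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
    stop_validation("'", name, "' must be a single positive integer, got ",
                    deparse(substitute(x)))
  as.integer(x)
}
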