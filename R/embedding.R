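#' Construct a per-spot embedding matrix
#'
#' Dense spot-by-dimension real matrix, e.g. PCA scores of one modality or a
#' language-model embedding of the expression profiles.
#'
#' @param values Numeric spot-by-dim matrix with finite entries.
#' @param spot_ids Character spot identifiers (row names).
#' @param source One of `"pca"`, `"llm"`, `"zero"`, `"mock"`.
#' @return An object of class `embedding_matrix`.
#' @export
embedding_matrix <- function(values, spot_ids = rownames(values),
                             source = c("pca", "llm", "zero", "mock")) {
  source <- match.arg(source)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop_validation("embedding matrix has non-finite entries")
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(nrow(values)))
  rownames(values) <- as.character(spot_ids)
  structure(list(values = values, spot_ids = rownames(values),
                 dim = ncol(values), source = source),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d spots x %d dims (source: %s)\n",
              nrow(x$values), x$dim, x$source))
  invisible(x)
}

#' @export
dim.embedding_matrix <- function(x) dim(x$values)

#' Define an embedding provider
#'
#' A pluggable source for the per-spot language-model embedding. Kinds:
#' \describe{
#'   \item{`external_file`}{reads a precomputed embedding (e.g. scGPT output)
#'     from a delimited file, spots in the aligned row order.}
#'   \item{`zero`}{the all-zeros embedding — the ablation that removes the
#'     language-model signal while leaving the architecture untouched.}
#'   \item{`mock`}{a seeded random linear projection of the (normalized)
#'     expression matrix plus Gaussian noise; informative by construction,
#'     used for testing without model weights.}
#'   \item{`pca_fallback`}{PCA of the expression matrix.}
#' }
#'
#' @param kind Provider kind, see above.
#' @param dim Embedding width. Defaults to 512 for `external_file` (the
#'   typical transformer output width) and 64 otherwise.
#' @param path File path, required for `external_file`.
#' @param seed RNG seed for `mock`.
#' @param noise_sd Gaussian noise level for `mock`.
#' @return An object of class `embedding_provider`.
#' @export
embedding_provider <- function(kind = c("external_file", "zero", "mock", "pca_fallback"),
                               dim = NULL, path = NULL, seed = 0L, noise_sd = 0.1) {
  kind <- match.arg(kind)
  if (is.null(dim)) dim <- if (kind == "external_file") 512L else 64L
  dim <- assert_scalar_count(dim, "dim")
  if (kind == "external_file" && is.null(path))
    stop_validation("external_file provider needs a path")
  structure(list(kind = kind, dim = dim, path = path,
                 seed = as.integer(seed), noise_sd = noise_sd),
            class = "embedding_provider")
}

#' Produce the per-spot embedding for one modality
#'
#' @param provider An [embedding_provider()].
#' @param m An [omics_matrix()] (typically the normalized RNA modality; its
#'   spot count fixes N).
#' @return An [embedding_matrix()] of shape N x `provider$dim` (for
#'   `external_file`, the file's width).
#' @export
embed_spots <- function(provider, m) {
  stopifnot(inherits(provider, "embedding_provider"), inherits(m, "omics_matrix"))
  n <- nrow(m$values)
  switch(provider$kind,
    zero = embedding_matrix(matrix(0, n, provider$dim), spot_ids = m$spot_ids,
                            source = "zero"),
    mock = with_seed(provider$seed, {
      d_in <- ncol(m$values)
      proj <- matrix(rnorm(d_in * provider$dim, sd = 1 / sqrt(d_in)),
                     d_in, provider$dim)
      e <- m$values %*% proj
      if (provider$noise_sd > 0)
        e <- e + matrix(rnorm(length(e), sd = provider$noise_sd), nrow(e), ncol(e))
      embedding_matrix(e, spot_ids = m$spot_ids, source = "mock")
    }),
    pca_fallback = {
      e <- pca_embed(m, n_components = min(provider$dim, nrow(m$values),
                                           ncol(m$values)))
      embedding_matrix(e$values, spot_ids = m$spot_ids, source = "pca")
    },
    external_file = {
      e <- import_embedding(provider$path, expected_n = n)
      embedding_matrix(e$values, spot_ids = m$spot_ids, source = "llm")
    })
}

#' Match feature names against a gene vocabulary
#'
#' Splits feature names into those found in the vocabulary of a pre-trained
#' single-cell model and those absent, preserving input order. Matching is
#' exact by default; set `case = "insensitive"` to compare upper-cased.
#'
#' @param feature_names Character vector.
#' @param vocab Character vector of vocabulary symbols (or a list with a
#'   `symbols` element as returned by [read_vocabulary()]).
#' @param case `"sensitive"` (default) or `"insensitive"`.
#' @return List with character vectors `matched` and `unmatched`.
#' @export
match_vocabulary <- function(feature_names, vocab,
                             case = c("sensitive", "insensitive")) {
  case <- match.arg(case)
  if (is.list(vocab)) vocab <- vocab$symbols
  vocab <- as.character(vocab)
  f <- as.character(feature_names)
  hit <- if (case == "sensitive") f %in% vocab else toupper(f) %in% toupper(vocab)
  if (!any(hit) && length(f))
    warning("no feature names matched the vocabulary")
  list(matched = f[hit], unmatched = f[!hit])
}

#' Read a newline-delimited gene vocabulary
#'
#' @param path File path, one symbol per line.
#' @param name Identifier for the vocabulary.
#' @return List with `symbols` (character) and `name`.
#' @export
read_vocabulary <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  symbols <- unique(trimws(readLines(path)))
  symbols <- symbols[nzchar(symbols)]
  if (!length(symbols)) stop_validation("empty vocabulary in ", path)
  list(symbols = symbols, name = name)
}

#' Write / read an embedding matrix as tab-delimited text
#'
#' Round-trips to full double precision, spots in row order.
#'
#' @param e An [embedding_matrix()].
#' @param path File path.
#' @return `export_embedding` returns `path` invisibly; `import_embedding`
#'   returns an [embedding_matrix()].
#' @export
export_embedding <- function(e, path) {
  stopifnot(inherits(e, "embedding_matrix"))
  df <- data.frame(spot_id = e$spot_ids,
                   format(e$values, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("spot_id", paste0("d", seq_len(e$dim)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param expected_n Required row count; a mismatch is an error.
#' @rdname export_embedding
#' @export
import_embedding <- function(path, expected_n = NULL) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- tab[[1L]]
  if (!is.null(expected_n) && nrow(mat) != expected_n)
    stop_validation("embedding file has ", nrow(mat),
                    " rows but ", expected_n, " spots are expected")
  embedding_matrix(mat, source = "llm")
}
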