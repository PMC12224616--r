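#' Construct a spot-by-feature omics matrix
#'
#' The basic container for one modality of a spatial multi-omics experiment:
#' a numeric matrix with spots as rows and features (genes, peaks or
#' antibody-derived tags) as columns, tagged with its modality.
#'
#' @param values Numeric matrix, spots in rows, features in columns. Counts
#'   or normalized values; negative entries are rejected for raw input.
#' @param spot_ids Character vector of unique spot identifiers (row names).
#' @param feature_names Character vector of feature names (column names).
#' @param modality One of `"rna"`, `"atac"`, `"adt"`.
#' @param normalized Logical; `TRUE` once [normalize_modality()] has run
#'   (negative entries are then permitted).
#' @return An object of class `omics_matrix`.
#' @examples
#' m <- omics_matrix(matrix(rpois(6, 5), 3, 2),
#'                   spot_ids = c("s1", "s2", "s3"),
#'                   feature_names = c("GeneA", "GeneB"))
#' dim(m$values)
#' @export
omics_matrix <- function(values, spot_ids = rownames(values),
                         feature_names = colnames(values),
                         modality = c("rna", "atac", "adt"),
                         normalized = FALSE) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(nrow(values)))
  if (is.null(feature_names)) feature_names <- paste0("feat_", seq_len(ncol(values)))
  spot_ids <- as.character(spot_ids)
  feature_names <- as.character(feature_names)
  if (length(spot_ids) != nrow(values))
    stop_validation("spot_ids length (", length(spot_ids),
                    ") does not match row count (", nrow(values), ")")
  if (length(feature_names) != ncol(values))
    stop_validation("feature_names length (", length(feature_names),
                    ") does not match column count (", ncol(values), ")")
  if (anyDuplicated(spot_ids))
    stop_validation("duplicate spot IDs: ",
                    paste(unique(spot_ids[duplicated(spot_ids)]), collapse = ", "))
  if (!normalized && any(values < 0, na.rm = TRUE))
    stop_validation("negative entries in raw ", modality, " matrix")
  if (anyNA(values))
    stop_validation("missing values in ", modality, " matrix")
  dimnames(values) <- list(spot_ids, feature_names)
  structure(list(values = values, spot_ids = spot_ids,
                 feature_names = feature_names, modality = modality,
                 normalized = normalized),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d spots x %d features (%s)\n",
              x$modality, nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Construct a spot coordinate table
#'
#' @param coords Numeric spot-by-2 matrix of x/y positions (platform units).
#' @param spot_ids Character vector of unique spot identifiers.
#' @return An object of class `spot_coords`.
#' @export
spot_coords <- function(coords, spot_ids = rownames(coords)) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L)
    stop_validation("coordinates must have exactly 2 columns, got ", ncol(coords))
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(nrow(coords)))
  spot_ids <- as.character(spot_ids)
  if (length(spot_ids) != nrow(coords))
    stop_validation("spot_ids length does not match coordinate rows")
  if (anyDuplicated(spot_ids))
    stop_validation("duplicate spot IDs in coordinates")
  if (anyNA(coords)) stop_validation("missing values in coordinates")
  key <- paste(round(coords[, 1] / 1e-9), round(coords[, 2] / 1e-9))
  if (anyDuplicated(key))
    stop_validation("duplicate coordinate rows (within 1e-9)")
  rownames(coords) <- spot_ids
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, spot_ids = spot_ids), class = "spot_coords")
}

#' @export
print.spot_coords <- function(x, ...) {
  cat(sprintf("<spot_coords> %d spots\n", nrow(x$coords)))
  invisible(x)
}

#' Read one modality from disk
#'
#' Supported formats: `delimited` (header row of feature names, first column
#' spot IDs, comma- or tab-separated); `matrix_market` (10x-style layout: a
#' `.mtx` file of features x spots plus companion `features.tsv`/`genes.tsv`
#' and `barcodes.tsv` in the same directory); `sce` (an in-memory
#' `SingleCellExperiment`, features x cells, passed instead of a path).
#'
#' @param path File path (for `sce`, a `SingleCellExperiment` object).
#' @param format One of `"delimited"`, `"matrix_market"`, `"sce"`.
#' @param modality Modality tag for the result, see [omics_matrix()].
#' @param assay For `sce`, which assay to take (default first).
#' @return An [omics_matrix()].
#' @export
read_modality <- function(path, format = c("delimited", "matrix_market", "sce"),
                          modality = c("rna", "atac", "adt"), assay = 1L) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  if (format == "sce") {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
      stop_format("reading a SingleCellExperiment requires the SummarizedExperiment package")
    mat <- t(as.matrix(SummarizedExperiment::assay(path, assay)))
    return(omics_matrix(mat, modality = modality))
  }
  if (!file.exists(path)) stop_format("file not found: ", path)
  if (format == "delimited") {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
    tab <- tryCatch(
      read.table(path, header = TRUE, sep = sep, row.names = 1L,
                 check.names = FALSE, comment.char = ""),
      error = function(e) stop_format("cannot parse delimited file ", path,
                                      ": ", conditionMessage(e)))
    mat <- as.matrix(tab)
    if (!is.numeric(mat))
      stop_format("non-numeric entries in ", path,
                  " (first offending column: ",
                  colnames(tab)[which(!vapply(tab, is.numeric, TRUE))[1]], ")")
    return(omics_matrix(mat, modality = modality))
  }
  # matrix_market: features x spots on disk, as written by 10x tooling
  mm <- tryCatch(Matrix::readMM(path),
                 error = function(e) stop_format("cannot parse Matrix Market file ",
                                                 path, ": ", conditionMessage(e)))
  dir <- dirname(path)
  feat_file <- c(file.path(dir, "features.tsv"), file.path(dir, "genes.tsv"))
  feat_file <- feat_file[file.exists(feat_file)][1]
  bc_file <- file.path(dir, "barcodes.tsv")
  if (is.na(feat_file) || !file.exists(bc_file))
    stop_format("matrix_market layout needs features.tsv (or genes.tsv) and barcodes.tsv next to ", path)
  feats <- read.table(feat_file, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  bcs <- readLines(bc_file)
  if (length(feats) != nrow(mm))
    stop_format("features.tsv has ", length(feats), " entries but matrix has ",
                nrow(mm), " rows")
  if (length(bcs) != ncol(mm))
    stop_format("barcodes.tsv has ", length(bcs), " entries but matrix has ",
                ncol(mm), " columns")
  omics_matrix(t(as.matrix(mm)), spot_ids = bcs, feature_names = feats,
               modality = modality)
}

#' Read a spot coordinate file
#'
#' Delimited text with columns `spot_id`, `x`, `y` (header required).
#'
#' @param path File path.
#' @return A [spot_coords()].
#' @export
read_coords <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(tab)))
    stop_format("coordinate file must have columns spot_id,x,y; found: ",
                paste(names(tab), collapse = ","))
  spot_coords(as.matrix(tab[, c("x", "y")]), spot_ids = tab$spot_id)
}

#' Align two modalities and coordinates on shared spot IDs
#'
#' Inner join on spot identifiers: spots present in all three inputs are kept,
#' in the order of the first modality; dropped spots are reported via a
#' message.
#'
#' @param m1,m2 [omics_matrix()] objects of the two modalities.
#' @param p A [spot_coords()].
#' @return A list with elements `m1`, `m2`, `coords`, all sharing identical
#'   spot order, and `n_dropped`, the number of spots discarded.
#' @export
align_spots <- function(m1, m2, p) {
  stopifnot(inherits(m1, "omics_matrix"), inherits(m2, "omics_matrix"),
            inherits(p, "spot_coords"))
  shared <- intersect(intersect(m1$spot_ids, m2$spot_ids), p$spot_ids)
  if (length(shared) == 0L)
    stop_validation("no shared spot IDs across the two modalities and coordinates")
  keep <- m1$spot_ids[m1$spot_ids %in% shared]
  n_dropped <- (length(m1$spot_ids) - length(keep)) +
    (length(m2$spot_ids) - length(keep)) + (length(p$spot_ids) - length(keep))
  if (n_dropped > 0)
    message("align_spots: dropped ", n_dropped, " unshared spot entries; ",
            length(keep), " spots retained")
  sub <- function(m, ids) {
    omics_matrix(m$values[ids, , drop = FALSE], spot_ids = ids,
                 feature_names = m$feature_names, modality = m$modality,
                 normalized = m$normalized)
  }
  list(m1 = sub(m1, keep), m2 = sub(m2, keep),
       coords = spot_coords(p$coords[keep, , drop = FALSE], spot_ids = keep),
       n_dropped = n_dropped)
}

#' Normalize one modality
#'
#' `library_size_log1p` (default for RNA/ATAC) scales every spot to the median
#' library size then applies `log1p`; `clr` (default for ADT) applies the
#' centered log-ratio across features within each spot,
#' `log1p(x) - mean(log1p(x))`; `none` returns the input unchanged (but
#' tagged normalized).
#'
#' @param m An [omics_matrix()].
#' @param method `"library_size_log1p"`, `"clr"`, `"none"`, or `NULL` to use
#'   the modality default.
#' @param target_sum Library-size target; `NULL` uses the median library size.
#' @return A normalized [omics_matrix()].
#' @examples
#' m <- omics_matrix(matrix(c(2, 8), 1, 2), spot_ids = "s1",
#'                   feature_names = c("a", "b"))
#' normalize_modality(m, "library_size_log1p", target_sum = 10)$values
#' @export
normalize_modality <- function(m, method = NULL, target_sum = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  if (is.null(method))
    method <- if (m$modality == "adt") "clr" else "library_size_log1p"
  method <- match.arg(method, c("library_size_log1p", "clr", "none"))
  x <- m$values
  if (method == "none") {
    out <- x
  } else if (method == "library_size_log1p") {
    lib <- rowSums(x)
    zero <- lib == 0
    if (any(zero))
      warning(sum(zero), " spot(s) with zero library size left as zeros")
    if (is.null(target_sum)) {
      pos <- lib[!zero]
      target_sum <- if (length(pos)) stats::median(pos) else 1
    }
    scale <- ifelse(zero, 0, target_sum / pmax(lib, 1e-300))
    out <- log1p(x * scale)
  } else { # clr per spot across features
    lx <- log1p(x)
    out <- lx - rowMeans(lx)
  }
  if (any(!is.finite(out))) stop_validation("non-finite values after normalization")
  omics_matrix(out, spot_ids = m$spot_ids, feature_names = m$feature_names,
               modality = m$modality, normalized = TRUE)
}

#' Reduce a modality to a low-dimensional embedding by PCA
#'
#' Column-centered principal component scores. The sign of every component is
#' fixed so that its largest-magnitude loading is positive, making results
#' reproducible across platforms.
#'
#' @param m An [omics_matrix()] (normally normalized first).
#' @param n_components Number of components (`<= min(N, n features)`).
#' @param seed Kept for interface stability; PCA itself is deterministic.
#' @return An [embedding_matrix()] with `source = "pca"`.
#' @export
pca_embed <- function(m, n_components = 50L, seed = 0L) {
  stopifnot(inherits(m, "omics_matrix"))
  n_components <- assert_scalar_count(n_components, "n_components")
  x <- m$values
  bound <- min(nrow(x), ncol(x))
  if (n_components > bound)
    stop_validation("n_components (", n_components,
                    ") exceeds min(N, features) = ", bound)
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  rot <- pc$rotation
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2L, flip, `*`)
  embedding_matrix(scores, spot_ids = m$spot_ids, source = "pca")
}
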