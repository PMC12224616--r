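# Synthetic spatial multi-omics generator: contiguous domains on a 2-D
# lattice with domain-specific signal in both modalities, a ground-truth
# labeling, and an optional informative per-spot embedding standing in for
# a language-model output.

domain_layout <- function(rows, cols, n_domains,
                          layout = c("blocks", "stripes", "voronoi"),
                          seed = 0L) {
  layout <- match.arg(layout)
  grid <- expand.grid(x = seq_len(cols), y = seq_len(rows))
  n <- nrow(grid)
  lab <- switch(layout,
    stripes = {
      band <- ceiling(grid$x / (cols / n_domains))
      pmin(band, n_domains)
    },
    blocks = {
      nbr <- max(1L, floor(sqrt(n_domains)))
      nbc <- ceiling(n_domains / nbr)
      rb <- pmin(ceiling(grid$y / (rows / nbr)), nbr)
      cb <- pmin(ceiling(grid$x / (cols / nbc)), nbc)
      tile <- (rb - 1L) * nbc + cb
      ((tile - 1L) %% n_domains) + 1L
    },
    voronoi = with_seed(seed, {
      centers <- grid[sample.int(n, n_domains), , drop = FALSE]
      d2 <- outer(grid$x, centers$x, `-`)^2 + outer(grid$y, centers$y, `-`)^2
      max.col(-d2, ties.method = "first")
    }))
  list(grid = grid, labels = as.integer(lab))
}

#' Generate a synthetic spatial multi-omics dataset
#'
#' Spots sit on a `rows` x `cols` lattice partitioned into spatially
#' contiguous domains. Each domain carries its own mean profile in both
#' modalities: RNA counts are negative-binomial around domain-specific
#' log-means (per-feature, per-domain shifts with standard deviation
#' `effect_size * 0.5` on the log scale, 0.5 being roughly the within-domain
#' spread of log-normalized counts at these depths) with independent
#' Bernoulli dropout; modality 2 is either a continuous log-normal protein
#' (ADT) signal or sparse binarized chromatin-accessibility (ATAC) counts.
#' Fully deterministic per seed.
#'
#' @param rows,cols Lattice dimensions (default 20 x 20).
#' @param n_domains Number of domains (default 4).
#' @param layout `"blocks"` (default), `"stripes"`, or `"voronoi"`.
#' @param rna_features,mod2_features Feature counts (defaults 100 and 30).
#' @param modality2 `"adt"` (default) or `"atac"`.
#' @param effect_size Between-domain mean shift in within-domain noise-SD
#'   units (default 2).
#' @param effect_size_mod2 Effect size for modality 2; defaults to
#'   `effect_size`. Set to 0 to put domain signal in RNA (and any informative
#'   embedding) only.
#' @param dropout_rate Independent zeroing probability for RNA counts
#'   (default 0.2).
#' @param dispersion Negative-binomial dispersion (default 0.5, i.e.
#'   `size = 2`).
#' @param seed RNG seed.
#' @return List with `rna`, `mod2` ([omics_matrix()]), `coords`
#'   ([spot_coords()]), and `truth` (a `domain_assignment` with the
#'   generating labels).
#' @export
simulate_spatial_multiomics <- function(rows = 20L, cols = 20L, n_domains = 4L,
                                        layout = "blocks",
                                        rna_features = 100L, mod2_features = 30L,
                                        modality2 = c("adt", "atac"),
                                        effect_size = 2, effect_size_mod2 = NULL,
                                        dropout_rate = 0.2, dispersion = 0.5,
                                        seed = 0L) {
  modality2 <- match.arg(modality2)
  rows <- assert_scalar_count(rows, "rows")
  cols <- assert_scalar_count(cols, "cols")
  n_domains <- assert_scalar_count(n_domains, "n_domains")
  n <- rows * cols
  if (n_domains > n)
    stop_validation("n_domains (", n_domains, ") exceeds spot count (", n, ")")
  if (effect_size < 0) stop_validation("effect_size must be nonnegative")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_validation("dropout_rate must be in [0, 1)")
  if (is.null(effect_size_mod2)) effect_size_mod2 <- effect_size
  lay <- domain_layout(rows, cols, n_domains, layout, seed = seed)
  labels <- lay$labels
  ids <- sprintf("spot_%04d", seq_len(n))
  with_seed(seed, {
    # RNA: NB counts around domain log-means, then dropout
    base_rna <- rnorm(rna_features, log(5), 0.5)
    shift_rna <- matrix(rnorm(n_domains * rna_features,
                              sd = effect_size * 0.5),
                        n_domains, rna_features)
    mu <- exp(sweep(shift_rna[labels, , drop = FALSE], 2L, base_rna, `+`))
    rna <- matrix(rnbinom(n * rna_features, mu = mu, size = 1 / dispersion),
                  n, rna_features)
    if (dropout_rate > 0) {
      keep <- matrix(rbinom(n * rna_features, 1L, 1 - dropout_rate),
                     n, rna_features)
      rna <- rna * keep
    }
    m2 <- if (modality2 == "adt") {
      base <- rnorm(mod2_features, log(50), 0.5)
      shift <- matrix(rnorm(n_domains * mod2_features,
                            sd = effect_size_mod2 * 0.5),
                      n_domains, mod2_features)
      lmu <- sweep(shift[labels, , drop = FALSE], 2L, base, `+`)
      exp(lmu + matrix(rnorm(n * mod2_features, sd = 0.5), n, mod2_features))
    } else {
      base <- rnorm(mod2_features, -2, 0.5)
      shift <- matrix(rnorm(n_domains * mod2_features,
                            sd = effect_size_mod2), n_domains, mod2_features)
      p <- plogis(sweep(shift[labels, , drop = FALSE], 2L, base, `+`))
      matrix(rbinom(n * mod2_features, 1L, p), n, mod2_features)
    }
    list(
      rna = omics_matrix(rna, spot_ids = ids,
                         feature_names = sprintf("gene_%03d", seq_len(rna_features)),
                         modality = "rna"),
      mod2 = omics_matrix(m2, spot_ids = ids,
                          feature_names = sprintf("%s_%03d", modality2,
                                                  seq_len(mod2_features)),
                          modality = modality2),
      coords = spot_coords(as.matrix(lay$grid), spot_ids = ids),
      truth = structure(list(labels = labels, n_domains = n_domains,
                             method = "ground_truth"),
                        class = "domain_assignment")
    )
  })
}

#' Informative per-spot embedding from known domains
#'
#' One Gaussian anchor vector per domain plus per-spot noise — a stand-in
#' for a language-model embedding that carries domain signal by
#' construction. With `noise_sd = 0`, spots of the same domain get identical
#' rows.
#'
#' @param truth A `domain_assignment` (or integer label vector).
#' @param dim Embedding width (>= 2, default 64).
#' @param noise_sd Per-spot Gaussian noise SD (default 0.2; anchors are
#'   standard normal, so separation is about `sqrt(2 * dim)` between
#'   anchors).
#' @param seed RNG seed.
#' @return An [embedding_matrix()] with `source = "llm"`.
#' @export
make_informative_embedding <- function(truth, dim = 64L, noise_sd = 0.2,
                                       seed = 0L) {
  labels <- if (inherits(truth, "domain_assignment")) truth$labels else
    as.integer(truth)
  dim <- assert_scalar_count(dim, "dim")
  if (dim < 2L) stop_validation("embedding dim must be at least 2")
  k <- max(labels)
  n <- length(labels)
  with_seed(seed, {
    anchors <- matrix(rnorm(k * dim), k, dim)
    e <- anchors[labels, , drop = FALSE]
    if (noise_sd > 0) e <- e + matrix(rnorm(n * dim, sd = noise_sd), n, dim)
    embedding_matrix(e, spot_ids = sprintf("spot_%04d", seq_len(n)),
                     source = "llm")
  })
}

#' Write a synthetic dataset to a fixture directory
#'
#' Writes the formats [read_modality()] and [read_coords()] consume:
#' `rna.csv`, `mod2.csv` (spots x features, first column `spot_id`),
#' `coords.csv` (`spot_id,x,y`), and `truth_labels.csv` (`spot_id,label`).
#'
#' @param sim Result of [simulate_spatial_multiomics()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wm <- function(m, path) {
    df <- data.frame(spot_id = m$spot_ids, m$values, check.names = FALSE)
    colnames(df) <- c("spot_id", m$feature_names)
    write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  }
  wm(sim$rna, file.path(dir, "rna.csv"))
  wm(sim$mod2, file.path(dir, "mod2.csv"))
  write.table(data.frame(spot_id = sim$coords$spot_ids,
                         x = sim$coords$coords[, 1], y = sim$coords$coords[, 2]),
              file.path(dir, "coords.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(spot_id = sim$coords$spot_ids,
                         label = sim$truth$labels),
              file.path(dir, "truth_labels.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
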