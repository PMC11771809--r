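# Synthetic spatial transcriptomics generator.
#
# Emulates the statistical regime the method assumes: spatially clustered
# cell types, type-specific expression programs under negative-binomial
# counting noise with independent dropout, and a tissue image whose local
# intensity reflects local type composition.

#' Configuration for the synthetic generator
#'
#' @param n_cells number of cells/spots.
#' @param n_genes number of genes.
#' @param n_types number of cell types (spatial clusters).
#' @param cluster_spread spatial cluster standard deviation as a fraction of
#'   the image side length.
#' @param signal_genes_per_type number of marker genes elevated in each type.
#' @param signal_log_fold natural-log fold elevation of marker genes over the
#'   baseline mean.
#' @param dropout_rate probability that any observed count is zeroed
#'   (technical dropout), in \[0, 1\].
#' @param baseline_mean negative-binomial mean of non-marker genes.
#' @param nb_size negative-binomial size (inverse-dispersion) parameter.
#' @param image_size side length of the square synthetic image in pixels;
#'   coordinates are drawn in the same pixel unit.
#' @param image_noise_sd standard deviation of per-pixel Gaussian noise added
#'   to the smoothed type-intensity field.
#' @param seed integer RNG seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_cells = 300, n_genes = 200, n_types = 4,
                         cluster_spread = 0.08, signal_genes_per_type = 10,
                         signal_log_fold = 1.5, dropout_rate = 0.3,
                         baseline_mean = 0.5, nb_size = 2,
                         image_size = 128, image_noise_sd = 0.05, seed = 0) {
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_types = as.integer(n_types), cluster_spread = cluster_spread,
              signal_genes_per_type = as.integer(signal_genes_per_type),
              signal_log_fold = signal_log_fold, dropout_rate = dropout_rate,
              baseline_mean = baseline_mean, nb_size = nb_size,
              image_size = as.integer(image_size),
              image_noise_sd = image_noise_sd, seed = as.integer(seed))
  if (cfg$n_types > cfg$n_cells) stopf_("n_types must not exceed n_cells")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1) {
    stopf_("dropout_rate must be in [0, 1]")
  }
  for (f in c("n_cells", "n_genes", "n_types", "cluster_spread",
              "baseline_mean", "nb_size", "image_size")) {
    if (cfg[[f]] <= 0) stopf_("%s must be positive", f)
  }
  if (cfg$signal_genes_per_type * cfg$n_types > cfg$n_genes) {
    stopf_("too many signal genes for n_genes")
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a synthetic spatial dataset
#'
#' Cell types are placed as Gaussian spatial clusters inside the image
#' frame.  Counts are negative-binomial with type-specific elevated means on
#' each type's marker genes, then zeroed independently with probability
#' `dropout_rate`.  The image is the per-type base-intensity field of the
#' nearest cell, Gaussian-smoothed, plus pixel noise — so local patches are
#' informative of local type composition.  Bit-reproducible from the seed.
#'
#' @param config a [synth_config()].
#' @return A [spatial_dataset()] with `cell_types` set.
#' @export
simulate_spatial_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed_(config$seed, {
    n <- config$n_cells
    g <- config$n_genes
    t_n <- config$n_types
    side <- config$image_size

    centers <- cbind(runif(t_n, 0.2 * side, 0.8 * side),
                     runif(t_n, 0.2 * side, 0.8 * side))
    # near-even type sizes, remainder to the first types
    sizes <- rep(n %/% t_n, t_n)
    if (n %% t_n > 0) sizes[seq_len(n %% t_n)] <- sizes[seq_len(n %% t_n)] + 1
    type_idx <- rep(seq_len(t_n), times = sizes)
    sd_px <- config$cluster_spread * side
    coords <- centers[type_idx, , drop = FALSE] +
      matrix(rnorm(2 * n, sd = sd_px), n, 2)
    coords[, 1] <- pmin(pmax(coords[, 1], 0.5), side - 0.5)
    coords[, 2] <- pmin(pmax(coords[, 2], 0.5), side - 0.5)

    # mean matrix: baseline everywhere, elevated marker block per type
    mu <- matrix(config$baseline_mean, n, g)
    s <- config$signal_genes_per_type
    for (t in seq_len(t_n)) {
      genes_t <- ((t - 1) * s + 1):(t * s)
      mu[type_idx == t, genes_t] <- config$baseline_mean * exp(config$signal_log_fold)
    }
    counts <- matrix(rnbinom(n * g, mu = mu, size = config$nb_size), n, g)
    if (config$dropout_rate > 0) {
      keep <- matrix(rbinom(n * g, 1, 1 - config$dropout_rate), n, g)
      counts <- counts * keep
    }

    base_int <- seq(0.25, 0.85, length.out = t_n)
    image <- render_type_image_(coords, type_idx, base_int, side,
                                config$image_noise_sd)

    spatial_dataset(
      cell_ids = sprintf("cell_%04d", seq_len(n)),
      coords = coords,
      counts = counts,
      gene_ids = sprintf("gene_%04d", seq_len(g)),
      image = image,
      cell_types = paste0("type", type_idx)
    )
  })
}

# Voronoi-by-cell intensity field, separable Gaussian blur, pixel noise.
render_type_image_ <- function(coords, type_idx, base_int, side, noise_sd,
                               blur_sigma = 2) {
  px <- seq_len(side) - 0.5
  grid <- cbind(rep(px, times = side), rep(px, each = side))  # (x, y) per pixel
  # nearest cell per pixel, chunked to bound memory
  n <- nrow(coords)
  nearest <- integer(nrow(grid))
  chunk <- 4096L
  cs2 <- rowSums(coords^2)
  for (start in seq(1, nrow(grid), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(grid))
    d2 <- outer(rowSums(grid[idx, , drop = FALSE]^2), rep(1, n)) -
      2 * grid[idx, , drop = FALSE] %*% t(coords) +
      outer(rep(1, length(idx)), cs2)
    nearest[idx] <- max.col(-d2, ties.method = "first")
  }
  vals <- base_int[type_idx[nearest]]
  img <- matrix(NA_real_, side, side)
  # grid row index = pixel y (image row), col index = pixel x
  img[cbind(match(grid[, 2], px), match(grid[, 1], px))] <- vals
  img <- blur_matrix_(img, blur_sigma)
  img <- img + matrix(rnorm(side * side, sd = noise_sd), side, side)
  pmin(pmax(img, 0), 1)
}

# separable Gaussian blur via a row-normalized band matrix
blur_matrix_ <- function(img, sigma) {
  if (sigma <= 0) return(img)
  m <- nrow(img)
  r <- ceiling(2 * sigma)
  offsets <- -r:r
  w <- exp(-offsets^2 / (2 * sigma^2))
  S <- matrix(0, m, m)
  for (k in seq_along(offsets)) {
    idx <- seq_len(m) + offsets[k]
    ok <- idx >= 1 & idx <= m
    S[cbind(which(ok), idx[ok])] <- S[cbind(which(ok), idx[ok])] + w[k]
  }
  S <- S / rowSums(S)
  S %*% img %*% t(S)
}

#' Ground-truth contact graph of a synthetic dataset
#'
#' The k-nearest-neighbour contact graph over the generated coordinates,
#' used as the planted positive edge set in end-to-end evaluations.
#'
#' @param dataset a [spatial_dataset()].
#' @param k neighbours per cell before symmetrization (default 5).
#' @return A `cell_graph` (see [build_knn_graph()]).
#' @export
planted_truth <- function(dataset, k = 5) {
  build_knn_graph(dataset$coords, k = k)
}
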