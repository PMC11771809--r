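# End-to-end orchestration: simulate/load -> preprocess -> graph -> train ->
# evaluate -> analyze, plus the false-edge robustness protocol.

#' Default end-to-end run configuration
#'
#' One seed drives every stochastic stage (data generation, edge split,
#' negative sampling, false-edge injection, parameter initialisation)
#' through fixed offsets, so a run is a deterministic function of the
#' configuration.
#'
#' @param seed master seed.
#' @param use_image run the dual-stream model (FALSE = expression-only
#'   ablation).
#' @param epochs maximum training epochs (a desk-scale default; the
#'   full-protocol preset is 1000).
#' @param synth a [synth_config()] for the generated dataset; ignored when
#'   `dataset` is supplied to [run_pipeline()].
#' @param resolution optimizer preset, see [train_presets()].
#' @param noise_fraction fraction of training positives to inject as false
#'   edges (0 disables the robustness protocol).
#' @param ... overrides for the remaining fields (k, min_spots, train_frac,
#'   val_frac, patch_w, patch_h, featurizer_grid, threshold,
#'   distal_quantile, weights, model).
#' @return named list.
#' @export
run_config <- function(seed = 0, use_image = TRUE, epochs = 300,
                       synth = NULL, resolution = "single_cell",
                       noise_fraction = 0, ...) {
  seed <- as.integer(seed)
  cfg <- list(
    seed = seed,
    synth = synth %||% synth_config(seed = seed),
    use_image = use_image,
    min_spots = 10,
    patch_w = 32, patch_h = 32,
    featurizer_grid = 4,
    k = 5,
    train_frac = 0.7, val_frac = 0.15,
    noise_fraction = noise_fraction,
    resolution = resolution,
    epochs = as.integer(epochs),
    weights = loss_weights(),
    model = model_config(),
    threshold = 0.5,
    distal_quantile = 0.95,
    split_seed = seed + 1L,
    model_seed = seed + 2L,
    inject_seed = seed + 3L
  )
  modifyList(cfg, list(...))
}

#' Run the full inference pipeline
#'
#' Simulates (or accepts) a spatial dataset, filters and normalizes the
#' counts, featurizes image patches, builds the k-NN contact graph, splits
#' edges with matched negatives (optionally injecting false edges), trains
#' the dual-stream GAT autoencoder, evaluates on the held-out test edges
#' and produces the downstream communication summaries.  When `out_dir` is
#' given, all artifacts (edge list, metrics JSON, embeddings, adjacency,
#' history, config, manifest) are written there.
#'
#' @param config a [run_config()].
#' @param dataset optional [spatial_dataset()]; by default one is simulated
#'   from `config$synth`.
#' @param out_dir optional output directory.
#' @param verbose progress-print interval in epochs (0 = quiet).
#' @return list of class `pipeline_result` with the dataset, graph, split,
#'   trained model, test `metrics`, noise-discrimination metrics (if
#'   injected), predicted interactions, distal calls and communication
#'   summary.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL,
                         out_dir = NULL, verbose = 0) {
  dataset <- dataset %||% simulate_spatial_dataset(config$synth)

  fg <- filter_genes(dataset$counts, min_spots = config$min_spots)
  x_expr <- normalize_counts(fg$counts)

  x_img <- NULL
  if (isTRUE(config$use_image) && !is.null(dataset$image)) {
    x_img <- image_features(dataset,
                            patch_spec(config$patch_w, config$patch_h),
                            make_meanpool_featurizer(config$featurizer_grid))$values
  }
  ablation <- is.null(x_img)

  graph <- build_knn_graph(dataset$coords, k = config$k)
  split <- split_edges(graph, config$train_frac, config$val_frac,
                       seed = config$split_seed)
  if (config$noise_fraction > 0) {
    split <- inject_false_edges(split, graph, config$noise_fraction,
                                seed = config$inject_seed)
  }

  model <- init_model(d_expr = ncol(x_expr),
                      d_img = if (ablation) NULL else ncol(x_img),
                      config = config$model, seed = config$model_seed)
  tc <- train_presets(config$resolution, max_epochs = config$epochs,
                      seed = config$seed)
  weights <- config$weights
  if (ablation) weights$gamma <- 0
  trained <- train_model(model, x_expr, x_img, split, tc, weights,
                         verbose = verbose)

  metrics <- evaluate_model(trained, x_expr, x_img,
                            split$test_pos, split$test_neg,
                            threshold = config$threshold)
  noise_metrics <- if (nrow(split$injected_false) > 0) {
    score_noise_discrimination(trained, x_expr, x_img, split)
  } else NULL

  A_prime <- predict_scores(trained, x_expr, x_img)
  predicted <- predict_interactions(A_prime, threshold = config$threshold)
  distal <- call_distal_edges(predicted, graph, dataset$coords,
                              distance_quantile = config$distal_quantile,
                              cell_types = dataset$cell_types)
  comm <- if (!is.null(dataset$cell_types)) {
    communication_strength(predicted, dataset$cell_types)
  } else NULL

  result <- structure(
    list(dataset = dataset, x_expr = x_expr, x_img = x_img, graph = graph,
         split = split, trained = trained, metrics = metrics,
         noise_metrics = noise_metrics, predicted = predicted,
         distal = distal, communication = comm, ablation = ablation,
         config = config),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    Z <- embeddings(trained, x_expr, x_img)
    edges_tab <- split_edge_table_(split, trained, x_expr, x_img,
                                   dataset$cell_ids)
    save_outputs(out_dir,
                 edges = edges_tab,
                 metrics = metrics,
                 embeddings = Z,
                 adjacency = unclass(A_prime),
                 history = trained$history,
                 config = serializable_config_(config, ablation),
                 mode = if (ablation) "ablation" else "full")
    result$out_dir <- out_dir
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s mode, test AUC-ROC %.3f (%d test edges)\n",
              if (x$ablation) "ablation" else "full",
              x$metrics$auc_roc, x$metrics$n_pos))
  invisible(x)
}

split_edge_table_ <- function(split, trained, x_expr, x_img, cell_ids) {
  blocks <- list(
    list(split$train_pos, 1, "train", FALSE),
    list(split$train_neg, 0, "train", FALSE),
    list(split$val_pos, 1, "val", FALSE),
    list(split$val_neg, 0, "val", FALSE),
    list(split$test_pos, 1, "test", FALSE),
    list(split$test_neg, 0, "test", FALSE),
    list(split$injected_false, 0, "train", TRUE))
  out <- do.call(rbind, lapply(blocks, function(b) {
    if (nrow(b[[1]]) == 0) return(NULL)
    data.frame(i = b[[1]][, 1], j = b[[1]][, 2], label = b[[2]],
               split = b[[3]], is_injected = b[[4]])
  }))
  out$score <- predict_scores(trained, x_expr, x_img,
                              as.matrix(out[, c("i", "j")]))
  data.frame(cell_a = cell_ids[out$i], cell_b = cell_ids[out$j],
             score = out$score, label = out$label, split = out$split,
             is_injected = out$is_injected)
}

serializable_config_ <- function(config, ablation) {
  cfg <- config
  cfg$synth <- unclass(cfg$synth)
  cfg$ablation <- ablation
  cfg
}

#' Run the false-edge robustness protocol
#'
#' Trains one model per injection fraction (default grid 10%-50%) on the
#' same dataset, split and initialisation, and tabulates validation and
#' test metrics together with the noise-discrimination AUC (true training
#' edges vs injected false edges) per fraction.
#'
#' @param config a [run_config()].
#' @param fractions injection fractions; 0 rows reproduce a plain run.
#' @param dataset optional dataset shared across fractions.
#' @param verbose see [run_pipeline()].
#' @return data.frame with one row per fraction: fraction, n_injected,
#'   val_auc, test_auc, test_ap, noise_auc.
#' @export
run_robustness <- function(config = run_config(),
                           fractions = seq(0.1, 0.5, by = 0.1),
                           dataset = NULL, verbose = 0) {
  dataset <- dataset %||% simulate_spatial_dataset(config$synth)
  rows <- lapply(fractions, function(f) {
    cfg <- config
    cfg$noise_fraction <- f
    res <- run_pipeline(cfg, dataset = dataset, verbose = verbose)
    data.frame(
      fraction = f,
      n_injected = nrow(res$split$injected_false),
      val_auc = res$trained$best_val_auc,
      test_auc = res$metrics$auc_roc,
      test_ap = res$metrics$average_precision,
      noise_auc = if (!is.null(res$noise_metrics)) res$noise_metrics$auc_roc
                  else NA_real_)
  })
  do.call(rbind, rows)
}
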