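# Shared small training fixture: a compact synthetic sample with both
# modalities, its contact graph, an edge split and an initialized model.
train_fixture <- function(n = 60, seed = 0, epochs = 5, use_image = TRUE) {
  d <- simulate_spatial_dataset(synth_config(n_cells = n, n_genes = 40,
                                             n_types = 3,
                                             signal_genes_per_type = 5,
                                             image_size = 48, seed = seed))
  x_e <- normalize_counts(filter_genes(d$counts, 3)$counts)
  x_i <- if (use_image) {
    image_features(d, patch_spec(12, 12), make_meanpool_featurizer(2))$values
  } else NULL
  g <- build_knn_graph(d$coords, 5)
  s <- split_edges(g, 0.7, 0.15, seed = seed + 1)
  m <- init_model(ncol(x_e), if (use_image) ncol(x_i) else NULL,
                  model_config(heads = c(2, 2), dims = c(4, 8), d_z = 8,
                               d_hidden = 16), seed = seed + 2)
  cfg <- train_presets("single_cell", max_epochs = epochs, seed = seed)
  list(d = d, x_e = x_e, x_i = x_i, g = g, s = s, m = m, cfg = cfg)
}
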