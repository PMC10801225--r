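## End-to-end experiment runner: clean -> split -> standardize -> graph
## -> train -> test metrics.  Used by the main classification
## experiments and, with modality subsets, by the ablation study, so the
## all-modalities ablation row is by construction identical to the main
## run for the same seed.

#' Run one classification experiment on a cohort table
#'
#' Cleans the table, performs the stratified 80/10/10 split (before
#' standardization), z-scores continuous features from train statistics,
#' builds the cognitive-similarity population graph, trains the GCN with
#' the standard protocol (100 epochs, Adam lr 0.01, validation every 5
#' epochs, best-validation checkpoint), and evaluates on the test
#' partition.
#'
#' When modality groups are restricted, features of removed groups are
#' dropped from X.  The graph is still built from the cognitive measures
#' unless the cognitive group itself is removed, in which case it falls
#' back to all retained features (a message is emitted).
#'
#' @param table raw cohort `data.frame`.
#' @param seed experiment seed; per-stage seeds are derived from it.
#' @param groups modality group codes to keep, a subset of
#'   `c("D", "MRI", "CT", "NT", "BM")` (default all).
#' @param edge_threshold population-graph edge threshold (default 0.5).
#' @param fractions split fractions (default `c(0.8, 0.1, 0.1)`).
#' @param config optional [gcn_config()]; its seed is overridden by a
#'   derived seed.
#' @param keep_similarities store per-measure similarity matrices in the
#'   returned graph (default `FALSE` to save memory).
#' @return List with `model`, `graph`, `X`, `split`, `scaler`,
#'   `table_clean`, `table_std`, `probabilities`, `predictions`,
#'   `metrics` (test partition), and `groups`.
#' @export
run_classification <- function(table, seed, groups = names(group_codes()),
                               edge_threshold = 0.5,
                               fractions = c(0.8, 0.1, 0.1),
                               config = NULL,
                               keep_similarities = FALSE) {
  stopifnot(all(groups %in% names(group_codes())))
  if (length(groups) == 0L) stop("at least one modality group is required")
  feats <- unlist(feature_groups()[group_codes()[groups]],
                  use.names = FALSE)
  if (length(feats) == 0L) stop("subset removes all features")

  clean <- clean_features(table)
  split <- split_dataset(clean, fractions,
                         seed = derive_seed(seed, "split"))
  std <- standardize(clean, split)

  if ("CT" %in% groups) {
    measures <- feature_groups()$cognitive
  } else {
    measures <- feats
    message("cognitive measures removed; graph built from all ",
            "retained features: ", paste(measures, collapse = ", "))
  }
  graph <- population_graph(std$table, measures = measures,
                            edge_threshold = edge_threshold,
                            keep_similarities = keep_similarities)

  X <- feature_matrix(std$table, feats)
  cfg <- if (is.null(config)) gcn_config() else config
  cfg$seed <- derive_seed(seed, "init")
  model <- gcn_train(X, graph, clean$label, split, cfg)

  P <- gcn_forward(X, graph, model)
  pred <- predict_classes(P)
  te <- split$partition == "test"
  metrics <- evaluate_metrics(pred[te], clean$label[te])

  list(model = model, graph = graph, X = X, split = split,
       scaler = std$scaler, table_clean = clean, table_std = std$table,
       probabilities = P, predictions = pred, metrics = metrics,
       groups = groups, seed = seed)
}
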