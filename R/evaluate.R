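## Evaluation suite: neighborhood explanation stability and modality
## ablation.  (Shapley agreement lives in shapley.R.)

#' Neighborhood explanation-stability table
#'
#' For each edge-weight threshold e, collects the anchor's same-class
#' neighbors with edge weight > e, computes each neighbor's
#' display-normalized feature influences for its own predicted class,
#' and reports the per-feature distance |max - min| across the
#' neighborhood.  Small distances mean the explanation is stable under
#' the natural feature variation of near-identical patients.
#' Neighborhood sets are nested: a lower threshold only adds neighbors.
#'
#' @param anchor anchor node index or id.
#' @param graph `PopulationGraph` with labels.
#' @param model trained `GCNModel`.
#' @param X standardized feature matrix.
#' @param thresholds decreasing edge-weight thresholds (default
#'   `c(0.96, 0.94, 0.90, 0.85, 0.80)`).
#' @param normalized use display-normalized influences (default `TRUE`);
#'   otherwise raw probability variations.
#' @param rescale optionally rescale each feature's distances by their
#'   maximum over thresholds (default `FALSE`).
#' @return A `StabilityReport`: list with `anchor`, `thresholds`,
#'   `neighbors` (list per threshold), and `distances` (threshold x
#'   feature matrix); empty (with a warning) if no threshold yields a
#'   neighbor.
#' @export
stability_table <- function(anchor, graph, model, X,
                            thresholds = c(0.96, 0.94, 0.90, 0.85, 0.80),
                            normalized = TRUE, rescale = FALSE) {
  check_trained(model)
  if (is.null(graph$labels)) stop("graph has no class labels")
  a <- resolve_node(graph, anchor)
  cls <- graph$labels[a]
  nb_sets <- lapply(thresholds, function(e)
    neighborhood(graph, a, min_weight = e, same_class_as = cls))
  if (all(lengths(nb_sets) == 0L)) {
    warning("anchor has no same-class neighbors at any threshold")
    return(structure(list(anchor = a, thresholds = thresholds,
                          neighbors = nb_sets,
                          distances = matrix(NA_real_, 0L, ncol(X))),
                     class = "StabilityReport"))
  }
  cache <- occlusion_cache(X, graph, model)
  infl <- new.env(parent = emptyenv())
  influence_of <- function(i) {
    key <- as.character(i)
    if (!is.null(infl[[key]])) return(infl[[key]])
    Var <- feature_influences_cached(cache, i)
    y <- class_levels()[which.max(attr(Var, "base"))]
    v <- Var[, y]
    if (normalized) v <- suppressWarnings(normalize_influences(v))
    infl[[key]] <- v
    v
  }
  D <- matrix(NA_real_, length(thresholds), ncol(X),
              dimnames = list(sprintf("e>%.2f", thresholds),
                              colnames(X)))
  for (t in seq_along(thresholds)) {
    nb <- nb_sets[[t]]
    if (length(nb) == 0L) next
    V <- t(vapply(nb, influence_of, numeric(ncol(X))))
    D[t, ] <- apply(V, 2L, function(col) abs(max(col) - min(col)))
  }
  if (rescale) {
    mx <- apply(D, 2L, max, na.rm = TRUE)
    mx[mx == 0] <- 1
    D <- sweep(D, 2L, mx, "/")
  }
  structure(list(anchor = a, thresholds = thresholds,
                 neighbors = nb_sets, distances = D),
            class = "StabilityReport")
}

#' Modality ablation study
#'
#' Trains a fresh model per modality subset per seed via
#' [run_classification()] and tabulates per-class precision/recall/F1,
#' macro F1 (MCF) and accuracy (MCA) on the test partition.
#'
#' @param subsets list of modality-code vectors (subsets of
#'   `c("D", "MRI", "CT", "NT", "BM")`); names are used as row labels.
#' @param cohort raw cohort `data.frame`.
#' @param seeds integer vector of experiment seeds.
#' @param ... further arguments passed to [run_classification()].
#' @return An `AblationReport` data frame: one row per subset x seed,
#'   columns subset, seed, precision/recall/F1 per class (percent), mcf,
#'   mca.
#' @export
modality_ablation <- function(subsets, cohort, seeds, ...) {
  if (is.null(names(subsets)))
    names(subsets) <- vapply(subsets, paste, "", collapse = "+")
  rows <- list()
  for (s in names(subsets)) {
    if (length(subsets[[s]]) == 0L) stop("empty modality subset: ", s)
    for (seed in seeds) {
      res <- run_classification(cohort, seed, groups = subsets[[s]], ...)
      m <- res$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        subset = s, seed = seed,
        precision_nc = m$precision[["NC"]],
        precision_mci = m$precision[["MCI"]],
        precision_ad = m$precision[["AD"]],
        recall_nc = m$recall[["NC"]],
        recall_mci = m$recall[["MCI"]],
        recall_ad = m$recall[["AD"]],
        f1_nc = m$f1[["NC"]], f1_mci = m$f1[["MCI"]],
        f1_ad = m$f1[["AD"]],
        mcf = m$mcf, mca = m$mca, row.names = NULL)
    }
  }
  structure(do.call(rbind, rows),
            class = c("AblationReport", "data.frame"))
}
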