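## Decomposition-based explanations.
##
## The influence of an input element on a node's classification is the
## change in predicted class probability when that element is occluded:
##   Var_i(y|x)   = p(y|x) - p(y|x \ T_i)        (single feature)
##   GrpVar(y|x)  = p(y|x) - p(y|x \ T_{1..a})   (all features of a group)
##   EdgVar(y|x)  = p(y|x) - p(y|x \ E_c)        (all edges to class c)
## Positive influence supports the class, negative opposes it.  Because
## probabilities sum to one, the three class-wise variations of any one
## occlusion sum to zero: probability lost by one class is displaced to
## the others, which is what grounds the factual/counterfactual pairing.

check_trained <- function(model) {
  if (!inherits(model, "GCNModel") || !isTRUE(model$trained))
    stop("model must be a trained GCNModel")
}

#' Per-feature occlusion influences for one node
#'
#' Masks each of the node's features in turn and returns the resulting
#' probability variation for every class.
#'
#' @param node node index or id.
#' @param model trained `GCNModel`.
#' @param graph `PopulationGraph`.
#' @param X standardized feature matrix used at training time.
#' @param use_fast use the batched neighborhood kernel (default); the
#'   slow path runs one full forward per occlusion.
#' @return 13 x 3 matrix: rows features, columns classes; entry (i, y) is
#'   Var_i(y|x).  The unmasked probabilities are attached as attribute
#'   `"base"`.
#' @export
feature_influences <- function(node, model, graph, X, use_fast = TRUE) {
  check_trained(model)
  i <- resolve_node(graph, node)
  cache <- occlusion_cache(X, graph, model)
  feature_influences_cached(cache, i, use_fast)
}

feature_influences_cached <- function(cache, i, use_fast = TRUE) {
  d <- ncol(cache$X)
  Delta <- diag(-cache$X[i, ], d)        # row m zeroes feature m
  P <- node_delta_probs(cache, i, Delta, use_fast)
  base <- node_delta_probs(cache, i, matrix(0, 1L, d), use_fast)[1L, ]
  Var <- matrix(base, d, length(base), byrow = TRUE) - P
  dimnames(Var) <- list(colnames(cache$X), names(base))
  attr(Var, "base") <- base
  Var
}

#' Per-modality-group occlusion influences for one node
#'
#' All features of a group are masked concurrently; with a group of one
#' this reduces exactly to [feature_influences()].
#'
#' @inheritParams feature_influences
#' @param groups named list of feature-name vectors (default the five
#'   modality groups).
#' @return `length(groups)` x 3 influence matrix with attribute `"base"`.
#' @export
group_influences <- function(node, model, graph, X,
                             groups = feature_groups(), use_fast = TRUE) {
  check_trained(model)
  if (any(lengths(groups) == 0L)) stop("empty feature group")
  i <- resolve_node(graph, node)
  cache <- occlusion_cache(X, graph, model)
  d <- ncol(X)
  Delta <- matrix(0, length(groups), d, dimnames = list(names(groups),
                                                        colnames(X)))
  for (g in seq_along(groups)) {
    cols <- match(groups[[g]], colnames(X))
    if (anyNA(cols)) stop("group references unknown feature")
    Delta[g, cols] <- -X[i, cols]
  }
  P <- node_delta_probs(cache, i, Delta, use_fast)
  base <- node_delta_probs(cache, i, matrix(0, 1L, d), use_fast)[1L, ]
  Var <- matrix(base, nrow(Delta), length(base), byrow = TRUE) - P
  dimnames(Var) <- list(names(groups), names(base))
  attr(Var, "base") <- base
  Var
}

#' Edge-silencing influences per neighbor class
#'
#' For each class c, every edge from the node to a neighbor labeled c is
#' zeroed, the normalized adjacency is recomputed (degrees change), and
#' the probability variation from the unmodified prediction is returned.
#' Silencing a class with no connected neighbors is an exact no-op.
#'
#' @inheritParams feature_influences
#' @return 3 x 3 matrix: rows silenced classes, columns output classes;
#'   attribute `"base"` holds the unmodified probabilities.
#' @export
edge_class_influences <- function(node, model, graph, X) {
  check_trained(model)
  if (is.null(graph$labels)) stop("graph has no class labels")
  i <- resolve_node(graph, node)
  base <- gcn_forward(X, graph, model)[i, ]
  Var <- matrix(0, length(class_levels()), length(base),
                dimnames = list(class_levels(), names(base)))
  for (cl in class_levels()) {
    nb <- neighborhood(graph, i, min_weight = 0, same_class_as = cl)
    if (length(nb) == 0L) next     # nothing silenced: exact no-op
    p2 <- gcn_forward(X, graph, model,
                      mask_spec(edges = data.frame(node = i, class = cl)))[i, ]
    Var[cl, ] <- base - p2
  }
  attr(Var, "base") <- base
  Var
}

#' Class composition of a node's graph neighborhood
#'
#' @param node node index or id.
#' @param graph `PopulationGraph` with labels.
#' @param weighted if `TRUE`, shares are proportional to edge weights
#'   rather than neighbor counts.
#' @return Named numeric vector of percentages per class (sums to 100,
#'   or all zeros with a warning for an isolated node).
#' @export
neighbor_class_profile <- function(node, graph, weighted = FALSE) {
  if (is.null(graph$labels)) stop("graph has no class labels")
  i <- resolve_node(graph, node)
  nb <- neighborhood(graph, i, min_weight = 0)
  out <- setNames(numeric(length(class_levels())), class_levels())
  if (length(nb) == 0L) {
    warning("node ", i, " is isolated; neighbor profile is all zeros")
    return(out)
  }
  w <- if (weighted) graph$A[i, nb] else rep(1, length(nb))
  agg <- tapply(w, factor(graph$labels[nb], levels = class_levels()), sum)
  agg[is.na(agg)] <- 0
  setNames(as.numeric(100 * agg / sum(agg)), class_levels())
}

#' Normalize an influence vector for display
#'
#' Each influence is divided by the mean absolute influence of the
#' vector, so the mean magnitude becomes one while signs and ratios are
#' preserved.  Raw probability variations should be kept alongside; the
#' rescaling is cosmetic.
#'
#' @param v numeric influence vector.
#' @return The rescaled vector (unchanged, with a warning, if all zero).
#' @export
normalize_influences <- function(v) {
  m <- mean(abs(v))
  if (m == 0) {
    warning("all influences are zero; returning unchanged")
    return(v)
  }
  v / m
}

#' Discretize a feature value into a clinical or qualitative bin
#'
#' GDS and MMSE use published clinical cutoffs (GDS: normal <= 9, mild
#' depressive 10-19, severe depressive >= 20; MMSE: severe dementia <= 9,
#' moderate dementia 10-20, mild dementia 21-24, normal cognition >= 25).
#' Categorical features map to their level names.  Every other continuous
#' feature is binned by its signed distance from the pooled (all-class)
#' mean in SD units: very low (< -1.5), low, nominal, not so high, high,
#' very high (>= +1.5); for features where lower values are clinically
#' worse the sign is flipped before binning so that the label tracks
#' abnormality.
#'
#' @param name feature name.
#' @param value feature value in original units.
#' @param pooled_stats data frame from [pooled_feature_stats()].
#' @param flip_low_worse flip the sign convention for lower-is-worse
#'   features (default `TRUE`).
#' @return A bin label (character).
#' @export
discretize_feature <- function(name, value, pooled_stats,
                               flip_low_worse = TRUE) {
  if (name == "gender")
    return(if (value == 1) "male" else "female")
  if (name %in% c("abeta", "tau"))
    return(if (value > 0) "positive" else "negative")
  if (name == "gds") {
    return(if (value <= 9) "normal"
           else if (value <= 19) "mild depressive"
           else "severe depressive")
  }
  if (name == "mmse") {
    return(if (value <= 9) "severe dementia"
           else if (value <= 20) "moderate dementia"
           else if (value <= 24) "mild dementia"
           else "normal cognition")
  }
  row <- match(name, pooled_stats$feature)
  if (is.na(row)) stop("unknown feature name: ", name)
  z <- (value - pooled_stats$mean[row]) / pooled_stats$sd[row]
  if (flip_low_worse && name %in% low_is_worse_features()) z <- -z
  if (z < -1.5) "very low"
  else if (z < -0.5) "low"
  else if (z < 0.5) "nominal"
  else if (z < 1.0) "not so high"
  else if (z < 1.5) "high"
  else "very high"
}

#' Deviation of a record from matched healthy references
#'
#' For each continuous feature, the deviation is the record's value minus
#' the mean over normal-control subjects of the same gender within
#' `age_window` years of age.  An empty stratum widens the window in
#' steps of five years with a warning.
#'
#' @param record a single cohort row (original units).
#' @param reference_table cohort table (original units) from which NC
#'   rows are drawn.
#' @param age_window initial age half-window in years (default 5).
#' @return Named numeric vector of deviations (original units).
#' @export
reference_deviation <- function(record, reference_table, age_window = 5) {
  nc <- reference_table[reference_table$label == "NC", , drop = FALSE]
  if (nrow(nc) == 0L) stop("reference table contains no NC subjects")
  same_gender <- nc[nc$gender == record$gender, , drop = FALSE]
  if (nrow(same_gender) == 0L)
    stop("no NC subjects of the record's gender in the reference table")
  w <- age_window
  repeat {
    stratum <- same_gender[abs(same_gender$age - record$age) <= w, ,
                           drop = FALSE]
    if (nrow(stratum) > 0L) break
    w <- w + 5
    warning("empty reference stratum; widening age window to +/-", w,
            " years")
  }
  if (nrow(stratum) == 1L)
    warning("reference stratum has a single NC subject")
  feats <- continuous_features()
  dev <- vapply(feats,
                function(f) record[[f]] - mean(stratum[[f]]), 0)
  setNames(dev, feats)
}

## runner-up class with the clinically-adjacent tie rule: on a tie for
## second place the class nearer the predicted one in NC < MCI < AD
## order wins (earlier class on an exact distance tie)
runner_up_class <- function(p, tie_rule = c("adjacent", "index")) {
  tie_rule <- match.arg(tie_rule)
  cls <- class_levels()
  y_star <- which.max(p)
  rest <- setdiff(seq_along(p), y_star)
  pr <- p[rest]
  if (tie_rule == "adjacent" && abs(diff(pr)) < 1e-12) {
    dist <- abs(rest - y_star)
    return(cls[rest[which.min(dist)]])
  }
  cls[rest[which.max(pr)]]
}

#' Full explanation bundle for one node
#'
#' Assembles the factual/counterfactual explanation of a node's
#' classification: feature, group, and edge-class influences, neighbor
#' class profile, display-normalized influences, and (when the raw
#' cohort table is supplied) discretized feature bins, deviations from
#' matched healthy references, and rendered text.
#'
#' @inheritParams feature_influences
#' @param raw_table optional cohort table in original (unstandardized)
#'   units, used for bins, deviations and text.
#' @param floor minimum absolute normalized influence for a feature to
#'   be verbalized (default 0.25).
#' @param tie_rule runner-up tie rule (see details in
#'   [explain_node()] source): `"adjacent"` (default) or `"index"`.
#' @return An `ExplanationBundle`.
#' @export
explain_node <- function(node, model, graph, X, raw_table = NULL,
                         floor = 0.25, tie_rule = "adjacent") {
  check_trained(model)
  i <- resolve_node(graph, node)
  Var <- feature_influences(i, model, graph, X)
  base <- attr(Var, "base")
  y_star <- class_levels()[which.max(base)]
  y_prime <- runner_up_class(base, tie_rule)
  Grp <- group_influences(i, model, graph, X)
  Edg <- edge_class_influences(i, model, graph, X)
  profile <- neighbor_class_profile(i, graph)

  norm_fact <- suppressWarnings(normalize_influences(Var[, y_star]))
  norm_cf <- suppressWarnings(normalize_influences(Var[, y_prime]))

  bundle <- structure(
    list(node = i, id = graph$ids[i],
         probabilities = base,
         predicted = y_star, runner_up = y_prime,
         feature_influences = Var,
         group_influences = Grp,
         edge_influences = Edg,
         neighbor_profile = profile,
         normalized = list(factual = norm_fact, counterfactual = norm_cf),
         floor = floor),
    class = "ExplanationBundle")

  if (!is.null(raw_table)) {
    stats <- pooled_feature_stats(raw_table)
    record <- raw_table[i, ]
    bundle$values <- setNames(as.numeric(record[feature_names()]),
                              feature_names())
    bundle$bins <- vapply(feature_names(), function(f)
      discretize_feature(f, record[[f]], stats), "")
    bundle$deviations <- suppressWarnings(
      reference_deviation(record, raw_table))
    bundle$text <- render_text(bundle, bundle$bins, bundle$deviations,
                               floor = floor)
  }
  bundle
}

#' Render an explanation bundle as text sentences
#'
#' One sentence per influential feature (absolute normalized influence
#' above `floor`), ordered by decreasing influence magnitude, for the
#' factual and the counterfactual class.
#'
#' @param bundle an `ExplanationBundle`.
#' @param discretizations named character vector of bin labels per
#'   feature.
#' @param deviations named numeric vector of deviations from the matched
#'   healthy reference (continuous features).
#' @param floor minimum absolute normalized influence (default 0.25).
#' @return List with character vectors `factual` and `counterfactual`.
#' @export
render_text <- function(bundle, discretizations, deviations,
                        floor = 0.25) {
  sentence_set <- function(ninf, cls) {
    keep <- which(abs(ninf) >= floor)
    keep <- keep[order(abs(ninf[keep]), decreasing = TRUE)]
    vapply(keep, function(k) {
      f <- names(ninf)[k]
      dev <- if (f %in% names(deviations))
        sprintf("%+.2f vs. matched healthy reference", deviations[[f]])
      else "categorical"
      sprintf("%s is %s (%s), which %s %s",
              toupper(f), discretizations[[f]], dev,
              if (ninf[k] > 0) "supports" else "opposes", cls)
    }, "")
  }
  list(factual = sentence_set(bundle$normalized$factual,
                              bundle$predicted),
       counterfactual = sentence_set(bundle$normalized$counterfactual,
                                     bundle$runner_up))
}

#' Serialize an explanation bundle to JSON
#'
#' @param bundle an `ExplanationBundle`.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_bundle_json <- function(bundle, path) {
  ser <- list(
    node = bundle$node, id = bundle$id,
    probabilities = as.list(bundle$probabilities),
    predicted = bundle$predicted, runner_up = bundle$runner_up,
    feature_influences = as.list(as.data.frame(bundle$feature_influences)),
    group_influences = as.list(as.data.frame(bundle$group_influences)),
    edge_influences = as.list(as.data.frame(bundle$edge_influences)),
    neighbor_profile = as.list(bundle$neighbor_profile),
    normalized = lapply(bundle$normalized, as.list),
    values = if (!is.null(bundle$values)) as.list(bundle$values),
    bins = if (!is.null(bundle$bins)) as.list(bundle$bins),
    deviations = if (!is.null(bundle$deviations))
      as.list(bundle$deviations),
    text = bundle$text)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
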