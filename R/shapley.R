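## Shapley-value attribution for a node's predicted-class probability.
##
## Out-of-coalition features are replaced by values drawn from a
## background set (the training rows); the Shapley value of feature i is
## its average marginal contribution over coalitions.  Exact mode
## enumerates all 2^p coalitions and averages the value function over
## every background row (feasible for toy p); sampled mode uses
## permutation sampling with one background draw per permutation.  Both
## modes evaluate coalitions through the same batched row-delta kernel
## used by the decomposition explainer.

#' Shapley attributions for one node
#'
#' Attributes `p(target_class | x)` over the node's features.
#'
#' @param node node index or id.
#' @param model trained `GCNModel`.
#' @param graph `PopulationGraph`.
#' @param X standardized feature matrix.
#' @param background matrix of background feature rows (typically the
#'   training rows of X).
#' @param mode `"sampled"` (permutation sampling, default) or `"exact"`
#'   (full enumeration; refused above 20 features).
#' @param n_perm number of permutations in sampled mode (default 2000).
#' @param seed RNG seed for sampling.
#' @param target_class class whose probability is attributed (default
#'   the node's predicted class).
#' @return Named numeric vector of per-feature attributions, with
#'   attributes `"base"` (p(target|x)), `"baseline"` (mean background
#'   prediction) and `"target"`.
#' @export
shapley_values <- function(node, model, graph, X, background,
                           mode = c("sampled", "exact"), n_perm = 2000L,
                           seed = 1L, target_class = NULL) {
  mode <- match.arg(mode)
  check_trained(model)
  if (is.null(background) || nrow(background) == 0L)
    stop("background set must be non-empty")
  i <- resolve_node(graph, node)
  cache <- occlusion_cache(X, graph, model)
  x <- X[i, ]
  p <- length(x)
  base_probs <- node_delta_probs(cache, i, matrix(0, 1L, p))[1L, ]
  if (is.null(target_class))
    target_class <- class_levels()[which.max(base_probs)]
  tc <- match(target_class, class_levels())

  ## value of a batch of full feature rows (rows of Xi replace x)
  eval_rows <- function(rows) {
    Delta <- sweep(rows, 2L, x, "-")
    node_delta_probs(cache, i, Delta)[, tc]
  }

  if (mode == "exact") {
    if (p > 20L) stop("exact enumeration refused for more than 20 features")
    phi <- shapley_exact(function(S) {
      ## v(S): masked features replaced by each background row, averaged
      rows <- background
      rows[, S] <- matrix(x[S], nrow(background), sum(S), byrow = TRUE)
      mean(eval_rows(rows))
    }, p)
  } else {
    set.seed(seed)
    phi <- numeric(p)
    bg_idx <- sample.int(nrow(background), n_perm, replace = TRUE)
    perms <- replicate(n_perm, sample.int(p), simplify = FALSE)
    ## build the full evaluation batch: per permutation a chain of p+1
    ## rows walking from the background row to x in permutation order
    rows <- matrix(0, n_perm * (p + 1L), p)
    r <- 0L
    for (m in seq_len(n_perm)) {
      cur <- background[bg_idx[m], ]
      rows[r + 1L, ] <- cur
      for (k in seq_len(p)) {
        cur[perms[[m]][k]] <- x[perms[[m]][k]]
        rows[r + 1L + k, ] <- cur
      }
      r <- r + p + 1L
    }
    vals <- eval_rows(rows)
    r <- 0L
    for (m in seq_len(n_perm)) {
      chain <- vals[(r + 1L):(r + p + 1L)]
      phi[perms[[m]]] <- phi[perms[[m]]] + diff(chain)
      r <- r + p + 1L
    }
    phi <- phi / n_perm
  }
  names(phi) <- colnames(X)
  attr(phi, "base") <- base_probs[tc]
  attr(phi, "baseline") <- attr(phi, "base") - sum(phi)
  attr(phi, "target") <- target_class
  phi
}

## exact Shapley over a coalition value function v(S) taking a logical
## inclusion vector; enumerates all 2^p coalitions once
shapley_exact <- function(v, p) {
  n_coal <- 2L^p
  vals <- numeric(n_coal)
  members <- vector("list", n_coal)
  for (k in seq_len(n_coal)) {
    S <- as.logical(bitwAnd(k - 1L, 2L^(seq_len(p) - 1L)))
    members[[k]] <- S
    vals[k] <- v(S)
  }
  sizes <- vapply(members, sum, 0L)
  ## weight |S|! (p-|S|-1)! / p!
  wts <- exp(lfactorial(0:(p - 1L)) + lfactorial(p - 1L - (0:(p - 1L))) -
             lfactorial(p))
  phi <- numeric(p)
  bit <- 2L^(seq_len(p) - 1L)
  for (k in seq_len(n_coal)) {
    S <- members[[k]]
    for (j in seq_len(p)) {
      if (!S[j]) {
        k_with <- k + bit[j]
        phi[j] <- phi[j] + wts[sizes[k] + 1L] * (vals[k_with] - vals[k])
      }
    }
  }
  phi
}

#' Agreement between decomposition influences and Shapley attributions
#'
#' For each node, computes the decomposition influence vector and the
#' Shapley attribution vector for the node's predicted class, pools the
#' (feature, node) pairs within each predicted class, and reports the
#' Pearson correlation and the sign-agreement rate per class.
#'
#' @param nodes node indices to evaluate.
#' @param model trained `GCNModel`.
#' @param graph `PopulationGraph`.
#' @param X standardized feature matrix.
#' @param background background rows for [shapley_values()].
#' @param n_perm permutations per node for sampled Shapley.
#' @param seed RNG seed.
#' @param verbose print progress (default `FALSE`).
#' @return A list with per-class `r`, `sign_agreement`, `n_pairs`, and
#'   the pooled pairs data frame.
#' @export
method_agreement <- function(nodes, model, graph, X, background,
                             n_perm = 2000L, seed = 1L, verbose = FALSE) {
  check_trained(model)
  pairs <- vector("list", length(nodes))
  for (k in seq_along(nodes)) {
    i <- resolve_node(graph, nodes[k])
    Var <- feature_influences(i, model, graph, X)
    base <- attr(Var, "base")
    y_star <- class_levels()[which.max(base)]
    phi <- shapley_values(i, model, graph, X, background,
                          mode = "sampled", n_perm = n_perm,
                          seed = derive_seed(seed, paste0("shap", i)),
                          target_class = y_star)
    pairs[[k]] <- data.frame(node = i, class = y_star,
                             feature = rownames(Var),
                             decomposition = Var[, y_star],
                             shapley = as.numeric(phi),
                             row.names = NULL)
    if (verbose && k %% 10L == 0L)
      message("method_agreement: ", k, "/", length(nodes), " nodes")
  }
  pooled <- do.call(rbind, pairs)
  per_class <- lapply(split(pooled, factor(pooled$class,
                                           levels = class_levels())),
                      function(df) {
    if (nrow(df) < 2L ||
        sd(df$decomposition) == 0 || sd(df$shapley) == 0)
      return(list(r = NA_real_, sign_agreement = NA_real_,
                  n_pairs = nrow(df)))
    nz <- df$decomposition != 0 & df$shapley != 0
    list(r = cor(df$decomposition, df$shapley),
         sign_agreement = mean(sign(df$decomposition[nz]) ==
                               sign(df$shapley[nz])),
         n_pairs = nrow(df))
  })
  list(per_class = per_class, pairs = pooled)
}
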