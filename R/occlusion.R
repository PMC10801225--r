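## Fast occluded forwards for a single node.
##
## All feature-level occlusions and Shapley evaluations modify only one
## row of X.  For the standard 2-layer architecture the effect of a
## row-i delta on node i's own prediction factors through its graph
## neighborhood, so a batch of M occlusions costs O(|N(i)| * M * hidden)
## instead of M full-graph forward passes.  The batched path is exact
## (verified against full forwards in the test suite) and implemented in
## compiled code; a plain full-forward path is kept both as fallback for
## non-standard architectures and as the independent oracle.

## Precompute the quantities shared by all row-delta evaluations.
occlusion_cache <- function(X, graph, model) {
  At <- if (inherits(graph, "PopulationGraph")) graph$At else graph
  At <- as.matrix(At)
  B <- as.matrix(At %*% (X %*% model$W[[1L]]))
  B <- sweep(B, 2L, model$b[[1L]], "+")
  structure(list(X = X, graph = graph, At = At, model = model, B = B,
                 fast = length(model$W) == 2L &&
                   model$widths[1L] != model$widths[2L]),
            class = "occlusion_cache")
}

## Class probabilities of `node` under a batch of additive deltas to its
## feature row.  Delta is M x d; returns M x C probabilities.
node_delta_probs <- function(cache, node, Delta, use_fast = TRUE) {
  model <- cache$model
  Delta <- matrix(Delta, ncol = model$widths[1L])
  if (!use_fast || !cache$fast)
    return(node_delta_probs_full(cache, node, Delta))
  At <- cache$At
  nb <- which(At[node, ] != 0)
  D <- Delta %*% model$W[[1L]]
  logits <- .occl_logits(cache$B[nb, , drop = FALSE], At[node, nb], D,
                         model$W[[2L]], model$b[[2L]])
  P <- softmax_rows(logits)
  colnames(P) <- model$classes
  P
}

## oracle path: one full-graph forward per delta
node_delta_probs_full <- function(cache, node, Delta) {
  M <- nrow(Delta)
  P <- matrix(0, M, length(cache$model$classes))
  for (m in seq_len(M)) {
    X2 <- cache$X
    X2[node, ] <- X2[node, ] + Delta[m, ]
    P[m, ] <- gcn_forward(X2, cache$graph, cache$model)[node, ]
  }
  colnames(P) <- cache$model$classes
  P
}
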