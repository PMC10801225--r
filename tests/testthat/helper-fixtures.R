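## Shared fixtures, built once per test run.

## small end-to-end run (180 subjects) reused across explanation and
## evaluation tests
small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- generate_cohort(default_spec(), seed = 42,
                             n_override = c(60, 80, 40))
      cache <<- run_classification(tab, seed = 3,
                                   keep_similarities = TRUE)
    }
    cache
  }
})

## hand-built tiny graph: N nodes, given adjacency, labels
toy_graph <- function(A, labels = NULL, ids = NULL) {
  structure(list(A = A, At = normalize_adjacency(A), labels = labels,
                 ids = if (is.null(ids)) sprintf("S%04d", seq_len(nrow(A)))
                       else ids,
                 edge_threshold = 0, S = NULL),
            class = "PopulationGraph")
}

## model with hand-set weights, marked trained
toy_model <- function(W, b = NULL) {
  widths <- c(nrow(W[[1]]), vapply(W, ncol, 0L))
  if (is.null(b)) b <- lapply(W, function(w) numeric(ncol(w)))
  structure(list(W = W, b = b, widths = widths,
                 config = gcn_config(layers = length(W)),
                 classes = class_levels(), trained = TRUE),
            class = "GCNModel")
}

## explicit-loop evaluation of the convolution stack: scalar loops only,
## no matrix products -- the independent oracle for the forward pass
conv_forward_loop <- function(X, At, W, b) {
  H <- X
  L <- length(W)
  for (l in seq_len(L)) {
    n <- nrow(H); dout <- ncol(W[[l]])
    Z <- matrix(0, n, dout)
    for (i in seq_len(n))
      for (k in seq_len(dout)) {
        s <- b[[l]][k]
        for (j in seq_len(n))
          for (f in seq_len(ncol(H)))
            s <- s + At[i, j] * H[j, f] * W[[l]][f, k]
        Z[i, k] <- s
      }
    if (l < L) {
      Hn <- pmax(Z, 0)
      H <- if (ncol(Hn) == ncol(H)) Hn + H else Hn
    } else {
      P <- matrix(0, n, dout)
      for (i in seq_len(n)) {
        e <- exp(Z[i, ] - max(Z[i, ]))
        P[i, ] <- e / sum(e)
      }
      H <- P
    }
  }
  H
}

## dense-formula oracle for the normalized adjacency
norm_adj_oracle <- function(A) {
  Ahat <- A + diag(nrow(A))
  D <- diag(rowSums(Ahat))
  Dm <- diag(1 / sqrt(diag(D)))
  Dm %*% Ahat %*% Dm
}

expect_prob_rows <- function(P, tol = 1e-9) {
  expect_true(all(abs(rowSums(P) - 1) < tol))
}
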