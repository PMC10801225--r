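## Population-graph construction.
##
## Node-to-node similarity is computed per cognitive measure as one minus
## the pairwise Euclidean distance rescaled by the maximum pairwise
## distance; the per-measure similarities are combined (arithmetic mean),
## min-max rescaled over the off-diagonal, and thresholded to give the
## weighted adjacency A.  The propagation matrix is the self-looped
## symmetric normalization D^{-1/2} (A + I) D^{-1/2}.

#' Per-measure node similarity matrix
#'
#' Pairwise Euclidean distances between the scalar measurements are
#' scaled into \[0, 1\] by the maximum pairwise distance and subtracted
#' from one; the diagonal (a node's connection to itself) is forced to
#' zero.
#'
#' @param values numeric vector, one measurement per node (length >= 2).
#' @return N x N similarity matrix with zero diagonal.
#' @export
measure_similarity <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2L, !anyNA(values))
  n <- length(values)
  d <- abs(outer(values, values, "-"))
  dmax <- max(d)
  if (dmax == 0) {
    warning("all measurements equal; off-diagonal similarity set to 1")
    S <- matrix(1, n, n)
  } else {
    S <- 1 - d / dmax
  }
  diag(S) <- 0
  S
}

#' Combine per-measure similarities into a weighted adjacency
#'
#' The element-wise mean of the supplied similarity matrices is min-max
#' rescaled to \[0, 1\] over the off-diagonal entries; entries below
#' `edge_threshold` are zeroed (no significant similarity, hence no
#' edge).  The result is symmetric with zero diagonal.
#'
#' @param similarities list of same-shape similarity matrices (typically
#'   the three cognitive measures: memory, executive function, language).
#' @param edge_threshold minimum surviving edge weight in \[0, 1\]
#'   (default 0.5).
#' @param labels optional per-node class labels (needed for
#'   class-filtered neighborhoods and edge-silencing explanations).
#' @param ids optional node identifiers.
#' @param keep_similarities logical; store the per-measure matrices in
#'   the returned graph (default `TRUE`).
#' @return A `PopulationGraph`: list with `A` (adjacency), `At`
#'   (normalized adjacency), `labels`, `ids`, `edge_threshold`, and
#'   optionally `S` (per-measure similarities).
#' @export
build_adjacency <- function(similarities, edge_threshold = 0.5,
                            labels = NULL, ids = NULL,
                            keep_similarities = TRUE) {
  stopifnot(is.list(similarities), length(similarities) >= 1L)
  dims <- vapply(similarities, function(S) dim(S), integer(2L))
  if (any(dims != dims[1L]))
    stop("similarity matrices have mismatched shapes")
  if (edge_threshold < 0 || edge_threshold > 1)
    stop("edge_threshold must lie in [0, 1]")
  A <- Reduce(`+`, similarities) / length(similarities)
  off <- row(A) != col(A)
  rng <- range(A[off])
  A <- if (rng[2] > rng[1]) (A - rng[1]) / (rng[2] - rng[1])
       else matrix(1, nrow(A), ncol(A))
  A[A < edge_threshold] <- 0
  A <- (A + t(A)) / 2          # guard against asymmetric rounding
  diag(A) <- 0
  n <- nrow(A)
  if (!is.null(labels) && length(labels) != n)
    stop("labels length must equal node count")
  g <- structure(
    list(A = A, At = normalize_adjacency(A),
         labels = labels,
         ids = if (is.null(ids)) sprintf("S%04d", seq_len(n)) else ids,
         edge_threshold = edge_threshold,
         S = if (keep_similarities) similarities else NULL),
    class = "PopulationGraph")
  g
}

#' Self-looped symmetric adjacency normalization
#'
#' Computes D^{-1/2} (A + I) D^{-1/2}, where D is the degree matrix of
#' the self-looped adjacency A + I.  Degrees are always >= 1, so the
#' result is well defined and has strictly positive diagonal.
#'
#' @param A symmetric adjacency matrix (or a `PopulationGraph`).
#' @return The normalized adjacency matrix.
#' @export
normalize_adjacency <- function(A) {
  if (inherits(A, "PopulationGraph")) A <- A$A
  Ahat <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Ahat))
  Ahat * tcrossprod(dinv)
}

#' Graph neighborhood above an edge-weight threshold
#'
#' @param graph a `PopulationGraph`.
#' @param node node index or id.
#' @param min_weight minimum (exclusive) edge weight.
#' @param same_class_as optional class label; restrict to nodes with this
#'   label.
#' @return Integer vector of neighbor node indices.
#' @export
neighborhood <- function(graph, node, min_weight = 0,
                         same_class_as = NULL) {
  i <- resolve_node(graph, node)
  nb <- which(graph$A[i, ] > min_weight)
  nb <- setdiff(nb, i)
  if (!is.null(same_class_as)) {
    if (is.null(graph$labels)) stop("graph has no class labels")
    nb <- nb[graph$labels[nb] == same_class_as]
  }
  nb
}

resolve_node <- function(graph, node) {
  if (is.character(node)) {
    i <- match(node, graph$ids)
    if (is.na(i)) stop("unknown node id: ", node)
    return(i)
  }
  i <- as.integer(node)
  if (is.na(i) || i < 1L || i > nrow(graph$A))
    stop("node index out of range: ", node)
  i
}

#' Export / import the adjacency as an edge list or Matrix Market file
#'
#' `write_edge_tsv` writes a whitespace-separated `i j weight` list of
#' the upper-triangle nonzero edges; `write_adjacency_mtx` writes the
#' sparse symmetric adjacency in Matrix Market format.
#'
#' @param graph a `PopulationGraph` (or adjacency matrix for export).
#' @param path file path.
#' @return The path, invisibly (readers return the adjacency matrix).
#' @export
write_edge_tsv <- function(graph, path) {
  A <- if (inherits(graph, "PopulationGraph")) graph$A else graph
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], weight = A[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_tsv
#' @param n node count (edge lists do not record isolated trailing
#'   nodes).
#' @export
read_edge_tsv <- function(path, n = NULL) {
  df <- utils::read.table(path, header = TRUE)
  if (is.null(n)) n <- max(df$i, df$j)
  A <- matrix(0, n, n)
  A[cbind(df$i, df$j)] <- df$weight
  A[cbind(df$j, df$i)] <- df$weight
  A
}

#' @rdname write_edge_tsv
#' @export
write_adjacency_mtx <- function(graph, path) {
  A <- if (inherits(graph, "PopulationGraph")) graph$A else graph
  Matrix::writeMM(Matrix::Matrix(A, sparse = TRUE), path)
  invisible(path)
}

#' @rdname write_edge_tsv
#' @export
read_adjacency_mtx <- function(path) {
  as.matrix(Matrix::readMM(path))
}

#' Build the population graph from a standardized cohort table
#'
#' Convenience wrapper: computes one similarity matrix per graph measure
#' (default the three cognitive composites) and combines them with
#' [build_adjacency()].  Distances are taken on the standardized scores
#' so no measure dominates.
#'
#' @param table standardized cohort `data.frame`.
#' @param measures feature names defining similarity (default
#'   `c("mem", "exf", "lan")`).
#' @param edge_threshold passed to [build_adjacency()].
#' @param keep_similarities passed to [build_adjacency()].
#' @return A `PopulationGraph`.
#' @export
population_graph <- function(table, measures = c("mem", "exf", "lan"),
                             edge_threshold = 0.5,
                             keep_similarities = TRUE) {
  stopifnot(all(measures %in% names(table)))
  sims <- lapply(measures, function(m) measure_similarity(table[[m]]))
  names(sims) <- measures
  build_adjacency(sims, edge_threshold = edge_threshold,
                  labels = table$label, ids = table$id,
                  keep_similarities = keep_similarities)
}
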