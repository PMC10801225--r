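## Spectral graph convolutional network.
##
## Layer rule: H_{l+1} = relu(At %*% H_l %*% W_l + b_l), with a residual
## connection added only when input and output widths agree (a residual
## across a width change is dimensionally impossible).  The final layer
## applies a row-wise softmax.  Training is transductive: the forward
## pass runs over the whole graph, the cross-entropy loss is evaluated on
## training rows only, optimized with Adam.
##
## Masking contract (used by the explanation module): masked (node,
## feature) cells contribute nothing to any weighted sum they enter —
## omitted, not renormalized.  Because a cell enters the computation only
## through weighted sums of the first propagation, omission is realized
## by zeroing the cell's contribution.  Masked edge groups zero the
## target node's rows/columns of A for neighbors of a class, after which
## the normalized adjacency is recomputed (degrees change).

#' GCN hyperparameter configuration
#'
#' @param hidden hidden-layer width (default 32).
#' @param layers number of graph-convolution layers (default 2).
#' @param lr Adam learning rate (default 0.01).
#' @param epochs training epochs (default 100).
#' @param val_every validation cadence in epochs (default 5).
#' @param seed RNG seed for weight initialization.
#' @return A list of class `gcn_config`.
#' @export
gcn_config <- function(hidden = 32L, layers = 2L, lr = 0.01,
                       epochs = 100L, val_every = 5L, seed = 1L) {
  structure(list(hidden = as.integer(hidden), layers = as.integer(layers),
                 lr = lr, epochs = as.integer(epochs),
                 val_every = as.integer(val_every), seed = as.integer(seed)),
            class = "gcn_config")
}

## Glorot-style scaled uniform init
init_gcn <- function(d_in, d_out = 3L, config = gcn_config()) {
  set.seed(config$seed)
  widths <- c(d_in, rep(config$hidden, config$layers - 1L), d_out)
  W <- vector("list", config$layers)
  b <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    s <- sqrt(6 / (widths[l] + widths[l + 1L]))
    W[[l]] <- matrix(runif(widths[l] * widths[l + 1L], -s, s),
                     widths[l], widths[l + 1L])
    b[[l]] <- numeric(widths[l + 1L])
  }
  structure(list(W = W, b = b, widths = widths, config = config,
                 classes = class_levels(), trained = FALSE),
            class = "GCNModel")
}

#' Mask specification for occluded forward passes
#'
#' @param features two-column matrix/data.frame of (node, feature) cells
#'   to silence; feature may be an index or name.
#' @param edges data.frame with columns `node` and `class`: all edges
#'   from `node` to neighbors labeled `class` are zeroed (and the
#'   normalized adjacency recomputed).
#' @return A `MaskSpec`; empty arguments give the identity mask.
#' @export
mask_spec <- function(features = NULL, edges = NULL) {
  structure(list(features = features, edges = edges), class = "MaskSpec")
}

apply_feature_mask <- function(X, features) {
  if (is.null(features)) return(X)
  features <- as.data.frame(features)
  names(features) <- c("node", "feature")[seq_len(ncol(features))]
  fidx <- features$feature
  if (is.character(fidx) || is.factor(fidx)) {
    fidx <- match(as.character(fidx), colnames(X))
    if (anyNA(fidx)) stop("mask references unknown feature name")
  }
  fidx <- as.integer(fidx)
  nidx <- as.integer(features$node)
  if (any(nidx < 1L | nidx > nrow(X))) stop("mask references unknown node")
  if (any(fidx < 1L | fidx > ncol(X))) stop("mask references unknown feature")
  X[cbind(nidx, fidx)] <- 0   # omitted from every weighted sum
  X
}

apply_edge_mask <- function(graph, edges) {
  if (is.null(edges) || nrow(edges) == 0L) return(graph$At)
  if (is.null(graph$labels)) stop("graph has no class labels")
  A <- graph$A
  for (k in seq_len(nrow(edges))) {
    i <- resolve_node(graph, edges$node[k])
    sel <- which(graph$labels == as.character(edges$class[k]))
    A[i, sel] <- 0
    A[sel, i] <- 0
  }
  normalize_adjacency(A)
}

#' GCN forward pass (optionally masked)
#'
#' Runs the spectral convolution stack over the whole graph and returns
#' per-node class probabilities.  With a `MaskSpec`, masked feature cells
#' are omitted from the weighted sums and masked edge groups are zeroed
#' in A before renormalization.
#'
#' @param X feature matrix (N x d).
#' @param graph a `PopulationGraph` (or a precomputed normalized
#'   adjacency matrix, in which case edge masks are not supported).
#' @param model a `GCNModel`.
#' @param mask optional `MaskSpec`.
#' @return N x 3 matrix of class probabilities (rows sum to 1).
#' @export
gcn_forward <- function(X, graph, model, mask = NULL) {
  if (inherits(graph, "PopulationGraph")) {
    At <- if (!is.null(mask) && !is.null(mask$edges))
      apply_edge_mask(graph, mask$edges) else graph$At
  } else {
    if (!is.null(mask) && !is.null(mask$edges))
      stop("edge masks require a PopulationGraph, not a bare matrix")
    At <- graph
  }
  if (nrow(X) != nrow(At)) stop("X and adjacency dimensions disagree")
  if (ncol(X) != model$widths[1L])
    stop("X width ", ncol(X), " does not match model input width ",
         model$widths[1L])
  if (!is.null(mask)) X <- apply_feature_mask(X, mask$features)
  H <- X
  L <- length(model$W)
  for (l in seq_len(L)) {
    Z <- At %*% (H %*% model$W[[l]])
    Z <- sweep(Z, 2L, model$b[[l]], "+")
    if (l < L) {
      Hn <- relu(Z)
      H <- if (ncol(Hn) == ncol(H)) Hn + H else Hn
    } else {
      H <- softmax_rows(Z)
    }
  }
  P <- as.matrix(H)
  colnames(P) <- model$classes
  rownames(P) <- rownames(X)
  P
}

## forward keeping intermediates for backprop (2-layer fast path works
## for any depth; residuals handled as in gcn_forward)
gcn_forward_cache <- function(X, At, model) {
  L <- length(model$W)
  Hs <- vector("list", L + 1L); Hs[[1L]] <- X
  Zs <- vector("list", L)
  AH <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    AH[[l]] <- At %*% H
    Z <- sweep(AH[[l]] %*% model$W[[l]], 2L, model$b[[l]], "+")
    Zs[[l]] <- Z
    if (l < L) {
      Hn <- relu(Z)
      H <- if (ncol(Hn) == ncol(H)) Hn + H else Hn
    } else {
      H <- softmax_rows(as.matrix(Z))
    }
    Hs[[l + 1L]] <- H
  }
  list(P = as.matrix(Hs[[L + 1L]]), Hs = Hs, Zs = Zs, AH = AH)
}

## cross-entropy loss on the training rows plus analytic gradients for
## every layer (exposed internally so tests can finite-difference it)
gcn_loss_grads <- function(model, X, At, Y, tr) {
  L <- length(model$W)
  fc <- gcn_forward_cache(X, At, model)
  P <- fc$P
  idx <- cbind(tr, max.col(Y[tr, , drop = FALSE], ties.method = "first"))
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dZ <- (P - Y)
  dZ[-tr, ] <- 0
  dZ <- dZ / length(tr)
  gW <- vector("list", L); gb <- vector("list", L)
  dH_skip <- NULL   # residual gradient flowing past a relu block
  for (l in rev(seq_len(L))) {
    gW[[l]] <- as.matrix(crossprod(fc$AH[[l]], dZ))
    gb[[l]] <- colSums(dZ)
    if (l > 1L) {
      dH <- At %*% (dZ %*% t(model$W[[l]]))   # At symmetric
      if (!is.null(dH_skip)) dH <- dH + dH_skip
      ## H_{l-1} = relu(Z_{l-1}) (+ H_{l-2} when widths equal); the
      ## skip path passes dH through unchanged to the layer below
      dZ <- as.matrix(dH * (fc$Zs[[l - 1L]] > 0))
      dH_skip <- if (ncol(fc$Hs[[l]]) == ncol(fc$Hs[[l - 1L]]))
        as.matrix(dH) else NULL
    }
  }
  list(loss = loss, gW = gW, gb = gb, P = P)
}

#' Train the GCN (transductive, Adam)
#'
#' Forward passes run over the whole graph; the cross-entropy loss and
#' gradients are computed on training rows only.  Validation accuracy is
#' recorded every `val_every` epochs and the checkpoint with the best
#' validation accuracy (earliest on ties) is returned.  Deterministic for
#' a fixed config seed.
#'
#' @param X feature matrix.
#' @param graph `PopulationGraph` or normalized adjacency matrix.
#' @param labels character/factor vector of class labels.
#' @param split a `SplitAssignment`.
#' @param config a [gcn_config()].
#' @return A trained `GCNModel` with a `history` data frame (epoch, loss,
#'   val_acc) attached.
#' @export
gcn_train <- function(X, graph, labels, split, config = gcn_config()) {
  At <- if (inherits(graph, "PopulationGraph")) graph$At else graph
  At <- as.matrix(At)
  labels <- factor(as.character(labels), levels = class_levels())
  tr <- which(split$partition == "train")
  va <- which(split$partition == "validation")
  if (length(tr) == 0L) stop("empty train partition")
  C <- length(class_levels())
  Y <- matrix(0, nrow(X), C)
  Y[cbind(seq_len(nrow(X)), as.integer(labels))] <- 1

  model <- init_gcn(ncol(X), C, config)
  L <- length(model$W)

  ## Adam state
  mW <- lapply(model$W, function(w) w * 0); vW <- mW
  mb <- lapply(model$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  AX <- At %*% X   # constant first propagation
  best <- list(acc = -Inf, W = model$W, b = model$b, epoch = 0L)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     val_acc = numeric())
  ylab <- as.integer(labels)

  for (epoch in seq_len(config$epochs)) {
    lg <- gcn_loss_grads(model, X, At, Y, tr)
    loss <- lg$loss
    gW <- lg$gW
    gb <- lg$gb
    ## Adam update
    t_ <- epoch
    for (l in seq_len(L)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      mhat <- mW[[l]] / (1 - beta1^t_); vhat <- vW[[l]] / (1 - beta2^t_)
      model$W[[l]] <- model$W[[l]] - config$lr * as.matrix(mhat / (sqrt(vhat) + eps))
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      mbh <- mb[[l]] / (1 - beta1^t_); vbh <- vb[[l]] / (1 - beta2^t_)
      model$b[[l]] <- model$b[[l]] - config$lr * mbh / (sqrt(vbh) + eps)
    }

    val_acc <- NA_real_
    if (length(va) > 0L && epoch %% config$val_every == 0L) {
      Pv <- gcn_forward_cache(X, At, model)$P
      pred <- max.col(Pv[va, , drop = FALSE], ties.method = "first")
      val_acc <- mean(pred == ylab[va])
      if (val_acc > best$acc)
        best <- list(acc = val_acc, W = model$W, b = model$b,
                     epoch = epoch)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = loss,
                                   val_acc = val_acc))
  }
  if (is.finite(best$acc)) {
    model$W <- best$W; model$b <- best$b
    model$best_epoch <- best$epoch
    model$best_val_acc <- best$acc
  }
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Predicted class labels from a probability matrix
#'
#' @param P N x 3 probability matrix.
#' @return Factor of predicted labels (ties broken toward the earlier
#'   class in NC < MCI < AD order).
#' @export
predict_classes <- function(P) {
  factor(class_levels()[max.col(P, ties.method = "first")],
         levels = class_levels())
}

#' Classification metrics: per-class precision/recall/F1, macro F1, accuracy
#'
#' The confusion matrix is oriented with true classes as rows and
#' predictions as columns.  A class absent from the labels gets F1 = 0
#' with a warning.  All metrics are percentages.
#'
#' @param predictions factor/character of predicted labels.
#' @param labels factor/character of true labels.
#' @return List with `precision`, `recall`, `f1` (named per class, in
#'   percent), `mcf` (macro F1, percent), `mca` (accuracy, percent), and
#'   `confusion`.
#' @export
evaluate_metrics <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have the same length")
  cls <- class_levels()
  predictions <- factor(as.character(predictions), levels = cls)
  labels <- factor(as.character(labels), levels = cls)
  conf <- table(true = labels, predicted = predictions)
  cm <- matrix(conf, length(cls), length(cls))
  prec <- diag(cm) / colSums(cm)
  rec <- diag(cm) / rowSums(cm)
  names(prec) <- names(rec) <- cls
  prec[is.nan(prec)] <- 0
  f1 <- 2 * prec * rec / (prec + rec)
  f1[is.nan(f1)] <- 0
  absent <- cls[rowSums(conf) == 0]
  if (length(absent) > 0L) {
    warning("class(es) absent from labels: ", paste(absent, collapse = ", "),
            "; F1 defined as 0")
    rec[absent] <- 0
    f1[absent] <- 0
  }
  list(precision = 100 * prec, recall = 100 * rec, f1 = 100 * f1,
       mcf = 100 * mean(f1), mca = 100 * mean(predictions == labels),
       confusion = conf)
}

#' Save / load a model checkpoint as JSON
#'
#' Weights are serialized in full double precision.
#'
#' @param model a `GCNModel`.
#' @param path file path.
#' @return The path invisibly; the loader returns the model.
#' @export
write_model_json <- function(model, path) {
  obj <- list(widths = model$widths,
              W = lapply(model$W, function(w)
                list(dim = dim(w), data = as.numeric(w))),
              b = model$b,
              config = unclass(model$config),
              classes = model$classes,
              trained = model$trained,
              best_epoch = model$best_epoch,
              best_val_acc = model$best_val_acc)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  W <- lapply(obj$W, function(w)
    matrix(as.numeric(w$data), w$dim[1], w$dim[2]))
  cfg <- do.call(gcn_config, as.list(obj$config)[c("hidden", "layers", "lr",
                                                   "epochs", "val_every",
                                                   "seed")])
  structure(list(W = W, b = lapply(seq_along(W),
                                   function(l) as.numeric(obj$b[[l]])),
                 widths = as.integer(obj$widths), config = cfg,
                 classes = obj$classes,
                 trained = isTRUE(obj$trained[1L]),
                 best_epoch = obj$best_epoch,
                 best_val_acc = obj$best_val_acc),
            class = "GCNModel")
}
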