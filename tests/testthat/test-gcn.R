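test_that("forward pass equals the explicit-loop convolution oracle", {
  set.seed(11)
  for (trial in 1:3) {
    n <- sample(3:5, 1)
    A <- matrix(runif(n * n), n); A <- (A + t(A)) / 2; diag(A) <- 0
    g <- toy_graph(A)
    X <- matrix(rnorm(n * 4), n, 4)
    ## 2 layers, width change (no residual possible at layer 1)
    W <- list(matrix(rnorm(4 * 6, sd = 0.5), 4, 6),
              matrix(rnorm(6 * 3, sd = 0.5), 6, 3))
    b <- list(rnorm(6, sd = 0.1), rnorm(3, sd = 0.1))
    model <- toy_model(W, b)
    P <- gcn_forward(X, g, model)
    expect_lt(max(abs(P - conv_forward_loop(X, g$At, W, b))), 1e-10)
    expect_prob_rows(P)
  }
  ## equal-width hidden layers engage the residual path
  n <- 4
  A <- matrix(0.5, n, n); diag(A) <- 0
  g <- toy_graph(A)
  X <- matrix(rnorm(n * 3), n, 3)
  W <- list(matrix(rnorm(9, sd = 0.4), 3, 3),
            matrix(rnorm(9, sd = 0.4), 3, 3))
  b <- list(rnorm(3, sd = 0.1), rnorm(3, sd = 0.1))
  model <- toy_model(W, b)
  expect_lt(max(abs(gcn_forward(X, g, model) -
                    conv_forward_loop(X, g$At, W, b))), 1e-10)
})

test_that("a single isolated node reduces to a softmax of its own features", {
  At <- matrix(1, 1, 1)
  x <- matrix(c(0.3, -1.2), 1, 2)
  W <- list(matrix(c(1, 0, 0, 1, 0.5, -0.5), 2, 3))
  model <- toy_model(W)
  z <- as.numeric(x %*% W[[1]])
  expect_equal(as.numeric(gcn_forward(x, At, model)),
               exp(z) / sum(exp(z)), tolerance = 1e-12)
})

test_that("feature masks follow the omission contract", {
  run <- small_run()
  X <- run$X; g <- run$graph; model <- run$model
  ## empty mask is the identity
  expect_identical(gcn_forward(X, g, model, mask_spec()),
                   gcn_forward(X, g, model))
  ## a dead feature (zero first-layer column) changes nothing when masked
  model2 <- model
  model2$W[[1]][3, ] <- 0
  P0 <- gcn_forward(X, g, model2)
  Pm <- gcn_forward(X, g, model2,
                    mask_spec(features = cbind(seq_len(nrow(X)), 3)))
  expect_equal(Pm, P0, tolerance = 1e-12)
  ## masking everything makes the output invariant to permuting X
  full <- mask_spec(features = as.matrix(expand.grid(seq_len(nrow(X)),
                                                     seq_len(ncol(X)))))
  Pa <- gcn_forward(X, g, model, full)
  Xperm <- X[sample(nrow(X)), ]
  Pb <- gcn_forward(Xperm, g, model, full)
  expect_equal(Pa, Pb, tolerance = 1e-12, ignore_attr = TRUE)
  expect_prob_rows(Pa)
  ## unknown cells are rejected
  expect_error(gcn_forward(X, g, model,
                           mask_spec(features = cbind(1, 99))),
               "unknown feature")
  expect_error(gcn_forward(X, g, model,
                           mask_spec(features = cbind(nrow(X) + 1, 1))),
               "unknown node")
  ## feature masks can use names
  Pn <- gcn_forward(X, g, model,
                    mask_spec(features = data.frame(node = 1,
                                                    feature = "mem")))
  X2 <- X; X2[1, "mem"] <- 0
  expect_equal(Pn, gcn_forward(X2, g, model), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  set.seed(13)
  n <- 6
  A <- matrix(runif(n * n), n); A <- (A + t(A)) / 2; diag(A) <- 0
  At <- normalize_adjacency(A)
  X <- matrix(rnorm(n * 4), n, 4)
  Y <- diag(3)[sample(1:3, n, replace = TRUE), ]
  tr <- 1:4
  model <- popgcn:::init_gcn(4, 3, gcn_config(hidden = 5, seed = 2))
  lg <- popgcn:::gcn_loss_grads(model, X, At, Y, tr)
  eps <- 1e-6
  for (l in 1:2) for (idx in list(c(1, 1), c(2, 3))) {
    m2 <- model; m2$W[[l]][idx[1], idx[2]] <- m2$W[[l]][idx[1], idx[2]] + eps
    up <- popgcn:::gcn_loss_grads(m2, X, At, Y, tr)$loss
    m2$W[[l]][idx[1], idx[2]] <- m2$W[[l]][idx[1], idx[2]] - 2 * eps
    dn <- popgcn:::gcn_loss_grads(m2, X, At, Y, tr)$loss
    expect_equal(lg$gW[[l]][idx[1], idx[2]], (up - dn) / (2 * eps),
                 tolerance = 1e-5)
  }
  m2 <- model; m2$b[[2]][1] <- m2$b[[2]][1] + eps
  up <- popgcn:::gcn_loss_grads(m2, X, At, Y, tr)$loss
  m2$b[[2]][1] <- m2$b[[2]][1] - 2 * eps
  dn <- popgcn:::gcn_loss_grads(m2, X, At, Y, tr)$loss
  expect_equal(lg$gb[[2]][1], (up - dn) / (2 * eps), tolerance = 1e-5)
})

test_that("training is deterministic and fits separable data perfectly", {
  set.seed(31)
  n <- 60
  x1 <- c(rnorm(n / 2, -2, 0.3), rnorm(n / 2, 2, 0.3))
  labels <- rep(c("NC", "AD"), each = n / 2)
  X <- cbind(x1, rnorm(n, sd = 0.3))
  colnames(X) <- c("f1", "f2")
  g <- build_adjacency(list(measure_similarity(x1)),
                       edge_threshold = 0.5, labels = labels)
  split <- structure(list(partition = factor(
    rep(c("train", "validation", "test"), length.out = n),
    levels = c("train", "validation", "test")),
    fractions = c(1, 1, 1) / 3, seed = 0), class = "SplitAssignment")
  cfg <- gcn_config(hidden = 8, seed = 5)
  m1 <- gcn_train(X, g, labels, split, cfg)
  m2 <- gcn_train(X, g, labels, split, cfg)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$history, m2$history)
  P <- gcn_forward(X, g, m1)
  tr <- split$partition == "train"
  expect_equal(mean(predict_classes(P)[tr] == labels[tr]), 1.0)
  expect_error(gcn_train(X, g, labels,
                         structure(list(partition = factor(
                           rep("test", n),
                           levels = c("train", "validation", "test"))),
                           class = "SplitAssignment"), cfg),
               "empty train")
})

test_that("random labels yield chance-level test accuracy", {
  set.seed(17)
  n <- 150
  labels <- sample(rep(class_levels(), n / 3))
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  g <- build_adjacency(list(measure_similarity(X[, 1])),
                       edge_threshold = 0.3, labels = labels)
  split <- split_dataset(data.frame(label = labels), seed = 1,
                         fractions = c(0.6, 0.2, 0.2))
  m <- gcn_train(X, g, labels, split, gcn_config(hidden = 8, seed = 3))
  te <- split$partition == "test"
  acc <- mean(predict_classes(gcn_forward(X, g, m))[te] == labels[te])
  expect_gt(acc, 0.05)
  expect_lt(acc, 0.65)
})

test_that("classification metrics match hand-computed values", {
  perfect <- evaluate_metrics(c("NC", "MCI", "AD"), c("NC", "MCI", "AD"))
  expect_equal(unname(perfect$precision), rep(100, 3))
  expect_equal(perfect$mcf, 100)
  expect_equal(perfect$mca, 100)

  ## confusion [[2,0,0],[1,1,0],[0,0,2]] (rows true, cols predicted)
  truth <- c("NC", "NC", "MCI", "MCI", "AD", "AD")
  pred <- c("NC", "NC", "NC", "MCI", "AD", "AD")
  m <- evaluate_metrics(pred, truth)
  expect_equal(unname(m$confusion["NC", ]), c(2, 0, 0), ignore_attr = TRUE)
  expect_equal(unname(m$confusion["MCI", ]), c(1, 1, 0), ignore_attr = TRUE)
  expect_equal(unname(m$precision[["NC"]]), 100 * 2 / 3)
  expect_equal(unname(m$recall[["MCI"]]), 50)
  expect_equal(unname(m$precision[["AD"]]), 100)
  expect_equal(m$mca, 100 * 5 / 6)

  ## all-one-class predictor on balanced labels
  m2 <- evaluate_metrics(rep("NC", 6), rep(class_levels(), each = 2))
  expect_equal(m2$mca, 100 / 3, tolerance = 1e-9)
  expect_equal(m2$mcf, 100 / 6, tolerance = 1e-9)

  ## class absent from labels warns and gets F1 = 0
  expect_warning(m3 <- evaluate_metrics(c("NC", "MCI"), c("NC", "MCI")),
                 "AD")
  expect_equal(unname(m3$f1[["AD"]]), 0)
  expect_error(evaluate_metrics("NC", c("NC", "MCI")), "length")
})

test_that("model checkpoints round-trip through JSON", {
  run <- small_run()
  f <- tempfile(fileext = ".json")
  write_model_json(run$model, f)
  m2 <- read_model_json(f)
  expect_equal(m2$W, run$model$W, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m2$b, run$model$b, tolerance = 1e-12)
  P1 <- gcn_forward(run$X, run$graph, run$model)
  P2 <- gcn_forward(run$X, run$graph, m2)
  expect_equal(P1, P2, tolerance = 1e-12)
})

test_that("training on the synthetic cohort beats chance with AD well recalled", {
  run <- small_run()
  expect_gt(run$metrics$mca, 50)
  expect_gt(run$metrics$recall[["AD"]], 50)
  ## history records validation accuracy every 5 epochs
  h <- run$model$history
  expect_equal(nrow(h), 100L)
  expect_true(all(!is.na(h$val_acc[h$epoch %% 5 == 0])))
  expect_true(all(is.na(h$val_acc[h$epoch %% 5 != 0])))
})
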