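test_that("every occlusion's class-wise variations sum to zero", {
  run <- small_run()
  set.seed(91)
  nodes <- sample(nrow(run$X), 6)
  for (i in nodes) {
    Var <- feature_influences(i, run$model, run$graph, run$X)
    expect_lt(max(abs(rowSums(Var))), 1e-9)
    Grp <- group_influences(i, run$model, run$graph, run$X)
    expect_lt(max(abs(rowSums(Grp))), 1e-9)
    Edg <- edge_class_influences(i, run$model, run$graph, run$X)
    expect_lt(max(abs(rowSums(Edg))), 1e-9)
  }
})

test_that("fast occluded forwards agree with full-graph forwards", {
  run <- small_run()
  cache <- popgcn:::occlusion_cache(run$X, run$graph, run$model)
  set.seed(92)
  for (i in sample(nrow(run$X), 3)) {
    Delta <- rbind(matrix(rnorm(3 * ncol(run$X)), 3), 0)
    fast <- popgcn:::node_delta_probs(cache, i, Delta, use_fast = TRUE)
    full <- popgcn:::node_delta_probs(cache, i, Delta, use_fast = FALSE)
    expect_lt(max(abs(fast - full)), 1e-10)
  }
})

test_that("a dead feature has zero influence for every class", {
  run <- small_run()
  model <- run$model
  model$W[[1]][match("thv", colnames(run$X)), ] <- 0
  Var <- feature_influences(5, model, run$graph, run$X)
  expect_equal(unname(Var["thv", ]), rep(0, 3), tolerance = 1e-12)
})

test_that("a hand-computed softmax difference matches the influence", {
  ## one isolated node, one linear layer: occluding feature i shifts the
  ## logits by exactly -x_i * W[i, ]
  At <- matrix(1, 1, 1)
  g <- structure(list(A = matrix(0, 1, 1), At = At, labels = "NC",
                      ids = "S0001", edge_threshold = 0, S = NULL),
                 class = "PopulationGraph")
  W <- list(matrix(c(2, -1, 0, 1, -0.5, 0.5), 2, 3))
  x <- matrix(c(0.8, -0.4), 1, 2, dimnames = list("S0001", c("f1", "f2")))
  model <- toy_model(W)
  soft <- function(z) exp(z) / sum(exp(z))
  p_full <- soft(as.numeric(x %*% W[[1]]))
  Var <- feature_influences(1, model, g, x)
  for (i in 1:2) {
    xi <- x; xi[1, i] <- 0
    expect_equal(unname(Var[i, ]),
                 p_full - soft(as.numeric(xi %*% W[[1]])),
                 tolerance = 1e-12)
  }
})

test_that("a group of one reduces exactly to the single-feature influence", {
  run <- small_run()
  Var <- feature_influences(7, run$model, run$graph, run$X)
  Grp <- group_influences(7, run$model, run$graph, run$X,
                          groups = list(solo = "mmse"))
  expect_equal(unname(Grp["solo", ]), unname(Var["mmse", ]),
               tolerance = 1e-12)
  expect_error(group_influences(7, run$model, run$graph, run$X,
                                groups = list(bad = character(0))),
               "empty")
})

test_that("masking all five groups at once equals full occlusion", {
  run <- small_run()
  Grp <- group_influences(9, run$model, run$graph, run$X,
                          groups = list(all = feature_names()))
  cache <- popgcn:::occlusion_cache(run$X, run$graph, run$model)
  base <- popgcn:::node_delta_probs(cache, 9, matrix(0, 1, 13))[1, ]
  full <- popgcn:::node_delta_probs(cache, 9,
                                    matrix(-run$X[9, ], 1, 13))[1, ]
  expect_equal(unname(Grp["all", ]), unname(base - full),
               tolerance = 1e-12)
})

test_that("group influences are not additive when features interact", {
  run <- small_run()
  Var <- feature_influences(11, run$model, run$graph, run$X)
  Grp <- group_influences(11, run$model, run$graph, run$X)
  y <- run$predictions[11]
  cg <- feature_groups()$cognitive
  expect_false(isTRUE(all.equal(Grp["cognitive", as.character(y)],
                                sum(Var[cg, as.character(y)]),
                                tolerance = 1e-9)))
})

test_that("silencing an edgeless class is a bit-identical no-op", {
  run <- small_run()
  g <- run$graph
  ## fabricate a node with no AD neighbors: drop those edges first
  i <- which(run$table_clean$label == "NC")[1]
  ad <- which(g$labels == "AD")
  g$A[i, ad] <- 0; g$A[ad, i] <- 0
  g$At <- normalize_adjacency(g$A)
  expect_length(neighborhood(g, i, same_class_as = "AD"), 0L)
  base <- gcn_forward(run$X, g, run$model)[i, ]
  masked <- gcn_forward(run$X, g, run$model,
                        mask_spec(edges = data.frame(node = i,
                                                     class = "AD")))[i, ]
  expect_identical(base, masked)
  Edg <- edge_class_influences(i, run$model, g, run$X)
  expect_identical(unname(Edg["AD", ]), rep(0, 3))
})

test_that("silencing every class isolates the node to its self-loop", {
  run <- small_run()
  i <- 14
  mask <- mask_spec(edges = data.frame(node = i, class = class_levels()))
  P <- gcn_forward(run$X, run$graph, run$model, mask)[i, ]
  gi <- run$graph
  gi$A[i, ] <- 0; gi$A[, i] <- 0
  gi$At <- normalize_adjacency(gi$A)
  expect_equal(P, gcn_forward(run$X, gi, run$model)[i, ],
               tolerance = 1e-12)
})

test_that("edge silencing matches a hand-recomputed two-node forward", {
  A <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
  g <- toy_graph(A, labels = c("NC", "MCI"))
  X <- matrix(c(1, -1, 0.5, 0.2), 2, 2,
              dimnames = list(g$ids, c("f1", "f2")))
  set.seed(44)
  W <- list(matrix(rnorm(6, sd = 0.5), 2, 3))
  model <- toy_model(W)
  Edg <- edge_class_influences(1, model, g, X)
  ## silencing MCI leaves node 1 with only its self-loop: At row = (1, 0)
  soft <- function(z) exp(z) / sum(exp(z))
  p_base <- soft(as.numeric((g$At %*% X %*% W[[1]])[1, ]))
  p_iso <- soft(as.numeric(X[1, ] %*% W[[1]])) # Ahat = I after silencing
  expect_equal(unname(Edg["MCI", ]), p_base - p_iso, tolerance = 1e-12)
  expect_equal(unname(Edg["NC", ]), rep(0, 3))   # no NC neighbors
})

test_that("neighbor class profiles count and weight correctly", {
  A <- matrix(0, 5, 5)
  A[1, 2:5] <- c(0.9, 0.6, 0.3, 0); A[2:5, 1] <- A[1, 2:5]
  g <- toy_graph(A, labels = c("MCI", "NC", "NC", "MCI", "AD"))
  prof <- neighbor_class_profile(1, g)
  expect_equal(unname(prof), c(2, 1, 0) / 3 * 100)  # node 5 disconnected
  wprof <- neighbor_class_profile(1, g, weighted = TRUE)
  expect_equal(unname(wprof), c(1.5, 0.3, 0) / 1.8 * 100,
               tolerance = 1e-12)
  gi <- toy_graph(matrix(0, 2, 2), labels = c("NC", "AD"))
  expect_warning(p0 <- neighbor_class_profile(1, gi), "isolated")
  expect_equal(unname(p0), c(0, 0, 0))
})

test_that("display normalization scales to unit mean magnitude", {
  expect_equal(normalize_influences(c(0.02, -0.04, 0.06)),
               c(0.5, -1.0, 1.5))
  v <- c(0.03, -0.03, 0.03)
  expect_equal(normalize_influences(v), c(1, -1, 1))
  set.seed(9)
  w <- rnorm(13, sd = 0.01)
  expect_identical(sign(normalize_influences(w)), sign(w))
  expect_equal(mean(abs(normalize_influences(w))), 1)
  expect_warning(z <- normalize_influences(rep(0, 5)), "zero")
  expect_equal(z, rep(0, 5))
})

test_that("feature discretization uses clinical cutoffs and SD bins", {
  stats <- data.frame(feature = continuous_features(),
                      mean = 0, sd = 1)
  stats$mean[stats$feature == "age"] <- 70
  stats$sd[stats$feature == "age"] <- 5
  expect_equal(discretize_feature("mmse", 22.4, stats), "mild dementia")
  expect_equal(discretize_feature("mmse", 8, stats), "severe dementia")
  expect_equal(discretize_feature("mmse", 29, stats), "normal cognition")
  expect_equal(discretize_feature("gds", 7.1, stats), "normal")
  expect_equal(discretize_feature("gds", 15, stats), "mild depressive")
  expect_equal(discretize_feature("gds", 25, stats), "severe depressive")
  ## value at the pooled mean is nominal
  expect_equal(discretize_feature("age", 70, stats), "nominal")
  expect_equal(discretize_feature("age", 76, stats), "high")
  expect_equal(discretize_feature("age", 62, stats), "very low")
  ## lower-is-worse features flip the sign convention
  expect_equal(discretize_feature("mem", -2, stats), "very high")
  expect_equal(discretize_feature("mem", -2, stats,
                                  flip_low_worse = FALSE), "very low")
  expect_equal(discretize_feature("gender", 2, stats), "female")
  expect_equal(discretize_feature("tau", 1, stats), "positive")
  expect_error(discretize_feature("nope", 1, stats), "unknown feature")
})

test_that("reference deviations are taken from matched healthy strata", {
  tab <- generate_cohort(default_spec(), seed = 61,
                         n_override = c(80, 20, 20))
  nc <- tab[tab$label == "NC", ]
  rec <- nc[5, ]
  stratum <- nc[nc$gender == rec$gender & abs(nc$age - rec$age) <= 5, ]
  dev <- reference_deviation(rec, tab)
  expect_equal(dev[["mmse"]], rec$mmse - mean(stratum$mmse))
  ## a record equal to its stratum mean deviates by zero everywhere
  rec2 <- rec
  for (f in continuous_features()) rec2[[f]] <- mean(stratum[[f]])
  ## keep age/gender so the stratum itself is unchanged
  rec2$age <- rec$age; rec2$gender <- rec$gender
  dev2 <- reference_deviation(rec2, tab)
  expect_lt(max(abs(dev2[setdiff(continuous_features(), "age")])), 1e-9)
  ## MMSE two points below the stratum mean
  rec3 <- rec; rec3$mmse <- mean(stratum$mmse) - 2
  expect_equal(reference_deviation(rec3, tab)[["mmse"]], -2)
  ## empty stratum widens with a warning until a match appears
  tab2 <- tab[tab$label != "NC" | tab$age < 70, ]
  rec4 <- rec; rec4$age <- 85
  rec4$gender <- tab2$gender[tab2$label == "NC"][1]
  expect_warning(reference_deviation(rec4, tab2), "widening")
  expect_error(reference_deviation(rec, tab[tab$label != "NC", ]),
               "no NC")
})

test_that("runner-up selection breaks ties toward the adjacent class", {
  expect_equal(popgcn:::runner_up_class(c(NC = 0.5, MCI = 0.3, AD = 0.2)),
               "MCI")
  ## AD predicted, NC/MCI tied: MCI is adjacent
  expect_equal(popgcn:::runner_up_class(c(NC = 0.25, MCI = 0.25,
                                          AD = 0.5)), "MCI")
  ## MCI predicted, NC/AD tied at distance one: earlier class wins
  expect_equal(popgcn:::runner_up_class(c(NC = 0.25, MCI = 0.5,
                                          AD = 0.25)), "NC")
})

test_that("counterfactual consistency: lost probability goes to other classes", {
  run <- small_run()
  set.seed(93)
  for (i in sample(nrow(run$X), 5)) {
    Var <- feature_influences(i, run$model, run$graph, run$X)
    y <- class_levels()[which.max(attr(Var, "base"))]
    neg <- Var[, y] < 0
    if (any(neg)) {
      others <- setdiff(class_levels(), y)
      expect_true(all(rowSums(Var[neg, others, drop = FALSE]) > 0))
    }
  }
})

test_that("explanation bundles render coherent text and serialize", {
  run <- small_run()
  i <- which(run$split$partition == "test")[1]
  bundle <- explain_node(i, run$model, run$graph, run$X,
                         raw_table = run$table_clean)
  expect_s3_class(bundle, "ExplanationBundle")
  expect_equal(sum(bundle$probabilities), 1, tolerance = 1e-9)
  expect_true(bundle$predicted != bundle$runner_up)
  expect_equal(mean(abs(bundle$normalized$factual)), 1, tolerance = 1e-9)

  ## sentences: ordered by influence magnitude, all above the floor
  txt <- bundle$text$factual
  ninf <- bundle$normalized$factual
  kept <- names(sort(abs(ninf[abs(ninf) >= 0.25]), decreasing = TRUE))
  expect_length(txt, length(kept))
  if (length(txt) > 0) {
    expect_true(grepl(toupper(kept[1]), txt[1], fixed = TRUE))
    expect_true(all(grepl("supports|opposes", txt)))
  }
  ## floor above everything suppresses all sentences
  silent <- render_text(bundle, bundle$bins, bundle$deviations,
                        floor = Inf)
  expect_length(silent$factual, 0L)

  f <- tempfile(fileext = ".json")
  write_bundle_json(bundle, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$predicted, bundle$predicted)
  expect_equal(unlist(obj$probabilities),
               bundle$probabilities, tolerance = 1e-12)
})

test_that("untrained models are rejected by the explainers", {
  run <- small_run()
  m <- run$model; m$trained <- FALSE
  expect_error(feature_influences(1, m, run$graph, run$X), "trained")
  expect_error(shapley_values(1, m, run$graph, run$X, run$X), "trained")
})
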