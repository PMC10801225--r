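## Run configuration and the staged pipeline driver behind the
## command-line interface.  Every default that has a published value
## uses it (80/10/10 split, 100 epochs, Adam lr 0.01, validation every
## 5 epochs, stability thresholds 0.96/0.94/0.90/0.85/0.80); the
## remaining defaults are the package's documented choices.

#' Default run configuration
#'
#' @param outdir output directory for pipeline artifacts.
#' @param seed master seed; each stage derives its own seed from it.
#' @return A `RunConfig` list; round-trips through YAML unchanged.
#' @export
default_config <- function(outdir = "popgcn_run", seed = 1L) {
  structure(list(
    paths = list(outdir = outdir, input_csv = NULL),
    seed = as.integer(seed),
    cohort = list(n = c(NC = 754L, MCI = 1095L, AD = 363L),
                  biomarker_positive_first = FALSE,
                  missing_rate = 0, outlier_rate = 0),
    preprocess = list(lower = 0.05, upper = 0.95, window = 8L,
                      fractions = c(0.8, 0.1, 0.1)),
    graph = list(edge_threshold = 0.5,
                 measures = c("mem", "exf", "lan")),
    model = list(layers = 2L, hidden = 32L, lr = 0.01, epochs = 100L,
                 val_every = 5L),
    explain = list(floor = 0.25, tie_rule = "adjacent"),
    evaluate = list(thresholds = c(0.96, 0.94, 0.90, 0.85, 0.80),
                    shapley_mode = "sampled", n_perm = 2000L,
                    nodes_per_class = 50L)),
    class = "RunConfig")
}

#' Read / write a run configuration as YAML
#'
#' @param config a `RunConfig`.
#' @param path YAML file path.
#' @return `write_config` the path invisibly; `read_config` the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  base <- unclass(default_config())
  for (sect in names(obj)) {
    if (is.list(base[[sect]])) {
      for (k in names(obj[[sect]])) {
        v <- obj[[sect]][[k]]
        if (is.null(v)) base[[sect]][k] <- list(NULL)
        else base[[sect]][[k]] <- v
      }
    } else {
      base[[sect]] <- obj[[sect]]
    }
  }
  base$seed <- as.integer(base$seed)
  n <- unlist(base$cohort$n)
  if (is.null(names(n)) || !all(class_levels() %in% names(n)))
    names(n) <- class_levels()
  base$cohort$n <- setNames(as.integer(n[class_levels()]),
                            class_levels())
  for (k in c("epochs", "val_every", "hidden", "layers"))
    base$model[[k]] <- as.integer(base$model[[k]])
  base$preprocess$window <- as.integer(base$preprocess$window)
  base$evaluate$n_perm <- as.integer(base$evaluate$n_perm)
  base$evaluate$nodes_per_class <-
    as.integer(base$evaluate$nodes_per_class)
  structure(base, class = "RunConfig")
}

artifact_path <- function(config, name) {
  file.path(config$paths$outdir, name)
}

require_artifact <- function(config, name, produced_by) {
  p <- artifact_path(config, name)
  if (!file.exists(p))
    stop("missing artifact '", name, "'; run the '", produced_by,
         "' command first", call. = FALSE)
  p
}

log_line <- function(config, ...) {
  dir.create(config$paths$outdir, showWarnings = FALSE, recursive = TRUE)
  line <- sprintf("[%s] seed=%d %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  config$seed, paste0(...))
  cat(line, "\n", file = artifact_path(config, "run.log"),
      append = TRUE, sep = "")
}

#' Run a pipeline stage
#'
#' Commands: `simulate` (write the synthetic cohort CSV and spec YAML),
#' `preprocess` (clean, split, standardize), `build-graph` (adjacency
#' edge list + Matrix Market export), `train` (model checkpoint and
#' history), `explain` (explanation bundle JSON + figures for a node),
#' `stability` (stability distance table), `compare-shap`
#' (decomposition/Shapley agreement), `ablate` (modality ablation
#' table), `report` (bundle + figures for a chosen node).  Each command
#' reads the artifacts of its prerequisites from `config$paths$outdir`
#' and errors, naming the missing prerequisite, if they are absent.
#'
#' @param command one of the commands above.
#' @param config a `RunConfig`.
#' @param node node index for `explain`/`stability`/`report` (default:
#'   chosen automatically).
#' @return Invisibly, a list of the artifact paths written.
#' @export
run_pipeline <- function(command = c("simulate", "preprocess",
                                     "build-graph", "train", "explain",
                                     "stability", "compare-shap",
                                     "ablate", "report"),
                         config = default_config(), node = NULL) {
  command <- match.arg(command)
  dir.create(config$paths$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- character()

  load_cohort <- function() {
    if (!is.null(config$paths$input_csv))
      read_cohort_csv(config$paths$input_csv)
    else read_cohort_csv(require_artifact(config, "cohort.csv",
                                          "simulate"))
  }
  load_state <- function() {
    clean <- read_cohort_csv(require_artifact(config, "clean.csv",
                                              "preprocess"))
    split <- read_split_json(require_artifact(config, "split.json",
                                              "preprocess"))
    std <- read_cohort_csv(require_artifact(config, "standardized.csv",
                                            "preprocess"))
    list(clean = clean, split = split, std = std)
  }
  load_graph <- function(std) {
    A <- read_adjacency_mtx(require_artifact(config, "adjacency.mtx",
                                             "build-graph"))
    g <- structure(list(A = A, At = normalize_adjacency(A),
                        labels = std$label, ids = std$id,
                        edge_threshold = config$graph$edge_threshold,
                        S = NULL),
                   class = "PopulationGraph")
    g
  }

  if (command == "simulate") {
    spec <- default_spec(config$cohort$biomarker_positive_first)
    tab <- generate_cohort(spec, derive_seed(config$seed, "cohort"),
                           n_override = config$cohort$n)
    if (config$cohort$missing_rate > 0 || config$cohort$outlier_rate > 0)
      tab <- inject_artifacts(tab, config$cohort$missing_rate,
                              config$cohort$outlier_rate,
                              derive_seed(config$seed, "artifacts"))
    out <- c(write_cohort_csv(tab, artifact_path(config, "cohort.csv")),
             write_spec_yaml(spec, artifact_path(config, "spec.yaml")))
    log_line(config, "simulate: ", nrow(tab), " subjects")
  } else if (command == "preprocess") {
    tab <- load_cohort()
    clean <- clean_features(tab, config$preprocess$lower,
                            config$preprocess$upper,
                            config$preprocess$window)
    split <- split_dataset(clean, config$preprocess$fractions,
                           seed = derive_seed(config$seed, "split"))
    std <- standardize(clean, split)
    out <- c(write_cohort_csv(clean, artifact_path(config, "clean.csv")),
             write_cohort_csv(std$table,
                              artifact_path(config, "standardized.csv")),
             write_split_json(split, artifact_path(config, "split.json")),
             write_scaler_json(std$scaler,
                               artifact_path(config, "scaler.json")))
    log_line(config, "preprocess: ", nrow(clean), " rows cleaned/split")
  } else if (command == "build-graph") {
    st <- load_state()
    g <- population_graph(st$std, measures = config$graph$measures,
                          edge_threshold = config$graph$edge_threshold,
                          keep_similarities = FALSE)
    out <- c(write_edge_tsv(g, artifact_path(config, "edges.tsv")),
             write_adjacency_mtx(g, artifact_path(config,
                                                  "adjacency.mtx")))
    log_line(config, "build-graph: ", sum(g$A > 0) / 2, " edges")
  } else if (command == "train") {
    st <- load_state()
    g <- load_graph(st$std)
    X <- feature_matrix(st$std)
    cfg <- gcn_config(hidden = config$model$hidden,
                      layers = config$model$layers,
                      lr = config$model$lr,
                      epochs = config$model$epochs,
                      val_every = config$model$val_every,
                      seed = derive_seed(config$seed, "init"))
    model <- gcn_train(X, g, st$clean$label, st$split, cfg)
    hist_path <- artifact_path(config, "history.csv")
    write.csv(model$history, hist_path, row.names = FALSE)
    te <- st$split$partition == "test"
    metrics <- evaluate_metrics(
      predict_classes(gcn_forward(X, g, model))[te],
      st$clean$label[te])
    jsonlite::write_json(
      list(mcf = metrics$mcf, mca = metrics$mca,
           precision = as.list(metrics$precision),
           recall = as.list(metrics$recall), f1 = as.list(metrics$f1)),
      artifact_path(config, "metrics.json"), auto_unbox = TRUE,
      digits = NA)
    out <- c(write_model_json(model, artifact_path(config, "model.json")),
             hist_path, artifact_path(config, "metrics.json"))
    log_line(config, sprintf("train: test MCA %.2f%% MCF %.2f%%",
                             metrics$mca, metrics$mcf))
  } else if (command %in% c("explain", "report")) {
    st <- load_state()
    g <- load_graph(st$std)
    X <- feature_matrix(st$std)
    model <- read_model_json(require_artifact(config, "model.json",
                                              "train"))
    if (is.null(node)) node <- which(st$split$partition == "test")[1L]
    bundle <- explain_node(node, model, g, X, raw_table = st$clean,
                           floor = config$explain$floor,
                           tie_rule = config$explain$tie_rule)
    bpath <- artifact_path(config, sprintf("explanation_node%d.json",
                                           bundle$node))
    write_bundle_json(bundle, bpath)
    figs <- c(
      save_figure(plot_influences(bundle),
                  artifact_path(config,
                                sprintf("influences_node%d", bundle$node))),
      save_figure(plot_group_influences(bundle),
                  artifact_path(config,
                                sprintf("groups_node%d", bundle$node))),
      save_figure(plot_neighbor_profile(bundle),
                  artifact_path(config,
                                sprintf("neighbors_node%d",
                                        bundle$node))))
    out <- c(bpath, figs)
    log_line(config, command, ": node ", bundle$node, " predicted ",
             bundle$predicted)
  } else if (command == "stability") {
    st <- load_state()
    g <- load_graph(st$std)
    X <- feature_matrix(st$std)
    model <- read_model_json(require_artifact(config, "model.json",
                                              "train"))
    if (is.null(node)) {
      ## default anchor: an MCI test node with the most same-class
      ## neighbors at the loosest threshold
      cand <- which(st$split$partition == "test" & st$clean$label == "MCI")
      if (length(cand) == 0L) cand <- which(st$clean$label == "MCI")
      counts <- vapply(cand, function(i)
        length(neighborhood(g, i, min(config$evaluate$thresholds),
                            same_class_as = g$labels[i])), 0L)
      node <- cand[which.max(counts)]
    }
    rep <- stability_table(node, g, model, X,
                           thresholds = config$evaluate$thresholds)
    spath <- artifact_path(config, "stability.csv")
    write.csv(data.frame(threshold = rownames(rep$distances),
                         rep$distances, check.names = FALSE),
              spath, row.names = FALSE)
    out <- c(spath,
             save_figure(plot_stability(rep),
                         artifact_path(config, "stability")))
    log_line(config, "stability: anchor ", rep$anchor)
  } else if (command == "compare-shap") {
    st <- load_state()
    g <- load_graph(st$std)
    X <- feature_matrix(st$std)
    model <- read_model_json(require_artifact(config, "model.json",
                                              "train"))
    te <- which(st$split$partition == "test")
    pred <- predict_classes(gcn_forward(X, g, model))
    nodes <- unlist(lapply(class_levels(), function(cl) {
      cand <- te[pred[te] == cl]
      head(cand, config$evaluate$nodes_per_class)
    }))
    bg <- X[st$split$partition == "train", , drop = FALSE]
    agg <- method_agreement(nodes, model, g, X, bg,
                            n_perm = config$evaluate$n_perm,
                            seed = derive_seed(config$seed, "shapley"))
    jpath <- artifact_path(config, "shap_agreement.json")
    jsonlite::write_json(
      lapply(agg$per_class, function(x)
        list(r = x$r, sign_agreement = x$sign_agreement,
             n_pairs = x$n_pairs)),
      jpath, auto_unbox = TRUE, digits = NA)
    write.csv(agg$pairs, artifact_path(config, "shap_pairs.csv"),
              row.names = FALSE)
    out <- c(jpath, artifact_path(config, "shap_pairs.csv"),
             save_figure(plot_agreement(agg),
                         artifact_path(config, "shap_agreement")))
    log_line(config, "compare-shap: ", length(nodes), " nodes")
  } else if (command == "ablate") {
    tab <- load_cohort()
    subsets <- list(
      "All modalities" = c("D", "MRI", "CT", "NT", "BM"),
      "D+MRI+CT+NT" = c("D", "MRI", "CT", "NT"),
      "D+CT+NT+BM" = c("D", "CT", "NT", "BM"),
      "D+MRI+NT+BM" = c("D", "MRI", "NT", "BM"),
      "D+MRI+CT+BM" = c("D", "MRI", "CT", "BM"),
      "MRI+CT+NT+BM" = c("MRI", "CT", "NT", "BM"))
    rep <- modality_ablation(subsets, tab, seeds = config$seed,
                             edge_threshold = config$graph$edge_threshold)
    apath <- artifact_path(config, "ablation.csv")
    write.csv(rep, apath, row.names = FALSE)
    out <- apath
    log_line(config, "ablate: ", length(subsets), " subsets")
  }
  invisible(out)
}
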