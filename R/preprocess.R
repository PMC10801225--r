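## Cleaning, splitting and standardization.
##
## Outliers (values outside the class-wise 5th-95th percentile band) and
## missing values are replaced by a centered moving mean of window length
## 8 computed within the class; the split into train/validation/test is
## stratified and happens BEFORE standardization; z-scoring uses
## train-partition statistics only.

#' Replace outliers and missing values by a within-class moving mean
#'
#' For each continuous feature within each class, values outside the
#' \[`lower`, `upper`\] percentile interval (computed once, on the
#' original values) and missing values are replaced by the centered
#' moving mean of the clean cells in a window of length `window`
#' (`window/2` rows before and after, shrunk at class boundaries, in
#' stored row order).  If no clean cell falls inside the window, the
#' class mean of the clean cells is used.  Categorical features have
#' missing values replaced by the class mode.
#'
#' @param table cohort `data.frame` with a `label` column.
#' @param lower,upper percentile bounds defining outliers (defaults 0.05
#'   and 0.95).
#' @param window moving-mean window length (default 8).
#' @return The cleaned table (no missing values remain).
#' @export
clean_features <- function(table, lower = 0.05, upper = 0.95, window = 8) {
  stopifnot("label" %in% names(table), window >= 2)
  half <- floor(window / 2)
  for (cl in unique(table$label)) {
    rows <- which(table$label == cl)
    for (f in continuous_features()) {
      x <- table[rows, f]
      if (all(is.na(x)))
        stop("all values absent for feature '", f, "' in class ", cl)
      q <- quantile(x, c(lower, upper), na.rm = TRUE, names = FALSE,
                    type = 7)
      bad <- is.na(x) | x < q[1] | x > q[2]
      if (!any(bad)) next
      if (all(bad))
        stop("no clean values for feature '", f, "' in class ", cl)
      clean_mean <- mean(x[!bad])
      xnew <- x
      for (i in which(bad)) {
        win <- max(1L, i - half):min(length(x), i + half)
        win <- setdiff(win, i)
        nb <- win[!bad[win]]
        xnew[i] <- if (length(nb) > 0L) mean(x[nb]) else clean_mean
      }
      table[rows, f] <- xnew
    }
    for (f in categorical_features()) {
      x <- table[rows, f]
      if (all(is.na(x)))
        stop("all values absent for feature '", f, "' in class ", cl)
      if (anyNA(x)) {
        tabx <- table(x)
        mode_val <- as.numeric(names(tabx)[which.max(tabx)])
        x[is.na(x)] <- mode_val
        table[rows, f] <- x
      }
    }
  }
  table
}

#' Stratified train/validation/test split
#'
#' Rows are assigned at random to the three partitions, stratified by
#' class so the class imbalance is preserved in every partition.  The
#' split is performed before any standardization.
#'
#' @param table cohort `data.frame` with a `label` column.
#' @param fractions length-3 numeric summing to 1 (train, validation,
#'   test); default `c(0.8, 0.1, 0.1)`.
#' @param seed integer RNG seed.
#' @return A `SplitAssignment`: list with `partition` (factor aligned to
#'   rows, levels train/validation/test), `fractions`, `seed`.
#' @export
split_dataset <- function(table, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three non-negative numbers summing to 1")
  set.seed(seed)
  parts <- c("train", "validation", "test")
  assign <- character(nrow(table))
  for (cl in unique(table$label)) {
    rows <- which(table$label == cl)
    n <- length(rows)
    if (all(fractions > 0) && n < 3L)
      stop("class ", cl, " has fewer than 3 rows; cannot populate all partitions")
    cnt <- floor(fractions * n)
    rem <- n - sum(cnt)
    if (rem > 0L) {
      frac_part <- fractions * n - cnt
      add <- order(frac_part, decreasing = TRUE)[seq_len(rem)]
      cnt[add] <- cnt[add] + 1L
    }
    if (any(cnt == 0L & fractions > 0))
      stop("class ", cl, " too small to populate every requested partition")
    lab <- rep(parts, cnt)
    assign[rows] <- lab[sample.int(n)]
  }
  structure(list(partition = factor(assign, levels = parts),
                 fractions = fractions, seed = seed),
            class = "SplitAssignment")
}

#' Z-score continuous features using train-partition statistics
#'
#' Continuous features are centered and scaled by the mean and SD of the
#' training rows only (no information from validation/test rows is
#' used).  Categorical encodings are left untouched.
#'
#' @param table cleaned cohort `data.frame`.
#' @param split a `SplitAssignment` from [split_dataset()].
#' @return List with `table` (standardized) and `scaler` (a `ScalerStats`
#'   data frame: feature, mean, sd) for inverse transforms and display.
#' @export
standardize <- function(table, split) {
  stopifnot(inherits(split, "SplitAssignment"),
            length(split$partition) == nrow(table))
  tr <- split$partition == "train"
  if (!any(tr)) stop("empty train partition")
  feats <- continuous_features()
  mu <- vapply(feats, function(f) mean(table[tr, f]), 0)
  sg <- vapply(feats, function(f) sd(table[tr, f]), 0)
  zero <- feats[sg == 0 | is.na(sg)]
  if (length(zero) > 0L)
    stop("zero train-partition SD for feature(s): ",
         paste(zero, collapse = ", "))
  for (f in feats) table[[f]] <- (table[[f]] - mu[[f]]) / sg[[f]]
  scaler <- structure(
    data.frame(feature = feats, mean = unname(mu), sd = unname(sg)),
    class = c("ScalerStats", "data.frame"))
  list(table = table, scaler = scaler)
}

#' Extract the feature matrix X from a cohort table
#'
#' @param table cohort `data.frame`.
#' @param features feature names to keep (default all 13).
#' @return Numeric matrix (rows = subjects, columns = features).
#' @export
feature_matrix <- function(table, features = feature_names()) {
  X <- as.matrix(table[, features, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- table$id
  X
}

#' Serialize a split assignment or scaler stats to JSON
#'
#' @param x a `SplitAssignment` or `ScalerStats`.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_split_json <- function(x, path) {
  stopifnot(inherits(x, "SplitAssignment"))
  jsonlite::write_json(
    list(partition = as.character(x$partition),
         fractions = x$fractions, seed = x$seed),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_split_json
#' @export
read_split_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(partition = factor(obj$partition,
                                    levels = c("train", "validation", "test")),
                 fractions = obj$fractions, seed = obj$seed),
            class = "SplitAssignment")
}

#' @rdname write_split_json
#' @export
write_scaler_json <- function(x, path) {
  jsonlite::write_json(as.list(x), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_split_json
#' @export
read_scaler_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(data.frame(feature = obj$feature, mean = obj$mean, sd = obj$sd),
            class = c("ScalerStats", "data.frame"))
}
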