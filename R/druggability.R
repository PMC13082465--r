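# Random-forest pocket-druggability model: nested cross-validation with a
# preprocessing grid (imbalance handling x scaling x forest hyperparameters)
# and mean-impurity-decrease feature importance averaged over folds and
# grid cells.

#' Cross-validation / grid configuration for the druggability model
#'
#' @param outer_folds,inner_folds Fold counts of the nested CV.
#' @param num_trees,mtry_frac Forest hyperparameter grid (`mtry_frac` is the
#'   fraction of features tried per split; `NA` means the ranger default).
#' @param imbalance Imbalance-handling strategies: `"none"`,
#'   `"downsample"` (majority class downsampled in training folds),
#'   `"weights"` (inverse class-frequency case weights).
#' @param scaling Feature scaling strategies: `"none"`, `"standard"`.
#' @param seed Integer seed controlling folds, downsampling and forests.
#' @return A list of class `rpi_cv_config`.
#' @export
cv_config <- function(outer_folds = 5, inner_folds = 3,
                      num_trees = c(200, 500), mtry_frac = c(NA, 1 / 3),
                      imbalance = c("none", "downsample", "weights"),
                      scaling = c("none", "standard"), seed = 1L) {
  structure(list(outer_folds = outer_folds, inner_folds = inner_folds,
    num_trees = num_trees, mtry_frac = mtry_frac,
    imbalance = imbalance, scaling = scaling, seed = as.integer(seed)),
    class = "rpi_cv_config")
}

#' Train the random-forest druggability classifier
#'
#' Nested cross-validation: stratified outer folds estimate generalization
#' (sensitivity, ROC-AUC, balanced accuracy per fold); an inner grid search
#' over forest hyperparameters and a superimposed preprocessing grid
#' (imbalance handling x scaling) picks the configuration refit on each
#' outer training set. `NA` features are imputed with training-fold medians.
#' Feature importance is the mean impurity decrease, normalized to sum to 1
#' per model and averaged over all folds and grid cells.
#'
#' @param features Tibble of numeric features (e.g. rows from
#'   [assemble_features()]); non-numeric columns such as `pocket_id` are
#'   dropped.
#' @param labels Logical (or two-level) vector: does the pocket host a
#'   stabilizer candidate?
#' @param config An [cv_config()].
#' @return An object of class `rpi_druggability` with elements `folds`
#'   (per-outer-fold metrics and selected configuration), `importance`
#'   (tibble summing to 1), `grid`, `config`.
#' @export
train_druggability <- function(features, labels, config = cv_config()) {
  x <- as_tibble(features)
  x <- x[vapply(x, is.numeric, logical(1))]
  y <- as.logical(labels)
  stopifnot(nrow(x) == length(y))
  if (length(unique(y)) < 2) abort("labels contain a single class")
  if (length(y) < 20) abort("need at least 20 labeled pockets")
  x <- x[, vapply(x, function(v) any(is.finite(v)), logical(1)), drop = FALSE]

  grid <- tidyr::expand_grid(
    num_trees = config$num_trees, mtry_frac = config$mtry_frac,
    imbalance = config$imbalance, scaling = config$scaling
  )

  withr::with_seed(config$seed, {
    outer <- stratified_folds(y, config$outer_folds)
    fold_rows <- list()
    importances <- list()
    for (k in seq_len(config$outer_folds)) {
      tr <- outer != k
      te <- !tr
      inner <- stratified_folds(y[tr], config$inner_folds)

      cell_auc <- map_dbl(seq_len(nrow(grid)), function(g) {
        aucs <- map_dbl(seq_len(config$inner_folds), function(j) {
          itr <- inner != j
          fit <- fit_cell(x[tr, ][itr, ], y[tr][itr], grid[g, ])
          importances[[length(importances) + 1]] <<- fit$importance
          score_auc(predict_cell(fit, x[tr, ][!itr, ]), y[tr][!itr])
        })
        mean(aucs, na.rm = TRUE)
      })
      best <- which.max(cell_auc)
      fit <- fit_cell(x[tr, ], y[tr], grid[best, ])
      importances[[length(importances) + 1]] <- fit$importance
      prob <- predict_cell(fit, x[te, ])
      pred <- prob >= 0.5
      yy <- y[te]
      fold_rows[[k]] <- bind_cols(
        tibble(fold = k,
          sensitivity = mean(pred[yy]),
          specificity = if (any(!yy)) mean(!pred[!yy]) else NA_real_,
          balanced_accuracy = (mean(pred[yy]) +
            if (any(!yy)) mean(!pred[!yy]) else NA_real_) / 2,
          auc = score_auc(prob, yy)),
        grid[best, ])
    }
  })

  imp <- bind_rows(importances) |>
    group_by(.data$feature) |>
    summarise(importance = mean(.data$importance), .groups = "drop")
  imp$importance <- imp$importance / sum(imp$importance)
  imp <- arrange(imp, desc(.data$importance))

  structure(list(folds = bind_rows(fold_rows), importance = imp,
    grid = grid, config = config, features = names(x)),
    class = "rpi_druggability")
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

median_impute <- function(x, medians = NULL) {
  if (is.null(medians)) {
    medians <- vapply(x, function(v) median(v[is.finite(v)]), numeric(1))
    medians[!is.finite(medians)] <- 0
  }
  for (j in seq_along(x)) x[[j]][!is.finite(x[[j]])] <- medians[j]
  list(x = x, medians = medians)
}

fit_cell <- function(x, y, cell) {
  imp <- median_impute(x)
  x <- imp$x
  center <- scale_sd <- NULL
  if (cell$scaling == "standard") {
    center <- vapply(x, mean, numeric(1))
    scale_sd <- pmax(vapply(x, sd, numeric(1)), 1e-12)
    x <- as_tibble(scale(x, center, scale_sd))
  }
  w <- NULL
  if (cell$imbalance == "downsample") {
    n_min <- min(table(y))
    keep <- unlist(lapply(unique(y), function(cls) {
      sample(which(y == cls), n_min)
    }))
    x <- x[keep, ]
    y <- y[keep]
  } else if (cell$imbalance == "weights") {
    tab <- table(y)
    w <- as.numeric(1 / tab[as.character(y)])
  }
  mtry <- if (is.na(cell$mtry_frac)) NULL else max(1, floor(cell$mtry_frac * ncol(x)))
  fit <- ranger::ranger(
    x = as.data.frame(x), y = factor(y, levels = c(FALSE, TRUE)),
    num.trees = cell$num_trees, mtry = mtry, probability = TRUE,
    importance = "impurity", case.weights = w,
    num.threads = 1, seed = sample.int(.Machine$integer.max, 1)
  )
  raw <- fit$variable.importance
  raw <- pmax(raw, 0)
  total <- sum(raw)
  imp_tbl <- tibble(feature = names(raw),
    importance = if (total > 0) raw / total else rep(1 / length(raw), length(raw)))
  list(fit = fit, medians = imp$medians, center = center, scale_sd = scale_sd,
    importance = imp_tbl)
}

predict_cell <- function(cellfit, x) {
  x <- median_impute(x, cellfit$medians)$x
  if (!is.null(cellfit$center)) {
    x <- as_tibble(scale(x, cellfit$center, cellfit$scale_sd))
  }
  predict(cellfit$fit, data = as.data.frame(x))$predictions[, "TRUE"]
}

score_auc <- function(prob, y) {
  if (length(unique(y)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
}

#' @export
print.rpi_druggability <- function(x, ...) {
  cat("<rpi_druggability> nested CV over", nrow(x$folds), "outer folds\n")
  print(glance(x))
  cat("top features:\n")
  print(head(x$importance, 5))
  invisible(x)
}

#' @rdname train_druggability
#' @param x An `rpi_druggability` object.
#' @param ... Unused.
#' @export
tidy.rpi_druggability <- function(x, ...) x$importance

#' @rdname train_druggability
#' @export
glance.rpi_druggability <- function(x, ...) {
  tibble(
    mean_auc = mean(x$folds$auc, na.rm = TRUE),
    mean_sensitivity = mean(x$folds$sensitivity, na.rm = TRUE),
    mean_balanced_accuracy = mean(x$folds$balanced_accuracy, na.rm = TRUE),
    n_folds = nrow(x$folds)
  )
}

#' @rdname train_druggability
#' @param object An `rpi_druggability` object.
#' @param top_n Number of features plotted.
#' @export
autoplot.rpi_druggability <- function(object, top_n = 20, ...) {
  d <- head(object$importance, top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$feature, .data$importance))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean impurity decrease (normalized)", y = NULL,
      title = "Druggability feature importance") +
    ggplot2::theme_minimal()
}
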