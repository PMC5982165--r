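#' Enumerate repetition-wise k-folds
#'
#' All `choose(n_repetitions, n_train)` ways of selecting the training
#' repetitions (20 partitions for 6 repetitions, 3 training), in
#' deterministic lexicographic order; the remaining repetitions form the
#' test set.
#'
#' @param n_repetitions available movement repetitions.
#' @param n_train repetitions used for training per fold.
#' @return A tibble with columns `fold`, `train` (list of integer vectors)
#'   and `test`.
#' @export
enumerate_kfolds <- function(n_repetitions = 6, n_train = 3) {
  n_repetitions <- check_count(n_repetitions, "n_repetitions")
  n_train <- check_count(n_train, "n_train")
  if (n_train >= n_repetitions) {
    abort("`n_train` must be smaller than `n_repetitions`")
  }
  tr <- combn(n_repetitions, n_train, simplify = FALSE)
  tibble(fold = seq_along(tr),
         train = tr,
         test = purrr::map(tr, ~setdiff(seq_len(n_repetitions), .x)))
}

feature_columns <- function(features, drop_channels = integer(0)) {
  cols <- grep("^ch[0-9]+_", names(features), value = TRUE)
  if (length(drop_channels)) {
    drop <- paste0("ch", drop_channels, "_")
    cols <- cols[!grepl(paste0("^(", paste(drop, collapse = "|"), ")"),
                        cols)]
  }
  cols
}

#' Train the one-vs-all movement classifier
#'
#' Fits one binary RBF-kernel support-vector machine per movement class
#' (rest included) against all others; prediction takes the class whose
#' decision function is largest (farthest from the separating hyperplane).
#' Features are z-scored with parameters frozen at training;
#' `(cost, gamma)` are selected by inner cross-validated grid search on the
#' training data only.
#'
#' @param train_features feature table (from [build_feature_table()]) with
#'   `label` and `ch*_*` columns.
#' @param seed integer seed for the inner fold assignment.
#' @param cost_grid,gamma_grid hyperparameter candidates; length-1 grids
#'   skip the search.
#' @param inner_folds inner cross-validation folds for the search.
#' @param drop_channels channel ids whose feature columns are excluded
#'   (classifier retraining without removed channels).
#' @return An object of class `emg_classifier`.
#' @export
train_classifier <- function(train_features, seed = 0,
                             cost_grid = c(1, 10), gamma_grid = NULL,
                             inner_folds = 3, drop_channels = integer(0)) {
  cols <- feature_columns(train_features, drop_channels)
  X <- as.matrix(train_features[cols])
  y <- as.integer(train_features$label)
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("training set contains a single class")
  gamma_grid <- gamma_grid %||% (1 / ncol(X))
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Z <- scale(X, ctr, scl)

  fit_ova <- function(Z, y, cost, gamma) {
    lapply(classes, function(k) {
      yk <- factor(ifelse(y == k, "yes", "no"), levels = c("yes", "no"))
      fit <- e1071::svm(Z, yk, kernel = "radial", cost = cost,
                        gamma = gamma, scale = FALSE)
      fit
    })
  }
  predict_ova <- function(machines, Z) {
    dec <- vapply(machines, function(fit) {
      pr <- predict(fit, Z, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      if (colnames(dv)[1] == "no/yes") -dv[, 1] else dv[, 1]
    }, numeric(nrow(Z)))
    if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1)
    classes[max.col(dec, ties.method = "first")]
  }

  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  best <- grid[1, ]
  if (nrow(grid) > 1) {
    best <- with_seed(seed, {
      folds <- sample(rep(seq_len(inner_folds), length.out = nrow(Z)))
      cv <- vapply(seq_len(nrow(grid)), function(g) {
        mean(vapply(seq_len(inner_folds), function(k) {
          tr <- folds != k
          if (length(unique(y[tr])) < length(classes)) return(NA_real_)
          m <- fit_ova(Z[tr, , drop = FALSE], y[tr], grid$cost[g],
                       grid$gamma[g])
          mean(predict_ova(m, Z[!tr, , drop = FALSE]) == y[!tr])
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      grid[which.max(cv), ]
    })
  }
  machines <- fit_ova(Z, y, best$cost, best$gamma)
  structure(list(machines = machines, classes = classes, columns = cols,
                 center = ctr, scale = scl, best = as.list(best),
                 predict_ova = NULL),
            class = "emg_classifier")
}

#' @export
print.emg_classifier <- function(x, ...) {
  cat(sprintf(
    "<emg_classifier> %d one-vs-all RBF-SVMs over classes {%s} (cost %g, gamma %g)\n",
    length(x$machines), paste(range(x$classes), collapse = ".."),
    x$best$cost, x$best$gamma))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.emg_classifier <- function(x, ...) {
  tibble(n_classes = length(x$classes), n_features = length(x$columns),
         cost = x$best$cost, gamma = x$best$gamma)
}

# raw one-vs-all argmax predictions for a feature table
predict_raw <- function(model, features) {
  Z <- scale(as.matrix(features[model$columns]), model$center, model$scale)
  dec <- vapply(model$machines, function(fit) {
    pr <- predict(fit, Z, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    if (colnames(dv)[1] == "no/yes") -dv[, 1] else dv[, 1]
  }, numeric(nrow(Z)))
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1)
  model$classes[max.col(dec, ties.method = "first")]
}

#' Majority vote over the last three raw window predictions
#'
#' Each window's output label is the mode of the last three raw
#' predictions (fewer at the start of the stream); a full tie among
#' distinct labels falls back to the current window's raw prediction.
#'
#' @param raw integer/character vector of raw per-window predictions in
#'   stream order.
#' @return Vector of voted labels, same length.
#' @export
majority_vote <- function(raw, span = 3) {
  n <- length(raw)
  out <- raw
  for (i in seq_len(n)) {
    h <- raw[max(1, i - span + 1):i]
    tb <- table(h)
    mx <- max(tb)
    winners <- names(tb)[tb == mx]
    out[i] <- if (length(winners) == 1) {
      if (is.numeric(raw)) as.numeric(winners) else winners
    } else {
      raw[i]
    }
  }
  out
}

#' Predict a window stream with majority-vote post-processing
#'
#' @param model an `emg_classifier`.
#' @param test_features feature table in stream (window) order.
#' @return A tibble with `window`, `label`, `raw` and `voted` predictions.
#' @export
predict_stream <- function(model, test_features) {
  missing_cols <- setdiff(model$columns, names(test_features))
  if (length(missing_cols)) {
    abort(sprintf("test features lack column(s): %s",
                  paste(head(missing_cols, 3), collapse = ", ")))
  }
  raw <- predict_raw(model, test_features)
  tibble(window = test_features$window,
         label = test_features$label,
         raw = raw,
         voted = majority_vote(raw))
}

# rest windows carry repetition 0; attribute them to the most recent
# movement repetition so repetition-wise folds cover rest windows too
effective_repetition <- function(repetition) {
  out <- repetition
  last <- 1L
  for (i in seq_along(out)) {
    if (out[i] == 0L) out[i] <- last else last <- out[i]
  }
  out
}

#' Run one classification setting over repetition folds
#'
#' The seven settings compare classification with and without fault
#' tolerance: (1) clean train / clean test; (2) clean train / contaminated
#' test; (3) retraining and testing without channels marked for removal;
#' (4) clean train / TVARMA-reconstructed test; (5) retraining and testing
#' on TVARMA-reconstructed data; (6) clean train / Kalman-reconstructed
#' test; (7) retraining and testing on Kalman-reconstructed data.
#'
#' @param setting integer 1-7.
#' @param bundles named list of aligned feature tables: `clean`,
#'   `contaminated`, and (for settings 4-7) `tvarma` / `tvk`.
#' @param folds fold tibble from [enumerate_kfolds()] (or a subset of its
#'   rows).
#' @param removed_channels channels excluded in setting 3 (those whose
#'   removal flag fired).
#' @param ... passed to [train_classifier()] (e.g. `cost_grid`).
#' @return A tibble of class `emg_eval` with columns `setting`, `fold`,
#'   `accuracy` (percent) and a list-column `confusion`.
#' @export
run_setting <- function(setting, bundles, folds, removed_channels = integer(0),
                        ...) {
  stopifnot(setting %in% 1:7)
  pick <- switch(as.character(setting),
    "1" = c("clean", "clean"),
    "2" = c("clean", "contaminated"),
    "3" = c("clean", "contaminated"),
    "4" = c("clean", "tvarma"),
    "5" = c("tvarma", "tvarma"),
    "6" = c("clean", "tvk"),
    "7" = c("tvk", "tvk"))
  for (b in unique(pick)) {
    if (is.null(bundles[[b]])) {
      abort(sprintf("setting %d requires the `%s` feature bundle",
                    setting, b))
    }
  }
  drop <- if (setting == 3) removed_channels else integer(0)
  train_tbl <- bundles[[pick[1]]]
  test_tbl <- bundles[[pick[2]]]
  eff_rep <- effective_repetition(train_tbl$repetition)
  classes <- sort(unique(train_tbl$label))

  res <- purrr::map_dfr(seq_len(nrow(folds)), function(i) {
    tr_rep <- folds$train[[i]]
    te_rep <- folds$test[[i]]
    tr <- eff_rep %in% tr_rep
    te <- eff_rep %in% te_rep
    model <- train_classifier(train_tbl[tr, ], drop_channels = drop, ...)
    pred <- predict_stream(model, test_tbl[te, ])
    cm <- table(factor(pred$label, levels = classes),
                factor(pred$voted, levels = classes))
    tibble(setting = setting, fold = folds$fold[i],
           accuracy = 100 * mean(pred$voted == pred$label),
           confusion = list(cm))
  })
  new_tibble(res, class = "emg_eval")
}

#' Accuracy summaries of an evaluation table
#'
#' @param x an `emg_eval` tibble (possibly row-bound over settings,
#'   contaminants and cases).
#' @param ... grouping columns (defaults to every factor column present
#'   among `setting`, `contaminant`, `case`).
#' @return A tibble of mean accuracies with fold counts.
#' @export
summarize_accuracy <- function(x, ...) {
  groups <- rlang::enquos(...)
  if (length(groups) == 0) {
    present <- intersect(c("setting", "contaminant", "case"), names(x))
    groups <- rlang::syms(present)
    x |>
      dplyr::group_by(!!!groups) |>
      dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                       sd_accuracy = sd(.data$accuracy),
                       n_folds = dplyr::n(), .groups = "drop")
  } else {
    x |>
      dplyr::group_by(!!!groups) |>
      dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                       sd_accuracy = sd(.data$accuracy),
                       n_folds = dplyr::n(), .groups = "drop")
  }
}

#' Plot per-setting accuracies of an evaluation
#'
#' @param object an `emg_eval` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.emg_eval <- function(object, ...) {
  df <- as_tibble(object)
  df$setting <- factor(df$setting)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$setting,
                                        y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = "classification setting", y = "accuracy (%)",
                  title = "Movement classification accuracy by setting")
  if ("contaminant" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~contaminant)
  }
  p
}
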