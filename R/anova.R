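#' Three-factor full-factorial ANOVA of classification accuracy
#'
#' Fixed-effects decomposition of mean accuracy into classification-setting,
#' contaminant and channel-case main effects, all two-way interactions and
#' the three-way interaction, with fold-level replicates as the error term.
#' Group 95% confidence intervals (based on the pooled residual mean
#' square) support the multiple-comparison rule that two means differ
#' significantly when their intervals are disjoint.
#'
#' @param results a tibble with numeric `accuracy` and factors `setting`,
#'   `contaminant`, `case` (coerced to factors), one row per fold
#'   replicate.
#' @param response,factors column names, overridable for other designs.
#' @return An object of class `emg_anova`: the underlying `aov` fit, the
#'   effects table, and per-level interval tables.
#' @export
anova3 <- function(results,
                   response = "accuracy",
                   factors = c("setting", "contaminant", "case")) {
  missing_cols <- setdiff(c(response, factors), names(results))
  if (length(missing_cols)) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(results[c(response, factors)])
  for (f in factors) df[[f]] <- factor(df[[f]])
  cells <- table(df[factors])
  if (any(cells == 0)) abort("design has empty cells: full factorial required")
  if (all(cells < 2)) abort("at least 2 replicates per cell are required")
  form <- stats::as.formula(paste(response, "~",
                                  paste(factors, collapse = " * ")))
  fit <- stats::aov(form, data = df)
  sm <- summary(fit)[[1]]
  effects <- tibble(
    term = trimws(rownames(sm)),
    df = sm$Df,
    sumsq = sm$`Sum Sq`,
    meansq = sm$`Mean Sq`,
    statistic = sm$`F value`,
    p.value = sm$`Pr(>F)`
  )
  y <- df[[response]]
  if (sum((y - mean(y))^2) <= 1e-12 * length(y) * max(1, mean(y)^2)) {
    inform("response has (numerically) zero variance: F ratios undefined")
    effects$statistic <- NA_real_
    effects$p.value <- NA_real_
  }
  mse <- effects$meansq[effects$term == "Residuals"]
  dfe <- effects$df[effects$term == "Residuals"]
  intervals <- lapply(factors, function(f) {
    agg <- stats::aggregate(df[[response]], list(level = df[[f]]),
                            function(v) c(mean = mean(v), n = length(v)))
    m <- agg$x[, "mean"]; n <- agg$x[, "n"]
    half <- qt(0.975, dfe) * sqrt(mse / n)
    tibble(factor = f, level = as.character(agg$level), mean = m,
           n = as.integer(n), lower = m - half, upper = m + half)
  })
  structure(list(fit = fit, effects = effects,
                 intervals = dplyr::bind_rows(intervals),
                 response = response, factors = factors,
                 mse = mse, df_resid = dfe),
            class = "emg_anova")
}

#' @export
print.emg_anova <- function(x, ...) {
  cat(sprintf("<emg_anova> %s ~ %s\n", x$response,
              paste(x$factors, collapse = " * ")))
  print(as.data.frame(x$effects), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.emg_anova <- function(x, ...) x$effects

#' @exportS3Method generics::glance
glance.emg_anova <- function(x, ...) {
  ss <- x$effects$sumsq
  tibble(ss_total = sum(ss),
         ss_residual = x$effects$sumsq[x$effects$term == "Residuals"],
         df_residual = x$df_resid,
         mse = x$mse)
}

#' Multiple comparisons by confidence-interval overlap
#'
#' Pairs of levels whose 95% intervals are disjoint are declared
#' significantly different.
#'
#' @param x an `emg_anova`.
#' @param factor_name one of the model's factors.
#' @return A tibble of level pairs with interval bounds and a
#'   `significant` flag.
#' @export
compare_levels <- function(x, factor_name) {
  stopifnot(inherits(x, "emg_anova"))
  iv <- x$intervals[x$intervals$factor == factor_name, ]
  if (nrow(iv) == 0) abort(sprintf("unknown factor `%s`", factor_name))
  pairs <- combn(nrow(iv), 2)
  tibble(
    level1 = iv$level[pairs[1, ]],
    level2 = iv$level[pairs[2, ]],
    mean1 = iv$mean[pairs[1, ]],
    mean2 = iv$mean[pairs[2, ]],
    significant = iv$lower[pairs[2, ]] > iv$upper[pairs[1, ]] |
      iv$lower[pairs[1, ]] > iv$upper[pairs[2, ]]
  )
}

#' Plot group means with 95% intervals from a three-factor ANOVA
#'
#' @param object an `emg_anova`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.emg_anova <- function(object, ...) {
  ggplot2::ggplot(object$intervals,
                  ggplot2::aes(x = .data$level, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::facet_wrap(~factor, scales = "free_x") +
    ggplot2::labs(x = NULL, y = object$response,
                  title = "Group means with 95% intervals (disjoint = significant)")
}
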