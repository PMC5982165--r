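test_that("repetition folds enumerate every train/test split", {
  f <- enumerate_kfolds(6, 3)
  expect_equal(nrow(f), 20)
  expect_equal(nrow(enumerate_kfolds(2, 1)), 2)
  expect_equal(nrow(enumerate_kfolds(4, 2)), 6)
  for (i in seq_len(nrow(f))) {
    expect_length(intersect(f$train[[i]], f$test[[i]]), 0)
    expect_setequal(c(f$train[[i]], f$test[[i]]), 1:6)
  }
  # every repetition appears in exactly choose(5, 2) = 10 training triples
  counts <- table(unlist(f$train))
  expect_equal(unname(as.vector(counts)), rep(10, 6))
  expect_error(enumerate_kfolds(4, 4), "smaller")
})

test_that("majority voting suppresses isolated flips and keeps runs", {
  expect_equal(majority_vote(c("A", "A", "B", "A")), c("A", "A", "A", "A"))
  expect_equal(majority_vote(rep("C", 5)), rep("C", 5))
  expect_equal(majority_vote(c("A", "B", "C"))[3], "C")  # 3-way tie -> raw
  expect_equal(majority_vote(c(4L, 7L, 7L, 2L)), c(4L, 7L, 7L, 7L))

  set.seed(10)
  for (i in 1:10) {
    raw <- sample(1:3, 30, replace = TRUE)
    voted <- majority_vote(raw)
    runs <- which(raw[-1] == raw[-30]) + 1  # second element of any run
    expect_equal(voted[runs], raw[runs])
  }
})

make_features <- function(n_classes = 3, reps = 2, per = 10, sep = 5,
                          seed = 1) {
  set.seed(seed)
  rows <- n_classes * reps * per
  centers <- matrix(sep * rnorm(n_classes * 4), n_classes, 4)
  lab <- rep(rep(seq_len(n_classes) - 1L, each = per), reps)
  rep_id <- rep(seq_len(reps), each = n_classes * per)
  X <- centers[lab + 1L, ] + 0.1 * matrix(rnorm(rows * 4), rows, 4)
  tibble::tibble(ch1_MAV = X[, 1], ch1_RMS = X[, 2],
                 ch2_MAV = X[, 3], ch2_RMS = X[, 4],
                 window = seq_len(rows), label = lab, repetition = rep_id)
}

test_that("the one-vs-all classifier separates well-separated classes", {
  ft <- make_features()
  model <- train_classifier(ft, seed = 1, cost_grid = c(1, 10))
  pred <- predict_stream(model, ft)
  expect_equal(mean(pred$raw == ft$label), 1)

  single <- ft[ft$label == 0, ]
  expect_error(train_classifier(single), "single class")

  m2 <- train_classifier(ft, seed = 1, cost_grid = c(1, 10))
  expect_identical(model$best, m2$best)

  # dropping a channel removes its feature columns
  m3 <- train_classifier(ft, seed = 1, drop_channels = 2)
  expect_equal(m3$columns, c("ch1_MAV", "ch1_RMS"))
  expect_error(predict_stream(m3, ft["ch2_MAV"]), "lack")
})

test_that("setting 2 with an identical bundle reproduces setting 1", {
  ft <- make_features(reps = 2)
  folds <- enumerate_kfolds(2, 1)
  bundles <- list(clean = ft, contaminated = ft)
  r1 <- run_setting(1, bundles, folds, cost_grid = 1)
  r2 <- run_setting(2, bundles, folds, cost_grid = 1)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_true(all(r1$accuracy >= 90))
  # confusion matrix conserves the number of test windows
  cm <- r1$confusion[[1]]
  expect_equal(sum(cm), sum(ft$repetition == folds$test[[1]]))
  expect_error(run_setting(4, bundles, folds), "tvarma")
})

test_that("three-factor ANOVA matches a brute-force two-pass oracle", {
  set.seed(12)
  d <- tidyr::expand_grid(setting = c("s1", "s2"), contaminant = c("a", "b"),
                          case = c("c1", "c2"), fold = 1:3)
  d$accuracy <- 70 + 5 * (d$setting == "s2") - 3 * (d$contaminant == "b") +
    1.5 * (d$setting == "s2" & d$case == "c2") + rnorm(nrow(d))
  fit <- anova3(d)

  # brute-force balanced-design sums of squares from cell means
  gm <- mean(d$accuracy)
  ss <- function(means, reps) sum(reps * (means - gm)^2)
  n <- nrow(d)
  mA <- tapply(d$accuracy, d$setting, mean)
  mB <- tapply(d$accuracy, d$contaminant, mean)
  mC <- tapply(d$accuracy, d$case, mean)
  ssA <- ss(mA, n / 2); ssB <- ss(mB, n / 2); ssC <- ss(mC, n / 2)
  mAB <- tapply(d$accuracy, list(d$setting, d$contaminant), mean)
  ssAB <- ss(mAB, n / 4) - ssA - ssB
  mAC <- tapply(d$accuracy, list(d$setting, d$case), mean)
  ssAC <- ss(mAC, n / 4) - ssA - ssC
  mBC <- tapply(d$accuracy, list(d$contaminant, d$case), mean)
  ssBC <- ss(mBC, n / 4) - ssB - ssC
  mABC <- tapply(d$accuracy, list(d$setting, d$contaminant, d$case), mean)
  ssABC <- ss(mABC, n / 8) - ssA - ssB - ssC - ssAB - ssAC - ssBC
  ss_tot <- sum((d$accuracy - gm)^2)
  ss_res <- ss_tot - ssA - ssB - ssC - ssAB - ssAC - ssBC - ssABC

  eff <- tidy(fit)
  get_ss <- function(term) eff$sumsq[eff$term == term]
  expect_equal(get_ss("setting"), ssA, tolerance = 1e-8)
  expect_equal(get_ss("contaminant"), ssB, tolerance = 1e-8)
  expect_equal(get_ss("case"), ssC, tolerance = 1e-8)
  expect_equal(get_ss("setting:contaminant"), ssAB, tolerance = 1e-8)
  expect_equal(get_ss("setting:case"), ssAC, tolerance = 1e-8)
  expect_equal(get_ss("contaminant:case"), ssBC, tolerance = 1e-8)
  expect_equal(get_ss("setting:contaminant:case"), ssABC, tolerance = 1e-8)
  expect_equal(get_ss("Residuals"), ss_res, tolerance = 1e-8)
  # exact partition of total sum of squares
  expect_equal(sum(eff$sumsq), ss_tot, tolerance = 1e-8 * ss_tot)
})

test_that("ANOVA recovers a pure main effect and flags degenerate input", {
  set.seed(13)
  d <- tidyr::expand_grid(setting = c("s1", "s2"), contaminant = c("a", "b"),
                          case = c("c1", "c2"), fold = 1:50)
  d$accuracy <- 60 + 8 * (d$setting == "s2") + rnorm(nrow(d))
  fit <- anova3(d)
  eff <- tidy(fit)
  expect_lt(eff$p.value[eff$term == "setting"], 1e-10)
  inter <- eff[grepl(":", eff$term), ]
  expect_true(all(inter$p.value > 0.05))
  cmp <- compare_levels(fit, "setting")
  expect_true(cmp$significant)

  const <- d; const$accuracy <- 50
  fit0 <- anova3(const)
  f0 <- tidy(fit0)$statistic
  expect_true(all(is.na(f0) | f0 == 0 | is.nan(f0)))

  incomplete <- d[!(d$setting == "s1" & d$contaminant == "a"), ]
  expect_error(anova3(incomplete), "empty cells")
})
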