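test_that("confusion metrics count the study-design example correctly", {
  # 24 songs, 13 hits; one flop misclassified as a hit
  truth <- c(rep("hit", 13), rep("flop", 11))
  pred <- truth; pred[14] <- "hit"
  cm <- confusion_metrics(truth, pred)
  expect_equal(cm$accuracy, 23 / 24)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 10 / 11)
  expect_equal(unname(cm$counts), c(13L, 1L, 10L, 0L))

  perfect <- confusion_metrics(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  expect_warning(cm2 <- confusion_metrics(rep("flop", 5), rep("flop", 5)),
                 "sensitivity undefined")
  expect_true(is.na(cm2$sensitivity))
  expect_error(confusion_metrics(truth, pred[-1]), "equal length")
})

test_that("exact binomial upper tail matches enumeration", {
  expect_equal(exact_binomial_test(0, 10, 0.5)$p_value, 1)
  expect_equal(exact_binomial_test(9, 10, 0.5)$p_value, 11 / 1024,
               tolerance = 1e-12)
  # full enumeration oracle over random triples
  set.seed(9)
  for (i in 1:200) {
    n <- sample(1:20, 1)
    s <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    manual <- sum(vapply(s:n, function(x)
      choose(n, x) * p0^x * (1 - p0)^(n - x), numeric(1)))
    expect_equal(exact_binomial_test(s, n, p0)$p_value, min(1, manual),
                 tolerance = 1e-10)
  }
  # cross-check against the distribution function
  expect_equal(exact_binomial_test(4800, 5000, 0.54)$p_value,
               pbinom(4799, 5000, 0.54, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(exact_binomial_test(11, 10, 0.5), "successes")
  expect_error(exact_binomial_test(5, 10, 1), "p0")
})

oracle_model <- function(label_col = "label") {
  structure(list(), class = "oracle_clf")
}
# deterministic test doubles for the bootstrap comparison
predict.oracle_clf <- function(object, newdata, type = "class", ...) {
  newdata$label
}
coin_model <- function() structure(list(), class = "coin_clf")
predict.coin_clf <- function(object, newdata, type = "class", ...) {
  sample(c("hit", "flop"), nrow(newdata), replace = TRUE)
}

test_that("bootstrap comparison separates an oracle from a coin flip", {
  registerS3method("predict", "oracle_clf", predict.oracle_clf,
                   envir = globalenv())
  registerS3method("predict", "coin_clf", predict.coin_clf,
                   envir = globalenv())
  pool <- data.table::data.table(
    label = rep(c("hit", "flop"), 50),
    avg_immersion = rnorm(100), retreat = rnorm(100))
  bc <- bootstrap_compare(function(tr) coin_model(),
                          function(tr) oracle_model(),
                          pool, iterations = 50, train_n = 60, test_n = 60,
                          seed = 1)
  r <- bc$comparison$overall
  expect_equal(r$ci_b, c(1, 1))            # oracle is always perfect
  expect_lt(r$t, -10)                      # (flip - oracle) strongly negative
  expect_equal(r$df, 98L)
  expect_lt(r$p_value, 1e-6)

  # self-comparison: same factory twice gives a null t most of the time
  bc2 <- bootstrap_compare(function(tr) oracle_model(),
                           function(tr) oracle_model(),
                           pool, iterations = 20, train_n = 50, test_n = 50,
                           seed = 2)
  expect_equal(bc2$comparison$overall$t, 0)

  expect_error(bootstrap_compare(function(tr) oracle_model(),
                                 function(tr) oracle_model(),
                                 pool, iterations = 1), "iterations")
})

test_that("k-fold overfitting check reports three consistent series", {
  set.seed(3)
  train <- data.table::data.table(
    label = rep(c("hit", "flop"), each = 30),
    avg_immersion = c(rnorm(30, 5), rnorm(30, 3)),
    retreat = c(rnorm(30, 0.1, 0.01), rnorm(30, 0.3, 0.01)))
  observed <- train[seq(1, 60, by = 3)]
  kc <- suppressWarnings(
    kfold_overfit_check(function(tr) suppressWarnings(
      logistic_baseline(tr, "model2")), train, observed, k = 5, seed = 1))
  expect_equal(nrow(kc$accuracies), 5L)
  expect_gt(kc$means[["train"]], 0.9)
  expect_gt(kc$means[["test"]], 0.9)
  expect_true(kc$consistent)
  expect_error(kfold_overfit_check(function(tr) logistic_baseline(tr),
                                   train, observed, k = 61), "k exceeds")
})

test_that("permuted labels drive held-out accuracy to chance", {
  set.seed(21)
  train <- data.table::data.table(
    label = sample(rep(c("hit", "flop"), each = 40)),
    avg_immersion = rnorm(80), retreat = rnorm(80))
  kc <- suppressWarnings(
    kfold_overfit_check(function(tr) logistic_baseline(tr, "model2"),
                        train, train, k = 5, seed = 2))
  # binomial noise around 0.5 for 16-row held-out folds
  expect_lt(abs(kc$means[["test"]] - 0.5), 0.2)
})

test_that("logistic baselines handle flat predictors and separation", {
  flat <- data.table::data.table(
    label = rep(c("hit", "flop"), each = 10),
    avg_immersion = rep(4.1, 20), retreat = runif(20, 0.15, 0.2))
  fit <- logistic_baseline(flat, "model1")
  expect_lt(abs(fit$coefficients[["avg_immersion"]]), 1e-6)
  expect_equal(fit$confusion$accuracy, 0.5)  # majority-rate with even split

  sep <- data.table::data.table(
    label = rep(c("hit", "flop"), each = 10),
    avg_immersion = c(rnorm(10, 6), rnorm(10, 2)),
    retreat = runif(20, 0.15, 0.2))
  expect_warning(fit2 <- logistic_baseline(sep, "model2"), "ridge")
  expect_true(fit2$separated)
  expect_equal(fit2$confusion$accuracy, 1)

  expect_error(logistic_baseline(flat[label == "hit"], "model1"),
               "both classes")
})

test_that("VIF follows the closed form for two correlated predictors", {
  set.seed(14)
  n <- 4000
  x1 <- rnorm(n)
  x2 <- 0.51 * x1 + sqrt(1 - 0.51^2) * rnorm(n)
  tab <- data.table::data.table(
    label = ifelse(rbinom(n, 1, plogis(x1)) == 1, "hit", "flop"),
    avg_immersion = x1, retreat = x2)
  fit <- logistic_baseline(tab, "model2")
  r <- cor(x1, x2)
  expect_equal(unname(fit$vif["avg_immersion"]), 1 / (1 - r^2),
               tolerance = 1e-8)
  expect_equal(unname(fit$vif["retreat"]), 1 / (1 - r^2), tolerance = 1e-8)
  # at exactly r = 0.51 the closed form gives 1.3515
  expect_equal(1 / (1 - 0.51^2), 1.35154, tolerance = 1e-4)
})

test_that("effect statistics match hand computation and conventions", {
  # identical groups: null everything
  es0 <- effect_stats(c(1, 2, 3, 1, 2, 3),
                      c("flop", "flop", "flop", "hit", "hit", "hit"))
  expect_equal(es0$t, 0)
  expect_equal(es0$d, 0)

  # {0,2} flop vs {1,3} hit: d = (1-2)/sqrt(2), t = d / sqrt(1/2 + 1/2)
  es <- effect_stats(c(0, 2, 1, 3), c("flop", "flop", "hit", "hit"))
  expect_equal(es$d, -1 / sqrt(2), tolerance = 1e-12)
  expect_equal(es$t, -1 / sqrt(2), tolerance = 1e-12)
  expect_equal(es$df, 2L)
  # agreement with the standard pooled-variance t test
  tt <- t.test(c(0, 2), c(1, 3), var.equal = TRUE)
  expect_equal(es$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(es$p, tt$p.value, tolerance = 1e-12)

  # perfectly linear data: r = 1
  esr <- effect_stats(1:10, y = 2 * (1:10) + 3)
  expect_equal(esr$r, 1)

  # zero pooled variance with unequal means flags an infinite statistic
  esi <- effect_stats(c(1, 1, 2, 2), c("flop", "flop", "hit", "hit"))
  expect_true(esi$infinite)
})
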