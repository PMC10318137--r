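#' Confusion-matrix summary for hit/flop classification
#'
#' Hits are the positive class: sensitivity is recall on hits, specificity
#' recall on flops. Rates undefined because the truth lacks a class are
#' returned as `NA` with a warning.
#'
#' @param truth,predicted character vectors of `"hit"`/`"flop"` labels of
#'   equal length.
#' @return list of class `confusion_summary`: `accuracy`, `sensitivity`,
#'   `specificity`, and the `counts` (TP, FP, TN, FN).
#' @export
confusion_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  truth <- normalize_label(truth)
  predicted <- normalize_label(predicted)
  tp <- sum(truth == "hit" & predicted == "hit")
  fn <- sum(truth == "hit" & predicted == "flop")
  tn <- sum(truth == "flop" & predicted == "flop")
  fp <- sum(truth == "flop" & predicted == "hit")
  sens <- if (tp + fn == 0) { warning("no hits in truth; sensitivity undefined",
                                      call. = FALSE); NA_real_ } else tp / (tp + fn)
  spec <- if (tn + fp == 0) { warning("no flops in truth; specificity undefined",
                                      call. = FALSE); NA_real_ } else tn / (tn + fp)
  structure(list(accuracy = (tp + tn) / length(truth),
                 sensitivity = sens, specificity = spec,
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("accuracy %.3f | sensitivity %.3f | specificity %.3f\n",
              x$accuracy, x$sensitivity, x$specificity))
  print(x$counts)
  invisible(x)
}

#' Exact one-sided binomial test against a base rate
#'
#' Upper-tail exact test: the probability of observing at least `successes`
#' correct classifications out of `n` when each is independently correct
#' with probability `p0`. Computed as an explicit sum of binomial point
#' probabilities; no normal approximation.
#'
#' @param successes,n counts with `0 <= successes <= n`.
#' @param p0 null success probability in (0, 1); for hit classification
#'   the natural default is the hit base rate of the evaluated set.
#' @return list of class `binomial_test`: `successes`, `n`, `p0`,
#'   `p_value`.
#' @export
exact_binomial_test <- function(successes, n, p0) {
  assert_scalar_number(n, "n", lo = 1)
  assert_scalar_number(successes, "successes", lo = 0, hi = n)
  assert_scalar_number(p0, "p0")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly in (0, 1)", call. = FALSE)
  p <- min(1, sum(dbinom(seq(successes, n), n, p0)))
  structure(list(successes = successes, n = n, p0 = p0, p_value = p),
            class = "binomial_test")
}

#' @export
print.binomial_test <- function(x, ...) {
  cat(sprintf("exact binomial: %d/%d vs p0 = %.3f, upper-tail p = %.4g\n",
              x$successes, x$n, x$p0, x$p_value))
  invisible(x)
}

#' Bootstrap comparison of two classifiers
#'
#' Per iteration, training and test sets are drawn with replacement from a
#' synthetic pool; both model factories are fitted on the training draw
#' and their accuracies (overall, hits only, flops only) recorded on the
#' test draw. Reports 95% percentile confidence intervals per model and a
#' pooled two-sample Student t across iterations (model A minus model B)
#' with `df = 2 * iterations - 2`.
#'
#' @param factory_a,factory_b functions `(train_table) -> model`; the
#'   returned model must support `predict(model, newdata, type = "class")`.
#' @param pool synthetic table to resample from (must contain the label
#'   column used by the models).
#' @param iterations bootstrap iterations (default 1000).
#' @param train_n,test_n draw sizes (default 5000 each).
#' @param seed integer seed.
#' @param label_col label column name.
#' @return list of class `bootstrap_comparison` with per-metric CI, mean,
#'   t statistic, df and p value, plus the raw per-iteration accuracies.
#' @export
bootstrap_compare <- function(factory_a, factory_b, pool, iterations = 1000L,
                              train_n = 5000L, test_n = 5000L, seed = 1L,
                              label_col = "label") {
  if (iterations < 2L) stop("iterations must be >= 2", call. = FALSE)
  pool <- as.data.table(pool)
  if (nrow(pool) < 2L) stop("pool too small to resample from", call. = FALSE)
  set.seed(as.integer(seed))
  metrics <- c("overall", "hits", "flops")
  acc <- array(NA_real_, dim = c(iterations, 2L, 3L),
               dimnames = list(NULL, c("a", "b"), metrics))
  for (it in seq_len(iterations)) {
    tr <- pool[sample.int(nrow(pool), train_n, replace = TRUE)]
    te <- pool[sample.int(nrow(pool), test_n, replace = TRUE)]
    truth <- normalize_label(te[[label_col]])
    for (side in c("a", "b")) {
      fac <- if (side == "a") factory_a else factory_b
      pred <- normalize_label(predict(fac(tr), te, type = "class"))
      acc[it, side, "overall"] <- mean(pred == truth)
      acc[it, side, "hits"] <- mean(pred[truth == "hit"] == "hit")
      acc[it, side, "flops"] <- mean(pred[truth == "flop"] == "flop")
    }
  }
  df <- 2L * iterations - 2L
  res <- lapply(metrics, function(m) {
    xa <- acc[, "a", m]; xb <- acc[, "b", m]
    sp2 <- (var(xa) + var(xb)) / 2
    tval <- if (sp2 == 0) ifelse(mean(xa) == mean(xb), 0, Inf * sign(mean(xa) - mean(xb)))
            else (mean(xa) - mean(xb)) / sqrt(sp2 * 2 / iterations)
    list(ci_a = unname(quantile(xa, c(0.025, 0.975), na.rm = TRUE)),
         ci_b = unname(quantile(xb, c(0.025, 0.975), na.rm = TRUE)),
         mean_a = mean(xa), mean_b = mean(xb),
         t = tval, df = df, p_value = 2 * pt(-abs(tval), df))
  })
  names(res) <- metrics
  structure(list(iterations = iterations, comparison = res, accuracies = acc),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat("<bootstrap_comparison>", x$iterations, "iterations\n")
  for (m in names(x$comparison)) {
    r <- x$comparison[[m]]
    cat(sprintf("  %-7s A %.3f [%.3f, %.3f] vs B %.3f [%.3f, %.3f], t(%d) = %.2f\n",
                m, r$mean_a, r$ci_a[1], r$ci_a[2], r$mean_b, r$ci_b[1],
                r$ci_b[2], r$df, r$t))
  }
  invisible(x)
}

#' K-fold overfitting check
#'
#' Fits the supplied pipeline on each k-fold training complement of the
#' synthetic training half and records accuracy on the training folds, the
#' held-out fold, and the small observed feature table. Large, consistent
#' accuracies across all three indicate the model is not merely memorizing
#' the synthetic training data.
#'
#' @param pipeline function `(train_table) -> model` supporting
#'   `predict(model, newdata, type = "class")`.
#' @param train synthetic training half.
#' @param observed observed song-level feature table.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold draw.
#' @param consistency_band maximum spread of the three mean accuracies for
#'   the `consistent` flag (default 0.10).
#' @param label_col label column name.
#' @return list of class `kfold_check` with the three accuracy series,
#'   their means/SDs, and the `consistent` flag.
#' @export
kfold_overfit_check <- function(pipeline, train, observed, k = 10L, seed = 1L,
                                consistency_band = 0.10, label_col = "label") {
  train <- as.data.table(train)
  if (k > nrow(train)) stop("k exceeds the number of rows", call. = FALSE)
  y <- normalize_label(train[[label_col]])
  set.seed(as.integer(seed))
  fold <- make_folds(as.integer(y == "hit"), k)
  obs_truth <- normalize_label(as.data.table(observed)[[label_col]])
  acc <- data.table(fold = seq_len(k), train = NA_real_, test = NA_real_,
                    observed = NA_real_)
  for (v in seq_len(k)) {
    tr <- train[fold != v]
    model <- pipeline(tr)
    acc$train[v] <- mean(normalize_label(
      predict(model, tr, type = "class")) == y[fold != v])
    acc$test[v] <- mean(normalize_label(
      predict(model, train[fold == v], type = "class")) == y[fold == v])
    acc$observed[v] <- mean(normalize_label(
      predict(model, observed, type = "class")) == obs_truth)
  }
  means <- vapply(acc[, .(train, test, observed)], mean, numeric(1))
  sds <- vapply(acc[, .(train, test, observed)], sd, numeric(1))
  structure(list(accuracies = acc, means = means, sds = sds,
                 consistent = diff(range(means)) <= consistency_band),
            class = "kfold_check")
}

#' Logistic regression baselines on the song-level feature table
#'
#' Model 1 regresses the hit indicator on average immersion alone; Model 2
#' adds retreat. Fitting is by maximum likelihood; under complete
#' separation the fit is replaced by a lightly ridge-penalized logistic
#' regression with a warning. Reports in-sample classification at the 0.5
#' cutoff, a likelihood-ratio chi-square against the intercept-only model,
#' and (for Model 2) the variance inflation factor of each predictor from
#' the cross-regression R-squared.
#'
#' @param features song-level feature table ([featurize()] output or a
#'   synthetic counterpart with the same columns).
#' @param model `"model1"` (immersion only) or `"model2"` (adds retreat).
#' @param threshold classification cutoff (default 0.5; ties are hits).
#' @return an `nf_logistic_baseline` with coefficients, `confusion`,
#'   `lr_chisq`/`lr_df`/`lr_p`, and `vif`; supports
#'   `predict(, newdata, type = "class")`.
#' @export
logistic_baseline <- function(features, model = c("model2", "model1"),
                              threshold = 0.5) {
  model <- match.arg(model)
  features <- as.data.table(features)
  predictors <- if (model == "model1") "avg_immersion" else
    c("avg_immersion", "retreat")
  y <- as.integer(normalize_label(features$label) == "hit")
  if (length(unique(y)) < 2L) {
    stop("feature table must contain both classes", call. = FALSE)
  }
  X <- as.matrix(features[, predictors, with = FALSE])
  dat <- data.frame(y = y, X)
  fml <- as.formula(paste("y ~", paste(predictors, collapse = "+")))
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || !fit$converged) {
    warning("separation detected; refitting with a small ridge penalty",
            call. = FALSE)
    rfit <- fit_logistic_ridge(X, y, lambda = 0.01)
    coefs <- setNames(rfit$beta, c("(Intercept)", predictors))
    p_hat <- predict_prob(rfit, X)
    ll1 <- sum(y * log(pmax(p_hat, 1e-12)) +
                 (1 - y) * log(pmax(1 - p_hat, 1e-12)))
  } else {
    coefs <- coef(fit)
    coefs[is.na(coefs)] <- 0  # aliased predictor (e.g. constant column)
    p_hat <- fit$fitted.values
    ll1 <- as.numeric(stats::logLik(fit))
  }
  p_bar <- mean(y)
  ll0 <- sum(y * log(p_bar) + (1 - y) * log(1 - p_bar))
  lr <- max(0, 2 * (ll1 - ll0))
  lr_df <- length(predictors)
  pred <- ifelse(p_hat >= threshold, "hit", "flop")
  vif <- if (length(predictors) < 2L) NULL else {
    vapply(predictors, function(p) {
      r2 <- summary(lm(as.formula(paste(p, "~ .")),
                       data = as.data.frame(X)))$r.squared
      1 / (1 - r2)
    }, numeric(1))
  }
  structure(list(model = model, predictors = predictors,
                 coefficients = coefs, separated = separated,
                 confusion = confusion_metrics(features$label, pred),
                 lr_chisq = lr, lr_df = lr_df,
                 lr_p = pchisq(lr, lr_df, lower.tail = FALSE),
                 threshold = threshold, vif = vif),
            class = "nf_logistic_baseline")
}

#' @export
predict.nf_logistic_baseline <- function(object, newdata,
                                         type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.data.table(newdata)
  X <- cbind(1, as.matrix(newdata[, object$predictors, with = FALSE]))
  p <- plogis(pmin(30, pmax(-30, drop(X %*% object$coefficients))))
  if (type == "prob") p else ifelse(p >= object$threshold, "hit", "flop")
}

#' @export
print.nf_logistic_baseline <- function(x, ...) {
  cat("<logistic baseline>", x$model, "on",
      paste(x$predictors, collapse = " + "), "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  LR chi-sq(%d) = %.3f, p = %.4g; in-sample accuracy %.3f\n",
              x$lr_df, x$lr_chisq, x$lr_p, x$confusion$accuracy))
  if (!is.null(x$vif)) cat("  VIF:", paste(sprintf("%s %.3f", names(x$vif),
                                                   x$vif), collapse = ", "), "\n")
  invisible(x)
}

#' Two-group and correlation effect statistics
#'
#' With `group` supplied: pooled-variance two-sample Student t with
#' `df = n1 + n2 - 2` and Cohen's d = (mean(flop) - mean(hit)) / pooled SD.
#' Groups are ordered (flop, hit), so a variable that is *higher* in hits
#' yields negative t and d. With `y` supplied instead: Pearson correlation
#' with its t-based p value.
#'
#' @param x numeric vector.
#' @param group optional hit/flop labels aligned with `x`.
#' @param y optional second numeric vector for a correlation.
#' @return list with `t`, `df`, `p`, and `d` (group mode) or `r` (
#'   correlation mode). A zero pooled variance with unequal means sets
#'   `infinite = TRUE`.
#' @export
effect_stats <- function(x, group = NULL, y = NULL) {
  if (!is.null(group)) {
    g <- normalize_label(group)
    x1 <- x[g == "flop"]; x2 <- x[g == "hit"]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2L || n2 < 2L) stop("need >= 2 observations per group",
                                 call. = FALSE)
    sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
    delta <- mean(x1) - mean(x2)
    if (sp2 == 0) {
      return(list(t = ifelse(delta == 0, 0, Inf * sign(delta)),
                  df = n1 + n2 - 2L, p = ifelse(delta == 0, 1, 0),
                  d = ifelse(delta == 0, 0, Inf * sign(delta)),
                  infinite = delta != 0))
    }
    tval <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2L
    list(t = tval, df = df, p = 2 * pt(-abs(tval), df),
         d = delta / sqrt(sp2), infinite = FALSE)
  } else if (!is.null(y)) {
    stopifnot(length(x) == length(y), length(x) >= 3L)
    r <- cor(x, y)
    df <- length(x) - 2L
    tval <- r * sqrt(df / (1 - r^2))
    list(r = r, t = tval, df = df, p = 2 * pt(-abs(tval), df))
  } else {
    stop("supply either `group` or `y`", call. = FALSE)
  }
}
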