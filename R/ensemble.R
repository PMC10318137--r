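# Super-learner ensemble: candidate learners are tuned by stratified
# 5-fold cross-validation, their out-of-fold predictions form the matrix
# Z, and the ensemble weight vector beta solves a non-negative least
# squares problem on Z (then normalized to the probability simplex). The
# ensemble prediction is sum_j beta_j * learner_j(x).

# stratified fold assignment; guarantees both classes in every training
# complement (re-drawn a bounded number of times otherwise)
make_folds <- function(y, folds) {
  n <- length(y)
  if (folds > n) stop("more folds than rows", call. = FALSE)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  for (attempt in 1:25) {
    fold <- integer(n)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    ok <- all(vapply(seq_len(folds), function(v) {
      tr <- y[fold != v]
      length(unique(tr)) == 2L
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build folds with both classes in every training fold",
       call. = FALSE)
}

grid_points <- function(grid) {
  g <- do.call(expand.grid, c(grid, list(stringsAsFactors = FALSE,
                                         KEEP.OUT.ATTRS = FALSE)))
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

#' Tune one learner by stratified V-fold cross-validation
#'
#' Evaluates every grid point by the cross-validated mean squared error of
#' predicted class-1 probabilities and returns the minimizer; exact ties
#' are broken by grid order (first listed hyperparameter varying fastest).
#'
#' @param spec a [learner_spec()].
#' @param train training table containing `features` and `label_col`.
#' @param features feature column names.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold draw.
#' @param label_col name of the hit/flop label column.
#' @return list with the selected `hyper`, its `cv_mse`, and the full
#'   `grid_mse` vector.
#' @export
tune_learner <- function(spec, train, features = c("avg_immersion", "retreat"),
                         folds = 5L, seed = 1L, label_col = "label") {
  stopifnot(inherits(spec, "learner_spec"))
  train <- as.data.table(train)
  y <- as.integer(normalize_label(train[[label_col]]) == "hit")
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  X <- scale_features(as.matrix(train[, features, with = FALSE]))$X
  set.seed(as.integer(seed))
  fold <- make_folds(y, folds)
  pts <- grid_points(spec$grid)
  mse <- vapply(pts, function(hyper) {
    pr <- numeric(length(y))
    for (v in seq_len(folds)) {
      tr <- fold != v
      fit <- fit_learner(spec$name, hyper, X[tr, , drop = FALSE], y[tr])
      pr[!tr] <- predict_prob(fit, X[!tr, , drop = FALSE])
    }
    mean((pr - y)^2)
  }, numeric(1))
  best <- which.min(mse)  # which.min returns the first minimum: grid-order tie-break
  list(hyper = pts[[best]], cv_mse = mse[best], grid_mse = mse)
}

scale_features <- function(X, center = NULL, scale = NULL) {
  center <- center %||% colMeans(X)
  scale <- scale %||% apply(X, 2L, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(X = sweep(sweep(X, 2L, center, `-`), 2L, scale, `/`),
       center = center, scale = scale)
}

#' Out-of-fold prediction matrix for a set of learners
#'
#' Every training row is predicted by models whose training data excluded
#' that row's fold; the resulting matrix Z (one column per learner) is the
#' input to ensemble weight estimation.
#'
#' @param learners named list; each element a list with `name` and `hyper`.
#' @param train training table.
#' @param features feature column names.
#' @param folds number of folds.
#' @param seed integer seed for the fold draw.
#' @param label_col label column name.
#' @return list with matrix `Z` (probabilities in `[0,1]`), labels `y`,
#'   and the `fold` assignment.
#' @export
cv_out_of_fold <- function(learners, train,
                           features = c("avg_immersion", "retreat"),
                           folds = 5L, seed = 1L, label_col = "label") {
  train <- as.data.table(train)
  y <- as.integer(normalize_label(train[[label_col]]) == "hit")
  Xraw <- as.matrix(train[, features, with = FALSE])
  sc <- scale_features(Xraw)
  set.seed(as.integer(seed))
  fold <- make_folds(y, folds)
  Z <- matrix(NA_real_, nrow = length(y), ncol = length(learners),
              dimnames = list(NULL, names(learners)))
  for (j in seq_along(learners)) {
    lrn <- learners[[j]]
    Xj <- if (lrn$name == "logistic") Xraw else sc$X
    for (v in seq_len(folds)) {
      tr <- fold != v
      fit <- fit_learner(lrn$name, lrn$hyper, Xj[tr, , drop = FALSE], y[tr])
      Z[!tr, j] <- predict_prob(fit, Xj[!tr, , drop = FALSE])
    }
  }
  list(Z = Z, y = y, fold = fold)
}

# exact least squares over the probability simplex by active-set
# enumeration: for every non-empty subset of columns solve the
# equality-constrained problem through its KKT system and keep the best
# non-negative solution. Exact and cheap for the handful of learners used.
simplex_lsq <- function(Z, y) {
  p <- ncol(Z)
  A <- crossprod(Z); b <- crossprod(Z, y)
  best <- NULL; best_rss <- Inf
  for (mask in seq_len(2^p - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
    k <- length(S)
    kkt <- rbind(cbind(2 * A[S, S, drop = FALSE], 1), c(rep(1, k), 0))
    sol <- tryCatch(solve(kkt, c(2 * b[S], 1)), error = function(e) NULL)
    if (is.null(sol)) next
    beta_s <- sol[seq_len(k)]
    if (any(beta_s < -1e-10)) next
    beta <- numeric(p); beta[S] <- pmax(beta_s, 0)
    beta <- beta / sum(beta)
    rss <- sum((y - drop(Z %*% beta))^2)
    if (rss < best_rss - 1e-12) { best_rss <- rss; best <- beta }
  }
  best %||% rep(1 / p, p)
}

#' Ensemble weights by cross-validated risk minimization
#'
#' Minimizes `sum_i (y_i - sum_j beta_j Z_ij)^2` over the probability
#' simplex (`beta_j >= 0`, `sum beta_j = 1`), i.e. non-negative least
#' squares with a sum-to-one constraint, solved exactly by active-set
#' enumeration. Solving on the simplex directly guarantees the ensemble's
#' cross-validated risk never exceeds the best single learner's (each
#' learner is a simplex vertex). Per-learner risk is the mean squared
#' error of that learner's out-of-fold column.
#'
#' @param Z out-of-fold probability matrix (rows: training rows; columns:
#'   learners), or the list returned by [cv_out_of_fold()].
#' @param y 0/1 labels (ignored when `Z` is a `cv_out_of_fold()` result).
#' @return list with `beta` (simplex weights), `cv_risk` per learner, and
#'   `ensemble_risk`.
#' @export
fit_ensemble_weights <- function(Z, y = NULL) {
  if (is.list(Z) && !is.null(Z$Z)) { y <- Z$y; Z <- Z$Z }
  if (is.null(dim(Z)) || ncol(Z) == 0L || nrow(Z) == 0L) {
    stop("Z must be a non-empty matrix of out-of-fold predictions",
         call. = FALSE)
  }
  stopifnot(length(y) == nrow(Z))
  beta <- if (ncol(Z) == 1L) 1 else simplex_lsq(Z, y)
  beta <- setNames(as.numeric(beta), colnames(Z))
  list(beta = beta,
       cv_risk = setNames(colMeans((Z - y)^2), colnames(Z)),
       ensemble_risk = mean((drop(Z %*% beta) - y)^2))
}

#' Fit the super-learner ensemble
#'
#' Full training path: learn feature scaling on the training table, select
#' hyperparameters (grid tuning or fixed settings), compute out-of-fold
#' predictions, estimate simplex weights by cross-validated risk
#' minimization, and refit every learner on the full training table.
#'
#' @param train training table with feature columns and a hit/flop label.
#' @param features feature column names (default `avg_immersion`,
#'   `retreat`, the two neural measures the ensemble uses).
#' @param specs learner specifications ([default_learner_specs()]).
#' @param tune if `TRUE`, grid-tune each learner by V-fold CV; if `FALSE`,
#'   use `hypers`.
#' @param hypers named list of hyperparameter lists used when
#'   `tune = FALSE` (default [selected_hyperparameters()]).
#' @param folds folds for tuning and out-of-fold prediction (default 5).
#' @param seed integer seed.
#' @param threshold classification cutoff; a predicted probability equal
#'   to the threshold is classified as a hit (default 0.5).
#' @param label_col label column name.
#' @return an `nf_ensemble` model.
#' @export
fit_ensemble <- function(train, features = c("avg_immersion", "retreat"),
                         specs = default_learner_specs(), tune = FALSE,
                         hypers = selected_hyperparameters(), folds = 5L,
                         seed = 1L, threshold = 0.5, label_col = "label") {
  train <- as.data.table(train)
  y <- as.integer(normalize_label(train[[label_col]]) == "hit")
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  Xraw <- as.matrix(train[, features, with = FALSE])
  sc <- scale_features(Xraw)
  if (tune) {
    hypers <- lapply(seq_along(specs), function(j) {
      tune_learner(specs[[j]], train, features, folds,
                   seed = derive_seed(seed, paste0("tune_", names(specs)[j])),
                   label_col = label_col)$hyper
    })
    names(hypers) <- names(specs)
  } else {
    hypers <- hypers[names(specs)]
  }
  learners <- lapply(seq_along(specs), function(j) {
    list(name = specs[[j]]$name, hyper = hypers[[j]])
  })
  names(learners) <- names(specs)
  oof <- cv_out_of_fold(learners, train, features, folds,
                        seed = derive_seed(seed, "oof"), label_col = label_col)
  w <- fit_ensemble_weights(oof)
  set.seed(derive_seed(seed, "refit"))
  fitted <- lapply(learners, function(lrn) {
    Xj <- if (lrn$name == "logistic") Xraw else sc$X
    fit_learner(lrn$name, lrn$hyper, Xj, y)
  })
  structure(list(learners = fitted, hypers = hypers, beta = w$beta,
                 cv_risk = w$cv_risk, ensemble_risk = w$ensemble_risk,
                 threshold = threshold, center = sc$center, scale = sc$scale,
                 features = features, label_col = label_col,
                 oof = oof, seed = as.integer(seed)),
            class = "nf_ensemble")
}

check_simplex <- function(beta, tol = 1e-9) {
  if (any(beta < -tol) || abs(sum(beta) - 1) > tol) {
    stop("ensemble weights must be non-negative and sum to 1", call. = FALSE)
  }
  invisible(beta)
}

#' Predict with a fitted ensemble
#'
#' @param object an `nf_ensemble`.
#' @param newdata table containing the model's feature columns.
#' @param type `"prob"` for class-1 (hit) probabilities, `"class"` for
#'   `"hit"`/`"flop"` labels (hit iff probability >= threshold).
#' @param ... unused.
#' @return numeric probabilities or character labels.
#' @export
predict.nf_ensemble <- function(object, newdata,
                                type = c("prob", "class"), ...) {
  type <- match.arg(type)
  check_simplex(object$beta)
  newdata <- as.data.table(newdata)
  Xraw <- as.matrix(newdata[, object$features, with = FALSE])
  Xs <- scale_features(Xraw, object$center, object$scale)$X
  probs <- vapply(names(object$learners), function(nm) {
    l <- object$learners[[nm]]
    Xj <- if (inherits(l, "nf_logistic")) Xraw else Xs
    predict_prob(l, Xj)
  }, numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) probs <- matrix(probs, nrow = 1L)
  p <- drop(probs %*% object$beta)
  if (type == "prob") p else ifelse(p >= object$threshold, "hit", "flop")
}

#' @export
print.nf_ensemble <- function(x, ...) {
  cat("<nf_ensemble> super-learner on", paste(x$features, collapse = ", "),
      "\n")
  for (nm in names(x$beta)) {
    cat(sprintf("  %-9s beta = %.4f  cv risk = %.4f\n", nm, x$beta[nm],
                x$cv_risk[nm]))
  }
  cat(sprintf("  ensemble cv risk = %.4f, threshold = %.2f\n",
              x$ensemble_risk, x$threshold))
  invisible(x)
}
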