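# Candidate learners for the super-learner ensemble.
#
# Each learner is fitted through fit_learner(name, hyper, X, y) and
# predicts class-1 probabilities through predict_prob(). X is a numeric
# matrix; the ensemble passes z-scored features to knn/svm/ann and raw
# features to the logistic learner (whose fit is scale-equivariant).

# ---- logistic ridge (IRLS, penalty 1/cost, intercept unpenalized) ----

fit_logistic_ridge <- function(X, y, cost = 1, lambda = NULL,
                               maxit = 60L, tol = 1e-9) {
  Xd <- cbind(`(Intercept)` = 1, X)
  lam <- lambda %||% (1 / cost)
  D <- diag(c(0, rep(lam, ncol(X))), nrow = ncol(Xd))
  beta <- numeric(ncol(Xd))
  for (it in seq_len(maxit)) {
    eta <- pmin(30, pmax(-30, drop(Xd %*% beta)))
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-8)
    z <- eta + (y - p) / w
    XtW <- t(Xd * w)
    beta_new <- solve(XtW %*% Xd + D, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  structure(list(beta = drop(beta)), class = c("nf_logistic", "nf_learner"))
}

#' Class-1 probability predictions from a fitted candidate learner
#'
#' @param object a fitted learner (`nf_logistic`, `nf_knn`, `nf_svm`,
#'   `nf_ann`).
#' @param X numeric feature matrix on the scale the learner was fitted on.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(object, X, ...) UseMethod("predict_prob")

#' @export
predict_prob.nf_logistic <- function(object, X, ...) {
  eta <- drop(cbind(1, X) %*% object$beta)
  plogis(pmin(30, pmax(-30, eta)))
}

# ---- k-nearest neighbors ----
# Euclidean distance; probability = fraction of the k nearest training
# rows labeled 1; distance ties resolved by training-row order (stable sort).

fit_knn <- function(X, y, k = 3L) {
  structure(list(X = X, y = y, k = as.integer(min(k, nrow(X)))),
            class = c("nf_knn", "nf_learner"))
}

#' @export
predict_prob.nf_knn <- function(object, X, ...) {
  Xtr <- object$X; k <- object$k
  tr_sq <- rowSums(Xtr^2)
  out <- numeric(nrow(X))
  chunk <- 512L
  for (start in seq(1L, nrow(X), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(X))
    d2 <- outer(rowSums(X[idx, , drop = FALSE]^2), tr_sq, `+`) -
      2 * X[idx, , drop = FALSE] %*% t(Xtr)
    out[idx] <- apply(d2, 1L, function(d) {
      mean(object$y[order(d, method = "radix")[seq_len(k)]])
    })
  }
  out
}

# ---- kernel machine (regularized least squares + Platt scaling) ----
# Trained by kernel ridge on +/-1 targets rather than a margin dual so the
# indefinite tanh Gram matrix is handled without special cases; decision
# values are mapped to probabilities by a fitted logistic (Platt) link.

kernel_matrix <- function(kernel, X1, X2, gamma, coef0 = 1, degree = 3) {
  G <- X1 %*% t(X2)
  switch(kernel,
    radial = {
      d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * G
      exp(-gamma * pmax(d2, 0))
    },
    polynomial = (gamma * G + coef0)^degree,
    tanh = tanh(gamma * G),
    stop("unknown kernel: ", kernel, call. = FALSE))
}

fit_svm_krls <- function(X, y, cost = 10, kernel = "tanh", gamma = NULL) {
  gamma <- gamma %||% (1 / ncol(X))
  K <- kernel_matrix(kernel, X, X, gamma)
  lam <- 1 / cost
  ys <- 2 * y - 1
  alpha <- tryCatch(solve(K + lam * diag(nrow(K)), ys),
                    error = function(e)
                      solve(K + (lam + 1e-6) * diag(nrow(K)), ys))
  f <- drop(K %*% alpha)
  platt <- fit_logistic_ridge(matrix(f, ncol = 1), y, lambda = 1e-3)
  structure(list(X = X, alpha = drop(alpha), kernel = kernel, gamma = gamma,
                 platt = platt),
            class = c("nf_svm", "nf_learner"))
}

#' @export
predict_prob.nf_svm <- function(object, X, ...) {
  f <- drop(kernel_matrix(object$kernel, X, object$X, object$gamma) %*%
              object$alpha)
  predict_prob(object$platt, matrix(f, ncol = 1))
}

# ---- single-hidden-layer neural network (via nnet) ----
# Logistic hidden units; output "softmax" over the two classes or "linear"
# (identity output clipped to [0,1]); L2 weight decay; 500 epochs.

fit_ann <- function(X, y, activation = "softmax", size = 5L, decay = 1) {
  if (activation == "softmax") {
    targets <- nnet::class.ind(factor(y, levels = c(0, 1)))
    fit <- nnet::nnet(x = X, y = targets, size = size, decay = decay,
                      softmax = TRUE, maxit = 500L, trace = FALSE,
                      MaxNWts = 5000L)
  } else {
    fit <- nnet::nnet(x = X, y = y, size = size, decay = decay,
                      linout = TRUE, maxit = 500L, trace = FALSE,
                      MaxNWts = 5000L)
  }
  structure(list(fit = fit, activation = activation),
            class = c("nf_ann", "nf_learner"))
}

#' @export
predict_prob.nf_ann <- function(object, X, ...) {
  p <- predict(object$fit, X)
  p <- if (object$activation == "softmax") p[, "1"] else drop(p)
  pmin(1, pmax(0, p))
}

# ---- dispatcher ----

fit_learner <- function(name, hyper, X, y) {
  switch(name,
    logistic = fit_logistic_ridge(X, y, cost = hyper$cost %||% 1),
    knn = fit_knn(X, y, k = hyper$k %||% 3L),
    svm = fit_svm_krls(X, y, cost = hyper$cost %||% 10,
                       kernel = hyper$kernel %||% "tanh"),
    ann = fit_ann(X, y, activation = hyper$activation %||% "softmax",
                  size = hyper$size %||% 5L, decay = hyper$decay %||% 1),
    stop("unknown learner: ", name, call. = FALSE))
}

#' Candidate learner specifications
#'
#' The four candidate learners with their default hyperparameter grids:
#' logistic cost \{1, 10, 100\}; KNN neighbors \{3, 5, 8, 10\}; kernel
#' machine cost \{1, 10, 100\} x kernel \{radial, polynomial, tanh\}; ANN
#' activation \{linear, softmax\} x hidden size \{1, 5, 10\} x decay
#' \{0, 1, 10\}.
#'
#' @return named list of `learner_spec` objects.
#' @seealso [selected_hyperparameters()] for the settings used when grid
#'   tuning is disabled.
#' @export
default_learner_specs <- function() {
  list(
    logistic = learner_spec("logistic", list(cost = c(1, 10, 100))),
    knn = learner_spec("knn", list(k = c(3L, 5L, 8L, 10L))),
    svm = learner_spec("svm", list(cost = c(1, 10, 100),
                                   kernel = c("radial", "polynomial", "tanh"))),
    ann = learner_spec("ann", list(activation = c("linear", "softmax"),
                                   size = c(1L, 5L, 10L),
                                   decay = c(0, 1, 10))))
}

#' Construct a learner specification
#'
#' @param name one of `"logistic"`, `"knn"`, `"svm"`, `"ann"`.
#' @param grid named list mapping hyperparameter to candidate values.
#' @return a `learner_spec`.
#' @export
learner_spec <- function(name, grid) {
  name <- match.arg(name, c("logistic", "knn", "svm", "ann"))
  stopifnot(is.list(grid), length(grid) >= 1L, !is.null(names(grid)))
  structure(list(name = name, grid = grid), class = "learner_spec")
}

#' Reference hyperparameter settings
#'
#' The settings used when tuning is disabled: logistic cost 1; KNN k = 3;
#' kernel machine cost 10 with tanh kernel; ANN softmax output, hidden
#' size 5, decay 1.
#'
#' @return named list of hyperparameter lists, one per learner.
#' @export
selected_hyperparameters <- function() {
  list(logistic = list(cost = 1),
       knn = list(k = 3L),
       svm = list(cost = 10, kernel = "tanh"),
       ann = list(activation = "softmax", size = 5L, decay = 1))
}
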