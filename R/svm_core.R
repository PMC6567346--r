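#' RBF kernel parameters
#'
#' The kernel is `K(x, xi) = exp(-(gamma / sigma) * ||x - xi||^2)`. The
#' divisor `sigma` defaults to 1, reducing to the usual single-parameter
#' RBF form; it is kept explicit so a data-variance normalization can be
#' configured without changing `gamma` grids.
#'
#' @param gamma positive kernel width parameter.
#' @param sigma positive divisor, default 1.
#' @return an object of class `kernel_params`.
#' @export
kernel_params <- function(gamma, sigma = 1) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (sigma <= 0) stop("sigma must be > 0")
  structure(list(gamma = gamma, sigma = sigma), class = "kernel_params")
}

#' Radial basis function kernel
#'
#' @param x,xi numeric vectors of equal length.
#' @param params a [kernel_params()].
#' @return `exp(-(gamma/sigma) * ||x - xi||^2)`, in (0, 1].
#' @export
rbf_kernel <- function(x, xi, params) {
  if (!all(is.finite(x)) || !all(is.finite(xi))) stop("non-finite input")
  stopifnot(length(x) == length(xi))
  exp(-(params$gamma / params$sigma) * sum((x - xi)^2))
}

# kernel matrix between rows of A (m x d) and rows of B (k x d)
rbf_cross <- function(A, B, gamma_eff) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma_eff * pmax(d2, 0))
}

#' Fit a soft-margin RBF support vector machine
#'
#' Trains a binary SVM on a feature table by solving the dual problem
#' (maximize `sum(a) - 0.5 * t(a*y) K (a*y)` subject to `0 <= a_i <= C`,
#' `sum(a_i y_i) = 0`) with a sequential-minimal-optimization solver, to
#' KKT tolerance `tol`. Labels must be +1 (high) / -1 (low). Training
#' points with `a_i > tol` are retained as support vectors; the bias is
#' the average over unbounded support vectors (`tol < a_i < C - tol`).
#'
#' Min-max feature scaling is fit on the training rows unless a
#' `scaling` matrix is supplied (e.g. one fit on a larger design); the
#' scaling is stored in the model and applied automatically by
#' [classify()] and [predict.breath_svm()].
#'
#' @param table a `feature_table` from [build_design()] (columns `f1`,
#'   `f2`, ..., `label`), or any data.frame shaped like one.
#' @param gamma,sigma RBF kernel parameters; see [kernel_params()].
#' @param C positive box constraint on the dual coefficients.
#' @param tol KKT tolerance (default 1e-3).
#' @param max_passes cap on full SMO passes over the data (default 100).
#' @param seed integer seed for the solver's randomized pair selection.
#' @param scaling optional pre-fit scaling matrix (see [fit_scaling()]).
#' @return an object of class `breath_svm` with components
#'   `support_vectors` (matrix, scaled space), `dual_coefs` (`a_i * y_i`),
#'   `bias`, `n_sv`, `kernel` ([kernel_params()]), `scaling`,
#'   `label_map`, and the training call.
#' @examples
#' runs <- generate_dataset(3, sensors = default_sensors(noise_sd = 0),
#'                          master_seed = 7)
#' tab <- build_design(runs, default_scheme(), "SteadyState", period = 25)
#' fit <- breath_svm(tab, gamma = 0.125, C = 1)
#' fit
#' @export
breath_svm <- function(table, gamma, C, sigma = 1, tol = 1e-3,
                       max_passes = 100, seed = 1, scaling = NULL) {
  cl <- match.call()
  fc <- feature_cols(table)
  if (nrow(table) == 0L || length(fc) == 0L) stop("empty feature table")
  if (!all(table$label %in% c(-1, 1)))
    stop("labels must be encoded +1 (high) / -1 (low)")
  if (length(unique(table$label)) < 2L)
    stop("training data must contain both classes")
  if (C <= 0) stop("C must be > 0")
  if (tol <= 0) stop("tol must be > 0")
  if (max_passes < 1) stop("max_passes must be >= 1")

  if (is.null(scaling)) scaling <- fit_scaling(table)
  scaled <- apply_scaling(table, scaling)
  X <- as.matrix(scaled[, fc, drop = FALSE])
  y <- as.numeric(scaled$label)
  kp <- kernel_params(gamma, sigma)
  gamma_eff <- kp$gamma / kp$sigma

  old <- local_seed(seed)
  on.exit(restore_seed(old))
  sol <- .smo_solve(X, y, gamma_eff, C, tol, as.integer(max_passes))

  keep <- sol$alpha > tol
  structure(
    list(support_vectors = X[keep, , drop = FALSE],
         dual_coefs = sol$alpha[keep] * y[keep],
         alpha = sol$alpha[keep],
         sv_labels = y[keep],
         bias = sol$b,
         n_sv = sum(keep),
         kernel = kp,
         C = C, tol = tol, seed = seed,
         passes = sol$passes,
         scaling = scaling,
         label_map = c(`1` = "high", `-1` = "low"),
         call = cl),
    class = "breath_svm"
  )
}

#' SVM decision value in the scaled feature space
#'
#' Computes `f(x) = sum_i dual_coefs[i] * K(x, sv[i]) + bias`. The input
#' must already be in the model's scaled space; [classify()] handles raw
#' readings.
#'
#' @param model a `breath_svm` (or unpacked equivalent).
#' @param x numeric vector (one point) or matrix (one row per point),
#'   dimensionality matching the model.
#' @return numeric decision value(s).
#' @export
decision_value <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  dim_m <- ncol(model$scaling)
  if (ncol(x) != dim_m)
    stop(sprintf("x has %d features, model expects %d", ncol(x), dim_m))
  if (model$n_sv == 0L) return(rep(model$bias, nrow(x)))
  gamma_eff <- model$kernel$gamma / model$kernel$sigma
  Kx <- rbf_cross(x, model$support_vectors, gamma_eff)
  drop(Kx %*% model$dual_coefs) + model$bias
}

#' Classify raw sensor readings
#'
#' Applies the model's stored min-max scaling, computes the decision
#' value, and maps its sign to a class: `high` when `f(x) >= 0` (ties
#' deliberately classify as high), `low` otherwise.
#'
#' @param model a `breath_svm`.
#' @param x_raw numeric vector or matrix of raw (unscaled) readings.
#' @return character vector of class tags.
#' @export
classify <- function(model, x_raw) {
  x_raw <- if (is.matrix(x_raw)) x_raw else matrix(x_raw, nrow = 1)
  if (!all(is.finite(x_raw))) stop("non-finite input")
  x <- scale_raw(x_raw, model$scaling)
  f <- decision_value(model, x)
  ifelse(f >= 0, "high", "low")
}

scale_raw <- function(x, scaling) {
  lo <- scaling["min", ]; hi <- scaling["max", ]
  span <- ifelse(hi > lo, hi - lo, 1)
  sweep(sweep(x, 2, lo), 2, span, "/") *
    rep(ifelse(hi > lo, 1, 0), each = nrow(x))
}

#' @export
print.breath_svm <- function(x, ...) {
  cat("Soft-margin RBF SVM (SMO)\n")
  cat(sprintf("  gamma = %g, sigma = %g, C = %g\n",
              x$kernel$gamma, x$kernel$sigma, x$C))
  cat(sprintf("  support vectors: %d   bias: %.6g\n", x$n_sv, x$bias))
  invisible(x)
}

#' @export
summary.breath_svm <- function(object, ...) {
  n_bounded <- sum(object$alpha >= object$C - object$tol)
  structure(
    list(model = object, n_bounded = n_bounded,
         dual_balance = sum(object$dual_coefs)),
    class = "summary.breath_svm"
  )
}

#' @export
print.summary.breath_svm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  bounded (a = C) support vectors: %d\n", x$n_bounded))
  cat(sprintf("  dual equality residual sum(a_i y_i): %.3g\n", x$dual_balance))
  invisible(x)
}

#' @export
coef.breath_svm <- function(object, ...) {
  object$dual_coefs
}

#' Predict method for breath_svm models
#'
#' @param object a `breath_svm`.
#' @param newdata a `feature_table`, data.frame with the model's feature
#'   columns, or a numeric matrix of raw readings.
#' @param type `"class"` for class tags, `"decision"` for decision values.
#' @param ... unused.
#' @export
predict.breath_svm <- function(object, newdata,
                               type = c("class", "decision"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else {
    fc <- feature_cols(newdata)
    as.matrix(newdata[, fc, drop = FALSE])
  }
  xs <- scale_raw(x, object$scaling)
  f <- decision_value(object, xs)
  if (type == "decision") f else ifelse(f >= 0, "high", "low")
}

#' Plot the decision boundary of a two-feature model
#'
#' Draws the f(x) = 0 contour in raw feature coordinates with the
#' support vectors marked.
#'
#' @param x a `breath_svm` fit on two features.
#' @param grid_n resolution of the contour grid.
#' @param ... passed to [graphics::contour()].
#' @export
plot.breath_svm <- function(x, grid_n = 120, ...) {
  if (ncol(x$scaling) != 2L) stop("plot supports two-feature models only")
  lo <- x$scaling["min", ]; hi <- x$scaling["max", ]
  pad <- 0.15 * (hi - lo)
  g1 <- seq(lo[1] - pad[1], hi[1] + pad[1], length.out = grid_n)
  g2 <- seq(lo[2] - pad[2], hi[2] + pad[2], length.out = grid_n)
  grid <- as.matrix(expand.grid(f1 = g1, f2 = g2))
  f <- decision_value(x, scale_raw(grid, x$scaling))
  z <- matrix(f, grid_n, grid_n)
  graphics::contour(g1, g2, z, levels = 0, drawlabels = FALSE,
                    xlab = "sensor 1", ylab = "sensor 2", ...)
  sv_raw <- sweep(sweep(x$support_vectors, 2, hi - lo, "*"), 2, lo, "+")
  graphics::points(sv_raw, pch = ifelse(x$sv_labels > 0, 19, 1))
  invisible(x)
}

#' Dual objective of a fitted (or candidate) solution
#'
#' `sum(a) - 0.5 * sum_ij a_i a_j y_i y_j K(x_i, x_j)` evaluated on
#' arbitrary alphas over a training design; used for solver diagnostics.
#'
#' @param X scaled feature matrix.
#' @param y +1/-1 labels.
#' @param alpha dual variables.
#' @param gamma_eff effective kernel width (gamma / sigma).
#' @export
dual_objective <- function(X, y, alpha, gamma_eff) {
  K <- rbf_cross(X, X, gamma_eff)
  ay <- alpha * y
  sum(alpha) - 0.5 * drop(ay %*% K %*% ay)
}
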