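#' Hyperparameter grid for (gamma, C)
#'
#' Defaults reproduce the published cross-validation grid: gamma in
#' 2^-3 .. 2^1 (5 values) by C in 2^-3 .. 2^2 (6 values).
#'
#' @param gammas,Cs positive numeric vectors.
#' @return an object of class `param_grid`.
#' @export
param_grid <- function(gammas = 2^(-3:1), Cs = 2^(-3:2)) {
  if (length(gammas) == 0L || length(Cs) == 0L) stop("grid must be non-empty")
  if (any(gammas <= 0) || any(Cs <= 0)) stop("grid entries must be > 0")
  structure(list(gammas = as.numeric(gammas), Cs = as.numeric(Cs)),
            class = "param_grid")
}

#' Leave-one-run-out splits
#'
#' One split per (held-out low run, held-out high run) pair, i.e. the
#' full cross-product: `n_low * n_high` splits, each testing on exactly
#' that pair and training on everything else. With `paired = TRUE`, only
#' the i-th low with i-th high pairs are used (requires equal class
#' counts).
#'
#' @param dataset list of `run_record`s, at least two runs per class.
#' @param paired use index-paired splits instead of the cross-product.
#' @return list of splits, each `list(train = indices, test = indices)`.
#' @export
loro_splits <- function(dataset, paired = FALSE) {
  labels <- vapply(dataset, function(r) r$label, character(1))
  lo <- which(labels == "low"); hi <- which(labels == "high")
  if (length(lo) < 2L || length(hi) < 2L)
    stop("each class needs at least two runs for leave-one-run-out CV")
  pairs <- if (paired) {
    if (length(lo) != length(hi)) stop("paired splits need equal class counts")
    cbind(lo, hi)
  } else {
    as.matrix(expand.grid(lo = lo, hi = hi))
  }
  all_idx <- seq_along(dataset)
  lapply(seq_len(nrow(pairs)), function(i) {
    test <- as.integer(pairs[i, ])
    list(train = setdiff(all_idx, test), test = test)
  })
}

# Sample every run's segment rows once; CV then only indexes this list.
per_run_rows <- function(dataset, scheme, segment, period) {
  lapply(dataset, function(r) {
    w <- segment_window(scheme, segment, r$introduction_s)
    sample_features(r, w, period)
  })
}

# Pooled reading-level CV accuracy for a set of (gamma, C) cells.
# Scaling is refit inside every split on the training rows only, so no
# held-out reading influences its own preprocessing.
cv_pooled <- function(rows, splits, gammas, Cs, sigma = 1, tol = 1e-3,
                      max_passes = 100, seed = 1) {
  correct <- matrix(0, nrow = length(Cs), ncol = length(gammas))
  total <- 0
  for (sp in splits) {
    train_tab <- do.call(rbind, rows[sp$train])
    class(train_tab) <- c("feature_table", "data.frame")
    test_tab <- do.call(rbind, rows[sp$test])
    fc <- feature_cols(train_tab)
    x_test <- as.matrix(test_tab[, fc, drop = FALSE])
    truth <- ifelse(test_tab$label > 0, "high", "low")
    total <- total + length(truth)
    for (ci in seq_along(Cs)) for (gi in seq_along(gammas)) {
      fit <- breath_svm(train_tab, gamma = gammas[gi], C = Cs[ci],
                        sigma = sigma, tol = tol, max_passes = max_passes,
                        seed = seed)
      pred <- classify(fit, x_test)
      correct[ci, gi] <- correct[ci, gi] + sum(pred == truth)
    }
  }
  list(accuracy = 100 * correct / total, n_readings = total)
}

#' Pooled CV accuracy at a single (gamma, C)
#'
#' Runs the full leave-one-run-out procedure: for every split, build the
#' training design, fit scaling, train, and classify every sampled
#' reading of the held-out runs. Accuracy is pooled over readings across
#' all splits (correct readings / total readings), in percent.
#'
#' @param dataset list of `run_record`s.
#' @param scheme a [segment_scheme()].
#' @param segment segment name.
#' @param gamma,C SVM hyperparameters.
#' @param period feature sampling period, seconds.
#' @param paired see [loro_splits()].
#' @param ... passed to [breath_svm()] (`sigma`, `tol`, `max_passes`, `seed`).
#' @return accuracy in percent.
#' @export
cv_accuracy <- function(dataset, scheme, segment, gamma, C, period = 5,
                        paired = FALSE, ...) {
  rows <- per_run_rows(dataset, scheme, segment, period)
  splits <- loro_splits(dataset, paired = paired)
  cv_pooled(rows, splits, gammas = gamma, Cs = C, ...)$accuracy[1, 1]
}

#' Grid search over (gamma, C) by leave-one-run-out CV
#'
#' Fills the full accuracy matrix (rows = C, columns = gamma) and selects
#' the best cell; ties are broken toward smaller C, then smaller gamma.
#'
#' @inheritParams cv_accuracy
#' @param grid a [param_grid()].
#' @return an object of class `cv_result`: `accuracy` matrix (percent),
#'   `best` list (gamma, C, accuracy), `grid`, `n_readings`.
#' @export
grid_search <- function(dataset, scheme, segment, grid = param_grid(),
                        period = 5, paired = FALSE, ...) {
  stopifnot(inherits(grid, "param_grid"))
  rows <- per_run_rows(dataset, scheme, segment, period)
  splits <- loro_splits(dataset, paired = paired)
  res <- cv_pooled(rows, splits, gammas = grid$gammas, Cs = grid$Cs, ...)
  acc <- res$accuracy
  dimnames(acc) <- list(C = format(grid$Cs), gamma = format(grid$gammas))
  # best cell, ties toward smaller C then smaller gamma (grids are stored
  # ascending, so the first max in column-major order after transposing
  # the preference is found by explicit search)
  best_ci <- 1L; best_gi <- 1L
  for (gi in seq_along(grid$gammas)) for (ci in seq_along(grid$Cs)) {
    if (acc[ci, gi] > acc[best_ci, best_gi] + 1e-12 ||
        (abs(acc[ci, gi] - acc[best_ci, best_gi]) <= 1e-12 &&
         (grid$Cs[ci] < grid$Cs[best_ci] ||
          (grid$Cs[ci] == grid$Cs[best_ci] &&
           grid$gammas[gi] < grid$gammas[best_gi]))))
      { best_ci <- ci; best_gi <- gi }
  }
  structure(
    list(accuracy = acc,
         best = list(gamma = grid$gammas[best_gi], C = grid$Cs[best_ci],
                     accuracy = acc[best_ci, best_gi]),
         grid = grid, segment = segment, n_readings = res$n_readings),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Leave-one-run-out CV, segment %s (%d pooled readings)\n",
              x$segment, x$n_readings))
  print(round(x$accuracy, 2))
  cat(sprintf("best: gamma = %g, C = %g, accuracy = %.2f%%\n",
              x$best$gamma, x$best$C, x$best$accuracy))
  invisible(x)
}

#' Grid search across every segment of a scheme
#'
#' @inheritParams grid_search
#' @return an object of class `segment_report`: data.frame with one row
#'   per segment (segment, gamma, C, accuracy) plus the per-segment
#'   `cv_result`s in attribute `results`.
#' @export
segment_sweep <- function(dataset, scheme, grid = param_grid(), period = 5,
                          paired = FALSE, ...) {
  segs <- names(scheme$segments)
  results <- lapply(segs, function(sg)
    grid_search(dataset, scheme, sg, grid = grid, period = period,
                paired = paired, ...))
  names(results) <- segs
  tab <- data.frame(
    segment = segs,
    gamma = vapply(results, function(r) r$best$gamma, numeric(1)),
    C = vapply(results, function(r) r$best$C, numeric(1)),
    accuracy = vapply(results, function(r) r$best$accuracy, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  attr(tab, "results") <- results
  class(tab) <- c("segment_report", "data.frame")
  tab
}

#' @export
print.segment_report <- function(x, ...) {
  cat("Best leave-one-run-out CV cell per segment\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Export a CV accuracy matrix or segment report as delimited text
#' @param x a `cv_result` or `segment_report`.
#' @param path output file.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "cv_result")) {
    df <- as.data.frame(x$accuracy)
    df <- cbind(C = rownames(x$accuracy), df)
    utils::write.csv(df, path, row.names = FALSE)
  } else if (inherits(x, "segment_report")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else stop("unsupported report type")
  invisible(path)
}
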