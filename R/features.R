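#' Named time segments of a sensor response
#'
#' Segments are windows in seconds relative to the start of the chemical
#' introduction phase. The defaults are the five published response
#' segments: Baseline 0--50, Rise 65--85, SteadyState 150--400, Fall
#' 450--500, LateFall 500--600.
#'
#' @param segments named list of numeric length-2 windows `(start, end)`.
#' @return an object of class `segment_scheme`.
#' @export
segment_scheme <- function(segments) {
  stopifnot(is.list(segments), length(segments) >= 1L,
            !is.null(names(segments)), all(nzchar(names(segments))))
  for (nm in names(segments)) {
    w <- segments[[nm]]
    if (!is.numeric(w) || length(w) != 2L || w[1] < 0 || w[1] >= w[2])
      stop(sprintf("segment '%s' must satisfy 0 <= start < end", nm))
  }
  structure(list(segments = lapply(segments, as.numeric)),
            class = "segment_scheme")
}

#' @rdname segment_scheme
#' @export
default_scheme <- function() {
  segment_scheme(list(
    Baseline    = c(0, 50),
    Rise        = c(65, 85),
    SteadyState = c(150, 400),
    Fall        = c(450, 500),
    LateFall    = c(500, 600)
  ))
}

#' Absolute time window of a named segment
#'
#' @param scheme a [segment_scheme()].
#' @param name segment name.
#' @param introduction_time absolute time (s) the chemical was introduced.
#' @return numeric `(start, end)` in absolute run time.
#' @export
segment_window <- function(scheme, name, introduction_time) {
  stopifnot(inherits(scheme, "segment_scheme"))
  w <- scheme$segments[[name]]
  if (is.null(w))
    stop(sprintf("unknown segment '%s' (known: %s)", name,
                 paste(names(scheme$segments), collapse = ", ")))
  introduction_time + w
}

#' Sample fixed-interval feature rows from one run
#'
#' Readings are taken at `start, start + period, ...` up to `end`
#' (inclusive). Each row carries the sensor outputs at that time, the
#' run id, and the run's label encoded +1 (high) / -1 (low). A window may
#' end exactly at the protocol end, where the final grid time has no raw
#' sample (samples live at `0, dt, ..., duration - dt`); such grid points
#' are dropped.
#'
#' @param run a `run_record`.
#' @param window numeric `(start, end)`, absolute seconds.
#' @param period sampling period, seconds (> 0).
#' @return data.frame with columns `run_id`, `t`, `f1`, `f2`, ..., `label`.
#' @export
sample_features <- function(run, window, period) {
  stopifnot(inherits(run, "run_record"))
  if (period <= 0) stop("period must be positive")
  duration <- nrow(run$series) * run$dt
  if (window[1] < 0 || window[2] > duration || window[1] > window[2])
    stop("window lies outside the run")
  grid <- seq(window[1], window[2], by = period)
  idx <- round(grid / run$dt) + 1L
  keep <- idx >= 1L & idx <= nrow(run$series)
  grid <- grid[keep]; idx <- idx[keep]
  x <- run$series[idx, , drop = FALSE]
  out <- data.frame(run_id = run$run_id, t = grid,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(x))) out[[paste0("f", k)]] <- unname(x[, k])
  out$label <- if (run$label == "high") 1 else -1
  out
}

#' Build the design table for one segment across a dataset
#'
#' Concatenates [sample_features()] over all runs; rows keep their
#' `run_id` so cross-validation can split by run.
#'
#' @param dataset list of `run_record`s.
#' @param scheme a [segment_scheme()].
#' @param segment segment name.
#' @param period sampling period, seconds (default 5).
#' @return a `feature_table`: data.frame of feature rows, with a
#'   `scaling` attribute once [fit_scaling()] has been applied.
#' @export
build_design <- function(dataset, scheme, segment, period = 5) {
  if (length(dataset) == 0L) stop("dataset is empty")
  rows <- lapply(dataset, function(r) {
    w <- segment_window(scheme, segment, r$introduction_s)
    sample_features(r, w, period)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("feature_table", "data.frame")
  tab
}

feature_cols <- function(table) {
  grep("^f[0-9]+$", names(table), value = TRUE)
}

#' Min-max feature scaling
#'
#' `fit_scaling()` computes per-feature (min, max) from a training table;
#' `apply_scaling()` maps each feature through
#' `(x - min) / (max - min)`. A degenerate feature (max == min) maps to 0.
#' Values outside the training range scale outside [0, 1]; they are not
#' clipped.
#'
#' @param table a `feature_table`.
#' @param scaling matrix with rows `min` and `max`, one column per feature.
#' @return `fit_scaling`: the scaling matrix. `apply_scaling`: the table
#'   with features scaled and the scaling stored as an attribute.
#' @export
fit_scaling <- function(table) {
  fc <- feature_cols(table)
  if (nrow(table) == 0L || length(fc) == 0L) stop("empty feature table")
  vals <- vapply(fc, function(cn) range(table[[cn]]), numeric(2))
  rownames(vals) <- c("min", "max")
  vals
}

#' @rdname fit_scaling
#' @export
apply_scaling <- function(table, scaling) {
  fc <- feature_cols(table)
  stopifnot(length(fc) == ncol(scaling))
  for (j in seq_along(fc)) {
    lo <- scaling["min", j]; hi <- scaling["max", j]
    table[[fc[j]]] <- if (hi > lo) (table[[fc[j]]] - lo) / (hi - lo)
      else rep(0, nrow(table))
  }
  attr(table, "scaling") <- scaling
  table
}

#' Export a feature table as delimited text
#' @param table a `feature_table`.
#' @param path output file.
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  names(df)[names(df) == "t"] <- "t_s"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
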