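PACK_VERSION <- "breathsvm-1"

#' Pack a trained SVM into a flat deployable layout
#'
#' Flattens a [breath_svm()] model into the fixed-layout container used
#' for constrained-memory deployment: row-major support-vector array,
#' dual coefficients, per-feature scaling bounds, effective kernel width
#' `gamma_eff = gamma / sigma`, and bias. Packing is lossless:
#' `unpack_model(pack_model(m))` reproduces every decision value.
#'
#' @param model a `breath_svm`.
#' @return an object of class `packed_model`.
#' @export
pack_model <- function(model) {
  stopifnot(inherits(model, "breath_svm"))
  dim_m <- ncol(model$scaling)
  structure(
    list(version = PACK_VERSION,
         dim = dim_m,
         n_sv = model$n_sv,
         gamma_eff = model$kernel$gamma / model$kernel$sigma,
         bias = model$bias,
         sv = as.numeric(t(model$support_vectors)),
         coefs = as.numeric(model$dual_coefs),
         scale_min = as.numeric(model$scaling["min", ]),
         scale_max = as.numeric(model$scaling["max", ]),
         label_map = as.list(model$label_map)),
    class = "packed_model"
  )
}

validate_packed <- function(p) {
  need <- c("version", "dim", "n_sv", "gamma_eff", "bias", "sv", "coefs",
            "scale_min", "scale_max", "label_map")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("packed model missing fields: ",
                         paste(miss, collapse = ", "))
  if (length(p$sv) != p$n_sv * p$dim)
    stop(sprintf("sv array has %d values, expected n_sv*dim = %d",
                 length(p$sv), p$n_sv * p$dim))
  if (length(p$coefs) != p$n_sv)
    stop("coefs length inconsistent with n_sv")
  if (length(p$scale_min) != p$dim || length(p$scale_max) != p$dim)
    stop("scaling arrays inconsistent with dim")
  invisible(p)
}

#' @rdname pack_model
#' @param packed a `packed_model`.
#' @export
unpack_model <- function(packed) {
  validate_packed(packed)
  sv <- matrix(packed$sv, ncol = packed$dim, byrow = TRUE)
  scaling <- rbind(min = packed$scale_min, max = packed$scale_max)
  coefs <- as.numeric(packed$coefs)
  structure(
    list(support_vectors = sv,
         dual_coefs = coefs,
         alpha = abs(coefs),
         sv_labels = ifelse(coefs >= 0, 1, -1),
         bias = packed$bias,
         n_sv = packed$n_sv,
         kernel = kernel_params(packed$gamma_eff, 1),
         C = NA_real_, tol = NA_real_, seed = NA_integer_,
         passes = NA_integer_,
         scaling = scaling,
         label_map = unlist(packed$label_map),
         call = NULL),
    class = "breath_svm"
  )
}

#' Write / read a packed model as versioned JSON
#'
#' Values are rendered in decimal with full double precision, so a file
#' round trip preserves decision values.
#'
#' @param packed a `packed_model`.
#' @param path file path.
#' @export
write_packed <- function(packed, path) {
  validate_packed(packed)
  jsonlite::write_json(unclass(packed), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_packed
#' @export
read_packed <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$sv <- as.numeric(p$sv)
  p$coefs <- as.numeric(p$coefs)
  p$scale_min <- as.numeric(p$scale_min)
  p$scale_max <- as.numeric(p$scale_max)
  p$label_map <- as.list(p$label_map)
  class(p) <- "packed_model"
  validate_packed(p)
  p
}

#' @export
print.packed_model <- function(x, ...) {
  cat(sprintf("<packed_model %s> dim=%d n_sv=%d gamma_eff=%g (%d bytes @4B)\n",
              x$version, x$dim, x$n_sv, x$gamma_eff, memory_footprint(x, 4)))
  invisible(x)
}

#' Memory footprint of a packed model
#'
#' `bytes_per_value * (n_sv*dim + n_sv + 2*dim + 2)`: the support-vector
#' array, dual coefficients, the two scaling arrays, gamma_eff and bias.
#'
#' @param packed a `packed_model`.
#' @param bytes_per_value 4 (single precision deployment) or 8.
#' @return bytes.
#' @export
memory_footprint <- function(packed, bytes_per_value = 4) {
  if (!bytes_per_value %in% c(4, 8))
    stop("bytes_per_value must be 4 or 8")
  bytes_per_value *
    (packed$n_sv * packed$dim + packed$n_sv + 2 * packed$dim + 2)
}

fmt9 <- function(x) sprintf("%.9g", x)

#' Emit a static C-array rendering of a packed model
#'
#' Produces self-contained C header text: constant tables for every
#' packed field (9 significant digits, the single-precision deployment
#' assumption) plus a reference decision-function routine. Output is
#' byte-identical for identical models.
#'
#' @param packed a `packed_model`.
#' @return a single character string of C source.
#' @export
emit_source <- function(packed) {
  validate_packed(packed)
  arr <- function(v) paste(fmt9(v), collapse = ", ")
  paste0(
    "/* ", packed$version, " packed RBF-SVM model (generated) */\n",
    "#ifndef BREATHSVM_MODEL_H\n#define BREATHSVM_MODEL_H\n\n",
    "#include <math.h>\n\n",
    sprintf("#define SVM_DIM %d\n", packed$dim),
    sprintf("#define SVM_N_SV %d\n", packed$n_sv),
    sprintf("static const float svm_gamma = %sf;\n", fmt9(packed$gamma_eff)),
    sprintf("static const float svm_bias = %sf;\n", fmt9(packed$bias)),
    sprintf("static const float svm_sv[%d] = {%s};\n",
            max(1L, packed$n_sv * packed$dim), arr(packed$sv)),
    sprintf("static const float svm_coefs[%d] = {%s};\n",
            max(1L, packed$n_sv), arr(packed$coefs)),
    sprintf("static const float svm_scale_min[SVM_DIM] = {%s};\n",
            arr(packed$scale_min)),
    sprintf("static const float svm_scale_max[SVM_DIM] = {%s};\n",
            arr(packed$scale_max)),
    "\n/* decision value for one raw reading; >= 0 means class \"high\" */\n",
    "static float svm_decision(const float *x_raw) {\n",
    "  float xs[SVM_DIM];\n",
    "  int i, j;\n",
    "  for (j = 0; j < SVM_DIM; ++j) {\n",
    "    float span = svm_scale_max[j] - svm_scale_min[j];\n",
    "    xs[j] = span > 0 ? (x_raw[j] - svm_scale_min[j]) / span : 0.0f;\n",
    "  }\n",
    "  float f = svm_bias;\n",
    "  for (i = 0; i < SVM_N_SV; ++i) {\n",
    "    float d2 = 0.0f;\n",
    "    for (j = 0; j < SVM_DIM; ++j) {\n",
    "      float d = xs[j] - svm_sv[i * SVM_DIM + j];\n",
    "      d2 += d * d;\n",
    "    }\n",
    "    f += svm_coefs[i] * expf(-svm_gamma * d2);\n",
    "  }\n",
    "  return f;\n",
    "}\n\n#endif\n"
  )
}

#' Classify a stream of readings one at a time
#'
#' Emulates the on-device loop: readings arrive in time order and each
#' reading falling inside the window on the period grid is scaled,
#' pushed through the decision function, and labeled immediately, with
#' no lookahead and constant memory beyond the model. The per-reading
#' labels are identical to batch classification of the same rows.
#'
#' @param packed a `packed_model` (a `breath_svm` is packed on the fly).
#' @param readings data.frame or matrix with a time column `t` (seconds)
#'   followed by one column per feature, ordered by time.
#' @param window numeric `(start, end)` absolute window, seconds.
#' @param period sampling period, seconds; readings are classified when
#'   `t` lies on `start, start + period, ...` within the window.
#' @return list with `labels` (data.frame `t`, `label`) and `state`, a
#'   `stream_state`: counts per class, running majority, last timestamp.
#' @export
stream_classify <- function(packed, readings, window, period = 5) {
  if (inherits(packed, "breath_svm")) packed <- pack_model(packed)
  validate_packed(packed)
  model <- unpack_model(packed)
  readings <- as.data.frame(readings)
  tcol <- if ("t" %in% names(readings)) "t" else names(readings)[1]
  tv <- readings[[tcol]]
  if (is.unsorted(tv, strictly = FALSE))
    stop("readings must arrive in time order")
  xcols <- setdiff(names(readings), tcol)[seq_len(packed$dim)]

  state <- list(n_seen = 0L, n_classified = 0L,
                counts = c(high = 0L, low = 0L),
                majority = NA_character_, last_t = -Inf)
  on_grid <- function(t) {
    t >= window[1] - 1e-9 && t <= window[2] + 1e-9 &&
      abs((t - window[1]) / period - round((t - window[1]) / period)) < 1e-9
  }
  out_t <- numeric(0); out_lab <- character(0)
  for (i in seq_len(nrow(readings))) {
    t <- tv[i]
    state$n_seen <- state$n_seen + 1L
    state$last_t <- t
    if (!on_grid(t)) next
    x <- as.numeric(readings[i, xcols])
    lab <- classify(model, x)
    state$n_classified <- state$n_classified + 1L
    state$counts[lab] <- state$counts[lab] + 1L
    state$majority <- if (state$counts["high"] >= state$counts["low"])
      "high" else "low"
    out_t <- c(out_t, t); out_lab <- c(out_lab, lab)
  }
  if (state$n_classified == 0L) state$majority <- NA_character_
  class(state) <- "stream_state"
  list(labels = data.frame(t = out_t, label = out_lab,
                           stringsAsFactors = FALSE),
       state = state)
}

#' @export
print.stream_state <- function(x, ...) {
  cat(sprintf("<stream_state> seen=%d classified=%d high=%d low=%d majority=%s\n",
              x$n_seen, x$n_classified, x$counts["high"], x$counts["low"],
              ifelse(is.na(x$majority), "none", x$majority)))
  invisible(x)
}
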