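#' VOC footprint for a blood-glucose class
#'
#' A footprint is the pair of concentration intervals an artificial breath
#' sample is drawn from: acetone in parts-per-million and ethanol in
#' parts-per-billion. The defaults are the published biomarker ranges for
#' low (50--100 mg/dL) and high (180--240 mg/dL) blood glucose: acetone
#' 1--3 ppm vs 5--7 ppm, ethanol 0--20 ppb vs 35--50 ppb.
#'
#' @param label class tag, `"low"` or `"high"`.
#' @param acetone_range numeric length-2, acetone interval in ppm.
#' @param ethanol_range numeric length-2, ethanol interval in ppb.
#' @return an object of class `voc_footprint`.
#' @seealso [default_footprints()], [sample_footprint()]
#' @export
voc_footprint <- function(label, acetone_range, ethanol_range) {
  label <- match.arg(label, c("low", "high"))
  check_range <- function(r, what) {
    if (!is.numeric(r) || length(r) != 2L || anyNA(r))
      stop(sprintf("%s must be a numeric interval of length 2", what))
    if (r[1] < 0 || r[1] > r[2])
      stop(sprintf("%s must satisfy 0 <= lower <= upper", what))
  }
  check_range(acetone_range, "acetone_range")
  check_range(ethanol_range, "ethanol_range")
  structure(
    list(label = label,
         acetone_range = as.numeric(acetone_range),
         ethanol_range = as.numeric(ethanol_range)),
    class = "voc_footprint"
  )
}

#' Default low/high blood-glucose VOC footprints
#'
#' @param mixture if `FALSE`, the ethanol channel is zeroed (acetone-only
#'   experiments); if `"ethanol"`, the acetone channel is zeroed.
#' @return named list with elements `low` and `high`.
#' @export
default_footprints <- function(mixture = TRUE) {
  low  <- voc_footprint("low",  c(1, 3), c(0, 20))
  high <- voc_footprint("high", c(5, 7), c(35, 50))
  if (identical(mixture, FALSE)) {
    low$ethanol_range <- high$ethanol_range <- c(0, 0)
  } else if (identical(mixture, "ethanol")) {
    low$acetone_range <- high$acetone_range <- c(0, 0)
  }
  list(low = low, high = high)
}

#' Timed flow protocol for the three-chamber apparatus
#'
#' Phases are contiguous, non-overlapping intervals with a clean-air flow
#' rate each. The default reproduces the 15-minute chamber schedule:
#' clean 0--300 s at 1.5 L/min, introduce 300--360 s at 0, transport
#' 360--405 s at 0.5, steady 405--720 s at 0, clear 720--900 s at 1.5.
#'
#' @param phases data.frame with columns `name`, `start`, `end` (seconds)
#'   and `flow` (L/min).
#' @return an object of class `flow_protocol`.
#' @export
flow_protocol <- function(phases) {
  stopifnot(is.data.frame(phases),
            all(c("name", "start", "end", "flow") %in% names(phases)))
  phases <- phases[order(phases$start), , drop = FALSE]
  if (any(phases$flow < 0)) stop("flow rates must be >= 0")
  if (any(phases$end <= phases$start)) stop("each phase must have end > start")
  if (nrow(phases) > 1L &&
      any(abs(phases$start[-1L] - phases$end[-nrow(phases)]) > 1e-9))
    stop("phases must be contiguous and non-overlapping")
  rownames(phases) <- NULL
  structure(list(phases = phases), class = "flow_protocol")
}

#' @rdname flow_protocol
#' @export
default_protocol <- function() {
  flow_protocol(data.frame(
    name  = c("clean", "introduce", "transport", "steady", "clear"),
    start = c(0, 300, 360, 405, 720),
    end   = c(300, 360, 405, 720, 900),
    flow  = c(1.5, 0, 0.5, 0, 1.5),
    stringsAsFactors = FALSE
  ))
}

#' Total protocol duration in seconds
#' @param protocol a [flow_protocol()].
#' @export
protocol_duration <- function(protocol) {
  max(protocol$phases$end)
}

#' Start of the chemical-introduction phase
#'
#' Segment windows are defined relative to this instant.
#' @param protocol a [flow_protocol()].
#' @export
introduction_time <- function(protocol) {
  i <- match("introduce", protocol$phases$name)
  if (is.na(i)) stop("protocol has no 'introduce' phase")
  protocol$phases$start[i]
}

#' Metal-oxide sensor specification
#'
#' The simulated sensor output relaxes first-order toward
#' `baseline + sens_acetone * log1p(c_acetone) + sens_ethanol * log1p(c_ethanol)`
#' with time constant `tau_rise` when rising and `tau_fall` when falling,
#' where the concentrations are those in the sensor chamber. `lag` is the
#' evaporation/diffusion delay before the VOC chamber starts to fill after
#' the chemical is introduced (70 s observed in sealed-chamber tests).
#' Independent Gaussian noise of standard deviation `noise_sd` is added to
#' every raw sample. `residual_spike` enables a transient positive
#' excursion at the steady-to-clear boundary emulating residual ethanol
#' carried over from the VOC chamber.
#'
#' @param name sensor id.
#' @param baseline clean-air output level (abstract output units).
#' @param sens_acetone,sens_ethanol response gain per log-concentration
#'   (ppm for acetone, ppb for ethanol).
#' @param tau_rise,tau_fall response time constants, seconds.
#' @param lag evaporation/diffusion delay, seconds.
#' @param noise_sd per-sample Gaussian noise sd, output units.
#' @param residual_spike logical; inject the clear-phase carry-over spike.
#' @return an object of class `sensor_spec`.
#' @export
sensor_spec <- function(name, baseline, sens_acetone, sens_ethanol,
                        tau_rise, tau_fall, lag = 70, noise_sd = 0.05,
                        residual_spike = FALSE) {
  if (tau_rise <= 0 || tau_fall <= 0) stop("tau_rise and tau_fall must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (lag < 0) stop("lag must be >= 0")
  structure(
    list(name = name, baseline = baseline,
         sens_acetone = sens_acetone, sens_ethanol = sens_ethanol,
         tau_rise = tau_rise, tau_fall = tau_fall, lag = lag,
         noise_sd = noise_sd, residual_spike = isTRUE(residual_spike)),
    class = "sensor_spec"
  )
}

#' Default two-sensor array
#'
#' Two cross-sensitive sensors with distinct (acetone, ethanol) gain pairs,
#' so the two classes are separable in the 2-D feature plane.
#'
#' @param noise_sd per-sample noise sd applied to both sensors; 0 gives a
#'   deterministic noiseless simulation.
#' @return list of two [sensor_spec()] objects.
#' @export
default_sensors <- function(noise_sd = 0.05) {
  list(
    sensor_spec("sensor1", baseline = 10, sens_acetone = 8.0,
                sens_ethanol = 1.5, tau_rise = 20, tau_fall = 60,
                noise_sd = noise_sd),
    sensor_spec("sensor2", baseline = 12, sens_acetone = 5.0,
                sens_ethanol = 3.0, tau_rise = 25, tau_fall = 70,
                noise_sd = noise_sd)
  )
}

#' Draw one concentration pair from a footprint
#'
#' Each concentration is drawn uniformly within its interval; the draw is
#' reproducible for a fixed seed.
#'
#' @param footprint a [voc_footprint()].
#' @param seed integer seed.
#' @return named numeric vector `c(acetone = ppm, ethanol = ppb)`.
#' @export
sample_footprint <- function(footprint, seed) {
  stopifnot(inherits(footprint, "voc_footprint"))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  a <- stats::runif(1, footprint$acetone_range[1], footprint$acetone_range[2])
  e <- stats::runif(1, footprint$ethanol_range[1], footprint$ethanol_range[2])
  c(acetone = a, ethanol = e)
}

# Seed handling: save/restore .Random.seed so simulator calls do not
# perturb the caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Advection rate per (L/min) of flow, 1/s. Scales the first-order exchange
# clean air -> VOC chamber -> sensor chamber -> exhaust.
.k_adv <- 0.08
# Evaporation fill rate of the VOC chamber once the lag has elapsed, 1/s.
.k_evap <- 0.05

#' Simulate one labeled sensor-array run
#'
#' Gas transport uses a two-compartment first-order cascade. During the
#' introduce phase, once `lag` seconds have elapsed the VOC chamber fills
#' toward the drawn concentration with rate `0.05` per second; the source
#' stays active until the end of the last transport (flow > 0, pre-clear)
#' phase, when the sample is depleted. Whenever flow is positive, mass is
#' advected down the chain at rate `0.08 * flow` per second: clean air
#' dilutes the VOC chamber and the VOC chamber feeds the sensor chamber,
#' so the clean and clear phases wash both chambers out. With zero flow
#' (introduce, steady) the sensor-chamber concentration is frozen, which
#' produces the steady-state plateau. Both gases follow the same dynamics
#' independently; everything is linear in the drawn concentrations.
#'
#' If the protocol has no positive-flow phase at all, the run is treated
#' as a sealed single-chamber experiment: the sensors sit in the chamber
#' the chemical evaporates into, and respond once the lag elapses.
#'
#' @param protocol a [flow_protocol()].
#' @param sensors list of [sensor_spec()] objects (at least one).
#' @param footprint a [voc_footprint()]; concentrations are drawn from it.
#' @param seed integer seed controlling the concentration draw and noise.
#' @param dt sampling interval, seconds (default 1).
#' @param run_id identifier; defaults to `"run<seed>_<label>"`.
#' @return an object of class `run_record`: list with `run_id`, `label`,
#'   `seed`, `concentrations`, `dt`, `introduction_s`, `time` and `series`
#'   (matrix, one column per sensor).
#' @export
simulate_run <- function(protocol, sensors, footprint, seed, dt = 1,
                         run_id = NULL) {
  stopifnot(inherits(protocol, "flow_protocol"),
            inherits(footprint, "voc_footprint"))
  if (dt <= 0) stop("dt must be positive")
  if (length(sensors) < 1L) stop("at least one sensor is required")
  for (s in sensors) stopifnot(inherits(s, "sensor_spec"))

  old <- local_seed(seed)
  on.exit(restore_seed(old))

  conc <- c(
    acetone = stats::runif(1, footprint$acetone_range[1], footprint$acetone_range[2]),
    ethanol = stats::runif(1, footprint$ethanol_range[1], footprint$ethanol_range[2])
  )

  ph <- protocol$phases
  duration <- protocol_duration(protocol)
  n <- as.integer(round(duration / dt))
  time <- dt * (seq_len(n) - 1L)
  sealed <- all(ph$flow <= 0)

  intro_i <- which(ph$name == "introduce")
  t_fill <- if (length(intro_i)) ph$start[intro_i[1]] else 0
  # source is depleted when the last positive-flow phase before the final
  # clearing phase ends; in a sealed run it never depletes
  flowing <- which(ph$flow > 0)
  t_deplete <- if (sealed) Inf else {
    last_clear <- max(flowing)
    pre_clear <- setdiff(flowing, last_clear)
    if (length(pre_clear)) max(ph$end[pre_clear]) else ph$start[last_clear]
  }

  flow_at <- function(t) {
    i <- findInterval(t, ph$start)
    i <- max(1L, min(i, nrow(ph)))
    ph$flow[i]
  }

  nsens <- length(sensors)
  lags <- vapply(sensors, function(s) s$lag, numeric(1))
  # chamber filling is delayed by the evaporation/diffusion lag; use the
  # first sensor's lag as the apparatus lag (it is a chamber property)
  lag <- lags[1]

  c_voc <- c(acetone = 0, ethanol = 0)
  c_sen <- c(acetone = 0, ethanol = 0)
  conc_series <- matrix(0, nrow = n, ncol = 2,
                        dimnames = list(NULL, c("acetone", "ethanol")))
  for (i in seq_len(n)) {
    t <- time[i]
    fl <- flow_at(t)
    fill <- if (t >= t_fill + lag && t < t_deplete)
      .k_evap * (conc - c_voc) else c(acetone = 0, ethanol = 0)
    adv <- .k_adv * fl
    d_voc <- fill - adv * c_voc
    d_sen <- adv * (c_voc - c_sen)
    c_voc <- pmax(c_voc + dt * d_voc, 0)
    c_sen <- pmax(c_sen + dt * d_sen, 0)
    conc_series[i, ] <- if (sealed) c_voc else c_sen
  }

  clear_i <- which(ph$name == "clear")
  t_clear <- if (length(clear_i)) ph$start[clear_i[1]] else Inf

  series <- matrix(NA_real_, nrow = n, ncol = nsens)
  colnames(series) <- vapply(sensors, function(s) s$name, character(1))
  for (k in seq_len(nsens)) {
    s <- sensors[[k]]
    target <- s$baseline +
      s$sens_acetone * log1p(conc_series[, "acetone"]) +
      s$sens_ethanol * log1p(conc_series[, "ethanol"])
    if (s$residual_spike && is.finite(t_clear)) {
      # carry-over bump: residual ethanol flushed into the sensor chamber
      amp <- 0.5 * s$sens_ethanol * log1p(conc["ethanol"])
      spike <- ifelse(time >= t_clear,
                      amp * exp(-(time - t_clear) / 15), 0)
      target <- target + spike
    }
    y <- numeric(n)
    y[1] <- s$baseline
    for (i in seq_len(n - 1L)) {
      tau <- if (target[i + 1L] >= y[i]) s$tau_rise else s$tau_fall
      y[i + 1L] <- y[i] + dt * (target[i + 1L] - y[i]) / tau
    }
    if (s$noise_sd > 0) y <- y + stats::rnorm(n, 0, s$noise_sd)
    series[, k] <- y
  }
  if (!all(is.finite(series))) stop("simulation produced non-finite output")

  if (is.null(run_id)) run_id <- sprintf("run%d_%s", as.integer(seed), footprint$label)
  structure(
    list(run_id = run_id, label = footprint$label, seed = as.integer(seed),
         concentrations = conc, dt = dt,
         introduction_s = if (length(intro_i)) ph$start[intro_i[1]] else 0,
         time = time, series = series),
    class = "run_record"
  )
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record %s> label=%s  %d samples @ dt=%gs  acetone=%.2f ppm  ethanol=%.1f ppb\n",
              x$run_id, x$label, nrow(x$series), x$dt,
              x$concentrations["acetone"], x$concentrations["ethanol"]))
  invisible(x)
}

#' Plot a simulated run's sensor traces
#' @param x a `run_record`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.run_record <- function(x, ...) {
  graphics::matplot(x$time, x$series, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "sensor output",
                    main = sprintf("%s (%s)", x$run_id, x$label), ...)
  graphics::legend("topright", colnames(x$series), lty = 1,
                   col = seq_len(ncol(x$series)), bty = "n")
  invisible(x)
}

#' Generate a balanced labeled dataset of synthetic runs
#'
#' Produces `n_per_class` low runs followed by `n_per_class` high runs.
#' Per-run seeds are `master_seed + run index` (1-based), so a dataset is
#' reproducible from its master seed alone.
#'
#' @param n_per_class runs per class (>= 1).
#' @param protocol,sensors,footprints simulator configuration;
#'   `footprints` is a list with elements `low` and `high`.
#' @param master_seed integer master seed.
#' @param dt sampling interval, seconds.
#' @return list of `run_record`s, length `2 * n_per_class`.
#' @export
generate_dataset <- function(n_per_class,
                             protocol = default_protocol(),
                             sensors = default_sensors(),
                             footprints = default_footprints(),
                             master_seed = 1, dt = 1) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  stopifnot(all(c("low", "high") %in% names(footprints)))
  runs <- vector("list", 2L * n_per_class)
  idx <- 1L
  for (label in c("low", "high")) {
    fp <- footprints[[label]]
    for (j in seq_len(n_per_class)) {
      seed <- as.integer(master_seed) + idx
      runs[[idx]] <- simulate_run(protocol, sensors, fp, seed = seed, dt = dt,
                                  run_id = sprintf("run%02d_%s", idx, label))
      idx <- idx + 1L
    }
  }
  runs
}

#' Write runs as delimited text files with a JSON manifest
#'
#' One CSV per run with columns `time_s`, then one column per sensor,
#' named `<run_id>_<label>.csv`; labels and provenance go to
#' `manifest.json` in the same directory.
#'
#' @param runs list of `run_record`s.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_runs <- function(runs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(runs))
  meta <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    df <- data.frame(time_s = r$time, r$series, check.names = FALSE)
    paths[i] <- file.path(dir, sprintf("%s.csv", r$run_id))
    utils::write.csv(df, paths[i], row.names = FALSE)
    meta[[i]] <- list(run_id = r$run_id, label = r$label, seed = r$seed,
                      dt = r$dt, introduction_s = r$introduction_s,
                      acetone_ppm = unname(r$concentrations["acetone"]),
                      ethanol_ppb = unname(r$concentrations["ethanol"]),
                      file = basename(paths[i]))
  }
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, file.path(dir, "manifest.json")))
}

#' Read runs written by [write_runs()]
#' @param dir directory containing run CSVs and `manifest.json`.
#' @return list of `run_record`s.
#' @export
read_runs <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  meta <- jsonlite::read_json(mf, simplifyVector = FALSE)
  lapply(meta, function(m) {
    df <- utils::read.csv(file.path(dir, m$file), check.names = FALSE)
    series <- as.matrix(df[, -1, drop = FALSE])
    structure(
      list(run_id = m$run_id, label = m$label, seed = m$seed,
           concentrations = c(acetone = m$acetone_ppm, ethanol = m$ethanol_ppb),
           dt = m$dt, introduction_s = m$introduction_s,
           time = df$time_s, series = series),
      class = "run_record"
    )
  })
}
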