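#' Estimate pump flow rate from dispense measurements
#'
#' The device doses open loop: a step's volume is delivered by running a
#' peristaltic pump for `volume / flow_rate` seconds. The flow rate is
#' calibrated by running the pump for fixed intervals and weighing or reading
#' off the dispensed volume. The default estimator is the mean of the
#' per-measurement ratios `volume / time`, with its sample standard deviation
#' as the dispersion summary; a through-origin least-squares slope is
#' available as an alternative (the dispersion then is still the SD of the
#' per-measurement ratios).
#'
#' @param measurements Data frame with columns `run_time_s` (> 0) and
#'   `volume_ml` (>= 0), one row per dispense measurement.
#' @param method `"ratio"` (default, mean of per-measurement rates) or
#'   `"regression"` (through-origin least squares of volume on time).
#' @param scale_factor Dimensionless multiplier on delivered volume, kept at
#'   1.0 by calibration; see [pump_time_for_volume()].
#' @return A list of class `"tp_pump_calibration"` with `flow_rate` (mL/s),
#'   `flow_rate_sd`, `n_measurements`, `scale_factor` and `method`.
#' @examples
#' m <- data.frame(run_time_s = c(10, 20, 30), volume_ml = c(11, 22, 33))
#' estimate_flow_rate(m)
#' @export
estimate_flow_rate <- function(measurements, method = c("ratio", "regression"),
                               scale_factor = 1.0) {
  method <- match.arg(method)
  stopifnot(is.data.frame(measurements),
            all(c("run_time_s", "volume_ml") %in% names(measurements)))
  t <- as.numeric(measurements$run_time_s)
  v <- as.numeric(measurements$volume_ml)
  if (length(t) == 0L) {
    stop("need at least one dispense measurement", call. = FALSE)
  }
  if (any(!is.finite(t) | t <= 0)) {
    stop("all run times must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(v) | v < 0)) {
    stop("all dispensed volumes must be non-negative and finite",
         call. = FALSE)
  }
  rates <- v / t
  q <- switch(method,
              ratio = mean(rates),
              regression = sum(t * v) / sum(t * t))
  if (q <= 0) {
    stop("estimated flow rate is not positive; check the measurements",
         call. = FALSE)
  }
  pump_calibration(flow_rate = q,
                   flow_rate_sd = if (length(rates) > 1L) stats::sd(rates) else 0,
                   n_measurements = length(rates),
                   scale_factor = scale_factor,
                   method = method)
}

#' Construct a pump calibration directly
#'
#' @param flow_rate Mean flow rate in mL/s, > 0.
#' @param flow_rate_sd Standard deviation of per-measurement rates, >= 0.
#' @param n_measurements Number of measurements behind the estimate.
#' @param scale_factor Dimensionless multiplier on delivered volume, > 0
#'   (default 1.0); adjustable when e.g. a different pump model is fitted.
#' @param method Label of the estimator used.
#' @return A list of class `"tp_pump_calibration"`.
#' @export
pump_calibration <- function(flow_rate, flow_rate_sd = 0, n_measurements = 0L,
                             scale_factor = 1.0, method = "ratio") {
  stopifnot(is.numeric(flow_rate), length(flow_rate) == 1L, flow_rate > 0,
            flow_rate_sd >= 0, scale_factor > 0)
  structure(list(flow_rate = as.numeric(flow_rate),
                 flow_rate_sd = as.numeric(flow_rate_sd),
                 n_measurements = as.integer(n_measurements),
                 scale_factor = as.numeric(scale_factor),
                 method = method),
            class = "tp_pump_calibration")
}

#' @export
print.tp_pump_calibration <- function(x, ...) {
  cat(sprintf("<pump calibration: %.4g +/- %.2g mL/s (n = %d, %s), volume scale %.3g>\n",
              x$flow_rate, x$flow_rate_sd, x$n_measurements, x$method,
              x$scale_factor))
  invisible(x)
}

#' Pump run time needed to deliver a volume
#'
#' `volume * scale_factor / flow_rate`, unrounded; quantization to the
#' controller tick happens only when a schedule is compiled.
#'
#' @param volume_ml Volume to deliver in mL, >= 0 (vectorized).
#' @param calibration A [pump_calibration()].
#' @return Run time(s) in seconds.
#' @examples
#' cal <- pump_calibration(1.10)
#' pump_time_for_volume(250, cal) # ~227 s, about 4 minutes
#' @export
pump_time_for_volume <- function(volume_ml, calibration) {
  stopifnot(inherits(calibration, "tp_pump_calibration"),
            is.numeric(volume_ml))
  if (any(!is.finite(volume_ml) | volume_ml < 0)) {
    stop("volumes must be non-negative and finite", call. = FALSE)
  }
  volume_ml * calibration$scale_factor / calibration$flow_rate
}

#' Read dispense measurements from CSV
#'
#' @param path CSV file with header `run_time_s,volume_ml`.
#' @return Data frame suitable for [estimate_flow_rate()].
#' @export
read_calibration_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("run_time_s", "volume_ml") %in% names(d))) {
    stop("calibration CSV must have columns run_time_s and volume_ml",
         call. = FALSE)
  }
  d[c("run_time_s", "volume_ml")]
}

#' Simulate a pump dispense calibration experiment
#'
#' Emulates the bench calibration: the pump is run for each of `run_times_s`
#' seconds, `replicates` times, and the dispensed volume is recorded. Each
#' measurement's realized flow rate is drawn from a Gaussian around
#' `true_rate` with standard deviation `rate_sd`, mirroring stroke-to-stroke
#' and read-off variability.
#'
#' @param run_times_s Vector of pump activation times (default 8 intervals,
#'   10 to 80 s).
#' @param replicates Measurements per interval (default 3).
#' @param true_rate True mean flow rate in mL/s (default 1.10).
#' @param rate_sd Per-measurement rate standard deviation (default 0.02).
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with columns `run_time_s`, `volume_ml`.
#' @export
simulate_dispense_measurements <- function(run_times_s = seq(10, 80, by = 10),
                                           replicates = 3L,
                                           true_rate = 1.10,
                                           rate_sd = 0.02,
                                           seed = NULL) {
  stopifnot(all(run_times_s > 0), replicates >= 1L, true_rate > 0,
            rate_sd >= 0)
  t <- rep(run_times_s, each = replicates)
  rates <- with_seed(seed, stats::rnorm(length(t), true_rate, rate_sd))
  data.frame(run_time_s = t, volume_ml = pmax(0, rates) * t)
}
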