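#' Compile a routine into a timed actuation schedule
#'
#' Turns each step into the device's cycle: dose the step's blend into the
#' premix container (pumps run sequentially), open the top valve to transfer
#' by gravity, soak for the programmed duration, then open the drain. By
#' default the next step's premix is dosed during the current soak
#' (`config$prefetch`), so the tissue container refills immediately after
#' draining and the tissue is exposed to air only for the drain/refill
#' transition. All times are quantized to the controller tick; the residual
#' dosing volume error from quantization is reported per step.
#'
#' @param routine A [routine()]; must validate against `config`.
#' @param config A [device_config()].
#' @param calibration A [pump_calibration()] converting dose volumes to pump
#'   run times.
#' @return A list of class `"tp_schedule"`: `actions` (data frame with
#'   columns `start_time`, `kind`, `target`, `duration`, `step`), `steps`
#'   (per-step summary with soak windows, dose seconds and quantization
#'   residuals), `dose_plans`, `total_soak_time`, `total_wall_time_estimate`
#'   (seconds), `routine`.
#' @examples
#' sched <- compile_routine(get_routine(builtin_pi_routines(), 2),
#'                          device_config(), pump_calibration(1.10))
#' sched$total_soak_time / 3600  # hours of programmed soak
#' @export
compile_routine <- function(routine, config, calibration) {
  stopifnot(inherits(routine, "tp_routine"),
            inherits(config, "tp_device_config"),
            inherits(calibration, "tp_pump_calibration"))
  report <- validate_routine(routine, config)
  if (!is_valid(report)) {
    stop("routine does not compile:\n  ",
         paste(sprintf("step %s: %s",
                       ifelse(is.na(report$step), "-", report$step),
                       report$message), collapse = "\n  "),
         call. = FALSE)
  }
  tick <- config$controller_tick
  n <- nrow(routine$steps)
  transfer_dur <- quantize(
    config$exchange_volume / config$transfer_flow_rate + config$valve_latency,
    tick)

  plans <- vector("list", n)
  dose_times <- vector("list", n)    # quantized per-stock pump seconds
  dose_dur <- numeric(n)
  residual <- numeric(n)
  for (k in seq_len(n)) {
    plans[[k]] <- blend(routine$steps$concentration[k],
                        config$exchange_volume, config$stocks, calibration)
    tq <- quantize(plans[[k]]$doses$pump_time_s, tick)
    dose_times[[k]] <- tq
    dose_dur[k] <- sum(tq[plans[[k]]$doses$volume_ml > 0])
    residual[k] <- sum((tq - plans[[k]]$doses$pump_time_s) *
                         calibration$flow_rate / calibration$scale_factor)
  }

  soak_s <- routine$steps$duration_min * 60
  feas <- dose_dur + transfer_dur <= soak_s
  if (config$prefetch && any(!feas[-1])) {
    warning("premix for step(s) ",
            paste(which(!feas[-1]) + 1L, collapse = ", "),
            " cannot be dosed and transferred within the preceding soak; ",
            "the refill will be delayed", call. = FALSE)
  }

  actions <- list()
  emit <- function(start, kind, target, duration = NA_real_, step = NA_integer_) {
    actions[[length(actions) + 1L]] <<- data.frame(
      start_time = quantize(start, tick), kind = kind, target = target,
      duration = duration, step = step)
  }
  emit_dose <- function(t0, k) {
    # pumps run one after the other off a shared time base
    doses <- plans[[k]]$doses
    t <- t0
    for (j in seq_len(nrow(doses))) {
      if (doses$volume_ml[j] > 0 && dose_times[[k]][j] > 0) {
        pump <- paste0("pump", doses$pump_id[j])
        emit(t, "pump_on", pump, step = k)
        emit(t + dose_times[[k]][j], "pump_off", pump, step = k)
        t <- t + dose_times[[k]][j]
      }
    }
    t
  }

  soak_start <- soak_end <- drain_close <- numeric(n)
  prev_drain_close <- 0
  prev_soak_start <- 0
  for (k in seq_len(n)) {
    dose_start <- if (k == 1L) 0 else if (config$prefetch) prev_soak_start
      else prev_drain_close
    dose_end <- emit_dose(dose_start, k)
    fill_start <- max(dose_end, prev_drain_close)
    emit(fill_start, "top_valve_open", "top_valve", step = k)
    emit(fill_start + transfer_dur, "top_valve_close", "top_valve", step = k)
    soak_start[k] <- quantize(fill_start + transfer_dur, tick)
    emit(soak_start[k], "soak_wait", "controller", duration = soak_s[k],
         step = k)
    soak_end[k] <- soak_start[k] + soak_s[k]
    emit(soak_end[k], "drain_open", "drain_valve", step = k)
    drain_close[k] <- soak_end[k] + quantize(config$drain_time, tick)
    emit(drain_close[k], "drain_close", "drain_valve", step = k)
    prev_drain_close <- drain_close[k]
    prev_soak_start <- soak_start[k]
  }

  actions <- do.call(rbind, actions)
  actions <- actions[order(actions$start_time,
                           match(actions$kind,
                                 c("pump_off", "drain_close", "top_valve_close",
                                   "pump_on", "top_valve_open", "drain_open",
                                   "soak_wait"))), ]
  rownames(actions) <- NULL

  steps <- data.frame(
    step = seq_len(n),
    target_concentration = routine$steps$concentration,
    duration_min = routine$steps$duration_min,
    dose_time_s = dose_dur,
    quantization_residual_ml = residual,
    soak_start = soak_start,
    soak_end = soak_end,
    premix_ready = feas
  )
  structure(list(actions = actions,
                 steps = steps,
                 dose_plans = plans,
                 total_soak_time = sum(soak_s),
                 total_wall_time_estimate = drain_close[n],
                 routine = routine,
                 config = config,
                 calibration = calibration),
            class = "tp_schedule")
}

#' @export
print.tp_schedule <- function(x, ...) {
  cat(sprintf("<schedule: routine %d \"%s\", %d steps>\n",
              x$routine$id, x$routine$name, nrow(x$steps)))
  cat(sprintf("  total soak %.1f h, estimated wall time %.1f h, %d actions\n",
              x$total_soak_time / 3600, x$total_wall_time_estimate / 3600,
              nrow(x$actions)))
  invisible(x)
}

#' Total solvent consumption of a schedule
#'
#' Sums, per stock, the volume the compiled schedule will draw, so the
#' reservoirs can be loaded with enough solvent before the run (as one would
#' when filling the bottles on the bench).
#'
#' @param schedule A `"tp_schedule"`.
#' @return Named numeric vector of mL per stock.
#' @examples
#' sched <- compile_routine(get_routine(builtin_pi_routines(), 1),
#'                          device_config(), pump_calibration(1.10))
#' required_stock_volumes(sched)
#' @export
required_stock_volumes <- function(schedule) {
  stopifnot(inherits(schedule, "tp_schedule"))
  per_plan <- vapply(schedule$dose_plans, function(p) p$doses$volume_ml,
                     numeric(nrow(schedule$config$stocks)))
  out <- rowSums(per_plan)
  names(out) <- schedule$config$stocks$name
  out
}

#' Print the action timeline of a schedule
#'
#' @param schedule A `"tp_schedule"`.
#' @param max_rows Maximum rows to print (default all).
#' @return The actions data frame, invisibly.
#' @export
schedule_timeline <- function(schedule, max_rows = Inf) {
  stopifnot(inherits(schedule, "tp_schedule"))
  a <- schedule$actions
  shown <- utils::head(a, max_rows)
  cat(sprintf("%10s  %-16s %-12s %8s  %s\n",
              "t (s)", "action", "target", "dur (s)", "step"))
  for (i in seq_len(nrow(shown))) {
    cat(sprintf("%10.1f  %-16s %-12s %8s  %4d\n",
                shown$start_time[i], shown$kind[i], shown$target[i],
                ifelse(is.na(shown$duration[i]), "",
                       sprintf("%.0f", shown$duration[i])),
                shown$step[i]))
  }
  if (nrow(a) > nrow(shown)) cat("  ...", nrow(a) - nrow(shown), "more\n")
  invisible(a)
}
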