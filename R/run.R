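safe_state <- function(device, n_pumps = 3L) {
  for (p in seq_len(n_pumps)) dev_pump_off(device, p)
  dev_top_valve(device, FALSE)
  dev_drain_valve(device, FALSE)
  invisible(device)
}

apply_action <- function(device, kind, target) {
  switch(kind,
         pump_on = dev_pump_on(device, as.integer(sub("pump", "", target))),
         pump_off = dev_pump_off(device, as.integer(sub("pump", "", target))),
         top_valve_open = dev_top_valve(device, TRUE),
         top_valve_close = dev_top_valve(device, FALSE),
         drain_open = dev_drain_valve(device, TRUE),
         drain_close = dev_drain_valve(device, FALSE),
         soak_wait = TRUE,
         stop("unknown action kind: ", kind))
}

#' Execute a compiled schedule against a hardware backend
#'
#' Steps through every scheduled action in order, advancing the backend's
#' clock between actions (the virtual device integrates its mass balance
#' during each advance, so a 10-hour protocol simulates in well under a
#' second). Emits a progress record at the start of every soak with the
#' current step, target concentration, elapsed schedule time and estimated
#' time remaining.
#'
#' Pause, resume and abort — the keypad interventions on the physical device —
#' are injected as timed commands: `commands = data.frame(time = 3600,
#' command = "abort")`. Pausing stops all pumps and closes both valves,
#' freezes the schedule timer, and shifts every remaining action by the pause
#' duration on resume (so interrupted doses deliver their remaining volume).
#' Commands that land after the run has finished are logged as no-ops with a
#' warning. Any actuation failure, or a simulator fault such as a container
#' overflow, halts the run in the safe state: pumps off, both valves closed,
#' keeping the tissue submerged in whatever liquid is present.
#'
#' @param schedule A [compile_routine()] schedule.
#' @param device A hardware backend (see [virtual_device()]).
#' @param commands Optional data frame with columns `time` (seconds, on the
#'   wall clock of the run) and `command` (`"pause"`, `"resume"`, `"abort"`).
#' @return A list of class `"tp_run_log"`: `events` (data frame: `time`,
#'   `type`, `detail`, `step`, container volumes and concentrations),
#'   `status` (`"completed"`, `"aborted"` or `"faulted"`), `final_state`
#'   snapshot, and the schedule.
#' @export
run_schedule <- function(schedule, device, commands = NULL) {
  stopifnot(inherits(schedule, "tp_schedule"))
  if (!is.null(commands)) {
    stopifnot(is.data.frame(commands),
              all(c("time", "command") %in% names(commands)),
              all(commands$command %in% c("pause", "resume", "abort")))
    commands <- commands[order(commands$time), , drop = FALSE]
  } else {
    commands <- data.frame(time = numeric(), command = character())
  }
  actions <- schedule$actions
  n_pumps <- nrow(schedule$config$stocks)
  events <- list()
  t <- 0; shift <- 0; paused <- FALSE; pause_t <- NA_real_
  saved <- NULL
  status <- "completed"
  log_event <- function(type, detail, step = NA_integer_) {
    snap <- dev_snapshot(device)
    events[[length(events) + 1L]] <<- data.frame(
      time = t, type = type, detail = detail, step = step,
      premix_volume = snap$premix$volume,
      premix_concentration = snap$premix$concentration,
      tissue_volume = snap$tissue$volume,
      tissue_concentration = snap$tissue$concentration,
      waste_volume = snap$waste$volume)
  }
  halt <- function(new_status, why) {
    safe_state(device, n_pumps)
    status <<- new_status
    log_event(new_status, why)
  }

  ai <- 1L; ci <- 1L
  log_event("run_start", sprintf("routine %d \"%s\"", schedule$routine$id,
                                 schedule$routine$name))
  while (ai <= nrow(actions) || ci <= nrow(commands)) {
    if (ai > nrow(actions) && !paused) break  # run complete; late commands are no-ops
    t_act <- if (ai <= nrow(actions) && !paused)
      actions$start_time[ai] + shift else Inf
    t_cmd <- if (ci <= nrow(commands)) commands$time[ci] else Inf
    if (is.infinite(t_act) && is.infinite(t_cmd)) break
    t_next <- min(t_act, t_cmd)
    if (t_next > t) {
      dev_advance(device, t_next - t)
      t <- t_next
    }
    if (inherits(device, "virtual_device") && device$fault_flag) {
      halt("faulted", "device fault during advance")
      break
    }
    if (t_cmd <= t_act) {
      cmd <- commands$command[ci]; ci <- ci + 1L
      if (cmd == "abort") {
        halt("aborted", "abort command")
        break
      } else if (cmd == "pause" && !paused) {
        saved <- list(pump_on = if (inherits(device, "virtual_device"))
          device$pump_on else rep(FALSE, n_pumps),
          top = isTRUE(device$top_open), drain = isTRUE(device$drain_open))
        safe_state(device, n_pumps)
        paused <- TRUE; pause_t <- t
        log_event("paused", "run paused; actuators in safe state")
      } else if (cmd == "resume" && paused) {
        shift <- shift + (t - pause_t)
        for (p in which(saved$pump_on)) dev_pump_on(device, p)
        if (saved$top) dev_top_valve(device, TRUE)
        if (saved$drain) dev_drain_valve(device, TRUE)
        paused <- FALSE
        log_event("resumed", sprintf("schedule shifted by %.1f s", t - pause_t))
      } else {
        log_event("command_ignored", paste("no-op command:", cmd))
      }
    } else {
      kind <- actions$kind[ai]; target <- actions$target[ai]
      step <- actions$step[ai]
      ok <- apply_action(device, kind, target)
      log_event(kind, target, step)
      if (kind == "soak_wait") {
        elapsed <- t - shift
        log_event("progress",
                  sprintf("step %d/%d: target %.0f%%, elapsed %.0f s, remaining %.0f s",
                          step, nrow(schedule$steps),
                          schedule$steps$target_concentration[step] * 100,
                          elapsed,
                          schedule$total_wall_time_estimate - elapsed),
                  step)
      }
      ai <- ai + 1L
      if (!isTRUE(ok)) {
        halt("faulted", sprintf("actuation failure: %s %s", kind, target))
        break
      }
      if (inherits(device, "virtual_device") && device$fault_flag) {
        halt("faulted", "device fault")
        break
      }
    }
  }
  if (paused && status == "completed" && ai <= nrow(actions)) {
    # paused with no resume scheduled: the run cannot finish
    status <- "aborted"
    log_event("aborted", "paused with no resume; run finalized in safe state")
  }
  # commands arriving after the run has ended are no-ops
  if (ci <= nrow(commands)) {
    warning("command(s) after run end ignored: ",
            paste(commands$command[ci:nrow(commands)], collapse = ", "),
            call. = FALSE)
    for (j in ci:nrow(commands)) {
      t <- commands$time[j]
      log_event("command_ignored",
                paste("command on finished run:", commands$command[j]))
    }
  }
  if (status == "completed") log_event("run_end", "all steps completed")
  structure(list(events = do.call(rbind, events),
                 status = status,
                 final_state = dev_snapshot(device),
                 schedule = schedule),
            class = "tp_run_log")
}

#' @export
print.tp_run_log <- function(x, ...) {
  cat(sprintf("<run log: %s, %d events, final tissue %.1f mL at %s>\n",
              x$status, nrow(x$events), x$final_state$tissue$volume,
              if (is.na(x$final_state$tissue$concentration)) "-" else
                sprintf("%.1f%%", x$final_state$tissue$concentration * 100)))
  invisible(x)
}

#' Tissue-container concentration at each soak
#'
#' Convenience accessor pulling, per step, the tissue-container ethanol
#' concentration recorded when the soak began.
#'
#' @param run_log A [run_schedule()] log.
#' @return Data frame with columns `step`, `target_concentration`,
#'   `soak_concentration`, `soak_volume`.
#' @export
soak_concentrations <- function(run_log) {
  stopifnot(inherits(run_log, "tp_run_log"))
  ev <- run_log$events
  soaks <- ev[ev$type == "soak_wait", , drop = FALSE]
  data.frame(step = soaks$step,
             target_concentration =
               run_log$schedule$steps$target_concentration[soaks$step],
             soak_concentration = soaks$tissue_concentration,
             soak_volume = soaks$tissue_volume)
}

#' Write a run log as JSON lines
#'
#' @param run_log A [run_schedule()] log.
#' @param path Output file; one JSON object per event.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(run_log, path) {
  stopifnot(inherits(run_log, "tp_run_log"))
  ev <- run_log$events
  lines <- vapply(seq_len(nrow(ev)), function(i) {
    as.character(jsonlite::toJSON(as.list(ev[i, ]), auto_unbox = TRUE,
                                  digits = NA, na = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Replay a run log's actuation events against a fresh backend
#'
#' Re-executes the logged actuation events at their recorded times. On a
#' virtual device created with the same configuration and seed this
#' reproduces the original final state exactly.
#'
#' @param run_log A [run_schedule()] log.
#' @param device A fresh hardware backend.
#' @return A device snapshot after replay.
#' @export
replay_log <- function(run_log, device) {
  stopifnot(inherits(run_log, "tp_run_log"))
  kinds <- c("pump_on", "pump_off", "top_valve_open", "top_valve_close",
             "drain_open", "drain_close")
  ev <- run_log$events
  ev <- ev[ev$type %in% kinds, , drop = FALSE]
  t <- 0
  for (i in seq_len(nrow(ev))) {
    if (ev$time[i] > t) {
      dev_advance(device, ev$time[i] - t)
      t <- ev$time[i]
    }
    apply_action(device, ev$type[i], ev$detail[i])
  }
  end_t <- max(run_log$events$time)
  if (end_t > t) dev_advance(device, end_t - t)
  dev_snapshot(device)
}

#' Flush the system
#'
#' Maintenance utility mirroring the on-device Flush: opens both valves and
#' runs all pumps simultaneously for `duration` seconds to rinse lines and
#' containers, then closes and stops everything. On the virtual device all
#' liquid is routed through to the waste bottle, leaving both containers
#' empty.
#'
#' @param device A hardware backend.
#' @param config A [device_config()].
#' @param duration Seconds, > 0.
#' @return A `"tp_run_log"` with status `"completed"` or `"faulted"`.
#' @export
flush_system <- function(device, config, duration) {
  stopifnot(inherits(config, "tp_device_config"), duration > 0)
  n_pumps <- nrow(config$stocks)
  events <- list()
  t <- 0
  log_event <- function(type, detail) {
    snap <- dev_snapshot(device)
    events[[length(events) + 1L]] <<- data.frame(
      time = t, type = type, detail = detail, step = NA_integer_,
      premix_volume = snap$premix$volume,
      premix_concentration = snap$premix$concentration,
      tissue_volume = snap$tissue$volume,
      tissue_concentration = snap$tissue$concentration,
      waste_volume = snap$waste$volume)
  }
  ok <- TRUE
  ok <- isTRUE(dev_top_valve(device, TRUE)) && ok
  log_event("top_valve_open", "top_valve")
  ok <- isTRUE(dev_drain_valve(device, TRUE)) && ok
  log_event("drain_open", "drain_valve")
  for (p in seq_len(n_pumps)) {
    ok <- isTRUE(dev_pump_on(device, p)) && ok
    log_event("pump_on", paste0("pump", p))
  }
  dev_advance(device, duration)
  t <- duration
  for (p in seq_len(n_pumps)) {
    dev_pump_off(device, p)
    log_event("pump_off", paste0("pump", p))
  }
  dev_top_valve(device, FALSE)
  log_event("top_valve_close", "top_valve")
  dev_drain_valve(device, FALSE)
  log_event("drain_close", "drain_valve")
  status <- if (!ok || (inherits(device, "virtual_device") && device$fault_flag))
    "faulted" else "completed"
  log_event(status, "flush finished")
  structure(list(events = do.call(rbind, events),
                 status = status,
                 final_state = dev_snapshot(device),
                 schedule = NULL),
            class = "tp_run_log")
}
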