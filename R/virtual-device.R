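#' Hardware backend contract
#'
#' The run-time engine talks to hardware through seven S3 generics, so any
#' backend — the built-in simulator or a driver for real relays — can stand
#' behind a run:
#'
#' * `dev_pump_on(device, pump_id)` / `dev_pump_off(device, pump_id)`
#' * `dev_top_valve(device, open)` / `dev_drain_valve(device, open)`
#' * `dev_self_test(device, component)`
#' * `dev_advance(device, dt)` (no-op for real hardware; integrates simulated
#'   time for the virtual device)
#' * `dev_snapshot(device)`
#'
#' Commands are idempotent (opening an open valve is a no-op) and return
#' `TRUE` on success, `FALSE` when the component does not respond;
#' `dev_self_test()` has no lasting side effects.
#'
#' @param device A backend object.
#' @param pump_id Integer pump index.
#' @param open Logical; target valve position.
#' @param component Component id, e.g. `"pump2"`, `"top_valve"`,
#'   `"drain_valve"`, `"keypad"`.
#' @param dt Simulated seconds to integrate.
#' @name hardware_backend
NULL

#' @rdname hardware_backend
#' @export
dev_pump_on <- function(device, pump_id) UseMethod("dev_pump_on")
#' @rdname hardware_backend
#' @export
dev_pump_off <- function(device, pump_id) UseMethod("dev_pump_off")
#' @rdname hardware_backend
#' @export
dev_top_valve <- function(device, open) UseMethod("dev_top_valve")
#' @rdname hardware_backend
#' @export
dev_drain_valve <- function(device, open) UseMethod("dev_drain_valve")
#' @rdname hardware_backend
#' @export
dev_self_test <- function(device, component) UseMethod("dev_self_test")
#' @rdname hardware_backend
#' @export
dev_advance <- function(device, dt) UseMethod("dev_advance")
#' @rdname hardware_backend
#' @export
dev_snapshot <- function(device) UseMethod("dev_snapshot")

#' Create a virtual tissue processor
#'
#' A mass-balance simulator of the two-container flow path: three peristaltic
#' pumps draw from finite stock reservoirs into the premix container, the top
#' ball valve transfers premix to the tissue container by gravity, and the
#' drain valve empties the tissue container into the waste bottle. The premix
#' container mixes perfectly and instantaneously. Volume and ethanol mass are
#' conserved exactly across stocks, containers, waste and any overflow spill.
#'
#' @param config A [device_config()]; supplies stocks, capacities and
#'   transfer/drain flow rates.
#' @param flow_rate Nominal pump flow rate in mL/s applied to every pump
#'   (default 1.10), or a vector with one rate per stock.
#' @param noise_sd Per-pump flow-rate standard deviation in mL/s (default 0);
#'   a realized rate is drawn each time a pump switches on.
#' @param seed Integer seed for the device's private noise stream; runs with
#'   equal seeds and command sequences are identical.
#' @param premix_volume,premix_concentration Initial premix contents.
#' @param tissue_volume,tissue_concentration Initial tissue-container
#'   contents.
#' @return An environment of class `"virtual_device"`.
#' @examples
#' dev <- virtual_device(device_config())
#' dev_pump_on(dev, 3); dev_advance(dev, 10); dev_pump_off(dev, 3)
#' dev_snapshot(dev)$premix
#' @export
virtual_device <- function(config, flow_rate = 1.10, noise_sd = 0,
                           seed = NULL,
                           premix_volume = 0, premix_concentration = 0,
                           tissue_volume = 0, tissue_concentration = 0) {
  stopifnot(inherits(config, "tp_device_config"),
            all(flow_rate > 0), all(noise_sd >= 0))
  n_pumps <- nrow(config$stocks)
  flow_rate <- rep_len(flow_rate, n_pumps)
  noise_sd <- rep_len(noise_sd, n_pumps)
  dev <- new.env(parent = emptyenv())
  dev$config <- config
  dev$time <- 0
  dev$stock_volumes <- rep_len(config$stock_volume, n_pumps)
  names(dev$stock_volumes) <- config$stocks$name
  dev$stock_conc <- config$stocks$concentration
  dev$pump_rate <- flow_rate
  dev$noise_sd <- noise_sd
  dev$pump_on <- rep(FALSE, n_pumps)
  dev$pump_actual <- flow_rate      # realized rate, redrawn at each switch-on
  dev$top_open <- FALSE
  dev$drain_open <- FALSE
  dev$premix <- list(volume = premix_volume,
                     mass = premix_volume * premix_concentration,
                     capacity = config$premix_capacity)
  dev$tissue <- list(volume = tissue_volume,
                     mass = tissue_volume * tissue_concentration,
                     capacity = config$tissue_capacity)
  dev$waste <- list(volume = 0, mass = 0)
  dev$spill <- list(volume = 0, mass = 0)
  dev$faults <- list()
  dev$fault_flag <- FALSE
  dev$stock_warned <- rep(FALSE, n_pumps)
  dev$events <- list()
  dev$initial_volume <- sum(dev$stock_volumes) + premix_volume + tissue_volume
  dev$initial_mass <- sum(dev$stock_volumes * dev$stock_conc) +
    dev$premix$mass + dev$tissue$mass
  dev$rng <- local({
    if (is.null(seed)) seed <- 0L
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    s
  })
  class(dev) <- "virtual_device"
  dev
}

# Draw from the device's private RNG stream without touching the caller's.
device_draw <- function(dev, mean, sd) {
  if (sd <= 0) return(mean)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", dev$rng, globalenv())
  x <- stats::rnorm(1L, mean, sd)
  dev$rng <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  else rm(".Random.seed", envir = globalenv())
  max(x, 0)
}

record_event <- function(dev, type, detail) {
  dev$events[[length(dev$events) + 1L]] <-
    list(time = dev$time, type = type, detail = detail)
  invisible(NULL)
}

component_ids <- function(dev) {
  c(paste0("pump", seq_along(dev$pump_on)), "top_valve", "drain_valve",
    "keypad")
}

fault_of <- function(dev, component) dev$faults[[component]]

is_dead <- function(dev, component) {
  f <- fault_of(dev, component)
  !is.null(f) && f$mode == "dead"
}

rate_multiplier <- function(dev, component) {
  f <- fault_of(dev, component)
  if (!is.null(f) && f$mode == "degraded") f$multiplier else 1
}

#' @export
dev_pump_on.virtual_device <- function(device, pump_id) {
  comp <- paste0("pump", pump_id)
  if (is_dead(device, comp)) {
    record_event(device, "command_failed", paste(comp, "did not respond"))
    return(invisible(FALSE))
  }
  if (!device$pump_on[pump_id]) {
    device$pump_on[pump_id] <- TRUE
    device$pump_actual[pump_id] <-
      device_draw(device, device$pump_rate[pump_id], device$noise_sd[pump_id])
  }
  invisible(TRUE)
}

#' @export
dev_pump_off.virtual_device <- function(device, pump_id) {
  device$pump_on[pump_id] <- FALSE
  invisible(TRUE)
}

#' @export
dev_top_valve.virtual_device <- function(device, open) {
  if (is_dead(device, "top_valve")) {
    record_event(device, "command_failed", "top_valve did not respond")
    return(invisible(FALSE))
  }
  device$top_open <- isTRUE(open)
  invisible(TRUE)
}

#' @export
dev_drain_valve.virtual_device <- function(device, open) {
  if (is_dead(device, "drain_valve")) {
    record_event(device, "command_failed", "drain_valve did not respond")
    return(invisible(FALSE))
  }
  device$drain_open <- isTRUE(open)
  invisible(TRUE)
}

#' @export
dev_self_test.virtual_device <- function(device, component) {
  if (!component %in% component_ids(device)) {
    stop("unknown component: ", component, call. = FALSE)
  }
  f <- fault_of(device, component)
  if (is.null(f)) {
    list(component = component, ok = TRUE, detail = "OK")
  } else if (f$mode == "dead") {
    list(component = component, ok = FALSE, detail = "no response")
  } else {
    list(component = component, ok = FALSE,
         detail = sprintf("degraded (rate x%g)", f$multiplier))
  }
}

# Move `amount` mL at concentration `conc` into a container, spilling any
# excess over capacity as a fault (never silently clipped).
pour_into <- function(dev, which, amount, conc) {
  cont <- dev[[which]]
  room <- cont$capacity - cont$volume
  kept <- min(amount, max(room, 0))
  excess <- amount - kept
  cont$volume <- cont$volume + kept
  cont$mass <- cont$mass + kept * conc
  dev[[which]] <- cont
  if (excess > 1e-9) {
    dev$spill$volume <- dev$spill$volume + excess
    dev$spill$mass <- dev$spill$mass + excess * conc
    if (!dev$fault_flag) {
      dev$fault_flag <- TRUE
      record_event(dev, "fault",
                   sprintf("%s container overflow (%.2f mL spilled)",
                           which, excess))
    }
  }
  invisible(NULL)
}

# One bucket-brigade update over h seconds with the current actuator states:
# stocks -> premix -> tissue -> waste, each transfer clamped by availability.
# Exact whenever no container has simultaneous inflow and outflow (see
# dev_advance).
step_segment <- function(dev, h) {
  cfg <- dev$config
  # pumps -> premix
  active <- which(dev$pump_on)
  for (i in active) {
    rate <- dev$pump_actual[i] * rate_multiplier(dev, paste0("pump", i))
    delta <- min(rate * h, dev$stock_volumes[i])
    if (delta > 0) {
      dev$stock_volumes[i] <- dev$stock_volumes[i] - delta
      pour_into(dev, "premix", delta, dev$stock_conc[i])
    }
    if (dev$stock_volumes[i] <= 1e-9 && !dev$stock_warned[i]) {
      dev$stock_warned[i] <- TRUE
      record_event(dev, "warning",
                   sprintf("stock \"%s\" exhausted; pump %d running dry",
                           cfg$stocks$name[i], i))
    }
  }
  # premix -> tissue (gravity transfer)
  if (dev$top_open && dev$premix$volume > 0) {
    rate <- cfg$transfer_flow_rate * rate_multiplier(dev, "top_valve")
    amt <- min(rate * h, dev$premix$volume)
    conc <- dev$premix$mass / dev$premix$volume
    dev$premix$volume <- dev$premix$volume - amt
    dev$premix$mass <- dev$premix$mass - amt * conc
    if (dev$premix$volume < 1e-12) {   # avoid drift in an emptied container
      dev$premix$volume <- 0; dev$premix$mass <- max(dev$premix$mass, 0)
      if (dev$premix$mass < 1e-12) dev$premix$mass <- 0
    }
    pour_into(dev, "tissue", amt, conc)
  }
  # tissue -> waste (drain); a residual fraction can be configured but the
  # clamp below still drains all drainable liquid given enough open time
  if (dev$drain_open && dev$tissue$volume > 0) {
    rate <- cfg$drain_flow_rate * rate_multiplier(dev, "drain_valve")
    drainable <- dev$tissue$volume * (1 - cfg$residual_fraction)
    amt <- min(rate * h, drainable)
    conc <- dev$tissue$mass / dev$tissue$volume
    dev$tissue$volume <- dev$tissue$volume - amt
    dev$tissue$mass <- dev$tissue$mass - amt * conc
    if (dev$tissue$volume < 1e-12) {
      dev$tissue$volume <- 0
      if (dev$tissue$mass < 1e-12) dev$tissue$mass <- 0
    }
    dev$waste$volume <- dev$waste$volume + amt
    dev$waste$mass <- dev$waste$mass + amt * conc
  }
  dev$time <- dev$time + h
  invisible(NULL)
}

#' @export
dev_advance.virtual_device <- function(device, dt) {
  stopifnot(dt >= 0)
  if (dt == 0) return(invisible(device))
  # Sequential clamped transfers are exact over any horizon as long as no
  # container is filled and emptied at once; when one is (only the flush
  # utility opens a valve while liquid is still arriving), substep at the
  # controller tick so within-substep concentration error stays first-order.
  rem <- dt
  tick <- device$config$controller_tick
  while (rem > 1e-12) {
    pumping <- any(device$pump_on & device$stock_volumes > 0)
    inflow_tissue <- device$top_open &&
      (device$premix$volume > 0 || pumping)
    mixed <- (device$top_open && device$premix$volume > 0 && pumping) ||
      (device$drain_open && device$tissue$volume > 0 && inflow_tissue)
    h <- if (mixed) min(rem, tick) else rem
    step_segment(device, h)
    rem <- rem - h
  }
  invisible(device)
}

#' Inject a component fault into a virtual device
#'
#' @param device A [virtual_device()].
#' @param component One of `"pump1"`..`"pump3"`, `"top_valve"`,
#'   `"drain_valve"`, `"keypad"`.
#' @param mode `"dead"` (component ignores commands and fails self-test) or
#'   `"degraded"` (flow rate multiplied by `multiplier`).
#' @param multiplier Rate multiplier for degraded mode (e.g. 0.5 halves the
#'   flow, doubling the time to move a given volume).
#' @return The device, invisibly.
#' @export
inject_fault <- function(device, component, mode = c("dead", "degraded"),
                         multiplier = 1) {
  stopifnot(inherits(device, "virtual_device"))
  mode <- match.arg(mode)
  if (!component %in% component_ids(device)) {
    stop("unknown component: ", component, " (known: ",
         paste(component_ids(device), collapse = ", "), ")", call. = FALSE)
  }
  stopifnot(multiplier > 0)
  device$faults[[component]] <- list(mode = mode, multiplier = multiplier)
  record_event(device, "fault_injected",
               sprintf("%s: %s%s", component, mode,
                       if (mode == "degraded") sprintf(" x%g", multiplier) else ""))
  invisible(device)
}

#' @export
dev_snapshot.virtual_device <- function(device) {
  conc <- function(cont) if (cont$volume > 1e-12) cont$mass / cont$volume else NA_real_
  structure(list(
    time = device$time,
    premix = list(volume = device$premix$volume,
                  concentration = conc(device$premix)),
    tissue = list(volume = device$tissue$volume,
                  concentration = conc(device$tissue)),
    waste = list(volume = device$waste$volume, mass = device$waste$mass),
    spill = device$spill,
    stock_volumes = device$stock_volumes,
    pump_on = device$pump_on,
    top_open = device$top_open,
    drain_open = device$drain_open,
    faults = names(device$faults),
    fault_flag = device$fault_flag,
    mass_balance = mass_balance(device)
  ), class = "tp_device_snapshot")
}

#' @export
print.tp_device_snapshot <- function(x, ...) {
  fmtc <- function(c) if (is.na(c)) "-" else sprintf("%.1f%%", c * 100)
  cat(sprintf("<device @ t = %.1f s>\n", x$time))
  cat(sprintf("  premix: %.1f mL (%s)   tissue: %.1f mL (%s)   waste: %.1f mL\n",
              x$premix$volume, fmtc(x$premix$concentration),
              x$tissue$volume, fmtc(x$tissue$concentration), x$waste$volume))
  cat(sprintf("  stocks: %s\n",
              paste(sprintf("%s %.0f mL", names(x$stock_volumes),
                            x$stock_volumes), collapse = ", ")))
  cat(sprintf("  pumps on: %s   top valve: %s   drain: %s%s\n",
              paste(which(x$pump_on), collapse = ",") |>
                (\(s) if (nzchar(s)) s else "none")(),
              if (x$top_open) "open" else "closed",
              if (x$drain_open) "open" else "closed",
              if (x$fault_flag) "   [FAULT]" else ""))
  invisible(x)
}

#' Volume and ethanol mass balance of a virtual device
#'
#' Conservation check: everything initially in the stock reservoirs and
#' containers must be accounted for by current stock levels, the two
#' containers, the waste bottle and any overflow spill.
#'
#' @param device A [virtual_device()].
#' @return List with `volume_error` and `ethanol_error` (mL, should be ~0)
#'   plus the current totals.
#' @export
mass_balance <- function(device) {
  stopifnot(inherits(device, "virtual_device"))
  vol_now <- sum(device$stock_volumes) + device$premix$volume +
    device$tissue$volume + device$waste$volume + device$spill$volume
  mass_now <- sum(device$stock_volumes * device$stock_conc) +
    device$premix$mass + device$tissue$mass + device$waste$mass +
    device$spill$mass
  list(volume_initial = device$initial_volume,
       volume_now = vol_now,
       volume_error = vol_now - device$initial_volume,
       ethanol_initial = device$initial_mass,
       ethanol_now = mass_now,
       ethanol_error = mass_now - device$initial_mass)
}

#' Per-component self-test of a device
#'
#' Sequentially tests each pump, both valves and the input device, mirroring
#' the on-device diagnostic that reports e.g. "Pump 1 OK" per component.
#' Report order is deterministic: pumps 1..3, top valve, drain valve, input.
#'
#' @param device A hardware backend.
#' @return Data frame of class `"tp_component_status"` with columns
#'   `component`, `ok`, `detail`.
#' @export
sanity_check <- function(device) {
  comps <- if (inherits(device, "virtual_device")) component_ids(device) else
    c("pump1", "pump2", "pump3", "top_valve", "drain_valve", "keypad")
  rows <- lapply(comps, function(cp) {
    st <- dev_self_test(device, cp)
    data.frame(component = st$component, ok = st$ok, detail = st$detail)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tp_component_status", "data.frame")
  out
}

#' @export
print.tp_component_status <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %s\n", x$component[i],
                if (x$ok[i]) "OK" else paste("FAULT:", x$detail[i])))
  }
  invisible(x)
}
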