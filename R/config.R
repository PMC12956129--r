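#' Define the set of stock solutions
#'
#' @param name Character vector of labels.
#' @param concentration_pct Ethanol concentration of each stock, in percent.
#' @param pump_id Integer pump index feeding each stock (1..n).
#' @return A data frame with columns `name`, `concentration` (fraction) and
#'   `pump_id`, sorted by ascending concentration. Concentrations must be
#'   pairwise distinct.
#' @examples
#' default_stocks()
#' @export
stock_set <- function(name, concentration_pct, pump_id = seq_along(name)) {
  stopifnot(is.character(name),
            length(name) == length(concentration_pct),
            length(name) == length(pump_id))
  conc <- as.numeric(concentration_pct) / 100
  if (any(!is.finite(conc) | conc < 0 | conc > 1)) {
    stop("stock concentrations must be percentages in [0, 100]", call. = FALSE)
  }
  if (anyDuplicated(conc)) {
    stop("stock concentrations must be pairwise distinct", call. = FALSE)
  }
  ord <- order(conc)
  data.frame(name = name[ord], concentration = conc[ord],
             pump_id = as.integer(pump_id)[ord])
}

#' Default stock reservoirs: water, 70% ethanol, absolute ethanol
#'
#' @return A stock set as from [stock_set()].
#' @export
default_stocks <- function() {
  stock_set(c("water", "EtOH70", "EtOH100"), c(0, 70, 100), c(1L, 2L, 3L))
}

#' Device configuration
#'
#' Collects the geometry and actuation timings the scheduler and simulator
#' need. Defaults describe the reference build: a 300 mL tissue container
#' exchanged with 250 mL per step, gravity transfer through the top ball
#' valve, and a servo drain to the waste bottle.
#'
#' @param stocks Stock set from [stock_set()]; default [default_stocks()].
#' @param exchange_volume mL of fresh solution delivered per step (default
#'   250). Must not exceed `tissue_capacity`.
#' @param transfer_flow_rate mL/s of the gravity-driven premix-to-tissue
#'   transfer (default 10; a configuration value, not a measured one).
#' @param drain_flow_rate mL/s through the open drain valve (default 10).
#' @param drain_time Seconds the drain valve is held open per step (default
#'   30, enough to empty `exchange_volume` at `drain_flow_rate` with margin).
#' @param valve_latency Seconds allowed for a valve to actuate (default 2).
#' @param controller_tick Seconds; resolution to which all scheduled times and
#'   pump run times are quantized (default 0.1).
#' @param tissue_capacity,premix_capacity Container capacities in mL
#'   (defaults 300).
#' @param residual_fraction Fraction of the tissue-container volume left
#'   behind by a drain (default 0: complete drain).
#' @param prefetch When `TRUE` (default) the next step's solution is premixed
#'   during the current soak so the container refills right after draining;
#'   `FALSE` schedules strictly serially.
#' @param stock_volume Initial mL in each stock reservoir of a simulated
#'   device (default 1000); a vector gives per-stock loads. Long routines
#'   consume more than 1000 mL of some stocks — size the load with
#'   [required_stock_volumes()] before a run, as one would when filling the
#'   solvent bottles.
#' @return A list of class `"tp_device_config"`.
#' @export
device_config <- function(stocks = default_stocks(),
                          exchange_volume = 250,
                          transfer_flow_rate = 10,
                          drain_flow_rate = 10,
                          drain_time = 30,
                          valve_latency = 2,
                          controller_tick = 0.1,
                          tissue_capacity = 300,
                          premix_capacity = 300,
                          residual_fraction = 0,
                          prefetch = TRUE,
                          stock_volume = 1000) {
  stopifnot(is.data.frame(stocks),
            all(c("name", "concentration", "pump_id") %in% names(stocks)),
            exchange_volume > 0, transfer_flow_rate > 0, drain_flow_rate > 0,
            drain_time > 0, valve_latency >= 0, controller_tick > 0,
            residual_fraction >= 0, residual_fraction < 1,
            is.logical(prefetch), all(stock_volume > 0))
  if (is.unsorted(stocks$concentration, strictly = TRUE)) {
    stop("stocks must be sorted by strictly ascending concentration",
         call. = FALSE)
  }
  if (exchange_volume > tissue_capacity) {
    stop("exchange_volume (", exchange_volume,
         " mL) exceeds tissue container capacity (", tissue_capacity, " mL)",
         call. = FALSE)
  }
  if (exchange_volume > premix_capacity) {
    stop("exchange_volume (", exchange_volume,
         " mL) exceeds premix container capacity (", premix_capacity, " mL)",
         call. = FALSE)
  }
  structure(list(stocks = stocks,
                 exchange_volume = exchange_volume,
                 transfer_flow_rate = transfer_flow_rate,
                 drain_flow_rate = drain_flow_rate,
                 drain_time = drain_time,
                 valve_latency = valve_latency,
                 controller_tick = controller_tick,
                 tissue_capacity = tissue_capacity,
                 premix_capacity = premix_capacity,
                 residual_fraction = residual_fraction,
                 prefetch = prefetch,
                 stock_volume = stock_volume),
            class = "tp_device_config")
}

#' @export
print.tp_device_config <- function(x, ...) {
  cat("<device config>\n")
  cat(sprintf("  exchange volume: %g mL (tissue capacity %g mL)\n",
              x$exchange_volume, x$tissue_capacity))
  cat(sprintf("  transfer %g mL/s, drain %g mL/s for %g s, valve latency %g s, tick %g s\n",
              x$transfer_flow_rate, x$drain_flow_rate, x$drain_time,
              x$valve_latency, x$controller_tick))
  cat(sprintf("  premix %s, residual fraction %g\n",
              if (x$prefetch) "prefetched during previous soak" else "strictly serial",
              x$residual_fraction))
  cat("  stocks:\n")
  print(data.frame(name = x$stocks$name,
                   concentration_pct = x$stocks$concentration * 100,
                   pump_id = x$stocks$pump_id), row.names = FALSE)
  invisible(x)
}

#' Read a device configuration from a YAML or JSON file
#'
#' Recognized keys mirror the [device_config()] arguments; `stocks` is a list
#' of `{name, concentration_pct, pump_id}` records. Unknown keys are ignored.
#'
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @return A `"tp_device_config"`.
#' @export
read_device_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(raw$stocks)) {
    args$stocks <- stock_set(
      name = vapply(raw$stocks, function(s) as.character(s$name), character(1)),
      concentration_pct = vapply(raw$stocks,
                                 function(s) as.numeric(s$concentration_pct),
                                 numeric(1)),
      pump_id = vapply(raw$stocks, function(s) as.integer(s$pump_id),
                       integer(1))
    )
  }
  scalar_keys <- c("exchange_volume", "transfer_flow_rate", "drain_flow_rate",
                   "drain_time", "valve_latency", "controller_tick",
                   "tissue_capacity", "premix_capacity", "residual_fraction",
                   "prefetch", "stock_volume")
  for (k in intersect(scalar_keys, names(raw))) args[[k]] <- raw[[k]]
  do.call(device_config, args)
}
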