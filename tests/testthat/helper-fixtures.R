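# Shared fixtures: a nominal calibration, a provisioned config for full runs,
# and an independent brute-force blending oracle.

cal110 <- function() pump_calibration(1.10)

# Config with reservoirs sized for the given routine (default: enough for
# either builtin PI routine), as one would load the bottles before a run.
provisioned_config <- function(stock_volume = 1500, ...) {
  device_config(stock_volume = stock_volume, ...)
}

# Brute-force blending oracle: search all stock pairs and all volume splits on
# a `grid` mL grid for the split whose mixed concentration is closest to the
# target. Independent of blend()'s closed form.
brute_force_blend <- function(target, total_volume, stocks, grid = 0.1) {
  best <- list(err = Inf)
  n <- nrow(stocks)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      v_j <- seq(0, total_volume, by = grid)
      v_i <- total_volume - v_j
      achieved <- (stocks$concentration[i] * v_i +
                     stocks$concentration[j] * v_j) / total_volume
      k <- which.min(abs(achieved - target))
      if (abs(achieved[k] - target) < best$err) {
        best <- list(err = abs(achieved[k] - target),
                     achieved = achieved[k],
                     volumes = setNames(c(v_i[k], v_j[k]),
                                        stocks$name[c(i, j)]))
      }
    }
  }
  best
}

# Random actuation burst for property tests: issues a random command and
# advances a random dt, n times, against a virtual device.
random_actuation <- function(dev, n, seed) {
  set.seed(seed)
  n_pumps <- length(dev$pump_on)
  for (k in seq_len(n)) {
    cmd <- sample(c("pump_on", "pump_off", "top", "drain", "advance"), 1,
                  prob = c(0.2, 0.2, 0.2, 0.2, 0.2))
    switch(cmd,
           pump_on = dev_pump_on(dev, sample(n_pumps, 1)),
           pump_off = dev_pump_off(dev, sample(n_pumps, 1)),
           top = dev_top_valve(dev, runif(1) < 0.5),
           drain = dev_drain_valve(dev, runif(1) < 0.5),
           advance = dev_advance(dev, runif(1, 0, 30)))
  }
  dev_advance(dev, runif(1, 0, 30))
  dev
}
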