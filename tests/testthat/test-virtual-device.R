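test_that("pumping into the premix container follows perfect mixing", {
  cfg <- device_config()
  # premix preloaded with 100 mL at 70%; pump in 71.43 mL of water
  dev <- virtual_device(cfg, premix_volume = 100, premix_concentration = 0.70)
  dev_pump_on(dev, 1)                       # water
  dev_advance(dev, 71.43 / 1.10)
  dev_pump_off(dev, 1)
  snap <- dev_snapshot(dev)
  expect_equal(snap$premix$volume, 171.43, tolerance = 1e-8)
  expect_equal(snap$premix$concentration, 70 / 171.43, tolerance = 1e-8)

  # single-source fill of an empty container
  dev <- virtual_device(cfg)
  dev_pump_on(dev, 3)                       # absolute ethanol
  dev_advance(dev, 10)
  snap <- dev_snapshot(dev)
  expect_equal(snap$premix$volume, 11.0)
  expect_equal(snap$premix$concentration, 1.00)
})

test_that("advancing with no actuators on changes nothing", {
  dev <- virtual_device(device_config(), premix_volume = 50,
                        premix_concentration = 0.3)
  before <- dev_snapshot(dev)
  dev_advance(dev, 1234)
  after <- dev_snapshot(dev)
  expect_equal(after$premix, before$premix)
  expect_equal(after$tissue, before$tissue)
  expect_equal(after$stock_volumes, before$stock_volumes)
})

test_that("commands are idempotent and snapshots are detached copies", {
  dev <- virtual_device(device_config())
  dev_top_valve(dev, TRUE)
  dev_top_valve(dev, TRUE)
  expect_true(dev$top_open)
  dev_pump_on(dev, 2); dev_pump_on(dev, 2)
  expect_equal(sum(dev$pump_on), 1)
  s1 <- dev_snapshot(dev)
  s2 <- dev_snapshot(dev)
  expect_equal(s1$stock_volumes, s2$stock_volumes)
  dev_advance(dev, 10)
  expect_equal(s1$premix$volume, 0)  # snapshot unaffected by later flow
})

test_that("fault injection drives self-test and flow behaviour", {
  cfg <- device_config()
  dev <- virtual_device(cfg)
  expect_true(all(sanity_check(dev)$ok))
  inject_fault(dev, "pump2", "dead")
  st <- sanity_check(dev)
  expect_false(st$ok[st$component == "pump2"])
  expect_true(all(st$ok[st$component != "pump2"]))
  expect_false(dev_pump_on(dev, 2))
  expect_error(inject_fault(dev, "pump9", "dead"), "unknown component")

  # degraded drain at half rate takes twice the nominal time
  dev <- virtual_device(cfg, tissue_volume = 250, tissue_concentration = 0.5)
  inject_fault(dev, "drain_valve", "degraded", multiplier = 0.5)
  dev_drain_valve(dev, TRUE)
  dev_advance(dev, 250 / cfg$drain_flow_rate)   # nominal emptying time
  expect_equal(dev_snapshot(dev)$tissue$volume, 125)
  dev_advance(dev, 250 / cfg$drain_flow_rate)
  expect_equal(dev_snapshot(dev)$tissue$volume, 0)
})

test_that("sanity check reports all six components in fixed order", {
  st <- sanity_check(virtual_device(device_config()))
  expect_equal(st$component,
               c("pump1", "pump2", "pump3", "top_valve", "drain_valve",
                 "keypad"))
  expect_true(all(st$ok))
  # self test leaves no lasting side effects
  dev <- virtual_device(device_config())
  before <- dev_snapshot(dev)
  invisible(sanity_check(dev))
  expect_equal(dev_snapshot(dev)$stock_volumes, before$stock_volumes)
})

test_that("volume and ethanol mass are conserved under random actuation", {
  for (seed in 1:12) {
    cfg <- device_config(stock_volume = 400)
    dev <- virtual_device(cfg, seed = seed)
    random_actuation(dev, 40, seed = 1000 + seed)
    mb <- mass_balance(dev)
    expect_lt(abs(mb$volume_error), 1e-6)
    expect_lt(abs(mb$ethanol_error), 1e-6)
    # concentrations can never leave the stock range
    snap <- dev_snapshot(dev)
    for (c_now in c(snap$premix$concentration, snap$tissue$concentration)) {
      if (!is.na(c_now)) {
        expect_gte(c_now, min(cfg$stocks$concentration) - 1e-9)
        expect_lte(c_now, max(cfg$stocks$concentration) + 1e-9)
      }
    }
  }
})

test_that("equal seeds and command sequences give identical final states", {
  mk <- function() {
    dev <- virtual_device(device_config(), noise_sd = 0.02, seed = 99)
    random_actuation(dev, 30, seed = 7)
    dev_snapshot(dev)
  }
  a <- mk(); b <- mk()
  expect_equal(a$premix, b$premix)
  expect_equal(a$tissue, b$tissue)
  expect_equal(a$stock_volumes, b$stock_volumes)
  expect_equal(a$waste, b$waste)
})

test_that("pump noise reproduces the calibrated dispense variability", {
  dev <- virtual_device(device_config(stock_volume = 5000),
                        noise_sd = 0.02, seed = 3)
  rates <- replicate(200, {
    v0 <- dev_snapshot(dev)$premix$volume
    dev_pump_on(dev, 1); dev_advance(dev, 10); dev_pump_off(dev, 1)
    v <- dev_snapshot(dev)$premix$volume - v0
    # flush the dispensed aliquot through to waste before the next repeat
    dev_top_valve(dev, TRUE); dev_drain_valve(dev, TRUE)
    dev_advance(dev, 5)
    dev_top_valve(dev, FALSE); dev_drain_valve(dev, FALSE)
    v / 10
  })
  expect_equal(mean(rates), 1.10, tolerance = 0.01)
  expect_gt(sd(rates), 0.015)
  expect_lt(sd(rates), 0.025)
})

test_that("container overflow raises a fault, never silent clipping", {
  cfg <- device_config(premix_capacity = 300, stock_volume = 1000)
  dev <- virtual_device(cfg)
  dev_pump_on(dev, 1)
  dev_advance(dev, 400)   # 440 mL into a 300 mL container
  expect_true(dev$fault_flag)
  snap <- dev_snapshot(dev)
  expect_equal(snap$premix$volume, 300)
  expect_gt(snap$spill$volume, 0)
  expect_lt(abs(mass_balance(dev)$volume_error), 1e-6)
})

test_that("exhausting a stock logs a warning event and the pump runs dry", {
  dev <- virtual_device(device_config(stock_volume = 5))
  dev_pump_on(dev, 1)
  dev_advance(dev, 100)
  snap <- dev_snapshot(dev)
  expect_equal(unname(snap$stock_volumes["water"]), 0)
  expect_equal(snap$premix$volume, 5)
  types <- vapply(dev$events, function(e) e$type, character(1))
  expect_true("warning" %in% types)
})
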