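run_builtin <- function(id, cfg = provisioned_config(), commands = NULL,
                        seed = 1, device = NULL) {
  sched <- compile_routine(get_routine(builtin_pi_routines(), id), cfg,
                           cal110())
  dev <- if (is.null(device)) virtual_device(cfg, seed = seed) else device
  list(log = run_schedule(sched, dev, commands = commands), device = dev,
       schedule = sched)
}

test_that("the dehydration/rehydration series reproduces its concentration ladder", {
  res <- run_builtin(1)
  expect_equal(res$log$status, "completed")
  sc <- soak_concentrations(res$log)
  expect_equal(nrow(sc), 14)
  expect_true(all(abs(sc$soak_concentration - sc$target_concentration) < 0.005))
})

test_that("the post-stain series ends with the tissue in absolute ethanol", {
  res <- run_builtin(2)
  expect_equal(res$log$status, "completed")
  sc <- soak_concentrations(res$log)
  expect_equal(sc$soak_concentration[nrow(sc)], 1.00, tolerance = 1e-6)
})

test_that("the tissue stays submerged through every soak", {
  res <- run_builtin(1)
  sc <- soak_concentrations(res$log)
  # full exchange volume present at each soak, up to pump-time quantization
  expect_true(all(sc$soak_volume >= res$schedule$config$exchange_volume - 0.5))
})

test_that("a completed log contains every scheduled action exactly once and replays", {
  res <- run_builtin(2)
  ev <- res$log$events
  act <- res$schedule$actions
  for (kind in unique(act$kind)) {
    expect_equal(sum(ev$type == kind), sum(act$kind == kind), info = kind)
  }
  fresh <- virtual_device(provisioned_config(), seed = 1)
  replayed <- replay_log(res$log, fresh)
  expect_equal(replayed$tissue, res$log$final_state$tissue)
  expect_equal(replayed$waste, res$log$final_state$waste)
  expect_equal(replayed$stock_volumes, res$log$final_state$stock_volumes)
})

test_that("abort halts the run in the safe state with no later actions", {
  # serial mode so step 4's premix is not legitimately dosed during soak 3
  cfg <- provisioned_config(prefetch = FALSE)
  sched <- compile_routine(get_routine(builtin_pi_routines(), 2), cfg, cal110())
  t_abort <- sched$steps$soak_start[3] + 60    # during step 3's soak
  dev <- virtual_device(cfg, seed = 1)
  log <- run_schedule(sched, dev,
                      commands = data.frame(time = t_abort, command = "abort"))
  expect_equal(log$status, "aborted")
  expect_true(all(log$events$step[!is.na(log$events$step)] <= 3))
  expect_false(log$final_state$top_open)
  expect_false(log$final_state$drain_open)
  expect_false(any(log$final_state$pump_on))
})

test_that("pause and resume preserve the soak schedule and dose volumes", {
  cfg <- provisioned_config()
  sched <- compile_routine(get_routine(builtin_pi_routines(), 2), cfg, cal110())
  # pause mid-soak of step 2 for 500 s
  t_pause <- sched$steps$soak_start[2] + 100
  cmds <- data.frame(time = c(t_pause, t_pause + 500),
                     command = c("pause", "resume"))
  res <- run_builtin(2, cfg, commands = cmds)
  expect_equal(res$log$status, "completed")
  plain <- run_builtin(2, cfg)
  expect_equal(soak_concentrations(res$log)$soak_concentration,
               soak_concentrations(plain$log)$soak_concentration)
  # wall time extended by exactly the pause
  expect_equal(max(res$log$events$time), max(plain$log$events$time) + 500)

  # pause during the very first dose: remaining volume delivered on resume
  cmds <- data.frame(time = c(30, 430), command = c("pause", "resume"))
  res <- run_builtin(2, cfg, commands = cmds)
  expect_equal(res$log$status, "completed")
  sc <- soak_concentrations(res$log)
  expect_gte(sc$soak_volume[1], cfg$exchange_volume - 0.5)
  expect_true(all(abs(sc$soak_concentration - sc$target_concentration) < 0.005))
})

test_that("commands on a finished run are no-ops with a warning", {
  cfg <- provisioned_config()
  sched <- compile_routine(get_routine(builtin_pi_routines(), 2), cfg, cal110())
  late <- sched$total_wall_time_estimate + 1e6
  expect_warning(
    log <- run_schedule(sched, virtual_device(cfg, seed = 1),
                        commands = data.frame(time = late, command = "pause")),
    "after run end")
  expect_equal(log$status, "completed")
  expect_true("command_ignored" %in% log$events$type)
})

test_that("a dead pump faults the run into the safe state", {
  cfg <- provisioned_config()
  sched <- compile_routine(get_routine(builtin_pi_routines(), 2), cfg, cal110())
  dev <- virtual_device(cfg, seed = 1)
  inject_fault(dev, "pump2", "dead")
  log <- run_schedule(sched, dev)
  expect_equal(log$status, "faulted")
  expect_false(log$final_state$top_open)
  expect_false(log$final_state$drain_open)
  expect_false(any(log$final_state$pump_on))
  expect_true(any(grepl("pump2", log$events$detail[log$events$type == "faulted"])))
})

test_that("flush empties both containers and cycles each valve once", {
  cfg <- device_config()
  dev <- virtual_device(cfg, premix_volume = 60, premix_concentration = 0.5,
                        tissue_volume = 40, tissue_concentration = 0.7)
  log <- flush_system(dev, cfg, 60)
  expect_equal(log$status, "completed")
  expect_equal(log$final_state$premix$volume, 0)
  expect_equal(log$final_state$tissue$volume, 0)
  expect_equal(sum(log$events$type == "top_valve_open"), 1)
  expect_equal(sum(log$events$type == "top_valve_close"), 1)
  expect_equal(sum(log$events$type == "drain_open"), 1)
  expect_equal(sum(log$events$type == "drain_close"), 1)
  expect_lt(abs(mass_balance(dev)$volume_error), 1e-6)

  # flush against a dead pump faults but still exits with valves closed
  dev <- virtual_device(cfg, tissue_volume = 100, tissue_concentration = 0)
  inject_fault(dev, "pump1", "dead")
  log <- flush_system(dev, cfg, 60)
  expect_equal(log$status, "faulted")
  expect_false(log$final_state$top_open)
  expect_false(log$final_state$drain_open)
})

test_that("run logs serialize to JSON lines", {
  res <- run_builtin(2)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_run_log(res$log, f)
  lines <- readLines(f)
  expect_equal(length(lines), nrow(res$log$events))
  first <- jsonlite::fromJSON(lines[1])
  expect_equal(first$type, "run_start")
})
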