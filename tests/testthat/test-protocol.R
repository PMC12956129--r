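test_that("builtin PI routines transcribe the reference series", {
  store <- builtin_pi_routines()
  a <- get_routine(store, 1)
  b <- get_routine(store, 2)
  expect_equal(nrow(a$steps), 14)
  expect_equal(nrow(b$steps), 10)
  expect_equal(a$steps$concentration,
               c(50, 70, 85, 95, 100, 100, 95, 85, 70, 50, 30, 15, 0, 0) / 100)
  expect_equal(b$steps$concentration,
               c(0, 0, 15, 30, 50, 70, 85, 95, 100, 100) / 100)
  expect_true(all(a$steps$duration_min == 30))
  expect_true(all(b$steps$duration_min == 30))
  # the full workflow crosses more than 20 sequential exchanges
  expect_gt(nrow(a$steps) + nrow(b$steps), 20)
})

test_that("protocol store round-trips losslessly and writes deterministically", {
  store <- builtin_pi_routines()
  txt <- write_protocol_store(store)
  expect_identical(write_protocol_store(store), txt)  # byte-identical
  back <- read_protocol_store(txt)
  expect_equal(back, store)

  # arbitrary fractional concentrations survive too
  s2 <- protocol_store(list(
    routine(3, "odd one", list(exchange_step(0.333, 12.5),
                               exchange_step(0.07, 1)))))
  expect_equal(read_protocol_store(write_protocol_store(s2)), s2)

  # and via a file on disk
  f <- withr::local_tempfile(fileext = ".json")
  write_protocol_store(store, f)
  expect_equal(read_protocol_store(f), store)

  # empty store stays valid JSON with an empty routine list
  empty <- read_protocol_store(write_protocol_store(protocol_store()))
  expect_length(empty$routines, 0)
})

test_that("reader rejects malformed documents and flags offending entries", {
  txt <- write_protocol_store(builtin_pi_routines())
  expect_error(read_protocol_store(substr(txt, 1, nchar(txt) - 30)),
               "parse error")
  expect_error(read_protocol_store("{\"routines\": []}"), "format_version")
  expect_error(
    read_protocol_store(
      '{"format_version":1,"routines":[{"id":1,"name":"x",
        "steps":[{"concentration_pct":50}]}]}'),
    "step 1 in routine id 1")
  # two routines parse to a store of size 2
  two <- read_protocol_store(
    '{"format_version":1,"routines":[
       {"id":1,"name":"a","steps":[{"concentration_pct":0,"duration_min":5}]},
       {"id":2,"name":"b","steps":[{"concentration_pct":70,"duration_min":5}]}]}')
  expect_length(two$routines, 2)
  # duplicate ids violate the store invariant
  expect_error(
    read_protocol_store(
      '{"format_version":1,"routines":[{"id":1,"name":"a","steps":[]},
                                       {"id":1,"name":"b","steps":[]}]}'),
    "unique")
})

test_that("unknown keys are ignored on read and never emitted on write", {
  txt <- '{"format_version":1,"future_field":true,"routines":[
            {"id":1,"name":"a","vendor_note":"x",
             "steps":[{"concentration_pct":50,"duration_min":30,"color":"red"}]}]}'
  store <- read_protocol_store(txt)
  expect_length(store$routines, 1)
  out <- write_protocol_store(store)
  expect_false(grepl("future_field|vendor_note|color", out))
})

test_that("routine validation is total and reports the spec'd violations", {
  cfg <- device_config()
  store <- builtin_pi_routines()
  expect_true(is_valid(validate_routine(get_routine(store, 2), cfg)))

  # data-frame construction path permits out-of-range values so that files can
  # be inspected rather than rejected outright; validation flags them
  over <- routine(9, "too strong",
                  data.frame(concentration = 1.05, duration_min = 30))
  rep <- validate_routine(over, cfg)
  expect_false(is_valid(rep))
  expect_match(rep$message[1], "unreachable concentration")

  zero <- routine(9, "no soak",
                  data.frame(concentration = 0.5, duration_min = 0))
  rep <- validate_routine(zero, cfg)
  expect_match(rep$message[1], "non-positive duration")

  empty <- routine(9, "empty", list())
  rep <- validate_routine(empty, cfg)
  expect_match(rep$message[1], "empty routine")

  # totality: a badly out-of-range routine still yields a report, not an error
  mess <- routine(9, "mess",
                  data.frame(concentration = c(-1, 2, NA),
                             duration_min = c(-5, Inf, 30)))
  expect_s3_class(validate_routine(mess, cfg), "tp_validation_report")
})

test_that("step and routine constructors enforce their invariants", {
  expect_error(exchange_step(1.2, 30), "\\[0, 1\\]")
  expect_error(exchange_step(0.5, 0), "positive")
  expect_error(exchange_step(0.5, Inf), "positive, finite")
  expect_error(routine(0, "bad id"), "positive integer")
  expect_error(get_routine(builtin_pi_routines(), 99), "no routine")
})
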