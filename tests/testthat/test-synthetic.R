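test_that("a planted 5-hour flight is recovered as exactly one migratory episode", {
  plan <- phases(displacement_m = c(1500, 0, -1500),
                 duration_s = c(3600, 10800, 3600), duty = 0.95)
  spec <- scenario_spec(list(bird_spec("b1", list(
    night_plan("2018-09-20", plan)), latitude = 20)), seed = 21)
  sim <- generate_dataset(spec)
  eps <- extract_flight_episodes(sim$dataset)
  expect_length(eps, 1)
  expect_identical(eps[[1]]$class, "migratory")
})

test_that("a zero-duty spec produces an all-rest dataset without episodes", {
  plan <- phases(0, 18000, duty = 0)
  spec <- scenario_spec(list(bird_spec("b1", list(
    night_plan("2018-09-20", plan)))), rest_duty = 0,
    pressure_noise_sd = 0, seed = 2)
  sim <- generate_dataset(spec)
  expect_true(all(sim$dataset$activity$score == 0))
  expect_length(extract_flight_episodes(sim$dataset), 0)
})

test_that("a planted terminated exploratory flight is found by the detector", {
  plan <- phases(displacement_m = c(600, -600),
                 duration_s = c(2400, 1800), duty = 1)
  spec <- scenario_spec(list(bird_spec("b1", list(
    night_plan("2018-04-14", plan)))), pressure_noise_sd = 0, seed = 5)
  sim <- generate_dataset(spec)
  eps <- extract_flight_episodes(sim$dataset)
  expect_length(eps, 1)
  expect_identical(eps[[1]]$class, "short")
  ev <- detect_terminated_exploratory(eps)
  expect_identical(nrow(ev), 1L)
})

test_that("generation is bit-reproducible under a fixed seed", {
  spec <- demo_scenario(n_birds = 2, noise = 0.5, seed = 77)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_logger_csv(generate_dataset(spec)$dataset, f1)
  write_logger_csv(generate_dataset(spec)$dataset, f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_logger_csv(generate_dataset(spec, seed = 78)$dataset, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_dataset(demo_scenario(n_birds = 1), seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("in-flight activity matches the planted duty cycle", {
  plan <- phases(c(1000, 0, -1000), c(3600, 14400, 3600), duty = 0.8)
  spec <- scenario_spec(list(bird_spec("b1", list(
    night_plan("2018-09-20", plan)), scale_max = 10)), seed = 6)
  sim <- generate_dataset(spec)
  tr <- sim$truth$flights
  act <- sim$dataset$activity
  infl <- act[act$timestamp >= tr$start & act$timestamp <= tr$end, ]
  n <- nrow(infl)
  se <- sqrt(0.8 * 0.2 / (10 * n)) * 10    # binomial s.e. of the mean score
  expect_lt(abs(mean(infl$score) - 8), 4 * se)
})

test_that("both logger scales generate valid scores", {
  for (sc in c(5, 10)) {
    spec <- scenario_spec(list(bird_spec("b1", list(
      night_plan("2018-09-20", phases(c(800, -800), c(3600, 3600)))),
      scale_max = sc)), seed = 3)
    sim <- generate_dataset(spec)
    expect_true(all(sim$dataset$activity$score <= sc))
    expect_identical(unique(sim$dataset$activity$scale_max), as.integer(sc))
  }
})

test_that("infeasible plans fail loudly", {
  expect_error(phases(c(700), c(300)), "ceiling")      # 2.3 m/s sustained
  below <- phases(c(-500, 500), c(1800, 1800))
  spec <- scenario_spec(list(bird_spec("b1", list(
    night_plan("2018-09-20", below)))), seed = 1)
  expect_error(generate_dataset(spec), "below ground")
})

test_that("truth metrics match the dynamics functions on the noiseless path", {
  spec <- demo_scenario(n_birds = 1, noise = 0, seed = 10)
  sim <- generate_dataset(spec)
  tr <- sim$truth
  fid <- tr$flights$flight_id[1]
  ser <- tr$series[[fid]]
  expect_equal(tr$flights$level_fraction[1],
               classify_level_intervals(ser)$level_fraction)
  expect_equal(tr$flights$tortuosity[1],
               vertical_tortuosity(rolling_mean3(ser)))
})
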