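test_that("flight-level rule maps to >=6 of 10 and >=3 of 5", {
  expect_true(is_flight_level(6, 10))
  expect_false(is_flight_level(5, 10))
  expect_true(is_flight_level(3, 5))
  expect_false(is_flight_level(2, 5))
  expect_true(all(is_flight_level(6:10, 10)))
})

test_that("core hours need at least 7 flight-level samples of 12", {
  hour_start <- as.POSIXct("2018-04-14 22:00:00", tz = "UTC")
  mk_hour <- function(n_high) {
    mk_activity(c(rep(9, n_high), rep(0, 12 - n_high)), t0 = hour_start)
  }
  expect_length(find_core_hours(mk_hour(8)), 1)
  expect_length(find_core_hours(mk_hour(7)), 1)
  expect_length(find_core_hours(mk_hour(6)), 0)
  expect_length(find_core_hours(mk_activity(rep(0, 24), t0 = hour_start)), 0)
})

test_that("episodes extend by qualifying pre/post samples and classify by the 3 h rule", {
  # hours 22:00-01:59 all core; 3 qualifying samples in 21:00, 2 in 02:00
  t21 <- as.POSIXct("2018-04-14 21:00:00", tz = "UTC")
  pre_scores <- c(rep(0, 9), rep(8, 3))            # 21:45,21:50,21:55
  core_scores <- rep(8, 48)                        # 4 full hours
  post_scores <- c(rep(8, 2), rep(0, 10))          # 02:00, 02:05
  act <- mk_activity(c(pre_scores, core_scores, post_scores), t0 = t21)
  pres <- data.frame(bird_id = "b1", timestamp = act$timestamp,
                     pressure_hpa = altitude_to_pressure(
                       rep(1000, nrow(act))))
  d <- logger_dataset(activity = act, pressure = pres,
                      latitude = data.frame(bird_id = "b1",
                                            date = as.Date("2018-04-14"),
                                            latitude = 20))
  eps <- extract_flight_episodes(d)
  expect_length(eps, 1)
  e <- eps[[1]]
  expect_equal(e$duration_s, 4 * 3600 + 5 * 300)   # 4 h 25 min
  expect_identical(e$class, "migratory")
  expect_identical(e$n_pre, 3L)
  expect_identical(e$n_post, 2L)
  expect_identical(e$region, "Sahara")
  expect_identical(e$season, "spring")
  expect_equal(nrow(e$altitude), sum(act$timestamp >= e$start &
                                       act$timestamp <= e$end))
})

test_that("a 2-hour episode with quiet neighbours is a short flight", {
  t22 <- as.POSIXct("2018-04-14 22:00:00", tz = "UTC")
  act <- mk_activity(c(rep(0, 12), rep(8, 24), rep(0, 12)),
                     t0 = t22 - 3600)
  d <- logger_dataset(activity = act)
  eps <- extract_flight_episodes(d)
  expect_length(eps, 1)
  expect_equal(eps[[1]]$duration_s, 7200)
  expect_identical(eps[[1]]$class, "short")
  expect_length(extract_flight_episodes(
    logger_dataset(activity = mk_activity(rep(0, 48)))), 0)
})

test_that("regions split at 8 and 38 degrees North", {
  expect_identical(assign_region(45), "Europe")
  expect_identical(assign_region(20), "Sahara")
  expect_identical(assign_region(5), "subSaharan")
  expect_identical(assign_region(c(38, 8)), c("Sahara", "Sahara"))
  expect_identical(assign_region(NA), "unknown")
  expect_error(assign_region(100), "latitude")
})

test_that("season assignment follows the calendar and latitude rules", {
  expect_identical(as.character(assign_season(as.Date("2018-04-14"))),
                   "spring")
  expect_identical(as.character(assign_season(as.Date("2018-08-01"))),
                   "autumn")
  south <- data.frame(date = as.Date("2018-10-15") + (-3:3),
                      latitude = seq(40, 34, by = -1))
  expect_identical(as.character(
    assign_season(as.Date("2018-10-15"), south, rule = "latitude")),
    "autumn")
  north <- data.frame(date = as.Date("2018-10-15") + (-3:3),
                      latitude = seq(10, 16, by = 1))
  expect_identical(as.character(
    assign_season(as.Date("2018-10-15"), north, rule = "latitude")),
    "spring")
  flat <- data.frame(date = as.Date("2018-08-01") + (-3:3), latitude = 12)
  expect_identical(as.character(
    assign_season(as.Date("2018-08-01"), flat, rule = "latitude")),
    "autumn")  # stationary falls back to the calendar rule
})

test_that("planted flights are recovered exactly and episodes never overlap", {
  sim <- generate_dataset(demo_scenario(n_birds = 2, noise = 0), seed = 3)
  eps <- extract_flight_episodes(sim$dataset)
  truth <- sim$truth$flights
  expect_equal(length(eps), nrow(truth))   # recall and precision both 1
  tab <- episode_table(eps)
  for (b in unique(tab$bird_id)) {
    tb <- tab[tab$bird_id == b, ]
    tb <- tb[order(tb$start), ]
    if (nrow(tb) > 1)
      expect_true(all(as.numeric(tb$start[-1]) >=
                        as.numeric(tb$end[-nrow(tb)])))
    for (i in seq_len(nrow(tb))) {
      tr <- truth[truth$bird_id == b, ][i, ]
      expect_lte(abs(as.numeric(tb$start[i]) - as.numeric(tr$start)), 600)
      expect_lte(abs(as.numeric(tb$end[i]) - as.numeric(tr$end)), 600)
    }
  }
  expect_true(all(tab$duration_s[tab$class == "migratory"] > 10800))
  expect_true(all(tab$n_core_hours >= 1))
})
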