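test_that("a climb-then-descend short flight with a 600 m leg is a terminated exploratory", {
  # 40 min up 600 m, 30 min down 600 m: mean |rate| = 1200/4200 s > 0.1
  z <- c(seq(0, 600, by = 75), seq(500, 0, by = -100))
  ep <- mk_episode(z, id = "short1")
  ev <- detect_terminated_exploratory(list(ep))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "terminated")
  expect_false(ev$descent_first)
  expect_gt(ev$leg1_displacement, 500)
  expect_gt(mean_vertical_speed(rolling_mean3(ep$altitude)), 0.1)
})

test_that("sub-threshold climbs and level short flights yield no event", {
  z400 <- c(seq(0, 400, by = 50), seq(350, 0, by = -50))
  expect_identical(nrow(detect_terminated_exploratory(
    list(mk_episode(z400)))), 0L)
  level <- mk_episode(rep(100, 20))
  expect_identical(nrow(detect_terminated_exploratory(list(level))), 0L)
})

test_that("mid-flight to-and-fro movements are detected with leg order", {
  # climb, cruise, descend 700, ascend 800, cruise to the end (> 3 h)
  z <- c(seq(0, 2000, by = 200),            # climb to 2000
         rep(2000, 12),                     # cruise 1 h
         seq(1900, 1300, by = -100),        # -700
         seq(1400, 2100, by = 100),         # +800
         rep(2100, 12))                     # cruise on
  ep <- mk_episode(z, duration_s = 300 * (length(z) - 1), id = "mig1")
  expect_identical(ep$class, "migratory")
  ev <- detect_midflight_exploratory(list(ep))
  expect_identical(nrow(ev), 1L)
  expect_true(ev$descent_first)
  expect_lt(ev$leg1_displacement, -500)
  expect_gt(ev$leg2_displacement, 500)

  # ascent-first variant; cruise wiggles like real pressure data, so the
  # cruise does not merge with the adjacent climbs under the carry rule
  wig <- rep(c(8, -8), 6)
  z2 <- c(seq(0, 2000, by = 200), 2000 + cumsum(wig),
          seq(2075, 2600, by = 75), seq(2500, 2000, by = -100),
          2000 + cumsum(wig), seq(1800, 0, by = -200))
  ev2 <- detect_midflight_exploratory(list(
    mk_episode(z2, duration_s = 300 * (length(z2) - 1), id = "mig2")))
  expect_identical(nrow(ev2), 1L)
  expect_false(ev2$descent_first)
})

test_that("the initial climb and landing descent never form an event pair", {
  z <- c(seq(0, 2000, by = 100), rep(2000, 24), seq(1900, 0, by = -100))
  ep <- mk_episode(z, duration_s = 300 * (length(z) - 1), id = "edges")
  expect_identical(nrow(detect_midflight_exploratory(list(ep))), 0L)
})

test_that("windowed maximum ascent rates match the brute-force maximum", {
  s <- mk_series(c(0, 200, 500, 600))
  expect_equal(max_ascent_rate(s, 300)$max_rate, 1.0)
  expect_equal(max_ascent_rate(s, 1200)$max_rate, 0.5)

  flat <- max_ascent_rate(mk_series(rep(30, 10)), 300)
  expect_equal(flat$max_rate, 0)
  expect_false(flat$passes_filter)

  lone <- max_ascent_rate(mk_series(500), 1200)
  expect_true(is.na(lone$max_rate))
  expect_false(lone$passes_filter)
  # a series shorter than the window still fits inside a single window
  expect_equal(max_ascent_rate(mk_series(c(0, 10)), 1200)$max_rate,
               10 / 1200)

  set.seed(13)
  for (i in 1:100) {
    z <- cumsum(rnorm(sample(5:40, 1), 0, 80))
    t <- t_origin + 300 * (seq_along(z) - 1)
    for (w in c(300, 1200)) {
      got <- max_ascent_rate(altitude_series(t, z), w)$max_rate
      expect_equal(got, brute_max_ascent(as.numeric(t), z, w))
    }
  }
})

test_that("the total-climb filter uses the theoretical benchmark", {
  climb <- mk_series(seq(0, 1500, by = 125))   # total climb 1500 m
  expect_true(max_ascent_rate(climb, 300)$passes_filter)     # > 348 m
  expect_true(max_ascent_rate(climb, 1200)$passes_filter)    # > 1392 m
  small <- mk_series(c(0, 100, 200, 300, 350, 400))
  expect_false(max_ascent_rate(small, 1200)$passes_filter)
})

test_that("descents need 10 min, trimmed endpoints, and an activity mode", {
  # cruise at 2000, linear 400 m descent over 20 min, level afterwards
  z <- c(rep(2000, 4), 1900, 1800, 1700, 1600, rep(1600, 4))
  sm <- rolling_mean3(z)
  ep <- mk_episode(z, id = "d1", scores = rep(9, length(z)))
  seg <- extract_descents(list(ep))
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$mode, "active")
  expect_lt(seg$rate, 0)
  # oracle: trimmed-endpoint rate on the smoothed run
  dz <- diff(sm)
  run <- range(which(dz < 0))
  j0 <- run[1] + 1L; j1 <- run[2]          # run samples run[1]..run[2]+1
  expected <- (sm[j1] - sm[j0]) / (300 * (j1 - j0))
  expect_equal(seg$rate, expected)

  gl <- mk_episode(z, id = "d2",
                   scores = c(rep(9, 3), rep(0, 6), rep(9, 3)))
  sg <- extract_descents(list(gl))
  expect_identical(sg$mode, "glide")

  # a 5-min dip is far below the 10-min minimum
  dip <- mk_episode(c(rep(1000, 5), 800, rep(1000, 5)), id = "d3")
  expect_identical(nrow(extract_descents(list(dip))), 0L)
})

test_that("descent invariants hold on simulated flights", {
  sim <- generate_dataset(demo_scenario(n_birds = 3, noise = 0.4), seed = 8)
  eps <- extract_flight_episodes(sim$dataset)
  seg <- extract_descents(eps)
  if (nrow(seg)) {
    expect_true(all(seg$rate < 0))
    expect_true(all(seg$duration_s >= 600))
  }
  ev <- rbind(detect_terminated_exploratory(eps),
              detect_midflight_exploratory(eps))
  if (nrow(ev)) {
    expect_true(all(abs(ev$leg1_displacement) >= 500 |
                      abs(ev$leg2_displacement) >= 500))
  }
})

test_that("glide sink rates planted from the polar are recovered", {
  # glide at best glide: sink 10/11 m/s -> 272.7 m per 5 min, duty 0
  sink <- -glide_sink_rate(10, 11)
  drop_5min <- sink * 300
  z <- c(rep(3000, 4), 3000 - drop_5min * (1:10),
         rep(3000 - drop_5min * 10, 4))
  scores <- c(rep(9, 4), rep(0, 10), rep(9, 4))
  ep <- mk_episode(z, id = "g1", scores = scores)
  seg <- extract_descents(list(ep))
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$mode, "glide")
  # discretisation error of the 5-min grid plus 3-point smoothing
  expect_lt(abs(seg$rate - (-sink)), 0.1)
})
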