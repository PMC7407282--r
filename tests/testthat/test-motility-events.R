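test_that("constant series yields no events; bad input errors", {
  hs <- haustral_series(matrix(10, nrow = 2, ncol = 120), c(2, 4))
  expect_equal(nrow(detect_contraction_events(hs)), 0)
  expect_error(haustral_series(matrix(-1, 1, 120), 2), "positive")
})

test_that("a clean trapezoidal contraction is measured exactly", {
  hs <- trapezoid_series(baseline = 10, minimum = 6, onset = 30,
                         t_c = 2, t_r = 8)
  ev <- detect_contraction_events(hs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$occlusion_degree, 40)
  expect_equal(ev$occlusion_velocity, 2)     # (10 - 6) cm over 2 s
  expect_equal(ev$t_c, 2)
  expect_equal(ev$t_r, 8)
  expect_equal(ev$t_r / ev$t_c, 4)
})

test_that("occlusion degree is invariant to uniform rescaling", {
  hs <- trapezoid_series()
  hs2 <- haustral_series(hs$values * 3.7, hs$positions,
                         mode = hs$mode, dt = hs$dt)
  ev <- detect_contraction_events(hs)
  ev2 <- detect_contraction_events(hs2)
  expect_equal(ev2$occlusion_degree, ev$occlusion_degree)
  expect_equal(ev2$t_c, ev$t_c)
  expect_equal(ev2$t_r, ev$t_r)
})

test_that("time-mirrored events swap contraction and relaxation limbs", {
  hs <- trapezoid_series(t_c = 3, t_r = 9, onset = 30)
  mirrored <- haustral_series(hs$values[, ncol(hs$values):1, drop = FALSE],
                              hs$positions, mode = hs$mode, dt = hs$dt)
  ev <- detect_contraction_events(hs)
  evm <- detect_contraction_events(mirrored)
  expect_equal(evm$t_c, ev$t_r)
  expect_equal(evm$t_r, ev$t_c)
  expect_equal(evm$occlusion_degree, ev$occlusion_degree)
})

test_that("population occlusion degrees are recovered from synthetic data", {
  set.seed(99)
  true_deg <- pmin(pmax(stats::rnorm(10, 59, 18), 20), 90)
  vals <- matrix(10, nrow = 10, ncol = 120)
  for (h in 1:10) {
    depth <- 10 * true_deg[h] / 100
    onset <- 20 + 3 * h
    for (i in 1:120) {
      tt <- (i - 1) - onset
      if (tt >= 0 && tt < 5) vals[h, i] <- 10 - depth * tt / 5
      else if (tt >= 5 && tt < 7) vals[h, i] <- 10 - depth
      else if (tt >= 7 && tt < 22)
        vals[h, i] <- 10 - depth * (22 - tt) / 15
    }
  }
  vals <- pmax(vals + stats::rnorm(length(vals), sd = 0.1), 0.3)
  hs <- haustral_series(vals, seq(1.25, by = 2.5, length.out = 10))
  ev <- detect_contraction_events(hs)
  expect_equal(nrow(ev), 10)
  expect_lt(abs(mean(ev$occlusion_degree) - mean(true_deg)), 5)
})

test_that("timing ratio matches the in vivo contraction/relaxation means", {
  ev <- data.frame(t_c = c(8.64, 8.64), t_r = c(33, 33))
  expect_equal(round(relaxation_contraction_ratio(ev), 2), 3.82)
  expect_equal(relaxation_contraction_ratio(data.frame(t_c = 5, t_r = 5)),
               1.0)
  expect_equal(relaxation_contraction_ratio(data.frame(t_c = 2, t_r = 8)),
               4.0)
  expect_error(relaxation_contraction_ratio(data.frame()), "no events")
})

test_that("wave linking chains adjacent events with ordered onsets", {
  ev <- data.frame(haustrum = 1:5, position_cm = c(0, 2, 4, 6, 8),
                   onset = 0:4, end = 10:14,
                   occlusion_degree = 40, t_c = 2, t_r = 8)
  lw <- link_waves(ev)
  expect_equal(nrow(lw$waves), 1)
  expect_equal(lw$waves$direction, "antegrade")
  expect_equal(lw$waves$travel_distance, 8)
  expect_equal(lw$waves$travel_velocity, 2)
  expect_equal(nrow(lw$isolated), 0)

  ev_r <- ev
  ev_r$onset <- 4:0
  lw_r <- link_waves(ev_r)
  expect_equal(lw_r$waves$direction, "retrograde")
  expect_equal(lw_r$waves$travel_velocity, 2)

  single <- ev[1, ]
  lw_s <- link_waves(single)
  expect_equal(nrow(lw_s$waves), 0)
  expect_equal(nrow(lw_s$isolated), 1)

  # onset lags beyond the cap break the chain
  ev_far <- ev
  ev_far$onset <- c(0, 1, 2, 40, 41)
  lw_f <- link_waves(ev_far)
  expect_equal(max(lw_f$waves$n_events), 3)
})

test_that("linked waves never exceed the physically possible velocity", {
  set.seed(5)
  for (rep in 1:10) {
    hs <- simulate_haustral_series(
      data.frame(direction = sample(c("antegrade", "retrograde"), 1),
                 velocity_cm_s = stats::runif(1, 0.5, 4),
                 occlusion_pct = stats::runif(1, 25, 60), onset = 5),
      seed = rep)
    ev <- detect_contraction_events(hs)
    lw <- link_waves(ev, hs)
    if (NROW(lw$waves)) {
      vmax <- diff(range(hs$positions)) / hs$dt
      expect_true(all(lw$waves$travel_velocity <= vmax))
    }
  }
})

test_that("fold changes reproduce the stimulated/baseline ratios", {
  fc <- fold_change_summary(c(travel_velocity = 0.98,
                              travel_distance = 3.9),
                            c(travel_velocity = 2.2,
                              travel_distance = 5.3))
  expect_equal(round(fc[["travel_velocity"]], 1), 2.2)
  expect_equal(round(fc[["travel_distance"]], 2), 1.36)
  expect_equal(unname(fold_change_summary(c(a = 2), c(a = 2))), 1)
  expect_error(fold_change_summary(c(a = 0), c(a = 1)), "zero baseline")
})

test_that("in vivo motility index delegates to the binned formula", {
  # whole colon active for 20 s, then one segment for 20 s -> 120
  pos <- seq(1.25, by = 2.5, length.out = 10)
  ev <- data.frame(haustrum = c(1:10, 1),
                   position_cm = c(pos, pos[1]),
                   onset = c(rep(0, 10), 20),
                   end = c(rep(20, 10), 40))
  hs <- haustral_series(matrix(10, 10, 120), pos)
  expect_equal(in_vivo_motility_index(ev, hs), 120)
  expect_equal(in_vivo_motility_index(ev[0, ], hs), 0)
})

test_that("event-based motility index equals the integral oracle", {
  set.seed(21)
  pos <- seq(1.25, by = 2.5, length.out = 10)
  hs <- haustral_series(matrix(10, 10, 120), pos)
  brks <- seq(min(pos), max(pos), length.out = 6)
  for (rep in 1:5) {
    k <- sample(3:12, 1)
    ev <- data.frame(haustrum = sample(1:10, k, replace = TRUE))
    ev$position_cm <- pos[ev$haustrum]
    ev$onset <- stats::runif(k, 0, 100)
    ev$end <- pmin(ev$onset + stats::runif(k, 2, 30), 120)
    seg <- pmin(findInterval(ev$position_cm, brks,
                             rightmost.closed = TRUE), 5)
    act <- lapply(1:5, function(s) {
      r <- ev[seg == s, , drop = FALSE]
      if (!NROW(r)) NULL else cbind(r$onset, r$end)
    })
    expect_equal(in_vivo_motility_index(ev, hs),
                 oracle_motility_index(act), tolerance = 0.05)
  }
})

test_that("haustral series round-trip through delimited text", {
  hs <- simulate_haustral_series(
    data.frame(direction = "antegrade", velocity_cm_s = 2,
               occlusion_pct = 40, onset = 10), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(time = hs$time, t(hs$values))
  names(d) <- c("time", sprintf("h%d@%.2f", seq_along(hs$positions),
                                hs$positions))
  utils::write.csv(d, path, row.names = FALSE)
  back <- read_haustral_series(path)
  expect_equal(back$values, hs$values, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$positions, hs$positions, tolerance = 1e-6)
})
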