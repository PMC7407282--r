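test_that("Savitzky-Golay smoothing preserves quadratics, damps noise", {
  t <- seq(0, 10, by = 0.25)
  quad <- 0.01 + 0.002 * t + 0.0005 * t^2
  tr <- trajectory(t, quad, quad / 2, -quad)
  sm <- smooth_track(tr)
  expect_equal(sm$x, quad, tolerance = 1e-10)
  expect_equal(sm$y, quad / 2, tolerance = 1e-10)
  expect_equal(sm$z, -quad, tolerance = 1e-10)
  expect_equal(sm$t, t)

  set.seed(3)
  noisy <- trajectory(t, 0.05 + stats::rnorm(length(t), sd = 5e-4))
  smn <- smooth_track(noisy)
  expect_lt(stats::sd(smn$x), 5e-4 / 2)

  expect_error(smooth_track(trajectory(1:5, 1:5)), "smaller window")
  expect_error(smooth_track(tr, window = 10), "odd")
})

test_that("registration recovers translation offsets", {
  t <- seq(0, 30, by = 0.25)
  x <- c(rep(0, 20), seq(0, 0.19, length.out = length(t) - 20))
  base <- trajectory(t, x, rep(0, length(t)), rep(0, length(t)))
  reg0 <- register_track(base)
  expect_equal(unname(attr(reg0, "offsets")), c(0, 0, 0))

  shifted <- trajectory(t, x + 0.004, rep(-0.002, length(t)),
                        rep(0.001, length(t)))
  reg <- register_track(shifted)
  expect_equal(unname(attr(reg, "offsets")), c(0.004, -0.002, 0.001))
  expect_equal(reg$x, x, tolerance = 1e-12)
  expect_null(attr(reg, "registration_warning"))

  # an unstable dwell leaves a registration warning on the track
  bad <- trajectory(t, x + c(0.01, -0.01, 0.005, -0.005, 0, x[-(1:5)] * 0))
  expect_false(is.null(attr(register_track(bad), "registration_warning")))
})

test_that("pass segmentation finds complete and incomplete passes", {
  geo <- tube_geometry()
  t <- seq(0, 50, by = 0.25)
  full <- trajectory(t, seq(0, 0.20, length.out = length(t)))
  p <- segment_passes(full, geo)
  expect_length(p, 1)
  expect_true(p[[1]]$complete)

  short <- trajectory(t, seq(0, 0.15, length.out = length(t)))
  ps <- segment_passes(short, geo)
  expect_length(ps, 1)
  expect_false(ps[[1]]$complete)

  # three concatenated passes with manual resets
  one <- seq(0.005, 0.195, length.out = 80)
  x3 <- c(one, one, one)
  t3 <- seq_along(x3) * 0.25
  p3 <- segment_passes(trajectory(t3, x3), geo)
  expect_length(p3, 3)
  expect_true(all(vapply(p3, `[[`, TRUE, "complete")))
})

test_that("displacement detection matches the hand-traced examples", {
  t <- seq(0, 5, by = 0.25)
  adv <- trajectory(t, seq(0, 0.05, length.out = length(t)))
  d <- detect_propulsive_displacements(adv)
  expect_equal(nrow(d), 1)
  expect_equal(d$dx, 0.05, tolerance = 1e-9)
  expect_equal(d$U_x, 0.01, tolerance = 1e-9)   # 1 cm/s
  expect_equal(d$direction, "antegrade")

  # oscillation below the 10 mm rule
  osc <- trajectory(seq(0, 20, by = 0.25),
                    0.004 * sin(seq(0, 6 * pi, length.out = 81)))
  expect_equal(nrow(detect_propulsive_displacements(osc)), 0)

  # advance 30 mm then retreat 15 mm
  x <- c(seq(0, 0.030, length.out = 30), seq(0.030, 0.015,
                                             length.out = 15)[-1])
  ar <- trajectory(seq_along(x) * 0.25, x)
  d2 <- detect_propulsive_displacements(ar)
  expect_equal(nrow(d2), 2)
  expect_equal(d2$dx, c(0.030, -0.015), tolerance = 1e-9)
  expect_equal(d2$direction, c("antegrade", "retrograde"))
})

test_that("displacement detection equals the brute-force oracle", {
  set.seed(17)
  for (rep in 1:100) {
    tr <- random_track(sample(30:200, 1))
    got <- detect_propulsive_displacements(tr)
    want <- oracle_displacements(tr)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$dx, want$dx, tolerance = 1e-12)
      expect_equal(got$dt, want$dt, tolerance = 1e-12)
    }
  }
})

test_that("displacement detection is translation-invariant and mirror-equivariant", {
  set.seed(29)
  for (rep in 1:10) {
    tr <- random_track(150)
    d0 <- detect_propulsive_displacements(tr)
    shift <- tr; shift$x <- shift$x + 0.123
    d1 <- detect_propulsive_displacements(shift)
    expect_equal(d1$dx, d0$dx, tolerance = 1e-12)
    mirror <- tr; mirror$x <- 0.2 - mirror$x
    d2 <- detect_propulsive_displacements(mirror)
    expect_equal(sort(d2$dx), sort(-d0$dx), tolerance = 1e-12)
  }
})

test_that("no displacement velocity exceeds the peak instantaneous speed", {
  set.seed(31)
  for (rep in 1:10) {
    tr <- random_track(200)
    d <- detect_propulsive_displacements(tr)
    if (nrow(d)) {
      vmax <- max(abs(diff(tr$x) / diff(tr$t)))
      expect_true(all(abs(d$U_x) <= vmax + 1e-12))
    }
  }
})

test_that("residence times integrate to the pass duration", {
  geo <- tube_geometry()
  # constant 1 cm/s through the tube: 2 s per 2 cm unit
  t <- seq(0, 20, by = 0.05)
  tr <- trajectory(t, 0.01 * t)
  rt <- residence_times(tr, geo)
  expect_equal(rt$residence_s, rep(2, 10), tolerance = 0.06)
  expect_equal(sum(rt$residence_s), max(t) - min(t))

  # never leaving unit 1
  tr1 <- trajectory(seq(0, 60, by = 0.25), rep(0.01, 241))
  rt1 <- residence_times(tr1, geo)
  expect_equal(rt1$residence_s[1], 60)
  expect_equal(sum(rt1$residence_s[-1]), 0)

  # conservation on random tracks
  set.seed(13)
  for (rep in 1:10) {
    tr <- random_track(100)
    tr$x <- pmin(pmax(tr$x + 0.1, 0), 0.2)
    rt <- residence_times(tr, geo)
    expect_equal(sum(rt$residence_s), max(tr$t) - min(tr$t))
  }
})

test_that("occupancy density is a normalised cross-section histogram", {
  single <- trajectory(c(0, 1), c(0, 0), c(0.0005, 0.0005),
                       c(-0.0005, -0.0005))
  occ <- occupancy_density(list(single))
  expect_equal(sum(occ$density), 1, tolerance = 1e-12)
  expect_equal(sum(occ$density > 0), 1)

  set.seed(7)
  n <- 4000
  cloud <- trajectory(seq_len(n) * 0.25, rep(0, n),
                      stats::runif(n, -0.01, 0.01),
                      stats::runif(n, -0.01, 0.01))
  occ2 <- occupancy_density(list(cloud), bin = 0.005)
  expect_equal(sum(occ2$density), 1, tolerance = 1e-12)
  counts <- occ2$density * n
  inner <- counts[counts > 0]
  chi2 <- sum((inner - mean(inner))^2 / mean(inner))
  expect_lt(chi2, 2 * length(inner) + 6 * sqrt(2 * length(inner)))
  expect_error(occupancy_density(list()), "no passes")
})

test_that("distance-velocity histogram bins signed velocities", {
  d <- data.frame(dx = 0.05, dt = 5, U_x = 0.01,
                  direction = "antegrade", t_start = 0, t_end = 5)
  h <- distance_velocity_histogram(d)
  expect_equal(h$velocity_cm_s, 1.0)
  expect_equal(h$distance_cm, 5)

  d2 <- rbind(d, within(d, {dx <- -dx; U_x <- -U_x
                            direction <- "retrograde"}))
  h2 <- distance_velocity_histogram(d2)
  expect_equal(sort(h2$velocity_cm_s), c(-1, 1))
  expect_equal(h2$distance_cm, c(5, 5))
})

test_that("tracks round-trip through delimited text in m and mm", {
  t <- seq(0, 5, by = 0.25)
  tr <- trajectory(t, seq(0, 0.1, length.out = length(t)),
                   rep(0.001, length(t)), rep(-0.002, length(t)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_track(tr, path)
  back <- read_track(path)
  expect_equal(back$x, tr$x)
  # a millimetre file read with the units flag
  d <- utils::read.csv(path)
  d[, c("x", "y", "z")] <- d[, c("x", "y", "z")] * 1000
  utils::write.csv(d, path, row.names = FALSE)
  backmm <- read_track(path, units = "mm")
  expect_equal(backmm$x, tr$x, tolerance = 1e-12)
})
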