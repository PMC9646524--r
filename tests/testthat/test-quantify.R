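test_that("lamella growth is area gained per previous perimeter", {
  flat <- data.frame(t_s = 0:3, area_um2 = rep(100, 4),
                     perimeter_um = rep(40, 4))
  expect_equal(lamella_growth(flat), rep(0, 3))
  # circle growing from r = 10 to r = 10.1 in one frame
  circ <- data.frame(t_s = 0:1, area_um2 = pi * c(10, 10.1)^2,
                     perimeter_um = 2 * pi * c(10, 10.1))
  expect_equal(lamella_growth(circ), 0.1005, tolerance = 1e-6)
  shrink <- data.frame(t_s = 0:1, area_um2 = c(100, 90),
                       perimeter_um = c(40, 39))
  expect_lt(lamella_growth(shrink), 0)
  expect_error(lamella_growth(flat[1, ]), "at least 2")
  flat$perimeter_um[1] <- 0
  expect_error(lamella_growth(flat), "positive")
})

test_that("stack volume integrates slice areas trapezoidally", {
  empty <- replicate(3, matrix(FALSE, 4, 4), simplify = FALSE)
  expect_warning(v <- cell_volume(empty, 0.5, 0.1), "empty")
  expect_equal(v, 0)

  # constant footprint: A * dz * (n - 1)
  disc <- matrix(FALSE, 30, 30)
  disc[8:22, 8:22] <- TRUE
  A <- sum(disc) * 0.2^2
  expect_equal(cell_volume(replicate(5, disc, simplify = FALSE),
                           dz = 0.5, pixel_size = 0.2), A * 0.5 * 4)

  # volume scales as pixel_size^2 and dz (dimensional analysis)
  st <- replicate(4, disc, simplify = FALSE)
  expect_equal(cell_volume(st, 0.5, 0.2), 4 * cell_volume(st, 0.5, 0.1))
  expect_equal(cell_volume(st, 1.0, 0.1), 2 * cell_volume(st, 0.5, 0.1))

  # 3D array input is accepted
  arr <- array(FALSE, c(30, 30, 4)); arr[8:22, 8:22, ] <- TRUE
  expect_equal(cell_volume(arr, 0.5, 0.2), cell_volume(st, 0.5, 0.2))
})

test_that("rasterized sphere volume matches the analytic value within 2%", {
  sp <- make_sphere_stack(radius = 8, dz = 0.5, pixel_size = 0.1)
  v <- cell_volume(sp$masks, sp$dz, sp$pixel_size)
  expect_equal(v, 4 / 3 * pi * 8^3, tolerance = 0.02)
})

test_that("lamella area fraction isolates the thin rim", {
  # cell entirely below the critical height: all lamella
  thin <- replicate(3, {m <- matrix(FALSE, 20, 20); m[5:15, 5:15] <- TRUE; m},
                    simplify = FALSE)
  expect_equal(lamella_area_fraction(thin, dz = 0.5), 1)

  # vertical cylinder: same footprint at every height, no rim
  tall <- replicate(7, {m <- matrix(FALSE, 20, 20); m[5:15, 5:15] <- TRUE; m},
                    simplify = FALSE)
  expect_equal(lamella_area_fraction(tall, dz = 0.5), 0)

  # 1-um skirt of footprint 2A around a tall core of footprint A
  core <- matrix(FALSE, 40, 40); core[12:23, 12:23] <- TRUE     # 144 px
  skirt <- matrix(FALSE, 40, 40); skirt[8:24, 8:24] <- TRUE     # 289 px
  stopifnot(abs(sum(skirt) - 2 * sum(core)) <= 4)
  stack <- c(list(skirt, skirt, skirt),        # heights 0, 0.5, 1
             replicate(4, core, simplify = FALSE))  # 1.5 .. 3
  expect_equal(lamella_area_fraction(stack, dz = 0.5),
               1 - sum(core) / sum(skirt))
  expect_equal(lamella_area_fraction(stack, dz = 0.5), 0.5,
               tolerance = 0.01)

  expect_error(lamella_area_fraction(replicate(3, matrix(FALSE, 4, 4),
                                               simplify = FALSE)),
               "empty")
})

test_that("track speed and persistence behave on canonical paths", {
  st <- straight_track(n = 10, speed = 0.05)
  r <- speed_and_persistence(st)
  expect_equal(r$speed, 0.05)
  expect_equal(r$persistence, 1)

  r2 <- speed_and_persistence(loop_track())
  expect_equal(r2$persistence, 0)

  # frame cap: only the first max_frames samples are analysed
  long <- straight_track(n = 100)
  expect_equal(speed_and_persistence(long)$n_used, 71)
  expect_equal(speed_and_persistence(long, max_frames = 10)$n_used, 10)

  err <- tryCatch(speed_and_persistence(straight_track(n = 3)),
                  error = function(e) e)
  expect_s3_class(err, "viscomigration_track_rejected")
  expect_equal(err$reason, "too_short")
})

test_that("track statistics are invariant to rigid motions", {
  set.seed(33)
  for (k in 1:5) {
    tr <- make_prw_track(speed = 0.02, persistence_time = 50, n = 40,
                         seed = k)$track
    base <- speed_and_persistence(tr)
    th <- stats::runif(1, 0, 2 * pi)
    shift <- stats::rnorm(2, 0, 50)
    rot <- tr
    rot$x_um <- cos(th) * tr$x_um - sin(th) * tr$y_um + shift[1]
    rot$y_um <- sin(th) * tr$x_um + cos(th) * tr$y_um + shift[2]
    moved <- speed_and_persistence(rot)
    expect_equal(moved$speed, base$speed, tolerance = 1e-10)
    expect_equal(moved$persistence, base$persistence, tolerance = 1e-10)
  }
})

test_that("calcium spikes are counted per event with a strict 2x rule", {
  set.seed(1)
  flat <- data.frame(t_s = 1:50, value = 100 + rnorm(50, 0, 1))
  expect_equal(calcium_spike_count(flat), 0)

  v <- rep(100, 60)
  v[c(10:11, 25:26, 50:51)] <- 250
  expect_equal(calcium_spike_count(v, baseline = 100), 3)
  # a peak at exactly 2x baseline does not count (strict inequality)
  v2 <- rep(100, 60); v2[30] <- 200
  expect_equal(calcium_spike_count(v2, baseline = 100), 0)
  # contiguous supra-threshold run counts once; 1-sample dips merge
  v3 <- rep(100, 60); v3[20:28] <- 300; v3[24] <- 100
  expect_equal(calcium_spike_count(v3, baseline = 100), 1)
  v3[22:23] <- 100  # a 2-sample gap separates two events
  expect_equal(calcium_spike_count(v3, baseline = 100), 2)

  # scale invariance: multiplying trace and baseline changes nothing
  for (s in c(0.1, 3, 42)) {
    expect_equal(calcium_spike_count(s * v, baseline = 100 * s), 3)
  }
  expect_error(calcium_spike_count(v[1:5]), ">= 10 samples")
  expect_error(calcium_spike_count(v, baseline = 0), "positive")
})

test_that("front-to-rear ratio and its swap inverse", {
  expect_equal(front_rear_ratio(100, 100), 1)
  expect_equal(front_rear_ratio(167, 100), 1.67)
  expect_equal(front_rear_ratio(284, 100), 2.84)
  for (fr in list(c(150, 80), c(90, 210), c(55, 55))) {
    expect_equal(front_rear_ratio(fr[2], fr[1]),
                 1 / front_rear_ratio(fr[1], fr[2]))
  }
  expect_error(front_rear_ratio(100, 0), "positive")
})

test_that("edge-band ON-pixel density measures only the interior band", {
  pat <- make_edge_pattern(occupancy_in_band = 1, occupancy_out = 0,
                           seed = 2)
  expect_equal(storm_edge_density(pat$mask, pat$edge_polygon, 1.5,
                                  pat$pixel_size), 100, tolerance = 0.02)
  pat0 <- make_edge_pattern(occupancy_in_band = 0, occupancy_out = 1,
                            seed = 2)
  # a sliver of boundary pixels may straddle the band edge; stays near 0
  expect_lt(storm_edge_density(pat0$mask, pat0$edge_polygon, 1.5,
                               pat0$pixel_size), 0.5)
  # mixed occupancy: band value recovered despite dense interior
  patm <- make_edge_pattern(occupancy_in_band = 0.4, occupancy_out = 0.9,
                            seed = 7)
  d <- storm_edge_density(patm$mask, patm$edge_polygon, 1.5,
                          patm$pixel_size)
  expect_equal(d, 40, tolerance = 0.025)
})

test_that("pH recovery rate is the negated fitted slope", {
  t <- seq(0, 100, by = 5)
  exact <- data.frame(t_s = t, value = 1.0 - 0.02 * t)
  expect_equal(ph_recovery_rate(exact), 0.02)
  expect_equal(ph_recovery_rate(data.frame(t_s = t, value = rep(0.8, 21))), 0)
  # window selection restricts the fit
  two_phase_trace <- data.frame(t_s = t, value = c(rep(1.2, 10),
                                                   1.2 - 0.01 * (t[11:21] - t[10])))
  expect_equal(ph_recovery_rate(two_phase_trace, window = c(11, 21)), 0.01)
  expect_error(ph_recovery_rate(exact[1:2, ]), "at least 3")
  expect_error(ph_recovery_rate(data.frame(t_s = rep(1, 5),
                                           value = 1:5)), "degenerate")
})

test_that("retrograde flow is the magnitude of the position slope", {
  t <- seq(0, 30, by = 0.4)
  expect_equal(retrograde_flow(data.frame(t_s = t, s_um = 2 + 0.05 * t)),
               0.05)
  expect_equal(retrograde_flow(data.frame(t_s = t, s_um = 2 - 0.05 * t)),
               0.05)
  expect_equal(retrograde_flow(data.frame(t_s = t, s_um = rep(4, length(t)))),
               0)
  # halving the generated flow speed halves the estimate
  a <- retrograde_flow(make_kymograph_track(0.05, seed = 1)$positions)
  b <- retrograde_flow(make_kymograph_track(0.025, seed = 1)$positions)
  expect_equal(a / b, 2)
  expect_error(retrograde_flow(data.frame(t_s = 1, s_um = 2)), "at least 2")
})

test_that("medium chemistry conversions reproduce the printed values", {
  expect_equal(mass_to_molar(0.6, 65e3), 92.3, tolerance = 1e-3)
  expect_equal(mass_to_molar(0, 65e3), 0)
  expect_equal(mass_to_molar(0.0975, 5e5), 1.95)
  expect_error(mass_to_molar(0.6, 0), "positive")

  expect_equal(osmolarity_contribution(92), 92)
  expect_equal(osmolarity_contribution(0), 0)
  # contribution of the maximal dose is ~3e-4 of basal osmolarity
  expect_equal(osmolarity_contribution(mass_to_molar(0.6, 65e3)) / 3e5,
               3.1e-4, tolerance = 0.01)
})
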