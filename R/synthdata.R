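#' Ground-truth record attached to synthetic datasets
#'
#' Every generator returns, alongside its data, a `synth_truth` object
#' naming the generator, its true parameter values and the seed used, so
#' estimator-recovery tests can compare against known truth. Truth objects
#' round-trip through JSON via [write_truth_json()] / [read_truth_json()].
#'
#' @param generator_name character name of the generator.
#' @param parameters named list of true parameter values.
#' @param seed integer seed (or `NA` for deterministic generators).
#' @return An object of class `synth_truth`.
#' @export
synth_truth <- function(generator_name, parameters, seed = NA_integer_) {
  stopifnot(is.character(generator_name), is.list(parameters))
  structure(list(generator_name = generator_name, parameters = parameters,
                 seed = seed), class = "synth_truth")
}

#' Persistent random-walk cell track with known speed and persistence time
#'
#' The heading angle performs a Gaussian rotational random walk with
#' per-step variance `2 dt / persistence_time` (a stationary persistent
#' walk: straight motion as `persistence_time -> Inf`, diffusive motion as
#' it approaches 0); every step has length `speed * dt`, so frame-to-frame
#' speed is exactly `speed`.
#'
#' @param speed true speed (um/s).
#' @param persistence_time directional persistence time (s); `Inf` gives a
#'   straight track.
#' @param dt frame interval (s).
#' @param n number of samples (>= 4).
#' @param seed integer seed.
#' @return A list with `track` (data frame `t_s`, `x_um`, `y_um`) and
#'   `truth`.
#' @export
make_prw_track <- function(speed = 0.01, persistence_time = 60, dt = 10,
                           n = 60, seed = 1L) {
  if (n < 4) stop("n must be at least 4")
  if (speed < 0 || dt <= 0 || persistence_time < 0)
    stop("invalid track parameters")
  set.seed(seed)
  turn_sd <- if (is.infinite(persistence_time)) 0
             else sqrt(2 * dt / max(persistence_time, 1e-12))
  phi <- cumsum(c(stats::runif(1, 0, 2 * pi),
                  stats::rnorm(n - 2, 0, turn_sd)))
  steps <- speed * dt
  track <- data.frame(
    t_s = (seq_len(n) - 1) * dt,
    x_um = c(0, cumsum(steps * cos(phi))),
    y_um = c(0, cumsum(steps * sin(phi)))
  )
  list(track = track,
       truth = synth_truth("prw_track",
                           list(true_speed = speed,
                                persistence_time = persistence_time,
                                dt = dt, n = n), seed))
}

#' Rasterized sphere z-stack with known volume
#'
#' Slice `k` is the disc cut from a sphere of the given radius at height
#' `z_k`, rasterized with the pixel-centre-inside rule; slices run from the
#' bottom to the top of the sphere at spacing `dz`. The true volume is
#' `4/3 pi r^3`.
#'
#' @param radius sphere radius (um), must exceed `dz`.
#' @param dz slice spacing (um).
#' @param pixel_size pixel edge (um).
#' @param seed kept for interface symmetry; the stack is deterministic.
#' @return A list with `masks` (list of logical matrices), `dz`,
#'   `pixel_size` and `truth` (including `true_volume`).
#' @export
make_sphere_stack <- function(radius = 8, dz = 0.5, pixel_size = 0.1,
                              seed = NA_integer_) {
  if (radius <= dz) stop("radius must exceed the slice spacing dz")
  if (dz <= 0 || pixel_size <= 0) stop("dz and pixel_size must be positive")
  z <- seq(-radius, radius, by = dz)
  half <- ceiling(radius / pixel_size) + 2L
  ctr <- (seq_len(2L * half) - 0.5) * pixel_size - half * pixel_size
  d2 <- outer(ctr^2, ctr^2, `+`)
  masks <- lapply(z, function(zk) {
    r2 <- radius^2 - zk^2
    if (r2 <= 0) matrix(FALSE, length(ctr), length(ctr)) else d2 <= r2
  })
  list(masks = masks, dz = dz, pixel_size = pixel_size,
       truth = synth_truth("sphere_stack",
                           list(radius = radius, dz = dz,
                                pixel_size = pixel_size,
                                true_volume = 4 / 3 * pi * radius^3), seed))
}

#' Fluorescence trace with a known number of super-threshold spikes
#'
#' A flat baseline with additive Gaussian noise carrying `n_spikes`
#' three-sample plateaus at `amplitude_factor` times baseline, placed with
#' at least three baseline samples between consecutive events.
#'
#' @param baseline baseline intensity (> 0, arbitrary units).
#' @param n_spikes number of spikes to place.
#' @param amplitude_factor spike height as a multiple of baseline; values
#'   above 2 are detectable by the 2x rule.
#' @param noise_sd additive Gaussian noise s.d.
#' @param n number of samples.
#' @param seed integer seed.
#' @return A list with `trace` (data frame `t_s`, `value`) and `truth`
#'   (including `true_spike_count`).
#' @export
make_spike_trace <- function(baseline = 100, n_spikes = 5,
                             amplitude_factor = 2.5, noise_sd = 2,
                             n = 200, seed = 1L) {
  if (baseline <= 0) stop("baseline must be positive")
  if (n_spikes < 0) stop("n_spikes must be non-negative")
  width <- 3L; gap <- 3L
  need <- n_spikes * (width + gap) + gap
  if (need > n)
    stop("cannot place ", n_spikes, " spikes with the required gaps in ",
         n, " samples")
  set.seed(seed)
  v <- baseline + stats::rnorm(n, 0, noise_sd)
  if (n_spikes > 0) {
    # evenly spread the events, then jitter within the free slack
    slots <- floor(seq(gap + 1, n - width - gap + 1,
                       length.out = n_spikes))
    for (s in slots) v[s:(s + width - 1)] <- amplitude_factor * baseline +
        stats::rnorm(width, 0, noise_sd)
  }
  v <- pmax(v, 0)
  list(trace = data.frame(t_s = seq_len(n) - 1, value = v),
       truth = synth_truth("spike_trace",
                           list(baseline = baseline,
                                true_spike_count = n_spikes,
                                amplitude_factor = amplitude_factor,
                                noise_sd = noise_sd, n = n), seed))
}

#' Growing circular contour series with known edge growth per frame
#'
#' Frame areas follow `A_{i+1} = A_i + step_growth * P_i` for circles, so
#' the area-over-previous-perimeter growth statistic recovers
#' `step_growth` exactly.
#'
#' @param r0 initial radius (um, > 0).
#' @param step_growth true per-frame growth (um/frame).
#' @param n number of frames (>= 2).
#' @param dt frame interval (s).
#' @return A list with `contours` (data frame `t_s`, `area_um2`,
#'   `perimeter_um`) and `truth`.
#' @export
make_growing_contour <- function(r0 = 10, step_growth = 0.1, n = 10,
                                 dt = 5) {
  if (r0 <= 0) stop("r0 must be positive")
  if (n < 2) stop("need at least 2 frames")
  area <- numeric(n); per <- numeric(n)
  a <- pi * r0^2
  for (i in seq_len(n)) {
    r <- sqrt(a / pi)
    area[i] <- a; per[i] <- 2 * pi * r
    a <- a + step_growth * per[i]
  }
  list(contours = data.frame(t_s = (seq_len(n) - 1) * dt, area_um2 = area,
                             perimeter_um = per),
       truth = synth_truth("growing_contour",
                           list(r0 = r0, true_step_growth = step_growth,
                                n = n), NA_integer_))
}

#' Polarized-cell intensity pair with known front-to-rear ratio
#'
#' @param ratio true front/rear ratio (> 0).
#' @param noise_sd relative Gaussian noise on each region mean.
#' @param seed integer seed.
#' @return A list with `cell` (list `front_mean`, `rear_mean`) and `truth`.
#' @export
make_polarized_cell <- function(ratio = 1.67, noise_sd = 0, seed = 1L) {
  if (ratio <= 0) stop("ratio must be positive")
  set.seed(seed)
  rear <- 100 * exp(stats::rnorm(1, 0, noise_sd))
  front <- ratio * 100 * exp(stats::rnorm(1, 0, noise_sd))
  list(cell = list(front_mean = front, rear_mean = rear),
       truth = synth_truth("polarized_cell",
                           list(true_ratio = ratio, noise_sd = noise_sd),
                           seed))
}

#' Binary point pattern with known occupancy near a circular cell edge
#'
#' A disc-shaped cell whose interior pixels are ON with probability
#' `occupancy_in_band` within `band` of the edge and `occupancy_out`
#' further inside, emulating a thresholded super-resolution image of
#' edge-enriched actin.
#'
#' @param occupancy_in_band ON probability within the edge band.
#' @param occupancy_out ON probability in the deeper interior.
#' @param band band width (um).
#' @param radius cell radius (um).
#' @param pixel_size pixel edge (um).
#' @param n_vertices number of polygon vertices approximating the edge.
#' @param seed integer seed.
#' @return A list with `mask`, `edge_polygon`, `pixel_size` and `truth`.
#' @export
make_edge_pattern <- function(occupancy_in_band = 0.4, occupancy_out = 0.9,
                              band = 1.5, radius = 10, pixel_size = 0.1,
                              n_vertices = 180, seed = 1L) {
  if (any(c(occupancy_in_band, occupancy_out) < 0) ||
      any(c(occupancy_in_band, occupancy_out) > 1))
    stop("occupancies must lie in [0, 1]")
  if (band <= 0 || band >= radius) stop("band must lie in (0, radius)")
  set.seed(seed)
  half <- ceiling((radius + 1) / pixel_size)
  npx <- 2L * half
  cx <- half * pixel_size
  ctr <- (seq_len(npx) - 0.5) * pixel_size
  dx2 <- outer((ctr - cx)^2, (ctr - cx)^2, `+`)  # rows = y, cols = x
  r <- sqrt(dx2)
  inside <- r <= radius
  in_band <- inside & r >= radius - band
  mask <- matrix(FALSE, npx, npx)
  mask[in_band] <- stats::runif(sum(in_band)) < occupancy_in_band
  deep <- inside & !in_band
  mask[deep] <- stats::runif(sum(deep)) < occupancy_out
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  edge <- data.frame(x_um = cx + radius * cos(ang),
                     y_um = cx + radius * sin(ang))
  list(mask = mask, edge_polygon = edge, pixel_size = pixel_size,
       truth = synth_truth("edge_pattern",
                           list(true_occupancy = occupancy_in_band,
                                occupancy_out = occupancy_out, band = band,
                                radius = radius), seed))
}

#' Linear pH-recovery ratio trace with known slope
#'
#' The probe ratio declines linearly at the given recovery rate
#' (`value = r0 - slope * t`) with additive Gaussian noise, so the fitted
#' `-dR/dt` recovers `slope`.
#'
#' @param slope true recovery rate (ratio units/s, > 0 for recovery).
#' @param noise_sd additive noise s.d.
#' @param n number of samples.
#' @param dt sample interval (s).
#' @param r0 initial ratio value.
#' @param seed integer seed.
#' @return A list with `trace` and `truth` (including `true_slope`).
#' @export
make_ph_trace <- function(slope = 0.015, noise_sd = 0.001, n = 20, dt = 30,
                          r0 = 1.2, seed = 1L) {
  if (n < 3) stop("need at least 3 samples")
  set.seed(seed)
  t <- (seq_len(n) - 1) * dt
  list(trace = data.frame(t_s = t,
                          value = r0 - slope * t + stats::rnorm(n, 0, noise_sd)),
       truth = synth_truth("ph_trace",
                           list(true_slope = slope, noise_sd = noise_sd,
                                n = n), seed))
}

#' Kymograph feature positions with known retrograde flow speed
#'
#' @param flow_speed true flow speed (um/s).
#' @param dt sample interval (s).
#' @param n number of samples (>= 2).
#' @param noise_sd positional noise s.d. (um).
#' @param seed integer seed.
#' @return A list with `positions` (data frame `t_s`, `s_um`) and `truth`.
#' @export
make_kymograph_track <- function(flow_speed = 0.05, dt = 0.4, n = 75,
                                 noise_sd = 0, seed = 1L) {
  if (n < 2) stop("need at least 2 samples")
  if (flow_speed < 0) stop("flow_speed must be non-negative")
  set.seed(seed)
  t <- (seq_len(n) - 1) * dt
  list(positions = data.frame(
         t_s = t, s_um = 5 + flow_speed * t + stats::rnorm(n, 0, noise_sd)),
       truth = synth_truth("kymograph_track",
                           list(true_flow_speed = flow_speed, dt = dt,
                                n = n), seed))
}
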