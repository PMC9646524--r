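#' Per-frame leading-edge lamella growth
#'
#' Instantaneous growth of a cell's leading-edge lamella from a contour
#' series, computed as the area gained per unit of previous perimeter:
#' `Growth(i) = (Area(i) - Area(i-1)) / Perimeter(i-1)`.
#'
#' @param contours a data frame with columns `t_s`, `area_um2`,
#'   `perimeter_um` (times strictly increasing, at least 2 frames).
#' @return Numeric vector of per-step growth values (um), length
#'   `nrow(contours) - 1`.
#' @examples
#' sq <- data.frame(t_s = 0:2, area_um2 = c(100, 102, 104),
#'                  perimeter_um = c(40, 40.4, 40.8))
#' lamella_growth(sq)
#' @export
lamella_growth <- function(contours) {
  check_columns(contours, c("t_s", "area_um2", "perimeter_um"))
  if (nrow(contours) < 2) stop("need at least 2 frames")
  if (any(contours$area_um2 < 0)) stop("areas must be non-negative")
  prev_per <- contours$perimeter_um[-nrow(contours)]
  if (any(prev_per <= 0)) stop("perimeters must be positive")
  diff(contours$area_um2) / prev_per
}

#' Cell volume from a binary segmentation z-stack
#'
#' Integrates cross-sectional areas over slice spacing with the trapezoidal
#' rule: each adjacent slice pair contributes `dz * (A_k + A_{k+1}) / 2`,
#' where `A_k` is the ON-pixel count of slice `k` times `pixel_size^2`.
#' Removal of out-of-focus slices is the caller's responsibility.
#'
#' @param masks a list of logical/0-1 matrices (all the same shape), or a
#'   3D array with the slice as the third dimension, ordered along z.
#' @param dz slice spacing (um).
#' @param pixel_size pixel edge length (um).
#' @return Volume (um^3). An empty stack returns 0 with a warning.
#' @export
cell_volume <- function(masks, dz = 0.5, pixel_size = 0.1) {
  masks <- as_mask_list(masks)
  if (dz <= 0 || pixel_size <= 0) stop("dz and pixel_size must be positive")
  if (length(masks) < 2) stop("need at least 2 slices")
  areas <- vapply(masks, function(mm) sum(mm != 0), numeric(1)) * pixel_size^2
  if (all(areas == 0)) {
    warning("empty stack: volume 0")
    return(0)
  }
  sum(dz * (areas[-length(areas)] + areas[-1]) / 2)
}

#' Fraction of projected cell area occupied by thin lamella
#'
#' Classifies as lamella the part of the projected cell footprint that has
#' no cell material above a critical height (default 2 um, about twice the
#' typical lamella thickness). The fraction is `(P_all - P_above) / P_all`
#' where `P_all` is the projected area of the whole stack and `P_above`
#' that of the slices strictly above `h_crit`; slice `k` sits at height
#' `(k - 1) * dz`, with slice 1 on the substrate.
#'
#' @inheritParams cell_volume
#' @param h_crit critical height (um).
#' @return Fraction in `[0, 1]`.
#' @export
lamella_area_fraction <- function(masks, dz = 0.5, pixel_size = 0.1,
                                  h_crit = 2) {
  masks <- as_mask_list(masks)
  if (dz <= 0) stop("dz must be positive")
  heights <- (seq_along(masks) - 1) * dz
  proj <- Reduce(`|`, lapply(masks, function(mm) mm != 0))
  if (!any(proj)) stop("empty projection: no cell in the stack")
  above <- masks[heights > h_crit]
  proj_above <- if (length(above))
    Reduce(`|`, lapply(above, function(mm) mm != 0))
  else
    proj & FALSE
  (sum(proj) - sum(proj_above)) / sum(proj)
}

#' Mean frame-to-frame speed and persistence of a cell track
#'
#' Speed is the mean of frame displacements divided by their time
#' intervals; persistence is the net displacement between the first and
#' last analysed positions divided by the total point-to-point path length
#' (1 for straight motion, 0 for a closed loop). Tracks shorter than
#' `min_frames` samples are rejected; at most the first `max_frames`
#' samples are used.
#'
#' @param track a data frame with columns `t_s`, `x_um`, `y_um` and
#'   optionally `z_um`; times strictly increasing.
#' @param min_frames minimum number of samples (default 4).
#' @param max_frames maximum number of samples analysed (default 71).
#' @return A list with `speed` (um/s), `persistence` (in `[0, 1]`) and
#'   `n_used`. Too-short tracks raise an error of class
#'   `viscomigration_track_rejected` whose message carries the reason.
#' @export
speed_and_persistence <- function(track, min_frames = 4, max_frames = 71) {
  check_columns(track, c("t_s", "x_um", "y_um"))
  if (nrow(track) < min_frames) {
    cond <- structure(
      class = c("viscomigration_track_rejected", "error", "condition"),
      list(message = sprintf("track rejected: %d < %d frames",
                             nrow(track), min_frames),
           call = sys.call(-1), reason = "too_short"))
    stop(cond)
  }
  track <- track[seq_len(min(nrow(track), max_frames)), , drop = FALSE]
  if (any(diff(track$t_s) <= 0)) stop("track times must be strictly increasing")
  xyz <- cbind(track$x_um, track$y_um,
               if ("z_um" %in% names(track)) track$z_um else 0)
  steps <- sqrt(rowSums(diff(xyz)^2))
  net <- sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2))
  list(speed = mean(steps / diff(track$t_s)),
       persistence = if (sum(steps) > 0) net / sum(steps) else 0,
       n_used = nrow(track))
}

#' Count calcium spikes in a fluorescence intensity trace
#'
#' A spike is a distinct excursion whose peak intensity strictly exceeds
#' twice the baseline. Contiguous supra-threshold runs count once, and
#' runs separated by fewer than `refractory` sub-threshold samples are
#' merged into one event. The baseline defaults to the median of the
#' lowest quartile of the trace (robust to the spikes themselves) and can
#' be overridden with a fixed value or estimated from a pre-stimulus
#' window.
#'
#' @param trace a data frame with columns `t_s`, `value` (values >= 0), or
#'   a bare numeric vector of intensities.
#' @param baseline optional fixed baseline level.
#' @param baseline_window optional index range `c(i1, i2)` over which to
#'   average a pre-stimulus baseline.
#' @param factor threshold multiple of baseline (default 2, strict).
#' @param refractory minimum number of sub-threshold samples separating two
#'   events (default 2).
#' @return Integer spike count.
#' @export
calcium_spike_count <- function(trace, baseline = NULL,
                                baseline_window = NULL, factor = 2,
                                refractory = 2) {
  v <- if (is.data.frame(trace)) {
    check_columns(trace, c("t_s", "value"))
    trace$value
  } else as.numeric(trace)
  if (any(v < 0)) stop("intensities must be non-negative")
  if (is.null(baseline)) {
    if (!is.null(baseline_window)) {
      baseline <- mean(v[baseline_window[1]:baseline_window[2]])
    } else {
      if (length(v) < 10)
        stop("need >= 10 samples to estimate a baseline")
      baseline <- stats::median(v[v <= stats::quantile(v, 0.25)])
    }
  }
  if (baseline <= 0) stop("baseline must be positive")
  hot <- v > factor * baseline
  if (!any(hot)) return(0L)
  r <- rle(hot)
  # merge events separated by short sub-threshold gaps (interior gaps only)
  gaps <- which(!r$values & r$lengths < refractory)
  gaps <- gaps[gaps > 1 & gaps < length(r$values)]
  sum(r$values) - length(gaps)
}

#' Front-to-rear intensity ratio of a polarized cell
#'
#' @param front_mean mean intensity of the leading-edge region (> 0).
#' @param rear_mean mean intensity of the trailing-edge region (> 0).
#' @return `front_mean / rear_mean`.
#' @examples
#' front_rear_ratio(167, 100)  # 1.67
#' @export
front_rear_ratio <- function(front_mean, rear_mean) {
  if (any(rear_mean <= 0) || any(front_mean <= 0))
    stop("region mean intensities must be positive")
  front_mean / rear_mean
}

#' ON-pixel density near the cell edge of a binary super-resolution image
#'
#' Percentage of ON pixels among all pixels lying inside the cell and
#' within `band` of the cell edge, the standard readout for actin network
#' density in thresholded single-molecule reconstructions.
#'
#' @param mask logical/0-1 matrix (rows = y, columns = x).
#' @param edge_polygon closed cell outline: a data frame or matrix with
#'   columns `x_um`, `y_um` (the first vertex need not be repeated).
#' @param band distance from the edge defining the measurement band (um).
#' @param pixel_size pixel edge length (um). Pixel `[i, j]` is centred at
#'   `((j - 1/2) * pixel_size, (i - 1/2) * pixel_size)`.
#' @return Percentage of ON pixels in the band (0-100).
#' @export
storm_edge_density <- function(mask, edge_polygon, band = 1.5,
                               pixel_size = 0.1) {
  if (band <= 0 || pixel_size <= 0) stop("band and pixel_size must be positive")
  ep <- as.matrix(as.data.frame(edge_polygon)[, c("x_um", "y_um")])
  nr <- nrow(mask); nc <- ncol(mask)
  px <- (rep(seq_len(nc), each = nr) - 0.5) * pixel_size
  py <- (rep(seq_len(nr), times = nc) - 0.5) * pixel_size
  inside <- point_in_polygon(px, py, ep)
  d <- dist_to_polygon(px, py, ep)
  sel <- inside & d <= band
  if (!any(sel)) stop("no pixels fall in the edge band")
  100 * sum(mask[cbind(rep(seq_len(nr), times = nc)[sel],
                       rep(seq_len(nc), each = nr)[sel])] != 0) / sum(sel)
}

#' Rate of intracellular pH recovery
#'
#' Fits a least-squares line to the ratiometric pH-probe signal `R` over
#' the recovery window and returns `-dR/dt`, the conventional measure of
#' proton-efflux (NHE1) activity: the probe ratio falls as pH recovers, so
#' an active exchanger yields a positive rate.
#'
#' @param trace a data frame with columns `t_s`, `value`.
#' @param window optional index range `c(i1, i2)` selecting the recovery
#'   phase; default uses the whole trace.
#' @return Recovery rate (ratio units per second).
#' @export
ph_recovery_rate <- function(trace, window = NULL) {
  check_columns(trace, c("t_s", "value"))
  if (!is.null(window)) trace <- trace[window[1]:window[2], , drop = FALSE]
  if (nrow(trace) < 3) stop("need at least 3 samples in the fit window")
  if (length(unique(trace$t_s)) < 2) stop("degenerate time axis")
  -unname(stats::coef(stats::lm(value ~ t_s, data = trace))[2])
}

#' Retrograde flow speed from kymograph feature positions
#'
#' The flow rate is the magnitude of the least-squares slope of the
#' tracked feature position along the kymograph line against time
#' (equivalently the tangent of the kymograph angle after pixel/time
#' calibration).
#'
#' @param positions a data frame with columns `t_s`, `s_um` (>= 2 samples).
#' @return Flow speed (um/s).
#' @export
retrograde_flow <- function(positions) {
  check_columns(positions, c("t_s", "s_um"))
  if (nrow(positions) < 2) stop("need at least 2 samples")
  if (length(unique(positions$t_s)) < 2) stop("degenerate time axis")
  abs(unname(stats::coef(stats::lm(s_um ~ t_s, data = positions))[2]))
}

#' Convert a mass/volume percentage of a macromolecule to molarity
#'
#' `percent_w_v` grams per 100 mL is `percent_w_v * 10` g/L; dividing by
#' the molecular mass (Da = g/mol) and scaling gives micromolar.
#'
#' @param percent_w_v concentration in % w/v (g per 100 mL).
#' @param molecular_mass molecular mass (Da).
#' @return Concentration (uM).
#' @examples
#' mass_to_molar(0.6, 65e3)   # ~92 uM (0.6% of 65 kDa methylcellulose)
#' mass_to_molar(0.0975, 5e5) # ~1.95 uM (500 kDa dextran)
#' @export
mass_to_molar <- function(percent_w_v, molecular_mass) {
  if (any(molecular_mass <= 0)) stop("molecular mass must be positive")
  if (any(percent_w_v < 0)) stop("percentage must be non-negative")
  percent_w_v * 10 / molecular_mass * 1e6
}

#' Ideal-solution osmolarity contribution of a dissolved species
#'
#' For an ideal dilute solution of a non-dissociating macromolecule, each
#' micromolar of solute contributes one micro-osmolar.
#'
#' @param concentration_uM solute concentration (uM).
#' @return Osmolarity contribution (uOsm).
#' @export
osmolarity_contribution <- function(concentration_uM) {
  if (any(concentration_uM < 0)) stop("concentration must be non-negative")
  concentration_uM
}

# ---- shared input helpers ----

check_columns <- function(df, cols) {
  if (!is.data.frame(df)) stop("expected a data frame")
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

as_mask_list <- function(masks) {
  if (is.array(masks) && length(dim(masks)) == 3)
    masks <- lapply(seq_len(dim(masks)[3]), function(k) masks[, , k])
  if (!is.list(masks) || !length(masks)) stop("expected a list of mask matrices")
  shp <- dim(masks[[1]])
  for (mm in masks)
    if (!identical(dim(mm), shp)) stop("all masks must share the same shape")
  masks
}

# even-odd rule, vectorized over query points
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# minimum distance from query points to a closed polygon boundary
dist_to_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
         else 0
    d2 <- pmin(d2, (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
  }
  sqrt(d2)
}
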