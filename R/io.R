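#' Read a cell track from CSV
#'
#' Expects columns `t_s`, `x_um`, `y_um` and optionally `z_um`; validates
#' strictly increasing time.
#'
#' @param path CSV file path.
#' @return A track data frame.
#' @export
read_track_csv <- function(path) {
  tr <- utils::read.csv(path)
  check_columns(tr, c("t_s", "x_um", "y_um"))
  if (nrow(tr) < 2) stop("track must have at least 2 samples")
  if (any(diff(tr$t_s) <= 0)) stop("track times must be strictly increasing")
  tr
}

#' Write a cell track to CSV
#'
#' @param track a track data frame (`t_s`, `x_um`, `y_um`, optional `z_um`).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_track_csv <- function(track, path) {
  check_columns(track, c("t_s", "x_um", "y_um"))
  utils::write.csv(track, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated edge trace to CSV
#'
#' Columns: `time_s`, `edge_pos_um`, `edge_vel_um_s`, `density_per_um`,
#' `n_growing`, `n_capped`, `n_pointed`.
#'
#' @param trace an `edge_trace` from [simulate_actin()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_edge_trace_csv <- function(trace, path) {
  check_columns(trace, c("time_s", "edge_pos_um", "edge_vel_um_s",
                         "density_per_um"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Write an ensemble density summary to CSV
#'
#' Columns: `time_s`, `mean_density`, `sd_density`, `n_rep`.
#'
#' @param ens output of [ensemble_density()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_ensemble_csv <- function(ens, path) {
  out <- data.frame(time_s = ens$time_s, mean_density = ens$mean_density,
                    sd_density = ens$sd_density,
                    n_rep = attr(ens, "n_rep"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a two-phase solution
#'
#' Writes the scalar summary (speeds, fluxes, residuals, regime) as JSON
#' and the spatial fields as a CSV table (`x_um`, `theta_n`, `theta_c`,
#' `c_mM`, `p_Pa`, `v_n`).
#'
#' @param sol a `two_phase_solution`.
#' @param json_path,csv_path output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_solution <- function(sol, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(sol, "two_phase_solution"))
  if (!is.null(json_path)) {
    scal <- list(v0_um_s = sol$v0, v_c_um_s = sol$v_c,
                 J_water_f = sol$J_water_f, J_water_b = sol$J_water_b,
                 p_star_f = sol$p_star_f, p_star_b = sol$p_star_b,
                 d_g_f = sol$d_g_f, d_g_b = sol$d_g_b,
                 residuals = sol$residuals, converged = sol$converged,
                 iterations = sol$iterations, n_grid = sol$n_grid,
                 regime = unclass(sol$regime))
    jsonlite::write_json(scal, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(
      x_um = sol$x, theta_n = sol$theta_n, theta_c = sol$theta_c,
      c_mM = sol$c, p_Pa = sol$p, v_n = sol$v_n), csv_path,
      row.names = FALSE)
  }
  invisible(c(json_path, csv_path))
}

#' Write a viscosity sweep table to CSV
#'
#' @param sweep output of [speed_vs_viscosity()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  check_columns(sweep, c("viscosity_cP", "v0_um_s", "converged"))
  utils::write.csv(sweep, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / deserialize a ground-truth record
#'
#' @param truth a [synth_truth()] object.
#' @param path JSON file path.
#' @return `write_truth_json()` returns the path invisibly;
#'   `read_truth_json()` returns the `synth_truth` object.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synth_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$parameters <- as.list(obj$parameters)
  synth_truth(obj$generator_name, obj$parameters,
              if (is.null(obj$seed)) NA_integer_ else obj$seed)
}
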