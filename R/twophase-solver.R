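#' Steady-state solution of the two-phase confined-migration model
#'
#' Solves the coupled steady-state system for a confined cell on
#' `x in [0, L]` (rear to front, co-moving frame): cytosol incompressibility
#' and pressure balance against interfacial drag; water fluxes at both faces
#' set by hydraulic and osmotic pressure differences, with external face
#' pressures shifted by channel hydraulic resistance; the network force
#' balance with a position-dependent focal-adhesion coefficient
#' `eta_st0 * adhesion_profile(x/L)`; F-/G-actin interconversion with
#' saturating polymerization at the front and distributed depolymerization;
#' ion convection-diffusion with passive and polarized active boundary
#' fluxes; conservation of total actin; and the whole-cell force balance
#' including wall friction `xi * v0`. Discretization is a conservative
#' finite-difference scheme on a uniform grid with midpoint fluxes
#' (boundary derivatives one-sided at second order), closed by a damped
#' Newton iteration on all field values plus the scalars `v0`, `v_c` and
#' the rear pressure.
#'
#' All convective fluxes are taken relative to the moving cell, so the
#' front/rear boundary conditions involve `v - v0` exactly as the flux
#' conditions prescribe. Of the four actin flux boundary conditions, the
#' rear G-actin one is implied by the other three together with the
#' conservation laws; it is replaced by the total-actin constraint and
#' reported as the diagnostic `residuals$rear_gactin_flux`.
#'
#' @param params a [two_phase_params()] object.
#' @param regime a [regime_config()] object.
#' @param n_grid number of grid nodes (>= 50; default 200).
#' @param tol convergence tolerance on the scaled residual RMS.
#' @param max_iter maximum Newton iterations.
#' @param symmetric_polymerization if `TRUE`, the saturating polymerization
#'   flux is applied at both cell ends (mirror-symmetric configuration used
#'   to verify that symmetry forbids net motion).
#' @param J_active_f optional explicit front active ion flux, overriding the
#'   default `-gamma_polar * J_active_b` polarization rule.
#' @return An object of class `two_phase_solution`: a list with the cell
#'   speed `v0` (um/s), `v_c`, grid `x`, fields `theta_n`, `theta_c`, `c`,
#'   `p`, `v_n`, boundary fluxes `J_water_f`/`J_water_b`, face pressures
#'   `p_star_f`/`p_star_b`, hydraulic coefficients `d_g_f`/`d_g_b`,
#'   `residuals` (named diagnostics), `converged`, `iterations`.
#' @examples
#' \donttest{
#' sol <- solve_steady_state(two_phase_params(), regime_config("LV"),
#'                           n_grid = 80)
#' sol$v0 * 60  # um/min
#' }
#' @export
solve_steady_state <- function(params, regime, n_grid = 200, tol = 1e-9,
                               max_iter = 60,
                               symmetric_polymerization = FALSE,
                               J_active_f = NULL) {
  stopifnot(inherits(params, "two_phase_params"),
            inherits(regime, "regime_config"))
  if (n_grid < 50) stop("n_grid must be at least 50")
  if (regime$L_cell >= params$L0) stop("cell length must be below L0")

  N <- as.integer(n_grid)
  L <- regime$L_cell
  x <- seq(0, L, length.out = N)
  h <- x[2] - x[1]
  xm <- (x[-1] + x[-N]) / 2
  est_n <- regime$eta_st0 * adhesion_profile(x / L, regime$b_adh,
                                             regime$profile_shape)
  est_m <- regime$eta_st0 * adhesion_profile(xm / L, regime$b_adh,
                                             regime$profile_shape)
  l0 <- effective_channel_length(params$L0, L)
  mu <- regime$mu_cP * 1e-3
  d_g_f <- hydraulic_resistance(mu, l0 * params$dg_split, params$w)
  d_g_b <- hydraulic_resistance(mu, l0 * (1 - params$dg_split), params$w)
  Jab <- params$J_active_b
  Jaf <- if (is.null(J_active_f))
    polarized_ion_fluxes(Jab, regime$gamma_polar)$J_active_f else J_active_f

  eta <- params$eta_drag; ks <- params$k_sigma_n
  gam <- params$gamma_depoly
  # theta_n may decay to exponentially small values at the rear; the
  # swelling term uses the log-derivative theta_n'/theta_n, which stays
  # finite, so only strict positivity is required of iterates
  theta_floor <- 1e-300

  # residual of the fully coupled discrete system; u = (theta_n, theta_c,
  # c, v0, v_c, p_rear), residual blocks scaled to comparable magnitude
  resid <- function(u) {
    tn <- u[1:N]; tc <- u[(N + 1):(2 * N)]; cc <- u[(2 * N + 1):(3 * N)]
    v0 <- u[3 * N + 1]; vc <- u[3 * N + 2]; pb <- u[3 * N + 3]

    dtn_L <- (-3 * tn[1] + 4 * tn[2] - tn[3]) / (2 * h)
    dtn_R <- (3 * tn[N] - 4 * tn[N - 1] + tn[N - 2]) / (2 * h)
    tn_m <- (tn[-1] + tn[-N]) / 2
    f_m <- (eta * vc * tn_m - ks * diff(tn) / h) / (eta + est_m) - v0 * tn_m
    f_L <- (eta * vc * tn[1] - ks * dtn_L) / (eta + est_n[1]) - v0 * tn[1]
    f_R <- (eta * vc * tn[N] - ks * dtn_R) / (eta + est_n[N]) - v0 * tn[N]

    Jf <- params$J_actin_f0 * tc[N] / (params$theta_cc + tc[N])
    Jr <- if (symmetric_polymerization)
      params$J_actin_f0 * tc[1] / (params$theta_cc + tc[1]) else 0

    Rn <- numeric(N)
    Rn[1] <- f_L - Jr
    Rn[2:(N - 1)] <- (f_m[-1] - f_m[-(N - 1)]) / h + gam * tn[2:(N - 1)]
    Rn[N] <- f_R + Jf

    tc_m <- (tc[-1] + tc[-N]) / 2
    g_m <- tc_m * (vc - v0) - params$D_theta_c * diff(tc) / h
    g_R <- tc[N] * (vc - v0) -
      params$D_theta_c * (3 * tc[N] - 4 * tc[N - 1] + tc[N - 2]) / (2 * h)
    Rc <- numeric(N)
    Rc[1] <- (trapz(x, tn + tc) - L * params$theta_star) / L
    Rc[2:(N - 1)] <- (g_m[-1] - g_m[-(N - 1)]) / h - gam * tn[2:(N - 1)]
    Rc[N] <- g_R - Jf

    c_m <- (cc[-1] + cc[-N]) / 2
    q_m <- c_m * (vc - v0) - params$D_c * diff(cc) / h
    q_L <- cc[1] * (vc - v0) -
      params$D_c * (-3 * cc[1] + 4 * cc[2] - cc[3]) / (2 * h)
    q_R <- cc[N] * (vc - v0) -
      params$D_c * (3 * cc[N] - 4 * cc[N - 1] + cc[N - 2]) / (2 * h)
    Ri <- numeric(N)
    Ri[1] <- q_L - (-params$k_sol_b * (cc[1] - params$c0_b) + Jab)
    Ri[2:(N - 1)] <- (q_m[-1] - q_m[-(N - 1)]) / h
    Ri[N] <- q_R - (params$k_sol_f * (cc[N] - params$c0_f) - Jaf)

    dtn <- c(dtn_L, (tn[-c(1, 2)] - tn[-c(N - 1, N)]) / (2 * h), dtn_R)
    vn <- (eta * vc - ks * dtn / pmax(tn, theta_floor)) / (eta + est_n)
    p <- pb + cumtrapz(x, -eta * tn * (vc - vn))
    Jwf <- -params$alpha_f *
      ((p[N] - params$p0_f - d_g_f * v0) - params$RT * (cc[N] - params$c0_f)) /
      (1 + params$alpha_f * d_g_f)
    Jwb <- -params$alpha_b *
      ((p[1] - params$p0_b + d_g_b * v0) - params$RT * (cc[1] - params$c0_b)) /
      (1 + params$alpha_b * d_g_b)

    S1 <- (vc - v0) + Jwf
    S2 <- (vc - v0) - Jwb
    S3 <- -(params$p0_f - params$p0_b) -
      (d_g_f + d_g_b) * (v0 - Jwf) - trapz(x, est_n * tn * vn) -
      regime$xi * v0

    c(Rn / (gam * params$theta_star), Rc / (gam * params$theta_star),
      Ri, S1 / 1e-3, S2 / 1e-3, S3 / 10)
  }

  m <- 3L * N + 3L
  u <- c(rep(0.3 * params$theta_star, N), rep(0.7 * params$theta_star, N),
         rep((params$c0_f + params$c0_b) / 2, N), 1e-3, 1e-3, params$p0_b)
  ok_state <- function(u)
    all(is.finite(u)) && all(u[1:N] > theta_floor) &&
      all(u[(N + 1):(2 * N)] > 0) && all(u[(2 * N + 1):(3 * N)] > 0)

  rms <- function(r) sqrt(mean(r^2))
  R0 <- resid(u)
  it <- 0L
  while (rms(R0) >= tol && it < max_iter) {
    it <- it + 1L
    J <- matrix(0, m, m)
    for (j in seq_len(m)) {
      du <- 1e-7 * max(1, abs(u[j]))
      up <- u; up[j] <- up[j] + du
      J[, j] <- (resid(up) - R0) / du
    }
    step <- tryCatch(solve(J, -R0), error = function(e) {
      qr.solve(qr(J, LAPACK = TRUE), -R0)
    })
    lam <- 1
    n0 <- rms(R0)
    repeat {
      un <- u + lam * step
      if (ok_state(un)) {
        Rn <- resid(un)
        if (all(is.finite(Rn)) && rms(Rn) < n0) break
      }
      lam <- lam / 2
      if (lam < 1e-8) {
        un <- u; Rn <- R0
        break
      }
    }
    if (lam < 1e-8) break  # stalled: no productive step found
    u <- un; R0 <- Rn
  }

  converged <- rms(R0) < max(tol, 1e-8)
  if (!converged && rms(R0) > 1e-6) {
    cond <- structure(
      class = c("viscomigration_solver_error", "error", "condition"),
      list(message = sprintf(
        "two-phase solver did not converge (scaled residual RMS %.3e after %d iterations)",
        rms(R0), it), call = sys.call(-1),
        residual_rms = rms(R0), iterations = it))
    stop(cond)
  }

  tn <- u[1:N]; tc <- u[(N + 1):(2 * N)]; cc <- u[(2 * N + 1):(3 * N)]
  v0 <- u[3 * N + 1]; vc <- u[3 * N + 2]; pb <- u[3 * N + 3]
  dtn <- c((-3 * tn[1] + 4 * tn[2] - tn[3]) / (2 * h),
           (tn[-c(1, 2)] - tn[-c(N - 1, N)]) / (2 * h),
           (3 * tn[N] - 4 * tn[N - 1] + tn[N - 2]) / (2 * h))
  vn <- (eta * vc - ks * dtn / pmax(tn, theta_floor)) / (eta + est_n)
  p <- pb + cumtrapz(x, -eta * tn * (vc - vn))
  Jwf <- -params$alpha_f *
    ((p[N] - params$p0_f - d_g_f * v0) - params$RT * (cc[N] - params$c0_f)) /
    (1 + params$alpha_f * d_g_f)
  Jwb <- -params$alpha_b *
    ((p[1] - params$p0_b + d_g_b * v0) - params$RT * (cc[1] - params$c0_b)) /
    (1 + params$alpha_b * d_g_b)
  fp <- face_pressures(params$p0_f, params$p0_b, d_g_f, d_g_b, v0, Jwf, Jwb)

  force_terms <- c(dp0 = -(params$p0_f - params$p0_b),
                   hydraulic = -(d_g_f + d_g_b) * (v0 - Jwf),
                   traction = -trapz(x, est_n * tn * vn),
                   friction = -regime$xi * v0)
  g_L <- tc[1] * (vc - v0) -
    params$D_theta_c * (-3 * tc[1] + 4 * tc[2] - tc[3]) / (2 * h)
  Jr <- if (symmetric_polymerization)
    params$J_actin_f0 * tc[1] / (params$theta_cc + tc[1]) else 0

  res <- list(
    newton_rms = rms(R0),
    mass_conservation = abs(trapz(x, tn + tc) - L * params$theta_star) /
      (L * params$theta_star),
    force_balance = abs(sum(force_terms)) / max(abs(force_terms)),
    vc_variation = 0,  # v_c is a single scalar unknown: uniform by construction
    rear_gactin_flux = abs(g_L + Jr) /
      max(params$J_actin_f0, abs(vc - v0) * params$theta_star)
  )

  structure(list(
    v0 = v0, v_c = vc, x = x, theta_n = tn, theta_c = tc, c = cc, p = p,
    v_n = vn, J_water_f = Jwf, J_water_b = Jwb,
    p_star_f = fp$p_star_f, p_star_b = fp$p_star_b,
    d_g_f = d_g_f, d_g_b = d_g_b, force_terms = force_terms,
    residuals = res, converged = converged, iterations = it,
    params = params, regime = regime, n_grid = N,
    symmetric_polymerization = symmetric_polymerization
  ), class = "two_phase_solution")
}

#' @export
print.two_phase_solution <- function(x, ...) {
  cat(sprintf("Two-phase steady state (%s regime, %.2f cP, L = %g um, %d nodes)\n",
              x$regime$name, x$regime$mu_cP, x$regime$L_cell, x$n_grid))
  cat(sprintf("  v0 = %.5g um/s (%.4g um/min), v_c = %.5g um/s\n",
              x$v0, x$v0 * 60, x$v_c))
  cat(sprintf("  J_water front/back = %.4g / %.4g um/s\n",
              x$J_water_f, x$J_water_b))
  cat(sprintf("  residuals: mass %.2e, force balance %.2e, newton %.2e (%d it)\n",
              x$residuals$mass_conservation, x$residuals$force_balance,
              x$residuals$newton_rms, x$iterations))
  invisible(x)
}

#' Cell speed across a sweep of medium viscosities
#'
#' Solves the two-phase model once per viscosity value, recomputing the
#' hydraulic resistance from the viscosity while holding every other
#' regime input fixed. Rows whose solve fails are reported as
#' non-converged with `NA` speed; the sweep continues.
#'
#' @param params a [two_phase_params()] object.
#' @param regime a [regime_config()] template whose `mu_cP` is replaced per
#'   sweep value.
#' @param viscosities_cP viscosities to evaluate (cP, > 0).
#' @param ... passed on to [solve_steady_state()].
#' @return A data frame with columns `viscosity_cP`, `v0_um_s`, `converged`.
#' @export
speed_vs_viscosity <- function(params, regime, viscosities_cP, ...) {
  stopifnot(all(viscosities_cP > 0))
  rows <- lapply(viscosities_cP, function(mu) {
    r <- regime; r$mu_cP <- mu
    sol <- tryCatch(solve_steady_state(params, r, ...),
                    error = function(e) NULL)
    if (is.null(sol)) data.frame(viscosity_cP = mu, v0_um_s = NA_real_,
                                 converged = FALSE)
    else data.frame(viscosity_cP = mu, v0_um_s = sol$v0,
                    converged = sol$converged)
  })
  do.call(rbind, rows)
}

# trapezoid helpers shared across the package
trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
cumtrapz <- function(x, y) c(0, cumsum(diff(x) * (y[-length(y)] + y[-1]) / 2))
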