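test_that("adhesion profiles match their closed forms", {
  expect_equal(adhesion_profile(0.5, 0.3, "quadratic"), 0.3)
  expect_equal(adhesion_profile(c(0, 1), 0.3, "quadratic"), c(1, 1))
  expect_equal(adhesion_profile(c(0, 1), 0.7, "quadratic"), c(1, 1))
  expect_equal(adhesion_profile(0.5, 0.25, "quartic"), 0.296875)
  expect_equal(adhesion_profile(c(0, 1), 0.25, "quartic"), c(0.25, 1))
  # bounded between the minimum and 1 over the whole cell
  xb <- seq(0, 1, by = 0.01)
  for (shape in c("quadratic", "quartic")) {
    y <- adhesion_profile(xb, 0.3, shape)
    expect_true(all(y >= 0.3 - 1e-12 & y <= 1 + 1e-12))
  }
  expect_error(adhesion_profile(1.2, 0.3, "quadratic"), "\\[0, 1\\]")
  expect_error(adhesion_profile(0.5, 1.4, "quadratic"), "\\[0, 1\\]")
})

test_that("channel hydraulics follow the pipe-flow estimate", {
  expect_equal(hydraulic_resistance(0, 100, 3.5), 0)
  expect_equal(hydraulic_resistance(2e-3, 2 * 75, 3.5),
               2 * hydraulic_resistance(2e-3, 75, 3.5))
  # regime ratio fixed by the printed cell lengths: (8 * 75) / (0.77 * 115)
  r <- hydraulic_resistance(8e-3, effective_channel_length(200, 125), 3.5) /
    hydraulic_resistance(0.77e-3, effective_channel_length(200, 85), 3.5)
  expect_equal(r, (8 * 75) / (0.77 * 115))
  expect_equal(r, 6.7758, tolerance = 1e-4)
  expect_error(hydraulic_resistance(1e-3, 100, 0), "positive")

  expect_equal(effective_channel_length(200, 85), 115)
  expect_equal(effective_channel_length(200, 125), 75)
  expect_equal(effective_channel_length(200, 200), 0)
  expect_error(effective_channel_length(200, 201), "exceeds")

  expect_equal(channel_cross_section(3.5, 10), 35)
})

test_that("water flux and face pressures have the stated forms and signs", {
  # osmotic-hydraulic equilibrium: no flux
  expect_equal(water_flux(1e-3, p_face = 500, p_star = 0,
                          c_face = 341, c0 = 340, RT = 500), 0)
  expect_equal(water_flux(0, 100, 0, 350, 340, 2577), 0)
  # hyperosmotic interior draws water in
  expect_gt(water_flux(1e-3, 0, 0, 345, 340, 2577), 0)

  fp <- face_pressures(10, 20, 0.5, 0.4, v0 = 0, J_water_f = 0,
                       J_water_b = 0)
  expect_equal(fp, list(p_star_f = 10, p_star_b = 20))
  fp0 <- face_pressures(10, 20, 0, 0, v0 = 0.5, J_water_f = 1,
                        J_water_b = -1)
  expect_equal(fp0, list(p_star_f = 10, p_star_b = 20))
  # forward motion compresses the front column, rarefies the rear
  fp1 <- face_pressures(0, 0, 0.5, 0.5, v0 = 0.1, J_water_f = 0,
                        J_water_b = 0)
  expect_gt(fp1$p_star_f, fp1$p_star_b)
})

test_that("pointwise network force balance solves for v_n", {
  par <- two_phase_params()
  # no adhesion, no swelling gradient: network rides with the cytosol
  expect_equal(network_velocity(0.3, 0, v_c = 0.02, par, eta_st_local = 0),
               0.02)
  # rigid anchoring
  expect_lt(abs(network_velocity(0.3, 0, 0.02, par, eta_st_local = 1e12)),
            1e-10)
  # swelling gradient alone pushes the network rearward
  expect_lt(network_velocity(0.3, 0.01, 0, par, eta_st_local = 10), 0)
  expect_warning(v <- network_velocity(0, 0.01, 0.02, par, 10), "degenerate|dropped")
  expect_equal(v, par$eta_drag * 0.02 / (par$eta_drag + 10))
})

test_that("polarized fluxes and NHE1 knockdown follow the prescription", {
  fl <- polarized_ion_fluxes(-3, 1.67)
  expect_equal(fl$J_active_f, 5.01)
  expect_equal(abs(fl$J_active_f / fl$J_active_b), 1.67)
  expect_equal(abs(polarized_ion_fluxes(-2, 2.84)$J_active_f / -2), 2.84)
  fl1 <- polarized_ion_fluxes(-3, 1)
  expect_equal(abs(fl1$J_active_f), abs(fl1$J_active_b))
  expect_error(polarized_ion_fluxes(-3, 0), "positive")

  par <- two_phase_params()
  kd <- knockdown_nhe1(par)
  expect_equal(kd$J_active_b, 0)
  expect_identical(knockdown_nhe1(kd), kd)
  kd$J_active_b <- par$J_active_b
  expect_equal(kd, par)  # nothing else touched
})

test_that("converged steady states satisfy the model's conservation laws", {
  for (regime in c("LV", "HV")) {
    sol <- coarse_solve(regime)
    expect_true(sol$converged)
    expect_lt(sol$residuals$mass_conservation, 1e-6)
    expect_lt(sol$residuals$force_balance, 1e-6)
    expect_equal(sol$residuals$vc_variation, 0)
    expect_lt(sol$residuals$rear_gactin_flux, 0.05)  # dropped BC, O(h) at N=60
    expect_true(all(sol$theta_n >= 0))
    expect_true(all(sol$theta_c >= 0))
    expect_true(all(sol$c >= 0))
    expect_gt(sol$v0, 0)
    # reported network velocity is consistent with the pointwise balance
    est <- sol$regime$eta_st0 *
      adhesion_profile(sol$x / max(sol$x), sol$regime$b_adh,
                       sol$regime$profile_shape)
    i <- 30  # interior node
    dtn <- (sol$theta_n[i + 1] - sol$theta_n[i - 1]) /
      (sol$x[i + 1] - sol$x[i - 1])
    expect_equal(sol$v_n[i],
                 network_velocity(sol$theta_n[i], dtn, sol$v_c,
                                  sol$params, est[i]),
                 tolerance = 1e-8)
  }
})

test_that("a mirror-symmetric configuration cannot move", {
  par <- two_phase_params()
  reg <- regime_config("custom", b_adh = 0.3, profile_shape = "quadratic",
                       gamma_polar = 1, L_cell = 100, mu_cP = 1)
  sol <- solve_steady_state(par, reg, n_grid = 60,
                            symmetric_polymerization = TRUE,
                            J_active_f = par$J_active_b)
  expect_lt(abs(sol$v0), 1e-6)
  expect_lt(abs(sol$J_water_f + sol$J_water_b), 1e-8)
})

test_that("speed rises with ion-flux polarization and with the HV regime", {
  par <- two_phase_params()
  v_gamma <- vapply(c(1, 2, 3), function(g) {
    reg <- regime_config("HV")
    reg$gamma_polar <- g
    solve_steady_state(par, reg, n_grid = 60)$v0
  }, numeric(1))
  expect_true(all(diff(v_gamma) >= 0))

  vLV <- coarse_solve("LV")$v0
  vHV <- coarse_solve("HV")$v0
  expect_gt(vHV, vLV)

  kLV <- coarse_solve("LV", knockdown_nhe1(par))$v0
  kHV <- coarse_solve("HV", knockdown_nhe1(par))$v0
  expect_lt(kLV, vLV)
  expect_lt(kHV, vHV)
  expect_gt(1 - kHV / vHV, 1 - kLV / vLV)
})

test_that("the viscosity sweep runs per-row and tolerates failures", {
  par <- two_phase_params()
  reg <- regime_config("HV")
  one <- speed_vs_viscosity(par, reg, 8, n_grid = 60)
  expect_equal(one$v0_um_s, coarse_solve("HV")$v0)
  sw <- speed_vs_viscosity(par, reg, c(0.77, 8), n_grid = 60)
  expect_equal(nrow(sw), 2)
  expect_true(all(sw$converged))
  # an impossible solve yields a non-converged row, not an abort
  bad <- speed_vs_viscosity(par, reg, c(0.77, 8), n_grid = 60, max_iter = 0)
  expect_equal(nrow(bad), 2)
  expect_true(all(!bad$converged))
  expect_true(all(is.na(bad$v0_um_s)))
})

test_that("solver input validation and failure diagnostics work", {
  par <- two_phase_params()
  expect_error(solve_steady_state(par, regime_config("LV"), n_grid = 20),
               "at least 50")
  err <- tryCatch(
    solve_steady_state(par, regime_config("LV"), n_grid = 60, max_iter = 0),
    error = function(e) e)
  expect_s3_class(err, "viscomigration_solver_error")
  expect_true(is.numeric(err$residual_rms))
  expect_error(two_phase_params(dg_split = 1.5), "\\[0, 1\\]")
  expect_error(regime_config("custom", gamma_polar = -1), "positive")
})
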