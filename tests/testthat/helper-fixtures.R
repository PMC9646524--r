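# short, coarse configurations for fast unit tests; acceptance-scale runs
# live in test-acceptance.R

fast_actin <- function(eta_cP = 8, seed = 1L, t_load = 2, t_end = 4, ...) {
  actin_sim_params(eta_cP = eta_cP, dt = 0.01, t_load = t_load,
                   t_end = t_end, n_seed = 30, seed = seed, ...)
}

coarse_solve <- function(regime = "LV", params = two_phase_params(), ...) {
  solve_steady_state(params, regime_config(regime), n_grid = 60, ...)
}

# a square loop track returning to its start
loop_track <- function(side = 10, dt = 10) {
  data.frame(t_s = (0:4) * dt,
             x_um = c(0, side, side, 0, 0),
             y_um = c(0, 0, side, side, 0))
}

straight_track <- function(n = 10, speed = 0.05, dt = 10) {
  data.frame(t_s = (seq_len(n) - 1) * dt,
             x_um = (seq_len(n) - 1) * speed * dt,
             y_um = 0)
}
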