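#' Parameters for the stochastic lamellipodial actin simulator
#'
#' Bundles and validates every tunable of the filament-resolved simulator of
#' branched actin network growth at a cell leading edge. The network grows
#' against a constant membrane-tension load `F0` and, from `t_load` onwards,
#' an additional linear-viscous load `k_scale * eta_visc * v_prev` set by the
#' extracellular fluid viscosity and the edge velocity of the previous
#' iteration.
#'
#' Unit conventions: viscosity in Pa s (use `eta_cP` for centipoise input,
#' 1 cP = 1e-3 Pa s), lengths in micrometres, times in seconds, forces per
#' unit edge width in pN/um.
#'
#' @param eta_visc extracellular viscosity (Pa s). Ignored when `eta_cP` is
#'   given.
#' @param eta_cP convenience alternative: viscosity in centipoise.
#' @param k_scale dimensionless scaling constant of the viscous load.
#' @param F0 membrane-tension force per unit edge width (pN/um).
#' @param kon_rate free-load elongation speed of a barbed end (um/s).
#' @param branch_rate branching events per working filament per second.
#' @param cap_rate capping events per growing filament per second.
#' @param branch_angle mother-daughter branching angle (rad, default 70 deg).
#' @param edge_width lateral width of the simulated edge segment (um).
#' @param delta monomer half-size of the polymerization ratchet (um).
#' @param kBT thermal energy (pN um).
#' @param dt time step (s). Per-filament event probabilities per step must
#'   stay below 0.1.
#' @param t_load time at which the viscous load switches on (s).
#' @param t_end end of the simulation (s).
#' @param working_band distance behind the edge within which a growing
#'   barbed end bears load and may branch (um).
#' @param density_band width of the band behind the edge over which the
#'   reported actin density is counted (um).
#' @param n_seed number of seed filaments per micrometre of edge.
#' @param seed integer seed for the random number stream.
#'
#' @return An object of class `actin_sim_params` (a validated list).
#' @seealso [simulate_actin()], [ensemble_density()]
#' @examples
#' p <- actin_sim_params(eta_cP = 8, t_end = 8, seed = 1)
#' p$eta_visc  # 0.008 Pa s
#' @export
actin_sim_params <- function(eta_visc = 8e-4, eta_cP = NULL,
                             k_scale = 1e5, F0 = 50, kon_rate = 0.3,
                             branch_rate = 1.0, cap_rate = 0.4,
                             branch_angle = 70 * pi / 180,
                             edge_width = 1, delta = 0.0027, kBT = 0.0041,
                             dt = 0.005, t_load = 6, t_end = 12,
                             working_band = 0.05, density_band = 1,
                             n_seed = 50, seed = 1L) {
  if (!is.null(eta_cP)) eta_visc <- eta_cP * 1e-3
  stopifnot(is.numeric(eta_visc), length(eta_visc) == 1L)
  if (eta_visc < 0) stop("extracellular viscosity must be non-negative")
  if (k_scale <= 0) stop("k_scale must be positive")
  if (any(c(F0, kon_rate, branch_rate, cap_rate) < 0))
    stop("rates and forces must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  if (t_load < 0) stop("t_load must be non-negative")
  # t_load past t_end is permitted: the viscous load then never engages,
  # giving a reference zero-load run
  if (working_band <= 0 || density_band <= 0 || edge_width <= 0)
    stop("bands and edge_width must be positive")
  if (n_seed < 1) stop("need at least one seed filament per um")
  p_max <- 1 - exp(-max(branch_rate, cap_rate) * dt)
  if (p_max >= 0.1)
    stop("per-step event probability ", signif(p_max, 3),
         " >= 0.1; reduce dt or the kinetic rates")
  structure(list(
    eta_visc = eta_visc, k_scale = k_scale, F0 = F0, kon_rate = kon_rate,
    branch_rate = branch_rate, cap_rate = cap_rate,
    branch_angle = branch_angle, edge_width = edge_width, delta = delta,
    kBT = kBT, dt = dt, t_load = t_load, t_end = t_end,
    working_band = working_band, density_band = density_band,
    n_seed = n_seed, seed = as.integer(seed)
  ), class = "actin_sim_params")
}

#' Viscous loading force on the leading edge
#'
#' The drag force per unit edge width exerted by the extracellular fluid on
#' a protruding edge, modelled as a linear-viscous dashpot: the force scales
#' linearly with the fluid viscosity and with the edge velocity of the
#' previous iteration. A retracting edge (`v_prev <= 0`) experiences no
#' forward drag; the force is clamped at zero.
#'
#' @param k_scale dimensionless scaling constant (default 100,000).
#' @param eta_visc extracellular viscosity (Pa s).
#' @param v_prev edge velocity from the previous iteration (um/s).
#' @return Force per unit edge width (pN/um).
#' @examples
#' viscous_load(1e5, 8e-4, 0.05)  # 4
#' @export
viscous_load <- function(k_scale, eta_visc, v_prev) {
  if (any(k_scale <= 0)) stop("k_scale must be positive")
  if (any(eta_visc < 0)) stop("extracellular viscosity must be non-negative")
  k_scale * eta_visc * pmax(v_prev, 0)
}

#' Total load at the leading edge
#'
#' Sum of the membrane-tension contribution and the viscous contribution,
#' both per unit edge width.
#'
#' @param F0 membrane-tension force per unit width (pN/um), non-negative.
#' @param F_eta viscous force per unit width (pN/um).
#' @return Total force per unit width (pN/um).
#' @export
total_load <- function(F0, F_eta) {
  if (any(F0 < 0)) stop("F0 must be non-negative")
  F0 + F_eta
}

#' Brownian-ratchet force-velocity relation with shared load
#'
#' Protrusion velocity of an edge pushed by `n_working` load-bearing
#' filaments against a total force `F_total` per unit width. The load is
#' shared equally and each filament elongates as a thermal ratchet, giving
#' `kon_rate * exp(-F_total * edge_width * delta / (n_working * kBT))`.
#' With no working filaments the edge stalls. The law is supplied through
#' `params$fv_law` if present, so alternative force-velocity relations can
#' be plugged in; the default is the exponential ratchet.
#'
#' @param F_total total force per unit edge width (pN/um).
#' @param n_working number of load-bearing filaments (count, >= 0).
#' @param params an [actin_sim_params()] object.
#' @return Edge velocity (um/s).
#' @examples
#' p <- actin_sim_params()
#' force_velocity(0, 10, p)  # == p$kon_rate
#' @export
force_velocity <- function(F_total, n_working, params) {
  if (any(n_working < 0)) stop("n_working must be non-negative")
  law <- params$fv_law
  if (is.null(law)) law <- ratchet_law
  ifelse(n_working > 0, law(F_total, pmax(n_working, 1), params), 0)
}

ratchet_law <- function(F_total, n_working, params) {
  params$kon_rate *
    exp(-F_total * params$edge_width * params$delta / (n_working * params$kBT))
}

# fresh simulator state: seed filaments at the edge, orientations uniform in
# +/- branch_angle/2 about the edge normal
new_lamellipodium <- function(params) {
  n0 <- round(params$n_seed * params$edge_width)
  nmax <- max(4L * n0, 1024L)
  st <- list(
    pos = numeric(nmax), ori = numeric(nmax), growing = logical(nmax),
    lat = numeric(nmax), birth = numeric(nmax),
    n_fil = n0, edge = 0, v_prev = params$kon_rate, t = 0,
    n_pointed = n0, n_capped = 0
  )
  st$ori[1:n0] <- stats::runif(n0, -params$branch_angle / 2,
                               params$branch_angle / 2)
  st$lat[1:n0] <- stats::runif(n0, 0, params$edge_width)
  st$growing[1:n0] <- TRUE
  st
}

grow_arrays <- function(st, need) {
  nmax <- length(st$pos)
  if (st$n_fil + need <= nmax) return(st)
  newmax <- max(2L * nmax, st$n_fil + need)
  for (f in c("pos", "ori", "lat", "birth")) {
    v <- st[[f]]; length(v) <- newmax; v[is.na(v)] <- 0; st[[f]] <- v
  }
  g <- st$growing; length(g) <- newmax; g[is.na(g)] <- FALSE; st$growing <- g
  st
}

#' Advance the lamellipodium state by one time step
#'
#' One iteration of the stochastic dynamics: the edge advances by the
#' force-velocity law under the current total load (membrane tension plus,
#' for `t >= t_load`, the viscous load computed from the previous edge
#' velocity); growing barbed ends elongate toward the edge at
#' `kon_rate * cos(orientation)` and, while within the working band and able
#' to keep up, advance with the edge; each growing filament caps with
#' probability `1 - exp(-cap_rate * dt)`; each surviving working filament
#' branches with probability `1 - exp(-branch_rate * dt)`, the daughter
#' starting at the mother's barbed position with orientation offset by
#' `+/- branch_angle` and its pointed end anchored to the mother.
#'
#' Randomness is drawn from the current R random number stream; seed it via
#' [simulate_actin()] for reproducible runs.
#'
#' @param state internal simulator state (see [simulate_actin()]).
#' @param params an [actin_sim_params()] object.
#' @return The updated state, with `state$v_prev` holding the velocity used.
#' @keywords internal
actin_step <- function(state, params) {
  dt <- params$dt
  st <- state
  st$t <- st$t + dt
  idx <- seq_len(st$n_fil)
  g <- idx[st$growing[idx]]
  work <- g[st$edge - st$pos[g] <= params$working_band]

  F_eta <- if (st$t >= params$t_load)
    viscous_load(params$k_scale, params$eta_visc, st$v_prev) else 0
  v <- force_velocity(total_load(params$F0, F_eta), length(work), params)
  st$edge <- st$edge + v * dt

  # free elongation toward the edge; working ends that can keep up ride along
  if (length(g)) {
    sp <- params$kon_rate * pmax(cos(st$ori[g]), 0)
    st$pos[g] <- pmin(st$pos[g] + sp * dt, st$edge)
  }

  p_cap <- 1 - exp(-params$cap_rate * dt)
  capped <- g[stats::runif(length(g)) < p_cap]
  if (length(capped)) {
    st$growing[capped] <- FALSE
    st$n_capped <- st$n_capped + length(capped)
  }

  mothers <- setdiff(work, capped)
  mothers <- mothers[stats::runif(length(mothers)) <
                       1 - exp(-params$branch_rate * dt)]
  nb <- length(mothers)
  if (nb) {
    st <- grow_arrays(st, nb)
    newi <- st$n_fil + seq_len(nb)
    st$pos[newi] <- st$pos[mothers]
    st$lat[newi] <- (st$lat[mothers] +
                       stats::runif(nb, -0.05, 0.05)) %% params$edge_width
    st$ori[newi] <- st$ori[mothers] +
      sample(c(-1, 1), nb, replace = TRUE) * params$branch_angle
    st$birth[newi] <- st$t
    st$growing[newi] <- TRUE
    st$n_fil <- st$n_fil + nb
    st$n_pointed <- st$n_pointed + nb
  }
  st$v_prev <- v
  st
}

#' Simulate leading-edge actin network growth under viscous load
#'
#' Runs the filament-resolved stochastic simulation from `t = 0` to
#' `params$t_end`, switching the viscous load on at `params$t_load`, and
#' records an edge trace sampled every `dt`. The run is deterministic given
#' `params$seed`.
#'
#' The reported density is the number of filament barbed ends (growing or
#' capped) within `density_band` behind the edge, per micrometre of edge.
#'
#' @param params an [actin_sim_params()] object.
#' @return A data frame of class `edge_trace` with columns `time_s`,
#'   `edge_pos_um`, `edge_vel_um_s`, `density_per_um`, `n_growing`,
#'   `n_capped`, `n_pointed` (the last two are cumulative event counts;
#'   `n_pointed` counts seed filaments plus branch events).
#' @examples
#' tr <- simulate_actin(actin_sim_params(eta_cP = 8, t_load = 1, t_end = 2,
#'                                       seed = 7))
#' head(tr)
#' @export
simulate_actin <- function(params) {
  stopifnot(inherits(params, "actin_sim_params"))
  set.seed(params$seed)
  st <- new_lamellipodium(params)
  nt <- floor(params$t_end / params$dt + 1e-9)
  out <- matrix(0, nt, 7)
  for (i in seq_len(nt)) {
    st <- actin_step(st, params)
    idx <- seq_len(st$n_fil)
    out[i, ] <- c(st$t, st$edge, st$v_prev,
                  sum(st$pos[idx] >= st$edge - params$density_band) /
                    params$edge_width,
                  sum(st$growing[idx]), st$n_capped, st$n_pointed)
  }
  tr <- as.data.frame(out)
  names(tr) <- c("time_s", "edge_pos_um", "edge_vel_um_s", "density_per_um",
                 "n_growing", "n_capped", "n_pointed")
  class(tr) <- c("edge_trace", "data.frame")
  tr
}

#' Ensemble mean and spread of simulated actin density
#'
#' Runs `n_rep` independently seeded simulations and summarizes the density
#' trace per time point, mirroring ensemble-averaged readouts of leading
#' edge actin density. Also carries the ensemble means of the edge velocity
#' and the cumulative pointed-end and capped-end counters, which are needed
#' to inspect the branching response to a load step.
#'
#' @param params an [actin_sim_params()] object; its `seed` field is ignored.
#' @param n_rep number of replicate simulations (default 20).
#' @param base_seed replicate `i` uses seed `base_seed + i - 1`.
#' @param seeds optional explicit vector of `n_rep` seeds overriding
#'   `base_seed`; duplicated seeds are permitted but trigger a warning since
#'   they make the ensemble degenerate.
#' @return A data frame with columns `time_s`, `mean_density`, `sd_density`,
#'   `mean_vel`, `mean_pointed`, `mean_capped` and attribute `n_rep`.
#' @export
ensemble_density <- function(params, n_rep = 20, base_seed = 1L,
                             seeds = NULL) {
  stopifnot(inherits(params, "actin_sim_params"))
  if (n_rep < 2) stop("n_rep must be at least 2")
  if (is.null(seeds)) seeds <- base_seed + seq_len(n_rep) - 1L
  if (length(seeds) != n_rep) stop("length(seeds) must equal n_rep")
  if (anyDuplicated(seeds))
    warning("duplicated seeds: ensemble replicates are not independent")
  runs <- lapply(seeds, function(s) {
    p <- params; p$seed <- as.integer(s); simulate_actin(p)
  })
  dens <- vapply(runs, `[[`, numeric(nrow(runs[[1]])), "density_per_um")
  out <- data.frame(
    time_s = runs[[1]]$time_s,
    mean_density = rowMeans(dens),
    sd_density = apply(dens, 1, stats::sd),
    mean_vel = rowMeans(vapply(runs, `[[`, numeric(nrow(runs[[1]])),
                               "edge_vel_um_s")),
    mean_pointed = rowMeans(vapply(runs, `[[`, numeric(nrow(runs[[1]])),
                                   "n_pointed")),
    mean_capped = rowMeans(vapply(runs, `[[`, numeric(nrow(runs[[1]])),
                                  "n_capped"))
  )
  attr(out, "n_rep") <- n_rep
  out
}
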