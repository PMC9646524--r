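#' Core parameters of the two-phase confined-migration model
#'
#' Assembles the physical constants of the one-dimensional two-phase model
#' of a confined cell: the F-actin network and the cytosol are treated as
#' interpenetrating fluid phases exchanging momentum through interfacial
#' drag, with transmembrane water fluxes driven by hydraulic and osmotic
#' pressure differences and ion fluxes that are passive (leak) plus actively
#' polarized (the osmotic engine, NHE1-like). Regime-dependent quantities
#' (adhesion profile, wall friction, cell length, medium viscosity,
#' polarization ratio) live in [regime_config()].
#'
#' Unit system: Pa, um, s; concentrations in mM; `RT` in Pa/mM so that
#' `RT * (c - c0)` is an osmotic pressure in Pa (8.314 J/(mol K) x 310 K =
#' 2577 Pa per mM). Defaults are documented stand-ins of literature
#' magnitude for a confined mesenchymal cell; see the package vignette for
#' the reasoning behind each value.
#'
#' @param eta_drag interfacial friction coefficient between cytosol and
#'   network, per unit network concentration (Pa s um^-2 mM^-1).
#' @param k_sigma_n network swelling-pressure coefficient (Pa/mM);
#'   `sigma_n = k_sigma_n * theta_n`.
#' @param gamma_depoly F-actin depolymerization rate (1/s).
#' @param D_theta_c G-actin diffusion coefficient (um^2/s).
#' @param D_c ion diffusion coefficient (um^2/s).
#' @param alpha_f,alpha_b membrane water permeability at the front/back
#'   face (um/(Pa s)).
#' @param RT gas constant times absolute temperature (Pa/mM).
#' @param k_sol_f,k_sol_b passive ion permeability front/back (um/s).
#' @param J_active_b active ion flux at the rear face (mM um/s,
#'   inward-positive; a negative default encodes rear efflux).
#' @param J_actin_f0 maximal polymerization flux at the front (mM um/s).
#' @param theta_cc polymerization saturation constant (mM).
#' @param theta_star mean total (F+G) actin concentration (mM).
#' @param c0_f,c0_b external ion concentrations at the channel ends (mM).
#' @param p0_f,p0_b hydraulic pressures at the channel ends (Pa).
#' @param L0 channel length (um).
#' @param w smallest cross-sectional channel dimension (um).
#' @param dg_split fraction of the effective channel length assigned to the
#'   front side when splitting the hydraulic resistance (default 0.5,
#'   symmetric split).
#'
#' @return An object of class `two_phase_params`.
#' @seealso [regime_config()], [solve_steady_state()]
#' @export
two_phase_params <- function(eta_drag = 3000, k_sigma_n = 100,
                             gamma_depoly = 0.005, D_theta_c = 50,
                             D_c = 300, alpha_f = 3e-3, alpha_b = 3e-3,
                             RT = 2577, k_sol_f = 0.05, k_sol_b = 0.05,
                             J_active_b = -3, J_actin_f0 = 0.05,
                             theta_cc = 0.3, theta_star = 0.5,
                             c0_f = 340, c0_b = 340, p0_f = 0, p0_b = 0,
                             L0 = 200, w = 3.5, dg_split = 0.5) {
  if (any(c(D_theta_c, D_c, RT, L0, w, theta_star) <= 0))
    stop("diffusivities, RT, L0, w and theta_star must be positive")
  if (any(c(alpha_f, alpha_b, k_sol_f, k_sol_b) < 0))
    stop("permeabilities must be non-negative")
  if (dg_split < 0 || dg_split > 1) stop("dg_split must lie in [0, 1]")
  structure(list(
    eta_drag = eta_drag, k_sigma_n = k_sigma_n,
    gamma_depoly = gamma_depoly, D_theta_c = D_theta_c, D_c = D_c,
    alpha_f = alpha_f, alpha_b = alpha_b, RT = RT,
    k_sol_f = k_sol_f, k_sol_b = k_sol_b, J_active_b = J_active_b,
    J_actin_f0 = J_actin_f0, theta_cc = theta_cc, theta_star = theta_star,
    c0_f = c0_f, c0_b = c0_b, p0_f = p0_f, p0_b = p0_b,
    L0 = L0, w = w, dg_split = dg_split
  ), class = "two_phase_params")
}

#' Viscosity-regime configuration
#'
#' The measured regime constants that distinguish confined migration in
#' low-viscosity (LV, 0.77 cP) and high-viscosity (HV, 8 cP) medium: focal
#' adhesions are distributed symmetrically (high at both cell ends,
#' quadratic profile with minimum `b_adh = 0.3`) at LV and polarized to the
#' leading edge (quartic profile, minimum `b_adh = 0.25` at the rear) at
#' HV; the adhesion coefficient scale at HV is 8x the LV one; cell-wall
#' friction is 180 (LV) vs 900 (HV) Pa s/um; the active ion-flux
#' polarization ratio is 1.67 (LV) vs 2.84 (HV); and the confined cell
#' length is 85 (LV) vs 125 (HV) um for a 200 um channel.
#'
#' @param name `"LV"`, `"HV"` or `"custom"`.
#' @param b_adh adhesion-profile minimum, in `[0, 1]`.
#' @param profile_shape `"quadratic"` or `"quartic"`.
#' @param eta_st0 focal-adhesion coefficient scale (Pa s um^-2 mM^-1). The
#'   default LV scale is a stand-in; HV uses 8x that value.
#' @param xi cell-wall friction coefficient (Pa s/um, whole-cell).
#' @param gamma_polar front/back active ion-flux magnitude ratio (> 0).
#' @param L_cell cell length (um), must be below the channel length.
#' @param mu_cP extracellular medium viscosity (cP).
#' @return An object of class `regime_config`.
#' @examples
#' regime_config("HV")
#' regime_config("custom", b_adh = 0.5, profile_shape = "quadratic",
#'               eta_st0 = 10, xi = 300, gamma_polar = 2, L_cell = 100,
#'               mu_cP = 3)
#' @export
regime_config <- function(name = c("LV", "HV", "custom"), b_adh = NULL,
                          profile_shape = NULL, eta_st0 = NULL, xi = NULL,
                          gamma_polar = NULL, L_cell = NULL, mu_cP = NULL) {
  name <- match.arg(name)
  eta_st_lv0 <- 15
  def <- switch(name,
    LV = list(b_adh = 0.3, profile_shape = "quadratic",
              eta_st0 = eta_st_lv0, xi = 180, gamma_polar = 1.67,
              L_cell = 85, mu_cP = 0.77),
    HV = list(b_adh = 0.25, profile_shape = "quartic",
              eta_st0 = 8 * eta_st_lv0, xi = 900, gamma_polar = 2.84,
              L_cell = 125, mu_cP = 8),
    custom = list(b_adh = 0.3, profile_shape = "quadratic",
                  eta_st0 = eta_st_lv0, xi = 180, gamma_polar = 1,
                  L_cell = 100, mu_cP = 1))
  for (f in names(def)) {
    v <- get(f)
    if (!is.null(v)) def[[f]] <- v
  }
  if (def$b_adh < 0 || def$b_adh > 1) stop("b_adh must lie in [0, 1]")
  if (def$xi <= 0) stop("xi must be positive")
  if (def$gamma_polar <= 0) stop("gamma_polar must be positive")
  if (!def$profile_shape %in% c("quadratic", "quartic"))
    stop("profile_shape must be 'quadratic' or 'quartic'")
  structure(c(list(name = name), def), class = "regime_config")
}

#' Normalized focal-adhesion strength profile along the cell
#'
#' The quadratic profile `4 (1 - b) (x - 1/2)^2 + b` is high at both cell
#' ends with minimum `b` at mid-cell (the low-viscosity pattern); the
#' quartic profile `(1 - b) x^4 + b` is high at the leading edge (`x = 1`)
#' and low at the trailing edge (the high-viscosity pattern).
#'
#' @param x_norm normalized position along the cell, in `[0, 1]` (0 = rear,
#'   1 = front); vectorized.
#' @param b_adh profile minimum, in `[0, 1]`.
#' @param profile_shape `"quadratic"` or `"quartic"`.
#' @return Normalized strength values in `[b_adh, 1]`.
#' @examples
#' adhesion_profile(0.5, 0.3, "quadratic")  # 0.3
#' adhesion_profile(c(0, 1), 0.25, "quartic")  # 0.25, 1
#' @export
adhesion_profile <- function(x_norm, b_adh,
                             profile_shape = c("quadratic", "quartic")) {
  profile_shape <- match.arg(profile_shape)
  if (any(x_norm < 0 | x_norm > 1))
    stop("x_norm must lie in [0, 1]")
  if (b_adh < 0 || b_adh > 1) stop("b_adh must lie in [0, 1]")
  if (profile_shape == "quadratic")
    4 * (1 - b_adh) * (x_norm - 0.5)^2 + b_adh
  else
    (1 - b_adh) * x_norm^4 + b_adh
}

#' Hydraulic resistance of a confining channel segment
#'
#' Pipe-flow estimate `d_g = 12 mu l0 / w^2` of the pressure cost per unit
#' velocity of driving the fluid column in a narrow channel.
#'
#' @param mu viscosity of the extracellular medium (Pa s).
#' @param l0 effective channel length (um).
#' @param w smallest cross-sectional dimension (um).
#' @return Hydraulic resistance coefficient (Pa s/um).
#' @examples
#' hydraulic_resistance(8e-3, 75, 3.5)
#' @export
hydraulic_resistance <- function(mu, l0, w) {
  if (any(w <= 0)) stop("channel dimension w must be positive")
  if (any(l0 < 0)) stop("l0 must be non-negative")
  if (any(mu < 0)) stop("viscosity must be non-negative")
  12 * mu * l0 / w^2
}

#' Effective channel length ahead of and behind a confined cell
#'
#' `l0 = L0 - L`: the part of the channel not occupied by the cell.
#'
#' @param L0 channel length (um).
#' @param L_cell cell length (um), at most `L0`.
#' @return Effective channel length (um).
#' @export
effective_channel_length <- function(L0, L_cell) {
  if (any(L_cell > L0)) stop("cell length exceeds channel length")
  L0 - L_cell
}

#' Cross-sectional area of a rectangular confining channel
#'
#' @param width,height channel cross-section dimensions (um).
#' @return Area (um^2).
#' @examples
#' channel_cross_section(3.5, 10)  # 35
#' @export
channel_cross_section <- function(width, height) {
  if (any(width <= 0) || any(height <= 0))
    stop("channel dimensions must be positive")
  width * height
}

#' Transmembrane water flux
#'
#' Water crosses the membrane down its chemical potential gradient:
#' `J_water = -alpha * ((p_face - p_star) - RT (c_face - c0))`, positive
#' inward. Hydrostatic excess inside pushes water out; osmotic excess
#' inside draws water in.
#'
#' @param alpha membrane water permeability (um/(Pa s)).
#' @param p_face intracellular pressure at the face (Pa).
#' @param p_star external pressure experienced by the face (Pa).
#' @param c_face intracellular ion concentration at the face (mM).
#' @param c0 external ion concentration (mM).
#' @param RT gas constant times temperature (Pa/mM).
#' @return Water flux (um/s), inward-positive.
#' @export
water_flux <- function(alpha, p_face, p_star, c_face, c0, RT) {
  if (any(alpha < 0)) stop("alpha must be non-negative")
  -alpha * ((p_face - p_star) - RT * (c_face - c0))
}

#' External pressures experienced by the cell faces
#'
#' Hydraulic resistance in the channel shifts the pressure felt by a moving
#' cell away from the channel-end values: `p*_f = p0_f + d_g_f (v0 -
#' J_water_f)` and `p*_b = p0_b - d_g_b (v0 + J_water_b)`.
#'
#' @param p0_f,p0_b pressures at the channel ends (Pa).
#' @param d_g_f,d_g_b hydraulic resistance coefficients (Pa s/um).
#' @param v0 cell velocity (um/s).
#' @param J_water_f,J_water_b water fluxes at the faces (um/s, inward-positive).
#' @return A list with `p_star_f` and `p_star_b` (Pa).
#' @export
face_pressures <- function(p0_f, p0_b, d_g_f, d_g_b, v0,
                           J_water_f, J_water_b) {
  if (any(c(d_g_f, d_g_b) < 0)) stop("hydraulic resistance must be non-negative")
  list(p_star_f = p0_f + d_g_f * (v0 - J_water_f),
       p_star_b = p0_b - d_g_b * (v0 + J_water_b))
}

#' Local network velocity from the network force balance
#'
#' Solves the pointwise force balance on the actin network, in which the
#' swelling-pressure gradient, interfacial drag from the cytosol and focal
#' adhesion resistance compete:
#' `v_n = (eta v_c - k_sigma_n (dtheta_n/dx) / theta_n) / (eta + eta_st)`.
#' At a degenerate point (`theta_n = 0`) the swelling-gradient term is
#' dropped with a warning and the drag-only limit returned.
#'
#' @param theta_n local network concentration (mM).
#' @param dtheta_n_dx local network concentration gradient (mM/um).
#' @param v_c cytosol velocity (um/s).
#' @param params a [two_phase_params()] object.
#' @param eta_st_local local (non-normalized) focal-adhesion coefficient.
#' @return Network velocity (um/s).
#' @export
network_velocity <- function(theta_n, dtheta_n_dx, v_c, params,
                             eta_st_local) {
  if (any(theta_n < 0)) stop("theta_n must be non-negative")
  grad_term <- ifelse(theta_n > 0,
                      params$k_sigma_n * dtheta_n_dx / pmax(theta_n, 1e-300),
                      0)
  if (any(theta_n == 0))
    warning("theta_n = 0 at some points; swelling-gradient term dropped there")
  (params$eta_drag * v_c - grad_term) / (params$eta_drag + eta_st_local)
}

#' Polarized active ion fluxes from the rear flux and polarization ratio
#'
#' The rear active flux is prescribed and the front flux set to
#' `-gamma_polar` times it, so the magnitude ratio front/back equals the
#' polarization ratio (measured as the front-to-rear intensity ratio of the
#' relevant transporter). With a rear efflux (negative inward flux) this
#' yields a front influx `gamma_polar` times stronger.
#'
#' @param J_active_b rear active ion flux (mM um/s, inward-positive).
#' @param gamma_polar polarization ratio (> 0).
#' @return A list with `J_active_f` and `J_active_b`.
#' @examples
#' polarized_ion_fluxes(-3, 1.67)
#' @export
polarized_ion_fluxes <- function(J_active_b, gamma_polar) {
  if (gamma_polar <= 0) stop("gamma_polar must be positive")
  list(J_active_f = -gamma_polar * J_active_b, J_active_b = J_active_b)
}

#' Switch off active ion fluxes (NHE1 knockdown)
#'
#' Returns a parameter set in which both active ion fluxes are zero,
#' emulating inhibition of the transporter that powers the osmotic engine.
#' All other parameters are unchanged; the operation is idempotent.
#'
#' @param params a [two_phase_params()] object.
#' @return The modified parameter object.
#' @export
knockdown_nhe1 <- function(params) {
  stopifnot(inherits(params, "two_phase_params"))
  params$J_active_b <- 0
  params
}
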