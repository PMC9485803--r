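#' Right-hand side of the coupled glucose-insulin-glucagon system
#'
#' Pure function computing the instantaneous derivatives.  Glucose runs
#' in mg/dL, insulin in 10 pM, glucagon in pM; the delayed glucose
#' arguments of the dose-response functions are supplied in mM by the
#' caller (the simulator's history mechanism):
#'
#' * dG/dt = -(SG + a1 I) G + a2 A + R(t - tau)/V
#' * dI/dt = -n1 I + gamma1 psi(G(t - tau1))
#' * dA/dt = -n2 A + gamma2 phi(G(t - tau2))
#'
#' @param t time, min.
#' @param state numeric `c(G, I, A)` in internal units
#'   (mg/dL, 10 pM, pM).
#' @param g_lag1_mM glucose at `t - tau1`, mM.
#' @param g_lag2_mM glucose at `t - tau2`, mM.
#' @param r_delayed exogenous glucose arrival at `t - tau`,
#'   mg/(kg min).
#' @param params an [iigi_params()] object.
#' @param anchor an [hysteresis_anchor()], or `NULL` while the anchor is
#'   still ahead (rising-branch-only evaluation).
#' @param continuity_correction passed to [glucagon_dose_response()].
#' @return numeric `c(dG, dI, dA)` per minute.
#' @export
iigi_rhs <- function(t, state, g_lag1_mM, g_lag2_mM, r_delayed,
                     params, anchor = NULL,
                     continuity_correction = FALSE) {
  G <- state[[1]]; I <- state[[2]]; A <- state[[3]]
  # a far-future anchor keeps both dose-responses on their rising branch
  eff_anchor <- if (is.null(anchor))
    structure(list(g_hyst = 1, t_hyst = Inf), class = "iigi_anchor")
  else anchor
  psi <- insulin_dose_response(g_lag1_mM, t, params, eff_anchor)
  phi <- glucagon_dose_response(g_lag2_mM, t, params$k1, params$k2,
                                eff_anchor, continuity_correction)
  c(-(params$sg + params$a1 * I) * G + params$a2 * A + r_delayed / params$V,
    -params$n1 * I + params$gamma1 * psi,
    -params$n2 * A + params$gamma2 * phi)
}

#' Fasting equilibrium of the model
#'
#' Given a fasting glucose level and a parameter set, returns the
#' hormone levels that make the insulin and glucagon equations
#' stationary, plus the glucagon-action value that then also makes the
#' glucose equation stationary with no infusion:
#' `I0 = gamma1 psi_rising(G0)/n1`, `A0 = gamma2 exp(-k1 G0)/n2`,
#' `a2_eq = (SG + a1 I0) G0[mg/dL] / A0`.  Used by the synthetic-subject
#' generator to guarantee flat pre-infusion trajectories.
#'
#' @param params an [iigi_params()] object (its `a2` is ignored).
#' @param g0_mM fasting glucose, mM.
#' @return list with `i0` (10 pM), `a0` (pM) and `a2_eq`
#'   (mg/dL (pM min)^-1).
#' @export
solve_equilibrium <- function(params, g0_mM) {
  if (g0_mM <= 0) stop("'g0_mM' must be > 0", call. = FALSE)
  h_rise <- if (params$variant == "model1_hill") params$h else params$h1
  psi0 <- hill_response(g0_mM, h_rise, params$K, params$psi_scale)
  i0 <- params$gamma1 * psi0 / params$n1
  a0 <- params$gamma2 * exp(-params$k1 * g0_mM) / params$n2
  if (a0 <= 0 || !is.finite(a0))
    stop("degenerate equilibrium: fasting glucagon is zero", call. = FALSE)
  a2_eq <- (params$sg + params$a1 * i0) * mm_to_mgdl(g0_mM) / a0
  list(i0 = i0, a0 = a0, a2_eq = a2_eq)
}
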