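#' Fixed physiological constants
#'
#' Literature-derived constants that are never estimated: the insulin and
#' glucagon degradation rates, the glucose-dependent glucose clearance
#' rate, the glucose distribution volume, the Hill half-max glucose
#' (from in-vitro islet dose-response data) and the dose-response
#' prefactor.
#'
#' @return named list of fixed constants.
#' @export
iigi_fixed_constants <- function() {
  list(
    sg        = 0.014,  # min^-1, glucose-dependent glucose clearance
    n1        = 0.14,   # min^-1, insulin degradation
    n2        = 0.08,   # min^-1, glucagon degradation
    V         = 1.35,   # dL/kg, glucose distribution volume
    K         = 17,     # mM, Hill half-max glucose
    psi_scale = 1.5     # dimensionless dose-response prefactor
  )
}

#' Model parameter set
#'
#' Assembles the full parameter set of the coupled
#' glucose-insulin-glucagon system.  Parameters are partitioned into a
#' fixed set (literature constants, see [iigi_fixed_constants()]), an
#' estimated set (`a1`, `a2`, `gamma1`, `gamma2`, `k1`, and `h` or
#' `h1`/`h2` depending on the variant) and a manually adjusted set
#' (the delays `tau`, `tau1`, `tau2` and the glucagon recovery constant
#' `k2`).
#'
#' @param a1 insulin sensitivity, (10 pM min)^-1.
#' @param a2 glucagon action, mg/dL (pM min)^-1.
#' @param gamma1 insulin secretion scale, 10 pM min^-1.
#' @param gamma2 glucagon secretion scale, pM min^-1.
#' @param k1 glucagon suppression constant, mM^-1.
#' @param k2 glucagon recovery constant, mM^-1 (manually adjusted).
#' @param h Hill coefficient (variant `"model1_hill"` only).
#' @param h1,h2 rising/falling Hill coefficients (variant
#'   `"model2_hysteresis"` only).
#' @param tau delay on the exogenous glucose arrival, min.
#' @param tau1 delay on insulin secretion, min.
#' @param tau2 delay on glucagon suppression, min.
#' @param variant `"model1_hill"` or `"model2_hysteresis"`.
#' @param fixed optional named list overriding entries of
#'   [iigi_fixed_constants()] (an explicit override is required; the
#'   constants are not free parameters).
#' @return an object of class `iigi_params`.
#' @export
iigi_params <- function(a1, a2, gamma1, gamma2, k1, k2,
                        h = NULL, h1 = NULL, h2 = NULL,
                        tau = 0, tau1 = 0, tau2 = 0,
                        variant = c("model1_hill", "model2_hysteresis"),
                        fixed = list()) {
  variant <- match.arg(variant)
  fc <- utils::modifyList(iigi_fixed_constants(), fixed)

  num1 <- function(x, nm, min = 0, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    if (strict && x <= min)
      stop(sprintf("'%s' must be > %g", nm, min), call. = FALSE)
    if (!strict && x < min)
      stop(sprintf("'%s' must be >= %g", nm, min), call. = FALSE)
    x
  }
  # couplings and secretion scales may be exactly 0 (decoupled limits
  # used in verification); rate constants and Hill coefficients may not
  a1     <- num1(a1, "a1", strict = FALSE)
  a2     <- num1(a2, "a2", strict = FALSE)
  gamma1 <- num1(gamma1, "gamma1", strict = FALSE)
  gamma2 <- num1(gamma2, "gamma2", strict = FALSE)
  k1     <- num1(k1, "k1"); k2 <- num1(k2, "k2")
  tau    <- num1(tau, "tau", strict = FALSE)
  tau1   <- num1(tau1, "tau1", strict = FALSE)
  tau2   <- num1(tau2, "tau2", strict = FALSE)

  if (variant == "model1_hill") {
    if (is.null(h) || !is.null(h1) || !is.null(h2))
      stop("variant 'model1_hill' requires 'h' and forbids 'h1'/'h2'",
           call. = FALSE)
    h <- num1(h, "h")
  } else {
    if (is.null(h1) || is.null(h2) || !is.null(h))
      stop("variant 'model2_hysteresis' requires 'h1' and 'h2' and forbids 'h'",
           call. = FALSE)
    h1 <- num1(h1, "h1"); h2 <- num1(h2, "h2")
  }

  structure(
    list(a1 = a1, a2 = a2, gamma1 = gamma1, gamma2 = gamma2,
         k1 = k1, k2 = k2, h = h, h1 = h1, h2 = h2,
         tau = tau, tau1 = tau1, tau2 = tau2,
         sg = fc$sg, n1 = fc$n1, n2 = fc$n2, V = fc$V,
         K = fc$K, psi_scale = fc$psi_scale,
         variant = variant),
    class = "iigi_params")
}

#' @export
print.iigi_params <- function(x, ...) {
  cat("IIGI model parameters (", x$variant, ")\n", sep = "")
  est <- c("a1", "a2", "gamma1", "gamma2", "k1",
           if (x$variant == "model1_hill") "h" else c("h1", "h2"))
  man <- c("tau", "tau1", "tau2", "k2")
  fix <- c("sg", "n1", "n2", "V", "K", "psi_scale")
  show <- function(nms, label) {
    v <- unlist(x[nms])
    cat(" ", label, ": ",
        paste(sprintf("%s=%g", names(v), v), collapse = ", "), "\n", sep = "")
  }
  show(est, "estimated"); show(man, "manual"); show(fix, "fixed")
  invisible(x)
}

#' Hysteresis anchor
#'
#' The glucose-curve maximum `(G_hyst, t_hyst)` at which both
#' dose-response functions switch from their rising to their falling
#' branch.  In fitting mode the anchor comes from the measured glucose
#' profile ([detect_hysteresis_anchor()]); in pure forward simulation it
#' is located by a rising-branch-only pre-run.
#'
#' @param g_hyst glucose at the curve maximum, mM.
#' @param t_hyst time of the maximum, min, in (0, t_end].
#' @return an object of class `iigi_anchor`.
#' @export
hysteresis_anchor <- function(g_hyst, t_hyst) {
  if (!is.numeric(g_hyst) || length(g_hyst) != 1L || !is.finite(g_hyst) ||
      g_hyst <= 0)
    stop("'g_hyst' must be a single positive number (mM)", call. = FALSE)
  if (!is.numeric(t_hyst) || length(t_hyst) != 1L || !is.finite(t_hyst) ||
      t_hyst <= 0)
    stop("'t_hyst' must be a single positive time (min)", call. = FALSE)
  structure(list(g_hyst = g_hyst, t_hyst = t_hyst), class = "iigi_anchor")
}

#' @export
print.iigi_anchor <- function(x, ...) {
  cat(sprintf("Hysteresis anchor: G_hyst = %.3g mM at t_hyst = %g min\n",
              x$g_hyst, x$t_hyst))
  invisible(x)
}

#' Published per-group parameter ranges
#'
#' Min/max of each estimated and manually adjusted parameter across the
#' seven fitted subjects of each group (Hill-variant fits), used for
#' range-uniform synthetic draws and fitting initial guesses.  Units as
#' in [iigi_params()].
#'
#' @param group `"CS"` (control subjects) or `"T2D"`.
#' @return named list of `c(min, max)` ranges.
#' @export
iigi_param_ranges <- function(group = c("CS", "T2D")) {
  group <- match.arg(group)
  if (group == "CS") {
    list(a1 = c(5.5e-5, 1.2e-3), a2 = c(0.052, 0.59),
         gamma1 = c(3.2, 21), gamma2 = c(0.92, 8.12),
         k1 = c(0.046, 0.48), k2 = c(0.35, 0.55),
         h  = c(1.3, 2.3), tau = c(0, 5.3), tau1 = c(0, 12), tau2 = c(0, 0))
  } else {
    list(a1 = c(5e-5, 1.1e-4), a2 = c(0.11, 0.5),
         gamma1 = c(2.0, 10), gamma2 = c(1.4, 8.6),
         k1 = c(0.1, 0.23), k2 = c(0.33, 0.60),
         h  = c(1.0, 1.9), tau = c(0, 12), tau1 = c(0, 45), tau2 = c(0, 5))
  }
}
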