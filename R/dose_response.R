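#' Hill dose-response for glucose-dependent insulin secretion
#'
#' `psi = psi_scale * G^h / (K^h + G^h)`, the sigmoidal secretion drive
#' used by the single-Hill insulin variant and by the rising branch of
#' the hysteresis variant.  Bounded in `[0, psi_scale)` and monotone
#' nondecreasing in glucose.
#'
#' @param g_mM glucose, mM (vectorised).
#' @param h Hill coefficient, > 0.
#' @param K half-max glucose, mM.
#' @param psi_scale dimensionless prefactor.
#' @return secretion drive, dimensionless.
#' @export
hill_response <- function(g_mM, h, K = 17, psi_scale = 1.5) {
  if (any(!is.finite(g_mM)) || any(g_mM < 0))
    stop("'g_mM' must be finite and >= 0", call. = FALSE)
  if (h <= 0 || K <= 0) stop("'h' and 'K' must be > 0", call. = FALSE)
  # (G/K)^h form avoids overflow for large h * log(G)
  r <- (g_mM / K)^h
  psi_scale * r / (1 + r)
}

#' Branch-matching constant of the hysteretic insulin dose-response
#'
#' The falling branch `C1 * G^h2 / (K^h2 + G^h2)` is anchored so that it
#' meets the rising branch `psi_scale * G^h1 / (K^h1 + G^h1)` exactly at
#' the glucose-curve maximum `G_hyst`:
#' `C1 = psi_scale * (G^h1/(K^h1+G^h1)) * ((K^h2+G^h2)/G^h2)` at
#' `G = G_hyst`.
#'
#' @param h1 rising Hill coefficient.
#' @param h2 falling Hill coefficient.
#' @param K half-max glucose, mM.
#' @param g_hyst anchor glucose, mM.
#' @param psi_scale dimensionless prefactor.
#' @return the matching constant C1, dimensionless.
#' @export
c1_adjustment <- function(h1, h2, K = 17, g_hyst, psi_scale = 1.5) {
  if (any(c(h1, h2, K, g_hyst) <= 0))
    stop("'h1', 'h2', 'K' and 'g_hyst' must all be > 0", call. = FALSE)
  r1 <- (g_hyst / K)^h1
  r2 <- (g_hyst / K)^h2
  psi_scale * (r1 / (1 + r1)) * ((1 + r2) / r2)
}

#' Insulin dose-response (both model variants)
#'
#' Dispatches on the parameter set's variant: the single-Hill variant
#' evaluates [hill_response()] with `h`; the hysteresis variant uses the
#' rising Hill curve (`h1`) before the anchor time and the C1-matched
#' falling curve (`h2`) from the anchor time on.  Branch selection uses
#' the undelayed clock time `t`.
#'
#' @param g_mM glucose, mM.
#' @param t time, min (used only for branch selection under hysteresis).
#' @param params an [iigi_params()] object.
#' @param anchor an [hysteresis_anchor()]; required for the hysteresis
#'   variant, ignored otherwise.
#' @return secretion drive psi, dimensionless.
#' @export
insulin_dose_response <- function(g_mM, t, params, anchor = NULL) {
  if (params$variant == "model1_hill")
    return(hill_response(g_mM, params$h, params$K, params$psi_scale))
  if (is.null(anchor))
    stop("hysteresis variant requires an anchor", call. = FALSE)
  if (t < anchor$t_hyst) {
    hill_response(g_mM, params$h1, params$K, params$psi_scale)
  } else {
    C1 <- c1_adjustment(params$h1, params$h2, params$K, anchor$g_hyst,
                        params$psi_scale)
    r2 <- (g_mM / params$K)^params$h2
    C1 * r2 / (1 + r2)
  }
}

#' Glucagon dose-response
#'
#' Exponentially decreasing secretion drive with distinct suppression
#' (`k1`, rising glucose) and recovery (`k2`, falling glucose)
#' constants.  Before the anchor time `phi = exp(-k1 G)`; from the
#' anchor time on `phi = exp(-k2 G) + yshift` with
#' `yshift = exp(-k1 G_hyst)`.  As printed, the two branches differ by
#' `exp(-k2 G_hyst)` at the switch; `continuity_correction = TRUE`
#' instead uses `yshift = exp(-k1 G_hyst) - exp(-k2 G_hyst)`, which
#' makes phi exactly continuous there (off by default).
#'
#' @param g_mM glucose, mM.
#' @param t time, min (branch selection).
#' @param k1 suppression constant, mM^-1.
#' @param k2 recovery constant, mM^-1.
#' @param anchor an [hysteresis_anchor()].
#' @param continuity_correction logical; see Details.
#' @return secretion drive phi, dimensionless.
#' @export
glucagon_dose_response <- function(g_mM, t, k1, k2, anchor,
                                   continuity_correction = FALSE) {
  if (any(!is.finite(g_mM)) || any(g_mM < 0))
    stop("'g_mM' must be finite and >= 0", call. = FALSE)
  if (k1 <= 0 || k2 <= 0) stop("'k1' and 'k2' must be > 0", call. = FALSE)
  if (is.null(anchor)) stop("glucagon dose-response requires an anchor",
                            call. = FALSE)
  if (t < anchor$t_hyst) {
    exp(-k1 * g_mM)
  } else {
    yshift <- exp(-k1 * anchor$g_hyst)
    if (continuity_correction) yshift <- yshift - exp(-k2 * anchor$g_hyst)
    exp(-k2 * g_mM) + yshift
  }
}
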