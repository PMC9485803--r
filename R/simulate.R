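#' Default blood-sampling schedule (min)
#'
#' Samples at 15, 10 and 0 min before and 5...240 min after the start of
#' the infusion, the schedule used on both the oral-challenge and the
#' infusion days.
#'
#' @return numeric vector of 20 sampling times.
#' @export
default_sample_times <- function() {
  c(-15, -10, 0, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50,
    60, 70, 90, 120, 150, 180, 240)
}

# Breakpoints where the right-hand side loses smoothness: infusion block
# edges shifted by tau, the anchor time, and their first- and
# second-order delay images under tau1/tau2.  The integrator restarts at
# each so that every segment has a smooth RHS.
rhs_breakpoints <- function(params, schedule, anchor, t_end) {
  base <- c(schedule$block_start_times, schedule$t_end) + params$tau
  if (!is.null(anchor) && is.finite(anchor$t_hyst))
    base <- c(base, anchor$t_hyst)
  lags <- unique(c(0, params$tau1, params$tau2))
  imgs <- as.vector(outer(base, lags, `+`))
  imgs <- c(imgs, as.vector(outer(imgs, lags, `+`)))
  bp <- sort(unique(imgs))
  bp <- bp[bp > 1e-9 & bp < t_end - 1e-9]
  c(0, bp, t_end)
}

#' Simulate the coupled system
#'
#' Integrates the three-state delay system by the method of steps:
#' the time axis is split at every breakpoint where the right-hand side
#' loses smoothness (infusion block edges shifted by `tau`, the anchor
#' time, and their delay images under `tau1`/`tau2`), segments are
#' additionally capped at the smallest positive state delay, and each
#' segment is integrated with `deSolve::lsoda` using the accumulated
#' dense solution (linear interpolation on a fine grid) as the delayed
#' glucose history.  The history for `t <= 0` is the constant initial
#' state (overnight-fast steady state).
#'
#' @param params an [iigi_params()] object.
#' @param schedule an [infusion_schedule()].
#' @param anchor an [hysteresis_anchor()], or `NULL` to keep both
#'   dose-responses on the rising branch for the whole run (used
#'   internally for forward-mode anchor location).
#' @param initial named or unnamed numeric `c(G, I, A)` in data units:
#'   glucose mM, insulin pM, glucagon pM.
#' @param t_end end of integration, min.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param hist_dt spacing of the stored dense solution, min.
#' @param continuity_correction passed to [glucagon_dose_response()].
#' @return an object of class `iigi_trajectory` with elements `times`,
#'   `states` (columns G mg/dL, I 10 pM, A pM), the inputs, and solver
#'   metadata (`n_rhs_evals`, `rtol`, `atol`).
#' @export
simulate_iigi <- function(params, schedule, anchor, initial,
                          t_end = 240, rtol = 1e-8, atol = 1e-10,
                          hist_dt = 0.25, continuity_correction = FALSE) {
  stopifnot(inherits(params, "iigi_params"), inherits(schedule, "iigi_schedule"))
  if (length(initial) != 3L || any(!is.finite(initial)) || any(initial < 0))
    stop("'initial' must be nonnegative finite c(G_mM, I_pM, A_pM)",
         call. = FALSE)
  y0 <- c(G = mm_to_mgdl(initial[[1]]),
          I = pm_to_internal_insulin(initial[[2]]),
          A = initial[[3]])

  rate <- delayed_rate(build_infusion_rate(schedule), params$tau)
  bp <- rhs_breakpoints(params, schedule, anchor, t_end)

  # cap segment width at the smallest positive state delay so delayed
  # lookups always fall in already-integrated history
  pos_lags <- c(params$tau1, params$tau2)
  pos_lags <- pos_lags[pos_lags > 0]
  wmax <- if (length(pos_lags)) min(pos_lags) else Inf
  segs <- bp[1]
  for (i in seq_len(length(bp) - 1L)) {
    a <- bp[i]; b <- bp[i + 1L]
    if (b - a > wmax) {
      k <- ceiling((b - a) / wmax)
      segs <- c(segs, a + (b - a) * seq_len(k) / k)
    } else segs <- c(segs, b)
  }

  # accumulated dense history
  cap <- ceiling(t_end / hist_dt) + length(segs) + 16L
  ht <- numeric(cap); hy <- matrix(0, cap, 3L)
  ht[1L] <- 0; hy[1L, ] <- y0; nh <- 1L

  g_at <- function(tq) {
    # delayed glucose lookup, mg/dL; constant history for t <= 0
    if (tq <= 0) return(y0[[1L]])
    j <- findInterval(tq, ht[seq_len(nh)])
    if (j >= nh) return(hy[nh, 1L])
    w <- (tq - ht[j]) / (ht[j + 1L] - ht[j])
    (1 - w) * hy[j, 1L] + w * hy[j + 1L, 1L]
  }

  # inlined RHS (same arithmetic as iigi_rhs, without per-call dispatch)
  sg <- params$sg; a1 <- params$a1; a2 <- params$a2
  n1 <- params$n1; n2 <- params$n2
  gamma1 <- params$gamma1; gamma2 <- params$gamma2
  k1 <- params$k1; k2 <- params$k2; V <- params$V
  K <- params$K; psc <- params$psi_scale
  tau1 <- params$tau1; tau2 <- params$tau2
  hyst <- params$variant == "model2_hysteresis"
  h_rise <- if (hyst) params$h1 else params$h
  t_hyst <- if (is.null(anchor)) Inf else anchor$t_hyst
  if (!is.null(anchor)) {
    yshift <- exp(-k1 * anchor$g_hyst)
    if (continuity_correction) yshift <- yshift - exp(-k2 * anchor$g_hyst)
    if (hyst) C1 <- c1_adjustment(params$h1, params$h2, K, anchor$g_hyst, psc)
  }

  n_eval <- 0L
  deriv <- function(t, y, p) {
    n_eval <<- n_eval + 1L
    g1 <- (if (tau1 == 0) y[[1L]] else g_at(t - tau1)) / MGDL_PER_MM
    g2 <- (if (tau2 == 0) y[[1L]] else g_at(t - tau2)) / MGDL_PER_MM
    if (t < t_hyst) {
      r <- (g1 / K)^h_rise
      psi <- psc * r / (1 + r)
      phi <- exp(-k1 * g2)
    } else {
      if (hyst) {
        r <- (g1 / K)^params$h2
        psi <- C1 * r / (1 + r)
      } else {
        r <- (g1 / K)^h_rise
        psi <- psc * r / (1 + r)
      }
      phi <- exp(-k2 * g2) + yshift
    }
    G <- y[[1L]]; I <- y[[2L]]; A <- y[[3L]]
    list(c(-(sg + a1 * I) * G + a2 * A + rate(t) / V,
           -n1 * I + gamma1 * psi,
           -n2 * A + gamma2 * phi))
  }

  y <- y0
  for (i in seq_len(length(segs) - 1L)) {
    a <- segs[i]; b <- segs[i + 1L]
    times <- seq(a, b, by = hist_dt)
    if (times[length(times)] < b) times <- c(times, b)
    sol <- deSolve::lsoda(y, times, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop(sprintf("integration failed on segment [%g, %g]", a, b),
           call. = FALSE)
    newy <- unname(sol[-1L, 2:4, drop = FALSE])
    if (any(newy < -1e-8))
      stop("integration produced a negative concentration beyond tolerance",
           call. = FALSE)
    idx <- nh + seq_len(nrow(newy))
    if (max(idx) > length(ht)) {  # grow storage if needed
      ht <- c(ht, numeric(length(ht)))
      hy <- rbind(hy, matrix(0, nrow(hy), 3L))
    }
    ht[idx] <- sol[-1L, 1L]; hy[idx, ] <- newy; nh <- max(idx)
    y <- newy[nrow(newy), ]
  }

  structure(
    list(times = ht[seq_len(nh)],
         states = hy[seq_len(nh), , drop = FALSE],
         params = params, schedule = schedule, anchor = anchor,
         initial = unname(unlist(initial)), t_end = t_end,
         rtol = rtol, atol = atol, hist_dt = hist_dt,
         continuity_correction = continuity_correction,
         n_rhs_evals = n_eval),
    class = "iigi_trajectory")
}

#' @export
print.iigi_trajectory <- function(x, ...) {
  cat(sprintf(
    "IIGI trajectory: [%g, %g] min, %d stored points, %d RHS evaluations\n",
    min(x$times), x$t_end, length(x$times), x$n_rhs_evals))
  invisible(x)
}

#' Sample a trajectory at a measurement schedule
#'
#' Linear interpolation of the dense solution, converted back to data
#' units (glucose mM, insulin pM, glucagon pM).  Times at or before 0
#' return the initial (fasting) state; times beyond the trajectory end
#' are an error.  Solver round-off in `[-1e-8, 0)` is clamped to zero.
#'
#' @param traj an `iigi_trajectory`.
#' @param times sampling times, min (default [default_sample_times()]).
#' @return data frame with columns `time_min`, `glucose_mM`,
#'   `insulin_pM`, `glucagon_pM`.
#' @export
sample_trajectory <- function(traj, times = default_sample_times()) {
  stopifnot(inherits(traj, "iigi_trajectory"))
  if (any(times > traj$t_end + 1e-9))
    stop("sampling time outside the trajectory domain", call. = FALSE)
  G0 <- traj$initial
  out <- matrix(NA_real_, length(times), 3L)
  pre <- times <= 0
  out[pre, ] <- matrix(c(mm_to_mgdl(G0[1]), pm_to_internal_insulin(G0[2]),
                         G0[3]), sum(pre), 3L, byrow = TRUE)
  if (any(!pre)) {
    for (j in 1:3)
      out[!pre, j] <- stats::approx(traj$times, traj$states[, j],
                                    xout = times[!pre], rule = 2)$y
  }
  out[out < 0 & out > -1e-8] <- 0
  if (any(out < 0))
    stop("trajectory contains negative concentrations beyond tolerance",
         call. = FALSE)
  data.frame(time_min = times,
             glucose_mM = mgdl_to_mm(out[, 1]),
             insulin_pM = internal_insulin_to_pm(out[, 2]),
             glucagon_pM = out[, 3])
}

#' Locate the glucose maximum of a trajectory on its dense grid
#'
#' @param traj an `iigi_trajectory`.
#' @return an [hysteresis_anchor()] at the dense-grid argmax (earliest
#'   tie), glucose converted to mM.
#' @export
trajectory_anchor <- function(traj) {
  post <- traj$times > 0
  i <- which.max(traj$states[post, 1L])
  hysteresis_anchor(mgdl_to_mm(traj$states[post, 1L][i]),
                    traj$times[post][i])
}

#' Forward simulation with self-consistent anchor
#'
#' In pure forward mode the anchor is not known beforehand: the system
#' is first run with both dose-responses held on their rising branch to
#' locate the glucose maximum, then re-simulated with the anchor fixed
#' at that maximum.
#'
#' @inheritParams simulate_iigi
#' @param ... passed on to [simulate_iigi()].
#' @return an `iigi_trajectory` (with the detected anchor attached).
#' @export
simulate_forward <- function(params, schedule, initial, t_end = 240, ...) {
  pre <- simulate_iigi(params, schedule, anchor = NULL, initial = initial,
                       t_end = t_end, ...)
  anchor <- trajectory_anchor(pre)
  simulate_iigi(params, schedule, anchor = anchor, initial = initial,
                t_end = t_end, ...)
}

#' Counterfactual re-simulation from a fitted subject
#'
#' Re-runs the simulation underlying a fit with named parameter fields
#' and/or the infusion schedule replaced, everything else held — the
#' substitution experiments that probe how much of a subject's glucose
#' profile is driven by the exogenous arrival profile versus their own
#' parameters.
#'
#' @param fit an `iigi_fit` from [fit_model()].
#' @param param_overrides named list of [iigi_params()] fields to
#'   replace (estimated or manual; overriding fixed constants requires
#'   `allow_fixed_override = TRUE`).
#' @param schedule optional replacement [infusion_schedule()].
#' @param allow_fixed_override logical.
#' @param ... passed to [simulate_iigi()].
#' @return an `iigi_trajectory`.
#' @export
substitute_and_simulate <- function(fit, param_overrides = list(),
                                    schedule = NULL,
                                    allow_fixed_override = FALSE, ...) {
  stopifnot(inherits(fit, "iigi_fit"))
  fixed_nms <- c("sg", "n1", "n2", "V", "K", "psi_scale")
  if (!allow_fixed_override && any(names(param_overrides) %in% fixed_nms))
    stop("overriding fixed constants requires allow_fixed_override = TRUE",
         call. = FALSE)
  p <- fit$params
  for (nm in names(param_overrides)) {
    if (!nm %in% names(p)) stop(sprintf("unknown parameter '%s'", nm),
                                call. = FALSE)
    p[[nm]] <- param_overrides[[nm]]
  }
  sched <- if (is.null(schedule)) fit$schedule else schedule
  simulate_iigi(p, sched, fit$anchor, fit$initial_state, t_end = fit$t_end,
                ...)
}
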