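#' Assay coefficients of variation
#'
#' Default CVs of the glucose, insulin and glucagon assays, which define
#' both the least-squares weights and the synthetic noise scale.
#'
#' @return named numeric vector (glucose 2%, insulin 3%, glucagon 5.5%).
#' @export
iigi_default_cvs <- function() {
  c(glucose = 0.02, insulin = 0.03, glucagon = 0.055)
}

#' CV-weighted residual vector
#'
#' `r = (y_data - y_sim) / (CV * y_data)` per analyte, concatenated in
#' fixed analyte order (glucose, insulin, glucagon) then time.  In
#' unweighted mode raw residuals are returned in the same order.  A
#' configurable assay floor bounds the weight denominator away from zero
#' for values near the detection limit (relevant for glucagon).
#'
#' @param data observed subject series (data frame with `time_min`,
#'   `glucose_mM`, `insulin_pM`, `glucagon_pM`).
#' @param sim simulated series on the same schedule.
#' @param cvs named CVs as in [iigi_default_cvs()].
#' @param weighting `"cv_weighted"` or `"unweighted"`.
#' @param floor named per-analyte lower bounds for the weight
#'   denominator, in data units.
#' @return numeric residual vector of length `3 * nrow(data)`.
#' @export
weighted_residuals <- function(data, sim, cvs = iigi_default_cvs(),
                               weighting = c("cv_weighted", "unweighted"),
                               floor = c(glucose = 0.5, insulin = 1,
                                         glucagon = 1)) {
  weighting <- match.arg(weighting)
  if (nrow(data) != nrow(sim) ||
      max(abs(data$time_min - sim$time_min)) > 1e-9)
    stop("data and simulation must share the sampling schedule",
         call. = FALSE)
  cols <- c(glucose = "glucose_mM", insulin = "insulin_pM",
            glucagon = "glucagon_pM")
  out <- lapply(names(cols), function(an) {
    y <- data[[cols[[an]]]]; yh <- sim[[cols[[an]]]]
    if (weighting == "unweighted") return(y - yh)
    if (any(y <= 0))
      stop(sprintf("nonpositive %s value under CV weighting", an),
           call. = FALSE)
    (y - yh) / (cvs[[an]] * pmax(y, floor[[an]]))
  })
  unlist(out, use.names = FALSE)
}

# Free-parameter bookkeeping per variant
free_param_names <- function(variant) {
  c("a1", "a2", "gamma1", "gamma2", "k1",
    if (variant == "model1_hill") "h" else c("h1", "h2"))
}

free_param_bounds <- function(variant) {
  nms <- free_param_names(variant)
  lower <- c(a1 = 1e-7, a2 = 1e-4, gamma1 = 1e-3, gamma2 = 1e-3, k1 = 1e-3,
             h = 0.5, h1 = 0.5, h2 = 0.5)
  upper <- c(a1 = 0.05, a2 = 10, gamma1 = 200, gamma2 = 100, k1 = 5,
             h = 4, h1 = 4, h2 = 4)
  list(lower = lower[nms], upper = upper[nms])
}

default_start <- function(variant, group = NULL, data = NULL) {
  rng <- if (is.null(group)) {
    # midpoints spanning both groups
    list(a1 = c(5e-5, 1.2e-3), a2 = c(0.052, 0.59), gamma1 = c(2, 21),
         gamma2 = c(0.92, 8.6), k1 = c(0.046, 0.48), h = c(1.0, 2.3))
  } else iigi_param_ranges(group)
  mid <- vapply(rng, mean, numeric(1))
  st <- c(a1 = mid[["a1"]], a2 = mid[["a2"]], gamma1 = mid[["gamma1"]],
          gamma2 = mid[["gamma2"]], k1 = mid[["k1"]],
          h = mid[["h"]], h1 = mid[["h"]], h2 = mid[["h"]])
  if (!is.null(data)) {
    # anchor the secretion scales and a2 to the observed fasting state by
    # inverting the equilibrium algebra at mid-range k1/h/a1
    fc <- iigi_fixed_constants()
    base <- data[data$time_min <= 0, , drop = FALSE]
    g0 <- mean(base$glucose_mM)
    i0 <- pm_to_internal_insulin(mean(base$insulin_pM))
    a0 <- mean(base$glucagon_pM)
    if (g0 > 0 && i0 > 0 && a0 > 0) {
      psi0 <- hill_response(g0, st[["h"]], fc$K, fc$psi_scale)
      bds <- free_param_bounds("model1_hill")
      clip <- function(v, nm) min(max(v, bds$lower[[nm]]), bds$upper[[nm]])
      st[["gamma1"]] <- clip(fc$n1 * i0 / psi0, "gamma1")
      st[["gamma2"]] <- clip(fc$n2 * a0 / exp(-st[["k1"]] * g0), "gamma2")
      st[["a2"]] <- clip((fc$sg + st[["a1"]] * i0) * mm_to_mgdl(g0) / a0,
                         "a2")
    }
  }
  st[free_param_names(variant)]
}

build_params <- function(theta, manual, variant, fixed = list()) {
  th <- as.list(theta)
  if (variant == "model1_hill") {
    iigi_params(a1 = th$a1, a2 = th$a2, gamma1 = th$gamma1,
                gamma2 = th$gamma2, k1 = th$k1, k2 = manual$k2,
                h = th$h, tau = manual$tau, tau1 = manual$tau1,
                tau2 = manual$tau2, variant = variant, fixed = fixed)
  } else {
    iigi_params(a1 = th$a1, a2 = th$a2, gamma1 = th$gamma1,
                gamma2 = th$gamma2, k1 = th$k1, k2 = manual$k2,
                h1 = th$h1, h2 = th$h2, tau = manual$tau, tau1 = manual$tau1,
                tau2 = manual$tau2, variant = variant, fixed = fixed)
  }
}

#' Fit the model to one subject's series
#'
#' Weighted Levenberg-Marquardt estimation (via `minpack.lm::nls.lm`) of
#' the free parameter set (`a1`, `a2`, `gamma1`, `gamma2`, `k1` and the
#' Hill coefficient(s)) with the physiological constants fixed and the
#' manual set (`tau`, `tau1`, `tau2`, `k2`) held at supplied values.
#' The initial state is the mean of the baseline (`t <= 0`) samples; the
#' hysteresis anchor is detected from the measured glucose profile.
#' Several seeded starts guard against the sensitivity to initial
#' guesses seen in some subjects; the best converged objective is kept.
#'
#' @param data observed subject series.
#' @param schedule the subject's [infusion_schedule()].
#' @param variant model variant to fit.
#' @param manual named list with `tau`, `tau1`, `tau2`, `k2`.
#' @param weighting `"cv_weighted"` (default) or `"unweighted"`.
#' @param cvs assay CVs.
#' @param start optional named start vector for the free set; defaults
#'   to mid-range values (`group` selects the group-specific ranges).
#' @param group optional `"CS"`/`"T2D"` used only for default starts.
#' @param n_starts number of starts (first = `start`, the rest drawn
#'   uniformly within the bounds from `seed`).
#' @param seed integer seed for the extra starts.
#' @param fixed optional overrides of fixed constants.
#' @param rtol,atol,hist_dt solver settings for the embedded simulations.
#' @param control passed to `minpack.lm::nls.lm.control`.  The default
#'   sizes the finite-difference step (`epsfcn`) to the integration
#'   tolerance rather than machine epsilon: the residuals carry solver
#'   noise, and steps below that floor produce useless Jacobians.
#' @return an object of class `iigi_fit`: estimates, standard errors and
#'   t-based p-values, residuals, RSS, adjusted R-squared, AICc,
#'   convergence info, iteration log, and the inputs needed to
#'   re-simulate.
#' @export
fit_model <- function(data, schedule,
                      variant = c("model1_hill", "model2_hysteresis"),
                      manual = list(tau = 0, tau1 = 0, tau2 = 0, k2 = 0.5),
                      weighting = c("cv_weighted", "unweighted"),
                      cvs = iigi_default_cvs(),
                      start = NULL, group = NULL, n_starts = 5, seed = 1,
                      fixed = list(),
                      rtol = 1e-8, atol = 1e-10, hist_dt = 0.25,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12,
                        epsfcn = 1e-8)) {
  variant <- match.arg(variant)
  weighting <- match.arg(weighting)
  stopifnot(all(c("tau", "tau1", "tau2", "k2") %in% names(manual)))

  base <- data[data$time_min <= 0, , drop = FALSE]
  if (nrow(base) < 1L) stop("no baseline (t <= 0) samples", call. = FALSE)
  init <- c(mean(base$glucose_mM), mean(base$insulin_pM),
            mean(base$glucagon_pM))
  anchor <- detect_hysteresis_anchor(data)
  times <- data$time_min
  t_end <- max(times)

  nms <- free_param_names(variant)
  bds <- free_param_bounds(variant)
  if (is.null(start)) start <- default_start(variant, group, data)
  start <- start[nms]

  iter_log <- new.env(parent = emptyenv()); iter_log$sse <- numeric()
  resid_fn <- function(theta) {
    names(theta) <- nms
    p <- try(build_params(theta, manual, variant, fixed), silent = TRUE)
    if (inherits(p, "try-error")) return(rep(1e6, 3L * nrow(data)))
    tr <- try(simulate_iigi(p, schedule, anchor, init, t_end = t_end,
                            rtol = rtol, atol = atol, hist_dt = hist_dt),
              silent = TRUE)
    if (inherits(tr, "try-error")) return(rep(1e6, 3L * nrow(data)))
    sim <- sample_trajectory(tr, times)
    r <- weighted_residuals(data, sim, cvs, weighting)
    iter_log$sse <- c(iter_log$sse, sum(r^2))
    r
  }

  starts <- list(start)
  if (n_starts > 1) {
    rs <- local({
      set.seed(seed)
      replicate(n_starts - 1L,
                stats::runif(length(nms), bds$lower, bds$upper),
                simplify = FALSE)
    })
    rs <- lapply(rs, function(v) stats::setNames(v, nms))
    starts <- c(starts, rs)
  }

  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(par = st, lower = bds$lower,
                                  upper = bds$upper, fn = resid_fn,
                                  control = control), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("all Levenberg-Marquardt starts failed", call. = FALSE)

  theta <- stats::setNames(unclass(best$par), nms)
  params <- build_params(theta, manual, variant, fixed)
  traj <- simulate_iigi(params, schedule, anchor, init, t_end = t_end,
                        rtol = rtol, atol = atol, hist_dt = hist_dt)
  sim <- sample_trajectory(traj, times)
  r <- weighted_residuals(data, sim, cvs, weighting)
  rss <- sum(r^2)
  n <- length(r); p_free <- length(nms)

  # asymptotic covariance from a central-difference Jacobian at the optimum
  J <- matrix(NA_real_, n, p_free)
  for (j in seq_len(p_free)) {
    dj <- pmax(abs(theta[j]) * 1e-5, 1e-10)
    up <- theta; up[j] <- up[j] + dj
    dn <- theta; dn[j] <- dn[j] - dj
    J[, j] <- (resid_fn(up) - resid_fn(dn)) / (2 * dj)
  }
  s2 <- rss / (n - p_free)
  JtJ <- crossprod(J)
  cov <- try(solve(JtJ) * s2, silent = TRUE)
  singular <- inherits(cov, "try-error") || any(!is.finite(diag(cov))) ||
    any(diag(cov) < 0)
  se <- if (singular) rep(NA_real_, p_free) else sqrt(diag(cov))
  tval <- theta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p_free, lower.tail = FALSE)

  st <- fit_statistics_internal(data, r, rss, n, p_free, cvs, weighting)

  structure(
    list(estimates = theta, se = stats::setNames(se, nms),
         p_values = stats::setNames(pval, nms),
         manual = manual[c("tau", "tau1", "tau2", "k2")],
         fixed = utils::modifyList(iigi_fixed_constants(), fixed),
         variant = variant, params = params, anchor = anchor,
         initial_state = init, schedule = schedule, data = data,
         residuals = r, rss = rss, n = n, p = p_free,
         adj_r_squared = st$adj_r_squared, aicc = st$aicc,
         weighting = weighting, cvs = cvs,
         converged = best$info %in% 1:3, info = best$info,
         message = best$message, t_end = t_end,
         iteration_sse = iter_log$sse,
         data_hash = series_hash(data),
         singular_jacobian = singular),
    class = "iigi_fit")
}

# adjusted R^2 on the fitted (weighted) scale with per-analyte means,
# plus AICc
fit_statistics_internal <- function(data, r, rss, n, p_free, cvs,
                                    weighting) {
  mean_model <- data
  for (cl in c("glucose_mM", "insulin_pM", "glucagon_pM"))
    mean_model[[cl]] <- mean(data[[cl]])
  r0 <- weighted_residuals(data, mean_model, cvs, weighting)
  tss <- sum(r0^2)
  adj <- 1 - (rss / (n - p_free)) / (tss / (n - 1))
  list(adj_r_squared = adj, aicc = aicc(rss, n, p_free))
}

#' Fit statistics of a completed fit
#'
#' @param fit an `iigi_fit`.
#' @return list with `adj_r_squared`, `se`, `p_values`, `aicc`.
#' @export
fit_statistics <- function(fit) {
  stopifnot(inherits(fit, "iigi_fit"))
  if (fit$n <= fit$p + 1)
    stop("statistics undefined: n <= p + 1", call. = FALSE)
  list(adj_r_squared = fit$adj_r_squared, se = fit$se,
       p_values = fit$p_values, aicc = fit$aicc)
}

#' @export
print.iigi_fit <- function(x, ...) {
  cat(sprintf("IIGI model fit (%s, %s), %sconverged\n", x$variant,
              x$weighting, if (x$converged) "" else "NOT "))
  tab <- data.frame(estimate = x$estimates, se = x$se, p = x$p_values)
  print(signif(tab, 3))
  cat(sprintf("n = %d, p = %d, RSS = %.4g, adj R^2 = %.4f, AICc = %.1f\n",
              x$n, x$p, x$rss, x$adj_r_squared, x$aicc))
  cat(sprintf("manual: tau = %g, tau1 = %g, tau2 = %g, k2 = %g\n",
              x$manual$tau, x$manual$tau1, x$manual$tau2, x$manual$k2))
  invisible(x)
}

#' Grid search over the manually adjusted parameters
#'
#' Runs [fit_model()] at every combination of candidate values for
#' `tau`, `tau1`, `tau2` and `k2` and keeps the tuple with the smallest
#' weighted SSE (ties broken toward smaller `tau`, then `tau1`, `tau2`,
#' then smaller `k2`), mirroring the manual visual adjustment used with
#' clinical profiles.
#'
#' @param data,schedule as in [fit_model()].
#' @param grids named list of candidate vectors for `tau`, `tau1`,
#'   `tau2`, `k2` (missing entries default to the single value in
#'   `manual_default`).
#' @param manual_default fallback singleton values.
#' @param ... passed to [fit_model()].
#' @return list with `manual` (the selected tuple), `fit` (its
#'   `iigi_fit`) and `sse_grid` (a data frame of all tuples and SSEs).
#' @export
grid_adjust_manual <- function(data, schedule, grids = list(),
                               manual_default = list(tau = 0, tau1 = 0,
                                                     tau2 = 0, k2 = 0.5),
                               ...) {
  nm <- c("tau", "tau1", "tau2", "k2")
  full <- lapply(nm, function(x)
    if (!is.null(grids[[x]])) grids[[x]] else manual_default[[x]])
  names(full) <- nm
  if (any(vapply(full, length, 1L) == 0L))
    stop("empty candidate grid", call. = FALSE)
  tuples <- expand.grid(full, KEEP.OUT.ATTRS = FALSE)
  fits <- vector("list", nrow(tuples))
  sses <- numeric(nrow(tuples))
  for (i in seq_len(nrow(tuples))) {
    fits[[i]] <- fit_model(data, schedule,
                           manual = as.list(tuples[i, , drop = FALSE]), ...)
    sses[i] <- fits[[i]]$rss
  }
  ord <- order(sses, tuples$tau, tuples$tau1, tuples$tau2, tuples$k2)
  best <- ord[1L]
  list(manual = as.list(tuples[best, , drop = FALSE]), fit = fits[[best]],
       sse_grid = cbind(tuples, sse = sses))
}

# stable hash of a subject series (used to guard model comparisons)
series_hash <- function(data) {
  f <- tempfile()
  on.exit(unlink(f))
  utils::write.csv(format(data, digits = 15), f, row.names = FALSE)
  unname(tools::md5sum(f))
}
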