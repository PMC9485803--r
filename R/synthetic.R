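#' Synthetic infusion profile
#'
#' Draws a glucose infusion profile of the shape seen in the two study
#' groups: control subjects (CS) get a bimodal profile (two smooth bumps
#' peaking near ~20 and ~65 min, over within ~120 min), subjects with
#' type 2 diabetes (T2D) a single broad prolonged bump extending up to
#' ~180 min.  The continuous shape is integrated over 15-min blocks and
#' normalised so the blocks sum to `total_g` exactly.
#'
#' @param group `"CS"` or `"T2D"`.
#' @param total_g total glucose to deliver, g, in (0, 75] by default
#'   (the oral-challenge-matched ceiling).
#' @param weight_kg body weight, kg.
#' @param block_min block width, min.
#' @param t_end experiment duration, min.
#' @param max_total_g configurable ceiling.
#' @return an [infusion_schedule()].  Uses the current RNG state.
#' @export
gen_infusion_profile <- function(group = c("CS", "T2D"), total_g,
                                 weight_kg = 75, block_min = 15,
                                 t_end = 240, max_total_g = 75) {
  group <- match.arg(group)
  if (total_g <= 0) stop("'total_g' must be > 0", call. = FALSE)
  if (total_g > max_total_g)
    stop(sprintf("'total_g' exceeds the %g g ceiling", max_total_g),
         call. = FALSE)
  edges <- seq(0, t_end, by = block_min)
  if (group == "CS") {
    m1 <- stats::runif(1, 15, 28); s1 <- stats::runif(1, 8, 11)
    m2 <- stats::runif(1, 60, 80); s2 <- stats::runif(1, 11, 15)
    w1 <- stats::runif(1, 0.45, 0.62)
    mass <- function(a, b)
      w1 * (stats::pnorm(b, m1, s1) - stats::pnorm(a, m1, s1)) +
      (1 - w1) * (stats::pnorm(b, m2, s2) - stats::pnorm(a, m2, s2))
    cutoff <- 120
  } else {
    m1 <- stats::runif(1, 50, 70); s1 <- stats::runif(1, 28, 38)
    mass <- function(a, b) stats::pnorm(b, m1, s1) - stats::pnorm(a, m1, s1)
    cutoff <- 180
  }
  g <- mass(edges[-length(edges)], edges[-1L])
  g[edges[-length(edges)] >= cutoff] <- 0
  g <- g / sum(g) * total_g
  infusion_schedule(g, weight_kg, block_min = block_min)
}

#' Draw a synthetic subject's parameter set
#'
#' `"range_uniform"` draws each estimated/manual parameter uniformly
#' within its group's published range ([iigi_param_ranges()]), with the
#' delays rounded to the 5-min grid of the infusion-adjustment protocol;
#' `"table_resample"` returns one published per-subject row verbatim.
#' Fixed constants are always at their literature values.
#'
#' @param group `"CS"` or `"T2D"`.
#' @param mode `"range_uniform"` or `"table_resample"`.
#' @param variant model variant of the returned set (for the hysteresis
#'   variant under `"range_uniform"`, `h1`/`h2` are drawn independently
#'   from the `h` range unless given in `override`).
#' @param override named list forcing specific parameter values after
#'   the draw.
#' @return an [iigi_params()] object.  Uses the current RNG state.
#' @export
gen_subject_params <- function(group = c("CS", "T2D"),
                               mode = c("range_uniform", "table_resample"),
                               variant = c("model1_hill",
                                           "model2_hysteresis"),
                               override = list()) {
  group <- match.arg(group); mode <- match.arg(mode)
  variant <- match.arg(variant)
  if (mode == "range_uniform") {
    rng <- iigi_param_ranges(group)
    draw <- function(nm) stats::runif(1, rng[[nm]][1], rng[[nm]][2])
    draw5 <- function(nm) 5 * round(draw(nm) / 5)
    vals <- list(a1 = draw("a1"), a2 = draw("a2"), gamma1 = draw("gamma1"),
                 gamma2 = draw("gamma2"), k1 = draw("k1"), k2 = draw("k2"),
                 tau = draw5("tau"), tau1 = draw5("tau1"),
                 tau2 = draw5("tau2"))
    if (variant == "model1_hill") vals$h <- draw("h")
    else { vals$h1 <- draw("h"); vals$h2 <- draw("h") }
  } else {
    tab <- if (variant == "model1_hill") {
      iigi_fixture_table(if (group == "CS") "cs_model1" else "t2d_model1")
    } else {
      iigi_fixture_table(if (group == "CS") "cs_model2" else "t2d_model2")
    }
    row <- tab[sample.int(nrow(tab), 1L), , drop = FALSE]
    vals <- as.list(row[, setdiff(names(row), c("subject", "group")),
                        drop = FALSE])
  }
  vals <- utils::modifyList(vals, override)
  vals$variant <- variant
  do.call(iigi_params, vals)
}

#' Generate one complete synthetic subject
#'
#' Draws parameters and a fasting glucose level, closes the fasting
#' state via [solve_equilibrium()] (so the pre-infusion trajectory is
#' exactly flat and `a2` is the equilibrium-consistent value), draws an
#' infusion profile, simulates forward with self-consistent anchor
#' detection, samples at the experimental schedule, and adds independent
#' multiplicative Gaussian noise per analyte at the assay CVs
#' (truncated at zero).
#'
#' @param group `"CS"` or `"T2D"`.
#' @param seed integer seed; the subject is reproducible bit-for-bit.
#' @param variant model variant.
#' @param cvs noise CVs (set to `NULL` or zeros for noiseless output).
#' @param g0_range fasting glucose range, mM (defaults: CS 4.8-6.0,
#'   T2D 7.0-10.0).
#' @param total_g_range total infused glucose range, g (defaults:
#'   CS 20-50, T2D 45-75, reflecting the stronger incretin sparing in
#'   CS).
#' @param weight_range body-weight range, kg.
#' @param override passed to [gen_subject_params()].
#' @param sample_times sampling schedule.
#' @param max_attempts redraw attempts on degenerate equilibria.
#' @param ... solver settings passed to [simulate_forward()].
#' @return an object of class `iigi_subject`: true parameters, fasting
#'   state, schedule, anchor, noiseless and noisy sampled series, seed.
#' @export
gen_subject <- function(group = c("CS", "T2D"), seed,
                        variant = c("model1_hill", "model2_hysteresis"),
                        cvs = iigi_default_cvs(),
                        g0_range = NULL, total_g_range = NULL,
                        weight_range = c(70, 100),
                        override = list(),
                        sample_times = default_sample_times(),
                        max_attempts = 10, ...) {
  group <- match.arg(group); variant <- match.arg(variant)
  if (is.null(g0_range))
    g0_range <- if (group == "CS") c(4.8, 6.0) else c(7.0, 10.0)
  if (is.null(total_g_range))
    total_g_range <- if (group == "CS") c(20, 50) else c(45, 75)
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    params <- gen_subject_params(group, "range_uniform", variant,
                                 override = override)
    g0 <- stats::runif(1, g0_range[1], g0_range[2])
    eq <- try(solve_equilibrium(params, g0), silent = TRUE)
    if (inherits(eq, "try-error")) next
    # replace the drawn a2 by the equilibrium-consistent value
    params$a2 <- eq$a2_eq
    total_g <- stats::runif(1, total_g_range[1], total_g_range[2])
    weight <- stats::runif(1, weight_range[1], weight_range[2])
    schedule <- gen_infusion_profile(group, total_g, weight)
    init <- c(g0, internal_insulin_to_pm(eq$i0), eq$a0)
    # anchor at the argmax of the SAMPLED glucose series (the same rule
    # the fitter applies to measured data), iterated to a fixed point so
    # that refitting the noiseless series reproduces the generator
    # exactly
    t_end <- max(sample_times)
    traj <- try(simulate_iigi(params, schedule, NULL, init, t_end = t_end,
                              ...), silent = TRUE)
    if (inherits(traj, "try-error")) next
    anchor <- try(detect_hysteresis_anchor(
      sample_trajectory(traj, sample_times)), silent = TRUE)
    if (inherits(anchor, "try-error")) next
    ok <- FALSE
    for (it in 1:5) {
      traj <- try(simulate_iigi(params, schedule, anchor, init,
                                t_end = t_end, ...), silent = TRUE)
      if (inherits(traj, "try-error")) break
      a2nd <- detect_hysteresis_anchor(sample_trajectory(traj, sample_times))
      if (abs(a2nd$t_hyst - anchor$t_hyst) < 1e-9 &&
          abs(a2nd$g_hyst - anchor$g_hyst) < 1e-12) { ok <- TRUE; break }
      anchor <- a2nd
    }
    if (!ok) next
    if (anchor$t_hyst <= 0 || anchor$g_hyst <= g0 + 1e-9) next
    noiseless <- sample_trajectory(traj, sample_times)
    noisy <- noiseless
    if (!is.null(cvs) && any(cvs > 0)) {
      cols <- c(glucose = "glucose_mM", insulin = "insulin_pM",
                glucagon = "glucagon_pM")
      for (an in names(cols)) {
        y <- noisy[[cols[[an]]]]
        noisy[[cols[[an]]]] <-
          pmax(0, y * (1 + cvs[[an]] * stats::rnorm(length(y))))
      }
    }
    return(structure(
      list(group = group, seed = seed, params = params,
           g0_mM = g0, i0_pM = internal_insulin_to_pm(eq$i0),
           a0_pM = eq$a0, schedule = schedule, anchor = anchor,
           noiseless = noiseless, noisy = noisy, attempt = attempt),
      class = "iigi_subject"))
  }
  stop(sprintf("failed to generate a valid subject in %d attempts",
               max_attempts), call. = FALSE)
}

#' @export
print.iigi_subject <- function(x, ...) {
  cat(sprintf(
    "Synthetic %s subject (seed %d): G0 = %.2f mM, %.1f g infused\n",
    x$group, x$seed, x$g0_mM, sum(x$schedule$grams_per_block)))
  invisible(x)
}

# retry a subject draw under deterministically bumped seeds so one
# pathological draw cannot abort a whole cohort or study
gen_subject_retry <- function(group, seed, ..., n_retries = 5) {
  for (k in 0:n_retries) {
    s <- try(gen_subject(group, seed = seed + k * 1000003L, ...),
             silent = TRUE)
    if (!inherits(s, "try-error")) return(s)
  }
  stop(sprintf("subject generation failed for seed %d after %d seed bumps",
               seed, n_retries), call. = FALSE)
}

#' Generate a synthetic cohort
#'
#' Per-subject seeds are derived deterministically from one master seed,
#' so the cohort is reproducible bit-for-bit.
#'
#' @param n_cs,n_t2d group sizes (>= 0).
#' @param seed master seed.
#' @param ... passed to [gen_subject()].
#' @return list with `subjects` (list of `iigi_subject`) and `manifest`
#'   (data frame of seeds, groups and true parameter values for
#'   recovery scoring).
#' @export
gen_cohort <- function(n_cs, n_t2d, seed, ...) {
  set.seed(seed)
  n <- n_cs + n_t2d
  seeds <- sample.int(.Machine$integer.max %/% 2L, max(n, 1L))
  groups <- c(rep("CS", n_cs), rep("T2D", n_t2d))
  subjects <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- gen_subject_retry(groups[i], seed = seeds[i], ...)
    s <- subjects[[i]]
    seeds[i] <- s$seed  # record the seed actually used
    p <- s$params
    rows[[i]] <- data.frame(
      subject_id = sprintf("%s%02d", groups[i], i), group = groups[i],
      seed = seeds[i], g0_mM = s$g0_mM, i0_pM = s$i0_pM, a0_pM = s$a0_pM,
      weight_kg = s$schedule$weight_kg,
      total_g = sum(s$schedule$grams_per_block),
      a1 = p$a1, a2 = p$a2, gamma1 = p$gamma1, gamma2 = p$gamma2,
      k1 = p$k1, k2 = p$k2,
      h = if (is.null(p$h)) NA_real_ else p$h,
      h1 = if (is.null(p$h1)) NA_real_ else p$h1,
      h2 = if (is.null(p$h2)) NA_real_ else p$h2,
      tau = p$tau, tau1 = p$tau1, tau2 = p$tau2)
  }
  manifest <- if (n) do.call(rbind, rows) else
    data.frame(subject_id = character(), group = character(),
               seed = integer())
  list(subjects = subjects, manifest = manifest)
}
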