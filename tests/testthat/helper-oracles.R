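# Independent reference implementations used as oracles.  These share no
# code with the package paths they check: the arrival rate, the
# dose-response formulas and the integrator are all rewritten from the
# model definition.

# fixed-step RK4 method-of-steps reference for the three-state delay
# system; delays and t_hyst must be multiples of dt
rk4_reference <- function(params, schedule, anchor, initial, t_end = 240,
                          dt = 0.01) {
  p <- params
  g0 <- initial[1] * 18.016
  i0 <- initial[2] / 10
  a0 <- initial[3]
  n <- round(t_end / dt)
  G <- numeric(n + 1); I <- numeric(n + 1); A <- numeric(n + 1)
  G[1] <- g0; I[1] <- i0; A[1] <- a0

  rate_at <- function(t) {
    ts <- t - p$tau
    if (ts < 0 || ts >= schedule$t_end) return(0)
    blk <- floor((ts - schedule$block_start_times[1]) / schedule$block_min) + 1
    schedule$grams_per_block[blk] / schedule$block_min * 1000 /
      schedule$weight_kg
  }
  t_hyst <- if (is.null(anchor)) Inf else anchor$t_hyst
  hyst <- p$variant == "model2_hysteresis"
  h_up <- if (hyst) p$h1 else p$h
  C1 <- if (hyst && !is.null(anchor)) {
    r1 <- (anchor$g_hyst / p$K)^p$h1; r2 <- (anchor$g_hyst / p$K)^p$h2
    p$psi_scale * (r1 / (1 + r1)) * ((1 + r2) / r2)
  } else NA_real_
  yshift <- if (!is.null(anchor)) exp(-p$k1 * anchor$g_hyst) else NA_real_

  psi_at <- function(g_mgdl, t) {
    g <- g_mgdl / 18.016
    if (t < t_hyst || !hyst) {
      hh <- if (t < t_hyst) h_up else h_up  # single-Hill uses h always
      r <- (g / p$K)^hh
      p$psi_scale * r / (1 + r)
    } else {
      r <- (g / p$K)^p$h2
      C1 * r / (1 + r)
    }
  }
  phi_at <- function(g_mgdl, t) {
    g <- g_mgdl / 18.016
    if (t < t_hyst) exp(-p$k1 * g) else exp(-p$k2 * g) + yshift
  }
  # linear interpolation on the running grid; constant history for t <= 0
  g_lag <- function(tq) {
    if (tq <= 0) return(g0)
    x <- tq / dt
    j <- floor(x)
    w <- x - j
    if (j + 2 > n + 1) return(G[n + 1])
    (1 - w) * G[j + 1] + w * G[j + 2]
  }
  deriv <- function(t, g, i, a) {
    gl1 <- if (p$tau1 == 0) g else g_lag(t - p$tau1)
    gl2 <- if (p$tau2 == 0) g else g_lag(t - p$tau2)
    c(-(p$sg + p$a1 * i) * g + p$a2 * a + rate_at(t) / p$V,
      -p$n1 * i + p$gamma1 * psi_at(gl1, t),
      -p$n2 * a + p$gamma2 * phi_at(gl2, t))
  }
  for (s in seq_len(n)) {
    t <- (s - 1) * dt
    y <- c(G[s], I[s], A[s])
    k1v <- deriv(t, y[1], y[2], y[3])
    y2 <- y + dt / 2 * k1v
    k2v <- deriv(t + dt / 2, y2[1], y2[2], y2[3])
    y3 <- y + dt / 2 * k2v
    k3v <- deriv(t + dt / 2, y3[1], y3[2], y3[3])
    y4 <- y + dt * k3v
    k4v <- deriv(t + dt, y4[1], y4[2], y4[3])
    yn <- y + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    G[s + 1] <- yn[1]; I[s + 1] <- yn[2]; A[s + 1] <- yn[3]
  }
  list(times = (0:n) * dt, G = G, I = I, A = A)
}

# brute-force exact Mann-Whitney p by recursive subset enumeration
# (independent of the package's combn-based path)
mw_bruteforce_p <- function(x, y) {
  n <- length(x); m <- length(y); pool <- c(x, y)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  us <- c()
  subsets <- function(start, chosen) {
    if (length(chosen) == n) {
      us <<- c(us, u_of(pool[chosen], pool[-chosen]))
      return(invisible())
    }
    if (start > n + m) return(invisible())
    for (i in start:(n + m)) subsets(i + 1, c(chosen, i))
  }
  subsets(1, integer())
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# a small deterministic synthetic subject reused across tests (cached)
test_subject <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42, ...) {
    key <- paste0("s", seed, paste(c(...), collapse = "_"))
    if (is.null(cache[[key]]))
      cache[[key]] <- gen_subject("CS", seed = seed, ...)
    cache[[key]]
  }
})

manual_of <- function(subject) {
  list(tau = subject$params$tau, tau1 = subject$params$tau1,
       tau2 = subject$params$tau2, k2 = subject$params$k2)
}

true_free <- function(subject) {
  p <- subject$params
  c(a1 = p$a1, a2 = p$a2, gamma1 = p$gamma1, gamma2 = p$gamma2,
    k1 = p$k1, h = p$h)
}

# random draw of a physiologically plausible parameter set + schedule for
# oracle comparisons (delays on the 5-min grid so the fixed-step
# reference hits them exactly)
random_oracle_case <- function(variant = "model1_hill") {
  if (variant == "model1_hill") {
    params <- gen_subject_params("CS", "range_uniform", variant)
  } else {
    params <- gen_subject_params("CS", "range_uniform", variant)
  }
  g0 <- runif(1, 4.8, 6.0)
  eq <- solve_equilibrium(params, g0)
  params$a2 <- eq$a2_eq
  schedule <- gen_infusion_profile("CS", runif(1, 25, 50), runif(1, 70, 95))
  init <- c(g0, internal_insulin_to_pm(eq$i0), eq$a0)
  anchor <- hysteresis_anchor(g_hyst = runif(1, 8, 10),
                              t_hyst = 5 * sample(6:12, 1))
  list(params = params, schedule = schedule, init = init, anchor = anchor)
}
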