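test_that("CV-weighted residuals follow the per-analyte weighting rule", {
  d <- data.frame(time_min = c(0, 10), glucose_mM = c(5, 6),
                  insulin_pM = c(50, 60), glucagon_pM = c(10, 8))
  # identical series gives a zero vector
  expect_equal(weighted_residuals(d, d), rep(0, 6))
  s <- d; s$glucose_mM <- c(4.9, 6)
  r <- weighted_residuals(d, s)
  # single glucose discrepancy: (5 - 4.9) / (0.02 * 5) = 1
  expect_equal(r[1], 1)
  expect_equal(r[-1], rep(0, 5))
  # analyte-major ordering: glucose, insulin, glucagon blocks
  s2 <- d; s2$glucagon_pM <- c(9, 8)
  r2 <- weighted_residuals(d, s2)
  expect_equal(which(r2 != 0), 5L)
  expect_equal(r2[5], (10 - 9) / (0.055 * 10))
  # total SSE decomposes over analytes
  s3 <- d; s3$glucose_mM <- d$glucose_mM * 1.02
  s3$insulin_pM <- d$insulin_pM * 0.98; s3$glucagon_pM <- d$glucagon_pM * 1.1
  r3 <- weighted_residuals(d, s3)
  sse_parts <- sum(weighted_residuals(d, within(d, glucose_mM <- s3$glucose_mM))^2) +
    sum(weighted_residuals(d, within(d, insulin_pM <- s3$insulin_pM))^2) +
    sum(weighted_residuals(d, within(d, glucagon_pM <- s3$glucagon_pM))^2)
  expect_equal(sum(r3^2), sse_parts)
  # unweighted mode returns raw differences
  expect_equal(weighted_residuals(d, s, weighting = "unweighted"),
               c(0.1, 0, 0, 0, 0, 0))
  # schedule mismatch is an error
  s4 <- s; s4$time_min <- c(0, 11)
  expect_error(weighted_residuals(d, s4), "schedule")
  d0 <- d; d0$glucose_mM[1] <- 0
  expect_error(weighted_residuals(d0, d0), "nonpositive")
})

test_that("noiseless refits recover the generating parameters", {
  s <- test_subject(seed = 42)
  fit <- fit_model(s$noiseless, s$schedule, manual = manual_of(s),
                   group = "CS", n_starts = 1, hist_dt = 0.5)
  tru <- true_free(s)
  expect_lt(max(abs(fit$estimates - tru[names(fit$estimates)]) /
                  tru[names(fit$estimates)]), 1e-3)
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-6)
  # perfect fit drives the weighted adjusted R^2 to 1
  expect_gt(fit$adj_r_squared, 1 - 1e-8)
  # the optimizer never returns a worse objective than it started from,
  # and the returned optimum is (numerically) the best SSE it evaluated
  expect_lte(fit$rss, fit$iteration_sse[1])
  expect_lte(fit$rss, min(fit$iteration_sse) * (1 + 1e-6) + 1e-12)
})

test_that("fit is invariant to the unit system of the input file", {
  # feeding the same series expressed in mg/dL, converted back at the
  # boundary, yields identical estimates
  s <- test_subject(seed = 42)
  d <- s$noiseless
  d_mgdl <- d
  d_mgdl$glucose_mM <- mgdl_to_mm(mm_to_mgdl(d$glucose_mM))
  f1 <- fit_model(d, s$schedule, manual = manual_of(s), group = "CS",
                  n_starts = 1, hist_dt = 0.5)
  f2 <- fit_model(d_mgdl, s$schedule, manual = manual_of(s), group = "CS",
                  n_starts = 1, hist_dt = 0.5)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-10)
})

test_that("fit statistics agree with a reference nonlinear regression", {
  # two-parameter exponential toy problem fitted by both nls() and the
  # same machinery used for the model fits
  set.seed(9)
  x <- seq(0, 10, length.out = 40)
  y <- 3.2 * exp(-0.45 * x) + rnorm(40, 0, 0.05)
  res_fn <- function(th) y - th[1] * exp(-th[2] * x)
  lm_fit <- minpack.lm::nls.lm(c(A = 1, k = 0.1), fn = res_fn)
  nls_fit <- nls(y ~ A * exp(-k * x), start = list(A = 1, k = 0.1))
  sm <- summary(nls_fit)
  expect_equal(unname(coef(lm_fit)), unname(coef(nls_fit)),
               tolerance = 1e-6)
  # standard errors via (J'J)^-1 s^2 match the nls summary
  th <- coef(lm_fit)
  J <- cbind(exp(-th[2] * x), -th[1] * x * exp(-th[2] * x))
  s2 <- sum(residuals(lm_fit)^2) / (40 - 2)
  se <- sqrt(diag(solve(crossprod(J)) * s2))
  expect_equal(unname(se), unname(sm$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
  # and the t-based p-values follow
  pv <- 2 * pt(abs(th / se), df = 38, lower.tail = FALSE)
  expect_equal(unname(pv), unname(sm$coefficients[, "Pr(>|t|)"]),
               tolerance = 1e-4)
})

test_that("manual-parameter grid search recovers a generating delay", {
  s <- test_subject(seed = 203, override = list(tau1 = 30, tau = 0, tau2 = 0))
  grids <- list(tau1 = c(0, 15, 30, 45))
  g <- grid_adjust_manual(s$noiseless, s$schedule, grids = grids,
                          manual_default = list(tau = s$params$tau,
                                                tau2 = s$params$tau2,
                                                k2 = s$params$k2),
                          group = "CS", n_starts = 1, hist_dt = 0.5)
  expect_equal(g$manual$tau1, 30)
  # the selected tuple attains the smallest SSE on the grid
  expect_equal(g$fit$rss, min(g$sse_grid$sse))
  # singleton grids reduce to a plain fit
  g1 <- grid_adjust_manual(s$noiseless, s$schedule,
                           grids = list(tau1 = 30),
                           manual_default = list(tau = s$params$tau,
                                                 tau2 = s$params$tau2,
                                                 k2 = s$params$k2),
                           group = "CS", n_starts = 1, hist_dt = 0.5)
  f <- fit_model(s$noiseless, s$schedule,
                 manual = list(tau = s$params$tau, tau1 = 30,
                               tau2 = s$params$tau2, k2 = s$params$k2),
                 group = "CS", n_starts = 1, hist_dt = 0.5)
  expect_equal(g1$fit$estimates, f$estimates, tolerance = 1e-8)
  expect_error(grid_adjust_manual(s$noiseless, s$schedule,
                                  grids = list(tau1 = numeric(0))),
               "empty")
})
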