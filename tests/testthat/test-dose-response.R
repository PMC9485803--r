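test_that("Hill response reproduces closed-form values and bounds", {
  # half-max symmetry: at G = K the Hill term is 1/2 regardless of h
  for (h in c(0.7, 1, 1.9, 3.5))
    expect_equal(hill_response(17, h), 0.75)
  expect_equal(hill_response(0, 2), 0)
  # direct arithmetic at h = 1: 1.5 * 8.5 / (17 + 8.5)
  expect_equal(hill_response(8.5, 1), 0.5)
  # bounds and monotonicity over random inputs
  set.seed(1)
  for (i in 1:20) {
    g <- sort(runif(50, 0, 40)); h <- runif(1, 0.5, 4)
    v <- hill_response(g, h)
    expect_true(all(v >= 0 & v < 1.5))
    expect_true(all(diff(v) >= 0))
  }
  expect_error(hill_response(-1, 2), "finite")
  expect_error(hill_response(5, -2), "> 0")
})

test_that("C1 makes the two hysteresis branches meet at the anchor", {
  # equal coefficients collapse to the plain prefactor
  expect_equal(c1_adjustment(1.7, 1.7, 17, 9.2), 1.5)
  # branch equality at the anchor for arbitrary shapes
  set.seed(2)
  for (i in 1:25) {
    h1 <- runif(1, 0.6, 3); h2 <- runif(1, 0.6, 3)
    K <- runif(1, 10, 25); gh <- runif(1, 5, 15)
    C1 <- c1_adjustment(h1, h2, K, gh)
    rising <- hill_response(gh, h1, K)
    falling <- C1 * (gh / K)^h2 / (1 + (gh / K)^h2)
    expect_equal(falling, rising, tolerance = 1e-12)
  }
  # independent root-finding oracle for a fixed case: solve for the
  # constant that equates the branches at the anchor
  f <- function(C1) C1 * (12 / 17)^2 / (1 + (12 / 17)^2) -
    hill_response(12, 1.3, 17)
  C1_root <- uniroot(f, c(0.1, 10), tol = 1e-12)$root
  expect_equal(c1_adjustment(1.3, 2.0, 17, 12), C1_root, tolerance = 1e-9)
  expect_error(c1_adjustment(1.3, 2.0, 17, 0), "> 0")
})

test_that("insulin dose-response dispatches on variant and branch", {
  anchor <- hysteresis_anchor(9.5, 40)
  p1 <- iigi_params(a1 = 5e-4, a2 = 0.2, gamma1 = 8, gamma2 = 3,
                    k1 = 0.25, k2 = 0.5, h = 1.8)
  p2 <- iigi_params(a1 = 5e-4, a2 = 0.2, gamma1 = 8, gamma2 = 3,
                    k1 = 0.25, k2 = 0.5, h1 = 1.3, h2 = 2.0,
                    variant = "model2_hysteresis")
  # single-Hill variant ignores time entirely
  expect_equal(insulin_dose_response(7, 10, p1, anchor),
               hill_response(7, 1.8))
  expect_equal(insulin_dose_response(7, 200, p1, anchor),
               hill_response(7, 1.8))
  # hysteresis rising branch equals the h1 Hill curve
  expect_equal(insulin_dose_response(7, 10, p2, anchor),
               hill_response(7, 1.3))
  # with a steeper falling branch, psi below the anchor is lower on the
  # way down than on the way up
  g_grid <- seq(1, anchor$g_hyst - 0.5, length.out = 20)
  up <- vapply(g_grid, insulin_dose_response, numeric(1), t = 10,
               params = p2, anchor = anchor)
  down <- vapply(g_grid, insulin_dose_response, numeric(1), t = 100,
                 params = p2, anchor = anchor)
  expect_true(all(down < up))
  # the two branches agree at the anchor point itself
  expect_equal(insulin_dose_response(anchor$g_hyst, 39.9, p2, anchor),
               insulin_dose_response(anchor$g_hyst, 40, p2, anchor),
               tolerance = 1e-12)
  expect_error(insulin_dose_response(7, 10, p2, NULL), "anchor")
})

test_that("hysteresis variant with h1 = h2 reproduces the single-Hill variant", {
  anchor <- hysteresis_anchor(9.5, 40)
  p1 <- iigi_params(a1 = 5e-4, a2 = 0.2, gamma1 = 8, gamma2 = 3,
                    k1 = 0.25, k2 = 0.5, h = 1.7)
  p2 <- iigi_params(a1 = 5e-4, a2 = 0.2, gamma1 = 8, gamma2 = 3,
                    k1 = 0.25, k2 = 0.5, h1 = 1.7, h2 = 1.7,
                    variant = "model2_hysteresis")
  for (g in c(0.5, 3, 9.5, 14, 25)) for (t in c(5, 40, 150))
    expect_equal(insulin_dose_response(g, t, p2, anchor),
                 insulin_dose_response(g, t, p1, anchor),
                 tolerance = 1e-14)
})

test_that("glucagon dose-response follows the printed two-branch form", {
  anchor <- hysteresis_anchor(9.0, 45)
  # rising branch at zero glucose is exp(0) = 1
  expect_equal(glucagon_dose_response(0, 10, 0.26, 0.5, anchor), 1)
  # direct evaluation on the rising branch
  expect_equal(glucagon_dose_response(5, 10, 0.26, 0.5, anchor),
               exp(-1.3))
  # value at the switch is forced by the printed yshift
  expect_equal(glucagon_dose_response(9.0, 45, 0.26, 0.5, anchor),
               exp(-0.5 * 9) + exp(-0.26 * 9))
  # the branch discontinuity at the anchor is exactly exp(-k2 G_hyst)
  set.seed(3)
  for (i in 1:10) {
    k1 <- runif(1, 0.05, 0.5); k2 <- runif(1, 0.3, 0.7)
    gh <- runif(1, 7, 12)
    a <- hysteresis_anchor(gh, 40)
    jump <- glucagon_dose_response(gh, 40, k1, k2, a) -
      glucagon_dose_response(gh, 39.999, k1, k2, a)
    expect_equal(jump, exp(-k2 * gh), tolerance = 1e-12)
    # optional continuity-corrected mode closes the jump
    jump_cc <- glucagon_dose_response(gh, 40, k1, k2, a, TRUE) -
      glucagon_dose_response(gh, 39.999, k1, k2, a, TRUE)
    expect_equal(jump_cc, 0, tolerance = 1e-12)
  }
  # strictly decreasing in glucose on each branch; (0, 1] when rising
  g <- seq(0, 20, by = 0.5)
  rising <- glucagon_dose_response(g, 10, 0.26, 0.5, anchor)
  falling <- glucagon_dose_response(g, 100, 0.26, 0.5, anchor)
  expect_true(all(diff(rising) < 0) && all(diff(falling) < 0))
  expect_true(all(rising > 0 & rising <= 1))
  expect_error(glucagon_dose_response(-2, 10, 0.26, 0.5, anchor), "finite")
})
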