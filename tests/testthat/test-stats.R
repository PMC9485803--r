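test_that("AICc follows the closed form and penalty monotonicity", {
  expect_equal(aicc(10, 10, 2), 10 * log(1) + 4 + 12 / 7)
  # extra parameter at unchanged RSS strictly raises AICc
  set.seed(10)
  for (i in 1:10) {
    rss <- runif(1, 0.1, 100); n <- sample(20:80, 1); p <- sample(2:6, 1)
    expect_gt(aicc(rss, n, p + 1), aicc(rss, n, p))
  }
  # the additive likelihood constant cancels in differences: shifting
  # both models by the same constant leaves the difference unchanged
  d1 <- aicc(5, 60, 6) - aicc(4, 60, 7)
  expect_equal((aicc(5, 60, 6) + 3) - (aicc(4, 60, 7) + 3), d1)
  expect_error(aicc(10, 5, 6), "undefined")
  expect_error(aicc(0, 10, 2), "> 0")
})

test_that("model comparison flags near-ties and guards data identity", {
  s <- test_subject(seed = 42)
  f1 <- fit_model(s$noiseless, s$schedule, manual = manual_of(s),
                  group = "CS", n_starts = 1, hist_dt = 0.5)
  cmp_self <- compare_models(f1, f1)
  expect_equal(cmp_self$delta_aicc, 0)
  expect_equal(cmp_self$preferred, "indistinguishable")
  expect_equal(cmp_self$delta_aicc, f1$aicc - f1$aicc)
  s2 <- test_subject(seed = 7)
  f_other <- fit_model(s2$noiseless, s2$schedule, manual = manual_of(s2),
                       group = "CS", n_starts = 1, hist_dt = 0.5)
  expect_error(compare_models(f1, f_other), "identical data")
})

test_that("exact Mann-Whitney matches independent enumeration and wilcox.test", {
  # U for the published glucagon-suppression columns: every T2D value
  # exceeds exactly one CS value (0.046)
  k1_t2d <- iigi_fixture_table("t2d_model1")$k1
  k1_cs <- iigi_fixture_table("cs_model1")$k1
  mw <- mann_whitney_exact(k1_t2d, k1_cs)
  expect_equal(mw$u, 7)
  expect_lt(mw$p_value, 0.05)  # significant, as reported for k1
  # identical multisets give p = 1
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # agreement with base wilcox.test (exact, tie-free) on random data
  set.seed(11)
  for (i in 1:8) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    mw <- mann_whitney_exact(x, y)
    wt <- wilcox.test(x, y, exact = TRUE)
    expect_equal(unname(mw$u), unname(wt$statistic))
    expect_equal(mw$p_value, wt$p.value, tolerance = 1e-12)
  }
  # agreement with the brute-force recursive oracle under ties
  set.seed(12)
  for (i in 1:6) {
    x <- sample(1:4, 4, replace = TRUE); y <- sample(1:4, 4, replace = TRUE)
    expect_equal(mann_whitney_exact(x, y)$p_value, mw_bruteforce_p(x, y))
  }
  expect_error(mann_whitney_exact(numeric(0), 1:3), "nonempty")
})

test_that("Spearman rank correlation matches cor.test and behaves", {
  # perfectly monotone pair
  expect_equal(spearman_rank(1:6, (1:6)^3)$rho, 1)
  # negating one vector negates rho
  set.seed(13)
  x <- rnorm(7); y <- rnorm(7)
  expect_equal(spearman_rank(x, -y)$rho, -spearman_rank(x, y)$rho,
               tolerance = 1e-12)
  # mid-rank Pearson formula computed independently
  x10 <- rnorm(10); y10 <- rnorm(10)
  sr <- spearman_rank(x10, y10)
  expect_equal(sr$rho, cor(rank(x10), rank(y10)), tolerance = 1e-12)
  expect_equal(sr$rho, unname(cor.test(x10, y10, method = "spearman")$estimate),
               tolerance = 1e-12)
  # exact enumeration agrees with cor.test's exact p for small n
  x6 <- rnorm(6); y6 <- rnorm(6)
  expect_equal(spearman_rank(x6, y6)$p_value,
               cor.test(x6, y6, method = "spearman", exact = TRUE)$p.value,
               tolerance = 1e-9)
  expect_error(spearman_rank(rep(1, 5), rnorm(5)), "constant")
})

test_that("group summaries reproduce the published mean/SEM cells", {
  t1 <- iigi_fixture_table("cs_model1")
  t2 <- iigi_fixture_table("t2d_model1")
  both <- rbind(t1, t2)
  s <- summarize_parameters(both)
  cell <- function(param, group, what)
    s[[what]][s$parameter == param & s$group == group]
  # glucagon suppression: T2D 0.16 +/- 0.015, CS 0.26 +/- 0.047.  The
  # published per-subject values are themselves rounded to 2 s.f., so a
  # recomputed SEM can land one unit in the last digit away from the
  # published cell (here 0.048 vs 0.047)
  expect_equal(cell("k1", "T2D", "mean_2sf"), 0.16)
  expect_equal(cell("k1", "T2D", "sem_2sf"), 0.015)
  expect_equal(cell("k1", "CS", "mean_2sf"), 0.26)
  expect_lte(abs(cell("k1", "CS", "sem_2sf") - 0.047), 0.001 + 1e-12)
  # insulin secretion scale: CS mean 9.0
  expect_equal(cell("gamma1", "CS", "mean_2sf"), 9.0)
  # SEM definition: sample SD over sqrt(n)
  v <- t1$gamma1
  expect_equal(cell("gamma1", "CS", "sem"), sd(v) / sqrt(7))
  # ranges bracket the mean
  expect_true(all(s$min <= s$mean & s$mean <= s$max))
  # degenerate column: repeated identical value
  df <- data.frame(group = rep(c("A", "B"), each = 3), x = rep(2, 6))
  s0 <- summarize_parameters(df, "x")
  expect_equal(s0$sem, c(0, 0))
  expect_equal(s0$min, s0$max)
  expect_error(summarize_parameters(data.frame(group = "A", x = 1), "x"),
               "at least 2")
})

test_that("full published summary table is reproduced at 2 significant figures", {
  tabs <- rbind(iigi_fixture_table("cs_model1"),
                iigi_fixture_table("t2d_model1"))
  s <- summarize_parameters(tabs,
                            c("a1", "a2", "gamma1", "gamma2", "k1", "k2",
                              "h", "tau1", "tau"))
  printed <- list(  # parameter, group, mean, SEM as printed
    list("a1", "T2D", 8.4e-5, 0.75e-5), list("a1", "CS", 52e-5, 15e-5),
    list("a2", "T2D", 0.29, 0.059),     list("a2", "CS", 0.25, 0.069),
    list("gamma1", "T2D", 5.5, 1.1),    list("gamma1", "CS", 9.0, 2.2),
    list("gamma2", "T2D", 3.9, 0.92),   list("gamma2", "CS", 3.1, 0.92),
    list("k1", "T2D", 0.16, 0.015),     list("k1", "CS", 0.26, 0.047),
    list("k2", "T2D", 0.51, 0.046),     list("k2", "CS", 0.50, 0.029),
    list("h", "T2D", 1.4, 0.15),        list("h", "CS", 1.9, 0.14),
    list("tau1", "T2D", 26, 5.5),       list("tau1", "CS", 1.7, 1.7),
    list("tau", "T2D", 7.1, 1.9),       list("tau", "CS", 1.2, 0.80))
  # means reproduce exactly at 2 s.f.; SEMs may differ by one unit in
  # the last printed digit because the per-subject inputs are rounded
  last_digit_unit <- function(v) 10^(floor(log10(abs(v))) - 1)
  for (row in printed) {
    got <- s[s$parameter == row[[1]] & s$group == row[[2]], ]
    expect_equal(got$mean_2sf, row[[3]],
                 label = sprintf("mean %s %s", row[[1]], row[[2]]))
    expect_lte(abs(got$sem_2sf - row[[4]]),
               last_digit_unit(row[[4]]) + 1e-12,
               label = sprintf("SEM %s %s deviation", row[[1]], row[[2]]))
  }
})
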