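#' Small-sample corrected Akaike information criterion
#'
#' Gaussian profile-likelihood form with additive constants dropped:
#' `AICc = n log(RSS/n) + 2p + 2p(p+1)/(n-p-1)`.  Only differences on a
#' shared dataset are meaningful, so the dropped constant is irrelevant.
#'
#' @param rss residual sum of squares (weighted scale), > 0.
#' @param n number of observations.
#' @param p number of free parameters; requires `n > p + 1`.
#' @return AICc value.
#' @export
aicc <- function(rss, n, p) {
  if (n <= p + 1) stop("AICc undefined for n <= p + 1", call. = FALSE)
  if (rss <= 0) stop("'rss' must be > 0", call. = FALSE)
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' AICc comparison of the two insulin-response variants
#'
#' @param fit1 `iigi_fit` of the single-Hill variant.
#' @param fit2 `iigi_fit` of the hysteresis variant, on the identical
#'   data and weighting.
#' @return list with `delta_aicc` (AICc1 - AICc2; positive favours the
#'   hysteresis variant), `preferred` (`"model1_hill"`,
#'   `"model2_hysteresis"`, or `"indistinguishable"` when
#'   `|delta| < 2`), and both AICc values.
#' @export
compare_models <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "iigi_fit"), inherits(fit2, "iigi_fit"))
  if (!identical(fit1$data_hash, fit2$data_hash) ||
      !identical(fit1$weighting, fit2$weighting))
    stop("fits must share the identical data and weighting", call. = FALSE)
  delta <- fit1$aicc - fit2$aicc
  preferred <- if (abs(delta) < 2) "indistinguishable"
    else if (delta > 0) fit2$variant else fit1$variant
  list(delta_aicc = delta, preferred = preferred,
       aicc1 = fit1$aicc, aicc2 = fit2$aicc)
}

#' Exact Mann-Whitney U test
#'
#' `U` counts pairs with `x_i > y_j`, plus one half per tie.  For
#' combined sample sizes up to `exact_max` the two-sided p-value is
#' computed by full enumeration of all `choose(n+m, n)` group labelings
#' of the pooled values (valid under ties); beyond that, the normal
#' approximation with tie correction and continuity correction is used.
#' The two-sided exact p is `2 min(P(U <= u), P(U >= u))` capped at 1.
#'
#' @param x,y numeric samples (x is the first group; U counts `x > y`).
#' @param exact_max largest combined size for exact enumeration.
#' @return list with `u` and `p_value`.
#' @export
mann_whitney_exact <- function(x, y, exact_max = 25) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be nonempty", call. = FALSE)
  u_stat <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u <- u_stat(x, y)
  n <- length(x); m <- length(y)
  if (n + m <= exact_max) {
    pool <- c(x, y)
    labelings <- utils::combn(n + m, n)
    us <- apply(labelings, 2L, function(idx)
      u_stat(pool[idx], pool[-idx]))
    eps <- 1e-9
    p <- 2 * min(mean(us <= u + eps), mean(us >= u - eps))
    p <- min(1, p)
  } else {
    mu <- n * m / 2
    ties <- table(c(x, y)); N <- n + m
    sig2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    p <- min(1, p)
  }
  list(u = u, p_value = p)
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of mid-ranks.  The p-value is exact
#' (full permutation enumeration of one margin) for `n <= exact_max`,
#' otherwise via the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` with `n - 2` df.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact_max largest n for exact enumeration (default 8).
#' @return list with `rho` and `p_value` (two-sided).
#' @export
spearman_rank <- function(x, y, exact_max = 8) {
  n <- length(x)
  if (n != length(y) || n < 3L)
    stop("'x' and 'y' must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant input vector", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p)
}

# all permutations of 1..n as an (n!) x n matrix
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' Per-group parameter summary table
#'
#' Mean, SEM (sample SD with n-1 denominator over sqrt(n)) and range of
#' each parameter by group, from per-subject parameter rows (fixture
#' tables or fitted cohorts).  Absent manual delays must already be
#' encoded as 0 by the reader.  Values are kept at full precision; a
#' display copy rounded to 2 significant figures matches the printed
#' convention.
#'
#' @param params_df data frame of per-subject parameters with a `group`
#'   column.
#' @param param_cols which columns to summarise (default: all numeric
#'   columns except identifiers).
#' @return data frame with columns `parameter`, `group`, `n`, `mean`,
#'   `sem`, `min`, `max` and the 2-significant-figure display columns
#'   `mean_2sf`, `sem_2sf`; class `iigi_summary`.
#' @export
summarize_parameters <- function(params_df, param_cols = NULL) {
  if (!"group" %in% names(params_df))
    stop("'params_df' must have a 'group' column", call. = FALSE)
  if (is.null(param_cols)) {
    param_cols <- setdiff(names(params_df)[vapply(params_df, is.numeric,
                                                  TRUE)],
                          c("subject", "subject_id", "seed"))
  }
  groups <- unique(params_df$group)
  if (any(table(params_df$group) < 2L))
    stop("need at least 2 subjects per group", call. = FALSE)
  rows <- list()
  for (pc in param_cols) {
    for (g in groups) {
      v <- params_df[[pc]][params_df$group == g]
      v <- v[is.finite(v)]
      n <- length(v)
      mu <- mean(v); sem <- stats::sd(v) / sqrt(n)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = pc, group = g, n = n, mean = mu, sem = sem,
        min = min(v), max = max(v),
        mean_2sf = signif(mu, 2), sem_2sf = signif(sem, 2))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("iigi_summary", "data.frame")
  out
}
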