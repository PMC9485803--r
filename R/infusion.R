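#' Glucose infusion schedule
#'
#' Grams of glucose infused per contiguous block (15 min by default, the
#' granularity at which the clinical infusion records are kept) plus the
#' subject's body weight, from which the plasma glucose arrival rate is
#' built.
#'
#' @param grams_per_block numeric vector of grams infused in each block,
#'   all >= 0.
#' @param weight_kg body weight, kg.
#' @param block_min block width, min (default 15).
#' @param t_start start of the first block, min (default 0).
#' @return an object of class `iigi_schedule`.
#' @export
infusion_schedule <- function(grams_per_block, weight_kg, block_min = 15,
                              t_start = 0) {
  if (!is.numeric(grams_per_block) || length(grams_per_block) < 1L ||
      any(!is.finite(grams_per_block)) || any(grams_per_block < 0))
    stop("'grams_per_block' must be nonnegative finite numbers", call. = FALSE)
  if (!is.numeric(weight_kg) || length(weight_kg) != 1L || weight_kg <= 0)
    stop("'weight_kg' must be a single positive number", call. = FALSE)
  if (block_min <= 0) stop("'block_min' must be > 0", call. = FALSE)
  nb <- length(grams_per_block)
  structure(
    list(block_start_times = t_start + block_min * (seq_len(nb) - 1L),
         grams_per_block = as.numeric(grams_per_block),
         weight_kg = weight_kg, block_min = block_min,
         t_end = t_start + block_min * nb),
    class = "iigi_schedule")
}

#' @export
print.iigi_schedule <- function(x, ...) {
  cat(sprintf(
    "Infusion schedule: %d x %g-min blocks, %.2f g total, %.1f kg subject\n",
    length(x$grams_per_block), x$block_min, sum(x$grams_per_block),
    x$weight_kg))
  invisible(x)
}

#' Plasma glucose arrival rate from an infusion schedule
#'
#' Converts grams-per-block to the piecewise-constant arrival rate
#' `R(t) = grams_i / block_min * 1000 / weight` in mg/(kg min) on block
#' `i`, zero outside the infusion window, right-continuous at block
#' boundaries.
#'
#' @param schedule an [infusion_schedule()].
#' @return a vectorised function `t -> R(t)` in mg/(kg min).
#' @export
build_infusion_rate <- function(schedule) {
  stopifnot(inherits(schedule, "iigi_schedule"))
  rates <- schedule$grams_per_block / schedule$block_min * 1000 /
    schedule$weight_kg
  starts <- schedule$block_start_times
  t0 <- starts[1L]; t_end <- schedule$t_end; bw <- schedule$block_min
  function(t) {
    idx <- floor((t - t0) / bw) + 1
    out <- numeric(length(t))
    inside <- t >= t0 & t < t_end
    out[inside] <- rates[idx[inside]]
    out
  }
}

#' Delay an arrival-rate function
#'
#' @param rate_fn a function of time, e.g. from [build_infusion_rate()].
#' @param tau delay, min, >= 0.
#' @return the function `t -> rate_fn(t - tau)`.
#' @export
delayed_rate <- function(rate_fn, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop("'tau' must be a single nonnegative number", call. = FALSE)
  if (tau == 0) return(rate_fn)
  function(t) rate_fn(t - tau)
}

#' Detect the hysteresis anchor from a measured series
#'
#' The anchor is the maximum of the sampled glucose profile over
#' `t >= 0` (ties broken toward the earliest time), matching the
#' numerical-maximum convention used when fitting measured IIGI
#' profiles.
#'
#' @param series a subject series data frame (see
#'   [read_subject_series()]) with columns `time_min` and `glucose_mM`.
#' @return an [hysteresis_anchor()].
#' @export
detect_hysteresis_anchor <- function(series) {
  if (!all(c("time_min", "glucose_mM") %in% names(series)))
    stop("series must have 'time_min' and 'glucose_mM' columns",
         call. = FALSE)
  post <- series[series$time_min >= 0 & is.finite(series$glucose_mM), ,
                 drop = FALSE]
  if (nrow(post) < 3L)
    stop("need at least 3 post-infusion-start samples to locate the anchor",
         call. = FALSE)
  post <- post[order(post$time_min), , drop = FALSE]
  i <- which.max(post$glucose_mM)  # which.max takes the earliest tie
  if (post$time_min[i] <= 0) {
    # flat or monotone-decreasing profile: fall back to the first t > 0
    # maximum among strictly positive times
    pos <- post[post$time_min > 0, , drop = FALSE]
    i2 <- which.max(pos$glucose_mM)
    return(hysteresis_anchor(pos$glucose_mM[i2], pos$time_min[i2]))
  }
  hysteresis_anchor(post$glucose_mM[i], post$time_min[i])
}
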