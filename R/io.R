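#' Read a subject series CSV
#'
#' Expects columns `time_min`, `glucose_mM`, `insulin_pM`,
#' `glucagon_pM`; times strictly increasing, concentrations nonnegative,
#' and at least one baseline (`t <= 0`) row.  Schema violations are
#' reported with the offending row number.
#'
#' @param path CSV file path.
#' @return validated data frame (a subject series).
#' @export
read_subject_series <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  validate_subject_series(df, where = path)
}

validate_subject_series <- function(df, where = "series") {
  need <- c("time_min", "glucose_mM", "insulin_pM", "glucagon_pM")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(df) < 2L) stop(sprintf("%s: too few rows", where), call. = FALSE)
  bad <- which(diff(df$time_min) <= 0)
  if (length(bad))
    stop(sprintf("%s: times not strictly increasing at row %d", where,
                 bad[1L] + 1L), call. = FALSE)
  for (cl in need[-1L]) {
    bad <- which(!is.finite(df[[cl]]) | df[[cl]] < 0)
    if (length(bad))
      stop(sprintf("%s: negative or non-finite %s at row %d", where, cl,
                   bad[1L]), call. = FALSE)
  }
  if (!any(df$time_min <= 0))
    stop(sprintf("%s: no baseline (t <= 0) rows", where), call. = FALSE)
  df[need]
}

#' Write a subject series CSV
#'
#' @param series subject series data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subject_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Read an infusion schedule CSV
#'
#' Expects columns `block_start_min` and `grams`; blocks must be
#' contiguous and equally wide.
#'
#' @param path CSV file path.
#' @param weight_kg subject body weight, kg.
#' @return an [infusion_schedule()].
#' @export
read_infusion_csv <- function(path, weight_kg) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("block_start_min", "grams")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: needs columns %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  df <- df[order(df$block_start_min), ]
  w <- unique(diff(df$block_start_min))
  if (length(w) != 1L)
    stop(sprintf("%s: blocks must be contiguous and equally wide", path),
         call. = FALSE)
  infusion_schedule(df$grams, weight_kg, block_min = w,
                    t_start = df$block_start_min[1L])
}

#' Write an infusion schedule CSV
#'
#' @param schedule an [infusion_schedule()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_infusion_csv <- function(schedule, path) {
  utils::write.csv(
    data.frame(block_start_min = schedule$block_start_times,
               grams = schedule$grams_per_block),
    path, row.names = FALSE)
  invisible(path)
}

#' Export a trajectory to CSV
#'
#' Writes `time_min, glucose_mM, insulin_pM, glucagon_pM` rows of the
#' dense solution.
#'
#' @param traj an `iigi_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time_min = traj$times,
                   glucose_mM = mgdl_to_mm(traj$states[, 1L]),
                   insulin_pM = internal_insulin_to_pm(traj$states[, 2L]),
                   glucagon_pM = traj$states[, 3L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Shipped per-subject parameter fixture tables
#'
#' The published per-subject parameter estimates for the two study
#' groups and the two model variants, as shipped CSV fixtures.  Absent
#' manual delays are encoded as 0.
#'
#' @param name one of `"cs_model1"`, `"t2d_model1"`, `"cs_model2"`,
#'   `"t2d_model2"`.
#' @return data frame with `subject`, `group` and parameter columns.
#' @export
iigi_fixture_table <- function(name = c("cs_model1", "t2d_model1",
                                        "cs_model2", "t2d_model2")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("fits_", name, ".csv"),
                      package = "iigidyn", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  df$group <- if (grepl("^cs", name)) "CS" else "T2D"
  df
}

#' Run configuration
#'
#' Bundles every tunable of a pipeline run: fixed-constant overrides,
#' weighting mode, CVs, manual grids, solver tolerances, master seed and
#' display rounding.  Unspecified fields resolve to the documented
#' defaults.  The configuration hash is embedded in reports so any run
#' is reproducible from (inputs, config, seed).
#'
#' @param ... fields to override.
#' @return list of class `iigi_config` with a `hash` attribute.
#' @export
iigi_config <- function(...) {
  cfg <- list(
    weighting = "cv_weighted",
    cvs = iigi_default_cvs(),
    fixed = list(),
    manual = list(tau = 0, tau1 = 0, tau2 = 0, k2 = 0.5),
    n_starts = 5,
    seed = 1,
    rtol = 1e-8, atol = 1e-10, hist_dt = 0.25,
    variant = "model1_hill",
    display_sig_figs = 2)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  cfg <- utils::modifyList(cfg, over)
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "iigi_config"
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(cfg[sort(names(cfg))], file = f)
  unname(tools::md5sum(f))
}

#' Score fitted parameters against a cohort truth manifest
#'
#' @param fits named list of `iigi_fit` objects, names matching
#'   `manifest$subject_id`.
#' @param manifest truth manifest from [gen_cohort()].
#' @return data frame of per-subject relative errors per free parameter,
#'   plus a `median_rel_error` attribute (named vector of per-parameter
#'   medians of `|est - true| / |true|`).
#' @export
recovery_scores <- function(fits, manifest) {
  rows <- lapply(names(fits), function(id) {
    tr <- manifest[manifest$subject_id == id, , drop = FALSE]
    if (nrow(tr) != 1L) stop(sprintf("subject '%s' not in manifest", id),
                             call. = FALSE)
    est <- fits[[id]]$estimates
    rel <- vapply(names(est), function(nm)
      abs(est[[nm]] - tr[[nm]]) / abs(tr[[nm]]), numeric(1))
    data.frame(subject_id = id, parameter = names(est),
               true = vapply(names(est), function(nm) tr[[nm]], numeric(1)),
               estimate = unname(est), rel_error = unname(rel))
  })
  out <- do.call(rbind, rows)
  med <- tapply(out$rel_error, out$parameter, stats::median)
  attr(out, "median_rel_error") <- med
  out
}
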