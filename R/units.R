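#' Unit conventions
#'
#' The model runs in mixed units: the glucose mass-balance equation is
#' written in mg/dL (consistent with the units of the glucagon-action
#' constant and of the infusion term R/V), while the two dose-response
#' functions take glucose in mM (consistent with the half-max constant
#' K = 17 mM and with the suppression/recovery constants in mM^-1).
#' Insulin is carried internally in units of 10 pM so that the insulin
#' sensitivity constant has its conventional (10 pM min)^-1 scale.
#' Data files always carry glucose in mM and insulin/glucagon in pM;
#' all conversions happen at the I/O boundary, never inside the dynamics.
#'
#' @name units
#' @keywords internal
NULL

#' Conversion factor: mg/dL of glucose per mM.
#' @export
MGDL_PER_MM <- 18.016

#' Convert glucose mM -> mg/dL.
#' @param g_mM glucose in mM.
#' @return glucose in mg/dL.
#' @export
mm_to_mgdl <- function(g_mM) g_mM * MGDL_PER_MM

#' Convert glucose mg/dL -> mM.
#' @param g_mgdl glucose in mg/dL.
#' @return glucose in mM.
#' @export
mgdl_to_mm <- function(g_mgdl) g_mgdl / MGDL_PER_MM

#' Convert insulin pM -> internal 10 pM units.
#' @param i_pM insulin in pM.
#' @return insulin in 10 pM units.
#' @export
pm_to_internal_insulin <- function(i_pM) i_pM / 10

#' Convert internal insulin (10 pM) -> pM.
#' @param i_int insulin in 10 pM units.
#' @return insulin in pM.
#' @export
internal_insulin_to_pm <- function(i_int) i_int * 10
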