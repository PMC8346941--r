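# Hb pre-adjustment for altitude and smoking, applied once before any
# percentile or curve analysis.

#' Hb adjustment policy
#'
#' Encodes the standard CDC/WHO altitude polynomial and the WHO any-smoker
#' decrement. With altitude A expressed in thousands of feet
#' (`A = meters * altitude_unit_factor`), the altitude correction subtracted
#' from measured Hb is `c(A) = altitude_coeff_linear * A +
#' altitude_coeff_quad * A^2` (defaults -0.032 and 0.022 g/dL), applied only
#' at or above `altitude_floor` meters (default 1000 m: lower elevations need
#' no adjustment). Smokers among women lose `smoking_decrement` g/dL
#' (default 0.3, the WHO any-smoker adjustment). Setting every coefficient to
#' zero makes both adjustments the identity.
#'
#' @param altitude_coeff_linear g/dL per thousand feet.
#' @param altitude_coeff_quad g/dL per thousand feet squared.
#' @param altitude_floor meters; adjustment applies only at/above this.
#' @param smoking_decrement g/dL subtracted for women who smoke.
#' @param altitude_unit_factor thousand-feet per meter.
#' @return object of class `adjustment_policy`.
#' @export
adjustment_policy <- function(altitude_coeff_linear = -0.032,
                              altitude_coeff_quad = 0.022,
                              altitude_floor = 1000,
                              smoking_decrement = 0.3,
                              altitude_unit_factor = 0.0032808) {
  stopifnot(altitude_floor >= 0, smoking_decrement >= 0,
            altitude_unit_factor > 0)
  structure(list(
    altitude_coeff_linear = altitude_coeff_linear,
    altitude_coeff_quad = altitude_coeff_quad,
    altitude_floor = altitude_floor,
    smoking_decrement = smoking_decrement,
    altitude_unit_factor = altitude_unit_factor
  ), class = "adjustment_policy")
}

#' Adjust Hb for altitude
#'
#' Vectorized over individuals. Records with missing altitude, or altitude
#' below the policy floor, pass through unchanged. Above the floor the CDC
#' polynomial correction is subtracted. A nonpositive adjusted Hb is an error
#' (never silently clipped).
#'
#' @param hb measured Hb, g/dL (positive).
#' @param altitude meters, `NA` for unmeasured.
#' @param policy an [adjustment_policy()].
#' @return adjusted Hb, g/dL.
#' @export
adjust_altitude <- function(hb, altitude, policy = adjustment_policy()) {
  stopifnot(all(hb > 0))
  if (any(!is.na(altitude) & altitude < 0)) stop("negative altitude")
  apply_to <- !is.na(altitude) & altitude >= policy$altitude_floor
  A <- altitude[apply_to] * policy$altitude_unit_factor
  corr <- policy$altitude_coeff_linear * A + policy$altitude_coeff_quad * A^2
  out <- hb
  out[apply_to] <- hb[apply_to] - corr
  if (any(out <= 0)) stop("altitude adjustment produced nonpositive Hb")
  out
}

#' Adjust Hb for smoking (women only)
#'
#' Women with a positive smoking flag lose the policy decrement; children,
#' nonsmokers, and records with unmeasured smoking status are unchanged.
#'
#' @param hb measured Hb, g/dL.
#' @param smoker `"positive"`, `"negative"`, or `NA` (unmeasured).
#' @param group `"child"` or `"woman"`, vectorized.
#' @param policy an [adjustment_policy()].
#' @return adjusted Hb, g/dL.
#' @export
adjust_smoking <- function(hb, smoker, group, policy = adjustment_policy()) {
  stopifnot(all(hb > 0))
  hit <- group == "woman" & !is.na(smoker) & smoker == "positive"
  out <- hb
  out[hit] <- hb[hit] - policy$smoking_decrement
  if (any(out <= 0)) stop("smoking adjustment produced nonpositive Hb")
  out
}

#' Apply both Hb adjustments to a record set, once
#'
#' Applies altitude then smoking adjustment and tags the result with an
#' `hb_adjusted` attribute. Re-adjusting an already adjusted set is an error:
#' the adjustments are not idempotent and must run exactly once per pipeline.
#'
#' @param records record data.frame.
#' @param policy an [adjustment_policy()].
#' @param enabled set `FALSE` to pass records through untouched (sensitivity
#'   runs); the adjusted tag is still set so downstream stages see one state.
#' @return records with adjusted `hb`.
#' @export
adjust_hb_records <- function(records, policy = adjustment_policy(),
                              enabled = TRUE) {
  if (isTRUE(attr(records, "hb_adjusted"))) {
    stop("records are already Hb-adjusted; re-adjusting is an error")
  }
  if (enabled) {
    records$hb <- adjust_altitude(records$hb, records$altitude, policy)
    records$hb <- adjust_smoking(records$hb, records$smoker, records$group,
                                 policy)
  }
  attr(records, "hb_adjusted") <- TRUE
  records
}
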