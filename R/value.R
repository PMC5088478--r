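#' Time-tradeoff vision utility map
#'
#' Utilities for the acuity levels the model touches, on the standard anchors
#' of 1.00 (normal bilateral vision permanently) and 0.00 (death). Utility
#' tracks acuity in the better-seeing eye.
#'
#' @param p an \code{\link{amd_parameters}} object.
#' @return named numeric vector, ordered from best to worst vision.
#' @export
utility_map <- function(p = amd_parameters()) {
  c("20/20-20/25 bilateral" = p$utility_bilateral_good,
    "20/20-20/25 unilateral" = p$utility_unilateral_good,
    "20/40-1" = p$utility_early,
    "20/126" = p$utility_20_126,
    "20/160+2" = p$utility_late,
    "20/160-2" = p$utility_20_160m2,
    "20/640" = p$utility_20_640,
    "NLP bilateral" = p$utility_bilateral_nlp)
}

#' Present value of a constant annual utility stream
#'
#' Discounted QALYs from living \code{years} years at a constant utility,
#' end-of-year convention:
#' \deqn{\mathrm{QALY} = u \sum_{t=1}^{Y} (1+r)^{-t}.}
#'
#' @param utility per-year utility in \[0,1\].
#' @param rate annual discount rate (fraction, >= 0).
#' @param years integer number of years (>= 0).
#' @return discounted QALYs.
#' @examples
#' discounted_annuity(0.789, 0.03, 12)  # 7.854
#' @export
discounted_annuity <- function(utility, rate, years) {
  if (any(years < 0)) stop("years must be >= 0", call. = FALSE)
  if (any(utility < 0 | utility > 1)) {
    stop("utility must lie in [0, 1]", call. = FALSE)
  }
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  utility * annuity_factor(rate, years)
}

#' Annuity (present-value) factor
#'
#' \eqn{\sum_{t=1}^{Y}(1+r)^{-t}}, equal to \code{years} at zero rate.
#'
#' @param rate annual discount rate (fraction).
#' @param years integer years.
#' @return present-value factor.
#' @export
annuity_factor <- function(rate, years) {
  ifelse(rate == 0, years, (1 - (1 + rate)^(-years)) / rate)
}

#' Treatment arms of the combined-eye model
#'
#' The three arms compared: sham (natural course), early ranibizumab
#' treatment (baseline acuity 20/40-20/80, outcome 20/40-1) and late
#' treatment (baseline <=20/160, outcome 20/160+2). The 12-year discounted
#' QALY accruals are registry inputs from the combined-eye model; the
#' outcome utilities and bonus/penalty components are carried alongside for
#' the consistency check in \code{\link{accrual_consistency}}.
#'
#' @param p an \code{\link{amd_parameters}} object.
#' @return data.frame with one row per arm: \code{arm}, \code{outcome_vision},
#'   \code{outcome_utility}, \code{accrual_12yr}.
#' @export
treatment_arms <- function(p = amd_parameters()) {
  out <- data.frame(
    arm = c("sham", "early", "late"),
    outcome_vision = c("20/640 (end state)", "20/40-1", "20/160+2"),
    outcome_utility = c(p$utility_20_640, p$utility_early, p$utility_late),
    accrual_12yr = c(p$accrual_sham, p$accrual_early, p$accrual_late),
    stringsAsFactors = FALSE
  )
  if (any(out$accrual_12yr < 0) || any(out$accrual_12yr > p$timeline_years)) {
    stop("arm accrual must lie in [0, timeline_years]", call. = FALSE)
  }
  if (!(p$accrual_early >= p$accrual_late && p$accrual_late >= p$accrual_sham)) {
    stop("expected arm ordering early >= late >= sham violated", call. = FALSE)
  }
  out
}

#' Unadjusted QALY gain of one arm over a reference arm
#'
#' Difference of 12-year discounted accruals, per treated patient, before the
#' eye-presentation and test-sensitivity adjustments.
#'
#' @param arm_accrual,reference_accrual 12-year discounted QALY accruals
#'   computed over the same timeline and discount rate.
#' @return QALY difference.
#' @examples
#' qaly_gain(7.924, 5.990)  # 1.934
#' @export
qaly_gain <- function(arm_accrual, reference_accrual) {
  arm_accrual - reference_accrual
}

#' Eye-presentation and sensitivity adjustment product
#'
#' The per-patient gain applies to the screened cohort only insofar as (i)
#' the first eye would have presented late (78.0\%), (ii) the second eye
#' would have presented late (62.2\%), and (iii) genetic testing detects the
#' progressor (90\%): three-way product 43.7\%. With the combined-eye
#' multiplier (85.7\%) folded in, the four-way product is 37.4\%.
#'
#' @param p an \code{\link{amd_parameters}} object.
#' @param include_combined include the combined-eye multiplier.
#' @return the product, a fraction.
#' @examples
#' adjustment_product(amd_parameters())        # 0.4366
#' adjustment_product(amd_parameters(), TRUE)  # 0.3742
#' @export
adjustment_product <- function(p = amd_parameters(),
                               include_combined = FALSE) {
  f <- p$first_eye_late_fraction * p$second_eye_late_fraction *
    p$test_sensitivity
  if (include_combined) f <- f * p$combined_eye_multiplier
  f
}

#' Adjusted QALY gain per early-treatment case
#'
#' Unadjusted gain scaled by the three-way adjustment product.
#'
#' @param unadjusted unadjusted QALY gain (>= 0).
#' @param p an \code{\link{amd_parameters}} object.
#' @return adjusted QALY gain.
#' @examples
#' adjusted_qaly_gain(1.363)  # 0.595
#' @export
adjusted_qaly_gain <- function(unadjusted, p = amd_parameters()) {
  if (any(unadjusted < 0)) stop("unadjusted gain must be >= 0", call. = FALSE)
  unadjusted * adjustment_product(p)
}

#' Percent quality-of-life gain
#'
#' A QALY gain expressed as a percentage of the sham-arm 12-year accrual.
#'
#' @param gain QALY gain.
#' @param sham_accrual sham-arm 12-year accrual (> 0).
#' @return percent.
#' @examples
#' percent_qol_gain(0.845, 5.990)  # 14.1
#' @export
percent_qol_gain <- function(gain, sham_accrual) {
  if (any(sham_accrual <= 0)) {
    stop("sham_accrual must be > 0", call. = FALSE)
  }
  100 * gain / sham_accrual
}

#' QALY gain per patient screened
#'
#' Adjusted per-early-case gain diluted over the patients screened to produce
#' one early-treatment case. The screened-per-early-case ratio is a primary
#' input whose derivation is not published; the division here (0.595 / 30.3 =
#' 0.0196) does not match either circulated per-screened figure (0.0185,
#' 0.0177), so the result is flagged approximate via attribute
#' \code{"approximate"}.
#'
#' @param adjusted_gain adjusted QALY gain per early-treatment case.
#' @param screened_per_early_case patients screened per early case (> 0).
#' @return QALY per screened patient, with attribute \code{"approximate"}.
#' @export
per_screened_gain <- function(adjusted_gain, screened_per_early_case) {
  if (any(screened_per_early_case <= 0)) {
    stop("screened_per_early_case must be > 0", call. = FALSE)
  }
  structure(adjusted_gain / screened_per_early_case, approximate = TRUE)
}

#' Consistency check: rebuild the early-arm accrual from components
#'
#' The registered 12-year accruals are authoritative inputs; the monthly
#' acuity trajectory behind them is under-specified, so this secondary path
#' (outcome-utility annuity + bilateral-good-vision bonus - adverse-event
#' disutility) is a loose cross-check, not an alternative computation.
#'
#' @param p an \code{\link{amd_parameters}} object.
#' @return list with \code{rebuilt}, \code{registered} and \code{difference}
#'   (rebuilt - registered) for the early arm.
#' @export
accrual_consistency <- function(p = amd_parameters()) {
  rebuilt <- discounted_annuity(p$utility_early, p$discount_rate,
                                p$timeline_years) +
    p$bonus_bilateral_good_vision - p$adverse_event_disutility
  list(rebuilt = rebuilt, registered = p$accrual_early,
       difference = rebuilt - p$accrual_early)
}

#' Patient value-gain table
#'
#' Per-arm 12-year accruals with unadjusted and adjusted incremental QALY
#' gains and percent quality-of-life gains over sham, plus the incremental
#' early-vs-late row the cost-utility analysis runs on and the per-screened
#' dilution.
#'
#' @param p an \code{\link{amd_parameters}} object.
#' @return data.frame with columns \code{cohort}, \code{accrual_12yr},
#'   \code{gain_unadjusted}, \code{qol_unadjusted_pct}, \code{gain_adjusted},
#'   \code{qol_adjusted_pct}.
#' @examples
#' value_table(amd_parameters())
#' @export
value_table <- function(p = amd_parameters()) {
  arms <- treatment_arms(p)
  sham <- arms$accrual_12yr[arms$arm == "sham"]
  gain_u <- qaly_gain(arms$accrual_12yr, sham)
  gain_a <- adjusted_qaly_gain(gain_u, p)
  inc_u <- qaly_gain(p$accrual_early, p$accrual_late)
  inc_a <- adjusted_qaly_gain(inc_u, p)
  out <- data.frame(
    cohort = c(arms$arm, "early_vs_late", "per_screened"),
    accrual_12yr = c(arms$accrual_12yr, NA, NA),
    gain_unadjusted = c(gain_u, inc_u,
                        as.numeric(per_screened_gain(inc_u,
                                                     p$screened_per_early_case))),
    gain_adjusted = c(gain_a, inc_a,
                      as.numeric(per_screened_gain(inc_a,
                                                   p$screened_per_early_case))),
    stringsAsFactors = FALSE
  )
  out$qol_unadjusted_pct <- percent_qol_gain(out$gain_unadjusted, sham)
  out$qol_adjusted_pct <- percent_qol_gain(out$gain_adjusted, sham)
  out[, c("cohort", "accrual_12yr", "gain_unadjusted", "qol_unadjusted_pct",
          "gain_adjusted", "qol_adjusted_pct")]
}
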