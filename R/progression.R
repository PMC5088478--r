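#' Extend cumulative fellow-eye conversion beyond the observed years
#'
#' Patients enter the model with NVAMD in one eye; the fellow eye converts
#' over time. Years 1 and 2 of the cumulative incremental conversion of the
#' baseline-unilateral pool are observed; later years are extrapolated by a
#' last-observation-carried-forward hazard: the mean of the year-1 and year-2
#' incremental conversions (as a fraction of the full baseline-unilateral
#' pool) is applied each year to the not-yet-converted remainder,
#'
#' \deqn{A_t = A_{t-1} + h (100 - A_{t-1}), \quad t \ge 3,}
#'
#' with \eqn{h = (A_1 + (A_2 - A_1))/2 / 100} (base case
#' \eqn{(21.2 + 16.8)/2 = 19.0\%}).
#'
#' @param year1_cum,year2_cum cumulative conversion at end of years 1 and 2,
#'   percent of the baseline-unilateral pool.
#' @param horizon final model year (>= 2).
#' @param hazard optional annual hazard override (fraction); default is the
#'   LOCF mean of the two observed incremental conversions.
#' @return data.frame with columns \code{year} (0..horizon) and
#'   \code{cumulative_incremental} (percent); the hazard used is attached as
#'   attribute \code{"annual_hazard"}.
#' @examples
#' a <- extend_cumulative_conversion(21.2, 38.0, 12)
#' a$cumulative_incremental[a$year == 12]  # 92.5
#' @export
extend_cumulative_conversion <- function(year1_cum, year2_cum, horizon = 12,
                                         hazard = NULL) {
  if (!is.numeric(horizon) || horizon < 2) {
    stop("horizon must be >= 2 years", call. = FALSE)
  }
  horizon <- as.integer(horizon)
  if (year1_cum < 0 || year2_cum > 100 || year1_cum > year2_cum) {
    stop("need 0 <= year1_cum <= year2_cum <= 100, got (",
         year1_cum, ", ", year2_cum, ")", call. = FALSE)
  }
  if (is.null(hazard)) {
    hazard <- mean(c(year1_cum, year2_cum - year1_cum)) / 100
  }
  cum <- numeric(horizon + 1L)
  cum[2L] <- year1_cum
  cum[3L] <- year2_cum
  if (horizon >= 3L) {
    for (t in 3L:horizon) {
      cum[t + 1L] <- cum[t] + hazard * (100 - cum[t])
    }
  }
  out <- data.frame(year = 0:horizon, cumulative_incremental = cum)
  attr(out, "annual_hazard") <- hazard
  out
}

#' Bilateral involvement from cumulative fellow-eye conversion
#'
#' A fraction of cases is bilateral at baseline; the rest are unilateral and
#' become bilateral as the fellow eye converts:
#' \deqn{B = 46.4 + 0.535\,A,} capped at 100.
#'
#' @param cumulative_incremental percent of the baseline-unilateral pool
#'   converted (vectorised, each in \[0,100\]).
#' @param baseline_pct percent of all cases bilateral at baseline.
#' @param unilateral_share multiplier converting the unilateral-pool percent
#'   to a percent of all cases.
#' @return percent of all cases with bilateral involvement.
#' @examples
#' bilateral_involvement(21.2)  # 57.7
#' @export
bilateral_involvement <- function(cumulative_incremental,
                                  baseline_pct = 46.4,
                                  unilateral_share = 0.535) {
  if (any(cumulative_incremental < 0 | cumulative_incremental > 100)) {
    stop("cumulative_incremental must lie in [0, 100]", call. = FALSE)
  }
  pmin(baseline_pct + cumulative_incremental * unilateral_share, 100)
}

#' Full fellow-eye conversion trajectory
#'
#' Combines the extended cumulative conversion with the bilateral-involvement
#' formula over the model horizon.
#'
#' @param p an \code{\link{amd_parameters}} object.
#' @param horizon model years; defaults to \code{p$timeline_years}.
#' @return data.frame of class \code{conversion_trajectory} with columns
#'   \code{year}, \code{cumulative_incremental}, \code{bilateral_involvement}
#'   and attribute \code{"annual_hazard"}.
#' @examples
#' conversion_trajectory(amd_parameters())
#' @export
conversion_trajectory <- function(p = amd_parameters(),
                                  horizon = p$timeline_years) {
  a <- extend_cumulative_conversion(p$year1_cumulative_conversion,
                                    p$year2_cumulative_conversion, horizon)
  a$bilateral_involvement <- bilateral_involvement(
    a$cumulative_incremental, p$baseline_bilateral_pct, p$unilateral_share)
  class(a) <- c("conversion_trajectory", "data.frame")
  a
}

#' Fellow-eye conversion-year distribution
#'
#' Year-over-year increments of the cumulative conversion, as probabilities
#' for sampling a conversion year in the microsimulation; residual mass after
#' the horizon is returned under year \code{NA} ("never within horizon").
#'
#' @param trajectory a \code{\link{conversion_trajectory}} (or the A-column
#'   data.frame from \code{\link{extend_cumulative_conversion}}).
#' @return data.frame with \code{year} (1..horizon, then NA) and \code{prob}
#'   summing to 1.
#' @export
conversion_year_distribution <- function(trajectory) {
  cum <- trajectory$cumulative_incremental / 100
  inc <- diff(cum)
  data.frame(year = c(trajectory$year[-1L], NA),
             prob = c(inc, 1 - cum[length(cum)]))
}
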