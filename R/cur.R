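#' Base-case per-capita screening cost
#'
#' Compounded genetic-test cost plus monitoring add-on (base case $1906 +
#' $299 = $2205 per screened patient).
#'
#' @param p an \code{\link{amd_parameters}} object.
#' @return USD per screened patient.
#' @export
base_per_capita_cost <- function(p = amd_parameters()) {
  per_capita_screening_cost(
    compound_to_treatment_age(p$genetic_test_cost, p$discount_rate,
                              p$compounding_periods),
    p$monitoring_addon)
}

#' National annual screening cost
#'
#' @param cohort screened persons per year (> 0).
#' @param per_capita screening/monitoring cost per screened patient (> 0).
#' @return USD (base case 944,400 x 2205 = $2.082 billion).
#' @examples
#' national_screening_cost(944400, 2205)
#' @export
national_screening_cost <- function(cohort, per_capita) {
  if (any(cohort < 0) || any(per_capita < 0)) {
    stop("cohort and per_capita must be >= 0", call. = FALSE)
  }
  cohort * per_capita
}

# per-patient negative cost magnitude and adjusted QALY gain used in the CUR
# closed form, at the registered (printed) precision
.cur_inputs <- function(p, perspective) {
  ledger <- cost_ledger(p, perspective)
  list(negative = -ledger$total_negative,
       gain = adjusted_qaly_gain(qaly_gain(p$accrual_early, p$accrual_late), p))
}

#' Cost-utility table by incremental early-treatment uptake
#'
#' For each incremental uptake percentage \eqn{q} of the annual 65-plus NVAMD
#' cohort shifted to early treatment: the (unrounded) patient count
#' \eqn{n = q/100 \times 161{,}754}, the fixed national screening cost, the
#' accrued negative costs \eqn{-n \times} (per-patient negative cost for the
#' perspective), their sum, per-screened-patient cost and QALY columns, and
#' the cost-utility ratio
#' \deqn{\mathrm{CUR} = \frac{\text{total cost}}{n \times 0.595}.}
#' A negative CUR denotes dominance: early treatment adds QALYs and saves
#' money.
#'
#' @param pcts uptake percentages, each in (0, 100\].
#' @param perspective \code{"societal"} or \code{"third_party"}.
#' @param p an \code{\link{amd_parameters}} object.
#' @param per_capita per-screened screening cost override (USD); default
#'   \code{\link{base_per_capita_cost}}.
#' @return data.frame of class \code{cur_table} with columns
#'   \code{incremental_pct}, \code{n_patients}, \code{screening_cost_total}
#'   and \code{negative_cost_total} and \code{total_cost} (all USD thousands,
#'   signed), \code{cost_per_screened}, \code{qaly_per_screened}, \code{cur}.
#' @examples
#' cur_table(c(1, 4.1, 10), "societal", amd_parameters())
#' @export
cur_table <- function(pcts, perspective = c("societal", "third_party"),
                      p = amd_parameters(), per_capita = NULL) {
  perspective <- match.arg(perspective)
  if (any(pcts <= 0) || any(pcts > 100)) {
    stop("uptake percentages must lie in (0, 100]; CUR is undefined at zero uptake",
         call. = FALSE)
  }
  if (is.null(per_capita)) per_capita <- base_per_capita_cost(p)
  inp <- .cur_inputs(p, perspective)
  screening_total <- national_screening_cost(p$annual_category3_cohort,
                                             per_capita)
  n <- pcts / 100 * p$annual_nvamd_cases_65plus
  negative_total <- -n * inp$negative
  total <- screening_total + negative_total
  out <- data.frame(
    incremental_pct = pcts,
    n_patients = n,
    screening_cost_total = screening_total / 1000,
    negative_cost_total = negative_total / 1000,
    total_cost = total / 1000,
    cost_per_screened = total / p$annual_category3_cohort,
    qaly_per_screened = n * inp$gain / p$annual_category3_cohort,
    cur = total / (n * inp$gain)
  )
  class(out) <- c("cur_table", "data.frame")
  out
}

#' Break-even uptake for a cost-effectiveness threshold
#'
#' Smallest incremental uptake at which the CUR falls to the threshold,
#' solved in closed form:
#' \deqn{n = \frac{S}{c^- + T\,\Delta Q},}
#' where \eqn{S} is the national screening cost, \eqn{c^-} the per-patient
#' negative-cost magnitude, \eqn{T} the threshold and \eqn{\Delta Q} the
#' adjusted per-patient QALY gain. \code{threshold = Inf} returns the uptake
#' at which total cost crosses zero (onset of dominance).
#'
#' @param threshold USD/QALY (> 0, may be \code{Inf}).
#' @param perspective \code{"societal"} or \code{"third_party"}.
#' @param p an \code{\link{amd_parameters}} object.
#' @param per_capita per-screened cost override (USD).
#' @return uptake percent (continuous; report to 1 decimal), with attributes
#'   \code{"n_patients"} and, when no uptake of at most 100\% meets the
#'   threshold, \code{"unattainable" = TRUE} (value \code{NA}).
#' @examples
#' round(breakeven_uptake(144000, "societal"), 1)  # 4.1
#' @export
breakeven_uptake <- function(threshold, perspective = c("societal", "third_party"),
                             p = amd_parameters(), per_capita = NULL) {
  perspective <- match.arg(perspective)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a positive $/QALY value", call. = FALSE)
  }
  if (is.null(per_capita)) per_capita <- base_per_capita_cost(p)
  inp <- .cur_inputs(p, perspective)
  screening_total <- national_screening_cost(p$annual_category3_cohort,
                                             per_capita)
  denom <- if (is.infinite(threshold)) inp$negative else
    inp$negative + threshold * inp$gain
  n <- screening_total / denom
  pct <- n / (p$annual_nvamd_cases_65plus / 100)
  if (!is.finite(pct) || pct <= 0 || pct > 100) {
    return(structure(NA_real_, unattainable = TRUE, n_patients = NA_real_))
  }
  structure(pct, n_patients = n)
}

#' Financial break-even: early-treatment cases funding the whole program
#'
#' Number of incremental early-treatment patients whose net societal saving
#' equals the national screening cost.
#'
#' @param p an \code{\link{amd_parameters}} object.
#' @param per_capita per-screened cost override (USD).
#' @return persons (real-valued; base case ~12,968), with attribute
#'   \code{"pct"} of the annual 65-plus NVAMD cohort.
#' @export
financial_breakeven_patients <- function(p = amd_parameters(),
                                         per_capita = NULL) {
  if (is.null(per_capita)) per_capita <- base_per_capita_cost(p)
  saving <- -net_cost_per_early_case(cost_ledger(p, "societal"))
  if (saving <= 0) {
    stop("net societal saving per early case is non-positive; no financial break-even",
         call. = FALSE)
  }
  s <- national_screening_cost(p$annual_category3_cohort, per_capita)
  n <- s / saving
  structure(n, pct = n / (p$annual_nvamd_cases_65plus / 100))
}

#' Return on investment
#'
#' \eqn{(\text{returned} - \text{expended}) / \text{expended} \times 100}.
#'
#' @param expended USD expended (> 0).
#' @param returned_magnitude USD returned, as a magnitude (>= 0).
#' @return percent.
#' @examples
#' roi(2205, 7500)  # ~240
#' @export
roi <- function(expended, returned_magnitude) {
  if (any(expended <= 0)) stop("expended must be > 0", call. = FALSE)
  (returned_magnitude - expended) / expended * 100
}

#' Payer-level 12-year return on investment
#'
#' Distributes the per-screened screening cost and negative-cost return over
#' payers and recomputes net cost, ROI, and the diminution of usual cost
#' (returned / expended). All ROI figures are recomputed from the dollar
#' cells; the out-of-pocket patient row is known to have circulated with an
#' ROI irreproducible from its own cells, so recomputation is the contract
#' here.
#'
#' @param p an \code{\link{amd_parameters}} object.
#' @return data.frame with payer (overall row first), expended, returned,
#'   net_cost (signed), roi_pct, diminution_pct.
#' @export
payer_roi_table <- function(p = amd_parameters()) {
  ps <- p$payer_shares
  overall <- data.frame(payer = "overall",
                        expended = base_per_capita_cost(p),
                        returned = p$negative_per_screened,
                        stringsAsFactors = FALSE)
  tab <- rbind(overall, ps[, c("payer", "expended", "returned")])
  tab$net_cost <- tab$expended - tab$returned
  tab$roi_pct <- roi(tab$expended, tab$returned)
  tab$diminution_pct <- tab$returned / tab$expended * 100
  tab
}

#' Societal saving per 1\% incremental uptake
#'
#' Dollars saved annually for each additional 1\% of the 65-plus NVAMD cohort
#' shifted to early treatment.
#'
#' @param p an \code{\link{amd_parameters}} object.
#' @return USD (base case ~$260 million).
#' @export
per_percent_saving <- function(p = amd_parameters()) {
  saving <- -net_cost_per_early_case(cost_ledger(p, "societal"))
  (p$annual_nvamd_cases_65plus / 100) * saving
}
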