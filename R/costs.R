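#' CPT line items of the genetic-testing cost build-up
#'
#' The nine Current Procedural Terminology (CPT) line items of the multi-gene
#' panel, priced at the 2012 National Limitation Amount (NLA).
#'
#' @return data.frame with \code{code}, \code{description}, \code{multiplier},
#'   \code{unit_amount} (USD).
#' @export
cpt_line_items <- function() {
  data.frame(
    code = c("83891", "83900", "83901", "83892", "83914", "83912", "83896",
             "83903", "83908"),
    description = c(
      "DNA isolation",
      "Nucleic acid amplification, multiplex, first two sequences",
      "Nucleic acid amplification, multiplex, each additional sequence",
      "Restriction endonuclease digestion, each",
      "Mutation identification by ligation/primer extension, each segment",
      "Interpretation and report",
      "Nucleic acid probe, each",
      "Mutation scanning by physical properties, single segment, each",
      "Signal amplification, each nucleic acid sequence"),
    multiplier = c(1, 1, 10, 2, 15, 1, 15, 15, 15),
    unit_amount = c(5.7, 47.8, 23.7, 5.7, 23.7, 5.7, 5.7, 23.7, 23.7),
    stringsAsFactors = FALSE
  )
}

#' Total cost of a CPT line-item build-up
#'
#' Sum of multiplier x unit amount over all lines, rounded to whole dollars.
#' The published build-up rounds some lines individually before summing, so
#' the exact sum can differ from a per-line-rounded total by about a dollar.
#'
#' @param items data.frame as from \code{\link{cpt_line_items}}.
#' @return total USD (whole dollars).
#' @examples
#' cpt_total(cpt_line_items())  # ~1461
#' @export
cpt_total <- function(items) {
  if (!is.data.frame(items) || nrow(items) == 0L) {
    stop("items must be a non-empty data.frame of CPT lines", call. = FALSE)
  }
  if (any(items$unit_amount < 0) || any(items$multiplier < 1)) {
    stop("unit amounts must be >= 0 and multipliers >= 1", call. = FALSE)
  }
  round(sum(items$multiplier * items$unit_amount))
}

#' Compound a cost from screening age to treatment age
#'
#' Screening outlays at age 65 are carried forward to the mean age of
#' treatment initiation at the discount rate: \eqn{c (1+r)^k}, rounded to
#' whole dollars. The base case uses 9 annual periods, which reproduces the
#' published chain $1461 -> $1906 (10 periods would give $1963); the period
#' count is a registered parameter.
#'
#' @param cost USD at screening (>= 0).
#' @param rate annual rate (fraction, >= 0).
#' @param periods integer compounding periods (>= 0).
#' @return USD at treatment age (whole dollars).
#' @examples
#' compound_to_treatment_age(1461, 0.03, 9)  # 1906
#' @export
compound_to_treatment_age <- function(cost, rate, periods) {
  if (any(cost < 0) || any(rate < 0) || any(periods < 0)) {
    stop("cost, rate and periods must be >= 0", call. = FALSE)
  }
  round(cost * (1 + rate)^periods)
}

#' Per-capita screening/monitoring cost
#'
#' Compounded genetic-test cost plus the closer-monitoring add-on (one extra
#' annual exam + optical coherence tomogram; the high-risk weighting is
#' folded into the add-on).
#'
#' @param compounded_test compounded test cost, USD.
#' @param monitoring_addon monitoring add-on, USD.
#' @return USD per screened patient.
#' @examples
#' per_capita_screening_cost(1906, 299)  # 2205
#' @export
per_capita_screening_cost <- function(compounded_test, monitoring_addon) {
  if (any(compounded_test < 0) || any(monitoring_addon < 0)) {
    stop("cost components must be >= 0", call. = FALSE)
  }
  compounded_test + monitoring_addon
}

#' Adjust unadjusted ledger components for eye presentation and sensitivity
#'
#' Negative-cost components are tabulated per early-treatment case assuming
#' both eyes present late and detection is certain; the screened-cohort
#' ledger scales each component by the three-way factor
#' 0.780 x 0.622 x 0.90 = 0.4366.
#'
#' @param components numeric vector of signed USD components.
#' @param factor adjustment factor in (0, 1\].
#' @return adjusted components, same sign convention.
#' @examples
#' ledger_adjust(-93699, 0.780 * 0.622 * 0.90)  # ~ -40914
#' @export
ledger_adjust <- function(components, factor) {
  if (factor <= 0 || factor > 1) stop("factor must lie in (0, 1]",
                                      call. = FALSE)
  components * factor
}

#' Per-early-case cost ledger under a cost perspective
#'
#' Assembles the signed 12-year cost components per incremental
#' early-treatment case. The screening side (+$66,873 = $57,805 screening +
#' $9,068 monitoring) is common to both perspectives. The societal
#' perspective nets off all three negative buckets (direct non-ophthalmic
#' medical, caregiver, employment); the third-party insurer perspective nets
#' off direct non-ophthalmic medical costs only. Negative-cost accrual starts
#' at month 7 after therapy initiation; at the model's annual resolution this
#' does not alter 12-year totals and is carried as metadata.
#'
#' @param p an \code{\link{amd_parameters}} object.
#' @param perspective \code{"societal"} or \code{"third_party"}.
#' @param from_unadjusted if TRUE, rebuild the adjusted components by scaling
#'   the unadjusted (column A) components with \code{\link{ledger_adjust}}
#'   instead of using the registered adjusted values.
#' @return list of class \code{cost_ledger}: perspective, screening
#'   components, signed negative components and sub-items, totals.
#' @examples
#' net_cost_per_early_case(cost_ledger(amd_parameters(), "societal"))
#' @export
cost_ledger <- function(p = amd_parameters(),
                        perspective = c("societal", "third_party"),
                        from_unadjusted = FALSE) {
  perspective <- match.arg(perspective)
  if (from_unadjusted) {
    f <- adjustment_product(p)
    direct_non_oph <- ledger_adjust(p$colA_direct_nonophthalmic, f)
    caregiver <- ledger_adjust(p$colA_caregiver, f)
    employment <- ledger_adjust(p$colA_employment, f)
    sub <- ledger_adjust(c(depression = p$colA_depression,
                           injuries = p$colA_injuries,
                           nursing_home = p$colA_nursing_home,
                           snf = p$colA_snf,
                           other_medical = p$colA_other_medical), f)
  } else {
    direct_non_oph <- p$negative_direct_nonophthalmic
    caregiver <- p$negative_caregiver
    employment <- p$negative_employment
    sub <- c(depression = p$negative_depression,
             injuries = p$negative_injuries,
             nursing_home = p$negative_nursing_home,
             snf = p$negative_snf,
             other_medical = p$negative_other_medical)
  }
  total_negative <- if (perspective == "societal") {
    direct_non_oph + caregiver + employment
  } else {
    direct_non_oph
  }
  stopifnot(total_negative <= 0)
  structure(list(
    perspective = perspective,
    screening_cost = p$cost_per_early_case_screening,
    screening_component = p$screening_component,
    monitoring_component = p$monitoring_component,
    direct_non_ophthalmic = direct_non_oph,
    direct_non_ophthalmic_items = sub,
    caregiver = if (perspective == "societal") caregiver else NA_real_,
    employment = if (perspective == "societal") employment else NA_real_,
    total_negative = total_negative,
    accrual_start_month = p$accrual_start_month
  ), class = "cost_ledger")
}

#' Net cost per incremental early-treatment case
#'
#' Screening cost plus (signed) total negative costs. Negative values denote
#' a net saving per early-treatment case.
#'
#' @param ledger a \code{\link{cost_ledger}}.
#' @return signed USD.
#' @examples
#' net_cost_per_early_case(cost_ledger(amd_parameters(), "third_party"))
#' @export
net_cost_per_early_case <- function(ledger) {
  stopifnot(inherits(ledger, "cost_ledger"))
  ledger$screening_cost + ledger$total_negative
}

#' @export
print.cost_ledger <- function(x, ...) {
  cat("Per-early-treatment-case cost ledger (", x$perspective,
      " perspective, 2012 USD)\n", sep = "")
  cat(sprintf("  screening/monitoring: +%s (%s + %s)\n",
              format(x$screening_cost, big.mark = ","),
              format(x$screening_component, big.mark = ","),
              format(x$monitoring_component, big.mark = ",")))
  cat(sprintf("  direct non-ophthalmic: %s\n",
              format(x$direct_non_ophthalmic, big.mark = ",")))
  if (x$perspective == "societal") {
    cat(sprintf("  caregiver: %s\n  employment: %s\n",
                format(x$caregiver, big.mark = ","),
                format(x$employment, big.mark = ",")))
  }
  cat(sprintf("  total negative: %s\n  net: %s\n",
              format(x$total_negative, big.mark = ","),
              format(net_cost_per_early_case(x), big.mark = ",")))
  invisible(x)
}
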