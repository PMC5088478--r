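#' Base-case model parameters
#'
#' Builds the full registry of model inputs for the cost-utility analysis of
#' genetic testing for neovascular age-related macular degeneration (NVAMD).
#' Every number used anywhere in the model resolves through this registry:
#' cohort sizes, 10-year progression rates, presentation-acuity fractions,
#' time-tradeoff vision utilities, 12-year QALY accruals per treatment arm,
#' the genetic-testing cost build-up, the signed negative-cost ledger, payer
#' cost shares, and cost-effectiveness thresholds. All monetary amounts are
#' 2012 US dollars; negative costs (costs averted by early treatment) are
#' stored with a negative sign.
#'
#' @param ... named overrides of individual parameters, e.g.
#'   \code{amd_parameters(discount_rate = 0)}. Unknown names are an error.
#' @param validate logical; run \code{\link{validate_parameters}} (default TRUE).
#' @return An object of class \code{amd_parameters}: a named list of
#'   parameters with a provenance label attached to each entry (see
#'   \code{\link{parameter_provenance}}).
#' @seealso \code{\link{load_parameters}}, \code{\link{write_parameters}},
#'   \code{\link{derive_cohort_counts}}
#' @examples
#' p <- amd_parameters()
#' p$annual_category3_cohort
#' p2 <- amd_parameters(discount_rate = 0)
#' @export
amd_parameters <- function(..., validate = TRUE) {
  p <- list(
    # horizon and discounting
    timeline_years = 12L,
    discount_rate = 0.03,
    screening_age = 65L,
    treatment_age = 75L,
    compounding_periods = 9L,
    accrual_start_month = 7L,
    # cohort
    annual_category3_cohort = 944400,
    annual_nvamd_cases_total = 171350,
    fraction_under_65 = 0.056,
    annual_nvamd_cases_65plus = 161754,
    # genetics and progression
    progression_10yr = 0.20,
    high_risk_fraction = 0.225,
    test_sensitivity = 0.90,
    # presentation acuity strata
    first_eye_late_fraction = 0.780,
    second_eye_late_fraction = 0.622,
    first_eye_early_fraction = 0.18,
    second_eye_early_fraction = 0.37,
    # eye-model multipliers
    combined_eye_multiplier = 0.857,
    first_eye_accrual_ratio = 0.853,
    # fellow-eye conversion model (percent scale)
    baseline_bilateral_pct = 46.4,
    unilateral_share = 0.535,
    year1_cumulative_conversion = 21.2,
    year2_cumulative_conversion = 38.0,
    # utilities (time-tradeoff, anchors 1.00 normal bilateral vision / 0.00 death)
    utility_early = 0.789,       # 20/40-1 in each eye
    utility_late = 0.658,        # 20/160+2
    utility_20_126 = 0.682,
    utility_20_160m2 = 0.657,
    utility_20_640 = 0.538,
    utility_bilateral_nlp = 0.26,
    utility_bilateral_good = 0.97,   # 20/20-20/25 both eyes
    utility_unilateral_good = 0.89,  # 20/20-20/25 one eye
    first_eye_utility_loss = 0.0398,
    # 12-year discounted QALY accruals per arm (combined-eye model)
    accrual_sham = 5.990,
    accrual_early = 7.924,
    accrual_late = 6.561,
    bonus_bilateral_good_vision = 0.121,
    bonus_eligible_fraction = 0.179,
    first_eye_gain = 0.0884,
    adverse_event_disutility = 0.045,
    # screening costs
    genetic_test_cost = 1461,
    monitoring_addon = 299,
    screened_per_early_case = 30.3,
    cost_per_early_case_screening = 66873,
    screening_component = 57805,
    monitoring_component = 9068,
    # negative costs per early-treatment case, unadjusted (column A, signed)
    colA_depression = -7169,
    colA_injuries = -3793,
    colA_nursing_home = -22351,
    colA_snf = -10193,
    colA_other_medical = -50194,
    colA_direct_nonophthalmic = -93699,
    colA_caregiver = -394929,
    colA_employment = -32288,
    colA_total_negative = -520917,
    # negative costs per early-treatment case, eye/sensitivity adjusted (column B, signed)
    negative_depression = -3130,
    negative_injuries = -1656,
    negative_nursing_home = -9759,
    negative_snf = -4451,
    negative_other_medical = -21917,
    negative_direct_nonophthalmic = -40914,
    negative_caregiver = -172443,
    negative_employment = -14098,
    # return per screened patient (overall negative costs, Table-8 scale)
    negative_per_screened = 7500,
    # thresholds
    who_threshold = 144000,
    us_threshold = 100000,
    # payer distribution of the $2205 screening cost and the $7500 return
    payer_shares = default_payer_shares()
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  class(p) <- "amd_parameters"
  if (validate) validate_parameters(p)
  p
}

#' Payer shares of screening expenditure and societal return
#'
#' Per screened patient: who pays the screening/monitoring cost and to whom
#' the negative (averted) costs accrue over the 12-year horizon.
#'
#' @return data.frame with payer, dollars expended, percent of expenditure,
#'   dollars returned (magnitude), percent of return.
#' @export
default_payer_shares <- function() {
  data.frame(
    payer = c("medicare", "medicaid", "commercial_medigap",
              "commercial_under_65", "patients"),
    expended = c(1559, 84, 348, 174, 40),
    expended_pct = c(70.7, 3.8, 15.8, 7.9, 1.8),
    returned = c(548, 53, 83, 53, 6765),
    returned_pct = c(7.3, 0.7, 1.1, 0.7, 90.2),
    stringsAsFactors = FALSE
  )
}

#' Provenance labels for every registered parameter
#'
#' Each model input is traceable to its primary data source: the AREDS
#' genotype/phenotype progression study (Yu et al.), the MARINA ranibizumab
#' trial, the fellow-eye conversion series (Barbazetto et al.), the
#' time-tradeoff utility database of >1100 ophthalmic patient interviews, the
#' 2012 national Medicare Fee Schedule CPT build-up, and the published
#' non-ophthalmic (Javitt et al.), caregiver (Schmier et al.) and employment
#' cost studies. Structural constants (horizon, discount rate, thresholds)
#' are labelled as base-case conventions.
#'
#' @return data.frame with columns \code{parameter} and \code{source}.
#' @export
parameter_provenance <- function() {
  src <- c(
    timeline_years = "base-case convention: mean NVAMD life expectancy",
    discount_rate = "base-case convention: 3% annual NPV discounting",
    screening_age = "base-case convention: screening age",
    treatment_age = "MARINA trial mean baseline age",
    compounding_periods = "cost build-up compounding chain (1461 -> 1906)",
    accrual_start_month = "negative-cost accrual start after therapy initiation",
    annual_category3_cohort = "Eye Diseases Prevalence Research Group estimates",
    annual_nvamd_cases_total = "Beaver Dam Study 15-year incidence",
    fraction_under_65 = "MARINA trial: cases presenting before age 65",
    annual_nvamd_cases_65plus = "derived: total x (1 - under-65 fraction)",
    progression_10yr = "Yu et al. AREDS Category 3 10-year progression",
    high_risk_fraction = "Yu et al.: 343/1527 high-risk genetic profiles",
    test_sensitivity = "Yu et al.: 10-year sensitivity for NVAMD progressors",
    first_eye_late_fraction = "practice series: 1st-eye presenting acuity <=20/160",
    second_eye_late_fraction = "practice series: 2nd-eye presenting acuity <=20/160",
    first_eye_early_fraction = "practice series: 1st-eye presenting acuity 20/40-20/80",
    second_eye_early_fraction = "practice series: 2nd-eye presenting acuity 20/40-20/80",
    combined_eye_multiplier = "combined-eye model multiplier (value-gain chain)",
    first_eye_accrual_ratio = "1st-eye vs 2nd-eye accrual rate (alternate statement)",
    baseline_bilateral_pct = "Barbazetto et al.: bilateral NVAMD at baseline",
    unilateral_share = "fellow-eye model: unilateral share multiplier",
    year1_cumulative_conversion = "Barbazetto et al.: year-1 fellow-eye conversion",
    year2_cumulative_conversion = "Barbazetto et al.: year-2 fellow-eye conversion",
    utility_early = "time-tradeoff utility database: 20/40-1 both eyes",
    utility_late = "time-tradeoff utility database: 20/160+2",
    utility_20_126 = "time-tradeoff utility database: 20/126",
    utility_20_160m2 = "time-tradeoff utility database: 20/160-2",
    utility_20_640 = "time-tradeoff utility database: 20/640",
    utility_bilateral_nlp = "time-tradeoff utility database: bilateral NLP",
    utility_bilateral_good = "time-tradeoff utility database: 20/20-20/25 both eyes",
    utility_unilateral_good = "time-tradeoff utility database: 20/20-20/25 one eye",
    first_eye_utility_loss = "utility database: unilateral loss 20/40-20/80 vs <=20/160",
    accrual_sham = "12-year discounted QALY accrual, sham arm",
    accrual_early = "12-year discounted QALY accrual, early ranibizumab",
    accrual_late = "12-year discounted QALY accrual, late ranibizumab",
    bonus_bilateral_good_vision = "MARINA: bonus for bilateral >=20/25 outcome",
    bonus_eligible_fraction = "MARINA: 17.9% achieving >=20/25 bilaterally",
    first_eye_gain = "first-eye model QALY gain",
    adverse_event_disutility = "MARINA adverse-event disutility",
    genetic_test_cost = "2012 Medicare Fee Schedule CPT build-up",
    monitoring_addon = "one extra annual exam + OCT, high-risk weighting folded in",
    screened_per_early_case = "base-case scenario: screened per early-treatment case",
    cost_per_early_case_screening = "screening/monitoring cost per early-treatment case",
    screening_component = "screening sub-component of per-early-case cost",
    monitoring_component = "monitoring sub-component of per-early-case cost",
    colA_depression = "Javitt et al.: depression costs, unadjusted",
    colA_injuries = "Javitt et al.: injury costs, unadjusted",
    colA_nursing_home = "Javitt et al.: nursing-home costs, unadjusted",
    colA_snf = "Javitt et al.: skilled-nursing-facility costs, unadjusted",
    colA_other_medical = "Javitt et al.: other Medicare costs, unadjusted",
    colA_direct_nonophthalmic = "Javitt et al.: direct non-ophthalmic total, unadjusted",
    colA_caregiver = "Schmier et al.: caregiver costs, unadjusted",
    colA_employment = "employment/wage-loss model, unadjusted",
    colA_total_negative = "unadjusted negative-cost total",
    negative_depression = "depression costs, eye/sensitivity adjusted",
    negative_injuries = "injury costs, eye/sensitivity adjusted",
    negative_nursing_home = "nursing-home costs, eye/sensitivity adjusted",
    negative_snf = "SNF costs, eye/sensitivity adjusted",
    negative_other_medical = "other medical costs, eye/sensitivity adjusted",
    negative_direct_nonophthalmic = "direct non-ophthalmic total, adjusted",
    negative_caregiver = "caregiver costs, adjusted",
    negative_employment = "employment costs, adjusted",
    negative_per_screened = "negative costs returned per screened patient",
    who_threshold = "WHO criterion: 3x US GDP per capita per QALY",
    us_threshold = "informal US cost-effectiveness upper limit",
    payer_shares = "payer distribution of screening cost and return"
  )
  data.frame(parameter = names(src), source = unname(src),
             stringsAsFactors = FALSE)
}

#' Documented alternate values for dual-printed constants
#'
#' A few inputs circulate in two variants in the source material; the registry
#' defaults carry the value used in the downstream arithmetic chains and the
#' alternates are recorded here as overrides a user may apply.
#'
#' @return data.frame with parameter, default, alternate and a note.
#' @export
parameter_alternates <- function() {
  data.frame(
    parameter = c("cost_per_early_case_screening", "combined_eye_multiplier",
                  "unilateral_share"),
    default = c(66873, 0.857, 0.535),
    alternate = c(66180, 0.853, 0.536),
    note = c(
      "alternate appears in the headline summary; default reproduces the cost ledger",
      "0.857 reproduces the 37.4% four-way product; 0.853 is the prose accrual ratio",
      "0.535 is the bilateral-involvement formula multiplier; 0.536 the prose share"
    ),
    stringsAsFactors = FALSE
  )
}

# parameters that must lie in [0,1]
.fraction_params <- c(
  "discount_rate", "fraction_under_65", "progression_10yr",
  "high_risk_fraction", "test_sensitivity",
  "first_eye_late_fraction", "second_eye_late_fraction",
  "first_eye_early_fraction", "second_eye_early_fraction",
  "combined_eye_multiplier", "first_eye_accrual_ratio", "unilateral_share",
  "utility_early", "utility_late", "utility_20_126", "utility_20_160m2",
  "utility_20_640", "utility_bilateral_nlp", "utility_bilateral_good",
  "utility_unilateral_good", "first_eye_utility_loss",
  "bonus_eligible_fraction"
)

.nonnegative_params <- c(
  "timeline_years", "screening_age", "treatment_age", "compounding_periods",
  "annual_category3_cohort", "annual_nvamd_cases_total",
  "annual_nvamd_cases_65plus", "accrual_sham", "accrual_early",
  "accrual_late", "bonus_bilateral_good_vision", "first_eye_gain",
  "adverse_event_disutility", "genetic_test_cost", "monitoring_addon",
  "screened_per_early_case", "cost_per_early_case_screening",
  "screening_component", "monitoring_component", "negative_per_screened",
  "who_threshold", "us_threshold"
)

.negative_cost_params <- c(
  "colA_depression", "colA_injuries", "colA_nursing_home", "colA_snf",
  "colA_other_medical", "colA_direct_nonophthalmic", "colA_caregiver",
  "colA_employment", "colA_total_negative",
  "negative_depression", "negative_injuries", "negative_nursing_home",
  "negative_snf", "negative_other_medical",
  "negative_direct_nonophthalmic", "negative_caregiver",
  "negative_employment"
)

#' Validate a parameter registry
#'
#' Checks bounds (fractions in \[0,1\], counts and costs non-negative, negative
#' cost components non-positive), internal consistency of the 65-plus NVAMD
#' count with the total and the under-65 fraction (within one person), payer
#' share percentages summing to 100 +/- 0.1 in both columns, and that every
#' parameter carries a provenance label.
#'
#' @param p an \code{amd_parameters} object.
#' @return \code{p}, invisibly, if valid; otherwise an error naming the
#'   offending parameter and bound.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "amd_parameters") || is.list(p))
  for (nm in .fraction_params) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("parameter '", nm, "' must be a fraction in [0, 1], got ",
           format(v), call. = FALSE)
    }
  }
  for (nm in .nonnegative_params) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("parameter '", nm, "' must be a non-negative number, got ",
           format(v), call. = FALSE)
    }
  }
  for (nm in .negative_cost_params) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v > 0) {
      stop("negative-cost parameter '", nm,
           "' must be stored with a non-positive sign, got ", format(v),
           call. = FALSE)
    }
  }
  implied <- p$annual_nvamd_cases_total * (1 - p$fraction_under_65)
  if (abs(implied - p$annual_nvamd_cases_65plus) > 1) {
    stop("annual_nvamd_cases_65plus (", p$annual_nvamd_cases_65plus,
         ") inconsistent with total x (1 - fraction_under_65) = ",
         round(implied, 2), " (tolerance 1 person)", call. = FALSE)
  }
  ps <- p$payer_shares
  req <- c("payer", "expended", "expended_pct", "returned", "returned_pct")
  if (!is.data.frame(ps) || !all(req %in% names(ps))) {
    stop("payer_shares must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(ps$expended_pct) - 100) > 0.1) {
    stop("payer screening-cost shares sum to ", sum(ps$expended_pct),
         "%, must be 100 +/- 0.1", call. = FALSE)
  }
  if (abs(sum(ps$returned_pct) - 100) > 0.1) {
    stop("payer negative-cost shares sum to ", sum(ps$returned_pct),
         "%, must be 100 +/- 0.1", call. = FALSE)
  }
  prov <- parameter_provenance()
  missing_prov <- setdiff(names(unclass(p)), prov$parameter)
  if (length(missing_prov)) {
    stop("no provenance label for parameter(s): ",
         paste(missing_prov, collapse = ", "), call. = FALSE)
  }
  invisible(p)
}

#' Load model parameters from a YAML configuration file
#'
#' Reads a flat key/value YAML document of parameter overrides and merges it
#' onto the base case. An empty file (or one containing only comments) yields
#' the base case unchanged. Unknown keys are rejected so that typos cannot
#' silently leave a default in place.
#'
#' @param path path to a YAML file, or \code{NULL} for the base case.
#' @return a validated \code{amd_parameters} object.
#' @examples
#' tf <- tempfile(fileext = ".yaml")
#' writeLines("discount_rate: 0.0", tf)
#' p <- load_parameters(tf)
#' p$discount_rate
#' @export
load_parameters <- function(path = NULL) {
  if (is.null(path)) return(amd_parameters())
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ov <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed config '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (is.null(ov) || length(ov) == 0L) return(amd_parameters())
  if (is.null(names(ov)) || any(names(ov) == "")) {
    stop("config must be a mapping of parameter names to values", call. = FALSE)
  }
  if ("payer_shares" %in% names(ov)) {
    ov$payer_shares <- do.call(rbind, lapply(ov$payer_shares, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  }
  do.call(amd_parameters, ov)
}

#' Write a parameter registry to YAML
#'
#' Emits the full registry as a flat YAML document, optionally annotated with
#' a provenance comment per key. Re-loading the file with
#' \code{\link{load_parameters}} reproduces an identical registry.
#'
#' @param p an \code{amd_parameters} object.
#' @param path output file path.
#' @param provenance logical; append a \code{#} source comment to each line.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(p, path, provenance = TRUE) {
  validate_parameters(p)
  q <- unclass(p)
  ps <- q$payer_shares
  q$payer_shares <- NULL
  prov <- parameter_provenance()
  lab <- stats::setNames(prov$source, prov$parameter)
  lines <- vapply(names(q), function(nm) {
    val <- yaml::as.yaml(stats::setNames(list(q[[nm]]), nm), precision = 12)
    val <- sub("\n$", "", val)
    if (provenance) paste0(val, "  # ", lab[[nm]]) else val
  }, character(1))
  rows <- lapply(seq_len(nrow(ps)), function(i) as.list(ps[i, ]))
  payer_yaml <- sub("\n$", "", yaml::as.yaml(list(payer_shares = rows),
                                             precision = 12))
  writeLines(c(lines, payer_yaml), path)
  invisible(path)
}

#' Derived cohort counts
#'
#' The annual 65-plus NVAMD incidence is the national total thinned by the
#' fraction presenting before age 65; uptake percentages in the cost-utility
#' tables are expressed against this count, so its per-1\% patient equivalent
#' is carried unrounded.
#'
#' @param p an \code{amd_parameters} object.
#' @return list with \code{annual_nvamd_cases_65plus} (real-valued) and
#'   \code{patients_per_percent} (count per 1\% uptake, unrounded).
#' @examples
#' derive_cohort_counts(amd_parameters())
#' @export
derive_cohort_counts <- function(p) {
  n65 <- p$annual_nvamd_cases_total * (1 - p$fraction_under_65)
  list(annual_nvamd_cases_65plus = n65,
       patients_per_percent = p$annual_nvamd_cases_65plus / 100)
}

#' @export
print.amd_parameters <- function(x, ...) {
  cat("Model parameter registry (", length(unclass(x)), " parameters)\n",
      sep = "")
  cat("  horizon: ", x$timeline_years, " years, discount rate ",
      100 * x$discount_rate, "%/yr, 2012 US dollars\n", sep = "")
  cat("  screened cohort: ", format(x$annual_category3_cohort, big.mark = ","),
      " Category 3 AMD patients/yr at age ", x$screening_age, "\n", sep = "")
  cat("  annual NVAMD cases 65+: ",
      format(x$annual_nvamd_cases_65plus, big.mark = ","), "\n", sep = "")
  cat("  per-capita screening cost: $",
      format(per_capita_screening_cost(
        compound_to_treatment_age(x$genetic_test_cost, x$discount_rate,
                                  x$compounding_periods),
        x$monitoring_addon), big.mark = ","), "\n", sep = "")
  invisible(x)
}
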