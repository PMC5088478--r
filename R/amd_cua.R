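#' Evaluate the full cost-utility model
#'
#' Runs every deterministic stage of the model on a parameter registry: the
#' fellow-eye conversion trajectory, the patient value-gain table, both
#' perspective cost ledgers, cost-utility tables over an uptake grid,
#' break-even uptakes at the WHO and US thresholds, the financial break-even,
#' the payer ROI distribution, and the per-1\%-uptake societal saving.
#'
#' @param p an \code{\link{amd_parameters}} object (or a YAML config path
#'   accepted by \code{\link{load_parameters}}).
#' @param uptake_grid uptake percentages for the cost-utility tables.
#' @return object of class \code{amd_cua} with components
#'   \code{params}, \code{trajectory}, \code{value}, \code{ledgers},
#'   \code{cur} (list of two \code{\link{cur_table}}s), \code{breakeven}
#'   (data.frame), \code{financial_breakeven}, \code{payer_roi},
#'   \code{per_percent_saving}, \code{per_capita_cost}.
#' @examples
#' fit <- amd_cua()
#' fit
#' coef(fit)
#' @export
amd_cua <- function(p = amd_parameters(),
                    uptake_grid = c(1, 2, 3, 4, 4.1, 4.5, 5, 10, 15, 20, 30)) {
  if (is.character(p)) p <- load_parameters(p)
  validate_parameters(p)
  perspectives <- c("societal", "third_party")
  ledgers <- lapply(stats::setNames(perspectives, perspectives),
                    cost_ledger, p = p)
  cur <- lapply(stats::setNames(perspectives, perspectives),
                function(persp) cur_table(uptake_grid, persp, p))
  be <- do.call(rbind, lapply(perspectives, function(persp) {
    do.call(rbind, lapply(c(who = p$who_threshold, us = p$us_threshold,
                            dominance = Inf), function(th) {
      b <- breakeven_uptake(th, persp, p)
      data.frame(perspective = persp, threshold = th,
                 uptake_pct = as.numeric(b),
                 n_patients = attr(b, "n_patients"),
                 unattainable = isTRUE(attr(b, "unattainable")))
    }))
  }))
  be$rule <- rep(c("who", "us", "dominance"), 2)
  rownames(be) <- NULL
  fb <- financial_breakeven_patients(p)
  structure(list(
    params = p,
    per_capita_cost = base_per_capita_cost(p),
    trajectory = conversion_trajectory(p),
    value = value_table(p),
    ledgers = ledgers,
    cur = cur,
    breakeven = be,
    financial_breakeven = data.frame(n_patients = as.numeric(fb),
                                     pct = attr(fb, "pct")),
    payer_roi = payer_roi_table(p),
    per_percent_saving = per_percent_saving(p)
  ), class = "amd_cua")
}

#' @export
print.amd_cua <- function(x, ...) {
  p <- x$params
  v <- x$value
  ag <- v$gain_adjusted[v$cohort == "early_vs_late"]
  cat("Cost-utility model: genetic screening for neovascular AMD\n")
  cat(sprintf("  %d-year horizon, %.0f%%/yr discounting, 2012 USD\n",
              p$timeline_years, 100 * p$discount_rate))
  cat(sprintf("  per-capita screening cost: $%s; national: $%.3f billion\n",
              format(x$per_capita_cost, big.mark = ","),
              national_screening_cost(p$annual_category3_cohort,
                                      x$per_capita_cost) / 1e9))
  cat(sprintf("  adjusted QALY gain per early-treatment case: %.3f\n", ag))
  cat(sprintf("  net cost per early case: societal $%s, third-party $%s\n",
              format(round(net_cost_per_early_case(x$ledgers$societal)),
                     big.mark = ","),
              format(round(net_cost_per_early_case(x$ledgers$third_party)),
                     big.mark = ",")))
  who <- x$breakeven[x$breakeven$rule == "who" &
                       x$breakeven$perspective == "societal", ]
  cat(sprintf("  societal break-even at $%s/QALY: %.1f%% uptake (%s patients)\n",
              format(p$who_threshold, big.mark = ","), who$uptake_pct,
              format(round(who$n_patients), big.mark = ",")))
  invisible(x)
}

#' @export
summary.amd_cua <- function(object, ...) {
  structure(object, class = c("summary.amd_cua", "amd_cua"))
}

#' @export
print.summary.amd_cua <- function(x, ...) {
  print.amd_cua(x)
  cat("\nFellow-eye conversion trajectory:\n")
  print(as.data.frame(lapply(x$trajectory, round, 1)), row.names = FALSE)
  cat("\nPatient value gains (QALY; % of sham accrual):\n")
  print(cbind(x$value[1], round(x$value[-1], 4)), row.names = FALSE)
  cat("\nCost-utility tables ($ thousands; $/QALY):\n")
  for (persp in names(x$cur)) {
    cat(" ", persp, "\n")
    print(cbind(round(x$cur[[persp]][1:5]),
                round(x$cur[[persp]][6:8], 4)), row.names = FALSE)
  }
  cat("\nPayer 12-year ROI (per patient screened):\n")
  print(cbind(x$payer_roi[1:4], round(x$payer_roi[5:6])), row.names = FALSE)
  invisible(x)
}

#' Headline model estimates
#'
#' @param object an \code{\link{amd_cua}} fit.
#' @param ... unused.
#' @return named numeric vector of the model's headline quantities.
#' @export
coef.amd_cua <- function(object, ...) {
  v <- object$value
  ag <- v$gain_adjusted[v$cohort == "early_vs_late"]
  who_s <- object$breakeven[object$breakeven$rule == "who" &
                              object$breakeven$perspective == "societal", ]
  us_s <- object$breakeven[object$breakeven$rule == "us" &
                             object$breakeven$perspective == "societal", ]
  c(adjusted_qaly_gain = ag,
    qol_gain_early_pct = v$qol_adjusted_pct[v$cohort == "early"],
    qol_gain_late_pct = v$qol_adjusted_pct[v$cohort == "late"],
    net_cost_societal = net_cost_per_early_case(object$ledgers$societal),
    net_cost_third_party = net_cost_per_early_case(object$ledgers$third_party),
    per_capita_cost = object$per_capita_cost,
    breakeven_who_pct = who_s$uptake_pct,
    breakeven_us_pct = us_s$uptake_pct,
    financial_breakeven_patients = object$financial_breakeven$n_patients,
    roi_overall_pct = object$payer_roi$roi_pct[object$payer_roi$payer == "overall"],
    per_percent_saving = object$per_percent_saving)
}

#' Cost-utility rows at new uptake points
#'
#' @param object an \code{\link{amd_cua}} fit.
#' @param uptake_pct uptake percentages in (0, 100].
#' @param perspective cost perspective.
#' @param ... unused.
#' @return a \code{\link{cur_table}} at the requested points.
#' @export
predict.amd_cua <- function(object, uptake_pct = 1,
                            perspective = c("societal", "third_party"), ...) {
  cur_table(uptake_pct, match.arg(perspective), object$params)
}

#' Plot the cost-utility ratio against uptake
#'
#' CUR as a function of incremental early-treatment uptake under both
#' perspectives, with the WHO and US threshold lines and the zero-cost
#' (dominance) crossing.
#'
#' @param x an \code{\link{amd_cua}} fit.
#' @param uptake_pct grid of uptake percentages.
#' @param ... passed to \code{matplot}.
#' @return \code{x}, invisibly.
#' @export
plot.amd_cua <- function(x, uptake_pct = seq(0.5, 30, by = 0.25), ...) {
  p <- x$params
  curves <- sapply(c("societal", "third_party"), function(persp) {
    cur_table(uptake_pct, persp, p)$cur
  })
  graphics::matplot(uptake_pct, curves / 1000, type = "l", lty = 1:2,
                    col = c("black", "grey40"),
                    xlab = "incremental early-treatment uptake (%)",
                    ylab = "cost-utility ratio ($1000/QALY)", ...)
  graphics::abline(h = c(p$who_threshold, p$us_threshold) / 1000,
                   lty = 3, col = "grey60")
  graphics::abline(h = 0, col = "grey80")
  graphics::legend("topright", c("societal", "third-party insurer",
                                 "thresholds"),
                   lty = c(1, 2, 3), col = c("black", "grey40", "grey60"),
                   bty = "n")
  invisible(x)
}

#' Simulate screened cohorts from a fitted model
#'
#' Draws patient-level cohorts via \code{\link{simulate_cohort}} under the
#' fit's parameters.
#'
#' @param object an \code{\link{amd_cua}} fit.
#' @param nsim number of cohorts.
#' @param seed integer seed for the first cohort; subsequent cohorts use
#'   \code{seed + 1, ...}.
#' @param n patients per cohort.
#' @param ... passed to \code{\link{simulate_cohort}}.
#' @return a single \code{amd_cohort} if \code{nsim = 1}, else a list.
#' @export
simulate.amd_cua <- function(object, nsim = 1, seed = 1, n = 10000, ...) {
  sims <- lapply(seq_len(nsim) - 1L, function(k) {
    simulate_cohort(n, seed = seed + k, p = object$params, ...)
  })
  if (nsim == 1) sims[[1]] else sims
}
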