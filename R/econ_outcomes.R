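# Economic outcomes: QALYs, years lived with chronic disease, health-care
# costs, and the scenario contrasts (ICER, ROI, single- vs multi-factor
# evaluation ratios).

# per-state utility weights (alive states; the higher of the weight-status
# and chronic-disease decrement applies)
state_utilities <- function(weight_decrements, disease_decrements) {
  prof <- risk_profiles()
  wdec <- weight_decrements[prof$weight + 1L]        # 24
  ddec <- c(0, disease_decrements)                   # 33
  u <- 1 - outer(wdec, ddec, pmax)                   # 24 x 33
  as.vector(u)
}

#' Total discounted QALYs from a cohort trace
#'
#' Each alive state contributes its discounted person-time weighted by
#' `1 - max(weight-status decrement, chronic-disease decrement)`; the death
#' state contributes nothing.
#'
#' @param trace A [run_cohort()] trace.
#' @param weight_decrements Utility decrements `c(normal, overweight, obese)`.
#' @param disease_decrements Utility decrement per disease (length 32).
#' @param discounted Use discounted person-time (default) or undiscounted.
#' @return Total QALYs.
#' @export
qaly_total <- function(trace, weight_decrements, disease_decrements,
                       discounted = TRUE) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (length(disease_decrements) != N_DISEASES) {
    stop("need one decrement per disease")
  }
  if (any(c(weight_decrements, disease_decrements) < 0) ||
      any(c(weight_decrements, disease_decrements) > 1)) {
    stop("decrements must be in [0, 1]")
  }
  u <- state_utilities(weight_decrements, disease_decrements)
  pt <- if (discounted) trace$person_time else trace$person_time_undiscounted
  sum(pt[, seq_len(N_STATES - 1), drop = FALSE] %*% u)
}

#' Discounted person-years lived with chronic disease
#'
#' @inheritParams qaly_total
#' @return Total (discounted) years in states with a chronic disease.
#' @export
disease_years <- function(trace, discounted = TRUE) {
  stopifnot(inherits(trace, "cohort_trace"))
  pt <- if (discounted) trace$person_time else trace$person_time_undiscounted
  dis_states <- (N_PROFILES + 1L):(N_STATES - 1L)  # disease id >= 1
  sum(pt[, dis_states, drop = FALSE])
}

#' Discounted health-care costs attributable to chronic disease
#'
#' @inheritParams qaly_total
#' @param cost_per_case_year A single flat annual cost applied to every
#'   disease-year, or a length-32 vector of per-disease annual costs.
#' @return Total discounted cost.
#' @export
healthcare_costs <- function(trace, cost_per_case_year, discounted = TRUE) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (any(cost_per_case_year < 0)) stop("costs must be non-negative")
  pt <- if (discounted) trace$person_time else trace$person_time_undiscounted
  if (length(cost_per_case_year) == 1L) {
    return(disease_years(trace, discounted) * cost_per_case_year)
  }
  if (length(cost_per_case_year) != N_DISEASES) {
    stop("cost must be scalar or one per disease")
  }
  costs <- rep(cost_per_case_year, each = N_PROFILES)  # states d>=1
  dis_states <- (N_PROFILES + 1L):(N_STATES - 1L)
  sum(pt[, dis_states, drop = FALSE] %*% costs)
}

#' Discounted cost of delivering the program
#'
#' @param annual_cost Cost per participant per program year.
#' @param years Number of program years (paid at years 0, 1, ...).
#' @param rate Annual discount rate.
#' @return Present value of the program cost.
#' @export
#' @examples
#' program_cost(50, 2, 0.015) # 99.26
program_cost <- function(annual_cost = 50, years = 2, rate = 0.015) {
  if (annual_cost < 0 || years < 1) stop("invalid program cost schedule")
  sum(annual_cost * discount_factor(rate, seq_len(years) - 1))
}

#' Incremental cost-effectiveness ratio
#'
#' `incremental_cost / |incremental_effect|`. Effects measured as
#' disease-years are negative when the program prevents them; the magnitude
#' is used and the sign is reported by the caller.
#'
#' @param incremental_cost Incremental cost (currency).
#' @param incremental_effect Incremental effect (QALYs, disease-years, ...).
#' @return Currency per effect unit; `NA` with a warning when the effect is
#'   zero.
#' @export
#' @examples
#' icer(99.26, -0.02642) # 3757
icer <- function(incremental_cost, incremental_effect) {
  if (incremental_effect == 0) {
    warning("zero incremental effect: ICER undefined")
    return(NA_real_)
  }
  incremental_cost / abs(incremental_effect)
}

#' Return on investment
#'
#' Program benefits (health-care cost savings) over program costs, as a
#' percentage.
#'
#' @param savings Discounted savings (currency).
#' @param cost Discounted program cost (currency, positive).
#' @return ROI in percent (unrounded; the conventional display rounds to a
#'   whole percent).
#' @export
#' @examples
#' round(roi(321.615, 99.26)) # 324
roi <- function(savings, cost) {
  if (cost <= 0) stop("program cost must be positive")
  savings / cost * 100
}

scenario_outcomes <- function(params, effect, transitions, cost_per_case) {
  trace <- run_cohort(params, effect, transitions)
  list(
    qalys = qaly_total(trace, params$weight_decrements,
                       params$diseases$utility_decrement),
    disease_years = disease_years(trace),
    life_years = sum(trace$person_time[, seq_len(N_STATES - 1)]),
    healthcare_cost = healthcare_costs(trace, cost_per_case)
  )
}

#' Compare a multi-factor program evaluation with a weight-status-only one
#'
#' Runs three cohorts on the same parameter set: no program (baseline), the
#' program restricted to its weight-status effect (behavioural odds
#' multipliers forced to 1), and the full program. Reports, for both program
#' readings, incremental QALYs and disease-years, ICERs (program costs only),
#' health-care cost savings and ROI, plus the single-factor / multi-factor
#' ratios that quantify how much a weight-only evaluation misstates the
#' program's value.
#'
#' @param params A [model_parameters()].
#' @param effect_full The program's full [program_effect()].
#' @param annual_program_cost,program_years Program cost schedule (defaults
#'   $50 per year for 2 years, discounted at the model rate).
#' @param cost_per_case_year Annual health-care cost per case-year used for
#'   savings: a flat figure (default 12174) or a length-32 per-disease
#'   vector; `NULL` uses the per-disease costs in `params`.
#' @param transitions Optional [precompute_transitions()] output to reuse
#'   (transition matrices do not depend on the program effect).
#' @return An object of class `"scenario_comparison"`: the three scenario
#'   outcome sets, a `contrasts` data frame (one row per program reading)
#'   and a `ratios` list (`icer_qaly`, `icer_disease_years`, `roi`).
#' @export
compare_scenarios <- function(params, effect_full,
                              annual_program_cost = 50, program_years = 2,
                              cost_per_case_year = 12174,
                              transitions = NULL) {
  stopifnot(inherits(effect_full, "program_effect"))
  if (is.null(cost_per_case_year)) {
    cost_per_case_year <- params$diseases$annual_cost
  }
  if (is.null(transitions)) transitions <- precompute_transitions(params)
  base <- scenario_outcomes(params, NULL, transitions, cost_per_case_year)
  w_only <- scenario_outcomes(params, weight_only_effect(effect_full),
                              transitions, cost_per_case_year)
  full <- scenario_outcomes(params, effect_full, transitions,
                            cost_per_case_year)
  cost <- program_cost(annual_program_cost, program_years,
                       params$discount_rate)

  contrast <- function(scn, label) {
    d_qaly <- scn$qalys - base$qalys
    d_dy <- scn$disease_years - base$disease_years
    savings <- base$healthcare_cost - scn$healthcare_cost
    data.frame(scenario = label, program_cost = cost,
               incr_qalys = d_qaly, incr_disease_years = d_dy,
               icer_qaly = icer(cost, d_qaly),
               icer_disease_years = icer(cost, d_dy),
               savings = savings, roi = roi(savings, cost))
  }
  contrasts <- rbind(contrast(w_only, "weight_only"),
                     contrast(full, "all_factors"))
  ratios <- list(
    icer_qaly = contrasts$icer_qaly[1] / contrasts$icer_qaly[2],
    icer_disease_years =
      contrasts$icer_disease_years[1] / contrasts$icer_disease_years[2],
    roi = contrasts$roi[1] / contrasts$roi[2]
  )
  structure(list(baseline = base, weight_only = w_only, all_factors = full,
                 contrasts = contrasts, ratios = ratios,
                 program_cost = cost, effect = effect_full),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("<scenario_comparison> program cost", round(x$program_cost, 2), "\n")
  df <- x$contrasts
  df$icer_qaly <- round(df$icer_qaly)
  df$icer_disease_years <- round(df$icer_disease_years)
  df$savings <- round(df$savings, 3)
  df$roi <- round(df$roi)
  print(df, row.names = FALSE)
  cat(sprintf("  ratios (weight-only / all-factors): ICER[QALY] %.3f, ICER[disease-years] %.3f, ROI %.3f\n",
              x$ratios$icer_qaly, x$ratios$icer_disease_years, x$ratios$roi))
  invisible(x)
}
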