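# Epidemiological standardisation: rate ratios referenced to the general
# population (SMRs), multiplicative combination into conditional hazards and
# risk-adjusted incidences, rate-to-probability conversion, and incidence
# back-calculation from prevalence under an illness-death balance.

#' Rate ratios with population proportions for one dimension
#'
#' Bundles, for the categories of one risk factor (or of chronic-disease
#' status), a rate ratio per category (reference category = 1 by convention,
#' but any positive scale is accepted) and the population proportion in each
#' category.
#'
#' @param ratio Positive rate ratios (mortality rate ratios or relative
#'   risks), one per category.
#' @param proportion Population proportions per category, summing to 1.
#' @return An object of class `"category_ratios"`.
#' @export
#' @examples
#' category_ratios(c(1, 2), c(0.5, 0.5))
category_ratios <- function(ratio, proportion) {
  ratio <- as.numeric(ratio); proportion <- as.numeric(proportion)
  if (length(ratio) != length(proportion)) {
    stop("ratio and proportion must have equal length")
  }
  if (any(!is.finite(ratio)) || any(ratio <= 0)) stop("ratios must be positive")
  if (any(proportion < 0) || abs(sum(proportion) - 1) > 1e-8) {
    stop("proportions must be non-negative and sum to 1")
  }
  structure(list(ratio = ratio, proportion = proportion / sum(proportion)),
            class = "category_ratios")
}

#' Standardise rate ratios to the general population
#'
#' Converts category-referenced rate ratios into ratios relative to the whole
#' population: `SMR_k = MR_k / sum_k(P_k * MR_k)`. After standardisation the
#' population-weighted mean of the ratios is exactly 1, so the operation is
#' idempotent.
#'
#' @param ratios A [category_ratios()].
#' @return A [category_ratios()] whose `ratio` entries are SMRs.
#' @export
#' @examples
#' standardize_ratios(category_ratios(c(1, 2), c(0.5, 0.5)))$ratio # 2/3, 4/3
standardize_ratios <- function(ratios) {
  if (!inherits(ratios, "category_ratios")) stop("need a category_ratios object")
  denom <- sum(ratios$proportion * ratios$ratio)
  category_ratios(ratios$ratio / denom, ratios$proportion)
}

smr_factor <- function(ratios, category) {
  # category is a 1-based index; the inner division keeps the operation
  # correct whether ratios arrive raw or already standardised.
  ratios$ratio[category] / sum(ratios$proportion * ratios$ratio)
}

#' Conditional mortality hazard for a state
#'
#' Multiplies the age/sex baseline all-cause hazard `H` by the standardised
#' mortality ratio of the occupied category in each of the five dimensions
#' (weight, activity, fruit, vegetable, disease status), assuming no
#' synergistic or antagonistic effects:
#' `h* = H * prod_k SMR_k / sum(P_k SMR_k)`.
#'
#' @param H Baseline all-cause mortality hazard per year (age/sex specific).
#' @param ratios Named list of [category_ratios()] with elements `weight`,
#'   `activity`, `fruit`, `vegetable`, `disease` (raw or standardised; the
#'   internal renormalisation is idempotent).
#' @param profile 1-based risk-profile index (see [risk_profiles()]), or a
#'   list/row with the four category codes.
#' @param disease Disease status 0..32.
#' @return Hazard per year.
#' @export
combined_hazard <- function(H, ratios, profile, disease) {
  needed <- c(FACTORS, "disease")
  if (!all(needed %in% names(ratios))) {
    stop("ratios must supply dimensions: ", paste(needed, collapse = ", "))
  }
  if (H < 0) stop("baseline hazard must be non-negative")
  cats <- profile_categories(profile)
  f <- smr_factor(ratios$weight, cats["weight"] + 1L) *
    smr_factor(ratios$activity, cats["activity"] + 1L) *
    smr_factor(ratios$fruit, cats["fruit"] + 1L) *
    smr_factor(ratios$vegetable, cats["vegetable"] + 1L) *
    smr_factor(ratios$disease, disease + 1L)
  H * f
}

profile_categories <- function(profile) {
  if (is.numeric(profile) && length(profile) == 1L) {
    prof <- risk_profiles()[profile, ]
    c(weight = prof$weight, activity = prof$activity,
      fruit = prof$fruit, vegetable = prof$vegetable)
  } else {
    c(weight = profile[["weight"]], activity = profile[["activity"]],
      fruit = profile[["fruit"]], vegetable = profile[["vegetable"]])
  }
}

#' Risk-adjusted incidence of a chronic disease
#'
#' Scales a published age/sex-specific incidence `I` by the standardised
#' relative risk of the occupied category of each risk factor linked to the
#' disease: `I* = I * prod_k RR_k / sum(P_k RR_k)`. Under independent factor
#' distributions the population average of `I*` equals `I`. Factors not
#' linked to the disease contribute a factor of 1 (pass ratios of 1, or omit
#' them from `ratios`).
#'
#' @param I Incidence per person-year.
#' @param ratios Named list of [category_ratios()] for (a subset of) the four
#'   risk factors.
#' @param profile As in [combined_hazard()].
#' @return Adjusted incidence per person-year.
#' @export
adjusted_incidence <- function(I, ratios, profile) {
  if (I < 0) stop("incidence must be non-negative")
  unknown <- setdiff(names(ratios), FACTORS)
  if (length(unknown)) stop("unknown factor(s): ", paste(unknown, collapse = ", "))
  cats <- profile_categories(profile)
  f <- 1
  for (k in names(ratios)) {
    f <- f * smr_factor(ratios[[k]], cats[[k]] + 1L)
  }
  I * f
}

#' Convert an incidence rate to a per-cycle probability
#'
#' Standard exponential rate-to-probability transform
#' `p = 1 - exp(-I * t)` for a cycle of length `t` years.
#'
#' @param I_star Incidence per person-year (non-negative).
#' @param t Cycle length in years (positive).
#' @return Probability in `[0, 1)`.
#' @export
#' @examples
#' incidence_to_probability(0.01, 1) # 0.00995
incidence_to_probability <- function(I_star, t) {
  if (any(I_star < 0)) stop("incidence must be non-negative")
  if (t <= 0) stop("cycle length must be positive")
  1 - exp(-I_star * t)
}

# Prevalence at the end of an age interval under constant incidence i,
# non-diseased mortality m0 and diseased mortality m1 = mrr * m0, starting
# from prevalence prev_a. Closed-form solution of the two-state
# illness-death ODE  S' = -(i + m0) S,  C' = i S - m1 C.
illness_death_prevalence <- function(i, prev_a, m0, m1, interval) {
  s0 <- 1 - prev_a
  c0 <- prev_a
  a <- i + m0
  s1 <- s0 * exp(-a * interval)
  d <- m1 - a
  integral <- if (abs(d) < 1e-12) interval else (exp(d * interval) - 1) / d
  c1 <- exp(-m1 * interval) * (c0 + i * s0 * integral)
  c1 / (s1 + c1)
}

#' Back-calculate incidence from prevalence and mortality
#'
#' Finds the constant incidence over an age interval that, in a two-state
#' illness-death model with differential mortality, carries disease
#' prevalence from `prevalence_age_a` to `prevalence_age_b` (the
#' Podgor-Leske balance). The non-diseased mortality hazard is derived from
#' the general-population hazard and the diseased/non-diseased mortality
#' ratio so that the population hazard at the interval start equals
#' `mortality_general`. The nonlinear equation is solved by Newton-Raphson
#' (numerical derivative) to `|f| < tol`, with bisection fallback when a
#' Newton step leaves `[0, 10]`.
#'
#' @param prevalence_age_a,prevalence_age_b Prevalences in `[0, 1]` at the
#'   start and end of the interval.
#' @param mortality_general All-cause mortality hazard per year over the
#'   interval.
#' @param mortality_ratio_diseased Mortality hazard ratio, diseased vs
#'   non-diseased.
#' @param interval_years Interval length in years (positive).
#' @param tol Convergence tolerance on the prevalence residual.
#' @param max_iter Iteration cap.
#' @return Incidence per person-year (non-negative scalar).
#' @export
#' @examples
#' solve_incidence(0.05, 0.08, 0.01, 2, 5)
solve_incidence <- function(prevalence_age_a, prevalence_age_b,
                            mortality_general, mortality_ratio_diseased,
                            interval_years, tol = 1e-10, max_iter = 100L) {
  pa <- prevalence_age_a; pb <- prevalence_age_b
  if (pa < 0 || pa > 1 || pb < 0 || pb > 1) stop("prevalences must be in [0, 1]")
  if (interval_years <= 0) stop("interval must be positive")
  if (mortality_general < 0 || mortality_ratio_diseased <= 0) {
    stop("mortality inputs must be non-negative (ratio positive)")
  }
  m0 <- mortality_general / (1 - pa + pa * mortality_ratio_diseased)
  m1 <- m0 * mortality_ratio_diseased
  f <- function(i) illness_death_prevalence(i, pa, m0, m1, interval_years) - pb

  lo <- 0; hi <- 10
  f_lo <- f(lo)
  if (f_lo > tol) {
    stop("target prevalence below the minimum achievable with zero incidence ",
         "(residual ", format(f_lo, digits = 6), ")")
  }
  if (f(hi) < -tol) stop("no root with incidence in [0, 10] per person-year")

  crude <- max((pb - pa) / interval_years, 1e-8)
  i_cur <- crude
  for (iter in seq_len(max_iter)) {
    f_cur <- f(i_cur)
    if (abs(f_cur) < tol) return(max(i_cur, 0))
    if (f_cur > 0) hi <- i_cur else lo <- i_cur
    h <- max(1e-7, 1e-7 * abs(i_cur))
    deriv <- (f(i_cur + h) - f(i_cur - h)) / (2 * h)
    step_ok <- is.finite(deriv) && deriv != 0
    i_next <- if (step_ok) i_cur - f_cur / deriv else NA_real_
    if (!step_ok || i_next < 0 || i_next > 10) {
      i_next <- (lo + hi) / 2  # bisection fallback on the bracket
    }
    i_cur <- i_next
  }
  stop("solve_incidence did not converge; residual ",
       format(f(i_cur), digits = 6))
}

#' Annual health-care cost per prevalent case
#'
#' Allocates total health expenditure to one diagnosis category and divides
#' by the number of prevalent cases:
#' `total_expenditure * category_proportion / (prevalence * population)`.
#'
#' @param total_expenditure Total direct health-care expenditure (currency).
#' @param category_proportion Fraction of expenditure attributable to the
#'   diagnosis category.
#' @param prevalence Prevalence of the condition (proportion).
#' @param population Population count.
#' @return Currency per case per year.
#' @export
#' @examples
#' per_case_cost(1000, 0.5, 0.25, 100) # 20
per_case_cost <- function(total_expenditure, category_proportion, prevalence,
                          population) {
  if (total_expenditure < 0 || category_proportion < 0) {
    stop("expenditure inputs must be non-negative")
  }
  if (prevalence <= 0 || population <= 0) {
    stop("prevalent cases must be positive")
  }
  total_expenditure * category_proportion / (prevalence * population)
}
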