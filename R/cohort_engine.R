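# Lifetime Markov cohort engine over the 793 states: each cycle applies
# mortality, then chronic-disease incidence among the disease-free, then the
# joint risk-factor transition, accumulating discounted person-time.

#' Discount factor
#'
#' Present-value factor `(1 + rate)^(-years_elapsed)`; year 0 is
#' undiscounted.
#'
#' @param rate Annual discount rate (fraction per year, >= 0).
#' @param years_elapsed Years since model start.
#' @return Discount factor(s).
#' @export
#' @examples
#' discount_factor(0.015, 0) # 1
#' 50 * sum(discount_factor(0.015, 0:1)) # 99.26: two program years at $50
discount_factor <- function(rate, years_elapsed) {
  if (rate < 0) stop("discount rate must be non-negative")
  (1 + rate)^(-years_elapsed)
}

#' Allocate competing incident diseases within one cycle
#'
#' Given per-disease adjusted incidence rates, the probability of remaining
#' disease-free over a cycle of length `t` is `exp(-sum(rates) * t)`; the
#' complementary incidence probability is allocated to diseases in proportion
#' to their rates. With a single disease this reduces to the exponential
#' rate-to-probability transform.
#'
#' @param rates Non-negative incidence rates per disease (per person-year).
#' @param t Cycle length in years.
#' @return List with `stay` (probability of no incident disease) and `probs`
#'   (per-disease incidence probabilities); `stay + sum(probs) == 1`.
#' @export
competing_incidence <- function(rates, t = 1) {
  if (any(rates < 0)) stop("rates must be non-negative")
  total <- sum(rates)
  stay <- exp(-total * t)
  probs <- if (total == 0) rep(0, length(rates)) else
    (1 - stay) * rates / total
  list(stay = stay, probs = probs)
}

#' Assemble and validate the full model parameter set
#'
#' @param initial_distribution A [joint_risk_distribution()] at the starting
#'   age.
#' @param coefficients A [transition_coefficients()] for the two-year joint
#'   risk-factor transition model.
#' @param life_table Data frame `age`, `sex` (0 = female, 1 = male),
#'   `hazard` (all-cause mortality per year).
#' @param diseases Data frame with 32 rows: `disease`, `mortality_ratio`
#'   (diseased vs no chronic disease), `utility_decrement` in `[0, 1]`,
#'   `annual_cost` (currency per case-year), `prevalence` (population
#'   proportion, used as the disease-status weights in standardisation).
#' @param disease_rr List of four matrices (`weight` 32 x 3, `activity`,
#'   `fruit`, `vegetable` 32 x 2): relative risks of disease incidence per
#'   factor category; rows must be 1 for factors not linked to the disease.
#' @param mortality_ratios List of four numeric vectors (`weight` length 3,
#'   others length 2): all-cause mortality rate ratios per factor category.
#' @param population List of four proportion vectors matching the factor
#'   category counts: the fixed population distribution used as
#'   standardisation weights.
#' @param incidence 3-d array `[32 diseases, ages, 2 sexes]` of incidence
#'   rates per person-year, with age dimnames.
#' @param weight_decrements Utility decrements `c(normal, overweight,
#'   obese)`; first entry 0.
#' @param linkage A `linkage_matrix` (defaults to the packaged table).
#' @param discount_rate Annual discount rate (default 0.015).
#' @param horizon Simulated years (default 84, ages 10 through 93).
#' @param cycle_length Markov cycle in years, 1 or 2 (default 1; two-year
#'   transition estimates are annualised via [per_cycle_matrix()]).
#' @param start_age Cohort starting age (default 10).
#' @param sex_mix Proportion of the cohort that is female (default 0.5).
#' @return A validated object of class `"model_parameters"`.
#' @export
model_parameters <- function(initial_distribution, coefficients, life_table,
                             diseases, disease_rr, mortality_ratios,
                             population, incidence,
                             weight_decrements = c(0, 0, 0),
                             linkage = load_linkage(),
                             discount_rate = 0.015, horizon = 84,
                             cycle_length = 1, start_age = 10,
                             sex_mix = 0.5) {
  p <- structure(list(
    initial_distribution = joint_risk_distribution(initial_distribution),
    coefficients = coefficients, life_table = life_table,
    diseases = diseases, disease_rr = disease_rr,
    mortality_ratios = mortality_ratios, population = population,
    incidence = incidence, weight_decrements = as.numeric(weight_decrements),
    linkage = linkage, discount_rate = discount_rate, horizon = horizon,
    cycle_length = cycle_length, start_age = start_age, sex_mix = sex_mix
  ), class = "model_parameters")
  validate_model_parameters(p)
  p
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  cat(sprintf("  %d diseases, horizon %g y from age %g, cycle %g y, discount %.3g/y, female share %.2f\n",
              nrow(x$diseases), x$horizon, x$start_age, x$cycle_length,
              x$discount_rate, x$sex_mix))
  invisible(x)
}

validate_model_parameters <- function(p) {
  stopifnot(inherits(p$coefficients, "transition_coefficients"))
  lt <- p$life_table
  if (!all(c("age", "sex", "hazard") %in% names(lt))) {
    stop("life table needs columns age, sex, hazard")
  }
  if (any(lt$hazard < 0)) stop("life-table hazards must be non-negative")
  d <- p$diseases
  need <- c("disease", "mortality_ratio", "utility_decrement", "annual_cost",
            "prevalence")
  if (!all(need %in% names(d))) {
    stop("diseases table needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(d) != N_DISEASES) stop("diseases table must have 32 rows")
  if (any(d$mortality_ratio <= 0)) stop("mortality ratios must be positive")
  if (any(d$utility_decrement < 0 | d$utility_decrement > 1)) {
    stop("utility decrements must be in [0, 1]")
  }
  if (any(d$annual_cost < 0)) stop("annual costs must be non-negative")
  if (any(d$prevalence < 0) || sum(d$prevalence) >= 1) {
    stop("disease prevalences must be non-negative and sum to < 1")
  }
  sizes <- c(weight = 3L, activity = 2L, fruit = 2L, vegetable = 2L)
  for (f in names(sizes)) {
    rr <- p$disease_rr[[f]]
    if (is.null(rr) || !all(dim(rr) == c(N_DISEASES, sizes[[f]]))) {
      stop("disease_rr$", f, " must be a ", N_DISEASES, " x ", sizes[[f]],
           " matrix")
    }
    if (any(rr <= 0)) stop("relative risks must be positive")
    unlinked <- p$linkage[, f] == 0L
    if (any(abs(rr[unlinked, ] - 1) > 1e-12)) {
      stop("disease_rr$", f, " must be 1 for diseases not linked to ", f)
    }
    mr <- p$mortality_ratios[[f]]
    if (length(mr) != sizes[[f]] || any(mr <= 0)) {
      stop("mortality_ratios$", f, " must be ", sizes[[f]], " positive values")
    }
    pp <- p$population[[f]]
    if (length(pp) != sizes[[f]] || any(pp < 0) || abs(sum(pp) - 1) > 1e-8) {
      stop("population$", f, " must be ", sizes[[f]],
           " proportions summing to 1")
    }
  }
  if (!is.array(p$incidence) ||
      !all(dim(p$incidence)[c(1, 3)] == c(N_DISEASES, 2L))) {
    stop("incidence must be a [32, ages, 2] array")
  }
  if (any(p$incidence < 0)) stop("incidence rates must be non-negative")
  if (is.null(dimnames(p$incidence)[[2]])) {
    stop("incidence array needs age dimnames")
  }
  if (length(p$weight_decrements) != 3L ||
      any(p$weight_decrements < 0 | p$weight_decrements > 1)) {
    stop("weight_decrements must be 3 values in [0, 1]")
  }
  if (p$discount_rate < 0) stop("discount rate must be non-negative")
  if (!p$cycle_length %in% c(1, 2)) stop("cycle_length must be 1 or 2")
  if (p$horizon <= 0 || p$horizon %% p$cycle_length != 0) {
    stop("horizon must be a positive multiple of cycle_length")
  }
  if (p$sex_mix < 0 || p$sex_mix > 1) stop("sex_mix must be in [0, 1]")
  ages_needed <- seq(p$start_age, p$start_age + p$horizon - p$cycle_length,
                     by = p$cycle_length)
  for (s in 0:1) {
    have <- lt$age[lt$sex == s]
    if (!all(ages_needed %in% have)) {
      stop("life table does not cover ages ", min(ages_needed), "-",
           max(ages_needed), " for sex ", s)
    }
  }
  if (!all(as.character(ages_needed) %in% dimnames(p$incidence)[[2]])) {
    stop("incidence array does not cover the simulated ages")
  }
  invisible(TRUE)
}

# standardised SMR products used every cycle (fixed population weights)
engine_constants <- function(params) {
  prof <- risk_profiles()
  std <- function(r, pp) standardize_ratios(category_ratios(r, pp))$ratio
  sw <- std(params$mortality_ratios$weight, params$population$weight)
  sp <- std(params$mortality_ratios$activity, params$population$activity)
  sf <- std(params$mortality_ratios$fruit, params$population$fruit)
  sv <- std(params$mortality_ratios$vegetable, params$population$vegetable)
  p_dis <- c(1 - sum(params$diseases$prevalence), params$diseases$prevalence)
  sd <- std(c(1, params$diseases$mortality_ratio), p_dis)
  F24 <- sw[prof$weight + 1L] * sp[prof$activity + 1L] *
    sf[prof$fruit + 1L] * sv[prof$vegetable + 1L]
  # per-disease standardised RR product across profiles (32 x 24)
  RR <- matrix(1, N_DISEASES, N_PROFILES)
  for (f in FACTORS) {
    rrf <- params$disease_rr[[f]]
    ppf <- params$population[[f]]
    srr <- rrf / rowSums(rrf * rep(ppf, each = N_DISEASES))
    RR <- RR * srr[, prof[[f]] + 1L]
  }
  list(F24 = F24, sd = sd, RR = RR)
}

hazard_lookup <- function(life_table, sex) {
  lt <- life_table[life_table$sex == sex, ]
  h <- lt$hazard
  names(h) <- as.character(lt$age)
  h
}

#' Precompute per-cycle risk-factor transition matrices
#'
#' Transition matrices depend only on sex, age and the coefficient set, not
#' on the program effect, so scenario comparisons and PSA draws reuse them
#' across cohort runs.
#'
#' @param params A [model_parameters()].
#' @return List with elements `"0"` (female) and `"1"` (male), each a list of
#'   24 x 24 matrices, one per cycle.
#' @export
precompute_transitions <- function(params) {
  n_cyc <- params$horizon / params$cycle_length
  ages <- params$start_age + params$cycle_length * (seq_len(n_cyc) - 1)
  out <- list()
  for (s in 0:1) {
    out[[as.character(s)]] <- lapply(ages, function(a) {
      per_cycle_matrix(params$coefficients, s, a, params$cycle_length)
    })
  }
  out
}

#' Run the lifetime Markov cohort
#'
#' Places the (program-modified) initial joint risk-factor distribution in
#' the no-chronic-disease states at the starting age, then iterates cycles
#' applying, in order: mortality (standardised-ratio-adjusted hazards),
#' competing chronic-disease incidence among the disease-free, and the joint
#' risk-factor transition (in diseased and disease-free states alike).
#' Diseased states never revert; death is absorbing. Female and male cohorts
#' are run in parallel and combined by `sex_mix`. Person-time equals state
#' occupancy at cycle start times cycle length (no half-cycle correction),
#' discounted by elapsed years since model start.
#'
#' @param params A [model_parameters()].
#' @param effect A [program_effect()] applied to the initial distribution,
#'   or `NULL` for the baseline scenario.
#' @param transitions Optional output of [precompute_transitions()].
#' @return An object of class `"cohort_trace"`: matrices `occupancy`
#'   (`n_cycles + 1` rows x 793 states), `person_time` (discounted) and
#'   `person_time_undiscounted` (`n_cycles` rows x 793), plus run metadata.
#' @export
run_cohort <- function(params, effect = NULL, transitions = NULL) {
  validate_model_parameters(params)
  if (is.null(transitions)) transitions <- precompute_transitions(params)
  t_cyc <- params$cycle_length
  n_cyc <- params$horizon / t_cyc
  cons <- engine_constants(params)
  init <- apply_program_effect(params$initial_distribution, effect)
  ages <- params$start_age + t_cyc * (seq_len(n_cyc) - 1)
  age_chr <- as.character(ages)
  disc <- discount_factor(params$discount_rate, t_cyc * (seq_len(n_cyc) - 1))

  run_sex <- function(sex) {
    hz <- hazard_lookup(params$life_table, sex)
    trans <- transitions[[as.character(sex)]]
    occ <- matrix(0, N_PROFILES, N_DISEASE_STATUS)  # alive block
    occ[, 1] <- as.numeric(init)
    dead <- 0
    occupancy <- matrix(0, n_cyc + 1, N_STATES)
    pt <- matrix(0, n_cyc, N_STATES)
    ptu <- matrix(0, n_cyc, N_STATES)
    for (j in seq_len(n_cyc)) {
      occupancy[j, ] <- c(as.vector(occ), dead)
      ptu[j, 1:(N_STATES - 1)] <- as.vector(occ) * t_cyc
      pt[j, ] <- ptu[j, ] * disc[j]
      # 1. mortality
      H <- hz[[age_chr[j]]]
      hstar <- H * outer(cons$F24, cons$sd)
      p_die <- 1 - exp(-hstar * t_cyc)
      dead <- dead + sum(occ * p_die)
      occ <- occ * (1 - p_die)
      # 2. competing incidence among the disease-free
      col0 <- occ[, 1]
      rates <- cons$RR * params$incidence[, age_chr[j], sex + 1L]  # 32 x 24
      rho <- colSums(rates)
      stay <- exp(-rho * t_cyc)
      share <- sweep(rates, 2, ifelse(rho > 0, rho, 1), "/")
      inc_mass <- sweep(share, 2, col0 * (1 - stay), "*")  # 32 x 24
      occ[, 1] <- col0 * stay
      occ[, -1] <- occ[, -1] + t(inc_mass)
      # 3. joint risk-factor transition within every disease stratum
      occ <- crossprod(trans[[j]], occ)
    }
    occupancy[n_cyc + 1, ] <- c(as.vector(occ), dead)
    list(occupancy = occupancy, pt = pt, ptu = ptu)
  }

  f <- run_sex(0)
  m <- run_sex(1)
  w <- params$sex_mix
  structure(list(
    occupancy = w * f$occupancy + (1 - w) * m$occupancy,
    person_time = w * f$pt + (1 - w) * m$pt,
    person_time_undiscounted = w * f$ptu + (1 - w) * m$ptu,
    by_sex = list(female = f, male = m),
    n_cycles = n_cyc, cycle_length = t_cyc, start_age = params$start_age,
    discount_rate = params$discount_rate
  ), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  alive_end <- 1 - x$occupancy[nrow(x$occupancy), N_STATES]
  cat("<cohort_trace>", x$n_cycles, "cycles of", x$cycle_length,
      "y from age", x$start_age, "\n")
  cat(sprintf("  discounted life-years %.3f; surviving fraction at end %.4f\n",
              sum(x$person_time[, -N_STATES]), alive_end))
  invisible(x)
}
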