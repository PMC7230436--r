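# Synthetic parameter sets: complete, internally consistent model inputs
# (life table, initial joint distribution, transition coefficients, disease
# parameters) emulating the shape of national survey / burden-of-disease
# inputs, pure in a seed. These are qualitative stand-ins, not calibrated to
# any country.

#' Configuration for the synthetic parameter generator
#'
#' @param seed Mandatory integer seed; generation is pure in it.
#' @param start_age,horizon Cohort start age and simulated years.
#' @param gompertz_a,gompertz_b Baseline mortality hazard
#'   `a * exp(b * age)` (Gompertz-like, increasing in age).
#' @param male_hazard_ratio Male vs female baseline hazard ratio.
#' @param incidence_range Range (per person-year, log-uniform) of disease
#'   incidence at the reference age 40.
#' @param incidence_age_slope Range of the exponential age slope of
#'   incidence.
#' @param rr_range Range of incidence relative risks for linked risky
#'   categories.
#' @param mr_range Range of all-cause mortality rate ratios for risky
#'   factor categories.
#' @param disease_mr_range Range of diseased-vs-healthy mortality ratios.
#' @param decrement_range Range of per-disease utility decrements.
#' @param cost_range Range of per-disease annual costs (currency).
#' @param prevalence_range Range of per-disease population prevalences.
#' @param concentration Dirichlet concentration of the initial joint
#'   distribution around its expected cell values.
#' @return A list of class `"fixture_config"`.
#' @export
fixture_config <- function(seed, start_age = 10, horizon = 84,
                           gompertz_a = 5e-5, gompertz_b = 0.085,
                           male_hazard_ratio = 1.4,
                           incidence_range = c(1e-5, 2e-3),
                           incidence_age_slope = c(0.02, 0.06),
                           rr_range = c(1.1, 1.8),
                           mr_range = c(1.05, 1.6),
                           disease_mr_range = c(1.2, 3),
                           decrement_range = c(0.03, 0.3),
                           cost_range = c(1000, 20000),
                           prevalence_range = c(0.001, 0.02),
                           concentration = 500) {
  if (missing(seed)) stop("seed is mandatory")
  ranges <- list(incidence_range, incidence_age_slope, rr_range, mr_range,
                 disease_mr_range, decrement_range, cost_range,
                 prevalence_range)
  if (any(vapply(ranges, function(r) any(r <= 0) || r[2] < r[1], logical(1)))) {
    stop("all ranges must be positive and increasing")
  }
  structure(list(seed = as.integer(seed), start_age = start_age,
                 horizon = horizon, gompertz_a = gompertz_a,
                 gompertz_b = gompertz_b,
                 male_hazard_ratio = male_hazard_ratio,
                 incidence_range = incidence_range,
                 incidence_age_slope = incidence_age_slope,
                 rr_range = rr_range, mr_range = mr_range,
                 disease_mr_range = disease_mr_range,
                 decrement_range = decrement_range, cost_range = cost_range,
                 prevalence_range = prevalence_range,
                 concentration = concentration),
            class = "fixture_config")
}

synthetic_life_table <- function(config) {
  ages <- 0:110
  base <- config$gompertz_a * exp(config$gompertz_b * ages)
  rbind(
    data.frame(age = ages, sex = 0L, hazard = base),
    data.frame(age = ages, sex = 1L, hazard = base * config$male_hazard_ratio)
  )
}

synthetic_initial_distribution <- function(config) {
  # product of realistic childhood marginals, jittered on the simplex
  prof <- risk_profiles()
  pw <- c(0.70, 0.20, 0.10)   # normal / overweight / obese at age 10
  pp <- c(0.70, 0.30)         # not meeting / meeting activity
  pf <- c(0.60, 0.40)
  pv <- c(0.65, 0.35)
  mean_cell <- pw[prof$weight + 1L] * pp[prof$activity + 1L] *
    pf[prof$fruit + 1L] * pv[prof$vegetable + 1L]
  draw <- stats::rgamma(N_PROFILES, shape = config$concentration * mean_cell)
  joint_risk_distribution(draw / sum(draw))
}

synthetic_coefficients <- function(config) {
  str <- transition_structure()
  terms <- str$terms
  beta <- stats::rnorm(nrow(terms), 0, 0.05)
  set_term <- function(name, value) beta[terms$name == name] <<- value
  # outcome prevalence levels (log-odds vs all-reference)
  set_term("w1", -0.6); set_term("w2", -1.3)
  set_term("p1", -0.8); set_term("f1", -0.4); set_term("v1", -0.7)
  # persistence: current status strongly predicts the same status next wave
  set_term("w1|cw1", 2.0); set_term("w2|cw2", 2.6); set_term("w1|cw2", 0.8)
  set_term("w2|cw1", 0.6)
  set_term("p1|cp", 1.6); set_term("f1|cf", 1.5); set_term("v1|cv", 1.5)
  # mild age drift toward higher weight, less activity
  set_term("w1|age", 0.10); set_term("w2|age", 0.12); set_term("p1|age", -0.08)
  # positive association between the healthy behaviours
  for (nm in c("p1:f1", "p1:v1", "f1:v1")) set_term(nm, 0.3)
  transition_coefficients(str, beta)
}

#' Generate a complete synthetic parameter set
#'
#' Draws a full [model_parameters()] object: a Gompertz-like life table
#' (hazard increasing in age), a simplex-valid initial joint distribution, a
#' transition model with strong status persistence, and 32 disease
#' specifications whose relative-risk pattern matches the packaged linkage
#' table exactly (RR = 1 wherever a factor is not linked). Risky categories
#' (higher weight, not meeting a recommendation) always carry ratios >= 1,
#' so beneficial program effects act in the expected direction.
#'
#' @param config A [fixture_config()].
#' @return A validated [model_parameters()] object.
#' @export
#' @examples
#' params <- generate_parameter_set(fixture_config(seed = 1))
generate_parameter_set <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    linkage <- load_linkage()
    life_table <- synthetic_life_table(config)
    init <- synthetic_initial_distribution(config)
    coef <- synthetic_coefficients(config)

    runif_r <- function(n, r) stats::runif(n, r[1], r[2])
    diseases <- data.frame(
      disease = rownames(linkage),
      mortality_ratio = runif_r(N_DISEASES, config$disease_mr_range),
      utility_decrement = runif_r(N_DISEASES, config$decrement_range),
      annual_cost = runif_r(N_DISEASES, config$cost_range),
      prevalence = runif_r(N_DISEASES, config$prevalence_range)
    )

    rr_draw <- function(linked, ncat) {
      # ratios >= 1 in riskier categories, exactly 1 when unlinked
      m <- matrix(1, N_DISEASES, ncat)
      if (ncat == 3L) {
        r1 <- ifelse(linked, runif_r(N_DISEASES, config$rr_range), 1)
        m[, 2] <- r1
        m[, 3] <- ifelse(linked, r1 * runif_r(N_DISEASES, c(1.05, 1.5)), 1)
      } else {
        # category 0 (not meeting the recommendation) carries the excess risk
        m[, 1] <- ifelse(linked, runif_r(N_DISEASES, config$rr_range), 1)
      }
      m
    }
    disease_rr <- list(
      weight = rr_draw(linkage[, "weight"] == 1L, 3L),
      activity = rr_draw(linkage[, "activity"] == 1L, 2L),
      fruit = rr_draw(linkage[, "fruit"] == 1L, 2L),
      vegetable = rr_draw(linkage[, "vegetable"] == 1L, 2L)
    )

    mr1 <- runif_r(1, config$mr_range)
    mortality_ratios <- list(
      weight = c(1, mr1, mr1 * runif_r(1, c(1.1, 1.5))),
      activity = c(runif_r(1, config$mr_range), 1),
      fruit = c(runif_r(1, config$mr_range), 1),
      vegetable = c(runif_r(1, config$mr_range), 1)
    )
    population <- list(weight = c(0.40, 0.35, 0.25),
                       activity = c(0.75, 0.25),
                       fruit = c(0.60, 0.40),
                       vegetable = c(0.70, 0.30))

    ages <- seq(config$start_age, config$start_age + config$horizon - 1)
    base_inc <- exp(stats::runif(N_DISEASES, log(config$incidence_range[1]),
                                 log(config$incidence_range[2])))
    slope <- runif_r(N_DISEASES, config$incidence_age_slope)
    sex_mult <- runif_r(N_DISEASES, c(0.8, 1.25))
    inc <- array(0, dim = c(N_DISEASES, length(ages), 2L),
                 dimnames = list(rownames(linkage), as.character(ages),
                                 c("female", "male")))
    curve <- exp(outer(slope, ages - 40))
    inc[, , 1] <- pmin(base_inc * curve, 0.05)
    inc[, , 2] <- pmin(base_inc * sex_mult * curve, 0.05)

    wdec <- stats::runif(1, 0.01, 0.03)
    model_parameters(
      initial_distribution = init, coefficients = coef,
      life_table = life_table, diseases = diseases, disease_rr = disease_rr,
      mortality_ratios = mortality_ratios, population = population,
      incidence = inc,
      weight_decrements = c(0, wdec, wdec + stats::runif(1, 0.01, 0.04)),
      linkage = linkage, discount_rate = 0.015, horizon = config$horizon,
      cycle_length = 1, start_age = config$start_age, sex_mix = 0.5
    )
  })
}

#' Generate the null parameter set
#'
#' Same life table and structural shape as [generate_parameter_set()], but
#' all rate ratios 1, all incidences 0, all utility decrements and costs 0,
#' and null transition coefficients. On this set the cohort reduces to the
#' life table in closed form: survival equals life-table survival and QALYs
#' equal discounted life expectancy, whatever program effect is applied.
#'
#' @param config A [fixture_config()].
#' @return A validated [model_parameters()] object.
#' @export
generate_null_parameter_set <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    linkage <- load_linkage()
    ages <- seq(config$start_age, config$start_age + config$horizon - 1)
    inc <- array(0, dim = c(N_DISEASES, length(ages), 2L),
                 dimnames = list(rownames(linkage), as.character(ages),
                                 c("female", "male")))
    ones <- function(ncat) matrix(1, N_DISEASES, ncat)
    model_parameters(
      initial_distribution = synthetic_initial_distribution(config),
      coefficients = transition_coefficients(transition_structure(), 0),
      life_table = synthetic_life_table(config),
      diseases = data.frame(disease = rownames(linkage), mortality_ratio = 1,
                            utility_decrement = 0, annual_cost = 0,
                            prevalence = 0.005),
      disease_rr = list(weight = ones(3L), activity = ones(2L),
                        fruit = ones(2L), vegetable = ones(2L)),
      mortality_ratios = list(weight = c(1, 1, 1), activity = c(1, 1),
                              fruit = c(1, 1), vegetable = c(1, 1)),
      population = list(weight = c(0.40, 0.35, 0.25),
                        activity = c(0.75, 0.25), fruit = c(0.60, 0.40),
                        vegetable = c(0.70, 0.30)),
      incidence = inc, weight_decrements = c(0, 0, 0), linkage = linkage,
      discount_rate = 0.015, horizon = config$horizon, cycle_length = 1,
      start_age = config$start_age, sex_mix = 0.5
    )
  })
}
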