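# shared fixtures, built in code and cached for the test session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  .fixture_cache[[key]]
}

test_params <- function(seed = 1, horizon = 84) {
  cached(sprintf("params_%d_%d", seed, horizon),
         generate_parameter_set(fixture_config(seed = seed,
                                               horizon = horizon)))
}

test_null_params <- function(seed = 1, horizon = 84) {
  cached(sprintf("null_%d_%d", seed, horizon),
         generate_null_parameter_set(fixture_config(seed = seed,
                                                    horizon = horizon)))
}

test_transitions <- function(seed = 1, horizon = 84) {
  cached(sprintf("trans_%d_%d", seed, horizon),
         precompute_transitions(test_params(seed, horizon)))
}

# discrete forward simulation of the two-state illness-death cohort,
# independent of the closed-form balance inside solve_incidence
forward_prevalence <- function(incidence, prev_a, mortality_general,
                               mortality_ratio, interval, steps = 20000) {
  m0 <- mortality_general / (1 - prev_a + prev_a * mortality_ratio)
  m1 <- m0 * mortality_ratio
  dt <- interval / steps
  S <- 1 - prev_a
  C <- prev_a
  for (k in seq_len(steps)) {
    C_new <- C * (1 - m1 * dt) + S * incidence * dt
    S <- S * (1 - (incidence + m0) * dt)
    C <- C_new
  }
  C / (S + C)
}

# life-table survival of a mixed cohort from the model start age, by cycle
life_table_survival <- function(params) {
  ages <- params$start_age + seq_len(params$horizon / params$cycle_length) *
    params$cycle_length - params$cycle_length
  surv_sex <- function(s) {
    lt <- params$life_table[params$life_table$sex == s, ]
    h <- lt$hazard[match(ages, lt$age)]
    cumprod(c(1, exp(-h * params$cycle_length)))[seq_along(ages)]
  }
  params$sex_mix * surv_sex(0) + (1 - params$sex_mix) * surv_sex(1)
}
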