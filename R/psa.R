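# Probabilistic sensitivity analysis: draw parameter sets from their
# uncertainty distributions (beta for probabilities/incidences/prevalences,
# log-normal for rate ratios, normal for transition coefficients), rerun the
# scenario comparison, and summarise 2.5th/97.5th percentiles.

#' Uncertainty specification for PSA
#'
#' Hyperparameters are derived from the point estimates in `base` plus
#' relative 95% CI widths: a ratio `r` means a CI of `point / r` to
#' `point * r` for log-normal quantities (`sdlog = log(r) / 1.96`) and
#' `point * (1 -/+ rel)` for beta quantities (moment matching with
#' `sd = rel * point / 1.96`). Setting a width to 0 (or `initial_ess` to
#' `Inf`) makes the corresponding draw degenerate at the point estimate.
#'
#' @param base A [model_parameters()] object.
#' @param rr_ci_ratio CI ratio for incidence relative risks (log-normal).
#' @param mr_ci_ratio CI ratio for mortality rate ratios, factor-level and
#'   disease-level (log-normal).
#' @param incidence_rel Relative half-width for disease incidence (beta,
#'   applied as one draw per disease scaling its whole age curve).
#' @param prevalence_rel Relative half-width for disease prevalences (beta).
#' @param coef_sd Normal SD for transition-model coefficients: `NULL` to use
#'   the fitted standard errors stored in the coefficients (0 when absent),
#'   or a scalar.
#' @param initial_ess Effective sample size for per-cell beta draws of the
#'   24-cell initial distribution (renormalised to the simplex); `Inf` keeps
#'   it fixed.
#' @return A list of class `"uncertainty_spec"`.
#' @export
uncertainty_spec <- function(base, rr_ci_ratio = 1.2, mr_ci_ratio = 1.2,
                             incidence_rel = 0.2, prevalence_rel = 0.2,
                             coef_sd = NULL, initial_ess = 5000) {
  stopifnot(inherits(base, "model_parameters"))
  if (rr_ci_ratio < 1 || mr_ci_ratio < 1) stop("CI ratios must be >= 1")
  if (incidence_rel < 0 || incidence_rel >= 1 ||
      prevalence_rel < 0 || prevalence_rel >= 1) {
    stop("relative widths must be in [0, 1)")
  }
  if (initial_ess <= 0) stop("initial_ess must be positive")
  structure(list(
    rr_sdlog = log(rr_ci_ratio) / stats::qnorm(0.975),
    mr_sdlog = log(mr_ci_ratio) / stats::qnorm(0.975),
    incidence_rel_sd = incidence_rel / stats::qnorm(0.975),
    prevalence_rel_sd = prevalence_rel / stats::qnorm(0.975),
    coef_sd = coef_sd, initial_ess = initial_ess
  ), class = "uncertainty_spec")
}

# beta draw with given mean and sd (moment matching); degenerate when sd = 0
# or when the mean is outside (0, 1)
rbeta_ms <- function(n, mean, sd) {
  if (sd == 0 || mean <= 0 || mean >= 1) return(rep(mean, n))
  v <- sd^2
  vmax <- mean * (1 - mean)
  if (v >= vmax) v <- 0.99 * vmax
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

# log-normal multiplier draw with median `point`
rlnorm_pt <- function(n, point, sdlog) {
  if (sdlog == 0) return(rep(point, n))
  point * stats::rlnorm(n, 0, sdlog)
}

#' Draw one parameter set from its uncertainty distributions
#'
#' @param base A [model_parameters()] object (point estimates).
#' @param spec An [uncertainty_spec()].
#' @param seed Integer seed; the draw is pure in it.
#' @return A valid [model_parameters()] object.
#' @export
draw_parameter_set <- function(base, spec, seed) {
  stopifnot(inherits(base, "model_parameters"),
            inherits(spec, "uncertainty_spec"))
  with_seed(seed, {
    p <- base

    # initial distribution: per-cell beta, renormalised to the simplex
    if (is.finite(spec$initial_ess)) {
      p0 <- as.numeric(base$initial_distribution)
      draw <- vapply(p0, function(m) {
        rbeta_ms(1, m, sqrt(m * (1 - m) / spec$initial_ess))
      }, numeric(1))
      if (sum(draw) > 0) {
        p$initial_distribution <- joint_risk_distribution(draw / sum(draw))
      }
    }

    # incidence: one beta draw per disease at its age-40 (or first-age)
    # reference value, scaling the whole age curve
    if (spec$incidence_rel_sd > 0) {
      ages <- dimnames(base$incidence)[[2]]
      ref <- if ("40" %in% ages) "40" else ages[1]
      for (d in seq_len(N_DISEASES)) {
        i0 <- base$incidence[d, ref, 1]
        if (i0 <= 0) next
        mult <- rbeta_ms(1, i0, spec$incidence_rel_sd * i0) / i0
        p$incidence[d, , ] <- pmin(base$incidence[d, , ] * mult, 1)
      }
    }

    # relative risks: log-normal around the point, linked entries only
    if (spec$rr_sdlog > 0) {
      for (f in FACTORS) {
        rr <- base$disease_rr[[f]]
        varies <- rr != 1
        rr[varies] <- rlnorm_pt(sum(varies), rr[varies], spec$rr_sdlog)
        p$disease_rr[[f]] <- rr
      }
    }

    # mortality rate ratios: factor categories and disease ratios
    if (spec$mr_sdlog > 0) {
      for (f in FACTORS) {
        mr <- base$mortality_ratios[[f]]
        varies <- mr != 1
        mr[varies] <- rlnorm_pt(sum(varies), mr[varies], spec$mr_sdlog)
        p$mortality_ratios[[f]] <- mr
      }
      p$diseases$mortality_ratio <-
        rlnorm_pt(N_DISEASES, base$diseases$mortality_ratio, spec$mr_sdlog)
    }

    # prevalences: beta per disease (renormalisation guard: keep sum < 1)
    if (spec$prevalence_rel_sd > 0) {
      prev <- vapply(base$diseases$prevalence, function(m) {
        rbeta_ms(1, m, spec$prevalence_rel_sd * m)
      }, numeric(1))
      if (sum(prev) >= 1) prev <- prev / sum(prev) * 0.99
      p$diseases$prevalence <- prev
    }

    # transition coefficients: normal around the point
    sds <- if (is.null(spec$coef_sd)) {
      if (is.null(base$coefficients$se)) 0 else base$coefficients$se
    } else {
      spec$coef_sd
    }
    if (any(sds > 0, na.rm = TRUE)) {
      vals <- base$coefficients$values
      sds <- rep_len(ifelse(is.na(sds), 0, sds), length(vals))
      p$coefficients <- transition_coefficients(
        base$coefficients$structure, stats::rnorm(length(vals), vals, sds),
        base$coefficients$se)
    }

    validate_model_parameters(p)
    p
  })
}

#' Run a probabilistic sensitivity analysis
#'
#' Repeats [compare_scenarios()] on `n_sims` parameter sets drawn from
#' `spec` and summarises each output quantity by its deterministic point
#' estimate and the 2.5th/97.5th percentiles over simulations. Draws whose
#' model evaluation fails are excluded and counted.
#'
#' @param base A [model_parameters()] object.
#' @param spec An [uncertainty_spec()].
#' @param effect_full The program's full [program_effect()].
#' @param n_sims Number of simulations (>= 2; 10000 for production-quality
#'   intervals).
#' @param seed Integer master seed; per-draw seeds are derived from it.
#' @param ... Passed to [compare_scenarios()] (program cost schedule, flat
#'   cost).
#' @return An object of class `"psa_summary"`: a data frame with columns
#'   `quantity`, `point`, `lower`, `upper`, plus attributes `n_sims`,
#'   `n_failed`, `seed`.
#' @export
run_psa <- function(base, spec, effect_full, n_sims = 10000, seed, ...) {
  stopifnot(n_sims >= 2)
  if (missing(seed)) stop("seed is mandatory")
  extract <- function(cmp) {
    c(incr_qalys_weight_only = cmp$contrasts$incr_qalys[1],
      incr_qalys_all_factors = cmp$contrasts$incr_qalys[2],
      incr_disease_years_weight_only = cmp$contrasts$incr_disease_years[1],
      incr_disease_years_all_factors = cmp$contrasts$incr_disease_years[2],
      icer_qaly_weight_only = cmp$contrasts$icer_qaly[1],
      icer_qaly_all_factors = cmp$contrasts$icer_qaly[2],
      icer_qaly_ratio = cmp$ratios$icer_qaly,
      icer_disease_years_weight_only = cmp$contrasts$icer_disease_years[1],
      icer_disease_years_all_factors = cmp$contrasts$icer_disease_years[2],
      icer_disease_years_ratio = cmp$ratios$icer_disease_years,
      roi_weight_only = cmp$contrasts$roi[1],
      roi_all_factors = cmp$contrasts$roi[2],
      roi_ratio = cmp$ratios$roi)
  }
  base_transitions <- precompute_transitions(base)
  point <- extract(compare_scenarios(base, effect_full, ...,
                                     transitions = base_transitions))
  # transition matrices depend only on the coefficients: reuse them when the
  # spec puts no uncertainty on the coefficients
  coef_sds <- if (is.null(spec$coef_sd)) base$coefficients$se else spec$coef_sd
  coef_fixed <- is.null(coef_sds) || all(coef_sds == 0, na.rm = TRUE)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_sims))
  draws <- matrix(NA_real_, n_sims, length(point),
                  dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (i in seq_len(n_sims)) {
    res <- tryCatch({
      pars <- draw_parameter_set(base, spec, sub_seeds[i])
      extract(compare_scenarios(
        pars, effect_full, ...,
        transitions = if (coef_fixed) base_transitions))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
    } else {
      draws[i, ] <- res
    }
  }
  if (n_failed > 0) {
    warning(n_failed, " of ", n_sims, " PSA draws failed and were excluded")
  }
  ok <- stats::complete.cases(draws)
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(quantity = names(point), point = unname(point),
                    lower = qs[1, ], upper = qs[2, ], row.names = NULL)
  flagged <- out$point < out$lower | out$point > out$upper
  if (any(flagged)) {
    attr(out, "point_outside_ci") <- out$quantity[flagged]
  }
  attr(out, "n_sims") <- n_sims
  attr(out, "n_failed") <- n_failed
  attr(out, "seed") <- seed
  class(out) <- c("psa_summary", class(out))
  out
}

#' @export
print.psa_summary <- function(x, ...) {
  cat("<psa_summary>", attr(x, "n_sims"), "simulations, seed",
      attr(x, "seed"), "\n")
  df <- as.data.frame(x)
  df[, -1] <- signif(df[, -1], 5)
  print(df, row.names = FALSE)
  invisible(x)
}
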