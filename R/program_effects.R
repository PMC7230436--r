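# Program effects: odds multipliers applied to the baseline joint
# risk-factor distribution, one factor at a time, with renormalisation
# inside every stratum of the remaining factors.

#' Joint risk-factor distribution
#'
#' A probability distribution over the 24 joint risk-factor profiles in
#' [risk_profiles()] order.
#'
#' @param p Numeric vector of 24 non-negative probabilities summing to 1
#'   (within 1e-12 after an internal renormalisation guard of 1e-8).
#' @return A named numeric vector of class `"joint_risk_distribution"`.
#' @export
#' @examples
#' joint_risk_distribution(rep(1 / 24, 24))
joint_risk_distribution <- function(p) {
  p <- as.numeric(p)
  if (length(p) != N_PROFILES) stop("distribution must have 24 entries")
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("distribution entries must be finite and non-negative")
  }
  if (abs(sum(p) - 1) > 1e-8) {
    stop("distribution must sum to 1 (got ", format(sum(p), digits = 10), ")")
  }
  p <- p / sum(p)
  names(p) <- risk_profiles()$label
  structure(p, class = "joint_risk_distribution")
}

#' @export
print.joint_risk_distribution <- function(x, ...) {
  cat("<joint_risk_distribution> over 24 weight x activity x fruit x",
      "vegetable profiles\n")
  print(round(unclass(x), 5), ...)
  invisible(x)
}

#' Program effect as odds multipliers per risk-factor category
#'
#' A program acting at the model starting age multiplies the odds of being in
#' each non-reference category of each risk factor. Reference categories
#' (normal weight; not meeting a behavioural recommendation) are fixed at 1.
#' An odds ratio of 0.7 for obesity means a 30% reduction in the odds of
#' being obese.
#'
#' @param overweight_or,obesity_or Odds multipliers for weight categories 1
#'   and 2.
#' @param activity_or,fruit_or,vegetable_or Odds multipliers for meeting the
#'   respective behavioural recommendation.
#' @return An object of class `"program_effect"`: a list of per-factor
#'   multiplier vectors (weight length 3, others length 2, first entry 1).
#' @export
#' @examples
#' program_effect(obesity_or = 0.7, activity_or = 1.1)
program_effect <- function(overweight_or = 1, obesity_or = 1, activity_or = 1,
                           fruit_or = 1, vegetable_or = 1) {
  ors <- c(overweight_or, obesity_or, activity_or, fruit_or, vegetable_or)
  if (any(!is.finite(ors)) || any(ors <= 0)) {
    stop("odds multipliers must be positive and finite")
  }
  structure(
    list(weight = c(1, overweight_or, obesity_or),
         activity = c(1, activity_or),
         fruit = c(1, fruit_or),
         vegetable = c(1, vegetable_or)),
    class = "program_effect"
  )
}

#' @export
print.program_effect <- function(x, ...) {
  cat("<program_effect> odds multipliers\n")
  cat(sprintf("  overweight %.3g, obesity %.3g, activity %.3g, fruit %.3g, vegetable %.3g\n",
              x$weight[2], x$weight[3], x$activity[2], x$fruit[2], x$vegetable[2]))
  invisible(x)
}

is_null_effect <- function(effect) {
  all(abs(unlist(effect) - 1) == 0)
}

#' Restrict a program effect to weight status only
#'
#' Returns the same effect with all behavioural odds multipliers reset to 1,
#' i.e. the "weight-status-only" reading of the program used in single-factor
#' evaluations.
#'
#' @param effect A [program_effect()].
#' @export
weight_only_effect <- function(effect) {
  program_effect(overweight_or = effect$weight[2], obesity_or = effect$weight[3])
}

#' Apply one factor's odds multipliers to a joint distribution
#'
#' Within every stratum defined by the other three factors, each cell's
#' probability is multiplied by the category's odds multiplier and the
#' stratum is renormalised so its total mass is unchanged. This multiplies
#' the conditional odds of each category (vs the reference) by exactly the
#' supplied multiplier while leaving the marginal distribution of the other
#' factors untouched. Strata with zero mass pass through unchanged.
#'
#' @param dist A [joint_risk_distribution()].
#' @param factor One of `"weight"`, `"activity"`, `"fruit"`, `"vegetable"`.
#' @param multipliers Positive multipliers, one per category of `factor`
#'   (length 3 for weight, 2 otherwise).
#' @return A [joint_risk_distribution()].
#' @export
apply_factor_effect <- function(dist, factor, multipliers) {
  factor <- match.arg(factor, FACTORS)
  dist <- joint_risk_distribution(dist)
  ncat <- if (factor == "weight") N_WEIGHT else N_BINARY
  if (length(multipliers) != ncat) {
    stop("need ", ncat, " multipliers for factor '", factor, "'")
  }
  if (any(!is.finite(multipliers)) || any(multipliers <= 0)) {
    stop("multipliers must be positive and finite")
  }
  prof <- risk_profiles()
  cat_idx <- prof[[factor]] + 1L
  others <- setdiff(FACTORS, factor)
  stratum <- interaction(prof[others], drop = FALSE)
  p <- unclass(dist)
  out <- p
  for (s in levels(stratum)) {
    sel <- stratum == s
    tot <- sum(p[sel])
    if (tot == 0) next  # zero-mass stratum: avoid 0/0, pass through
    w <- p[sel] * multipliers[cat_idx[sel]]
    out[sel] <- w / sum(w) * tot
  }
  joint_risk_distribution(out)
}

#' Apply a full program effect to a joint distribution
#'
#' Sequentially composes [apply_factor_effect()] over the four risk factors.
#' The composite is not guaranteed to be order-invariant, so the order is
#' fixed (weight, activity, fruit, vegetable by default) and configurable.
#'
#' @param dist A [joint_risk_distribution()].
#' @param effect A [program_effect()], or `NULL` for no effect.
#' @param order Character vector giving the composition order of the four
#'   factors.
#' @return A [joint_risk_distribution()].
#' @export
#' @examples
#' d0 <- joint_risk_distribution(rep(1 / 24, 24))
#' apply_program_effect(d0, program_effect(obesity_or = 0.7))
apply_program_effect <- function(dist, effect,
                                 order = c("weight", "activity", "fruit",
                                           "vegetable")) {
  dist <- joint_risk_distribution(dist)
  if (is.null(effect)) return(dist)
  if (!inherits(effect, "program_effect")) stop("effect must be a program_effect")
  if (!setequal(order, FACTORS) || length(order) != 4L) {
    stop("order must be a permutation of the four factors")
  }
  for (f in order) {
    dist <- apply_factor_effect(dist, f, effect[[f]])
  }
  dist
}
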