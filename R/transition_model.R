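# Joint multinomial-logit model of two-year transitions among the 24
# risk-factor combinations. The linear predictor of a joint outcome category
# decomposes into outcome-component main effects (dummies w1, w2, p1, f1,
# v1), covariate effects attached to those components (sex, age, current
# status), and association terms among the outcome components (products of
# dummies across factors). The all-reference category (normal weight, not
# meeting any recommendation) has linear predictor 0.

OUTCOME_DUMMIES <- c("w1", "w2", "p1", "f1", "v1")
TRANSITION_COVARIATES <- c("sex", "age", "cw1", "cw2", "cp", "cf", "cv")

# 24 x 5 outcome-component dummy matrix in risk_profiles() order
outcome_dummy_matrix <- function() {
  prof <- risk_profiles()
  cbind(w1 = as.numeric(prof$weight == 1), w2 = as.numeric(prof$weight == 2),
        p1 = prof$activity, f1 = prof$fruit, v1 = prof$vegetable)
}

# dummies grouped by the factor they belong to (weight has two)
dummy_factor <- c(w1 = "weight", w2 = "weight", p1 = "activity",
                  f1 = "fruit", v1 = "vegetable")

#' Describe the terms of a joint transition model
#'
#' The model structure lists which covariates modulate the outcome-component
#' main effects and which orders of association among the outcome components
#' are included. Associations of order k are products of one dummy from each
#' of k distinct factors (weight contributes either its overweight or its
#' obese dummy), capturing interdependence among the jointly modelled
#' outcomes.
#'
#' @param covariates Subset of `c("sex", "age", "cw1", "cw2", "cp", "cf",
#'   "cv")`: sex (0 = female, 1 = male), age (entered as (age - 40) / 10),
#'   and current-status dummies for weight overweight/obese, activity, fruit
#'   and vegetable.
#' @param associations Integer orders of outcome-component associations to
#'   include, from 2:4. Default `c(2, 3)` (two-way and three-way).
#' @return An object of class `"transition_structure"` with a `terms` data
#'   frame (`name`, `covariate`, and the dummy subset of each term).
#' @export
#' @examples
#' transition_structure()
transition_structure <- function(covariates = TRANSITION_COVARIATES,
                                 associations = c(2L, 3L)) {
  if (length(covariates) && !all(covariates %in% TRANSITION_COVARIATES)) {
    stop("unknown covariate(s): ",
         paste(setdiff(covariates, TRANSITION_COVARIATES), collapse = ", "))
  }
  if (length(associations) && !all(associations %in% 2:4)) {
    stop("association orders must be in 2:4")
  }
  terms <- list()
  add <- function(dummies, covariate) {
    terms[[length(terms) + 1L]] <<- list(
      name = if (covariate == "(1)") paste(dummies, collapse = ":")
             else paste(paste(dummies, collapse = ":"), covariate, sep = "|"),
      covariate = covariate, dummies = dummies)
  }
  for (d in OUTCOME_DUMMIES) add(d, "(1)")
  for (d in OUTCOME_DUMMIES) for (cv in covariates) add(d, cv)
  factors_list <- list(weight = c("w1", "w2"), activity = "p1",
                       fruit = "f1", vegetable = "v1")
  for (ord in sort(unique(as.integer(associations)))) {
    fsets <- utils::combn(names(factors_list), ord, simplify = FALSE)
    for (fs in fsets) {
      combos <- expand.grid(factors_list[fs], stringsAsFactors = FALSE)
      for (i in seq_len(nrow(combos))) add(unlist(combos[i, ]), "(1)")
    }
  }
  structure(list(
    covariates = covariates,
    associations = sort(unique(as.integer(associations))),
    terms = data.frame(
      name = vapply(terms, `[[`, "", "name"),
      covariate = vapply(terms, `[[`, "", "covariate"),
      stringsAsFactors = FALSE
    ),
    dummies = lapply(terms, `[[`, "dummies"),
    age_center = 40, age_scale = 10
  ), class = "transition_structure")
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("<transition_structure>", nrow(x$terms), "terms;",
      length(x$covariates), "covariates; association orders",
      paste(x$associations, collapse = ","), "\n")
  invisible(x)
}

# 24 x nterms matrix: outcome part of each term evaluated at each category
outcome_design <- function(structure) {
  D <- outcome_dummy_matrix()
  O <- vapply(structure$dummies, function(ds) {
    apply(D[, ds, drop = FALSE], 1, prod)
  }, numeric(N_PROFILES))
  colnames(O) <- structure$terms$name
  O
}

#' Coefficients of a joint transition model
#'
#' @param structure A [transition_structure()].
#' @param values Numeric coefficient per term (default all 0, the null model
#'   with uniform transition probabilities).
#' @param se Optional standard errors per term.
#' @return An object of class `"transition_coefficients"`.
#' @export
transition_coefficients <- function(structure = transition_structure(),
                                    values = 0, se = NULL) {
  nt <- nrow(structure$terms)
  values <- rep_len(as.numeric(values), nt)
  if (!is.null(se)) se <- rep_len(as.numeric(se), nt)
  if (any(!is.finite(values))) stop("coefficient values must be finite")
  structure(list(structure = structure, values = values, se = se,
                 O = outcome_design(structure)),
            class = "transition_coefficients")
}

#' @export
print.transition_coefficients <- function(x, ...) {
  cat("<transition_coefficients>", length(x$values), "terms\n")
  df <- data.frame(term = x$structure$terms$name, value = round(x$values, 4))
  if (!is.null(x$se)) df$se <- round(x$se, 4)
  print(utils::head(df, 12))
  if (nrow(df) > 12) cat("  ...", nrow(df) - 12, "more terms\n")
  invisible(x)
}

# covariate vector (named) for one record
covariate_vector <- function(structure, sex, age, current) {
  cats <- profile_categories(current)
  c("(1)" = 1, sex = as.numeric(sex),
    age = (age - structure$age_center) / structure$age_scale,
    cw1 = as.numeric(cats[["weight"]] == 1),
    cw2 = as.numeric(cats[["weight"]] == 2),
    cp = as.numeric(cats[["activity"]]), cf = as.numeric(cats[["fruit"]]),
    cv = as.numeric(cats[["vegetable"]]))
}

softmax <- function(eta) {
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Joint transition probabilities for one subject profile
#'
#' Evaluates the multinomial logit: the probability of each of the 24 joint
#' outcome categories two years later, given sex, age and current profile.
#'
#' @param coef A [transition_coefficients()].
#' @param sex 0 (female) or 1 (male).
#' @param age Age in years at the start of the transition.
#' @param current Current risk profile: 1-based index or a list/row with the
#'   four category codes.
#' @return Numeric 24-vector of probabilities (positive, summing to 1) in
#'   [risk_profiles()] order.
#' @export
transition_probabilities <- function(coef, sex, age, current) {
  stopifnot(inherits(coef, "transition_coefficients"))
  x <- covariate_vector(coef$structure, sex, age, current)
  u <- x[coef$structure$terms$covariate]
  eta <- as.vector(coef$O %*% (coef$values * u))
  p <- softmax(eta)
  names(p) <- risk_profiles()$label
  p
}

#' Two-year transition matrix over the 24 profiles
#'
#' @inheritParams transition_probabilities
#' @return 24 x 24 row-stochastic matrix; rows are current profiles, columns
#'   next profiles.
#' @export
transition_matrix <- function(coef, sex, age) {
  stopifnot(inherits(coef, "transition_coefficients"))
  str <- coef$structure
  prof <- risk_profiles()
  X <- cbind("(1)" = 1, sex = as.numeric(sex),
             age = (age - str$age_center) / str$age_scale,
             cw1 = as.numeric(prof$weight == 1),
             cw2 = as.numeric(prof$weight == 2),
             cp = prof$activity, cf = prof$fruit, cv = prof$vegetable)
  U <- X[, str$terms$covariate, drop = FALSE]
  Eta <- (U * matrix(coef$values, N_PROFILES, length(coef$values),
                     byrow = TRUE)) %*% t(coef$O)
  P <- exp(Eta - apply(Eta, 1, max))
  m <- P / rowSums(P)
  dimnames(m) <- list(risk_profiles()$label, risk_profiles()$label)
  m
}

#' Per-cycle transition matrix
#'
#' The transition model is estimated on a two-year panel. For a two-year
#' Markov cycle the model matrix is used directly; for a one-year cycle the
#' principal matrix square root is taken (via eigendecomposition) and
#' projected to the nearest valid stochastic matrix by clipping negative
#' entries to zero and renormalising rows. The projection deviation
#' (max |(M^(1/2))^2 - M|) is recorded in attribute `"root_deviation"`.
#'
#' @inheritParams transition_probabilities
#' @param cycle_years Cycle length, 1 or 2 years.
#' @return 24 x 24 row-stochastic matrix for one cycle.
#' @export
per_cycle_matrix <- function(coef, sex, age, cycle_years = 1) {
  if (!cycle_years %in% c(1, 2)) stop("cycle_years must be 1 or 2")
  M <- transition_matrix(coef, sex, age)
  if (cycle_years == 2) return(M)
  stochastic_root(M)
}

# principal square root of a stochastic matrix, projected back onto the
# set of row-stochastic matrices
stochastic_root <- function(M) {
  ev <- eigen(M)
  vals <- sqrt(as.complex(ev$values))
  S <- ev$vectors %*% diag(vals) %*% solve(ev$vectors)
  if (max(abs(Im(S))) > 1e-6) {
    warning("matrix square root has imaginary components up to ",
            format(max(abs(Im(S))), digits = 3), "; real part used")
  }
  S <- Re(S)
  S[S < 0] <- 0
  rs <- rowSums(S)
  if (any(rs == 0)) stop("stochastic projection failure: zero row")
  S <- S / rs
  attr(S, "root_deviation") <- max(abs(S %*% S - M))
  S
}

#' Simulate a two-year transition panel
#'
#' Draws subjects with random sex, baseline age and baseline profile, then
#' evolves each through `waves` two-year transitions by sampling from
#' [transition_probabilities()]. One row is emitted per observed transition.
#'
#' @param coef A [transition_coefficients()].
#' @param n Number of subjects.
#' @param waves Number of two-year transitions per subject.
#' @param seed Integer seed (mandatory; the panel is pure in the seed).
#' @param age_range Integer range baseline ages are drawn from uniformly.
#' @param initial Optional [joint_risk_distribution()] for baseline profiles
#'   (default uniform over the 24 profiles).
#' @return A data frame with columns `subject`, `sex`, `age`, `w0`, `p0`,
#'   `f0`, `v0`, `w1`, `p1`, `f1`, `v1`.
#' @export
simulate_panel <- function(coef, n, waves = 1L, seed, age_range = c(20L, 60L),
                           initial = NULL) {
  stopifnot(inherits(coef, "transition_coefficients"), n > 0, waves >= 1)
  if (missing(seed)) stop("seed is mandatory")
  p0 <- if (is.null(initial)) rep(1 / N_PROFILES, N_PROFILES) else
    as.numeric(joint_risk_distribution(initial))
  prof <- risk_profiles()
  with_seed(seed, {
    sex <- stats::rbinom(n, 1L, 0.5)
    age_pool <- seq(age_range[1], age_range[2])
    age0 <- age_pool[sample.int(length(age_pool), n, replace = TRUE)]
    cur <- sample.int(N_PROFILES, n, replace = TRUE, prob = p0)
    out <- vector("list", waves)
    for (w in seq_len(waves)) {
      age <- age0 + 2L * (w - 1L)
      nxt <- integer(n)
      # subjects sharing (sex, age, current) share a probability vector
      key <- interaction(sex, age, cur, drop = TRUE)
      for (k in levels(key)) {
        idx <- which(key == k)
        i <- idx[1]
        pr <- transition_probabilities(coef, sex[i], age[i], cur[i])
        nxt[idx] <- sample.int(N_PROFILES, length(idx), replace = TRUE,
                               prob = pr)
      }
      out[[w]] <- data.frame(
        subject = seq_len(n), sex = sex, age = age,
        w0 = prof$weight[cur], p0 = prof$activity[cur], f0 = prof$fruit[cur],
        v0 = prof$vegetable[cur],
        w1 = prof$weight[nxt], p1 = prof$activity[nxt], f1 = prof$fruit[nxt],
        v1 = prof$vegetable[nxt])
      cur <- nxt
      if (any(age + 2L > 100L)) {
        warning("panel ages exceed 100; transition model extrapolating")
      }
    }
    do.call(rbind, out)
  })
}

# aggregate panel records into unique covariate patterns with outcome counts
aggregate_panel <- function(structure, data) {
  needed <- c("sex", "age", "w0", "p0", "f0", "v0", "w1", "p1", "f1", "v1")
  if (!all(needed %in% names(data))) {
    stop("panel data must have columns: ", paste(needed, collapse = ", "))
  }
  cur <- profile_index(data$w0, data$p0, data$f0, data$v0)
  nxt <- profile_index(data$w1, data$p1, data$f1, data$v1)
  X <- cbind("(1)" = 1, sex = data$sex,
             age = (data$age - structure$age_center) / structure$age_scale,
             cw1 = as.numeric(data$w0 == 1), cw2 = as.numeric(data$w0 == 2),
             cp = data$p0, cf = data$f0, cv = data$v0)
  key <- apply(X, 1, paste, collapse = "\r")
  pat <- !duplicated(key)
  Xp <- X[pat, , drop = FALSE]
  pid <- match(key, key[pat])
  Y <- matrix(0, nrow(Xp), N_PROFILES)
  for (i in seq_along(pid)) Y[pid[i], nxt[i]] <- Y[pid[i], nxt[i]] + 1
  list(X = Xp, Y = Y, n = rowSums(Y))
}

# log-likelihood, gradient and (optionally) Hessian on aggregated data
joint_logit_objective <- function(beta, O, U, Y, n, ridge = 0,
                                  hessian = FALSE) {
  Eta <- (U * matrix(beta, nrow(U), length(beta), byrow = TRUE)) %*% t(O)
  m <- apply(Eta, 1, max)
  lse <- m + log(rowSums(exp(Eta - m)))
  ll <- sum(Y * Eta) - sum(n * lse) - ridge * sum(beta^2)
  P <- exp(Eta - lse)
  R <- Y - n * P
  grad <- colSums(U * (R %*% O)) - 2 * ridge * beta
  out <- list(ll = ll, grad = grad)
  if (hessian) {
    nt <- length(beta)
    H <- matrix(0, nt, nt)
    for (i in seq_len(nrow(U))) {
      p <- P[i, ]
      g <- crossprod(O, p)
      M <- crossprod(O, O * p) - tcrossprod(g)
      H <- H - n[i] * (M * tcrossprod(U[i, ]))
    }
    out$hessian <- H - diag(2 * ridge, nt)
  }
  out
}

#' Fit the joint transition model by maximum likelihood
#'
#' Maximises the exact multinomial log-likelihood of the specified term
#' structure on two-year panel records, by BFGS with analytic gradient
#' followed by Newton refinement with the analytic Hessian. Standard errors
#' come from the inverse observed information. An optional L2 ridge guards
#' against separation.
#'
#' @param data Panel records as produced by [simulate_panel()] (columns
#'   `sex`, `age`, `w0`, `p0`, `f0`, `v0`, `w1`, `p1`, `f1`, `v1`).
#' @param structure A [transition_structure()].
#' @param ridge Non-negative L2 penalty (default 0).
#' @param max_iter Newton refinement cap.
#' @return A [transition_coefficients()] with `se`, plus attributes/fields
#'   `loglik`, `loglik_null`, `gradient_norm`, `converged`, `n_records`.
#' @export
fit_joint_logit <- function(data, structure = transition_structure(),
                            ridge = 0, max_iter = 50L) {
  agg <- aggregate_panel(structure, data)
  O <- outcome_design(structure)
  covmap <- structure$terms$covariate
  U <- agg$X[, covmap, drop = FALSE]
  Y <- agg$Y; n <- agg$n
  nt <- nrow(structure$terms)

  if (ridge == 0 && any(colSums(Y) == 0)) {
    warning("some outcome categories unobserved; consider ridge > 0")
  }

  fn <- function(b) -joint_logit_objective(b, O, U, Y, n, ridge)$ll
  gr <- function(b) -joint_logit_objective(b, O, U, Y, n, ridge)$grad
  opt <- stats::optim(rep(0, nt), fn, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  beta <- opt$par

  # Newton polish to drive the gradient norm down
  obj <- joint_logit_objective(beta, O, U, Y, n, ridge, hessian = TRUE)
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(obj$grad^2)) < 1e-8 * max(1, sum(n))) break
    step <- tryCatch(solve(obj$hessian, obj$grad),
                     error = function(e) NULL)
    if (is.null(step)) break
    cand <- beta - step
    obj_c <- joint_logit_objective(cand, O, U, Y, n, ridge, hessian = TRUE)
    halvings <- 0
    while (obj_c$ll < obj$ll && halvings < 30) {
      cand <- (beta + cand) / 2
      obj_c <- joint_logit_objective(cand, O, U, Y, n, ridge, hessian = TRUE)
      halvings <- halvings + 1
    }
    if (obj_c$ll < obj$ll) break
    beta <- cand; obj <- obj_c
  }

  grad_norm <- sqrt(sum(obj$grad^2)) / max(1, sum(n))
  converged <- grad_norm < 1e-6
  if (!converged) {
    warning("fit_joint_logit: per-record gradient norm ",
            format(grad_norm, digits = 3),
            " above 1e-6 (possible separation; try ridge > 0)")
  }
  vcov <- tryCatch(solve(-obj$hessian), error = function(e) {
    warning("information matrix singular; SEs unavailable"); NULL
  })
  se <- if (is.null(vcov)) rep(NA_real_, nt) else sqrt(pmax(diag(vcov), 0))

  res <- transition_coefficients(structure, beta, se)
  res$loglik <- joint_logit_objective(beta, O, U, Y, n, 0)$ll
  res$loglik_null <- joint_logit_objective(rep(0, nt), O, U, Y, n, 0)$ll
  res$gradient_norm <- grad_norm
  res$converged <- converged
  res$n_records <- sum(n)
  res
}
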