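# Parameter-directory readers/writers and result serialisation. All files
# are plain text (CSV/JSON); a write/load round trip preserves unrounded
# values to full double precision.

#' Run configuration
#'
#' @param params_dir,out_dir Input and output directories.
#' @param horizon,cycle_length,discount_rate,sex_mix Model settings (see
#'   [model_parameters()]).
#' @param seed Master seed for stochastic components.
#' @param verbose Logical.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(params_dir = NULL, out_dir = NULL, horizon = 84,
                       cycle_length = 1, discount_rate = 0.015,
                       sex_mix = 0.5, seed = 1L, verbose = FALSE) {
  if (discount_rate < 0) stop("discount rate must be non-negative")
  if (horizon %% cycle_length != 0) {
    stop("horizon must be a multiple of cycle_length")
  }
  structure(list(params_dir = params_dir, out_dir = out_dir,
                 horizon = horizon, cycle_length = cycle_length,
                 discount_rate = discount_rate, sex_mix = sex_mix,
                 seed = as.integer(seed), verbose = verbose),
            class = "run_config")
}

write_csv_full <- function(df, path) {
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
}

#' Write a model parameter set to a directory
#'
#' Serialises a [model_parameters()] object as the documented set of CSV and
#' JSON files (`initial_distribution.csv`, `life_table.csv`, `diseases.csv`,
#' `disease_rr.csv`, `mortality_ratios.csv`, `population.csv`,
#' `incidence.csv`, `linkage.csv`, `coefficients.json`, `settings.json`).
#'
#' @param params A [model_parameters()] object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_parameters <- function(params, dir) {
  validate_model_parameters(params)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prof <- risk_profiles()
  write_csv_full(data.frame(label = prof$label,
                            probability = as.numeric(params$initial_distribution)),
                 file.path(dir, "initial_distribution.csv"))
  write_csv_full(params$life_table, file.path(dir, "life_table.csv"))
  write_csv_full(params$diseases, file.path(dir, "diseases.csv"))

  rr_long <- do.call(rbind, lapply(FACTORS, function(f) {
    m <- params$disease_rr[[f]]
    data.frame(disease = rep(params$diseases$disease, ncol(m)),
               factor = f, category = rep(seq_len(ncol(m)) - 1L,
                                          each = N_DISEASES),
               rr = as.vector(m))
  }))
  write_csv_full(rr_long, file.path(dir, "disease_rr.csv"))

  mr_long <- do.call(rbind, lapply(FACTORS, function(f) {
    data.frame(factor = f,
               category = seq_along(params$mortality_ratios[[f]]) - 1L,
               ratio = params$mortality_ratios[[f]])
  }))
  write_csv_full(mr_long, file.path(dir, "mortality_ratios.csv"))

  pop_long <- do.call(rbind, lapply(FACTORS, function(f) {
    data.frame(factor = f, category = seq_along(params$population[[f]]) - 1L,
               proportion = params$population[[f]])
  }))
  write_csv_full(pop_long, file.path(dir, "population.csv"))

  inc <- params$incidence
  ages <- dimnames(inc)[[2]]
  inc_long <- data.frame(
    disease_id = rep(seq_len(N_DISEASES), times = length(ages) * 2L),
    age = rep(rep(as.integer(ages), each = N_DISEASES), times = 2L),
    sex = rep(0:1, each = N_DISEASES * length(ages)),
    incidence = as.vector(inc))
  write_csv_full(inc_long, file.path(dir, "incidence.csv"))

  lk <- params$linkage
  utils::write.csv(data.frame(disease = rownames(lk), unclass(lk)[, FACTORS]),
                   file.path(dir, "linkage.csv"), row.names = FALSE)

  cf <- params$coefficients
  jsonlite::write_json(list(
    covariates = cf$structure$covariates,
    associations = cf$structure$associations,
    terms = data.frame(name = cf$structure$terms$name,
                       covariate = cf$structure$terms$covariate,
                       value = cf$values,
                       se = if (is.null(cf$se)) NA_real_ else cf$se)
  ), file.path(dir, "coefficients.json"), digits = NA, auto_unbox = TRUE)

  jsonlite::write_json(list(
    discount_rate = params$discount_rate, horizon = params$horizon,
    cycle_length = params$cycle_length, start_age = params$start_age,
    sex_mix = params$sex_mix,
    weight_decrements = params$weight_decrements
  ), file.path(dir, "settings.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

read_num_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df
}

#' Load a model parameter set from a directory
#'
#' Reads the files written by [write_parameters()] and revalidates every
#' invariant; violations are reported with the offending file.
#'
#' @param dir Directory containing the parameter files.
#' @return A validated [model_parameters()] object.
#' @export
load_parameters <- function(dir) {
  need <- c("initial_distribution.csv", "life_table.csv", "diseases.csv",
            "disease_rr.csv", "mortality_ratios.csv", "population.csv",
            "incidence.csv", "linkage.csv", "coefficients.json",
            "settings.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("parameter directory is missing: ", paste(missing, collapse = ", "))
  }
  wrap <- function(file, expr) {
    tryCatch(expr, error = function(e) {
      stop(file, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  init_df <- read_num_csv(file.path(dir, "initial_distribution.csv"))
  init <- wrap("initial_distribution.csv", {
    stopifnot(identical(init_df$label, risk_profiles()$label))
    joint_risk_distribution(init_df$probability)
  })
  life_table <- read_num_csv(file.path(dir, "life_table.csv"))
  diseases <- read_num_csv(file.path(dir, "diseases.csv"))
  linkage <- wrap("linkage.csv", load_linkage(file.path(dir, "linkage.csv")))

  rr_long <- read_num_csv(file.path(dir, "disease_rr.csv"))
  disease_rr <- wrap("disease_rr.csv", {
    lapply(stats::setNames(nm = FACTORS), function(f) {
      sub <- rr_long[rr_long$factor == f, ]
      ncat <- max(sub$category) + 1L
      m <- matrix(NA_real_, N_DISEASES, ncat)
      for (k in seq_len(ncat)) {
        sk <- sub[sub$category == k - 1L, ]
        m[match(sk$disease, diseases$disease), k] <- sk$rr
      }
      stopifnot(!anyNA(m))
      m
    })
  })

  mr_long <- read_num_csv(file.path(dir, "mortality_ratios.csv"))
  mortality_ratios <- lapply(stats::setNames(nm = FACTORS), function(f) {
    sub <- mr_long[mr_long$factor == f, ]
    sub$ratio[order(sub$category)]
  })
  pop_long <- read_num_csv(file.path(dir, "population.csv"))
  population <- lapply(stats::setNames(nm = FACTORS), function(f) {
    sub <- pop_long[pop_long$factor == f, ]
    sub$proportion[order(sub$category)]
  })

  inc_long <- read_num_csv(file.path(dir, "incidence.csv"))
  ages <- sort(unique(inc_long$age))
  incidence <- wrap("incidence.csv", {
    a <- array(NA_real_, dim = c(N_DISEASES, length(ages), 2L),
               dimnames = list(diseases$disease, as.character(ages),
                               c("female", "male")))
    idx <- cbind(inc_long$disease_id, match(inc_long$age, ages),
                 inc_long$sex + 1L)
    a[idx] <- inc_long$incidence
    stopifnot(!anyNA(a))
    a
  })

  cf_json <- jsonlite::read_json(file.path(dir, "coefficients.json"),
                                 simplifyVector = TRUE)
  coefficients <- wrap("coefficients.json", {
    str <- transition_structure(covariates = cf_json$covariates,
                                associations = cf_json$associations)
    stopifnot(identical(str$terms$name, cf_json$terms$name))
    se <- cf_json$terms$se
    if (all(is.na(se))) se <- NULL
    transition_coefficients(str, cf_json$terms$value, se)
  })

  st <- jsonlite::read_json(file.path(dir, "settings.json"),
                            simplifyVector = TRUE)
  model_parameters(
    initial_distribution = init, coefficients = coefficients,
    life_table = life_table, diseases = diseases, disease_rr = disease_rr,
    mortality_ratios = mortality_ratios, population = population,
    incidence = incidence, weight_decrements = st$weight_decrements,
    linkage = linkage, discount_rate = st$discount_rate,
    horizon = st$horizon, cycle_length = st$cycle_length,
    start_age = st$start_age, sex_mix = st$sex_mix
  )
}

#' Write scenario-comparison results
#'
#' Emits a display CSV shaped like the published comparison tables (program
#' effect columns, cost, incremental effects, ICERs, ROIs and ratios, with
#' conventional rounding) plus `results.json` holding the unrounded values
#' and run metadata.
#'
#' @param results A [compare_scenarios()] result or a list of them.
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded in the metadata.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir, seed = NA_integer_) {
  if (inherits(results, "scenario_comparison")) results <- list(results)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(results, function(cmp) {
    e <- cmp$effect
    data.frame(
      alpha1 = e$weight[2], alpha2 = e$weight[3], psi1 = e$activity[2],
      lambda1 = e$fruit[2], tau1 = e$vegetable[2],
      cost = round(cmp$program_cost, 2),
      incr_qalys_1 = round(cmp$contrasts$incr_qalys[1], 4),
      icer_qaly_1 = round(cmp$contrasts$icer_qaly[1]),
      incr_qalys_2 = round(cmp$contrasts$incr_qalys[2], 4),
      icer_qaly_2 = round(cmp$contrasts$icer_qaly[2]),
      icer_qaly_ratio = round(cmp$ratios$icer_qaly, 3),
      incr_dy_1 = round(cmp$contrasts$incr_disease_years[1], 5),
      icer_dy_1 = round(cmp$contrasts$icer_disease_years[1]),
      incr_dy_2 = round(cmp$contrasts$incr_disease_years[2], 5),
      icer_dy_2 = round(cmp$contrasts$icer_disease_years[2]),
      icer_dy_ratio = round(cmp$ratios$icer_disease_years, 3),
      savings_1 = round(cmp$contrasts$savings[1], 3),
      roi_1 = round(cmp$contrasts$roi[1]),
      savings_2 = round(cmp$contrasts$savings[2], 3),
      roi_2 = round(cmp$contrasts$roi[2]),
      roi_ratio = round(cmp$ratios$roi, 3))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "comparison.csv"),
                   row.names = FALSE)
  raw <- lapply(results, function(cmp) {
    list(effect = unclass(cmp$effect), program_cost = cmp$program_cost,
         contrasts = cmp$contrasts, ratios = cmp$ratios)
  })
  jsonlite::write_json(
    list(results = raw,
         metadata = list(seed = seed, package_version =
                           as.character(utils::packageVersion("healmod")),
                         timestamp = format(Sys.time(), tz = "UTC"))),
    file.path(dir, "results.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
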