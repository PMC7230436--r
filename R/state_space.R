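# State space: 24 joint risk-factor combinations x 33 disease statuses + death.

FACTORS <- c("weight", "activity", "fruit", "vegetable")
N_WEIGHT <- 3L
N_BINARY <- 2L
N_PROFILES <- 24L
N_DISEASES <- 32L
N_DISEASE_STATUS <- 33L
N_STATES <- 793L

#' Enumerate the 24 joint risk-factor profiles
#'
#' A profile combines weight status (0 = normal, 1 = overweight, 2 = obese),
#' physical activity (0 = not meeting, 1 = meeting recommendations), fruit
#' consumption (0/1) and vegetable consumption (0/1). Profiles are enumerated
#' lexicographically with weight varying slowest and vegetable fastest, so
#' profile 1 is (0,0,0,0) and profile 24 is (2,1,1,1).
#'
#' @return A data frame with 24 rows and integer columns `weight`, `activity`,
#'   `fruit`, `vegetable`, plus a `label` column such as `"w0p1f0v1"`.
#' @export
#' @examples
#' risk_profiles()
risk_profiles <- function() {
  grid <- expand.grid(
    vegetable = 0:1, fruit = 0:1, activity = 0:1, weight = 0:2,
    KEEP.OUT.ATTRS = FALSE
  )[, c("weight", "activity", "fruit", "vegetable")]
  grid <- grid[order(grid$weight, grid$activity, grid$fruit, grid$vegetable), ]
  rownames(grid) <- NULL
  grid$label <- sprintf("w%dp%df%dv%d", grid$weight, grid$activity,
                        grid$fruit, grid$vegetable)
  grid
}

#' Index of a risk profile in the canonical enumeration
#'
#' @param weight,activity,fruit,vegetable Integer category codes (vectorised).
#' @return 1-based index into [risk_profiles()].
#' @export
#' @examples
#' profile_index(0, 0, 0, 0) # 1
#' profile_index(2, 1, 1, 1) # 24
profile_index <- function(weight, activity, fruit, vegetable) {
  stopifnot(all(weight %in% 0:2), all(activity %in% 0:1),
            all(fruit %in% 0:1), all(vegetable %in% 0:1))
  as.integer(((weight * 2L + activity) * 2L + fruit) * 2L + vegetable + 1L)
}

#' Build the full Markov state space
#'
#' States are ordered disease-major: for disease status d = 0 (no chronic
#' disease) through 32, the 24 risk profiles in [risk_profiles()] order, then
#' the absorbing death state last. This yields 24 x 33 + 1 = 793 states.
#'
#' @param disease_names Optional character vector of 32 disease names used for
#'   labels; defaults to the packaged linkage table's names.
#' @return A data frame with 793 rows: `state` (1-based index), `disease`
#'   (0..32, `NA` for death), `weight`, `activity`, `fruit`, `vegetable`
#'   (`NA` for death), `dead` (logical) and `label`.
#' @export
#' @examples
#' ss <- build_state_space()
#' nrow(ss) # 793
build_state_space <- function(disease_names = NULL) {
  prof <- risk_profiles()
  alive <- do.call(rbind, lapply(0:N_DISEASES, function(d) {
    data.frame(
      disease = d,
      weight = prof$weight, activity = prof$activity,
      fruit = prof$fruit, vegetable = prof$vegetable,
      dead = FALSE,
      label = paste0("d", d, "_", prof$label)
    )
  }))
  ss <- rbind(alive, data.frame(disease = NA_integer_, weight = NA_integer_,
                                activity = NA_integer_, fruit = NA_integer_,
                                vegetable = NA_integer_, dead = TRUE,
                                label = "dead"))
  ss <- cbind(state = seq_len(nrow(ss)), ss)
  rownames(ss) <- NULL
  stopifnot(nrow(ss) == N_STATES)
  ss
}

#' Index of a Markov state
#'
#' Inverse of the enumeration in [build_state_space()].
#'
#' @param disease Disease status 0..32 (vectorised).
#' @param profile 1-based risk-profile index 1..24 (vectorised).
#' @return 1-based state index in 1..792.
#' @export
state_index <- function(disease, profile) {
  stopifnot(all(disease %in% 0:N_DISEASES), all(profile %in% seq_len(N_PROFILES)))
  as.integer(disease * N_PROFILES + profile)
}

#' @rdname state_index
#' @export
dead_state_index <- function() N_STATES

#' Load the disease / risk-factor linkage table
#'
#' The linkage records, for each of the 32 chronic diseases, which of the four
#' risk factors has a statistically significant relative risk on its
#' incidence. Unlinked factors contribute a relative risk of 1 everywhere.
#'
#' @param table Path to a CSV with columns
#'   `disease,weight,activity,fruit,vegetable` (0/1 indicators), or a data
#'   frame of that shape. Defaults to the packaged table.
#' @return A 32 x 4 integer matrix of 0/1 indicators with disease names as row
#'   names, class `"linkage_matrix"`.
#' @export
#' @examples
#' lk <- load_linkage()
#' linked_factors(lk, "Diabetes")
load_linkage <- function(table = NULL) {
  if (is.null(table)) {
    table <- system.file("extdata", "disease_linkage.csv", package = "healmod",
                         mustWork = TRUE)
  }
  df <- if (is.character(table)) {
    utils::read.csv(table, stringsAsFactors = FALSE)
  } else {
    as.data.frame(table)
  }
  needed <- c("disease", FACTORS)
  if (!all(needed %in% names(df))) {
    stop("linkage table must have columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(df) != N_DISEASES) {
    stop("linkage table must have exactly ", N_DISEASES, " disease rows, got ",
         nrow(df))
  }
  m <- as.matrix(df[, FACTORS])
  if (!all(m %in% c(0L, 1L))) stop("linkage indicators must be 0/1")
  storage.mode(m) <- "integer"
  rownames(m) <- trimws(df$disease)
  class(m) <- c("linkage_matrix", class(m))
  m
}

canonical_disease <- function(x) tolower(trimws(x))

#' @rdname load_linkage
#' @param linkage A `linkage_matrix`.
#' @param disease A disease name (matched case-insensitively, trimmed).
#' @export
linked_factors <- function(linkage, disease) {
  i <- match(canonical_disease(disease), canonical_disease(rownames(linkage)))
  if (is.na(i)) stop("unknown disease: ", disease)
  FACTORS[linkage[i, ] == 1L]
}

#' @rdname load_linkage
#' @export
disease_names <- function(linkage = load_linkage()) rownames(linkage)
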