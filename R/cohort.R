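# Cohort design: sample metadata, per-group effects, age coupling, and the
# per-sample modifiers the read simulator consumes.

#' Build a sample metadata table
#'
#' Convenience constructor for a balanced cohort: for every region x condition
#' cell, `n_per_cell` donors with ages drawn uniformly from `age_range` and
#' alternating sex.
#'
#' @param n_per_cell Donors per region x condition cell.
#' @param regions Character vector of brain-region labels.
#' @param conditions Character vector of condition labels.
#' @param age_range Numeric length-2 range of donor ages (years).
#' @param seed Integer seed for the age draw.
#' @return Tibble with columns sample_id, region, condition, age, sex.
#' @export
cohort_samples <- function(n_per_cell = 4L,
                           regions = c("SN", "MTG", "AMG"),
                           conditions = c("CT", "PD"),
                           age_range = c(60, 95),
                           seed = 1L) {
  set.seed(assert_scalar_int(seed, "seed"))
  grid <- expand.grid(idx = seq_len(n_per_cell), condition = conditions,
                      region = regions, stringsAsFactors = FALSE)
  n <- nrow(grid)
  tibble(
    sample_id = paste0(grid$region, "_", grid$condition, "_", grid$idx),
    region = grid$region,
    condition = grid$condition,
    age = round(runif(n, age_range[1], age_range[2]), 1),
    sex = rep_len(c("F", "M"), n)
  )
}

#' Cohort design: group effects, age coupling and editing coupling
#'
#' Couples the sample metadata to the generative effects the simulator
#' applies: multiplicative per-condition effects on the back-splice fraction
#' and on the editing mean, a linear age trend on expected circRNA output in
#' one designated region, and an optional per-sample latent factor that
#' couples circRNA output inversely to editing (the anti-correlation
#' structure reported for brain cohorts).
#'
#' @param samples Sample metadata tibble (see [cohort_samples()]).
#' @param circ_effects Named positive multipliers on circ_fraction per
#'   condition (names must cover the conditions present).
#' @param editing_effects Named positive multipliers on the editing mean per
#'   condition.
#' @param age_slope Per-year relative slope of expected circRNA output in
#'   `age_slope_region` (0 disables).
#' @param age_slope_region Region the age trend applies to.
#' @param couple_editing If `TRUE`, draw a per-sample factor `u` uniform on
#'   `couple_range`; circRNA output is scaled by `u` and editing by `1/u`.
#' @param couple_range Range of the latent coupling factor.
#' @param seed Integer seed; all cohort randomness derives from it.
#' @return A list of class `cohort_design`: `samples`, `modifiers` (tibble
#'   sample_id, circ_mult, edit_mult), plus the parameters.
#' @examples
#' d <- cohort_design(cohort_samples(2, seed = 1), seed = 1)
#' d$modifiers
#' @export
cohort_design <- function(samples = cohort_samples(),
                          circ_effects = c(CT = 1, PD = 1),
                          editing_effects = c(CT = 1, PD = 1),
                          age_slope = 0,
                          age_slope_region = "SN",
                          couple_editing = FALSE,
                          couple_range = c(0.5, 1.5),
                          seed = 1L) {
  if (nrow(samples) == 0) abort("`samples` must have at least one row.")
  if (anyDuplicated(samples$sample_id)) abort("sample ids must be unique.")
  missing_c <- setdiff(unique(samples$condition), names(circ_effects))
  if (length(missing_c)) {
    abort(paste0("`circ_effects` missing conditions: ",
                 paste(missing_c, collapse = ", ")))
  }
  missing_e <- setdiff(unique(samples$condition), names(editing_effects))
  if (length(missing_e)) {
    abort(paste0("`editing_effects` missing conditions: ",
                 paste(missing_e, collapse = ", ")))
  }
  if (any(circ_effects <= 0) || any(editing_effects <= 0)) {
    abort("effect multipliers must be positive.")
  }
  seed <- assert_scalar_int(seed, "seed")
  set.seed(seed)
  n <- nrow(samples)
  u <- if (couple_editing) runif(n, couple_range[1], couple_range[2]) else rep(1, n)
  age_ref <- mean(samples$age)
  age_term <- ifelse(samples$region == age_slope_region,
                     pmax(0.05, 1 + age_slope * (samples$age - age_ref)), 1)
  modifiers <- tibble(
    sample_id = samples$sample_id,
    circ_mult = unname(circ_effects[samples$condition]) * age_term * u,
    edit_mult = unname(editing_effects[samples$condition]) / u
  )
  structure(list(samples = as_tibble(samples), modifiers = modifiers,
                 age_slope = age_slope, age_slope_region = age_slope_region,
                 age_ref = age_ref, couple_editing = couple_editing,
                 seed = seed),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "<cohort_design> %d samples (%s x %s), age slope %.3g in %s, editing coupling %s\n",
    nrow(x$samples),
    paste(unique(x$samples$region), collapse = "/"),
    paste(unique(x$samples$condition), collapse = "/"),
    x$age_slope, x$age_slope_region,
    if (x$couple_editing) "on" else "off"))
  invisible(x)
}
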