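# Synthetic purchaser-decedent cohorts with known true exposure-outcome
# odds ratios and a known differential control-selection mechanism. The
# generator emulates the structure of the restricted linkage data: a case
# group of firearm suicide decedents, a pre-selection pool of eligible
# motor-vehicle-crash controls, person-level covariates, and visit-level
# ICD-9-CM code lists over the lookback window.

#' Specify one synthetic exposure
#'
#' @param name exposure label; must name a category or component of the
#'   code map used at generation time.
#' @param baseline_prevalence_controls exposure prevalence in the
#'   pre-selection control pool (also the living source population the pool
#'   represents), in (0, 1).
#' @param true_or true exposure-case odds ratio; case prevalence is derived
#'   via the logistic identity `p_case = OR p / (1 - p + OR p)`.
#' @param selection_rr relative probability that an exposed eligible
#'   control is retained versus an unexposed one; 1 means no differential
#'   selection. This is the exact selection odds ratio the mechanism
#'   induces, so the true OR_select equals `selection_rr`.
#' @param benchmark_rate exposure rate in the living benchmark population;
#'   defaults to `baseline_prevalence_controls` (the pool is representative
#'   of the living source by construction).
#' @return list of class `exposure_spec`.
#' @export
exposure_spec <- function(name, baseline_prevalence_controls, true_or,
                          selection_rr = 1,
                          benchmark_rate = baseline_prevalence_controls) {
  if (baseline_prevalence_controls <= 0 || baseline_prevalence_controls >= 1) {
    stop("baseline_prevalence_controls must lie in (0, 1)")
  }
  if (true_or <= 0) stop("true_or must be positive")
  if (selection_rr <= 0) stop("selection_rr must be positive")
  if (benchmark_rate <= 0 || benchmark_rate >= 1) {
    stop("benchmark_rate must lie in (0, 1)")
  }
  structure(list(
    name = name,
    baseline_prevalence_controls = baseline_prevalence_controls,
    true_or = true_or,
    selection_rr = selection_rr,
    benchmark_rate = benchmark_rate
  ), class = "exposure_spec")
}

#' Default synthetic exposure set
#'
#' Six category-level exposures whose post-selection control prevalences
#' and observable (selection-biased) odds ratios are of the order seen in
#' real purchaser-decedent data; selection ratios are chosen so that
#' substance-related exposures are most over-represented among crash
#' controls. True ORs equal the observable crude OR times the selection
#' ratio.
#'
#' @return list of `exposure_spec`.
#' @export
default_exposure_specs <- function() {
  list(
    exposure_spec("suicidal ideation/attempt", 0.010, 7.9, 1.71),
    exposure_spec("mental illness", 0.063, 2.7, 1.30),
    exposure_spec("substance use", 0.047, 2.5, 2.00),
    exposure_spec("pain", 0.055, 1.9, 1.30),
    exposure_spec("chronic disease", 0.157, 1.8, 1.50),
    exposure_spec("assault", 0.013, 0.72, 1.60)
  )
}

#' Default covariate marginals
#'
#' Categorical covariate distributions typical of handgun-purchaser
#' decedents (male-dominated, mostly married, mostly metro). Probabilities
#' sum to 1 per covariate.
#'
#' @return named list of category-probability vectors for `sex`,
#'   `marital_status`, `education`, `urbanicity`.
#' @export
default_covariate_marginals <- function() {
  list(
    sex = c("male" = 0.916, "female" = 0.084),
    marital_status = c("married/partner" = 0.496, "divorced" = 0.198,
                       "never married" = 0.247, "widowed" = 0.053,
                       "unknown" = 0.006),
    education = c("high school or less" = 0.489, "some college" = 0.258,
                  "associates" = 0.080, "bachelor" = 0.100,
                  "graduate" = 0.058, "unknown" = 0.015),
    urbanicity = c("large metro" = 0.619, "small metro" = 0.302,
                   "non-metro" = 0.079)
  )
}

#' Build and validate a simulation configuration
#'
#' @param n_cases number of firearm-suicide cases (default 3862, the real
#'   cohort scale).
#' @param n_controls_target expected number of retained crash controls
#'   after selection (default 1553).
#' @param exposure_specs list of [exposure_spec()] objects.
#' @param covariate_marginals per-covariate category-probability maps; each
#'   must sum to 1 within 1e-9.
#' @param lookback_years exposure lookback window in calendar years
#'   (default 3).
#' @param pool_multiplier size of the pre-selection control pool relative
#'   to `n_controls_target` (default 2).
#' @param noise_visit_rate probability that a person receives a visit
#'   carrying only non-mapped codes, dated up to twice the lookback before
#'   death so the window filter is exercised (default 0.3).
#' @param missing_covariate_rate probability that sex (and independently
#'   urbanicity) is recorded as missing (default 0.0045 each, about 0.9%
#'   of persons affected overall).
#' @param age_case,age_control `c(mean, sd)` of the per-group age
#'   distributions, truncated to [20, 100] years.
#' @param death_date_range inclusive calendar range of death dates.
#' @param confounding if TRUE, exposure odds are doubled for persons over
#'   60; because cases are older on average this induces genuine
#'   confounding by age while leaving the age-conditional OR at `true_or`.
#' @param seed integer seed; all generation randomness flows from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_cases = 3862, n_controls_target = 1553,
                              exposure_specs = default_exposure_specs(),
                              covariate_marginals = default_covariate_marginals(),
                              lookback_years = 3,
                              pool_multiplier = 2,
                              noise_visit_rate = 0.3,
                              missing_covariate_rate = 0.0045,
                              age_case = c(56.0, 16.7),
                              age_control = c(50.8, 15.8),
                              death_date_range = c("2008-01-01", "2013-12-31"),
                              confounding = FALSE,
                              seed = 1) {
  if (n_cases < 1 || n_controls_target < 1) {
    stop("n_cases and n_controls_target must be at least 1")
  }
  if (lookback_years <= 0) stop("lookback_years must be positive")
  if (!length(exposure_specs)) stop("at least one exposure_spec is required")
  exposure_specs <- lapply(exposure_specs, function(s) {
    if (!inherits(s, "exposure_spec")) do.call(exposure_spec, s) else s
  })
  nm <- vapply(exposure_specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate exposure names in exposure_specs")
  for (v in names(covariate_marginals)) {
    p <- covariate_marginals[[v]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("covariate marginals for '", v, "' must be non-negative and sum to 1")
    }
  }
  structure(list(
    n_cases = as.integer(n_cases),
    n_controls_target = as.integer(n_controls_target),
    exposure_specs = exposure_specs,
    covariate_marginals = covariate_marginals,
    lookback_years = lookback_years,
    pool_multiplier = pool_multiplier,
    noise_visit_rate = noise_visit_rate,
    missing_covariate_rate = missing_covariate_rate,
    age_case = age_case, age_control = age_control,
    death_date_range = as.Date(death_date_range),
    confounding = isTRUE(confounding),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# truncated-normal ages via inverse CDF
rtruncnorm_age <- function(n, mean, sd, lo = 20, hi = 100) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

.case_cause_codes <- c("X72", "X73", "X74")
.control_cause_codes <- c("V03.1", "V23.4", "V43.5", "V47.5", "V49.4", "V80.4")
.noise_codes <- c("486", "599.0", "780.6")

# prefixes usable as generated codes for one exposure label (category or
# component of the code map)
label_prefixes <- function(code_map, label) {
  hit <- code_map$component == label | code_map$category == label
  if (!any(hit)) {
    stop("exposure name '", label, "' is not a category or component of the code map")
  }
  code_map$prefix[hit]
}

#' Generate a synthetic cohort with known truth
#'
#' Generates `n_cases` firearm-suicide cases and a pre-selection pool of
#' `n_controls_target * pool_multiplier` eligible crash controls. Exposure
#' indicators are drawn independently across exposures (no joint structure
#' is imposed) with control prevalence `baseline_prevalence_controls` and
#' case prevalence derived from `true_or` via the logistic identity, so the
#' population case/control exposure odds ratio equals `true_or`. Each
#' exposed person receives at least one visit inside the lookback window
#' carrying a code mapped to that exposure; noise visits with non-mapped
#' codes (and dates up to twice the lookback before death) exercise the
#' coder's specificity. Differential selection of the control pool is a
#' separate step: see [apply_selection()].
#'
#' Under a fixed seed all outputs are bit-reproducible.
#'
#' @param config a [simulation_config()].
#' @param code_map code map used to assign visit codes to exposures
#'   (default [default_code_map()]).
#' @param make_visits generate the visit table (default TRUE; FALSE returns
#'   `visits = NULL` and is much faster for estimator studies that work
#'   from the true indicators).
#' @return list with `persons` (person table with `status`),
#'   `visits` (person_id, visit_date, codes with `;`-separated fields),
#'   `exposure_truth` (person_id plus one 0/1 column per exposure), and
#'   `truth` (data.frame echoing the generating parameters per exposure,
#'   including `or_select_true = selection_rr` and the derived
#'   `prevalence_cases`).
#' @export
generate_cohort <- function(config, code_map = default_code_map(),
                            make_visits = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  n_ca <- config$n_cases
  n_pool <- as.integer(round(config$n_controls_target * config$pool_multiplier))
  n <- n_ca + n_pool
  status <- rep(c("case", "control"), c(n_ca, n_pool))

  cause <- character(n)
  cause[status == "case"] <- sample(.case_cause_codes, n_ca, replace = TRUE)
  cause[status == "control"] <- sample(.control_cause_codes, n_pool, replace = TRUE)

  dr <- config$death_date_range
  death_date <- dr[1] + floor(stats::runif(n) * (as.numeric(dr[2] - dr[1]) + 1))
  age <- numeric(n)
  age[status == "case"] <- rtruncnorm_age(n_ca, config$age_case[1], config$age_case[2])
  age[status == "control"] <- rtruncnorm_age(n_pool, config$age_control[1],
                                             config$age_control[2])

  cm <- config$covariate_marginals
  draw_cat <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  persons <- data.frame(
    person_id = sprintf("P%06d", seq_len(n)),
    underlying_cause_icd10 = cause,
    death_date = death_date,
    sex = draw_cat(cm$sex),
    age_years = round(age, 1),
    death_year = as.integer(format(death_date, "%Y")),
    marital_status = draw_cat(cm$marital_status),
    education = draw_cat(cm$education),
    urbanicity = draw_cat(cm$urbanicity),
    status = status,
    stringsAsFactors = FALSE
  )
  persons$sex[stats::runif(n) < config$missing_covariate_rate] <- "missing"
  persons$urbanicity[stats::runif(n) < config$missing_covariate_rate] <- "missing"

  specs <- config$exposure_specs
  truth <- do.call(rbind, lapply(specs, function(s) {
    p0 <- s$baseline_prevalence_controls
    p1 <- s$true_or * p0 / (1 - p0 + s$true_or * p0)
    data.frame(
      exposure = s$name,
      prevalence_controls_pool = p0,
      prevalence_cases = p1,
      true_or = s$true_or,
      selection_rr = s$selection_rr,
      or_select_true = s$selection_rr,
      benchmark_rate = s$benchmark_rate,
      stringsAsFactors = FALSE
    )
  }))

  exposure_truth <- data.frame(person_id = persons$person_id,
                               stringsAsFactors = FALSE)
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    p <- ifelse(status == "case",
                truth$prevalence_cases[i], truth$prevalence_controls_pool[i])
    if (config$confounding) {
      odds <- p / (1 - p) * ifelse(age > 60, 2, 1)
      p <- odds / (1 + odds)
    }
    exposure_truth[[s$name]] <- as.integer(stats::runif(n) < p)
    if (sum(exposure_truth[[s$name]]) == 0L) {
      warning("no exposed persons realized for '", s$name,
              "' at the requested prevalence and sample size")
    }
  }

  visits <- NULL
  if (make_visits) {
    lb <- config$lookback_years
    win_start <- shift_years(persons$death_date, -lb)
    win_len <- as.numeric(persons$death_date - win_start)

    vlist <- list()
    for (s in specs) {
      exposed <- which(exposure_truth[[s$name]] == 1L)
      if (!length(exposed)) next
      prefs <- label_prefixes(code_map, s$name)
      vdate <- win_start[exposed] +
        floor(stats::runif(length(exposed)) * (win_len[exposed] + 1))
      code <- sample(prefs, length(exposed), replace = TRUE)
      extra <- sample(.noise_codes, length(exposed), replace = TRUE)
      vlist[[length(vlist) + 1L]] <- data.frame(
        person_id = persons$person_id[exposed],
        visit_date = vdate,
        codes = paste(code, extra, sep = ";"),
        stringsAsFactors = FALSE
      )
    }
    noisy <- which(stats::runif(n) < config$noise_visit_rate)
    if (length(noisy)) {
      span <- as.numeric(persons$death_date[noisy] -
                           shift_years(persons$death_date[noisy], -2 * lb))
      vdate <- persons$death_date[noisy] - floor(stats::runif(length(noisy)) * span)
      vlist[[length(vlist) + 1L]] <- data.frame(
        person_id = persons$person_id[noisy],
        visit_date = vdate,
        codes = sample(.noise_codes, length(noisy), replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    visits <- if (length(vlist)) do.call(rbind, vlist) else
      data.frame(person_id = character(0), visit_date = as.Date(character(0)),
                 codes = character(0), stringsAsFactors = FALSE)
    visits <- visits[order(visits$person_id, visits$visit_date, visits$codes), ,
                     drop = FALSE]
    rownames(visits) <- NULL
  }

  list(persons = persons, visits = visits,
       exposure_truth = exposure_truth, truth = truth)
}

#' Differentially select controls from the eligible pool
#'
#' Each control is retained independently with probability proportional to
#' `prod(selection_rr_e ^ exposed_e)` over the exposures, scaled so the
#' expected retained count equals `n_target` (probabilities are capped at
#' 1). With all `selection_rr = 1` this is simple random subsampling; with
#' `selection_rr > 1` exposed controls are over-represented among those
#' retained, and the induced selection odds ratio for each exposure equals
#' its `selection_rr`.
#'
#' @param controls data.frame of pool controls (any columns; must include
#'   `person_id`).
#' @param exposures 0/1 indicator table keyed by `person_id` covering every
#'   control (e.g. the generator's `exposure_truth`).
#' @param specs list of [exposure_spec()] giving `name` and `selection_rr`
#'   per exposure.
#' @param n_target expected number of retained controls.
#' @param seed integer seed.
#' @return the retained subset of `controls`.
#' @export
apply_selection <- function(controls, exposures, specs, n_target, seed = 1) {
  specs <- lapply(specs, function(s) {
    if (!inherits(s, "exposure_spec")) do.call(exposure_spec, s) else s
  })
  idx <- match(controls$person_id, exposures$person_id)
  if (any(is.na(idx))) {
    stop("controls without an exposure row: ",
         paste(utils::head(controls$person_id[is.na(idx)], 10), collapse = ", "))
  }
  w <- rep(1, nrow(controls))
  for (s in specs) {
    if (s$selection_rr <= 0) stop("selection_rr must be positive")
    x <- exposures[[s$name]][idx]
    if (is.null(x)) stop("exposure table lacks column '", s$name, "'")
    w <- w * s$selection_rr^x
  }
  p <- pmin(1, n_target / sum(w) * w)
  set.seed(seed)
  controls[stats::runif(nrow(controls)) < p, , drop = FALSE]
}

#' Write a generated cohort to disk
#'
#' Persons and visits as CSV with documented headers; truth as JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    persons = file.path(dir, "persons.csv"),
    visits = file.path(dir, "visits.csv"),
    exposure_truth = file.path(dir, "exposure_truth.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(cohort$persons, paths["persons"], row.names = FALSE)
  if (!is.null(cohort$visits)) {
    utils::write.csv(cohort$visits, paths["visits"], row.names = FALSE)
  }
  utils::write.csv(cohort$exposure_truth, paths["exposure_truth"], row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
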