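# Exposure phenotyping: turn visit-level ICD-9-CM diagnosis and
# external-cause codes into person-level binary indicators for six clinical
# categories (and their components) over a lookback window ending at death.

#' The exposure taxonomy
#'
#' The fixed category/component taxonomy for hospital-visit exposures: six
#' categories, each with its named components ("assault" has none and is
#' matched directly). A code map may only use these labels.
#'
#' @return named list mapping category label to character vector of
#'   component labels (empty vector for direct-match categories).
#' @export
exposure_taxonomy <- function() {
  list(
    "mental illness" = c(
      "depression", "anxiety", "PTSD", "bipolar", "schizophrenia"
    ),
    "substance use" = c(
      "alcohol use disorder/poisoning",
      "drug use disorder/poisoning",
      "opioid use disorder/poisoning",
      "sedative/hypnotic/anxiolytic use disorder/poisoning",
      "cannabis use disorder",
      "stimulant use disorder/poisoning"
    ),
    "pain" = c(
      "rheumatoid arthritis/osteoarthritis",
      "migraine/chronic headache",
      "fibromyalgia/chronic pain/fatigue"
    ),
    "chronic disease" = c(
      "acute MI", "heart failure", "hypertension",
      "stroke/transient ischemic attack", "asthma", "COPD", "diabetes",
      "TBI", "epilepsy", "cancer"
    ),
    "assault" = character(0),
    "suicidal ideation/attempt" = c("suicidal ideation", "suicide attempt")
  )
}

#' Load and validate an exposure code map
#'
#' A code map is a CSV (or YAML) table with columns `category`, `component`,
#' `prefix`: each row says that any ICD-9-CM code starting with `prefix`
#' (after stripping the decimal point) flags that component. Category and
#' component labels must come from [exposure_taxonomy()]; for direct-match
#' categories (assault) the component equals the category label. Duplicate
#' (component, prefix) rows are dropped with a warning; an empty map is an
#' error. Intent restrictions (e.g. unintentional-only drug poisonings) are
#' encoded in the map itself by listing only the unintentional external-cause
#' prefixes.
#'
#' @param path path to a CSV (columns category, component, prefix) or a YAML
#'   file (list of records with those fields).
#' @return a data.frame of class `code_map` with columns `category`,
#'   `component`, `prefix` (prefixes kept as supplied; matching normalizes).
#' @export
load_code_map <- function(path) {
  if (!file.exists(path)) stop("code map file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    map <- do.call(rbind, lapply(recs, function(r) {
      data.frame(
        category = r$category, component = r$component,
        prefix = as.character(r$prefix), stringsAsFactors = FALSE
      )
    }))
  } else {
    map <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  }
  validate_code_map(map)
}

#' @rdname load_code_map
#' @param map a data.frame with columns `category`, `component`, `prefix`.
#' @export
validate_code_map <- function(map) {
  if (is.null(map) || nrow(map) == 0L) {
    stop("code map is empty: at least one (category, component, prefix) row is required")
  }
  needed <- c("category", "component", "prefix")
  if (!all(needed %in% names(map))) {
    stop("code map must have columns: ", paste(needed, collapse = ", "))
  }
  map <- map[, needed]
  map$prefix <- trimws(map$prefix)
  if (any(map$prefix == "" | is.na(map$prefix))) {
    stop("code map contains empty prefixes (rows ",
         paste(which(map$prefix == "" | is.na(map$prefix)), collapse = ", "), ")")
  }
  tax <- exposure_taxonomy()
  bad_cat <- !(map$category %in% names(tax))
  if (any(bad_cat)) {
    stop("code map rows with category outside the taxonomy: ",
         paste(unique(map$category[bad_cat]), collapse = ", "),
         " (row ", paste(which(bad_cat), collapse = ", "), ")")
  }
  ok_comp <- mapply(function(cat, comp) {
    comps <- tax[[cat]]
    if (length(comps) == 0L) comp == cat else comp %in% comps
  }, map$category, map$component)
  if (any(!ok_comp)) {
    stop("code map rows with component outside the taxonomy for their category: ",
         paste(unique(map$component[!ok_comp]), collapse = ", "))
  }
  dup <- duplicated(map[, c("component", "prefix")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (component, prefix) rows dropped from code map")
    map <- map[!dup, , drop = FALSE]
  }
  rownames(map) <- NULL
  class(map) <- c("code_map", "data.frame")
  map
}

#' The illustrative default code map
#'
#' Loads the code map shipped with the package
#' (`inst/extdata/codemap_illustrative.csv`). This map is an illustrative
#' stand-in assembled from standard ICD-9-CM groupings; it is *not* an
#' authoritative clinical code list. The code map is a first-class input:
#' analyses of real data should supply a validated list via
#' [load_code_map()].
#'
#' @return a `code_map` data.frame.
#' @export
default_code_map <- function() {
  load_code_map(system.file("extdata", "codemap_illustrative.csv",
                            package = "qbaselect", mustWork = TRUE))
}

# Shift dates by whole calendar years; Feb 29 in a non-leap target year
# normalizes to Mar 1 (POSIXlt normalization), matching seq.Date.
shift_years <- function(dates, n) {
  lt <- as.POSIXlt(dates)
  lt$year <- lt$year + n
  as.Date(lt)
}

#' Code person-level exposures from visit records
#'
#' For each person, sets `any_visit = 1` if they have at least one visit in
#' the closed window `[death_date - lookback_years, death_date]` (calendar
#' arithmetic, not 365-day years), and flags each mapped component whose
#' prefix matches any code of any in-window visit, in any diagnostic field.
#' Matching strips decimal points from both code and prefix and anchors the
#' prefix at the start of the code. Category flags are the OR of their
#' component flags (direct-match categories match their own rows).
#'
#' @param persons data.frame with `person_id`, `death_date` (Date or
#'   coercible).
#' @param visits data.frame with `person_id`, `visit_date`, `codes`
#'   (semicolon-separated ICD-9-CM code string per visit).
#' @param code_map a `code_map`, default [default_code_map()].
#' @param lookback_years window length in calendar years before death
#'   (default 3).
#' @return data.frame with `person_id`, `any_visit`, one 0/1 column per
#'   category and per component (names are the taxonomy labels). Attributes
#'   `categories` and `components` give the column groupings.
#' @export
code_exposures <- function(persons, visits, code_map = default_code_map(),
                           lookback_years = 3) {
  stopifnot(is.data.frame(persons), is.data.frame(visits))
  code_map <- validate_code_map(code_map)
  persons$death_date <- as.Date(persons$death_date)

  orphans <- setdiff(unique(visits$person_id), persons$person_id)
  if (length(orphans)) {
    stop("visits reference person_ids absent from the person table: ",
         paste(utils::head(orphans, 10), collapse = ", "))
  }

  n <- nrow(persons)
  cats <- names(exposure_taxonomy())
  cats <- cats[cats %in% code_map$category]
  comps <- unique(code_map$component[code_map$component != code_map$category])

  out <- data.frame(person_id = persons$person_id, stringsAsFactors = FALSE)
  out$any_visit <- integer(n)
  for (cl in c(cats, comps)) out[[cl]] <- integer(n)

  if (nrow(visits) > 0L) {
    visits$visit_date <- as.Date(visits$visit_date)
    idx <- match(visits$person_id, persons$person_id)
    death <- persons$death_date[idx]
    if (any(visits$visit_date > death)) {
      bad <- unique(visits$person_id[visits$visit_date > death])
      stop("visits dated after death for person_ids: ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
    win_start <- shift_years(death, -lookback_years)
    in_win <- visits$visit_date >= win_start & visits$visit_date <= death

    vis <- visits[in_win, , drop = FALSE]
    vidx <- idx[in_win]
    out$any_visit[unique(vidx)] <- 1L

    if (nrow(vis) > 0L) {
      code_list <- strsplit(as.character(vis$codes), ";", fixed = TRUE)
      n_codes <- lengths(code_list)
      if (any(n_codes == 0L)) {
        stop("visits with empty code lists for person_ids: ",
             paste(utils::head(unique(vis$person_id[n_codes == 0L]), 10),
                   collapse = ", "))
      }
      long_pid <- rep(vidx, n_codes)
      long_code <- icd_normalize(unlist(code_list, use.names = FALSE))

      # per map target (component, or category for direct-match rows),
      # flag persons carrying any code matching one of its prefixes
      map_clean <- code_map
      map_clean$prefix_clean <- icd_normalize(code_map$prefix)
      target <- ifelse(map_clean$component == map_clean$category,
                       map_clean$category, map_clean$component)
      for (tg in unique(target)) {
        prefs <- map_clean$prefix_clean[target == tg]
        hit <- rep(FALSE, length(long_code))
        for (p in prefs) hit <- hit | startsWith(long_code, p)
        out[[tg]][unique(long_pid[hit])] <- 1L
      }
    }
  }

  # category = OR of components
  tax <- exposure_taxonomy()
  for (cat in cats) {
    cc <- intersect(tax[[cat]], names(out))
    if (length(cc)) {
      out[[cat]] <- as.integer(out[[cat]] | Reduce(`|`, out[, cc, drop = FALSE]))
    }
  }
  # any category implies any_visit (true by construction: flags come from
  # in-window visits), keep the invariant explicit anyway
  if (length(cats)) {
    out$any_visit <- as.integer(out$any_visit | Reduce(`|`, out[, cats, drop = FALSE]))
  }

  attr(out, "categories") <- cats
  attr(out, "components") <- comps
  out
}

# percentage to one decimal as printed in descriptive tables
pct1 <- function(count, n) {
  ifelse(n > 0, round(100 * count / n, 1), NA_real_)
}

#' Descriptive case/control summary table
#'
#' Per-group N, mean (SD) age, and counts with percentages for each
#' covariate level and each exposure flag, mirroring the usual "Table 1" of
#' a case-control report. Percentages are `100 * count / group N` rounded to
#' one decimal; an empty group reports `NA` percentages rather than dividing
#' by zero.
#'
#' @param persons data.frame with a `status` column (`"case"`/`"control"`)
#'   and the usual covariates; `status` is derived from
#'   `underlying_cause_icd10` via [classify_manner()] if absent.
#' @param exposures optional exposure matrix from [code_exposures()], merged
#'   on `person_id`.
#' @return data.frame with columns `section`, `variable`, `n_case`,
#'   `pct_case`, `n_control`, `pct_control` (for the age row the `n_*`
#'   columns carry the mean and `pct_*` the SD).
#' @export
summarize_table_one <- function(persons, exposures = NULL) {
  if (!"status" %in% names(persons)) {
    persons$status <- classify_manner(persons$underlying_cause_icd10)$status
  }
  cases <- persons[persons$status == "case", , drop = FALSE]
  ctrls <- persons[persons$status == "control", , drop = FALSE]
  n_ca <- nrow(cases)
  n_co <- nrow(ctrls)

  rows <- list()
  add <- function(section, variable, n_case, pct_case, n_control, pct_control) {
    rows[[length(rows) + 1L]] <<- data.frame(
      section = section, variable = variable,
      n_case = n_case, pct_case = pct_case,
      n_control = n_control, pct_control = pct_control,
      stringsAsFactors = FALSE
    )
  }
  add("group", "N", n_ca, NA_real_, n_co, NA_real_)

  if ("age_years" %in% names(persons)) {
    add("sociodemographic", "age, mean (SD)",
        if (n_ca) round(mean(cases$age_years), 1) else NA_real_,
        if (n_ca) round(stats::sd(cases$age_years), 1) else NA_real_,
        if (n_co) round(mean(ctrls$age_years), 1) else NA_real_,
        if (n_co) round(stats::sd(ctrls$age_years), 1) else NA_real_)
  }
  for (v in intersect(c("sex", "education", "marital_status", "urbanicity"),
                      names(persons))) {
    for (lev in sort(unique(as.character(persons[[v]])))) {
      ca <- sum(cases[[v]] == lev, na.rm = TRUE)
      co <- sum(ctrls[[v]] == lev, na.rm = TRUE)
      add(v, lev, ca, pct1(ca, n_ca), co, pct1(co, n_co))
    }
  }

  if (!is.null(exposures)) {
    flag_cols <- setdiff(names(exposures), "person_id")
    e_ca <- exposures[match(cases$person_id, exposures$person_id), , drop = FALSE]
    e_co <- exposures[match(ctrls$person_id, exposures$person_id), , drop = FALSE]
    for (fc in flag_cols) {
      ca <- sum(e_ca[[fc]], na.rm = TRUE)
      co <- sum(e_co[[fc]], na.rm = TRUE)
      add("health conditions", fc, ca, pct1(ca, n_ca), co, pct1(co, n_co))
    }
  }
  do.call(rbind, rows)
}
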