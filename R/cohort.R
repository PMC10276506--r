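# Cohort definition from ICD-10 underlying cause of death, plus eligibility
# filtering. Cases are firearm suicide decedents (X72-X74); controls are
# unintentional motor-vehicle-crash occupants/drivers. Intentional and
# undetermined-intent transport deaths (X82, Y03, Y32) are excluded
# structurally: those codes are simply absent from the control set.

#' Normalize an ICD code string
#'
#' Upper-cases, trims whitespace, and strips the optional decimal point, so
#' that `"V19.0"` and `"v190"` compare equal.
#'
#' @param code character vector of ICD codes (ICD-9-CM or ICD-10).
#' @return character vector of normalized codes.
#' @export
icd_normalize <- function(code) {
  toupper(gsub("[.[:space:]]", "", as.character(code)))
}

# Case set: X72 (handgun), X73 (long gun), X74 (other/unspecified firearm),
# including any fourth-character subdivision.
.case_roots <- c("X72", "X73", "X74")

# Control set: motor-vehicle-crash occupant/driver deaths. Three-character
# ranges match any subcode of a root in the range; four-character entries
# match only the listed subcodes (and their further subdivisions).
.mvc_roots <- sprintf("V%02d", c(2:4, 12:14, 20:79, 83:86))
.mvc_four <- c(
  "V090", "V092",
  sprintf("V19%d", c(0:2, 4:6)),
  sprintf("V80%d", 3:5),
  sprintf("V81%d", 0:1),
  sprintf("V82%d", 0:1),
  sprintf("V87%d", 0:8),
  sprintf("V88%d", 0:8),
  "V890", "V892"
)

#' Expanded cause-of-death code sets
#'
#' Returns the fully expanded case and control membership sets used by
#' [classify_manner()]. Control membership is tested first on the
#' three-character root, then on the four-character prefix.
#'
#' @return a list with elements `case_roots`, `control_roots`,
#'   `control_four_char`.
#' @export
cause_code_sets <- function() {
  list(
    case_roots = .case_roots,
    control_roots = .mvc_roots,
    control_four_char = .mvc_four
  )
}

#' Classify underlying cause of death into case / control / ineligible
#'
#' A decedent is a case if the underlying cause is a firearm suicide code
#' (X72-X74, any subdivision) and a control if it falls in the
#' motor-vehicle-crash occupant/driver inclusion list. Codes are accepted
#' with or without a decimal point. Empty or unparseable codes classify as
#' ineligible; the function never throws on bad input.
#'
#' @param underlying_cause_icd10 character vector of ICD-10 codes.
#' @return a data.frame with columns `code` (as supplied), `status`
#'   (`"case"`, `"control"`, or `"ineligible"`), and `matched_rule` (the
#'   code-set entry that matched, or `NA`).
#' @examples
#' classify_manner(c("X72", "V19.3", "V190", "W34"))
#' @export
classify_manner <- function(underlying_cause_icd10) {
  code <- icd_normalize(underlying_cause_icd10)
  code[is.na(code)] <- ""
  root <- substr(code, 1L, 3L)
  four <- substr(code, 1L, 4L)
  valid <- grepl("^[A-Z][0-9]{2}", code)

  status <- rep("ineligible", length(code))
  rule <- rep(NA_character_, length(code))

  is_case <- valid & root %in% .case_roots
  status[is_case] <- "case"
  rule[is_case] <- root[is_case]

  is_ctl3 <- valid & !is_case & root %in% .mvc_roots
  status[is_ctl3] <- "control"
  rule[is_ctl3] <- root[is_ctl3]

  is_ctl4 <- valid & !is_case & !is_ctl3 & nchar(code) >= 4L & four %in% .mvc_four
  status[is_ctl4] <- "control"
  rule[is_ctl4] <- four[is_ctl4]

  data.frame(
    code = as.character(underlying_cause_icd10),
    status = status,
    matched_rule = rule,
    stringsAsFactors = FALSE
  )
}

.is_missing_level <- function(x) {
  is.na(x) | x %in% c("", "missing")
}

#' Apply eligibility filters to a person table
#'
#' Filters are applied in a fixed, documented order so that exclusion counts
#' are reproducible: (1) age under `min_age` (or missing age), (2) missing
#' sex, (3) missing county urbanicity. Each person is counted once, at the
#' first filter that removes them. The boundary is inclusive: a person aged
#' exactly `min_age` is retained.
#'
#' @param persons data.frame with at least `person_id`, `age_years`, `sex`,
#'   `urbanicity`.
#' @param min_age minimum age in years at death; default 21, the legal
#'   handgun purchase age.
#' @return a list with `persons` (the retained rows) and `report`, itself a
#'   list with counts `n_input`, `n_excluded_age`, `n_excluded_missing`,
#'   `n_retained` and an `exclusions` data.frame (`person_id`, `reason`).
#'   The counts always reconcile:
#'   `n_input == n_excluded_age + n_excluded_missing + n_retained`.
#' @export
apply_eligibility <- function(persons, min_age = 21) {
  stopifnot(is.data.frame(persons))
  needed <- c("person_id", "age_years", "sex", "urbanicity")
  missing_cols <- setdiff(needed, names(persons))
  if (length(missing_cols)) {
    stop("persons table lacks columns: ", paste(missing_cols, collapse = ", "))
  }

  n_input <- nrow(persons)
  excl_age <- is.na(persons$age_years) | persons$age_years < min_age
  excl_sex <- !excl_age & .is_missing_level(persons$sex)
  excl_urb <- !excl_age & !excl_sex & .is_missing_level(persons$urbanicity)

  reason <- rep(NA_character_, n_input)
  reason[excl_age] <- "age"
  reason[excl_sex] <- "missing_sex"
  reason[excl_urb] <- "missing_urbanicity"

  keep <- is.na(reason)
  report <- list(
    n_input = n_input,
    n_excluded_age = sum(excl_age),
    n_excluded_missing = sum(excl_sex) + sum(excl_urb),
    n_retained = sum(keep),
    exclusions = data.frame(
      person_id = persons$person_id[!keep],
      reason = reason[!keep],
      stringsAsFactors = FALSE
    )
  )
  list(persons = persons[keep, , drop = FALSE], report = report)
}
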