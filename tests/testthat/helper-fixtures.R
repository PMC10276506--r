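# In-code fixtures shared across test files.

# minimal person table; all covariates complete unless overridden
make_persons <- function(n, status = "case", age = 45,
                         death_date = as.Date("2012-06-01"),
                         sex = "male", urbanicity = "large metro",
                         id_prefix = "T") {
  if (n == 0L) {
    return(data.frame(person_id = character(0),
                      underlying_cause_icd10 = character(0),
                      death_date = as.Date(character(0)),
                      sex = character(0), age_years = numeric(0),
                      death_year = integer(0), marital_status = character(0),
                      education = character(0), urbanicity = character(0),
                      status = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    person_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    underlying_cause_icd10 = ifelse(rep(status, length.out = n) == "case",
                                    "X72", "V43.5"),
    death_date = rep(as.Date(death_date), length.out = n),
    sex = rep(sex, length.out = n),
    age_years = rep(age, length.out = n),
    death_year = as.integer(format(rep(as.Date(death_date), length.out = n), "%Y")),
    marital_status = "married/partner",
    education = "high school or less",
    urbanicity = rep(urbanicity, length.out = n),
    status = rep(status, length.out = n),
    stringsAsFactors = FALSE
  )
}

# expand a 2x2 table into person-level outcome / exposure vectors
# a = exposed cases, b = exposed controls, c = unexposed cases, d = unexposed controls
expand_2x2 <- function(a, b, c, d) {
  list(
    y = rep(c(1, 0, 1, 0), c(a, b, c, d)),
    x = rep(c(1, 1, 0, 0), c(a, b, c, d))
  )
}

# a small mixed-covariate logistic fixture with a fixed seed
make_glm_fixture <- function(n = 30, seed = 42) {
  set.seed(seed)
  x <- cbind(`(Intercept)` = 1,
             exposure = rbinom(n, 1, 0.4),
             age = round(rnorm(n, 50, 10), 1))
  eta <- -0.5 + 0.8 * x[, "exposure"] + 0.02 * (x[, "age"] - 50)
  y <- rbinom(n, 1, plogis(eta))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(x = x, y = y)
}

# the fully printed published inputs for the headline exposure
headline_qba_inputs <- function() {
  list(or_observed = 4.92, ci_low = 3.27, ci_high = 7.40,
       rate_sample = 8.00, rate_benchmark = 4.67)
}
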