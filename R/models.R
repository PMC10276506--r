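# Odds-ratio estimation: binomial-logistic maximum likelihood (IRLS) with
# heteroskedasticity-consistent sandwich standard errors, and the model
# hierarchy used for case-control exposure screens: one adjusted model per
# exposure ("separate"), or all exposures entered together ("simultaneous").

Z95 <- 1.959964

#' Fit a logistic regression by maximum likelihood
#'
#' Thin wrapper around binomial IRLS (`stats::glm.fit`, epsilon 1e-12, at
#' most 100 iterations) with explicit design checks and separation
#' flagging. The design must carry its own intercept column.
#'
#' @param x numeric design matrix including an intercept column; columns
#'   must be named.
#' @param y binary outcome vector (0/1 or logical), both classes present.
#' @return list of class `logit_fit`: `coefficients`, `fitted`, `model_cov`
#'   (inverse expected information), `converged`, `separated` (TRUE when
#'   any |coefficient| exceeds 15 with an exploding SE; such fits are
#'   non-reportable), `n`, `k`, plus the design and outcome for downstream
#'   variance computation.
#' @export
fit_logistic <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L) stop("outcome has a single class; cannot estimate")
  const0 <- apply(x, 2L, function(col) all(col == 0))
  if (any(const0)) {
    stop("constant-zero design columns: ",
         paste(colnames(x)[const0], collapse = ", "))
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }

  fit <- stats::glm.fit(x, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  info <- crossprod(x * sqrt(w))
  model_cov <- tryCatch(solve(info), error = function(e) {
    matrix(Inf, ncol(x), ncol(x), dimnames = list(colnames(x), colnames(x)))
  })
  se <- sqrt(pmax(diag(model_cov), 0))
  # intercept excluded: with untransformed continuous covariates (e.g.
  # calendar year) it is legitimately large without any separation
  chk <- colnames(x) != "(Intercept)"
  separated <- any(abs(beta[chk]) > 15 & (se[chk] > 15 | !is.finite(se[chk])))

  structure(list(
    coefficients = beta,
    fitted = mu,
    model_cov = model_cov,
    converged = isTRUE(fit$converged),
    separated = separated,
    n = nrow(x), k = ncol(x),
    x = x, y = y
  ), class = "logit_fit")
}

#' Heteroskedasticity-consistent sandwich covariance
#'
#' Computes `B^{-1} M B^{-1}` for a fitted logistic model, where `B` is the
#' expected information `X' W X` (W = mu(1-mu)) and `M` the outer product of
#' the per-observation score contributions `x_i (y_i - mu_i)`. The HC1
#' flavor applies the small-sample factor `n / (n - k)`; HC0 omits it.
#'
#' @param x design matrix; or a `logit_fit`, in which case `y` and `coef`
#'   are taken from the fit.
#' @param y binary outcome.
#' @param coef fitted coefficient vector.
#' @param type `"HC1"` (default) or `"HC0"`.
#' @return symmetric covariance matrix with design column names.
#' @export
robust_covariance <- function(x, y = NULL, coef = NULL, type = c("HC1", "HC0")) {
  type <- match.arg(type)
  if (inherits(x, "logit_fit")) {
    fit <- x
    x <- fit$x; y <- fit$y; coef <- fit$coefficients
  }
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  eta <- drop(x %*% coef)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  bread <- crossprod(x * sqrt(w))
  bi <- tryCatch(solve(bread), error = function(e) {
    stop("singular bread (information) matrix")
  })
  scores <- x * (y - mu)
  meat <- crossprod(scores)
  v <- bi %*% meat %*% bi
  if (type == "HC1") v <- v * n / (n - k)
  (v + t(v)) / 2
}

# one ORResult row per requested term
or_rows <- function(fit, vcov_rob, terms, model_id, variant) {
  beta <- fit$coefficients[terms]
  se <- sqrt(diag(vcov_rob)[terms])
  data.frame(
    term = terms,
    or = exp(beta),
    ci_low = exp(beta - Z95 * se),
    ci_high = exp(beta + Z95 * se),
    se_ln_or = se,
    n = fit$n,
    model_id = model_id,
    variant = variant,
    estimable = TRUE,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

non_estimable_row <- function(term, n, model_id, variant) {
  data.frame(
    term = term, or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    se_ln_or = NA_real_, n = n, model_id = model_id, variant = variant,
    estimable = FALSE, stringsAsFactors = FALSE
  )
}

#' Build the adjusted-covariate design matrix
#'
#' Fixed covariate set: sex, age (continuous, years), death year
#' (continuous), marital status, education, county urbanicity. Reference
#' levels: female, married/partner, high school or less, large metro;
#' "unknown" is kept as its own level. Unused levels are dropped so small
#' cohorts stay full rank.
#'
#' @param persons person table after eligibility filtering.
#' @return numeric model matrix with intercept.
#' @export
covariate_design <- function(persons) {
  d <- data.frame(
    sex = factor(persons$sex, levels = c("female", "male")),
    age = as.numeric(persons$age_years),
    death_year = as.numeric(persons$death_year),
    marital = factor(persons$marital_status,
                     levels = c("married/partner", "divorced", "never married",
                                "widowed", "unknown")),
    education = factor(persons$education,
                       levels = c("high school or less", "some college",
                                  "associates", "bachelor", "graduate",
                                  "unknown")),
    urbanicity = factor(persons$urbanicity,
                        levels = c("large metro", "small metro", "non-metro"))
  )
  d <- droplevels(d)
  keep <- vapply(d, function(col) {
    if (is.factor(col)) nlevels(col) > 1L else isTRUE(stats::var(col) > 0)
  }, logical(1))
  form <- stats::as.formula(paste("~", paste(names(d)[keep], collapse = " + ")))
  stats::model.matrix(form, d)
}

#' Fit the case-control model hierarchy
#'
#' `variant = "separate"` fits one covariate-adjusted logistic model per
#' exposure term; `variant = "simultaneous"` enters all terms in a single
#' adjusted model. Terms whose model shows separation are reported as
#' non-estimable rows and the run continues. Standard errors are HC1
#' sandwich by default.
#'
#' @param persons eligible person table with `status` column and covariates.
#' @param exposures exposure matrix from [code_exposures()] (or any 0/1
#'   indicator table keyed by `person_id`).
#' @param variant `"separate"` or `"simultaneous"`.
#' @param terms exposure columns to model; defaults to the category columns
#'   of `exposures` (its `"categories"` attribute) or all non-id columns.
#' @param adjust include the covariate set (default TRUE; FALSE gives crude
#'   intercept + exposure models).
#' @param hc sandwich flavor passed to [robust_covariance()].
#' @return data.frame of ORResult rows: `term`, `or`, `ci_low`, `ci_high`,
#'   `se_ln_or`, `n`, `model_id`, `variant`, `estimable`.
#' @export
run_hierarchy <- function(persons, exposures,
                          variant = c("separate", "simultaneous"),
                          terms = NULL, adjust = TRUE, hc = "HC1") {
  variant <- match.arg(variant)
  if (is.null(terms)) {
    terms <- attr(exposures, "categories")
    if (is.null(terms)) terms <- setdiff(names(exposures), "person_id")
  }
  missing_terms <- setdiff(terms, names(exposures))
  if (length(missing_terms)) {
    stop("exposure matrix lacks columns: ", paste(missing_terms, collapse = ", "))
  }
  em <- exposures[match(persons$person_id, exposures$person_id), , drop = FALSE]
  if (any(is.na(em$person_id))) {
    stop("persons without an exposure row: ",
         paste(utils::head(persons$person_id[is.na(em$person_id)], 10),
               collapse = ", "))
  }
  y <- as.integer(persons$status == "case")
  covd <- if (adjust) covariate_design(persons) else
    matrix(1, nrow(persons), 1, dimnames = list(NULL, "(Intercept)"))
  if (nrow(covd) != nrow(persons)) {
    stop("covariate design dropped rows (missing or unknown covariate ",
         "levels); apply eligibility filtering first")
  }

  fit_one <- function(term_set, model_id) {
    xe <- as.matrix(em[, term_set, drop = FALSE])
    colnames(xe) <- term_set
    x <- cbind(covd, xe)
    fit <- fit_logistic(x, y)
    if (fit$separated || !fit$converged) {
      return(do.call(rbind, lapply(term_set, non_estimable_row,
                                   n = fit$n, model_id = model_id,
                                   variant = variant)))
    }
    or_rows(fit, robust_covariance(fit, type = hc), term_set, model_id, variant)
  }

  if (variant == "separate") {
    out <- lapply(terms, function(tm) {
      tryCatch(fit_one(tm, paste0("separate:", tm)),
               error = function(e) non_estimable_row(tm, length(y),
                                                     paste0("separate:", tm),
                                                     variant))
    })
    do.call(rbind, out)
  } else {
    fit_one(terms, "simultaneous")
  }
}
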