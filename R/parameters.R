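#' Derive a standard error from a 95% range
#'
#' Uncertain inputs are reported as a point estimate with a (low, high) range
#' interpreted as an approximate 95% interval, so the standard error is the
#' range width divided by four.
#'
#' @param low,high Numeric vectors of range bounds (same units as the
#'   parameter). Recycled to a common length.
#' @param id Optional character vector of parameter names used in error
#'   messages.
#' @return Numeric vector `(high - low) / 4`.
#' @examples
#' derive_se(0.14, 0.21)
#' derive_se(139.6, 223.3)
#' @export
derive_se <- function(low, high, id = NULL) {
  bad <- which(high < low)
  if (length(bad) > 0) {
    who <- if (is.null(id)) paste0("element ", bad) else id[bad]
    rlang::abort(paste0(
      "`high` must be >= `low`; violated for: ",
      paste(who, collapse = ", ")
    ))
  }
  (high - low) / 4
}

#' Fit sampling distributions to a parameter table
#'
#' Probabilities get beta distributions by the method of moments
#' (`alpha = m * (m (1 - m) / s^2 - 1)`, `beta = (1 - m) * (m (1 - m) / s^2 - 1)`);
#' costs get `normal(mean, se)`. Parameters with `se = 0` become point masses.
#' If a probability's variance violates the beta moment condition
#' (`s^2 >= m (1 - m)`), the standard deviation is clamped to
#' `0.99 * sqrt(m (1 - m))` with a warning, preserving the mean.
#'
#' @param params A validated parameter tibble (see [read_parameters()]).
#' @return The input tibble with columns `family` ("beta", "normal" or
#'   "point"), `shape1`, `shape2` (beta), and `sd` (the possibly clamped
#'   sampling standard deviation).
#' @export
fit_distributions <- function(params) {
  params <- validate_parameters(params)
  m <- params$mean
  s <- params$se
  fam <- ifelse(s == 0, "point", ifelse(params$kind == "probability", "beta", "normal"))

  # clamp probability SDs that violate the moment condition
  clamp <- fam == "beta" & s^2 >= m * (1 - m)
  if (any(clamp)) {
    rlang::warn(paste0(
      "Beta moment condition violated; clamping sd for: ",
      paste(params$id[clamp], collapse = ", ")
    ))
    s[clamp] <- 0.99 * sqrt(m[clamp] * (1 - m[clamp]))
  }

  k <- ifelse(fam == "beta", m * (1 - m) / s^2 - 1, NA_real_)
  params$family <- fam
  params$shape1 <- ifelse(fam == "beta", m * k, NA_real_)
  params$shape2 <- ifelse(fam == "beta", (1 - m) * k, NA_real_)
  params$sd <- ifelse(fam == "point", 0, s)
  params
}

#' Validate a parameter table
#'
#' Checks the schema (`id`, `label`, `kind`, `mean`, `low`, `high`, `source`),
#' uniqueness of ids, `low <= mean <= high`, domain constraints per kind
#' (probabilities in `[0, 1]`, costs `>= 0`), and fills the `se` column via
#' [derive_se()]. All violations are reported together in a single error.
#'
#' @param params A data frame of parameters.
#' @return The validated tibble with an `se` column.
#' @export
validate_parameters <- function(params) {
  params <- tibble::as_tibble(params)
  if (nrow(params) == 0) rlang::abort("no parameters: the parameter table is empty")
  required <- c("id", "label", "kind", "mean", "low", "high", "source")
  missing_cols <- setdiff(required, names(params))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("parameter table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }

  problems <- character()
  note <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, paste0(what, ": ", paste(params$id[rows], collapse = ", ")))
    }
  }
  dup <- which(duplicated(params$id))
  if (length(dup) > 0) {
    problems <- c(problems, paste0("duplicate id: ", paste(unique(params$id[dup]), collapse = ", ")))
  }
  note(which(!params$kind %in% c("probability", "cost")), "unknown kind")
  ok_kind <- params$kind %in% c("probability", "cost")
  note(which(params$high < params$low), "low > high")
  note(which(params$mean < params$low | params$mean > params$high), "mean outside [low, high]")
  is_p <- ok_kind & params$kind == "probability"
  note(which(is_p & (params$low < 0 | params$high > 1)), "probability outside [0, 1]")
  is_c <- ok_kind & params$kind == "cost"
  note(which(is_c & params$low < 0), "negative cost")

  if (length(problems) > 0) {
    rlang::abort(paste0("invalid parameter table:\n- ", paste(problems, collapse = "\n- ")))
  }
  params$se <- derive_se(params$low, params$high, params$id)
  params
}

#' Read a parameter table from delimited text
#'
#' The file is a UTF-8 CSV with columns `id`, `label`, `kind`
#' (`probability`/`cost`), `mean`, `low`, `high`, `source`; decimal points,
#' no thousands separators. The table is validated and the derived `se`
#' column is added.
#'
#' @param path Path to the CSV file.
#' @return A validated parameter tibble.
#' @seealso [uganda_parameters()] for the packaged study table.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("parameter file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), label = readr::col_character(),
    kind = readr::col_character(), mean = readr::col_double(),
    low = readr::col_double(), high = readr::col_double(),
    source = readr::col_character()
  ))
  validate_parameters(raw)
}

#' Write a parameter table to delimited text
#'
#' Writes only the schema columns, so `read_parameters(write_parameters(x))`
#' round-trips value-identically.
#'
#' @param params A parameter tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  cols <- c("id", "label", "kind", "mean", "low", "high", "source")
  readr::write_csv(params[, cols], path)
  invisible(path)
}

#' Read economic constants
#'
#' Constants (GDP per capita, discount rate, annual incidence, ...) are fixed
#' in the probabilistic analysis: they have no ranges and are never sampled.
#'
#' @param path Path to a two-column CSV (`id`, `value`).
#' @return A named list of numeric constants.
#' @export
read_constants <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("constants file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), value = readr::col_double()
  ))
  validate_constants(stats::setNames(as.list(raw$value), raw$id))
}

#' @rdname read_constants
#' @param constants A named list of constants to validate.
#' @export
validate_constants <- function(constants) {
  required <- c(
    "gdp_per_capita", "discount_rate", "age_at_death",
    "remaining_life_expectancy", "annual_incidence", "anc_attendance",
    "cesarean_rate", "facility_delivery_rate"
  )
  missing <- setdiff(required, names(constants))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing economic constants: ", paste(missing, collapse = ", ")))
  }
  vals <- unlist(constants[required])
  if (any(vals < 0)) {
    rlang::abort(paste0(
      "economic constants must be nonnegative: ",
      paste(required[vals < 0], collapse = ", ")
    ))
  }
  fracs <- c("anc_attendance", "cesarean_rate", "facility_delivery_rate", "discount_rate")
  bad <- fracs[unlist(constants[fracs]) > 1]
  if (length(bad) > 0) {
    rlang::abort(paste0("constants expected in [0, 1]: ", paste(bad, collapse = ", ")))
  }
  constants
}

#' Packaged Uganda study inputs
#'
#' The packaged encodings of the study's probability table (27 rows) and
#' itemized 2010 US$ unit costs (24 rows), and the economic constants.
#'
#' @return `uganda_parameters()`: a validated parameter tibble;
#'   `uganda_constants()`: a named list of constants.
#' @export
uganda_parameters <- function() {
  read_parameters(system.file("extdata", "uganda_parameters.csv", package = "abcost", mustWork = TRUE))
}

#' @rdname uganda_parameters
#' @export
uganda_constants <- function() {
  read_constants(system.file("extdata", "uganda_constants.csv", package = "abcost", mustWork = TRUE))
}

#' Derive training and conditional provider probabilities from raw shares
#'
#' Raw provider shares of all induced abortions (doctor, clinical officer,
#' nurse/midwife, dispenser, lay practitioner, self) are collapsed into the
#' probability that the provider is trained (doctor + clinical officer +
#' nurse/midwife) and the conditional shares within the trained and untrained
#' groups (renormalized to sum to 1 within each group).
#'
#' @param shares Named numeric vector with entries `doctor`,
#'   `clinical_officer`, `nurse_midwife`, `dispenser`, `lay_practitioner`,
#'   `self_induction`, summing to 1 within 0.01.
#' @return A list with `p_trained`, and tibbles `trained` and `untrained` of
#'   conditional shares (`provider`, `share`). A group with zero mass gets an
#'   empty tibble and is flagged with `degenerate`.
#' @examples
#' derive_provider_probabilities(c(
#'   doctor = 0.20, clinical_officer = 0.17, nurse_midwife = 0.19,
#'   dispenser = 0.07, lay_practitioner = 0.22, self_induction = 0.15
#' ))
#' @export
derive_provider_probabilities <- function(shares) {
  trained_ids <- c("doctor", "clinical_officer", "nurse_midwife")
  untrained_ids <- c("dispenser", "lay_practitioner", "self_induction")
  missing <- setdiff(c(trained_ids, untrained_ids), names(shares))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing provider shares: ", paste(missing, collapse = ", ")))
  }
  tot <- sum(shares[c(trained_ids, untrained_ids)])
  if (abs(tot - 1) > 0.01) {
    rlang::abort(paste0("provider shares must sum to 1 (got ", format(tot), ")"))
  }
  cond <- function(ids) {
    mass <- sum(shares[ids])
    if (mass <= 0) {
      return(tibble::tibble(provider = character(), share = numeric()))
    }
    tibble::tibble(provider = ids, share = as.numeric(shares[ids]) / mass)
  }
  p_trained <- sum(shares[trained_ids]) / tot
  list(
    p_trained = p_trained,
    trained = cond(trained_ids),
    untrained = cond(untrained_ids),
    degenerate = p_trained %in% c(0, 1)
  )
}

#' Derive the abortion-failure probability from retry counts
#'
#' @param n_retry Number of women needing a second (or later) attempt.
#' @param n_total Number of women observed.
#' @return `n_retry / n_total`.
#' @examples
#' derive_failure_probability(8, 47) # ~0.17
#' @export
derive_failure_probability <- function(n_retry, n_total) {
  if (n_total <= 0) rlang::abort("n_total must be positive")
  if (n_retry < 0 || n_retry > n_total) rlang::abort("need 0 <= n_retry <= n_total")
  n_retry / n_total
}

#' Derive the hospitalization fraction among treated complications
#'
#' @param n_hospital Number receiving hospital care.
#' @param n_treated Number treated for complications.
#' @return `n_hospital / n_treated`.
#' @examples
#' derive_hospitalization_fraction(47828, 109926) # ~0.435
#' @export
derive_hospitalization_fraction <- function(n_hospital, n_treated) {
  if (n_treated <= 0) rlang::abort("n_treated must be positive")
  if (n_hospital < 0 || n_hospital > n_treated) rlang::abort("need 0 <= n_hospital <= n_treated")
  n_hospital / n_treated
}
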