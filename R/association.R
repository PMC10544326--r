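## Association scans: per-unit Firth fits with covariate adjustment,
## subtype-specific outcomes, optional stratum filters, and the
## carrier-by-age interaction (age-trend) model.

outcome_case_ids <- function(phenotypes, outcome) {
  if (outcome == "overall") {
    return(phenotypes$subject_id[phenotypes$status == "case"])
  }
  parts <- stratify(phenotypes, "subtype")
  ids <- parts[[outcome]]
  if (is.null(ids)) {
    pb_abort(sprintf("unknown outcome '%s'", outcome), "pb_config_error")
  }
  ids
}

#' Scan units for association with disease
#'
#' Fits, for every unit of a carrier matrix and every requested outcome, a
#' Firth penalized-likelihood logistic regression of case status on carrier
#' status with covariate adjustment (default: age in years, continuous, and
#' first-degree family history). Outcome-specific case sets (ER-positive,
#' ER-negative, triple-negative) are compared against the full control
#' group. Units with no carriers among the analysed subjects are skipped, as
#' are subjects missing an adjustment covariate or, for subtype outcomes,
#' the required markers (listwise deletion per fit).
#'
#' @param cm A carrier matrix ([build_carrier_matrix()] or
#'   [as_carrier_matrix()]).
#' @param phenotypes Phenotype tibble (subject_id, status, age_years,
#'   family_history, er, pr, her2).
#' @param outcomes Subset of `c("overall", "er_pos", "er_neg",
#'   "triple_negative")`.
#' @param adjustment Covariate column names in `phenotypes`; use
#'   `character(0)` for unadjusted fits.
#' @param units Units to scan (default: all columns of `cm`).
#' @param stratum_ids Optional subject ids restricting the analysed subjects
#'   (e.g. a family-history stratum plus all controls).
#' @param stratum Label recorded in the output for such a restriction.
#' @param conf.level Confidence level for Wald intervals.
#' @return A tibble (class `pb_scan`): unit, outcome, stratum,
#'   n_case_carriers, n_control_carriers, n_cases, n_controls, or, ci_low,
#'   ci_high, p_wald, converged, iterations.
#' @export
association_scan <- function(cm, phenotypes,
                             outcomes = "overall",
                             adjustment = c("age_years", "family_history"),
                             units = NULL, stratum_ids = NULL,
                             stratum = NA_character_,
                             conf.level = 0.95) {
  check_cols(phenotypes, c("subject_id", "status"), "phenotype table")
  check_cols(phenotypes, adjustment, "phenotype table")
  units <- units %||% carrier_units(cm)
  bad_units <- setdiff(units, carrier_units(cm))
  if (length(bad_units) > 0) {
    pb_abort(sprintf("unknown unit(s): %s", paste(bad_units, collapse = ", ")),
             "pb_config_error")
  }
  ph <- phenotypes
  if (!is.null(stratum_ids)) ph <- ph[ph$subject_id %in% stratum_ids, ]
  control_ids <- ph$subject_id[ph$status == "control"]
  rows <- list()
  for (oc in outcomes) {
    case_ids <- intersect(outcome_case_ids(phenotypes, oc), ph$subject_id)
    if (length(case_ids) == 0) {
      rlang::warn(sprintf("outcome '%s': no eligible cases; skipped", oc))
      next
    }
    ids <- c(case_ids, control_ids)
    sub <- ph[match(ids, ph$subject_id), c("subject_id", adjustment),
              drop = FALSE]
    sub$y <- as.numeric(sub$subject_id %in% case_ids)
    keep <- stats::complete.cases(sub[, adjustment, drop = FALSE])
    sub <- sub[keep, , drop = FALSE]
    cmi <- match(sub$subject_id, cm$subject_id)
    for (u in units) {
      carrier <- cm[[u]][cmi]
      kc <- sum(carrier[sub$y == 1])
      kk <- sum(carrier[sub$y == 0])
      if (kc + kk == 0) next
      X <- cbind(`(Intercept)` = 1, carrier = carrier)
      for (cv in adjustment) X <- cbind(X, sub[[cv]])
      colnames(X) <- c("(Intercept)", "carrier", adjustment)
      fit <- tryCatch(fit_firth(X, sub$y),
                      error = function(e) NULL)
      if (is.null(fit)) next
      wi <- if (fit$converged) wald_inference(fit, "carrier", conf.level) else {
        tibble::tibble(term = "carrier", or = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, p_wald = NA_real_)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        unit = u, outcome = oc, stratum = stratum,
        n_case_carriers = kc, n_control_carriers = kk,
        n_cases = sum(sub$y == 1), n_controls = sum(sub$y == 0),
        or = wi$or, ci_low = wi$ci_low, ci_high = wi$ci_high,
        p_wald = wi$p_wald,
        converged = fit$converged, iterations = fit$iterations
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      unit = character(), outcome = character(), stratum = character(),
      n_case_carriers = integer(), n_control_carriers = integer(),
      n_cases = integer(), n_controls = integer(),
      or = double(), ci_low = double(), ci_high = double(),
      p_wald = double(), converged = logical(), iterations = integer()
    )
  }
  structure(out, class = c("pb_scan", class(out)))
}

#' Carrier-by-age interaction (age trend of the odds ratio)
#'
#' Firth fit of case status on carrier, age, family history and the
#' carrier-by-age interaction, with age centred at a reference (default 50
#' years). Returns the per-year odds-ratio multiplier
#' `exp(beta_interaction)` with its Wald interval, and the implied
#' age-specific odds-ratio function
#' `OR(t) = exp(beta_carrier + beta_int * (t - t_ref))` for cumulative-risk
#' estimation. The multiplier is invariant to the choice of reference age;
#' only the carrier main effect is re-anchored.
#'
#' @param cm Carrier matrix.
#' @param phenotypes Phenotype tibble.
#' @param unit Unit (column of `cm`) to model.
#' @param age_ref Reference age in years.
#' @param adjust_fh Include family history as a covariate.
#' @param conf.level Confidence level.
#' @return A list of class `pb_age_trend`: `multiplier`, `ci_low`,
#'   `ci_high`, `p_wald` (per-year OR multiplier scale), `or_at_ref` (OR at
#'   the reference age) with `or_at_ref_ci`, `age_ref`, `or_function`
#'   (vectorised over age), `fit` (the underlying `firth_fit`), and
#'   `n_carriers`.
#' @export
fit_age_trend <- function(cm, phenotypes, unit, age_ref = 50,
                          adjust_fh = TRUE, conf.level = 0.95) {
  check_cols(phenotypes, c("subject_id", "status", "age_years"),
             "phenotype table")
  if (!unit %in% carrier_units(cm)) {
    pb_abort(sprintf("unknown unit '%s'", unit), "pb_config_error")
  }
  ph <- phenotypes
  carrier <- cm[[unit]][match(ph$subject_id, cm$subject_id)]
  if (sum(carrier, na.rm = TRUE) < 2) {
    pb_abort("age trend needs at least 2 carriers", "pb_model_error")
  }
  dat <- tibble::tibble(
    y = as.numeric(ph$status == "case"),
    carrier = carrier,
    age_c = ph$age_years - age_ref
  )
  covs <- c("carrier", "age_c")
  if (adjust_fh) {
    check_cols(ph, "family_history", "phenotype table")
    dat$family_history <- ph$family_history
    covs <- c(covs, "family_history")
  }
  dat$carrier_age <- dat$carrier * dat$age_c
  covs <- c(covs, "carrier_age")
  dat <- dat[stats::complete.cases(dat), ]
  X <- cbind(`(Intercept)` = 1, as.matrix(dat[covs]))
  fit <- fit_firth(X, dat$y)
  wi_int <- wald_inference(fit, "carrier_age", conf.level)
  wi_car <- wald_inference(fit, "carrier", conf.level)
  b_car <- unname(fit$beta["carrier"])
  b_int <- unname(fit$beta["carrier_age"])
  structure(
    list(
      unit = unit,
      multiplier = wi_int$or,
      ci_low = wi_int$ci_low, ci_high = wi_int$ci_high,
      p_wald = wi_int$p_wald,
      or_at_ref = wi_car$or,
      or_at_ref_ci = c(wi_car$ci_low, wi_car$ci_high),
      age_ref = age_ref,
      or_function = function(t) exp(b_car + b_int * (t - age_ref)),
      fit = fit,
      n_carriers = sum(dat$carrier)
    ),
    class = "pb_age_trend"
  )
}

#' @export
print.pb_age_trend <- function(x, ...) {
  cat(sprintf(
    "Age trend for %s: per-year OR multiplier %.3f (%.3f-%.3f), p = %.3g\n",
    x$unit, x$multiplier, x$ci_low, x$ci_high, x$p_wald
  ))
  cat(sprintf("OR at age %g: %.2f (%.2f-%.2f), %d carriers\n",
              x$age_ref, x$or_at_ref, x$or_at_ref_ci[1], x$or_at_ref_ci[2],
              x$n_carriers))
  invisible(x)
}
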