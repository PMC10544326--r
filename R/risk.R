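## Cumulative (absolute) risk from age-specific odds ratios and population
## incidence, by the constrained-incidence recursion: carrier and non-carrier
## hazards are chosen so that, band by band, the population incidence equals
## the survivor-weighted mixture of the two, with the carrier hazard RR times
## the non-carrier hazard (rare-disease approximation RR ~= OR).

check_incidence <- function(inc) {
  inc <- tibble::as_tibble(inc)
  check_cols(inc, c("age_start", "age_end", "rate_per_py"), "incidence table")
  inc <- dplyr::arrange(inc, .data$age_start)
  if (nrow(inc) == 0 || inc$age_start[1] != 0 ||
      any(inc$age_start[-1] != inc$age_end[-nrow(inc)])) {
    pb_abort("incidence bands must be contiguous from age 0", "pb_schema_error")
  }
  if (any(inc$rate_per_py < 0) || any(is.na(inc$rate_per_py))) {
    pb_abort("incidence rates must be non-negative", "pb_schema_error")
  }
  inc
}

as_or_function <- function(or_fn) {
  if (is.function(or_fn)) return(or_fn)
  if (is.numeric(or_fn) && length(or_fn) == 1L && or_fn > 0) {
    force(or_fn)
    return(function(t) rep(or_fn, length(t)))
  }
  pb_abort("`or_fn` must be a positive scalar or a function of age",
           "pb_config_error")
}

#' Constrained carrier and non-carrier hazards
#'
#' Forward band-by-band recursion maintaining disease-free survivor
#' fractions S1 (carriers) and S0 (non-carriers), both 1 at age 0. In each
#' band the non-carrier hazard is
#' `lambda0 = lambda_pop * (f*S1 + (1-f)*S0) / (f*S1*RR + (1-f)*S0)` and the
#' carrier hazard `lambda1 = RR * lambda0`, after which survivor fractions
#' are updated by `S <- S * exp(-lambda * width)`. This constrains the
#' survivor-weighted mixture of the two hazards to reproduce the population
#' incidence exactly in every band.
#'
#' @param or_fn Age-specific odds ratio: positive scalar or function of age
#'   (evaluated at band midpoints); used as the rate ratio under the
#'   rare-disease approximation.
#' @param incidence Incidence table (age_start, age_end, rate_per_py),
#'   contiguous from age 0.
#' @param f Carrier frequency at birth, in `[0, 1)`.
#' @return Tibble: age_start, age_end, rate_pop, rr, hazard_carrier,
#'   hazard_noncarrier, surv_carrier, surv_noncarrier (survivor fractions at
#'   the band start).
#' @export
constrained_baseline <- function(or_fn, incidence, f) {
  inc <- check_incidence(incidence)
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f >= 1) {
    pb_abort("`f` must be a carrier frequency in [0, 1)", "pb_config_error")
  }
  or_fn <- as_or_function(or_fn)
  nb <- nrow(inc)
  mid <- (inc$age_start + inc$age_end) / 2
  rr <- or_fn(mid)
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    pb_abort("odds ratios must be positive and finite", "pb_config_error")
  }
  width <- inc$age_end - inc$age_start
  l0 <- l1 <- s1 <- s0 <- numeric(nb)
  S1 <- S0 <- 1
  for (b in seq_len(nb)) {
    s1[b] <- S1
    s0[b] <- S0
    mix <- f * S1 + (1 - f) * S0
    l0[b] <- inc$rate_per_py[b] * mix / (f * S1 * rr[b] + (1 - f) * S0)
    l1[b] <- rr[b] * l0[b]
    S1 <- S1 * exp(-l1[b] * width[b])
    S0 <- S0 * exp(-l0[b] * width[b])
  }
  strained <- which(inc$rate_per_py * rr * width > 0.1)
  if (length(strained) > 0) {
    rlang::warn(sprintf(
      "incidence x RR x width exceeds 0.1 in %d band(s) (first: [%g,%g)); the rare-disease approximation RR ~= OR is strained there",
      length(strained), inc$age_start[strained[1]], inc$age_end[strained[1]]
    ))
  }
  tibble::tibble(
    age_start = inc$age_start, age_end = inc$age_end,
    rate_pop = inc$rate_per_py, rr = rr,
    hazard_carrier = l1, hazard_noncarrier = l0,
    surv_carrier = s1, surv_noncarrier = s0
  )
}

#' Cumulative risk curve for carriers
#'
#' Converts an odds ratio (optionally with a per-year age multiplier, as
#' from [fit_age_trend()]) and a population incidence table into carrier and
#' non-carrier cumulative risk curves, `F(T) = 1 - exp(-sum lambda * width)`
#' over bands below T. The confidence band re-runs the whole recursion at
#' the odds ratio's interval bounds (plug-in propagation).
#'
#' @param or Odds-ratio point estimate (at the reference age when a
#'   multiplier is given).
#' @param ci_low,ci_high Optional confidence bounds for `or`.
#' @param or_age_multiplier Optional per-year OR multiplier; the OR then
#'   varies log-linearly with age around `age_ref`.
#' @param incidence Incidence table (age_start, age_end, rate_per_py).
#' @param f Carrier frequency at birth.
#' @param age_ref Reference age for the age-varying OR.
#' @return A tibble (class `pb_risk_curve`): age (band ends), risk_carrier,
#'   risk_noncarrier, risk_population, ci_low, ci_high; attribute `f`.
#' @examples
#' inc <- generate_incidence_table("bc_like")
#' curve <- cumulative_risk_curve(9.75, 1.81, 52.69, incidence = inc, f = 0.001)
#' curve[curve$age == 80, ]
#' @export
cumulative_risk_curve <- function(or, ci_low = NULL, ci_high = NULL,
                                  or_age_multiplier = NULL,
                                  incidence, f, age_ref = 50) {
  make_fn <- function(o) {
    if (is.null(or_age_multiplier)) {
      as_or_function(o)
    } else {
      function(t) o * or_age_multiplier^(t - age_ref)
    }
  }
  inc <- check_incidence(incidence)
  width <- inc$age_end - inc$age_start
  risk_from <- function(o) {
    hz <- constrained_baseline(make_fn(o), inc, f)
    list(
      carrier = 1 - exp(-cumsum(hz$hazard_carrier * width)),
      noncarrier = 1 - exp(-cumsum(hz$hazard_noncarrier * width))
    )
  }
  point <- risk_from(or)
  lo <- if (!is.null(ci_low)) risk_from(ci_low)$carrier else rep(NA_real_, nrow(inc))
  hi <- if (!is.null(ci_high)) risk_from(ci_high)$carrier else rep(NA_real_, nrow(inc))
  out <- tibble::tibble(
    age = inc$age_end,
    risk_carrier = point$carrier,
    risk_noncarrier = point$noncarrier,
    risk_population = 1 - exp(-cumsum(inc$rate_per_py * width)),
    ci_low = lo, ci_high = hi
  )
  structure(out, class = c("pb_risk_curve", class(out)),
            f = f, or = or)
}

#' Classify risk curves against a high-risk threshold
#'
#' Labels each curve high-risk or not according to whether the carrier
#' cumulative risk at the threshold age reaches the threshold (default: the
#' 30 percent-by-age-80 surveillance threshold).
#'
#' @param curves A named list of `pb_risk_curve` objects (names = units), or
#'   a single curve.
#' @param threshold Risk threshold in `[0, 1]`.
#' @param age Threshold age; each curve must extend to it.
#' @return Tibble: unit, risk_at_age, threshold, high_risk.
#' @export
threshold_report <- function(curves, threshold = 0.30, age = 80) {
  if (inherits(curves, "pb_risk_curve")) curves <- list(curve = curves)
  rows <- lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    if (max(cv$age) < age) {
      pb_abort(sprintf("curve '%s' ends at age %g, before threshold age %g",
                       nm, max(cv$age), age),
               "pb_config_error")
    }
    r <- cv$risk_carrier[which.min(abs(cv$age - age))]
    tibble::tibble(unit = nm, risk_at_age = r, threshold = threshold,
                   high_risk = r >= threshold)
  })
  dplyr::bind_rows(rows)
}
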