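## Internal helpers shared across modules.

## stop with a classed condition so callers/tests can match on class
pb_abort <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "panelburden_error"), ...)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    pb_abort(
      sprintf("`%s` must be a single probability in [0, 1], got %s",
              field, deparse(substitute(x))),
      "pb_config_error"
    )
  }
  invisible(x)
}

check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x != round(x)) {
    pb_abort(sprintf("`%s` must be a positive integer count", field),
             "pb_config_error")
  }
  invisible(as.integer(x))
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    pb_abort(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      "pb_schema_error"
    )
  }
  invisible(df)
}

## Numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 30
  out[big] <- x[big]
  out[!big] <- log1p(exp(x[!big]))
  out
}

## Derive a child RNG seed from a master seed and a stream label, so each
## generated table has its own stream and adding one does not perturb others.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
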