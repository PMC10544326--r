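## Firth bias-reduced penalized-likelihood logistic regression.
##
## Maximizes the Jeffreys-prior-penalized binomial log-likelihood
##   l*(beta) = l(beta) + 1/2 log det I(beta),  I(beta) = X' W X,
##   W = diag(pi_i (1 - pi_i)),
## by Newton-Raphson on the modified score
##   U*_r(beta) = sum_i (y_i - pi_i + h_i (1/2 - pi_i)) x_ir,
## where h_i are the diagonal elements of the hat matrix
##   H = W^{1/2} X (X'WX)^{-1} X' W^{1/2}.
## Step-halving is applied whenever a Newton step fails to increase l*.
## The penalty keeps estimates finite even under complete separation, where
## ordinary maximum likelihood diverges.

firth_quantities <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  pi <- plogis(eta)
  w <- pi * (1 - pi)
  XW <- X * w
  info <- crossprod(X, XW)
  ch <- tryCatch(chol(info), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  # h = diag(W^{1/2} X info^{-1} X' W^{1/2})
  Xs <- X * sqrt(w)
  V <- backsolve(ch, forwardsolve(t(ch), t(Xs)))
  h <- colSums(V * t(Xs))
  score <- drop(crossprod(X, y - pi + h * (0.5 - pi)))
  pll <- sum(y * eta - log1pexp(eta)) + sum(log(diag(ch)))
  list(pi = pi, w = w, info = info, chol = ch, h = h,
       score = score, pll = pll)
}

#' Fit Firth penalized-likelihood logistic regression
#'
#' @param X Design matrix including the intercept column; must have full
#'   column rank.
#' @param y Binary response vector (0/1).
#' @param tol Convergence tolerance on the maximum absolute modified score.
#' @param xtol Secondary stopping rule: the fit is also declared converged
#'   when a full Newton step changes no coefficient by more than `xtol`
#'   (the step is still taken, so the remaining error is of order `xtol`
#'   squared). This catches the case where rounding noise in the score sum
#'   floors `max |U*|` just above `tol` on large design matrices.
#' @param max_iter Maximum Newton iterations.
#' @param max_halvings Maximum step-halvings per iteration.
#' @return An object of class `firth_fit`: `beta` (named coefficients, log
#'   odds units), `cov` (inverse penalized information at the optimum),
#'   `penalized_loglik`, `iterations`, `converged`, `max_score_norm`, `n`.
#'   Non-convergence returns the fit with `converged = FALSE` and a warning.
#' @examples
#' X <- cbind(1, c(rep(1, 5), rep(0, 15)))
#' y <- c(rep(1, 5), rep(0, 15))  # complete separation
#' fit <- fit_firth(X, y)
#' fit$converged; fit$beta
#' @export
fit_firth <- function(X, y, tol = 1e-6, xtol = 1e-6, max_iter = 100L,
                      max_halvings = 25L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) {
    pb_abort("`y` must be binary 0/1", "pb_model_error")
  }
  if (nrow(X) != length(y)) {
    pb_abort("nrow(X) must equal length(y)", "pb_model_error")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]] %||%
      qrX$pivot[(qrX$rank + 1):ncol(X)]
    pb_abort(sprintf("design matrix is rank deficient; collinear column(s): %s",
                     paste(dep, collapse = ", ")),
             "pb_rank_error")
  }
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  beta <- rep(0, p)
  q <- firth_quantities(X, y, beta)
  if (is.null(q)) pb_abort("singular information at start", "pb_model_error")
  iter <- 0L
  converged <- FALSE
  repeat {
    if (max(abs(q$score)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    iter <- iter + 1L
    delta <- backsolve(q$chol, forwardsolve(t(q$chol), q$score))
    if (max(abs(delta)) < xtol) {
      qc <- firth_quantities(X, y, beta + delta)
      if (!is.null(qc)) {
        beta <- beta + delta
        q <- qc
      }
      converged <- TRUE
      break
    }
    if (max(abs(q$score)) < 1e-3) {
      # near the optimum Newton is contractive and the penalized likelihood
      # differences fall below floating-point noise; take the full step
      qc <- firth_quantities(X, y, beta + delta)
      if (!is.null(qc)) {
        beta <- beta + delta
        q <- qc
        next
      }
    }
    step <- 1
    for (half in 0:max_halvings) {
      cand <- beta + step * delta
      qc <- firth_quantities(X, y, cand)
      if (!is.null(qc) && is.finite(qc$pll) && qc$pll > q$pll - 1e-12) {
        beta <- cand
        q <- qc
        break
      }
      step <- step / 2
    }
  }
  if (!converged) {
    rlang::warn(sprintf(
      "Firth fit did not converge in %d iterations (max |U*| = %.3g)",
      max_iter, max(abs(q$score))
    ))
  }
  cov <- chol2inv(q$chol)
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(
    list(
      beta = setNames(beta, colnames(X)),
      cov = cov,
      penalized_loglik = q$pll,
      iterations = iter,
      converged = converged,
      max_score_norm = max(abs(q$score)),
      n = length(y)
    ),
    class = "firth_fit"
  )
}

#' Formula interface to the Firth fit
#'
#' @param formula Model formula with a binary (0/1 or case/control factor)
#'   response.
#' @param data Data frame; rows with missing model variables are dropped.
#' @param ... Passed to [fit_firth()].
#' @return A `firth_fit` object (see [fit_firth()]).
#' @export
firth_glm <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.numeric(y) - 1
  if (is.character(y)) y <- as.numeric(y == "case")
  X <- stats::model.matrix(formula, mf)
  fit_firth(X, y, ...)
}

#' @export
print.firth_fit <- function(x, ...) {
  cat(sprintf(
    "Firth penalized-likelihood logistic fit (n = %d, %s in %d iterations)\n",
    x$n, if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  print(tidy.firth_fit(x))
  invisible(x)
}

#' Tidy a Firth fit
#'
#' One row per coefficient with Wald standard errors, z statistics, two-sided
#' p values and (optionally) Wald confidence bounds on the log-odds scale.
#'
#' @param x A `firth_fit`.
#' @param conf.int Add `conf.low`/`conf.high` columns.
#' @param conf.level Confidence level for the Wald interval.
#' @param ... Unused.
#' @return A tibble with columns term, estimate, std.error, statistic,
#'   p.value.
#' @method tidy firth_fit
#' @export
tidy.firth_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$cov))
  z <- x$beta / se
  out <- tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * pnorm(-abs(unname(z)))
  )
  if (isTRUE(conf.int)) {
    zq <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - zq * out$std.error
    out$conf.high <- out$estimate + zq * out$std.error
  }
  out
}

#' Glance at a Firth fit
#'
#' @param x A `firth_fit`.
#' @param ... Unused.
#' @return One-row tibble: penalized_loglik, iterations, converged,
#'   max_score_norm, nobs.
#' @method glance firth_fit
#' @export
glance.firth_fit <- function(x, ...) {
  tibble::tibble(
    penalized_loglik = x$penalized_loglik,
    iterations = x$iterations,
    converged = x$converged,
    max_score_norm = x$max_score_norm,
    nobs = x$n
  )
}

#' Wald inference for one coefficient on the odds-ratio scale
#'
#' Computes `exp(beta_j)` with the Wald interval `exp(beta_j +/- z * SE_j)`
#' and the two-sided normal-reference p value, as used for the association
#' scans.
#'
#' @param fit A converged `firth_fit`.
#' @param index Coefficient name or position.
#' @param conf.level Confidence level.
#' @return One-row tibble: term, or, ci_low, ci_high, p_wald.
#' @export
wald_inference <- function(fit, index, conf.level = 0.95) {
  if (!inherits(fit, "firth_fit")) {
    pb_abort("`fit` must be a firth_fit", "pb_model_error")
  }
  if (!fit$converged) {
    pb_abort("Wald inference requires a converged fit", "pb_model_error")
  }
  if (is.character(index)) index <- match(index, names(fit$beta))
  if (is.na(index) || index < 1 || index > length(fit$beta)) {
    pb_abort("`index` does not name a coefficient", "pb_model_error")
  }
  b <- fit$beta[index]
  se <- sqrt(fit$cov[index, index])
  zq <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(fit$beta)[index],
    or = exp(unname(b)),
    ci_low = exp(unname(b) - zq * se),
    ci_high = exp(unname(b) + zq * se),
    p_wald = 2 * pnorm(-abs(unname(b) / se))
  )
}
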