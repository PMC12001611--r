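#' Intervention effect table
#'
#' Summarises a fitted segmented regression as the six interpretable
#' quantities, in fixed order: baseline level, pre-intervention trend,
#' difference in intercepts, immediate effect (change in levels at
#' intervention onset), gradual effect (change in slopes), and
#' post-intervention trend. Each row carries the estimate, its standard
#' error (from the full coefficient covariance, so linear combinations such
#' as the immediate effect under the Bernal parametrization are handled
#' correctly), the t statistic, residual degrees of freedom, and a
#' two-sided p-value.
#'
#' The table is numerically identical whichever parametrization was fitted:
#' the two parametrizations describe the same pre/post lines, and each row
#' maps to the appropriate coefficient or combination under the fitted tag.
#' In particular the immediate effect is `beta_2 + delta * beta_3` under
#' Bernal but `beta_2` directly under Wagner, while the difference in
#' intercepts is `beta_2` under Bernal but `beta_2 - delta * beta_3` under
#' Wagner. Conflating the two is the classic misinterpretation this package
#' guards against: they differ whenever the slope changes (`beta_3 != 0`)
#' and `delta != 0`.
#'
#' For an exact (zero-residual) fit all standard errors are 0 and p-values
#' are reported as `NA` with `exact_fit = TRUE`, not as 0.
#'
#' @param fit An [its_fit()] object.
#' @return A tibble of class `its_effects` with columns `label`, `estimate`,
#'   `se`, `statistic`, `df`, `p.value`, `exact_fit`, and attributes
#'   `parametrization`, `delta`, `m`, `n`.
#'
#' @examples
#' d <- its_data(data.frame(t = 0:5, y = c(0, 1, 2, 3, 5, 7)), t, y, delta = 3)
#' its_effects(its_fit(d, "bernal"))
#' @export
its_effects <- function(fit) {
  stopifnot(inherits(fit, "its_fit"))
  rows <- dplyr::bind_rows(
    effect_row(fit, "baseline level", c(1, 0, 0, 0)),
    trend_estimates(fit)[1, ],
    difference_in_intercepts(fit),
    immediate_effect(fit),
    gradual_effect(fit),
    trend_estimates(fit)[2, ]
  )
  structure(rows,
            parametrization = fit$parametrization,
            delta = fit$delta, m = fit$m, n = fit$n,
            class = c("its_effects", class(rows)))
}

# one labeled effect row from a weight vector on the coefficients
effect_row <- function(fit, label, weights) {
  est <- drop(crossprod(weights, fit$beta))
  se <- linear_combination_se(fit, weights)
  # fits rebuilt from published coefficients may lack a covariance matrix:
  # point estimates stand, inference columns are NA
  tst <- if (is.na(se) || is.na(fit$df)) {
    list(statistic = NA_real_, p.value = NA_real_, exact_fit = FALSE)
  } else {
    t_test(est, se, fit$df)
  }
  tibble::tibble(
    label = label, estimate = est, se = se,
    statistic = tst$statistic, df = fit$df, p.value = tst$p.value,
    exact_fit = tst$exact_fit
  )
}

#' Immediate effect (change in levels at intervention onset)
#'
#' The difference between the post- and pre-intervention model means at
#' `T = delta`. Equals `beta_2 + delta * beta_3` under the Bernal
#' parametrization and `beta_2` under Wagner; the value is identical either
#' way on the same data.
#'
#' @param fit An [its_fit()] object.
#' @return A one-row effect tibble (see [its_effects()]).
#' @export
immediate_effect <- function(fit) {
  w <- switch(fit$parametrization,
    bernal = c(0, 0, 1, fit$delta),
    wagner = c(0, 0, 1, 0)
  )
  effect_row(fit, "immediate effect", w)
}

#' Gradual effect (change in slopes)
#'
#' `beta_3`, the difference between the post- and pre-intervention trends;
#' identical under both parametrizations.
#'
#' @inheritParams immediate_effect
#' @return A one-row effect tibble.
#' @export
gradual_effect <- function(fit) {
  effect_row(fit, "gradual effect", c(0, 0, 0, 1))
}

#' Difference in intercepts between the pre- and post-intervention lines
#'
#' The vertical gap between the two fitted lines at `T = 0` (not at the
#' intervention time). Equals `beta_2` under the Bernal parametrization and
#' `beta_2 - delta * beta_3` under Wagner.
#'
#' @inheritParams immediate_effect
#' @return A one-row effect tibble.
#' @export
difference_in_intercepts <- function(fit) {
  w <- switch(fit$parametrization,
    bernal = c(0, 0, 1, 0),
    wagner = c(0, 0, 1, -fit$delta)
  )
  effect_row(fit, "difference in intercepts", w)
}

#' Pre- and post-intervention trends
#'
#' Pre-intervention trend is `beta_1`; post-intervention trend is
#' `beta_1 + beta_3` (identical under both parametrizations).
#'
#' @inheritParams immediate_effect
#' @return A two-row effect tibble (pre-intervention trend first).
#' @export
trend_estimates <- function(fit) {
  dplyr::bind_rows(
    effect_row(fit, "pre-intervention trend", c(0, 1, 0, 0)),
    effect_row(fit, "post-intervention trend", c(0, 1, 0, 1))
  )
}

#' Standard error of a linear combination of coefficients
#'
#' `sqrt(w' Sigma w)` for weight vector `w` on
#' `(beta_0, beta_1, beta_2, beta_3)`, using the full 4x4 coefficient
#' covariance. Reduces to the coefficient standard error for a unit weight
#' vector. This is how the package obtains standard errors for quantities
#' that are combinations of coefficients (immediate effect under Bernal,
#' difference in intercepts under Wagner, post-intervention trend).
#'
#' @param fit An [its_fit()] object.
#' @param weights Numeric 4-vector of weights.
#' @return Nonnegative standard error.
#' @export
linear_combination_se <- function(fit, weights) {
  stopifnot(inherits(fit, "its_fit"))
  weights <- as.numeric(weights)
  if (length(weights) != 4L || !all(is.finite(weights))) {
    stop("`weights` must be 4 finite numbers", call. = FALSE)
  }
  v <- drop(crossprod(weights, fit$vcov %*% weights))
  if (is.na(v)) return(NA_real_) # no covariance available
  sqrt(max(v, 0)) # clamp tiny negative round-off
}

#' Two-sided t test for an effect estimate
#'
#' `p = 2 * P(T_df >= |estimate/se|)` with the residual degrees of freedom
#' `N - 4`. A zero standard error signals an exact (zero-residual) fit: the
#' p-value is undefined and returned as `NA` with `exact_fit = TRUE`, never
#' as 0.
#'
#' @param estimate Effect estimate.
#' @param se Standard error (>= 0).
#' @param df Residual degrees of freedom (>= 1).
#' @return List with `statistic`, `p.value`, `exact_fit`.
#' @export
t_test <- function(estimate, se, df) {
  stopifnot(df >= 1, se >= 0)
  if (se == 0) {
    return(list(statistic = NA_real_, p.value = NA_real_, exact_fit = TRUE))
  }
  tstat <- estimate / se
  list(statistic = tstat,
       p.value = 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE),
       exact_fit = FALSE)
}

#' Re-express a fit under the other parametrization
#'
#' Maps a fitted model between the Bernal and Wagner parametrizations using
#' the identity `beta_2^W = beta_2^B + delta * beta_3`. Coefficients
#' `beta_0`, `beta_1`, `beta_3` are unchanged; the covariance is transformed
#' as `J Sigma J'` where `J` is the identity except that row 3 gains
#' `+/- delta` in column 4. The result equals a direct refit under the other
#' design matrix, and converting twice returns the original fit.
#'
#' @param fit An [its_fit()] object.
#' @return An `its_fit` object under the other parametrization.
#' @export
convert_parametrization <- function(fit) {
  stopifnot(inherits(fit, "its_fit"))
  to <- if (fit$parametrization == "bernal") "wagner" else "bernal"
  s <- if (to == "wagner") fit$delta else -fit$delta
  J <- diag(4)
  J[3, 4] <- s
  beta <- drop(J %*% fit$beta)
  names(beta) <- names(fit$beta)
  vcov <- J %*% fit$vcov %*% t(J)
  dimnames(vcov) <- dimnames(fit$vcov)
  out <- fit
  out$parametrization <- to
  out$beta <- beta
  out$vcov <- vcov
  out
}

#' @export
print.its_effects <- function(x, digits = 4, ...) {
  cat("Intervention effect table (", attr(x, "parametrization"),
      " parametrization; delta = ", attr(x, "delta"),
      ", m = ", attr(x, "m"), ", n = ", attr(x, "n"), ")\n", sep = "")
  NextMethod()
}
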