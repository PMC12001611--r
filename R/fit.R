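#' Fit a segmented regression to an interrupted time series
#'
#' Estimates the four-coefficient segmented regression
#' \deqn{y_t = \beta_0 + \beta_1 T + \beta_2 X_t + \beta_3 Z_t}
#' where `X_t` is the post-intervention indicator and the interaction `Z_t`
#' is `X_t T` (Bernal parametrization) or `X_t (T - delta)` (Wagner
#' parametrization). The two parametrizations describe the same pair of
#' fitted pre/post lines; only the meaning of `beta_2` changes: it is the
#' difference in intercepts at `T = 0` under Bernal, and the immediate
#' change in level at `T = delta` under Wagner.
#'
#' The default `method = "closed_form"` evaluates the ordinary-algebra
#' estimators: `beta_0` and `beta_1` come from the pre-intervention segment
#' sums alone, `beta_3` is the difference between the post- and pre-segment
#' simple-regression slopes, and `beta_2` follows from the segment
#' intercepts. Coefficient variances use the matching closed forms; the
#' off-diagonal covariances (needed for standard errors of linear
#' combinations such as the immediate effect under Bernal) come from the
#' full matrix expression `sigma2 * solve(t(X) %*% X)`. The closed-form path
#' is cross-checked against the matrix solution at 1e-8 relative tolerance
#' on every call and stops on any discrepancy. `method = "matrix"` returns
#' the QR-based normal-equation solution directly.
#'
#' @param data An [its_data()] object (or a plain data frame together with
#'   `...` arguments forwarded to [its_data()]).
#' @param parametrization `"bernal"` or `"wagner"`.
#' @param method `"closed_form"` (default) or `"matrix"`.
#' @param ... When `data` is not yet an `its_data`, forwarded to
#'   [its_data()] (e.g. `time`, `outcome`, `delta`).
#'
#' @return An object of class `its_fit`: a list with elements
#'   `parametrization`, `beta` (named 4-vector), `vcov` (4x4 covariance
#'   matrix), `sigma2` (residual variance, RSS/(N-4)), `df` (N-4), `delta`,
#'   `m`, `n`, `fitted`, `residuals`, `data` and `method`.
#'
#' @examples
#' df <- data.frame(t = 0:5, y = c(0, 1, 2, 3, 5, 7))
#' fit <- its_fit(its_data(df, t, y, delta = 3), "bernal")
#' coef(fit)
#' @export
its_fit <- function(data, parametrization = c("bernal", "wagner"),
                    method = c("closed_form", "matrix"), ...) {
  if (!inherits(data, "its_data")) data <- its_data(data, ...)
  parametrization <- match.arg(parametrization)
  method <- match.arg(method)
  switch(method,
    matrix = fit_ols_matrix(data, parametrization),
    closed_form = fit_closed_form(data, parametrization)
  )
}

#' Matrix ordinary least squares fit
#'
#' Solves the normal equations for the chosen design matrix via a QR
#' decomposition, returning `beta = (X'X)^{-1} X'y`, residual variance
#' `sigma2 = RSS / (N - 4)` and covariance `sigma2 * (X'X)^{-1}`. This is
#' the reference path the closed-form estimators are checked against, and
#' the only source of off-diagonal covariances.
#'
#' @inheritParams its_fit
#' @return An `its_fit` object; see [its_fit()].
#' @export
fit_ols_matrix <- function(data, parametrization = c("bernal", "wagner")) {
  stopifnot(inherits(data, "its_data"))
  parametrization <- match.arg(parametrization)
  X <- its_design_matrix(data, parametrization)
  y <- data$outcome
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient; segmented regression is not identifiable",
         call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  df <- nrow(X) - ncol(X)
  sigma2 <- estimate_sigma2(resid, nrow(X), ncol(X))
  xtx_inv <- matrix(NA_real_, ncol(X), ncol(X))
  piv <- qrX$pivot
  xtx_inv[piv, piv] <- chol2inv(qr.R(qrX))
  vcov <- sigma2 * xtx_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  new_its_fit(parametrization, beta, vcov, sigma2, df, data, fitted, resid,
              method = "matrix")
}

#' Closed-form segmented regression fit
#'
#' Evaluates the ordinary-algebra estimators from per-segment sums (see
#' [segment_summaries()]): the pre-segment simple regression gives
#' `beta_0`, `beta_1`; the post-segment simple regression gives the
#' post-intervention slope and intercept, from which `beta_3` (slope
#' difference) and `beta_2` follow, with `beta_2^W = beta_2^B +
#' delta * beta_3`. Diagonal variances use [closed_form_variances()];
#' off-diagonals are completed from the matrix covariance. Agreement with
#' [fit_ols_matrix()] is asserted at 1e-8 relative tolerance.
#'
#' @inheritParams its_fit
#' @return An `its_fit` object; see [its_fit()].
#' @export
fit_closed_form <- function(data, parametrization = c("bernal", "wagner")) {
  stopifnot(inherits(data, "its_data"))
  parametrization <- match.arg(parametrization)
  delta <- attr(data, "delta")
  ss <- segment_summaries(data)
  pre <- ss[ss$segment == "pre", ]
  post <- ss[ss$segment == "post", ]
  if (pre$centered_ss <= 0 || post$centered_ss <= 0) {
    stop("zero centered sum of squares in a segment; slope not estimable",
         call. = FALSE)
  }

  # simple-regression intercept/slope per segment from raw sums
  den_pre <- pre$sum_t^2 - pre$count * pre$sum_t2   # = -m * centered_ss_pre
  den_post <- post$sum_t^2 - post$count * post$sum_t2
  b0 <- (pre$sum_ty * pre$sum_t - pre$sum_y * pre$sum_t2) / den_pre
  b1 <- (pre$sum_t * pre$sum_y - pre$count * pre$sum_ty) / den_pre
  slope_post <- (post$sum_t * post$sum_y - post$count * post$sum_ty) / den_post
  intercept_post <- (post$sum_ty * post$sum_t - post$sum_y * post$sum_t2) / den_post
  b3 <- slope_post - b1
  b2_bernal <- intercept_post - b0
  b2 <- switch(parametrization,
    bernal = b2_bernal,
    wagner = b2_bernal + delta * b3
  )
  beta <- c("(Intercept)" = b0, time = b1, post = b2, interaction = b3)

  X <- its_design_matrix(data, parametrization)
  fitted <- drop(X %*% beta)
  resid <- data$outcome - fitted
  df <- nrow(X) - 4L
  sigma2 <- estimate_sigma2(resid, nrow(X), 4L)

  cf_var <- closed_form_variances(pre, post, sigma2, delta)
  diag_cf <- c(cf_var[["var_beta0"]], cf_var[["var_beta1"]],
               switch(parametrization,
                      bernal = cf_var[["var_beta2_bernal"]],
                      wagner = cf_var[["var_beta2_wagner"]]),
               cf_var[["var_beta3"]])

  oracle <- fit_ols_matrix(data, parametrization)
  check_close(beta, oracle$beta, 1e-8,
              "closed-form coefficients disagree with the matrix solution")
  check_close(diag_cf, diag(oracle$vcov), 1e-8,
              "closed-form variances disagree with the matrix covariance diagonal")

  # full covariance: matrix off-diagonals, closed-form diagonal
  vcov <- oracle$vcov
  diag(vcov) <- diag_cf

  new_its_fit(parametrization, beta, vcov, sigma2, df, data, fitted, resid,
              method = "closed_form")
}

# relative agreement guard used by the closed-form self-check
check_close <- function(a, b, tol, msg) {
  scale <- pmax(abs(a), abs(b), 1)
  if (any(abs(a - b) / scale > tol)) {
    stop("internal consistency failure: ", msg, call. = FALSE)
  }
  invisible(TRUE)
}

new_its_fit <- function(parametrization, beta, vcov, sigma2, df, data,
                        fitted, resid, method) {
  structure(
    list(
      parametrization = parametrization,
      beta = beta,
      vcov = vcov,
      sigma2 = sigma2,
      df = df,
      delta = attr(data, "delta"),
      m = attr(data, "m"),
      n = attr(data, "n"),
      fitted = fitted,
      residuals = resid,
      data = data,
      method = method
    ),
    class = "its_fit"
  )
}

#' Residual variance estimate
#'
#' `RSS / (N - p)` with `p` the number of model columns (4 for the
#' segmented regression fits in this package).
#'
#' @param residuals Numeric vector of residuals.
#' @param n_obs Number of observations `N`.
#' @param n_params Number of model columns `p`.
#' @return Nonnegative residual variance.
#' @export
estimate_sigma2 <- function(residuals, n_obs, n_params) {
  stopifnot(length(residuals) == n_obs)
  df <- n_obs - n_params
  if (df < 1) stop("nonpositive residual degrees of freedom", call. = FALSE)
  sum(residuals^2) / df
}

#' Closed-form coefficient variances
#'
#' Evaluates the printed variance formulas for the five coefficient
#' estimators from per-segment sufficient statistics:
#' \itemize{
#'   \item `var(beta0) = sigma2 * sum(t^2_pre) / (m * Spre)`
#'   \item `var(beta1) = sigma2 / Spre`
#'   \item `var(beta3) = sigma2 * (1/Spre + 1/Spost)`
#'   \item `var(beta2^B) = sigma2 * (sum(t^2_pre)/(m*Spre) + sum(t^2_post)/(n*Spost))`
#'   \item `var(beta2^W) = sigma2 * (sum((t-delta)^2_pre)/(m*Spre) +
#'         sum((t-delta)^2_post)/(n*Spost))`
#' }
#' where `Spre`, `Spost` are the centered sums of squares of times in each
#' segment. Each equals the corresponding diagonal entry of
#' `sigma2 * solve(t(X) %*% X)` under the matching parametrization.
#'
#' @param pre,post Single rows of [segment_summaries()] output (pre and post
#'   segment respectively).
#' @param sigma2 Residual variance estimate.
#' @param delta Intervention time.
#' @return Named list with `var_beta0`, `var_beta1`, `var_beta3`,
#'   `var_beta2_bernal`, `var_beta2_wagner`.
#' @export
closed_form_variances <- function(pre, post, sigma2, delta) {
  if (pre$centered_ss <= 0 || post$centered_ss <= 0) {
    stop("zero centered sum of squares in a segment", call. = FALSE)
  }
  stopifnot(sigma2 >= 0)
  # sum((t - delta)^2) recovered from the stored sums
  sum_td2 <- function(s) s$sum_t2 - 2 * delta * s$sum_t + s$count * delta^2
  list(
    var_beta0 = sigma2 * pre$sum_t2 / (pre$count * pre$centered_ss),
    var_beta1 = sigma2 / pre$centered_ss,
    var_beta3 = sigma2 * (1 / pre$centered_ss + 1 / post$centered_ss),
    var_beta2_bernal = sigma2 * (pre$sum_t2 / (pre$count * pre$centered_ss) +
                                   post$sum_t2 / (post$count * post$centered_ss)),
    var_beta2_wagner = sigma2 * (sum_td2(pre) / (pre$count * pre$centered_ss) +
                                   sum_td2(post) / (post$count * post$centered_ss))
  )
}

#' @export
coef.its_fit <- function(object, ...) object$beta

#' @export
vcov.its_fit <- function(object, ...) object$vcov

#' @export
fitted.its_fit <- function(object, ...) object$fitted

#' @export
residuals.its_fit <- function(object, ...) object$residuals

#' @export
print.its_fit <- function(x, digits = 4, ...) {
  cat("Segmented regression fit (", x$parametrization, " parametrization)\n",
      sep = "")
  cat("N =", x$m + x$n, "(m =", x$m, ", n =", x$n, "), delta =", x$delta,
      ", residual df =", x$df, "\n")
  cat("sigma^2 =", signif(x$sigma2, digits), "\n\nCoefficients:\n")
  tab <- cbind(Estimate = x$beta, `Std. Error` = sqrt(diag(x$vcov)))
  print(signif(tab, digits))
  invisible(x)
}

#' Reconstruct a fit from published coefficients
#'
#' Builds an `its_fit` object from coefficient values (and optionally a
#' covariance matrix) reported elsewhere, so the effect machinery —
#' [immediate_effect()], [difference_in_intercepts()],
#' [convert_parametrization()], [its_effects()] — can be applied to
#' published results without the raw data. With no covariance, standard
#' errors and p-values are reported as `NA`; point estimates are exact.
#'
#' @param beta Coefficients `(beta_0, beta_1, beta_2, beta_3)` under
#'   `parametrization`.
#' @param delta Intervention time.
#' @param parametrization `"bernal"` or `"wagner"`.
#' @param vcov Optional 4x4 coefficient covariance matrix.
#' @param df Residual degrees of freedom (needed for p-values).
#' @param m,n Optional segment sizes, for display.
#' @return An `its_fit` object without data, fitted values or residuals.
#' @export
its_fit_from_coef <- function(beta, delta,
                              parametrization = c("bernal", "wagner"),
                              vcov = NULL, df = NA_integer_,
                              m = NA_integer_, n = NA_integer_) {
  parametrization <- match.arg(parametrization)
  stopifnot(length(beta) == 4, all(is.finite(beta)), is.finite(delta))
  nm <- c("(Intercept)", "time", "post", "interaction")
  beta <- stats::setNames(as.numeric(beta), nm)
  if (is.null(vcov)) {
    vcov <- matrix(NA_real_, 4, 4, dimnames = list(nm, nm))
  } else {
    stopifnot(is.matrix(vcov), all(dim(vcov) == 4))
    dimnames(vcov) <- list(nm, nm)
  }
  structure(
    list(parametrization = parametrization, beta = beta, vcov = vcov,
         sigma2 = NA_real_, df = df, delta = delta, m = m, n = n,
         fitted = NULL, residuals = NULL, data = NULL,
         method = "from_coef"),
    class = "its_fit"
  )
}
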