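#' Assemble and validate an interrupted time series dataset
#'
#' Builds the validated single-series dataset that every other function in
#' segits consumes. The series is partitioned at the intervention time
#' `delta`: observations with time `T < delta` form the pre-intervention
#' segment and observations with `T >= delta` form the post-intervention
#' segment. Note the boundary convention: an observation recorded exactly at
#' `delta` belongs to the post-intervention segment. Many applied datasets
#' code the first post-intervention month at `delta`, so this matters.
#'
#' Times are used as given; they need not start at zero, but the baseline
#' level coefficient is always interpreted as the mean outcome at `T = 0`,
#' so the time origin chosen by the analyst determines what "baseline" means.
#' Set `reorigin = TRUE` to shift times so the first observation sits at 0.
#'
#' @param data A data frame with one row per time point.
#' @param time,outcome Columns of `data` holding numeric time and the
#'   continuous outcome (tidy-eval; bare column names).
#' @param delta Intervention time, in the same units as `time`. Exactly one
#'   of `delta` and `indicator` must be supplied.
#' @param indicator Optional column of `data` holding a binary
#'   post-intervention indicator (0 pre, 1 post). `delta` is then inferred as
#'   the earliest time with indicator 1; the indicator must be consistent
#'   with the `T >= delta` rule (monotone 0 to 1 in time).
#' @param reorigin If `TRUE`, subtract the first observation time from all
#'   times (and from `delta`) so the series starts at `T = 0`.
#'
#' @return A tibble of class `its_data` with columns `time`, `outcome` and
#'   `post` (0/1), sorted by time, carrying attributes `delta`, `m` (number
#'   of pre-intervention observations), `n` (post-intervention observations).
#'
#' @examples
#' df <- data.frame(t = 0:5, y = c(1, 1, 1, 2, 2, 2))
#' d <- its_data(df, t, y, delta = 3)
#' attr(d, "m") # 3 pre-intervention points
#' @export
its_data <- function(data, time, outcome, delta = NULL, indicator = NULL,
                     reorigin = FALSE) {
  stopifnot(is.data.frame(data))
  times <- dplyr::pull(data, {{ time }})
  ys <- dplyr::pull(data, {{ outcome }})
  ind_quo <- rlang::enquo(indicator)
  has_ind <- !rlang::quo_is_null(ind_quo)
  if (is.null(delta) && !has_ind) {
    stop("supply exactly one of `delta` or `indicator`", call. = FALSE)
  }
  if (!is.null(delta) && has_ind) {
    stop("supply exactly one of `delta` or `indicator`, not both", call. = FALSE)
  }

  drop <- is.na(ys)
  if (any(drop)) {
    message(sum(drop), " row(s) with missing outcome dropped")
  }

  if (has_ind) {
    ind <- dplyr::pull(data, !!ind_quo)[!drop]
    delta <- infer_delta(times[!drop], ind)
  }
  new_its_data(times[!drop], ys[!drop], delta, reorigin = reorigin)
}

#' Construct an `its_data` object from bare vectors
#'
#' Lower-level constructor behind [its_data()]; performs all validation.
#'
#' @param times Numeric vector of strictly increasing observation times.
#' @param outcomes Numeric vector of outcomes, same length.
#' @param delta Intervention time; `T >= delta` is post-intervention.
#' @param reorigin If `TRUE`, re-origin times at the first observation.
#' @return A tibble of class `its_data`; see [its_data()].
#' @export
new_its_data <- function(times, outcomes, delta, reorigin = FALSE) {
  if (length(times) != length(outcomes)) {
    stop("`times` and `outcomes` must have the same length", call. = FALSE)
  }
  times <- as.double(times)
  outcomes <- as.double(outcomes)
  if (!all(is.finite(times)) || !all(is.finite(outcomes))) {
    stop("non-finite values in times or outcomes", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta)) {
    stop("`delta` must be a single finite number", call. = FALSE)
  }
  ord <- order(times)
  times <- times[ord]
  outcomes <- outcomes[ord]
  if (anyDuplicated(times)) {
    stop("duplicate time values: a single-series design needs one observation per time",
         call. = FALSE)
  }
  if (reorigin) {
    delta <- delta - times[1L]
    times <- times - times[1L]
  }

  post <- as.integer(times >= delta)
  m <- sum(post == 0L)
  n <- sum(post == 1L)
  if (m < 2L || length(unique(times[post == 0L])) < 2L) {
    stop("pre-intervention segment needs at least 2 distinct time points (has ",
         m, ")", call. = FALSE)
  }
  if (n < 2L || length(unique(times[post == 1L])) < 2L) {
    stop("post-intervention segment needs at least 2 distinct time points (has ",
         n, ")", call. = FALSE)
  }
  if (m + n - 4L < 1L) {
    stop("need at least 5 observations for positive residual degrees of freedom",
         call. = FALSE)
  }
  if (max(abs(times)) > 1e6) {
    warning("times are large in magnitude; consider `reorigin = TRUE` for ",
            "numerical conditioning", call. = FALSE)
  }

  out <- tibble::tibble(time = times, outcome = outcomes, post = post)
  structure(out,
            delta = delta, m = m, n = n,
            class = c("its_data", class(out)))
}

# delta inferred from a 0/1 indicator; must match the T >= delta rule exactly
infer_delta <- function(times, indicator) {
  if (!all(indicator %in% c(0, 1))) {
    stop("indicator column must be 0/1", call. = FALSE)
  }
  ord <- order(times)
  ind <- indicator[ord]
  if (is.unsorted(ind)) {
    stop("non-monotone intervention indicator: must switch 0 -> 1 once",
         call. = FALSE)
  }
  if (!any(ind == 1)) stop("indicator never reaches 1", call. = FALSE)
  if (!any(ind == 0)) stop("indicator never 0", call. = FALSE)
  delta <- min(times[indicator == 1])
  mism <- xor(indicator == 1, times >= delta)
  if (any(mism)) {
    stop("indicator inconsistent with T >= delta rule", call. = FALSE)
  }
  delta
}

#' @export
print.its_data <- function(x, ...) {
  cat("<its_data> N =", nrow(x),
      "(m =", attr(x, "m"), "pre, n =", attr(x, "n"), "post),",
      "delta =", attr(x, "delta"), "\n")
  NextMethod()
}

#' Per-segment sufficient statistics
#'
#' The closed-form estimators depend on the data only through per-segment
#' sums: count, sum of times, sum of squared times, sum of outcomes, sum of
#' time-outcome products, the segment mean time, and the centered sum of
#' squares of times. This returns them as a two-row tibble (pre, post).
#'
#' @param data An [its_data()] object.
#' @return A tibble with one row per segment and columns `segment`, `count`,
#'   `sum_t`, `sum_t2`, `sum_y`, `sum_ty`, `mean_t`, `centered_ss`.
#' @export
segment_summaries <- function(data) {
  stopifnot(inherits(data, "its_data"))
  dplyr::group_by(data, segment = ifelse(.data$post == 1, "post", "pre")) |>
    dplyr::summarise(
      count = dplyr::n(),
      sum_t = sum(.data$time),
      sum_t2 = sum(.data$time^2),
      sum_y = sum(.data$outcome),
      sum_ty = sum(.data$time * .data$outcome),
      mean_t = mean(.data$time),
      centered_ss = sum((.data$time - mean(.data$time))^2),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$segment)) # pre first, then post
}

#' Design matrix for a segmented regression parametrization
#'
#' Columns are (intercept, time, post-indicator, interaction). Under the
#' `"bernal"` parametrization the interaction is `post * T`; under
#' `"wagner"` it is `post * (T - delta)`. The two matrices are identical in
#' the first three columns and differ in the fourth by exactly
#' `delta * post` per row.
#'
#' @param data An [its_data()] object.
#' @param parametrization `"bernal"` or `"wagner"`.
#' @return A numeric matrix with `N` rows and 4 columns.
#' @export
its_design_matrix <- function(data, parametrization = c("bernal", "wagner")) {
  stopifnot(inherits(data, "its_data"))
  parametrization <- match.arg(parametrization)
  delta <- attr(data, "delta")
  interaction <- switch(parametrization,
    bernal = data$post * data$time,
    wagner = data$post * (data$time - delta)
  )
  X <- cbind(1, data$time, data$post, interaction)
  colnames(X) <- c("(Intercept)", "time", "post", "interaction")
  X
}
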