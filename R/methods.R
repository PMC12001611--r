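#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a segmented regression fit
#'
#' One row per coefficient with estimate, standard error, t statistic and
#' two-sided p-value. Use [its_effects()] for the interpreted effect table;
#' `tidy()` reports the raw coefficients whose meaning depends on the
#' parametrization.
#'
#' @param x An [its_fit()] object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy its_fit
#' @export
tidy.its_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  purrr::map2_dfr(x$beta, se, function(est, s) {
    tst <- t_test(est, s, x$df)
    tibble::tibble(estimate = est, std.error = s,
                   statistic = tst$statistic, p.value = tst$p.value)
  }) |>
    dplyr::mutate(term = names(x$beta), .before = 1)
}

#' Glance at a segmented regression fit
#'
#' @param x An [its_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble with `parametrization`, `delta`, `m`, `n`,
#'   `nobs`, `sigma2`, `df.residual`, `r.squared`.
#' @method glance its_fit
#' @export
glance.its_fit <- function(x, ...) {
  y <- x$data$outcome
  tss <- sum((y - mean(y))^2)
  rss <- sum(x$residuals^2)
  tibble::tibble(
    parametrization = x$parametrization,
    delta = x$delta, m = x$m, n = x$n, nobs = x$m + x$n,
    sigma2 = x$sigma2, df.residual = x$df,
    r.squared = if (tss > 0) 1 - rss / tss else NA_real_
  )
}

#' Augment the data with fitted values and residuals
#'
#' @param x An [its_fit()] object.
#' @param ... Unused.
#' @return The model data with `.fitted` and `.resid` columns appended.
#' @method augment its_fit
#' @export
augment.its_fit <- function(x, ...) {
  tibble::as_tibble(x$data) |>
    dplyr::mutate(.fitted = x$fitted, .resid = x$residuals)
}

#' Plot a fitted segmented regression
#'
#' Draws the observed series with distinct pre/post point colours, the
#' fitted line over each segment, a vertical dot-dashed line at the
#' intervention time, and a dashed backward extension of the
#' post-intervention line to `T = 0`. The extension visualises the two
#' readings of `beta_2`: the gap between the lines at `T = 0` is the
#' difference in intercepts, while the gap at `T = delta` is the immediate
#' effect.
#'
#' @param object An [its_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot its_fit
#' @export
autoplot.its_fit <- function(object, ...) {
  fit <- object
  d <- tibble::as_tibble(fit$data) |>
    dplyr::mutate(period = factor(ifelse(.data$post == 1, "post", "pre"),
                                  levels = c("pre", "post")))
  b <- fit$beta
  delta <- fit$delta
  # pre/post line (intercept, slope) in plain coordinates
  pre_line <- c(b[[1]], b[[2]])
  post_int <- switch(fit$parametrization,
    bernal = b[[1]] + b[[3]],
    wagner = b[[1]] + b[[3]] - b[[4]] * delta
  )
  post_line <- c(post_int, b[[2]] + b[[4]])
  seg <- function(int, slope, from, to, type) {
    tibble::tibble(x = c(from, to), y = int + slope * c(from, to), linetype = type)
  }
  t_pre <- d$time[d$post == 0]
  t_post <- d$time[d$post == 1]
  lines <- dplyr::bind_rows(
    seg(pre_line[1], pre_line[2], min(t_pre), delta, "pre fit") |>
      dplyr::mutate(grp = "pre"),
    seg(post_line[1], post_line[2], delta, max(t_post), "post fit") |>
      dplyr::mutate(grp = "post"),
    seg(post_line[1], post_line[2], 0, delta, "post extension") |>
      dplyr::mutate(grp = "ext")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$outcome)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$period)) +
    ggplot2::geom_line(
      data = lines[lines$grp != "ext", ],
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$grp),
      linewidth = 0.7
    ) +
    ggplot2::geom_line(
      data = lines[lines$grp == "ext", ],
      ggplot2::aes(x = .data$x, y = .data$y),
      linetype = "dashed"
    ) +
    ggplot2::geom_vline(xintercept = delta, linetype = "dotdash") +
    ggplot2::labs(x = "time", y = "outcome", colour = "period") +
    ggplot2::theme_minimal()
}

#' Save a fitted-model plot to file
#'
#' Thin wrapper around [autoplot.its_fit()] and [ggplot2::ggsave()].
#'
#' @param fit An [its_fit()] object.
#' @param path Output file (extension selects the device, e.g. `.png`,
#'   `.svg`, `.pdf`).
#' @param width,height Plot size in inches.
#' @return `path`, invisibly.
#' @export
plot_its_fit <- function(fit, path, width = 7, height = 4.5) {
  p <- autoplot(fit)
  ggplot2::ggsave(path, plot = p, width = width, height = height)
  invisible(path)
}
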