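#' Read an interrupted time series from a CSV file
#'
#' Reads a comma-separated file with a header row, pulls the named time and
#' outcome columns, and builds a validated [its_data()]. The intervention
#' time comes either from `delta` directly or is inferred from a 0/1
#' `indicator_column` as the earliest time with indicator 1 (the indicator
#' must then be consistent with the `T >= delta` rule). Rows with a missing
#' outcome are dropped with a message. Exactly one of `delta` and
#' `indicator_column` must be supplied.
#'
#' @param path CSV file path.
#' @param time_column,outcome_column Column names (strings).
#' @param delta Intervention time, or `NULL` to infer from the indicator.
#' @param indicator_column Optional name of a 0/1 post-intervention column.
#' @param reorigin If `TRUE`, re-origin times at the first observation.
#' @return An [its_data()] object.
#' @export
read_its_csv <- function(path, time_column = "time", outcome_column = "outcome",
                         delta = NULL, indicator_column = NULL,
                         reorigin = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c(time_column, outcome_column, indicator_column)
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop("missing column(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  for (col in need) {
    if (!is.numeric(df[[col]])) {
      stop("column `", col, "` is not numeric", call. = FALSE)
    }
  }
  if (is.null(indicator_column)) {
    its_data(df, time = !!rlang::sym(time_column),
             outcome = !!rlang::sym(outcome_column),
             delta = delta, reorigin = reorigin)
  } else {
    its_data(df, time = !!rlang::sym(time_column),
             outcome = !!rlang::sym(outcome_column),
             delta = delta, indicator = !!rlang::sym(indicator_column),
             reorigin = reorigin)
  }
}

#' Assemble a report document for a fitted model
#'
#' Bundles the six-row effect table with fit metadata and provenance so it
#' can be rendered to CSV or plain text by [write_its_report()].
#'
#' @param fit An [its_fit()] object.
#' @param input Optional description of the input data (e.g. file path).
#' @param time_column,outcome_column Optional provenance: source column names.
#' @return A list of class `its_report` with elements `effects`, `meta`.
#' @export
its_report <- function(fit, input = NA_character_,
                       time_column = NA_character_,
                       outcome_column = NA_character_) {
  stopifnot(inherits(fit, "its_fit"))
  list(
    effects = its_effects(fit),
    meta = tibble::tibble(
      parametrization = fit$parametrization,
      delta = fit$delta, m = fit$m, n = fit$n, N = fit$m + fit$n,
      sigma2 = fit$sigma2, df = fit$df,
      input = input, time_column = time_column,
      outcome_column = outcome_column,
      tool = paste0("segits ", as.character(utils::packageVersion("segits")))
    )
  ) |> structure(class = "its_report")
}

# interpretation column: which coefficient (or combination) each row is
# under the fitted parametrization
effect_interpretation <- function(parametrization) {
  if (parametrization == "bernal") {
    c("beta0", "beta1", "beta2", "beta2 + delta*beta3", "beta3",
      "beta1 + beta3")
  } else {
    c("beta0", "beta1", "beta2 - delta*beta3", "beta2", "beta3",
      "beta1 + beta3")
  }
}

#' Write a report to CSV or plain text
#'
#' CSV format writes the six effect rows (label, estimate, se, statistic,
#' df, p.value) rounded to `digits` significant figures. Text format adds a
#' metadata header and an interpretation column naming which coefficient or
#' combination each row corresponds to under the fitted parametrization.
#'
#' @param report An [its_report()] object.
#' @param path Output file path.
#' @param format `"csv"` or `"text"`.
#' @param digits Significant digits for rendered numbers (default 4).
#' @return `path`, invisibly.
#' @export
write_its_report <- function(report, path, format = c("csv", "text"),
                             digits = 4) {
  stopifnot(inherits(report, "its_report"))
  format <- match.arg(format)
  eff <- tibble::as_tibble(report$effects) |>
    dplyr::select("label", "estimate", "se", "statistic", "df", "p.value") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.double), ~ signif(.x, digits)))
  if (format == "csv") {
    readr::write_csv(eff, path)
  } else {
    meta <- report$meta
    eff$interpretation <- effect_interpretation(meta$parametrization)
    widths <- vapply(names(eff), nchar, 1L)
    fmt_row <- function(vals) {
      paste(vapply(seq_along(vals), function(i) {
        formatC(as.character(vals[[i]]),
                width = max(widths[i], 12), flag = "-")
      }, ""), collapse = " ")
    }
    lines <- c(
      "Segmented regression intervention effect report",
      sprintf("parametrization: %s  delta: %g  m: %d  n: %d  sigma2: %g  df: %d",
              meta$parametrization, meta$delta, meta$m, meta$n,
              signif(meta$sigma2, digits), meta$df),
      sprintf("input: %s  tool: %s", meta$input, meta$tool),
      "",
      fmt_row(as.list(names(eff))),
      vapply(seq_len(nrow(eff)), function(r) fmt_row(as.list(eff[r, ])), "")
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write an interrupted time series dataset to CSV
#'
#' Columns `time`, `outcome`, `post`; readable back with [read_its_csv()]
#' (using the `post` column as the indicator, or the stored delta).
#'
#' @param data An [its_data()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_its_csv <- function(data, path) {
  stopifnot(inherits(data, "its_data"))
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}
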