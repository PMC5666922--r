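# Validation of calibrated parameter sets against the experimental
# standard-test targets via the normalized mean-absolute-error metric.

#' Assemble a comparison table of calibrated models vs experiment
#'
#' Evaluates each criterion's responder at its optimal parameter set and
#' lines the predictions up against the experimental targets, one row per
#' response.
#'
#' @param bundles A single `response_bundle` used for every criterion, or a
#'   named list of bundles (one per criterion).
#' @param optima Named list of parameter vectors, one per criterion; names
#'   become the criterion columns.
#' @param targets Experimental target table ([experimental_targets()]).
#' @return Data frame of class `comparison_table`: `response`, one column
#'   per criterion, and `experimental`.
#' @export
build_comparison <- function(bundles, optima,
                             targets = experimental_targets()) {
  stopifnot(is.list(optima), length(optima) >= 1, !is.null(names(optima)))
  if (inherits(bundles, "response_bundle")) {
    bundles <- stats::setNames(rep(list(bundles), length(optima)),
                               names(optima))
  }
  stopifnot(setequal(names(bundles), names(optima)))
  out <- data.frame(response = targets$response)
  for (cr in names(optima)) {
    pred <- evaluate_responses(bundles[[cr]], optima[[cr]])
    if (!all(targets$response %in% names(pred))) {
      stop("schema error: responder for ", cr, " misses response(s): ",
           paste(setdiff(targets$response, names(pred)), collapse = ", "))
    }
    out[[cr]] <- unname(pred[targets$response])
  }
  out$experimental <- targets$target
  structure(out, class = c("comparison_table", "data.frame"))
}

#' Normalized mean absolute errors of a comparison table
#'
#' For each response row the values are put on a common scale by dividing by
#' the row maximum (taken over the criterion columns and the experimental
#' value); the normalized error of criterion `c` on response `r` is then
#' `|value[r, c] - experimental[r]| / rowmax[r]`. Per-response errors
#' average over criteria; per-criterion errors average over responses.
#' `method = "range"` instead divides by the row range (max - min), offered
#' for sensitivity analysis; the row-maximum normalization is the default
#' because it is the form consistent with the reference calibration results
#' shipped with the package.
#'
#' @param table `comparison_table` (or data frame with a `response` column,
#'   criterion columns, and an `experimental` column).
#' @param method `"max"` (default) or `"range"`.
#' @return List of class `normalized_error_report`: `per_response` (named
#'   vector), `per_criterion` (named vector), `denominators`, `errors`
#'   (response x criterion matrix), `method`.
#' @export
normalized_errors <- function(table, method = c("max", "range")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table), "response" %in% names(table),
            "experimental" %in% names(table))
  crit_cols <- setdiff(names(table), c("response", "experimental"))
  if (length(crit_cols) < 1) stop("need at least one criterion column")
  vals <- as.matrix(table[, c(crit_cols, "experimental")])
  if (any(!is.finite(vals))) stop("all table entries must be finite")
  denom <- switch(method,
                  max = apply(vals, 1, max),
                  range = apply(vals, 1, max) - apply(vals, 1, min))
  if (any(denom <= 0)) stop("domain error: non-positive row denominator")
  err <- abs(table[, crit_cols, drop = FALSE] - table$experimental) / denom
  err <- as.matrix(err)
  rownames(err) <- table$response
  structure(list(
    per_response = stats::setNames(rowMeans(err), table$response),
    per_criterion = colMeans(err),
    denominators = stats::setNames(denom, table$response),
    errors = err,
    method = method
  ), class = "normalized_error_report")
}

#' @export
print.normalized_error_report <- function(x, ...) {
  cat("Normalized MAE (", x$method, "-normalized):\n", sep = "")
  cat("  per criterion:\n")
  print(round(x$per_criterion, 4))
  cat("  per response:\n")
  print(round(x$per_response, 3))
  invisible(x)
}

#' Write a comparison table and its error report to CSV
#'
#' Criterion columns, the experimental column, the per-response normalized
#' MAE column, and a trailing per-criterion MAE row.
#'
#' @param table `comparison_table`.
#' @param report Matching `normalized_error_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(table, report, path) {
  out <- as.data.frame(table)
  out$normalized_mae <- unname(report$per_response[out$response])
  out <- .format_numeric_df(out)
  tail_row <- out[1, ]
  tail_row[,] <- ""
  tail_row$response <- "Normalized MAE"
  crit_cols <- setdiff(names(table), c("response", "experimental"))
  for (cc in crit_cols) {
    tail_row[[cc]] <- formatC(signif(report$per_criterion[[cc]], 6),
                              format = "g", digits = 6)
  }
  out <- rbind(out, tail_row)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- packaged reference calibration results -----------------------------

#' Reference calibration results shipped with the package
#'
#' The published reference calibration of the virtual disc: per criterion,
#' the optimal parameter values, per-variable goals and desirabilities
#' (`reference_calibration()`), and the comparison of the re-simulated
#' optima against the experimental standard-test values
#' (`reference_comparison()`, whose `published_error` column holds the
#' reported row-normalized MAE).
#'
#' @param criterion 1, 2 or 3.
#' @return `reference_calibration()`: data frame with columns `variable`,
#'   `role`, `goal`, `target`, `value`, `desirability`.
#'   `reference_comparison()`: data frame with columns `response`,
#'   `criterion1..3`, `experimental`, `published_error`.
#' @export
reference_calibration <- function(criterion) {
  stopifnot(criterion %in% 1:3)
  path <- system.file("extdata",
                      sprintf("reference_calibration_criterion%d.csv",
                              criterion),
                      package = "ivdcalib")
  utils::read.csv(path)
}

#' @rdname reference_calibration
#' @export
reference_comparison <- function() {
  utils::read.csv(system.file("extdata", "reference_comparison.csv",
                              package = "ivdcalib"))
}

#' Optimal parameter set of a reference calibration criterion
#'
#' @param criterion 1, 2 or 3.
#' @return Named numeric vector of the eleven parameters.
#' @export
reference_optimum <- function(criterion) {
  tab <- reference_calibration(criterion)
  inp <- tab[tab$role == "input", ]
  stats::setNames(inp$value, inp$variable)[parameter_names()]
}
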