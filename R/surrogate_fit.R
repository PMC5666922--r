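# Per-response polynomial surrogate fitting: ordinary least squares on
# physical-unit designs, backward elimination on coefficient p-values,
# sequential (Type I) ANOVA reporting, and train/test error metrics.

#' Candidate term labels for a polynomial surrogate
#'
#' Builds the model-term vocabulary: linear terms, optional pure quadratics
#' and optional pairwise interactions over the given factor names. The
#' intercept is always implied and never listed. On a two-level design pure
#' quadratics are aliased with the intercept and should be left out.
#'
#' @param factors Character vector of factor names.
#' @param quadratic Include `I(x^2)` terms?
#' @param interactions Include all pairwise `x:y` terms?
#' @return Character vector of term labels.
#' @export
candidate_terms <- function(factors, quadratic = FALSE, interactions = FALSE) {
  terms <- factors
  if (quadratic) terms <- c(terms, paste0("I(", factors, "^2)"))
  if (interactions && length(factors) > 1) {
    cmb <- utils::combn(factors, 2)
    terms <- c(terms, paste(cmb[1, ], cmb[2, ], sep = ":"))
  }
  terms
}

#' Fit one response surrogate with p-value term selection
#'
#' Ordinary least squares of a response column on the candidate terms (in
#' physical units), followed by backward elimination: while any retained,
#' unprotected term has a coefficient p-value above `alpha`, the least
#' significant one is dropped and the model refit. The intercept and any
#' `keep` terms are protected. Reports the sequential (Type I) ANOVA of the
#' final model.
#'
#' @param design Physical-unit design data frame.
#' @param y Numeric response vector, one value per run.
#' @param response Response name used for labelling.
#' @param terms Candidate term labels (default: all linear terms).
#' @param alpha Selection threshold on the p-value, in (0, 1); default 0.05.
#' @param keep Term labels never dropped, regardless of significance.
#' @param select Disable elimination entirely with `select = FALSE`.
#' @return Object of class `fitted_response`: list with `response`, `terms`
#'   (selected), `coefficients` (including `(Intercept)`), `r_squared`,
#'   `df_residual`, `anova` (data frame with Df, Sum Sq, Mean Sq, F value,
#'   p-value and significance code), and the underlying `lm` fit.
#' @export
fit_response <- function(design, y, response = "y",
                         terms = candidate_terms(names(design)),
                         alpha = 0.05, keep = NULL, select = TRUE) {
  stopifnot(is.data.frame(design), length(y) == nrow(design))
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  dat <- cbind(design, .y = y)

  if (stats::var(y) == 0) {
    # degenerate constant response: intercept only, R^2 reported as 0
    fit <- stats::lm(.y ~ 1, data = dat)
    return(.as_fitted_response(fit, response, character(0), r2 = 0))
  }

  current <- terms
  repeat {
    fml <- stats::reformulate(if (length(current)) current else "1",
                              response = ".y")
    fit <- stats::lm(fml, data = dat)
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      stop("aliasing error: confounded term(s) in the requested model: ",
           paste(names(cf)[is.na(cf)], collapse = ", "))
    }
    if (nrow(dat) <= length(cf)) {
      stop("more selected terms than runs; reduce the candidate set")
    }
    if (!select || length(current) == 0) break
    # summary.lm warns on essentially perfect fits; zero-noise campaigns
    # are exactly that, and elimination then simply retains everything
    pv <- suppressWarnings(summary(fit))$coefficients[, "Pr(>|t|)"]
    pv <- pv[setdiff(names(pv), c("(Intercept)", keep))]
    droppable <- pv[pv > alpha]
    if (length(droppable) == 0) break
    worst <- names(droppable)[which.max(droppable)]
    current <- setdiff(current, worst)
  }
  r2 <- suppressWarnings(summary(fit))$r.squared
  .as_fitted_response(fit, response, current, r2 = r2)
}

.as_fitted_response <- function(fit, response, terms, r2) {
  # anova.lm warns on essentially perfect fits (zero-noise campaigns);
  # the sequential sums of squares themselves remain well defined
  an <- suppressWarnings(stats::anova(fit))
  an_df <- data.frame(
    term = rownames(an),
    Df = an$Df,
    `Sum Sq` = an$`Sum Sq`,
    `Mean Sq` = an$`Mean Sq`,
    `F value` = an$`F value`,
    `Pr(>F)` = an$`Pr(>F)`,
    signif = significance_code(an$`Pr(>F)`),
    check.names = FALSE
  )
  rownames(an_df) <- NULL
  structure(list(
    response = response,
    terms = terms,
    coefficients = stats::coef(fit),
    r_squared = r2,
    df_residual = fit$df.residual,
    anova = an_df,
    fit = fit
  ), class = "fitted_response")
}

#' Map p-values to the conventional significance codes
#'
#' `0 '***' 0.001 '**' 0.01 '*' 0.05 '.' 0.1 ' ' 1`.
#'
#' @param p Numeric vector of p-values (NA allowed, e.g. residual rows).
#' @return Character vector of codes.
#' @export
significance_code <- function(p) {
  out <- character(length(p))
  out[!is.na(p)] <- as.character(cut(p[!is.na(p)],
                                     breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
                                     labels = c("***", "**", "*", ".", "")))
  out[is.na(p)] <- ""
  out
}

#' @export
print.fitted_response <- function(x, ...) {
  cat("Surrogate for ", x$response, ": ", length(x$terms),
      " selected term(s), R^2 = ", format(x$r_squared, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Fit surrogates for every response column
#'
#' @param design Physical-unit design data frame.
#' @param responses Data frame of response columns (runs x responses).
#' @param ... Passed to [fit_response()].
#' @return Named list of `fitted_response` objects, class `response_fit_set`.
#' @export
fit_all_responses <- function(design, responses, ...) {
  fits <- lapply(names(responses), function(nm) {
    fit_response(design, responses[[nm]], response = nm, ...)
  })
  names(fits) <- names(responses)
  structure(fits, class = "response_fit_set")
}

#' Convert fitted surrogates to a response bundle
#'
#' Fitted models become drop-in responders: the result evaluates through
#' [evaluate_responses()] exactly like the reference bundle. Only linear
#' terms can be represented; fits containing quadratic or interaction terms
#' are refused.
#'
#' @param fits `response_fit_set` from [fit_all_responses()].
#' @return `response_bundle` with provenance `"fitted"`.
#' @export
as_bundle <- function(fits) {
  b <- lapply(fits, function(f) {
    cf <- f$coefficients
    lin <- cf[setdiff(names(cf), "(Intercept)")]
    if (any(grepl("[:^]", names(lin)))) {
      stop("only linear fits can be converted to a response bundle")
    }
    list(intercept = unname(cf["(Intercept)"]), coefficients = lin)
  })
  structure(b, class = "response_bundle", provenance = "fitted")
}

#' Prediction error metrics for one response
#'
#' Mean absolute error and root mean squared error between observed and
#' predicted values, in absolute response units and as percent-relative
#' variants (each deviation divided by `|y_obs|` before averaging, x100),
#' plus the observed-predicted correlation on a percent scale. A zero
#' observed value makes the percent variants undefined; they are returned
#' as `NA` with `zero_obs = TRUE` rather than silently as infinity.
#'
#' @param y_obs,y_pred Equal-length numeric vectors, `length >= 1`.
#' @return One-row data frame: `mae`, `rmse`, `mae_pct`, `rmse_pct`,
#'   `correlation_pct`, `zero_obs`.
#' @examples
#' error_metrics(c(1, 2), c(2, 4))
#' @export
error_metrics <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 1)
  d <- y_obs - y_pred
  mae <- mean(abs(d))
  rmse <- sqrt(mean(d^2))
  zero_obs <- any(y_obs == 0)
  if (zero_obs) {
    mae_pct <- NA_real_
    rmse_pct <- NA_real_
  } else {
    rel <- d / abs(y_obs)
    mae_pct <- 100 * mean(abs(rel))
    rmse_pct <- 100 * sqrt(mean(rel^2))
  }
  corr <- if (length(y_obs) > 1 && stats::sd(y_obs) > 0 &&
              stats::sd(y_pred) > 0) {
    100 * stats::cor(y_obs, y_pred)
  } else if (all(d == 0)) 100 else NA_real_
  data.frame(mae = mae, rmse = rmse, mae_pct = mae_pct, rmse_pct = rmse_pct,
             correlation_pct = corr, zero_obs = zero_obs)
}

#' Evaluate fitted surrogates on held-out runs
#'
#' Predicts every response at the test design and reports
#' [error_metrics()] per response against the held-out observations.
#'
#' @param models `response_fit_set` or `response_bundle`.
#' @param test_design Physical-unit design data frame.
#' @param test_responses Data frame of observed responses for those runs.
#' @return Data frame, one row per response, with the metric columns.
#' @export
evaluate_on_test <- function(models, test_design, test_responses) {
  bundle <- if (inherits(models, "response_fit_set")) as_bundle(models) else models
  missing_resp <- setdiff(names(bundle), names(test_responses))
  if (length(missing_resp)) {
    stop("schema error: response column(s) missing: ",
         paste(missing_resp, collapse = ", "))
  }
  pred <- simulate_batch(test_design, bundle)
  out <- do.call(rbind, lapply(names(bundle), function(nm) {
    cbind(response = nm, error_metrics(test_responses[[nm]], pred[[nm]]))
  }))
  rownames(out) <- NULL
  out
}

#' Write ANOVA tables of a fit set to CSV
#'
#' One block per response, mirroring the conventional sequential-ANOVA
#' layout with significance codes.
#'
#' @param fits `response_fit_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_anova_csv <- function(fits, path) {
  blocks <- do.call(rbind, lapply(fits, function(f) {
    cbind(response = f$response, .format_numeric_df(f$anova))
  }))
  rownames(blocks) <- NULL
  utils::write.csv(blocks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
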