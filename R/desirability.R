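# Derringer-Harrington desirability scoring and multi-start maximization of
# the overall desirability over the material-parameter box.

#' One-sided desirability ramp
#'
#' Maps a response value to `[0, 1]` against a one-sided goal. For
#' `direction = "max"`: 0 below `low`, `((f - low)/(high - low))^s` on the
#' ramp, 1 above `high`; `direction = "min"` is the mirror image.
#'
#' @param f Response value(s).
#' @param low,high Ramp bounds, `low < high` (response units).
#' @param s Ramp exponent, `> 0` (1 = linear).
#' @param direction `"max"` or `"min"`.
#' @return Desirability value(s) in `[0, 1]`.
#' @examples
#' desirability_one_sided(0.5, 0, 1, direction = "max")
#' @export
desirability_one_sided <- function(f, low, high, s = 1,
                                   direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (low >= high) stop("domain error: low must be < high")
  stopifnot(s > 0)
  ramp <- pmin(pmax((f - low) / (high - low), 0), 1)^s
  if (direction == "max") ramp else {
    pmin(pmax((f - high) / (low - high), 0), 1)^s
  }
}

#' Two-sided (target) desirability
#'
#' Standard Derringer target form: rises as `((f - low)/(target - low))^s`
#' on `[low, target]`, falls as `((high - f)/(high - target))^s` on
#' `[target, high]`, and is 0 outside `[low, high]`. Degenerate sides
#' (`low == target` or `target == high`) collapse to a step: desirability 1
#' exactly at the target, 0 beyond the degenerate side. This limit arises
#' when an experimental target sits at (or outside) the span of responses
#' reachable over the search box.
#'
#' @param f Response value(s).
#' @param low,target,high Bounds and target, `low <= target <= high`,
#'   `low < high`.
#' @param s Ramp exponent, `> 0`, applied to both sides.
#' @return Desirability value(s) in `[0, 1]`.
#' @examples
#' desirability_target(0.5, 0, 1, 2)
#' @export
desirability_target <- function(f, low, target, high, s = 1) {
  if (low >= high) stop("domain error: low must be < high")
  if (target < low || target > high) {
    stop("domain error: target must lie within [low, high]")
  }
  stopifnot(s > 0)
  up <- if (target > low) {
    pmin(pmax((f - low) / (target - low), 0), 1)^s
  } else as.numeric(f >= target)
  down <- if (target < high) {
    pmin(pmax((high - f) / (high - target), 0), 1)^s
  } else as.numeric(f <= target)
  d <- pmin(up, down)
  d[f < low | f > high] <- 0
  d
}

#' In-range desirability
#'
#' 1 inside `[low, high]`, 0 outside: an in-range goal acts as a feasibility
#' constraint, not a graded preference.
#'
#' @param f Value(s).
#' @param low,high Bounds, `low < high`.
#' @return 0/1 value(s).
#' @export
desirability_in_range <- function(f, low, high) {
  if (low >= high) stop("domain error: low must be < high")
  as.numeric(f >= low & f <= high)
}

#' Overall desirability (weighted geometric mean)
#'
#' `D = (prod d_r^w_r)^(1 / sum w_r)` over the targeted responses only;
#' in-range variables act as constraints and are excluded from the product.
#' Any zero desirability forces `D = 0`.
#'
#' @param d Desirabilities of the targeted responses, all in `[0, 1]`.
#' @param weights Importance weights, `> 0` (default all 1, reducing to the
#'   plain geometric mean).
#' @return Overall desirability in `[0, 1]`.
#' @examples
#' overall_desirability(c(0.907, 1.000, 0.999, 0.989, 0.772, 0.428))
#' @export
overall_desirability <- function(d, weights = rep(1, length(d))) {
  if (length(d) == 0) stop("domain error: empty targeted set")
  stopifnot(length(weights) == length(d), all(weights > 0))
  if (any(d < 0 | d > 1)) stop("desirabilities must lie in [0, 1]")
  if (any(d == 0)) return(0)
  exp(sum(weights * log(d)) / sum(weights))
}

#' Construct a per-variable goal specification
#'
#' @param variable Variable name (response or input).
#' @param goal One of `"target"`, `"in_range"`, `"maximize"`, `"minimize"`.
#' @param target Target value (required for target goals).
#' @param low,high Bounds A and B (variable units), `low < high`.
#' @param s Desirability exponent, `> 0` (default 1).
#' @param weight Importance weight (default 1).
#' @return List of class `goal_spec`.
#' @export
goal_spec <- function(variable, goal = c("target", "in_range", "maximize",
                                         "minimize"),
                      target = NA_real_, low, high, s = 1, weight = 1) {
  goal <- match.arg(goal)
  if (low >= high) stop("domain error: low must be < high (", variable, ")")
  if (goal == "target") {
    if (is.na(target)) stop("target goals need a target value (", variable, ")")
    if (target < low || target > high) {
      stop("domain error: target outside [low, high] (", variable, ")")
    }
  }
  structure(list(variable = variable, goal = goal, target = target,
                 low = low, high = high, s = s, weight = weight),
            class = "goal_spec")
}

#' Per-response bounds of a simulated campaign
#'
#' The default desirability bounds A/B for each response: its minimum and
#' maximum over the training response table. When an experimental target
#' falls outside that span the bound is widened to include it, so that the
#' target form stays well defined (the affected side degenerates, see
#' [desirability_target()]).
#'
#' @param responses Data frame of simulated responses (runs x responses).
#' @return Data frame with columns `response`, `min`, `max`.
#' @export
response_bounds <- function(responses) {
  data.frame(response = names(responses),
             min = vapply(responses, min, numeric(1)),
             max = vapply(responses, max, numeric(1)),
             row.names = NULL)
}

#' Build the goal configuration for one adjustment criterion
#'
#' The three adjustment criteria of the calibration study:
#' criterion 1 sets *every* response to its experimental target;
#' criterion 2 targets the six stiffnesses and keeps the nine bulges
#' in-range; criterion 3 targets the nine bulges and keeps the six
#' stiffnesses in-range. All eleven inputs are in-range in every criterion.
#'
#' @param criterion 1, 2 or 3.
#' @param bounds Per-response bounds from [response_bounds()] (A/B of each
#'   response's desirability), typically taken from the training campaign.
#' @param targets Experimental target table ([experimental_targets()]).
#' @param ranges Input parameter ranges ([default_parameter_ranges()]).
#' @return List of class `criterion_config`: `criterion`, `input_goals`,
#'   `output_goals` (lists of [goal_spec()]).
#' @export
criterion_config <- function(criterion, bounds,
                             targets = experimental_targets(),
                             ranges = default_parameter_ranges()) {
  stopifnot(criterion %in% 1:3)
  r <- parameter_ranges(ranges)
  input_goals <- lapply(seq_len(nrow(r)), function(i) {
    goal_spec(r$parameter[i], "in_range", low = r$min[i], high = r$max[i])
  })
  names(input_goals) <- r$parameter
  stopifnot(all(targets$response %in% bounds$response))
  output_goals <- lapply(seq_len(nrow(targets)), function(i) {
    resp <- targets$response[i]
    tgt <- targets$target[i]
    j <- match(resp, bounds$response)
    lo <- min(bounds$min[j], tgt)
    hi <- max(bounds$max[j], tgt)
    targeted <- switch(as.character(criterion),
                       `1` = TRUE,
                       `2` = targets$class[i] == "stiffness",
                       `3` = targets$class[i] == "bulge")
    goal_spec(resp, if (targeted) "target" else "in_range",
              target = tgt, low = lo, high = hi)
  })
  names(output_goals) <- targets$response
  structure(list(criterion = criterion, input_goals = input_goals,
                 output_goals = output_goals),
            class = "criterion_config")
}

.goal_desirability <- function(g, f) {
  switch(g$goal,
         target = desirability_target(f, g$low, g$target, g$high, g$s),
         in_range = desirability_in_range(f, g$low, g$high),
         maximize = desirability_one_sided(f, g$low, g$high, g$s, "max"),
         minimize = desirability_one_sided(f, g$low, g$high, g$s, "min"))
}

#' Score a parameter set under a criterion configuration
#'
#' Evaluates the responder at `params`, computes every per-variable
#' desirability, and aggregates the targeted responses into the overall
#' desirability `D`. In-range goals act as constraints: with
#' `enforce = "all"` (default) a violated input or output in-range goal
#' forces `D = 0`; `"outputs"` ignores input containment (useful when
#' scoring an externally supplied optimum that sits outside the box);
#' `"none"` aggregates the targeted desirabilities unconditionally.
#'
#' @param bundle Responder (`response_bundle`).
#' @param config `criterion_config`.
#' @param params Named parameter vector.
#' @param enforce Constraint handling, see above.
#' @return List: `predictions`, `table` (variable, goal, value,
#'   desirability), `D`.
#' @export
score_point <- function(bundle, config, params,
                        enforce = c("all", "outputs", "none")) {
  enforce <- match.arg(enforce)
  pred <- evaluate_responses(bundle, params)
  in_d <- vapply(config$input_goals, function(g) {
    .goal_desirability(g, unname(params[g$variable]))
  }, numeric(1))
  out_d <- vapply(config$output_goals, function(g) {
    .goal_desirability(g, unname(pred[g$variable]))
  }, numeric(1))
  targeted <- vapply(config$output_goals, function(g) g$goal == "target",
                     logical(1))
  w <- vapply(config$output_goals, function(g) g$weight, numeric(1))
  D <- overall_desirability(out_d[targeted], w[targeted])
  if (enforce == "all" && any(in_d == 0)) D <- 0
  if (enforce %in% c("all", "outputs") && any(out_d[!targeted] == 0)) D <- 0
  tab <- data.frame(
    variable = c(names(in_d), names(out_d)),
    goal = c(vapply(config$input_goals, `[[`, "", "goal"),
             vapply(config$output_goals, `[[`, "", "goal")),
    value = c(unname(params[names(in_d)]), unname(pred[names(out_d)])),
    desirability = c(unname(in_d), unname(out_d))
  )
  list(predictions = pred, table = tab, D = D)
}

#' Maximize overall desirability over the parameter box
#'
#' Seeded multi-start bounded maximization of `D`: uniform starts inside the
#' search box (plus the box midpoint), each polished with bounded
#' quasi-Newton (`L-BFGS-B` on `-D`). Ties within `1e-9` in `D` are broken
#' by the smallest coded-parameter norm, making the result deterministic for
#' a fixed seed. The search box is the operative input constraint; pass an
#' expanded box ([expand_ranges()]) to search beyond the design ranges.
#'
#' @param bundle Responder (`response_bundle`).
#' @param config `criterion_config`.
#' @param box Search box (`ivd_ranges`); defaults to the ranges implied by
#'   the config's input goals.
#' @param n_starts Number of random starts, `>= 1` (default 64).
#' @param seed Integer seed (default 1).
#' @return Object of class `optimization_result`: `params` (`ivd_params`-like
#'   named vector), `predictions`, `table`, `D`, `diagnostics`.
#' @export
optimize_desirability <- function(bundle, config, box = NULL, n_starts = 64,
                                  seed = 1) {
  stopifnot(n_starts >= 1)
  if (is.null(box)) {
    box <- parameter_ranges(data.frame(
      parameter = names(config$input_goals),
      min = vapply(config$input_goals, `[[`, 0, "low"),
      max = vapply(config$input_goals, `[[`, 0, "high")))
  }
  box <- parameter_ranges(box)
  k <- nrow(box)
  lower <- box$min
  upper <- box$max
  nm <- box$parameter

  # precompute the affine responder as a matrix-vector product and the goal
  # parameters as aligned vectors; the objective runs ~10^5 times
  goals <- config$output_goals
  resp_names <- vapply(goals, `[[`, "", "variable")
  b0 <- vapply(bundle[resp_names], `[[`, 0, "intercept")
  B <- t(vapply(bundle[resp_names], function(m) {
    row <- stats::setNames(numeric(k), nm)
    row[names(m$coefficients)] <- m$coefficients
    row
  }, numeric(k)))
  g_lo <- vapply(goals, `[[`, 0, "low")
  g_hi <- vapply(goals, `[[`, 0, "high")
  g_tg <- vapply(goals, `[[`, 0, "target")
  g_s <- vapply(goals, `[[`, 0, "s")
  g_w <- vapply(goals, `[[`, 0, "weight")
  targeted <- vapply(goals, function(g) g$goal == "target", logical(1))

  vector_d <- function(pred) {
    d <- numeric(length(pred))
    # in-range goals: 0/1 feasibility
    ir <- !targeted
    d[ir] <- as.numeric(pred[ir] >= g_lo[ir] & pred[ir] <= g_hi[ir])
    tg <- which(targeted)
    up_den <- g_tg[tg] - g_lo[tg]
    dn_den <- g_hi[tg] - g_tg[tg]
    up <- ifelse(up_den > 0,
                 pmin(pmax((pred[tg] - g_lo[tg]) / pmax(up_den, 1e-300), 0), 1),
                 as.numeric(pred[tg] >= g_tg[tg]))
    dn <- ifelse(dn_den > 0,
                 pmin(pmax((g_hi[tg] - pred[tg]) / pmax(dn_den, 1e-300), 0), 1),
                 as.numeric(pred[tg] <= g_tg[tg]))
    d[tg] <- pmin(up, dn)^g_s[tg]
    d[tg][pred[tg] < g_lo[tg] | pred[tg] > g_hi[tg]] <- 0
    d
  }

  # in-range input goals are enforced by the box itself during the search
  objective <- function(x) {
    pred <- drop(b0 + B %*% x)
    if (any(!is.finite(pred))) {
      stop("responder error: non-finite prediction at ",
           paste(format(x, digits = 4), collapse = ", "))
    }
    d <- vector_d(pred)
    if (any(d[!targeted] == 0) || any(d[targeted] == 0)) return(0)
    exp(sum(g_w[targeted] * log(d[targeted])) / sum(g_w[targeted]))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * k), n_starts, k)
  starts <- sweep(sweep(starts, 2, upper - lower, `*`), 2, lower, `+`)
  starts[1, ] <- (lower + upper) / 2

  coded_norm <- function(x) sqrt(sum(((x - (lower + upper) / 2) /
                                        ((upper - lower) / 2))^2))
  clamp <- function(x) pmin(pmax(x, lower), upper)
  n_conv <- 0
  cands <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[i, ], function(x) -objective(x),
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 60)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) n_conv <- n_conv + 1
    cands[[i]] <- list(par = fit$par, D = -fit$value)
  }
  cands <- Filter(Negate(is.null), cands)
  if (length(cands) == 0) stop("optimizer failed from every start")
  # the desirability surface is piecewise smooth with ridges at goal kinks;
  # polish the leading quasi-Newton candidates with a box-clamped simplex
  ord <- order(-vapply(cands, `[[`, 0, "D"),
               vapply(cands, function(cn) coded_norm(cn$par), 0))
  for (i in utils::head(ord, 5L)) {
    fit <- tryCatch(
      stats::optim(cands[[i]]$par, function(x) -objective(clamp(x)),
                   method = "Nelder-Mead",
                   control = list(maxit = 3000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && -fit$value > cands[[i]]$D) {
      cands[[i]] <- list(par = clamp(fit$par), D = -fit$value)
    }
  }
  best <- NULL
  for (cand in cands) {
    if (is.null(best) ||
        cand$D > best$D + 1e-9 ||
        (abs(cand$D - best$D) <= 1e-9 &&
         coded_norm(cand$par) < coded_norm(best$par))) {
      best <- cand
    }
  }
  params <- stats::setNames(best$par, nm)
  scored <- score_point(bundle, config, params, enforce = "outputs")
  structure(list(
    params = params,
    predictions = scored$predictions,
    table = scored$table,
    D = scored$D,
    diagnostics = list(n_starts = n_starts, converged = n_conv, seed = seed,
                       box = as.data.frame(box),
                       bounds = data.frame(
                         response = names(config$output_goals),
                         low = vapply(config$output_goals, `[[`, 0, "low"),
                         high = vapply(config$output_goals, `[[`, 0, "high")))
  ), class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("Desirability optimum: D =", format(x$D, digits = 4), "\n")
  print(format(x$params, digits = 6), quote = FALSE)
  invisible(x)
}

#' Serialize an optimization result
#'
#' Writes the result as JSON (full detail) and as a CSV in the conventional
#' goal/value/desirability layout with a trailing overall-desirability row.
#'
#' @param result `optimization_result`.
#' @param path_json,path_csv Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_optimization_result <- function(result, path_json = NULL,
                                      path_csv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(list(
      params = as.list(result$params),
      D = result$D,
      table = result$table,
      diagnostics = result$diagnostics
    ), path_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(path_csv)) {
    tab <- .format_numeric_df(result$table)
    tab <- rbind(tab, data.frame(variable = "Overall Desirability",
                                 goal = "", value = "",
                                 desirability = formatC(signif(result$D, 6),
                                                        format = "g",
                                                        digits = 6)))
    utils::write.csv(tab, path_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(c(path_json, path_csv))
}
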