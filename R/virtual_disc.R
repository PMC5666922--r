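# Virtual disc responder: the reference bundle of affine response surfaces
# that stands in for the finite-element solver. Each of the 15 responses is
# intercept + sparse linear coefficients over the 11 physical parameters.
# Two transcription notes are recorded in the bundle metadata: the shear
# stiffness surface is mislabelled "Cort_stiff" in its source listing, and
# small coefficients typeset as "x 10-0.5" are read as 1e-5-scale values
# (the only reading consistent with the published predictions).

#' The packaged reference response-surface bundle
#'
#' Returns the 15 reference response surfaces of the virtual disc: for each
#' response, an intercept and sparse linear coefficients over the physical
#' material parameters, in the response's own units. The bundle is affine by
#' construction (no quadratic or interaction terms), which makes zero-noise
#' simulation campaigns exactly interpolable by first-order surrogates.
#'
#' @return Named list of class `response_bundle`; each element is
#'   `list(intercept = , coefficients = named numeric)`. Attribute
#'   `provenance` is `"reference"`.
#' @export
reference_bundle <- function() {
  b <- list(
    Comp_bulgeA = list(
      intercept = 0.453125,
      coefficients = c(C10 = -0.150922, C0 = -0.154598, Fiber12 = -4.4e-5,
                       Fiber56 = -2.8e-5, Fiber78 = -2.3e-5,
                       Fiber910 = -2.5e-5, Annulus_E = -0.034134,
                       Annulus_mu = 0.262148, Cartil_E = -0.001137,
                       Cartil_mu = 0.040998)),
    Comp_bulgeL = list(
      intercept = 0.169454,
      coefficients = c(C10 = -0.084948, C0 = -0.087169, Fiber12 = -5e-5,
                       Annulus_E = -0.006264, Annulus_mu = 0.088348,
                       Cartil_E = -0.001015, Cartil_mu = 0.031074)),
    Comp_bulgeP = list(
      intercept = 1.206599,
      coefficients = c(C10 = -0.91178, C0 = -0.915255, Annulus_E = -0.113434,
                       Annulus_mu = 0.442496, Cartil_E = -0.003303,
                       Cartil_mu = 0.117189)),
    Comp_stiff = list(
      intercept = -635.243327,
      coefficients = c(C10 = 822.048324, C0 = 834.364625,
                       Annulus_E = 180.06106, Annulus_mu = 2051.947822,
                       Cartil_E = 5.673156)),
    Shear_stiff = list(
      intercept = -70.312808,
      coefficients = c(C10 = 199.672441, C0 = 199.736145, Fiber12 = 0.02166,
                       Fiber34 = 0.055155, Fiber56 = 0.031639,
                       Fiber78 = 0.057449, Fiber910 = 0.044255,
                       Annulus_E = 58.151336, Annulus_mu = -72.981833,
                       Cartil_E = 0.926751, Cartil_mu = -16.717294)),
    Exte_bulgeL = list(
      intercept = 0.083398,
      coefficients = c(Fiber910 = 0.00016, Annulus_mu = 0.028063,
                       Cartil_E = -0.001135)),
    Exte_bulgeP = list(
      intercept = -0.243941,
      coefficients = c(Fiber910 = 0.001987, Annulus_mu = 0.76198,
                       Cartil_E = -0.003522)),
    Exte_stiff = list(
      intercept = 6.205107,
      coefficients = c(Fiber910 = -0.01339, Annulus_mu = 2.595841,
                       Cartil_E = 0.008305)),
    LBend_bulgeL = list(
      intercept = 1.574761,
      coefficients = c(C10 = -1.014308, Annulus_mu = -0.929876,
                       Cartil_E = -0.017706, Cartil_mu = 1.620387)),
    LBend_bulgeP = list(
      intercept = 2.995354,
      coefficients = c(C10 = -3.019289, C0 = -3.118902, Annulus_E = -0.212027,
                       Annulus_mu = 1.351171, Cartil_E = -0.023247,
                       Cartil_mu = 0.84824)),
    LBend_stiff = list(
      intercept = -1.428516,
      coefficients = c(C10 = 1.708987, Annulus_E = 0.297374,
                       Annulus_mu = 3.014858, Cartil_E = 0.041594,
                       Cartil_mu = -1.896308)),
    Flex_bulgeL = list(
      intercept = 0.125918,
      coefficients = c(C10 = -0.064104, C0 = -0.060597, Fiber12 = -3.1e-5,
                       Annulus_E = -0.00418, Annulus_mu = 0.04945,
                       Cartil_E = -0.000311, Cartil_mu = -0.019064)),
    Flex_bulgeP = list(
      intercept = 0.681909,
      coefficients = c(C10 = -0.920479, C0 = -0.921496, Annulus_E = -0.048626,
                       Annulus_mu = -0.113105, Cartil_mu = 0.039252)),
    Flex_stiff = list(
      intercept = -0.697824,
      coefficients = c(C10 = 1.433372, C0 = 1.443693, Annulus_E = 0.269714,
                       Annulus_mu = 2.099688, Cartil_E = 0.013196,
                       Cartil_mu = -0.368862)),
    Tors_stiff = list(
      intercept = -2.079685,
      coefficients = c(C10 = 1.056596, C0 = 0.901329, Fiber34 = 0.00263,
                       Fiber56 = -0.000469, Fiber78 = 0.001202,
                       Annulus_E = 0.908448, Annulus_mu = -0.905043,
                       Cartil_E = 0.013001, Cartil_mu = -0.521362))
  )
  structure(b, class = "response_bundle", provenance = "reference",
            notes = c(
              "shear stiffness surface mislabelled 'Cort_stiff' at source",
              "coefficients typeset as 'x 10-0.5' transcribed as 1e-5 scale"))
}

#' @export
print.response_bundle <- function(x, ...) {
  cat("Response-surface bundle (", length(x), " responses, provenance: ",
      attr(x, "provenance") %||% "unknown", ")\n", sep = "")
  for (nm in names(x)) {
    cat("  ", nm, ": intercept ", format(x[[nm]]$intercept, digits = 6),
        " + ", length(x[[nm]]$coefficients), " linear term(s)\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a response-surface bundle at one parameter set
#'
#' Each response is the affine form `b0 + sum_i b_i x_i` in physical units.
#' Deterministic; responses with no stored coefficient for a parameter are
#' simply insensitive to it.
#'
#' @param bundle `response_bundle`.
#' @param params Named numeric vector covering every parameter the bundle
#'   references (an `ivd_params` vector, or any named vector — validity
#'   checks are the caller's concern so that out-of-box probes remain
#'   possible).
#' @return Named numeric vector, one value per bundle response.
#' @examples
#' evaluate_responses(reference_bundle(),
#'                    material_parameters(0.125, 0.03, 532.5, 509, 479,
#'                                        431.5, 384, 4.1, 0.35, 39, 0.35))
#' @export
evaluate_responses <- function(bundle, params) {
  stopifnot(inherits(bundle, "response_bundle") || is.list(bundle))
  p <- unclass(params)
  needed <- unique(unlist(lapply(bundle, function(m) names(m$coefficients))))
  if (!all(needed %in% names(p))) {
    stop("schema error: parameter(s) missing from set: ",
         paste(setdiff(needed, names(p)), collapse = ", "))
  }
  vapply(bundle, function(m) {
    m$intercept + sum(m$coefficients * p[names(m$coefficients)])
  }, numeric(1))
}

#' Simulate a response table for a design (the virtual FE campaign)
#'
#' Evaluates the bundle at every run of a physical-unit design and adds
#' optional independent Gaussian noise per response. With `noise_sd = 0`
#' the table is exactly affine in the design.
#'
#' @param design Physical-unit design data frame (runs x parameters).
#' @param bundle `response_bundle` (default [reference_bundle()]).
#' @param noise_sd Gaussian noise standard deviation: a single number applied
#'   to all responses, or a named vector per response, in response units.
#'   Default 0 (noise-free).
#' @param seed Integer seed, required when `noise_sd > 0`.
#' @return Data frame (runs x responses).
#' @export
simulate_batch <- function(design, bundle = reference_bundle(), noise_sd = 0,
                           seed = NULL) {
  stopifnot(is.data.frame(design))
  if (identical(attr(design, "coding"), "coded")) {
    stop("design must be decoded to physical units before simulation")
  }
  resp <- names(bundle)
  sd_vec <- if (length(noise_sd) == 1) {
    stats::setNames(rep(noise_sd, length(resp)), resp)
  } else {
    if (!all(resp %in% names(noise_sd))) {
      stop("per-response noise_sd must name every response")
    }
    noise_sd[resp]
  }
  if (any(sd_vec < 0)) stop("noise standard deviations must be >= 0")
  out <- t(apply(design, 1, function(row) {
    evaluate_responses(bundle, stats::setNames(as.numeric(row), names(design)))
  }))
  out <- as.data.frame(out)
  names(out) <- resp
  if (any(sd_vec > 0)) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    for (nm in resp) {
      if (sd_vec[nm] > 0) {
        out[[nm]] <- out[[nm]] + stats::rnorm(nrow(out), 0, sd_vec[nm])
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Reference noise preset
#'
#' A per-response noise standard deviation equal to a fraction (default 2%)
#' of that response's total range over the design box — the affine range is
#' `sum_i |b_i| (max_i - min_i)`. Used for robustness experiments; the
#' pipeline default remains noise-free.
#'
#' @param bundle `response_bundle`.
#' @param ranges `ivd_ranges` box.
#' @param frac Fraction of the range (default 0.02).
#' @return Named numeric vector of standard deviations.
#' @export
noise_preset <- function(bundle = reference_bundle(),
                         ranges = default_parameter_ranges(), frac = 0.02) {
  r <- parameter_ranges(ranges)
  span <- stats::setNames(r$max - r$min, r$parameter)
  vapply(bundle, function(m) {
    frac * sum(abs(m$coefficients) * span[names(m$coefficients)])
  }, numeric(1))
}

#' Serialize a response bundle to JSON
#'
#' @param bundle `response_bundle`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bundle_json <- function(bundle, path) {
  obj <- list(
    provenance = attr(bundle, "provenance") %||% "fitted",
    notes = attr(bundle, "notes"),
    responses = lapply(bundle, function(m) {
      list(intercept = m$intercept, coefficients = as.list(m$coefficients))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a response bundle from JSON
#'
#' @param path JSON path written by [write_bundle_json()].
#' @return `response_bundle`.
#' @export
read_bundle_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  b <- lapply(obj$responses, function(m) {
    list(intercept = as.numeric(m$intercept),
         coefficients = unlist(m$coefficients))
  })
  structure(b, class = "response_bundle",
            provenance = obj$provenance %||% "fitted",
            notes = unlist(obj$notes))
}
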