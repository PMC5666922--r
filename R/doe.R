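# Design-of-experiments generation over the 11 coded material parameters.
# Regular two-level fractions are built by hand (base design in Yates order
# plus generator words); run counts for the design families are exact
# integer arithmetic.

#' Run counts of the classical design families
#'
#' Exact number of runs a design method requires for `k` factors:
#' full two-level factorial `2^k`, full three-level factorial `3^k`, central
#' composite design `2^k + 2k` (factorial core plus axial points, no centre
#' replicates), Box-Behnken designs from the classical published run-count
#' table, regular two-level fractions `2^(k-p)`, or a user-chosen `n_runs`
#' for random designs.
#'
#' @param method One of `"full_factorial_2level"`, `"full_factorial_3level"`,
#'   `"ccd"`, `"bbd"`, `"fractional_2level"`, `"random_uniform"`.
#' @param k Number of factors, `>= 1`.
#' @param p Fraction exponent (required for `fractional_2level`).
#' @param n_runs Run count (required for `random_uniform`).
#' @return Integer-valued run count (double, since `3^11` exceeds the
#'   integer range comfortably representable everywhere).
#' @examples
#' design_size("fractional_2level", k = 11, p = 4) # 128
#' design_size("bbd", k = 11)                      # 176
#' @export
design_size <- function(method = c("full_factorial_2level",
                                   "full_factorial_3level", "ccd", "bbd",
                                   "fractional_2level", "random_uniform"),
                        k, p = NULL, n_runs = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(k), length(k) == 1, k >= 1, k == round(k))
  # classical BBD design-point counts (no centre replicates)
  bbd_runs <- c(`3` = 12, `4` = 24, `5` = 40, `6` = 48, `7` = 56,
                `9` = 120, `10` = 160, `11` = 176, `12` = 192, `16` = 384)
  switch(method,
    full_factorial_2level = 2^k,
    full_factorial_3level = 3^k,
    ccd = 2^k + 2 * k,
    bbd = {
      key <- as.character(k)
      if (!key %in% names(bbd_runs)) {
        stop("unsupported design: no Box-Behnken run count for k = ", k)
      }
      unname(bbd_runs[key])
    },
    fractional_2level = {
      if (is.null(p)) stop("fractional_2level requires the fraction exponent p")
      stopifnot(p >= 1, p < k, p == round(p))
      2^(k - p)
    },
    random_uniform = {
      if (is.null(n_runs)) stop("random_uniform requires n_runs")
      stopifnot(n_runs >= 1, n_runs == round(n_runs))
      n_runs
    }
  )
}

#' Default generator words for the packaged 2^(11-4) fraction
#'
#' Generator words over the seven base factors for the four aliased factors
#' of the 128-run fraction, chosen so that every word of the defining
#' contrast subgroup has length at least four (resolution IV): the fraction
#' estimates all main effects clear of two-factor interactions, which is all
#' a first-order surrogate needs.
#'
#' @return Named list: aliased factor position -> integer vector of base
#'   factor positions whose product generates it.
#' @export
default_generators <- function() {
  list(`8` = c(1, 2, 3, 4), `9` = c(1, 2, 5, 6),
       `10` = c(1, 3, 5, 7), `11` = c(2, 4, 6, 7))
}

#' Words of the defining contrast subgroup of a regular fraction
#'
#' Expands the generator words into all 2^p - 1 defining words (as sorted
#' integer vectors of factor positions, aliased factors included). The
#' design resolution is the minimum word length.
#'
#' @param generators Generator list as [default_generators()].
#' @param k Total factor count.
#' @return List of integer vectors.
#' @export
defining_words <- function(generators, k = 11) {
  p <- length(generators)
  gen_words <- lapply(seq_along(generators), function(i) {
    sort(c(generators[[i]], as.integer(names(generators)[i])))
  })
  words <- list()
  for (mask in seq_len(2^p - 1)) {
    w <- integer(0)
    for (i in seq_len(p)) {
      if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0) {
        # symmetric difference: shared factors square away
        w <- sort(c(setdiff(w, gen_words[[i]]), setdiff(gen_words[[i]], w)))
      }
    }
    words[[mask]] <- w
  }
  words
}

#' Generate a regular two-level fractional factorial design
#'
#' Builds the `2^(k-p)` coded design: the base factors form a full two-level
#' factorial in Yates order, and each aliased factor is the elementwise
#' product of the base columns named by its generator word. Every column of
#' a regular fraction is balanced (equal counts of -1 and +1) and all column
#' pairs are orthogonal.
#'
#' @param k Total factor count (default 11).
#' @param p Fraction exponent (default 4, giving 128 runs).
#' @param generators Generator list mapping aliased factor positions
#'   (`k - p + 1` ... `k`) to base-factor index vectors; default
#'   [default_generators()] for `k = 11, p = 4`.
#' @param factor_names Column names; defaults to [parameter_names()] when
#'   `k == 11`, else `F1 ... Fk`.
#' @return Data frame of -1/+1 levels with attributes `coding = "coded"`,
#'   `generators`, and `defining_words`.
#' @export
fractional_factorial <- function(k = 11, p = 4,
                                 generators = NULL, factor_names = NULL) {
  stopifnot(k >= 2, p >= 1, p < k)
  if (is.null(generators)) {
    if (k == 11 && p == 4) {
      generators <- default_generators()
    } else {
      stop("no default generators for k = ", k, ", p = ", p,
           "; supply them explicitly")
    }
  }
  if (length(generators) != p) {
    stop("generator parse error: expected ", p, " generator words, got ",
         length(generators))
  }
  base_k <- k - p
  gen_pos <- as.integer(names(generators))
  if (any(is.na(gen_pos)) || !setequal(gen_pos, (base_k + 1):k)) {
    stop("generator parse error: aliased positions must be ",
         base_k + 1, "..", k)
  }
  if (any(vapply(generators, function(g) any(g < 1 | g > base_k), TRUE))) {
    stop("generator parse error: words must index base factors 1..", base_k)
  }
  if (is.null(factor_names)) {
    factor_names <- if (k == 11) parameter_names() else paste0("F", seq_len(k))
  }
  stopifnot(length(factor_names) == k)

  n <- 2^base_k
  base_cols <- lapply(seq_len(base_k), function(j) {
    rep(rep(c(-1, 1), each = 2^(j - 1)), length.out = n)
  })
  m <- matrix(0, n, k)
  for (j in seq_len(base_k)) m[, j] <- base_cols[[j]]
  for (i in seq_len(p)) {
    m[, gen_pos[i]] <- apply(m[, generators[[i]], drop = FALSE], 1, prod)
  }
  design <- as.data.frame(m)
  names(design) <- factor_names
  attr(design, "coding") <- "coded"
  attr(design, "generators") <- generators
  attr(design, "defining_words") <- defining_words(generators, k)
  design
}

#' Decode a coded design into physical parameter values
#'
#' Affine map per factor: coded -1 to the range minimum, +1 to the maximum.
#'
#' @param design Coded design (data frame in `[-1, 1]`).
#' @param ranges `ivd_ranges` table covering every design column.
#' @return Data frame of physical values with `coding = "physical"`.
#' @export
decode_design <- function(design, ranges) {
  r <- parameter_ranges(ranges)
  if (!all(names(design) %in% r$parameter)) {
    stop("schema error: design columns not covered by ranges: ",
         paste(setdiff(names(design), r$parameter), collapse = ", "))
  }
  out <- design
  for (nm in names(design)) {
    i <- match(nm, r$parameter)
    # convex-combination form: -1 and +1 hit the bounds exactly in floats
    out[[nm]] <- ((1 - design[[nm]]) * r$min[i] +
                    (1 + design[[nm]]) * r$max[i]) / 2
  }
  attr(out, "coding") <- "physical"
  attr(out, "generators") <- attr(design, "generators")
  attr(out, "defining_words") <- attr(design, "defining_words")
  out
}

#' Encode a physical design into coded units
#'
#' Inverse of [decode_design()].
#'
#' @param design Physical-unit design data frame.
#' @param ranges `ivd_ranges` table covering every design column.
#' @return Coded data frame with `coding = "coded"`.
#' @export
encode_design <- function(design, ranges) {
  r <- parameter_ranges(ranges)
  if (!all(names(design) %in% r$parameter)) {
    stop("schema error: design columns not covered by ranges: ",
         paste(setdiff(names(design), r$parameter), collapse = ", "))
  }
  out <- design
  for (nm in names(design)) {
    i <- match(nm, r$parameter)
    mid <- (r$min[i] + r$max[i]) / 2
    hw <- (r$max[i] - r$min[i]) / 2
    out[[nm]] <- (design[[nm]] - mid) / hw
  }
  attr(out, "coding") <- "coded"
  out
}

#' Generate a random uniform test design
#'
#' Draws `n` runs uniformly inside the (optionally expanded) parameter box,
#' for held-out testing of fitted surrogates. Reproducible for a fixed seed;
#' box-vertex duplicates are almost surely absent and are rejected if drawn.
#'
#' @param n Number of runs (default 30).
#' @param ranges `ivd_ranges` table.
#' @param seed Integer seed (required).
#' @param expand Box expansion factor (`>= 1`, default 1).
#' @return Physical-unit design data frame.
#' @export
test_design <- function(n = 30, ranges = default_parameter_ranges(), seed,
                        expand = 1) {
  stopifnot(n >= 1, n == round(n))
  if (missing(seed)) stop("a seed is required for random designs")
  r <- if (expand > 1) expand_ranges(ranges, expand) else parameter_ranges(ranges)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- vapply(seq_len(nrow(r)),
              function(i) stats::runif(n, r$min[i], r$max[i]),
              numeric(n))
  m <- matrix(m, nrow = n)
  # a draw landing exactly on a vertex (probability zero, but guard anyway)
  at_vertex <- apply(m, 1, function(row) all(row %in% c(r$min, r$max)))
  if (any(at_vertex)) {
    m[at_vertex, ] <- vapply(seq_len(nrow(r)),
                             function(i) stats::runif(sum(at_vertex),
                                                      r$min[i], r$max[i]),
                             numeric(sum(at_vertex)))
  }
  out <- as.data.frame(m)
  names(out) <- r$parameter
  attr(out, "coding") <- "physical"
  attr(out, "seed") <- seed
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a design matrix to CSV with a JSON sidecar
#'
#' The CSV carries a `Run` index column followed by the factor columns; the
#' sidecar (same path with extension `.json`) records the design metadata
#' (coding, generators and defining words where present).
#'
#' @param design Design data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  out <- cbind(Run = seq_len(nrow(design)), .format_numeric_df(design))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    coding = attr(design, "coding"),
    n_runs = nrow(design),
    factors = names(design),
    generators = attr(design, "generators"),
    defining_words = attr(design, "defining_words")
  )
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Read a design matrix written by [write_design_csv()]
#'
#' @param path CSV path.
#' @return Design data frame (metadata restored from the sidecar if found).
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  df$Run <- NULL
  side <- sub("\\.csv$", ".json", path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(df, "coding") <- meta$coding
  }
  df
}

# fixed-width significant-digit formatting for byte-stable artefacts
.format_numeric_df <- function(df, digits = 6) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- formatC(signif(out[[nm]], digits), format = "g",
                           digits = digits)
    }
  }
  out
}
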