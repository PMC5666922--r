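#' @keywords internal
"_PACKAGE"

#' Names of the eleven disc material parameters
#'
#' The calibrated material space of the disc model: two Mooney-Rivlin
#' constants for the nucleus pulposus (`C10`, `C0`, MPa), the elastic moduli
#' of the five collagen fiber layers of the annulus (`Fiber12` ... `Fiber910`,
#' MPa, numbered outermost to innermost), the annulus ground-substance
#' modulus (`Annulus_E`, MPa) and Poisson ratio (`Annulus_mu`), and the
#' endplate cartilage modulus (`Cartil_E`, MPa) and Poisson ratio
#' (`Cartil_mu`).
#'
#' @return Character vector of length 11, in canonical order.
#' @export
parameter_names <- function() {
  c("C10", "C0", "Fiber12", "Fiber34", "Fiber56", "Fiber78", "Fiber910",
    "Annulus_E", "Annulus_mu", "Cartil_E", "Cartil_mu")
}

#' Construct a validated material parameter set
#'
#' Bundles the eleven material parameters of the disc model into a named
#' numeric vector and checks physical validity: all moduli must be strictly
#' positive and both Poisson ratios must lie in (0, 0.5). Containment in the
#' calibration design ranges is deliberately *not* enforced (optimal
#' parameter sets may legitimately fall outside them); use
#' [within_design_range()] to report it.
#'
#' @param c10,c0 Mooney-Rivlin constants of the nucleus pulposus (MPa).
#' @param fiber12,fiber34,fiber56,fiber78,fiber910 Elastic moduli of the
#'   five annulus fiber layers (MPa).
#' @param annulus_e Annulus ground-substance elastic modulus (MPa).
#' @param annulus_mu Annulus ground-substance Poisson ratio.
#' @param cartil_e Endplate cartilage elastic modulus (MPa).
#' @param cartil_mu Endplate cartilage Poisson ratio.
#' @return Named numeric vector of class `ivd_params`.
#' @examples
#' material_parameters(0.125, 0.03, 532.5, 509, 479, 431.5, 384, 4.1, 0.35,
#'                     39, 0.35)
#' @export
material_parameters <- function(c10, c0, fiber12, fiber34, fiber56, fiber78,
                                fiber910, annulus_e, annulus_mu, cartil_e,
                                cartil_mu) {
  p <- c(C10 = c10, C0 = c0, Fiber12 = fiber12, Fiber34 = fiber34,
         Fiber56 = fiber56, Fiber78 = fiber78, Fiber910 = fiber910,
         Annulus_E = annulus_e, Annulus_mu = annulus_mu,
         Cartil_E = cartil_e, Cartil_mu = cartil_mu)
  as_material_parameters(p)
}

#' Coerce a named vector to a material parameter set
#'
#' @param x Named numeric vector containing all eleven parameters (extra
#'   names are dropped; order is normalised).
#' @return Named numeric vector of class `ivd_params`.
#' @export
as_material_parameters <- function(x) {
  nm <- parameter_names()
  if (!all(nm %in% names(x))) {
    stop("missing parameter(s): ", paste(setdiff(nm, names(x)), collapse = ", "))
  }
  p <- as.numeric(x[nm])
  names(p) <- nm
  if (any(!is.finite(p))) stop("all parameters must be finite")
  moduli <- nm[!nm %in% c("Annulus_mu", "Cartil_mu")]
  if (any(p[moduli] <= 0)) {
    stop("moduli must be strictly positive: ",
         paste(moduli[p[moduli] <= 0], collapse = ", "))
  }
  mus <- p[c("Annulus_mu", "Cartil_mu")]
  if (any(mus <= 0 | mus >= 0.5)) {
    stop("Poisson ratios must lie in (0, 0.5)")
  }
  structure(p, class = "ivd_params")
}

#' @export
print.ivd_params <- function(x, ...) {
  cat("Disc material parameters (MPa; Poisson ratios dimensionless):\n")
  print(format(unclass(x), digits = 6), quote = FALSE)
  invisible(x)
}

#' Default design ranges of the material parameters
#'
#' The box bounds over which the calibration campaign is designed: the
#' nucleus Mooney-Rivlin constants, the five fiber-layer moduli (stepping
#' down from the outermost layer), the annulus ground substance, and the
#' endplate cartilage.
#'
#' @return Data frame of class `ivd_ranges` with columns `parameter`, `min`,
#'   `max` (units as in [material_parameters()]).
#' @export
default_parameter_ranges <- function() {
  parameter_ranges(data.frame(
    parameter = parameter_names(),
    min = c(0.11, 0.02, 515, 503, 455, 408, 360, 4.0, 0.25, 23, 0.3),
    max = c(0.14, 0.04, 550, 515, 503, 455, 408, 4.2, 0.45, 55, 0.4)
  ))
}

#' Validate a parameter-range table
#'
#' @param x Data frame with columns `parameter`, `min`, `max`.
#' @return `x` with class `ivd_ranges`, rows in canonical parameter order.
#' @export
parameter_ranges <- function(x) {
  stopifnot(is.data.frame(x), all(c("parameter", "min", "max") %in% names(x)))
  if (!all(parameter_names() %in% x$parameter)) {
    stop("ranges must cover all 11 parameters")
  }
  x <- x[match(parameter_names(), x$parameter),
         c("parameter", "min", "max"), drop = FALSE]
  rownames(x) <- NULL
  if (any(!is.finite(x$min)) || any(!is.finite(x$max)) || any(x$min >= x$max)) {
    stop("each range must satisfy min < max with finite bounds")
  }
  structure(x, class = c("ivd_ranges", "data.frame"))
}

#' Report containment of a parameter set in the design ranges
#'
#' Containment is a diagnostic, not a validity requirement: desirability
#' optima may sit outside the design box, particularly when the search box
#' is expanded (see [expand_ranges()]).
#'
#' @param params `ivd_params` vector or coercible named vector.
#' @param ranges `ivd_ranges` table; defaults to [default_parameter_ranges()].
#' @return Named logical vector, one entry per parameter.
#' @export
within_design_range <- function(params, ranges = default_parameter_ranges()) {
  p <- as_material_parameters(params)
  r <- parameter_ranges(ranges)
  out <- p >= r$min & p <= r$max
  names(out) <- r$parameter
  out
}

#' Symmetrically expand parameter ranges about their midpoints
#'
#' Multiplies every half-width by `factor`, keeping midpoints fixed. Used to
#' widen the desirability search box beyond the design ranges. Poisson-ratio
#' rows are clamped to (0, 0.5) and moduli to strictly positive values so
#' expanded boxes remain physically valid.
#'
#' @param ranges `ivd_ranges` table.
#' @param factor Expansion factor, `>= 1`.
#' @return Expanded `ivd_ranges` table.
#' @export
expand_ranges <- function(ranges, factor = 1.25) {
  r <- parameter_ranges(ranges)
  stopifnot(is.numeric(factor), length(factor) == 1, factor >= 1)
  mid <- (r$min + r$max) / 2
  hw <- (r$max - r$min) / 2 * factor
  r$min <- mid - hw
  r$max <- mid + hw
  mu <- r$parameter %in% c("Annulus_mu", "Cartil_mu")
  r$min[mu] <- pmax(r$min[mu], 1e-6)
  r$max[mu] <- pmin(r$max[mu], 0.5 - 1e-6)
  r$min[!mu] <- pmax(r$min[!mu], 1e-9)
  parameter_ranges(r)
}

#' Disc geometry used by the boundary-condition load conversions
#'
#' Defaults describe a medium-sized healthy lumbar disc: a 50 x 35 mm
#' elliptical footprint, 10 mm height, loaded through steel supports with a
#' 1440 mm^2 contact area. The centroid distances `cg_flexion` and
#' `cg_lateral` (lever arms of the anterior-area and half-area pressure
#' patches about the instantaneous axis of rotation) are never fixed by the
#' experimental protocol; when `NULL` they default to the half-ellipse
#' centroid distance of the relevant footprint half, 4a/(3*pi) with `a` the
#' semi-axis normal to the bending axis.
#'
#' @param width,depth,height Footprint width, depth and disc height (mm).
#' @param support_area Upper support contact area S (mm^2).
#' @param anterior_area Anterior pressure-patch area S_a (mm^2).
#' @param half_area Half-footprint area S/2 used in lateral bending (mm^2).
#' @param torsion_radius Radius R at which tangential node forces act (mm).
#' @param cg_flexion,cg_lateral Centroid lever arms (mm), or `NULL` for the
#'   half-ellipse default.
#' @return List of class `disc_geometry`.
#' @export
disc_geometry <- function(width = 50, depth = 35, height = 10,
                          support_area = 1440, anterior_area = 745,
                          half_area = 720, torsion_radius = 25,
                          cg_flexion = NULL, cg_lateral = NULL) {
  if (is.null(cg_flexion)) cg_flexion <- 4 * (depth / 2) / (3 * pi)
  if (is.null(cg_lateral)) cg_lateral <- 4 * (width / 2) / (3 * pi)
  g <- list(width = width, depth = depth, height = height,
            support_area = support_area, anterior_area = anterior_area,
            half_area = half_area, torsion_radius = torsion_radius,
            cg_flexion = cg_flexion, cg_lateral = cg_lateral)
  vals <- unlist(g)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry values must be finite and strictly positive")
  }
  if (g$half_area > g$support_area) {
    stop("half_area cannot exceed support_area")
  }
  structure(g, class = "disc_geometry")
}

#' @export
print.disc_geometry <- function(x, ...) {
  cat("Disc geometry (mm, mm^2):\n")
  print(format(unlist(unclass(x)), digits = 6), quote = FALSE)
  invisible(x)
}

#' Catalogue of the fifteen calibrated responses
#'
#' Six stiffnesses and nine bulges, grouped by the standard mechanical test
#' that produces them. Stiffness responses are load/displacement slopes
#' (N/mm for translational tests, N.m/deg for rotational tests); bulge
#' responses are radial outward wall displacements (mm) at the anterior
#' (A), lateral (L) or posterior (P) location.
#'
#' @return Data frame with columns `response`, `class`, `test`, `units`.
#' @export
response_catalogue <- function() {
  data.frame(
    response = c("Comp_bulgeA", "Comp_bulgeL", "Comp_bulgeP", "Comp_stiff",
                 "Shear_stiff", "Exte_bulgeL", "Exte_bulgeP", "Exte_stiff",
                 "LBend_bulgeL", "LBend_bulgeP", "LBend_stiff",
                 "Flex_bulgeL", "Flex_bulgeP", "Flex_stiff", "Tors_stiff"),
    class = c("bulge", "bulge", "bulge", "stiffness",
              "stiffness", "bulge", "bulge", "stiffness",
              "bulge", "bulge", "stiffness",
              "bulge", "bulge", "stiffness", "stiffness"),
    test = c("compression", "compression", "compression", "compression",
             "shear", "extension", "extension", "extension",
             "lateral_bending", "lateral_bending", "lateral_bending",
             "flexion", "flexion", "flexion", "torsion"),
    units = c("mm", "mm", "mm", "N/mm",
              "N/mm", "mm", "mm", "N.m/deg",
              "mm", "mm", "N.m/deg",
              "mm", "mm", "N.m/deg", "N.m/deg")
  )
}

#' Standard-test loads
#'
#' The load magnitude applied in each of the six standard tests of the
#' experimental protocol the model is calibrated against.
#'
#' @return Data frame with columns `test`, `load`, `unit` (`N` for
#'   translational tests, `N.m` for moments).
#' @export
standard_test_loads <- function() {
  data.frame(
    test = c("compression", "flexion", "extension", "lateral_bending",
             "shear", "torsion"),
    load = c(500, 5, 4, 10.6, 450, 10),
    unit = c("N", "N.m", "N.m", "N.m", "N", "N.m")
  )
}

#' Experimental calibration targets
#'
#' The fifteen experimental values (six stiffnesses, nine bulges) the disc
#' model is adjusted to, joined to the response catalogue.
#'
#' @return [response_catalogue()] with an extra `target` column.
#' @export
experimental_targets <- function() {
  cat15 <- response_catalogue()
  tg <- c(Comp_bulgeA = 0.5, Comp_bulgeL = 0.35, Comp_bulgeP = 0.75,
          Comp_stiff = 810, Shear_stiff = 300,
          Exte_bulgeL = 0.1, Exte_bulgeP = 0.24, Exte_stiff = 1.53,
          LBend_bulgeL = 2.11, LBend_bulgeP = 1.13, LBend_stiff = 2.0,
          Flex_bulgeL = 0.07, Flex_bulgeP = 0.73, Flex_stiff = 1.18,
          Tors_stiff = 2.1)
  cat15$target <- unname(tg[cat15$response])
  cat15
}

# ---- boundary-condition load conversions --------------------------------

.check_moment_unit <- function(value, unit) {
  unit <- match.arg(unit, c("N.mm", "N.m"))
  if (unit == "N.m") value * 1000 else value
}

#' Compression pressure on the upper support
#'
#' Converts the compression test load into the uniform pressure applied to
#' the upper steel support: `P = F_max / S`.
#'
#' @param f_max Maximum compression load (N), `>= 0`.
#' @param s Support contact area (mm^2), `> 0`.
#' @return Pressure (MPa).
#' @examples
#' compression_pressure(500, 1440)
#' @export
compression_pressure <- function(f_max, s) {
  stopifnot(is.numeric(f_max), is.numeric(s))
  if (any(f_max < 0)) stop("f_max must be non-negative")
  if (any(s <= 0)) stop("area must be strictly positive")
  f_max / s
}

#' Flexion pressure on the anterior area
#'
#' Converts the flexion moment into the pressure applied over the anterior
#' area of the disc: `P = B_max / (S_a * CG)`, with `CG` the lever arm of the
#' anterior patch about the instantaneous axis of rotation. Moments are in
#' N.mm in the package's canonical units; pass `unit = "N.m"` to convert
#' (x 1000) at the interface.
#'
#' @param b_max Maximum flexion moment, `> 0` (N.mm, or N.m with
#'   `unit = "N.m"`); zero is allowed and returns zero pressure.
#' @param s_a Anterior area (mm^2), `> 0`.
#' @param cg Centroid lever arm (mm), `> 0`.
#' @param unit Moment unit of `b_max`.
#' @return Pressure (MPa).
#' @examples
#' flexion_pressure(5000, 745, 10)
#' flexion_pressure(5, 745, 10, unit = "N.m")
#' @export
flexion_pressure <- function(b_max, s_a, cg, unit = c("N.mm", "N.m")) {
  b_max <- .check_moment_unit(b_max, match.arg(unit))
  stopifnot(is.numeric(b_max), is.numeric(s_a), is.numeric(cg))
  if (any(b_max < 0)) stop("moment must be non-negative")
  if (any(s_a <= 0) || any(cg <= 0)) {
    stop("area and centroid distance must be strictly positive")
  }
  b_max / (s_a * cg)
}

#' Lateral-bending pressure on the half footprint
#'
#' `P = LB_max / ((S/2) * CG)`: same conversion as [flexion_pressure()] with
#' the half-footprint area in place of the anterior area.
#'
#' @param lb_max Maximum lateral-bending moment (N.mm, or N.m with
#'   `unit = "N.m"`).
#' @param half_area Half-footprint area S/2 (mm^2), `> 0`.
#' @param cg Centroid lever arm (mm), `> 0`.
#' @param unit Moment unit of `lb_max`.
#' @return Pressure (MPa).
#' @examples
#' lateral_bending_pressure(10600, 720, 10)
#' @export
lateral_bending_pressure <- function(lb_max, half_area, cg,
                                     unit = c("N.mm", "N.m")) {
  flexion_pressure(lb_max, half_area, cg, unit = match.arg(unit))
}

#' Per-node tangential force for the torsion test
#'
#' The torsion moment is applied as equal tangential forces on `n` peripheral
#' nodes at radius `R`: `F_t = T_max / (n * R)`, so that the node forces sum
#' back to the applied torque.
#'
#' @param t_max Maximum torsion moment (N.mm, or N.m with `unit = "N.m"`).
#' @param n Number of loaded nodes, integer `>= 1`.
#' @param r Loading radius (mm), `> 0`.
#' @param unit Moment unit of `t_max`.
#' @return Force per node (N).
#' @examples
#' torsion_node_force(10000, 40, 25)
#' @export
torsion_node_force <- function(t_max, n, r, unit = c("N.mm", "N.m")) {
  t_max <- .check_moment_unit(t_max, match.arg(unit))
  stopifnot(is.numeric(t_max), is.numeric(n), is.numeric(r))
  if (any(n < 1) || any(n != round(n))) stop("n must be an integer >= 1")
  if (any(r <= 0)) stop("radius must be strictly positive")
  if (any(t_max < 0)) stop("moment must be non-negative")
  t_max / (n * r)
}

#' Per-node shear force
#'
#' The shear load is split evenly over the `n` loaded nodes of the upper
#' support: `F_s = F_max / n`.
#'
#' @param f_max Maximum shear load (N), `>= 0`.
#' @param n Number of loaded nodes, integer `>= 1`.
#' @return Force per node (N).
#' @examples
#' shear_node_force(450, 45)
#' @export
shear_node_force <- function(f_max, n) {
  stopifnot(is.numeric(f_max), is.numeric(n))
  if (any(n < 1) || any(n != round(n))) stop("n must be an integer >= 1")
  if (any(f_max < 0)) stop("f_max must be non-negative")
  f_max / n
}

# ---- configuration ------------------------------------------------------

#' Load a disc-model configuration
#'
#' Reads a YAML configuration holding the disc geometry, the standard-test
#' loads, the experimental targets and the parameter design ranges, and
#' returns them as validated package objects. The packaged default
#' configuration reproduces the protocol values exactly.
#'
#' @param path Path to a YAML file; default is the packaged configuration.
#' @return List of class `disc_config` with elements `geometry`
#'   (`disc_geometry`), `loads` (data frame), `targets` (data frame) and
#'   `ranges` (`ivd_ranges`).
#' @export
load_config <- function(path = system.file("extdata", "default_config.yaml",
                                           package = "ivdcalib")) {
  raw <- yaml::read_yaml(path)
  geom <- do.call(disc_geometry, raw$geometry)
  loads <- do.call(rbind, lapply(raw$loads, as.data.frame))
  targets <- do.call(rbind, lapply(raw$targets, as.data.frame))
  ranges <- parameter_ranges(do.call(rbind, lapply(raw$ranges, as.data.frame)))
  structure(list(geometry = geom, loads = loads, targets = targets,
                 ranges = ranges),
            class = "disc_config")
}

#' Serialize a disc-model configuration back to YAML
#'
#' Inverse of [load_config()]: re-serializing the packaged default
#' configuration reproduces its values exactly.
#'
#' @param config `disc_config` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "disc_config"))
  raw <- list(
    geometry = lapply(unclass(config$geometry), identity),
    loads = lapply(seq_len(nrow(config$loads)),
                   function(i) as.list(config$loads[i, ])),
    targets = lapply(seq_len(nrow(config$targets)),
                     function(i) as.list(config$targets[i, ])),
    ranges = lapply(seq_len(nrow(config$ranges)),
                    function(i) as.list(as.data.frame(config$ranges)[i, ]))
  )
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}
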