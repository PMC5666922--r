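test_that("boundary-condition load conversions match direct arithmetic", {
  # compression: P = F/S
  expect_equal(compression_pressure(500, 1440), 500 / 1440)
  expect_equal(compression_pressure(0, 1440), 0)
  expect_equal(compression_pressure(1440, 1440), 1)

  # flexion: P = B / (S_a * CG), moments canonically in N.mm
  expect_equal(flexion_pressure(5000, 745, 10), 5000 / 7450)
  expect_equal(flexion_pressure(5, 745, 10, unit = "N.m"),
               flexion_pressure(5000, 745, 10))
  expect_equal(flexion_pressure(0, 745, 3), 0)
  expect_equal(flexion_pressure(5000, 745, 20),
               flexion_pressure(5000, 745, 10) / 2)

  # lateral bending over the half footprint
  expect_equal(lateral_bending_pressure(10600, 720, 10), 10600 / 7200)
  expect_equal(lateral_bending_pressure(0, 720, 5), 0)
  expect_equal(lateral_bending_pressure(3 * 10600, 720, 10),
               3 * lateral_bending_pressure(10600, 720, 10))

  # torsion node force: F = T / (n R); node forces recover the torque
  expect_equal(torsion_node_force(10000, 40, 25), 10)
  expect_equal(torsion_node_force(10000, 1, 25), 400)
  expect_equal(40 * torsion_node_force(10000, 40, 25) * 25, 10000)

  # shear node force: F = F_max / n
  expect_equal(shear_node_force(450, 45), 10)
  expect_equal(shear_node_force(450, 1), 450)
  expect_equal(shear_node_force(0, 7), 0)

  expect_error(compression_pressure(500, 0), "positive")
  expect_error(flexion_pressure(5000, 745, 0), "positive")
  expect_error(torsion_node_force(10000, 0, 25), "integer")
  expect_error(shear_node_force(450, 0), "integer")
})

test_that("conversions are degree-1 homogeneous in load, degree -1 in divisor", {
  set.seed(11)
  for (i in 1:25) {
    load <- runif(1, 1, 1e4)
    div <- runif(1, 1, 2e3)
    cg <- runif(1, 1, 30)
    k <- runif(1, 0.5, 5)
    expect_equal(compression_pressure(k * load, div),
                 k * compression_pressure(load, div), tolerance = 1e-13)
    expect_equal(compression_pressure(load, k * div),
                 compression_pressure(load, div) / k, tolerance = 1e-13)
    expect_equal(flexion_pressure(k * load, div, cg),
                 k * flexion_pressure(load, div, cg), tolerance = 1e-13)
    expect_equal(flexion_pressure(load, div, k * cg),
                 flexion_pressure(load, div, cg) / k, tolerance = 1e-13)
    n <- sample(1:60, 1)
    expect_equal(torsion_node_force(k * load, n, cg),
                 k * torsion_node_force(load, n, cg), tolerance = 1e-13)
    expect_equal(shear_node_force(k * load, n),
                 k * shear_node_force(load, n), tolerance = 1e-13)
  }
})

test_that("material-parameter validation enforces physical bounds only", {
  p <- material_parameters(0.125, 0.03, 532.5, 509, 479, 431.5, 384,
                           4.1, 0.35, 39, 0.35)
  expect_s3_class(p, "ivd_params")
  expect_named(p, parameter_names())

  expect_error(material_parameters(-0.1, 0.03, 532.5, 509, 479, 431.5, 384,
                                   4.1, 0.35, 39, 0.35), "positive")
  expect_error(material_parameters(0.125, 0.03, 532.5, 509, 479, 431.5, 384,
                                   4.1, 0.55, 39, 0.35), "Poisson")
  expect_error(as_material_parameters(c(C10 = 0.1)), "missing parameter")

  # design-range containment is reported, not enforced: the reference
  # criterion-1 optimum is a valid parameter set partly outside the box
  opt1 <- as_material_parameters(reference_optimum(1))
  inside <- within_design_range(opt1)
  expect_false(all(inside))
  expect_false(inside[["C10"]])     # 0.102 < 0.11
  expect_false(inside[["Fiber56"]]) # 517.692 > 503
  expect_true(inside[["Cartil_E"]])

  vertex <- as_material_parameters(
    c(C10 = 0.11, C0 = 0.02, Fiber12 = 515, Fiber34 = 503, Fiber56 = 455,
      Fiber78 = 408, Fiber910 = 360, Annulus_E = 4, Annulus_mu = 0.25,
      Cartil_E = 55, Cartil_mu = 0.4))
  expect_true(all(within_design_range(vertex)))
})

test_that("the packaged configuration reproduces the protocol and round-trips", {
  cfg <- load_config()
  expect_equal(unclass(cfg$geometry)[c("width", "depth", "height",
                                       "support_area", "anterior_area",
                                       "half_area", "torsion_radius")],
               list(width = 50, depth = 35, height = 10, support_area = 1440,
                    anterior_area = 745, half_area = 720, torsion_radius = 25))
  expect_equal(cfg$loads[order(cfg$loads$test), ],
               standard_test_loads()[order(standard_test_loads()$test), ],
               ignore_attr = TRUE)
  expect_equal(cfg$targets$target, experimental_targets()$target)
  expect_equal(as.data.frame(cfg$ranges),
               as.data.frame(default_parameter_ranges()))

  # serialize and reload: values identical
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  cfg2 <- load_config(tmp)
  expect_equal(unclass(cfg2$geometry), unclass(cfg$geometry))
  expect_equal(cfg2$targets$target, cfg$targets$target)
  expect_equal(as.data.frame(cfg2$ranges), as.data.frame(cfg$ranges))
})

test_that("range expansion keeps midpoints and physical validity", {
  r <- default_parameter_ranges()
  ex <- expand_ranges(r, 1.25)
  expect_equal((ex$min + ex$max) / 2, (r$min + r$max) / 2)
  expect_equal(ex$max - ex$min, 1.25 * (r$max - r$min))
  wide <- expand_ranges(r, 3)
  mu <- wide$parameter %in% c("Annulus_mu", "Cartil_mu")
  expect_true(all(wide$max[mu] < 0.5))
  expect_true(all(wide$min > 0))
  expect_error(expand_ranges(r, 0.8))
})
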