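test_that("generated polygons satisfy the angle-sum identity and bounds", {
  cfg <- geometry_config()
  for (seed in 1:20) {
    for (n in c(3L, 4L)) {
      p <- generate_polygon(n, cfg, seed = seed)
      expect_equal(sum(p$interior_angles), (n - 2) * 180, tolerance = 1e-9)
      b <- cfg$interior_angle_bounds[[as.character(n)]]
      expect_true(all(p$interior_angles >= b[1] & p$interior_angles <= b[2]))
      expect_true(psicat:::polygon_is_convex(as.matrix(p$vertices)))
    }
  }
})

test_that("infeasible interior-angle bounds raise a configuration error", {
  cfg <- geometry_config(interior_angle_bounds = list(`3` = c(170, 175),
                                                      `4` = c(50, 130)))
  expect_error(generate_polygon(3, cfg, seed = 1), "infeasible")
})

test_that("polygon generation is a pure function of (config, seed)", {
  cfg <- geometry_config()
  a <- generate_polygon(4, cfg, seed = 99)
  b <- generate_polygon(4, cfg, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, generate_polygon(4, cfg, seed = 100)))
})

test_that("geometry_config validates its invariants", {
  expect_error(geometry_config(interior_angle_bounds =
                                 list(`3` = c(120, 30), `4` = c(50, 130))),
               "0 < min < max < 180")
  expect_error(geometry_config(nosci_rotation_bounds = c(0, 90)), "min")
  expect_error(geometry_config(inducer_radius = 3), "inducer_radius")
})

test_that("SCI targets are collinear and no-SCI rotations stay in bounds", {
  cfg <- geometry_config()
  for (seed in 1:10) {
    p <- generate_polygon(3, cfg, seed = seed)
    sci <- make_target(p, "SCI", cfg)
    expect_lt(max(measure_rotation_offsets(sci)), 1e-6)
    nosci <- make_target(p, "noSCI", cfg, seed = seed + 1)
    dev <- measure_rotation_offsets(nosci)
    expect_true(all(dev >= cfg$nosci_rotation_bounds[1] - 1e-9 &
                      dev <= cfg$nosci_rotation_bounds[2] + 1e-9))
  }
})

test_that("SCI and no-SCI targets share inducer centres and radii", {
  p <- generate_polygon(4, seed = 5)
  sci <- make_target(p, "SCI")
  nosci <- make_target(p, "noSCI", seed = 6)
  expect_equal(sci$inducers[c("cx", "cy", "radius", "mouth_angle")],
               nosci$inducers[c("cx", "cy", "radius", "mouth_angle")])
})

test_that("congruent primers trace the target mouths; incongruent deviate", {
  cfg <- geometry_config()
  for (seed in 1:8) {
    p <- generate_polygon(3, cfg, seed = seed)
    tgt <- make_target(p, "SCI", cfg)
    con <- make_primer(tgt, "con", cfg)
    expect_lt(max(measure_primer_deviation(con, tgt)), 1e-6)
    expect_equal(nrow(con$segments), 2 * p$n_vertices)
    inc <- make_primer(tgt, "inc", cfg, seed = seed + 50)
    expect_true(all(measure_primer_deviation(inc, tgt) >=
                      cfg$nosci_rotation_bounds[1] - 1e-9))
  }
})

test_that("incongruent primer of a no-SCI target is the collinear figure", {
  p <- generate_polygon(3, seed = 3)
  nosci <- make_target(p, "noSCI", seed = 4)
  sci <- make_target(p, "SCI")
  inc <- make_primer(nosci, "inc", seed = 5)
  expect_lt(max(measure_primer_deviation(inc, sci)), 1e-6)
})
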