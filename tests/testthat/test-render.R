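test_that("rendering is deterministic and respects the canvas", {
  p <- generate_polygon(3, seed = 1)
  tgt <- make_target(p, "SCI")
  r1 <- render_raster(tgt, pixels_per_degree = 16)
  r2 <- render_raster(tgt, pixels_per_degree = 16)
  expect_identical(r1, r2)
  # canvas corners are far from all inducers -> black
  expect_equal(r1[1, 1], 0)
  expect_equal(r1[1, ncol(r1)], 0)
  expect_true(any(r1 > 0))
  expect_error(render_raster(tgt, pixels_per_degree = 0), "pixels_per_degree")
})

test_that("SCI and no-SCI renders of one polygon have matched ink area", {
  for (seed in 1:5) {
    p <- generate_polygon(4, seed = seed)
    sci <- render_raster(make_target(p, "SCI"), pixels_per_degree = 24)
    nosci <- render_raster(make_target(p, "noSCI", seed = seed + 10),
                           pixels_per_degree = 24)
    expect_lt(abs(sum(sci) - sum(nosci)) / sum(sci), 0.01)
  }
})

test_that("PNG and SVG writers emit byte-identical output on repeat", {
  p <- generate_polygon(3, seed = 2)
  tgt <- make_target(p, "SCI")
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.png"); f2 <- file.path(d, "b.png")
  write_stimulus_png(tgt, f1, pixels_per_degree = 16)
  write_stimulus_png(tgt, f2, pixels_per_degree = 16)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  s1 <- file.path(d, "a.svg")
  write_stimulus_svg(tgt, s1)
  svg <- readLines(s1)
  expect_true(any(grepl("fill=\"white\"", svg)))
  expect_true(any(grepl("rect", svg)))
})

test_that("SVG paths round-trip the inducer geometry", {
  p <- generate_polygon(3, seed = 7)
  tgt <- make_target(p, "SCI")
  d <- withr::local_tempdir()
  f <- file.path(d, "t.svg")
  write_stimulus_svg(tgt, f)
  paths <- grep("^<path", readLines(f), value = TRUE)
  expect_length(paths, 3)
  # the path starts at the inducer centre (M cx cy)
  starts <- do.call(rbind, lapply(paths, function(x) {
    as.numeric(strsplit(sub('.*d="M ([^L]+)L.*', "\\1", x), " ")[[1]][1:2])
  }))
  expect_equal(starts[, 1], tgt$inducers$cx, tolerance = 1e-4)
  expect_equal(starts[, 2], tgt$inducers$cy, tolerance = 1e-4)
})

test_that("primer renders red segments of the configured length", {
  cfg <- geometry_config()
  p <- generate_polygon(3, seed = 4)
  tgt <- make_target(p, "SCI", cfg)
  pri <- make_primer(tgt, "con", cfg)
  seg_len <- sqrt((pri$segments$x1 - pri$segments$x0)^2 +
                    (pri$segments$y1 - pri$segments$y0)^2)
  expect_equal(seg_len, rep(cfg$primer_segment_length, 6))
  r <- render_raster(pri, pixels_per_degree = 24)
  expect_identical(attr(r, "ink"), "red")
  expect_true(sum(r) > 0)
})

test_that("gen_stimuli writes files and a manifest", {
  d <- withr::local_tempdir()
  man <- gen_stimuli(4, seed = 1, outdir = d, formats = "svg")
  expect_equal(nrow(man), 4)
  expect_true(file.exists(file.path(d, "manifest.json")))
  expect_true(all(file.exists(unlist(man$files))))
  expect_setequal(unique(man$congruency), c("con", "inc"))
})
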