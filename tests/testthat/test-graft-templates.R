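# small fixture template used throughout: irrational circumference avoids
# pixel-boundary ties between implementation and oracle
tiny_template <- graft_template("tiny", length = 20, proximal_diameter = 8,
                                ring_axial_positions = c(6, 14),
                                strut_amplitude = 4, strut_wire_width = 0.6,
                                n_peaks_per_ring = 3)

test_that("template construction validates its inputs", {
  t1 <- graft_template("u", length = 100, proximal_diameter = 30,
                       ring_axial_positions = c(10, 30, 50, 70, 90),
                       strut_amplitude = 12, strut_wire_width = 0.5,
                       n_peaks_per_ring = 8)
  expect_false(t1$tapered)
  expect_equal(t1$n_strut_rings, 5)
  t2 <- graft_template("t", length = 100, proximal_diameter = 34,
                       distal_diameter = 30,
                       ring_axial_positions = c(10, 90),
                       strut_amplitude = 12, strut_wire_width = 0.5,
                       n_peaks_per_ring = 8)
  expect_true(t2$tapered)
  expect_error(
    graft_template("bad", length = 100, proximal_diameter = 30,
                   ring_axial_positions = c(10, 110),
                   strut_amplitude = 12, strut_wire_width = 0.5,
                   n_peaks_per_ring = 8),
    "within \\[0, length\\]")
  expect_error(
    graft_template("bad", length = 100, proximal_diameter = -1,
                   strut_amplitude = 12, strut_wire_width = 0.5,
                   n_peaks_per_ring = 8),
    "non-positive")
  expect_error(
    graft_template("bad", length = 100, proximal_diameter = 30,
                   strut_amplitude = 2, strut_wire_width = 3,
                   n_peaks_per_ring = 8),
    "smaller than")
  expect_error(as_graft_template(list(name = "x", length = 100)),
               "missing key")
})

test_that("the bundled repository loads and flattens", {
  repo <- template_repository()
  expect_true(all(c("thoracic-straight-30", "thoracic-tapered-34-30") %in%
                    names(repo)))
  expect_false(repo[["thoracic-straight-30"]]$tapered)
  expect_true(repo[["thoracic-tapered-34-30"]]$tapered)
})

test_that("uniform flattening has unrolled-cylinder geometry", {
  t1 <- graft_template("u", length = 100, proximal_diameter = 30,
                       ring_axial_positions = c(10, 30, 50, 70, 90),
                       strut_amplitude = 12, strut_wire_width = 0.5,
                       n_peaks_per_ring = 8)
  m <- flatten_uniform(t1, resolution = 0.5)
  expect_equal(nrow(m$pixels), 200)                  # 100 mm / 0.5
  expect_equal(ncol(m$pixels), round(pi * 30 / 0.5)) # ~188.5 -> 188
  expect_equal(m$al_period, pi * 30)                 # exact period stored
  expect_true(m$periodic_al)
  # width equals pi*D to within one pixel
  expect_lt(abs(m$al_extent - pi * 30), m$resolution)
  # no struts -> all-zero mask
  t0 <- graft_template("bare", length = 50, proximal_diameter = 20,
                       strut_amplitude = 6, strut_wire_width = 0.5,
                       n_peaks_per_ring = 6)
  expect_equal(sum(flatten_uniform(t0, 0.5)$pixels), 0)
  expect_error(flatten_uniform(t1, resolution = 0), "positive")
  expect_error(flatten_uniform(graft_template("t", length = 10,
                                              proximal_diameter = 12,
                                              distal_diameter = 10,
                                              strut_amplitude = 3,
                                              strut_wire_width = 0.5,
                                              n_peaks_per_ring = 4), 0.5),
               "non-tapered")
})

test_that("uniform strut rasterization matches the per-pixel oracle", {
  m <- flatten_uniform(tiny_template, resolution = 0.5, margin = 0.5)
  oracle <- oracle_strut_mask_uniform(tiny_template, 0.5,
                                      deployed_diameter = 8, margin = 0.5)
  expect_gt(sum(oracle), 0)
  expect_identical(m$pixels, oracle)
})

test_that("tapered flattening develops the frustum correctly", {
  tt <- graft_template("tap", length = 20, proximal_diameter = 10,
                       distal_diameter = 8,
                       ring_axial_positions = c(6, 14),
                       strut_amplitude = 4, strut_wire_width = 0.6,
                       n_peaks_per_ring = 3)
  m <- flatten_tapered(tt, resolution = 0.5, margin = 0.5)
  # per-row valid AL extent equals the local circumference (linear taper)
  rows <- nrow(m$pixels)
  pgd <- (seq_len(rows) - 0.5) * m$resolution
  expect_equal(m$row_period, pi * (10 - 2 * pgd / 20), tolerance = 1e-12)
  # strut pixels match the frustum-surface oracle (<= 2 px discrepancy
  # tolerated at the exact wire-boundary where chord sampling differs)
  oracle <- oracle_strut_mask_tapered(tt, 0.5, 10, 8, 0.5)
  inval <- outer(2 * pi * (10 / 2 - pgd / 20),
                 (seq_len(ncol(m$pixels)) - 0.5) * 0.5,
                 function(c0, a) a >= c0)
  mism <- sum(m$pixels != pmax(oracle, inval))
  expect_lte(mism, 2)
  # zero taper defers to the uniform path
  t0 <- graft_template("flat", length = 20, proximal_diameter = 8,
                       distal_diameter = 8,
                       ring_axial_positions = c(6, 14),
                       strut_amplitude = 4, strut_wire_width = 0.6,
                       n_peaks_per_ring = 3)
  expect_identical(flatten_tapered(t0, 0.5, margin = 0.5)$pixels,
                   flatten_uniform(t0, 0.5, margin = 0.5)$pixels)
})

test_that("strut masks respect ring periodicity and resolution consistency", {
  m <- flatten_uniform(tiny_template, resolution = 0.25, margin = 0.5)
  # circular symmetry: shifting by one strut period changes few pixels
  # (the period is not an integer pixel count, so allow the discretization
  # boundary to move)
  period_px <- m$al_period / tiny_template$n_peaks_per_ring / m$resolution
  shift <- round(period_px)
  rolled <- m$pixels[, c((shift + 1):ncol(m$pixels), 1:shift)]
  expect_lt(mean(rolled != m$pixels), 0.02)
  # rasterization at r and r/2 agrees after 2x downsampling
  hi <- flatten_uniform(tiny_template, resolution = 0.125, margin = 0.5)
  lo <- m$pixels
  n2c <- 2 * ncol(lo); n2r <- 2 * nrow(lo)
  hi_crop <- hi$pixels[seq_len(min(n2r, nrow(hi$pixels))),
                       seq_len(min(n2c, ncol(hi$pixels)))]
  # majority-downsample the fine mask onto the coarse grid
  rr <- (seq_len(nrow(hi_crop)) + 1) %/% 2
  cc <- (seq_len(ncol(hi_crop)) + 1) %/% 2
  agg <- rowsum(t(rowsum(hi_crop, rr)), cc)   # transposed sums per 2x2 block
  down <- t(agg) >= 2
  lo_crop <- lo[seq_len(nrow(down)), seq_len(ncol(down))]
  expect_lt(mean(down != (lo_crop == 1)), 0.02)
})

test_that("masks export to PNG with a JSON sidecar", {
  m <- flatten_uniform(tiny_template, resolution = 0.5, margin = 0.5)
  path <- file.path(tempdir(), "mask.png")
  write_mask_png(m, path)
  expect_true(file.exists(path))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$n_cols, ncol(m$pixels))
  expect_equal(meta$al_period_mm, m$al_period, tolerance = 1e-9)
  img <- png::readPNG(path)
  expect_equal(dim(img), dim(m$pixels))
})
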