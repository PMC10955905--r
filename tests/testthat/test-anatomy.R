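# cylinder labelmap: radius R, axis z, centred in the volume
make_cylinder_labelmap <- function(R = 15, n_xy = 50, n_z = 40, voxel = 1) {
  ctr <- (n_xy / 2) * voxel
  xc <- (seq_len(n_xy) - 0.5) * voxel
  lab <- array(0L, c(n_xy, n_xy, n_z))
  disc <- outer((xc - ctr)^2, (xc - ctr)^2, `+`) <= R^2
  for (k in seq_len(n_z)) lab[, , k] <- disc
  storage.mode(lab) <- "integer"
  list(lab = lab, center = ctr)
}

test_that("centerline of a straight cylinder lies on its axis", {
  fix <- make_cylinder_labelmap()
  cl <- compute_centerline(fix$lab, spacing = c(1, 1, 1))
  expect_lt(max(abs(cl$points[, 1] - fix$center)), 1e-6)
  expect_lt(max(abs(cl$points[, 2] - fix$center)), 1e-6)
  expect_true(all(abs(cl$local_diameter - 30) < 0.5))
  expect_true(all(diff(cl$arclength) > 0))
  # frames orthonormal
  fr <- cl$frame
  for (m in list(fr$tangent, fr$normal, fr$binormal))
    expect_equal(rowSums(m^2), rep(1, nrow(m)), tolerance = 1e-9)
  expect_lt(max(abs(rowSums(fr$tangent * fr$normal))), 1e-9)
  expect_error(compute_centerline(array(0L, c(5, 5, 5)), c(1, 1, 1)),
               "empty")
})

test_that("centerline of a torus-arc labelmap tracks the generating arc", {
  # arc of radius 200 in the x-z plane, axial-slice circular cross-sections
  voxel <- 0.8
  nz <- 150
  zc <- (seq_len(nz) - 0.5) * voxel
  cx <- 200 - sqrt(200^2 - zc^2)
  nx <- ceiling((max(cx) + 30) / voxel)
  xc <- (seq_len(nx) - 0.5) * voxel
  lab <- array(0L, c(nx, nx, nz))
  for (k in seq_len(nz))
    lab[, , k] <- outer((xc - (cx[k] + 14))^2, (xc - 14)^2, `+`) <= 12^2
  storage.mode(lab) <- "integer"
  cl <- compute_centerline(lab, spacing = rep(voxel, 3))
  # every measured station within 1 voxel of the arc
  err <- vapply(seq_len(nrow(cl$points)), function(i) {
    z <- cl$points[i, 3]
    sqrt((cl$points[i, 1] - (200 - sqrt(200^2 - z^2) + 14))^2 +
           (cl$points[i, 2] - 14)^2)
  }, 0)
  expect_lt(max(err), voxel)
})

test_that("a disconnected lumen warns and keeps the largest component", {
  fix <- make_cylinder_labelmap(R = 10, n_xy = 30, n_z = 30)
  lab <- fix$lab
  lab[, , 11:13] <- 0L                     # sever the cylinder
  lab[1:3, 1:3, 11:13] <- 1L               # small floating island
  expect_warning(cl <- compute_centerline(lab, c(1, 1, 1)), "disconnected")
  # the surviving piece is a straight cylinder section
  expect_lt(max(abs(cl$points[, 1] - fix$center)), 1e-6)
})

test_that("fenestration measurement recovers angle, AL and PGD", {
  fix <- make_cylinder_labelmap(R = 15, n_xy = 50, n_z = 60)
  cl <- compute_centerline(fix$lab, c(1, 1, 1))
  ctr <- fix$center
  # ostium at 90 deg clockwise-from-anterior, 40 mm below a graft top at
  # station 5: direction e2 = tangent x datum
  ost <- c(ctr, ctr + 15, 45 + cl$arclength[1])
  sp <- measure_fenestration(cl, ost, datum = c(1, 0, 0),
                             deployed_diameter = 30, graft_top_station = 5,
                             vessel = "RRA", diameter = 6)
  expect_equal(sp$phi, 90, tolerance = 0.2)
  expect_equal(sp$AL, (90 / 360) * pi * 30, tolerance = 0.05)
  expect_equal(sp$PGD, 40, tolerance = 0.2)
  # ostium on the datum ray -> phi = 0, AL = 0
  sp0 <- measure_fenestration(cl, c(ctr + 15, ctr, 45 + cl$arclength[1]),
                              datum = c(1, 0, 0), deployed_diameter = 30,
                              graft_top_station = 5)
  expect_lt(min(sp0$phi, 360 - sp0$phi), 0.2)            # circularly ~0
  expect_lt(min(sp0$AL, pi * 30 - sp0$AL), 0.05)         # AL ~0 mod period
  # AL is linear in phi with slope pi*D/360: doubling D doubles AL
  sp2 <- measure_fenestration(cl, ost, datum = c(1, 0, 0),
                              deployed_diameter = 60, graft_top_station = 5)
  expect_equal(sp2$AL, 2 * sp$AL, tolerance = 1e-9)
  # out-of-coverage ostium names the vessel
  expect_error(
    measure_fenestration(cl, ost, datum = c(1, 0, 0), deployed_diameter = 30,
                         graft_top_station = 5, vessel = "LRA",
                         graft_length = 30),
    "LRA")
})

test_that("PGD is invariant to rigid rotation of the whole anatomy", {
  case <- generate_case("tortuous", seed = 7)
  cl <- compute_centerline(case$labelmap, case$spacing)
  ost <- case$ostia_truth
  sp <- measure_fenestration(cl, as.numeric(ost[3, c("x", "y", "z")]),
                             datum = case$datum, deployed_diameter = 26,
                             graft_top_station = 20)
  # rotate the labelmap and the ostium by 90 deg about z:
  # (x, y) -> (y, X - x) in voxel space
  lab_rot <- aperm(case$labelmap, c(2, 1, 3))
  lab_rot <- lab_rot[, dim(lab_rot)[2]:1, ]
  storage.mode(lab_rot) <- "integer"
  X <- dim(case$labelmap)[1] * case$spacing[1]
  ost_rot <- c(ost$y[3], X - ost$x[3], ost$z[3])
  cl_rot <- compute_centerline(lab_rot, case$spacing)
  sp_rot <- measure_fenestration(cl_rot, ost_rot, datum = c(0, 1, 0),
                                 deployed_diameter = 26,
                                 graft_top_station = 20)
  expect_equal(sp_rot$PGD, sp$PGD, tolerance = 0.1)
})

test_that("fenestration masks rasterize rigid disc constellations", {
  s1 <- fenestration_spec("CA", AL = 20, PGD = 40, diameter = 6)
  m <- build_fenestration_mask(list(s1), resolution = 0.5, al_period = 60,
                               pgd_extent = 100)
  idx <- which(m$pixels == 1, arr.ind = TRUE)
  # disc centred at col 40, row 80 (0-based), radius 6 px
  expect_equal(mean(idx[, 2] - 0.5), 40, tolerance = 0.1)
  expect_equal(mean(idx[, 1] - 0.5), 80, tolerance = 0.1)
  expect_true(all((idx[, 2] - 0.5 - 40)^2 + (idx[, 1] - 0.5 - 80)^2 <= 6^2))
  # two fenestrations 10 mm apart -> centroid distance 20 px on the mask
  s2 <- fenestration_spec("SMA", AL = 20, PGD = 50, diameter = 6)
  m2 <- build_fenestration_mask(list(s1, s2), 0.5, 60, 100)
  idx2 <- which(m2$pixels == 1, arr.ind = TRUE)
  rows <- sort(as.numeric(tapply(idx2[, 1], idx2[, 1] > 90, mean)))
  expect_equal(diff(rows), 20, tolerance = 0.5)
  # disc pixel count within 5% of pi r^2 / res^2 for r >= 2 mm
  for (r in c(2, 3, 4.5)) {
    sp <- fenestration_spec("X", AL = 30, PGD = 50, diameter = 2 * r)
    mm <- build_fenestration_mask(list(sp), 0.5, 60, 100)
    expect_equal(sum(mm$pixels), pi * r^2 / 0.25, tolerance = 0.05)
  }
  # overlapping discs are rejected
  expect_error(
    build_fenestration_mask(list(s1, fenestration_spec("X", AL = 22,
                                                       PGD = 41,
                                                       diameter = 6)),
                            0.5, 60, 100),
    "overlap")
  # a disc crossing the fabric edge is rejected
  expect_error(
    build_fenestration_mask(list(fenestration_spec("X", AL = 10, PGD = 2,
                                                   diameter = 6)),
                            0.5, 60, 100),
    "edge")
})
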