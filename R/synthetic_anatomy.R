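#' Generate a synthetic aortic anatomy with full ground truth
#'
#' Builds a parametric aorta -- straight, arc, or helically tortuous
#' centerline with circular axial cross-sections -- rasterizes it into a
#' binary labelmap at CT-angiography voxel scale, and places the four
#' visceral ostia (celiac, SMA, right/left renal) at known angles and
#' arclength stations.  Every quantity a downstream stage should recover is
#' returned as ground truth, so the whole pipeline is testable without any
#' clinical data.
#'
#' The synthetic lumen model has circular cross-sections in axial planes
#' centred on the generating curve; per-seed jitter moves each vessel a few
#' degrees/millimetres around clinically plausible base positions (CA
#' proximal-anterior, SMA ~14 mm distal-anterior, renals lateral/posterior
#' 18-21 mm distal of the CA).  `noise_sd` adds white per-slice
#' perturbation to the lumen centre before rasterization, emulating
#' segmentation roughness; the smooth generating curve remains the truth.
#'
#' @param profile `"straight"`, `"arc"` (radius 300 mm), or `"tortuous"`
#'   (two-axis sinusoidal wander).
#' @param noise_sd per-slice centre noise, mm (default 0).
#' @param seed integer seed; the case is fully deterministic given it.
#' @param voxel isotropic voxel spacing, mm (default 0.7).
#' @param aorta_length axial lumen extent, mm (default 150).
#' @param lumen_diameter proximal lumen diameter, mm (default 26; tapers by
#'   1 mm over the length).
#' @param graft_top_station proximal graft edge, mm arclength (default 20).
#' @param datum datum direction (default anterior `c(1, 0, 0)`).
#' @return an object of class `synthetic_case`: `labelmap` (3D 0/1 array),
#'   `spacing`, `centerline_truth` (`eval(s)` closure, dense points,
#'   length), `lumen_radius_profile`, `ostia_truth` (data frame: vessel,
#'   phi, station, diameter, prioritized, x, y, z), `graft_top_station`,
#'   `datum`, `seed`.
#' @export
generate_case <- function(profile = c("straight", "arc", "tortuous"),
                          noise_sd = 0, seed = 1, voxel = 0.7,
                          aorta_length = 150, lumen_diameter = 26,
                          graft_top_station = 20, datum = c(1, 0, 0)) {
  profile <- match.arg(profile)
  rng <- .with_seed(seed)
  on.exit(rng())
  # generating curve: centre (cx(z), cy(z)) per axial position z
  center_xy <- switch(
    profile,
    straight = function(z) cbind(0 * z, 0 * z),
    arc = function(z) {
      R <- 300
      cbind(R - sqrt(pmax(R^2 - z^2, 0)), 0 * z)
    },
    tortuous = function(z)
      cbind(8 * sin(2 * pi * z / 110), 6 * sin(2 * pi * z / 140 + 1))
  )
  radius_at <- function(z) (lumen_diameter - z / aorta_length) / 2
  # volume sized per axis from the actual centerline wander plus the
  # largest lumen radius
  z_max <- aorta_length
  nz <- ceiling(z_max / voxel)
  zc <- (seq_len(nz) - 0.5) * voxel
  ctr <- center_xy(zc)
  jit <- if (noise_sd > 0)
    matrix(stats::rnorm(2 * nz, 0, noise_sd), nz, 2) else matrix(0, nz, 2)
  rr <- radius_at(zc)
  pad <- radius_at(0) + 4 * noise_sd + 2
  x_rng <- range(ctr[, 1] + jit[, 1]) + c(-pad, pad)
  y_rng <- range(ctr[, 2] + jit[, 2]) + c(-pad, pad)
  nx <- ceiling(diff(x_rng) / voxel) + 1L
  ny <- ceiling(diff(y_rng) / voxel) + 1L
  lab <- array(0L, c(nx, ny, nz))
  # voxel (i, j, k) centre sits at ((i,j,k) - 0.5) * voxel in the labelmap
  # frame; the world -> labelmap shift is recorded as `origin`
  xc <- x_rng[1] + (seq_len(nx) - 0.5) * voxel
  yc <- y_rng[1] + (seq_len(ny) - 0.5) * voxel
  for (k in seq_len(nz)) {
    dx2 <- (xc - (ctr[k, 1] + jit[k, 1]))^2
    dy2 <- (yc - (ctr[k, 2] + jit[k, 2]))^2
    lab[, , k] <- outer(dx2, dy2, `+`) <= rr[k]^2
  }
  storage.mode(lab) <- "integer"
  shift <- c(x_rng[1], y_rng[1], 0)
  # analytic arclength parameterization of the (noise-free) truth curve,
  # expressed in the labelmap frame
  z_dense <- seq(0, z_max, length.out = 4096)
  p_dense <- cbind(center_xy(z_dense), z_dense)
  s_dense <- c(0, cumsum(sqrt(rowSums(diff(p_dense)^2))))
  z_of_s <- stats::splinefun(s_dense, z_dense, method = "natural")
  truth_eval <- function(s) {
    z <- z_of_s(s)
    sweep(cbind(center_xy(z), z), 2, shift)
  }
  truth_tangent <- function(s) {
    h <- 1e-4
    d <- truth_eval(s + h) - truth_eval(s - h)
    d / sqrt(rowSums(d^2))
  }
  total_len <- max(s_dense)
  # vessel constellation: base positions + per-seed jitter
  base <- data.frame(
    vessel = c("CA", "SMA", "RRA", "LRA"),
    phi = c(30, 0, 105, 255),
    pgd = c(22, 37, 40, 42),
    diameter = c(7, 7, 5.5, 5.5),
    prioritized = c(TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  base$phi <- (base$phi + stats::runif(4, -3, 3)) %% 360
  base$pgd <- base$pgd + stats::runif(4, -1.2, 1.2)
  base$station <- graft_top_station + base$pgd
  ost <- matrix(0, 4, 3)
  for (v in 1:4) {
    s_v <- base$station[v]
    foot <- truth_eval(s_v)[1, ]
    tang <- truth_tangent(s_v)[1, ]
    dproj <- project_datum(matrix(tang, 1), datum)[1, ]
    e2 <- cross3(tang, dproj)
    a <- base$phi[v] * pi / 180
    r_here <- radius_at(foot[3])
    ost[v, ] <- foot + r_here * (cos(a) * dproj + sin(a) * e2)
  }
  ostia <- cbind(base[, c("vessel", "phi", "station", "pgd", "diameter",
                          "prioritized")],
                 data.frame(x = ost[, 1], y = ost[, 2], z = ost[, 3]))
  structure(
    list(labelmap = lab, spacing = rep(voxel, 3),
         origin = shift,
         centerline_truth = list(eval = truth_eval, tangent = truth_tangent,
                                 length = total_len),
         lumen_radius_profile = rr,
         ostia_truth = ostia,
         graft_top_station = graft_top_station,
         datum = datum, profile = profile, noise_sd = noise_sd, seed = seed),
    class = "synthetic_case"
  )
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case> %s (seed %d, noise %.2g mm): %s voxels, %d ostia\n",
              x$profile, x$seed, x$noise_sd,
              paste(dim(x$labelmap), collapse = "x"), nrow(x$ostia_truth)))
  invisible(x)
}

#' Ground-truth (AL, PGD) of a case's ostia for a given plan frame
#'
#' Expresses the generator's known ostium placements in the same graft
#' surface frame the pipeline plans in: PGD is the truth-curve arclength
#' from the physical graft-top point (the measured centerline's
#' `graft_top_station` projected onto the truth curve) to each ostium
#' station, and AL converts the true angle at the deployed diameter.  This
#' removes the arbitrary arclength-origin difference between the voxelized
#' measurement and the analytic truth, so deviations reflect genuine
#' pipeline error.
#'
#' @param case a [generate_case()] result.
#' @param centerline the measured [compute_centerline()] result.
#' @param graft_top_station proximal graft edge on the measured centerline,
#'   mm.
#' @param deployed_diameter deployed graft diameter used by the plan, mm.
#' @return named list of `c(AL, PGD)` per vessel.
#' @export
case_truth_uv <- function(case, centerline, graft_top_station,
                          deployed_diameter) {
  p_top <- centerline$curve$eval(graft_top_station)[1, ]
  s_grid <- seq(0, case$centerline_truth$length, by = 0.5)
  pts <- case$centerline_truth$eval(s_grid)
  i0 <- which.min(rowSums(sweep(pts, 2, p_top)^2))
  lo <- max(1, i0 - 1); hi <- min(length(s_grid), i0 + 1)
  opt <- stats::optimize(function(s)
    sum((case$centerline_truth$eval(s)[1, ] - p_top)^2),
    interval = c(s_grid[lo], s_grid[hi]), tol = 1e-8)
  s0 <- opt$minimum
  out <- lapply(seq_len(nrow(case$ostia_truth)), function(i)
    c(AL = case$ostia_truth$phi[i] / 360 * pi * deployed_diameter,
      PGD = case$ostia_truth$station[i] - s0))
  stats::setNames(out, case$ostia_truth$vessel)
}

# Run code under a temporary RNG state; returns a restore function.
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a synthetic case to disk in the formats the anatomy module reads
#'
#' Emits `<dir>/lumen.nii.gz` (binary labelmap) and `<dir>/ostia.csv`.
#'
#' @param case a [generate_case()] result.
#' @param dir output directory (created if needed).
#' @return named list of the two paths.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nii <- file.path(dir, "lumen.nii.gz")
  img <- RNifti::asNifti(case$labelmap)
  RNifti::pixdim(img) <- case$spacing
  RNifti::writeNifti(img, nii)
  csv <- file.path(dir, "ostia.csv")
  df <- case$ostia_truth[, c("vessel", "x", "y", "z", "diameter", "prioritized")]
  utils::write.csv(df, csv, row.names = FALSE)
  # voxel-centre origin used when rasterizing, so coordinates round-trip
  jsonlite::write_json(list(origin = case$origin, spacing = case$spacing),
                       file.path(dir, "grid.json"), auto_unbox = TRUE,
                       digits = NA)
  list(labelmap = nii, ostia = csv)
}

#' Construct an adversarial case with a known search outcome
#'
#' Three kinds, each verified by construction:
#' \describe{
#'   \item{`blocked_renal`}{mask-level case where the rigid search fails at
#'     every offset but a single posterior relaxation of the right renal
#'     (2 mm) yields a valid fit.}
#'   \item{`no_fit`}{fully strut-covered graft; even the relaxed search
#'     must return `valid = FALSE`.}
#'   \item{`edge_fenestration`}{a 3D case whose renal ostium lies beyond
#'     the graft's distal coverage, so measurement raises an
#'     out-of-coverage error.}
#' }
#'
#' @param kind one of `"blocked_renal"`, `"no_fit"`, `"edge_fenestration"`.
#' @param seed integer seed (used by `edge_fenestration` jitter).
#' @return a list with `kind`, `expected`, and kind-specific elements
#'   (`graft_mask` + `specs`, or a `synthetic_case` + `graft_length`).
#' @export
generate_adversarial <- function(kind = c("blocked_renal", "no_fit",
                                          "edge_fenestration"), seed = 1) {
  kind <- match.arg(kind)
  res <- 0.25
  if (kind == "blocked_renal") {
    # 10 x 10 mm graft; single-pixel-scale fenestrations: a prioritized SMA
    # and a right renal 2 mm further around.  The graft is solid strut
    # except two clear discs whose relative AL spacing differs from the
    # constellation's by exactly 2 mm posterior (+AL for phi < 180), so no
    # rigid offset fits but a 2 mm renal relaxation does.
    n <- 40L
    period <- n * res
    # single-pixel fenestrations centred on pixel centres
    specs <- list(
      fenestration_spec("SMA", phi = 60, AL = px_center(10, res),
                        PGD = px_center(10, res), diameter = 0.2,
                        prioritized = TRUE),
      fenestration_spec("RRA", phi = 100, AL = px_center(20, res),
                        PGD = px_center(20, res), diameter = 0.2,
                        prioritized = FALSE)
    )
    px <- matrix(1L, n, n)
    clear <- function(al_px, pgd_px, r_px) {
      hole <- .disc_mask(px_center(al_px, res), px_center(pgd_px, res),
                         r_px * res, n, n, res, period)
      px[hole == 1L] <<- 0L
    }
    clear(12, 14, 2.6)          # SMA hole at offset (+2 px, +4 px)
    clear(30, 24, 2.6)          # renal hole 2 mm (8 px) posterior of rigid
    graft <- mask2d(px, res, al_period = period, periodic_al = TRUE)
    list(kind = kind, graft_mask = graft, specs = specs,
         expected = list(plain_valid = FALSE, relaxed_valid = TRUE,
                         renal_shift_mm = 2))
  } else if (kind == "no_fit") {
    n <- 40L
    specs <- list(
      fenestration_spec("SMA", phi = 60, AL = px_center(10, res),
                        PGD = px_center(10, res), diameter = 0.2,
                        prioritized = TRUE),
      fenestration_spec("RRA", phi = 100, AL = px_center(20, res),
                        PGD = px_center(20, res), diameter = 0.2,
                        prioritized = FALSE)
    )
    graft <- mask2d(matrix(1L, n, n), res, al_period = n * res,
                    periodic_al = TRUE)
    list(kind = kind, graft_mask = graft, specs = specs,
         expected = list(relaxed_valid = FALSE))
  } else {
    case <- generate_case("straight", seed = seed)
    # a graft short enough that the LRA station falls beyond coverage
    list(kind = kind, case = case, graft_length = 40,
         expected = list(error_vessel = "LRA"))
  }
}
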