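#' Fit a smooth, arclength-parameterized curve through ordered 3D points
#'
#' The centerline samples (per-slice lumen centroids) are smoothed with a
#' cubic smoothing spline per coordinate against a chord-length parameter,
#' then reparameterized by arclength.  With fewer than ten points an
#' interpolating natural cubic spline is used instead, since there is too
#' little data to estimate a smoothing parameter.
#'
#' @param points n x 3 matrix of ordered coordinates, mm; n >= 4 after
#'   removal of duplicate consecutive points (removed with a warning).
#' @param spar smoothing parameter passed to [stats::smooth.spline()];
#'   `NULL` selects it by generalized cross-validation.
#' @return an object of class `centerline_curve` with elements
#'   `eval(s, deriv = 0)` (position/derivatives at arclength `s`, mm) and
#'   `length` (total arclength, mm).
#' @export
fit_centerline_spline <- function(points, spar = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("`points` must be n x 3", call. = FALSE)
  dup <- c(FALSE, rowSums((points[-1, , drop = FALSE] -
                           points[-nrow(points), , drop = FALSE])^2) < 1e-18)
  if (any(dup)) {
    warning(sum(dup), " duplicate consecutive point(s) removed")
    points <- points[!dup, , drop = FALSE]
  }
  n <- nrow(points)
  if (n < 4) stop("need at least 4 distinct points", call. = FALSE)
  t_chord <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  coord_fun <- vector("list", 3)
  for (c_i in 1:3) {
    if (n >= 10) {
      fit <- if (is.null(spar)) stats::smooth.spline(t_chord, points[, c_i])
             else stats::smooth.spline(t_chord, points[, c_i], spar = spar)
      coord_fun[[c_i]] <- local({
        f <- fit
        function(t, deriv = 0) stats::predict(f, t, deriv = deriv)$y
      })
    } else {
      coord_fun[[c_i]] <- local({
        f <- stats::splinefun(t_chord, points[, c_i], method = "natural")
        function(t, deriv = 0) f(t, deriv = deriv)
      })
    }
  }
  eval_t <- function(t, deriv = 0)
    cbind(coord_fun[[1]](t, deriv), coord_fun[[2]](t, deriv),
          coord_fun[[3]](t, deriv))
  # arclength reparameterization on a dense grid, one refinement pass
  m <- max(2048L, 8L * n)
  t_dense <- seq(t_chord[1], t_chord[n], length.out = m)
  for (pass in 1:2) {
    p_dense <- eval_t(t_dense)
    s_dense <- c(0, cumsum(sqrt(rowSums(diff(p_dense)^2))))
    if (pass == 1) {
      # resample t so stations are uniform in arclength
      t_dense <- stats::approx(s_dense, t_dense,
                               xout = seq(0, max(s_dense), length.out = m))$y
    }
  }
  t_of_s <- stats::splinefun(s_dense, t_dense, method = "natural")
  total <- max(s_dense)
  structure(
    list(
      eval = function(s, deriv = 0) eval_t(t_of_s(s), deriv = deriv),
      length = total,
      n_points = n
    ),
    class = "centerline_curve"
  )
}

#' @export
print.centerline_curve <- function(x, ...) {
  cat(sprintf("<centerline_curve> arclength %.1f mm from %d points\n",
              x$length, x$n_points))
  invisible(x)
}

# Unit tangents at arclength stations.
curve_tangent <- function(curve, s) {
  d <- curve$eval(s, deriv = 1)
  d / sqrt(rowSums(d^2))
}

# Curvature magnitude (1/mm) at arclength stations, |r' x r''| / |r'|^3.
curve_curvature <- function(curve, s) {
  d1 <- curve$eval(s, deriv = 1)
  d2 <- curve$eval(s, deriv = 2)
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  sqrt(rowSums(cr^2)) / sqrt(rowSums(d1^2))^3
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize3 <- function(v) v / sqrt(sum(v^2))

# Rotation-minimizing frames by the double-reflection method.
# points: m x 3 stations; tangents: m x 3 unit tangents.
# Returns list(normal, binormal), each m x 3, orthonormal with the tangent.
rmf_frames <- function(points, tangents, init_normal = NULL) {
  m <- nrow(points)
  t1 <- tangents[1, ]
  if (is.null(init_normal)) {
    ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    init_normal <- normalize3(ref - sum(ref * t1) * t1)
  } else {
    init_normal <- normalize3(init_normal - sum(init_normal * t1) * t1)
  }
  normal <- matrix(0, m, 3)
  normal[1, ] <- init_normal
  for (i in seq_len(m - 1)) {
    v1 <- points[i + 1, ] - points[i, ]
    c1 <- sum(v1 * v1)
    if (c1 < 1e-18) { normal[i + 1, ] <- normal[i, ]; next }
    rL <- normal[i, ] - (2 / c1) * sum(v1 * normal[i, ]) * v1
    tL <- tangents[i, ] - (2 / c1) * sum(v1 * tangents[i, ]) * v1
    v2 <- tangents[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    normal[i + 1, ] <- if (c2 < 1e-18) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthonormalize against drift
    normal[i + 1, ] <- normalize3(
      normal[i + 1, ] - sum(normal[i + 1, ] * tangents[i + 1, ]) * tangents[i + 1, ])
  }
  binormal <- cbind(tangents[, 2] * normal[, 3] - tangents[, 3] * normal[, 2],
                    tangents[, 3] * normal[, 1] - tangents[, 1] * normal[, 3],
                    tangents[, 1] * normal[, 2] - tangents[, 2] * normal[, 1])
  list(normal = normal, binormal = binormal)
}

# Project a fixed datum direction into the cross-section plane at each
# station, normalized.  Errors if the datum is (near-)parallel to a tangent.
project_datum <- function(tangents, datum) {
  datum <- normalize3(datum)
  proj <- sweep(tangents, 1, tangents %*% datum, `*`)
  d <- matrix(datum, nrow(tangents), 3, byrow = TRUE) - proj
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm < 1e-6))
    stop("datum vector is parallel to the centerline tangent", call. = FALSE)
  d / nrm
}
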