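#' Deployed graft diameter from the proximal landing zone
#'
#' The deployed diameter is the mean lumen diameter over the proximal
#' landing zone -- the first 10% of the graft's length measured from the top
#' of the graft -- capped at the template's fabric diameter (the fabric
#' cannot expand beyond its manufactured size; below that it conforms to
#' the wall, giving the interference fit that prevents migration).
#'
#' @param centerline an [compute_centerline()] result.
#' @param template a [graft_template()].
#' @param graft_top_station proximal graft edge, mm of centerline arclength.
#' @return deployed diameter, mm.
#' @export
size_graft_diameter <- function(centerline, template, graft_top_station) {
  zone <- c(graft_top_station, graft_top_station + 0.10 * template$length)
  s_max <- max(centerline$arclength)
  if (zone[1] < 0 || zone[2] > s_max)
    stop("landing zone [", sprintf("%.1f, %.1f", zone[1], zone[2]),
         "] mm is outside the centerline extent", call. = FALSE)
  s <- seq(zone[1], zone[2], length.out = 256)
  d <- stats::approx(centerline$arclength, centerline$local_diameter,
                     xout = s, rule = 2, ties = mean)$y
  min(mean(d), template$proximal_diameter)
}

#' Loft an open-cylinder graft mesh along the centerline
#'
#' Sweeps rings of `n_circ` vertices along the fitted centerline curve
#' between `graft_top_station` and `graft_top_station + length`.  The ring
#' frame at each station is the datum direction projected into the
#' cross-section plane (so the longitudinal seam follows the phi = 0 datum
#' generator and the mesh's AL origin coincides with the measurement
#' datum).  The seam column is duplicated, making the mesh an explicit
#' topological disk; triangles are oriented consistently outward.
#'
#' Circumferential vertex `j` (0-based) sits at
#' `phi = j * 360/n_circ` degrees, clockwise viewed from proximal.
#'
#' @param curve a `centerline_curve` (or an `aortic_centerline`, whose
#'   curve is used).
#' @param diameters deployed diameters `c(proximal, distal)`, mm; a single
#'   value gives a uniform tube.  Interpolated linearly between rings.
#' @param graft_top_station proximal edge station, mm arclength.
#' @param length graft length, mm.
#' @param n_axial number of rings (>= 4); default one ring per mm.
#' @param n_circ number of circumferential segments (>= 8; default 96).
#' @param datum datum direction for the seam (default anterior).
#' @return an object of class `graft_mesh` with `vertices` (V x 3, mm),
#'   `faces` (F x 3, 1-based, outward orientation), `grid_shape`
#'   `(n_axial, n_circ)`, `seam_vertices` (two columns of duplicated seam
#'   indices), `boundary_loops` (proximal and distal rings), per-vertex
#'   `station` and `phi`, and the ring `radius` per station.
#' @export
loft_graft_mesh <- function(curve, diameters, graft_top_station, length,
                            n_axial = NULL, n_circ = 96, datum = c(1, 0, 0)) {
  if (inherits(curve, "aortic_centerline")) curve <- curve$curve
  if (is.null(n_axial)) n_axial <- ceiling(length / 1) + 1L
  if (n_axial < 4) stop("n_axial must be >= 4", call. = FALSE)
  if (n_circ < 8) stop("n_circ must be >= 8", call. = FALSE)
  if (graft_top_station < 0 || graft_top_station + length > curve$length + 1e-6)
    stop("graft extent is outside the centerline", call. = FALSE)
  if (length(diameters) == 1) diameters <- rep(diameters, 2)
  s <- seq(graft_top_station, graft_top_station + length, length.out = n_axial)
  centers <- curve$eval(s)
  tang <- curve_tangent(curve, s)
  e1 <- project_datum(tang, datum)
  e2 <- cbind(tang[, 2] * e1[, 3] - tang[, 3] * e1[, 2],
              tang[, 3] * e1[, 1] - tang[, 1] * e1[, 3],
              tang[, 1] * e1[, 2] - tang[, 2] * e1[, 1])
  radius <- (diameters[1] +
               (diameters[2] - diameters[1]) * (s - s[1]) / length) / 2
  # curvature sanity: the loft self-intersects where 1/kappa < radius
  kap <- curve_curvature(curve, s)
  n_tight <- sum(kap * radius > 1, na.rm = TRUE)
  if (n_tight > 0)
    warning("loft may self-intersect at ", n_tight,
            " station(s) (curvature radius < graft radius)")
  nc1 <- n_circ + 1L                     # seam column duplicated
  phi <- seq(0, 360, length.out = nc1) * pi / 180
  V <- matrix(0, n_axial * nc1, 3)
  for (i in seq_len(n_axial)) {
    ring <- centers[rep(i, nc1), ] +
      radius[i] * (cos(phi) %o% c(1, 1, 1) * e1[rep(i, nc1), ] +
                     sin(phi) %o% c(1, 1, 1) * e2[rep(i, nc1), ])
    V[(i - 1L) * nc1 + seq_len(nc1), ] <- ring
  }
  vid <- function(i, j) (i - 1L) * nc1 + j   # i axial (1..n_axial), j circ (1..nc1)
  faces <- matrix(0L, 2L * (n_axial - 1L) * n_circ, 3)
  f <- 0L
  for (i in seq_len(n_axial - 1L)) {
    j <- seq_len(n_circ)
    a <- vid(i, j); b <- vid(i + 1L, j); c_ <- vid(i + 1L, j + 1L); d <- vid(i, j + 1L)
    faces[f + seq_len(n_circ), ] <- cbind(a, c_, b)
    faces[f + n_circ + seq_len(n_circ), ] <- cbind(a, d, c_)
    f <- f + 2L * n_circ
  }
  # outward orientation check on the first quad: flip all if needed
  n0 <- cross3(V[faces[1, 2], ] - V[faces[1, 1], ],
               V[faces[1, 3], ] - V[faces[1, 1], ])
  outward <- V[faces[1, 1], ] - centers[1, ]
  if (sum(n0 * outward) < 0) faces <- faces[, c(1, 3, 2)]
  structure(
    list(
      vertices = V, faces = faces,
      grid_shape = c(n_axial = n_axial, n_circ = n_circ),
      seam_vertices = cbind(start = vid(seq_len(n_axial), 1L),
                            end = vid(seq_len(n_axial), nc1)),
      boundary_loops = list(proximal = vid(1L, seq_len(nc1)),
                            distal = vid(n_axial, seq_len(nc1))),
      station = rep(s, each = nc1),
      phi = rep(phi * 180 / pi, n_axial),
      radius = radius,
      graft_top_station = graft_top_station,
      length = length
    ),
    class = "graft_mesh"
  )
}

#' @export
print.graft_mesh <- function(x, ...) {
  cat(sprintf("<graft_mesh> %d vertices, %d faces (%d x %d grid), L=%g mm\n",
              nrow(x$vertices), nrow(x$faces),
              x$grid_shape[1], x$grid_shape[2], x$length))
  invisible(x)
}

#' Total surface area of a triangle mesh
#'
#' @param mesh a `graft_mesh` (or any list with `vertices` and `faces`).
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; F_ <- mesh$faces
  a <- V[F_[, 2], ] - V[F_[, 1], ]
  b <- V[F_[, 3], ] - V[F_[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# Unique undirected edges of a face matrix (columns: v1 < v2).
mesh_edges <- function(faces) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Euler characteristic V - E + F of a mesh
#'
#' A mesh cut open to a topological disk has characteristic 1.
#'
#' @param mesh a `graft_mesh`.
#' @return integer Euler characteristic.
#' @export
mesh_euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh$faces)) + nrow(mesh$faces)
}

#' Write a mesh as ASCII STL
#'
#' @param mesh a `graft_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh_stl <- function(mesh, path) {
  V <- mesh$vertices; F_ <- mesh$faces
  a <- V[F_[, 2], ] - V[F_[, 1], ]
  b <- V[F_[, 3], ] - V[F_[, 1], ]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-30)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid graft", con)
  tri <- sprintf(
    "facet normal %g %g %g\n outer loop\n  vertex %g %g %g\n  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet",
    n[, 1], n[, 2], n[, 3],
    V[F_[, 1], 1], V[F_[, 1], 2], V[F_[, 1], 3],
    V[F_[, 2], 1], V[F_[, 2], 2], V[F_[, 2], 3],
    V[F_[, 3], 1], V[F_[, 3], 2], V[F_[, 3], 3])
  writeLines(tri, con)
  writeLines("endsolid graft", con)
  invisible(path)
}
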