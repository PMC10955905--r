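#' Barycentric coordinates of a 2D point in a triangle
#'
#' Closed-form inversion of the affine map: with `T` the 2x2 matrix of edge
#' vectors relative to vertex 3, `lambda = T^-1 (p - p3)` and
#' `lambda3 = 1 - lambda1 - lambda2`.  The point is inside the triangle iff
#' all coordinates are non-negative; the coordinates always sum to 1.
#'
#' @param p 2D point.
#' @param tri 3 x 2 matrix of triangle vertices.
#' @return numeric `c(lambda1, lambda2, lambda3)`.
#' @export
barycentric_coords <- function(p, tri) {
  x1 <- tri[1, 1]; y1 <- tri[1, 2]
  x2 <- tri[2, 1]; y2 <- tri[2, 2]
  x3 <- tri[3, 1]; y3 <- tri[3, 2]
  det_t <- (x1 - x3) * (y2 - y3) - (x2 - x3) * (y1 - y3)
  if (abs(det_t) < 1e-14)
    stop("degenerate triangle (det(T) = 0)", call. = FALSE)
  l1 <- ((y2 - y3) * (p[1] - x3) + (x3 - x2) * (p[2] - y3)) / det_t
  l2 <- ((y3 - y1) * (p[1] - x3) + (x1 - x3) * (p[2] - y3)) / det_t
  c(l1, l2, 1 - l1 - l2)
}

# Vectorized barycentric coordinates of points (px, py) w.r.t. one triangle
# per row of (x1..y3).  Returns a 3-column matrix.
.bary_rows <- function(px, py, x1, y1, x2, y2, x3, y3) {
  det_t <- (x1 - x3) * (y2 - y3) - (x2 - x3) * (y1 - y3)
  l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det_t
  l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det_t
  cbind(l1, l2, 1 - l1 - l2)
}

# Uniform-grid spatial index over the uv triangles; cached on the
# parameterization object by uv_to_surface().
.build_uv_index <- function(param, faces, n_cells = 64L) {
  uv <- param$uv
  fx <- cbind(uv[faces[, 1], 1], uv[faces[, 2], 1], uv[faces[, 3], 1])
  fy <- cbind(uv[faces[, 1], 2], uv[faces[, 2], 2], uv[faces[, 3], 2])
  xmin <- min(uv[, 1]); xmax <- max(uv[, 1])
  ymin <- min(uv[, 2]); ymax <- max(uv[, 2])
  sx <- (xmax - xmin) / n_cells; sy <- (ymax - ymin) / n_cells
  cell_of <- function(x, y) {
    cx <- pmin(pmax(floor((x - xmin) / sx), 0), n_cells - 1)
    cy <- pmin(pmax(floor((y - ymin) / sy), 0), n_cells - 1)
    cx * n_cells + cy + 1
  }
  lo <- cell_of(apply(fx, 1, min), apply(fy, 1, min))
  hi <- cell_of(apply(fx, 1, max), apply(fy, 1, max))
  buckets <- vector("list", n_cells * n_cells)
  for (f in seq_len(nrow(faces))) {
    cx0 <- (lo[f] - 1) %/% n_cells; cy0 <- (lo[f] - 1) %% n_cells
    cx1 <- (hi[f] - 1) %/% n_cells; cy1 <- (hi[f] - 1) %% n_cells
    for (cx in cx0:cx1) for (cy in cy0:cy1) {
      k <- cx * n_cells + cy + 1
      buckets[[k]] <- c(buckets[[k]], f)
    }
  }
  list(buckets = buckets, cell_of = cell_of, fx = fx, fy = fy)
}

#' Map a 2D (AL, PGD) point onto the 3D graft surface
#'
#' Locates the uv triangle containing the point (via a uniform-grid spatial
#' index over the 2D faces), computes its barycentric coordinates there,
#' and applies them to the same triangle's 3D vertices.  Points that fall
#' in a numerical gap between triangles are snapped to the nearest triangle
#' when within tolerance.
#'
#' @param param a [embed_rectangle()] parameterization.
#' @param mesh the corresponding [loft_graft_mesh()] mesh.
#' @param p 2D point `c(AL, PGD)` in mm, inside the rectangle.
#' @param snap_tol barycentric snap tolerance for points just outside all
#'   triangles.
#' @return 3D point on the graft surface (named attribute `face` gives the
#'   triangle index).
#' @export
uv_to_surface <- function(param, mesh, p, snap_tol = 1e-6) {
  idx <- attr(param, "uv_index")
  if (is.null(idx)) idx <- .build_uv_index(param, mesh$faces)
  cand <- idx$buckets[[idx$cell_of(p[1], p[2])]]
  best_f <- NA_integer_; best_l <- NULL; best_short <- -Inf
  search_sets <- list(cand, seq_len(nrow(mesh$faces)))
  for (set in search_sets) {
    if (!length(set)) next
    lam <- .bary_rows(p[1], p[2],
                      idx$fx[set, 1], idx$fy[set, 1],
                      idx$fx[set, 2], idx$fy[set, 2],
                      idx$fx[set, 3], idx$fy[set, 3])
    shortfall <- apply(lam, 1, min)
    j <- which.max(shortfall)
    if (shortfall[j] > best_short) {
      best_short <- shortfall[j]; best_f <- set[j]; best_l <- lam[j, ]
    }
    if (best_short >= 0) break    # strictly inside a candidate triangle
  }
  if (best_short < -snap_tol)
    stop(sprintf("point (%.2f, %.2f) lies outside the parameterized rectangle",
                 p[1], p[2]), call. = FALSE)
  l <- pmax(best_l, 0); l <- l / sum(l)
  f <- mesh$faces[best_f, ]
  out <- l[1] * mesh$vertices[f[1], ] + l[2] * mesh$vertices[f[2], ] +
    l[3] * mesh$vertices[f[3], ]
  attr(out, "face") <- best_f
  out
}

#' Deviation between two points on the developed graft surface
#'
#' The alignment deviation `delta = sqrt(dAL^2 + dPGD^2)` in the developed
#' (AL, PGD) plane, the curved distance on the graft surface.  The AL
#' difference is taken on the shorter arc when the circumferential period
#' is supplied.
#'
#' @param center_uv,truth_uv points `c(AL, PGD)` in mm.
#' @param period graft circumference, mm, or `NULL` for plain Euclidean.
#' @return delta in mm.
#' @export
alignment_deviation <- function(center_uv, truth_uv, period = NULL) {
  dal <- center_uv[1] - truth_uv[1]
  if (!is.null(period)) dal <- wrap_al(dal, period)
  sqrt(dal^2 + (center_uv[2] - truth_uv[2])^2)
}

#' Map a fitted 2D design onto the 3D graft surface
#'
#' Applies the fitted global offset (and any per-vessel relaxation) to each
#' measured fenestration, maps the resulting (AL, PGD) centres through the
#' parameterization to 3D, and computes the per-vessel deviation `delta_f`
#' against ground truth.  By default the ground truth is the measured
#' ostium position itself (so `delta_f` reflects the displacement the
#' search introduced); an explicit `truth_uv` -- e.g. from a synthetic
#' ground-truth generator or a manual plan -- may be supplied.
#'
#' @param fit a valid `fit_result`.
#' @param specs the measured [fenestration_spec()]s.
#' @param param,mesh parameterization and mesh.
#' @param design_image optional [mask2d()] overlay carried along for
#'   texture export.
#' @param truth_uv optional named list/matrix of ground-truth `(AL, PGD)`
#'   per vessel.
#' @param force map even an invalid fit (default `FALSE`).
#' @return an object of class `mapped_design` with `fen_centers_uv`,
#'   `fen_centers_3d`, `delta_f`, the inputs, and the design image.
#' @export
map_design <- function(fit, specs, param, mesh, design_image = NULL,
                       truth_uv = NULL, force = FALSE) {
  if (!fit$valid && !force)
    stop("fit is not valid; pass force = TRUE to map anyway", call. = FALSE)
  period <- fit$al_period
  vn <- vapply(specs, `[[`, "", "vessel")
  idx <- .build_uv_index(param, mesh$faces)
  attr(param, "uv_index") <- idx
  centers_uv <- matrix(0, length(specs), 2, dimnames = list(vn, c("AL", "PGD")))
  centers_3d <- matrix(0, length(specs), 3, dimnames = list(vn, NULL))
  delta_f <- stats::setNames(numeric(length(specs)), vn)
  for (v in seq_along(specs)) {
    shift <- fit$per_vessel_shift[[vn[v]]] %||% c(0, 0)
    al <- (specs[[v]]$AL + fit$dAL + shift[1]) %% period
    pgd <- specs[[v]]$PGD + fit$dPGD + shift[2]
    if (pgd < 0 || pgd > param$rect[2])
      stop("fitted centre for ", vn[v], " falls outside the rectangle",
           call. = FALSE)
    centers_uv[v, ] <- c(al, pgd)
    centers_3d[v, ] <- uv_to_surface(param, mesh, c(al, pgd))
    truth <- if (!is.null(truth_uv)) truth_uv[[vn[v]]]
             else c(specs[[v]]$AL, specs[[v]]$PGD)
    delta_f[v] <- alignment_deviation(centers_uv[v, ], truth, period = period)
  }
  structure(
    list(fen_centers_uv = centers_uv, fen_centers_3d = centers_3d,
         delta_f = delta_f, fit = fit, specs = specs,
         design_image = design_image),
    class = "mapped_design"
  )
}

#' @export
print.mapped_design <- function(x, ...) {
  cat("<mapped_design>\n")
  for (v in rownames(x$fen_centers_uv))
    cat(sprintf("  %s: AL=%.2f PGD=%.2f mm -> (%.1f, %.1f, %.1f), delta_f=%.2f mm\n",
                v, x$fen_centers_uv[v, 1], x$fen_centers_uv[v, 2],
                x$fen_centers_3d[v, 1], x$fen_centers_3d[v, 2],
                x$fen_centers_3d[v, 3], x$delta_f[v]))
  invisible(x)
}

#' Write a textured OBJ (+ MTL + PNG) of the mapped design
#'
#' Vertex uv coordinates come from the parameterization (normalized to
#' [0, 1]); the design image is written as the texture so a standard viewer
#' interpolates it across faces barycentrically.
#'
#' @param mesh,param mesh and parameterization.
#' @param design [mask2d()] design image (struts + fenestrations).
#' @param path output OBJ path (MTL and PNG are written alongside).
#' @return `path`, invisibly.
#' @export
write_textured_obj <- function(mesh, param, design, path) {
  base <- sub("\\.obj$", "", path)
  png_path <- paste0(base, ".png")
  mtl_path <- paste0(base, ".mtl")
  img <- 1 - design$pixels + 0.0    # struts dark on light fabric
  png::writePNG(img, target = png_path)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("mtllib %s", basename(mtl_path)), "usemtl graft"), con)
  V <- mesh$vertices
  writeLines(sprintf("v %.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]), con)
  uvn <- cbind(param$uv[, 1] / param$rect[1], 1 - param$uv[, 2] / param$rect[2])
  writeLines(sprintf("vt %.6f %.6f", uvn[, 1], uvn[, 2]), con)
  F_ <- mesh$faces
  writeLines(sprintf("f %d/%d %d/%d %d/%d",
                     F_[, 1], F_[, 1], F_[, 2], F_[, 2], F_[, 3], F_[, 3]), con)
  writeLines(c("newmtl graft", "Kd 1 1 1",
               sprintf("map_Kd %s", basename(png_path))), mtl_path)
  invisible(path)
}
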