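#' Derive the aortic centerline from a binary lumen labelmap
#'
#' Computes the centroid of each axial lumen cross-section, smooths the
#' centroids with a spline of best fit ([fit_centerline_spline()]), and
#' resamples the curve at regular arclength stations.  The local diameter at
#' each station is the equivalent-area circle diameter of the cross-section;
#' per-station orthonormal (tangent, normal, binormal) frames are propagated
#' by rotation-minimizing transport.
#'
#' Voxel `(i, j, k)` (1-based) has its centre at `(i - 0.5, j - 0.5,
#' k - 0.5) * spacing` mm; the third array dimension is the axial direction.
#'
#' @param labelmap 3D binary array (lumen = 1), or the path to a NIfTI file.
#' @param spacing voxel spacing, mm, length 3; taken from the NIfTI header
#'   when `labelmap` is a path.
#' @param station_spacing arclength spacing of the output stations, mm.
#' @param spar smoothing parameter for the centerline spline.  The default
#'   (0.7) suppresses the arclength inflation that per-slice segmentation
#'   roughness would otherwise cause -- an under-smoothed centroid
#'   polyline is systematically too long, which biases every PGD
#'   measurement -- while leaving clinical-scale tortuosity (wavelengths
#'   of tens of mm) intact.  `NULL` selects smoothing by GCV.
#' @return an object of class `aortic_centerline` with `points`,
#'   `arclength`, `local_diameter`, `frame` (list of `tangent`, `normal`,
#'   `binormal` matrices), and the underlying `curve`.
#' @export
compute_centerline <- function(labelmap, spacing = NULL, station_spacing = 1,
                               spar = 0.7) {
  if (is.character(labelmap)) {
    img <- RNifti::readNifti(labelmap)
    spacing <- RNifti::pixdim(img)[1:3]
    labelmap <- (as.array(img) != 0)
  }
  if (length(dim(labelmap)) != 3) stop("labelmap must be 3D", call. = FALSE)
  if (is.null(spacing) || length(spacing) != 3)
    stop("`spacing` must have length 3", call. = FALSE)
  vox <- which(labelmap != 0, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("labelmap is empty", call. = FALSE)
  vox <- .largest_component_if_needed(vox, dim(labelmap))
  k <- vox[, 3]
  counts <- tabulate(k, nbins = max(k))
  slices <- which(counts > 0)
  if (length(slices) < 4)
    stop("lumen must span at least 4 axial slices", call. = FALSE)
  cx <- rowsum(as.numeric(vox[, 1]), k)[, 1] / counts[slices]
  cy <- rowsum(as.numeric(vox[, 2]), k)[, 1] / counts[slices]
  centroids <- cbind((cx - 0.5) * spacing[1],
                     (cy - 0.5) * spacing[2],
                     (slices - 0.5) * spacing[3])
  area <- counts[slices] * spacing[1] * spacing[2]
  d_eq <- 2 * sqrt(area / pi)
  curve <- fit_centerline_spline(centroids, spar = spar)
  s <- seq(0, curve$length, by = station_spacing)
  if (s[length(s)] < curve$length) s <- c(s, curve$length)
  pts <- curve$eval(s)
  tangent <- curve_tangent(curve, s)
  fr <- rmf_frames(pts, tangent)
  # slice arclength positions for diameter interpolation
  s_slice <- vapply(seq_len(nrow(centroids)), function(i) {
    d2 <- rowSums(sweep(pts, 2, centroids[i, ])^2)
    s[which.min(d2)]
  }, 0)
  dia <- stats::approx(s_slice, d_eq, xout = s, rule = 2, ties = mean)$y
  structure(
    list(points = pts, arclength = s, local_diameter = dia,
         frame = list(tangent = tangent, normal = fr$normal,
                      binormal = fr$binormal),
         curve = curve),
    class = "aortic_centerline"
  )
}

#' @export
print.aortic_centerline <- function(x, ...) {
  cat(sprintf(
    "<aortic_centerline> %.1f mm, %d stations, lumen diameter %.1f-%.1f mm\n",
    max(x$arclength), length(x$arclength),
    min(x$local_diameter), max(x$local_diameter)))
  invisible(x)
}

# Keep only the largest 6-connected component when a cheap necessary
# condition for connectivity fails (contiguous non-empty z-range and overlap
# between consecutive slices).  The full check builds the voxel adjacency
# graph, so it only runs on the suspicious path.
.largest_component_if_needed <- function(vox, dims) {
  k <- vox[, 3]
  kr <- range(k)
  contiguous <- all(tabulate(k, nbins = kr[2])[kr[1]:kr[2]] > 0)
  overlap_ok <- contiguous
  if (contiguous && kr[1] < kr[2]) {
    key <- vox[, 1] + dims[1] * (vox[, 2] - 1)
    by_slice <- split(key, k)
    for (i in seq_len(length(by_slice) - 1)) {
      if (!any(by_slice[[i]] %in% by_slice[[i + 1]])) { overlap_ok <- FALSE; break }
    }
  }
  if (overlap_ok) return(vox)
  warning("lumen labelmap is disconnected; using the largest component")
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required to split disconnected labelmaps",
         call. = FALSE)
  lin <- vox[, 1] + dims[1] * (vox[, 2] - 1) + dims[1] * dims[2] * (vox[, 3] - 1)
  idx <- seq_along(lin)
  edges <- NULL
  for (off in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    nb <- lin + off[1] + dims[1] * off[2] + dims[1] * dims[2] * off[3]
    hit <- match(nb, lin)
    ok <- !is.na(hit) &
      (off[1] == 0 | vox[, 1] < dims[1]) &
      (off[2] == 0 | vox[, 2] < dims[2]) &
      (off[3] == 0 | vox[, 3] < dims[3])
    edges <- rbind(edges, cbind(idx[ok], hit[ok]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(lin) - igraph::vcount(g)))
  comp <- igraph::components(g)
  vox[comp$membership == which.max(comp$csize), , drop = FALSE]
}

#' Fenestration specification in graft surface coordinates
#'
#' Direct constructor; normally produced by [measure_fenestration()].
#'
#' @param vessel vessel label (`"CA"`, `"SMA"`, `"RRA"`, `"LRA"`, or other).
#' @param phi circumferential angle from the datum vector, degrees in
#'   `[0, 360)`, measured clockwise when viewed from proximal.  May be `NA`
#'   when a spec is built directly from AL.
#' @param AL arclength position, mm.
#' @param PGD proximal graft distance, mm (>= 0).
#' @param diameter fenestration (vessel) diameter, mm.
#' @param prioritized logical; prioritized vessels (typically CA/SMA) are
#'   never displaced by the relaxation fallback.
#' @return an object of class `fenestration_spec`.
#' @export
fenestration_spec <- function(vessel, phi = NA_real_, AL, PGD, diameter,
                              prioritized = FALSE) {
  if (!is.na(phi) && (phi < 0 || phi >= 360))
    stop("phi must be in [0, 360)", call. = FALSE)
  if (PGD < 0) stop("PGD must be >= 0", call. = FALSE)
  if (diameter <= 0) stop("diameter must be positive", call. = FALSE)
  structure(
    list(vessel = as.character(vessel), phi = phi, AL = AL, PGD = PGD,
         diameter = diameter, prioritized = isTRUE(prioritized)),
    class = "fenestration_spec"
  )
}

#' @export
print.fenestration_spec <- function(x, ...) {
  cat(sprintf("<fenestration_spec> %s: AL=%.2f mm, PGD=%.2f mm, d=%.1f mm%s%s\n",
              x$vessel, x$AL, x$PGD, x$diameter,
              if (!is.na(x$phi)) sprintf(" (phi=%.1f deg)", x$phi) else "",
              if (x$prioritized) " [prioritized]" else ""))
  invisible(x)
}

#' Measure a fenestration's (AL, PGD) position from 3D anatomy
#'
#' Projects the ostium centre onto the centerline; PGD is the centerline
#' arclength from the proximal graft edge (`graft_top_station`) to the foot
#' point, and phi is the angle of the ostium direction about the local
#' tangent, measured from the datum vector projected into the cross-section
#' plane, clockwise when viewed from proximal.  AL converts phi at the
#' deployed graft diameter: `AL = phi/360 * pi * D`.
#'
#' @param centerline an [compute_centerline()] result (or any object with
#'   `curve` and `arclength`).
#' @param ostium 3D ostium centre, mm.
#' @param datum 3D datum direction (default patient-anterior `c(1, 0, 0)`);
#'   must not be parallel to the local tangent.
#' @param deployed_diameter deployed graft diameter, mm.
#' @param graft_top_station proximal graft edge position, mm of centerline
#'   arclength.
#' @param vessel,diameter,prioritized passed through to the returned spec.
#' @param graft_length optional graft length, mm; when supplied, an ostium
#'   whose PGD falls outside `[0, graft_length]` raises an out-of-coverage
#'   error naming the vessel.
#' @return a [fenestration_spec()].
#' @export
measure_fenestration <- function(centerline, ostium, datum = c(1, 0, 0),
                                 deployed_diameter, graft_top_station,
                                 vessel = "other", diameter = 6,
                                 prioritized = FALSE, graft_length = NULL) {
  curve <- centerline$curve
  s_grid <- centerline$arclength
  d2 <- rowSums(sweep(centerline$points, 2, ostium)^2)
  i0 <- which.min(d2)
  if (i0 == 1L || i0 == length(s_grid))
    stop("ostium for ", vessel, " projects outside the centerline extent",
         call. = FALSE)
  bracket <- c(s_grid[i0 - 1L], s_grid[i0 + 1L])
  opt <- stats::optimize(function(s) sum((curve$eval(s)[1, ] - ostium)^2),
                         interval = bracket, tol = 1e-8)
  s_foot <- opt$minimum
  foot <- curve$eval(s_foot)[1, ]
  tang <- curve_tangent(curve, s_foot)[1, ]
  dproj <- project_datum(matrix(tang, 1), datum)[1, ]
  e2 <- cross3(tang, dproj)
  u <- ostium - foot
  u <- u - sum(u * tang) * tang
  if (sqrt(sum(u^2)) < 1e-9)
    stop("ostium for ", vessel, " lies on the centerline", call. = FALSE)
  phi <- atan2(sum(u * e2), sum(u * dproj)) * 180 / pi
  phi <- phi %% 360
  pgd <- s_foot - graft_top_station
  if (!is.null(graft_length) && (pgd < 0 || pgd > graft_length))
    stop("vessel ", vessel, " (PGD = ", sprintf("%.1f", pgd),
         " mm) is outside the graft coverage", call. = FALSE)
  al <- phi / 360 * pi * deployed_diameter
  fenestration_spec(vessel, phi = phi, AL = al, PGD = max(pgd, 0),
                    diameter = diameter, prioritized = prioritized)
}

#' Read ostia from a CSV file
#'
#' Expected columns: `vessel, x, y, z, diameter, prioritized` (coordinates
#' in mm, image space).
#'
#' @param path CSV path.
#' @return data frame of ostia.
#' @export
read_ostia <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vessel", "x", "y", "z", "diameter", "prioritized")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("ostia file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$prioritized <- as.logical(df$prioritized)
  df
}

# Rasterize one fenestration disc into an existing-size canvas.
# Returns integer matrix n_row x n_col.
.disc_mask <- function(al, pgd, radius, n_row, n_col, resolution, al_period) {
  px <- matrix(0L, n_row, n_col)
  al <- al %% al_period
  r_rows <- which(abs(px_center(seq_len(n_row) - 1L, resolution) - pgd) <= radius)
  if (!length(r_rows)) return(px)
  al_c <- px_center(seq_len(n_col) - 1L, resolution)
  dal <- abs(al_c - al)
  dal <- pmin(dal, al_period - dal)     # discs wrap across the AL seam
  for (i in r_rows) {
    dp <- px_center(i - 1L, resolution) - pgd
    hit <- dal^2 + dp^2 <= radius^2
    px[i, hit] <- 1L
  }
  px
}

#' Build the fenestration mask from measured specs
#'
#' Each fenestration is rasterized as a filled disc of its own diameter
#' centred at `(AL mod al_period, PGD)`.  Relative distances between the
#' fenestrations are preserved exactly (the constellation is rigid); the
#' mask itself is not AL-periodic -- periodicity is applied during the
#' search.
#'
#' @param specs list of [fenestration_spec()] objects (>= 1).
#' @param resolution pixel size, mm/px.
#' @param al_period graft circumference, mm (sets the column count).
#' @param pgd_extent graft length, mm (sets the row count).
#' @return a [mask2d()].
#' @export
build_fenestration_mask <- function(specs, resolution = 0.25, al_period,
                                    pgd_extent) {
  if (!length(specs)) stop("need at least one fenestration spec", call. = FALSE)
  n_col <- as.integer(round(al_period / resolution))
  n_row <- as.integer(round(pgd_extent / resolution))
  for (sp in specs) {
    if (sp$PGD - sp$diameter / 2 < 0 || sp$PGD + sp$diameter / 2 > pgd_extent)
      stop("fenestration ", sp$vessel, " crosses the graft fabric edge",
           call. = FALSE)
  }
  if (length(specs) > 1) {
    for (i in seq_len(length(specs) - 1)) for (j in (i + 1):length(specs)) {
      dal <- abs(specs[[i]]$AL - specs[[j]]$AL) %% al_period
      dal <- min(dal, al_period - dal)
      dd <- sqrt(dal^2 + (specs[[i]]$PGD - specs[[j]]$PGD)^2)
      if (dd < (specs[[i]]$diameter + specs[[j]]$diameter) / 2)
        stop("fenestration discs for ", specs[[i]]$vessel, " and ",
             specs[[j]]$vessel, " overlap", call. = FALSE)
    }
  }
  px <- matrix(0L, n_row, n_col)
  for (sp in specs) {
    px <- px | .disc_mask(sp$AL, sp$PGD, sp$diameter / 2,
                          n_row, n_col, resolution, al_period)
  }
  storage.mode(px) <- "integer"
  mask2d(px, resolution, al_period = al_period, periodic_al = FALSE)
}
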