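#' Parametric stent-graft template
#'
#' Describes a commercial tube endograft by the few key variables the
#' planning algorithm needs: overall dimensions and the zigzag strut-ring
#' pattern.  Strut rings are symmetric triangular zigzags with
#' `n_peaks_per_ring` apices; `strut_amplitude` is the peak-to-peak axial
#' height of one ring and `strut_wire_width` the wire thickness.  The
#' template is flagged tapered when the proximal and distal fabric diameters
#' differ.
#'
#' @param name device name (free text).
#' @param length graft fabric length, mm.
#' @param proximal_diameter,distal_diameter fabric diameters at the proximal
#'   and distal edges, mm.  `distal_diameter` defaults to the proximal one
#'   (uniform graft).
#' @param ring_axial_positions numeric vector of strut-ring centre positions,
#'   mm from the proximal edge, strictly increasing, all within
#'   `[0, length]`.  May be empty (strut-free fabric).
#' @param strut_amplitude peak-to-peak axial height of a zigzag ring, mm.
#' @param strut_wire_width wire width, mm; must be smaller than the
#'   amplitude.
#' @param n_peaks_per_ring number of up-apices per ring.
#' @return an object of class `graft_template`.
#' @examples
#' graft_template("demo", length = 100, proximal_diameter = 30,
#'                ring_axial_positions = c(10, 30, 50, 70, 90),
#'                strut_amplitude = 12, strut_wire_width = 0.5,
#'                n_peaks_per_ring = 8)
#' @export
graft_template <- function(name, length, proximal_diameter,
                           distal_diameter = proximal_diameter,
                           ring_axial_positions = numeric(0),
                           strut_amplitude, strut_wire_width,
                           n_peaks_per_ring) {
  need <- c(length = length, proximal_diameter = proximal_diameter,
            distal_diameter = distal_diameter,
            strut_amplitude = strut_amplitude,
            strut_wire_width = strut_wire_width,
            n_peaks_per_ring = n_peaks_per_ring)
  bad <- names(need)[!is.finite(need) | need <= 0]
  if (length(bad))
    stop("non-positive or missing template value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  pos <- as.numeric(ring_axial_positions)
  if (length(pos)) {
    if (any(diff(pos) <= 0))
      stop("ring_axial_positions must be strictly increasing", call. = FALSE)
    if (any(pos < 0 | pos > length))
      stop("ring_axial_positions must lie within [0, length]", call. = FALSE)
  }
  if (strut_wire_width >= strut_amplitude)
    stop("strut_wire_width must be smaller than strut_amplitude", call. = FALSE)
  if (n_peaks_per_ring < 2 || n_peaks_per_ring != round(n_peaks_per_ring))
    stop("n_peaks_per_ring must be an integer >= 2", call. = FALSE)
  structure(
    list(
      name = as.character(name)[1],
      length = as.numeric(length),
      proximal_diameter = as.numeric(proximal_diameter),
      distal_diameter = as.numeric(distal_diameter),
      n_strut_rings = length(pos),
      strut_amplitude = as.numeric(strut_amplitude),
      strut_wire_width = as.numeric(strut_wire_width),
      n_peaks_per_ring = as.integer(n_peaks_per_ring),
      ring_axial_positions = pos,
      tapered = !isTRUE(all.equal(as.numeric(proximal_diameter),
                                  as.numeric(distal_diameter)))
    ),
    class = "graft_template"
  )
}

#' @export
print.graft_template <- function(x, ...) {
  cat(sprintf(
    "<graft_template> %s: L=%g mm, D=%g->%g mm%s, %d rings (A=%g, wire=%g, %d peaks)\n",
    x$name, x$length, x$proximal_diameter, x$distal_diameter,
    if (x$tapered) " (tapered)" else "", x$n_strut_rings,
    x$strut_amplitude, x$strut_wire_width, x$n_peaks_per_ring))
  invisible(x)
}

#' Build a template from a descriptor list
#'
#' Accepts the key-value form used by the JSON template repository.
#'
#' @param descriptor named list with the fields of [graft_template()].
#' @return a `graft_template`.
#' @export
as_graft_template <- function(descriptor) {
  required <- c("name", "length", "proximal_diameter", "strut_amplitude",
                "strut_wire_width", "n_peaks_per_ring")
  missing <- setdiff(required, names(descriptor))
  if (length(missing))
    stop("template descriptor is missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  graft_template(
    name = descriptor$name,
    length = descriptor$length,
    proximal_diameter = descriptor$proximal_diameter,
    distal_diameter = descriptor$distal_diameter %||% descriptor$proximal_diameter,
    ring_axial_positions = unlist(descriptor$ring_axial_positions %||% numeric(0)),
    strut_amplitude = descriptor$strut_amplitude,
    strut_wire_width = descriptor$strut_wire_width,
    n_peaks_per_ring = descriptor$n_peaks_per_ring
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load the bundled graft-template repository
#'
#' The repository is a JSON list of template descriptors.  The bundled file
#' contains illustrative straight and tapered thoracic tube-graft shapes
#' (dimensions are representative, not vendor-certified).
#'
#' @param path path to a repository JSON file; defaults to the bundled one.
#' @return named list of `graft_template` objects.
#' @export
template_repository <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "graft_templates.json", package = "fenplan")
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(entries, as_graft_template)
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

# ---- strut rasterization -------------------------------------------------

# Half-period apex sequence of one zigzag ring in (theta_deg, y) coordinates.
# Up-apices (y = center - A/2) at theta = k * 360/n; extended beyond one turn
# so AL wrap is handled by plain segment distances.
.ring_apices <- function(center, amplitude, n_peaks) {
  half <- 360 / n_peaks / 2
  m <- seq(-2L, 2L * n_peaks + 2L)       # half-period index, extended
  theta <- m * half
  y <- center + ifelse(m %% 2 == 0, -amplitude / 2, amplitude / 2)
  cbind(theta = theta, y = y)
}

# Minimum distance from points (px, py) to a set of segments.
.dist_to_segments <- function(px, py, x1, y1, x2, y2) {
  best <- rep(Inf, length(px))
  for (k in seq_along(x1)) {
    dx <- x2[k] - x1[k]; dy <- y2[k] - y1[k]
    len2 <- dx * dx + dy * dy
    if (len2 < 1e-18) {
      d2 <- (px - x1[k])^2 + (py - y1[k])^2
    } else {
      t <- ((px - x1[k]) * dx + (py - y1[k]) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (px - (x1[k] + t * dx))^2 + (py - (y1[k] + t * dy))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Flatten a uniform-diameter graft template to a 2D strut mask
#'
#' The cylinder is unwound to a single rectangle of width pi * D
#' (circumference at the deployed diameter) by the graft length.  Pixels
#' covered by strut wire -- inflated by the configurable safety margin that
#' keeps cautery clear of metal -- are 1; open fabric is 0.  The AL axis is
#' periodic.
#'
#' @param template a non-tapered [graft_template()].
#' @param resolution pixel size, mm/px (default 0.25).
#' @param deployed_diameter diameter at which the graft is deployed in the
#'   aorta, mm; defaults to the template's fabric diameter.  Masks must be
#'   built at the deployed diameter so AL on the mask matches AL on the
#'   implanted graft.
#' @param margin safety dilation around the wire, mm (default 1).
#' @return a periodic-AL [mask2d()].
#' @export
flatten_uniform <- function(template, resolution = 0.25,
                            deployed_diameter = NULL, margin = 1) {
  stopifnot(inherits(template, "graft_template"))
  if (template$tapered)
    stop("flatten_uniform() requires a non-tapered template", call. = FALSE)
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  D <- deployed_diameter %||% template$proximal_diameter
  circ <- pi * D
  n_col <- as.integer(round(circ / resolution))
  n_row <- as.integer(round(template$length / resolution))
  px <- matrix(0L, n_row, n_col)
  half_width <- template$strut_wire_width / 2 + margin
  al_c <- px_center(seq_len(n_col) - 1L, resolution)
  for (zc in template$ring_axial_positions) {
    ap <- .ring_apices(zc, template$strut_amplitude, template$n_peaks_per_ring)
    ax <- ap[, "theta"] / 360 * circ
    ay <- ap[, "y"]
    rows <- which(abs(px_center(seq_len(n_row) - 1L, resolution) - zc) <=
                    template$strut_amplitude / 2 + half_width + resolution)
    if (!length(rows)) next
    pgd_c <- px_center(rows - 1L, resolution)
    grid <- expand.grid(al = al_c, pgd = pgd_c)
    d <- .dist_to_segments(grid$al, grid$pgd,
                           ax[-length(ax)], ay[-length(ay)], ax[-1], ay[-1])
    hit <- matrix(d <= half_width, nrow = length(al_c))
    px[rows, ] <- px[rows, ] | t(hit)
  }
  storage.mode(px) <- "integer"
  mask2d(px, resolution, al_period = circ, periodic_al = TRUE)
}

#' Flatten a tapered graft template to a 2D strut mask
#'
#' The frustum is developed isometrically onto an annular sector and the
#' strut zigzags rasterized there, then resampled into a rectangular
#' (AL, PGD) grid whose column count corresponds to the largest local
#' circumference.  Each PGD row's valid AL extent equals the local
#' circumference; cells outside it are marked 1 (treated as strut, i.e.
#' not placeable).  Zero taper defers to [flatten_uniform()].
#'
#' @inheritParams flatten_uniform
#' @param deployed_proximal,deployed_distal deployed diameters at the two
#'   ends, mm; default to the template's fabric diameters.
#' @return a periodic-AL [mask2d()] with a per-row period.
#' @export
flatten_tapered <- function(template, resolution = 0.25,
                            deployed_proximal = NULL, deployed_distal = NULL,
                            margin = 1) {
  stopifnot(inherits(template, "graft_template"))
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  Dp <- deployed_proximal %||% template$proximal_diameter
  Dd <- deployed_distal %||% template$distal_diameter
  if (isTRUE(all.equal(Dp, Dd))) {
    m <- flatten_uniform(template, resolution,
                         deployed_diameter = Dp, margin = margin)
    m$row_period <- rep(pi * Dp, nrow(m$pixels))
    return(m)
  }
  L <- template$length
  rp <- Dp / 2; rd <- Dd / 2
  slope <- (rd - rp) / L                 # radius change per mm of axis
  q <- sqrt(1 + slope^2)                 # slant length per mm of axis
  y_apex <- -rp / slope                  # cone apex station (may be < 0 or > L)
  s_frac <- abs(slope) / q               # developed-angle compression factor
  radius_at <- function(y) rp + slope * y
  to_sector <- function(theta, y) {      # theta in radians
    ell <- abs(y - y_apex) * q
    cbind(ell * cos(theta * s_frac), ell * sin(theta * s_frac))
  }
  n_col <- as.integer(round(pi * max(Dp, Dd) / resolution))
  n_row <- as.integer(round(L / resolution))
  pgd_all <- px_center(seq_len(n_row) - 1L, resolution)
  al_all <- px_center(seq_len(n_col) - 1L, resolution)
  row_circ <- 2 * pi * radius_at(pgd_all)
  px <- matrix(0L, n_row, n_col)
  # cells beyond the local circumference are invalid
  invalid <- outer(row_circ, al_all, function(c0, a) a >= c0)
  half_width <- template$strut_wire_width / 2 + margin
  for (zc in template$ring_axial_positions) {
    ap <- .ring_apices(zc, template$strut_amplitude, template$n_peaks_per_ring)
    # each zigzag leg is straight in (theta, y) and very nearly straight
    # under the sector development (sagitta << pixel size for clinical
    # tapers), so a few chords per leg rasterize it faithfully
    n_s <- 4L
    x1 <- y1 <- x2 <- y2 <- numeric(0)
    for (k in seq_len(nrow(ap) - 1L)) {
      tt <- seq(0, 1, length.out = n_s + 1L)
      th <- (ap[k, "theta"] + tt * (ap[k + 1L, "theta"] - ap[k, "theta"])) * pi / 180
      yy <- ap[k, "y"] + tt * (ap[k + 1L, "y"] - ap[k, "y"])
      pts <- to_sector(th, yy)
      x1 <- c(x1, pts[-nrow(pts), 1]); y1 <- c(y1, pts[-nrow(pts), 2])
      x2 <- c(x2, pts[-1, 1]);         y2 <- c(y2, pts[-1, 2])
    }
    rows <- which(abs(pgd_all - zc) <=
                    template$strut_amplitude / 2 + half_width + resolution)
    if (!length(rows)) next
    sub <- which(!invalid[rows, , drop = FALSE], arr.ind = TRUE)
    if (!nrow(sub)) next
    y_p <- pgd_all[rows[sub[, 1]]]
    theta_p <- al_all[sub[, 2]] / radius_at(y_p)
    pmap <- to_sector(theta_p, y_p)
    d <- .dist_to_segments(pmap[, 1], pmap[, 2], x1, y1, x2, y2)
    hit <- d <= half_width
    px[cbind(rows[sub[hit, 1]], sub[hit, 2])] <- 1L
  }
  px[invalid] <- 1L
  storage.mode(px) <- "integer"
  mask2d(px, resolution, al_period = pi * max(Dp, Dd), periodic_al = TRUE,
         row_period = row_circ)
}

#' Flatten a graft template (dispatching on the tapered flag)
#'
#' @inheritParams flatten_uniform
#' @param ... passed to [flatten_uniform()] or [flatten_tapered()].
#' @return a [mask2d()].
#' @export
flatten_graft <- function(template, resolution = 0.25, ...) {
  if (template$tapered) flatten_tapered(template, resolution, ...)
  else flatten_uniform(template, resolution, ...)
}
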