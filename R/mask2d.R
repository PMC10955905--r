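#' Discretized binary mask in (AL, PGD) space
#'
#' A `mask2d` is a binary image laid out with rows along the proximal graft
#' distance (PGD) axis and columns along the arclength (AL) axis, together
#' with its physical resolution.  Row 0 is the proximal graft edge; column 0
#' is the datum ray (AL = 0).  Pixel `(i, j)` (0-based) covers the half-open
#' cell `[j*res, (j+1)*res) x [i*res, (i+1)*res)` in (AL, PGD) millimetres.
#'
#' For graft masks the AL axis is periodic: the true circumference
#' `al_period` is stored separately from the rounded column count so that
#' AL-to-column conversions use the exact period.  Tapered graft masks carry
#' a per-row period (`row_period`), the local circumference at each PGD row.
#'
#' @param pixels integer or logical matrix of 0/1 values (rows = PGD,
#'   columns = AL).
#' @param resolution pixel edge length in mm.
#' @param al_period true AL period in mm (circumference); defaults to the
#'   column extent for non-periodic masks.
#' @param periodic_al logical; `TRUE` for graft masks, whose AL axis wraps.
#' @param row_period optional numeric vector, one local AL period (mm) per
#'   row, for tapered graft masks.
#' @return an object of class `mask2d`.
#' @export
mask2d <- function(pixels, resolution, al_period = NULL, periodic_al = FALSE,
                   row_period = NULL) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive number", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (!all(pixels %in% c(0L, 1L)))
    stop("`pixels` must be strictly binary (0/1)", call. = FALSE)
  if (is.null(al_period)) al_period <- ncol(pixels) * resolution
  if (!is.null(row_period) && length(row_period) != nrow(pixels))
    stop("`row_period` must have one entry per row", call. = FALSE)
  structure(
    list(
      pixels = pixels,
      resolution = resolution,
      al_extent = ncol(pixels) * resolution,
      pgd_extent = nrow(pixels) * resolution,
      al_period = al_period,
      periodic_al = isTRUE(periodic_al),
      row_period = row_period
    ),
    class = "mask2d"
  )
}

#' @export
print.mask2d <- function(x, ...) {
  cat(sprintf(
    "<mask2d> %d x %d px @ %.3g mm/px (PGD %.1f mm x AL %.1f mm)%s, %d strut px\n",
    nrow(x$pixels), ncol(x$pixels), x$resolution,
    x$pgd_extent, x$al_extent,
    if (x$periodic_al) sprintf(", periodic AL (period %.2f mm)", x$al_period) else "",
    sum(x$pixels)
  ))
  invisible(x)
}

# mm -> 0-based pixel index (half-open cells)
mm_to_px <- function(mm, resolution) as.integer(floor(mm / resolution))

# centre of 0-based pixel index, in mm
px_center <- function(idx, resolution) (idx + 0.5) * resolution

#' Write a mask as a PNG image with a JSON sidecar
#'
#' Strut/fenestration pixels are written white on black.  The sidecar
#' records resolution and physical extents so the image is self-describing.
#'
#' @param mask a [mask2d()].
#' @param path output PNG path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "mask2d"))
  png::writePNG(mask$pixels + 0, target = path)   # integer -> double image
  meta <- list(
    resolution_mm_per_px = mask$resolution,
    al_extent_mm = mask$al_extent,
    pgd_extent_mm = mask$pgd_extent,
    al_period_mm = mask$al_period,
    periodic_al = mask$periodic_al,
    n_rows = nrow(mask$pixels),
    n_cols = ncol(mask$pixels)
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
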