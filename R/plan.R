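#' End-to-end fenestration planning
#'
#' Runs the full pipeline: centerline extraction, deployed-diameter sizing,
#' graft-template flattening, fenestration measurement and mask building,
#' alignment search (with posterior relaxation fallback), graft-mesh
#' lofting, rectangle parameterization, and texture mapping.  Deterministic
#' for fixed inputs.
#'
#' @param config a named list (or the path to a YAML/JSON file) with:
#'   \describe{
#'     \item{labelmap}{path to a NIfTI lumen labelmap, or a 3D array (then
#'       `spacing` is required).}
#'     \item{spacing}{voxel spacing, mm (array input only).}
#'     \item{ostia}{path to an ostia CSV or a data frame with columns
#'       `vessel, x, y, z, diameter, prioritized`.}
#'     \item{template}{template name in the repository, or a descriptor
#'       list ([as_graft_template()]).}
#'     \item{template_file}{optional repository JSON path.}
#'     \item{graft_top_station}{proximal graft edge, mm of centerline
#'       arclength (required).}
#'     \item{datum}{datum direction, default `c(1, 0, 0)`.}
#'     \item{resolution}{mask resolution, mm/px, default 0.25.}
#'     \item{margin}{strut safety margin, mm, default 1.}
#'     \item{n_circ}{mesh circumferential segments, default 96.}
#'     \item{max_posterior_shift}{renal relaxation bound, mm, default 3.}
#'     \item{out_dir}{optional output directory for artifacts.}
#'   }
#' @return an object of class `plan_report`.
#' @export
plan_fenestrations <- function(config) {
  if (is.character(config)) config <- .read_config(config)
  for (key in c("labelmap", "ostia", "template", "graft_top_station"))
    if (is.null(config[[key]]))
      stop("config is missing required entry '", key, "'", call. = FALSE)
  datum <- config$datum %||% c(1, 0, 0)
  resolution <- config$resolution %||% 0.25
  margin <- config$margin %||% 1
  n_circ <- config$n_circ %||% 96
  max_shift <- config$max_posterior_shift %||% 3
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- tic() - t0
    message(sprintf("stage %-12s %6.2f s", name, timings[[name]]))
    out
  }

  template <- stage("template", {
    if (is.character(config$template)) {
      repo <- template_repository(config$template_file)
      if (!config$template %in% names(repo))
        stop("unknown template '", config$template, "'")
      repo[[config$template]]
    } else as_graft_template(config$template)
  })
  centerline <- stage("centerline", {
    if (is.character(config$labelmap)) compute_centerline(config$labelmap)
    else compute_centerline(config$labelmap, config$spacing)
  })
  deployed <- stage("sizing", {
    dp <- size_graft_diameter(centerline, template, config$graft_top_station)
    dd <- if (template$tapered)
      min(template$distal_diameter, dp * template$distal_diameter /
            template$proximal_diameter) else dp
    c(proximal = dp, distal = dd)
  })
  graft_mask <- stage("flatten", {
    if (template$tapered)
      flatten_tapered(template, resolution, deployed_proximal = deployed[1],
                      deployed_distal = deployed[2], margin = margin)
    else flatten_uniform(template, resolution,
                         deployed_diameter = deployed[1], margin = margin)
  })
  ostia <- if (is.character(config$ostia)) read_ostia(config$ostia)
           else config$ostia
  specs <- stage("measure", {
    lapply(seq_len(nrow(ostia)), function(i)
      measure_fenestration(centerline,
                           ostium = as.numeric(ostia[i, c("x", "y", "z")]),
                           datum = datum,
                           deployed_diameter = deployed[1],
                           graft_top_station = config$graft_top_station,
                           vessel = ostia$vessel[i],
                           diameter = ostia$diameter[i],
                           prioritized = ostia$prioritized[i],
                           graft_length = template$length))
  })
  fit <- stage("search", {
    find_fit(graft_mask, specs, resolution, max_posterior_shift = max_shift)
  })
  if (!fit$valid) {
    report <- structure(
      list(template_used = template$name, deployed_diameter = deployed,
           fit = fit, specs = specs, instructions = NULL,
           deviations = fit$deviations, valid = FALSE,
           artifacts = list(), graft_mask = graft_mask,
           al_period = graft_mask$al_period),
      class = "plan_report")
    attr(report, "timings") <- timings
    return(report)
  }
  mesh <- stage("mesh", {
    loft_graft_mesh(centerline, deployed, config$graft_top_station,
                    template$length, n_circ = n_circ, datum = datum)
  })
  param <- stage("parameterize", {
    embed_rectangle(mesh, rect = c(graft_mask$al_period, template$length))
  })
  mapped <- stage("map", {
    fen_mask <- build_fenestration_mask(specs, resolution,
                                        graft_mask$al_period,
                                        template$length)
    design <- mask2d(pmin(graft_mask$pixels + fen_mask$pixels, 1L),
                     resolution, al_period = graft_mask$al_period,
                     periodic_al = TRUE)
    map_design(fit, specs, param, mesh, design_image = design)
  })
  instructions <- data.frame(
    vessel = rownames(mapped$fen_centers_uv),
    AL_mm = round(mapped$fen_centers_uv[, "AL"] %% graft_mask$al_period, 2),
    PGD_mm = round(mapped$fen_centers_uv[, "PGD"], 2),
    diameter_mm = vapply(specs, `[[`, 0, "diameter"),
    relaxation_mm = vapply(rownames(mapped$fen_centers_uv), function(v)
      round(fit$per_vessel_shift[[v]][1], 2), 0),
    row.names = NULL
  )
  report <- structure(
    list(template_used = template$name, deployed_diameter = deployed,
         fit = fit, specs = specs, instructions = instructions,
         deviations = mapped$delta_f, valid = TRUE,
         mesh = mesh, param = param, mapped = mapped,
         graft_mask = graft_mask, al_period = graft_mask$al_period),
    class = "plan_report")
  attr(report, "timings") <- timings
  if (!is.null(config$out_dir)) render_instructions(report, config$out_dir)
  report
}

#' @export
print.plan_report <- function(x, ...) {
  cat(sprintf("<plan_report> template %s, deployed D = %.1f mm: %s\n",
              x$template_used, x$deployed_diameter[1],
              if (x$valid) "VALID plan" else "NO VALID FIT"))
  if (x$valid) print(x$instructions)
  invisible(x)
}

.read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Render operating-room modification instructions
#'
#' Writes `instructions.csv` (vessel, AL, PGD, diameter, relaxation note),
#' `instructions.png` (the flattened graft with strut pattern, labelled
#' fenestration circles and a legend stating the conventions), a JSON
#' report, and -- when the mesh was built -- a textured OBJ of the 3D
#' design.
#'
#' @param report a valid `plan_report`.
#' @param dir output directory.
#' @return named list of artifact paths, invisibly.
#' @export
render_instructions <- function(report, dir) {
  if (!report$valid)
    stop("cannot render instructions for an invalid plan", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(csv = file.path(dir, "instructions.csv"),
                png = file.path(dir, "instructions.png"),
                json = file.path(dir, "report.json"))
  utils::write.csv(report$instructions, paths$csv, row.names = FALSE)
  gm <- report$graft_mask
  cols <- c(CA = "#D55E00", SMA = "#0072B2", RRA = "#009E73", LRA = "#CC79A7")
  grDevices::png(paths$png, width = 1000,
                 height = round(1000 * gm$pgd_extent / gm$al_extent) + 160,
                 type = "cairo")
  op <- graphics::par(mar = c(6, 4, 3, 1))
  graphics::image(x = seq(0, gm$al_extent, length.out = ncol(gm$pixels)),
                  y = seq(0, gm$pgd_extent, length.out = nrow(gm$pixels)),
                  z = t(gm$pixels)[, nrow(gm$pixels):1],
                  col = c("white", "grey40"), useRaster = TRUE,
                  xlab = "AL from datum (mm)",
                  ylab = "PGD (mm, proximal edge at top)",
                  main = sprintf("Graft modification instructions - %s",
                                 report$template_used), axes = TRUE)
  th <- seq(0, 2 * pi, length.out = 73)
  for (i in seq_len(nrow(report$instructions))) {
    v <- report$instructions$vessel[i]
    al <- report$instructions$AL_mm[i]
    pgd_plot <- gm$pgd_extent - report$instructions$PGD_mm[i]
    r <- report$instructions$diameter_mm[i] / 2
    graphics::polygon(al + r * cos(th), pgd_plot + r * sin(th),
                      border = cols[[v]] %||% "black", lwd = 3)
    lab <- if (report$instructions$relaxation_mm[i] != 0)
      sprintf("%s (relaxed %+.1f mm AL)", v,
              report$instructions$relaxation_mm[i]) else v
    graphics::text(al, pgd_plot + r + 2.5, lab, col = cols[[v]] %||% "black",
                   cex = 1.2, font = 2)
  }
  graphics::mtext(sprintf(
    "deployed D %.1f mm; AL clockwise from anterior datum viewed from proximal; circles = cautery holes",
    report$deployed_diameter[1]), side = 1, line = 4.5, cex = 0.9)
  graphics::par(op)
  grDevices::dev.off()
  write_plan_json(report, paths$json)
  if (!is.null(report$mesh)) {
    paths$obj <- file.path(dir, "graft_design.obj")
    write_textured_obj(report$mesh, report$param,
                       report$mapped$design_image, paths$obj)
  }
  invisible(paths)
}

#' Serialize a plan report to JSON
#'
#' Timings and bulky geometry are excluded, so reruns of the same inputs
#' produce byte-identical files.
#'
#' @param report a `plan_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(report, path) {
  out <- list(
    template_used = report$template_used,
    deployed_diameter_mm = as.list(report$deployed_diameter),
    valid = report$valid,
    fit = list(dAL_mm = report$fit$dAL, dPGD_mm = report$fit$dPGD,
               relaxed = report$fit$relaxed,
               per_vessel_shift_mm = report$fit$per_vessel_shift,
               overlap_pixels = report$fit$overlap_pixels),
    deviations_mm = as.list(report$deviations),
    instructions = report$instructions
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 6,
                       na = "null", pretty = TRUE)
  invisible(path)
}
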