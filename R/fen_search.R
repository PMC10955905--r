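#' @title Alignment search over the graft mask
#' @description Operations that slide the fenestration constellation over
#'   the flattened graft, enumerate strut-free alignments, pick the one
#'   minimizing the summed surface deviation, and -- when no rigid fit
#'   exists -- relax the renal fenestrations posteriorly by a bounded
#'   amount.
#' @name fen_search
NULL

# Signed AL difference wrapped to the shortest arc, in (-period/2, period/2].
wrap_al <- function(x, period) {
  w <- ((x + period / 2) %% period) - period / 2
  ifelse(w == -period / 2, period / 2, w)
}

fit_result <- function(dal_px, dpgd_px, resolution, al_period,
                       per_vessel_shift, valid, deviations, overlap_pixels,
                       relaxed = FALSE, diagnostics = list()) {
  structure(
    list(
      dAL = if (is.na(dal_px)) NA_real_ else wrap_al(dal_px * resolution, al_period),
      dPGD = if (is.na(dpgd_px)) NA_real_ else dpgd_px * resolution,
      dal_px = dal_px, dpgd_px = dpgd_px,
      per_vessel_shift = per_vessel_shift,
      valid = valid, deviations = deviations,
      overlap_pixels = overlap_pixels,
      relaxed = relaxed, diagnostics = diagnostics,
      resolution = resolution, al_period = al_period
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<fit_result> valid: dAL=%.2f mm, dPGD=%.2f mm, sum(delta)=%.2f mm%s\n",
                x$dAL, x$dPGD, sum(x$deviations),
                if (x$relaxed) " (relaxed)" else ""))
    shifted <- names(x$per_vessel_shift)[vapply(x$per_vessel_shift,
                                                function(s) any(s != 0), TRUE)]
    for (v in shifted)
      cat(sprintf("  %s relaxed by (%.2f, %.2f) mm\n", v,
                  x$per_vessel_shift[[v]][1], x$per_vessel_shift[[v]][2]))
  } else {
    cat(sprintf("<fit_result> NO VALID FIT (min residual overlap %d px)\n",
                x$overlap_pixels))
  }
  invisible(x)
}

#' Count overlapping pixels between graft struts and shifted fenestrations
#'
#' The fenestration mask is shifted by `offset = c(dAL_px, dPGD_px)` pixels;
#' the AL axis wraps modulo the graft period.  A fenestration pixel pushed
#' beyond the proximal or distal fabric edge makes the alignment invalid:
#' the count returned is then the full fenestration pixel count (sentinel
#' "complete overlap"), since a hole crossing the fabric edge would
#' compromise the seal.
#'
#' @param graft graft strut [mask2d()].
#' @param fen fenestration [mask2d()] on the same resolution and column
#'   grid.
#' @param offset integer vector `c(dAL_px, dPGD_px)`.
#' @return integer overlap count (0 iff the alignment is valid).
#' @export
count_overlap <- function(graft, fen, offset) {
  if (abs(graft$resolution - fen$resolution) > 1e-12)
    stop("graft and fenestration masks must share a resolution", call. = FALSE)
  if (ncol(graft$pixels) != ncol(fen$pixels))
    stop("graft and fenestration masks must share the AL column grid",
         call. = FALSE)
  idx <- which(fen$pixels != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  r <- idx[, 1] - 1L + as.integer(offset[2])
  if (any(r < 0L | r >= nrow(graft$pixels))) return(nrow(idx))
  cc <- (idx[, 2] - 1L + as.integer(offset[1])) %% ncol(graft$pixels)
  sum(graft$pixels[cbind(r + 1L, cc + 1L)])
}

# Cross-correlation overlap map via FFT: circular along AL, linear (zero
# padded) along PGD.  Returns the integer overlap count for every offset
# (dal in 0..N-1, dpgd in dpgd_range).
.overlap_map <- function(graft, fen) {
  G <- graft$pixels; F_ <- fen$pixels
  if (ncol(F_) != ncol(G))
    stop("masks must share the AL column grid", call. = FALSE)
  R <- nrow(G); N <- ncol(G); Rf <- nrow(F_)
  idx <- which(F_ != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("fenestration mask is empty", call. = FALSE)
  minr <- min(idx[, 1]) - 1L; maxr <- max(idx[, 1]) - 1L
  dpgd_range <- seq.int(-minr, R - 1L - maxr)
  P <- R + Rf
  Gp <- matrix(0, P, N); Gp[1:R, ] <- G
  Fp <- matrix(0, P, N); Fp[1:Rf, ] <- F_
  corr <- Re(stats::fft(stats::fft(Gp) * Conj(stats::fft(Fp)), inverse = TRUE)) /
    (P * N)
  C <- matrix(0L, length(dpgd_range), N)
  for (i in seq_along(dpgd_range)) {
    row <- (dpgd_range[i] %% P) + 1L
    C[i, ] <- as.integer(round(corr[row, ]))
  }
  list(counts = C, dpgd_range = dpgd_range, n_col = N)
}

#' Enumerate all strut-free graft alignments
#'
#' Slides the fenestration mask over the graft mask on a pixel grid
#' (periodic in AL, bounded in PGD so no fenestration crosses a fabric
#' edge) and returns every offset with zero strut overlap.  Implemented as
#' 2D cross-correlation with circular AL padding; exactly equivalent to
#' exhaustive evaluation of [count_overlap()].
#'
#' @param graft,fen graft and fenestration [mask2d()]s (same resolution).
#' @param al_step,pgd_step search increments in pixels (>= 1).
#' @return data frame with integer columns `dal_px`, `dpgd_px` of valid
#'   offsets; attributes `n_tested` and `min_overlap`.
#' @export
search_alignments <- function(graft, fen, al_step = 1, pgd_step = 1) {
  if (al_step < 1 || pgd_step < 1) stop("steps must be >= 1", call. = FALSE)
  if (abs(graft$resolution - fen$resolution) > 1e-12)
    stop("graft and fenestration masks must share a resolution", call. = FALSE)
  om <- .overlap_map(graft, fen)
  dal <- seq.int(0L, om$n_col - 1L, by = as.integer(al_step))
  keep_r <- seq.int(1L, length(om$dpgd_range), by = as.integer(pgd_step))
  sub <- om$counts[keep_r, dal + 1L, drop = FALSE]
  hit <- which(sub == 0L, arr.ind = TRUE)
  out <- data.frame(dal_px = dal[hit[, 2]],
                    dpgd_px = om$dpgd_range[keep_r][hit[, 1]])
  out <- out[order(out$dpgd_px, out$dal_px), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- length(sub)
  attr(out, "min_overlap") <- min(sub)
  out
}

#' Select the optimal alignment among valid offsets
#'
#' Minimizes the summed per-vessel deviation `delta = sqrt(dAL^2 + dPGD^2)`
#' (mm, AL taken on the shorter arc) relative to the measured vessel
#' positions.  Ties are broken deterministically: smallest `|dPGD|`, then
#' smallest `|dAL|`, then lexicographically.
#'
#' @param valid_offsets data frame from [search_alignments()]; must be
#'   non-empty.
#' @param specs list of [fenestration_spec()]s (used for vessel names).
#' @param resolution mm per pixel.
#' @param al_period graft circumference, mm.
#' @return a `fit_result`.
#' @export
select_optimal <- function(valid_offsets, specs, resolution, al_period) {
  if (!nrow(valid_offsets))
    stop("no valid offsets: relaxed search required", call. = FALSE)
  dal_mm <- wrap_al(valid_offsets$dal_px * resolution, al_period)
  dpgd_mm <- valid_offsets$dpgd_px * resolution
  dev1 <- sqrt(dal_mm^2 + dpgd_mm^2)
  total <- dev1 * length(specs)
  ord <- order(total, abs(dpgd_mm), abs(dal_mm),
               valid_offsets$dpgd_px, valid_offsets$dal_px)
  k <- ord[1]
  vn <- vapply(specs, `[[`, "", "vessel")
  deviations <- stats::setNames(rep(dev1[k], length(specs)), vn)
  shifts <- stats::setNames(rep(list(c(0, 0)), length(specs)), vn)
  fit_result(valid_offsets$dal_px[k], valid_offsets$dpgd_px[k],
             resolution, al_period, shifts, TRUE, deviations, 0L)
}

# Default posterior AL direction per vessel: toward phi = 180 deg
# (patient-posterior) from the vessel's nominal angle.
.posterior_sign <- function(spec, al_period) {
  phi <- spec$phi
  if (is.na(phi)) phi <- (spec$AL %% al_period) / al_period * 360
  if (phi < 180) +1 else -1
}

#' Search with bounded posterior relaxation of non-prioritized vessels
#'
#' First attempts the rigid search ([search_alignments()]); the rigid
#' solution is always preferred when one exists.  Otherwise each
#' non-prioritized vessel (typically the renals) may shift independently in
#' its posterior AL direction by up to `max_posterior_shift` mm
#' (pixel-quantized) while prioritized vessels stay rigid.  Among feasible
#' combinations the fit minimizing the summed deviation (relaxation shifts
#' included in each vessel's delta) is returned; if none is feasible the
#' result has `valid = FALSE` with nearest-miss diagnostics.
#'
#' @param graft graft strut [mask2d()].
#' @param specs list of [fenestration_spec()]s.
#' @param resolution mm per pixel; defaults to the graft mask's.
#' @param max_posterior_shift maximum per-vessel posterior AL shift, mm.
#' @param posterior_sign optional named vector of +1/-1 AL shift directions
#'   per vessel; defaults to "toward patient-posterior" from each vessel's
#'   nominal angle.
#' @return a `fit_result` (always; `valid` may be `FALSE`).
#' @export
relaxed_search <- function(graft, specs, resolution = graft$resolution,
                           max_posterior_shift = 3, posterior_sign = NULL) {
  vn <- vapply(specs, `[[`, "", "vessel")
  period <- graft$al_period
  pgd_extent <- graft$pgd_extent
  fen_all <- build_fenestration_mask(specs, resolution, period, pgd_extent)
  plain <- search_alignments(graft, fen_all)
  if (nrow(plain)) {
    fit <- select_optimal(plain, specs, resolution, period)
    fit$diagnostics <- list(n_tested = attr(plain, "n_tested"),
                            n_valid = nrow(plain), relaxation_used = FALSE)
    return(fit)
  }
  S <- as.integer(floor(max_posterior_shift / resolution))
  signs <- vapply(specs, .posterior_sign, 0, al_period = period)
  names(signs) <- vn
  if (!is.null(posterior_sign)) signs[names(posterior_sign)] <- posterior_sign
  n_row <- nrow(graft$pixels); n_col <- ncol(graft$pixels)
  # common offset grid: every vessel must stay within the fabric
  maps <- vector("list", length(specs))
  for (v in seq_along(specs)) {
    fm <- mask2d(.disc_mask(specs[[v]]$AL, specs[[v]]$PGD,
                            specs[[v]]$diameter / 2, n_row, n_col,
                            resolution, period),
                 resolution, al_period = period)
    maps[[v]] <- .overlap_map(graft, fm)
  }
  lo <- max(vapply(maps, function(m) min(m$dpgd_range), 0))
  hi <- min(vapply(maps, function(m) max(m$dpgd_range), 0))
  if (lo > hi) {
    return(fit_result(NA_integer_, NA_integer_, resolution, period,
                      stats::setNames(rep(list(c(0, 0)), length(specs)), vn),
                      FALSE, stats::setNames(rep(NA_real_, length(specs)), vn),
                      sum(fen_all$pixels), relaxed = TRUE,
                      diagnostics = list(reason = "no in-bounds offsets")))
  }
  dpgd <- seq.int(lo, hi)
  dal_mm_w <- wrap_al((0:(n_col - 1)) * resolution, period)
  dpgd_mm <- dpgd * resolution
  best_dev <- array(0, c(length(dpgd), n_col, length(specs)))
  best_s <- array(0L, c(length(dpgd), n_col, length(specs)))
  for (v in seq_along(specs)) {
    rows <- match(dpgd, maps[[v]]$dpgd_range)
    O <- maps[[v]]$counts[rows, , drop = FALSE]
    s_max <- if (specs[[v]]$prioritized) 0L else S
    bd <- matrix(Inf, length(dpgd), n_col)
    bs <- matrix(NA_integer_, length(dpgd), n_col)
    for (s in 0:s_max) {
      # fenestration shifted posteriorly by s px: overlap at column dal is
      # O at column dal + sign*s (mod n_col)
      cols <- ((0:(n_col - 1)) + signs[v] * s) %% n_col + 1L
      clear <- O[, cols, drop = FALSE] == 0L
      dal_tot <- wrap_al((0:(n_col - 1)) * resolution +
                           signs[v] * s * resolution, period)
      dev <- sqrt(outer(dpgd_mm^2, dal_tot^2, `+`))
      upd <- clear & (dev < bd)
      bd[upd] <- dev[upd]
      bs[upd] <- s
    }
    best_dev[, , v] <- bd
    best_s[, , v] <- bs
  }
  total <- apply(best_dev, c(1, 2), sum)
  if (!any(is.finite(total))) {
    resid <- Reduce(`+`, lapply(seq_along(specs), function(v) {
      rows <- match(dpgd, maps[[v]]$dpgd_range)
      maps[[v]]$counts[rows, , drop = FALSE]
    }))
    return(fit_result(NA_integer_, NA_integer_, resolution, period,
                      stats::setNames(rep(list(c(0, 0)), length(specs)), vn),
                      FALSE, stats::setNames(rep(NA_real_, length(specs)), vn),
                      min(resid), relaxed = TRUE,
                      diagnostics = list(reason = "struts block every offset",
                                         min_residual_overlap = min(resid))))
  }
  tot_shift <- apply(best_s, c(1, 2), function(x) sum(abs(x)))
  cand <- which(is.finite(total), arr.ind = TRUE)
  cd <- total[cand]
  ord <- order(cd, tot_shift[cand], abs(dpgd_mm[cand[, 1]]),
               abs(dal_mm_w[cand[, 2]]), dpgd[cand[, 1]], cand[, 2])
  k <- cand[ord[1], ]
  dal_px <- k[2] - 1L; dpgd_px <- dpgd[k[1]]
  shifts <- lapply(seq_along(specs), function(v)
    as.numeric(c(signs[v] * best_s[k[1], k[2], v] * resolution, 0)))
  names(shifts) <- vn
  deviations <- stats::setNames(best_dev[k[1], k[2], ], vn)
  fit_result(dal_px, dpgd_px, resolution, period, shifts, TRUE, deviations,
             0L, relaxed = any(best_s[k[1], k[2], ] > 0),
             diagnostics = list(relaxation_used = any(best_s[k[1], k[2], ] > 0)))
}

#' Find the optimal graft alignment (rigid search, then relaxation)
#'
#' Convenience wrapper: runs the rigid search and selection; when no rigid
#' fit exists, falls back to [relaxed_search()].
#'
#' @inheritParams relaxed_search
#' @return a `fit_result`.
#' @export
find_fit <- function(graft, specs, resolution = graft$resolution,
                     max_posterior_shift = 3, posterior_sign = NULL) {
  relaxed_search(graft, specs, resolution, max_posterior_shift, posterior_sign)
}
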