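# Independent brute-force oracles.  These deliberately share no code with
# the package implementation: scalar loops, direct formulas.

# scalar point-to-segment distance
.pt_seg <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx^2 + dy^2
  if (l2 < 1e-18) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- max(0, min(1, ((px - x1) * dx + (py - y1) * dy) / l2))
  sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2)
}

# zigzag apex polyline of one ring, in (theta_deg, y); up-apices proximal
oracle_ring_apices <- function(center, amplitude, n_peaks, m_lo = -2,
                               m_hi = NULL) {
  if (is.null(m_hi)) m_hi <- 2 * n_peaks + 2
  half <- 360 / n_peaks / 2
  m <- seq(m_lo, m_hi)
  list(theta = m * half,
       y = center + ifelse(m %% 2 == 0, -amplitude / 2, amplitude / 2))
}

# per-pixel nested-loop rasterization of a uniform graft's struts
oracle_strut_mask_uniform <- function(template, resolution, deployed_diameter,
                                      margin) {
  circ <- pi * deployed_diameter
  n_col <- round(circ / resolution)
  n_row <- round(template$length / resolution)
  hw <- template$strut_wire_width / 2 + margin
  out <- matrix(0L, n_row, n_col)
  for (zc in template$ring_axial_positions) {
    ap <- oracle_ring_apices(zc, template$strut_amplitude,
                             template$n_peaks_per_ring)
    ax <- ap$theta / 360 * circ; ay <- ap$y
    for (i in seq_len(n_row)) {
      y <- (i - 0.5) * resolution
      if (abs(y - zc) > template$strut_amplitude / 2 + hw + resolution) next
      for (j in seq_len(n_col)) {
        al <- (j - 0.5) * resolution
        d <- Inf
        for (k in seq_len(length(ax) - 1))
          d <- min(d, .pt_seg(al, y, ax[k], ay[k], ax[k + 1], ay[k + 1]))
        if (d <= hw) out[i, j] <- 1L
      }
    }
  }
  out
}

# per-pixel rasterization on the developed frustum (annular sector);
# zigzag legs sampled with many chords
oracle_strut_mask_tapered <- function(template, resolution, d_prox, d_dist,
                                      margin, chords = 64) {
  L <- template$length
  rp <- d_prox / 2; rd <- d_dist / 2
  slope <- (rd - rp) / L
  q <- sqrt(1 + slope^2)
  y_apex <- -rp / slope
  s_frac <- abs(slope) / q
  sector <- function(theta_rad, y) {
    ell <- abs(y - y_apex) * q
    c(ell * cos(theta_rad * s_frac), ell * sin(theta_rad * s_frac))
  }
  n_col <- round(pi * max(d_prox, d_dist) / resolution)
  n_row <- round(L / resolution)
  hw <- template$strut_wire_width / 2 + margin
  out <- matrix(0L, n_row, n_col)
  for (zc in template$ring_axial_positions) {
    ap <- oracle_ring_apices(zc, template$strut_amplitude,
                             template$n_peaks_per_ring)
    segs <- NULL
    for (k in seq_len(length(ap$theta) - 1)) {
      tt <- seq(0, 1, length.out = chords + 1)
      th <- (ap$theta[k] + tt * (ap$theta[k + 1] - ap$theta[k])) * pi / 180
      yy <- ap$y[k] + tt * (ap$y[k + 1] - ap$y[k])
      pts <- t(mapply(sector, th, yy))
      segs <- rbind(segs, cbind(pts[-nrow(pts), ], pts[-1, ]))
    }
    for (i in seq_len(n_row)) {
      y <- (i - 0.5) * resolution
      if (abs(y - zc) > template$strut_amplitude / 2 + hw + resolution) next
      r_here <- rp + slope * y
      circ_here <- 2 * pi * r_here
      for (j in seq_len(n_col)) {
        al <- (j - 0.5) * resolution
        if (al >= circ_here) next
        p <- sector(al / r_here, y)
        d <- Inf
        for (k in seq_len(nrow(segs)))
          d <- min(d, .pt_seg(p[1], p[2], segs[k, 1], segs[k, 2],
                              segs[k, 3], segs[k, 4]))
        if (d <= hw) out[i, j] <- 1L
      }
    }
  }
  out
}

# nested-loop overlap count at one offset (independent of count_overlap)
brute_overlap <- function(gpx, fpx, dal, dpgd) {
  nr <- nrow(gpx); nc <- ncol(gpx)
  total <- 0L; n_fen <- 0L
  for (i in seq_len(nrow(fpx))) for (j in seq_len(ncol(fpx))) {
    if (fpx[i, j] == 0L) next
    n_fen <- n_fen + 1L
    r <- i + dpgd
    if (r < 1 || r > nr) return(-1L)  # out of bounds sentinel
    cc <- ((j - 1 + dal) %% nc) + 1
    total <- total + gpx[r, cc]
  }
  total
}

# exhaustive valid-offset set
brute_valid_offsets <- function(graft, fen) {
  gpx <- graft$pixels; fpx <- fen$pixels
  idx <- which(fpx != 0, arr.ind = TRUE)
  lo <- -(min(idx[, 1]) - 1); hi <- nrow(gpx) - max(idx[, 1])
  out <- NULL
  for (dpgd in lo:hi) for (dal in 0:(ncol(gpx) - 1)) {
    if (brute_overlap(gpx, fpx, dal, dpgd) == 0L)
      out <- rbind(out, c(dal, dpgd))
  }
  out
}

# shortest-arc deviation by explicit minimization over wraps
brute_wrap_delta <- function(a, b, period) {
  best <- Inf
  for (k in -3:3)
    best <- min(best, sqrt((a[1] - b[1] + k * period)^2 + (a[2] - b[2])^2))
  best
}

# exhaustive relaxed search: minimal total deviation over
# (global offset) x (per-vessel posterior shift), single-pixel fenestrations
# not assumed -- uses disc pixel sets per vessel.
brute_relaxed_optimum <- function(graft, specs, resolution, max_shift,
                                  signs) {
  gpx <- graft$pixels
  nr <- nrow(gpx); nc <- ncol(gpx)
  period <- graft$al_period
  S <- floor(max_shift / resolution)
  # per-vessel pixel sets
  vess <- lapply(specs, function(sp) {
    m <- matrix(0L, nr, nc)
    r <- sp$diameter / 2
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      dal <- abs((j - 0.5) * resolution - (sp$AL %% period))
      dal <- min(dal, period - dal)
      if (dal^2 + ((i - 0.5) * resolution - sp$PGD)^2 <= r^2) m[i, j] <- 1L
    }
    m
  })
  wrap <- function(x) {
    w <- ((x + period / 2) %% period) - period / 2
    if (w == -period / 2) period / 2 else w
  }
  # the rigid-constellation solution is always preferred: only when no
  # rigid offset exists does the relaxation grid come into play
  eval_grid <- function(relax) {
    best <- Inf; feasible <- FALSE
    for (dpgd in (-nr):nr) for (dal in 0:(nc - 1)) {
      tot <- 0
      ok <- TRUE
      for (v in seq_along(specs)) {
        smax <- if (!relax || specs[[v]]$prioritized) 0 else S
        bv <- Inf
        for (s in 0:smax) {
          o <- brute_overlap(gpx, vess[[v]], dal + signs[v] * s, dpgd)
          if (o == 0L) {
            dev <- sqrt(wrap(dal * resolution + signs[v] * s * resolution)^2 +
                          (dpgd * resolution)^2)
            bv <- min(bv, dev)
          }
        }
        if (!is.finite(bv)) { ok <- FALSE; break }
        tot <- tot + bv
      }
      if (ok) { feasible <- TRUE; best <- min(best, tot) }
    }
    list(feasible = feasible, best_total = best)
  }
  rigid <- eval_grid(relax = FALSE)
  if (rigid$feasible) rigid else eval_grid(relax = TRUE)
}

# straight-line points for a trivial centerline
straight_points <- function(n = 40, length = 150) {
  cbind(0, 0, seq(0, length, length.out = n))
}

# a small straight-cylinder mesh fixture
cyl_fixture <- function(D = 30, L = 100, n_axial = 21, n_circ = 24) {
  curve <- fit_centerline_spline(straight_points(20, L + 20))
  loft_graft_mesh(curve, D, 10, L, n_axial = n_axial, n_circ = n_circ)
}

# brute-force nearest-point back-projection of a 3D point to uv space
back_project_uv <- function(mesh, param, q) {
  best_d <- Inf; best_uv <- NULL
  for (f in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[f, ], ]
    e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    w <- q - tri[1, ]
    proj <- w - sum(w * nrm) * nrm
    # barycentric of proj in (e1, e2) basis
    a11 <- sum(e1 * e1); a12 <- sum(e1 * e2); a22 <- sum(e2 * e2)
    b1 <- sum(proj * e1); b2 <- sum(proj * e2)
    det <- a11 * a22 - a12^2
    l2 <- (a22 * b1 - a12 * b2) / det
    l3 <- (a11 * b2 - a12 * b1) / det
    l1 <- 1 - l2 - l3
    lc <- pmax(c(l1, l2, l3), 0); lc <- lc / sum(lc)
    pt <- lc[1] * tri[1, ] + lc[2] * tri[2, ] + lc[3] * tri[3, ]
    d <- sqrt(sum((q - pt)^2))
    if (d < best_d) {
      best_d <- d
      uvtri <- param$uv[mesh$faces[f, ], ]
      best_uv <- lc[1] * uvtri[1, ] + lc[2] * uvtri[2, ] + lc[3] * uvtri[3, ]
    }
  }
  best_uv
}
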