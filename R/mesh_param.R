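#' Cotangent-weight discrete Laplacian of a triangle mesh
#'
#' Builds the sparse symmetric Laplacian `L = D - W`, where for each
#' interior edge `ij` the weight is `w_ij = (cot(alpha_ij) + cot(beta_ij))/2`
#' with `alpha_ij`, `beta_ij` the two angles opposite the edge (boundary
#' edges use the single available cotangent), and the diagonal is the row
#' sum of weights.  Every row therefore sums to zero and, with this sign
#' convention, `L` is positive semi-definite.  With `weights = "uniform"`
#' all edge weights are 1 (the Tutte/graph Laplacian), which ignores the 3D
#' geometry.
#'
#' @param mesh a [loft_graft_mesh()] result (or any list with `vertices`
#'   and `faces`); must be manifold (no edge with more than two incident
#'   triangles).
#' @param weights `"cotangent"` (default) or `"uniform"`.
#' @return a sparse symmetric `Matrix::dgCMatrix`.
#' @export
cotangent_laplacian <- function(mesh, weights = c("cotangent", "uniform")) {
  weights <- match.arg(weights)
  V <- mesh$vertices; F_ <- mesh$faces
  n <- nrow(V)
  ed <- rbind(F_[, c(2, 3, 1)], F_[, c(3, 1, 2)])[, 1:2, drop = FALSE]
  # rows: for corner k of each face, the opposite edge (i, j)
  ii <- c(F_[, 2], F_[, 3], F_[, 1])
  jj <- c(F_[, 3], F_[, 1], F_[, 2])
  kk <- c(F_[, 1], F_[, 2], F_[, 3])
  key <- pmin(ii, jj) * (n + 1) + pmax(ii, jj)
  mult <- table(key)
  if (any(mult > 2))
    stop("mesh is non-manifold: an edge has more than 2 incident triangles",
         call. = FALSE)
  if (weights == "cotangent") {
    a <- V[ii, ] - V[kk, ]
    b <- V[jj, ] - V[kk, ]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    area2 <- sqrt(rowSums(cr^2))
    if (any(area2 < 1e-12))
      stop("mesh contains a degenerate face", call. = FALSE)
    w_half <- rowSums(a * b) / area2 / 2          # cot(angle at k) / 2
  } else {
    # each undirected edge appears once or twice; make the summed weight 1
    w_half <- as.numeric(1 / mult[as.character(key)])
  }
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii),
                            x = c(w_half, w_half), dims = c(n, n))
  D <- Matrix::Diagonal(x = Matrix::rowSums(W))
  methods::as(D - W, "CsparseMatrix")
}

#' Harmonic embedding of the cut graft mesh onto a rectangle
#'
#' Pins the mesh boundary to a rectangle in (AL, PGD) millimetres --
#' proximal ring on the top edge, distal ring on the bottom, the two seam
#' copies on the left/right edges, each spaced proportionally to 3D chord
#' length -- and solves the Laplacian system for the interior vertices,
#' one linear solve per coordinate (Dirichlet harmonic form
#' `L_II v_I = -L_IB v_B`).  The resulting map is the discrete harmonic
#' (Pinkall-Polthier) parameterization; each interior vertex ends up at the
#' weighted average of its neighbours.
#'
#' @param mesh a [loft_graft_mesh()] result.
#' @param L optional precomputed Laplacian from [cotangent_laplacian()].
#' @param rect rectangle extents `c(al_extent, pgd_extent)` in mm; defaults
#'   to the unrolled graft (`2*pi*max(radius)` by graft length).
#' @return an object of class `parameterization`: `uv` (V x 2, mm),
#'   `rect`, `boundary` (pinned vertex indices), `flipped_faces` (indices
#'   of orientation-inverted uv triangles; empty for a valid bijection).
#' @export
embed_rectangle <- function(mesh, L = NULL, rect = NULL) {
  if (is.null(rect)) rect <- c(2 * pi * max(mesh$radius), mesh$length)
  if (is.null(L)) L <- cotangent_laplacian(mesh)
  V <- mesh$vertices
  n <- nrow(V)
  uv <- matrix(NA_real_, n, 2)
  chord_pos <- function(ids) {
    d <- c(0, cumsum(sqrt(rowSums(diff(V[ids, , drop = FALSE])^2))))
    d / d[length(d)]
  }
  # boundary identification comes from the mesh's stored index lists, so
  # the embedding is independent of vertex numbering
  top <- mesh$boundary_loops$proximal; bot <- mesh$boundary_loops$distal
  left <- mesh$seam_vertices[, "start"]; right <- mesh$seam_vertices[, "end"]
  uv[top, ] <- cbind(chord_pos(top) * rect[1], 0)
  uv[bot, ] <- cbind(chord_pos(bot) * rect[1], rect[2])
  uv[left, ] <- cbind(0, chord_pos(left) * rect[2])
  uv[right, ] <- cbind(rect[1], chord_pos(right) * rect[2])
  boundary <- sort(unique(c(top, bot, left, right)))
  interior <- setdiff(seq_len(n), boundary)
  if (length(interior)) {
    L_ii <- L[interior, interior, drop = FALSE]
    L_ib <- L[interior, boundary, drop = FALSE]
    rhs <- -L_ib %*% uv[boundary, , drop = FALSE]
    sol <- tryCatch(
      as.matrix(Matrix::solve(L_ii, rhs)),
      error = function(e) stop("singular embedding system: ",
                               conditionMessage(e), call. = FALSE))
    uv[interior, ] <- sol
  }
  area2 <- (uv[mesh$faces[, 2], 1] - uv[mesh$faces[, 1], 1]) *
           (uv[mesh$faces[, 3], 2] - uv[mesh$faces[, 1], 2]) -
           (uv[mesh$faces[, 3], 1] - uv[mesh$faces[, 1], 1]) *
           (uv[mesh$faces[, 2], 2] - uv[mesh$faces[, 1], 2])
  dominant <- sign(sum(sign(area2)))
  flipped <- which(sign(area2) != dominant | area2 == 0)
  if (length(flipped))
    warning(length(flipped), " flipped face(s) in the parameterization")
  structure(
    list(uv = uv, rect = rect, boundary = boundary,
         flipped_faces = flipped, orientation = dominant),
    class = "parameterization"
  )
}

#' @export
print.parameterization <- function(x, ...) {
  cat(sprintf("<parameterization> %d vertices onto %.1f x %.1f mm, %d flipped face(s)\n",
              nrow(x$uv), x$rect[1], x$rect[2], length(x$flipped_faces)))
  invisible(x)
}

#' Maximum interior harmonicity residual of a parameterization
#'
#' For a discrete harmonic map the Laplacian applied to the uv coordinates
#' vanishes at every interior vertex; this returns the largest absolute
#' residual, a direct check of the embedding equations.
#'
#' @param mesh,param the mesh and its [embed_rectangle()] result.
#' @param L optional precomputed Laplacian.
#' @return max abs residual (mm-weighted).
#' @export
harmonic_residual <- function(mesh, param, L = NULL) {
  if (is.null(L)) L <- cotangent_laplacian(mesh)
  interior <- setdiff(seq_len(nrow(param$uv)), param$boundary)
  if (!length(interior)) return(0)
  r <- L[interior, , drop = FALSE] %*% param$uv
  max(abs(as.matrix(r)))
}

#' Mean quasi-conformal distortion of a parameterization
#'
#' For each face, the linear map from the 3D triangle (in its own plane) to
#' its uv image has singular values `s1 >= s2`; the quasi-conformal error
#' is `s1/s2 - 1` (0 for a perfectly angle-preserving map).  Returns the
#' area-weighted mean over faces.
#'
#' @param mesh,param the mesh and its parameterization.
#' @return mean quasi-conformal error (dimensionless, >= 0).
#' @export
qc_distortion <- function(mesh, param) {
  V <- mesh$vertices; F_ <- mesh$faces; uv <- param$uv
  e1 <- V[F_[, 2], ] - V[F_[, 1], ]
  e2 <- V[F_[, 3], ] - V[F_[, 1], ]
  l1 <- sqrt(rowSums(e1^2))
  x1 <- e1 / l1
  h <- rowSums(e2 * x1)
  perp <- e2 - h * x1
  w <- sqrt(rowSums(perp^2))
  # 3D triangle in local plane coords: p1=(0,0), p2=(l1,0), p3=(h,w)
  q1 <- uv[F_[, 2], ] - uv[F_[, 1], ]
  q2 <- uv[F_[, 3], ] - uv[F_[, 1], ]
  # J solves J %*% [ (l1,0), (h,w) ] = [ q1, q2 ]
  a <- q1[, 1] / l1
  c_ <- q1[, 2] / l1
  b <- (q2[, 1] - a * h) / w
  d <- (q2[, 2] - c_ * h) / w
  # singular values of [[a,b],[c,d]]
  t1 <- a^2 + b^2 + c_^2 + d^2
  t2 <- sqrt(pmax((a^2 + b^2 - c_^2 - d^2)^2 + 4 * (a * c_ + b * d)^2, 0))
  s1 <- sqrt(pmax(t1 + t2, 0) / 2)
  s2 <- sqrt(pmax(t1 - t2, 0) / 2)
  qc <- s1 / pmax(s2, 1e-30) - 1
  area <- l1 * w / 2
  sum(qc * area) / sum(area)
}
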