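#' @section Forward model:
#' The forward solver uses linear (P1) triangular finite elements with the
#' complete electrode model: finite-width boundary electrodes with contact
#' impedance, a prescribed net current per electrode, and zero net current on
#' passive electrodes. Electrode voltages enter the linear system as extra
#' unknowns and a Lagrange multiplier grounds the system by forcing the
#' electrode voltages to sum to zero.
#' @name eitlf-forward
#' @keywords internal
NULL

# Locate the boundary edges covered by each electrode. Returns a data frame
# of edges (node a, node b, length, electrode id).
electrode_edges <- function(mesh, electrodes) {
  bn <- mesh$boundary
  nb <- length(bn)
  a <- bn
  b <- bn[c(2:nb, 1L)]
  mx <- (mesh$nodes[a, 1L] + mesh$nodes[b, 1L]) / 2
  my <- (mesh$nodes[a, 2L] + mesh$nodes[b, 2L]) / 2
  ang <- atan2(my, mx) %% (2 * pi)
  len <- sqrt((mesh$nodes[a, 1L] - mesh$nodes[b, 1L])^2 +
              (mesh$nodes[a, 2L] - mesh$nodes[b, 2L])^2)
  halfw <- (electrodes$width / 2) / electrodes$radius  # half arc angle
  elec <- rep(NA_integer_, nb)
  for (l in seq_len(electrodes$n)) {
    d <- abs((ang - electrodes$angles[l] + pi) %% (2 * pi) - pi)
    elec[d <= halfw] <- l
  }
  keep <- !is.na(elec)
  if (!all(tabulate(elec[keep], electrodes$n) > 0)) {
    abort("mesh boundary too coarse: an electrode covers no boundary edge.")
  }
  list(a = a[keep], b = b[keep], len = len[keep], elec = elec[keep])
}

# Assemble the complete-electrode-model system matrix (sparse, symmetric)
# and the unit-current right-hand sides for all adjacent pairs.
# Unknown ordering: node potentials (nn), electrode voltages (nE), ground
# Lagrange multiplier (1).
cem_system <- function(mesh, electrodes) {
  nn <- nrow(mesh$nodes)
  nE <- electrodes$n
  tri <- mesh$tri
  p <- mesh$nodes
  x1 <- p[tri[, 1L], 1L]; y1 <- p[tri[, 1L], 2L]
  x2 <- p[tri[, 2L], 1L]; y2 <- p[tri[, 2L], 2L]
  x3 <- p[tri[, 3L], 1L]; y3 <- p[tri[, 3L], 2L]
  b1 <- y2 - y3; b2 <- y3 - y1; b3 <- y1 - y2
  c1 <- x3 - x2; c2 <- x1 - x3; c3 <- x2 - x1
  A4 <- 4 * mesh$areas
  s <- mesh$sigma
  bb <- cbind(b1, b2, b3)
  cc <- cbind(c1, c2, c3)
  ii <- jj <- vv <- vector("list", 9L)
  k <- 0L
  for (i in 1:3) {
    for (j in 1:3) {
      k <- k + 1L
      ii[[k]] <- tri[, i]
      jj[[k]] <- tri[, j]
      vv[[k]] <- s * (bb[, i] * bb[, j] + cc[, i] * cc[, j]) / A4
    }
  }

  ed <- electrode_edges(mesh, electrodes)
  z <- electrodes$contact_impedance[ed$elec]
  h <- ed$len
  # node-node contact terms: (h / z) * [[1/3, 1/6], [1/6, 1/3]]
  ii <- c(ii, list(ed$a, ed$b, ed$a, ed$b))
  jj <- c(jj, list(ed$a, ed$b, ed$b, ed$a))
  vv <- c(vv, list(h / (3 * z), h / (3 * z), h / (6 * z), h / (6 * z)))
  # node-electrode coupling: -(h / (2 z)) for each edge node
  eidx <- nn + ed$elec
  ii <- c(ii, list(ed$a, eidx, ed$b, eidx))
  jj <- c(jj, list(eidx, ed$a, eidx, ed$b))
  vv <- c(vv, list(-h / (2 * z), -h / (2 * z), -h / (2 * z), -h / (2 * z)))
  # electrode-electrode diagonal: |e_l| / z_l
  ii <- c(ii, list(eidx))
  jj <- c(jj, list(eidx))
  vv <- c(vv, list(h / z))
  # grounding row/column: sum of electrode voltages = 0
  gidx <- nn + nE + 1L
  ii <- c(ii, list(nn + seq_len(nE), rep(gidx, nE)))
  jj <- c(jj, list(rep(gidx, nE), nn + seq_len(nE)))
  vv <- c(vv, list(rep(1, nE), rep(1, nE)))

  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(gidx, gidx))

  # unit-current RHS for adjacent pair d: +1 into electrode d, -1 out of d+1
  B <- matrix(0, nrow = gidx, ncol = nE)
  for (d in seq_len(nE)) {
    B[nn + d, d] <- 1
    B[nn + (d %% nE) + 1L, d] <- -1
  }
  list(A = A, B = B, nn = nn, nE = nE,
       grad_coef = list(b = bb, c = cc, A4 = A4))
}

# Solve the CEM system for all adjacent unit-current injections.
# Returns node potentials (nn x nE) and electrode voltages (nE x nE),
# both per unit current.
cem_fields <- function(mesh, electrodes) {
  sys <- cem_system(mesh, electrodes)
  X <- tryCatch(
    as.matrix(Matrix::solve(sys$A, sys$B)),
    error = function(e) {
      abort(paste0("forward solver failed (singular system): ",
                   conditionMessage(e)),
            class = "eitlf_error_solver")
    }
  )
  list(U = X[seq_len(sys$nn), , drop = FALSE],
       V = X[sys$nn + seq_len(sys$nE), , drop = FALSE],
       sys = sys)
}

#' Solve the EIT forward problem
#'
#' Computes the noise-free boundary voltage frame for a conductivity
#' distribution under the adjacent protocol, using the complete electrode
#' model (see [disk_mesh()] and [electrode_array()]).
#'
#' @param mesh An `eit_mesh` carrying the element conductivities.
#' @param electrodes An `eit_electrodes`.
#' @param protocol An [adjacent_protocol()]; its `current` scales the output.
#' @return An `eit_frame` (role "measured") of length
#'   `protocol$n_measurements`, in volts.
#' @examples
#' el <- electrode_array(16)
#' pr <- adjacent_protocol(el)
#' m <- disk_mesh(0.2, n_rings = 6, sigma = 0.2)
#' u <- solve_forward(m, el, pr)
#' @export
solve_forward <- function(mesh, electrodes, protocol) {
  stopifnot(inherits(mesh, "eit_mesh"), inherits(electrodes, "eit_electrodes"),
            inherits(protocol, "eit_protocol"))
  if (electrodes$n != protocol$n_electrodes) {
    abort("electrode array and protocol disagree on electrode count.")
  }
  f <- cem_fields(mesh, electrodes)
  V <- f$V * protocol$current
  d <- protocol$injection_of
  vals <- V[cbind(protocol$measurements[, 1L], d)] -
          V[cbind(protocol$measurements[, 2L], d)]
  new_frame(vals, protocol, role = "measured")
}

#' Element-to-pixel area-overlap weights
#'
#' Maps between the finite element mesh and the reconstruction raster. Each
#' triangle's area is distributed over the pixels it overlaps (approximated
#' by a 9-point barycentric subdivision of the triangle); weights are
#' row-normalized so each element row sums to 1. A pixel conductivity map
#' `sigma_px` induces element values `W %*% sigma_px`, and an element-wise
#' sensitivity row maps to pixels through the same weights.
#'
#' @param mesh An `eit_mesh`.
#' @param grid A [pixel_grid()].
#' @return A sparse `n_elements x grid$M` matrix with unit row sums.
#' @export
pixel_weights <- function(mesh, grid) {
  stopifnot(inherits(mesh, "eit_mesh"), inherits(grid, "pixel_grid"))
  if (abs(mesh$radius - grid$radius) > 1e-12) {
    abort("mesh and grid disagree on the domain radius.")
  }
  tri <- mesh$tri
  p <- mesh$nodes
  ne <- nrow(tri)
  # barycentric sample points: centroids of a 9-fold subdivision
  bary <- rbind(
    c(1, 1, 1) / 3,
    c(4, 1, 1) / 6, c(1, 4, 1) / 6, c(1, 1, 4) / 6,
    c(2, 3, 1) / 6, c(2, 1, 3) / 6, c(3, 2, 1) / 6,
    c(1, 2, 3) / 6, c(3, 1, 2) / 6, c(1, 3, 2) / 6
  )
  np <- nrow(bary)
  x1 <- p[tri[, 1L], 1L]; y1 <- p[tri[, 1L], 2L]
  x2 <- p[tri[, 2L], 1L]; y2 <- p[tri[, 2L], 2L]
  x3 <- p[tri[, 3L], 1L]; y3 <- p[tri[, 3L], 2L]
  h <- grid$pixel_size
  ei <- rep(seq_len(ne), times = np)
  px <- numeric(0); py <- numeric(0)
  for (q in seq_len(np)) {
    px <- c(px, bary[q, 1L] * x1 + bary[q, 2L] * x2 + bary[q, 3L] * x3)
    py <- c(py, bary[q, 1L] * y1 + bary[q, 2L] * y2 + bary[q, 3L] * y3)
  }
  col <- pmin(pmax(floor((px + grid$radius) / h) + 1L, 1L), grid$n)
  row <- pmin(pmax(floor((grid$radius - py) / h) + 1L, 1L), grid$n)
  pid <- grid$index[cbind(row, col)]
  ok <- !is.na(pid)
  W <- Matrix::sparseMatrix(i = ei[ok], j = pid[ok], x = rep(1, sum(ok)),
                            dims = c(ne, grid$M))
  rs <- Matrix::rowSums(W)
  # elements whose samples all fall on unsupported pixels: snap to the
  # nearest supported pixel centre
  bad <- which(rs == 0)
  if (length(bad)) {
    cen <- mesh$centroids[bad, , drop = FALSE]
    nearest <- vapply(seq_along(bad), function(k) {
      d2 <- (grid$centers[, 1L] - cen[k, 1L])^2 +
            (grid$centers[, 2L] - cen[k, 2L])^2
      which.min(d2)
    }, integer(1))
    W <- W + Matrix::sparseMatrix(i = bad, j = nearest, x = rep(1, length(bad)),
                                  dims = c(ne, grid$M))
    rs <- Matrix::rowSums(W)
  }
  Matrix::Diagonal(x = 1 / rs) %*% W
}

#' Sensitivity (Jacobian) matrix of the adjacent protocol
#'
#' Computes the derivative of every boundary voltage with respect to each
#' pixel conductivity at the mesh's (reference) conductivity, by the adjoint
#' method: for measurement pair m under drive d,
#' `dV/dsigma_e = -I * area_e * grad(u_m) . grad(u_d)` per element, where
#' `u_d`, `u_m` are the unit-current fields of the drive and measurement
#' pairs. Element sensitivities are aggregated to pixels with
#' [pixel_weights()].
#'
#' @param mesh An `eit_mesh` at the reference conductivity.
#' @param electrodes An `eit_electrodes`.
#' @param protocol An [adjacent_protocol()].
#' @param grid A [pixel_grid()].
#' @param weights Optional precomputed [pixel_weights()] matrix.
#' @return An `N x M` matrix of class `eit_sensitivity` (volts per S/m),
#'   with attributes `normalized = "raw"` and the grid.
#' @export
compute_sensitivity <- function(mesh, electrodes, protocol, grid,
                                weights = NULL) {
  stopifnot(inherits(grid, "pixel_grid"))
  if (electrodes$n != protocol$n_electrodes) {
    abort("electrode array and protocol disagree on electrode count.")
  }
  f <- cem_fields(mesh, electrodes)
  gc_ <- f$sys$grad_coef
  tri <- mesh$tri
  U <- f$U
  # per-element field gradients for each of the nE unit injections
  gx <- (gc_$b[, 1L] * U[tri[, 1L], ] + gc_$b[, 2L] * U[tri[, 2L], ] +
         gc_$b[, 3L] * U[tri[, 3L], ]) / (2 * mesh$areas)
  gy <- (gc_$c[, 1L] * U[tri[, 1L], ] + gc_$c[, 2L] * U[tri[, 2L], ] +
         gc_$c[, 3L] * U[tri[, 3L], ]) / (2 * mesh$areas)
  N <- protocol$n_measurements
  d <- protocol$injection_of
  m <- protocol$measurements[, 1L]
  S_elem <- matrix(0, N, nrow(tri))
  for (r in seq_len(N)) {
    S_elem[r, ] <- -protocol$current * mesh$areas *
      (gx[, d[r]] * gx[, m[r]] + gy[, d[r]] * gy[, m[r]])
  }
  W <- weights %||% pixel_weights(mesh, grid)
  if (ncol(W) != grid$M || nrow(W) != nrow(tri)) {
    abort("pixel weight matrix does not match mesh/grid dimensions.",
          class = "eitlf_error_dimension")
  }
  S <- as.matrix(S_elem %*% W)
  structure(S, normalized = "raw", grid = grid, class = "eit_sensitivity")
}

#' Column-normalize a sensitivity matrix
#'
#' Rescales each column of the sensitivity matrix so its (signed) sum equals
#' 1, the convention under which the mean of a voltage-change frame equals
#' `alpha * n / N` for a uniform change `alpha` over `n` working pixels.
#' An `"absolute"` mode normalizes by the sum of absolute values instead,
#' for scenes where mixed-sign columns are expected.
#'
#' @param S An `eit_sensitivity` or plain numeric matrix.
#' @param mode `"signed"` (default) or `"absolute"` column sums.
#' @return The normalized matrix with attribute `normalized` set to the mode;
#'   idempotent for a matrix already normalized in the same mode.
#' @export
normalize_sensitivity <- function(S, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (identical(attr(S, "normalized"), mode)) return(S)
  cs <- if (mode == "signed") colSums(S) else colSums(abs(S))
  tol <- 1e-12 * max(abs(cs))
  bad <- which(abs(cs) <= tol)
  if (length(bad)) {
    abort(sprintf("degenerate column sum(s) in sensitivity normalization at pixel(s) %s.",
                  paste(utils::head(bad, 5L), collapse = ", ")),
          class = "eitlf_error_degenerate_column")
  }
  out <- sweep(unclass(S), 2L, cs, "/")
  structure(out, normalized = mode, grid = attr(S, "grid"),
            class = "eit_sensitivity")
}

#' @export
print.eit_sensitivity <- function(x, ...) {
  cat(sprintf("<eit_sensitivity> %d x %d (%s)\n", nrow(x), ncol(x),
              attr(x, "normalized") %||% "raw"))
  invisible(x)
}
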