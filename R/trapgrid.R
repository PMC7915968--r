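#' Trap lattice fitted from three anchor traps
#'
#' The trap array is a 2-D Bravais lattice; measuring one trap center and
#' its two nearest lattice neighbors fully determines origin, both basis
#' vectors, and hence any rotation of the device in the field of view.
#' Coordinates are 0-based (row, col) pixels with pixel centers at integers.
#'
#' @param anchor1 Numeric length-2 (row, col): a reference trap center.
#' @param anchor2 Center of its nearest neighbor along the first lattice
#'   direction.
#' @param anchor3 Center of its nearest neighbor along the second lattice
#'   direction.
#' @param counts_u,counts_v Number of traps generated along each lattice
#'   direction (>= 1), starting at `anchor1`.
#' @return An object of class `trap_lattice` with `origin`, `basis_u`,
#'   `basis_v`, `counts_u`, `counts_v`.
#' @export
fit_lattice <- function(anchor1, anchor2, anchor3, counts_u, counts_v) {
  a1 <- as.numeric(anchor1); a2 <- as.numeric(anchor2); a3 <- as.numeric(anchor3)
  if (length(a1) != 2L || length(a2) != 2L || length(a3) != 2L)
    stop("anchors must be (row, col) pairs")
  counts_u <- as.integer(counts_u); counts_v <- as.integer(counts_v)
  if (counts_u < 1L || counts_v < 1L) stop("counts must be >= 1")
  u <- a2 - a1
  v <- a3 - a1
  cross <- abs(u[1] * v[2] - u[2] * v[1])
  if (cross <= 1e-6)
    stop("anchors are collinear: lattice basis is degenerate")
  structure(list(origin = a1, basis_u = u, basis_v = v,
                 counts_u = counts_u, counts_v = counts_v),
            class = "trap_lattice")
}

#' Trap centers generated by a lattice
#'
#' @param lattice A [trap_lattice].
#' @return Data frame with columns `trap_id`, `i`, `j` (lattice indices,
#'   0-based) and `row`, `col` (0-based pixel coordinates). Trap ids run
#'   over `j` (slow) and `i` (fast).
#' @export
lattice_centers <- function(lattice) {
  stopifnot(inherits(lattice, "trap_lattice"))
  ij <- expand.grid(i = 0:(lattice$counts_u - 1L),
                    j = 0:(lattice$counts_v - 1L))
  row <- lattice$origin[1] + ij$i * lattice$basis_u[1] + ij$j * lattice$basis_v[1]
  col <- lattice$origin[2] + ij$i * lattice$basis_u[2] + ij$j * lattice$basis_v[2]
  data.frame(trap_id = seq_len(nrow(ij)), i = ij$i, j = ij$j,
             row = row, col = col)
}

#' Render the periodic diamond trap mask
#'
#' Assigns each pixel to at most one trap region: pixel `p` belongs to trap
#' `k` iff `|a|/d_u + |b|/d_v <= 1`, where `(a, b)` are `p`'s coordinates
#' relative to center `k` expressed in the frame of the lattice unit vectors
#' (lengths in pixels). The tiles are rhombi ("diamonds") aligned with the
#' lattice, independent of any cell morphology. Traps whose diamond extends
#' beyond the image are excluded from the mask and reported, since partial
#' tiles would bias optical volume.
#'
#' @param lattice A [trap_lattice].
#' @param image_shape Integer length-2 `(n_rows, n_cols)`.
#' @param tile_half_diagonals Numeric length-2 `(d_u, d_v)`, the diamond
#'   half-diagonals in pixels along the two lattice directions. Each must be
#'   positive and at most half the corresponding lattice spacing, which
#'   guarantees disjoint tiles. Default `0.45 *` the spacings.
#' @return An object of class `trap_mask` with `labels` (integer matrix,
#'   0 = background), `centers` (data frame from [lattice_centers()]
#'   restricted to rendered traps), `tile` (the half-diagonals), and
#'   `excluded` (data frame of edge-excluded lattice sites).
#' @export
render_mask <- function(lattice, image_shape,
                        tile_half_diagonals = NULL) {
  stopifnot(inherits(lattice, "trap_lattice"))
  image_shape <- as.integer(image_shape)
  nr <- image_shape[1]; nc <- image_shape[2]
  lu <- sqrt(sum(lattice$basis_u^2))
  lv <- sqrt(sum(lattice$basis_v^2))
  if (is.null(tile_half_diagonals))
    tile_half_diagonals <- 0.45 * c(lu, lv)
  d <- as.numeric(tile_half_diagonals)
  du <- d[1]; dv <- d[2]
  if (du <= 0 || dv <= 0) stop("tile half-diagonals must be positive")
  if (du > lu / 2 + 1e-9 || dv > lv / 2 + 1e-9)
    stop("tile half-diagonals exceed half the lattice spacing: tiles would overlap")

  uhat <- lattice$basis_u / lu
  vhat <- lattice$basis_v / lv
  # p - center = a*uhat + b*vhat  =>  (a, b) = Minv %*% (p - center)
  M <- cbind(uhat, vhat)             # rows: (row, col) components
  Minv <- solve(M)
  # diamond extent along image axes (support of the L1 ball in the uv frame)
  ext_r <- du * abs(uhat[1]) + dv * abs(vhat[1])
  ext_c <- du * abs(uhat[2]) + dv * abs(vhat[2])

  centers <- lattice_centers(lattice)
  labels <- matrix(0L, nr, nc)
  keep <- logical(nrow(centers))
  for (k in seq_len(nrow(centers))) {
    cr <- centers$row[k]; cc <- centers$col[k]
    if (cr - ext_r < 0 || cr + ext_r > nr - 1 ||
        cc - ext_c < 0 || cc + ext_c > nc - 1) next
    keep[k] <- TRUE
    r0 <- max(0L, floor(cr - ext_r)); r1 <- min(nr - 1L, ceiling(cr + ext_r))
    c0 <- max(0L, floor(cc - ext_c)); c1 <- min(nc - 1L, ceiling(cc + ext_c))
    rows <- r0:r1; cols <- c0:c1
    dr <- rows - cr
    dc <- cols - cc
    A <- outer(Minv[1, 1] * dr, Minv[1, 2] * dc, "+")
    B <- outer(Minv[2, 1] * dr, Minv[2, 2] * dc, "+")
    inside <- (abs(A) / du + abs(B) / dv) <= 1 + 1e-12
    sub <- labels[rows + 1L, cols + 1L]
    if (any(sub[inside] != 0L))
      stop("overlapping trap tiles: reduce tile half-diagonals")
    sub[inside] <- centers$trap_id[k]
    labels[rows + 1L, cols + 1L] <- sub
  }
  structure(list(labels = labels,
                 centers = centers[keep, , drop = FALSE],
                 tile = c(d_u = du, d_v = dv),
                 excluded = centers[!keep, , drop = FALSE]),
            class = "trap_mask")
}

#' @export
print.trap_mask <- function(x, ...) {
  cat(sprintf("trap_mask: %d traps rendered (%d edge-excluded), tile d_u=%.2f d_v=%.2f px\n",
              nrow(x$centers), nrow(x$excluded), x$tile[1], x$tile[2]))
  invisible(x)
}
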