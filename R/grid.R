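#' Build a 2D cell-centered simulation grid with a heated tumor region
#'
#' The domain is the rectangle `[-x_half, x_half] x [-y_half, y_half]`
#' discretised into uniform cells; temperatures live at cell centers. The
#' tumor mask marks the cells carrying the nanoparticle source:
#' \describe{
#'   \item{`"slab"`}{all cells with `|x| <= tumor_radius`, spanning the
#'     full y extent — the needle-track injection geometry used by the
#'     default liver scenarios.}
#'   \item{`"disc"`}{cells with `x^2 + y^2 <= tumor_radius^2`.}
#'   \item{`"none"`}{no heated region (mask empty).}
#' }
#'
#' @param x_half,y_half Domain half-widths in m. Default 20 mm.
#' @param dx,dy Cell sizes in m. Default 0.5 mm.
#' @param tumor_shape `"slab"`, `"disc"` or `"none"`.
#' @param tumor_radius Half-width / radius of the heated region in m.
#' @param boundary `"robin"` (convective, default) or `"insulated"`,
#'   applied to all four outer edges.
#' @param h Robin heat-transfer coefficient in W/K/m^2.
#' @param T_ext External temperature for the Robin condition, degC.
#' @return Object of class `"simulation_grid"`: cell-center coordinate
#'   vectors `x`, `y`, sizes `nx`, `ny`, logical `tumor_mask` (nx-by-ny
#'   matrix), and the boundary description.
#' @export
#' @examples
#' g <- simulation_grid(dx = 2e-3, dy = 2e-3)
#' sum(g$tumor_mask)
simulation_grid <- function(x_half = 0.02, y_half = 0.02,
                            dx = 0.5e-3, dy = dx,
                            tumor_shape = c("slab", "disc", "none"),
                            tumor_radius = 0.01,
                            boundary = c("robin", "insulated"),
                            h = 200, T_ext = 37) {
  tumor_shape <- match.arg(tumor_shape)
  boundary <- match.arg(boundary)
  check_positive(x_half, "x_half"); check_positive(y_half, "y_half")
  check_positive(dx, "dx"); check_positive(dy, "dy")
  check_nonneg(h, "h")
  nx <- max(1L, round(2 * x_half / dx))
  ny <- max(1L, round(2 * y_half / dy))
  x <- -x_half + (seq_len(nx) - 0.5) * dx
  y <- -y_half + (seq_len(ny) - 0.5) * dy
  mask <- switch(
    tumor_shape,
    slab = matrix(abs(x) <= tumor_radius, nx, ny),
    disc = outer(x, y, function(px, py) px^2 + py^2 <= tumor_radius^2),
    none = matrix(FALSE, nx, ny)
  )
  if (tumor_shape != "none") check_positive(tumor_radius, "tumor_radius")
  structure(
    list(x = x, y = y, nx = nx, ny = ny, dx = dx, dy = dy,
         x_half = x_half, y_half = y_half,
         tumor_shape = tumor_shape, tumor_radius = tumor_radius,
         tumor_mask = mask, boundary = boundary, h = h, T_ext = T_ext),
    class = "simulation_grid"
  )
}

#' Nanoparticle source map on a grid
#'
#' @param grid A [simulation_grid()].
#' @param q_np Uniform volumetric source strength inside the tumor mask,
#'   W/m^3 (or a full nx-by-ny matrix for non-uniform sources).
#' @return nx-by-ny matrix in W/m^3, zero outside the mask for scalar
#'   `q_np`.
#' @export
source_map <- function(grid, q_np) {
  stopifnot(inherits(grid, "simulation_grid"))
  if (is.matrix(q_np)) {
    if (!all(dim(q_np) == c(grid$nx, grid$ny))) {
      stop_invalid("source matrix must be nx-by-ny")
    }
    if (any(q_np < 0)) stop_invalid("source map must be non-negative")
    return(q_np)
  }
  check_nonneg(q_np, "q_np")
  q <- matrix(0, grid$nx, grid$ny)
  q[grid$tumor_mask] <- q_np
  q
}

# Bilinear interpolation weights from cell centers for a set of probe
# points. Returns a sparse-ish list: for each point, up to 4 linear indices
# and weights. Points must lie inside the physical domain; beyond the
# outermost cell centers the interpolation clamps to the edge cell
# (constant extrapolation over the final half-cell).
probe_weights <- function(grid, points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop_invalid("probe points must be n-by-2 (x, y)")
  inside <- pts[, 1] >= -grid$x_half & pts[, 1] <= grid$x_half &
    pts[, 2] >= -grid$y_half & pts[, 2] <= grid$y_half
  if (!all(inside)) stop_invalid("probe point outside the domain")
  idx1 <- function(p, centers, d, n) {
    f <- (p - centers[1]) / d + 1
    i0 <- floor(f)
    frac <- f - i0
    if (i0 < 1) { i0 <- 1; frac <- 0 }
    if (i0 >= n) { i0 <- n - 1; frac <- 1 }
    if (n == 1) { i0 <- 1; frac <- 0 }
    list(i0 = i0, frac = frac)
  }
  lapply(seq_len(nrow(pts)), function(j) {
    ix <- idx1(pts[j, 1], grid$x, grid$dx, grid$nx)
    iy <- idx1(pts[j, 2], grid$y, grid$dy, grid$ny)
    i1 <- min(ix$i0 + 1, grid$nx)
    j1 <- min(iy$i0 + 1, grid$ny)
    cells <- c(ix$i0 + (iy$i0 - 1) * grid$nx,
               i1 + (iy$i0 - 1) * grid$nx,
               ix$i0 + (j1 - 1) * grid$nx,
               i1 + (j1 - 1) * grid$nx)
    w <- c((1 - ix$frac) * (1 - iy$frac), ix$frac * (1 - iy$frac),
           (1 - ix$frac) * iy$frac, ix$frac * iy$frac)
    list(cells = cells, weights = w)
  })
}

#' Interpolate a temperature field at probe points
#'
#' Bilinear interpolation from cell centers; exact at cell centers.
#'
#' @param grid A [simulation_grid()].
#' @param field nx-by-ny matrix of cell values (e.g. degC).
#' @param points n-by-2 matrix of (x, y) coordinates in m.
#' @return Numeric vector of interpolated values.
#' @export
probe_field <- function(grid, field, points) {
  stopifnot(inherits(grid, "simulation_grid"))
  w <- probe_weights(grid, points)
  v <- as.numeric(field)
  vapply(w, function(pw) sum(v[pw$cells] * pw$weights), numeric(1))
}
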