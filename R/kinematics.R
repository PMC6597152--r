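#' Displacement field on a pixel grid
#'
#' Container for the two in-plane displacement components produced by
#' elastic registration of a frame pair. Matrices follow the image
#' convention: x along columns, y along rows; displacements are in um.
#'
#' @param ux,uy Matrices of displacement components, um.
#' @param pixel_size Pixel spacing, um/px.
#' @param frame_j,delta Reference frame index and frame increment of the
#'   registered pair (metadata).
#' @return Object of class `displacement_field`.
#' @export
displacement_field <- function(ux, uy, pixel_size = 1, frame_j = NA_integer_,
                               delta = NA_integer_) {
  ux <- as.matrix(ux); uy <- as.matrix(uy)
  if (!identical(dim(ux), dim(uy)))
    stop("displacement_field: components must have the same shape", call. = FALSE)
  if (!all(is.finite(ux)) || !all(is.finite(uy)))
    stop("displacement_field: non-finite displacements", call. = FALSE)
  structure(list(ux = ux, uy = uy, pixel_size = pixel_size,
                 frame_j = frame_j, delta = delta),
            class = "displacement_field")
}

# d/dx along columns, d/dy along rows; central differences in the interior,
# one-sided at the borders; exact for fields linear in the coordinates.
fd_grad <- function(M, h, dim = c("x", "y")) {
  dim <- match.arg(dim)
  if (dim == "y") return(t(fd_grad(t(M), h, "x")))
  nc <- ncol(M)
  if (nc < 3L) stop("fd_grad: need at least 3 columns", call. = FALSE)
  G <- matrix(0, nrow(M), nc)
  G[, 2:(nc - 1)] <- (M[, 3:nc] - M[, 1:(nc - 2)]) / (2 * h)
  G[, 1] <- (M[, 2] - M[, 1]) / h
  G[, nc] <- (M[, nc] - M[, nc - 1]) / h
  G
}

#' Displacement gradient of a registration field
#'
#' Per-pixel gradient of the displacement vector: second-order central
#' differences at interior pixels, first-order one-sided at the borders,
#' scaled by the pixel size so the result is dimensionless.
#'
#' @param u A [displacement_field()] (grid at least 3x3).
#' @return List of matrices `dux_dx`, `dux_dy`, `duy_dx`, `duy_dy` with class
#'   `displacement_gradient`.
#' @export
displacement_gradient <- function(u) {
  if (any(dim(u$ux) < 3L))
    stop("displacement_gradient: grid must be at least 3x3", call. = FALSE)
  s <- u$pixel_size
  structure(
    list(dux_dx = fd_grad(u$ux, s, "x"), dux_dy = fd_grad(u$ux, s, "y"),
         duy_dx = fd_grad(u$uy, s, "x"), duy_dy = fd_grad(u$uy, s, "y")),
    class = "displacement_gradient"
  )
}

#' Deformation gradient and Jacobian from a displacement gradient
#'
#' Per-pixel deformation gradient `F = grad u + I` and its determinant
#' `det F`, which under local mass conservation equals the ratio of the
#' earlier to the later tissue density.
#'
#' @param grad_u A `displacement_gradient` (see [displacement_gradient()]).
#' @return List with the four components `F11`, `F12`, `F21`, `F22` and
#'   `detF`, class `deformation_field`.
#' @export
deformation_gradient <- function(grad_u) {
  F11 <- grad_u$dux_dx + 1
  F12 <- grad_u$dux_dy
  F21 <- grad_u$duy_dx
  F22 <- grad_u$duy_dy + 1
  structure(list(F11 = F11, F12 = F12, F21 = F21, F22 = F22,
                 detF = F11 * F22 - F12 * F21),
            class = "deformation_field")
}

#' Small-strain tensor fields
#'
#' Symmetrized strain `eps = (grad u + grad u^T) / 2`: the x-strain, y-strain
#' and shear strain maps of the registration output (`eps_xy = eps_yx` by
#' construction).
#'
#' @inheritParams deformation_gradient
#' @return List of matrices `eps_xx`, `eps_yy`, `eps_xy`.
#' @export
strain_tensor <- function(grad_u) {
  list(eps_xx = grad_u$dux_dx,
       eps_yy = grad_u$duy_dy,
       eps_xy = (grad_u$dux_dy + grad_u$duy_dx) / 2)
}

#' Density-ratio map container
#'
#' Per-node ratio of earlier to later density on a stated square grid. The
#' value 0 is the off-mask sentinel: off-mask nodes carry exactly 0 and the
#' mask is stored explicitly.
#'
#' @param xi Matrix of ratios (x along columns, y along rows).
#' @param mask Logical matrix, TRUE where the ratio is defined.
#' @param x0,y0 Position of node (row 1, col 1), um.
#' @param spacing Node spacing, um.
#' @param frame_j,delta Frame pair metadata.
#' @return Object of class `density_ratio_map`.
#' @export
density_ratio_map <- function(xi, mask = NULL, x0 = 0, y0 = 0, spacing = 1,
                              frame_j = NA_integer_, delta = NA_integer_) {
  xi <- as.matrix(xi)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(xi), ncol(xi))
  mask <- as.matrix(mask)
  if (!identical(dim(xi), dim(mask)))
    stop("density_ratio_map: xi and mask shapes differ", call. = FALSE)
  xi[!mask] <- 0
  if (any(xi[mask] <= 0))
    stop("density_ratio_map: on-mask ratios must be positive", call. = FALSE)
  structure(list(xi = xi, mask = mask, x0 = x0, y0 = y0, spacing = spacing,
                 frame_j = frame_j, delta = delta),
            class = "density_ratio_map")
}

#' Experimental density ratio from a displacement field
#'
#' `det F` of the registered pair at every pixel: the earlier/later density
#' ratio implied by local mass conservation (> 1 where tissue locally
#' spreads and thins).
#'
#' @param u A [displacement_field()].
#' @param mask Optional logical matrix restricting the map to pixels inside
#'   the tissue in both frames; default all pixels.
#' @param x0,y0 Position of pixel (1, 1), um.
#' @return A [density_ratio_map()] on the pixel grid.
#' @export
density_ratio_from_displacement <- function(u, mask = NULL, x0 = 0, y0 = 0) {
  dg <- deformation_gradient(displacement_gradient(u))
  density_ratio_map(dg$detF, mask, x0 = x0, y0 = y0, spacing = u$pixel_size,
                    frame_j = u$frame_j, delta = u$delta)
}

#' Computational density ratio between two frames of a simulation
#'
#' Node-wise ratio of the frame-`j` density to the frame-`j+delta` density
#' on the computational grid. A node is on-mask only if it lies inside the
#' tissue at both frames; off-mask nodes carry the 0 sentinel.
#'
#' @param series A `frame_series`.
#' @param j Earlier frame index (1-based; frame 1 is t = 0).
#' @param delta Frame increment (default 5, i.e. 25 min at 5-min frames).
#' @return A [density_ratio_map()] on the computational grid.
#' @export
computational_density_ratio <- function(series, j, delta = 5) {
  n <- length(series$times)
  if (j < 1L || j + delta > n)
    stop("computational_density_ratio: frame pair out of range", call. = FALSE)
  mask <- series$inside[[j]] & series$inside[[j + delta]]
  xi <- matrix(0, nrow(mask), ncol(mask))
  xi[mask] <- series$rho[[j]][mask] / series$rho[[j + delta]][mask]
  g <- series$grid
  density_ratio_map(xi, mask, x0 = g$x0, y0 = g$y0, spacing = g$h,
                    frame_j = j, delta = delta)
}

#' Interpolate a pixel-grid ratio map onto the computational grid
#'
#' Bilinear interpolation of the ratio values at the computational grid
#' nodes. A node is on-mask only when all four surrounding pixels are
#' on-mask; interpolated values at masked nodes are set to the 0 sentinel.
#'
#' @param map A [density_ratio_map()] on a pixel grid that covers the
#'   computational grid extent.
#' @param grid A [sim_grid()].
#' @return A [density_ratio_map()] on `grid`.
#' @export
interpolate_ratio_to_grid <- function(map, grid) {
  px <- map$x0 + (seq_len(ncol(map$xi)) - 1) * map$spacing
  py <- map$y0 + (seq_len(nrow(map$xi)) - 1) * map$spacing
  if (grid$xs[1] < px[1] - 1e-9 || grid$xs[grid$nx] > px[length(px)] + 1e-9 ||
      grid$ys[1] < py[1] - 1e-9 || grid$ys[grid$ny] > py[length(py)] + 1e-9)
    stop("interpolate_ratio_to_grid: pixel grid does not cover the computational grid",
         call. = FALSE)
  qx <- rep(grid$xs, each = grid$ny)
  qy <- rep(grid$ys, times = grid$nx)
  vals <- pracma::interp2(px, py, map$xi, qx, qy, method = "linear")
  # surrounding-pixel indices for the mask rule
  fx <- pmin(pmax(floor((qx - map$x0) / map$spacing) + 1L, 1L), length(px) - 1L)
  fy <- pmin(pmax(floor((qy - map$y0) / map$spacing) + 1L, 1L), length(py) - 1L)
  nr <- nrow(map$mask)
  m00 <- map$mask[cbind(fy, fx)]
  m01 <- map$mask[cbind(fy, fx + 1L)]
  m10 <- map$mask[cbind(fy + 1L, fx)]
  m11 <- map$mask[cbind(fy + 1L, fx + 1L)]
  ok <- m00 & m01 & m10 & m11 & is.finite(vals) & vals > 0
  xi <- matrix(ifelse(ok, vals, 0), grid$ny, grid$nx)
  density_ratio_map(xi, matrix(ok, grid$ny, grid$nx),
                    x0 = grid$x0, y0 = grid$y0, spacing = grid$h,
                    frame_j = map$frame_j, delta = map$delta)
}
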