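#' Fixed Cartesian simulation grid
#'
#' Square-cell Eulerian grid on which the level set and density fields live.
#' Node (row `j`, column `i`) sits at `(x0 + (i-1)*h, y0 + (j-1)*h)`: x runs
#' along columns, y along rows, matching the image convention used for
#' pixel-grid maps.
#'
#' @param x0,y0 Coordinates of the first node, um.
#' @param h Node spacing, um (square cells).
#' @param nx,ny Number of nodes along x (columns) and y (rows); at least 16.
#' @return An object of class `sim_grid`.
#' @examples
#' g <- sim_grid(-1500, -1500, h = 20, nx = 151, ny = 151)
#' @export
sim_grid <- function(x0, y0, h, nx, ny) {
  if (!is.finite(h) || h <= 0) stop("sim_grid: h must be > 0", call. = FALSE)
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 16L || ny < 16L) stop("sim_grid: need at least 16x16 nodes", call. = FALSE)
  structure(
    list(x0 = x0, y0 = y0, h = h, nx = nx, ny = ny,
         xs = x0 + (seq_len(nx) - 1) * h,
         ys = y0 + (seq_len(ny) - 1) * h),
    class = "sim_grid"
  )
}

#' Square grid centred on a point
#'
#' Convenience constructor: a square domain of side `extent` um centred on
#' `(cx, cy)` with spacing `h`.
#'
#' @param extent Side length of the domain, um.
#' @param h Node spacing, um.
#' @param cx,cy Domain centre, um.
#' @return A [sim_grid()].
#' @export
sim_grid_centered <- function(extent, h, cx = 0, cy = 0) {
  n <- floor(extent / h) + 1L
  sim_grid(cx - (n - 1) * h / 2, cy - (n - 1) * h / 2, h, n, n)
}

# Shift a matrix by (dj, di) rows/cols; vacated entries take `fill`.
# mshift(M, 0, 1) puts at [j, i] the value formerly at [j, i+1] (east neighbour).
mshift <- function(M, dj, di, fill = NA_real_) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(fill, nr, nc)
  js <- seq_len(nr); is <- seq_len(nc)
  jsrc <- js + dj; isrc <- is + di
  jok <- jsrc >= 1L & jsrc <= nr
  iok <- isrc >= 1L & isrc <= nc
  out[js[jok], is[iok]] <- M[jsrc[jok], isrc[iok]]
  out
}

#' Signed area and orientation of a closed polygon
#'
#' Shoelace formula. `polygon_area` returns the absolute enclosed area;
#' `ensure_ccw` reorders the vertices counter-clockwise if needed.
#'
#' @param xy Two-column matrix of vertices (x, y), um, not repeating the
#'   first vertex at the end.
#' @return `polygon_area`: area in um^2. `ensure_ccw`: the vertex matrix.
#' @export
polygon_area <- function(xy) {
  abs(polygon_area_signed(xy))
}

polygon_area_signed <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' @rdname polygon_area
#' @export
ensure_ccw <- function(xy) {
  if (polygon_area_signed(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

# Even-odd point-in-polygon test, vectorised over query points.
point_in_polygon <- function(px, py, xy) {
  xp <- xy[, 1]; yp <- xy[, 2]
  n <- length(xp)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((yp[i] > py) != (yp[j] > py))
    if (any(crosses)) {
      xin <- (xp[j] - xp[i]) * (py[crosses] - yp[i]) / (yp[j] - yp[i]) + xp[i]
      inside[crosses] <- xor(inside[crosses], px[crosses] < xin)
    }
    j <- i
  }
  inside
}

# Minimum distance from each query point to a closed polyline. Fully
# vectorised (outer point-by-segment matrices) when the product is small;
# otherwise chunked over segments.
dist_to_contour <- function(px, py, xy) {
  x1 <- xy[, 1]; y1 <- xy[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  np <- length(px); ns <- length(x1)
  if (as.double(np) * ns <= 5e5) {
    # flat ns*np layout: segment quantities recycle along the fast dimension
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- pmax(dx * dx + dy * dy, .Machine$double.eps)
    wx <- rep(px, each = ns) - x1
    wy <- rep(py, each = ns) - y1
    t <- (wx * dx + wy * dy) / L2
    t[t < 0] <- 0; t[t > 1] <- 1
    ex <- wx - t * dx
    ey <- wy - t * dy
    d2 <- matrix(ex * ex + ey * ey, ns, np)
    tp <- t(d2)
    return(sqrt(tp[cbind(seq_len(np), max.col(-tp, ties.method = "first"))]))
  }
  best <- rep(Inf, np)
  for (s in seq_len(ns)) {
    dx <- x2[s] - x1[s]; dy <- y2[s] - y1[s]
    L2 <- dx * dx + dy * dy
    if (L2 == 0) {
      d2 <- (px - x1[s])^2 + (py - y1[s])^2
    } else {
      t <- ((px - x1[s]) * dx + (py - y1[s]) * dy) / L2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (px - x1[s] - t * dx)^2 + (py - y1[s] - t * dy)^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Signed distance field to a closed contour
#'
#' Exact point-to-polyline distance at every grid node, negative inside the
#' contour (even-odd rule).
#'
#' @param contour Two-column (x, y) vertex matrix, um.
#' @param grid A [sim_grid()].
#' @return Matrix (`ny` x `nx`) of signed distances, um.
#' @export
signed_distance <- function(contour, grid) {
  px <- rep(grid$xs, each = grid$ny)
  py <- rep(grid$ys, times = grid$nx)
  d <- dist_to_contour(px, py, contour)
  inside <- point_in_polygon(px, py, contour)
  matrix(ifelse(inside, -d, d), grid$ny, grid$nx)
}

#' Resample a closed contour by arc length
#'
#' Returns `n` points equally spaced along the closed polyline, starting at
#' the first input vertex.
#'
#' @param xy Two-column vertex matrix.
#' @param n Number of output points.
#' @return Two-column matrix with `n` rows.
#' @export
resample_contour <- function(xy, n) {
  closed <- rbind(xy, xy[1, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  s <- seq(0, L, length.out = n + 1L)[-(n + 1L)]
  ix <- findInterval(s, cum, rightmost.closed = TRUE)
  t <- (s - cum[ix]) / pmax(seg[ix], .Machine$double.eps)
  cbind(
    closed[ix, 1] + t * (closed[ix + 1, 1] - closed[ix, 1]),
    closed[ix, 2] + t * (closed[ix + 1, 2] - closed[ix, 2])
  )
}

# Does any segment pair of the closed polyline properly intersect?
# O(n^2); used only when validating external input.
contour_self_intersects <- function(xy) {
  n <- nrow(xy)
  x1 <- xy[, 1]; y1 <- xy[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    # skip the closing segment's adjacency with segment 1
    if (i == 1L) js <- js[js != n]
    if (!length(js)) next
    o1 <- orient(x1[i], y1[i], x2[i], y2[i], x1[js], y1[js])
    o2 <- orient(x1[i], y1[i], x2[i], y2[i], x2[js], y2[js])
    o3 <- orient(x1[js], y1[js], x2[js], y2[js], x1[i], y1[i])
    o4 <- orient(x1[js], y1[js], x2[js], y2[js], x2[i], y2[i])
    if (any(o1 != o2 & o3 != o4 & o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0))
      return(TRUE)
  }
  FALSE
}

# Validate a boundary contour: >= 8 points, closed handled implicitly,
# optionally simple.
as_contour <- function(xy, check_simple = FALSE) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("contour must be a two-column (x, y) matrix", call. = FALSE)
  if (nrow(xy) >= 2L && all(xy[1, ] == xy[nrow(xy), ]))
    xy <- xy[-nrow(xy), , drop = FALSE]
  if (nrow(xy) < 8L) stop("contour must have at least 8 points", call. = FALSE)
  if (!all(is.finite(xy))) stop("contour has non-finite coordinates", call. = FALSE)
  if (check_simple && contour_self_intersects(xy))
    stop("contour is self-intersecting", call. = FALSE)
  ensure_ccw(unname(xy))
}
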