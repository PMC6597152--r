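#' Protocol for generating a synthetic experiment dataset
#'
#' Defines the ground-truth parameters and the noise model of a
#' pseudo-experimental dataset emulating segmented time-lapse data: a
#' simulated spreading explant whose per-frame contours are resampled more
#' densely than the computational edge and jittered (edge-segmentation
#' error), and whose density-ratio maps are resampled to a pixel grid and
#' perturbed by multiplicative log-normal noise.
#'
#' The default edge jitter (sd 13 um, about 5 px at 2.6 um/px) sits at the
#' stated upper bound for boundary-segmentation error of about 2 cell
#' widths; the ratio-noise magnitude (sdlog 0.02) and the pixel spacing of
#' the ratio maps are stated modelling choices.
#'
#' @param theta_star Ground-truth [parameter_set()].
#' @param shape Initial shape: `"circle"`, `"ellipse"` or `"blob"`.
#' @param area_mm2 Initial explant area, mm^2 (observed explants span about
#'   0.14-2.23 mm^2). Default 0.28 (a 300-um-radius disk).
#' @param frame_interval Frame interval, h. Default 5 minutes.
#' @param t_end Duration, h. Default 10.
#' @param delta Frame increment for ratio-map pairs. Default 5.
#' @param edge_jitter_um Gaussian jitter sd per contour coordinate, um.
#' @param ratio_noise_sdlog sdlog of the multiplicative log-normal noise on
#'   on-mask ratio values.
#' @param point_multiplier Experimental contours carry this many times the
#'   computational edge's point count (> 1).
#' @param pixel_size Pixel size of the emulated images, um/px.
#' @param ratio_map_spacing Node spacing of the emulated ratio-map pixel
#'   grid, um, or `NULL` (the default) to emit the maps directly on the
#'   computational grid, as a preprocessing pipeline that resamples
#'   registration output onto the analysis grid would.
#' @param seed Integer seed for the dataset's randomness.
#' @return Object of class `synthetic_protocol`.
#' @export
synthetic_protocol <- function(theta_star,
                               shape = c("circle", "ellipse", "blob"),
                               area_mm2 = 0.28,
                               frame_interval = 5 / 60, t_end = 10,
                               delta = 5, edge_jitter_um = 13,
                               ratio_noise_sdlog = 0.02,
                               point_multiplier = 3, pixel_size = 2.6,
                               ratio_map_spacing = NULL, seed = 1L) {
  shape <- match.arg(shape)
  if (edge_jitter_um < 0 || ratio_noise_sdlog < 0)
    stop("synthetic_protocol: noise magnitudes must be >= 0", call. = FALSE)
  if (point_multiplier <= 1)
    stop("synthetic_protocol: point_multiplier must be > 1", call. = FALSE)
  validate_parameter_set(theta_star)
  structure(
    list(theta_star = theta_star, shape = shape, area_mm2 = area_mm2,
         frame_interval = frame_interval, t_end = t_end, delta = delta,
         edge_jitter_um = edge_jitter_um,
         ratio_noise_sdlog = ratio_noise_sdlog,
         point_multiplier = point_multiplier, pixel_size = pixel_size,
         ratio_map_spacing = ratio_map_spacing, seed = as.integer(seed)),
    class = "synthetic_protocol"
  )
}

#' Construct an initial explant contour
#'
#' Closed simple contour of a requested area: a circle, a 2:1 ellipse, or a
#' smoothed random blob (circle with a low-order Fourier perturbation of the
#' radius). The polygon is rescaled so its shoelace area matches the request
#' to well within 0.5%.
#'
#' @param shape `"circle"`, `"ellipse"` or `"blob"`.
#' @param area_mm2 Enclosed area, mm^2.
#' @param n_points Number of polygon vertices. Default 96.
#' @param axis_ratio Major/minor axis ratio for the ellipse. Default 2.
#' @param blob_amplitude Relative radius perturbation of the blob (0 gives a
#'   circle). Default 0.15. Modes 2-4 with random phases are used; seed the
#'   RNG for reproducibility.
#' @param cx,cy Centre, um.
#' @return Two-column (x, y) vertex matrix, um, counter-clockwise.
#' @export
make_initial_contour <- function(shape = c("circle", "ellipse", "blob"),
                                 area_mm2, n_points = 96, axis_ratio = 2,
                                 blob_amplitude = 0.15, cx = 0, cy = 0) {
  shape <- match.arg(shape)
  if (area_mm2 <= 0) stop("make_initial_contour: area must be > 0", call. = FALSE)
  area_um2 <- area_mm2 * 1e6
  R <- sqrt(area_um2 / pi)
  ang <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  r <- switch(shape,
    circle = rep(R, n_points),
    ellipse = {
      a <- R * sqrt(axis_ratio); b <- R / sqrt(axis_ratio)
      a * b / sqrt((b * cos(ang))^2 + (a * sin(ang))^2)
    },
    blob = {
      pert <- rep(0, n_points)
      for (k in 2:4) {
        amp <- blob_amplitude * stats::runif(1, 0.3, 1) / (k - 1)
        pert <- pert + amp * cos(k * ang + stats::runif(1, 0, 2 * pi))
      }
      R * (1 + pert)
    })
  xy <- cbind(cx + r * cos(ang), cy + r * sin(ang))
  # rescale about the centre so the polygon area is exact
  sc <- sqrt(area_um2 / polygon_area(xy))
  xy[, 1] <- cx + (xy[, 1] - cx) * sc
  xy[, 2] <- cy + (xy[, 2] - cy) * sc
  ensure_ccw(xy)
}

#' Generate a synthetic experiment dataset with known ground truth
#'
#' Simulates the model at the protocol's ground-truth parameters, then
#' derives the pseudo-experimental data products: per-frame contours
#' resampled at `point_multiplier` times the computational edge density with
#' i.i.d. Gaussian coordinate jitter, and per-pair density-ratio maps
#' bilinearly resampled onto a pixel grid with multiplicative log-normal
#' noise on the tissue mask. The returned truth record carries the
#' parameters, the seed and the noiseless frame series.
#'
#' @param protocol A [synthetic_protocol()].
#' @param grid A [sim_grid()] for the underlying simulation.
#' @param config A [model_config()].
#' @return List with `data` (an [experiment_dataset()]) and `truth`
#'   (list: `theta_star`, `seed`, `series`).
#' @export
generate_dataset <- function(protocol, grid, config = model_config()) {
  set.seed(protocol$seed)
  contour0 <- make_initial_contour(protocol$shape, protocol$area_mm2)
  schedule <- sim_schedule(protocol$frame_interval, protocol$t_end)
  series <- simulate(contour0, protocol$theta_star, grid, schedule, config)
  if (series$escaped)
    stop("generate_dataset: ground-truth simulation escaped the domain; ",
         "enlarge the grid", call. = FALSE)
  n <- length(series$times)

  exp_contours <- lapply(series$contours, function(ct) {
    m <- ceiling(protocol$point_multiplier * nrow(ct))
    pts <- resample_contour(ct, m)
    pts + matrix(stats::rnorm(2 * m, sd = protocol$edge_jitter_um), m, 2)
  })

  apply_noise <- function(map) {
    if (protocol$ratio_noise_sdlog > 0) {
      on <- map$mask
      map$xi[on] <- map$xi[on] *
        exp(stats::rnorm(sum(on), 0, protocol$ratio_noise_sdlog))
    }
    map
  }

  if (is.null(protocol$ratio_map_spacing)) {
    # maps on the computational grid (registration output already resampled
    # onto the analysis grid)
    ratio_maps <- lapply(seq_len(n - protocol$delta), function(j) {
      apply_noise(computational_density_ratio(series, j, protocol$delta))
    })
  } else {
    # maps on an offset pixel grid covering the computational grid
    s <- protocol$ratio_map_spacing
    x0 <- grid$xs[1] - s; y0 <- grid$ys[1] - s
    npx <- ceiling((grid$xs[grid$nx] - x0) / s) + 2L
    npy <- ceiling((grid$ys[grid$ny] - y0) / s) + 2L
    pxs <- x0 + (seq_len(npx) - 1) * s
    pys <- y0 + (seq_len(npy) - 1) * s
    qx <- pmin(pmax(rep(pxs, each = npy), grid$xs[1]), grid$xs[grid$nx])
    qy <- pmin(pmax(rep(pys, times = npx), grid$ys[1]), grid$ys[grid$ny])
    ratio_maps <- lapply(seq_len(n - protocol$delta), function(j) {
      xi_c <- computational_density_ratio(series, j, protocol$delta)
      vals <- pracma::interp2(grid$xs, grid$ys, xi_c$xi, qx, qy,
                              method = "linear")
      mvals <- pracma::interp2(grid$xs, grid$ys, xi_c$mask * 1, qx, qy,
                               method = "linear")
      on <- is.finite(mvals) & mvals >= 1 - 1e-9 & is.finite(vals) & vals > 0
      xi <- numeric(length(vals))
      xi[on] <- vals[on]
      apply_noise(density_ratio_map(matrix(xi, npy, npx), matrix(on, npy, npx),
                                    x0 = x0, y0 = y0, spacing = s,
                                    frame_j = j, delta = protocol$delta))
    })
  }

  data <- experiment_dataset(
    times = series$times, contours = exp_contours, ratio_maps = ratio_maps,
    delta = protocol$delta, initial_contour = contour0,
    pixel_size = protocol$pixel_size
  )
  list(data = data,
       truth = list(theta_star = protocol$theta_star, seed = protocol$seed,
                    series = series))
}

#' Analytic displacement fields for kinematics tests
#'
#' Closed-form displacement fields on a pixel grid, with the analytic
#' Jacobian `det F` attached as attribute `"detF"` for oracle use:
#' `zero` (det 1), `translation` (det 1), `dilation` with scale `s`
#' (det `(1+s)^2`), `shear` with shear `gamma` (det 1), and `radial` with
#' coefficient `a` (u = a*r*(x, y); det `(1+a*r)*(1+2*a*r)`).
#'
#' @param kind One of `"zero"`, `"translation"`, `"dilation"`, `"shear"`,
#'   `"radial"`.
#' @param nx,ny Pixels along x and y.
#' @param pixel_size Pixel size, um/px.
#' @param s,gamma,a,tx,ty Field parameters.
#' @return A [displacement_field()]; attribute `"detF"` is the matrix of
#'   analytic Jacobians.
#' @export
make_displacement_field <- function(kind = c("zero", "translation",
                                             "dilation", "shear", "radial"),
                                    nx = 32, ny = 32, pixel_size = 2.6,
                                    s = 0.1, gamma = 0.3, a = 1e-4,
                                    tx = 5, ty = -3) {
  kind <- match.arg(kind)
  X <- matrix(rep((seq_len(nx) - 1) * pixel_size, each = ny), ny, nx)
  Y <- matrix(rep((seq_len(ny) - 1) * pixel_size, times = nx), ny, nx)
  zero <- matrix(0, ny, nx)
  one <- matrix(1, ny, nx)
  f <- switch(kind,
    zero = list(ux = zero, uy = zero, det = one),
    translation = list(ux = zero + tx, uy = zero + ty, det = one),
    dilation = list(ux = s * X, uy = s * Y, det = one * (1 + s)^2),
    shear = list(ux = gamma * Y, uy = zero, det = one),
    radial = {
      r <- sqrt(X^2 + Y^2)
      list(ux = a * r * X, uy = a * r * Y, det = (1 + a * r) * (1 + 2 * a * r))
    })
  u <- displacement_field(f$ux, f$uy, pixel_size = pixel_size)
  attr(u, "detF") <- f$det
  u
}
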