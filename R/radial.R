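#' One-dimensional radial reference solution for a circular explant
#'
#' Independent finite-volume solver for the radially symmetric case of the
#' spreading model: density rho(r, t) on a fixed 1D grid of cell centres with
#' explicit front tracking of the tissue radius R(t). The density obeys the
#' radial diffusion equation with the mass-limited logistic growth term; the
#' edge density is pinned at `rho_unstressed * exp(-F/k)` at the tracked
#' front, and the front moves at the model's edge speed evaluated from the
#' subcell density gradient at the interface. Used as a cross-check for the
#' 2D level-set solver on circular initial conditions; its discretization
#' (cell-centred finite volumes, continuously tracked front) is deliberately
#' different from the 2D scheme.
#'
#' @param params A [parameter_set()].
#' @param R0 Initial radius, um.
#' @param t_end End time, h.
#' @param frame_interval Output sampling interval, h.
#' @param config A [model_config()].
#' @param dr Radial cell size, um.
#' @param r_max Outer extent of the 1D grid, um.
#' @return List with `times` (h), `radius` (um, per frame), `rho` (matrix of
#'   radial profiles, cells x frames), `r` (cell-centre radii).
#' @export
radial_reference <- function(params, R0, t_end = 10, frame_interval = 5 / 60,
                             config = model_config(), dr = 2,
                             r_max = 4 * R0) {
  D <- params$k_over_b
  rho_b <- boundary_density(params, config)
  rho_lim <- limiting_density(params, config)
  coef <- -D * exp(params$F_over_k) / rho_u_sim(params, config)
  alpha <- params$alpha
  cap <- config$mass_cap_fraction

  r <- (seq_len(ceiling(r_max / dr)) - 0.5) * dr
  n <- length(r)
  r_edge <- seq_len(n) * dr          # outer face radius of each cell
  rho <- ifelse(r < R0, config$rho_init, rho_b)
  R <- R0
  m0 <- config$rho_init * pi * R0^2 * 1e-6
  m <- 0

  frame_times <- seq(0, t_end, by = frame_interval)
  out_R <- numeric(length(frame_times)); out_R[1] <- R
  out_rho <- matrix(NA_real_, n, length(frame_times)); out_rho[, 1] <- rho
  t <- 0
  dt_base <- 0.4 * dr^2 / (2 * D)
  if (alpha > 0) dt_base <- min(dt_base, 0.2 / alpha)

  for (fi in seq.int(2L, length(frame_times))) {
    t_target <- frame_times[fi]
    while (t < t_target - 1e-12) {
      i_f <- max(which(r < R))       # front cell (contains or abuts R)
      if (i_f >= n - 1L) stop("radial_reference: front reached grid edge")
      # slave the front cell to the interface: linear interpolation between
      # the last interior cell and the Dirichlet value at R, so all finite
      # differences span at least dr (unconditionally regular stencil)
      d1 <- R - r[i_f - 1L]          # >= dr by construction
      rho[i_f] <- rho_b + (rho[i_f - 1L] - rho_b) * (R - r[i_f]) / d1
      if (i_f + 1L <= n) rho[(i_f + 1L):n] <- rho_b
      grad_f <- (rho_b - rho[i_f - 1L]) / d1
      vel <- coef * grad_f
      dt <- min(dt_base, t_target - t,
                if (abs(vel) > 0) 0.4 * dr / abs(vel) else Inf)

      act <- seq_len(i_f - 1L)       # PDE cells; front cell is slaved
      flux <- r_edge[act] * (rho[act + 1L] - rho[act]) / dr
      inner <- c(0, flux[-length(flux)])   # inner-face flux (0 at r = 0)
      lap <- (flux - inner) / (r[act] * dr)
      q <- if (alpha > 0 && m < cap * m0)
        alpha * rho[act] * (1 - rho[act] / rho_lim) else numeric(length(act))
      rho[act] <- rho[act] + dt * (D * lap + q)

      if (length(q) && any(q != 0)) {
        m <- m + dt * sum(q * 2 * pi * r[act] * dr) * 1e-6
      }

      R <- R + dt * vel
      t <- t + dt
    }
    out_R[fi] <- R
    out_rho[, fi] <- rho
  }
  list(times = frame_times, radius = out_R, rho = out_rho, r = r)
}

#' Effective radius of each frame of a simulation
#'
#' Radius of the circle with the same enclosed area as each frame's boundary
#' contour: `sqrt(A/pi)`.
#'
#' @param series A `frame_series`.
#' @return Numeric vector of radii, um.
#' @export
effective_radius <- function(series) {
  sqrt(vapply(series$contours, polygon_area, numeric(1)) / pi)
}
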