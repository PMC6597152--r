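# Shared fixtures: everything is generated in code, sized for speed.

quick_theta <- function() parameter_set(0.8, 1000, 0.5, 1500)

# Small domain + short run for tests that need a full simulation.
quick_grid <- function(h = 20) sim_grid_centered(1200, h)

quick_schedule <- function(t_end = 2) sim_schedule(t_end = t_end)

quick_circle <- function(R = 250) make_initial_contour("circle", pi * (R / 1000)^2)

# A short synthetic dataset (2 h, 25 frames) on the quick grid.
quick_dataset <- function(theta = quick_theta(), seed = 11, jitter = 13,
                          noise = 0.02, t_end = 2) {
  proto <- synthetic_protocol(theta, area_mm2 = pi * 0.25^2, t_end = t_end,
                              edge_jitter_um = jitter,
                              ratio_noise_sdlog = noise, seed = seed)
  generate_dataset(proto, quick_grid())
}

# Hand-built frame_series with analytic density fields, for kinematics tests
# that need full control over rho and the masks.
fake_series <- function(grid, times, rho_fun, inside_fun) {
  n <- length(times)
  rho <- lapply(seq_len(n), function(j) {
    outer(grid$ys, grid$xs,
          function(y, x) rep_len(rho_fun(x, y, j), length(x)))
  })
  inside <- lapply(seq_len(n), function(j) {
    outer(grid$ys, grid$xs,
          function(y, x) rep_len(inside_fun(x, y, j), length(x)))
  })
  structure(list(times = times, rho = rho, inside = inside, grid = grid,
                 contours = NULL, center_rho = NA, escaped = FALSE),
            class = "frame_series")
}

# Construct an abc_posterior directly from a sample table (no simulations).
fake_posterior <- function(samples) {
  structure(list(samples = samples, n_attempted = nrow(samples),
                 threshold = Inf, priors = prior_spec(), seed = NULL),
            class = "abc_posterior")
}
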