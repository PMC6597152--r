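#' Experiment dataset: contours and density-ratio maps
#'
#' The kinematic data the model is fitted to: per-frame boundary contours
#' (the "experimental edge") and per-pair density-ratio maps on a pixel
#' grid, at a fixed frame interval. Frame 1 is the initial frame (t = 0);
#' `ratio_maps[[j]]` pairs frame `j` with frame `j + delta`.
#'
#' @param times Frame times, h (uniform spacing).
#' @param contours List of two-column (x, y) contour matrices, one per frame.
#' @param ratio_maps List of [density_ratio_map()]s for pairs
#'   `(j, j + delta)`, `j = 1 .. length(times) - delta`.
#' @param delta Frame increment between ratio-map pairs.
#' @param initial_contour Contour used to initialize candidate simulations
#'   (defaults to the first frame's contour).
#' @param pixel_size Pixel size of the source images, um/px (metadata).
#' @return Object of class `experiment_dataset`.
#' @export
experiment_dataset <- function(times, contours, ratio_maps, delta = 5,
                               initial_contour = NULL, pixel_size = NA_real_) {
  n <- length(times)
  if (n < delta + 1L)
    stop("experiment_dataset: need at least delta + 1 frames", call. = FALSE)
  if (length(contours) != n)
    stop("experiment_dataset: one contour per frame required", call. = FALSE)
  if (length(ratio_maps) != n - delta)
    stop("experiment_dataset: need one ratio map per (j, j + delta) pair",
         call. = FALSE)
  if (is.null(initial_contour)) initial_contour <- contours[[1]]
  structure(
    list(times = times, contours = contours, ratio_maps = ratio_maps,
         delta = as.integer(delta), initial_contour = initial_contour,
         pixel_size = pixel_size),
    class = "experiment_dataset"
  )
}

#' Pre-interpolate a dataset's ratio maps onto the computational grid
#'
#' Ratio maps that live on a pixel grid are bilinearly interpolated onto
#' the computational grid once, so repeated candidate evaluations (the ABC
#' loop) skip the per-candidate interpolation. Maps already on the grid are
#' left untouched.
#'
#' @param data An [experiment_dataset()].
#' @param grid A [sim_grid()].
#' @return The dataset with all ratio maps on `grid`.
#' @export
align_dataset <- function(data, grid) {
  data$ratio_maps <- lapply(data$ratio_maps, function(m) {
    if (identical(dim(m$xi), c(grid$ny, grid$nx)) &&
        abs(m$spacing - grid$h) < 1e-9 &&
        abs(m$x0 - grid$x0) < 1e-9 && abs(m$y0 - grid$y0) < 1e-9) m
    else interpolate_ratio_to_grid(m, grid)
  })
  data
}

#' Root-mean-square edge distance for one frame
#'
#' For each of the N computational edge points, the minimum Euclidean
#' distance to any line segment of the experimental edge polyline is taken;
#' the frame error is the root mean square of those N minimum distances.
#'
#' @param comp Computational boundary, two-column (x, y) matrix, um.
#' @param exp Experimental boundary, two-column (x, y) matrix, um (typically
#'   denser than the computational edge).
#' @return Frame distance error D_j, um.
#' @export
edge_distance_error <- function(comp, exp) {
  comp <- as.matrix(comp); exp <- as.matrix(exp)
  if (!nrow(comp) || !nrow(exp))
    stop("edge_distance_error: empty contour", call. = FALSE)
  d <- dist_to_contour(comp[, 1], comp[, 2], exp)
  sqrt(mean(d^2))
}

#' Distances error term over the whole series
#'
#' Sum of the per-frame RMS edge distances over all post-initial frames
#' (the t = 0 contour is the simulation's initial condition and is
#' excluded).
#'
#' @param series A `frame_series` from [simulate()].
#' @param data An [experiment_dataset()] on the same frame schedule.
#' @return List with `z_d` (um) and the per-frame vector `D_j`.
#' @export
distances_error <- function(series, data) {
  n <- length(series$times)
  if (length(data$times) != n ||
      max(abs(series$times - data$times)) > 1e-6)
    stop("distances_error: frame times do not match", call. = FALSE)
  Dj <- vapply(seq.int(2L, n), function(j) {
    edge_distance_error(series$contours[[j]], data$contours[[j]])
  }, numeric(1))
  list(z_d = sum(Dj), D_j = Dj)
}

#' Density-ratio error for one frame pair
#'
#' Root mean square of the node-wise difference between the computational
#' and experimental density-ratio maps over the full L1 x L2 computational
#' grid. Off-mask nodes carry the 0 sentinel in both maps, so nodes outside
#' both tissues contribute nothing while shape mismatch (on-mask in exactly
#' one map) is penalized by the full squared ratio.
#'
#' @param xi_comp,xi_exp [density_ratio_map()]s on the same grid.
#' @return Frame-pair error P_j (dimensionless).
#' @export
density_ratio_error_frame <- function(xi_comp, xi_exp) {
  if (!identical(dim(xi_comp$xi), dim(xi_exp$xi)))
    stop("density_ratio_error_frame: grid shapes differ", call. = FALSE)
  sqrt(mean((xi_comp$xi - xi_exp$xi)^2))
}

#' Density-ratios error term over the whole series
#'
#' Interpolates each experimental ratio map to the computational grid,
#' computes the matching computational ratio for the same `(j, j + delta)`
#' pair, and sums the per-pair RMS differences over
#' `j = 1 .. t_end - delta`.
#'
#' @inheritParams distances_error
#' @return List with `z_p` and the per-pair vector `P_j`.
#' @export
density_error <- function(series, data) {
  n <- length(series$times)
  delta <- data$delta
  if (n - delta < 1L)
    stop("density_error: delta exceeds the series length", call. = FALSE)
  if (length(data$ratio_maps) != n - delta)
    stop("density_error: ratio-map count does not match the series pairing",
         call. = FALSE)
  Pj <- vapply(seq_len(n - delta), function(j) {
    xi_c <- computational_density_ratio(series, j, delta)
    xi_e <- data$ratio_maps[[j]]
    if (!identical(dim(xi_e$xi), dim(xi_c$xi)) ||
        abs(xi_e$spacing - series$grid$h) > 1e-9) {
      xi_e <- interpolate_ratio_to_grid(xi_e, series$grid)
    }
    density_ratio_error_frame(xi_c, xi_e)
  }, numeric(1))
  list(z_p = sum(Pj), P_j = Pj)
}

#' Total ABC error
#'
#' `z = z_d + w * z_p` with default weight `w = 1000` (bringing the
#' distances and density-ratio terms to the same order). If the candidate
#' simulation escaped the computational domain, or the density at the
#' explant centre increased, or the solver failed numerically, the error is
#' the NaN sentinel (never accepted).
#'
#' @param z_d Distances error term, um.
#' @param z_p Density-ratios error term.
#' @param w Weight on the density term. Default 1000.
#' @param rejected_reason One of `"none"`, `"escaped_domain"`,
#'   `"center_density_increased"`, `"numerical_failure"`.
#' @return Total error z, or NaN when a rejection rule fired.
#' @export
total_error <- function(z_d, z_p, w = 1000, rejected_reason = "none") {
  if (rejected_reason != "none") return(NaN)
  z_d + w * z_p
}

#' Simulate a candidate and score it against a dataset
#'
#' Runs the model at `theta` from the dataset's initial contour, computes
#' the distances error, the density-ratios error and the rejection flags
#' (domain escape; any frame-to-frame rise of the centre density beyond a
#' relative tolerance of 1e-6; numerical failure), and assembles the total
#' error.
#'
#' @param theta A [parameter_set()].
#' @param data An [experiment_dataset()].
#' @param grid A [sim_grid()].
#' @param schedule A [sim_schedule()] matching the dataset frames.
#' @param config A [model_config()].
#' @param w Weight on the density-ratio term.
#' @return Object of class `error_breakdown`: `z_d`, `z_p`, `w`, `z`,
#'   per-frame `D_j` and `P_j`, and `rejected_reason`.
#' @export
evaluate_candidate <- function(theta, data, grid,
                               schedule = sim_schedule(),
                               config = model_config(), w = 1000) {
  series <- tryCatch(
    simulate(data$initial_contour, theta, grid, schedule, config),
    epiboly_numerical_failure = function(e) e,
    epiboly_empty_tissue = function(e) e
  )
  breakdown <- function(reason, Dj = NULL, Pj = NULL, zd = NA_real_,
                        zp = NA_real_) {
    structure(list(D_j = Dj, P_j = Pj, z_d = zd, z_p = zp, w = w,
                   z = total_error(zd, zp, w, reason),
                   rejected_reason = reason),
              class = "error_breakdown")
  }
  if (inherits(series, "condition")) return(breakdown("numerical_failure"))
  if (series$escaped || length(series$times) < length(data$times))
    return(breakdown("escaped_domain"))
  cr <- series$center_rho
  if (length(cr) > 1L && any(diff(cr) > 1e-6 * abs(cr[-length(cr)])))
    return(breakdown("center_density_increased"))
  de <- distances_error(series, data)
  pe <- density_error(series, data)
  breakdown("none", Dj = de$D_j, Pj = pe$P_j, zd = de$z_d, zp = pe$z_p)
}

#' @export
print.error_breakdown <- function(x, ...) {
  cat(sprintf("error_breakdown: z = %.4g (z_d = %.4g, z_p = %.4g, w = %g)%s\n",
              x$z, x$z_d, x$z_p, x$w,
              if (x$rejected_reason != "none")
                paste0(" [", x$rejected_reason, "]") else ""))
  invisible(x)
}

#' ABC rejection sampling of the posterior
#'
#' Repeatedly draws a parameter set from the prior, simulates it against
#' the dataset, and accepts it when the total error is at most `threshold`
#' (the NaN sentinel is never accepted). Stops after `n_accept` acceptances
#' or `budget` attempts, whichever comes first.
#'
#' @param data An [experiment_dataset()].
#' @param priors A [prior_spec()].
#' @param grid,schedule,config,w Passed to [evaluate_candidate()].
#' @param threshold Acceptance tolerance on the total error. Default 1500.
#' @param n_accept Number of accepted sets requested.
#' @param budget Maximum number of candidate simulations.
#' @param seed Optional integer seed for reproducibility.
#' @param keep_all Keep every evaluated candidate in `$trace` (parameters,
#'   z, rejection reason); useful for threshold calibration.
#' @param progress Print a line every `progress` candidates (0 = quiet).
#' @return Object of class `abc_posterior`: `samples` (data frame of
#'   accepted parameter sets with their errors), `n_attempted`, `threshold`,
#'   `priors`, `seed`, and optionally `trace`.
#' @export
abc_rejection <- function(data, priors, grid,
                          schedule = sim_schedule(),
                          config = model_config(), w = 1000,
                          threshold = 1500, n_accept = 200,
                          budget = 50 * n_accept, seed = NULL,
                          keep_all = FALSE, progress = 0) {
  if (threshold <= 0) stop("abc_rejection: threshold must be > 0", call. = FALSE)
  if (n_accept < 1L) stop("abc_rejection: n_accept must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  data <- align_dataset(data, grid)
  acc <- vector("list", n_accept)
  trace <- if (keep_all) vector("list", budget) else NULL
  n_acc <- 0L
  n_att <- 0L
  while (n_acc < n_accept && n_att < budget) {
    n_att <- n_att + 1L
    theta <- sample_prior(priors)
    eb <- evaluate_candidate(theta, data, grid, schedule, config, w)
    row <- data.frame(F_over_k = theta$F_over_k, k_over_b = theta$k_over_b,
                      alpha = theta$alpha,
                      rho_unstressed = theta$rho_unstressed,
                      z = eb$z, rejected_reason = eb$rejected_reason,
                      stringsAsFactors = FALSE)
    if (keep_all) trace[[n_att]] <- row
    if (is.finite(eb$z) && eb$z <= threshold) {
      n_acc <- n_acc + 1L
      acc[[n_acc]] <- row
    }
    if (progress > 0 && n_att %% progress == 0L)
      message(sprintf("abc: %d attempted, %d accepted", n_att, n_acc))
  }
  if (n_acc == 0L)
    stop("abc_rejection: no candidate met the threshold within the budget; ",
         "consider increasing the threshold", call. = FALSE)
  post <- structure(
    list(samples = do.call(rbind, acc[seq_len(n_acc)]),
         n_attempted = n_att, threshold = threshold, priors = priors,
         seed = seed,
         trace = if (keep_all) do.call(rbind, trace[seq_len(n_att)]) else NULL),
    class = "abc_posterior"
  )
  post
}

#' Reference table of prior draws and their errors
#'
#' Evaluates `n_sim` prior draws against the dataset and returns every
#' candidate with its total error. [abc_threshold_quantile()] turns such a
#' table into an acceptance threshold achieving a target acceptance
#' fraction, and [as_abc_posterior()] applies a threshold to the table.
#'
#' @inheritParams abc_rejection
#' @param n_sim Number of prior draws to evaluate.
#' @return Data frame with the four parameters, `z`, and `rejected_reason`.
#' @export
abc_reference_table <- function(data, priors, grid, n_sim,
                                schedule = sim_schedule(),
                                config = model_config(), w = 1000,
                                seed = NULL, progress = 0) {
  if (!is.null(seed)) set.seed(seed)
  data <- align_dataset(data, grid)
  rows <- vector("list", n_sim)
  for (i in seq_len(n_sim)) {
    theta <- sample_prior(priors)
    eb <- evaluate_candidate(theta, data, grid, schedule, config, w)
    rows[[i]] <- data.frame(F_over_k = theta$F_over_k,
                            k_over_b = theta$k_over_b, alpha = theta$alpha,
                            rho_unstressed = theta$rho_unstressed,
                            z = eb$z, rejected_reason = eb$rejected_reason,
                            stringsAsFactors = FALSE)
    if (progress > 0 && i %% progress == 0L)
      message(sprintf("abc: %d / %d candidates evaluated", i, n_sim))
  }
  do.call(rbind, rows)
}

#' @rdname abc_reference_table
#' @param table A reference table from [abc_reference_table()].
#' @param accept_fraction Target fraction of all candidates to accept.
#' @export
abc_threshold_quantile <- function(table, accept_fraction = 0.1) {
  z <- table$z[is.finite(table$z)]
  if (!length(z)) stop("abc_threshold_quantile: no finite errors", call. = FALSE)
  # quantile over all candidates (NaN sentinels count as rejections)
  k <- max(1L, ceiling(accept_fraction * nrow(table)))
  sort(z)[min(k, length(z))]
}

#' @rdname abc_reference_table
#' @param threshold Acceptance tolerance applied to the table.
#' @export
as_abc_posterior <- function(table, threshold, priors = prior_spec(),
                             seed = NULL) {
  keep <- is.finite(table$z) & table$z <= threshold
  if (!any(keep)) stop("as_abc_posterior: no candidate meets the threshold",
                       call. = FALSE)
  structure(
    list(samples = table[keep, , drop = FALSE], n_attempted = nrow(table),
         threshold = threshold, priors = priors, seed = seed, trace = table),
    class = "abc_posterior"
  )
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf(
    "abc_posterior: %d accepted of %d attempted (threshold %.4g)\n",
    nrow(x$samples), x$n_attempted, x$threshold))
  invisible(x)
}
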