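test_that("edge distance error reduces to point-to-segment geometry", {
  sq <- cbind(c(0, 100, 100, 0, 0, 50, 50, 25), c(0, 0, 100, 100, 60, 60, 30, 30))
  expect_equal(edge_distance_error(sq, sq), 0, tolerance = 1e-12)
  # one computational point at perpendicular distance 3 from a segment
  seg <- cbind(c(-100, 100, 100, -100), c(0, 0, 200, 200))
  expect_equal(edge_distance_error(cbind(10, 3), seg), 3, tolerance = 1e-12)
  # two points at distances 3 and 4
  comp <- cbind(c(10, 20), c(3, -4))
  expect_equal(edge_distance_error(comp, seg), sqrt((9 + 16) / 2),
               tolerance = 1e-12)
  expect_equal(sqrt((9 + 16) / 2), 3.5355, tolerance = 1e-4)
  expect_error(edge_distance_error(comp[0, , drop = FALSE], seg), "empty")
})

test_that("minimum distances match a dense-resampling brute-force oracle", {
  set.seed(21)
  for (rep in 1:20) {
    a <- make_initial_contour("blob", runif(1, 0.1, 0.5), n_points = 40)
    b <- make_initial_contour("blob", runif(1, 0.1, 0.5), n_points = 60)
    b <- b + runif(1, -30, 30)
    d_fast <- edge_distance_error(a, b)
    dense <- resample_contour(b, 50000)   # ~0.05-0.2 um spacing
    d2 <- vapply(seq_len(nrow(a)), function(i) {
      min((dense[, 1] - a[i, 1])^2 + (dense[, 2] - a[i, 2])^2)
    }, numeric(1))
    d_brute <- sqrt(mean(d2))
    expect_equal(d_fast, d_brute, tolerance = 1e-4)
  }
})

test_that("frame distance errors sum over post-initial frames", {
  ct <- quick_circle(200)
  n <- 13
  ser <- structure(list(times = (0:(n - 1)) / 12,
                        contours = rep(list(ct), n)),
                   class = "frame_series")
  data <- list(times = ser$times, contours = rep(list(ct), n))
  de <- distances_error(ser, data)
  expect_equal(de$z_d, 0, tolerance = 1e-12)
  expect_length(de$D_j, n - 1)
  # uniform per-frame error c sums to (n-1) * c
  shifted <- lapply(seq_len(n), function(i) ct + 5)
  de2 <- distances_error(ser, list(times = ser$times, contours = shifted))
  expect_equal(de2$z_d, sum(de2$D_j), tolerance = 1e-12)
  expect_true(all(abs(de2$D_j - de2$D_j[1]) < 1e-9))
  bad <- list(times = ser$times + 1, contours = ser$contours)
  expect_error(distances_error(ser, bad), "frame times")
})

test_that("density-ratio frame error follows the printed RMS formula", {
  mk <- function(m) density_ratio_map(m, m > 0, spacing = 1)
  a <- mk(matrix(2, 4, 4))
  expect_equal(density_ratio_error_frame(a, a), 0)
  b <- mk(matrix(2.1, 4, 4))
  expect_equal(density_ratio_error_frame(a, b), 0.1, tolerance = 1e-12)
  c1 <- mk(matrix(c(1.2, 1, 1, 1), 2, 2))
  c2 <- mk(matrix(1, 2, 2))
  expect_equal(density_ratio_error_frame(c1, c2), sqrt(0.04 / 4),
               tolerance = 1e-12)
  expect_error(density_ratio_error_frame(a, c1), "shapes differ")
})

test_that("total error combines the two terms and honours rejection flags", {
  expect_equal(total_error(500, 0.5), 1000)
  expect_equal(total_error(123.4, 0), 123.4)
  expect_equal(total_error(500, 0.5, w = 100), 550)
  expect_true(is.nan(total_error(500, 0.5, rejected_reason = "escaped_domain")))
  expect_true(is.nan(total_error(0, 0,
                                 rejected_reason = "center_density_increased")))
})

test_that("error arithmetic matches direct evaluation to machine precision", {
  set.seed(33)
  for (i in 1:50) {
    zd <- runif(1, 0, 2000); zp <- runif(1, 0, 2)
    expect_equal(total_error(zd, zp), zd + 1000 * zp, tolerance = 1e-12)
  }
})

test_that("the ground truth scores near zero on its own noiseless dataset", {
  ds <- quick_dataset(jitter = 0, noise = 0)
  eb <- evaluate_candidate(quick_theta(), ds$data, quick_grid(),
                           quick_schedule(t_end = 2))
  expect_identical(eb$rejected_reason, "none")
  expect_lt(eb$z, 10)
  expect_equal(eb$z, eb$z_d + 1000 * eb$z_p, tolerance = 1e-12)
  # determinism: same candidate, same data, same error
  eb2 <- evaluate_candidate(quick_theta(), ds$data, quick_grid(),
                            quick_schedule(t_end = 2))
  expect_identical(eb$z, eb2$z)
})

test_that("domain escape yields the NaN sentinel and is never accepted", {
  ds <- quick_dataset(jitter = 0, noise = 0)
  tiny <- sim_grid_centered(600, 20)
  runaway <- parameter_set(1.4, 5000, 0.9, 1100)
  eb <- evaluate_candidate(runaway, ds$data, tiny, quick_schedule(t_end = 2))
  expect_identical(eb$rejected_reason, "escaped_domain")
  expect_true(is.nan(eb$z))
})

test_that("rejection sampling accepts exactly the sub-threshold candidates", {
  ds <- quick_dataset()
  g <- quick_grid()
  sch <- quick_schedule(t_end = 2)
  post <- abc_rejection(ds$data, prior_spec(), g, sch, threshold = 1e9,
                        n_accept = 6, budget = 12, seed = 5, keep_all = TRUE)
  expect_true(all(post$samples$z <= 1e9))
  expect_true(all(is.finite(post$samples$z)))
  # NaN-sentinel candidates never appear among the accepted
  expect_true(all(post$samples$rejected_reason == "none"))
  post2 <- abc_rejection(ds$data, prior_spec(), g, sch, threshold = 1e9,
                         n_accept = 6, budget = 12, seed = 5)
  expect_equal(post$samples[names(post2$samples)], post2$samples)
  expect_error(
    abc_rejection(ds$data, prior_spec(), g, sch, threshold = 1e-6,
                  n_accept = 2, budget = 3, seed = 6),
    "threshold")
})

test_that("reference tables calibrate thresholds to an acceptance fraction", {
  tb <- data.frame(F_over_k = runif(40), k_over_b = runif(40, 500, 5000),
                   alpha = runif(40), rho_unstressed = runif(40, 1000, 2000),
                   z = c(sort(runif(30, 100, 1000)), rep(NaN, 10)),
                   rejected_reason = "none")
  thr <- abc_threshold_quantile(tb, accept_fraction = 0.25)
  post <- as_abc_posterior(tb, thr)
  expect_equal(nrow(post$samples), 10)   # 25% of 40, NaNs count as rejections
  expect_true(all(post$samples$z <= thr))
})

test_that("posterior summaries locate modes, means and the best sets", {
  set.seed(9)
  n <- 5000
  s <- data.frame(F_over_k = rnorm(n, 0.7, 0.05),
                  k_over_b = rnorm(n, 2000, 100),
                  alpha = rnorm(n, 0.5, 0.04),
                  rho_unstressed = rnorm(n, 1500, 50),
                  z = runif(n, 100, 1500))
  post <- fake_posterior(s)
  sm <- posterior_summaries(post, bins = 25)
  expect_equal(sm$modes[["F_over_k"]], 0.7, tolerance = 0.05 / sqrt(12))
  expect_equal(sm$means[["alpha"]], 0.5, tolerance = 3 * 0.04 / sqrt(n))
  expect_identical(sm$best_sets$z, sort(s$z)[1:3])

  same <- fake_posterior(data.frame(F_over_k = rep(0.4, 5),
                                    k_over_b = rep(900, 5),
                                    alpha = rep(0.2, 5),
                                    rho_unstressed = rep(1300, 5),
                                    z = rep(10, 5)))
  sm2 <- posterior_summaries(same)
  expect_equal(unname(sm2$modes), unname(sm2$means))
})

test_that("correlations use the best-z subset and flag degenerate columns", {
  n <- 200
  x <- seq(0, 1, length.out = n)
  s <- data.frame(F_over_k = x, k_over_b = -x, alpha = runif(n),
                  rho_unstressed = runif(n), z = seq_len(n))
  cm <- pairwise_correlations(fake_posterior(s), fraction = 0.2)
  expect_equal(cm["F_over_k", "F_over_k"], 1)
  expect_equal(cm["F_over_k", "k_over_b"], -1, tolerance = 1e-12)
  s2 <- s; s2$alpha <- 1
  expect_warning(cm2 <- pairwise_correlations(fake_posterior(s2), 0.2),
                 "zero-variance")
  expect_true(is.na(cm2["alpha", "F_over_k"]))
})

test_that("credible intervals are central percentile intervals", {
  same <- fake_posterior(data.frame(F_over_k = rep(0.4, 5),
                                    k_over_b = rep(900, 5),
                                    alpha = rep(0.2, 5),
                                    rho_unstressed = rep(1300, 5),
                                    z = rep(10, 5)))
  ci0 <- credible_intervals(same)
  expect_true(all(ci0["upper", ] - ci0["lower", ] == 0))
  set.seed(12)
  n <- 1e5
  s <- data.frame(F_over_k = runif(n), k_over_b = runif(n, 500, 5000),
                  alpha = runif(n), rho_unstressed = runif(n, 1000, 2000),
                  z = runif(n))
  ci <- credible_intervals(fake_posterior(s), level = 0.95)
  expect_lt(abs(ci["lower", "F_over_k"] - 0.025), 0.005)
  expect_lt(abs(ci["upper", "F_over_k"] - 0.975), 0.005)
  pr <- prior_spec()
  for (nm in colnames(ci)) {
    expect_gte(ci["lower", nm], pr[[nm]][1])
    expect_lte(ci["upper", nm], pr[[nm]][2])
  }
})

test_that("2D highest-density regions contain central points, not outliers", {
  set.seed(4)
  n <- 4000
  s <- data.frame(F_over_k = rnorm(n, 0.7, 0.1),
                  k_over_b = rnorm(n, 2000, 200),
                  alpha = runif(n), rho_unstressed = runif(n, 1000, 2000),
                  z = runif(n))
  post <- fake_posterior(s)
  expect_true(hdr2d_contains(post, "F_over_k", "k_over_b", 0.7, 2000))
  expect_false(hdr2d_contains(post, "F_over_k", "k_over_b", 0.1, 4500))
})
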