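param_names <- c("F_over_k", "k_over_b", "alpha", "rho_unstressed")

#' Posterior summaries: histograms, smoothed modes, means, best sets
#'
#' One-dimensional histograms and kernel-smoothed curves (Gaussian kernel,
#' Silverman bandwidth) per parameter, with the mode taken as the argmax of
#' the smoothed curve; two-dimensional histograms for all parameter pairs;
#' the posterior mean vector; and the three accepted sets with the smallest
#' total errors.
#'
#' @param post An `abc_posterior`.
#' @param bins Number of histogram bins per axis. Default 30.
#' @return List with `per_parameter` (named list with `hist`, `density`,
#'   `mode`, `mean`), `pair_histograms`, `means`, `modes`, `best_sets`.
#' @export
posterior_summaries <- function(post, bins = 30) {
  s <- post$samples
  if (!nrow(s)) stop("posterior_summaries: empty posterior", call. = FALSE)
  per <- lapply(param_names, function(nm) {
    x <- s[[nm]]
    h <- graphics::hist(x, breaks = bins, plot = FALSE)
    if (length(unique(x)) > 1L) {
      d <- stats::density(x, bw = "nrd0")
      mode <- d$x[which.max(d$y)]
    } else {
      d <- NULL
      mode <- x[1]
    }
    list(hist = h, density = d, mode = mode, mean = mean(x))
  })
  names(per) <- param_names
  pairs <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    nmi <- param_names[i]; nmj <- param_names[j]
    pairs[[paste(nmi, nmj, sep = ":")]] <-
      bin2d(s[[nmi]], s[[nmj]], bins = bins)
  }
  ord <- order(s$z)
  list(
    per_parameter = per,
    pair_histograms = pairs,
    means = vapply(param_names, function(nm) mean(s[[nm]]), numeric(1)),
    modes = vapply(param_names, function(nm) per[[nm]]$mode, numeric(1)),
    best_sets = s[ord[seq_len(min(3L, nrow(s)))], , drop = FALSE]
  )
}

# 2D histogram on an equal-width grid.
bin2d <- function(x, y, bins = 30, xlim = range(x), ylim = range(y)) {
  bx <- seq(xlim[1], xlim[2], length.out = bins + 1L)
  by <- seq(ylim[1], ylim[2], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(x, bx, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(y, by, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  list(xbreaks = bx, ybreaks = by, counts = counts)
}

#' Pairwise parameter correlations on the best-fitting subset
#'
#' Pearson correlation matrix of the four parameters over the fraction of
#' accepted samples with the smallest total errors (default: best 20%).
#' Zero-variance parameters yield NA entries (flagged by a warning, never
#' silently zero).
#'
#' @param post An `abc_posterior`.
#' @param fraction Fraction of accepted samples (smallest z) to use.
#' @return 4x4 correlation matrix (diagonal 1 where defined).
#' @export
pairwise_correlations <- function(post, fraction = 0.2) {
  s <- post$samples
  k <- max(3L, ceiling(fraction * nrow(s)))
  if (nrow(s) < 3L)
    stop("pairwise_correlations: need at least 3 accepted samples", call. = FALSE)
  sub <- s[order(s$z)[seq_len(min(k, nrow(s)))], param_names]
  degenerate <- vapply(sub, function(x) stats::var(x) == 0, logical(1))
  if (any(degenerate))
    warning("pairwise_correlations: zero-variance parameter(s): ",
            paste(param_names[degenerate], collapse = ", "))
  suppressWarnings(stats::cor(as.matrix(sub)))
}

#' Central credible intervals for each parameter
#'
#' Percentile intervals of the accepted samples: the
#' `[(1 - level)/2, (1 + level)/2]` quantiles per parameter.
#'
#' @param post An `abc_posterior`.
#' @param level Credible level. Default 0.95.
#' @return Matrix with rows `lower`, `upper` and one column per parameter.
#' @export
credible_intervals <- function(post, level = 0.95) {
  s <- post$samples
  if (nrow(s) < 2L)
    stop("credible_intervals: need at least 2 samples", call. = FALSE)
  probs <- c((1 - level) / 2, (1 + level) / 2)
  out <- vapply(param_names, function(nm) {
    stats::quantile(s[[nm]], probs, names = FALSE)
  }, numeric(2))
  rownames(out) <- c("lower", "upper")
  out
}

#' Does a point lie in the highest-density region of a 2D histogram?
#'
#' Builds a 2D histogram of two parameters over the accepted samples,
#' accumulates bins from densest down until `level` of the posterior mass is
#' covered, and reports whether the query point falls in one of those bins.
#'
#' @param post An `abc_posterior`.
#' @param par_x,par_y Parameter names.
#' @param x,y Query point.
#' @param level Mass level of the region. Default 0.95.
#' @param bins Bins per axis. Default 15.
#' @return Logical.
#' @export
hdr2d_contains <- function(post, par_x, par_y, x, y, level = 0.95, bins = 15) {
  s <- post$samples
  xs <- s[[par_x]]; ys <- s[[par_y]]
  xlim <- range(xs, x); ylim <- range(ys, y)
  b <- bin2d(xs, ys, bins = bins, xlim = xlim, ylim = ylim)
  ord <- order(b$counts, decreasing = TRUE)
  cum <- cumsum(b$counts[ord])
  need <- which(cum >= level * sum(b$counts))[1]
  keep <- matrix(FALSE, bins, bins)
  keep[ord[seq_len(need)]] <- TRUE
  ix <- pmin(pmax(findInterval(x, b$xbreaks, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(y, b$ybreaks, rightmost.closed = TRUE), 1L), bins)
  keep[ix, iy]
}

#' Triangle plot of an ABC posterior
#'
#' Corner-style summary: smoothed 1D histograms on the diagonal (dashed line
#' at the mode), 2D histograms below the diagonal with darker cells for more
#' frequently sampled values. Drawn with base graphics on the active device.
#'
#' @param post An `abc_posterior`.
#' @param bins Bins per axis.
#' @param truth Optional named numeric vector of ground-truth values to mark.
#' @return Invisibly, the [posterior_summaries()] used for the panels.
#' @export
triangle_plot <- function(post, bins = 30, truth = NULL) {
  sm <- posterior_summaries(post, bins = bins)
  s <- post$samples
  labs <- c(F_over_k = "F/k", k_over_b = "k/b (um^2/h)",
            alpha = "alpha (1/h)", rho_unstressed = "rho_u (cells/mm^2)")
  op <- graphics::par(mfrow = c(4, 4), mar = c(2.2, 2.2, 0.6, 0.6),
                      mgp = c(1.2, 0.3, 0), tcl = -0.2, cex = 0.7)
  on.exit(graphics::par(op), add = TRUE)
  greys <- grDevices::grey(seq(1, 0.1, length.out = 64))
  for (i in 1:4) for (j in 1:4) {
    nmi <- param_names[i]; nmj <- param_names[j]
    if (j > i) { graphics::plot.new(); next }
    if (i == j) {
      p <- sm$per_parameter[[nmi]]
      graphics::plot(p$hist, freq = FALSE, main = "", xlab = labs[nmi],
                     ylab = "", col = "grey85", border = "grey60")
      if (!is.null(p$density)) graphics::lines(p$density, lwd = 1.5)
      graphics::abline(v = p$mode, lty = 2)
      if (!is.null(truth) && nmi %in% names(truth))
        graphics::abline(v = truth[[nmi]], col = "red3")
    } else {
      b <- bin2d(s[[nmj]], s[[nmi]], bins = bins)
      graphics::image(
        x = (b$xbreaks[-1] + b$xbreaks[-length(b$xbreaks)]) / 2,
        y = (b$ybreaks[-1] + b$ybreaks[-length(b$ybreaks)]) / 2,
        z = b$counts, col = greys, xlab = labs[nmj], ylab = labs[nmi],
        main = "")
      graphics::abline(v = sm$modes[nmj], h = sm$modes[nmi], lty = 2,
                       col = "grey40")
      if (!is.null(truth) && all(c(nmj, nmi) %in% names(truth)))
        graphics::points(truth[[nmj]], truth[[nmi]], pch = 3, col = "red3",
                         lwd = 2)
    }
  }
  invisible(sm)
}
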