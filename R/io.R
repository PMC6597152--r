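#' Write and read per-frame boundary contours as CSV
#'
#' Plain-text exchange format for contour series: columns `frame`
#' (1-based), `point_index` (1-based within frame), `x_um`, `y_um`.
#' Contours are implicitly closed (the first vertex is not repeated).
#'
#' @param contours List of two-column (x, y) matrices, or a `frame_series`
#'   (its contours are written).
#' @param path CSV file path.
#' @return `write_contours`: `path`, invisibly. `read_contours`: list of
#'   contour matrices, ordered by frame.
#' @export
write_contours <- function(contours, path) {
  if (inherits(contours, "frame_series")) contours <- contours$contours
  rows <- lapply(seq_along(contours), function(f) {
    ct <- contours[[f]]
    data.frame(frame = f, point_index = seq_len(nrow(ct)),
               x_um = ct[, 1], y_um = ct[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours
#' @param check_simple Validate that each contour is non-self-intersecting
#'   (O(n^2); disable for very dense contours).
#' @export
read_contours <- function(path, check_simple = TRUE) {
  df <- utils::read.csv(path)
  need <- c("frame", "point_index", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("read_contours: header must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(df[need])
  if (!is.numeric(m)) {
    first_bad <- which(is.na(suppressWarnings(as.numeric(m))))[1]
    stop(sprintf("read_contours: malformed row at line %d",
                 ((first_bad - 1L) %% nrow(m)) + 2L), call. = FALSE)
  }
  bad <- which(!is.finite(rowSums(m)))
  if (length(bad))
    stop(sprintf("read_contours: malformed row at line %d", bad[1] + 1L),
         call. = FALSE)
  frames <- sort(unique(df$frame))
  lapply(frames, function(f) {
    sub <- df[df$frame == f, ]
    if (is.unsorted(sub$point_index)) {
      warning(sprintf("read_contours: frame %d points out of order; re-sorted", f))
      sub <- sub[order(sub$point_index), ]
    }
    as_contour(cbind(sub$x_um, sub$y_um), check_simple = check_simple)
  })
}

#' Write and read a density-ratio map as text grids plus a JSON sidecar
#'
#' Three files per map: `<prefix>_xi.txt` (tab-delimited value grid, row
#' per y), `<prefix>_mask.txt` (0/1 grid), `<prefix>.json` (origin,
#' spacing in um, frame pair). Off-mask values are forced to the 0
#' sentinel on read.
#'
#' @param map A [density_ratio_map()].
#' @param prefix File path prefix.
#' @return `write_ratio_map`: `prefix`, invisibly. `read_ratio_map`: a
#'   [density_ratio_map()].
#' @export
write_ratio_map <- function(map, prefix) {
  utils::write.table(map$xi, paste0(prefix, "_xi.txt"),
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  utils::write.table(map$mask * 1L, paste0(prefix, "_mask.txt"),
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  jsonlite::write_json(
    list(x0 = map$x0, y0 = map$y0, spacing = map$spacing,
         frame_j = map$frame_j, delta = map$delta,
         nrow = nrow(map$xi), ncol = ncol(map$xi)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_ratio_map
#' @export
read_ratio_map <- function(prefix) {
  side <- paste0(prefix, ".json")
  if (!file.exists(side))
    stop("read_ratio_map: missing JSON sidecar ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  xi <- as.matrix(utils::read.table(paste0(prefix, "_xi.txt"), sep = "\t"))
  mask <- as.matrix(utils::read.table(paste0(prefix, "_mask.txt"),
                                      sep = "\t")) != 0
  dimnames(xi) <- NULL; dimnames(mask) <- NULL
  if (nrow(xi) != meta$nrow || ncol(xi) != meta$ncol ||
      !identical(dim(xi), dim(mask)))
    stop("read_ratio_map: grid shape does not match the sidecar", call. = FALSE)
  if (!any(mask)) warning("read_ratio_map: mask is empty")
  xi[!mask] <- 0
  density_ratio_map(xi, mask, x0 = meta$x0, y0 = meta$y0,
                    spacing = meta$spacing,
                    frame_j = if (is.null(meta$frame_j)) NA else meta$frame_j,
                    delta = if (is.null(meta$delta)) NA else meta$delta)
}

#' Write and read a complete experiment dataset directory
#'
#' A dataset directory holds `contours.csv`, one ratio-map file triple per
#' frame pair under `ratio_maps/`, an `initial_contour.csv`, and
#' `manifest.json` (frame interval, delta, pixel size, file listing, and
#' for synthetic data the ground-truth parameters and seed).
#'
#' @param data An [experiment_dataset()].
#' @param dir Directory to create/populate.
#' @param truth Optional ground-truth record (from [generate_dataset()]);
#'   its parameters and seed are stored in the manifest (the frame series
#'   is not serialized).
#' @return `write_dataset`: `dir`, invisibly. `read_dataset`: a list with
#'   `data` and (if present) `truth` (parameters and seed only).
#' @export
write_dataset <- function(data, dir, truth = NULL) {
  dir.create(file.path(dir, "ratio_maps"), recursive = TRUE,
             showWarnings = FALSE)
  write_contours(data$contours, file.path(dir, "contours.csv"))
  write_contours(list(data$initial_contour),
                 file.path(dir, "initial_contour.csv"))
  prefixes <- vapply(seq_along(data$ratio_maps), function(j) {
    pre <- file.path("ratio_maps", sprintf("pair_%04d", j))
    write_ratio_map(data$ratio_maps[[j]], file.path(dir, pre))
    pre
  }, character(1))
  manifest <- list(
    frame_interval = diff(data$times[1:2]), n_frames = length(data$times),
    delta = data$delta, pixel_size = data$pixel_size,
    contours = "contours.csv", initial_contour = "initial_contour.csv",
    ratio_maps = prefixes
  )
  if (!is.null(truth))
    manifest$truth <- list(theta_star = unclass(truth$theta_star),
                           seed = truth$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  contours <- read_contours(file.path(dir, manifest$contours),
                            check_simple = FALSE)
  init <- read_contours(file.path(dir, manifest$initial_contour),
                        check_simple = FALSE)[[1]]
  maps <- lapply(manifest$ratio_maps, function(p) read_ratio_map(file.path(dir, p)))
  times <- (seq_len(manifest$n_frames) - 1L) * manifest$frame_interval
  data <- experiment_dataset(times, contours, maps, delta = manifest$delta,
                             initial_contour = init,
                             pixel_size = manifest$pixel_size)
  out <- list(data = data)
  if (!is.null(manifest$truth)) {
    th <- manifest$truth$theta_star
    out$truth <- list(
      theta_star = parameter_set(th$F_over_k, th$k_over_b, th$alpha,
                                 th$rho_unstressed),
      seed = manifest$truth$seed)
  }
  out
}

#' Export an ABC posterior as CSV
#'
#' Columns `F_over_k`, `k_over_b`, `alpha`, `rho_unstressed`, `z`.
#'
#' @param post An `abc_posterior`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(post, path) {
  utils::write.csv(
    post$samples[c(param_names, "z")], path, row.names = FALSE)
  invisible(path)
}
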