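#' Spherical head model with a cortical-shell source grid
#'
#' Combines the 64-channel montage with a quasi-uniform (Fibonacci lattice)
#' grid of source voxels on a spherical shell inside the sensor sphere. The
#' shell stands in for the cortical surface; voxel coordinates are reported
#' both in the dimensionless sphere frame and in millimetres (scalp radius
#' 90 mm) for MNI-like annotation.
#'
#' @param n_voxels number of source voxels (default 400; 2839 reproduces the
#'   density used for full cortical-surface mapping)
#' @param shell_radius radius of the source shell as a fraction of the sensor
#'   sphere radius (must be < 1)
#' @param montage data.frame of channel labels/positions
#'   (default [standard_montage_64()])
#' @param upper_only if TRUE keep only voxels with z > -0.3 (cortex does not
#'   extend to the bottom of the sphere); n_voxels is then reached after
#'   trimming
#' @return object of class `head_model` with fields `channel_labels`,
#'   `channel_positions` (channels x 3), `voxel_positions` (voxels x 3),
#'   `voxel_mm`, `n_voxels`, `radius`, `shell_radius`
#' @export
head_model <- function(n_voxels = 400, shell_radius = 0.75,
                       montage = standard_montage_64(), upper_only = TRUE) {
  stopifnot(n_voxels >= 2, shell_radius > 0, shell_radius < 1)
  chpos <- as.matrix(montage[, c("x", "y", "z")])
  rownames(chpos) <- montage$label

  # Fibonacci sphere lattice, optionally trimmed to the upper portion
  n_gen <- if (upper_only) ceiling(n_voxels / 0.62) else n_voxels
  repeat {
    i <- seq_len(n_gen) - 0.5
    phi <- acos(1 - 2 * i / n_gen)          # inclination
    theta <- pi * (1 + sqrt(5)) * i          # golden-angle azimuth
    v <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
    if (upper_only) v <- v[v[, 3] > -0.3, , drop = FALSE]
    if (nrow(v) >= n_voxels) break
    n_gen <- n_gen + 8
  }
  v <- v[seq_len(n_voxels), , drop = FALSE] * shell_radius

  hm <- list(channel_labels = montage$label,
             channel_positions = chpos,
             voxel_positions = v,
             voxel_mm = v * 90,
             n_voxels = n_voxels,
             radius = 1,
             shell_radius = shell_radius)
  class(hm) <- "head_model"
  validate_head_model(hm)
  hm
}

#' @export
print.head_model <- function(x, ...) {
  cat("<head_model> ", length(x$channel_labels), " channels, ",
      x$n_voxels, " voxels on shell r = ", x$shell_radius, "\n", sep = "")
  invisible(x)
}

#' @keywords internal
validate_head_model <- function(hm) {
  stopifnot(is.matrix(hm$channel_positions), ncol(hm$channel_positions) == 3,
            all(is.finite(hm$channel_positions)),
            all(is.finite(hm$voxel_positions)))
  rv <- sqrt(rowSums(hm$voxel_positions^2))
  if (any(rv >= hm$radius - 1e-9))
    stop("head_model: all voxels must lie strictly inside the sensor sphere")
  invisible(hm)
}

#' Index of the voxel closest to a target location
#'
#' @param hm head model
#' @param target length-3 vector in the sphere frame, or a label:
#'   `"right_frontal"` picks the voxel nearest the direction of electrode F6
#'   at shell depth (the planted-effect site used throughout).
#' @return integer voxel index
#' @export
nearest_voxel <- function(hm, target = "right_frontal") {
  if (is.character(target)) {
    target <- switch(target,
      right_frontal = {
        i <- match("F6", hm$channel_labels)
        hm$channel_positions[i, ] * hm$shell_radius
      },
      posterior = {
        i <- match("Oz", hm$channel_labels)
        hm$channel_positions[i, ] * hm$shell_radius
      },
      central = {
        i <- match("Cz", hm$channel_labels)
        hm$channel_positions[i, ] * hm$shell_radius
      },
      stop("unknown target label: ", target))
  }
  d2 <- rowSums((hm$voxel_positions - matrix(target, hm$n_voxels, 3, byrow = TRUE))^2)
  which.min(d2)
}

#' Voxel adjacency on the shell grid
#'
#' Two voxels are contiguous when their distance is below
#' `factor` times the median nearest-neighbour spacing of the grid. Used for
#' grouping significant voxels into clusters.
#'
#' @param hm head model
#' @param factor distance multiplier (default 1.6)
#' @return list: element i holds the integer neighbours of voxel i
#' @export
voxel_neighbors <- function(hm, factor = 1.6) {
  v <- hm$voxel_positions
  n <- nrow(v)
  d <- as.matrix(dist(v))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  thr <- factor * median(nn)
  lapply(seq_len(n), function(i) which(d[i, ] <= thr))
}
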