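## Analytic EEG forward model: current dipole in a homogeneous conducting
## sphere with an insulating boundary (no current leaves the scalp).
##
## For a dipole at eccentricity f = b/R on the z-axis with moment decomposed
## into a radial part m_r and a tangential part m_t, the surface potential at
## angular distance gamma (u = cos gamma) and azimuth phi from the tangential
## direction is the closed-form sum of the Legendre series
##
##   V = 1/(4 pi sigma R^2) * sum_n (2n+1)/n f^(n-1)
##         [ n m_r P_n(u) + m_t P_n^1(u) cos phi ]
##
## evaluated with generating functions:
##   radial:     m_r [ 2 (u - f)/d^3 + (1/d - 1)/f ]
##   tangential: m_t cos phi * s [ 2/d^3 + (d + 1) / (d (1 - f u + d)) ]
## with d = sqrt(1 - 2 f u + f^2), s = sin gamma. The dipole-at-centre limit
## is V = 3 m.e / (4 pi sigma R^2) for a unit observation direction e.

#' Potential of a dipole in a homogeneous sphere (closed form)
#'
#' @param dip_pos length-3 dipole location (inside the sphere)
#' @param moment length-3 dipole moment
#' @param elec matrix channels x 3 of electrode positions on the sphere surface
#' @param radius sphere radius
#' @param sigma conductivity (arbitrary units; fixes the output scale)
#' @return numeric vector, one potential per electrode
#' @export
sphere_dipole_potential <- function(dip_pos, moment, elec, radius = 1, sigma = 1) {
  b <- sqrt(sum(dip_pos^2))
  if (b >= radius - 1e-9) stop("dipole on or outside the sensor sphere")
  R <- radius
  e_hat <- elec / R
  k <- 1 / (4 * pi * sigma * R^2)

  if (b < 1e-12) { # centre: V = 3 m.e / (4 pi sigma R^2)
    return(k * 3 * as.numeric(e_hat %*% moment))
  }

  r0_hat <- dip_pos / b
  f <- b / R
  u <- as.numeric(e_hat %*% r0_hat)
  u <- pmin(pmax(u, -1), 1)
  s <- sqrt(pmax(0, 1 - u^2))
  d <- sqrt(1 - 2 * f * u + f^2)

  m_r <- sum(moment * r0_hat)
  m_t_vec <- moment - m_r * r0_hat

  # in-plane tangential unit vector at each electrode, orthogonal to r0_hat
  t_vec <- e_hat - outer(u, r0_hat)
  t_norm <- sqrt(rowSums(t_vec^2))
  ok <- t_norm > 1e-12
  mt_cosphi <- numeric(length(u))
  if (any(ok))
    mt_cosphi[ok] <- (t_vec[ok, , drop = FALSE] %*% m_t_vec) / t_norm[ok]

  v_rad <- m_r * (2 * (u - f) / d^3 + (1 / d - 1) / f)
  v_tan <- mt_cosphi * s * (2 / d^3 + (d + 1) / (d * (1 - f * u + d)))
  k * (v_rad + v_tan)
}

#' Leadfield for every voxel of a spherical head model
#'
#' Evaluates the analytic single-sphere dipole solution at each voxel for the
#' three Cartesian orientations and applies an average reference (each
#' orientation row then sums to zero over channels). The forward model is
#' deterministic given the geometry; `seed` is accepted for interface
#' symmetry with the stochastic generators and ignored.
#'
#' @param hm head model from [head_model()]
#' @param seed ignored (determinism contract: the leadfield depends only on
#'   geometry)
#' @return object of class `leadfield`: `gain` is an array
#'   voxels x 3 x channels, `head_model` the input model
#' @export
generate_leadfield <- function(hm, seed = NULL) {
  validate_head_model(hm)
  nch <- nrow(hm$channel_positions)
  nv <- hm$n_voxels
  gain <- array(0, dim = c(nv, 3L, nch),
                dimnames = list(NULL, c("x", "y", "z"), hm$channel_labels))
  I3 <- diag(3)
  for (v in seq_len(nv)) {
    for (o in 1:3) {
      g <- sphere_dipole_potential(hm$voxel_positions[v, ], I3[o, ],
                                   hm$channel_positions, radius = hm$radius)
      gain[v, o, ] <- g - mean(g) # average reference
    }
  }
  lf <- list(gain = gain, head_model = hm)
  class(lf) <- "leadfield"
  lf
}

#' @export
print.leadfield <- function(x, ...) {
  d <- dim(x$gain)
  cat("<leadfield> ", d[1], " voxels x 3 orientations x ", d[3], " channels\n", sep = "")
  invisible(x)
}

#' Leadfield as a channels x (3 * voxels) matrix
#'
#' Column order: voxel-major (v1x, v1y, v1z, v2x, ...).
#' @param lf leadfield
#' @return numeric matrix channels x 3V
#' @export
leadfield_matrix <- function(lf) {
  d <- dim(lf$gain)
  K <- matrix(aperm(lf$gain, c(3L, 2L, 1L)), nrow = d[3])
  rownames(K) <- dimnames(lf$gain)[[3]]
  K
}

#' Project source time courses to the sensors
#'
#' @param lf leadfield
#' @param voxel integer voxel index
#' @param moment length-3 orientation (dipole moment direction, scaled)
#' @param waveform numeric vector (source time course)
#' @return matrix channels x time
#' @export
project_source <- function(lf, voxel, moment, waveform) {
  topo <- as.numeric(t(lf$gain[voxel, , ]) %*% moment) # channels
  outer(topo, waveform)
}
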