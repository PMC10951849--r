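## Multivariate interaction measure (MIM): volume-conduction-robust
## functional connectivity between 3-dimensional source spaces.
##
## For voxels i, j with cross-spectral blocks S_ii, S_jj (3x3 Hermitian) and
## S_ij (3x3 complex),
##
##   MIM_ij = tr[ (Re S_ii)^-1  Im S_ij  (Re S_jj)^-1  (Im S_ij)' ]
##
## equivalently the sum of the three eigenvalues of that product. The
## imaginary part of the cross-spectrum vanishes for any instantaneous
## linear mixture of independent sources, so MIM is blind to volume
## conduction; the trace form is invariant to any non-singular real linear
## remixing within each voxel's 3-D source space.

#' Source-space cross-spectral blocks
#'
#' Applies the inverse operator to the per-trial band Fourier coefficients
#' and forms the trial-averaged cross-spectral matrix over all voxels'
#' source dimensions, averaged over the band bins (one 3V x 3V Hermitian
#' matrix).
#'
#' @param op inverse_operator
#' @param spectra band_spectra (>= 2 trials)
#' @param per_bin if TRUE return a list of per-bin cross-spectra instead of
#'   the band average
#' @return object of class `voxel_cross_spectrum`: `S` (3V x 3V complex),
#'   `n_voxels`, `n_trials`, `bins`
#' @export
voxel_cross_spectrum <- function(op, spectra, per_bin = FALSE) {
  d <- dim(spectra$coef)
  if (d[3] < 2) stop("need >= 2 trials for a full-rank cross-spectrum")
  sc <- source_coefficients(op, spectra)      # 3V x bins x trials
  nb <- dim(sc)[2]; ntr <- dim(sc)[3]
  Sb <- vector("list", nb)
  for (f in seq_len(nb)) {
    A <- matrix(sc[, f, ], nrow = dim(sc)[1]) # 3V x trials
    Sb[[f]] <- (A %*% Conj(t(A))) / ntr
  }
  S <- Reduce(`+`, Sb) / nb
  out <- list(S = if (per_bin) NULL else S, S_bins = if (per_bin) Sb else NULL,
              n_voxels = op$n_voxels, n_trials = ntr, bins = spectra$bins,
              per_bin = per_bin)
  class(out) <- "voxel_cross_spectrum"
  out
}

#' @export
print.voxel_cross_spectrum <- function(x, ...) {
  cat("<voxel_cross_spectrum> ", x$n_voxels, " voxels, ", x$n_trials,
      " trials, band ", min(x$bins), "-", max(x$bins), " Hz",
      if (x$per_bin) " (per bin)" else " (band-averaged)", "\n", sep = "")
  invisible(x)
}

#' MIM between two 3-D source spaces
#'
#' @param S_ii,S_jj 3x3 Hermitian auto-spectral blocks
#' @param S_ij 3x3 complex cross-spectral block
#' @param eps relative ridge added to near-singular real parts (logged via a
#'   warning when triggered)
#' @return scalar MIM >= 0
#' @export
mim_pair <- function(S_ii, S_jj, S_ij, eps = 1e-12) {
  herm_err <- max(Mod(S_ii - Conj(t(S_ii))), Mod(S_jj - Conj(t(S_jj))))
  if (herm_err > 1e-8 * max(Mod(S_ii), Mod(S_jj)))
    stop("auto-spectral blocks are not Hermitian (error ", signif(herm_err, 3), ")")
  Ri <- Re(S_ii); Rj <- Re(S_jj)
  Qi <- solve_real_block(Ri, eps)
  Qj <- solve_real_block(Rj, eps)
  Im_ij <- Im(S_ij)
  sum((Qi %*% Im_ij %*% Qj) * Im_ij)
}

## inverse of a 3x3 real spd block with relative ridge fallback
solve_real_block <- function(R, eps = 1e-12) {
  ridge <- eps * sum(diag(R)) / nrow(R)
  out <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(out) || !all(is.finite(out))) {
    warning("near-singular real part; ridge ", signif(ridge, 3), " applied")
    out <- solve(R + ridge * diag(nrow(R)))
  }
  out
}

#' Voxel-to-whole-brain MIM map
#'
#' For each voxel, the mean MIM between that voxel and every other voxel
#' (self-pairs excluded: MIM measures interactions between distinct areas).
#'
#' @param cs voxel_cross_spectrum (band-averaged)
#' @return numeric vector, one non-negative value per voxel
#' @export
mim_voxel_to_whole_brain <- function(cs) {
  if (cs$per_bin) stop("band-averaged cross-spectrum required")
  S <- cs$S
  V <- cs$n_voxels
  if (V < 2) stop("need >= 2 voxels")
  idx <- function(v) (3 * (v - 1) + 1):(3 * v)
  Qi <- vector("list", V)
  for (v in seq_len(V)) Qi[[v]] <- solve_real_block(Re(S[idx(v), idx(v)]))
  ImS <- Im(S)
  total <- numeric(V)
  for (i in seq_len(V - 1)) {
    ii <- idx(i)
    for (j in (i + 1):V) {
      jj <- idx(j)
      Mij <- ImS[ii, jj]
      m <- sum((Qi[[i]] %*% Mij %*% Qi[[j]]) * Mij)
      total[i] <- total[i] + m
      total[j] <- total[j] + m
    }
  }
  total / (V - 1)
}

#' MIM regulation contrast with voxel-wise permutation inference
#'
#' Per participant and condition the voxel-to-whole-brain MIM map of the
#' regulation segment is computed; the contrast is
#' map(reappraise) - map(maintain), and the group difference is tested with
#' [voxel_permutation_test()].
#'
#' @param maps_a,maps_b lists (one element per participant) with fields
#'   `reappraise` and `maintain` (per-voxel MIM maps), for the two groups
#' @param n_perm,seed,tails,alpha,neighbors,hm passed to
#'   [voxel_permutation_test()]
#' @return list: `contrast_a`, `contrast_b` (participant x voxel matrices)
#'   and `test` (voxel_stat_map)
#' @export
mim_contrast_and_test <- function(maps_a, maps_b, n_perm = 10000, seed = 1,
                                  tails = "two", alpha = 0.05,
                                  neighbors = NULL, hm = NULL) {
  contrast <- function(maps)
    do.call(rbind, lapply(maps, function(m) m$reappraise - m$maintain))
  ca <- contrast(maps_a)
  cb <- contrast(maps_b)
  test <- voxel_permutation_test(ca, cb, n_perm = n_perm, seed = seed,
                                 tails = tails, alpha = alpha,
                                 neighbors = neighbors, hm = hm)
  list(contrast_a = ca, contrast_b = cb, test = test)
}
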