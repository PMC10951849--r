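## Source analysis: band-limited Fourier coefficients of the regulation and
## baseline segments, the eLORETA inverse operator, baseline-ratio theta
## source power, and voxel-wise permutation inference.

#' Hanning-tapered band Fourier coefficients of an epoch segment
#'
#' Cuts the regulation (1-5 s) or baseline (-4.2 to -3.2 s) segment from each
#' trial, applies a Hanning taper over the segment, zero-pads to a common
#' 4-s equivalent length (so both segments share the same frequency grid)
#' and returns the complex coefficients at the requested band bins.
#' Coefficients are scaled so that |coef|^2 is the one-sided power spectral
#' density (microvolt^2/Hz); spectral density is invariant to the segment
#' length for stationary signals, which makes regulation/baseline power
#' ratios well calibrated.
#'
#' @param epochs eeg_epochs (normally ERP-subtracted)
#' @param segment "regulation" or "baseline", or a length-2 numeric window
#' @param band frequency band in Hz (default theta, 3.5-8.5)
#' @param bin_step frequency step of the output grid (0.5 Hz)
#' @param pad_s common zero-padded length in seconds (4)
#' @return object of class `band_spectra`: `coef` is a complex array
#'   channels x bins x trials, plus `bins`, `segment`, `condition`
#' @export
band_fourier <- function(epochs, segment = c("regulation", "baseline"),
                         band = c(3.5, 8.5), bin_step = 0.5, pad_s = 4) {
  if (is.character(segment)) {
    segment <- match.arg(segment)
    win <- switch(segment, regulation = c(1, 5), baseline = c(-4.2, -3.2))
    seg_label <- segment
  } else {
    win <- segment
    seg_label <- paste0("window[", win[1], ",", win[2], "]")
  }
  sf <- epochs$sfreq
  sel <- epochs$times >= win[1] - 1e-9 & epochs$times < win[2] - 1e-9
  L <- sum(sel)
  if (L < 2) stop("segment window not covered by the epoch")
  Lpad <- round(pad_s * sf)
  if (L > Lpad) stop("segment longer than the zero-padded length")
  df <- sf / Lpad
  bins <- seq(band[1], band[2], by = bin_step)
  bi <- bins / df
  if (max(abs(bi - round(bi))) > 1e-9)
    stop("band bins not on the padded frequency grid (step ", df, " Hz)")
  bi <- round(bi) + 1L
  if (max(bins) > sf / 2) stop("band exceeds Nyquist")

  d <- epochs$data
  nch <- dim(d)[1]; ntr <- dim(d)[3]
  taper <- hanning_taper(L)
  # PSD scaling: |coef|^2 = 2 |X|^2 / (fs * sum(taper^2))
  scale <- sqrt(2 / (sf * sum(taper^2)))
  seg <- matrix(aperm(d[, sel, , drop = FALSE], c(2, 1, 3)), nrow = L)
  seg <- seg * taper
  padded <- rbind(seg, matrix(0, Lpad - L, ncol(seg)))
  co <- mvfft(padded)[bi, , drop = FALSE] * scale
  co <- array(co, dim = c(length(bins), nch, ntr))
  co <- aperm(co, c(2, 1, 3))
  x <- list(coef = co, bins = bins, segment = seg_label,
            channel_labels = epochs$montage$label,
            condition = epochs$condition)
  class(x) <- "band_spectra"
  x
}

#' @export
print.band_spectra <- function(x, ...) {
  d <- dim(x$coef)
  cat("<band_spectra> ", d[1], " ch x ", d[2], " bins (", min(x$bins), "-",
      max(x$bins), " Hz) x ", d[3], " trials, segment ", x$segment, "\n",
      sep = "")
  invisible(x)
}

#' eLORETA inverse operator
#'
#' Iterative weighted minimum-norm solution: per-voxel 3 x 3 weights are
#' updated to the matrix square root of the voxel's projected resolution
#' block, W_v = (K_v' M K_v)^(1/2) with
#' M = pinv(sum_v K_v W_v^{-1} K_v' + alpha * I) on the average-reference
#' subspace, iterated to a fixed point. This weighting gives the
#' characteristic property of exact (zero-error) localisation of point
#' sources in noiseless data as alpha -> 0.
#'
#' @param lf leadfield (average-referenced)
#' @param alpha_reg Tikhonov regularisation as a fraction of the mean
#'   sensor-space trace (default 0.05; use ~0 for noiseless data)
#' @param tol fixed-point tolerance on the relative weight change (1e-6)
#' @param max_iter iteration cap (100)
#' @return object of class `inverse_operator`: `T` is a (3 V) x channels
#'   matrix of spatial filters (voxel-major rows), plus `convergence`
#' @export
eloreta_inverse <- function(lf, alpha_reg = 0.05, tol = 1e-6, max_iter = 100) {
  K <- leadfield_matrix(lf)              # ch x 3V
  nch <- nrow(K); nv <- ncol(K) / 3L
  H <- diag(nch) - 1 / nch               # average-reference projector
  K <- H %*% K
  Winv <- rep(list(diag(3)), nv)         # start from identity weights
  rel_change <- Inf
  iters <- 0L
  W_old <- NULL
  for (it in seq_len(max_iter)) {
    iters <- it
    # C = sum_v K_v W_v^-1 K_v'
    B <- matrix(0, 3L * nv, nch)
    for (v in seq_len(nv)) {
      idx <- (3 * (v - 1) + 1):(3 * v)
      B[idx, ] <- Winv[[v]] %*% t(K[, idx, drop = FALSE])
    }
    C <- K %*% B
    reg <- alpha_reg * sum(diag(C)) / nch
    M <- pinv_sym(H %*% (C + reg * diag(nch)) %*% H)
    W_new <- vector("list", nv)
    for (v in seq_len(nv)) {
      idx <- (3 * (v - 1) + 1):(3 * v)
      Kv <- K[, idx, drop = FALSE]
      W_new[[v]] <- sqrtm_psd(t(Kv) %*% M %*% Kv)
    }
    if (!is.null(W_old)) {
      num <- sum(vapply(seq_len(nv), function(v)
        sum((W_new[[v]] - W_old[[v]])^2), numeric(1)))
      den <- sum(vapply(W_new, function(w) sum(w^2), numeric(1)))
      rel_change <- sqrt(num / den)
    }
    W_old <- W_new
    Winv <- lapply(W_new, function(w) pinv_sym(w))
    if (rel_change < tol) break
  }
  if (rel_change >= tol)
    stop("eLORETA did not converge: relative change ", signif(rel_change, 3),
         " after ", iters, " iterations")
  # final M with the converged weights
  B <- matrix(0, 3L * nv, nch)
  for (v in seq_len(nv)) {
    idx <- (3 * (v - 1) + 1):(3 * v)
    B[idx, ] <- Winv[[v]] %*% t(K[, idx, drop = FALSE])
  }
  C <- K %*% B
  reg <- alpha_reg * sum(diag(C)) / nch
  M <- pinv_sym(H %*% (C + reg * diag(nch)) %*% H)
  Tmat <- B %*% M                         # 3V x ch spatial filters
  op <- list(T = Tmat, n_voxels = nv, alpha_reg = alpha_reg,
             convergence = list(iterations = iters, rel_change = rel_change),
             head_model = lf$head_model)
  class(op) <- "inverse_operator"
  op
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat("<inverse_operator> eLORETA, ", x$n_voxels, " voxels, alpha = ",
      x$alpha_reg, ", converged in ", x$convergence$iterations,
      " iterations (rel change ", signif(x$convergence$rel_change, 3), ")\n",
      sep = "")
  invisible(x)
}

#' Apply an inverse operator to band spectra
#'
#' @param op inverse_operator
#' @param spectra band_spectra (channels must match)
#' @return complex array (3 V) x bins x trials of source coefficients
#' @export
source_coefficients <- function(op, spectra) {
  d <- dim(spectra$coef)
  if (d[1] != ncol(op$T)) stop("channel count mismatch between operator and spectra")
  co <- matrix(spectra$coef, nrow = d[1])      # ch x (bins*trials)
  sc <- op$T %*% co                            # 3V x (bins*trials)
  array(sc, dim = c(nrow(op$T), d[2], d[3]))
}

#' Per-voxel band source power
#'
#' Squared norm of the 3-D source coefficient, averaged over trials and
#' summed over the band bins.
#'
#' @param op inverse_operator
#' @param spectra band_spectra
#' @return numeric vector, one power value per voxel
#' @export
source_band_power <- function(op, spectra) {
  sc <- source_coefficients(op, spectra)
  p <- Mod(sc)^2
  pv <- rowMeans(matrix(p, nrow = dim(p)[1]))  # mean over bins*trials
  pv <- pv * dim(p)[2]                         # sum over bins, mean over trials
  colSums(matrix(pv, nrow = 3L))               # collapse the 3 orientations
}

#' Regulation/baseline power-ratio contrast
#'
#' Per voxel: ratio = regulation power / baseline power within each
#' condition; the contrast is ratio(reappraise) - ratio(maintain).
#'
#' @param power_reg_reapp,power_base_reapp per-voxel power for the
#'   reappraisal condition (regulation and baseline segments)
#' @param power_reg_maint,power_base_maint same for the maintenance condition
#' @return list: `ratio_reappraise`, `ratio_maintain`, `contrast`
#' @export
power_ratio_contrast <- function(power_reg_reapp, power_base_reapp,
                                 power_reg_maint, power_base_maint) {
  check_base <- function(p, lab) {
    bad <- which(p <= 0)
    if (length(bad))
      stop("non-positive baseline power at voxel ", bad[1], " (", lab, ")")
  }
  check_base(power_base_reapp, "reappraise")
  check_base(power_base_maint, "maintain")
  rr <- power_reg_reapp / power_base_reapp
  rm_ <- power_reg_maint / power_base_maint
  list(ratio_reappraise = rr, ratio_maintain = rm_, contrast = rr - rm_)
}

#' Voxel-wise permutation test of a group difference
#'
#' Permutation distribution of the per-voxel group mean difference under
#' random relabelling; per-voxel p-values use the add-one rule
#' (b + 1)/(N + 1). No multiple-comparison correction is applied at voxel
#' level (recorded in the output metadata); significant voxels are grouped
#' into contiguous clusters on the source grid.
#'
#' @param values_a,values_b matrices participants x voxels
#' @param n_perm number of permutations (>= 100)
#' @param seed RNG seed
#' @param tails "two" (default) or "one" (tests mean(a) > mean(b))
#' @param alpha significance level for flagging voxels
#' @param neighbors optional voxel adjacency list (from [voxel_neighbors()])
#'   for cluster grouping
#' @param hm optional head model supplying neighbours/centroids
#' @return object of class `voxel_stat_map`: `difference`, `p_value`,
#'   `significant`, `clusters` (members, size, centroid if positions known),
#'   metadata
#' @export
voxel_permutation_test <- function(values_a, values_b, n_perm = 10000,
                                   seed = 1, tails = c("two", "one"),
                                   alpha = 0.05, neighbors = NULL, hm = NULL) {
  tails <- match.arg(tails)
  if (n_perm < 100) stop("n_perm must be >= 100")
  a <- as.matrix(values_a); b <- as.matrix(values_b)
  stopifnot(ncol(a) == ncol(b))
  na <- nrow(a); nb <- nrow(b)
  if (na < 2 || nb < 2) stop("need >= 2 participants per group")
  X <- rbind(a, b)
  obs <- colMeans(a) - colMeans(b)

  set.seed(seed)
  n <- na + nb
  P <- matrix(0, n_perm, n)
  for (i in seq_len(n_perm)) P[i, sample.int(n, na)] <- 1
  S1 <- P %*% X
  tot <- matrix(colSums(X), n_perm, ncol(X), byrow = TRUE)
  null_diff <- S1 / na - (tot - S1) / nb      # n_perm x voxels

  # tolerance guards exact ties (identity relabelling) against rounding
  # differences between the vectorised and the direct mean computation
  tol <- 1e-9 * max(abs(obs)) + 1e-300
  if (tails == "two") {
    exceed <- colSums(abs(null_diff) >= matrix(abs(obs) - tol, n_perm, ncol(X),
                                               byrow = TRUE))
  } else {
    exceed <- colSums(null_diff >= matrix(obs - tol, n_perm, ncol(X),
                                          byrow = TRUE))
  }
  p <- (exceed + 1) / (n_perm + 1)
  sig <- p < alpha

  clusters <- list()
  if (any(sig)) {
    if (is.null(neighbors) && !is.null(hm)) neighbors <- voxel_neighbors(hm)
    if (!is.null(neighbors)) {
      comps <- graph_components(which(sig), neighbors)
      clusters <- lapply(comps, function(cm) {
        cl <- list(members = cm, size = length(cm),
                   mean_difference = mean(obs[cm]))
        if (!is.null(hm)) {
          cl$centroid_mm <- colMeans(hm$voxel_mm[cm, , drop = FALSE])
        }
        cl
      })
      clusters <- clusters[order(-vapply(clusters, `[[`, numeric(1), "size"))]
    } else {
      clusters <- list(list(members = which(sig), size = sum(sig),
                            mean_difference = mean(obs[sig])))
    }
  }
  res <- list(difference = obs, p_value = p, significant = sig,
              clusters = clusters, tails = tails, alpha = alpha,
              n_permutations = n_perm, seed = seed,
              correction = "none (per-voxel permutation p-values)")
  class(res) <- "voxel_stat_map"
  res
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  cat("<voxel_stat_map> ", length(x$difference), " voxels, ",
      sum(x$significant), " significant (", x$tails, "-sided, alpha ",
      x$alpha, ", ", x$correction, ")\n", sep = "")
  for (cl in head(x$clusters, 5)) {
    cat("  cluster of ", cl$size, " voxel(s), mean diff ",
        signif(cl$mean_difference, 3), sep = "")
    if (!is.null(cl$centroid_mm))
      cat(sprintf(", centroid (%.0f, %.0f, %.0f) mm", cl$centroid_mm[1],
                  cl$centroid_mm[2], cl$centroid_mm[3]))
    cat("\n")
  }
  invisible(x)
}
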