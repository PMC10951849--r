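## Preprocessing chain: segment -> filter -> interpolate -> reject ->
## re-reference -> ICA. Each stage stamps a provenance flag so the order can
## be checked downstream.

#' Segment a continuous recording into 13-s epochs
#'
#' Cuts one epoch per instruction marker, spanning `epoch_span` seconds
#' around the marker sample (t = 0 at the instruction). Markers too close to
#' the recording edge are dropped with a warning.
#'
#' @param rec [eeg_continuous()]
#' @param marker_map named character vector mapping marker string ->
#'   condition label, e.g. `c("S 11" = "neutral", "S 12" = "maintain",
#'   "S 13" = "reappraise")`
#' @param epoch_span seconds around the instruction (default c(-6, 7))
#' @param montage optional montage data.frame; default the standard 64-channel
#'   cap matched by channel label
#' @return [eeg_epochs()]
#' @export
segment_epochs <- function(rec, marker_map = c("S 11" = "neutral",
                                               "S 12" = "maintain",
                                               "S 13" = "reappraise"),
                           epoch_span = c(-6, 7), montage = NULL) {
  ev <- rec$events[rec$events$marker %in% names(marker_map), , drop = FALSE]
  if (!nrow(ev)) stop("no instruction markers found in the recording")
  sf <- rec$sfreq
  pre <- round(-epoch_span[1] * sf)
  post <- round(epoch_span[2] * sf)
  nsamp <- ncol(rec$data)
  ok <- ev$sample - pre >= 1 & ev$sample + post <= nsamp
  if (any(!ok))
    warning(sum(!ok), " trial(s) dropped: epoch window exceeds the recording")
  ev <- ev[ok, , drop = FALSE]
  if (!nrow(ev)) stop("no complete epochs after edge trimming")

  nt <- pre + post + 1L
  nch <- nrow(rec$data)
  data <- array(0, dim = c(nch, nt, nrow(ev)))
  for (k in seq_len(nrow(ev)))
    data[, , k] <- rec$data[, (ev$sample[k] - pre):(ev$sample[k] + post)]
  times <- seq(epoch_span[1], epoch_span[2], by = 1 / sf)[seq_len(nt)]

  if (is.null(montage)) {
    std <- standard_montage_64()
    m <- match(rec$channel_labels, std$label)
    if (anyNA(m)) stop("channels not in the standard montage: ",
                       paste(rec$channel_labels[is.na(m)], collapse = ", "))
    montage <- std[m, , drop = FALSE]
  }
  eeg_epochs(data, times, sf, unname(marker_map[ev$marker]), montage,
             provenance = "segmented")
}

## linear detrend + demean, vectorised over rows of a ch x time matrix
detrend_rows <- function(x) {
  nt <- ncol(x)
  tc <- seq_len(nt) - (nt + 1) / 2
  ss <- sum(tc^2)
  slope <- (x %*% tc) / ss
  x <- x - outer(as.numeric(slope), tc)
  x - rowMeans(x)
}

#' Filter epochs (low-pass, high-pass, line-noise stop), detrend, demean
#'
#' Zero-phase (forward-backward) 4th-order Butterworth filtering applied per
#' trial and channel: low-pass at `lp` Hz (clipped below Nyquist with a
#' warning if needed), high-pass at `hp` Hz, band-stop at `stop_band` Hz
#' (skipped with a warning when the band reaches Nyquist), followed by
#' linear detrending and mean removal.
#'
#' @param epochs eeg_epochs
#' @param lp,hp low-/high-pass corner frequencies in Hz
#' @param stop_band length-2 band-stop interval in Hz (line noise)
#' @param order Butterworth order per pass
#' @return filtered eeg_epochs (provenance flag `filtered`)
#' @export
filter_epochs <- function(epochs, lp = 100, hp = 0.3, stop_band = c(48, 52),
                          order = 4) {
  if (!all(is.finite(epochs$data))) stop("non-finite values in the input data")
  sf <- epochs$sfreq
  nyq <- sf / 2
  if (lp >= nyq) {
    lp_eff <- 0.9 * nyq
    warning("low-pass ", lp, " Hz at or above Nyquist (", nyq,
            " Hz); clipped to ", lp_eff, " Hz")
    lp <- lp_eff
  }
  flt <- list(signal::butter(order, lp / nyq, type = "low"),
              signal::butter(order, hp / nyq, type = "high"))
  if (max(stop_band) < nyq) {
    flt <- c(flt, list(signal::butter(order, stop_band / nyq, type = "stop")))
  } else {
    warning("band-stop ", paste(stop_band, collapse = "-"),
            " Hz reaches Nyquist; skipped")
  }
  d <- epochs$data
  nch <- dim(d)[1]
  for (k in seq_len(dim(d)[3])) {
    x <- d[, , k]
    for (f in flt)
      x <- t(apply(x, 1, function(row) signal::filtfilt(f, row)))
    d[, , k] <- detrend_rows(x)
  }
  out <- epochs
  out$data <- d
  add_stage(out, "filtered")
}

## Perrin-style spherical-spline interpolation matrix (m = 4, 50 terms)
spline_g <- function(cosang, m = 4, nterms = 50) {
  out <- array(0, dim = dim(as.matrix(cosang)))
  x <- as.matrix(cosang)
  Pprev <- matrix(1, nrow(x), ncol(x)) # P0
  Pcur <- x                            # P1
  for (n in 1:nterms) {
    out <- out + (2 * n + 1) / (n^m * (n + 1)^m) * Pcur
    Pnext <- ((2 * n + 1) * x * Pcur - n * Pprev) / (n + 1)
    Pprev <- Pcur
    Pcur <- Pnext
  }
  out / (4 * pi)
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces the signals of `bad_channels` with a spherical-spline
#' reconstruction from the remaining channels (order m = 4).
#'
#' @param epochs eeg_epochs
#' @param bad_channels character vector of channel labels (duplicates are
#'   deduplicated)
#' @param lambda ridge regularisation added to the spline system
#' @return eeg_epochs with the bad channels replaced (flag `interpolated`)
#' @export
interpolate_channels <- function(epochs, bad_channels, lambda = 1e-5) {
  bad_channels <- unique(bad_channels)
  if (!length(bad_channels)) return(add_stage(epochs, "interpolated"))
  labels <- epochs$montage$label
  bad <- match(bad_channels, labels)
  if (anyNA(bad)) stop("unknown channel(s): ",
                       paste(bad_channels[is.na(bad)], collapse = ", "))
  good <- setdiff(seq_along(labels), bad)
  if (length(good) < 4) stop("need at least 4 good channels to interpolate")

  pos <- as.matrix(epochs$montage[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  Ggg <- spline_g(pos[good, ] %*% t(pos[good, ]))
  Gbg <- spline_g(pos[bad, , drop = FALSE] %*% t(pos[good, ]))
  ng <- length(good)
  A <- rbind(cbind(Ggg + lambda * diag(ng), rep(1, ng)),
             c(rep(1, ng), 0))
  d <- epochs$data
  nt <- dim(d)[2]; ntr <- dim(d)[3]
  Xg <- matrix(d[good, , ], nrow = ng)           # good x (time*trial)
  sol <- solve(A, rbind(Xg, 0))
  Xb <- Gbg %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], length(bad), ncol(Xg), byrow = TRUE)
  d[bad, , ] <- array(Xb, dim = c(length(bad), nt, ntr))
  out <- epochs
  out$data <- d
  add_stage(out, "interpolated")
}

#' Reject artifact trials by amplitude and high-frequency variance z-scores
#'
#' A trial is rejected when the z-score (across trials) of its maximum
#' absolute amplitude or of its high-frequency (> `hf_cutoff` Hz) power
#' exceeds `z_threshold`. Deterministic replacement for interactive
#' inspection.
#'
#' @param epochs eeg_epochs (>= 2 trials)
#' @param z_threshold rejection threshold in z units (default 4; Inf keeps
#'   everything)
#' @param hf_cutoff high-frequency cutoff in Hz (default 30)
#' @return list: `epochs` (surviving trials, samples untouched) and `log`
#'   (per-trial metrics, rejected indices, per-condition surviving counts)
#' @export
reject_artifact_trials <- function(epochs, z_threshold = 4, hf_cutoff = 30) {
  d <- epochs$data
  ntr <- dim(d)[3]
  if (ntr < 2) stop("need at least 2 trials")
  nt <- dim(d)[2]
  sf <- epochs$sfreq
  freqs <- (seq_len(nt) - 1) / nt * sf
  hf <- freqs > hf_cutoff & freqs <= sf / 2

  peak <- numeric(ntr); hfpow <- numeric(ntr)
  for (k in seq_len(ntr)) {
    x <- d[, , k]
    peak[k] <- max(abs(x))
    if (any(hf)) {
      spec <- mvfft(t(x))            # time x ch
      hfpow[k] <- mean(Mod(spec[hf, ])^2)
    }
  }
  zs <- function(v) if (sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / sd(v)
  bad <- zs(peak) > z_threshold | zs(hfpow) > z_threshold
  if (all(bad))
    stop("all trials rejected; raise z_threshold or inspect the recording")
  keep <- which(!bad)
  out <- subset_trials(epochs, keep)
  out <- add_stage(out, "artifact_rejected")
  log <- list(n_total = ntr, rejected = which(bad),
              peak = peak, hf_power = hfpow,
              z_threshold = z_threshold,
              surviving_by_condition = table(out$condition))
  list(epochs = out, log = log)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous channel mean at every sample; idempotent.
#'
#' @param epochs eeg_epochs
#' @return eeg_epochs (flag `rereferenced`)
#' @export
rereference_common_average <- function(epochs) {
  d <- epochs$data
  if (dim(d)[1] < 2) stop("need at least 2 channels")
  means <- colMeans(d)                       # time x trials
  d <- sweep(d, c(2, 3), means, "-")
  out <- epochs
  out$data <- d
  add_stage(out, "rereferenced")
}

## compact FastICA: symmetric decorrelation, tanh nonlinearity
fast_ica <- function(X, n_comp, seed = 1, max_iter = 200, tol = 1e-6) {
  # X: ch x T, rows centred by caller
  ch <- nrow(X); T <- ncol(X)
  cv <- tcrossprod(X) / T
  e <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_comp)
  K <- t(e$vectors[, keep]) / sqrt(e$values[keep])   # k x ch whitening
  Z <- K %*% X
  set.seed(seed)
  W <- matrix(rnorm(n_comp^2), n_comp)
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Wn <- (G %*% t(Z)) / T - diag(rowMeans(1 - G^2)) %*% W
    Wn <- sym_decor(Wn)
    delta <- max(abs(abs(diag(Wn %*% t(W))) - 1))
    W <- Wn
    if (delta < tol) break
  }
  if (!all(is.finite(W)))
    stop("ICA decomposition failed (non-finite unmixing matrix); ",
         "try fewer components")
  if (delta >= 1e-3)
    warning("ICA reached the iteration cap before full convergence ",
            "(delta = ", signif(delta, 3), "); components dominated by ",
            "Gaussian background may be unstable")
  S <- W %*% Z                                        # k x T sources
  A <- e$vectors[, keep] %*% (diag(sqrt(e$values[keep])) %*% t(W)) # ch x k mixing
  list(S = S, A = A, W = W, K = K, iterations = it)
}

#' Remove ocular components by ICA
#'
#' Runs ICA on trial-appended data and subtracts the contribution of every
#' component whose time course correlates with the ocular proxy (mean of the
#' frontopolar channels) above `r_threshold` in absolute value. Only the
#' identified components' contributions are removed, so the operation is the
#' identity when nothing crosses the threshold.
#'
#' @param epochs eeg_epochs
#' @param eog_proxy_channels channels serving as ocular proxy (default
#'   Fp1/Fp2)
#' @param r_threshold absolute correlation threshold (default 0.7)
#' @param n_components number of ICA components (default min(20, channels))
#' @param seed RNG seed for the ICA initialisation
#' @return list: `epochs` (cleaned, flag `ica_cleaned`), `removed` (component
#'   indices), `correlations`
#' @export
remove_ocular_components <- function(epochs, eog_proxy_channels = c("Fp1", "Fp2"),
                                     r_threshold = 0.7, n_components = NULL,
                                     seed = 1) {
  labels <- epochs$montage$label
  proxy_idx <- match(eog_proxy_channels, labels)
  if (anyNA(proxy_idx)) stop("proxy channel(s) not present: ",
                             paste(eog_proxy_channels[is.na(proxy_idx)],
                                   collapse = ", "))
  d <- epochs$data
  nch <- dim(d)[1]; nt <- dim(d)[2]; ntr <- dim(d)[3]
  n_comp <- n_components %||% min(20L, nch)
  X <- matrix(d, nrow = nch)                  # appended trials
  mu <- rowMeans(X)
  Xc <- X - mu
  ica <- fast_ica(Xc, n_comp, seed = seed)
  proxy <- colMeans(X[proxy_idx, , drop = FALSE])
  r <- as.numeric(cor(t(ica$S), proxy))
  removed <- which(abs(r) > r_threshold)
  if (length(removed)) {
    Xc <- Xc - ica$A[, removed, drop = FALSE] %*% ica$S[removed, , drop = FALSE]
  }
  out <- epochs
  out$data <- array(Xc + mu, dim = dim(d))
  out <- add_stage(out, "ica_cleaned")
  list(epochs = out, removed = removed, correlations = r)
}
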