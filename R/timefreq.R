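## Induced time-frequency analysis.
##
## Induced activity is isolated by subtracting each condition's trial-average
## (the evoked potential, time-locked to the instruction) from that
## condition's single trials. Power is then computed with a sliding 2-s
## Hanning window (50-ms slide) at 1-30 Hz in 0.5-Hz steps; a 2-s window
## makes the 0.5-Hz grid coincide with the DFT bins at any integer sampling
## rate. Amplitude normalisation: a sinusoid of amplitude A yields power
## A^2/2 (its variance) at its bin, in microvolt^2.

#' Subtract the per-condition evoked potential
#'
#' For each condition the across-trial mean waveform is subtracted from each
#' of that condition's trials, leaving induced (non-phase-locked) residuals.
#'
#' @param epochs eeg_epochs
#' @return eeg_epochs of induced residuals (per-condition trial means are 0)
#' @export
subtract_erp <- function(epochs) {
  d <- epochs$data
  for (cond in unique(epochs$condition)) {
    idx <- which(epochs$condition == cond)
    if (length(idx) < 2)
      stop("condition '", cond, "' has fewer than 2 trials")
    erp <- rowMeans(d[, , idx, drop = FALSE], dims = 2)
    for (k in idx) d[, , k] <- d[, , k] - erp
  }
  out <- epochs
  out$data <- d
  add_stage(out, "erp_subtracted")
}

#' Time-frequency representation container
#' @keywords internal
new_tfr <- function(power, freqs, times, baseline_state, label, channel_labels) {
  x <- list(power = power, freqs = freqs, times = times,
            baseline_state = baseline_state, label = label,
            channel_labels = channel_labels)
  class(x) <- "eeg_tfr"
  x
}

#' @export
print.eeg_tfr <- function(x, ...) {
  d <- dim(x$power)
  cat("<eeg_tfr> ", d[1], " ch x ", d[2], " freqs (", min(x$freqs), "-",
      max(x$freqs), " Hz) x ", d[3], " times, baseline ", x$baseline_state,
      if (nzchar(x$label)) paste0(", '", x$label, "'") else "", "\n", sep = "")
  invisible(x)
}

#' Sliding Hanning-window induced power
#'
#' Squared magnitude of the Hanning-tapered Fourier coefficient in a window
#' of `window_s` seconds centred at each output time (window \[t-1, t+1\]
#' for the default 2-s length), computed per trial and then averaged within
#' condition.
#'
#' @param epochs eeg_epochs (normally ERP-subtracted)
#' @param window_s taper length in seconds (2)
#' @param slide_s slide between window centres in seconds (0.05)
#' @param freqs analysis frequencies in Hz (1-30 in 0.5 steps); must lie on
#'   the window's DFT grid and below Nyquist
#' @param tmin,tmax restrict output window centres (defaults: full range
#'   admitting a complete window)
#' @param centre_times optional explicit vector of window-centre times
#'   (possibly non-contiguous, e.g. baseline plus regulation windows only);
#'   overrides tmin/tmax/slide_s
#' @return named list of `eeg_tfr`, one per condition present
#' @export
tfr_hanning <- function(epochs, window_s = 2.0, slide_s = 0.05,
                        freqs = seq(1, 30, by = 0.5),
                        tmin = NULL, tmax = NULL, centre_times = NULL) {
  sf <- epochs$sfreq
  L <- round(window_s * sf)
  nt <- length(epochs$times)
  if (L > nt) stop("epoch shorter than one analysis window")
  if (max(freqs) > sf / 2) stop("frequency above Nyquist (", sf / 2, " Hz)")
  df <- sf / L
  bin <- freqs / df
  if (max(abs(bin - round(bin))) > 1e-9)
    stop("requested frequencies not on the window DFT grid (step ", df, " Hz)")
  bin <- round(bin) + 1L

  half <- (L - 1) / 2
  lo <- epochs$times[1] + half / sf
  hi <- epochs$times[nt] - half / sf
  if (is.null(centre_times)) {
    tmin <- max(tmin %||% lo, lo)
    tmax <- min(tmax %||% hi, hi)
    centres <- seq(tmin, tmax, by = slide_s)
  } else {
    centres <- sort(centre_times)
    if (any(centres < lo - 1e-9) || any(centres > hi + 1e-9))
      stop("centre_times leave incomplete analysis windows")
  }
  cidx <- round((centres - epochs$times[1]) * sf) + 1L

  taper <- hanning_taper(L)
  norm <- 2 / sum(taper)
  nch <- dim(epochs$data)[1]
  ntr <- dim(epochs$data)[3]
  offs <- seq_len(L) - 1L - floor(half)

  conds <- unique(epochs$condition)
  pow <- lapply(conds, function(cd)
    array(0, dim = c(nch, length(freqs), length(centres))))
  names(pow) <- conds
  cond_idx <- lapply(conds, function(cd) which(epochs$condition == cd))
  names(cond_idx) <- conds

  # one transpose up front: time x (channel * trial)
  td <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = nt)
  for (w in seq_along(centres)) {
    seg <- td[cidx[w] + offs, , drop = FALSE]                    # L x (ch*tr)
    co <- mvfft(seg * taper)[bin, , drop = FALSE] * norm
    pw <- array(Mod(co)^2 / 2, dim = c(length(freqs), nch, ntr)) # A^2/2 for a tone
    for (cd in conds) {
      idx <- cond_idx[[cd]]
      m <- rowMeans(pw[, , idx, drop = FALSE], dims = 2)         # freq x ch
      pow[[cd]][, , w] <- t(m)
    }
  }
  lapply(conds, function(cd)
    new_tfr(pow[[cd]], freqs, centres, "raw", cd,
            epochs$montage$label)) |> setNames(conds)
}

#' Baseline-subtract a TFR
#'
#' Per channel and frequency, subtracts the mean power over the baseline
#' window (1.2-0.2 s before picture onset, i.e. \[-4.2, -3.2\] s on the
#' instruction-referenced axis) from every time point.
#'
#' @param tfr eeg_tfr
#' @param baseline length-2 window in seconds
#' @return eeg_tfr with `baseline_state = "subtracted"`
#' @export
baseline_subtract <- function(tfr, baseline = c(-4.2, -3.2)) {
  sel <- tfr$times >= baseline[1] & tfr$times <= baseline[2]
  if (!any(sel)) stop("baseline window not covered by TFR times")
  base <- apply(tfr$power[, , sel, drop = FALSE], c(1, 2), mean)
  out <- tfr
  out$power <- tfr$power - as.vector(base) # recycles over the time dimension
  out$baseline_state <- "subtracted"
  out
}

#' Regulation contrast between two TFRs
#'
#' Element-wise reappraisal-minus-maintenance difference.
#' @param tfr_reappraise,tfr_maintain eeg_tfr with matching axes
#' @return eeg_tfr labelled "reappraisal-maintenance"
#' @export
regulation_contrast <- function(tfr_reappraise, tfr_maintain) {
  if (!isTRUE(all.equal(tfr_reappraise$freqs, tfr_maintain$freqs)) ||
      !isTRUE(all.equal(tfr_reappraise$times, tfr_maintain$times)))
    stop("TFR axes do not match")
  if (tfr_reappraise$baseline_state != tfr_maintain$baseline_state)
    stop("TFR baseline states do not match")
  out <- tfr_reappraise
  out$power <- tfr_reappraise$power - tfr_maintain$power
  out$label <- "reappraisal-maintenance"
  out
}

#' Theta-band regulation summary per channel
#'
#' Mean power over the theta band (3.5-8.5 Hz) and the post-instruction
#' regulation window (1-5 s), one value per channel.
#'
#' @param tfr eeg_tfr (normally the baseline-subtracted contrast)
#' @param band,window frequency band (Hz) and time window (s)
#' @return named numeric vector, one value per channel
#' @export
theta_summary <- function(tfr, band = c(3.5, 8.5), window = c(1, 5)) {
  fs <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  ts <- tfr$times >= window[1] & tfr$times <= window[2]
  if (!any(fs) || !any(ts)) stop("band/window not covered by the TFR")
  val <- apply(tfr$power[, fs, ts, drop = FALSE], 1, mean)
  names(val) <- tfr$channel_labels
  val
}
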