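## Per-participant derived measures: sensor theta summaries, source power
## ratio contrasts, and MIM connectivity maps.

#' Sensor-level regulation-associated theta summary for one participant
#'
#' Chain: ERP subtraction -> sliding Hanning TFR (theta band) -> baseline
#' subtraction -> reappraisal-minus-maintenance contrast -> mean over the
#' theta band and regulation window, per channel.
#'
#' @param epochs eeg_epochs with maintain and reappraise trials
#' @param slide_s TFR slide in seconds (0.05 matches the full analysis;
#'   coarser values trade temporal sampling of the summary box for speed)
#' @param band,window theta band (Hz) and regulation window (s)
#' @param baseline baseline window (s)
#' @return named numeric vector, one value per channel
#' @export
participant_theta_summary <- function(epochs, slide_s = 0.05,
                                      band = c(3.5, 8.5), window = c(1, 5),
                                      baseline = c(-4.2, -3.2)) {
  ind <- subtract_erp(epochs)
  centres <- c(seq(baseline[1], baseline[2], by = slide_s),
               seq(window[1], window[2], by = slide_s))
  tf <- tfr_hanning(ind, freqs = seq(band[1], band[2], by = 0.5),
                    centre_times = centres)
  if (!all(c("maintain", "reappraise") %in% names(tf)))
    stop("both maintain and reappraise trials are required")
  ctr <- regulation_contrast(baseline_subtract(tf$reappraise, baseline),
                             baseline_subtract(tf$maintain, baseline))
  theta_summary(ctr, band = band, window = window)
}

#' Source power-ratio contrast for one participant
#'
#' Regulation/baseline theta power ratio per voxel and condition (eLORETA
#' source power of the Hanning-tapered segment spectra), contrasted
#' reappraise - maintain.
#'
#' @param epochs eeg_epochs
#' @param op inverse_operator
#' @return list: `contrast` (per-voxel), `ratio_reappraise`, `ratio_maintain`
#' @export
participant_source_contrast <- function(epochs, op) {
  ind <- subtract_erp(epochs)
  out <- list()
  pow <- list()
  for (cond in c("reappraise", "maintain")) {
    sub <- subset_trials(ind, ind$condition == cond)
    for (segm in c("regulation", "baseline")) {
      sp <- band_fourier(sub, segm)
      pow[[paste(cond, segm, sep = ".")]] <- source_band_power(op, sp)
    }
  }
  pr <- power_ratio_contrast(pow$reappraise.regulation, pow$reappraise.baseline,
                             pow$maintain.regulation, pow$maintain.baseline)
  pr
}

#' MIM voxel-to-whole-brain maps for one participant
#'
#' Theta-band MIM connectivity of the regulation segment, per condition.
#'
#' @param epochs eeg_epochs
#' @param op inverse_operator
#' @return list with per-voxel maps `reappraise` and `maintain`
#' @export
participant_mim_maps <- function(epochs, op) {
  ind <- subtract_erp(epochs)
  out <- list()
  for (cond in c("reappraise", "maintain")) {
    sub <- subset_trials(ind, ind$condition == cond)
    sp <- band_fourier(sub, "regulation")
    cs <- voxel_cross_spectrum(op, sp)
    out[[cond]] <- mim_voxel_to_whole_brain(cs)
  }
  out
}

#' Channels adjacent to a source voxel
#'
#' The k sensors closest (by angle) to the radial projection of a voxel,
#' used to judge whether a sensor cluster sits over a planted source.
#'
#' @param hm head model
#' @param voxel voxel index
#' @param k number of channels
#' @return integer channel indices
#' @export
effect_adjacent_channels <- function(hm, voxel, k = 6) {
  vdir <- hm$voxel_positions[voxel, ]
  vdir <- vdir / sqrt(sum(vdir^2))
  ang <- as.numeric(hm$channel_positions %*% vdir)
  order(-ang)[seq_len(k)]
}
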