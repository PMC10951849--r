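#' Epoched EEG container
#'
#' Channels x time x trials voltage array with a fixed time axis (t = 0 at
#' the onset of the regulation instruction), one condition label per trial,
#' the montage, and provenance flags recording which preprocessing stages
#' have been applied.
#'
#' @param data numeric array channels x time x trials (microvolts)
#' @param times numeric time axis in seconds, uniform step
#' @param sfreq sampling frequency (Hz)
#' @param condition character/factor, one label per trial
#'   (levels neutral/maintain/reappraise)
#' @param montage data.frame label/x/y/z for the rows of `data`
#' @param provenance character vector of applied stages
#' @return object of class `eeg_epochs`
#' @export
eeg_epochs <- function(data, times, sfreq, condition, montage,
                       provenance = character(0)) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[2] == length(times),
            dim(data)[3] == length(condition),
            dim(data)[1] == nrow(montage))
  dt <- diff(times)
  if (max(abs(dt - 1 / sfreq)) > 1e-9)
    stop("time axis must be uniform with step 1/sfreq")
  x <- list(data = data, times = times, sfreq = sfreq,
            condition = as.character(condition), montage = montage,
            provenance = provenance)
  class(x) <- "eeg_epochs"
  x
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> ", d[1], " ch x ", d[2], " samples x ", d[3], " trials @ ",
      x$sfreq, " Hz, t in [", min(x$times), ", ", max(x$times), "] s\n", sep = "")
  cat("  conditions:", paste(sprintf("%s=%d", names(table(x$condition)),
                                     table(x$condition)), collapse = " "), "\n")
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Subset trials of an epoched recording
#' @param epochs eeg_epochs
#' @param idx integer or logical trial selector
#' @return eeg_epochs
#' @export
subset_trials <- function(epochs, idx) {
  eeg_epochs(epochs$data[, , idx, drop = FALSE], epochs$times, epochs$sfreq,
             epochs$condition[idx], epochs$montage, epochs$provenance)
}

#' @keywords internal
has_stage <- function(epochs, stage) stage %in% epochs$provenance

## canonical preprocessing order; adding a stage after a later one warns
stage_order <- c("simulated", "segmented", "filtered", "interpolated",
                 "artifact_rejected", "rereferenced", "ica_cleaned",
                 "erp_subtracted")

#' @keywords internal
add_stage <- function(epochs, stage) {
  rank <- match(stage, stage_order)
  if (!is.na(rank)) {
    later <- intersect(epochs$provenance,
                       stage_order[seq_along(stage_order) > rank])
    later <- setdiff(later, "simulated")
    if (length(later))
      warning("stage '", stage, "' applied after ",
              paste(later, collapse = "/"),
              "; canonical order is ",
              paste(stage_order[-1], collapse = " -> "))
  }
  epochs$provenance <- c(epochs$provenance, stage)
  epochs
}

#' Continuous EEG container
#'
#' @param data channels x samples matrix (microvolts)
#' @param sfreq sampling frequency (Hz)
#' @param channel_labels character vector, one per row
#' @param events data.frame with columns `sample` (1-based index) and
#'   `marker` (string)
#' @return object of class `eeg_continuous`
#' @export
eeg_continuous <- function(data, sfreq, channel_labels,
                           events = data.frame(sample = integer(0),
                                               marker = character(0))) {
  stopifnot(sfreq > 0, nrow(data) == length(channel_labels))
  if (nrow(events) && (any(events$sample < 1) || any(events$sample > ncol(data))))
    stop("event sample indices outside the data range")
  x <- list(data = data, sfreq = sfreq, channel_labels = channel_labels,
            events = events)
  class(x) <- "eeg_continuous"
  x
}

#' @export
print.eeg_continuous <- function(x, ...) {
  cat("<eeg_continuous> ", nrow(x$data), " ch x ", ncol(x$data), " samples @ ",
      x$sfreq, " Hz, ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Concatenate epochs into a continuous recording with instruction markers
#'
#' Inverse of segmentation (up to the inter-trial gap): trials are laid out
#' back to back with `gap_s` seconds of zeros between them and an instruction
#' marker written at each trial's t = 0 sample.
#'
#' @param epochs eeg_epochs
#' @param gap_s gap between consecutive trials in seconds
#' @param marker_map named character vector mapping condition -> marker string
#' @return eeg_continuous
#' @export
epochs_to_continuous <- function(epochs, gap_s = 1,
                                 marker_map = c(neutral = "S 11",
                                                maintain = "S 12",
                                                reappraise = "S 13")) {
  d <- dim(epochs$data)
  nt <- d[2]; ntr <- d[3]
  gap <- round(gap_s * epochs$sfreq)
  total <- ntr * (nt + gap)
  out <- matrix(0, d[1], total)
  instr_off <- which.min(abs(epochs$times)) # sample of t = 0 within the epoch
  ev <- data.frame(sample = integer(ntr), marker = character(ntr))
  for (k in seq_len(ntr)) {
    start <- (k - 1) * (nt + gap)
    out[, start + seq_len(nt)] <- epochs$data[, , k]
    ev$sample[k] <- as.integer(start + instr_off)
    ev$marker[k] <- marker_map[[epochs$condition[k]]]
  }
  eeg_continuous(out, epochs$sfreq, epochs$montage$label, ev)
}
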