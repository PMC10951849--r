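## BrainVision (.vhdr/.vmrk/.eeg) reader and writer.
## Supported dialect: DataFormat=BINARY, DataOrientation=MULTIPLEXED,
## BinaryFormat INT_16 or IEEE_FLOAT_32 — the layout produced by BrainVision
## Recorder for a standard continuous recording.

parse_vhdr_sections <- function(lines) {
  sec <- NULL
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- character(0)
      next
    }
    if (!is.null(sec)) out[[sec]] <- c(out[[sec]], ln)
  }
  lapply(out, function(x) {
    kv <- strsplit(x, "=", fixed = TRUE)
    setNames(vapply(kv, function(p) paste(p[-1], collapse = "="), character(1)),
             vapply(kv, `[[`, character(1), 1))
  })
}

#' Read a BrainVision recording
#'
#' Parses the .vhdr header, the .vmrk marker file and the binary .eeg data
#' file. Voltages are scaled to microvolts using the per-channel resolution
#' field. Only the BINARY/MULTIPLEXED dialect with INT_16 or IEEE_FLOAT_32
#' samples is supported.
#'
#' @param header_path path to the .vhdr file
#' @return [eeg_continuous()] with events from Stimulus markers
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path)) stop("header file not found: ", header_path)
  lines <- readLines(header_path, warn = FALSE, encoding = "UTF-8")
  sec <- parse_vhdr_sections(lines)
  ci <- sec[["Common Infos"]]
  if (is.null(ci)) stop("malformed header (no [Common Infos]): ", header_path)
  if (!identical(toupper(ci[["DataFormat"]] %||% "BINARY"), "BINARY"))
    stop("unsupported DataFormat '", ci[["DataFormat"]], "' in ", header_path)
  if (!identical(toupper(ci[["DataOrientation"]] %||% "MULTIPLEXED"),
                 "MULTIPLEXED"))
    stop("unsupported DataOrientation '", ci[["DataOrientation"]], "'")
  nch <- as.integer(ci[["NumberOfChannels"]])
  sfreq <- 1e6 / as.numeric(ci[["SamplingInterval"]]) # header stores microseconds

  dir <- dirname(header_path)
  data_path <- file.path(dir, ci[["DataFile"]])
  marker_path <- if (!is.null(ci[["MarkerFile"]])) file.path(dir, ci[["MarkerFile"]]) else NULL
  if (!file.exists(data_path))
    stop("data file referenced by header not found: ", data_path)

  bi <- sec[["Binary Infos"]]
  fmt <- toupper(bi[["BinaryFormat"]] %||% "INT_16")
  if (!fmt %in% c("INT_16", "IEEE_FLOAT_32"))
    stop("unknown BinaryFormat '", fmt, "' in ", header_path)

  chinfo <- sec[["Channel Infos"]]
  labels <- character(nch)
  resolution <- rep(1, nch)
  for (i in seq_len(nch)) {
    entry <- chinfo[[paste0("Ch", i)]]
    if (is.null(entry)) stop("missing Ch", i, " entry in ", header_path)
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3]))
      resolution[i] <- as.numeric(parts[3])
  }

  sz <- file.size(data_path)
  bytes <- if (fmt == "INT_16") 2L else 4L
  if (sz %% (bytes * nch) != 0)
    stop("data length of ", data_path, " (", sz, " bytes) is not a multiple of ",
         nch, " channels x ", bytes, " bytes")
  nsamp <- sz / (bytes * nch)
  con <- file(data_path, "rb")
  on.exit(close(con))
  raw_vals <- if (fmt == "INT_16")
    readBin(con, "integer", n = nch * nsamp, size = 2, signed = TRUE,
            endian = "little")
  else
    readBin(con, "numeric", n = nch * nsamp, size = 4, endian = "little")
  data <- matrix(as.numeric(raw_vals), nrow = nch) * resolution

  events <- data.frame(sample = integer(0), marker = character(0))
  if (!is.null(marker_path) && file.exists(marker_path)) {
    msec <- parse_vhdr_sections(readLines(marker_path, warn = FALSE,
                                          encoding = "UTF-8"))
    mk <- msec[["Marker Infos"]]
    if (length(mk)) {
      rows <- lapply(mk, function(v) {
        p <- strsplit(v, ",", fixed = TRUE)[[1]]
        if (length(p) < 3 || !identical(p[1], "Stimulus")) return(NULL)
        data.frame(sample = as.integer(p[3]), marker = p[2])
      })
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (length(rows)) events <- do.call(rbind, rows)
      rownames(events) <- NULL
    }
  }
  eeg_continuous(data, sfreq, labels, events)
}

#' Write a continuous recording in BrainVision format
#'
#' Produces `<base>.vhdr`, `<base>.vmrk` and `<base>.eeg` (BINARY,
#' MULTIPLEXED). For INT_16 the voltages are quantised as
#' `round(microvolts / resolution)`.
#'
#' @param rec [eeg_continuous()]
#' @param base_path output path without extension
#' @param format "IEEE_FLOAT_32" (lossless for float data) or "INT_16"
#' @param resolution microvolts per bit for INT_16 (default 0.1)
#' @return invisibly, the .vhdr path
#' @export
write_brainvision <- function(rec, base_path, format = c("IEEE_FLOAT_32", "INT_16"),
                              resolution = 0.1) {
  format <- match.arg(format)
  base <- basename(base_path)
  nch <- nrow(rec$data)
  res <- if (format == "INT_16") resolution else 1
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "; written by thetareg",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / rec$sfreq, scientific = FALSE)),
    "[Binary Infos]",
    paste0("BinaryFormat=", format),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,µV", seq_len(nch), rec$channel_labels,
            format(res, scientific = FALSE)))
  writeLines(hdr, paste0(base_path, ".vhdr"), useBytes = TRUE)

  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]",
          "Codepage=UTF-8",
          paste0("DataFile=", base, ".eeg"),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0,20240101120000000000")
  if (nrow(rec$events))
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(rec$events)) + 1L,
                        rec$events$marker, rec$events$sample))
  writeLines(mk, paste0(base_path, ".vmrk"), useBytes = TRUE)

  con <- file(paste0(base_path, ".eeg"), "wb")
  on.exit(close(con))
  if (format == "INT_16") {
    q <- as.integer(pmin(pmax(round(rec$data / res), -32768), 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  }
  invisible(paste0(base_path, ".vhdr"))
}
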