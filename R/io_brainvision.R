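# BrainVision triplet (.vhdr INI header, .vmrk markers, .eeg binary).
# Reader supports multiplexed IEEE_FLOAT_32 and INT_16 with per-channel
# resolution scaling; the writer exists to generate round-trip fixtures.

.parse_ini <- function(lines) {
  out <- list()
  section <- ""
  for (ln in lines) {
    ln <- trimws(gsub("\ufeff", "", ln))   # strip BOM if present
    if (ln == "" || startsWith(ln, ";")) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && section != "") {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Reads the .vhdr/.vmrk/.eeg triplet, scales channels to microvolts using
#' the per-channel resolution, and maps markers to events. Supports
#' multiplexed binary data in IEEE float32 or int16.
#'
#' @param path_vhdr path to the .vhdr header file
#' @return an \code{\link{eeg_raw}} object; marker descriptions become the
#'   event \code{marker} strings
#' @export
read_brainvision <- function(path_vhdr) {
  if (!file.exists(path_vhdr))
    stop_data("header file not found: %s", path_vhdr)
  hdr <- .parse_ini(readLines(path_vhdr, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop_data("missing [Common Infos] in %s", path_vhdr)
  dir <- dirname(path_vhdr)
  eeg_path <- file.path(dir, ci$DataFile)
  vmrk_path <- if (!is.null(ci$MarkerFile)) file.path(dir, ci$MarkerFile)
               else NULL
  if (!file.exists(eeg_path))
    stop_data("data file missing: %s", eeg_path)
  if (!identical(toupper(ci$DataFormat %||% "BINARY"), "BINARY"))
    stop_data("only BINARY DataFormat is supported")
  if (!identical(toupper(ci$DataOrientation %||% "MULTIPLEXED"),
                 "MULTIPLEXED"))
    stop_data("only MULTIPLEXED orientation is supported")
  nch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)   # interval is microseconds
  fmt <- toupper(hdr[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
  chinfo <- hdr[["Channel Infos"]]
  if (length(chinfo) != nch)
    stop_data("channel count mismatch: header says %d, %d channel entries",
              nch, length(chinfo))
  labels <- character(nch); resolution <- rep(1, nch)
  for (i in seq_len(nch)) {
    parts <- strsplit(chinfo[[paste0("Ch", i)]], ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3]))
      resolution[i] <- as.numeric(parts[3])
  }
  sz <- file.size(eeg_path)
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    nval <- sz %/% 4
    raw_vals <- readBin(con, "numeric", n = nval, size = 4,
                        endian = "little")
  } else if (fmt == "INT_16") {
    nval <- sz %/% 2
    raw_vals <- readBin(con, "integer", n = nval, size = 2, signed = TRUE,
                        endian = "little")
  } else {
    stop_data("unknown BinaryFormat '%s'", fmt)
  }
  if (nval %% nch != 0)
    stop_data("data length %d not a multiple of %d channels", nval, nch)
  data <- matrix(raw_vals, nrow = nch)            # multiplexed
  data <- data * resolution
  events <- data.frame(sample = integer(), marker = character())
  if (!is.null(vmrk_path) && file.exists(vmrk_path)) {
    mk <- .parse_ini(readLines(vmrk_path, warn = FALSE))[["Marker Infos"]]
    for (key in names(mk)) {
      parts <- strsplit(mk[[key]], ",", fixed = TRUE)[[1]]
      if (length(parts) >= 3)
        events <- rbind(events, data.frame(
          sample = as.integer(parts[3]),
          marker = parts[2]))
    }
    events <- events[order(events$sample), , drop = FALSE]
    rownames(events) <- NULL
  }
  eeg_raw(data, fs, labels, events)
}

#' Write a BrainVision triplet (fixture writer)
#'
#' Writes an \code{eeg_raw} object as a .vhdr/.vmrk/.eeg triplet, for
#' round-trip testing of the reader. \code{int16} data are quantized by
#' \code{resolution} microvolts per bit.
#'
#' @param raw an \code{eeg_raw} object
#' @param path_vhdr output header path (siblings get matching names)
#' @param binary_format "IEEE_FLOAT_32" or "INT_16"
#' @param resolution microvolts per bit (int16 only)
#' @return invisibly, the header path
#' @export
write_brainvision <- function(raw, path_vhdr,
                              binary_format = "IEEE_FLOAT_32",
                              resolution = 0.1) {
  stopifnot(inherits(raw, "eeg_raw"))
  base <- sub("\\.vhdr$", "", path_vhdr)
  eeg_path <- paste0(base, ".eeg")
  vmrk_path <- paste0(base, ".vmrk")
  nch <- nrow(raw$data)
  res <- if (binary_format == "INT_16") rep(resolution, nch) else rep(1, nch)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(eeg_path)),
    paste0("MarkerFile=", basename(vmrk_path)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / raw$fs, scientific = FALSE)),
    "[Binary Infos]",
    paste0("BinaryFormat=", binary_format),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,µV", seq_len(nch), raw$labels,
            format(res, scientific = FALSE))
  )
  writeLines(hdr, path_vhdr)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]",
          paste0("DataFile=", basename(eeg_path)),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (nrow(raw$events))
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(raw$events)) + 1,
                        raw$events$marker, raw$events$sample))
  writeLines(mk, vmrk_path)
  con <- file(eeg_path, "wb")
  on.exit(close(con))
  if (binary_format == "IEEE_FLOAT_32") {
    writeBin(as.vector(raw$data), con, size = 4, endian = "little")
  } else if (binary_format == "INT_16") {
    q <- as.integer(pmin(pmax(round(raw$data / resolution), -32768), 32767))
    writeBin(as.vector(q), con, size = 2, endian = "little")
  } else {
    stop_config("unknown format '%s'", binary_format)
  }
  invisible(path_vhdr)
}
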