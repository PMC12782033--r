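# --- BrainVision (.vhdr / .vmrk / .eeg) I/O ---------------------------------
#
# Supported dialect: Brain Vision Data Exchange format 1.0, ASCII header,
# BINARY data, MULTIPLEXED or VECTORIZED orientation, IEEE_FLOAT_32 or
# INT_16 (with per-channel resolution) samples. Everything else is rejected
# with a file/line message.

parse_vhdr_sections <- function(lines, path) {
  sections <- list()
  current <- NULL
  for (i in seq_along(lines)) {
    ln <- sub(";.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    m <- regmatches(ln, regexec("^\\[(.+)\\]$", ln))[[1]]
    if (length(m) == 2) {
      current <- m[2]
      sections[[current]] <- character(0)
    } else if (!is.null(current)) {
      sections[[current]] <- c(sections[[current]], ln)
    }
  }
  sections
}

section_keyvals <- function(section) {
  kv <- strsplit(section, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  stats::setNames(trimws(vals), trimws(keys))
}

#' Read a BrainVision recording
#'
#' Reads the `.vhdr` header, its companion binary data file and the `.vmrk`
#' marker file, returning the data in microvolts with 0-based marker
#' sample indices.
#'
#' @param header_path Path to the `.vhdr` header.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path)) stop_invalid("header not found: %s", header_path)
  lines <- readLines(header_path, warn = FALSE)
  sec <- parse_vhdr_sections(lines, header_path)
  if (is.null(sec[["Common Infos"]])) {
    stop_invalid("%s: missing [Common Infos] section", header_path)
  }
  ci <- section_keyvals(sec[["Common Infos"]])
  bi <- section_keyvals(sec[["Binary Infos"]] %||% character(0))
  dirn <- dirname(header_path)

  data_file <- file.path(dirn, ci[["DataFile"]])
  marker_file <- if (!is.na(ci["MarkerFile"])) file.path(dirn, ci[["MarkerFile"]]) else NA
  if (!file.exists(data_file)) {
    stop_invalid("%s: DataFile '%s' not found", header_path, ci[["DataFile"]])
  }
  if (!identical(toupper(ci[["DataFormat"]]), "BINARY")) {
    stop_invalid("%s: unsupported DataFormat '%s' (BINARY only)",
                 header_path, ci[["DataFormat"]])
  }
  orientation <- toupper(ci[["DataOrientation"]])
  if (!orientation %in% c("MULTIPLEXED", "VECTORIZED")) {
    stop_invalid("%s: unsupported DataOrientation '%s'", header_path, orientation)
  }
  n_ch <- as.integer(ci[["NumberOfChannels"]])
  interval_us <- as.numeric(ci[["SamplingInterval"]])
  rate <- 1e6 / interval_us

  fmt <- toupper(bi[["BinaryFormat"]] %||% "IEEE_FLOAT_32")
  if (!fmt %in% c("IEEE_FLOAT_32", "INT_16")) {
    stop_invalid("%s: unsupported BinaryFormat '%s'", header_path, fmt)
  }

  ch_lines <- sec[["Channel Infos"]] %||% character(0)
  kv <- section_keyvals(ch_lines)
  parts <- strsplit(unname(kv), ",", fixed = TRUE)
  ch_names <- vapply(parts, `[`, "", 1)
  resolutions <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r) || r <= 0) 1 else r
  }, 0)
  if (length(ch_names) != n_ch) {
    stop_invalid("%s: NumberOfChannels=%d but %d channel lines",
                 header_path, n_ch, length(ch_names))
  }

  sz <- file.info(data_file)$size
  bytes <- if (fmt == "IEEE_FLOAT_32") 4L else 2L
  n_total <- sz / bytes
  if (n_total %% n_ch != 0) {
    stop_invalid("%s: data size (%d values) not divisible by %d channels",
                 data_file, n_total, n_ch)
  }
  n_samp <- as.integer(n_total / n_ch)
  con <- file(data_file, "rb")
  on.exit(close(con))
  raw_vals <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = n_total, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n = n_total, size = 2, signed = TRUE,
            endian = "little")
  }
  data <- if (orientation == "MULTIPLEXED") {
    matrix(raw_vals, nrow = n_ch, ncol = n_samp)           # sample-major
  } else {
    t(matrix(raw_vals, nrow = n_samp, ncol = n_ch))        # channel-major
  }
  data <- data * resolutions  # recycles down columns = per-channel scaling

  markers <- data.frame(sample = integer(0), code = integer(0))
  if (!is.na(marker_file) && file.exists(marker_file)) {
    mlines <- readLines(marker_file, warn = FALSE)
    mk <- grep("^Mk[0-9]+=", mlines, value = TRUE)
    if (length(mk) > 0) {
      fields <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
      type <- vapply(fields, `[`, "", 1)
      desc <- vapply(fields, `[`, "", 2)
      pos <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
      stim <- type == "Stimulus"
      codes <- suppressWarnings(as.integer(sub("^S\\s*", "", desc[stim])))
      # .vmrk positions are 1-based sample numbers
      markers <- data.frame(sample = pos[stim] - 1L, code = codes)
      markers <- markers[!is.na(markers$sample) & !is.na(markers$code), ,
                         drop = FALSE]
    }
  }
  eeg_recording(data, rate, ch_names, markers)
}

#' Write a BrainVision recording
#'
#' Writes the `.vhdr`/`.vmrk`/`.eeg` triplet (ASCII header v1.0,
#' multiplexed IEEE float32) readable by [read_brainvision()].
#'
#' @param rec An [eeg_recording()].
#' @param header_path Destination `.vhdr` path; the `.vmrk` and `.eeg`
#'   companions are written next to it.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_brainvision <- function(rec, header_path) {
  stopifnot(inherits(rec, "eeg_recording"))
  base <- sub("\\.vhdr$", "", header_path)
  data_path <- paste0(base, ".eeg")
  marker_path <- paste0(base, ".vmrk")
  stem <- basename(base)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", stem),
    sprintf("MarkerFile=%s.vmrk", stem),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(rec$data)),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$rate_hz),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)), rec$channel_names)
  )
  writeLines(hdr, header_path, useBytes = TRUE)

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", stem),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  )
  if (nrow(rec$markers) > 0) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,S%3d,%d,1,0",
                        seq_len(nrow(rec$markers)) + 1L,
                        rec$markers$code, rec$markers$sample + 1L))
  }
  writeLines(mk, marker_path, useBytes = TRUE)

  con <- file(data_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(c(vhdr = header_path, vmrk = marker_path, eeg = data_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
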