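#' Write an epoched dataset to disk
#'
#' Stores the numeric array as little-endian doubles (\code{<path>.dat})
#' next to a JSON sidecar (\code{<path>.json}) holding dimensions, time
#' axis, sampling rate, channel names, per-trial stimulus/class labels,
#' subject metadata and the provenance log.  The round-trip through
#' \code{\link{read_epochs}} is lossless.
#'
#' @param epochs an \code{\link{eeg_epochs}}.
#' @param path base path (without extension).
#' @return \code{path}, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  side <- list(schema = "eegmvpa-epochs-1",
               dim = dim(epochs$data),
               times_ms = epochs$times_ms,
               sfreq = epochs$sfreq,
               channel_names = epochs$channel_names,
               stimulus_id = epochs$stimulus_id,
               class_label = as.character(epochs$class_label),
               subject_id = epochs$subject_id,
               group = epochs$group,
               provenance = epochs$provenance)
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an epoched dataset written by \code{\link{write_epochs}}
#'
#' @param path base path (without extension).
#' @return an \code{\link{eeg_epochs}}.
#' @export
read_epochs <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(side$schema, "eegmvpa-epochs-1"))
    stop("unknown epochs schema: ", side$schema %||% "<missing>")
  d <- as.integer(side$dim)
  dat_path <- paste0(path, ".dat")
  n <- prod(d)
  if (file.info(dat_path)$size != 8 * n)
    stop("data file size does not match sidecar dimensions")
  con <- file(dat_path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  prov <- side$provenance
  if (is.data.frame(prov)) prov <- lapply(seq_len(nrow(prov)), function(i)
    as.list(prov[i, , drop = FALSE]))
  eeg_epochs(array(x, d), side$times_ms, side$sfreq, side$channel_names,
             side$stimulus_id, side$class_label,
             subject_id = side$subject_id %||% NA_character_,
             group = side$group %||% NA_character_,
             provenance = if (is.null(prov)) list() else prov)
}

#' Write a continuous recording in BrainVision format
#'
#' Emits the standard triplet: text header (\code{.vhdr}), marker file
#' (\code{.vmrk}, one Stimulus marker per event) and multiplexed
#' IEEE-float-32 binary data (\code{.eeg}).
#'
#' @param raw an \code{\link{eeg_raw}}.
#' @param path base path (without extension).
#' @return \code{path}, invisibly.
#' @export
write_brainvision <- function(raw, path) {
  stopifnot(inherits(raw, "eeg_raw"))
  base <- basename(path)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "", "[Common Infos]",
           paste0("DataFile=", base, ".eeg"),
           paste0("MarkerFile=", base, ".vmrk"),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", nrow(raw$data)),
           paste0("SamplingInterval=", format(1e6 / raw$sfreq, digits = 12)),
           "", "[Binary Infos]",
           "BinaryFormat=IEEE_FLOAT_32",
           "", "[Channel Infos]",
           sprintf("Ch%d=%s,,1,µV", seq_len(nrow(raw$data)),
                   raw$channel_names))
  writeLines(hdr, paste0(path, ".vhdr"), useBytes = TRUE)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "", "[Common Infos]",
          paste0("DataFile=", base, ".eeg"),
          "", "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (!is.null(raw$events) && nrow(raw$events) > 0)
    mk <- c(mk, sprintf("Mk%d=Stimulus,S%3d,%d,1,0",
                        seq_len(nrow(raw$events)) + 1L,
                        raw$events$stimulus_id, raw$events$sample))
  writeLines(mk, paste0(path, ".vmrk"), useBytes = TRUE)
  con <- file(paste0(path, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.vector(raw$data), con, size = 4, endian = "little")
  invisible(path)
}

bv_section <- function(lines, name) {
  starts <- grep("^\\[", lines)
  i <- grep(paste0("^\\[", name, "\\]$"), lines)
  if (length(i) == 0L) return(character(0))
  end <- c(starts[starts > i[1]], length(lines) + 1L)[1] - 1L
  lines[(i[1] + 1L):end]
}

bv_value <- function(lines, key) {
  l <- grep(paste0("^", key, "="), lines, value = TRUE)
  if (length(l) == 0L) return(NULL)
  sub(paste0("^", key, "="), "", l[1])
}

#' Read a BrainVision recording
#'
#' Supports the subset this package writes: multiplexed IEEE-float-32
#' binary data with a text header and Stimulus markers.  Channel types are
#' inferred from names: \code{EOG*} channels become \code{"eog"},
#' \code{REF} becomes \code{"ref"}, everything else \code{"eeg"}.
#'
#' @param path the \code{.vhdr} path or base path.
#' @param class_map optional function mapping stimulus ids to class
#'   labels, used to populate the event table (e.g. the synthetic
#'   design's animate/inanimate split); defaults to NA labels.
#' @return an \code{\link{eeg_raw}}.
#' @export
read_brainvision <- function(path, class_map = NULL) {
  vhdr <- if (grepl("\\.vhdr$", path)) path else paste0(path, ".vhdr")
  stopifnot(file.exists(vhdr))
  lines <- readLines(vhdr, warn = FALSE)
  common <- bv_section(lines, "Common Infos")
  if (!identical(bv_value(common, "DataFormat"), "BINARY") ||
      !identical(bv_value(common, "DataOrientation"), "MULTIPLEXED"))
    stop("unsupported BrainVision variant")
  if (!identical(bv_value(bv_section(lines, "Binary Infos"), "BinaryFormat"),
                 "IEEE_FLOAT_32"))
    stop("unsupported binary format")
  n_ch <- as.integer(bv_value(common, "NumberOfChannels"))
  sfreq <- 1e6 / as.numeric(bv_value(common, "SamplingInterval"))
  ch <- bv_section(lines, "Channel Infos")
  ch <- grep("^Ch[0-9]+=", ch, value = TRUE)
  names_ <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch), ","), `[[`, "", 1)
  dir_ <- dirname(vhdr)
  eeg_file <- file.path(dir_, bv_value(common, "DataFile"))
  n <- file.info(eeg_file)$size / 4
  con <- file(eeg_file, "rb")
  x <- readBin(con, "double", n = n, size = 4, endian = "little")
  close(con)
  data <- matrix(x, nrow = n_ch)
  types <- ifelse(grepl("^EOG", names_), "eog",
                  ifelse(names_ == "REF", "ref", "eeg"))
  events <- NULL
  vmrk <- file.path(dir_, bv_value(common, "MarkerFile") %||% "")
  if (nzchar(basename(vmrk)) && file.exists(vmrk)) {
    ml <- grep("^Mk[0-9]+=Stimulus,", readLines(vmrk, warn = FALSE),
               value = TRUE)
    if (length(ml) > 0) {
      parts <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
      sid <- as.integer(sub("^S *", "", vapply(parts, `[[`, "", 2)))
      events <- data.frame(
        sample = as.integer(vapply(parts, `[[`, "", 3)),
        stimulus_id = sid,
        class_label = if (is.null(class_map)) NA_character_
                      else as.character(class_map(sid)))
    } else {
      warning("no Stimulus markers found; empty event list")
      events <- data.frame(sample = integer(0), stimulus_id = integer(0),
                           class_label = character(0))
    }
  }
  eeg_raw(data, sfreq, names_, types, events)
}

#' Import a continuous recording from a standard format
#'
#' @param path file path.
#' @param format \code{"brainvision"} is supported; requesting another
#'   format is an error.
#' @param ... passed to the format reader.
#' @return an \code{\link{eeg_raw}}.
#' @export
import_continuous <- function(path, format = c("brainvision", "edf"), ...) {
  format <- match.arg(format)
  if (format != "brainvision")
    stop("unsupported format: ", format,
         " (only BrainVision import is implemented)")
  read_brainvision(path, ...)
}
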