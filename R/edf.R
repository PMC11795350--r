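#' Write an epoch array to an EDF file
#'
#' Minimal European Data Format (EDF) writer for the pipeline's
#' intermediate storage: each epoch becomes one 1-second data record, each
#' montage channel one signal with physical dimension uV. Samples are
#' quantized to 16-bit integers over a symmetric physical range covering
#' the data, so the round-trip error is bounded by half a quantization
#' step (`range/65536` uV).
#'
#' @param epochs an [epoch_array()].
#' @param path output file path.
#' @param patient_id,recording_id free-text header fields (default: subject
#'   id and condition).
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(epochs, path, patient_id = NULL, recording_id = NULL) {
  stopifnot(inherits(epochs, "epoch_array"))
  dat <- epochs$data
  ne <- dim(dat)[1]; nch <- dim(dat)[2]; ns <- dim(dat)[3]
  labels <- dimnames(dat)[[2]]
  patient_id <- patient_id %||% epochs$subject_id
  recording_id <- recording_id %||% epochs$condition
  record_dur <- ns / epochs$srate

  phys_max <- max(1, ceiling(max(abs(dat))))
  dig_max <- 32767L; dig_min <- -32768L

  pad <- function(x, w) {
    x <- substr(as.character(x), 1, w)
    formatC(x, width = w, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8),
    pad(patient_id, 80),
    pad(recording_id, 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256 + 256 * nch, 8),
    pad("", 44),
    pad(ne, 8),
    pad(format(record_dur, nsmall = 0), 8),
    pad(nch, 4)
  )
  sig_hdr <- paste0(
    paste0(vapply(labels, pad, "", w = 16), collapse = ""),
    paste0(rep(pad("AgAgCl electrode", 80), nch), collapse = ""),
    paste0(rep(pad("uV", 8), nch), collapse = ""),
    paste0(rep(pad(-phys_max, 8), nch), collapse = ""),
    paste0(rep(pad(phys_max, 8), nch), collapse = ""),
    paste0(rep(pad(dig_min, 8), nch), collapse = ""),
    paste0(rep(pad(dig_max, 8), nch), collapse = ""),
    paste0(rep(pad("", 80), nch), collapse = ""),
    paste0(rep(pad(ns, 8), nch), collapse = ""),
    paste0(rep(pad("", 32), nch), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)

  scale <- (dig_max - dig_min) / (2 * phys_max)
  for (e in seq_len(ne)) {
    block <- t(dat[e, , , drop = TRUE])           # samples x channels
    dig <- as.integer(round((block + phys_max) * scale) + dig_min)
    dig <- pmin(dig_max, pmax(dig_min, dig))
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Companion reader for [write_edf()]: parses the EDF header and data
#' records and returns both the continuous signal matrix (records
#' concatenated in time) and the record structure, so the result can be fed
#' either to [segment_epochs()] or reshaped directly into an epoch array.
#'
#' @param path EDF file path.
#' @return A list: `signals` (channels x samples matrix, physical units),
#'   `labels`, `srate`, `n_records`, `record_duration`, `samples_per_record`,
#'   `patient_id`, `recording_id`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    trimws(readChar(con, w, useBytes = TRUE))
  }
  rd(8)                                  # version
  patient_id <- rd(80)
  recording_id <- rd(80)
  rd(8); rd(8)                           # start date/time
  rd(8)                                  # header bytes
  rd(44)                                 # reserved
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))

  rdv <- function(w) vapply(seq_len(nch), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80)                                # transducer
  rdv(8)                                 # physical dimension
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)                                # prefiltering
  spr <- as.integer(rdv(8))              # samples per record
  rdv(32)                                # reserved
  if (length(unique(spr)) != 1) stop("heterogeneous sampling rates unsupported")
  ns <- spr[1]
  srate <- ns / record_dur

  signals <- matrix(0, nch, ns * n_records)
  for (r in seq_len(n_records)) {
    raw <- readBin(con, "integer", n = ns * nch, size = 2,
                   endian = "little", signed = TRUE)
    block <- matrix(raw, nrow = ns, ncol = nch)  # per-signal blocks
    phys <- sweep(sweep(block, 2, dig_min, "-"), 2,
                  (phys_max - phys_min) / (dig_max - dig_min), "*")
    phys <- sweep(phys, 2, phys_min, "+")
    signals[, ((r - 1) * ns + 1):(r * ns)] <- t(phys)
  }
  rownames(signals) <- labels
  list(signals = signals, labels = labels, srate = srate,
       n_records = n_records, record_duration = record_dur,
       samples_per_record = ns,
       patient_id = patient_id, recording_id = recording_id)
}

#' Rebuild an epoch array from an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @param subject_id,condition metadata overrides; default to the EDF
#'   patient/recording header fields.
#' @return An [epoch_array()].
#' @export
read_edf_epochs <- function(path, subject_id = NULL, condition = NULL) {
  e <- read_edf(path)
  ne <- e$n_records; nch <- length(e$labels); ns <- e$samples_per_record
  dat <- array(0, dim = c(ne, nch, ns))
  for (r in seq_len(ne)) {
    dat[r, , ] <- e$signals[, ((r - 1) * ns + 1):(r * ns)]
  }
  mont <- montage_1020()
  if (!identical(e$labels, as.character(mont))) {
    stop("EDF channel labels do not match the 30-channel 10-20 montage")
  }
  epoch_array(dat, subject_id = subject_id %||% e$patient_id,
              condition = condition %||% e$recording_id,
              srate = e$srate, montage = mont)
}
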