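# Dataset serialization: a flat CSV trial bundle and a minimal EDF
# (European Data Format) writer/reader. EDF stores 16-bit integers scaled by
# per-channel physical ranges, so round-trips are exact only up to the
# quantization step recorded in the header; the CSV bundle is lossless.
# Class labels are not an EDF concept and live in a CSV sidecar for both
# formats. One EDF data record holds one trial.

edf_field <- function(x, width) {
  s <- as.character(x)[1L]
  if (nchar(s) > width) stop("EDF header field too long: '", s, "'")
  formatC(s, width = width, flag = "-")
}

# Symmetric per-channel physical range with a short decimal representation,
# guaranteed to cover the data and to fit an 8-char header field.
edf_phys_range <- function(x) {
  r <- max(abs(x), 1e-6)
  r <- signif(r * 1.001, 4)
  while (nchar(format(r, scientific = FALSE)) > 7)
    r <- signif(r * 1.01, 3)
  r
}

write_labels_sidecar <- function(dataset, path) {
  utils::write.csv(data.frame(trial = seq_len(n_trials(dataset)),
                              label = dataset$labels),
                   path, row.names = FALSE)
}

read_labels_sidecar <- function(path, expected_trials) {
  lab <- utils::read.csv(path)
  if (!all(c("trial", "label") %in% names(lab)))
    stop("labels sidecar must have columns 'trial' and 'label'")
  if (nrow(lab) != expected_trials)
    stop("labels sidecar has ", nrow(lab), " rows but the recording has ",
         expected_trials, " trials")
  lab$label[order(lab$trial)]
}

#' Write a dataset to EDF plus a labels sidecar
#'
#' Produces \code{<prefix>.edf} (one data record per trial, one EDF signal
#' per channel, 16-bit quantization over a symmetric per-channel physical
#' range) and \code{<prefix>_labels.csv}.
#'
#' @param dataset An \code{\link{mi_dataset}}.
#' @param prefix Output path prefix.
#' @return Invisibly, the EDF path.
#' @export
write_edf <- function(dataset, prefix) {
  d <- dim(dataset$trials)
  ns <- d[2L]; nrec <- d[1L]; spr <- d[3L]
  dmin <- -32768L; dmax <- 32767L
  pr <- vapply(seq_len(ns), function(ch) edf_phys_range(dataset$trials[, ch, ]),
               numeric(1))

  path <- paste0(prefix, ".edf")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8), edf_field("synthetic MI EEG", 80),
    edf_field(dataset$provenance, 80),
    edf_field("01.01.26", 8), edf_field("00.00.00", 8),
    edf_field(256L + ns * 256L, 8), edf_field("", 44),
    edf_field(nrec, 8),
    edf_field(format(spr / dataset$sampling_rate, scientific = FALSE), 8),
    edf_field(ns, 4))
  per_sig <- function(fmt) paste(vapply(seq_len(ns), fmt, character(1)),
                                 collapse = "")
  hdr <- paste0(hdr,
    per_sig(function(i) edf_field(dataset$channel_names[i], 16)),
    per_sig(function(i) edf_field("", 80)),
    per_sig(function(i) edf_field("uV", 8)),
    per_sig(function(i) edf_field(format(-pr[i], scientific = FALSE), 8)),
    per_sig(function(i) edf_field(format(pr[i], scientific = FALSE), 8)),
    per_sig(function(i) edf_field(dmin, 8)),
    per_sig(function(i) edf_field(dmax, 8)),
    per_sig(function(i) edf_field("", 80)),
    per_sig(function(i) edf_field(spr, 8)),
    per_sig(function(i) edf_field("", 32)))
  writeChar(hdr, con, eos = NULL)

  for (rec in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      scale <- (dmax - dmin) / (2 * pr[ch])
      dig <- as.integer(round((dataset$trials[rec, ch, ] + pr[ch]) * scale + dmin))
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  write_labels_sidecar(dataset, paste0(prefix, "_labels.csv"))
  invisible(path)
}

#' Read an EDF recording written by \code{\link{write_edf}}
#'
#' Parses the EDF header and 16-bit samples; each data record becomes one
#' trial. Labels come from \code{<prefix>_labels.csv}.
#'
#' @param prefix Path prefix (so \code{<prefix>.edf} and the sidecar exist).
#' @return An \code{\link{mi_dataset}}.
#' @export
read_edf <- function(prefix) {
  path <- paste0(prefix, ".edf")
  if (!file.exists(path)) stop("no such EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(s) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (length(v) != 1L) NA_real_ else v
  }

  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # ids, date, time
  hdr_bytes <- num(rd(8))
  rd(44)
  nrec <- num(rd(8))
  dur <- num(rd(8))
  ns <- num(rd(4))
  if (!is.finite(ns) || ns < 1 || !is.finite(nrec) || nrec < 1 ||
      !is.finite(hdr_bytes) || !is.finite(dur) || dur <= 0)
    stop("corrupted EDF header")
  if (hdr_bytes != 256 + ns * 256) stop("corrupted EDF header (byte count)")

  labels_txt <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  rd(80 * ns); rd(8 * ns)
  pmin <- vapply(seq_len(ns), function(i) num(rd(8)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) num(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) num(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) num(rd(8)), numeric(1))
  rd(80 * ns)
  spr <- vapply(seq_len(ns), function(i) num(rd(8)), numeric(1))
  rd(32 * ns)
  if (length(unique(spr)) != 1L)
    stop("unsupported EDF: signals differ in samples per record")
  nt <- spr[1L]

  trials <- array(0, dim = c(nrec, ns, nt))
  for (rec in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nt, size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) != nt) stop("truncated EDF data section")
      q <- (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
      trials[rec, ch, ] <- (dig - dmin[ch]) * q + pmin[ch]
    }
  }
  labels <- read_labels_sidecar(paste0(prefix, "_labels.csv"), nrec)
  mi_dataset(trials, labels, nt / dur, channel_names = labels_txt,
             provenance = paste0("edf: ", path))
}

#' EDF quantization step per channel
#'
#' The amplitude resolution implied by a file's header:
#' \code{(physical max - physical min) / (digital max - digital min)}.
#' Round-tripped samples differ from the originals by at most this step.
#'
#' @param prefix Path prefix of an EDF file.
#' @return Numeric vector, one step per signal.
#' @export
edf_quantization_step <- function(prefix) {
  con <- file(paste0(prefix, ".edf"), "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8 + 80 + 80 + 8 + 8 + 8 + 44 + 8 + 8)
  ns <- as.numeric(trimws(rd(4)))
  rd(16 * ns + 80 * ns + 8 * ns)
  num8 <- function() vapply(seq_len(ns), function(i)
    as.numeric(trimws(rd(8))), numeric(1))
  pmin <- num8(); pmax <- num8(); dmin <- num8(); dmax <- num8()
  (pmax - pmin) / (dmax - dmin)
}

#' Write a dataset as a flat CSV bundle
#'
#' \code{<prefix>_data.csv} has columns trial, channel, sample_index, value;
#' \code{<prefix>_labels.csv} is the labels sidecar; \code{<prefix>_meta.json}
#' records the sampling rate and channel names. Lossless round trip.
#'
#' @param dataset An \code{\link{mi_dataset}}.
#' @param prefix Output path prefix.
#' @return Invisibly, the data CSV path.
#' @export
write_csv_bundle <- function(dataset, prefix) {
  d <- dim(dataset$trials)
  df <- data.frame(
    trial = rep(seq_len(d[1L]), each = d[2L] * d[3L]),
    channel = rep(rep(seq_len(d[2L]), each = d[3L]), times = d[1L]),
    sample_index = rep(seq_len(d[3L]), times = d[1L] * d[2L]),
    value = as.vector(aperm(dataset$trials, c(3L, 2L, 1L))))
  path <- paste0(prefix, "_data.csv")
  utils::write.csv(df, path, row.names = FALSE)
  write_labels_sidecar(dataset, paste0(prefix, "_labels.csv"))
  jsonlite::write_json(list(sampling_rate = dataset$sampling_rate,
                            channel_names = dataset$channel_names),
                       paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a CSV bundle written by \code{\link{write_csv_bundle}}
#' @param prefix Path prefix used when writing.
#' @return An \code{\link{mi_dataset}}.
#' @export
read_csv_bundle <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, "_data.csv"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  ntr <- max(df$trial); nch <- max(df$channel); nsm <- max(df$sample_index)
  if (nrow(df) != ntr * nch * nsm)
    stop("CSV bundle is incomplete: expected ", ntr * nch * nsm,
         " rows, found ", nrow(df))
  trials <- array(0, dim = c(ntr, nch, nsm))
  trials[cbind(df$trial, df$channel, df$sample_index)] <- df$value
  labels <- read_labels_sidecar(paste0(prefix, "_labels.csv"), ntr)
  mi_dataset(trials, labels, meta$sampling_rate,
             channel_names = meta$channel_names,
             provenance = paste0("csv-bundle: ", prefix))
}

#' Read or write a dataset in either supported format
#'
#' Dispatches on \code{format}: "csv-bundle" (lossless) or "edf" (16-bit
#' quantized). \code{path} is the bundle prefix in both cases.
#'
#' @param path Path prefix.
#' @param format "csv-bundle" or "edf".
#' @return \code{read_dataset}: an \code{\link{mi_dataset}}.
#' @export
read_dataset <- function(path, format = c("csv-bundle", "edf")) {
  format <- match.arg(format)
  switch(format, "csv-bundle" = read_csv_bundle(path), "edf" = read_edf(path))
}

#' @rdname read_dataset
#' @param dataset An \code{\link{mi_dataset}} to write.
#' @export
write_dataset <- function(dataset, path, format = c("csv-bundle", "edf")) {
  format <- match.arg(format)
  switch(format,
         "csv-bundle" = write_csv_bundle(dataset, path),
         "edf" = write_edf(dataset, path))
}
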