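# EDF (European Data Format) reader/writer for multichannel physiological
# recordings. Only the plain 16-bit EDF layout is handled: ASCII header,
# one header block per signal, then data records of little-endian int16
# samples. Channel labels follow the "<MODALITY> <name>" convention
# (e.g. "EEG AF3", "ECG ECG1", "GSR GSR"); the first token routes the
# channel to its modality when reading.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over each channel's physical
#' range, the EDF sample representation; a read-back therefore agrees with
#' the original to within one quantization step. The trial must span a whole
#' number of seconds in every modality (EDF stores fixed-duration records;
#' one-second records are used).
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  rates <- rec$sampling_rates
  n_sec <- unique(vapply(names(rec$signals), function(m)
    ncol(rec$signals[[m]]) / rates[[m]], numeric(1)))
  if (length(n_sec) != 1 || n_sec != round(n_sec))
    stop("write_edf: all modalities must span the same whole number of seconds")
  n_rec <- as.integer(n_sec)

  labels <- character(0); spr <- integer(0); chans <- list()
  pmin <- numeric(0); pmax <- numeric(0)
  for (m in names(rec$signals)) {
    x <- rec$signals[[m]]
    nm <- if (m == "EEG") eeg_channel_names(nrow(x))
          else if (nrow(x) == 1) m else paste0(m, seq_len(nrow(x)))
    for (i in seq_len(nrow(x))) {
      labels <- c(labels, paste(m, nm[i]))
      spr <- c(spr, as.integer(rates[[m]]))
      v <- x[i, ]
      lo <- min(v); hi <- max(v)
      if (hi - lo < 1e-12) { lo <- lo - 1; hi <- hi + 1 }
      pmin <- c(pmin, lo); pmax <- c(pmax, hi)
      chans <- c(chans, list(v))
    }
  }
  ns <- length(labels)

  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad(rec$trial_id, 80),
    "01.01.00", "00.00.00",
    edf_pad(256 * (ns + 1), 8),
    edf_pad(sprintf("valence=%g arousal=%g lo=%g hi=%g", rec$valence,
                    rec$arousal, rec$scale_bounds[1], rec$scale_bounds[2]), 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  fields <- list(
    vapply(labels, edf_pad, "", width = 16),
    rep(edf_pad("", 80), ns),
    rep(edf_pad("uV", 8), ns),
    vapply(pmin, edf_num, "", width = 8),
    vapply(pmax, edf_num, "", width = 8),
    rep(edf_pad(-32768, 8), ns),
    rep(edf_pad(32767, 8), ns),
    rep(edf_pad("", 80), ns),
    vapply(spr, edf_pad, "", width = 8),
    rep(edf_pad("", 32), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL,
                              useBytes = TRUE)
  # re-read the truncated ASCII physical ranges so quantization is computed
  # against exactly what a reader will see
  pmin_r <- as.numeric(vapply(pmin, edf_num, "", width = 8))
  pmax_r <- as.numeric(vapply(pmax, edf_num, "", width = 8))
  dig <- lapply(seq_len(ns), function(i) {
    v <- chans[[i]]
    d <- round((v - pmin_r[i]) / (pmax_r[i] - pmin_r[i]) * 65535 - 32768)
    as.integer(pmin(pmax(d, -32768), 32767))
  })
  for (r in seq_len(n_rec))
    for (i in seq_len(ns))
      writeBin(dig[[i]][((r - 1) * spr[i] + 1):(r * spr[i])], con,
               size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Channels are grouped into modalities by the first token of their label
#' (`"EEG ..."`, `"ECG ..."`, `"GSR ..."`); sampling rates come from the file
#' header (samples per record / record duration). Valence/arousal ratings are
#' recovered from the header's reserved field when the file was written by
#' [write_edf()], otherwise left `NA`.
#'
#' @param path EDF file path.
#' @param spec Named list of [modality_spec()]; every listed modality must be
#'   present in the file with the declared channel count.
#' @return A [recording()].
#' @export
read_edf <- function(path, spec = default_modalities()) {
  if (!file.exists(path)) stop("read_edf: no such file: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)
  subject_id <- trimws(rd(80)); trial_id <- trimws(rd(80))
  rd(16)
  rd(8)  # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8)); dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("read_edf: malformed header (signal count)")
  rdn <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- rdn(16); rdn(80); rdn(8)
  pmin <- as.numeric(rdn(8)); pmax <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8)); dmax <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8)); rdn(32)

  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- integer(n_rec * spr[i])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                   endian = "little")
      if (length(v) < spr[i])
        stop("read_edf: truncated file (record ", r, ", signal ", i, ")")
      raw[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- v
    }
  }

  mod_of <- vapply(strsplit(labels, "[ .]"), `[`, "", 1)
  known <- names(spec)
  bad <- setdiff(unique(mod_of), known)
  if (length(bad))
    stop("read_edf: cannot map channel label(s) ",
         paste(sQuote(labels[mod_of %in% bad]), collapse = ", "),
         " onto modalities ", paste(known, collapse = "/"))
  signals <- list(); rates <- list()
  for (m in known) {
    idx <- which(mod_of == m)
    if (!length(idx))
      stop("read_edf: modality missing from file: ", m)
    if (length(idx) != spec[[m]]$n_channels)
      stop("read_edf: modality ", m, " has ", length(idx),
           " channels in file, spec expects ", spec[[m]]$n_channels)
    rr <- unique(spr[idx]) / dur
    if (length(rr) != 1)
      stop("read_edf: inconsistent sampling rates within modality ", m)
    sig <- t(vapply(idx, function(i) {
      pmin[i] + (raw[[i]] + 32768) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i])
    }, numeric(n_rec * spr[idx[1]])))
    rownames(sig) <- sub("^[A-Z]+[ .]?", "", labels[idx])
    signals[[m]] <- sig
    rates[[m]] <- rr
  }

  val <- aro <- NA_real_; bounds <- c(1, 9)
  mt <- regmatches(reserved, regexec(
    "valence=([-0-9.eE]+) arousal=([-0-9.eE]+) lo=([-0-9.eE]+) hi=([-0-9.eE]+)",
    reserved))[[1]]
  if (length(mt) == 5) {
    val <- as.numeric(mt[2]); aro <- as.numeric(mt[3])
    bounds <- as.numeric(mt[4:5])
  }
  recording(subject_id, trial_id, signals, rates, val, aro, bounds,
            modalities = spec)
}

#' Standard 14-channel EEG montage labels
#'
#' @param n Number of channels (must be at most 14).
#' @return Character vector of electrode names (10-20 positions of a
#'   14-channel consumer headset).
#' @export
eeg_channel_names <- function(n = 14) {
  nm <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1", "O2", "P8", "T8",
          "FC6", "F4", "F8", "AF4")
  if (n > length(nm)) stop("eeg_channel_names: at most 14 channels")
  nm[seq_len(n)]
}
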