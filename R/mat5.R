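# Minimal MATLAB v5 (uncompressed) container I/O, sufficient for the
# documented per-subject layout used by AMIGOS-style affect datasets:
#   joined_data           1 x n_trials cell, each samples x 17 double
#                         (columns 1-14 EEG, 15-16 ECG, 17 GSR)
#   labels_selfassessment 1 x n_trials cell, each 1 x 2 double
#                         (valence, arousal; NaN marks an unlabeled trial)
#   fs                    1 x 1 double, common sampling rate in Hz
#   scale_bounds          1 x 2 double, rating scale (min, max)
#   subject_id            char row vector
# Only double arrays, cell arrays and char arrays are implemented, written
# uncompressed and little-endian. The reader also accepts the "small data
# element" packing other writers emit, but not compressed (miCOMPRESSED)
# elements. Unknown or missing keys fail loudly with the offending key name.

m5_int <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                     endian = "little")
m5_pad8 <- function(r) c(r, raw((8 - length(r) %% 8) %% 8))

m5_elt <- function(type, data_raw) {
  c(m5_int(type, 4), m5_int(length(data_raw), 4), m5_pad8(data_raw))
}

m5_array_header <- function(class_id, dims, name) {
  c(m5_elt(6L, c(m5_int(class_id, 4), m5_int(0L, 4))),      # array flags
    m5_elt(5L, m5_int(dims, 4)),                            # dimensions
    m5_elt(1L, charToRaw(name)))                            # name
}

m5_numeric <- function(x, name = "") {
  x <- as.matrix(x)
  body <- c(m5_array_header(6L, dim(x), name),
            m5_elt(9L, writeBin(as.numeric(x), raw(), size = 8,
                                endian = "little")))
  m5_elt(14L, body)
}

m5_char <- function(s, name = "") {
  codes <- utf8ToInt(s)
  body <- c(m5_array_header(4L, c(1L, length(codes)), name),
            m5_elt(4L, m5_int(codes, 2)))
  m5_elt(14L, body)
}

m5_cell <- function(items_raw, name = "") {
  body <- c(m5_array_header(1L, c(1L, length(items_raw)), name),
            do.call(c, c(items_raw, list(raw(0)))))
  m5_elt(14L, body)
}

m5_write_file <- function(elements_raw, path) {
  con <- file(path, "wb"); on.exit(close(con))
  desc <- charToRaw(edf_pad("MATLAB 5.0 MAT-file, written by emochart", 116))
  writeBin(desc, con)
  writeBin(raw(8), con)                       # subsystem offset
  writeBin(m5_int(0x0100L, 2), con)           # version
  writeBin(charToRaw("IM"), con)              # endian indicator
  for (e in elements_raw) writeBin(e, con)
  invisible(path)
}

# --- reader ---------------------------------------------------------------

m5_read_u <- function(r, off, size) {
  v <- readBin(r[(off + 1):(off + size)], "integer", size = size,
               signed = size == 4, endian = "little")
  if (size < 4 && v < 0) v <- v + 2^(8 * size)
  v
}

# parse one data element starting at 0-based offset; returns
# list(type, value_raw_or_parsed, next_off)
m5_read_tag <- function(r, off) {
  tw <- m5_read_u(r, off, 4)
  small_n <- bitwAnd(bitwShiftR(tw, 16), 0xFFFF)
  if (small_n != 0) {
    list(type = bitwAnd(tw, 0xFFFF), nbytes = small_n, data_off = off + 4,
         next_off = off + 8)
  } else {
    nb <- m5_read_u(r, off + 4, 4)
    list(type = tw, nbytes = nb, data_off = off + 8,
         next_off = off + 8 + nb + (8 - nb %% 8) %% 8)
  }
}

m5_read_numvec <- function(r, tag) {
  sz <- switch(as.character(tag$type), "1" = 1, "2" = 1, "3" = 2, "4" = 2,
               "5" = 4, "6" = 4, "7" = 4, "9" = 8,
               stop("mat5: unsupported numeric storage type ", tag$type))
  n <- tag$nbytes / sz
  if (tag$type == 9) {
    readBin(r[(tag$data_off + 1):(tag$data_off + tag$nbytes)], "double",
            n = n, size = 8, endian = "little")
  } else if (tag$type == 7) {
    readBin(r[(tag$data_off + 1):(tag$data_off + tag$nbytes)], "double",
            n = n, size = 4, endian = "little")
  } else {
    v <- readBin(r[(tag$data_off + 1):(tag$data_off + tag$nbytes)], "integer",
                 n = n, size = sz, signed = sz == 4, endian = "little")
    if (sz < 4) v <- ifelse(v < 0 & tag$type %in% c(2, 4), v + 2^(8 * sz), v)
    as.numeric(v)
  }
}

m5_parse_matrix <- function(r, off) {
  tag <- m5_read_tag(r, off)
  if (tag$type == 15)
    stop("mat5: compressed (miCOMPRESSED) elements are not supported")
  if (tag$type != 14) stop("mat5: expected miMATRIX, got type ", tag$type)
  pos <- tag$data_off
  ftag <- m5_read_tag(r, pos)
  class_id <- bitwAnd(m5_read_u(r, ftag$data_off, 4), 0xFF)
  pos <- ftag$next_off
  dtag <- m5_read_tag(r, pos)
  dims <- readBin(r[(dtag$data_off + 1):(dtag$data_off + dtag$nbytes)],
                  "integer", n = dtag$nbytes / 4, size = 4, endian = "little")
  pos <- dtag$next_off
  ntag <- m5_read_tag(r, pos)
  name <- if (ntag$nbytes > 0)
    rawToChar(r[(ntag$data_off + 1):(ntag$data_off + ntag$nbytes)]) else ""
  pos <- ntag$next_off

  value <- if (class_id == 1) {               # cell array
    items <- vector("list", prod(dims))
    for (i in seq_along(items)) {
      sub <- m5_parse_matrix(r, pos)
      items[[i]] <- sub$value
      pos <- sub$next_off
    }
    items
  } else if (class_id == 4) {                 # char
    ctag <- m5_read_tag(r, pos)
    intToUtf8(m5_read_numvec(r, ctag))
  } else if (class_id %in% c(6, 7, 8, 9, 10, 11, 12, 13)) {  # numeric
    vtag <- m5_read_tag(r, pos)
    matrix(m5_read_numvec(r, vtag), nrow = dims[1], ncol = prod(dims[-1]))
  } else {
    stop("mat5: unsupported array class ", class_id)
  }
  list(name = name, value = value, next_off = tag$next_off)
}

m5_read_file <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 128) stop("mat5: truncated file: ", path)
  magic <- rawToChar(r[127:128])
  if (magic != "IM")
    stop("mat5: not a little-endian MATLAB v5 file (endian tag ", magic, ")")
  off <- 128
  out <- list()
  while (off < length(r)) {
    el <- m5_parse_matrix(r, off)
    out[[el$name]] <- el$value
    off <- el$next_off
  }
  out
}

# --- AMIGOS-style layer ---------------------------------------------------

#' Write recordings of one subject to an AMIGOS-style MATLAB container
#'
#' All recordings must share a subject id and sampling rate; each trial
#' becomes one samples-by-17 matrix in the `joined_data` cell (EEG channels
#' in columns 1-14, ECG in 15-16, GSR in 17) with its valence/arousal pair in
#' `labels_selfassessment`. See the package README for the exact key layout.
#'
#' @param recordings List of [recording()] objects of a single subject.
#' @param path Output `.mat` path.
#' @return `path`, invisibly.
#' @export
write_amigos_container <- function(recordings, path) {
  stopifnot(length(recordings) >= 1)
  sid <- unique(vapply(recordings, function(r) r$subject_id, ""))
  if (length(sid) != 1)
    stop("write_amigos_container: recordings span multiple subjects")
  fs <- unique(unlist(lapply(recordings, function(r) r$sampling_rates)))
  if (length(fs) != 1)
    stop("write_amigos_container: container layout needs one common rate")
  data_cells <- lapply(recordings, function(r) {
    m5_numeric(t(rbind(r$signals$EEG, r$signals$ECG, r$signals$GSR)))
  })
  lab_cells <- lapply(recordings, function(r)
    m5_numeric(matrix(c(r$valence, r$arousal), 1)))
  bounds <- recordings[[1]]$scale_bounds
  m5_write_file(list(
    m5_cell(data_cells, "joined_data"),
    m5_cell(lab_cells, "labels_selfassessment"),
    m5_numeric(matrix(fs, 1, 1), "fs"),
    m5_numeric(matrix(bounds, 1, 2), "scale_bounds"),
    m5_char(sid, "subject_id")), path)
}

#' Read an AMIGOS-style MATLAB container
#'
#' Validates the documented key layout eagerly and fails naming the missing
#' or malformed key. Trials whose self-assessment contains `NaN` are returned
#' with `NA` ratings (unlabeled) so downstream labeling can exclude them.
#'
#' @param path `.mat` file path.
#' @param modalities Named list of [modality_spec()] giving the channel
#'   split of the 17 columns (default 14 EEG + 2 ECG + 1 GSR).
#' @param scale_bounds Rating scale used when the file does not carry one.
#' @return List of [recording()] objects, one per trial.
#' @export
read_amigos_container <- function(path, modalities = default_modalities(),
                                  scale_bounds = c(1, 9)) {
  vars <- m5_read_file(path)
  for (key in c("joined_data", "labels_selfassessment"))
    if (is.null(vars[[key]]))
      stop("read_amigos_container: required key missing: ", key)
  jd <- vars$joined_data; la <- vars$labels_selfassessment
  if (!is.list(jd) || !is.list(la))
    stop("read_amigos_container: key has wrong type: ",
         if (!is.list(jd)) "joined_data" else "labels_selfassessment")
  if (length(jd) != length(la))
    stop("read_amigos_container: joined_data and labels_selfassessment ",
         "disagree on trial count")
  fs <- if (!is.null(vars$fs)) as.numeric(vars$fs)[1] else
    modalities[[1]]$sampling_rate
  if (!is.null(vars$scale_bounds)) scale_bounds <- as.numeric(vars$scale_bounds)
  sid <- if (!is.null(vars$subject_id)) vars$subject_id else
    sub("\\.mat$", "", basename(path))

  n_ch <- vapply(modalities, function(m) m$n_channels, integer(1))
  lapply(seq_along(jd), function(i) {
    x <- jd[[i]]
    if (!is.matrix(x) || ncol(x) != sum(n_ch))
      stop("read_amigos_container: joined_data[[", i, "]] is not a samples x ",
           sum(n_ch), " matrix")
    ratings <- as.numeric(la[[i]])
    if (length(ratings) < 2)
      stop("read_amigos_container: labels_selfassessment[[", i,
           "]] needs (valence, arousal)")
    val <- ratings[1]; aro <- ratings[2]
    if (is.nan(val) || is.nan(aro)) val <- aro <- NA_real_
    sig <- list(); col <- 0L; rates <- list()
    for (m in names(modalities)) {
      sig[[m]] <- t(x[, (col + 1):(col + n_ch[[m]]), drop = FALSE])
      rates[[m]] <- fs
      col <- col + n_ch[[m]]
    }
    recording(sid, sprintf("trial%02d", i), sig, rates, val, aro,
              scale_bounds, modalities = modalities)
  })
}
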