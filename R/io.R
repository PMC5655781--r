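#' Labeled EEG trial dataset
#'
#' The universal container passed between all stages: an array of trials
#' (n x E x T), one integer class label per trial (0-based, indexing into
#' `class_names`), the sampling rate and electrode metadata.
#'
#' @param trials numeric array of dimension (n_trials, E, T).
#' @param labels integer vector of length n_trials with values in
#'   0..K-1 where K = `length(class_names)`.
#' @param fs sampling rate in Hz.
#' @param electrodes data.frame with columns `name`, `x`, `y`.
#' @param class_names character vector of class names (length K >= 2).
#' @param meta optional list of provenance attributes.
#' @return an object of class `eeg_dataset`.
#' @export
eeg_dataset <- function(trials, labels, fs, electrodes, class_names,
                        meta = list()) {
  trials <- as.array(trials)
  stopifnot(length(dim(trials)) == 3)
  labels <- as.integer(labels)
  stopifnot(length(labels) == dim(trials)[1])
  electrodes <- as.data.frame(electrodes)
  stopifnot(nrow(electrodes) == dim(trials)[2],
            length(class_names) >= 2,
            all(labels >= 0L), all(labels < length(class_names)))
  structure(list(trials = trials, labels = labels, fs = fs,
                 electrodes = electrodes,
                 class_names = as.character(class_names), meta = meta),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  d <- dim(x$trials)
  cat("<eeg_dataset> ", d[1], " trials x ", d[2], " electrodes x ", d[3],
      " samples @ ", x$fs, " Hz\n", sep = "")
  cat("  classes:", paste0(x$class_names, " (n=", tabulate(x$labels + 1L,
      nbins = length(x$class_names)), ")", collapse = ", "), "\n")
  invisible(x)
}

#' Number of trials / electrodes / samples of a dataset
#' @param dataset an `eeg_dataset`.
#' @return named integer vector (n, E, T).
#' @export
dataset_dims <- function(dataset) {
  d <- dim(dataset$trials)
  c(n = d[1], E = d[2], T = d[3])
}

#' Subset trials of a dataset
#' @param dataset an `eeg_dataset`.
#' @param idx trial indices (1-based).
#' @return the subset `eeg_dataset`.
#' @export
subset_trials <- function(dataset, idx) {
  eeg_dataset(dataset$trials[idx, , , drop = FALSE], dataset$labels[idx],
              dataset$fs, dataset$electrodes, dataset$class_names,
              dataset$meta)
}

# ---------------------------------------------------------------------------
# Canonical container (RDS bundle with a fixed schema)

#' Write / read the canonical dataset container
#'
#' The canonical on-disk form is an RDS bundle with named fields
#' `trials` (n x E x T), `labels` (0-based int), `fs`, `electrode_names`,
#' `electrode_positions` (E x 2), `class_names` and `meta` (provenance:
#' generator or source file, package version, seed). Writing then reading
#' round-trips losslessly; files written from identical content are
#' byte-identical.
#'
#' @param dataset an `eeg_dataset`.
#' @param path output file path (conventionally `.rds`).
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the `eeg_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  meta <- dataset$meta
  meta$container_version <- 1L
  bundle <- list(
    trials = dataset$trials, labels = dataset$labels, fs = dataset$fs,
    electrode_names = dataset$electrodes$name,
    electrode_positions = as.matrix(dataset$electrodes[, c("x", "y")]),
    class_names = dataset$class_names, meta = meta
  )
  saveRDS(bundle, path, version = 3)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  b <- readRDS(path)
  need <- c("trials", "labels", "fs", "electrode_names",
            "electrode_positions", "class_names")
  if (!all(need %in% names(b))) {
    stop("not a canonical eegdecode container (missing fields: ",
         paste(setdiff(need, names(b)), collapse = ", "), ")")
  }
  eeg_dataset(b$trials, b$labels, b$fs,
              data.frame(name = b$electrode_names,
                         x = b$electrode_positions[, 1],
                         y = b$electrode_positions[, 2]),
              b$class_names, b$meta)
}

# ---------------------------------------------------------------------------
# EDF / BDF reading (hand-rolled: no installed R reader for these formats)

read_fixed <- function(con, n) {
  raw <- readBin(con, "raw", n)
  if (length(raw) < n) stop("truncated file at byte offset ", seek(con))
  trimws(rawToChar(raw))
}

#' Read a continuous EEG recording
#'
#' Supports EDF/EDF+ (16-bit), BDF (24-bit BioSemi variant) and the canonical
#' container. Digital values are scaled to physical units using the header
#' calibration. For EDF+ files, annotations in an "EDF Annotations" signal
#' are parsed into events with sample-accurate onsets.
#'
#' @param path file path.
#' @param format one of "auto", "edf", "bdf", "rds".
#' @return for edf/bdf: list with `signals` (E x T matrix), `fs`,
#'   `channel_names`, and `events` (data.frame onset_s, onset_sample,
#'   description). For rds: an `eeg_dataset`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "bdf", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", bdf = "bdf", rds = "rds",
                     gdf = "gdf", ext)
  }
  if (format == "rds") return(read_dataset(path))
  if (format == "gdf") {
    stop("GDF is not supported; convert to EDF or the canonical container")
  }
  if (!format %in% c("edf", "bdf")) stop("unknown recording format: ", format)
  read_edf_like(path, bits = if (format == "bdf") 24L else 16L)
}

read_edf_like <- function(path, bits) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- readBin(con, "raw", 8)
  if (bits == 24L && version[1] != as.raw(255)) {
    stop("not a BDF file (missing 0xFF magic byte): ", path)
  }
  read_fixed(con, 80); read_fixed(con, 80); read_fixed(con, 8); read_fixed(con, 8)
  header_bytes <- as.integer(read_fixed(con, 8))
  read_fixed(con, 44)
  n_records <- as.integer(read_fixed(con, 8))
  record_dur <- as.numeric(read_fixed(con, 8))
  ns <- as.integer(read_fixed(con, 4))
  if (is.na(ns) || ns < 1) stop("corrupt header: bad signal count in ", path)
  labels <- vapply(seq_len(ns), function(i) read_fixed(con, 16), "")
  for (i in seq_len(ns)) read_fixed(con, 80)  # transducer
  for (i in seq_len(ns)) read_fixed(con, 8)   # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(read_fixed(con, 8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(read_fixed(con, 8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(read_fixed(con, 8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(read_fixed(con, 8)), 0)
  for (i in seq_len(ns)) read_fixed(con, 80)  # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(read_fixed(con, 8)), 0L)
  readBin(con, "raw", ns * 32)                # reserved
  pos <- seek(con)
  if (pos != header_bytes) seek(con, header_bytes)

  is_annot <- grepl("Annotations", labels)
  data_idx <- which(!is_annot)
  fs <- spr[data_idx] / record_dur
  if (length(unique(fs)) > 1) {
    stop("mixed per-signal sampling rates are not supported")
  }
  fs <- fs[1]
  signals <- matrix(0, length(data_idx), n_records * spr[data_idx[1]])
  annot_raw <- raw(0)
  bytes_per <- bits / 8L
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      nraw <- spr[i] * bytes_per
      raw_chunk <- readBin(con, "raw", nraw)
      if (length(raw_chunk) < nraw) {
        stop("truncated file: record ", r, ", signal ", i, " at byte offset ",
             seek(con))
      }
      if (is_annot[i]) {
        annot_raw <- c(annot_raw, raw_chunk)
      } else {
        if (bits == 16L) {
          dig <- readBin(raw_chunk, "integer", spr[i], size = 2,
                         signed = TRUE, endian = "little")
        } else {
          u <- as.integer(raw_chunk)
          dim(u) <- c(3, spr[i])
          dig <- u[1, ] + 256L * u[2, ] + 65536L * u[3, ]
          dig <- ifelse(dig >= 2^23, dig - 2^24, dig)
        }
        gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
        row <- match(i, data_idx)
        col0 <- (r - 1L) * spr[i]
        signals[row, (col0 + 1):(col0 + spr[i])] <-
          phys_min[i] + gain * (dig - dig_min[i])
      }
    }
  }
  events <- parse_edf_annotations(annot_raw, fs)
  list(signals = signals, fs = fs, channel_names = labels[data_idx],
       events = events)
}

# EDF+ time-stamped annotation lists (TALs):
# "<onset>[\x15<duration>]\x14<text>\x14...\x00"; a TAL whose annotation
# list is empty is a record timestamp and carries no event.
parse_edf_annotations <- function(annot_raw, fs) {
  empty <- data.frame(onset_s = numeric(0), onset_sample = integer(0),
                      description = character(0))
  if (length(annot_raw) == 0) return(empty)
  boundaries <- c(0L, which(annot_raw == as.raw(0)))
  out <- list()
  for (i in seq_len(length(boundaries) - 1L)) {
    seg <- annot_raw[(boundaries[i] + 1L):(boundaries[i + 1L] - 1L)]
    if (!length(seg) || all(seg == as.raw(0))) next
    tal <- rawToChar(seg[seg != as.raw(0)])
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (!length(parts)) next
    head <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head[1]))
    descs <- parts[-1]
    descs <- descs[nzchar(descs)]
    if (!is.na(onset) && length(descs)) {
      out[[length(out) + 1L]] <- data.frame(
        onset_s = onset, onset_sample = as.integer(round(onset * fs)),
        description = descs
      )
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Write a minimal EDF+ file
#'
#' Writes one data record per second, 16-bit samples, with an "EDF
#' Annotations" channel holding the supplied events. Mainly used to exchange
#' small recordings and to build test fixtures; calibration maps the signal
#' range onto the full digital range per channel.
#'
#' @param signals E x T numeric matrix (physical units).
#' @param fs sampling rate (Hz); T must be a multiple of fs.
#' @param channel_names character vector of length E.
#' @param path output path.
#' @param events optional data.frame with `onset_s` and `description`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, channel_names, path, events = NULL) {
  E <- nrow(signals); T_len <- ncol(signals)
  if (T_len %% fs != 0) stop("signal length must be a whole number of seconds")
  n_rec <- T_len / fs
  ns <- E + 1L  # + annotation channel
  annot_spr <- 30L  # 60 bytes per record
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  # numeric header fields are fixed 8-byte ASCII: reduce precision to fit
  fmt_num <- function(v) {
    for (digits in 7:1) {
      s <- formatC(signif(v, digits), format = "g", digits = digits,
                   width = -1)
      if (nchar(s) <= 8) return(s)
    }
    stop("cannot represent ", v, " in an 8-byte EDF header field")
  }
  phys_min <- apply(signals, 1, min); phys_max <- apply(signals, 1, max)
  same <- phys_max - phys_min < 1e-12
  phys_max[same] <- phys_min[same] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256L * (1L + ns), 8), pad("EDF+C", 44), pad(n_rec, 8), pad(1, 8),
    pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  lab <- c(channel_names, "EDF Annotations")
  writeChar(paste0(vapply(lab, pad, "", w = 16), collapse = ""), con, eos = NULL)
  writeChar(strrep(pad("", 80), ns), con, eos = NULL)
  writeChar(paste0(vapply(c(rep("uV", E), ""), pad, "", w = 8), collapse = ""),
            con, eos = NULL)
  num8 <- function(v) {
    paste0(vapply(vapply(v, fmt_num, ""), pad, "", w = 8), collapse = "")
  }
  writeChar(num8(c(phys_min, -1)), con, eos = NULL)
  writeChar(num8(c(phys_max, 1)), con, eos = NULL)
  writeChar(num8(c(rep(-32768, E), -32768)), con, eos = NULL)
  writeChar(num8(c(rep(32767, E), 32767)), con, eos = NULL)
  writeChar(strrep(pad("", 80), ns), con, eos = NULL)
  writeChar(num8(c(rep(fs, E), annot_spr)), con, eos = NULL)
  writeChar(strrep(pad("", 32), ns), con, eos = NULL)

  gain <- (phys_max - phys_min) / 65535
  for (r in seq_len(n_rec)) {
    for (e in seq_len(E)) {
      x <- signals[e, ((r - 1) * fs + 1):(r * fs)]
      dig <- as.integer(round((x - phys_min[e]) / gain[e]) - 32768)
      writeBin(dig, con, size = 2, endian = "little")
    }
    tals <- c(charToRaw(sprintf("+%d\x14\x14", r - 1L)), as.raw(0))
    if (!is.null(events)) {
      in_rec <- which(events$onset_s >= r - 1 & events$onset_s < r)
      for (i in in_rec) {
        tals <- c(tals,
                  charToRaw(sprintf("+%.7g\x14%s\x14", events$onset_s[i],
                                    events$description[i])),
                  as.raw(0))
      }
    }
    if (length(tals) > 2L * annot_spr) {
      stop("too many annotations in second ", r - 1L,
           " for the annotation channel capacity")
    }
    buf <- c(tals, raw(2L * annot_spr - length(tals)))
    writeBin(buf, con)
  }
  invisible(path)
}
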