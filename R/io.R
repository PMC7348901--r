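#' Read a multichannel ECG record from disk
#'
#' CSV records are samples x channels with one header row of channel names
#' (the sampling frequency is not part of the format and must be supplied).
#' WFDB records are the usual `.hea`/`.dat` pair with format-16 (16-bit
#' little-endian) interleaved samples; the sampling frequency comes from the
#' header.
#'
#' @param path path to the `.csv` file or to the WFDB header (with or without
#'   the `.hea` extension).
#' @param format `"auto"` (by extension), `"csv"` or `"wfdb"`.
#' @param fs sampling frequency in Hz; required for CSV.
#' @param channel_roles optional per-channel roles; for CSV, roles are
#'   guessed from header names starting with `abd`/`tho`/`ref` when not
#'   given.
#' @return a [multichannel_record()].
#' @export
read_record <- function(path, format = c("auto", "csv", "wfdb"),
                        fs = NULL, channel_roles = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (format == "csv") {
    if (!file.exists(path)) stop_input(sprintf("file not found: %s", path),
                                       class = "nsfecg_format_error")
    if (is.null(fs)) {
      stop_input("CSV records carry no sampling frequency; supply `fs`",
                 class = "nsfecg_format_error")
    }
    df <- utils::read.csv(path, check.names = FALSE)
    if (ncol(df) < 2L) {
      stop_input(sprintf("%s: a record needs at least 2 channels (found %d)",
                         path, ncol(df)), class = "nsfecg_format_error")
    }
    X <- t(as.matrix(df))
    roles <- channel_roles %||% {
      nm <- tolower(colnames(df))
      dplyr::case_when(
        startsWith(nm, "abd") ~ "abdominal",
        startsWith(nm, "tho") ~ "thoracic",
        startsWith(nm, "ref") ~ "reference",
        TRUE ~ "unknown"
      )
    }
    rec <- multichannel_record(X, fs, channel_roles = roles)
    rownames(rec$X) <- colnames(df)
    rec
  } else {
    read_wfdb(path, channel_roles = channel_roles)
  }
}

#' Write a multichannel ECG record to disk
#'
#' CSV output is samples x channels with a header row of channel names; when
#' the record carries simulated ground truth, a `<stem>_truth.csv` sidecar
#' with the source waveforms and a `<stem>_truth_peaks.json` file with the
#' true R-peak indices are written next to it.
#'
#' @param record a [multichannel_record()].
#' @param path output path (`.csv`, or WFDB record stem).
#' @param format `"csv"` (default) or `"wfdb"`.
#' @param truth_sidecar write the ground-truth sidecars when truth is
#'   present (default TRUE, CSV only).
#' @return invisibly, a character vector of the files written.
#' @export
write_record <- function(record, path, format = c("csv", "wfdb"),
                         truth_sidecar = TRUE) {
  format <- match.arg(format)
  if (!inherits(record, "multichannel_record")) {
    stop_input("`record` must be a `multichannel_record`")
  }
  if (format == "wfdb") return(write_wfdb(record, path))
  m <- nrow(record$X)
  nm <- rownames(record$X) %||% paste0(substr(record$channel_roles, 1, 3), seq_len(m))
  df <- as.data.frame(t(record$X))
  names(df) <- make.unique(nm)
  utils::write.csv(df, path, row.names = FALSE)
  written <- path
  if (truth_sidecar && !is.null(record$truth) && !is.null(record$truth$S)) {
    stem <- sub("\\.csv$", "", path)
    tdf <- as.data.frame(t(record$truth$S))
    names(tdf) <- record$truth$labels %||% paste0("source", seq_len(ncol(tdf)))
    tpath <- paste0(stem, "_truth.csv")
    utils::write.csv(tdf, tpath, row.names = FALSE)
    written <- c(written, tpath)
    if (!is.null(record$truth$r_peaks)) {
      ppath <- paste0(stem, "_truth_peaks.json")
      pk <- record$truth$r_peaks
      names(pk) <- record$truth$labels %||% paste0("source", seq_along(pk))
      jsonlite::write_json(pk, ppath)
      written <- c(written, ppath)
    }
  }
  invisible(written)
}

# ---- minimal WFDB (format 16) support -------------------------------------

write_wfdb <- function(record, stem) {
  m <- nrow(record$X)
  n <- ncol(record$X)
  name <- basename(stem)
  gain <- 200
  scaled <- round(record$X * gain)
  if (max(abs(scaled)) > 32767) {
    gain <- floor(32767 / max(abs(record$X)))
    if (gain < 1) gain <- 1
    scaled <- round(record$X * gain)
  }
  hea <- c(
    sprintf("%s %d %g %d", name, m, record$fs, n),
    sprintf("%s.dat 16 %d 16 0 %d 0 0 %s", name, gain, scaled[, 1],
            record$channel_roles)
  )
  hea_path <- paste0(stem, ".hea")
  dat_path <- paste0(stem, ".dat")
  writeLines(hea, hea_path)
  con <- file(dat_path, "wb")
  on.exit(close(con))
  writeBin(as.integer(as.vector(scaled)), con, size = 2, endian = "little")
  invisible(c(hea_path, dat_path))
}

read_wfdb <- function(path, channel_roles = NULL) {
  stem <- sub("\\.hea$", "", path)
  hea_path <- paste0(stem, ".hea")
  if (!file.exists(hea_path)) {
    stop_input(sprintf("WFDB header not found: %s", hea_path),
               class = "nsfecg_format_error")
  }
  lines <- readLines(hea_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4L) {
    stop_input(sprintf("%s:1: malformed WFDB record line", hea_path),
               class = "nsfecg_format_error")
  }
  m <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  if (is.na(fs) || fs <= 0) {
    stop_input(sprintf("%s:1: missing or invalid sampling frequency", hea_path),
               class = "nsfecg_format_error")
  }
  sig <- lines[2:(1 + m)]
  gains <- numeric(m)
  roles <- character(m)
  dat_file <- NULL
  for (i in seq_len(m)) {
    tok <- strsplit(trimws(sig[i]), "\\s+")[[1]]
    if (length(tok) < 2L || tok[2] != "16") {
      stop_input(sprintf("%s:%d: only format-16 signal lines are supported",
                         hea_path, i + 1L), class = "nsfecg_format_error")
    }
    dat_file <- dat_file %||% tok[1]
    if (tok[1] != dat_file) {
      stop_input(sprintf("%s:%d: all signals must share one .dat file",
                         hea_path, i + 1L), class = "nsfecg_format_error")
    }
    gains[i] <- if (length(tok) >= 3L) as.numeric(sub("\\(.*", "", tok[3])) else 200
    if (is.na(gains[i]) || gains[i] <= 0) gains[i] <- 200
    roles[i] <- if (length(tok) >= 9L) tok[9] else "unknown"
  }
  dat_path <- file.path(dirname(hea_path), dat_file)
  if (!file.exists(dat_path)) {
    stop_input(sprintf("WFDB signal file not found: %s", dat_path),
               class = "nsfecg_format_error")
  }
  con <- file(dat_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, integer(), n = m * n, size = 2, endian = "little",
                      signed = TRUE)
  if (length(raw_vals) < m * n) {
    stop_input(sprintf("%s: expected %d samples, found %d", dat_path, m * n,
                       length(raw_vals)), class = "nsfecg_format_error")
  }
  X <- matrix(raw_vals, nrow = m) / gains
  roles[!roles %in% c("abdominal", "thoracic", "reference", "unknown")] <- "unknown"
  multichannel_record(X, fs, channel_roles = channel_roles %||% roles)
}

# ---- run manifests ---------------------------------------------------------

# content fingerprint cheap enough to recompute anywhere; enough to detect
# accidental input swaps, not a cryptographic hash
record_fingerprint <- function(record) {
  X <- record$X
  sprintf("%dx%d@%g:%.10e:%.10e:%.10e",
          nrow(X), ncol(X), record$fs,
          sum(X), sum(abs(X)), sum(X[, 1]^2))
}

build_manifest <- function(record, config, decisions) {
  list(
    method = config$method,
    software_version = as.character(utils::packageVersion("nsfecg")),
    input_fingerprint = record_fingerprint(record),
    config_snapshot = config,
    decisions = decisions
  )
}

#' Write a run manifest as JSON
#'
#' @param manifest the `manifest` element of a pipeline run.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
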