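#' Read and write titration series as CSV
#'
#' Plain CSV with a header row (`quencher_conc, F[, replicate_id]`);
#' the control intensity, unit and optional liposome concentration
#' travel as `#key=value` comment lines so a written file reads back
#' into an identical object.
#'
#' @param series a [titration_series()].
#' @param path file path.
#' @return `read_titration_csv` returns a [titration_series()];
#'   `write_titration_csv` returns `path` invisibly.
#' @export
write_titration_csv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#F0=%.17g", series$F0), con)
  writeLines(paste0("#unit=", series$unit), con)
  if (!is.null(series$lip_conc))
    writeLines(sprintf("#lip_conc=%.17g", series$lip_conc), con)
  d <- data.frame(quencher_conc = series$quencher_conc, F = series$F)
  if (!is.null(series$replicate_id)) d$replicate_id <- series$replicate_id
  write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  meta <- read_hash_meta(path)
  d <- read.csv(path, comment.char = "#")
  titration_series(d$quencher_conc, d$F,
                   F0 = as.numeric(meta[["F0"]]),
                   unit = meta[["unit"]] %||% "M",
                   replicate_id = d$replicate_id,
                   lip_conc = if (!is.null(meta[["lip_conc"]]))
                     as.numeric(meta[["lip_conc"]]))
}

#' Read and write spectra as two-column CSV
#'
#' Columns `x, y` plus `#xunit=` / `#label=` comment lines.
#'
#' @param spectrum a [spectrum_xy()].
#' @param path file path.
#' @return `read_spectrum_csv` returns a [spectrum_xy()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#xunit=", spectrum$xunit), con)
  writeLines(paste0("#label=", spectrum$label), con)
  write.csv(data.frame(x = spectrum$x, y = spectrum$y), con,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  meta <- read_hash_meta(path)
  d <- read.csv(path, comment.char = "#")
  spectrum_xy(d$x, d$y, xunit = meta[["xunit"]] %||% "cm-1",
              label = meta[["label"]] %||% "")
}

#' Read and write photon streams
#'
#' Two equivalent on-disk forms: a two-column CSV
#' (`macro_time_s, micro_time_ns`) with `#key=value` metadata lines,
#' and a packed little-endian binary with the 8-byte magic header
#' `FLPHSTR1` followed by the photon count, duration and pulse period
#' as doubles, then the macro- and micro-time arrays.
#'
#' @param stream a [photon_stream()].
#' @param path file path.
#' @return readers return a [photon_stream()]; writers return `path`
#'   invisibly.
#' @export
write_photon_stream_csv <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(stream$meta$duration))
    writeLines(sprintf("#duration=%.17g", stream$meta$duration), con)
  if (!is.null(stream$meta$pulse_period_ns))
    writeLines(sprintf("#pulse_period_ns=%.17g",
                       stream$meta$pulse_period_ns), con)
  write.csv(data.frame(macro_time_s = stream$macro_times,
                       micro_time_ns = stream$micro_times),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_photon_stream_csv
#' @export
read_photon_stream_csv <- function(path) {
  meta <- read_hash_meta(path)
  d <- read.csv(path, comment.char = "#")
  photon_stream(d$macro_time_s, d$micro_time_ns,
                meta = list(
                  duration = if (!is.null(meta[["duration"]]))
                    as.numeric(meta[["duration"]]),
                  pulse_period_ns = if (!is.null(meta[["pulse_period_ns"]]))
                    as.numeric(meta[["pulse_period_ns"]])))
}

PHOTON_MAGIC <- "FLPHSTR1"

#' @rdname write_photon_stream_csv
#' @export
write_photon_stream_bin <- function(stream, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(PHOTON_MAGIC), con)
  n <- length(stream$macro_times)
  writeBin(as.double(c(n,
                       stream$meta$duration %||% NA_real_,
                       stream$meta$pulse_period_ns %||% NA_real_)),
           con, size = 8, endian = "little")
  writeBin(as.double(stream$macro_times), con, size = 8, endian = "little")
  writeBin(as.double(stream$micro_times), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_photon_stream_csv
#' @export
read_photon_stream_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (!identical(magic, PHOTON_MAGIC))
    fb_stop("not a packed photon-stream file (bad magic header)",
            "validation_error")
  hdr <- readBin(con, "double", 3, size = 8, endian = "little")
  n <- as.integer(hdr[1])
  macro <- readBin(con, "double", n, size = 8, endian = "little")
  micro <- readBin(con, "double", n, size = 8, endian = "little")
  photon_stream(macro, micro,
                meta = list(duration = if (!is.na(hdr[2])) hdr[2],
                            pulse_period_ns = if (!is.na(hdr[3])) hdr[3]))
}

#' Read and write correlation curves as CSV
#'
#' Columns `lag_s, G[, stderr]`.
#'
#' @param curve a [correlation_curve()].
#' @param path file path.
#' @return `read_correlation_csv` returns a [correlation_curve()].
#' @export
write_correlation_csv <- function(curve, path) {
  d <- data.frame(lag_s = curve$lags, G = curve$G)
  if (!is.null(curve$stderr)) d$stderr <- curve$stderr
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correlation_csv
#' @export
read_correlation_csv <- function(path) {
  d <- read.csv(path)
  correlation_curve(d$lag_s, d$G, stderr = d$stderr)
}

read_hash_meta <- function(path) {
  lines <- readLines(path, n = 50)
  lines <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", lines), "=", fixed = TRUE)
  setNames(lapply(kv, function(p) paste(p[-1], collapse = "=")),
           vapply(kv, `[`, "", 1))
}
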