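#' Read a 1-D signal from delimited text or WAV
#'
#' CSV/TSV files may hold a single value column (then `sample_rate` is
#' required) or a time column followed by a value column (the rate is then
#' inferred from the median time step).  WAV files (16-bit PCM or 32-bit
#' IEEE float, mono or multichannel) carry their own rate; one channel is
#' selected.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"csv"` or `"wav"`.
#' @param sample_rate required for single-column text input.
#' @param channel channel to select from multichannel WAV (default 1).
#' @param header does the text file carry a header row (default: detected).
#' @return list with `signal` (numeric vector) and `sample_rate`.
#' @export
read_signal <- function(path, format = c("auto", "csv", "wav"),
                        sample_rate = NULL, channel = 1L, header = NA) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = , tsv = , txt = "csv", wav = "wav",
                     stop(sprintf("unknown file extension '%s'", ext)))
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "wav") return(read_wav(path, channel = channel))

  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  nf <- utils::count.fields(path, sep = sep)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged delimited file: line %d has %d field(s), expected %d",
                 bad, nf[bad], nf[1L]))
  }
  if (is.na(header)) {
    first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
    header <- any(is.na(suppressWarnings(as.numeric(first))))
  }
  df <- utils::read.table(path, sep = sep, header = header)
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num)) stop("non-numeric values in signal file")
  if (ncol(df) == 1L) {
    if (is.null(sample_rate))
      stop("single-column input needs an explicit `sample_rate`")
    list(signal = df[[1L]], sample_rate = sample_rate)
  } else if (ncol(df) >= 2L) {
    tcol <- df[[1L]]
    dt <- diff(tcol)
    if (any(dt <= 0)) stop("time column must be strictly increasing")
    list(signal = df[[2L]], sample_rate = 1 / stats::median(dt))
  } else stop("empty signal file")
}

# --- minimal RIFF/WAVE support (PCM16 and IEEE float32); no audio package
# --- is depended upon, so the chunk walk is done directly with readBin

read_wav <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1L, size = 2L,
                               endian = "little", signed = FALSE),
        channels = readBin(raw[3:4], "integer", 1L, size = 2L,
                           endian = "little", signed = FALSE),
        sample_rate = readBin(raw[5:8], "integer", 1L, size = 4L,
                              endian = "little"),
        bits = readBin(raw[15:16], "integer", 1L, size = 2L,
                       endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV: missing fmt or data chunk")
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    vals <- readBin(data, "integer", length(data) %/% 2L, size = 2L,
                    endian = "little") / 32767
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    vals <- readBin(data, "double", length(data) %/% 4L, size = 4L,
                    endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bit)",
                 fmt$audio_format, fmt$bits))
  }
  nch <- fmt$channels
  if (channel < 1L || channel > nch)
    stop(sprintf("channel %d out of range 1..%d", channel, nch))
  sig <- vals[seq(channel, length(vals), by = nch)]
  list(signal = sig, sample_rate = fmt$sample_rate)
}

#' Write a mono signal as 16-bit PCM WAV
#'
#' @param signal numeric vector in `[-1, 1]` (clipped otherwise).
#' @param path output path.
#' @param sample_rate sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, sample_rate) {
  pcm <- as.integer(round(pmax(-1, pmin(1, signal)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")          # PCM
  writeBin(1L, con, size = 2L, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")          # block align
  writeBin(16L, con, size = 2L, endian = "little")         # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Write decomposition results to a directory
#'
#' Emits `imfs.csv` (time column plus one column per IMF, then residual and
#' filtered-out content), `diagnostics.json` (segments, filters, fusion map,
#' reconstruction error), and optionally PNG plots.
#'
#' @param result an `ebmd_result`.
#' @param out_dir output directory (created if absent).
#' @param plots also write diagnostic plots (default `FALSE`).
#' @return character vector of written paths, invisibly.
#' @export
write_result <- function(result, out_dir, plots = FALSE) {
  stopifnot(inherits(result, "ebmd_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(result$residual)
  df <- data.frame(time = (seq_len(n) - 1) / result$sample_rate)
  m <- imf_matrix(result)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- m[, j]
  df$residual <- result$residual
  df$filtered_out <- result$filtered_out
  csv_path <- file.path(out_dir, "imfs.csv")
  utils::write.csv(df, csv_path, row.names = FALSE)

  diag <- result$diagnostics
  js <- list(
    sample_rate = result$sample_rate,
    n = n,
    n_imfs = length(result$imfs),
    spectrum_axis = diag$spectrum_axis,
    spectrum = diag$spectrum,
    segments = diag$segments,
    filters = diag$filters,
    fusion_members = diag$fusion_members,
    imf_dominant_freq = vapply(result$imfs, function(s)
      s$signature$dominant_freq, numeric(1)),
    reconstruction_error = diag$reconstruction_error,
    config = unclass(result$config)[!vapply(unclass(result$config), is.null,
                                            logical(1))])
  json_path <- file.path(out_dir, "diagnostics.json")
  jsonlite::write_json(js, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(csv_path, json_path)
  if (plots) {
    p1 <- file.path(out_dir, "modes.png")
    grDevices::png(p1, width = 900, height = 600)
    print(autoplot.ebmd_result(result))
    grDevices::dev.off()
    p2 <- file.path(out_dir, "spectrum.png")
    grDevices::png(p2, width = 900, height = 400)
    print(plot_blaschke_spectrum(result))
    grDevices::dev.off()
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
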