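# Minimal RIFF/WAVE PCM16 mono reader and writer plus the CSV manifest
# format used to move datasets on and off disk.

#' Write a mono 16-bit PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16-bit integers.
#'
#' @param x Numeric waveform.
#' @param path Output file path.
#' @param fs Sampling rate in Hz.
#' @export
write_wav <- function(x, path, fs) {
  check_positive(fs, "fs")
  x <- pmin(1, pmax(-1, as.numeric(x)))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")            # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path File path.
#' @return List with `samples` (numeric in \[-1, 1\]) and `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) {
    rlang::abort(sprintf("not a RIFF file: %s", path), class = "pcgstack_invalid_input")
  }
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) {
    rlang::abort(sprintf("not a WAVE file: %s", path), class = "pcgstack_invalid_input")
  }
  fs <- NULL
  bits <- NULL
  channels <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) {
      rlang::abort("no data chunk found.", class = "pcgstack_invalid_input")
    }
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- sz - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      if (is.null(fs)) rlang::abort("data chunk before fmt.", class = "pcgstack_invalid_input")
      if (bits != 16L || channels != 1L) {
        rlang::abort("only mono 16-bit PCM supported.", class = "pcgstack_invalid_input")
      }
      pcm <- readBin(con, "integer", sz / 2L, size = 2, signed = TRUE,
                     endian = "little")
      return(list(samples = pcm / 32767, fs = fs))
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
}

#' Write a PCG dataset to WAV files with a CSV manifest
#'
#' @param dataset Tibble with `segment_id`, `subject_id`, `label`, `fs`,
#'   `samples` (as produced by [simulate_pcg_dataset()]).
#' @param dir Output directory (created if missing).
#' @return Path to the written `manifest.csv`, invisibly.
#' @export
write_pcg_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    p <- file.path(dir, paste0(dataset$segment_id[i], ".wav"))
    # normalize to fit the 16-bit range without clipping
    x <- dataset$samples[[i]]
    peak <- max(abs(x), 1e-12)
    write_wav(x / peak, p, dataset$fs[i])
    paths[i] <- p
  }
  manifest <- dplyr::mutate(
    dplyr::select(dataset, "segment_id", "subject_id", "label"),
    path = paths
  )
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a PCG dataset from a CSV manifest
#'
#' The manifest needs columns `segment_id`, `subject_id`, `label`, `path`;
#' relative paths resolve against the manifest's directory.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return Dataset tibble in the same shape [simulate_pcg_dataset()] emits.
#' @export
read_pcg_manifest <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("segment_id", "subject_id", "label", "path")
  if (!all(need %in% names(man))) {
    rlang::abort(sprintf("manifest must have columns %s", paste(need, collapse = ", ")),
                 class = "pcgstack_invalid_input")
  }
  base <- dirname(manifest_path)
  rows <- purrr::pmap(man, function(segment_id, subject_id, label, path, ...) {
    p <- if (file.exists(path)) path else file.path(base, path)
    if (!file.exists(p)) {
      rlang::abort(sprintf("audio file missing for segment '%s': %s", segment_id, path),
                   class = "pcgstack_invalid_input")
    }
    w <- read_wav(p)
    tibble::tibble(segment_id = segment_id, subject_id = subject_id,
                   label = as.integer(label), fs = w$fs, samples = list(w$samples))
  })
  dplyr::bind_rows(rows)
}
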