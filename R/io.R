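#' Read an ECG record from CSV
#'
#' Accepts either a one-column file of sample values (mV) or a two-column
#' file of (sample index, value); a header row is detected automatically.
#' The sampling rate is not stored in the CSV and must be supplied.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate (Hz); required.
#' @param id Optional record id; defaults to the file name.
#' @return An [ecg_record()].
#' @export
read_ecg_csv <- function(path, fs, id = basename(path)) {
  if (missing(fs)) stop("`fs` is required to read a CSV record", call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("%s: empty file", path), call. = FALSE)
  first_data <- 1L
  fields <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (any(is.na(suppressWarnings(as.numeric(fields))))) first_data <- 2L
  if (first_data > length(lines)) {
    stop(sprintf("%s: no data rows", path), call. = FALSE)
  }
  vals <- numeric(length(lines) - first_data + 1L)
  for (i in seq.int(first_data, length(lines))) {
    fields <- suppressWarnings(as.numeric(
      strsplit(lines[i], ",", fixed = TRUE)[[1]]))
    if (!length(fields) || length(fields) > 2L || anyNA(fields)) {
      stop(sprintf("%s: malformed row at line %d", path, i), call. = FALSE)
    }
    vals[i - first_data + 1L] <- fields[length(fields)]
  }
  ecg_record(vals, fs, id = id)
}

#' Write an ECG record to CSV
#'
#' Two columns: 0-based sample index and value in mV, with a header row.
#'
#' @param record An [ecg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  sig <- record_samples(record)
  utils::write.csv(
    data.frame(sample = seq_along(sig) - 1L, mV = sig),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Canonical JSON for the container payload (full double precision).
container_payload_json <- function(comp) {
  payload <- list(
    version = comp$version, fs = comp$fs,
    scheme = list(pre = comp$scheme$pre, post = comp$scheme$post,
                  central_width = comp$scheme$central_width,
                  target = comp$scheme$target, method = comp$scheme$method,
                  stride = comp$scheme$stride),
    nd = comp$nd,
    decoder = list(w_ho = comp$decoder$w_ho, b_o = comp$decoder$b_o),
    weights = comp$weights,
    r_peaks = comp$r_peaks,
    codes = as.matrix(comp$codes),
    mins = comp$mins, maxs = comp$maxs
  )
  jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE)
}

md5_of_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(s, tf, eos = NULL)
  unname(tools::md5sum(tf))
}

#' Write a compressed record container to disk
#'
#' Versioned JSON with explicit arrays (the decoder and codes are small, so a
#' binary format buys nothing) plus an md5 checksum of the payload; the
#' write/read round trip is bit-exact.
#'
#' @param comp A [compress_record()] container.
#' @param path Output path (conventionally `.ecgz.json`).
#' @return `path`, invisibly.
#' @export
write_compressed <- function(comp, path) {
  if (!inherits(comp, "compressed_record")) {
    stop("`comp` must be a compressed_record", call. = FALSE)
  }
  payload <- container_payload_json(comp)
  out <- sprintf('{"checksum":"%s","payload":%s}', md5_of_string(payload),
                 payload)
  writeLines(out, path)
  invisible(path)
}

#' Read a compressed record container from disk
#'
#' Verifies the format version and the payload checksum; a truncated or
#' edited file is rejected.
#'
#' @param path Path written by [write_compressed()].
#' @return A `compressed_record`.
#' @export
read_compressed <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  obj <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                  error = function(e) {
                    stop(sprintf("%s: not a valid compressed container (%s)",
                                 path, conditionMessage(e)), call. = FALSE)
                  })
  if (is.null(obj$checksum) || is.null(obj$payload)) {
    stop(sprintf("%s: missing checksum or payload", path), call. = FALSE)
  }
  # verify the checksum against the payload text exactly as stored
  m <- regexpr('"payload":', txt, fixed = TRUE)
  payload_txt <- substr(txt, m + attr(m, "match.length"), nchar(txt) - 1L)
  if (!identical(unname(obj$checksum), md5_of_string(payload_txt))) {
    stop(sprintf("%s: checksum mismatch; file corrupted", path), call. = FALSE)
  }
  p <- obj$payload
  if (!identical(p$version, "1.0")) {
    stop(sprintf("%s: unsupported container version '%s'", path, p$version),
         call. = FALSE)
  }
  sch <- segmentation_scheme(p$scheme$pre, p$scheme$post,
                             p$scheme$central_width, p$scheme$target,
                             p$scheme$method, p$scheme$stride)
  comp <- structure(list(
    version = p$version, fs = as.numeric(p$fs), scheme = sch,
    nd = as.integer(p$nd),
    decoder = list(w_ho = matrix(as.numeric(p$decoder$w_ho),
                                 nrow = p$nd),
                   b_o = as.numeric(p$decoder$b_o)),
    weights = as.numeric(p$weights),
    r_peaks = as.integer(p$r_peaks),
    codes = matrix(as.numeric(p$codes), ncol = p$nd),
    mins = as.numeric(p$mins), maxs = as.numeric(p$maxs)
  ), class = "compressed_record")
  comp
}
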