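#' Write a recording to disk
#'
#' Two interchange formats are supported. `"csv"` (canonical) writes a
#' UTF-8, '.'-decimal file with header `h_volts,v_volts,label` plus a
#' `# rate_hz:` comment line carrying the sampling rate. `"json"` writes a
#' single-object container with keys `horizontal`, `vertical`, `labels` and
#' `rate`, mirroring the variable layout of the MAT-style session files
#' produced by typical acquisition software.
#'
#' @param recording An [eog_recording()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @param overwrite Overwrite an existing file? Defaults to `FALSE`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = NULL, overwrite = FALSE) {
  stopifnot(inherits(recording, "eog_recording"))
  format <- infer_format(path, format)
  if (file.exists(path) && !overwrite) {
    stop("file exists; pass overwrite = TRUE to replace it: ", path, call. = FALSE)
  }
  labels <- recording$labels
  if (is.null(labels)) labels <- rep(NA_integer_, n_samples(recording))
  if (format == "csv") {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(sprintf("# rate_hz: %.17g", recording$sampling_rate), con)
    writeLines("h_volts,v_volts,label", con)
    writeLines(paste(
      sprintf("%.17g", recording$horizontal),
      sprintf("%.17g", recording$vertical),
      ifelse(is.na(labels), "", as.character(labels)),
      sep = ","
    ), con)
  } else {
    obj <- list(horizontal = recording$horizontal,
                vertical = recording$vertical,
                labels = labels,
                rate = recording$sampling_rate)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' Inverse of [write_recording()]. Both numeric channels must be present
#' and of equal length; a label column consisting only of missing values
#' yields an unlabelled recording.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @param sampling_rate Fallback sampling rate in Hz when the file does not
#'   record one (default 650).
#' @return An [eog_recording()].
#' @export
read_recording <- function(path, format = NULL, sampling_rate = 650) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- infer_format(path, format)
  if (format == "csv") {
    first <- readLines(path, n = 1L)
    rate <- sampling_rate
    skip <- 0L
    if (startsWith(first, "# rate_hz:")) {
      rate <- as.numeric(sub("# rate_hz:", "", first, fixed = TRUE))
      skip <- 1L
    }
    df <- utils::read.csv(path, skip = skip, header = TRUE,
                          colClasses = c("numeric", "numeric", "integer"))
    need <- c("h_volts", "v_volts")
    if (!all(need %in% names(df))) {
      stop("csv must contain columns h_volts and v_volts", call. = FALSE)
    }
    labels <- if ("label" %in% names(df) && any(!is.na(df$label))) df$label else NULL
    eog_recording(df$h_volts, df$v_volts, rate, labels)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    need <- c("horizontal", "vertical", "rate")
    if (!all(need %in% names(obj))) {
      stop("container must hold keys horizontal, vertical, rate", call. = FALSE)
    }
    labels <- obj$labels
    if (!is.null(labels) && all(is.na(labels))) labels <- NULL
    eog_recording(obj$horizontal, obj$vertical, obj$rate, labels)
  }
}

infer_format <- function(path, format) {
  if (!is.null(format)) {
    return(match.arg(format, c("csv", "json")))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext else "csv"
}
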