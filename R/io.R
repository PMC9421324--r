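#' Read a 1D diffraction pattern from two-column text
#'
#' Accepts whitespace- or comma-separated numeric text with `#` comment
#' lines; comments of the form `# key: value` are parsed into metadata
#' (recognized keys: `sample_id`, `d2o_fraction`, `temperature_C`).
#'
#' @param path File path.
#' @param q_units `"nm"` (q in nm^-1, default) or `"angstrom"` (q in A^-1,
#'   converted to nm^-1).
#' @return A [diffraction_pattern()].
#' @export
load_pattern <- function(path, q_units = c("nm", "angstrom")) {
  q_units <- match.arg(q_units)
  parsed <- .read_two_column(path)
  q <- parsed$data[[1]]
  if (q_units == "angstrom") q <- q * 10
  meta <- parsed$meta
  if (length(q) < 10) stop("pattern has fewer than 10 points: ", path)
  if (any(!is.finite(q)) || any(!is.finite(parsed$data[[2]]))) {
    stop("pattern contains NaN/NA values: ", path)
  }
  if (any(diff(q) <= 0)) stop("non-monotone q in ", path)
  diffraction_pattern(
    q, parsed$data[[2]],
    sample_id = if (!is.null(meta$sample_id)) meta$sample_id else
      NA_character_,
    d2o_fraction = if (!is.null(meta$d2o_fraction))
      as.numeric(meta$d2o_fraction) else NA_real_,
    temperature_C = if (!is.null(meta$temperature_C))
      as.numeric(meta$temperature_C) else NA_real_)
}

#' Read an FTIR spectrum from two-column text
#'
#' Same format as [load_pattern()] (wavenumber in cm^-1, absorbance).
#'
#' @param path File path.
#' @return An [ftir_spectrum()].
#' @export
load_spectrum <- function(path) {
  parsed <- .read_two_column(path)
  meta <- parsed$meta
  ftir_spectrum(
    parsed$data[[1]], parsed$data[[2]],
    temperature_C = if (!is.null(meta$temperature_C))
      as.numeric(meta$temperature_C) else NA_real_,
    sample_id = if (!is.null(meta$sample_id)) meta$sample_id else
      NA_character_)
}

.read_two_column <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  com <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (l in com) {
    m <- regmatches(l, regexec("^\\s*#\\s*([A-Za-z_0-9]+)\\s*:\\s*(.+)$", l))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) stop("no data rows in ", path)
  sep <- if (grepl(",", body[1])) "," else ""
  dat <- utils::read.table(text = body, sep = sep, header = FALSE,
                           col.names = c("x", "y"),
                           colClasses = "numeric")
  list(data = dat, meta = meta)
}

#' Write a pattern or spectrum as commented two-column text
#'
#' @param obj A [diffraction_pattern()] or [ftir_spectrum()].
#' @param path Output path.
#' @export
write_two_column <- function(obj, path) {
  meta <- c(sample_id = attr(obj, "sample_id"),
            d2o_fraction = attr(obj, "d2o_fraction"),
            temperature_C = attr(obj, "temperature_C"))
  meta <- meta[!is.na(meta)]
  hdr <- sprintf("# %s: %s", names(meta), as.character(meta))
  body <- apply(format(as.data.frame(obj), digits = 10, trim = TRUE,
                       scientific = FALSE), 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
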