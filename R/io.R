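#' Write a spectrum to a two-column text file
#'
#' Spectrometer-style ASCII export: '#'-prefixed header lines carrying
#' role/source and any scalar metadata, then one
#' `wavelength<sep>intensity` pair per line.  Numerics use 15
#' significant digits so round trips are faithful to 1e-12 relative.
#'
#' @param s A [spectrum1d()].
#' @param path Output file path.
#' @param dialect `"tsv"` (tab separator) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, dialect = c("tsv", "csv")) {
  stopifnot(inherits(s, "spectrum1d"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  hdr <- c(sprintf("# role: %s", s$role), sprintf("# source: %s", s$source))
  scalars <- Filter(function(v) is.atomic(v) && length(v) == 1, s$meta)
  hdr <- c(hdr, vapply(names(scalars), function(nm) {
    sprintf("# %s: %s", nm, format(scalars[[nm]], digits = 15))
  }, character(1)))
  body <- paste(format(s$wavelength, digits = 15, trim = TRUE),
                format(s$intensity, digits = 15, trim = TRUE), sep = sep)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a spectrum from a two-column text file
#'
#' Accepts tab-, comma- or whitespace-delimited two-column numeric
#' bodies with optional '#'-prefixed metadata headers (role and source
#' are recovered when present).  Wavelengths must be unique; a
#' decreasing grid is sorted with a warning.
#'
#' @param path Input file path.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @return A [spectrum1d()].
#' @export
read_spectrum <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 8) stop("a spectrum needs at least 8 data rows")
  sep <- switch(dialect, tsv = "\t", csv = ",",
                auto = if (grepl(",", body[1])) "," else "[\t ]+")
  parts <- strsplit(trimws(body), sep)
  bad <- which(lengths(parts) < 2)
  if (length(bad)) stop("malformed data row at line ", bad[1])
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  if (anyNA(w) || anyNA(y)) stop("non-numeric values in spectrum body")
  if (anyDuplicated(w)) {
    stop("duplicate wavelength value: ", w[which(duplicated(w))[1]], " nm")
  }
  if (all(diff(w) < 0)) {
    warning("wavelengths were in decreasing order; sorting")
  }
  o <- order(w)
  w <- w[o]
  y <- y[o]
  get_field <- function(key, default) {
    m <- grep(sprintf("^\\s*#\\s*%s:", key), hdr, value = TRUE)
    if (length(m)) trimws(sub(sprintf("^\\s*#\\s*%s:", key), "", m[1]))
    else default
  }
  role <- get_field("role", "emission")
  src <- get_field("source", "none")
  spectrum1d(w, y, role = role, source = src,
             meta = list(file = path))
}

#' Write an EEM as a CSV matrix
#'
#' Excitation wavelengths label the rows, emission wavelengths the
#' columns; the top-left cell is empty.
#'
#' @param e An [eem()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eem <- function(e, path) {
  stopifnot(inherits(e, "eem"))
  m <- e$intensity
  lines <- c(
    paste(c("", format(e$em, digits = 15, trim = TRUE)), collapse = ","),
    vapply(seq_along(e$ex), function(i) {
      paste(c(format(e$ex[i], digits = 15, trim = TRUE),
              format(m[i, ], digits = 15, trim = TRUE)), collapse = ",")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an EEM from a CSV matrix
#'
#' @param path Input file path in the [write_eem()] layout.
#' @return An [eem()].
#' @export
read_eem <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, check.names = FALSE)
  em <- as.numeric(raw[1, -1])
  ex <- as.numeric(raw[-1, 1])
  m <- as.matrix(raw[-1, -1])
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  eem(ex, em, m, meta = list(file = path))
}

#' Write CBC records to CSV or JSON
#'
#' @param records A [cbc_record()] or list of them.
#' @param path Output path; format chosen by extension (`.json` for
#'   JSON, otherwise CSV).
#' @return `path`, invisibly.
#' @export
write_cbc <- function(records, path) {
  if (inherits(records, "cbc_record")) records <- list(records)
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(hb_gdl = r$hb_gdl, rbc_1e6_per_ul = r$rbc_1e6_per_ul,
               hct_pct = r$hct_pct,
               mch_pg = if (is.null(r$mch_pg)) NA_real_ else r$mch_pg,
               age_years = r$age_years, sex = r$sex,
               neutrophils_pct = r$neutrophils_pct,
               lymphocytes_pct = r$lymphocytes_pct,
               eosinophils_pct = r$eosinophils_pct,
               basophils_pct = r$basophils_pct)
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read CBC records from CSV or JSON
#'
#' @param path Input path written by [write_cbc()] (or any table with
#'   the same column names).
#' @return A list of [cbc_record()] objects.
#' @export
read_cbc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)
  }
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    cbc_record(
      hb_gdl = r$hb_gdl, rbc_1e6_per_ul = r$rbc_1e6_per_ul,
      hct_pct = r$hct_pct,
      mch_pg = if (!is.null(r$mch_pg) && is.finite(r$mch_pg)) r$mch_pg
               else NULL,
      age_years = r$age_years, sex = r$sex,
      neutrophils_pct = r$neutrophils_pct %||% NA_real_,
      lymphocytes_pct = r$lymphocytes_pct %||% NA_real_,
      eosinophils_pct = r$eosinophils_pct %||% NA_real_,
      basophils_pct = r$basophils_pct %||% NA_real_,
      meta = list(file = path)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
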