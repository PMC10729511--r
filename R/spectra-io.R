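#' Read a time-resolved spectra matrix from wide CSV
#'
#' Canonical on-disk format: UTF-8 CSV, "." decimal, first column header
#' \code{wavenumber_cm-1}, remaining column headers the acquisition times in
#' decimal hours, numeric body. The axis is stored descending regardless of
#' file order; columns are sorted by time.
#'
#' @param path path to the CSV file.
#' @return A \linkS4class{SpectraSet}.
#' @seealso \code{\link{writeSpectraCSV}}
#' @export
readSpectraCSV <- function(path) {
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) < 2)
    stop("format error: file must contain a header and at least one data row")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("format error: ragged row %d (expected %d fields, found %d)",
                 bad, nf[1L], nf[bad]))
  }
  d <- utils::read.csv(path, check.names = FALSE, header = TRUE)
  if (ncol(d) < 2)
    stop("format error: need a wavenumber column plus at least one spectrum")
  if (!identical(names(d)[1L], "wavenumber_cm-1"))
    stop("format error: first column header must be 'wavenumber_cm-1'")
  times <- suppressWarnings(as.numeric(names(d)[-1L]))
  if (anyNA(times))
    stop("format error: non-numeric time header(s): ",
         paste(names(d)[-1L][is.na(times)], collapse = ", "))
  if (anyDuplicated(times))
    stop("validation error: duplicate time headers: ",
         paste(unique(times[duplicated(times)]), collapse = ", "))
  body <- as.matrix(d)
  if (anyNA(body)) {
    bad <- which(apply(is.na(body), 1L, any))[1L]
    stop(sprintf("format error: missing/non-numeric cell in data row %d", bad))
  }
  w <- body[, 1L]
  if (length(w) >= 2 && !(all(diff(w) > 0) || all(diff(w) < 0)))
    stop("validation error: wavenumber axis is not strictly monotonic")
  o <- order(times)
  SpectraSet(wavenumbers = w,
             intensities = t(body[, -1L, drop = FALSE][, o, drop = FALSE]),
             times = times[o],
             provenance = sprintf("read_csv(%s)", basename(path)))
}

#' Write a SpectraSet to wide CSV
#'
#' Inverse of \code{\link{readSpectraCSV}}: values round-trip exactly at the
#' declared number of significant digits.
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param path output path.
#' @param digits significant digits written (default 12).
#' @return \code{path}, invisibly.
#' @export
writeSpectraCSV <- function(s, path, digits = 12) {
  stopifnot(is(s, "SpectraSet"))
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  header <- paste(c("wavenumber_cm-1", fmt(s@times)), collapse = ",")
  body <- cbind(fmt(s@wavenumbers),
                matrix(fmt(t(s@intensities)), nrow = nChannels(s)))
  lines <- c(header, apply(body, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a reference table from long-form CSV
#'
#' Expected columns: \code{time_h}, \code{analyte}, \code{units},
#' \code{value}. Missing measurements may simply be absent rows.
#'
#' @param path path to the CSV file.
#' @return A \linkS4class{ReferenceTable}.
#' @export
readReferenceCSV <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, header = TRUE,
                       stringsAsFactors = FALSE)
  need <- c("time_h", "analyte", "units", "value")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  tp <- sort(unique(d$time_h))
  an <- unique(d$analyte)
  v <- matrix(NA_real_, length(tp), length(an), dimnames = list(NULL, an))
  u <- character(length(an)); names(u) <- an
  for (i in seq_len(nrow(d))) {
    v[match(d$time_h[i], tp), d$analyte[i]] <- d$value[i]
    u[[d$analyte[i]]] <- d$units[i]
  }
  ReferenceTable(timepoints = tp, values = v, units = u)
}

#' Write a reference table to long-form CSV
#'
#' @param ref a \linkS4class{ReferenceTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReferenceCSV <- function(ref, path) {
  stopifnot(is(ref, "ReferenceTable"))
  rows <- c("time_h,analyte,units,value")
  v <- ref@values
  for (a in colnames(v)) {
    ok <- !is.na(v[, a])
    rows <- c(rows, sprintf("%.10g,%s,%s,%.10g",
                            ref@timepoints[ok], a, ref@units[[a]], v[ok, a]))
  }
  writeLines(rows, path)
  invisible(path)
}

.jcampNum <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out
}

#' Read a single-block JCAMP-DX spectrum
#'
#' Minimal reader for the spectral exchange format: single block, tabular
#' \code{##XYDATA=(X++(Y..Y))} or \code{##XYPOINTS=(XY..XY)} data,
#' \code{XFACTOR}/\code{YFACTOR} scaling, and axis conversion to cm^-1 from
#' micrometers or nanometers. Compressed (DIF/DUP/SQZ) forms are not
#' supported.
#'
#' @param path path to the JCAMP-DX file.
#' @return A \linkS4class{Spectrum}.
#' @export
readJCAMP <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub(";.*$", "", lines)  # line comments
  isLabel <- grepl("^##", lines)
  if (sum(grepl("^##TITLE=", lines, ignore.case = TRUE)) > 1L)
    stop("unsupported: multi-block JCAMP-DX files are not supported")
  labs <- lines[isLabel]
  keys <- toupper(sub("^##([^=]*)=.*$", "\\1", labs))
  keys <- gsub("[ _-]", "", keys)
  vals <- trimws(sub("^##[^=]*=", "", labs))
  getLab <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) NULL else vals[i]
  }
  if (is.null(getLab("TITLE")))
    stop("format error: missing required label ##TITLE")
  dataKey <- if ("XYDATA" %in% keys) "XYDATA"
             else if ("XYPOINTS" %in% keys) "XYPOINTS"
             else stop("format error: no ##XYDATA or ##XYPOINTS block")
  npoints <- .jcampNum(getLab("NPOINTS"))
  if (is.null(getLab("NPOINTS")) || is.na(npoints))
    stop("format error: missing required label ##NPOINTS")
  xf <- .jcampNum(getLab("XFACTOR")); if (!length(xf) || is.na(xf)) xf <- 1
  yf <- .jcampNum(getLab("YFACTOR")); if (!length(yf) || is.na(yf)) yf <- 1
  xunits <- toupper(getLab("XUNITS") %||% "1/CM")

  start <- which(isLabel)[match(dataKey, keys)]
  stops <- which(grepl("^##", lines))
  stops <- stops[stops > start]
  end <- if (length(stops)) min(stops) - 1L else length(lines)
  body <- lines[seq(start + 1L, end)]
  body <- body[nzchar(trimws(body))]
  toks <- lapply(body, function(l)
    .jcampNum(strsplit(trimws(l), "[,; \t]+")[[1L]]))
  if (any(vapply(toks, anyNA, TRUE)))
    stop("format error: non-numeric value in data block")

  if (dataKey == "XYPOINTS") {
    flat <- unlist(toks)
    if (length(flat) %% 2L != 0L)
      stop("format error: odd number of values in XYPOINTS block")
    x <- flat[seq(1L, length(flat), by = 2L)] * xf
    y <- flat[seq(2L, length(flat), by = 2L)] * yf
  } else {
    x <- numeric(); y <- numeric()
    for (tk in toks) {
      if (length(tk) < 2L)
        stop("format error: XYDATA line with fewer than two values")
      ny <- length(tk) - 1L
      firstx <- .jcampNum(getLab("FIRSTX"))
      lastx <- .jcampNum(getLab("LASTX"))
      dx <- if (!is.null(getLab("FIRSTX")) && !is.null(getLab("LASTX")) &&
                npoints > 1) (lastx - firstx) / (npoints - 1) / xf else NA
      x <- c(x, tk[1L] + if (!is.na(dx)) dx * (seq_len(ny) - 1L) else
        seq_len(ny) - 1L)
      y <- c(y, tk[-1L])
    }
    x <- x * xf
    y <- y * yf
  }
  if (length(y) != npoints)
    stop(sprintf("format error: NPOINTS=%d but %d data points found",
                 npoints, length(y)))
  fx <- .jcampNum(getLab("FIRSTX")); lx <- .jcampNum(getLab("LASTX"))
  if (length(fx) && !is.na(fx) && abs(x[1L] - fx) > 1e-6 * max(1, abs(fx)))
    stop("format error: FIRSTX inconsistent with data block")
  if (length(lx) && !is.na(lx) &&
      abs(x[length(x)] - lx) > 1e-6 * max(1, abs(lx)))
    stop("format error: LASTX inconsistent with data block")
  if (grepl("MICROMETER", xunits)) x <- 1e4 / x
  else if (grepl("NANOMETER", xunits)) x <- 1e7 / x
  o <- order(x, decreasing = TRUE)
  Spectrum(wavenumbers = x[o], intensities = y[o])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
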