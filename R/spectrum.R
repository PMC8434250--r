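#' Construct a Raman spectrum
#'
#' A `raman_spectrum` is a wavenumber-indexed intensity trace with free-form
#' acquisition metadata (sample id, replicate index, laser power, scan count,
#' physical state, ...). The wavenumber axis is stored strictly ascending in
#' cm-1; constructors re-sort descending input and collapse duplicate
#' wavenumbers by averaging their intensities.
#'
#' @param wavenumber numeric vector of Raman shifts in cm-1 (length >= 8 for
#'   measured spectra; shorter vectors are allowed but flagged by
#'   [validate_spectrum()] when `strict = TRUE`).
#' @param intensity numeric vector of intensities in arbitrary units, same
#'   length as `wavenumber`.
#' @param meta named list of metadata; stored verbatim.
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber`, `intensity`, `meta`.
#' @examples
#' s <- raman_spectrum(c(300, 301, 302), c(1, 2, 1.5),
#'                     meta = list(sample = "demo"))
#' s
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = list()) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity must have equal length", call. = FALSE)
  if (length(wavenumber) == 0)
    stop("empty spectrum", call. = FALSE)
  if (!all(is.finite(wavenumber)) || !all(is.finite(intensity)))
    stop("spectrum contains non-finite values", call. = FALSE)
  o <- order(wavenumber)
  wavenumber <- wavenumber[o]
  intensity <- intensity[o]
  if (anyDuplicated(wavenumber)) {
    intensity <- as.numeric(tapply(intensity, factor(wavenumber, levels = unique(wavenumber)), mean))
    wavenumber <- unique(wavenumber)
  }
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 meta = as.list(meta)),
            class = "raman_spectrum")
}

#' Validate a Raman spectrum
#'
#' Checks the class invariants: equal-length finite axis and intensity,
#' strictly increasing axis, and (when `strict`) length >= 8.
#'
#' @param s a `raman_spectrum`.
#' @param strict require at least 8 points (the minimum for the smoothed
#'   derivatives used downstream).
#' @return `s`, invisibly; errors describe the violated invariant.
#' @export
validate_spectrum <- function(s, strict = FALSE) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (length(s$wavenumber) != length(s$intensity))
    stop("axis/intensity length mismatch", call. = FALSE)
  if (!all(is.finite(s$wavenumber)) || !all(is.finite(s$intensity)))
    stop("non-finite values in spectrum", call. = FALSE)
  if (is.unsorted(s$wavenumber, strictly = TRUE))
    stop("wavenumber axis not strictly increasing", call. = FALSE)
  if (strict && length(s$wavenumber) < 8)
    stop("spectrum has fewer than 8 points", call. = FALSE)
  invisible(s)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(x$wavenumber)
  cat(sprintf("Raman spectrum: %d points, %.1f-%.1f cm-1\n",
              length(x$wavenumber), rng[1], rng[2]))
  if (length(x$meta)) {
    keep <- vapply(x$meta, function(v) is.atomic(v) && length(v) == 1, TRUE)
    if (any(keep))
      cat("  meta:", paste(names(x$meta)[keep],
                           vapply(x$meta[keep], as.character, ""),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumber, intensity = x$intensity)
}

#' @export
range.raman_spectrum <- function(..., na.rm = FALSE) {
  range(..1$wavenumber)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumber)

# append one provenance entry (a character string) to spectrum metadata
add_provenance <- function(s, what) {
  s$meta$provenance <- c(s$meta$provenance, what)
  s
}

#' Read a spectrum from disk
#'
#' Reads two-column numeric text (CSV or TSV; `#`-prefixed comment lines may
#' carry `key: value` metadata) or a JCAMP-DX file with AFFN-encoded
#' `XYDATA=(X++(Y..Y))` or `XYPOINTS=(XY..XY)` tables. Descending axes are
#' re-sorted ascending and duplicate wavenumbers collapsed by mean.
#'
#' @param path file path.
#' @param dialect one of `"auto"`, `"csv"`, `"tsv"`, `"jcamp"`. `"auto"`
#'   dispatches on the file extension (`.jdx`/`.dx` are JCAMP, `.tsv`/`.txt`
#'   tab-separated, anything else comma-separated).
#' @return A [raman_spectrum] with header metadata in `$meta`.
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, dialect = c("auto", "csv", "tsv", "jcamp")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, jdx = , dx = "jcamp", tsv = , txt = "tsv", "csv")
  }
  if (dialect == "jcamp") return(read_jcamp(path))
  sep <- if (dialect == "tsv") "\t" else ","
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  is_comment <- startsWith(trimws(lines), "#")
  for (cl in lines[is_comment]) {
    body <- sub("^\\s*#\\s?", "", cl)
    m <- regmatches(body, regexec("^([^:]+):\\s*(.*)$", body))[[1]]
    if (length(m) == 3) {
      val <- utils::type.convert(m[3], as.is = TRUE)
      meta[[trimws(m[2])]] <- val
    }
  }
  data_lines <- lines[!is_comment & nzchar(trimws(lines))]
  if (!length(data_lines))
    stop("no data rows in ", path, call. = FALSE)
  parsed <- strsplit(data_lines, sep, fixed = TRUE)
  nums <- lapply(seq_along(parsed), function(i) {
    v <- suppressWarnings(as.numeric(trimws(parsed[[i]])))
    if (length(v) < 2 || any(is.na(v[1:2])))
      stop(sprintf("malformed row %d in %s: '%s'",
                   which(!is_comment & nzchar(trimws(lines)))[i], path,
                   data_lines[i]), call. = FALSE)
    v[1:2]
  })
  mat <- do.call(rbind, nums)
  raman_spectrum(mat[, 1], mat[, 2], meta = meta)
}

# Minimal JCAMP-DX reader: AFFN-encoded XYDATA=(X++(Y..Y)) and
# XYPOINTS=(XY..XY) only; compressed SQZ/DIF/DUP forms are not supported.
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(name) {
    pat <- paste0("^##", name, "\\s*=\\s*(.*)$")
    hit <- grep(pat, lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(pat, "\\1", hit[1], ignore.case = TRUE)
  }
  xfac <- as.numeric(get_field("XFACTOR") %||% "1")
  yfac <- as.numeric(get_field("YFACTOR") %||% "1")
  meta <- list(title = get_field("TITLE"), xunits = get_field("XUNITS"),
               yunits = get_field("YUNITS"))
  meta <- meta[!vapply(meta, is.null, TRUE)]

  start_xy <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  start_pt <- grep("^##XYPOINTS\\s*=", lines, ignore.case = TRUE)
  end_tag <- grep("^##", lines)
  block_after <- function(i) {
    nxt <- end_tag[end_tag > i]
    stop_at <- if (length(nxt)) min(nxt) - 1 else length(lines)
    lines[seq(i + 1, stop_at)]
  }
  if (length(start_xy)) {
    body <- block_after(start_xy[1])
    xs <- ys <- list()
    for (ln in body) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[,;[:space:]]+")[[1]]))
      v <- v[!is.na(v)]
      if (length(v) < 2) next
      x0 <- v[1]
      yrow <- v[-1]
      xs[[length(xs) + 1]] <- x0
      ys[[length(ys) + 1]] <- yrow
    }
    if (!length(xs)) stop("no XYDATA rows in ", path, call. = FALSE)
    # per-line X is the abscissa of the first Y; interpolate within lines
    nx <- lengths(ys)
    x_start <- unlist(xs) * xfac
    # infer step from consecutive line starts (or FIRSTX/LASTX/NPOINTS)
    npt <- sum(nx)
    firstx <- as.numeric(get_field("FIRSTX") %||% (x_start[1] / xfac)) * 1
    lastx <- get_field("LASTX")
    if (!is.null(lastx) && npt > 1) {
      step <- (as.numeric(lastx) - firstx) / (npt - 1)
    } else if (length(x_start) > 1) {
      step <- (x_start[2] - x_start[1]) / nx[1]
    } else {
      stop("cannot infer abscissa step in ", path, call. = FALSE)
    }
    wn <- unlist(lapply(seq_along(xs), function(i)
      x_start[i] + step * (seq_len(nx[i]) - 1)))
    raman_spectrum(wn, unlist(ys) * yfac, meta = meta)
  } else if (length(start_pt)) {
    body <- block_after(start_pt[1])
    v <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "[,;[:space:]]+"))))
    v <- v[!is.na(v)]
    if (length(v) < 2 || length(v) %% 2 != 0)
      stop("malformed XYPOINTS block in ", path, call. = FALSE)
    m <- matrix(v, ncol = 2, byrow = TRUE)
    raman_spectrum(m[, 1] * xfac, m[, 2] * yfac, meta = meta)
  } else {
    stop("no XYDATA/XYPOINTS block in ", path, call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectrum to two-column text
#'
#' Writes `# key: value` comment headers for every scalar metadata entry,
#' then one `wavenumber<sep>intensity` row per point at fixed decimal
#' precision, so that write -> read -> write is byte-identical.
#'
#' @param s a [raman_spectrum].
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param digits decimal places written for both columns.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, dialect = c("csv", "tsv"), digits = 6) {
  validate_spectrum(s)
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  con <- file(path, open = "wt")
  on.exit(close(con))
  scalars <- s$meta[vapply(s$meta, function(v) is.atomic(v) && length(v) == 1, TRUE)]
  for (k in names(scalars))
    writeLines(sprintf("# %s: %s", k, format(scalars[[k]], scientific = FALSE)), con)
  writeLines(sprintf(paste0("%.", digits, "f", sep, "%.", digits, "f"),
                     s$wavenumber, s$intensity), con)
  invisible(path)
}
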