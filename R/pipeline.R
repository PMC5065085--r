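# The six-stage ingestion pipeline: Clean, Uncomment, Get LDRs, Validate,
# Standardize, Decompress.  Every stage annotates problems in the report
# instead of failing, so even badly damaged files yield a record whose
# errors element says exactly what went wrong.

#' Clean raw JCAMP text
#'
#' Removes non-ASCII bytes, replaces tabs with single spaces, strips
#' leading/trailing spaces from every line and normalizes line endings to
#' `"\n"`.  Idempotent.
#'
#' @param text Character scalar, the raw file content.
#' @return The cleaned text (newline-terminated).
#' @export
jdx_clean <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  lines <- strsplit(text, "\r\n|\r|\n")[[1]]
  if (!length(lines)) lines <- ""
  ascii <- iconv(lines, from = "UTF-8", to = "ASCII", sub = "")
  bad <- is.na(ascii)  # not valid UTF-8; recover bytes as latin-1
  ascii[bad] <- iconv(lines[bad], from = "latin1", to = "ASCII", sub = "")
  lines <- ascii
  lines <- gsub("\t", " ", lines, fixed = TRUE)
  lines <- gsub("[^\x20-\x7e]", "", lines)
  lines <- trimws(lines)
  out <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!nzchar(trimws(out)))
    stop("file is empty after cleaning", call. = FALSE)
  out
}

#' Strip and collect comments
#'
#' JCAMP comments run from `"$$"` to the end of the line.  They are removed
#' from the text and saved with their 1-based line number, preserving order.
#' Idempotent.
#'
#' @param text Cleaned text (see [jdx_clean()]).
#' @return A list with `text` (comment-free, line count preserved) and
#'   `comments` (data frame of `line`, `text`).
#' @export
jdx_uncomment <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  cl <- integer(0)
  ct <- character(0)
  for (i in seq_along(lines)) {
    p <- regexpr("$$", lines[i], fixed = TRUE)
    if (p > 0L) {
      cl <- c(cl, i)
      ct <- c(ct, trimws(substr(lines[i], p + 2L, nchar(lines[i]))))
      lines[i] <- trimws(substr(lines[i], 1L, p - 1L))
    }
  }
  list(text = paste0(paste(lines, collapse = "\n"), "\n"),
       comments = data.frame(line = cl, text = ct, stringsAsFactors = FALSE))
}

#' Extract labelled data records
#'
#' Every line starting with `"##"` opens a record; lines that do not are
#' continuation lines appended (newline preserved) to the current record's
#' value.  Labels are normalized with [normalize_label()]; the label as
#' written is kept in `raw_label`.  Text before the first record is a
#' structural warning, not an error.
#'
#' @param text Uncommented text.
#' @return A list with `ldrs` (list of records) and `entries` (structural
#'   warning entries).
#' @export
jdx_get_ldrs <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ldrs <- list()
  entries <- .empty_entries()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "##")) {
      if (!is.null(cur)) ldrs[[length(ldrs) + 1L]] <- cur
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 0L) {
        entries <- rbind(entries, .entry(
          "GETLDRS", i, sprintf("LDR line has no '=': %s", ln), "warning"))
        raw_label <- substr(ln, 3L, nchar(ln))
        value <- ""
      } else {
        raw_label <- substr(ln, 3L, eq - 1L)
        value <- substr(ln, eq + 1L, nchar(ln))
      }
      cur <- new_ldr(label = .norm_label(raw_label), raw_label = raw_label,
                     value = value, line = i)
    } else if (is.null(cur)) {
      if (nzchar(ln)) {
        entries <- rbind(entries, .entry(
          "GETLDRS", i, sprintf("text before first LDR ignored: %s", ln),
          "warning"))
      }
    } else {
      cur$value <- paste0(cur$value, "\n", ln)
    }
  }
  if (!is.null(cur)) ldrs[[length(ldrs) + 1L]] <- cur
  list(ldrs = ldrs, entries = entries)
}

.required_labels <- c("TITLE", "JCAMPDX", "DATATYPE", "XUNITS", "YUNITS",
                      "FIRSTX", "LASTX", "NPOINTS", "END")
.numeric_labels <- c("FIRSTX", "LASTX", "DELTAX", "NPOINTS", "XFACTOR",
                     "YFACTOR", "FIRSTY", "MAXX", "MINX", "MAXY", "MINY")
.table_labels <- c("XYDATA", "PEAKTABLE")

#' Validate a JCAMP document
#'
#' Checks the presence of the required labels (TITLE, JCAMP-DX, DATA TYPE,
#' XUNITS, YUNITS, FIRSTX, LASTX, NPOINTS, one of XYDATA/PEAKTABLE, END),
#' that TITLE opens and END closes the document, that there is at most one
#' data-table record, that numeric fields parse as numbers and that NPOINTS
#' is a positive integer.  Every failure is one report entry; nothing is
#' raised.
#'
#' @param doc A [jdx_document()].
#' @return A parse report whose `is_valid` reflects errors only.
#' @export
jdx_validate <- function(doc) {
  stopifnot(inherits(doc, "jdx_document"))
  entries <- .validate_entries(doc)
  new_parse_report(entries)
}

.validate_entries <- function(doc) {
  entries <- .empty_entries()
  add <- function(line, msg) {
    entries <<- rbind(entries, .entry("VALIDATE", line, msg, "error"))
  }
  labs <- .doc_labels(doc)
  if (!length(labs)) {
    add(NA, "document contains no labelled data records")
    return(entries)
  }
  for (req in .required_labels) {
    if (!req %in% labs) add(NA, sprintf("required label %s is missing", req))
  }
  if (!any(.table_labels %in% labs))
    add(NA, "required data table (XYDATA or PEAKTABLE) is missing")
  if (labs[1] != "TITLE")
    add(doc$ldrs[[1]]$line, "first LDR must be TITLE")
  if (labs[length(labs)] != "END")
    add(doc$ldrs[[length(labs)]]$line, "last LDR must be END")
  for (tab in .table_labels) {
    if (sum(labs == tab) > 1L)
      add(NA, sprintf("more than one %s table in document", tab))
  }
  if ("BLOCKS" %in% labs)
    add(doc$ldrs[[which(labs == "BLOCKS")[1]]]$line,
        "multi-block (##BLOCKS=) link files are not supported")
  for (lab in .numeric_labels) {
    i <- which(labs == lab)
    if (!length(i)) next
    v <- trimws(strsplit(doc$ldrs[[i[1]]]$value, "\n")[[1]][1])
    if (is.na(suppressWarnings(as.numeric(v))))
      add(doc$ldrs[[i[1]]]$line,
          sprintf("label %s must be numeric, found '%s'", lab, v))
  }
  np <- .doc_num(doc, "NPOINTS")
  if (!is.na(np) && (np != round(np) || np < 1))
    add(NA, sprintf("NPOINTS must be a positive integer, found %s",
                    format(np)))
  entries
}

# Canonical unit spellings.  This set is an implementer's list (the format
# standard leaves unit vocabularies open); unknown units pass through with
# a warning.
.unit_canon <- c(
  "1/CM" = "1/CM", "CM-1" = "1/CM", "CM^-1" = "1/CM",
  "WAVENUMBERS" = "1/CM", "RECIPROCAL CENTIMETERS" = "1/CM",
  "NANOMETERS" = "NANOMETERS", "NANOMETER" = "NANOMETERS",
  "NM" = "NANOMETERS",
  "MICROMETERS" = "MICROMETERS", "MICROMETER" = "MICROMETERS",
  "MICRONS" = "MICROMETERS", "UM" = "MICROMETERS",
  "M/Z" = "M/Z", "MASS/CHARGE" = "M/Z", "AMU" = "M/Z",
  "TRANSMITTANCE" = "TRANSMITTANCE", "%T" = "TRANSMITTANCE",
  "PERCENT TRANSMITTANCE" = "TRANSMITTANCE",
  "ABSORBANCE" = "ABSORBANCE", "AU" = "ABSORBANCE", "A" = "ABSORBANCE",
  "RELATIVE ABUNDANCE" = "RELATIVE ABUNDANCE",
  "RELATIVE INTENSITY" = "RELATIVE ABUNDANCE",
  "INTENSITY" = "RELATIVE ABUNDANCE", "COUNTS" = "RELATIVE ABUNDANCE",
  "SECONDS" = "SECONDS", "HZ" = "HZ", "PPM" = "PPM")

.technique_map <- c(
  "INFRARED SPECTRUM" = "IR", "IR SPECTRUM" = "IR", "IR" = "IR",
  "UV/VIS SPECTRUM" = "UV", "UV-VIS SPECTRUM" = "UV",
  "UV/VISIBLE SPECTRUM" = "UV", "ULTRAVIOLET SPECTRUM" = "UV", "UV" = "UV",
  "MASS SPECTRUM" = "MS", "MS" = "MS",
  "NMR SPECTRUM" = "NMR", "NMR FID" = "NMR", "NMR" = "NMR",
  "RAMAN SPECTRUM" = "RAMAN", "RAMAN" = "RAMAN")

#' Map a DATA TYPE value to a short technique code
#'
#' @param datatype The DATA TYPE value as written in the file.
#' @return A short code (`"IR"`, `"UV"`, `"MS"`, `"NMR"`, `"RAMAN"`) or
#'   `"UNKNOWN"`.
#' @export
technique_code <- function(datatype) {
  if (is.na(datatype)) return("UNKNOWN")
  key <- toupper(trimws(datatype))
  if (key %in% names(.technique_map)) unname(.technique_map[key])
  else "UNKNOWN"
}

#' Standardize unit and numeric fields
#'
#' Maps XUNITS/YUNITS to canonical spellings (e.g. `"cm-1"`, `"CM^-1"` and
#' `"1/CM"` all become `"1/CM"`), trims numeric field values without loss of
#' precision, and logs every change as a warning with before/after values.
#' Unknown unit strings pass through unchanged with a warning.
#'
#' @param doc A [jdx_document()].
#' @return A list with `doc` (the standardized document), `entries`
#'   (warning entries) and `technique_code` (derived from DATA TYPE).
#' @export
jdx_standardize <- function(doc) {
  stopifnot(inherits(doc, "jdx_document"))
  entries <- .empty_entries()
  warn <- function(line, msg) {
    entries <<- rbind(entries, .entry("STANDARDIZE", line, msg, "warning"))
  }
  for (k in seq_along(doc$ldrs)) {
    ldr <- doc$ldrs[[k]]
    if (ldr$label %in% c("XUNITS", "YUNITS")) {
      key <- toupper(trimws(ldr$value))
      if (key %in% names(.unit_canon)) {
        canon <- unname(.unit_canon[key])
        if (!identical(ldr$value, canon)) {
          warn(ldr$line, sprintf("%s standardized: '%s' -> '%s'",
                                 ldr$label, ldr$value, canon))
          doc$ldrs[[k]]$value <- canon
        }
      } else {
        warn(ldr$line, sprintf("%s unit '%s' not recognized; left unchanged",
                               ldr$label, ldr$value))
      }
    } else if (ldr$label %in% .numeric_labels) {
      trimmed <- trimws(ldr$value)
      if (!identical(trimmed, ldr$value)) {
        warn(ldr$line, sprintf("%s value trimmed: '%s' -> '%s'",
                               ldr$label, ldr$value, trimmed))
        doc$ldrs[[k]]$value <- trimmed
      }
    }
  }
  tech <- technique_code(.doc_value(doc, "DATATYPE"))
  if (tech == "UNKNOWN" && !is.na(.doc_value(doc, "DATATYPE")))
    warn(NA, sprintf("DATA TYPE '%s' not mapped to a technique code",
                     .doc_value(doc, "DATATYPE")))
  list(doc = doc, entries = entries, technique_code = tech)
}

#' Decompress the data table of a document
#'
#' Routes `##XYDATA=` tables through the ASDF decoder
#' ([asdf_decode_table()]) and axis expansion ([expand_axis()]);
#' `##PEAKTABLE=` values are parsed as explicit XY pairs with
#' XFACTOR/YFACTOR applied.  Both the raw (as-stored) and processed
#' (expanded, real-valued) representations are retained.  A decoded count
#' that disagrees with NPOINTS, check-value mismatches and invalid
#' characters are report entries; decoding never aborts.
#'
#' @param doc A standardized [jdx_document()].
#' @return A list with `data` (a spectrum-data object or `NULL`) and
#'   `entries` (report entries, severities `error`/`warning`).
#' @export
jdx_decompress <- function(doc) {
  stopifnot(inherits(doc, "jdx_document"))
  entries <- .empty_entries()
  add <- function(line, msg, sev) {
    entries <<- rbind(entries, .entry("DECOMPRESS", line, msg, sev))
  }
  labs <- .doc_labels(doc)
  tab <- intersect(.table_labels, labs)
  if (!length(tab)) {
    add(NA, "no data table (XYDATA or PEAKTABLE) to decompress", "error")
    return(list(data = NULL, entries = entries))
  }
  tab <- tab[1]
  i <- which(labs == tab)[1]
  ldr <- doc$ldrs[[i]]

  npoints <- .doc_num(doc, "NPOINTS")
  firstx <- .doc_num(doc, "FIRSTX")
  lastx <- .doc_num(doc, "LASTX")
  deltax_stored <- .doc_num(doc, "DELTAX")
  xfactor <- .doc_num(doc, "XFACTOR", 1)
  yfactor <- .doc_num(doc, "YFACTOR", 1)
  if (is.na(xfactor)) xfactor <- 1
  if (is.na(yfactor)) yfactor <- 1
  xunits <- .doc_value(doc, "XUNITS", "")
  yunits <- .doc_value(doc, "YUNITS", "")

  value_lines <- strsplit(ldr$value, "\n", fixed = TRUE)[[1]]
  if (length(value_lines) && grepl("^\\s*\\(.*\\)\\s*$", value_lines[1]))
    value_lines <- value_lines[-1]

  if (tab == "PEAKTABLE") {
    pairs <- .parse_peak_pairs(value_lines)
    for (bad in pairs$bad)
      add(ldr$line, sprintf("unparseable peak entry '%s'", bad), "error")
    if (!nrow(pairs$xy)) {
      add(ldr$line, "peak table contains no data points", "error")
      return(list(data = NULL, entries = entries))
    }
    npts <- nrow(pairs$xy)
    axis <- axis_spec(
      firstx = if (is.na(firstx)) min(pairs$xy$x) else firstx,
      lastx = if (is.na(lastx)) max(pairs$xy$x) else lastx,
      npoints = if (is.na(npoints)) npts else max(1, npoints),
      deltax = NA, xfactor = xfactor, yfactor = yfactor,
      xunits = xunits, yunits = yunits)
    points <- data.frame(x = pairs$xy$x * xfactor,
                         y = pairs$xy$y * yfactor)
    if (!is.na(npoints) && npts != npoints)
      add(ldr$line, sprintf(
        "NPOINTS=%d but %d peak(s) decoded", as.integer(npoints), npts),
        "error")
    data <- new_spectrum_data(axis = axis, raw_y = pairs$xy$y,
                              raw_x = pairs$xy$x, points = points,
                              table_form = "PEAKTABLE",
                              raw_text = ldr$value)
    return(list(data = data, entries = entries))
  }

  # XYDATA grid table
  fx <- if (is.na(firstx)) 0 else firstx
  lx <- if (is.na(lastx)) fx + max(1, npoints - 1, na.rm = TRUE) else lastx
  np_for_axis <- if (is.na(npoints) || npoints < 1) NA else npoints
  if (is.na(np_for_axis)) {
    # axis grid unknown; decode without X checks, derive spacing afterwards
    dt <- asdf_decode_table(value_lines, axis = NULL)
    np_eff <- max(1L, length(dt$raw_y))
    axis <- tryCatch(
      axis_spec(firstx = fx, lastx = lx, npoints = np_eff,
                deltax = if (!is.na(deltax_stored) &&
                             deltax_stored != 0) deltax_stored else NA,
                xfactor = xfactor, yfactor = yfactor,
                xunits = xunits, yunits = yunits),
      error = function(e) {
        add(ldr$line, sprintf("degenerate axis (%s); unit X step assumed",
                              conditionMessage(e)), "error")
        axis_spec(firstx = fx, lastx = fx + np_eff - 1, npoints = np_eff,
                  deltax = 1, xfactor = xfactor, yfactor = yfactor,
                  xunits = xunits, yunits = yunits)
      })
  } else {
    axis <- tryCatch(
      axis_spec(firstx = fx, lastx = lx, npoints = np_for_axis,
                xfactor = xfactor, yfactor = yfactor,
                xunits = xunits, yunits = yunits),
      error = function(e) {
        add(ldr$line, sprintf("degenerate axis (%s); unit X step assumed",
                              conditionMessage(e)), "error")
        axis_spec(firstx = fx, lastx = fx + np_for_axis - 1,
                  npoints = np_for_axis, deltax = 1,
                  xfactor = xfactor, yfactor = yfactor,
                  xunits = xunits, yunits = yunits)
      })
    if (!is.na(deltax_stored) && axis$npoints > 1L &&
        !.close(deltax_stored, axis$deltax)) {
      add(ldr$line, sprintf(
        "stored DELTAX %s disagrees with (LASTX-FIRSTX)/(NPOINTS-1) = %s; recomputed value used",
        format(deltax_stored), format(axis$deltax)), "warning")
    }
    dt <- asdf_decode_table(value_lines, axis = axis)
  }
  if (nrow(dt$entries)) {
    for (r in seq_len(nrow(dt$entries))) {
      add(ldr$line + dt$entries$line[r], dt$entries$message[r], "error")
    }
  }
  if (!length(dt$raw_y)) {
    add(ldr$line, "no Y values decoded from XYDATA table", "error")
    return(list(data = NULL, entries = entries))
  }
  if (!is.na(npoints) && length(dt$raw_y) != npoints)
    add(ldr$line, sprintf("NPOINTS=%d but %d point(s) decoded",
                          as.integer(npoints), length(dt$raw_y)), "error")
  points <- expand_axis(axis, dt$raw_y)
  data <- new_spectrum_data(axis = axis, raw_y = dt$raw_y, points = points,
                            table_form = dt$form, raw_text = ldr$value)
  list(data = data, entries = entries)
}

.parse_peak_pairs <- function(lines) {
  xs <- numeric(0)
  ys <- numeric(0)
  bad <- character(0)
  for (ln in lines) {
    ln <- gsub(",\\s+", ",", trimws(ln))
    if (!nzchar(ln)) next
    toks <- strsplit(ln, "[;[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    for (tk in toks) {
      parts <- strsplit(tk, ",", fixed = TRUE)[[1]]
      ok <- length(parts) == 2L
      xv <- if (ok) suppressWarnings(as.numeric(parts[1])) else NA
      yv <- if (ok) suppressWarnings(as.numeric(parts[2])) else NA
      if (!ok || is.na(xv) || is.na(yv)) {
        bad <- c(bad, tk)
      } else {
        xs <- c(xs, xv)
        ys <- c(ys, yv)
      }
    }
  }
  list(xy = data.frame(x = xs, y = ys), bad = bad)
}

#' Parse JCAMP-DX text into a spectrum record
#'
#' Runs all pipeline stages in order (clean, uncomment, get LDRs, validate,
#' standardize, decompress), attaches comments to their records, and
#' assembles a spectrum record.  Malformed content never raises: the report
#' carries every discrepancy.  Only empty input is an error.
#'
#' @param text Character scalar, the file content.
#' @param id Optional 9-digit identifier; drawn from [jdx_next_id()] when
#'   omitted.
#' @param source_name Provenance string stored on the document.
#' @return A `jdx_spectrum` record.
#' @seealso [read_jdx()] to parse from a file path, [write_jcamp()] for the
#'   inverse.
#' @export
jdx_parse <- function(text, id = NULL, source_name = "text") {
  cleaned <- jdx_clean(text)
  unc <- jdx_uncomment(cleaned)
  got <- jdx_get_ldrs(unc$text)
  entries <- got$entries

  # comment attachment: a comment belongs to the record whose line range
  # covers it; comments before the first record are global.
  ldrs <- got$ldrs
  global <- data.frame(line = integer(0), text = character(0),
                       stringsAsFactors = FALSE)
  if (nrow(unc$comments)) {
    starts <- vapply(ldrs, function(l) l$line, integer(1))
    for (r in seq_len(nrow(unc$comments))) {
      cline <- unc$comments$line[r]
      owner <- if (length(starts)) max(which(starts <= cline), -Inf) else -Inf
      if (is.infinite(owner)) {
        global <- rbind(global, unc$comments[r, , drop = FALSE])
      } else {
        ldrs[[owner]]$comments <- c(ldrs[[owner]]$comments,
                                    stats::setNames(unc$comments$text[r],
                                                    cline))
      }
    }
  }
  doc <- jdx_document(ldrs = ldrs, global_comments = global,
                      source_name = source_name)

  entries <- rbind(entries, .validate_entries(doc))
  std <- jdx_standardize(doc)
  entries <- rbind(entries, std$entries)
  doc <- std$doc

  labs <- .doc_labels(doc)
  if ("BLOCKS" %in% labs) {
    data <- NULL  # link files hold several spectra; refuse, already reported
  } else if (any(.table_labels %in% labs)) {
    dec <- jdx_decompress(doc)
    entries <- rbind(entries, dec$entries)
    data <- dec$data
  } else {
    data <- NULL
  }

  if (is.null(id)) id <- jdx_next_id()
  new_spectrum_record(id = id, technique_code = std$technique_code,
                      document = doc, data = data,
                      report = new_parse_report(entries))
}

#' Read and parse a JCAMP-DX file
#'
#' @param path Path to a `.jdx`/`.dx` file.
#' @param id Optional 9-digit identifier.
#' @return A `jdx_spectrum` record.
#' @export
read_jdx <- function(path, id = NULL) {
  stopifnot(file.exists(path))
  text <- readChar(path, file.info(path)$size, useBytes = TRUE)
  jdx_parse(text, id = id, source_name = basename(path))
}

.fmt_x <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, digits = 10)
}

# Wrap an XYDATA table: every line starts with its X check value; in DIF
# mode each continuation line begins with a Y-check (the previous line's
# final Y restated as a plain value) and the X of that checked point.
.encode_xydata_lines <- function(raw_y, axis, form, line_width) {
  n <- length(raw_y)
  fmtx <- function(i0) .fmt_x(axis$firstx + i0 * axis$deltax)
  if (form %in% c("FIX", "PAC", "SQZ")) {
    lines <- character(0)
    i <- 1L
    while (i <= n) {
      line <- fmtx(i - 1L)
      firstv <- TRUE
      while (i <= n) {
        tok <- switch(form,
          FIX = paste0(" ", .int_str(raw_y[i])),
          PAC = if (firstv) paste0(" ", .int_str(raw_y[i]))
                else if (raw_y[i] < 0) .int_str(raw_y[i])
                else paste0("+", .int_str(raw_y[i])),
          SQZ = if (firstv) paste0(" ", .int_str(raw_y[i]))
                else .sqz_tok(raw_y[i]))
        if (!firstv && nchar(line) + nchar(tok) > line_width) break
        line <- paste0(line, tok)
        i <- i + 1L
        firstv <- FALSE
      }
      lines <- c(lines, line)
    }
    return(lines)
  }
  # DIF / DIFDUP
  units <- .dif_units(diff(raw_y), dup = identical(form, "DIFDUP"))
  line <- paste0(fmtx(0L), " ", .int_str(raw_y[1]))
  covered <- 1L
  lines <- character(0)
  fresh <- TRUE
  for (u in units) {
    if (!fresh && nchar(line) + nchar(u$str) > line_width) {
      lines <- c(lines, line)
      line <- paste0(fmtx(covered - 1L), " ", .int_str(raw_y[covered]))
      fresh <- TRUE
    }
    line <- paste0(line, u$str)
    covered <- covered + u$npts
    fresh <- FALSE
  }
  c(lines, line)
}

.encode_peaktable_lines <- function(raw_x, raw_y, line_width) {
  pairs <- paste0(.fmt_x(raw_x), ",", .fmt_x(raw_y))
  lines <- character(0)
  line <- ""
  for (p in pairs) {
    if (nzchar(line) && nchar(line) + 1L + nchar(p) > line_width) {
      lines <- c(lines, line)
      line <- ""
    }
    line <- if (nzchar(line)) paste0(line, " ", p) else p
  }
  c(lines, line)
}

#' Serialize a spectrum record back to JCAMP-DX
#'
#' Emits the records in their original order (using the labels exactly as
#' written), re-encoding the data table in the requested ASDF form.  Data
#' lines are wrapped so no line exceeds `line_width` characters; every
#' wrapped line is prefixed with its X check value and DIF-mode tables make
#' the next line begin with a Y-check value.  Peak tables keep their
#' explicit XY pairs regardless of `form`.
#'
#' @param record A `jdx_spectrum` with decoded data.
#' @param form Target table form, one of `"FIX"`, `"PAC"`, `"SQZ"`,
#'   `"DIF"`, `"DIFDUP"`.
#' @param line_width Maximum emitted data-line width (default 78, the
#'   legacy JCAMP convention).
#' @return The serialized file as one string.
#' @export
write_jcamp <- function(record, form = c("FIX", "PAC", "SQZ", "DIF",
                                         "DIFDUP"),
                        line_width = 78L) {
  form <- match.arg(form)
  stopifnot(inherits(record, "jdx_spectrum"), line_width >= 40L)
  out <- character(0)
  for (ldr in record$document$ldrs) {
    if (ldr$label %in% .table_labels && !is.null(record$data)) {
      if (ldr$label == "PEAKTABLE" ||
          identical(record$data$table_form, "PEAKTABLE")) {
        rx <- record$data$raw_x
        if (is.null(rx)) rx <- record$data$points$x / record$data$axis$xfactor
        body <- .encode_peaktable_lines(rx, record$data$raw_y, line_width)
        out <- c(out, paste0("##", ldr$raw_label, "=(XY..XY)"), body)
      } else {
        body <- .encode_xydata_lines(record$data$raw_y, record$data$axis,
                                     form, line_width)
        out <- c(out, paste0("##", ldr$raw_label, "=(X++(Y..Y))"), body)
      }
    } else {
      out <- c(out, paste0("##", ldr$raw_label, "=", ldr$value))
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
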