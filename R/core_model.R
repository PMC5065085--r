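# Shared domain types and axis-reconstruction arithmetic.
#
# A JCAMP-DX file is an ordered collection of LABELLED-DATA-RECORDs (LDRs),
# "##LABEL=value" units whose values may span several lines.  The tabulated
# Y values are stored as factor-scaled integers; physical points are
# reconstructed from FIRSTX/DELTAX/NPOINTS and YFACTOR.

#' Normalize a labelled-data-record label
#'
#' Extracts the label from a `##LABEL=` prefix and normalizes it:
#' uppercased with spaces, hyphens and underscores removed.  Normalization
#' is total and idempotent, so labels written by different JCAMP dialects
#' (`##XY DATA=`, `##Npoints=`) compare equal.
#'
#' @param raw A string beginning with `"##"` and containing `"="`.
#' @return The normalized label.
#' @examples
#' normalize_label("##XY DATA=")  # "XYDATA"
#' normalize_label("##Npoints=")  # "NPOINTS"
#' @export
normalize_label <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!startsWith(raw, "##"))
    stop(sprintf("malformed LDR (no '##'): %s", raw), call. = FALSE)
  eq <- regexpr("=", raw, fixed = TRUE)
  if (eq < 0L)
    stop(sprintf("malformed LDR (no '='): %s", raw), call. = FALSE)
  .norm_label(substr(raw, 3L, eq - 1L))
}

.norm_label <- function(label) {
  toupper(gsub("[ _-]", "", label))
}

# One ##LABEL=value record with provenance.
new_ldr <- function(label, raw_label, value, comments = character(0),
                    line = NA_integer_) {
  structure(list(label = label, raw_label = raw_label, value = value,
                 comments = comments, line = as.integer(line)),
            class = "jdx_ldr")
}

#' Construct a JCAMP document
#'
#' An ordered list of labelled data records plus the comments that were not
#' attached to any record; the lossless parse of one file.
#'
#' @param ldrs List of LDR objects (as produced by [jdx_get_ldrs()]).
#' @param global_comments Data frame of comments (`line`, `text`) preceding
#'   the first record.
#' @param source_name Provenance string.
#' @return A `jdx_document`.
#' @export
jdx_document <- function(ldrs = list(), global_comments = NULL,
                         source_name = "") {
  if (is.null(global_comments))
    global_comments <- data.frame(line = integer(0), text = character(0),
                                  stringsAsFactors = FALSE)
  structure(list(ldrs = ldrs, global_comments = global_comments,
                 source_name = source_name),
            class = "jdx_document")
}

.doc_labels <- function(doc) {
  vapply(doc$ldrs, function(l) l$label, character(1))
}

# First matching LDR value (single-line values are the common case) or
# `default` when the label is absent.
.doc_value <- function(doc, label, default = NA_character_) {
  labs <- .doc_labels(doc)
  i <- which(labs == label)
  if (!length(i)) return(default)
  doc$ldrs[[i[1]]]$value
}

.doc_num <- function(doc, label, default = NA_real_) {
  v <- .doc_value(doc, label)
  if (is.na(v)) return(default)
  first <- trimws(strsplit(v, "\n", fixed = TRUE)[[1]][1])
  suppressWarnings(as.numeric(first))
}

#' Construct an axis specification
#'
#' Holds the JCAMP axis metadata (FIRSTX, LASTX, DELTAX, NPOINTS, XFACTOR,
#' YFACTOR, XUNITS, YUNITS) from which physical X values and scaled Y values
#' are reconstructed.  FIRSTX/LASTX/DELTAX are taken as already being in
#' physical units; YFACTOR scales all tabulated Y values (and XFACTOR the
#' tabulated X of peak tables).  When `deltax` is omitted it is derived as
#' `(lastx - firstx) / (npoints - 1)`; when both are available the derived
#' value is used for expansion and the stored one only checked (see
#' [axis_consistent()]).
#'
#' @param firstx,lastx First and last X value, in X units.
#' @param npoints Number of points (positive integer).
#' @param deltax X step per point; derived from the other fields when `NULL`.
#' @param xfactor,yfactor Multipliers applied to tabulated X (peak tables)
#'   and Y values.
#' @param xunits,yunits Unit strings.
#' @return A `jdx_axis` object.
#' @export
axis_spec <- function(firstx, lastx, npoints, deltax = NULL, xfactor = 1,
                      yfactor = 1, xunits = "", yunits = "") {
  npoints <- as.integer(npoints)
  if (is.na(npoints) || npoints < 1L)
    stop("`npoints` must be a positive integer", call. = FALSE)
  derived <- if (npoints > 1L) (lastx - firstx) / (npoints - 1L) else 0
  if (is.null(deltax) || is.na(deltax)) deltax <- derived
  if (npoints > 1L && deltax == 0)
    stop("`deltax` must be non-zero when npoints > 1", call. = FALSE)
  structure(list(firstx = as.numeric(firstx), lastx = as.numeric(lastx),
                 deltax = as.numeric(deltax), npoints = npoints,
                 xfactor = as.numeric(xfactor),
                 yfactor = as.numeric(yfactor),
                 xunits = xunits, yunits = yunits),
            class = "jdx_axis")
}

#' Check internal consistency of an axis specification
#'
#' Verifies that `firstx + (npoints - 1) * deltax` agrees with `lastx`
#' within relative tolerance `1e-6` (absolute fallback `1e-9` near zero).
#' Inconsistency is a warning condition for the caller's report, never a
#' failure: text-format round-off routinely perturbs the stored DELTAX.
#'
#' @param axis A [axis_spec()].
#' @param deltax_stored Optionally, the DELTAX value as stored in the file
#'   (checked against the derived step).
#' @return `TRUE` when consistent.
#' @export
axis_consistent <- function(axis, deltax_stored = NULL) {
  ok <- TRUE
  if (axis$npoints > 1L) {
    implied <- axis$firstx + (axis$npoints - 1L) * axis$deltax
    ok <- ok && .close(implied, axis$lastx)
    if (!is.null(deltax_stored) && !is.na(deltax_stored))
      ok <- ok && .close(deltax_stored, axis$deltax)
  }
  ok
}

.close <- function(a, b, rel = 1e-6, abs_tol = 1e-9) {
  abs(a - b) <= max(rel * max(abs(a), abs(b)), abs_tol)
}

#' Expand stored Y values to physical XY points
#'
#' Reconstructs the physical point set from the decoded (factor-scaled
#' integer) Y table: `x_i = firstx + i * deltax` and `y_i = raw_y[i] *
#' yfactor`.  The output always has one row per input value; a mismatch with
#' `npoints` is the caller's to record, not an error here.
#'
#' @param axis A [axis_spec()].
#' @param raw_y Numeric vector of decoded Y values (before factor scaling).
#' @return A data frame with columns `x` and `y`.
#' @examples
#' a <- axis_spec(firstx = 400, lastx = 402, npoints = 3)
#' expand_axis(a, c(1, 2, 3))
#' @export
expand_axis <- function(axis, raw_y) {
  stopifnot(inherits(axis, "jdx_axis"), length(raw_y) >= 1L)
  i <- seq_along(raw_y) - 1
  data.frame(x = axis$firstx + i * axis$deltax,
             y = raw_y * axis$yfactor)
}

# Decoded spectrum payload: raw (as-stored) and processed representations.
new_spectrum_data <- function(axis, raw_y, points, table_form,
                              raw_x = NULL, raw_text = "") {
  structure(list(axis = axis, raw_y = raw_y, raw_x = raw_x,
                 points = points, table_form = table_form,
                 raw_text = raw_text),
            class = "jdx_spectrum_data")
}

# Report entries accumulated across pipeline stages.  `is_valid` is true
# iff no errors were recorded (warnings never invalidate a file).
new_parse_report <- function(entries = NULL) {
  if (is.null(entries))
    entries <- .empty_entries()
  errors <- entries[entries$severity == "error", c("stage", "line", "message")]
  warnings <- entries[entries$severity == "warning",
                      c("stage", "line", "message")]
  rownames(errors) <- NULL
  rownames(warnings) <- NULL
  structure(list(errors = errors, warnings = warnings,
                 is_valid = nrow(errors) == 0L),
            class = "jdx_report")
}

.empty_entries <- function() {
  data.frame(stage = character(0), line = integer(0),
             message = character(0), severity = character(0),
             stringsAsFactors = FALSE)
}

.entry <- function(stage, line, message, severity) {
  data.frame(stage = stage, line = as.integer(line), message = message,
             severity = severity, stringsAsFactors = FALSE)
}

#' @export
print.jdx_report <- function(x, ...) {
  cat(sprintf("JCAMP parse report: %s (%d error%s, %d warning%s)\n",
              if (x$is_valid) "valid" else "INVALID",
              nrow(x$errors), if (nrow(x$errors) == 1L) "" else "s",
              nrow(x$warnings), if (nrow(x$warnings) == 1L) "" else "s"))
  show <- function(df, tag) {
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  [%s] %s (line %s): %s\n", tag, df$stage[i],
                  ifelse(is.na(df$line[i]), "-", df$line[i]), df$message[i]))
    }
  }
  show(x$errors, "error")
  show(x$warnings, "warning")
  invisible(x)
}

#' Construct a spectrum record
#'
#' The unit the catalog stores: a 9-digit zero-padded identifier, the
#' technique code, the lossless document, the decoded data and the parse
#' report.
#'
#' @param id 9-digit zero-padded decimal string (see [jdx_next_id()]).
#' @param technique_code Short technique code (e.g. `"MS"`, `"IR"`, `"UV"`).
#' @param document A [jdx_document()].
#' @param data A spectrum-data object, or `NULL` when decoding was not
#'   possible.
#' @param report The accumulated parse report.
#' @param compound_ref Catalog identifier of the associated compound.
#' @return A `jdx_spectrum`.
#' @export
new_spectrum_record <- function(id, technique_code, document, data, report,
                                compound_ref = NA_character_) {
  if (!grepl("^[0-9]{9}$", id))
    stop("`id` must be exactly 9 decimal digits", call. = FALSE)
  structure(list(id = id, technique_code = technique_code,
                 compound_ref = compound_ref, document = document,
                 data = data, report = report),
            class = "jdx_spectrum")
}

#' @export
print.jdx_spectrum <- function(x, ...) {
  npts <- if (is.null(x$data)) 0L else length(x$data$raw_y)
  cat(sprintf("JCAMP spectrum %s [%s]: %d point%s, form %s, %s\n",
              x$id, x$technique_code, npts, if (npts == 1L) "" else "s",
              if (is.null(x$data)) "-" else x$data$table_form,
              if (x$report$is_valid) "valid" else "INVALID"))
  invisible(x)
}

.specdx_env <- new.env(parent = emptyenv())
.specdx_env$id_counter <- 0L

#' Generate the next spectrum identifier
#'
#' Monotonically increasing integer, zero-padded to 9 decimal digits
#' (e.g. `"000000115"`).  The counter is injectable for reproducible tests
#' via [jdx_reset_ids()].
#'
#' @return A 9-digit identifier string.
#' @export
jdx_next_id <- function() {
  .specdx_env$id_counter <- .specdx_env$id_counter + 1L
  sprintf("%09d", .specdx_env$id_counter)
}

#' Reset the spectrum identifier counter
#'
#' @param value The counter value after which the next identifier is drawn;
#'   `jdx_reset_ids(114)` makes the next id `"000000115"`.
#' @export
jdx_reset_ids <- function(value = 0L) {
  stopifnot(is.numeric(value), value >= 0, value < 1e9)
  .specdx_env$id_counter <- as.integer(value)
  invisible(NULL)
}
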