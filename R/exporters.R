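# Serializers: the pseudo-JCAMP XML dialect and SciData JSON-LD.
#
# Both exporters are deterministic: identical input (and injected
# timestamp) gives byte-identical output, so golden files are stable.
# Spectral data is carried twice — the <raw> table text exactly as stored
# in the file and the <pro>cessed expanded XY points — and every report
# entry is annotated in the errors element.

.xml_name <- function(label) {
  nm <- gsub("[^A-Za-z0-9.]", "", label)
  if (!nzchar(nm)) return("LDR")
  if (!grepl("^[A-Za-z]", nm)) nm <- paste0("L", nm)
  nm
}

#' Export a spectrum record as pseudo-JCAMP XML
#'
#' One element per labelled data record (element name = normalized label,
#' the label as written kept in a `label` attribute and the source line in
#' `line`), a `data` section with `raw` (verbatim table text) and `pro`
#' (expanded XY points) children, a `comments` section with line
#' provenance, and an `errors` element listing every report entry (present
#' and empty for clean files).
#'
#' @param record A `jdx_spectrum`.
#' @param include_raw,include_processed Which data representations to emit;
#'   at least one must be `TRUE`.
#' @param pretty Indent the output.
#' @return The XML document as one string (well-formed XML 1.0, UTF-8).
#' @export
to_xml <- function(record, include_raw = TRUE, include_processed = TRUE,
                   pretty = TRUE) {
  stopifnot(inherits(record, "jdx_spectrum"))
  if (!include_raw && !include_processed)
    stop("at least one of include_raw/include_processed must be TRUE",
         call. = FALSE)
  root <- xml2::xml_new_root("spectrum")
  xml2::xml_set_attr(root, "id", record$id)
  xml2::xml_set_attr(root, "technique", record$technique_code)

  meta <- xml2::xml_add_child(root, "metadata")
  for (ldr in record$document$ldrs) {
    el <- xml2::xml_add_child(meta, .xml_name(ldr$label))
    xml2::xml_set_attr(el, "label", ldr$raw_label)
    xml2::xml_set_attr(el, "line", as.character(ldr$line))
    xml2::xml_text(el) <- ldr$value
  }

  com <- xml2::xml_add_child(root, "comments")
  gc <- record$document$global_comments
  for (r in seq_len(nrow(gc))) {
    el <- xml2::xml_add_child(com, "comment")
    xml2::xml_set_attr(el, "line", as.character(gc$line[r]))
    xml2::xml_text(el) <- gc$text[r]
  }
  for (ldr in record$document$ldrs) {
    cs <- ldr$comments
    for (k in seq_along(cs)) {
      el <- xml2::xml_add_child(com, "comment")
      ln <- names(cs)[k]
      if (!is.null(ln) && nzchar(ln)) xml2::xml_set_attr(el, "line", ln)
      xml2::xml_set_attr(el, "ldr", ldr$label)
      xml2::xml_text(el) <- cs[[k]]
    }
  }

  if (!is.null(record$data)) {
    d <- xml2::xml_add_child(root, "data")
    xml2::xml_set_attr(d, "form", record$data$table_form)
    xml2::xml_set_attr(d, "npoints",
                       as.character(length(record$data$raw_y)))
    if (include_raw) {
      raw <- xml2::xml_add_child(d, "raw")
      xml2::xml_text(raw) <- record$data$raw_text
    }
    if (include_processed) {
      pro <- xml2::xml_add_child(d, "pro")
      pts <- record$data$points
      for (k in seq_len(nrow(pts))) {
        pt <- xml2::xml_add_child(pro, "pt")
        xml2::xml_set_attr(pt, "x", .fmt_x(pts$x[k]))
        xml2::xml_set_attr(pt, "y", format(pts$y[k], scientific = FALSE,
                                           trim = TRUE, digits = 12))
      }
    }
  }

  errs <- xml2::xml_add_child(root, "errors")
  rep <- record$report
  for (r in seq_len(nrow(rep$errors))) {
    el <- xml2::xml_add_child(errs, "error")
    xml2::xml_set_attr(el, "stage", rep$errors$stage[r])
    if (!is.na(rep$errors$line[r]))
      xml2::xml_set_attr(el, "line", as.character(rep$errors$line[r]))
    xml2::xml_text(el) <- rep$errors$message[r]
  }
  for (r in seq_len(nrow(rep$warnings))) {
    el <- xml2::xml_add_child(errs, "warning")
    xml2::xml_set_attr(el, "stage", rep$warnings$stage[r])
    if (!is.na(rep$warnings$line[r]))
      xml2::xml_set_attr(el, "line", as.character(rep$warnings$line[r]))
    xml2::xml_text(el) <- rep$warnings$message[r]
  }

  if (pretty) {
    tf <- tempfile(fileext = ".xml")
    on.exit(unlink(tf), add = TRUE)
    xml2::write_xml(root, tf, options = "format")
    paste0(paste(readLines(tf, warn = FALSE), collapse = "\n"), "\n")
  } else {
    paste0(as.character(root))
  }
}

.default_scidata_contexts <- c(
  "https://stuchalk.github.io/scidata/contexts/scidata.jsonld")

#' Export a spectrum record as SciData JSON-LD
#'
#' Emits a SciData envelope: context references, a methodology section
#' (technique and instrument metadata), a system section (the compound's
#' identifier facets, empty when no compound is supplied) and a dataset
#' section holding the processed point series of exactly one spectrum with
#' its axis metadata.  Node identifiers are fragment identifiers derived
#' from section name plus ordinal, so every graph node is locally unique.
#' The timestamp is injected by the caller — never wall-clock — so output
#' is byte-deterministic.
#'
#' @param record A `jdx_spectrum` with decoded data.
#' @param compound Optional compound record ([compound_record()]).
#' @param generated_at Timestamp string stored in the envelope.
#' @param context_refs Character vector of JSON-LD context locators.
#' @return The JSON-LD document as one string.
#' @export
to_scidata <- function(record, compound = NULL,
                       generated_at = "1970-01-01T00:00:00Z",
                       context_refs = .default_scidata_contexts) {
  stopifnot(inherits(record, "jdx_spectrum"), !is.null(record$data))
  pts <- record$data$points
  axis <- record$data$axis

  facets <- list()
  if (!is.null(compound)) {
    stopifnot(inherits(compound, "jdx_compound"))
    facet <- list("@id" = "compound/1", "@type" = "sdo:compound",
                  name = compound$preferred_name)
    if (!is.null(compound$smiles)) facet$smiles <- compound$smiles
    if (!is.null(compound$inchi)) facet$inchi <- compound$inchi
    if (!is.null(compound$inchikey)) facet$inchikey <- compound$inchikey
    if (!is.null(compound$pubchem_cid))
      facet$pubchem_cid <- compound$pubchem_cid
    if (!is.null(compound$wikidata_id))
      facet$wikidata_id <- compound$wikidata_id
    facets <- list(facet)
  }

  aspects <- list(list(
    "@id" = "measurement/1",
    "@type" = "sdo:measurement",
    techniqueType = record$technique_code,
    dataType = .doc_value(record$document, "DATATYPE", "")))
  origin <- .doc_value(record$document, "ORIGIN")
  if (!is.na(origin)) aspects[[1]]$instrument <- origin

  doc <- list(
    "@context" = c(as.list(context_refs),
                   list(list("@base" = paste0("spectrum/", record$id, "/")))),
    "@id" = paste0("spectrum/", record$id),
    generatedAt = generated_at,
    version = 1L,
    "@graph" = list(
      "@id" = "graph/1",
      "@type" = "sdo:scidataFramework",
      uid = record$id,
      title = .doc_value(record$document, "TITLE", ""),
      scidata = list(
        "@id" = "scidata/1",
        "@type" = "sdo:scientificData",
        methodology = list(
          "@id" = "methodology/1",
          evaluation = "experimental",
          aspects = aspects),
        system = list(
          "@id" = "system/1",
          facets = facets),
        dataset = list(
          "@id" = "dataset/1",
          source = "measurement/1",
          scope = "system/1",
          x_axis = list(
            "@id" = "axis/1",
            units = axis$xunits,
            first = axis$firstx,
            last = axis$lastx,
            step = axis$deltax),
          y_axis = list(
            "@id" = "axis/2",
            units = axis$yunits,
            factor = axis$yfactor),
          series = list(list(
            "@id" = "series/1",
            count = nrow(pts),
            x = pts$x,
            y = pts$y))))))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"))
}
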