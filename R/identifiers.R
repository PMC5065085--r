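# Compound identifier catalog and offline request builders for the
# PubChem, Wikidata and Splash integrations.
#
# Nothing in this module performs network I/O: every integration is a
# (request builder, response parser) pair.  A caller that wants live
# lookups supplies its own transport and feeds the response text back to
# the parsers, which keeps the library deterministic and testable offline.

#' Construct a compound record
#'
#' A chemical entity with its identifier bundle: preferred name, synonyms,
#' SMILES, InChI, InChIKey (validated against the 14-10-1 hyphenated
#' uppercase block pattern), PubChem CID (positive integer) and Wikidata
#' entity id.
#'
#' @param catalog_id Catalog identifier string.
#' @param preferred_name Display name.
#' @param synonyms Character vector of alternative names (CAS numbers are
#'   ordinary synonyms here).
#' @param smiles,inchi,inchikey,wikidata_id Optional identifier strings.
#' @param pubchem_cid Optional positive integer.
#' @return A `jdx_compound`.
#' @export
compound_record <- function(catalog_id, preferred_name,
                            synonyms = character(0), smiles = NULL,
                            inchi = NULL, inchikey = NULL,
                            pubchem_cid = NULL, wikidata_id = NULL) {
  stopifnot(is.character(catalog_id), nzchar(catalog_id),
            is.character(preferred_name))
  if (!is.null(inchikey) &&
      !grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", inchikey))
    stop(sprintf("invalid InChIKey '%s'", inchikey), call. = FALSE)
  if (!is.null(pubchem_cid)) {
    if (!is.numeric(pubchem_cid) || pubchem_cid != round(pubchem_cid) ||
        pubchem_cid < 1)
      stop("`pubchem_cid` must be a positive integer", call. = FALSE)
    pubchem_cid <- as.integer(pubchem_cid)
  }
  structure(list(catalog_id = catalog_id, preferred_name = preferred_name,
                 synonyms = as.character(synonyms), smiles = smiles,
                 inchi = inchi, inchikey = inchikey,
                 pubchem_cid = pubchem_cid, wikidata_id = wikidata_id),
            class = "jdx_compound")
}

#' Search a compound catalog by identifier
#'
#' Case-insensitive matching across the selected identifier fields.  Exact
#' matches (any identifier, a full name or synonym) rank first, then
#' name-prefix matches, then name-substring matches; ties break on
#' `catalog_id`, so the ranking is deterministic and independent of catalog
#' insertion order.  InChI and InChIKey require exact matches.
#'
#' @param catalog List of [compound_record()] objects.
#' @param text Non-empty query string.
#' @param fields Subset of `c("name", "smiles", "inchi", "inchikey",
#'   "cid")` to match against.
#' @return Ranked list of matching compound records; each carries
#'   `match_rank` and `matched_field` attributes.
#' @export
search_compounds <- function(catalog, text,
                             fields = c("name", "smiles", "inchi",
                                        "inchikey", "cid")) {
  fields <- match.arg(fields, several.ok = TRUE)
  text <- trimws(text)
  if (!nzchar(text)) stop("query text must be non-empty", call. = FALSE)
  tl <- tolower(text)
  rank <- numeric(0)
  fld <- character(0)
  idx <- integer(0)
  ids <- character(0)
  for (k in seq_along(catalog)) {
    rec <- catalog[[k]]
    best <- Inf
    bf <- NA_character_
    consider <- function(value, field) {
      if (field %in% fields && best > 1 && !is.null(value) &&
          any(tolower(as.character(value)) == tl)) {
        best <<- 1
        bf <<- field
      }
    }
    consider(rec$inchikey, "inchikey")
    consider(rec$inchi, "inchi")
    consider(rec$smiles, "smiles")
    consider(rec$pubchem_cid, "cid")
    if ("name" %in% fields) {
      nms <- tolower(c(rec$preferred_name, rec$synonyms))
      if (any(nms == tl) && best > 1) {
        best <- 1
        bf <- "name"
      } else if (best > 2 && any(startsWith(nms, tl))) {
        best <- 2
        bf <- "name"
      } else if (best > 3 && any(grepl(tl, nms, fixed = TRUE))) {
        best <- 3
        bf <- "name"
      }
    }
    if (is.finite(best)) {
      rank <- c(rank, best)
      fld <- c(fld, bf)
      idx <- c(idx, k)
      ids <- c(ids, rec$catalog_id)
    }
  }
  ord <- order(rank, ids)
  out <- vector("list", length(ord))
  for (j in seq_along(ord)) {
    rec <- catalog[[idx[ord[j]]]]
    attr(rec, "match_rank") <- rank[ord[j]]
    attr(rec, "matched_field") <- fld[ord[j]]
    out[[j]] <- rec
  }
  out
}

#' Write a compound catalog to a flat JSON file
#'
#' @param catalog List of [compound_record()] objects.
#' @param path Destination path.
#' @export
write_compound_catalog <- function(catalog, path) {
  recs <- lapply(catalog, function(r) {
    r <- unclass(r)
    r[!vapply(r, is.null, logical(1))]
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a compound catalog from a flat JSON file
#'
#' Every entry is revalidated through [compound_record()]; malformed JSON
#' or records that violate the identifier invariants raise an error.
#'
#' @param path Path to a catalog JSON file.
#' @return List of compound records.
#' @export
read_compound_catalog <- function(path) {
  stopifnot(file.exists(path))
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(recs)) stop("catalog file must hold a JSON array",
                           call. = FALSE)
  lapply(recs, function(r) {
    compound_record(catalog_id = r$catalog_id,
                    preferred_name = r$preferred_name,
                    synonyms = unlist(r$synonyms) %||% character(0),
                    smiles = r$smiles, inchi = r$inchi,
                    inchikey = r$inchikey, pubchem_cid = r$pubchem_cid,
                    wikidata_id = r$wikidata_id)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pubchem_base <- "https://pubchem.ncbi.nlm.nih.gov/rest/pug"

#' Build a PubChem PUG REST synonym request URL
#'
#' Constructs `<base>/compound/name/<encoded name>/synonym/JSON` following
#' the PUG REST input/operation/output specification.  Pure string
#' construction: no request is performed.
#'
#' @param name Non-empty compound name (URL-encoded in the path).
#' @return The request URL.
#' @examples
#' pubchem_synonym_request("aspirin")
#' @export
pubchem_synonym_request <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name)))
    stop("`name` must be a non-empty string", call. = FALSE)
  paste0(.pubchem_base, "/compound/name/",
         utils::URLencode(name, reserved = TRUE), "/synonym/JSON")
}

#' Parse a PubChem synonym-endpoint response
#'
#' Extracts the first CID and its synonym list from the JSON payload.
#' Fault-shaped payloads (the endpoint's error envelope) yield a
#' lookup-failed result rather than an error; only malformed JSON raises.
#'
#' @param payload JSON text as returned by the synonym endpoint.
#' @return A list with `ok`; on success also `cid` (integer) and
#'   `synonyms` (character vector), on a fault `message`.
#' @export
parse_pubchem_synonyms <- function(payload) {
  obj <- tryCatch(jsonlite::fromJSON(payload, simplifyVector = FALSE),
                  error = function(e) {
                    stop(sprintf("malformed JSON payload: %s",
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (!is.null(obj$Fault)) {
    msg <- obj$Fault$Message %||% obj$Fault$Code %||% "lookup failed"
    return(list(ok = FALSE, message = as.character(msg)))
  }
  info <- obj$InformationList$Information
  if (is.null(info) || !length(info))
    return(list(ok = FALSE, message = "no Information entries in payload"))
  first <- info[[1]]
  list(ok = TRUE,
       cid = as.integer(first$CID),
       synonyms = as.character(unlist(first$Synonym)) %||% character(0))
}

.wikidata_props <- c(inchikey = "P235", smiles = "P233", cid = "P662")

#' Build a Wikidata SPARQL query for a chemical identifier
#'
#' Returns a SPARQL SELECT retrieving the entity whose InChIKey (P235),
#' canonical SMILES (P233) or PubChem CID (P662) exactly matches `value`.
#' The property table is configurable via `properties` since vocabularies
#' evolve.  The literal is escaped so embedded quotes and backslashes
#' cannot break out of the string.
#'
#' @param identifier_kind One of `"inchikey"`, `"smiles"`, `"cid"`.
#' @param value Non-empty identifier value.
#' @param properties Named character vector mapping identifier kinds to
#'   Wikidata property ids.
#' @return The SPARQL query string.
#' @export
wikidata_query <- function(identifier_kind = c("inchikey", "smiles", "cid"),
                           value, properties = .wikidata_props) {
  identifier_kind <- match.arg(identifier_kind)
  if (!is.character(value) || length(value) != 1L || !nzchar(value))
    stop("`value` must be a non-empty string", call. = FALSE)
  esc <- gsub("\\", "\\\\", value, fixed = TRUE)
  esc <- gsub("\"", "\\\"", esc, fixed = TRUE)
  esc <- gsub("\n", "\\n", esc, fixed = TRUE)
  prop <- properties[[identifier_kind]]
  paste0("PREFIX wdt: <http://www.wikidata.org/prop/direct/>\n",
         "SELECT ?compound WHERE { ?compound wdt:", prop,
         " \"", esc, "\" . } LIMIT 1")
}

#' Build the Splash request payload for a spectrum
#'
#' Encodes the processed point list as an ordered ion list plus a
#' spectrum-type tag derived from the technique code — the JSON object the
#' Splash hashing service expects.  Negative intensities pass through
#' unmodified (they are flagged upstream by the pipeline, not here).
#'
#' @param data A spectrum-data object with at least one processed point.
#' @param technique_code Technique code (e.g. `"MS"`).
#' @return A list with `ions` (list of `mass`/`intensity` pairs, in point
#'   order) and `type`; serialize with `jsonlite::toJSON(..., auto_unbox =
#'   TRUE, digits = NA)` for a deterministic payload.
#' @export
splash_payload <- function(data, technique_code) {
  stopifnot(inherits(data, "jdx_spectrum_data"))
  pts <- data$points
  if (is.null(pts) || nrow(pts) < 1L)
    stop("spectrum has no processed points", call. = FALSE)
  list(ions = unname(Map(function(x, y) list(mass = x, intensity = y),
                         pts$x, pts$y)),
       type = toupper(technique_code))
}

#' Identifier fallback chain for a Wikidata lookup
#'
#' Returns the available identifiers of a compound in the order tried for
#' Wikidata resolution — InChIKey, then SMILES, then PubChem CID — skipping
#' absent ones.  An empty chain means the compound is taken as not present
#' in Wikidata.
#'
#' @param record A [compound_record()].
#' @return List of `list(kind =, value =)` entries, possibly empty.
#' @export
fallback_chain <- function(record) {
  stopifnot(inherits(record, "jdx_compound"))
  out <- list()
  if (!is.null(record$inchikey))
    out[[length(out) + 1L]] <- list(kind = "inchikey",
                                    value = record$inchikey)
  if (!is.null(record$smiles))
    out[[length(out) + 1L]] <- list(kind = "smiles", value = record$smiles)
  if (!is.null(record$pubchem_cid))
    out[[length(out) + 1L]] <- list(kind = "cid",
                                    value = as.character(record$pubchem_cid))
  out
}
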