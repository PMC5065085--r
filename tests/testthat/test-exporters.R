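parsed_difdup <- function() jdx_parse(minimal_uv_jcamp("0 1JT%jX"),
                                      id = "000000115")

test_that("XML export is well-formed with raw and processed sections", {
  rec <- parsed_difdup()
  x <- to_xml(rec)
  doc <- xml2::read_xml(x)  # strict parser accepts it
  expect_identical(xml2::xml_attr(doc, "id"), "000000115")

  raw <- xml2::xml_find_first(doc, "//data/raw")
  expect_match(xml2::xml_text(raw), "1JT%jX", fixed = TRUE)
  pro <- xml2::xml_find_all(doc, "//data/pro/pt")
  expect_identical(length(pro), 10L)

  # clean record: errors element present and empty
  errs <- xml2::xml_find_first(doc, "//errors")
  expect_false(is.na(xml2::xml_name(errs)))
  expect_identical(length(xml2::xml_find_all(errs, "./error")), 0L)

  # errored record: entries listed
  bad <- jdx_parse(minimal_uv_jcamp("0 1JT%j~X"), id = "000000116")
  doc2 <- xml2::read_xml(to_xml(bad))
  expect_gt(length(xml2::xml_find_all(doc2, "//errors/error")), 0)
})

test_that("XML metadata is a lossless multiset of the document's LDRs", {
  rec <- parsed_difdup()
  doc <- xml2::read_xml(to_xml(rec))
  els <- xml2::xml_find_all(doc, "//metadata/*")
  got <- sort(paste(
    vapply(els, function(e) normalize_label(
      paste0("##", xml2::xml_attr(e, "label"), "=")), ""),
    vapply(els, xml2::xml_text, ""), sep = "\r"))
  want <- sort(vapply(rec$document$ldrs,
                      function(l) paste(l$label, l$value, sep = "\r"), ""))
  expect_identical(got, want)
})

test_that("XML export honors the include options and rejects none", {
  rec <- parsed_difdup()
  doc <- xml2::read_xml(to_xml(rec, include_raw = FALSE))
  expect_identical(length(xml2::xml_find_all(doc, "//data/raw")), 0L)
  expect_identical(length(xml2::xml_find_all(doc, "//data/pro/pt")), 10L)
  doc <- xml2::read_xml(to_xml(rec, include_processed = FALSE))
  expect_identical(length(xml2::xml_find_all(doc, "//data/pro")), 0L)
  expect_identical(length(xml2::xml_find_all(doc, "//data/raw")), 1L)
  expect_error(to_xml(rec, include_raw = FALSE, include_processed = FALSE),
               "at least one")
})

test_that("SciData export is valid JSON-LD with a conserved dataset", {
  rec <- parsed_difdup()
  js <- to_scidata(rec, generated_at = "2016-01-01T00:00:00Z")
  expect_true(jsonlite::validate(js))
  obj <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  series <- obj[["@graph"]]$scidata$dataset$series[[1]]
  expect_identical(series$count, 10L)
  expect_identical(length(series$x), 10L)
  expect_identical(length(series$y), 10L)
  # axis units propagate verbatim
  expect_identical(obj[["@graph"]]$scidata$dataset$x_axis$units,
                   "NANOMETERS")
  # no compound: system present with zero facets
  expect_identical(length(obj[["@graph"]]$scidata$system$facets), 0L)
  expect_identical(obj$generatedAt, "2016-01-01T00:00:00Z")

  cmp <- compound_record("C001", "Aspirin",
                         inchikey = "BSYNRYMUTXBXSQ-UHFFFAOYSA-N",
                         pubchem_cid = 2244)
  obj2 <- jsonlite::fromJSON(to_scidata(rec, compound = cmp),
                             simplifyVector = FALSE)
  facets <- obj2[["@graph"]]$scidata$system$facets
  expect_identical(length(facets), 1L)
  expect_identical(facets[[1]]$inchikey, "BSYNRYMUTXBXSQ-UHFFFAOYSA-N")
})

test_that("serializations are byte-deterministic under a fixed timestamp", {
  rec <- parsed_difdup()
  expect_identical(to_xml(rec), to_xml(rec))
  expect_identical(to_scidata(rec, generated_at = "t0"),
                   to_scidata(rec, generated_at = "t0"))
  # graph node identifiers are locally unique
  obj <- jsonlite::fromJSON(to_scidata(rec), simplifyVector = TRUE,
                            flatten = TRUE)
  ids <- unlist(rapply(jsonlite::fromJSON(to_scidata(rec),
                                          simplifyVector = FALSE),
                       how = "unlist",
                       f = identity))
  ids <- ids[grepl("@id$", names(ids))]
  expect_identical(anyDuplicated(unname(ids)), 0L)
})
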