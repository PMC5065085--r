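test_that("compound records enforce identifier invariants", {
  ok <- compound_record("C9", "thing",
                        inchikey = "BSYNRYMUTXBXSQ-UHFFFAOYSA-N",
                        pubchem_cid = 2244)
  expect_s3_class(ok, "jdx_compound")
  expect_error(compound_record("C9", "x", inchikey = "notakey"), "InChIKey")
  expect_error(compound_record("C9", "x", pubchem_cid = 0), "positive")
  expect_error(compound_record("C9", "x", pubchem_cid = 2.5), "positive")
})

test_that("search ranks exact identifiers above name substrings", {
  cat <- demo_catalog()
  hits <- search_compounds(cat, "aspirin")
  expect_identical(hits[[1]]$catalog_id, "C001")
  expect_identical(attr(hits[[1]], "matched_field"), "name")

  hits <- search_compounds(cat, "BSYNRYMUTXBXSQ-UHFFFAOYSA-N")
  expect_identical(length(hits), 1L)
  expect_identical(hits[[1]]$catalog_id, "C001")
  expect_identical(attr(hits[[1]], "match_rank"), 1)

  expect_identical(search_compounds(cat, "zzz-not-present"), list())

  # prefix beats substring: "asp" prefixes Aspirin/Aspartame only
  hits <- search_compounds(cat, "asp")
  expect_identical(vapply(hits, function(h) h$catalog_id, ""),
                   c("C001", "C003"))

  # CID exact match
  hits <- search_compounds(cat, "2519")
  expect_identical(hits[[1]]$catalog_id, "C002")
  expect_identical(attr(hits[[1]], "matched_field"), "cid")

  # CAS numbers are ordinary synonyms
  hits <- search_compounds(cat, "50-78-2")
  expect_identical(hits[[1]]$catalog_id, "C001")

  expect_error(search_compounds(cat, "   "), "non-empty")
})

test_that("search ranking is invariant to catalog insertion order", {
  cat <- demo_catalog()
  set.seed(5)
  for (i in 1:10) {
    perm <- sample(length(cat))
    for (q in c("asp", "caffeine", "2244", "a")) {
      a <- vapply(search_compounds(cat, q), function(h) h$catalog_id, "")
      b <- vapply(search_compounds(cat[perm], q),
                  function(h) h$catalog_id, "")
      expect_identical(a, b, info = q)
    }
  }
})

test_that("catalogs round-trip through their flat JSON persistence", {
  path <- tempfile(fileext = ".json")
  write_compound_catalog(demo_catalog(), path)
  back <- read_compound_catalog(path)
  expect_identical(length(back), 3L)
  expect_identical(back[[1]]$preferred_name, "Aspirin")
  expect_identical(back[[1]]$pubchem_cid, 2244L)
  expect_identical(back[[3]]$inchikey, NULL)

  broken <- tempfile(fileext = ".json")
  writeLines("{not json", broken)
  expect_error(read_compound_catalog(broken))
})

test_that("PubChem synonym requests follow the PUG REST layout", {
  expect_identical(
    pubchem_synonym_request("aspirin"),
    "https://pubchem.ncbi.nlm.nih.gov/rest/pug/compound/name/aspirin/synonym/JSON")
  expect_match(pubchem_synonym_request("acetic acid"),
               "/compound/name/acetic%20acid/synonym/JSON", fixed = TRUE)
  expect_match(pubchem_synonym_request("2-propanol"),
               "/compound/name/2-propanol/", fixed = TRUE)
  expect_error(pubchem_synonym_request(""), "non-empty")
})

test_that("PubChem synonym payloads parse into valid compound data", {
  res <- parse_pubchem_synonyms(pubchem_synonym_fixture())
  expect_true(res$ok)
  expect_identical(res$cid, 2244L)
  expect_identical(length(res$synonyms), 3L)
  expect_identical(res$synonyms[1], "aspirin")

  # building a record from the parse satisfies the invariants
  rec <- compound_record("C100", res$synonyms[1],
                         synonyms = res$synonyms[-1],
                         pubchem_cid = res$cid)
  expect_s3_class(rec, "jdx_compound")

  fault <- parse_pubchem_synonyms(pubchem_fault_fixture())
  expect_false(fault$ok)
  expect_match(fault$message, "No CID found")

  expect_error(parse_pubchem_synonyms("not json"), "malformed JSON")
})

test_that("Wikidata queries quote and escape the identifier literal", {
  q <- wikidata_query("inchikey", "BSYNRYMUTXBXSQ-UHFFFAOYSA-N")
  expect_match(q, "wdt:P235", fixed = TRUE)
  expect_identical(
    lengths(regmatches(q, gregexpr("BSYNRYMUTXBXSQ-UHFFFAOYSA-N", q))), 1L)
  expect_match(q, "\"BSYNRYMUTXBXSQ-UHFFFAOYSA-N\"", fixed = TRUE)

  q <- wikidata_query("cid", "2244")
  expect_match(q, "wdt:P662 \"2244\"", fixed = TRUE)

  q <- wikidata_query("smiles", "C\\C=C\"evil")
  # escaped literal: removing escape pairs leaves exactly the 2 delimiters
  stripped <- gsub("\\\\.", "", q)
  expect_identical(
    lengths(regmatches(stripped, gregexpr("\"", stripped))), 2L)

  expect_error(wikidata_query("casnumber", "x"))
  expect_error(wikidata_query("cid", ""), "non-empty")
})

test_that("the Splash payload conserves the point list and tags the type", {
  rec <- jdx_parse(minimal_ms_jcamp())
  p <- splash_payload(rec$data, "MS")
  expect_identical(p$type, "MS")
  expect_identical(length(p$ions), 2L)
  expect_identical(p$ions[[1]], list(mass = 120, intensity = 999))
  # negative intensities pass through unmodified
  neg <- jdx_parse(minimal_uv_jcamp("0 1JT%jX"))
  pn <- splash_payload(neg$data, "UV")
  expect_identical(pn$ions[[10]]$intensity, -3)
})

test_that("the Wikidata fallback chain tries inchikey, smiles, then cid", {
  full <- compound_record("C1", "x", smiles = "CCO",
                          inchikey = "LFQSCWFLJHTTHZ-UHFFFAOYSA-N",
                          pubchem_cid = 702)
  chain <- fallback_chain(full)
  expect_identical(vapply(chain, function(e) e$kind, ""),
                   c("inchikey", "smiles", "cid"))
  only_cid <- compound_record("C2", "y", pubchem_cid = 5)
  expect_identical(vapply(fallback_chain(only_cid),
                          function(e) e$kind, ""), "cid")
  none <- compound_record("C3", "z")
  expect_identical(fallback_chain(none), list())
})

test_that("request builders are pure functions of their inputs", {
  set.seed(31)
  for (i in 1:25) {
    nm <- paste(sample(c(letters, " ", "-", "(", ")"), 12, replace = TRUE),
                collapse = "")
    expect_identical(pubchem_synonym_request(nm),
                     pubchem_synonym_request(nm))
    val <- paste(sample(c(LETTERS, "\"", "\\", "-"), 10, replace = TRUE),
                 collapse = "")
    expect_identical(wikidata_query("smiles", val),
                     wikidata_query("smiles", val))
  }
})
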