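# Handcrafted fixtures built in code (no binary data on disk).

# A minimal, valid UV/Vis file with a DIFDUP table holding the canonical
# ten-value worked example.
minimal_uv_jcamp <- function(table_lines = "0 1JT%jX",
                             npoints = 10,
                             extra = character(0)) {
  paste0(paste(c(
    "##TITLE=minimal uv fixture",
    "##JCAMP-DX=4.24",
    "##DATA TYPE=UV/VIS SPECTRUM",
    "##XUNITS=NANOMETERS",
    "##YUNITS=ABSORBANCE",
    "##FIRSTX=0",
    "##LASTX=9",
    "##DELTAX=1",
    sprintf("##NPOINTS=%d", npoints),
    "##XFACTOR=1",
    "##YFACTOR=1",
    extra,
    "##XYDATA=(X++(Y..Y))",
    table_lines,
    "##END="), collapse = "\n"), "\n")
}

minimal_ms_jcamp <- function(pairs = "120.0,999.0 43.0,500.0",
                             npoints = 2) {
  paste0(paste(c(
    "##TITLE=minimal ms fixture",
    "##JCAMP-DX=4.24",
    "##DATA TYPE=MASS SPECTRUM",
    "##XUNITS=M/Z",
    "##YUNITS=RELATIVE ABUNDANCE",
    "##FIRSTX=43",
    "##LASTX=120",
    sprintf("##NPOINTS=%d", npoints),
    "##XFACTOR=1",
    "##YFACTOR=1",
    "##PEAKTABLE=(XY..XY)",
    pairs,
    "##END="), collapse = "\n"), "\n")
}

pubchem_synonym_fixture <- function() {
  paste0(
    '{"InformationList":{"Information":[{"CID":2244,',
    '"Synonym":["aspirin","acetylsalicylic acid",',
    '"2-acetyloxybenzoic acid"]}]}}')
}

pubchem_fault_fixture <- function() {
  paste0('{"Fault":{"Code":"PUGREST.NotFound",',
         '"Message":"No CID found that matches the given name"}}')
}

demo_catalog <- function() {
  list(
    compound_record("C001", "Aspirin",
                    synonyms = c("acetylsalicylic acid", "50-78-2"),
                    smiles = "CC(=O)OC1=CC=CC=C1C(=O)O",
                    inchikey = "BSYNRYMUTXBXSQ-UHFFFAOYSA-N",
                    pubchem_cid = 2244),
    compound_record("C002", "Caffeine",
                    synonyms = c("1,3,7-trimethylxanthine"),
                    smiles = "CN1C=NC2=C1C(=O)N(C(=O)N2C)C",
                    inchikey = "RYYVLZVUVIJVGH-UHFFFAOYSA-N",
                    pubchem_cid = 2519),
    compound_record("C003", "Aspartame",
                    synonyms = c("22839-47-0"),
                    pubchem_cid = 134601))
}
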