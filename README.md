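# specdx

Parse, decompress and convert JCAMP-DX spectral data in R.

JCAMP-DX is the long-lived ASCII exchange format that most spectrometer
software can export: a sequence of labelled data records (`##LABEL=value`)
whose tabulated ordinates are factor-scaled integers, optionally
compressed in the **ASDF** family of forms (ASCII Squeezed Difference
Form).  Legacy compression is the main reason archived spectra are hard to
reuse, so the core of this package is a complete, annotating codec and
ingestion pipeline for those files, aimed at anyone building spectral
databases, converters or QC tooling.

## What it does

* **ASDF codec** — encode and decode all five tabular forms.  The
  pseudo-digit alphabet maps `@ A–I` / `a–i` to squeezed leading digits
  0…9 / −1…−9, `% J–R` / `j–r` to differences, and `S–Z s` to duplicate
  counts 1…9, where a DUP digit gives the *total* occurrence count of the
  preceding value or difference:

  | form   | encoding of `1 2 3 3 2 1 0 -1 -2 -3` | length |
  |--------|--------------------------------------|--------|
  | FIX    | `1 2 3 3 2 1 0 -1 -2 -3`             | 22     |
  | PAC    | `1+2+3+3+2+1+0-1-2-3`                | 19     |
  | SQZ    | `1BCCBA@abc`                         | 10     |
  | DIF    | `1JJ%jjjjjj`                         | 10     |
  | DIFDUP | `1JT%jX`                             | 6      |

* **Ingestion pipeline** — `jdx_parse()` runs clean → uncomment → get
  LDRs → validate → standardize → decompress, never fails on malformed
  content, and returns a record holding the lossless document, the raw
  and expanded data, and a report in which every discrepancy (missing
  labels, invalid characters, X/Y check-value mismatches, NPOINTS
  disagreements) is annotated.
* **Writer** — `write_jcamp()` re-serializes in any form with line
  wrapping and DIF check-value discipline; `parse → write → parse` is
  bit-exact on the stored integers.
* **Exporters** — `to_xml()` (pseudo-JCAMP XML with `<raw>`/`<pro>` data
  and an `<errors>` element) and `to_scidata()` (SciData JSON-LD with
  methodology/system/dataset sections); both byte-deterministic.
* **Identifier catalog** — compound records with names, SMILES, InChI,
  InChIKey and PubChem CID; ranked multi-identifier search; offline
  request builders and response parsers for PubChem PUG REST, Wikidata
  SPARQL and Splash payloads (no network I/O anywhere in the package).
* **Synthetic fixtures** — `generate_fixture()` writes seeded,
  realistic UV/Vis, IR and MS files in every form, and
  `corrupt_fixture()` injects controlled damage, so the whole stack is
  testable offline.
* **CLI** — `jdx_cli()` (and the `inst/cli/specdx` wrapper) exposes
  `parse`, `convert`, `search`, `generate` and `corrupt` subcommands.

## Worked example

```r
library(specdx)

v <- c(1, 2, 3, 3, 2, 1, 0, -1, -2, -3)
sapply(c("FIX", "PAC", "SQZ", "DIF", "DIFDUP"), function(f) asdf_encode(v, f))
#>                      FIX                      PAC                      SQZ
#> "1 2 3 3 2 1 0 -1 -2 -3"    "1+2+3+3+2+1+0-1-2-3"             "1BCCBA@abc"
#>                      DIF                   DIFDUP
#>             "1JJ%jjjjjj"                 "1JT%jX"

fx <- generate_fixture(fixture_spec("UVVIS", form = "DIFDUP", seed = 1),
                       id = "000000115")
fx$record
#> JCAMP spectrum 000000115 [UV]: 301 points, form DIFDUP, valid

cat(substr(fx$text, 1, 320))
#> ##TITLE=Synthetic UVVIS spectrum (seed 1)
#> ##JCAMP-DX=4.24
#> ##DATA TYPE=UV/VIS SPECTRUM
#> ...
#> ##XYDATA=(X++(Y..Y))
#> 200 0%TOM9l1k4%RLJJ7j8L2k7K7K1NK5mK6K9j6J0N2K3K6L9L6P3N9N3L4J02M5J24O7P9J00J10
#> 278 1162J29J26K01J51J46J88J76K56J46K36K37K48K34K17K85L06K71K66L04K76L13K57L25

rec2 <- jdx_parse(write_jcamp(fx$record, form = "FIX"))
identical(rec2$data$raw_y, fx$record$data$raw_y)
#> [1] TRUE

head(fx$record$data$points, 3)
#>     x y
#> 1 200 0
#> 2 202 0
#> 3 204 0
```

The first data line reads: X check `200`, first Y `0` plainly, then
differences (`%` zero, `T` a duplicate count, multi-digit differences
like `J02` = +102) — 301 stored integers in 78-character lines; the
processed points are recovered through `FIRSTX`/`DELTAX` and
`YFACTOR = 1e-4`.

See `vignettes/jcampdx-processing.Rmd` for the model, the conventions the
format leaves open and the package's choices for them.

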