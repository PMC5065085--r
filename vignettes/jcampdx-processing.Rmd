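---
title: "Processing JCAMP-DX spectra with specdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing JCAMP-DX spectra with specdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdx)
```

## The problem

JCAMP-DX is the de-facto ASCII exchange format for instrument spectra
(UV/Vis, IR, MS, NMR and more).  A file is a sequence of labelled data
records (LDRs) of the form `##LABEL=value`; the tabulated ordinates are
stored as factor-scaled integers, and — because the format predates cheap
disk space — those integers may be compressed in the ASDF family of forms
that replace digits, successive differences and run lengths with letter
pseudo-digits.  Thirty-plus years of dialects and sloppy writers mean that
real files routinely disagree with their own metadata, so a useful reader
must decode everything it can and *annotate* what it cannot, rather than
fail.  `specdx` implements that reader, the matching writer, exporters to
an XML dialect and to SciData JSON-LD, an identifier catalog for compound
search, and a synthetic spectrum generator that makes the whole stack
testable offline.

## The ASDF codec

The five tabular forms share one pseudo-digit alphabet:

| role              | characters            | values  |
|-------------------|-----------------------|---------|
| positive SQZ      | `@ A B C D E F G H I` | 0 … 9   |
| negative SQZ      | `a b c d e f g h i`   | −1 … −9 |
| positive DIF      | `% J K L M N O P Q R` | 0 … 9   |
| negative DIF      | `j k l m n o p q r`   | −1 … −9 |
| DUP               | `S T U V W X Y Z s`   | 1 … 9   |

A SQZ pseudo-digit replaces the leading digit *and* sign of a value; a DIF
pseudo-digit does the same for the difference from the previous value; a
DUP pseudo-digit repeats the preceding value-or-difference so that its
total occurrence count equals the DUP value.  Trailing ASCII digits extend
the magnitude of whichever token they follow, so values of any size are
representable.  The canonical ten-value example threads through all five
forms:

```{r}
v <- c(1, 2, 3, 3, 2, 1, 0, -1, -2, -3)
sapply(c("FIX", "PAC", "SQZ", "DIF", "DIFDUP"), function(f) asdf_encode(v, f))
asdf_decode_line("1JT%jX")$y
```

Design points worth stating explicitly:

* **DUP is a total count.** `T` (2) after `J` (+1) means the difference
  occurs twice in total, not twice more.  This is the only reading under
  which `1JT%jX` reproduces the FIX row above.
* **Encoder DUP threshold is 2**: any run of two or more identical
  consecutive differences is compressed (again forced by `JT` in the
  example).  Runs longer than nine re-emit the difference token with a
  fresh DUP digit, because a single DUP digit encodes at most 9.
* **`%` is the unique zero difference**; there is no negative zero.
* **`?` is a missing value**: decoded as 0 and reported, following the
  long-standing invalid-value convention of the format.
* The decoder is a per-character state machine; the test suite checks it
  exhaustively against a *separately written* brute-force decoder on every
  encodable string for sequences of length ≤ 6 over values in [−3, 3]
  (137,256 sequences × 5 forms), and round-trips 1,000 seeded random
  sequences of length up to 500 with values up to ±10⁶ in all forms.

## The ingestion pipeline

`jdx_parse()` runs six stages in a fixed order — clean, uncomment, get
LDRs, validate, standardize, decompress — and never raises on malformed
content (only an empty input is an error).  Every discrepancy becomes one
entry in the parse report: errors (missing required labels, undecodable
characters, count mismatches, failed check values) make `is_valid` false,
warnings (unit canonicalization, a stored `##DELTAX=` that disagrees with
the grid implied by `FIRSTX`/`LASTX`/`NPOINTS`) never do.

Conventions the format standard leaves open were fixed as follows:

* **Factor convention.** `FIRSTX`, `LASTX` and `DELTAX` are taken as
  already being in physical units; `XFACTOR` applies to the tabulated X of
  peak tables and `YFACTOR` to all tabulated Y.  This matches the dominant
  behaviour of legacy 4.24 writers, but instrument exports that scale
  `FIRSTX` through `XFACTOR` do exist — the convention is a single, stated
  choice, not a detected one.
* **DELTAX precedence.** When both `##DELTAX=` and the
  (`FIRSTX`,`LASTX`,`NPOINTS`) triple are present, the recomputed step
  `(LASTX−FIRSTX)/(NPOINTS−1)` drives the expansion and the stored value
  is only checked (relative tolerance 1e-6, absolute fallback 1e-9 near
  zero — text-format round-off scale).
* **Check values.**  Every data line starts with its X check value,
  compared against the expected grid position within half an X step.  In
  DIF mode each continuation line restates the previous line's final Y as
  a Y-check, which is verified and then dropped; on mismatch the
  chain-decoded value is kept and the mismatch (plus any knock-on
  mismatches) is reported.
* **Standardized fields.** The unit table (`cm-1`/`CM^-1` → `1/CM`, `nm` →
  `NANOMETERS`, `%T` → `TRANSMITTANCE`, …) and the DATA TYPE → technique
  code map are implementer's lists: the set of fields worth
  canonicalizing is not fixed by the format, so every applied change is
  logged as a warning with before/after values and unknown units pass
  through untouched.
* **Multi-block link files** (`##BLOCKS=`) hold several spectra and are
  rejected with one clear error naming the feature; the pipeline is a
  single-spectrum ingester.
* **Comment attachment.** A `$$` comment on an LDR line attaches to that
  LDR; whole-line comments between LDRs attach to the preceding LDR;
  comments before the first LDR become document-level comments.  This is
  a determinism choice — any consistent rule would do, but only one may
  be used.

The writer (`write_jcamp()`) re-emits the LDRs in original order under
their labels exactly as written, re-encodes the table in any requested
form, wraps data lines at a configurable width (default 78 characters,
the legacy convention) and maintains the X/Y check-value discipline
described above.  `parse → write → parse` preserves the decoded integer
table bit-exactly; the test suite drives this over the full technique ×
form × seed grid.

## Exports

`to_xml()` produces the pseudo-JCAMP XML dialect: one element per LDR
(element names are the normalized labels, the label as written is kept in
an attribute — normalized labels survive as XML names where exotic ones
would not), a `data` section holding the table text verbatim in `raw` and
the expanded points in `pro`, and an `errors` element that is always
present, listing every report entry.  `to_scidata()` emits a SciData
JSON-LD envelope with methodology / system / dataset sections; node
identifiers are fragment identifiers built from section name plus ordinal,
and the context reference list is a documented default that callers can
replace — the exact production vocabulary is deliberately configurable.
Both serializers take their timestamp from the caller and are
byte-deterministic, so golden-file comparisons are meaningful.

## Identifier catalog and integrations

The catalog is a flat JSON list of compound records (name, synonyms,
SMILES, InChI, InChIKey, PubChem CID, Wikidata id).  Search is
case-insensitive with a fixed ranking — exact identifier or full-name
match, then name prefix, then name substring, ties broken by catalog id —
so results are independent of insertion order.  InChI and InChIKey only
match exactly: substring hits on structure identifiers are more likely to
be accidents than intent.  CAS numbers are stored as ordinary synonyms
without checksum validation.

The PubChem builder constructs the PUG REST synonym URL
(`…/rest/pug/compound/name/<name>/synonym/JSON`); its parser extracts the
first CID and synonym list and maps the service's fault envelope to a
lookup-failed result.  The Wikidata builder emits a SPARQL SELECT against
a configurable property table (InChIKey P235, canonical SMILES P233,
PubChem CID P662) with the literal escaped; `fallback_chain()` orders a
compound's available identifiers InChIKey → SMILES → CID, and an empty
chain is interpreted as "not in Wikidata".  The Splash builder packs the
processed point list into the ion-list JSON payload the hashing service
expects; the hash algorithm itself is out of scope.  No function in the
package opens a network connection.

## The synthetic generator

`generate_fixture()` emulates the files users upload.  UV/Vis spectra are
sums of 3 Gaussian peaks (σ ≈ 30 nm, amplitudes 0.2–1 AU) on a 301-point
200–800 nm grid with 0.002 AU noise, stored through `YFACTOR = 1e-4`; IR
spectra are 8 transmittance dips on a *decreasing* 4000–400 cm⁻¹ grid
(441 points, `YFACTOR = 0.01`), which exercises negative `DELTAX`; MS
fixtures are 12-stick peak tables on m/z 15–350 with a 9999 base peak.
These sizes and noise levels are ordinary bench values for the three
techniques and are fixed defaults, not tuning knobs.  All randomness comes
from R's Mersenne-Twister generator seeded from the spec's integer seed,
so a spec yields byte-identical text on any platform.

What the generator does *not* emulate — Lorentzian/Voigt lineshapes,
isotope patterns, baseline drift, detector saturation, vendor-specific
LDR dialects — bounds what green tests mean: they demonstrate that the
codec, pipeline and exporters are mutually consistent and meet their
contracts on realistic geometry, not that every vendor's export parses.
`corrupt_fixture()` closes part of that gap by injecting the four damage
classes real files exhibit (stray bytes, truncated tables, missing
headers, broken DIF check chains) and asserting the specific report entry
each must produce.

## Numerical and scale choices

Decoded ordinates are kept as doubles holding exact integers (sums of
differences stay exact far beyond ±10⁶, well past any instrument's
dynamic range).  X check values are compared within half an X step, axis
self-consistency within 1e-6 relative.  The test suite's problem sizes —
the exhaustive ≤ 6-length oracle sweep, 1,000-sequence round-trip
property, the 3 × 5 × 10 fixture grid — were chosen as the smallest grids
that still cover every code path and every form combination; all are
fixed-seed and finish in a couple of minutes on one CPU.

## Known limitations

* NTUPLES/multi-dimensional data, NMR FIDs and chromatographic extensions
  are out of scope; `##BLOCKS=` compound files are rejected, not split.
* The factor convention above is a documented assumption; files whose
  writers scaled `FIRSTX` by `XFACTOR` will come out with a shifted axis
  (the report cannot detect this case).
* The SciData context URL list is a placeholder default, not a promise
  that the emitted vocabulary matches any particular published context
  version.
* Unit and technique canonicalization tables are intentionally small;
  unknown spellings pass through with a warning rather than guessing.
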