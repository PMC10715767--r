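---
title: "Positional parsing of plate reader exports: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional parsing of plate reader exports: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateparse)
```

## The problem and the stance

Plate reader exports have no standard: the same 96-well growth curve can
arrive as readings-in-rows, readings-in-columns, or a stack of plate-shaped
grids, wrapped in arbitrary preamble, labels and footers, in five file
dialects. Conventional parser functions find the data by instrument-specific
context clues (searching for a label, skipping a known number of lines),
which ties each parser to one instrument and one export option.

`plateparse` takes the opposite stance: **the location of data is user
knowledge, not something to infer**. A parser spec records positional facts
the user can read directly off the displayed file — "the first reading's
data cells are rows 6–101, columns 2–6" — and the engine does nothing but
act on those positions. This buys generality (any layout a rectangle can
describe) at the cost of requiring the user to state coordinates once per
export format. Everything in the design follows from making that statement
easy, checkable and reusable.

## The grid model

`read_raw_grid()` loads a file as a rectangular grid of *text* cells with
1-based addressing, cell (1, 1) top-left:

- no header row, no row skipping, no type inference — coordinates in a spec
  must match what a spreadsheet program shows, so the reader must not
  reinterpret the file;
- short rows are right-padded with empty strings; blank lines are kept;
  the number of grid rows equals the file's physical line count;
- values stay text verbatim at this stage (a decimal comma, an overflow
  marker, a stray label — all preserved), because coercion rules depend on
  the spec, not the file.

Dialects: `csv` (comma, RFC 4180 quoting), `csv2` (semicolon separator with
decimal commas — never auto-detected, because it shares the `.csv`
extension and misdetection would silently corrupt decimals), `tsv`, `txt`
(tab by default, `delimiter` overridable) and `excel` (first sheet by
default, selectable by name or 1-based index; multi-sheet handling is a
convenience of this implementation, not a convention of any instrument).
Encoding is UTF-8 first, latin-1 fallback with a warning.

## The parser specification

A `parser_spec()` captures, in declarative form, exactly the decisions a
user makes when parsing interactively:

| field | meaning | default |
|---|---|---|
| `data_format` | horizontal / vertical / matrix layout | — |
| `data_type` | single / timecourse / spectrum | — |
| `first_block` | rectangle of the first reading's *data cells only* | — |
| `num_readings`, `reading_names` | measurement channels (OD600, GFP, ...) | 1 |
| `block_stride` | rows (horizontal/matrix) or columns (vertical) between consecutive block starts | block height/width |
| `explicit_blocks` | per-reading rectangles for irregular exports | unset |
| `wells` | plate layout (row-major A1, A2, ...) or explicit list | 8 × 12 plate |
| `axis` | time/wavelength labels: explicit, from the grid, or uniform start/step | — (required unless single) |
| `sentinel_values` | tokens meaning "missing" | `""`, `NA`, `OVRFLW`, `OVER`, `Overflow`, `?` |

Choices worth justifying:

- **Stride placement of readings 2..N.** Exports overwhelmingly stack
  consecutive readings in consecutive row/column bands, so the default
  stride equals the block height (horizontal, matrix) or width (vertical) —
  immediately adjacent blocks. Decorated exports (a label row between
  blocks) just use a larger stride; genuinely irregular exports use
  `explicit_blocks`. The first block is always given explicitly; only the
  *repetition rule* is defaulted.
- **Timecourse orientation.** The well axis definitions force it: horizontal
  puts wells across columns, so time must run down the block's rows;
  vertical is the transpose. This is stated explicitly because a block
  alone does not reveal which axis is which.
- **Matrix format is single-type.** A plate-shaped block carries one value
  per well; a kinetic matrix export (one plate grid per timepoint) is
  expressed as one reading per timepoint, stacked by stride. Allowing a
  matrix block to be "timecourse" would make the well↔cell bijection
  ambiguous.
- **Sentinels.** Instruments write overflow markers instead of numbers; no
  published convention exists, so the default list covers the common forms
  and is fully overridable. Matching is case-insensitive after stripping
  surrounding whitespace. Missing propagates as missing — never as zero —
  because a zero is a measurement and an overflow is not.
- **Wells beyond row Z are unsupported.** No plate in scope is larger than
  16 × 24; inventing an `AA` convention would be guessing.

`validate_spec()` checks a spec against a grid and returns *findings*
(machine-readable code + human message) rather than throwing, so every
inconsistency is reported at once: blocks outside the grid, block dimensions
disagreeing with the well count for the declared format, axis label counts
disagreeing with block dimensions, and structural violations in
hand-deserialized specs. An empty report is the precondition for extraction.

## Serialization

Specs persist as versioned JSON (YAML accepted), not as a binary R object:
a saved parser is a long-lived laboratory artifact that users should be able
to read, diff and hand-edit, and other implementations should be able to
consume. Spreadsheet-style references (`"B6"`, `"B6:F101"`) are accepted on
load because that is the notation users see. Documents with unknown fields
or a different `schema_version` are rejected outright — half-understanding
a future spec would silently misparse data. `load_spec(save_spec(x))`
equals `x` field-for-field; the test suite asserts this across hundreds of
randomly drawn specs.

## Coercion and output

`coerce_block()` strips surrounding whitespace, maps sentinels to missing,
converts decimal commas when the dialect is csv2, and requires every
remaining cell to parse as a number — reporting *all* offending cells with
their grid coordinates in one error, since a misplaced block is the usual
cause and the fix is a coordinate change. The tidy table is long over wells
× axis and wide over readings, ordered well-major, with the axis column
named `time` or `wavelength` (overridable for downstream tools with other
conventions).

The join is **data-preserving**: tidy rows whose well lacks metadata are
kept with empty annotations (warning naming exactly the wells); metadata
rows for absent wells are dropped (warning likewise); output row count
always equals tidy row count. Dropping measurements because an annotation
file is incomplete would be strictly worse than blank annotation fields.
Output columns are metadata (well first, then file order), the axis key,
then the readings — "metadata on the left, data on the right"; the axis
column travels with the data block since it is a measurement key, not an
annotation. Output CSV is UTF-8 with missing values as empty fields and
numbers at round-trip precision.

Both join sides are canonicalized on the well key (`a01` → `A1`), so
hand-typed metadata joins zero-padded instrument output without fuss.

## The fixture generator

Proprietary instrument files cannot ship with a package, so the generator
fabricates them: measurement values uniform in 0.03–1.8 (an absorbance-like
range; values are never interpreted, so the distribution is cosmetic),
well-known decoration furniture (protocol/date preamble, per-block reading
labels, embedded plate row/column headers, blank separators, a footer),
sentinel injection at a configurable rate, and all five dialects. Every
bundle carries the spec whose coordinates point at the true blocks and the
ground-truth joined table; the invariant under test is always *engine output
= truth, exactly*. Ground-truth numerics are defined as the parse of the
rendered cell text, so equality is bitwise, not approximate.

The catalog (`style_catalog()`, 22 entries) covers the format × type cross
product (minus impossible matrix-kinetic combinations), plain and decorated
profiles, all dialects, a 384-well plate, explicit well lists, irregular
explicit blocks and sentinel-laden files. Fixtures are pure functions of
their style (seed included): the same style yields byte-identical files,
Excel included (the xlsx emitter uses fixed archive timestamps).

What fixtures do *not* emulate — and therefore what passing tests do not
prove: vendor-specific layout quirks beyond generic furniture, multi-line
quoted cells, exotic encodings, merged Excel cells, or formula cells.
Extraction from such files still works wherever a rectangle of numeric text
cells exists, but the test suite cannot vouch for it.

## Numerical and degenerate-input choices

- Tidy/join equality in tests is exact (tolerance zero): every value is a
  parse of decimal text, so approximate comparison would only mask bugs.
- A file with ragged rows is padded, never truncated; a wider-than-header
  line widens the grid.
- An all-blank file yields a grid of empty cells with one column; a 1 × 1
  grid with one explicit well is the minimal working fixture.
- Excel cells lose leading/trailing whitespace inside cell text (the reader
  normalises it); delimited dialects preserve it. Fixture text contains no
  surrounding whitespace, so dialect equivalence is exercised on the class
  of files where all five dialects can represent the same grid.
- Axis labels read from the grid are coerced to numbers only when *every*
  label parses (after decimal-comma handling for csv2); otherwise all stay
  text — mixed coercion would silently reorder downstream sorts.

## Problem sizes

The shipped tests parse the full 22-style catalog end-to-end (96- and
384-well plates, up to 101 spectral points), fuzz 200 out-of-block
perturbations per fixture, and round-trip 500 random specs; the whole suite
runs in well under a minute on a single core. These sizes exercise every
code path the generator can reach; they are small because plate exports are
small — a 384-well kinetic export is a few hundred kilobytes of text.

## Known limitations

- No heuristic location of data: a new export layout always needs a human
  to state coordinates once. This is the design stance, not an omission.
- No import of parser artifacts saved by other tools, binary R formats
  included; the JSON schema is this package's interchange format.
- No downstream analytics (growth rates, calibration, normalisation) — the
  output is deliberately the tidy, annotated table those tools consume.
- Quoted fields containing newlines would desynchronise the physical-line
  padding rule; no instrument export seen in the wild does this.
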