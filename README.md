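# plateparse

Multiwell plate readers measure absorbance, fluorescence and luminescence
across 6- to 384-well plates, but every instrument exports its numbers in its
own layout: measurements buried between preamble lines, labels and footers,
arranged in rows, columns or plate-shaped grids, in CSV, semicolon/decimal-
comma CSV, tab-delimited text or Excel. Analysis packages, on the other hand,
want tidy tables — one row per observation, one column per variable — with the
experimental annotations (strain, inducer, replicate, ...) attached.
`plateparse` bridges the two with **declarative parser specifications** that
locate measurement data **purely by position**: you state where the first
reading's block of data cells sits (1-based row/column coordinates, exactly as
the file appears in a spreadsheet), how the remaining readings are placed, and
which wells and timepoints/wavelengths the cells belong to. No instrument-
specific context clues, no heuristics — a spec built once is rerun on every
later export from the same instrument program.

## The model

A raw export is read as an *n* × *m* grid of text cells, verbatim: no header
inference, no row skipping, no type coercion, so spec coordinates always match
what you see when you open the file. A parser spec then declares:

- **data_format** — the layout convention:
  - *horizontal*: readings in rows, wells in columns (block = axis length × n
    wells; time runs down the block's rows);
  - *vertical*: readings in columns, wells in rows (the transpose);
  - *matrix*: the plate drawn as a grid that mimics the plate itself (8 × 12
    for a 96-well plate); cell (r, c) belongs to the well with row letter r
    and column number c.
- **data_type** — *single* (one value per well), *timecourse* (a time series
  per well) or *spectrum* (a wavelength sweep per well).
- **first_block** — the rectangle of the first reading's data cells
  (`B6:F101` style references welcome), plus either a **block_stride** for
  readings placed at regular offsets (default: immediately adjacent blocks)
  or **explicit_blocks** for irregular exports.
- **wells** — a plate layout (row-major `A1, A2, …, H12` order) or an
  explicit well list; **axis** — time/wavelength labels typed in, read out of
  the grid, or generated as `start + k·step`; **sentinel_values** — overflow
  tokens that become missing values.

Extraction coerces the block cells to numbers, maps them to wells, reshapes
to a tidy long table (long over wells × axis, wide over readings) and joins
the metadata on the canonical well key — metadata on the left, measurements
on the right, and no data row is ever dropped for want of annotation.

## A worked example

The package ships a deterministic fixture generator (no instrument files
needed). Here it fabricates a decorated vertical timecourse export — 96
wells, two readings (OD600, GFP), five timepoints, time labels embedded in a
header row — then parses it back:

```r
library(plateparse)
dir <- file.path(tempdir(), "demo")
cmd_fixture("vert-time-dec-csv", dir)          # raw.csv, spec.json, metadata.csv, truth.csv

spec <- load_spec(file.path(dir, "spec.json"))
spec
#> <parser_spec: vertical timecourse, 2 reading(s): OD600, GFP>
#>   first block rows 6-101, cols 2-6; stride 6
#>   wells: 8 x 12 plate (96 wells)
#>   axis: from_grid

grid <- read_raw_grid(file.path(dir, "raw.csv"))
grid
#> <cell_grid: 103 x 12, dialect csv>
#>      [,1]        [,2]          [,3]     [,4]     [,5]     [,6]   ...
#> [1,] "Protocol:" "GrowthAssay" ""       ""       ""       ""
#> [2,] "Date:"     "2026-01-12"  ""       ""       ""       ""
#> [3,] ""          ""            ""       ""       ""       ""
#> [4,] ""          "OD600"       ""       ""       ""       ""
#> [5,] ""          "0"           "30"     "60"     "90"     "120"
#> [6,] "A1"        "1.1178"      "1.4866" "0.5339" "1.7502" "1.1188"
#> ...

validate_spec(spec, grid)                      # 0 rows: the spec is consistent
ex <- extract_all(spec, grid)
ex
#> <extracted_data: 2 reading(s) x 96 well(s) x 5 axis point(s)>

tidy <- build_tidy(ex, spec)
joined <- join_metadata(tidy, read_metadata(file.path(dir, "metadata.csv")))
head(joined, 4)
#> # A tibble: 4 x 6
#>   well  strain inducer_uM  time OD600   GFP
#>   <chr> <chr>       <dbl> <dbl> <dbl> <dbl>
#> 1 A1    WT             10     0 1.12  0.853
#> 2 A1    WT             10    30 1.49  0.819
#> 3 A1    WT             10    60 0.534 0.739
#> 4 A1    WT             10    90 1.75  1.03
nrow(joined)
#> [1] 480        # 96 wells x 5 timepoints
```

The first block sits at rows 6–101, columns 2–6: 96 well rows by 5 time
columns, with the decoration (well labels in column 1, the reading name and
time row above) outside the block; the second reading's band starts 6 columns
(one stride) to the right. `write_output(joined, "out.csv")` writes the final
CSV at full precision, missing values as empty fields.

## Command line

```sh
inst/cli/plateparse run --parser spec.json --data raw.csv --metadata metadata.csv --out out.csv
#> parsed raw.csv: 2 reading(s) x 96 well(s) x 1 axis point(s) -> 96 row(s) in out.csv
inst/cli/plateparse validate --parser spec.json --data raw.csv
inst/cli/plateparse init-spec --out spec.json --data-format matrix --data-type single \
    --first-block B5:M12 --reading-names OD600
inst/cli/plateparse fixture --style matrix-single-dec-csv --dir demo/
```

Validation findings and warnings go to standard error; exit status is 0 on
success, 2 on validation findings, and a stable documented code per typed
error class (run `plateparse` with no arguments for the table).

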