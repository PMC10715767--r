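# Synthetic instrument-style exports with known ground truth. Real plate
# reader exports bury the measurements under preamble lines, per-block
# labels, embedded row/column headers and footers, in five file dialects;
# the generator fabricates that diversity deterministically so every parsing
# path can be exercised without a single proprietary instrument file.
# The one rule a bundle must obey: running the engine on its raw + spec +
# metadata reproduces its ground-truth joined table exactly.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Describe a synthetic fixture
#'
#' A fixture style captures everything that varies between instrument export
#' layouts: the format and data type, plate size, number of readings, axis
#' length, whether the file is decorated with export furniture (preamble
#' lines, per-block labels, embedded plate headers, a footer), how often
#' sentinel (overflow) tokens replace values, the file dialect, and the seed.
#' The same style always generates a byte-identical fixture.
#'
#' @param name Short identifier for the style.
#' @param data_format,data_type As in [parser_spec()].
#' @param plate_rows,plate_cols Plate dimensions.
#' @param num_readings Number of readings.
#' @param axis_len Number of timepoints/wavelengths (1 for single).
#' @param decorated Add realistic export furniture around the data.
#' @param sentinel_rate Fraction of data cells replaced by overflow tokens.
#' @param dialect Output dialect (`csv`, `csv2`, `tsv`, `txt`, `excel`).
#' @param seed RNG seed; the fixture is a pure function of the style.
#' @param axis_mode `"explicit"`, `"from_grid"`, `"uniform"`, or `NULL` to
#'   pick a sensible default (from_grid when decorated, else uniform for
#'   timecourse and explicit for spectrum).
#' @param well_mode `"plate"` or `"explicit"` (same wells, listed one by one).
#' @param irregular_blocks Place readings at irregular spacings and describe
#'   them with `explicit_blocks` instead of a stride (horizontal only).
#' @param sheet Sheet name used for Excel fixtures.
#' @return A `fixture_style` object.
#' @export
fixture_style <- function(name, data_format, data_type,
                          plate_rows = 8, plate_cols = 12,
                          num_readings = 1, axis_len = 1,
                          decorated = FALSE, sentinel_rate = 0,
                          dialect = "csv", seed = 1,
                          axis_mode = NULL, well_mode = "plate",
                          irregular_blocks = FALSE, sheet = "Sheet1") {
  data_format <- match.arg(data_format, PP_FORMATS)
  data_type <- match.arg(data_type, PP_TYPES)
  dialect <- match.arg(dialect, PP_DIALECTS)
  well_mode <- match.arg(well_mode, c("plate", "explicit"))
  if (identical(data_format, "matrix") && !identical(data_type, "single")) {
    pp_abort("invalid_style",
             "matrix format fixtures must be data_type \"single\" (kinetic matrix exports are expressed as one reading per timepoint)")
  }
  if (identical(data_type, "single") && axis_len != 1) {
    pp_abort("invalid_style", sprintf(
      "data_type \"single\" requires axis_len 1, got %d", axis_len))
  }
  if (!identical(data_type, "single") && axis_len < 2) {
    pp_abort("invalid_style", sprintf(
      "data_type \"%s\" requires axis_len >= 2, got %d", data_type, axis_len))
  }
  if (sentinel_rate < 0 || sentinel_rate >= 1) {
    pp_abort("invalid_style", "sentinel_rate must be in [0, 1)")
  }
  if (irregular_blocks && !identical(data_format, "horizontal")) {
    pp_abort("invalid_style", "irregular_blocks is implemented for horizontal fixtures")
  }
  if (identical(data_format, "matrix") && !identical(well_mode, "plate")) {
    pp_abort("invalid_style", "matrix format requires well_mode \"plate\"")
  }
  if (is.null(axis_mode) && !identical(data_type, "single")) {
    axis_mode <- if (decorated) "from_grid"
                 else if (identical(data_type, "timecourse")) "uniform"
                 else "explicit"
  }
  if (!is.null(axis_mode)) {
    axis_mode <- match.arg(axis_mode, c("explicit", "from_grid", "uniform"))
    if (identical(axis_mode, "from_grid") && !decorated) {
      pp_abort("invalid_style",
               "axis_mode \"from_grid\" needs a decorated layout (the labels live in the decoration)")
    }
    if (identical(data_type, "single")) {
      pp_abort("invalid_style", "data_type \"single\" takes no axis_mode")
    }
  }
  structure(list(
    name = name, data_format = data_format, data_type = data_type,
    plate_rows = as.integer(plate_rows), plate_cols = as.integer(plate_cols),
    num_readings = as.integer(num_readings), axis_len = as.integer(axis_len),
    decorated = isTRUE(decorated), sentinel_rate = sentinel_rate,
    dialect = dialect, seed = as.integer(seed), axis_mode = axis_mode,
    well_mode = well_mode, irregular_blocks = isTRUE(irregular_blocks),
    sheet = sheet
  ), class = "fixture_style")
}

#' @export
print.fixture_style <- function(x, ...) {
  cat(sprintf("<fixture_style \"%s\": %s %s, %dx%d plate, %d reading(s), axis %d, %s, %s, seed %d>\n",
              x$name, x$data_format, x$data_type, x$plate_rows, x$plate_cols,
              x$num_readings, x$axis_len,
              if (x$decorated) "decorated" else "plain", x$dialect, x$seed))
  invisible(x)
}

# number rendering: truth values are DEFINED as the parse of the rendered
# text, so engine output and ground truth are bit-identical doubles
render_number <- function(v, dialect) {
  txt <- formatC(v, format = "f", digits = 4)
  if (identical(dialect, "csv2")) txt <- sub(".", ",", txt, fixed = TRUE)
  txt
}

axis_label_text <- function(labels, dialect) {
  txt <- vapply(labels, function(l) format(l, scientific = FALSE, trim = TRUE), "")
  if (identical(dialect, "csv2")) txt <- sub(".", ",", txt, fixed = TRUE)
  txt
}

SENTINEL_TOKENS <- c("OVRFLW", "OVER", "?")

#' Generate a fixture bundle from a style
#'
#' Fabricates a raw export grid in the style's dialect, the parser spec whose
#' coordinates point at the true data blocks, a metadata table covering every
#' well, and the ground-truth joined table the engine must reproduce.
#' Measurement values are uniform random in an absorbance-like range
#' (0.03-1.8); sentinel-injected cells are recorded as missing in the truth.
#'
#' @param style A [fixture_style()].
#' @return A `fixture_bundle`: list with `style`, `grid` (a [cell_grid()]),
#'   `spec` ([parser_spec()]), `metadata` (tibble) and `truth` (tibble).
#' @export
generate_fixture <- function(style) {
  stopifnot(inherits(style, "fixture_style"))
  with_seed(style$seed, build_fixture(style))
}

build_fixture <- function(style) {
  n_wells <- style$plate_rows * style$plate_cols
  wells <- enumerate_wells(style$plate_rows, style$plate_cols)
  ax <- style$axis_len
  dialect <- style$dialect

  # measurement text + numeric truth (truth = parse of the text)
  readings <- lapply(seq_len(style$num_readings), function(i) {
    txt <- matrix(render_number(round(runif(n_wells * ax, 0.03, 1.8), 4), dialect),
                  nrow = n_wells, ncol = ax)
    vals <- matrix(as.numeric(gsub(",", ".", txt, fixed = TRUE)),
                   nrow = n_wells, ncol = ax)
    if (style$sentinel_rate > 0) {
      mask <- matrix(runif(n_wells * ax) < style$sentinel_rate, n_wells, ax)
      if (any(mask)) {
        txt[mask] <- sample(SENTINEL_TOKENS, sum(mask), replace = TRUE)
        vals[mask] <- NA_real_
      }
    }
    list(txt = txt, vals = vals)
  })
  reading_names <- if (style$num_readings == 1) "OD600" else
    c("OD600", "GFP", "RFP", "lum", paste0("ch", seq_len(max(0, style$num_readings - 4))))[
      seq_len(style$num_readings)]

  axis_labels <- switch(style$data_type,
    single = NULL,
    timecourse = seq(0, by = 30, length.out = ax),
    spectrum = seq(350, by = 5, length.out = ax))

  lay <- layout_fixture(style, wells, reading_names, readings, axis_labels)

  metadata <- tibble(
    well = wells,
    strain = sample(c("WT", "mutA", "mutB"), n_wells, replace = TRUE),
    inducer_uM = sample(c(0, 0.1, 1, 10), n_wells, replace = TRUE))
  attr(metadata, "well_column") <- "well"
  class(metadata) <- c("metadata_table", class(metadata))

  truth <- tibble(
    well = rep(wells, each = ax),
    strain = rep(metadata$strain, each = ax),
    inducer_uM = rep(metadata$inducer_uM, each = ax))
  if (!identical(style$data_type, "single")) {
    nm <- if (identical(style$data_type, "timecourse")) "time" else "wavelength"
    truth[[nm]] <- rep(axis_labels, times = n_wells)
  }
  for (i in seq_along(readings)) {
    truth[[reading_names[i]]] <- as.vector(t(readings[[i]]$vals))
  }

  structure(list(style = style, grid = lay$grid, spec = lay$spec,
                 metadata = metadata, truth = truth),
            class = "fixture_bundle")
}

# Deterministic layout: rows are built top-down; every coordinate recorded
# as it is laid out, then frozen into the emitted spec.
layout_fixture <- function(style, wells, reading_names, readings, axis_labels) {
  n_wells <- length(wells)
  ax <- style$axis_len
  dialect <- style$dialect
  dec <- style$decorated
  rows <- list()
  add_row <- function(cells) rows[[length(rows) + 1L]] <<- as.character(cells)

  if (dec) {
    add_row(c("Protocol:", "GrowthAssay"))
    add_row(c("Date:", "2026-01-12"))
    add_row("")
  }
  col_off <- if (dec) 1L else 0L
  ax_txt <- if (is.null(axis_labels)) NULL else axis_label_text(axis_labels, dialect)
  axis_ref <- NULL
  explicit_blocks <- NULL
  stride <- NULL

  if (identical(style$data_format, "horizontal")) {
    if (dec) add_row(c(rep("", col_off), wells))  # well header row
    first_data_row <- NA_integer_
    blocks_first_rows <- integer()
    for (i in seq_along(readings)) {
      if (style$irregular_blocks && i > 1) {
        for (k in seq_len(i)) add_row("")  # irregular gap
      }
      if (dec) add_row(c("Reading:", reading_names[i]))
      blocks_first_rows[i] <- length(rows) + 1L
      for (t in seq_len(ax)) {
        lead <- if (dec) {
          if (is.null(ax_txt)) "" else ax_txt[t]
        } else NULL
        add_row(c(lead, readings[[i]]$txt[, t]))
      }
    }
    first_data_row <- blocks_first_rows[1]
    first_block <- block_range(
      cell_ref(first_data_row, col_off + 1L),
      cell_ref(first_data_row + ax - 1L, col_off + n_wells))
    if (style$irregular_blocks) {
      explicit_blocks <- lapply(blocks_first_rows, function(r0) {
        block_range(cell_ref(r0, col_off + 1L),
                    cell_ref(r0 + ax - 1L, col_off + n_wells))
      })
    } else {
      stride <- ax + if (dec) 1L else 0L
    }
    if (identical(style$axis_mode, "from_grid")) {
      axis_ref <- block_range(cell_ref(first_data_row, 1L),
                              cell_ref(first_data_row + ax - 1L, 1L))
    }
  } else if (identical(style$data_format, "vertical")) {
    stride <- ax + if (dec) 1L else 0L
    band_col <- function(i) col_off + 1L + (i - 1L) * stride
    header_rows <- 0L
    if (dec) {
      hdr1 <- rep("", band_col(length(readings)) + ax - 1L)
      for (i in seq_along(readings)) hdr1[band_col(i)] <- reading_names[i]
      add_row(hdr1)
      header_rows <- 1L
      if (!is.null(ax_txt)) {
        hdr2 <- rep("", band_col(length(readings)) + ax - 1L)
        for (i in seq_along(readings)) {
          hdr2[band_col(i):(band_col(i) + ax - 1L)] <- ax_txt
        }
        add_row(hdr2)
        header_rows <- 2L
      }
    }
    first_data_row <- length(rows) + 1L
    for (w in seq_len(n_wells)) {
      line <- rep("", band_col(length(readings)) + ax - 1L)
      if (dec) line[1] <- wells[w]
      for (i in seq_along(readings)) {
        line[band_col(i):(band_col(i) + ax - 1L)] <- readings[[i]]$txt[w, ]
      }
      add_row(line)
    }
    first_block <- block_range(
      cell_ref(first_data_row, band_col(1L)),
      cell_ref(first_data_row + n_wells - 1L, band_col(1L) + ax - 1L))
    if (identical(style$axis_mode, "from_grid")) {
      axis_ref <- block_range(cell_ref(first_data_row - 1L, band_col(1L)),
                              cell_ref(first_data_row - 1L, band_col(1L) + ax - 1L))
    }
  } else { # matrix
    pr <- style$plate_rows; pc <- style$plate_cols
    blocks_first_rows <- integer()
    for (i in seq_along(readings)) {
      if (dec) {
        add_row(c("Reading:", reading_names[i]))
        add_row(c("", as.character(seq_len(pc))))
      }
      blocks_first_rows[i] <- length(rows) + 1L
      plate <- matrix(readings[[i]]$txt[, 1], nrow = pr, ncol = pc, byrow = TRUE)
      for (r in seq_len(pr)) {
        lead <- if (dec) LETTERS[r] else NULL
        add_row(c(lead, plate[r, ]))
      }
      if (dec) add_row("")
    }
    first_block <- block_range(
      cell_ref(blocks_first_rows[1], col_off + 1L),
      cell_ref(blocks_first_rows[1] + pr - 1L, col_off + pc))
    stride <- pr + if (dec) 3L else 0L
  }

  if (dec) {
    add_row("")
    add_row("End of report")
  }

  n_cols <- max(vapply(rows, length, 1L))
  cells <- matrix("", nrow = length(rows), ncol = n_cols)
  for (r in seq_along(rows)) {
    line <- rows[[r]]
    if (length(line)) cells[r, seq_along(line)] <- line
  }
  grid <- new_cell_grid(cells, dialect,
                        sheet = if (identical(dialect, "excel")) style$sheet else NULL)

  axis <- if (identical(style$data_type, "single")) NULL else switch(style$axis_mode,
    explicit = axis_explicit(axis_labels),
    uniform = axis_uniform(axis_labels[1], axis_labels[2] - axis_labels[1]),
    from_grid = axis_from_grid(axis_ref))

  spec <- parser_spec(
    data_format = style$data_format, data_type = style$data_type,
    first_block = first_block, num_readings = style$num_readings,
    reading_names = reading_names,
    block_stride = if (is.null(explicit_blocks)) stride else NULL,
    explicit_blocks = explicit_blocks,
    wells = if (identical(style$well_mode, "plate")) {
      wells_plate(style$plate_rows, style$plate_cols)
    } else {
      wells_explicit(wells)
    },
    axis = axis,
    dialect = dialect,
    sheet = if (identical(dialect, "excel")) style$sheet else NULL)

  list(grid = grid, spec = spec)
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle \"%s\": grid %d x %d, %d truth row(s)>\n",
              x$style$name, nrow(x$grid), ncol(x$grid), nrow(x$truth)))
  invisible(x)
}

#' The catalog of fixture styles
#'
#' A named list of styles spanning the full cross product of layout format
#' x data type (minus the impossible matrix-kinetic combinations) x plain/
#' decorated, with every file dialect represented, plus edge styles:
#' sentinel injection, an explicit well list, irregular explicit blocks, a
#' 384-well plate and a minimal 1-well fixture. Every catalog entry must
#' round-trip through the engine exactly.
#'
#' @return Named list of [fixture_style()]s.
#' @export
style_catalog <- function() {
  styles <- list(
    fixture_style("horiz-single-plain-csv", "horizontal", "single",
                  num_readings = 2, dialect = "csv", seed = 101),
    fixture_style("horiz-single-dec-tsv", "horizontal", "single",
                  num_readings = 3, decorated = TRUE, dialect = "tsv", seed = 102),
    fixture_style("horiz-time-plain-csv", "horizontal", "timecourse",
                  plate_rows = 2, plate_cols = 3, axis_len = 4,
                  dialect = "csv", seed = 103),
    fixture_style("horiz-time-dec-excel", "horizontal", "timecourse",
                  num_readings = 2, axis_len = 5, decorated = TRUE,
                  dialect = "excel", seed = 104),
    fixture_style("horiz-spec-plain-txt", "horizontal", "spectrum",
                  plate_rows = 2, plate_cols = 3, axis_len = 21,
                  dialect = "txt", seed = 105),
    fixture_style("horiz-spec-dec-csv2", "horizontal", "spectrum",
                  plate_rows = 2, plate_cols = 3, axis_len = 21,
                  decorated = TRUE, dialect = "csv2", seed = 106),
    fixture_style("vert-single-plain-tsv", "vertical", "single",
                  num_readings = 2, dialect = "tsv", seed = 107),
    fixture_style("vert-single-dec-csv", "vertical", "single",
                  num_readings = 2, decorated = TRUE, dialect = "csv", seed = 108),
    fixture_style("vert-time-plain-excel", "vertical", "timecourse",
                  plate_rows = 2, plate_cols = 3, num_readings = 2,
                  axis_len = 5, dialect = "excel", seed = 109),
    fixture_style("vert-time-dec-csv", "vertical", "timecourse",
                  num_readings = 2, axis_len = 5, decorated = TRUE,
                  dialect = "csv", seed = 110),
    fixture_style("vert-spec-plain-csv2", "vertical", "spectrum",
                  plate_rows = 2, plate_cols = 3, axis_len = 11,
                  dialect = "csv2", seed = 111),
    fixture_style("vert-spec-dec-txt", "vertical", "spectrum",
                  plate_rows = 4, plate_cols = 6, axis_len = 11,
                  decorated = TRUE, dialect = "txt", seed = 112),
    fixture_style("matrix-single-plain-csv", "matrix", "single",
                  dialect = "csv", seed = 113),
    fixture_style("matrix-single-dec-csv", "matrix", "single",
                  num_readings = 2, decorated = TRUE, dialect = "csv", seed = 114),
    fixture_style("matrix-single-dec-excel", "matrix", "single",
                  num_readings = 2, decorated = TRUE, dialect = "excel",
                  sheet = "data", seed = 115),
    fixture_style("matrix-single-plain-csv2", "matrix", "single",
                  num_readings = 2, dialect = "csv2", seed = 116),
    fixture_style("matrix-384-dec-tsv", "matrix", "single",
                  plate_rows = 16, plate_cols = 24, decorated = TRUE,
                  dialect = "tsv", seed = 117),
    fixture_style("horiz-single-sentinels-csv", "horizontal", "single",
                  num_readings = 2, decorated = TRUE, sentinel_rate = 0.05,
                  dialect = "csv", seed = 118),
    fixture_style("vert-single-explicitwells-csv", "vertical", "single",
                  plate_rows = 2, plate_cols = 3, well_mode = "explicit",
                  dialect = "csv", seed = 119),
    fixture_style("horiz-explicitblocks-dec-csv", "horizontal", "single",
                  num_readings = 2, decorated = TRUE, irregular_blocks = TRUE,
                  dialect = "csv", seed = 120),
    fixture_style("minimal-1x1-csv", "horizontal", "single",
                  plate_rows = 1, plate_cols = 1, dialect = "csv", seed = 121),
    fixture_style("matrix-single-sentinels-txt", "matrix", "single",
                  decorated = TRUE, sentinel_rate = 0.1, dialect = "txt",
                  seed = 122)
  )
  names(styles) <- vapply(styles, `[[`, "", "name")
  styles
}

# ---- serializing grids back to files --------------------------------------

quote_field <- function(x, sep) {
  needs <- grepl(sep, x, fixed = TRUE) | grepl("\"", x, fixed = TRUE) |
    grepl("\n", x, fixed = TRUE)
  x[needs] <- paste0("\"", gsub("\"", "\"\"", x[needs], fixed = TRUE), "\"")
  x
}

#' Write a cell grid to a raw file
#'
#' Serializes a grid verbatim in the requested dialect; re-reading the file
#' with [read_raw_grid()] reproduces the grid cell-for-cell.
#'
#' @param grid A [cell_grid()].
#' @param path Output path (use `.xlsx` for the excel dialect).
#' @param dialect Output dialect; defaults to the grid's own.
#' @param delimiter Separator override for the `txt` dialect.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, dialect = NULL, delimiter = NULL) {
  stopifnot(inherits(grid, "cell_grid"))
  dialect <- dialect %||% grid_dialect(grid)
  dialect <- match.arg(dialect, PP_DIALECTS)
  if (identical(dialect, "excel")) {
    write_xlsx_grid(unclass(grid), path, sheet = attr(grid, "sheet") %||% "Sheet1")
  } else {
    sep <- dialect_sep(dialect, delimiter)
    cells <- unclass(grid)
    lines <- apply(cells, 1, function(r) paste(quote_field(r, sep), collapse = sep))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

fixture_raw_filename <- function(style) {
  switch(style$dialect,
         excel = "raw.xlsx",
         tsv = "raw.tsv",
         txt = "raw.txt",
         "raw.csv")  # csv and csv2 share the extension
}

#' Write a fixture bundle to a directory
#'
#' Emits the four files a user-facing run needs: the raw export in the
#' style's dialect, the parser spec as JSON, the metadata as CSV, and the
#' ground-truth joined table as CSV.
#'
#' @param bundle A `fixture_bundle` from [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths (`raw`, `spec`, `metadata`,
#'   `truth`), invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    raw = file.path(dir, fixture_raw_filename(bundle$style)),
    spec = file.path(dir, "spec.json"),
    metadata = file.path(dir, "metadata.csv"),
    truth = file.path(dir, "truth.csv"))
  write_grid(bundle$grid, paths$raw)
  save_spec(bundle$spec, paths$spec)
  readr::write_csv(as.data.frame(bundle$metadata), paths$metadata, na = "")
  readr::write_csv(bundle$truth, paths$truth, na = "")
  invisible(paths)
}
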