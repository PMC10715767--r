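# Minimal xlsx emitter for the fixture generator: a workbook is a ZIP
# container of five XML parts. Entries are stored uncompressed with a
# table-driven CRC-32 and fixed timestamps, so the same grid always produces
# byte-identical files. Cells are written as inline strings — the grid is
# text, and the reader must see exactly that text.

crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    cc <- i
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L) == 1L) {
        bitwXor(-306674912L, bitwShiftR(cc, 1))  # 0xEDB88320, logical shift
      } else {
        bitwShiftR(cc, 1)
      }
    }
    tab[i + 1] <- cc
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (x in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8), crc32_table[bitwAnd(bitwXor(crc, x), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

le16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
le32 <- function(x) {
  x <- as.numeric(x)
  if (x >= 2^31) x <- x - 2^32
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

# Stored (method 0) ZIP archive; fixed DOS date/time for determinism.
zip_store <- function(entries, path) {
  body <- list(); central <- list(); offset <- 0
  dos_time <- le16(0x21); dos_date <- le16(0x5821)
  for (nm in names(entries)) {
    data <- entries[[nm]]
    name <- charToRaw(nm)
    crc <- crc32(data)
    lfh <- c(le32(0x04034b50), le16(20), le16(0), le16(0), dos_time, dos_date,
             le32(crc), le32(length(data)), le32(length(data)),
             le16(length(name)), le16(0))
    body[[nm]] <- c(lfh, name, data)
    central[[nm]] <- c(le32(0x02014b50), le16(20), le16(20), le16(0), le16(0),
                       dos_time, dos_date, le32(crc), le32(length(data)),
                       le32(length(data)), le16(length(name)), le16(0), le16(0),
                       le16(0), le16(0), le32(0), le32(offset), name)
    offset <- offset + length(lfh) + length(name) + length(data)
  }
  cdir <- do.call(c, unname(central))
  n <- length(entries)
  eocd <- c(le32(0x06054b50), le16(0), le16(0), le16(n), le16(n),
            le32(length(cdir)), le32(offset), le16(0))
  writeBin(c(do.call(c, unname(body)), cdir, eocd), path)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# 1-based column index -> spreadsheet letters (1 -> A, 27 -> AA)
col_letters <- function(j) {
  s <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    s <- paste0(LETTERS[r + 1], s)
    j <- (j - 1) %/% 26
  }
  s
}

XML_DECL <- '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n'

write_xlsx_grid <- function(cells, path, sheet = "Sheet1") {
  stopifnot(is.matrix(cells), is.character(cells))
  rows <- vapply(seq_len(nrow(cells)), function(i) {
    cs <- vapply(seq_len(ncol(cells)), function(j) {
      sprintf('<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
              col_letters(j), i, xml_escape(cells[i, j]))
    }, "")
    sprintf('<row r="%d">%s</row>', i, paste(cs, collapse = ""))
  }, "")
  sheet_xml <- paste0(
    XML_DECL,
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main"><sheetData>',
    paste(rows, collapse = ""), "</sheetData></worksheet>")
  entries <- list(
    "[Content_Types].xml" = charToRaw(paste0(
      XML_DECL,
      '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
      '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
      '<Default Extension="xml" ContentType="application/xml"/>',
      '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
      '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
      "</Types>")),
    "_rels/.rels" = charToRaw(paste0(
      XML_DECL,
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
      "</Relationships>")),
    "xl/workbook.xml" = charToRaw(paste0(
      XML_DECL,
      '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
      'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
      '<sheets><sheet name="', xml_escape(sheet), '" sheetId="1" r:id="rId1"/></sheets></workbook>')),
    "xl/_rels/workbook.xml.rels" = charToRaw(paste0(
      XML_DECL,
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
      '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
      "</Relationships>")),
    "xl/worksheets/sheet1.xml" = charToRaw(enc2utf8(sheet_xml)))
  zip_store(entries, path)
}
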