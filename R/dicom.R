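# Minimal DICOM Part-10 support: explicit-VR little-endian only, the small set
# of VRs the toolkit's metadata and fixtures use (DS, IS, US, UL, CS, SH, LO,
# UI, OW). This is deliberately not a general DICOM implementation: headers
# are key-value metadata here, and the sidecar JSON route is the primary one.
# Tags are addressed as "GGGG,EEEE" hex strings throughout.

.DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.DCM_STRING_VRS <- c("DS", "IS", "CS", "SH", "LO", "UI", "PN", "DA", "TM")

dcm_tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

dcm_parse_key <- function(key) {
  parts <- strsplit(toupper(key), ",", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stopf("malformed DICOM tag key '%s'", key)
  strtoi(parts, 16L)
}

uint16_raw <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
}

uint32_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

raw_uint16 <- function(r) as.integer(r[1L]) + 256L * as.integer(r[2L])

raw_uint32 <- function(r) sum(as.numeric(r) * c(1, 256, 65536, 16777216))

dcm_encode_element <- function(key, vr, value) {
  tag <- dcm_parse_key(key)
  if (vr %in% .DCM_STRING_VRS) {
    bytes <- charToRaw(as.character(value))
    if (length(bytes) %% 2L == 1L)
      bytes <- c(bytes, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  } else if (vr == "US") {
    bytes <- uint16_raw(value)
  } else if (vr == "UL") {
    bytes <- uint32_raw(value)
  } else if (vr == "OW") {
    bytes <- value  # caller supplies raw
  } else {
    stopf("unsupported VR '%s'", vr)
  }
  head <- c(uint16_raw(tag[1L]), uint16_raw(tag[2L]), charToRaw(vr))
  if (vr %in% .DCM_LONG_VRS) {
    c(head, as.raw(c(0L, 0L)), uint32_raw(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65534L) stopf("value too long for short-form VR '%s'", vr)
    c(head, uint16_raw(length(bytes)), bytes)
  }
}

# elements: named list keyed "GGGG,EEEE" of list(vr=, value=); pixels: integer
# matrix (rows x cols) stored as 16-bit unsigned little-endian, row-major.
dcm_write <- function(path, elements, pixels = NULL) {
  out <- c(raw(128L), charToRaw("DICM"),
           dcm_encode_element("0002,0010", "UI", "1.2.840.10008.1.2.1"))
  keys <- names(elements)
  ord <- order(vapply(keys, function(k) {
    tag <- dcm_parse_key(k); tag[1L] * 65536 + tag[2L]
  }, numeric(1L)))
  for (k in keys[ord])
    out <- c(out, dcm_encode_element(k, elements[[k]]$vr, elements[[k]]$value))
  if (!is.null(pixels)) {
    if (any(pixels < 0L) || any(pixels > 32767L))
      stopf("pixel values must be in [0, 32767] for 16-bit storage")
    out <- c(out, dcm_encode_element("0028,0010", "US", nrow(pixels)),
             dcm_encode_element("0028,0011", "US", ncol(pixels)),
             dcm_encode_element("0028,0100", "US", 16L))
    px <- writeBin(as.integer(t(pixels)), raw(), size = 2L, endian = "little")
    out <- c(out, dcm_encode_element("7FE0,0010", "OW", px))
  }
  writeBin(out, path)
  invisible(path)
}

dcm_is_dicom <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 132L)
  length(hdr) == 132L && identical(rawToChar(hdr[129:132]), "DICM")
}

# Parse a file written in explicit-VR little-endian; returns
# list(elements = named list of parsed scalar values, pixels = matrix or NULL).
dcm_read <- function(path) {
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 132L || !identical(rawToChar(buf[129:132]), "DICM"))
    stopf("'%s' is not a DICOM file", path)
  pos <- 133L
  elements <- list()
  pixels_raw <- NULL
  n <- length(buf)
  while (pos + 7L <= n) {
    group <- raw_uint16(buf[pos:(pos + 1L)])
    element <- raw_uint16(buf[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% .DCM_LONG_VRS) {
      len <- raw_uint32(buf[(pos + 8L):(pos + 11L)])
      pos <- pos + 12L
    } else {
      len <- raw_uint16(buf[(pos + 6L):(pos + 7L)])
      pos <- pos + 8L
    }
    val <- if (len > 0L) buf[pos:(pos + len - 1L)] else raw(0L)
    pos <- pos + len
    key <- dcm_tag_key(group, element)
    if (key == "7FE0,0010") {
      pixels_raw <- val
    } else if (vr %in% .DCM_STRING_VRS) {
      val <- val[val != as.raw(0L)]  # strip UI nul padding
      elements[[key]] <- sub(" +$", "", rawToChar(val))
    } else if (vr == "US") {
      elements[[key]] <- raw_uint16(val)
    } else if (vr == "UL") {
      elements[[key]] <- raw_uint32(val)
    }  # other VRs skipped
  }
  pixels <- NULL
  if (!is.null(pixels_raw)) {
    rows <- elements[["0028,0010"]]
    cols <- elements[["0028,0011"]]
    if (is.null(rows) || is.null(cols))
      stopf("pixel data present but Rows/Columns tags missing in '%s'", path)
    vals <- readBin(pixels_raw, "integer", rows * cols, size = 2L,
                    signed = FALSE, endian = "little")
    if (length(vals) != rows * cols)
      stopf("unparseable pixel data in '%s'", path)
    pixels <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  }
  list(elements = elements, pixels = pixels)
}
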