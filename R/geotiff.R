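# Minimal single-band GeoTIFF codec.
#
# The pipeline needs only uncompressed, strip-organised, single-band rasters
# with a geotransform (ModelPixelScale + ModelTiepoint) and an optional
# GDAL-style nodata tag.  Rather than depend on a system GIS stack, the
# package reads and writes that subset of the format directly.  Constraints:
# classic TIFF (not BigTIFF), compression 1 (none), one sample per pixel,
# 8/16/32-bit integers or 32/64-bit IEEE floats, either byte order on read,
# little-endian on write.

.TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `6` = 1L,
                     `8` = 2L, `9` = 4L, `11` = 4L, `12` = 8L)

# Parse `count` values of TIFF `type` from a raw vector starting at `off`
# (1-based).  Returns a double vector, or a character scalar for ASCII.
.tiff_parse_vals <- function(raw, off, type, count, endian) {
  size <- .TIFF_TYPE_SIZE[[as.character(type)]]
  if (is.null(size)) return(NULL)  # unknown type: caller skips the tag
  bytes <- raw[off:(off + size * count - 1L)]
  con <- rawConnection(bytes, "rb")
  on.exit(close(con))
  if (type == 2L) {                           # ASCII, NUL-terminated
    txt <- readBin(con, "raw", n = count)
    return(rawToChar(txt[txt != as.raw(0)]))
  }
  vals <- switch(as.character(type),
    `1` = readBin(con, "integer", n = count, size = 1L, signed = FALSE),
    `6` = readBin(con, "integer", n = count, size = 1L, signed = TRUE),
    `3` = readBin(con, "integer", n = count, size = 2L, signed = FALSE,
                  endian = endian),
    `8` = readBin(con, "integer", n = count, size = 2L, signed = TRUE,
                  endian = endian),
    `4` = readBin(con, "integer", n = count, size = 4L, endian = endian),
    `9` = readBin(con, "integer", n = count, size = 4L, endian = endian),
    `11` = readBin(con, "double", n = count, size = 4L, endian = endian),
    `12` = readBin(con, "double", n = count, size = 8L, endian = endian))
  vals <- as.double(vals)
  if (type == 4L) vals <- ifelse(vals < 0, vals + 2^32, vals)  # uint32
  vals
}

# Read the subset of TIFF described above.  Returns a list with fields
# width, height, values (numeric matrix, row-major source order preserved),
# pixel_scale, tiepoint, nodata (string or NULL), crs (string or NULL).
.tiff_read <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file (truncated): ", path)
  order_mark <- rawToChar(raw[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  magic <- .tiff_parse_vals(raw, 3L, 3L, 1L, endian)
  if (magic == 43) stop("BigTIFF is not supported: ", path)
  if (magic != 42) stop("not a TIFF file (bad magic): ", path)
  ifd_off <- .tiff_parse_vals(raw, 5L, 4L, 1L, endian)

  n_entries <- .tiff_parse_vals(raw, ifd_off + 1L, 3L, 1L, endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e_off <- ifd_off + 2L + (i - 1L) * 12L + 1L
    tag   <- .tiff_parse_vals(raw, e_off,      3L, 1L, endian)
    type  <- .tiff_parse_vals(raw, e_off + 2L, 3L, 1L, endian)
    count <- .tiff_parse_vals(raw, e_off + 4L, 4L, 1L, endian)
    if (!as.character(type) %in% names(.TIFF_TYPE_SIZE)) next
    size <- .TIFF_TYPE_SIZE[[as.character(type)]]
    val_off <- if (size * count <= 4) e_off + 8L else
      .tiff_parse_vals(raw, e_off + 8L, 4L, 1L, endian) + 1L
    tags[[as.character(tag)]] <- .tiff_parse_vals(raw, val_off, type, count,
                                                  endian)
  }
  next_ifd <- .tiff_parse_vals(
    raw, ifd_off + 2L + n_entries * 12L + 1L, 4L, 1L, endian)
  if (!is.na(next_ifd) && next_ifd != 0)
    stop("multi-page TIFF is not supported (expected a single band): ", path)

  tg <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }
  width  <- tg(256); height <- tg(257)
  if (is.null(width) || is.null(height))
    stop("TIFF lacks image dimensions: ", path)
  if (tg(259, 1) != 1) stop("compressed TIFF is not supported: ", path)
  spp <- tg(277, 1)
  if (spp != 1)
    stop("multi-band raster (", spp, " samples/pixel); expected single-band: ",
         path)
  bits <- tg(258, 1)
  fmt  <- tg(339, 1)   # 1 unsigned int, 2 signed int, 3 IEEE float
  rows_per_strip <- tg(278, height)
  offsets <- tg(273); counts <- tg(279)
  if (is.null(offsets)) stop("TIFF lacks strip offsets: ", path)
  if (tg(284, 1) != 1) stop("planar TIFF is not supported: ", path)

  n_px <- width * height
  vals <- numeric(0)
  for (s in seq_along(offsets)) {
    nbytes <- if (!is.null(counts)) counts[s] else
      rows_per_strip * width * bits / 8
    bytes <- raw[(offsets[s] + 1L):(offsets[s] + nbytes)]
    con <- rawConnection(bytes, "rb")
    n <- nbytes / (bits / 8)
    v <- if (fmt == 3) {
      readBin(con, "double", n = n, size = bits / 8L, endian = endian)
    } else if (bits == 8L) {
      as.double(readBin(con, "integer", n = n, size = 1L,
                        signed = (fmt == 2), endian = endian))
    } else if (bits == 16L) {
      as.double(readBin(con, "integer", n = n, size = 2L,
                        signed = (fmt == 2), endian = endian))
    } else if (bits == 32L) {
      v0 <- as.double(readBin(con, "integer", n = n, size = 4L,
                              endian = endian))
      if (fmt == 1) ifelse(v0 < 0, v0 + 2^32, v0) else v0
    } else {
      close(con)
      stop("unsupported sample layout (", bits, "-bit, format ", fmt, "): ",
           path)
    }
    close(con)
    vals <- c(vals, v)
  }
  vals <- vals[seq_len(n_px)]

  list(width = width, height = height,
       values = matrix(vals, nrow = height, ncol = width, byrow = TRUE),
       pixel_scale = tg(33550), tiepoint = tg(33922),
       nodata = tg(42113), crs = tg(34737),
       sample_format = fmt, bits = bits)
}

.tiff_entry <- function(tag, type, count, value_or_offset) {
  # value_or_offset: raw(4) already laid out
  con <- rawConnection(raw(0), "wb")
  writeBin(as.integer(tag), con, size = 2L, endian = "little")
  writeBin(as.integer(type), con, size = 2L, endian = "little")
  writeBin(as.integer(count), con, size = 4L, endian = "little")
  writeBin(value_or_offset, con)
  out <- rawConnectionValue(con)
  close(con)
  out
}

.tiff_pack <- function(x, type) {
  con <- rawConnection(raw(0), "wb")
  switch(as.character(type),
    `2` = writeBin(c(charToRaw(x), as.raw(0)), con),
    `3` = writeBin(as.integer(x), con, size = 2L, endian = "little"),
    `4` = writeBin(as.integer(x), con, size = 4L, endian = "little"),
    `12` = writeBin(as.double(x), con, size = 8L, endian = "little"))
  out <- rawConnectionValue(con)
  close(con)
  out
}

# Write a single-band GeoTIFF, little-endian, one strip.  `values` is a
# numeric matrix (row 1 = top row).  `integer_band` selects int32 storage.
.tiff_write <- function(path, values, pixel_scale, tiepoint, nodata_str,
                        crs = NULL, integer_band = FALSE) {
  height <- nrow(values); width <- ncol(values)
  bits <- if (integer_band) 32L else 64L
  fmt  <- if (integer_band) 2L else 3L
  strip_bytes <- width * height * bits / 8

  # tag payloads larger than 4 bytes live in a heap between IFD and strip
  heap <- list()
  heap_bytes <- 0L
  add_heap <- function(bytes) {
    if (length(bytes) %% 2L == 1L) bytes <- c(bytes, as.raw(0))  # word align
    heap[[length(heap) + 1L]] <<- bytes
    off <- heap_bytes
    heap_bytes <<- heap_bytes + length(bytes)
    off  # offset relative to heap start
  }

  inline4 <- function(x, type) {
    b <- .tiff_pack(x, type)
    c(b, raw(4L - length(b)))
  }

  entries <- list()
  deferred <- list()  # entries whose value slot needs heap offset patched
  add_tag <- function(tag, type, vals) {
    b <- .tiff_pack(vals, type)
    n <- if (type == 2L) length(b) else length(vals)
    if (length(b) <= 4L) {
      entries[[length(entries) + 1L]] <<-
        .tiff_entry(tag, type, n, c(b, raw(4L - length(b))))
    } else {
      rel <- add_heap(b)
      entries[[length(entries) + 1L]] <<- NA  # placeholder
      deferred[[length(deferred) + 1L]] <<-
        list(idx = length(entries), tag = tag, type = type, n = n, rel = rel)
    }
  }

  geokeys <- c(1L, 1L, 0L, 3L,        # version, rev, minor, number of keys
               1024L, 0L, 1L, 1L,     # GTModelType = projected
               1025L, 0L, 1L, 1L,     # GTRasterType = PixelIsArea
               3072L, 0L, 1L, 32767L) # user-defined projected CRS

  add_tag(256L, 4L, width)
  add_tag(257L, 4L, height)
  add_tag(258L, 3L, bits)
  add_tag(259L, 3L, 1L)
  add_tag(262L, 3L, 1L)
  entries[[length(entries) + 1L]] <- NA   # 273 StripOffsets, patched below
  strip_entry_idx <- length(entries)
  add_tag(277L, 3L, 1L)
  add_tag(278L, 4L, height)
  add_tag(279L, 4L, strip_bytes)
  add_tag(284L, 3L, 1L)
  add_tag(339L, 3L, fmt)
  add_tag(33550L, 12L, pixel_scale)
  add_tag(33922L, 12L, tiepoint)
  add_tag(34735L, 3L, geokeys)
  if (!is.null(crs) && nzchar(crs)) add_tag(34737L, 2L, paste0(crs, "|"))
  if (!is.null(nodata_str)) add_tag(42113L, 2L, nodata_str)

  n_entries <- length(entries)
  ifd_off <- 8L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  heap_off <- ifd_off + ifd_bytes
  strip_off <- heap_off + heap_bytes

  entries[[strip_entry_idx]] <- .tiff_entry(273L, 4L, 1L,
                                            inline4(strip_off, 4L))
  for (d in deferred)
    entries[[d$idx]] <- .tiff_entry(d$tag, d$type, d$n,
                                    inline4(heap_off + d$rel, 4L))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(2L * 21L, con, size = 2L, endian = "little")  # magic 42
  writeBin(ifd_off, con, size = 4L, endian = "little")
  writeBin(as.integer(n_entries), con, size = 2L, endian = "little")
  for (e in entries) writeBin(e, con)
  writeBin(0L, con, size = 4L, endian = "little")        # no next IFD
  for (h in heap) writeBin(h, con)
  flat <- as.vector(t(values))                           # row-major strip
  if (integer_band) {
    writeBin(as.integer(round(flat)), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(flat), con, size = 8L, endian = "little")
  }
  invisible(NULL)
}
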