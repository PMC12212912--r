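# Minimal EXIF support: writing and reading the DateTimeOriginal tag of a
# JPEG. Only the subset the pipeline needs is implemented — a single APP1
# segment carrying a little-endian TIFF header with IFD0 (DateTime 0x0132,
# Exif-IFD pointer 0x8769) and an Exif IFD (DateTimeOriginal 0x9003). The
# reader parses either byte order and tolerates other tags.

.u16 <- function(x) as.raw(c(bitwAnd(bitwShiftR(x, 8), 255), bitwAnd(x, 255)))
.u16le <- function(x) as.raw(c(bitwAnd(x, 255), bitwAnd(bitwShiftR(x, 8), 255)))
.u32le <- function(x) {
  as.raw(c(
    bitwAnd(x, 255), bitwAnd(bitwShiftR(x, 8), 255),
    bitwAnd(bitwShiftR(x, 16), 255), bitwAnd(bitwShiftR(x, 24), 255)
  ))
}

# One IFD entry: tag, type, count, value-or-offset (all little-endian).
.ifd_entry <- function(tag, type, count, value) {
  c(.u16le(tag), .u16le(type), .u32le(count), .u32le(value))
}

# Build the APP1 Exif payload for one timestamp string.
.exif_app1 <- function(ts_string) {
  stopifnot(nchar(ts_string) == 19) # "YYYY:MM:DD HH:MM:SS"
  ascii <- c(charToRaw(ts_string), as.raw(0)) # 20 bytes, NUL-terminated
  # TIFF layout (offsets relative to the TIFF header):
  #   0  "II" 42, IFD0 offset = 8
  #   8  IFD0: 2 entries (0x0132, 0x8769), next = 0   -> bytes 8..37
  #   38 DateTime string (20 bytes)
  #   58 Exif IFD: 1 entry (0x9003), next = 0         -> bytes 58..75
  #   76 DateTimeOriginal string (20 bytes)
  tiff <- c(
    charToRaw("II"), .u16le(42L), .u32le(8L),
    .u16le(2L),
    .ifd_entry(0x0132L, 2L, 20L, 38L),
    .ifd_entry(0x8769L, 4L, 1L, 58L),
    .u32le(0L),
    ascii,
    .u16le(1L),
    .ifd_entry(0x9003L, 2L, 20L, 76L),
    .u32le(0L),
    ascii
  )
  payload <- c(charToRaw("Exif"), as.raw(c(0, 0)), tiff)
  c(as.raw(c(0xFF, 0xE1)), .u16(length(payload) + 2L), payload)
}

# Write an sRGB pixel array to JPEG (via EBImage) and splice in an APP1
# Exif segment directly after the SOI marker.
.write_jpeg_with_exif <- function(pixels, path, timestamp, quality = 95) {
  img <- EBImage::Image(aperm(pixels / 255, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(img, path, quality = quality)
  if (!is.null(timestamp) && !is.na(timestamp)) {
    raw <- readBin(path, "raw", file.info(path)$size)
    if (length(raw) < 2 || raw[1] != 0xFF || raw[2] != 0xD8) {
      stop("not a JPEG after encoding: ", path)
    }
    app1 <- .exif_app1(.format_exif_time(timestamp))
    writeBin(c(raw[1:2], app1, raw[-(1:2)]), path)
  }
  invisible(path)
}

# Read an integer of `n` bytes at 1-based offset `at` within raw vector.
.read_uint <- function(raw, at, n, big_endian) {
  bytes <- as.integer(raw[at:(at + n - 1)])
  if (!big_endian) bytes <- rev(bytes)
  sum(bytes * 256^((n - 1):0))
}

#' Read the EXIF DateTimeOriginal timestamp of a JPEG
#'
#' Scans the JPEG's APP1 Exif segment for `DateTimeOriginal` (tag 0x9003
#' in the Exif sub-IFD), falling back to `DateTime` (0x0132 in IFD0).
#' Both TIFF byte orders are handled.
#'
#' @param path Path to a JPEG file.
#' @return The timestamp string `"YYYY:MM:DD HH:MM:SS"`, or `NA_character_`
#'   if the file carries no EXIF timestamp.
#' @export
read_exif_datetime <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 4 || raw[1] != 0xFF || raw[2] != 0xD8) return(NA_character_)
  pos <- 3L
  while (pos + 3 <= length(raw)) {
    if (raw[pos] != 0xFF) return(NA_character_)
    marker <- as.integer(raw[pos + 1])
    if (marker == 0xDA || marker == 0xD9) return(NA_character_) # image data
    seg_len <- .read_uint(raw, pos + 2L, 2L, big_endian = TRUE)
    if (marker == 0xE1 && seg_len >= 14 &&
        rawToChar(raw[(pos + 4L):(pos + 7L)]) == "Exif") {
      tiff0 <- pos + 10L # 1-based offset of TIFF header
      ts <- .parse_exif_tiff(raw, tiff0)
      if (!is.na(ts)) return(ts)
    }
    pos <- pos + 2L + seg_len
  }
  NA_character_
}

.parse_exif_tiff <- function(raw, tiff0) {
  order <- rawToChar(raw[tiff0:(tiff0 + 1L)])
  if (!order %in% c("II", "MM")) return(NA_character_)
  be <- order == "MM"
  ifd0 <- .read_uint(raw, tiff0 + 4L, 4L, be)
  read_ifd <- function(off) {
    start <- tiff0 + off
    n <- .read_uint(raw, start, 2L, be)
    entries <- lapply(seq_len(n), function(i) {
      at <- start + 2L + (i - 1L) * 12L
      list(
        tag = .read_uint(raw, at, 2L, be),
        type = .read_uint(raw, at + 2L, 2L, be),
        count = .read_uint(raw, at + 4L, 4L, be),
        value = .read_uint(raw, at + 8L, 4L, be)
      )
    })
    entries
  }
  get_ascii <- function(entry) {
    n <- entry$count
    off <- if (n <= 4) NA else entry$value
    if (is.na(off)) return(NA_character_)
    s <- rawToChar(raw[(tiff0 + off):(tiff0 + off + n - 2L)])
    s
  }
  ifd <- read_ifd(ifd0)
  tags <- vapply(ifd, `[[`, numeric(1), "tag")
  exif_ptr <- ifd[tags == 0x8769]
  if (length(exif_ptr)) {
    sub <- read_ifd(exif_ptr[[1]]$value)
    sub_tags <- vapply(sub, `[[`, numeric(1), "tag")
    hit <- sub[sub_tags == 0x9003]
    if (length(hit)) return(get_ascii(hit[[1]]))
  }
  hit <- ifd[tags == 0x0132]
  if (length(hit)) return(get_ascii(hit[[1]]))
  NA_character_
}
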