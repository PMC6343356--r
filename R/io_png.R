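## Minimal lossless PNG support for 8-bit RGB composites.
##
## No PNG package is available in the dependency set, so the codec is
## implemented here: R's memCompress/memDecompress provide the zlib stream,
## the compiled .crc32_raw provides chunk checksums. The writer emits
## filter-0 scanlines; the reader understands all five PNG filters so files
## from other writers also load.

u32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
}

be32 <- function(r) sum(as.numeric(r) * c(16777216, 65536, 256, 1))

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(.crc32_raw(body)))
}

#' Write an 8-bit RGB array as a PNG file
#'
#' @param rgb numeric array `[row, col, 3]` with values in `[0, 255]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_png_rgb <- function(rgb, path) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L) stop("rgb must be [row, col, 3]")
  if (min(rgb) < 0 || max(rgb) > 255) stop("channel values must be in [0, 255]")
  h <- d[1]; w <- d[2]
  px <- as.integer(round(aperm(rgb, c(3, 2, 1))))      # channel, col, row
  scan <- matrix(as.raw(px), nrow = 3L * w, ncol = h)
  raw_img <- as.vector(rbind(as.raw(0L), scan))        # filter byte 0 per row
  ihdr <- c(u32be(w), u32be(h), as.raw(c(8, 2, 0, 0, 0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", memCompress(raw_img, type = "gzip")), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

paeth <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

#' Read an 8-bit RGB PNG file
#'
#' @param path PNG path (8-bit truecolor, non-interlaced).
#' @return integer array `[row, col, 3]` with values in `[0, 255]`.
#' @export
read_png_rgb <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (!identical(raw_all[1:8], as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))))
    stop("not a PNG file: ", path)
  pos <- 9L
  w <- h <- NA_integer_
  idat <- raw(0)
  while (pos + 7 <= length(raw_all)) {
    len <- be32(raw_all[pos:(pos + 3)])
    type <- rawToChar(raw_all[(pos + 4):(pos + 7)])
    data <- if (len > 0) raw_all[(pos + 8):(pos + 7 + len)] else raw(0)
    if (type == "IHDR") {
      w <- be32(data[1:4]); h <- be32(data[5:8])
      if (data[9] != 8 || data[10] != 2 || data[13] != 0)
        stop("only 8-bit non-interlaced RGB PNGs are supported")
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  raw_img <- memDecompress(idat, type = "gzip")
  stride <- 3L * w
  out <- matrix(0L, nrow = h, ncol = stride)
  prev <- integer(stride)
  for (r in seq_len(h)) {
    off <- (r - 1L) * (stride + 1L)
    filt <- as.integer(raw_img[off + 1L])
    line <- as.integer(raw_img[off + 1L + seq_len(stride)])
    left <- function(v) c(0L, 0L, 0L, v[seq_len(stride - 3L)])
    cur <- switch(as.character(filt),
      "0" = line,
      "1" = { x <- line
              for (i in 4:stride) x[i] <- (x[i] + x[i - 3L]) %% 256L
              x },
      "2" = (line + prev) %% 256L,
      "3" = { x <- line
              for (i in seq_len(stride)) {
                a <- if (i > 3L) x[i - 3L] else 0L
                x[i] <- (x[i] + (a + prev[i]) %/% 2L) %% 256L
              }
              x },
      "4" = { x <- line
              for (i in seq_len(stride)) {
                a <- if (i > 3L) x[i - 3L] else 0L
                cc <- if (i > 3L) prev[i - 3L] else 0L
                x[i] <- (x[i] + paeth(a, prev[i], cc)) %% 256L
              }
              x },
      stop("unsupported PNG filter type: ", filt))
    out[r, ] <- cur
    prev <- cur
  }
  aperm(array(t(out), dim = c(3L, w, h)), c(3, 2, 1))
}

#' Export an RGB composite as PNG
#'
#' Lossless 8-bit export; reloading reproduces channel values exactly.
#'
#' @param composite an [rgb_composite].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_composite_png <- function(composite, path) {
  stopifnot(inherits(composite, "rgb_composite"))
  write_png_rgb(composite$channels, path)
}
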