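# Minimal 16-bit greyscale PNG encoder. The png and EBImage writers only
# emit 8-bit samples, which quantizes saliency maps too coarsely; PNG
# itself is simple enough to assemble directly: signature + IHDR + IDAT
# (zlib-wrapped deflate of filter-0 scanlines) + IEND. The deflate stream
# comes from memCompress(type = "gzip") with the gzip framing swapped for
# a zlib header and an Adler-32 trailer.

xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

.crc32_table <- local({
  tab <- numeric(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (c %% 2 == 1) xor32(c %/% 2, 3988292384) else c %/% 2  # 0xEDB88320
    }
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- 4294967295
  tab <- .crc32_table
  for (b in as.integer(bytes)) {
    crc <- xor32(crc %/% 256, tab[bitwXor(as.integer(crc %% 256), b) + 1])
  }
  4294967295 - crc  # final xor with 0xFFFFFFFF
}

be32 <- function(x) as.raw(c(x %/% 16777216, (x %/% 65536) %% 256,
                             (x %/% 256) %% 256, x %% 256))

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(be32(length(data)), body, be32(crc32(body)))
}

write_png16_grey <- function(v, path) {
  stopifnot(is.matrix(v), all(v >= 0), all(v <= 65535))
  h <- nrow(v); w <- ncol(v)
  v <- round(v)
  # scanlines: one filter byte (0) then big-endian 16-bit samples, row-major
  sl <- raw(h * (2 * w + 1))  # zero filter byte heads each scanline
  row_off <- (seq_len(h) - 1) * (2 * w + 1)
  hi <- as.raw(t(v) %/% 256)  # column-major over t(v) = row-major over v
  lo <- as.raw(t(v) %% 256)
  pos_hi <- rep(row_off, each = w) + 2 * rep(seq_len(w), h)
  sl[pos_hi] <- hi
  sl[pos_hi + 1] <- lo
  # memCompress's "gzip" type emits an RFC 1950 zlib stream (78 9c ...)
  # complete with Adler-32 trailer, which is exactly PNG's IDAT payload
  idat <- memCompress(sl, type = "gzip")
  ihdr <- c(be32(w), be32(h), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(
    as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", idat),
    png_chunk("IEND", raw(0))
  )
  writeBin(out, path)
  invisible(path)
}
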