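# Minimal uncompressed AVI (RIFF) container support. Frames are stored as
# BI_RGB 24-bit bottom-up DIBs ('00db' chunks), the only dialect that is
# bit-stable across platforms; compressed AVIs from other tools are rejected
# with a format error. Intensities quantize to 8-bit on write.

u32le <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                              endian = "little")
u16le <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                              endian = "little")
fourcc <- function(s) charToRaw(s)

riff_chunk <- function(id, payload) {
  sz <- length(payload)
  pad <- if (sz %% 2L == 1L) as.raw(0L) else raw(0)
  c(fourcc(id), u32le(sz), payload, pad)
}

riff_list <- function(type, payload) {
  riff_chunk("LIST", c(fourcc(type), payload))
}

# one grayscale [0,1] matrix -> bottom-up padded BGR pixel bytes
frame_to_dib <- function(img) {
  h <- nrow(img); w <- ncol(img)
  g <- matrix(as.integer(round(pmin(pmax(img, 0), 1) * 255)), h, w)
  row_bytes <- w * 3L
  pad_n <- (4L - row_bytes %% 4L) %% 4L
  rows <- vector("list", h)
  for (r in seq_len(h)) {
    px <- g[h - r + 1L, ]                     # bottom-up row order
    bgr <- as.raw(rep(px, each = 3L))         # gray -> B=G=R
    rows[[r]] <- c(bgr, raw(pad_n))
  }
  do.call(c, rows)
}

write_avi <- function(frames, fps, path) {
  stopifnot(length(frames) > 0)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  dibs <- lapply(frames, frame_to_dib)
  frame_bytes <- length(dibs[[1]])
  scale <- 1000L
  rate <- as.integer(round(fps * 1000))
  avih <- c(u32le(round(1e6 / fps)), u32le(frame_bytes * ceiling(fps)),
            u32le(0), u32le(0x10),           # AVIF_HASINDEX
            u32le(length(frames)), u32le(0), u32le(1), u32le(frame_bytes),
            u32le(w), u32le(h), u32le(0), u32le(0), u32le(0), u32le(0))
  strh <- c(fourcc("vids"), fourcc("DIB "), u32le(0), u16le(0), u16le(0),
            u32le(0), u32le(scale), u32le(rate), u32le(0),
            u32le(length(frames)), u32le(frame_bytes), u32le(-1), u32le(0),
            u16le(0), u16le(0), u16le(w), u16le(h))
  strf <- c(u32le(40), u32le(w), u32le(h), u16le(1), u16le(24), u32le(0),
            u32le(frame_bytes), u32le(0), u32le(0), u32le(0), u32le(0))
  hdrl <- riff_list("hdrl", c(
    riff_chunk("avih", avih),
    riff_list("strl", c(riff_chunk("strh", strh), riff_chunk("strf", strf)))))
  movi_payload <- do.call(c, lapply(dibs, function(d) riff_chunk("00db", d)))
  movi <- riff_list("movi", movi_payload)
  # idx1 offsets are relative to the position of the 'movi' fourcc
  chunk_sz <- 8L + frame_bytes + (frame_bytes %% 2L)
  offsets <- 4L + (seq_along(frames) - 1L) * chunk_sz
  idx <- do.call(c, lapply(offsets, function(o) {
    c(fourcc("00db"), u32le(0x10), u32le(o), u32le(frame_bytes))
  }))
  body <- c(fourcc("AVI "), hdrl, movi, riff_chunk("idx1", idx))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(fourcc("RIFF"), u32le(length(body)), body), con)
  invisible(path)
}

read_u32 <- function(bytes, off) {
  readBin(bytes[(off + 1):(off + 4)], "integer", size = 4L,
          endian = "little")
}

read_avi <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 12 || rawToChar(bytes[1:4]) != "RIFF" ||
      rawToChar(bytes[9:12]) != "AVI ") {
    stop("not an AVI (RIFF) file: ", path)
  }
  w <- h <- NULL; usec <- 50000; compression <- 0L; bitcount <- 24L
  rate <- scale <- NULL
  frames <- list()
  walk <- function(off, end) {
    while (off + 8 <= end) {
      id <- rawToChar(bytes[(off + 1):(off + 4)])
      sz <- read_u32(bytes, off + 4L)
      data0 <- off + 8L
      if (id == "LIST") {
        walk(data0 + 4L, data0 + sz)
      } else if (id == "avih") {
        usec <<- read_u32(bytes, data0)
        w <<- read_u32(bytes, data0 + 32L)
        h <<- read_u32(bytes, data0 + 36L)
      } else if (id == "strh" &&
                 rawToChar(bytes[(data0 + 1):(data0 + 4)]) == "vids") {
        scale <<- read_u32(bytes, data0 + 20L)
        rate <<- read_u32(bytes, data0 + 24L)
      } else if (id == "strf") {
        compression <<- read_u32(bytes, data0 + 16L)
        bitcount <<- readBin(bytes[(data0 + 15):(data0 + 16)], "integer",
                             size = 2L, endian = "little")
      } else if (id %in% c("00db", "00dc")) {
        frames[[length(frames) + 1L]] <<- bytes[(data0 + 1):(data0 + sz)]
      }
      off <- data0 + sz + (sz %% 2L)
    }
  }
  walk(12L, length(bytes))
  if (is.null(w) || is.null(h)) stop("malformed AVI: no 'avih' header")
  if (compression != 0L || bitcount != 24L) {
    stop("unsupported AVI codec: only uncompressed 24-bit BI_RGB is readable")
  }
  if (length(frames) == 0) stop("empty video: ", path)
  row_bytes <- w * 3L
  stride <- row_bytes + (4L - row_bytes %% 4L) %% 4L
  mats <- lapply(frames, function(d) {
    px <- as.integer(d)
    m <- matrix(0, nrow = h, ncol = w)
    for (r in seq_len(h)) {
      row <- px[((r - 1L) * stride + 1L):((r - 1L) * stride + row_bytes)]
      # take the B channel of B=G=R gray triples
      m[h - r + 1L, ] <- row[seq(1L, row_bytes, by = 3L)] / 255
    }
    m
  })
  fps <- if (!is.null(rate) && !is.null(scale) && scale > 0) {
    rate / scale
  } else {
    1e6 / usec
  }
  list(frames = mats, fps = fps)
}
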