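# Image readers/writers for PNG, TIFF and PGM/PPM. Pixels are
# normalized to [0, 1] by bit depth on load; no other rescaling or
# clipping happens silently.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = "png",
         tif = , tiff = "tiff",
         pgm = , ppm = , pnm = "pnm",
         stop_input("unsupported image format: '", ext, "' (", path, ")"))
}

read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header tokens (magic, dims, maxval), skipping comments
  read_token <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop_input("truncated PNM header: ", path)
      if (grepl("^[ \t\r\n]$", ch)) next
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || grepl("^[ \t\r\n]$", ch)) break
        tok <- paste0(tok, ch)
      }
      return(tok)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop_input("unsupported PNM magic '", magic, "': ", path)
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  channels <- if (magic %in% c("P3", "P6")) 3L else 1L
  npx <- w * h * channels
  vals <- if (magic %in% c("P2", "P3")) {
    scan(con, what = integer(), n = npx, quiet = TRUE)
  } else if (maxval < 256L) {
    as.integer(readBin(con, "raw", n = npx))
  } else {
    readBin(con, "integer", n = npx, size = 2L, signed = FALSE,
            endian = "big")
  }
  if (length(vals) < npx) stop_input("truncated PNM data: ", path)
  px <- vals / maxval
  if (channels == 1L) {
    matrix(px, nrow = h, ncol = w, byrow = TRUE)
  } else {
    arr <- array(0, c(h, w, 3L))
    for (ch in 1:3)
      arr[, , ch] <- matrix(px[seq(ch, npx, by = 3L)], h, w, byrow = TRUE)
    arr
  }
}

write_pnm <- function(img, path, bit_depth) {
  maxval <- 2L^bit_depth - 1L
  q <- round(img * maxval)
  con <- file(path, "wb")
  on.exit(close(con))
  channels <- if (length(dim(img)) == 3L) 3L else 1L
  magic <- if (channels == 3L) "P6" else "P5"
  dims <- if (channels == 3L) dim(img)[1:2] else dim(img)
  writeLines(c(magic, paste(dims[2], dims[1]), as.character(maxval)), con)
  vals <- if (channels == 3L) {
    as.integer(aperm(q, c(3L, 2L, 1L)))
  } else {
    as.integer(t(q))
  }
  if (bit_depth <= 8L) {
    writeBin(as.raw(vals), con)
  } else {
    writeBin(vals, con, size = 2L, endian = "big")
  }
}

#' Read a grayscale or color image
#'
#' Supports PNG, TIFF and PGM/PPM. Pixels are normalized to \[0, 1\] by
#' the file's bit depth; grayscale files stay single-channel (a matrix),
#' color files become `rows x cols x 3` arrays (any alpha channel is
#' dropped).
#'
#' @param path Image file path.
#' @return The pixel matrix/array with attributes `bit_depth` and
#'   `source_path`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_input("image file not found: ", path)
  fmt <- img_format(path)
  bit_depth <- 8L
  px <- switch(fmt,
    png = {
      x <- png::readPNG(path)
      # readPNG already scales to [0,1]; 16-bit files keep full precision
      x
    },
    tiff = tiff::readTIFF(path),
    pnm = {
      x <- read_pnm(path)
      x
    })
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 2L) px <- px[, , 1L]                # gray + alpha
    else if (dim(px)[3] >= 3L) px <- px[, , 1:3, drop = FALSE]
    if (length(dim(px)) == 3L && dim(px)[3] == 1L) px <- px[, , 1L]
  }
  attr(px, "bit_depth") <- bit_depth
  attr(px, "source_path") <- path
  px
}

#' Write an image to disk
#'
#' Values must already lie in \[0, 1\]; out-of-range input is an error
#' (clip before writing). The file is written atomically (temp file
#' plus rename). PNG output is 8-bit; TIFF and PGM/PPM support 8- or
#' 16-bit depths.
#'
#' @param img Matrix or `rows x cols x 3` array in \[0, 1\].
#' @param path Destination path; the extension selects the format.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bit_depth = 8L) {
  if (!bit_depth %in% c(8L, 16L)) stop_config("bit_depth must be 8 or 16")
  if (min(img) < 0 || max(img) > 1)
    stop_input("pixel values outside [0, 1]; clip before writing")
  fmt <- img_format(path)
  tmp <- tempfile(tmpext <- paste0(".", tools::file_ext(path)),
                  tmpdir = dirname(path))
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  switch(fmt,
    png = {
      if (bit_depth != 8L)
        stop_config("PNG output is 8-bit; use TIFF or PGM for 16-bit")
      png::writePNG(img, tmp)
    },
    tiff = tiff::writeTIFF(img, tmp, bits.per.sample = bit_depth),
    pnm = write_pnm(img, tmp, bit_depth))
  if (!file.rename(tmp, path)) stop_input("cannot write to ", path)
  ok <- TRUE
  invisible(path)
}
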