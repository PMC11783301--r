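# Image I/O and resizing. No image codec package exists in the supported
# dependency set, so two deliberately minimal formats are implemented by
# hand: binary PGM (P5) and uncompressed little-endian TIFF (8-bit
# grayscale for images/masks; 32-bit-float, 3 samples per pixel for FA
# maps). Both round-trip losslessly.
#
# Coordinates: matrices are (row, col) with the top-left origin; files
# store scanlines top to bottom.

format_of <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tif")
  if (ext %in% c("pgm")) return("pgm")
  stop(sprintf("unsupported image format '.%s' (use .pgm, .tif or .tiff)", ext),
       call. = FALSE)
}

#' Read a binary mask from disk
#'
#' Grayscale pixels above 127 become foreground.
#'
#' @param path A `.pgm` (binary P5) or uncompressed grayscale `.tif` file.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  m <- img > (127 / 255)
  storage.mode(m) <- "logical"
  m
}

#' Write a binary mask to disk as 0/255 grayscale
#' @param mask Logical matrix.
#' @param path Destination `.pgm` or `.tif` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  write_image(mask + 0, path)
}

#' Read a grayscale image
#' @param path A `.pgm` or uncompressed grayscale `.tif` file.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  switch(format_of(path),
         pgm = read_pgm(path),
         tif = {
           x <- read_tiff(path)
           if (length(dim(x)) == 3L) {
             stop("multi-channel TIFF: convert to grayscale first", call. = FALSE)
           }
           x
         })
}

#' Write a grayscale image (values in `[0, 1]`, stored as 8-bit)
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Destination `.pgm` or `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (min(img) < 0 || max(img) > 1) {
    stop("image values must lie in [0, 1]", call. = FALSE)
  }
  bytes <- as.integer(round(img * 255))
  switch(format_of(path),
         pgm = write_pgm(bytes, dim(img), path),
         tif = write_tiff_uint8(bytes, dim(img), path))
  invisible(path)
}

#' Read a 3-channel FA map from an uncompressed float TIFF
#' @param path A `.tif` written by [write_fa_map()].
#' @return `H x W x 3` numeric array, channels `(ts1, ts2, ds)`.
#' @export
read_fa_map <- function(path) {
  x <- read_tiff(path)
  if (length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop("FA map TIFF must carry exactly 3 samples per pixel", call. = FALSE)
  }
  dimnames(x) <- list(NULL, NULL, FA_CHANNELS)
  x
}

#' Write a 3-channel FA map as an uncompressed 32-bit-float TIFF
#' @param fa `H x W x 3` array with values in `[0, 1]`.
#' @param path Destination `.tif` path.
#' @return `path`, invisibly.
#' @export
write_fa_map <- function(fa, path) {
  stopifnot(length(dim(fa)) == 3L, dim(fa)[3] == 3L)
  if (min(fa) < 0 || max(fa) > 1) {
    stop("FA map values must lie in [0, 1]", call. = FALSE)
  }
  write_tiff_float(fa, path)
  invisible(path)
}

## ---- PGM -------------------------------------------------------------

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (magic != "P5") stop("not a binary PGM (P5) file", call. = FALSE)
  vals <- integer(3)
  got <- 0L
  while (got < 3L) {
    tok <- ""
    repeat {
      ch <- readChar(con, 1)
      if (ch == "#") {  # comment line
        repeat { ch <- readChar(con, 1); if (ch == "\n") break }
        next
      }
      if (grepl("[0-9]", ch)) { tok <- paste0(tok, ch) }
      else if (nzchar(tok)) break
    }
    got <- got + 1L
    vals[got] <- as.integer(tok)
  }
  w <- vals[1]; h <- vals[2]; maxv <- vals[3]
  raw <- readBin(con, "integer", n = w * h, size = 1, signed = FALSE)
  matrix(raw, nrow = h, ncol = w, byrow = TRUE) / maxv
}

write_pgm <- function(bytes, hw, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", hw[2], hw[1]), con, eos = NULL)
  # scanline order: row-major
  writeBin(as.raw(t(matrix(bytes, hw[1], hw[2]))), con)
}

## ---- minimal uncompressed little-endian TIFF -------------------------

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, planar = 284L,
               sample_format = 339L)

write_tiff <- function(data_raw, hw, spp, bits, sample_format, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L)
  data_offset <- 8L
  ifd_offset <- data_offset + length(data_raw)
  if (ifd_offset %% 2L) { data_pad <- TRUE; ifd_offset <- ifd_offset + 1L }
  else data_pad <- FALSE
  w4(ifd_offset)
  writeBin(data_raw, con)
  if (data_pad) writeBin(as.raw(0), con)
  entries <- list(
    list(TIFF_TAGS[["width"]], 3L, 1L, hw[2]),
    list(TIFF_TAGS[["length"]], 3L, 1L, hw[1]),
    list(TIFF_TAGS[["bits"]], 3L, spp, NA),   # value or offset, fixed below
    list(TIFF_TAGS[["compression"]], 3L, 1L, 1L),
    list(TIFF_TAGS[["photometric"]], 3L, 1L, 1L),
    list(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_offset),
    list(TIFF_TAGS[["spp"]], 3L, 1L, spp),
    list(TIFF_TAGS[["rows_per_strip"]], 3L, 1L, hw[1]),
    list(TIFF_TAGS[["strip_bytes"]], 4L, 1L, length(data_raw)),
    list(TIFF_TAGS[["planar"]], 3L, 1L, 1L),
    list(TIFF_TAGS[["sample_format"]], 3L, spp, NA)
  )
  n <- length(entries)
  extra_offset <- ifd_offset + 2L + n * 12L + 4L
  extra <- list()
  w2(n)
  for (e in entries) {
    tag <- e[[1]]; typ <- e[[2]]; cnt <- e[[3]]
    w2(tag); w2(typ); w4(cnt)
    if (tag == TIFF_TAGS[["bits"]] && spp > 1L) {
      w4(extra_offset)
      extra[[length(extra) + 1L]] <- rep(bits, spp)
      extra_offset <- extra_offset + 2L * spp
    } else if (tag == TIFF_TAGS[["sample_format"]] && spp > 1L) {
      w4(extra_offset)
      extra[[length(extra) + 1L]] <- rep(sample_format, spp)
      extra_offset <- extra_offset + 2L * spp
    } else {
      val <- if (tag == TIFF_TAGS[["bits"]]) bits
             else if (tag == TIFF_TAGS[["sample_format"]]) sample_format
             else e[[4]]
      if (typ == 3L) { w2(val); w2(0L) } else w4(val)
    }
  }
  w4(0L)  # no next IFD
  for (x in extra) w2(x)
  invisible(path)
}

write_tiff_uint8 <- function(bytes, hw, path) {
  data_raw <- as.raw(t(matrix(bytes, hw[1], hw[2])))
  write_tiff(data_raw, hw, spp = 1L, bits = 8L, sample_format = 1L, path)
}

write_tiff_float <- function(arr, path) {
  hw <- dim(arr)[1:2]
  # chunky layout: per scanline, samples interleaved
  interleaved <- aperm(arr, c(3L, 2L, 1L))  # channel, col, row
  data_raw <- writeBin(as.numeric(interleaved), raw(), size = 4,
                       endian = "little")
  write_tiff(data_raw, hw, spp = 3L, bits = 32L, sample_format = 3L, path)
}

read_tiff <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  all_bytes <- readBin(con, "raw", n = sz)
  r2 <- function(off) {  # 1-based offset
    sum(as.integer(all_bytes[off + 0:1]) * c(1, 256))
  }
  r4 <- function(off) {
    sum(as.numeric(all_bytes[off + 0:3]) * c(1, 256, 65536, 16777216))
  }
  if (rawToChar(all_bytes[1:2]) != "II" || r2(3) != 42) {
    stop("not a little-endian TIFF", call. = FALSE)
  }
  ifd <- r4(5) + 1
  n <- r2(ifd)
  tags <- list()
  for (i in seq_len(n)) {
    base <- ifd + 2 + (i - 1) * 12
    tag <- r2(base); typ <- r2(base + 2); cnt <- r4(base + 4)
    val <- if (typ == 3 && cnt == 1) r2(base + 8) else r4(base + 8)
    tags[[as.character(tag)]] <- list(type = typ, count = cnt, value = val)
  }
  need <- function(tag, default = NULL) {
    t <- tags[[as.character(tag)]]
    if (is.null(t)) {
      if (is.null(default)) stop("missing TIFF tag ", tag, call. = FALSE)
      return(default)
    }
    t$value
  }
  W <- need(256L); H <- need(257L)
  spp <- need(277L, 1)
  comp <- need(259L, 1)
  if (comp != 1) stop("only uncompressed TIFF is supported", call. = FALSE)
  bits_tag <- tags[["258"]]
  bits <- if (is.null(bits_tag)) 8
          else if (bits_tag$count == 1) bits_tag$value
          else r2(bits_tag$value + 1)
  sf_tag <- tags[["339"]]
  sfmt <- if (is.null(sf_tag)) 1
          else if (sf_tag$count == 1) sf_tag$value
          else r2(sf_tag$value + 1)
  so_tag <- tags[["273"]]
  if (so_tag$count != 1) stop("multi-strip TIFF is not supported", call. = FALSE)
  offset <- so_tag$value + 1
  npix <- W * H * spp
  if (bits == 8 && sfmt == 1) {
    vals <- as.integer(all_bytes[offset + seq_len(npix) - 1])
    out <- matrix(vals, nrow = H, ncol = W, byrow = TRUE) / 255
    return(out)
  }
  if (bits == 32 && sfmt == 3) {
    vals <- readBin(all_bytes[offset + seq_len(npix * 4) - 1], "numeric",
                    n = npix, size = 4, endian = "little")
    if (spp == 1) return(matrix(vals, nrow = H, ncol = W, byrow = TRUE))
    arr <- array(vals, dim = c(spp, W, H))
    return(aperm(arr, c(3L, 2L, 1L)))
  }
  stop("unsupported TIFF sample layout", call. = FALSE)
}

## ---- resizing --------------------------------------------------------

#' Resize an image, mask or FA map
#'
#' Bilinear interpolation for grayscale images; nearest-neighbour for
#' masks (so they stay binary) and for FA maps (so attention values stay
#' quantized). Resizing to the current size is the identity. Evaluation
#' metrics should always be computed at the original resolution; resizing
#' exists to feed the network.
#'
#' @param x Numeric matrix, logical matrix, or `H x W x C` array.
#' @param size Target side length (output is `size x size`).
#' @return The resized object, same type as the input.
#' @export
resize_to <- function(x, size) {
  stopifnot(size >= 1)
  if (is.matrix(x) && all(dim(x) == c(size, size))) return(x)
  if (is.logical(x)) {
    idx <- nearest_idx(dim(x), size)
    out <- x[idx$r, , drop = FALSE][, idx$c, drop = FALSE]
    return(out)
  }
  if (length(dim(x)) == 3L) {
    if (all(dim(x)[1:2] == c(size, size))) return(x)
    idx <- nearest_idx(dim(x)[1:2], size)
    return(x[idx$r, idx$c, , drop = FALSE])
  }
  bilinear_resize(x, size)
}

nearest_idx <- function(hw, size) {
  r <- pmin(pmax(round((seq_len(size) - 0.5) * hw[1] / size + 0.5), 1), hw[1])
  c <- pmin(pmax(round((seq_len(size) - 0.5) * hw[2] / size + 0.5), 1), hw[2])
  list(r = r, c = c)
}

bilinear_resize <- function(m, size) {
  interp_axis <- function(n_in, n_out) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    i0 <- pmin(pmax(floor(s), 1), n_in)
    i1 <- pmin(i0 + 1, n_in)
    w <- pmin(pmax(s - i0, 0), 1)
    list(i0 = i0, i1 = i1, w = w)
  }
  a <- interp_axis(nrow(m), size)
  b <- interp_axis(ncol(m), size)
  rows <- m[a$i0, , drop = FALSE] * (1 - a$w) + m[a$i1, , drop = FALSE] * a$w
  rows[, b$i0, drop = FALSE] * rep(1 - b$w, each = size) +
    rows[, b$i1, drop = FALSE] * rep(b$w, each = size)
}
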