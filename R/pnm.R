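#' Read a NetPBM image (PGM or PPM)
#'
#' Supports ASCII (P2/P3) and binary (P5/P6) graymaps and pixmaps with
#' maxval up to 65535. Grayscale images are returned as an integer matrix
#' (rows = image rows, origin top-left); RGB images as an integer
#' `nrow x ncol x 3` array. The maxval is attached as attribute `"maxval"`.
#'
#' NetPBM is used as the interchange image format because it is plain,
#' lossless and dependency-free; bright-field microscopy exports convert
#' to it losslessly.
#'
#' @param path file path
#' @return integer matrix or 3-d array with attribute `maxval`
#' @export
read_pnm <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop("unsupported image format (expected PGM/PPM magic P2/P3/P5/P6): ", path)
  }
  ascii <- magic %in% c("P2", "P3")
  rgb <- magic %in% c("P3", "P6")

  # header tokens: width height maxval, '#' comments allowed
  toks <- integer(0)
  buf <- character(0)
  while (length(toks) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PNM header: ", path)
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r", "")) break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf)) {
      toks <- c(toks, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- toks[1]; h <- toks[2]; maxval <- toks[3]
  npx <- w * h * if (rgb) 3L else 1L

  if (ascii) {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])
    vals <- vals[seq_len(npx)]
  } else if (maxval < 256L) {
    vals <- as.integer(readBin(con, "raw", npx))
  } else {
    vals <- readBin(con, "integer", npx, size = 2L, signed = FALSE,
                    endian = "big")
  }
  if (anyNA(vals) || length(vals) < npx) stop("truncated PNM pixel data: ", path)

  out <- if (rgb) {
    a <- array(0L, c(h, w, 3L))
    for (k in 1:3) a[, , k] <- matrix(vals[seq(k, npx, by = 3L)], h, w, byrow = TRUE)
    a
  } else {
    matrix(vals, h, w, byrow = TRUE)
  }
  attr(out, "maxval") <- maxval
  out
}

#' Write an 8-bit grayscale PGM image
#'
#' @param gray integer matrix with values in `[0, maxval]`
#' @param path output path
#' @param ascii write ASCII P2 (default) or binary P5
#' @param maxval maximum gray value (default 255)
#' @return `path`, invisibly
#' @export
write_pgm <- function(gray, path, ascii = TRUE, maxval = 255L) {
  stopifnot(is.matrix(gray))
  g <- matrix(as.integer(round(gray)), nrow(gray), ncol(gray))
  if (anyNA(g) || any(g < 0L) || any(g > maxval)) {
    stop("gray values must be integers in [0, ", maxval, "]")
  }
  v <- as.integer(t(g)) # row-major pixel order
  if (ascii) {
    con <- file(path, "wb") # binary mode: deterministic \n on all platforms
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(g), nrow(g)), as.character(maxval)),
               con, sep = "\n")
    writeLines(apply(g, 1L, paste, collapse = " "), con, sep = "\n")
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(g), nrow(g), maxval),
              con, eos = NULL)
    if (maxval < 256L) writeBin(as.raw(v), con)
    else writeBin(v, con, size = 2L, endian = "big")
  }
  invisible(path)
}
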