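#' @include segmentation.R
NULL

#' Read a grayscale frame image
#'
#' Reads PNG, TIFF or JPG via EBImage and uncompressed 8-bit BMP via the
#' package's own reader.  Color inputs are converted to luminance.
#'
#' @param path image file path.
#' @return integer matrix `[y, x]` with gray values 0-255.
#' @export
readFrame <- function(path) {
  if (grepl("\\.bmp$", path, ignore.case = TRUE)) return(readBmp8(path))
  e <- EBImage::readImage(path)
  a <- EBImage::imageData(e)
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)   # luminance
  clip255(t(a) * 255)
}

#' Write a grayscale frame image
#'
#' Format follows the file extension: `.png`, `.tif`/`.tiff`, `.jpg`/
#' `.jpeg` via EBImage, `.bmp` via the package's own 8-bit writer.
#'
#' @param img integer matrix `[y, x]`, 0-255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFrame <- function(img, path) {
  if (grepl("\\.bmp$", path, ignore.case = TRUE)) {
    writeBmp8(img, path)
  } else {
    EBImage::writeImage(toEBI(clip255(img)), path)
  }
  invisible(path)
}

# ---- minimal uncompressed 8-bit grayscale BMP -------------------------------
# BITMAPFILEHEADER + BITMAPINFOHEADER + 256-entry gray palette, rows stored
# bottom-up and padded to 4-byte multiples.

writeBmp8 <- function(img, path) {
  img <- clip255(img)
  H <- nrow(img); W <- ncol(img)
  rowBytes <- (W + 3L) %/% 4L * 4L
  dataSize <- rowBytes * H
  offset <- 14L + 40L + 256L * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(offset + dataSize), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(offset), con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")
  writeBin(as.integer(W), con, size = 4, endian = "little")
  writeBin(as.integer(H), con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")      # planes
  writeBin(8L, con, size = 2, endian = "little")      # bpp
  writeBin(0L, con, size = 4, endian = "little")      # BI_RGB
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  writeBin(c(2835L, 2835L), con, size = 4, endian = "little")  # 72 dpi
  writeBin(c(256L, 0L), con, size = 4, endian = "little")
  pal <- as.raw(rbind(0:255, 0:255, 0:255, 0L))   # B,G,R,reserved per entry
  writeBin(as.vector(pal), con)
  pad <- as.raw(rep(0, rowBytes - W))
  for (y in H:1) {
    writeBin(c(as.raw(img[y, ]), pad), con)
  }
  invisible(path)
}

readBmp8 <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1])
  u32 <- function(i) sum(as.numeric(raw[i + 0:3]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "BM") stop("not a BMP file: ", path)
  offset <- u32(11L)
  W <- u32(19L); H <- u32(23L)
  bpp <- u16(29L); comp <- u32(31L)
  if (bpp != 8 || comp != 0)
    stop("only uncompressed 8-bit BMP is supported")
  if (H > 2^31) stop("top-down BMP not supported")
  rowBytes <- (W + 3L) %/% 4L * 4L
  img <- matrix(0L, H, W)
  for (y in seq_len(H)) {
    start <- offset + (y - 1L) * rowBytes
    img[H - y + 1L, ] <- as.integer(raw[(start + 1L):(start + W)])
  }
  img
}
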