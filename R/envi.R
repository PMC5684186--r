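#' Read a hyperspectral cube from an ENVI header/binary file pair
#'
#' Supports the dialect written by line-scan NIR imagers and by
#' [write_envi_cube()]: a text header (`<path>.hdr` or the path itself if
#' it ends in `.hdr`) describing an uncompressed binary payload in BSQ or
#' BIL interleave, 16-bit unsigned (`data type = 12`) or 32-bit float
#' (`data type = 4`). A `wavelength` block is mandatory.
#'
#' @param path path to the header file, or to the binary file whose header
#'   sits alongside with an `.hdr` extension.
#' @param kind cube kind to stamp on the result (`"raw"` default).
#' @return A [hypercube()].
#' @export
read_envi_cube <- function(path, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (grepl("\\.hdr$", path)) {
    hdr_path <- path
    bin_path <- sub("\\.hdr$", ".dat", path)
  } else {
    hdr_path <- paste0(path, ".hdr")
    bin_path <- path
  }
  if (!file.exists(hdr_path))
    stop("ENVI header not found: ", hdr_path, call. = FALSE)
  if (!file.exists(bin_path))
    stop("ENVI binary payload not found: ", bin_path, call. = FALSE)
  hdr <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ENVI header missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(hdr[["wavelength"]]))
    stop("ENVI header lacks the mandatory wavelength block", call. = FALSE)
  samples <- as.integer(hdr[["samples"]])   # cols
  lines   <- as.integer(hdr[["lines"]])    # rows
  bands   <- as.integer(hdr[["bands"]])
  dtype   <- as.integer(hdr[["data type"]])
  interleave <- tolower(hdr[["interleave"]])
  byte_order <- if (is.null(hdr[["byte order"]])) 0L else
    as.integer(hdr[["byte order"]])
  wl <- as.numeric(strsplit(hdr[["wavelength"]], ",")[[1]])
  if (length(wl) != bands)
    stop("header declares ", bands, " bands but lists ", length(wl),
         " wavelengths", call. = FALSE)
  if (!interleave %in% c("bsq", "bil"))
    stop("unsupported interleave '", interleave, "' (bsq/bil only)",
         call. = FALSE)
  spec <- switch(as.character(dtype),
    "4"  = list(what = "numeric", size = 4L, signed = TRUE),
    "12" = list(what = "integer", size = 2L, signed = FALSE),
    stop("unsupported data type ", dtype, " (4 = float32, 12 = uint16)",
         call. = FALSE))
  n <- as.numeric(samples) * lines * bands
  expected_bytes <- n * spec$size
  actual_bytes <- file.size(bin_path)
  if (actual_bytes != expected_bytes)
    stop("payload size mismatch: header implies ", expected_bytes,
         " bytes, file has ", actual_bytes, call. = FALSE)
  endian <- if (byte_order == 0L) "little" else "big"
  con <- file(bin_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, what = spec$what, n = n, size = spec$size,
                      signed = spec$signed, endian = endian)
  raw_vals <- as.numeric(raw_vals)
  data <- array(NA_real_, c(lines, samples, bands))
  if (interleave == "bsq") {
    # band-major; within a band, samples (cols) vary fastest, then lines
    arr <- array(raw_vals, c(samples, lines, bands))
    data <- aperm(arr, c(2, 1, 3))
  } else { # bil: line-major; within a line, samples fastest, then bands
    arr <- array(raw_vals, c(samples, bands, lines))
    data <- aperm(arr, c(3, 1, 2))
  }
  pix <- if (!is.null(hdr[["pixel size um"]])) as.numeric(hdr[["pixel size um"]])
         else 156
  hypercube(data, wl, pixel_size_um = pix, kind = kind)
}

#' Write a hyperspectral cube as an ENVI header/binary pair
#'
#' @param cube a [hypercube()].
#' @param path output path; `.hdr` and `.dat` files are written with this
#'   stem (a trailing `.hdr` or `.dat` extension is stripped first).
#' @param interleave `"bsq"` (default) or `"bil"`.
#' @param data_type 4 for 32-bit float (default), 12 for 16-bit unsigned
#'   (values must be integers in 0..65535).
#' @return The header path, invisibly.
#' @export
write_envi_cube <- function(cube, path, interleave = c("bsq", "bil"),
                            data_type = 4L) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  data_type <- as.integer(data_type)
  if (!data_type %in% c(4L, 12L))
    stop("data_type must be 4 (float32) or 12 (uint16)", call. = FALSE)
  d <- dim(cube$data)
  if (d[3] < 1L) stop("cube has no bands", call. = FALSE)
  stem <- sub("\\.(hdr|dat)$", "", path)
  hdr_path <- paste0(stem, ".hdr")
  bin_path <- paste0(stem, ".dat")
  vals <- cube$data
  if (data_type == 12L) {
    if (any(is.na(vals)) || any(vals < 0 | vals > 65535) ||
        any(vals != round(vals)))
      stop("uint16 output requires integer values in 0..65535 and no NA",
           call. = FALSE)
  }
  flat <- if (interleave == "bsq") aperm(vals, c(2, 1, 3))
          else aperm(vals, c(2, 3, 1))
  con <- file(bin_path, "wb")
  on.exit(close(con))
  if (data_type == 4L) {
    writeBin(as.numeric(flat), con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(flat), con, size = 2L, endian = "little")
  }
  hdr <- c(
    "ENVI",
    "description = { nitramap hyperspectral cube }",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("pixel size um = ", format(cube$pixel_size_um, digits = 15)),
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, digits = 15, trim = TRUE,
                        scientific = FALSE), collapse = ", "),
           " }")
  )
  writeLines(hdr, hdr_path)
  invisible(hdr_path)
}

# Parse an ENVI text header into a named list; braced blocks are joined
# across lines with their braces stripped.
parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^ENVI", lines[1]))
    stop("not an ENVI header (missing ENVI magic line): ", path,
         call. = FALSE)
  lines <- lines[-1]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!grepl("=", ln)) { i <- i + 1L; next }
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (startsWith(val, "{")) {
      while (!grepl("\\}", val) && i < length(lines)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[i]))
      }
      if (!grepl("\\}", val))
        stop("unterminated '{' block for header field '", key, "'",
             call. = FALSE)
      val <- trimws(gsub("[{}]", "", val))
    }
    out[[key]] <- val
    i <- i + 1L
  }
  out
}

#' Export a leaf mask as a PNG and a run-length CSV
#'
#' The PNG is black/white (background 0, leaf 255); the CSV lists runs of
#' leaf pixels as `row,col_start,col_end` (1-based, inclusive).
#'
#' @param mask a [leaf_mask()].
#' @param png_path,csv_path output paths; either may be `NULL` to skip.
#' @return Invisibly, a list with the paths written.
#' @export
write_mask <- function(mask, png_path = NULL, csv_path = NULL) {
  m <- unclass(mask)
  if (!is.null(png_path)) {
    png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), png_path)
  }
  if (!is.null(csv_path)) {
    runs <- do.call(rbind, lapply(seq_len(nrow(m)), function(r) {
      rl <- rle(m[r, ])
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      on <- rl$values
      if (!any(on)) return(NULL)
      data.frame(row = r, col_start = starts[on], col_end = ends[on])
    }))
    if (is.null(runs))
      runs <- data.frame(row = integer(), col_start = integer(),
                         col_end = integer())
    utils::write.csv(runs, csv_path, row.names = FALSE)
  }
  invisible(list(png = png_path, csv = csv_path))
}
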