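#' Load a fluorescence micrograph as a gray-level matrix
#'
#' Reads an 8-bit PNG or TIFF raster and returns intensities on the 0--255
#' scale as a numeric matrix indexed \code{[row, col]}. RGB images are
#' collapsed to one channel either by standard luminance weighting
#' (0.299R + 0.587G + 0.114B) or by selecting a single channel; fluorescence
#' micrographs are effectively monochrome, so for SYBR-green staining the
#' \code{"green"} mode reproduces the raw signal.
#'
#' @param path file path to a PNG or TIFF image.
#' @param grayMode one of \code{"luminance"}, \code{"red"}, \code{"green"},
#'   \code{"blue"}.
#' @return numeric matrix, intensities in \code{[0, 255]}.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(64), 8, 8), f)
#' img <- loadImage(f)
#' dim(img)
#' @export
loadImage <- function(path, grayMode = c("luminance", "red", "green", "blue")) {
  grayMode <- match.arg(grayMode)
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image file '", path,
                                           "': ", conditionMessage(e)))
  a <- EBImage::imageData(img)
  nd <- length(dim(a))
  if (nd == 2L) {
    g <- a
  } else if (nd == 3L && dim(a)[3] >= 3L) {
    w <- switch(grayMode,
                luminance = c(0.299, 0.587, 0.114),
                red = c(1, 0, 0), green = c(0, 1, 0), blue = c(0, 0, 1))
    g <- a[, , 1] * w[1] + a[, , 2] * w[2] + a[, , 3] * w[3]
  } else if (nd == 3L && dim(a)[3] %in% c(1L, 2L)) {
    g <- a[, , 1]  # gray (+alpha)
  } else {
    stop("unsupported image layout: ", paste(dim(a), collapse = "x"),
         " (expected 8-bit grayscale or RGB)")
  }
  # EBImage stores [x = col, y = row] in [0, 1]; convert to [row, col] 0-255
  t(g) * 255
}

.recordColumns <- c("id", "row_min", "col_min", "row_max", "col_max",
                    "centroid_row", "centroid_col", "cph", "head_radius",
                    "tail_length", "tail_distance", "dna", "tdna",
                    "extent_moment", "olive_moment", "inertia_moment",
                    "box_ratio", "area", "class_label", "flag")

#' Empty comet record table
#'
#' @return zero-row data.frame with the canonical record columns.
#' @export
emptyRecords <- function() {
  df <- data.frame(matrix(numeric(0), nrow = 0, ncol = 18))
  names(df) <- .recordColumns[1:18]
  df$class_label <- character(0)
  df$flag <- character(0)
  df[, .recordColumns]
}

#' Write comet records to CSV
#'
#' One row per comet, fixed column order, header row. Numeric fields are
#' serialized with 6 significant digits and round-trip losslessly at that
#' precision through [readRecords()].
#'
#' @param records data.frame of comet records.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeRecords <- function(records, path) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(.recordColumns, names(records))
  if (length(missing))
    stop("records lack required columns: ", paste(missing, collapse = ", "))
  out <- records[, .recordColumns, drop = FALSE]
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) out[[cn]] <- signif(out[[cn]], 6)
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) stop("cannot write records to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read comet records written by [writeRecords()]
#'
#' @param path CSV file path.
#' @return data.frame of comet records.
#' @export
readRecords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(class_label = "character",
                                       flag = "character"))
  if (nrow(df) == 0) return(emptyRecords())
  df$flag[is.na(df$flag)] <- ""
  df[, .recordColumns]
}

#' Crop one comet from an image
#'
#' Returns the bounding-box crop of the image with every pixel outside the
#' comet's own mask set to zero, so neighboring comets never leak into a
#' crop.
#'
#' @param img numeric matrix.
#' @param mask integer label matrix of the same shape.
#' @param id label of the comet to crop.
#' @return numeric matrix of the bounding-box size.
#' @export
cropComet <- function(img, mask, id) {
  stopifnot(all(dim(img) == dim(mask)))
  sel <- mask == id
  if (!any(sel)) stop("label ", id, " not present in mask")
  ij <- which(sel, arr.ind = TRUE)
  r <- range(ij[, 1]); cc <- range(ij[, 2])
  crop <- img[r[1]:r[2], cc[1]:cc[2], drop = FALSE]
  crop[!sel[r[1]:r[2], cc[1]:cc[2], drop = FALSE]] <- 0
  crop
}

#' Write a label mask as a 16-bit TIFF
#'
#' Label values are stored verbatim in a 16-bit single-channel TIFF, so up
#' to 65535 comets per image round-trip exactly.
#'
#' @param mask integer label matrix.
#' @param path output TIFF path.
#' @return invisibly, the path.
#' @export
writeMask <- function(mask, path) {
  if (max(mask) > 65535) stop("more than 65535 labels cannot be stored")
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write label masks")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label mask written by [writeMask()]
#'
#' @param path TIFF path.
#' @return integer label matrix.
#' @export
readMask <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read label masks")
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
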