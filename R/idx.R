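# Reader/writer for the big-endian IDX image/label container (the standard
# distribution format for handwritten-digit data), so real digit files can
# replace the synthetic generator when available. Magic numbers: 2051 for
# image files (3 dimensions), 2049 for label files (1 dimension).

#' Read an IDX image file
#'
#' @param path IDX file with magic number 2051 (unsigned-byte images).
#' @param scale divide pixel values by 255 to get features in \[0, 1\].
#' @return list with `images` (n x (rows*cols) matrix, row-major pixels) and
#'   `dim = c(n, rows, cols)`.
#' @export
read_idx_images <- function(path, scale = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (magic != 2051L) stop("not an IDX image file (magic ", magic, " != 2051)")
  dims <- readBin(con, "integer", 3L, size = 4L, endian = "big")
  n_pix <- prod(dims)
  raw_px <- readBin(con, "integer", n_pix, size = 1L, signed = FALSE)
  if (length(raw_px) != n_pix) stop("truncated IDX image file")
  images <- matrix(raw_px, nrow = dims[1L], byrow = TRUE)
  if (scale) images <- images / 255
  list(images = images, dim = dims)
}

#' Read an IDX label file
#'
#' @param path IDX file with magic number 2049 (unsigned-byte labels).
#' @return integer vector of labels.
#' @export
read_idx_labels <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (magic != 2049L) stop("not an IDX label file (magic ", magic, " != 2049)")
  n <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  labels <- readBin(con, "integer", n, size = 1L, signed = FALSE)
  if (length(labels) != n) stop("truncated IDX label file")
  labels
}

#' Write images to an IDX file
#'
#' Inverse of [read_idx_images()]; used for round-trip tests and for
#' exporting synthetic digits in the standard container.
#'
#' @param images n x (rows*cols) matrix of pixel values in \[0, 1\] or
#'   \[0, 255\].
#' @param path output path.
#' @param rows,cols image grid dimensions.
#' @return `path`, invisibly.
#' @export
write_idx_images <- function(images, path, rows, cols) {
  if (ncol(images) != rows * cols) stop("images must have rows*cols columns")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(2051L, nrow(images), as.integer(rows), as.integer(cols)),
           con, size = 4L, endian = "big")
  writeBin(as.integer(t(images_to_bytes(images))), con, size = 1L)
  invisible(path)
}

images_to_bytes <- function(images) {
  m <- if (max(images) <= 1) round(images * 255) else round(images)
  matrix(as.integer(m), nrow = nrow(images))
}

#' Write labels to an IDX file
#'
#' @param labels integer labels in \[0, 255\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_idx_labels <- function(labels, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(2049L, length(labels)), con, size = 4L, endian = "big")
  writeBin(as.integer(labels), con, size = 1L)
  invisible(path)
}

#' Load an IDX image/label pair as a dataset
#'
#' @param image_path,label_path IDX files.
#' @return a `synthetic_dataset`-compatible object (`features`, `labels`).
#' @export
read_idx_dataset <- function(image_path, label_path) {
  imgs <- read_idx_images(image_path)
  labels <- read_idx_labels(label_path)
  if (nrow(imgs$images) != length(labels)) {
    stop("image and label files disagree on the number of instances")
  }
  new_synthetic_dataset(imgs$images, labels,
                        list(generator = "idx", image_path = image_path,
                             label_path = label_path))
}
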