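#' Grayscale image container
#'
#' A grayscale image is stored as a plain numeric H x W matrix on the
#' canonical intensity scale \[0, 1\] at load time; values outside \[0, 1\]
#' are legal after contrast transformation (no clipping is performed in the
#' processing path). Images must be at least 8 x 8 and contain only finite
#' values.
#'
#' @param pixels numeric matrix of intensities (rows = height, cols = width).
#' @return a validated numeric matrix of class `gray_image`.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  validate_gray_image(pixels)
  structure(pixels, class = c("gray_image", class(pixels)))
}

validate_gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 8L || ncol(pixels) < 8L) {
    stop("image must be at least 8 x 8 pixels", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("image contains non-finite pixel values", call. = FALSE)
  }
  invisible(pixels)
}

#' Read an image file as a grayscale matrix
#'
#' Reads a PNG file and returns intensities on \[0, 1\]. Color inputs are
#' converted to grayscale by standard luminance weighting
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel, if present, is dropped.
#'
#' @param path path to a PNG file.
#' @return numeric H x W matrix on \[0, 1\].
#' @export
read_gray_png <- function(path) {
  arr <- png::readPNG(path)
  img <- if (length(dim(arr)) == 2L) {
    arr
  } else {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  }
  validate_gray_image(img)
  img
}

#' Write a grayscale matrix to a PNG file
#'
#' Values are clipped to \[0, 1\] for display only; the in-memory processing
#' path never clips.
#'
#' @param img numeric H x W matrix.
#' @param path output file path.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(clamp(img, 0, 1), path)
  invisible(path)
}

# Separable bilinear resize expressed as two 1-D linear interpolation
# operators: out = A %*% img %*% t(B). Keeping the operators explicit gives
# an exact adjoint (t(A) %*% g %*% B) so gradients flow through the resize.
resize_operator <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_in))
  # align-corners-free mapping of output pixel centers into input coordinates
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  src <- clamp(src, 1, n_in)
  lo <- pmin(floor(src), n_in - 1L)
  w <- src - lo
  A <- matrix(0, n_out, n_in)
  A[cbind(seq_len(n_out), lo)] <- A[cbind(seq_len(n_out), lo)] + (1 - w)
  A[cbind(seq_len(n_out), lo + 1L)] <- A[cbind(seq_len(n_out), lo + 1L)] + w
  A
}

#' Bilinear image resize
#'
#' @param img numeric H x W matrix.
#' @param size target `c(height, width)`.
#' @return resized matrix.
#' @export
resize_image <- function(img, size) {
  size <- as.integer(size)
  A <- resize_operator(nrow(img), size[1])
  B <- resize_operator(ncol(img), size[2])
  A %*% img %*% t(B)
}

# Adjoint of resize_image: maps a gradient w.r.t. the resized image back to
# a gradient w.r.t. the original image.
resize_adjoint <- function(grad, orig_dim, resized_dim) {
  A <- resize_operator(orig_dim[1], resized_dim[1])
  B <- resize_operator(orig_dim[2], resized_dim[2])
  t(A) %*% grad %*% B
}
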