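#' Mean intensity of an image
#'
#' The brightness center \eqn{\mu = \frac{1}{HW}\sum_{x,y} I(x,y)} about
#' which the linear contrast transform pivots.
#'
#' @param img numeric H x W matrix (see [gray_image()] for the contract).
#' @return the scalar mean intensity.
#' @export
#' @examples
#' image_mean(matrix(0.5, 8, 8))
image_mean <- function(img) {
  validate_gray_image(img)
  mean(img)
}

#' Linear, mean-preserving contrast transform
#'
#' Applies \eqn{I'(x,y) = \alpha (I(x,y) - \mu) + \mu} with \eqn{\mu} the
#' image mean. Gains above 1 stretch the intensity spread, gains below 1
#' compress it; the mean is preserved exactly and the standard deviation is
#' scaled by \eqn{\alpha}. No clipping is applied, so outputs may leave
#' \[0, 1\] — this keeps the transform affine and differentiable. The
#' operation is out-of-place.
#'
#' @param img numeric H x W matrix.
#' @param alpha positive contrast gain.
#' @return transformed matrix of the same dimensions.
#' @export
#' @examples
#' img <- matrix(c(0, 100, 100, 200), 2, 2)
#' # apply_contrast(img, 2) doubles deviations from the mean 100
apply_contrast <- function(img, alpha) {
  validate_gray_image(img)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("`alpha` must be a single finite value > 0", call. = FALSE)
  }
  if (alpha == 1) return(img)  # exact identity, no floating-point round trip
  mu <- mean(img)
  alpha * (img - mu) + mu
}

#' Map a real pre-activation to the clinical contrast range (1, 3)
#'
#' The bounded mapping \eqn{f(x) = 1 + 2 / (1 + e^{-x})}: a scaled logistic
#' that is strictly increasing, maps 0 to the mid-range gain 2, and keeps
#' every output strictly inside the open interval (1, 3). The range matches
#' the span clinicians use when adjusting ultrasound contrast: gains below 1
#' over-compress the dynamic range while gains above 3 oversaturate key
#' regions. Applied elementwise to vectors.
#'
#' @param x finite numeric vector of pre-activations.
#' @return contrast gains in (1, 3), same length as `x`.
#' @export
#' @examples
#' map_to_contrast(0)      # exactly 2
#' map_to_contrast(c(-20, 20))
map_to_contrast <- function(x) {
  if (!is.numeric(x) || length(x) < 1L || !all(is.finite(x))) {
    stop("`x` must be finite numeric", call. = FALSE)
  }
  1 + 2 * stats::plogis(x)
}

# Derivative of map_to_contrast, used by the analytic backward pass.
map_to_contrast_grad <- function(x) {
  p <- stats::plogis(x)
  2 * p * (1 - p)
}

#' Expand an image into a stack of contrast-transformed views
#'
#' Applies [apply_contrast()] once per gain, producing a K x H x W array of
#' views of the same scene under K contrast conditions. Every view shares the
#' source image's mean (stored in the `source_mean` attribute).
#'
#' @param img numeric H x W matrix.
#' @param contrasts numeric vector of K gains, each strictly inside (1, 3)
#'   (gain exactly 1 is additionally accepted for identity checks).
#' @return K x H x W array with attribute `source_mean`; class `view_stack`.
#' @export
expand_views <- function(img, contrasts) {
  validate_gray_image(img)
  if (!is.numeric(contrasts) || length(contrasts) < 1L) {
    stop("`contrasts` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!all(is.finite(contrasts)) || any(contrasts <= 0)) {
    stop("contrast gains must be finite and > 0", call. = FALSE)
  }
  mu <- mean(img)
  K <- length(contrasts)
  centered <- img - mu
  stack <- array(0, dim = c(K, nrow(img), ncol(img)))
  for (k in seq_len(K)) {
    stack[k, , ] <- contrasts[k] * centered + mu
  }
  structure(stack, source_mean = mu, contrasts = contrasts,
            class = "view_stack")
}

#' @export
print.view_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<view_stack> %d views of a %d x %d image, mean %.4f\n",
              d[1], d[2], d[3], attr(x, "source_mean")))
  cat("contrasts:", paste(sprintf("%.3f", attr(x, "contrasts")),
                          collapse = " "), "\n")
  invisible(x)
}

#' Export a view stack as numbered PNG files
#'
#' Views are clipped to \[0, 1\] for display only. A JSON sidecar listing the
#' contrast gains is written alongside the images.
#'
#' @param stack a `view_stack`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the written file paths.
#' @export
write_views <- function(stack, dir, prefix = "view") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  K <- dim(stack)[1]
  paths <- character(K)
  for (k in seq_len(K)) {
    paths[k] <- file.path(dir, sprintf("%s_%02d.png", prefix, k))
    write_gray_png(stack[k, , ], paths[k])
  }
  sidecar <- file.path(dir, sprintf("%s_contrasts.json", prefix))
  jsonlite::write_json(
    list(contrasts = as.numeric(attr(stack, "contrasts")),
         source_mean = as.numeric(attr(stack, "source_mean"))),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sidecar))
}
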