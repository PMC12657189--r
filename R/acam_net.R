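# The texture decision network and the assembled adaptive-contrast block:
# image -> K pre-activations -> K contrast gains in (1, 3) -> K-view stack.
#
# Contrast prediction relies on local texture (edges, speckle grain) rather
# than semantics, so the decision network is deliberately shallow: two
# strided 3x3 convolutions (1 -> 8 -> 16 channels, softplus), global average
# pooling, and one fully connected layer (16 -> K). Under the defaults this
# is well under 5,000 parameters. The rectifying nonlinearity matters: the
# pooled magnitude of rectified edge responses grows with local contrast,
# which is the statistic the network must read out (a mean-preserving gain
# change leaves purely linear pooled features untouched). Softplus rather
# than ReLU keeps the whole path smooth, so analytic and finite-difference
# gradients agree everywhere.

#' Module configuration
#'
#' @param K number of contrast views to generate (default 10).
#' @param fusion how the K views enter the classifier: `"channel-stack"`
#'   feeds all views as input channels; `"logit-mean"` runs the backbone per
#'   view and averages the class scores.
#' @param input_size side length the texture network sees; images of other
#'   sizes are bilinearly resized on the decision branch only (default 64).
#' @return a list of class `acam_config`.
#' @export
acam_config <- function(K = 10L, fusion = c("channel-stack", "logit-mean"),
                        input_size = 64L) {
  fusion <- match.arg(fusion)
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("`K` must be >= 1", call. = FALSE)
  structure(list(K = K, fusion = fusion, input_size = as.integer(input_size),
                 contrast_lo = 1, contrast_hi = 3),
            class = "acam_config")
}

#' Initialize the texture decision network
#'
#' Weights are drawn from a small seeded uniform distribution and biases are
#' zero, so pre-activations start near 0 and the initial contrasts sit near
#' the mid-range gain 2.
#'
#' @param K number of output pre-activations (one per contrast view).
#' @param seed integer seed for the deterministic initialization.
#' @param init_scale multiplier on the fan-in-scaled uniform initialization
#'   half-widths (1 = He-style scaling; 0 = zero network). The final layer
#'   is initialized an order of magnitude smaller so pre-activations start
#'   near 0 and initial contrasts near the mid-range gain 2.
#' @return parameter list of class `texture_net`, with a `frozen` flag.
#' @export
texture_net_init <- function(K = 10L, seed = 1L, init_scale = 1) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("`K` must be >= 1", call. = FALSE)
  u <- function(n, fan_in, mult = 1) {
    stats::runif(n, -1, 1) * init_scale * mult * sqrt(2 / fan_in)
  }
  layers <- with_seed(seed, list(
    conv1 = list(W = matrix(u(9 * 1 * 8, 9), 9, 8),
                 b = numeric(8)),
    conv2 = list(W = matrix(u(9 * 8 * 16, 72), 72, 16),
                 b = numeric(16)),
    fc = list(W = matrix(u(16 * K, 16, mult = 0.1), 16, K),
              b = numeric(K))
  ))
  structure(list(layers = layers, K = K, seed = as.integer(seed),
                 frozen = FALSE),
            class = "texture_net")
}

#' Zero-initialized texture network (all weights and biases 0)
#'
#' Useful as a baseline: the pre-activations are identically 0 so every
#' generated contrast equals 2.
#'
#' @inheritParams texture_net_init
#' @export
texture_net_zero <- function(K = 10L) {
  texture_net_init(K = K, seed = 0L, init_scale = 0)
}

validate_texture_net <- function(params, K = NULL) {
  if (!inherits(params, "texture_net")) {
    stop("`params` must be a `texture_net` object", call. = FALSE)
  }
  if (!all(vapply(params$layers,
                  function(l) all(is.finite(l$W)) && all(is.finite(l$b)),
                  logical(1)))) {
    stop("texture network parameters contain non-finite values",
         call. = FALSE)
  }
  if (!is.null(K) && params$K != K) {
    stop(sprintf("texture network emits K = %d but configuration requires K = %d",
                 params$K, K), call. = FALSE)
  }
  invisible(params)
}

#' Number of trainable parameters in a texture network
#' @param params a `texture_net`.
#' @export
texture_net_n_params <- function(params) {
  count_params(params$layers)
}

# Forward pass with cache (for the analytic backward pass). `input_size`
# NULL means "use the image as-is".
texture_forward_cached <- function(img, params, input_size = NULL) {
  validate_gray_image(img)
  validate_texture_net(params)
  orig_dim <- dim(img)
  x0 <- img
  resized <- FALSE
  if (!is.null(input_size)) {
    input_size <- rep(as.integer(input_size), length.out = 2L)
    if (any(orig_dim != input_size)) {
      x0 <- resize_image(img, input_size)
      resized <- TRUE
    }
  }
  # the decision branch sees the brightness-centered image: contrast (the
  # spread about the mean) is what must be estimated, and the linear
  # transform itself pivots about the mean, so a global offset is nuisance
  x0 <- x0 - mean(x0)
  l <- params$layers
  c1 <- conv_forward(array(x0, dim = c(dim(x0), 1L)), l$conv1$W, l$conv1$b)
  a1 <- softplus_forward(c1$out)
  c2 <- conv_forward(a1, l$conv2$W, l$conv2$b)
  a2 <- softplus_forward(c2$out)
  g <- gap_forward(a2)
  x <- fc_forward(g, l$fc$W, l$fc$b)
  list(x = x,
       cache = list(c1 = c1, a1_pre = c1$out, c2 = c2, a2_pre = c2$out,
                    g = g, params = params, orig_dim = orig_dim,
                    resized = resized, resized_dim = dim(x0)))
}

#' Texture-network forward pass
#'
#' Maps a grayscale image to K raw pre-activations (before the bounded
#' contrast mapping). Deterministic given the image and parameters.
#'
#' @param img numeric H x W matrix.
#' @param params a `texture_net`.
#' @param input_size optional side length; the image is bilinearly resized
#'   to this size for the decision branch if it differs.
#' @return numeric vector of K finite pre-activations.
#' @export
texture_forward <- function(img, params, input_size = NULL) {
  texture_forward_cached(img, params, input_size)$x
}

# Backward pass: gradient of a loss w.r.t. the K pre-activations is pulled
# back to parameter gradients and to the (resized) input image.
texture_backward <- function(dx, fw) {
  cache <- fw$cache
  l <- cache$params$layers
  fcb <- fc_backward(dx, cache$g, l$fc$W)
  da2 <- gap_backward(fcb$dg, dim(cache$a2_pre))
  dc2 <- softplus_backward(da2, cache$a2_pre)
  c2b <- conv_backward(dc2, cache$c2$cache)
  dc1 <- softplus_backward(c2b$dx, cache$a1_pre)
  c1b <- conv_backward(dc1, cache$c1$cache)
  dimg_resized <- matrix(c1b$dx, cache$resized_dim[1], cache$resized_dim[2])
  # adjoint of the brightness centering
  dimg_resized <- dimg_resized - mean(dimg_resized)
  dimg <- if (cache$resized) {
    resize_adjoint(dimg_resized, cache$orig_dim, cache$resized_dim)
  } else {
    dimg_resized
  }
  list(grads = list(conv1 = list(W = c1b$dW, b = c1b$db),
                    conv2 = list(W = c2b$dW, b = c2b$db),
                    fc = list(W = fcb$dW, b = fcb$db)),
       dimg = dimg)
}

#' Generate adaptive contrast gains for an image
#'
#' Runs the texture network and maps each pre-activation through
#' [map_to_contrast()], yielding K gains strictly inside (1, 3).
#'
#' @inheritParams texture_forward
#' @return numeric vector of K contrast gains.
#' @export
generate_contrasts <- function(img, params, input_size = NULL) {
  map_to_contrast(texture_forward(img, params, input_size))
}

#' Full adaptive-contrast forward pass
#'
#' Image -> texture network -> K contrast gains -> K-view stack. The whole
#' path is differentiable with respect to both the image pixels and the
#' network parameters; [numerical_gradient_check()] verifies the analytic
#' gradients against finite differences.
#'
#' @inheritParams texture_forward
#' @return a `view_stack` (K x H x W array) with attribute
#'   `pre_activations`.
#' @export
acam_forward <- function(img, params, input_size = NULL) {
  fw <- texture_forward_cached(img, params, input_size)
  contrasts <- map_to_contrast(fw$x)
  stack <- expand_views(img, contrasts)
  attr(stack, "pre_activations") <- fw$x
  stack
}

# Full forward + backward for a gradient `dstack` w.r.t. the view stack.
# Returns parameter gradients and the image gradient, combining
#  (a) the direct path through the per-view affine transform and
#  (b) the decision path through the texture network.
acam_backward <- function(img, params, dstack, input_size = NULL,
                          fw = NULL, stack = NULL) {
  if (is.null(fw)) fw <- texture_forward_cached(img, params, input_size)
  contrasts <- map_to_contrast(fw$x)
  if (is.null(stack)) stack <- expand_views(img, contrasts)
  mu <- mean(img)
  centered <- img - mu
  K <- length(contrasts)
  dimg_direct <- matrix(0, nrow(img), ncol(img))
  dc <- numeric(K)
  for (k in seq_len(K)) {
    gk <- matrix(dstack[k, , ], nrow(img), ncol(img))
    dc[k] <- sum(gk * centered)
    # d view_k / d img_p = c_k * delta + (1 - c_k)/n  (mu couples all pixels)
    dimg_direct <- dimg_direct + contrasts[k] * gk +
      (1 - contrasts[k]) * mean(gk)
  }
  dx <- dc * map_to_contrast_grad(fw$x)
  tb <- texture_backward(dx, fw)
  list(grads = tb$grads, dimg = dimg_direct + tb$dimg, contrasts = contrasts)
}

#' Finite-difference check of the adaptive-contrast gradients
#'
#' Compares the analytic gradient of the probe loss (sum of squared view
#' pixels) with central finite differences, over a random sample of network
#' parameters and image pixels, and returns the maximum relative
#' discrepancy. All arithmetic is double precision.
#'
#' @param img numeric H x W matrix.
#' @param params a `texture_net`.
#' @param eps finite-difference step, in `[1e-6, 1e-3]`.
#' @param n_sample number of parameter/pixel coordinates probed per tensor.
#' @param seed seed for the coordinate sample.
#' @return the maximum relative error across probed coordinates.
#' @export
numerical_gradient_check <- function(img, params, eps = 1e-4,
                                     n_sample = 5L, seed = 1L) {
  if (eps < 1e-6 || eps > 1e-3) {
    stop("`eps` must lie in [1e-6, 1e-3]", call. = FALSE)
  }
  probe <- function(p, im) {
    st <- acam_forward(im, p)
    sum(unclass(st)^2)
  }
  st <- acam_forward(img, params)
  an <- acam_backward(img, params, 2 * unclass(st))
  rel_err <- function(a, n) abs(a - n) / pmax(abs(a), abs(n), 1e-6)
  errs <- c()
  with_seed(seed, {
    for (lname in names(params$layers)) {
      for (wname in c("W", "b")) {
        tensor <- params$layers[[lname]][[wname]]
        ids <- sample(length(tensor), min(n_sample, length(tensor)))
        for (i in ids) {
          pp <- params; pp$layers[[lname]][[wname]][i] <- tensor[i] + eps
          pm <- params; pm$layers[[lname]][[wname]][i] <- tensor[i] - eps
          num <- (probe(pp, img) - probe(pm, img)) / (2 * eps)
          errs <- c(errs, rel_err(an$grads[[lname]][[wname]][i], num))
        }
      }
    }
    pix <- sample(length(img), min(4L * n_sample, length(img)))
    for (i in pix) {
      ip <- img; ip[i] <- img[i] + eps
      im <- img; im[i] <- img[i] - eps
      num <- (probe(params, ip) - probe(params, im)) / (2 * eps)
      errs <- c(errs, rel_err(an$dimg[i], num))
    }
  })
  max(errs)
}

#' Freeze the texture network
#'
#' Sets the frozen flag; any subsequent optimization step leaves the
#' parameters bit-identical. Idempotent.
#'
#' @param params a `texture_net`.
#' @export
freeze_generator <- function(params) {
  validate_texture_net(params)
  params$frozen <- TRUE
  params
}

#' Serialize / restore texture-network parameters
#'
#' Checkpoints are written as JSON with full double precision: a header
#' (K, layer shapes, seed, frozen flag) followed by the flattened weights.
#'
#' @param params a `texture_net`.
#' @param path file path for the checkpoint.
#' @export
save_texture_net <- function(params, path) {
  validate_texture_net(params)
  obj <- list(
    header = list(K = params$K, seed = params$seed, frozen = params$frozen,
                  shapes = lapply(params$layers, function(l)
                    list(W = dim(l$W), b = length(l$b)))),
    weights = lapply(params$layers, function(l)
      list(W = as.numeric(l$W), b = as.numeric(l$b)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_texture_net
#' @export
load_texture_net <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- list()
  for (nm in names(obj$weights)) {
    layers[[nm]] <- list(
      W = matrix(obj$weights[[nm]]$W,
                 obj$header$shapes[[nm]]$W[1], obj$header$shapes[[nm]]$W[2]),
      b = as.numeric(obj$weights[[nm]]$b))
  }
  structure(list(layers = layers, K = as.integer(obj$header$K),
                 seed = as.integer(obj$header$seed),
                 frozen = isTRUE(obj$header$frozen)),
            class = "texture_net")
}

#' @export
print.texture_net <- function(x, ...) {
  cat(sprintf("<texture_net> K = %d, %d parameters%s\n", x$K,
              texture_net_n_params(x), if (x$frozen) " (frozen)" else ""))
  invisible(x)
}
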