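# Small reference classifier used to demonstrate and test the contrast
# block. Three strided 3x3 convolution blocks with ReLU, global average
# pooling and a linear head. It stands in for the large backbones
# practitioners would plug the module into; the adapter below handles how
# the K-view stack enters it.

#' Build a small reference classifier
#'
#' @param in_channels number of input channels (1 for a plain grayscale
#'   image, K for a channel-stacked view stack).
#' @param n_classes number of output classes.
#' @param widths channel widths of the three convolution blocks.
#' @param seed seed for the deterministic He-style initialization.
#' @return parameter list of class `backbone_net`.
#' @export
reference_backbone <- function(in_channels, n_classes, widths = c(16L, 32L, 32L),
                               seed = 1L) {
  in_channels <- as.integer(in_channels)
  n_classes <- as.integer(n_classes)
  if (in_channels < 1L || n_classes < 1L) {
    stop("`in_channels` and `n_classes` must be >= 1", call. = FALSE)
  }
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  layers <- with_seed(seed, {
    cins <- c(in_channels, widths[1], widths[2])
    l <- list()
    for (i in 1:3) {
      fi <- 9L * cins[i]
      l[[paste0("conv", i)]] <- list(
        W = matrix(he(fi, fi * widths[i]), fi, widths[i]),
        b = numeric(widths[i]))
    }
    l$fc <- list(W = matrix(he(widths[3], widths[3] * n_classes),
                            widths[3], n_classes),
                 b = numeric(n_classes))
    l
  })
  structure(list(layers = layers, in_channels = in_channels,
                 n_classes = n_classes, widths = as.integer(widths),
                 seed = as.integer(seed)),
            class = "backbone_net")
}

#' Number of trainable parameters in a backbone
#' @param net a `backbone_net`.
#' @export
backbone_n_params <- function(net) count_params(net$layers)

# Forward pass over an H x W x C array; returns logits and a cache.
backbone_forward_cached <- function(x, net) {
  d <- dim(x)
  if (length(d) == 2L) x <- array(x, dim = c(d, 1L))
  if (dim(x)[3] != net$in_channels) {
    stop(sprintf("backbone expects %d input channels, got %d",
                 net$in_channels, dim(x)[3]), call. = FALSE)
  }
  l <- net$layers
  c1 <- conv_forward(x, l$conv1$W, l$conv1$b)
  a1 <- relu_forward(c1$out)
  c2 <- conv_forward(a1, l$conv2$W, l$conv2$b)
  a2 <- relu_forward(c2$out)
  c3 <- conv_forward(a2, l$conv3$W, l$conv3$b)
  a3 <- relu_forward(c3$out)
  g <- gap_forward(a3)
  logits <- fc_forward(g, l$fc$W, l$fc$b)
  list(logits = logits,
       cache = list(c1 = c1, c2 = c2, c3 = c3, g = g, net = net))
}

#' Backbone forward pass
#'
#' @param x H x W x C array (or H x W matrix for single-channel input).
#' @param net a `backbone_net`.
#' @return numeric vector of `n_classes` logits.
#' @export
backbone_forward <- function(x, net) backbone_forward_cached(x, net)$logits

backbone_backward <- function(dlogits, fw) {
  cache <- fw$cache
  l <- cache$net$layers
  fcb <- fc_backward(dlogits, cache$g, l$fc$W)
  da3 <- gap_backward(fcb$dg, dim(cache$c3$out))
  dc3 <- relu_backward(da3, cache$c3$out)
  c3b <- conv_backward(dc3, cache$c3$cache)
  dc2 <- relu_backward(c3b$dx, cache$c2$out)
  c2b <- conv_backward(dc2, cache$c2$cache)
  dc1 <- relu_backward(c2b$dx, cache$c1$out)
  c1b <- conv_backward(dc1, cache$c1$cache)
  list(grads = list(conv1 = list(W = c1b$dW, b = c1b$db),
                    conv2 = list(W = c2b$dW, b = c2b$db),
                    conv3 = list(W = c3b$dW, b = c3b$db),
                    fc = list(W = fcb$dW, b = fcb$db)),
       dx = c1b$dx)
}

#' Adapt a classifier to consume a K-view stack
#'
#' In `channel-stack` mode the backbone's first layer consumes `n_views`
#' input channels (the literal stacked output of the contrast block). In
#' `logit-mean` mode a single-channel backbone is applied to each view and
#' the class scores are averaged.
#'
#' @param n_views number of contrast views.
#' @param backbone a `backbone_net` (or NULL to build one).
#' @param mode `"channel-stack"` or `"logit-mean"`.
#' @param n_classes used when `backbone` is NULL.
#' @param seed initialization seed when a backbone is built here.
#' @return a list of class `fused_classifier` with a `$forward(stack)`
#'   closure returning logits.
#' @export
fuse_input_adapter <- function(n_views, backbone = NULL,
                               mode = c("channel-stack", "logit-mean"),
                               n_classes = 6L, seed = 1L) {
  mode <- match.arg(mode)
  need_ch <- if (mode == "channel-stack") as.integer(n_views) else 1L
  if (is.null(backbone)) {
    backbone <- reference_backbone(need_ch, n_classes, seed = seed)
  } else if (backbone$in_channels != need_ch) {
    stop(sprintf("fusion mode '%s' with %d views needs a %d-channel backbone, got %d channels",
                 mode, n_views, need_ch, backbone$in_channels),
         call. = FALSE)
  }
  fused <- list(backbone = backbone, mode = mode,
                n_views = as.integer(n_views))
  fused$forward <- function(stack) fused_forward(stack, fused)$logits
  structure(fused, class = "fused_classifier")
}

# Forward through the fused classifier; `stack` is K x H x W (a view_stack)
# or an H x W matrix when n_views == 1 and the input is a plain image.
fused_forward <- function(stack, fused) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(1L, dim(stack)))
  K <- dim(stack)[1]
  if (fused$mode == "channel-stack") {
    x <- aperm(unclass(stack), c(2, 3, 1))
    fw <- backbone_forward_cached(x, fused$backbone)
    list(logits = fw$logits, caches = list(fw), mode = "channel-stack")
  } else {
    caches <- vector("list", K)
    logits <- 0
    for (k in seq_len(K)) {
      caches[[k]] <- backbone_forward_cached(
        matrix(stack[k, , ], dim(stack)[2], dim(stack)[3]), fused$backbone)
      logits <- logits + caches[[k]]$logits
    }
    list(logits = logits / K, caches = caches, mode = "logit-mean")
  }
}

# Backward through the fused classifier. Returns backbone parameter
# gradients and the gradient w.r.t. the view stack (K x H x W).
fused_backward <- function(dlogits, fw, fused) {
  if (fw$mode == "channel-stack") {
    bb <- backbone_backward(dlogits, fw$caches[[1]])
    dstack <- aperm(bb$dx, c(3, 1, 2))
    list(grads = bb$grads, dstack = dstack)
  } else {
    K <- length(fw$caches)
    grads <- NULL
    dstack <- NULL
    for (k in seq_len(K)) {
      bb <- backbone_backward(dlogits / K, fw$caches[[k]])
      if (is.null(dstack)) {
        dstack <- array(0, dim = c(K, dim(bb$dx)[1], dim(bb$dx)[2]))
        grads <- bb$grads
      } else {
        grads <- add_grads(grads, bb$grads)
      }
      dstack[k, , ] <- bb$dx[, , 1]
    }
    list(grads = grads, dstack = dstack)
  }
}

# Elementwise sum of two nested gradient lists.
add_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- add_grads(a[[nm]], b[[nm]])
    a
  } else {
    a + b
  }
}

scale_grads <- function(a, s) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- scale_grads(a[[nm]], s)
    a
  } else {
    a * s
  }
}

#' @export
print.backbone_net <- function(x, ...) {
  cat(sprintf("<backbone_net> %d -> (%s) -> %d classes, %d parameters\n",
              x$in_channels, paste(x$widths, collapse = ", "),
              x$n_classes, backbone_n_params(x)))
  invisible(x)
}
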