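# Seeded generator of six-class ultrasound-like phantom images.
#
# Each sample is a class-distinctive geometric scene on a dark background,
# corrupted with fully developed multiplicative speckle, then contrast-
# compressed by a recorded gain g (emulating operator-dependent settings)
# plus a small brightness jitter. The ideal restoring contrast
# alpha* = clamp(1/g, 1, 3) is stored with every sample and is the
# supervision signal for stage-1 training of the contrast generator.
#
# Class roster (loosely mirroring fetal-ultrasound standard planes):
#   0 abdomen  - ellipse with an inner dark disc (stomach bubble)
#   1 femur    - bright elongated bar (aspect ratio > 3)
#   2 cervix   - V-shaped wedge
#   3 thorax   - ellipse containing two bright lobes
#   4 brain    - ellipse with a bright midline echo
#   5 other    - random blob field

#' Phantom dataset specification
#'
#' @param n_total total number of images.
#' @param size image side length in pixels (square images).
#' @param proportions class mix over the six classes; the default follows
#'   the per-class counts 711, 1040, 1626, 1718, 3092, 4213 of the fetal
#'   standard-plane benchmark the generator emulates.
#' @param speckle_strength blend weight of the multiplicative speckle field,
#'   in `[0, 1]`.
#' @param gain_range range of the contrast-compression gain g; gains are
#'   drawn log-uniformly so that the restoring contrast 1/g is roughly
#'   uniform over `[1, 3]` under the default `[1/3, 1]`.
#' @param jitter brightness-jitter half-amplitude (uniform offset).
#' @param train_frac training fraction of the stratified split.
#' @param seed master seed; the whole dataset is a pure function of the
#'   spec including this seed.
#' @param test_gain_range optional alternate gain range applied only to
#'   test-split samples, for robustness experiments with unseen contrast
#'   compression at test time (NULL = same as `gain_range`).
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_total = 600L, size = 64L,
                         proportions = c(711, 1040, 1626, 1718, 3092, 4213),
                         speckle_strength = 0.5,
                         gain_range = c(1 / 3, 1),
                         jitter = 0.05,
                         train_frac = 0.7,
                         seed = 1L,
                         test_gain_range = NULL) {
  proportions <- proportions / sum(proportions)
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("class proportions must sum to 1", call. = FALSE)
  }
  if (length(proportions) != 6L) {
    stop("exactly six class proportions are required", call. = FALSE)
  }
  if (any(gain_range <= 0) || any(gain_range > 1)) {
    stop("`gain_range` must lie inside (0, 1]", call. = FALSE)
  }
  if (speckle_strength < 0 || speckle_strength > 1) {
    stop("`speckle_strength` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_total = as.integer(n_total), size = as.integer(size),
                 proportions = proportions,
                 speckle_strength = speckle_strength,
                 gain_range = gain_range, jitter = jitter,
                 train_frac = train_frac, seed = as.integer(seed),
                 test_gain_range = test_gain_range),
            class = "phantom_spec")
}

#' Largest-remainder apportionment of counts to class proportions
#'
#' Deterministically rounds `n * proportions` to integers that sum to `n`:
#' floors first, then distributes the remaining units to the classes with
#' the largest fractional parts (ties broken by class order).
#'
#' @param n total count.
#' @param proportions nonnegative weights (normalized internally).
#' @return integer vector of per-class counts summing to `n`.
#' @export
apportion_counts <- function(n, proportions) {
  p <- proportions / sum(proportions)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Render a clean (noise-free) phantom image for one class
#'
#' @param class_id integer class in 0..5.
#' @param size image side length.
#' @param seed seed controlling the geometry jitter of this sample.
#' @return numeric size x size matrix with values in `[0, 1]`.
#' @export
render_phantom <- function(class_id, size = 64L, seed = 1L) {
  if (!is.numeric(class_id) || length(class_id) != 1L ||
      !(class_id %in% 0:5)) {
    stop("`class_id` must be an integer in 0..5", call. = FALSE)
  }
  size <- as.integer(size)
  with_seed(seed, {
    # normalized coordinates in [-1, 1]
    u <- matrix(rep(seq(-1, 1, length.out = size), each = size), size, size)
    v <- matrix(rep(seq(-1, 1, length.out = size), times = size), size, size)
    bg <- 0.08
    img <- matrix(bg, size, size)
    jx <- stats::runif(1, -0.1, 0.1)
    jy <- stats::runif(1, -0.1, 0.1)
    if (class_id == 0) {            # abdomen: ellipse + inner dark disc
      a <- stats::runif(1, 0.55, 0.7); b <- stats::runif(1, 0.45, 0.6)
      body <- ((u - jx) / a)^2 + ((v - jy) / b)^2 <= 1
      img[body] <- 0.65
      dx <- stats::runif(1, -0.15, 0.05); dy <- stats::runif(1, -0.1, 0.1)
      r <- stats::runif(1, 0.15, 0.22)
      disc <- (u - jx - dx)^2 + (v - jy - dy)^2 <= r^2
      img[disc & body] <- 0.18
    } else if (class_id == 1) {     # femur: bright elongated bar
      ang <- stats::runif(1, -0.35, 0.35)
      ur <- (u - jx) * cos(ang) + (v - jy) * sin(ang)
      vr <- -(u - jx) * sin(ang) + (v - jy) * cos(ang)
      len <- stats::runif(1, 0.6, 0.75); wid <- stats::runif(1, 0.06, 0.09)
      bar <- abs(ur) <= wid & abs(vr) <= len
      img[bar] <- 0.9
    } else if (class_id == 2) {     # cervix: V-shaped wedge
      ap <- stats::runif(1, 0.35, 0.55)       # opening slope
      th <- stats::runif(1, 0.07, 0.1)        # arm thickness
      y0 <- jy - 0.4
      arm1 <- abs((u - jx) - ap * (v - y0)) <= th & (v - y0) >= 0 &
        (v - y0) <= 1.1
      arm2 <- abs((u - jx) + ap * (v - y0)) <= th & (v - y0) >= 0 &
        (v - y0) <= 1.1
      img[arm1 | arm2] <- 0.75
    } else if (class_id == 3) {     # thorax: ellipse with two bright lobes
      a <- stats::runif(1, 0.6, 0.72); b <- stats::runif(1, 0.5, 0.62)
      body <- ((u - jx) / a)^2 + ((v - jy) / b)^2 <= 1
      img[body] <- 0.45
      off <- stats::runif(1, 0.22, 0.3); r <- stats::runif(1, 0.14, 0.2)
      lobe1 <- (u - jx - off)^2 + (v - jy)^2 <= r^2
      lobe2 <- (u - jx + off)^2 + (v - jy)^2 <= r^2
      img[(lobe1 | lobe2) & body] <- 0.85
    } else if (class_id == 4) {     # brain: ellipse with bright midline
      a <- stats::runif(1, 0.62, 0.75); b <- stats::runif(1, 0.48, 0.6)
      body <- ((u - jx) / a)^2 + ((v - jy) / b)^2 <= 1
      img[body] <- 0.5
      th <- stats::runif(1, 0.03, 0.05)
      mid <- abs(u - jx) <= th & body
      img[mid] <- 0.95
    } else {                        # other: random blob field
      # fixed blob count and narrow radius/amplitude ranges keep the
      # scene's overall contrast amplitude stable across draws, so the
      # applied degradation gain stays identifiable from image statistics
      amps <- c(0.35, 0.45, 0.55, 0.65, 0.75, 0.85)
      for (i in 1:6) {
        cx <- stats::runif(1, -0.65, 0.65); cy <- stats::runif(1, -0.65, 0.65)
        r <- stats::runif(1, 0.14, 0.19)
        blob <- (u - cx)^2 + (v - cy)^2 <= r^2
        img[blob] <- amps[i]
      }
    }
    clamp(img, 0, 1)
  })
}

#' Add fully developed multiplicative speckle
#'
#' Blends the image with a copy multiplied by a unit-mean exponential field:
#' `(1 - strength) * img + strength * img * s`, `s ~ Exp(1)`. Strength 0
#' leaves the image untouched; the expected value of every pixel is
#' unchanged for any strength.
#'
#' @param img numeric H x W matrix.
#' @param strength blend weight in `[0, 1]`.
#' @param seed seed for the speckle field.
#' @return speckled image (clipped below at 0).
#' @export
apply_speckle <- function(img, strength, seed = 1L) {
  validate_gray_image(img)
  if (strength < 0 || strength > 1) {
    stop("`strength` must lie in [0, 1]", call. = FALSE)
  }
  if (strength == 0) return(img)
  s <- with_seed(seed, matrix(stats::rexp(length(img)), nrow(img), ncol(img)))
  pmax((1 - strength) * img + strength * img * s, 0)
}

#' Compress contrast and record the ideal restoring gain
#'
#' Applies the mean-preserving linear transform with gain `g <= 1`
#' (compression), then a uniform brightness offset in `[-jitter, +jitter]`.
#' Returns the degraded image together with the ideal restoring contrast
#' `alpha* = clamp(1/g, 1, 3)`; with zero jitter, re-applying the transform
#' at gain `alpha*` restores the input exactly (gains compose
#' multiplicatively).
#'
#' @param img numeric H x W matrix.
#' @param g compression gain in (0, 1].
#' @param jitter brightness-jitter half-amplitude (>= 0).
#' @param seed seed for the jitter draw.
#' @return list with elements `image` and `alpha_star`.
#' @export
degrade_contrast <- function(img, g, jitter = 0, seed = 1L) {
  validate_gray_image(img)
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0) {
    stop("`g` must be a single finite value > 0", call. = FALSE)
  }
  if (jitter < 0) stop("`jitter` must be >= 0", call. = FALSE)
  out <- apply_contrast(img, g)
  if (jitter > 0) {
    out <- out + with_seed(seed, stats::runif(1, -jitter, jitter))
  }
  list(image = out, alpha_star = clamp(1 / g, 1, 3))
}

#' Generate a complete phantom dataset
#'
#' Renders, speckles and contrast-degrades every sample according to the
#' spec, draws the compression gain log-uniformly from the spec's gain
#' range, and assigns a stratified train/test split (70/30 by default,
#' within one sample per class of the target fraction). The result is fully
#' reproducible from the spec.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `phantom_dataset` with elements `images` (list of
#'   H x W matrices), `manifest` (data.frame: id, class, g, alpha_star,
#'   split, seed) and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  counts <- apportion_counts(spec$n_total, spec$proportions)
  records <- list()
  images <- list()
  idx <- 0L
  for (cls in 0:5) {
    n_c <- counts[cls + 1]
    if (n_c == 0L) next
    n_train <- as.integer(round(spec$train_frac * n_c))
    split_tags <- c(rep("train", n_train), rep("test", n_c - n_train))
    # shuffle split assignment within the class, deterministically
    split_tags <- with_seed(derive_seed(spec$seed, 1000 + cls),
                            sample(split_tags))
    for (i in seq_len(n_c)) {
      idx <- idx + 1L
      s_render <- derive_seed(spec$seed, idx * 3 + 0)
      s_speckle <- derive_seed(spec$seed, idx * 3 + 1)
      s_degrade <- derive_seed(spec$seed, idx * 3 + 2)
      clean <- render_phantom(cls, spec$size, seed = s_render)
      speckled <- apply_speckle(clean, spec$speckle_strength,
                                seed = s_speckle)
      gr <- spec$gain_range
      if (split_tags[i] == "test" && !is.null(spec$test_gain_range)) {
        gr <- spec$test_gain_range
      }
      g <- with_seed(s_degrade,
                     exp(stats::runif(1, log(gr[1]), log(gr[2]))))
      deg <- degrade_contrast(speckled, g, spec$jitter,
                              seed = derive_seed(spec$seed, idx * 7 + 3))
      images[[idx]] <- deg$image
      records[[idx]] <- data.frame(
        id = sprintf("s%05d", idx), class = cls, g = g,
        alpha_star = deg$alpha_star, split = split_tags[i],
        seed = spec$seed)
    }
  }
  manifest <- do.call(rbind, records)
  rownames(manifest) <- NULL
  structure(list(images = images, manifest = manifest, spec = spec),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<phantom_dataset> %d images (%d x %d), %d train / %d test\n",
              nrow(m), x$spec$size, x$spec$size,
              sum(m$split == "train"), sum(m$split == "test")))
  print(table(class = m$class, split = m$split))
  invisible(x)
}

#' Write a phantom dataset to disk
#'
#' Layout: `<root>/<split>/<class>/<id>.png` plus `manifest.csv` with
#' columns path, class, g, alpha_star, split, seed. Images are clipped to
#' \[0, 1\] for storage; the in-memory dataset is the reference
#' representation.
#'
#' @param dataset a `phantom_dataset`.
#' @param root output directory.
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, root) {
  m <- dataset$manifest
  paths <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    d <- file.path(root, m$split[i], m$class[i])
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    paths[i] <- file.path(d, paste0(m$id[i], ".png"))
    write_gray_png(dataset$images[[i]], paths[i])
  }
  out <- cbind(path = paths, m[, c("class", "g", "alpha_star", "split",
                                   "seed")])
  mp <- file.path(root, "manifest.csv")
  utils::write.csv(out, mp, row.names = FALSE)
  invisible(mp)
}
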