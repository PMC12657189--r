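#' Fit a classifier with adaptive contrast adjustment
#'
#' The main entry point of the package: trains a grayscale-image classifier
#' on a phantom dataset in one of four modes and returns a fitted model
#' object.
#'
#' \describe{
#'   \item{`acam`}{(default) the adaptive contrast block — a shallow texture
#'     network predicting K contrast gains in (1, 3), expanded into a K-view
#'     stack — trained jointly with the backbone.}
#'   \item{`acam_two_stage`}{stage 1 first trains the contrast generator to
#'     regress the recorded ideal restoring contrast alpha*; the generator
#'     is then frozen and only the classifier is trained (stage 2).}
#'   \item{`rcj`}{random-contrast-jittering augmentation baseline.}
#'   \item{`plain`}{the bare backbone.}
#' }
#'
#' @param data a `phantom_dataset` from [generate_dataset()] (or any object
#'   with `$images` and a `$manifest` carrying `class`, `split` and — for
#'   the two-stage mode — `alpha_star`).
#' @param mode training mode, see Details.
#' @param config an [acam_config()] (K, fusion mode, decision-branch size).
#' @param train a [train_config()].
#' @param stage1 a [stage1_config()] (two-stage mode only).
#' @param n_classes number of classes (default 6).
#' @return an object of class `acam_fit` with `print`, `summary`, `coef`,
#'   `predict` and `plot` methods.
#' @export
#' @examples
#' \donttest{
#' spec <- phantom_spec(n_total = 60, size = 32, seed = 7)
#' ds <- generate_dataset(spec)
#' fit <- acam(ds, mode = "plain",
#'             train = train_config(epochs = 2, batch_size = 16))
#' fit
#' }
acam <- function(data, mode = c("acam", "plain", "rcj", "acam_two_stage"),
                 config = acam_config(), train = train_config(),
                 stage1 = stage1_config(), n_classes = 6L) {
  mode <- match.arg(mode)
  acam_params <- NULL
  stage1_out <- NULL
  if (mode == "acam_two_stage") {
    stage1_out <- train_stage1(data, cfg = stage1, K = config$K,
                               seed = derive_seed(train$seed, 41),
                               input_size = NULL)
    acam_params <- freeze_generator(stage1_out$params)
  }
  fit <- train_classifier(data, cfg = train, mode = mode,
                          acam_cfg = config, acam_params = acam_params,
                          n_classes = n_classes)
  fit$stage1_history <- stage1_out$history
  fit
}

#' @export
print.acam_fit <- function(x, ...) {
  cat(sprintf("<acam_fit> mode '%s', %d classes\n", x$mode, x$n_classes))
  if (!is.null(x$texture)) {
    cat(sprintf("  contrast generator: K = %d, %d parameters%s\n",
                x$texture$K, texture_net_n_params(x$texture),
                if (x$texture$frozen) " (frozen)" else ""))
  }
  cat(sprintf("  backbone: %d parameters (%d input channels)\n",
              backbone_n_params(x$fused$backbone),
              x$fused$backbone$in_channels))
  h <- x$history
  last <- h[nrow(h), ]
  cat(sprintf("  trained %d epochs; final train acc %.3f%s\n",
              nrow(h), last$train_acc,
              if (!is.na(last$test_acc)) {
                sprintf(", test acc %.3f", last$test_acc)
              } else ""))
  invisible(x)
}

#' @export
summary.acam_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.acam_fit")
}

#' @export
print.summary.acam_fit <- function(x, ...) {
  print(x$fit)
  cat("\nTraining history:\n")
  print(x$fit$history, row.names = FALSE)
  if (!is.null(x$fit$stage1_history)) {
    cat("\nStage-1 (contrast regression) loss by epoch:\n")
    print(round(x$fit$stage1_history, 5))
  }
  invisible(x)
}

#' Extract model coefficients
#'
#' Returns the flattened texture-network (contrast generator) parameters for
#' adaptive modes, or the backbone head weights otherwise.
#'
#' @param object an `acam_fit`.
#' @param ... unused.
#' @export
coef.acam_fit <- function(object, ...) {
  if (!is.null(object$texture)) {
    unlist(object$texture$layers)
  } else {
    unlist(object$fused$backbone$layers$fc)
  }
}

#' Predict from a fitted model
#'
#' @param object an `acam_fit`.
#' @param newdata a `phantom_dataset`, a list of images, or a single image
#'   matrix.
#' @param type `"class"` (0-based labels), `"prob"` (softmax score matrix)
#'   or `"contrast"` (the K generated contrast gains per image; adaptive
#'   modes only).
#' @param ... unused.
#' @export
predict.acam_fit <- function(object, newdata,
                             type = c("class", "prob", "contrast"), ...) {
  type <- match.arg(type)
  images <- if (inherits(newdata, "phantom_dataset")) {
    newdata$images
  } else if (is.matrix(newdata)) {
    list(newdata)
  } else {
    newdata
  }
  if (type == "contrast") {
    if (is.null(object$texture)) {
      stop("model has no contrast generator (non-adaptive mode)",
           call. = FALSE)
    }
    return(t(vapply(images, function(img) {
      generate_contrasts(img, object$texture, object$acam_input_size)
    }, numeric(object$texture$K))))
  }
  probs <- score_images(object, images)
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

#' Plot training history
#'
#' @param x an `acam_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.acam_fit <- function(x, ...) {
  h <- x$history
  ys <- cbind(train = h$train_acc, test = h$test_acc)
  graphics::matplot(h$epoch, ys, type = "b", pch = c(1, 2), lty = 1,
                    xlab = "epoch", ylab = "accuracy",
                    main = sprintf("training history (%s)", x$mode), ...)
  graphics::legend("bottomright", legend = colnames(ys), pch = c(1, 2),
                   col = 1:2, bty = "n")
  invisible(x)
}
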