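# Training harness: plain / random-contrast-jittering / joint adaptive /
# two-stage modes over the reference backbone. Everything is seeded and data
# order is serial, so runs are reproducible bit-for-bit.

#' Classifier training configuration
#'
#' Full-scale defaults are batch size 64, 20 epochs, learning rate 0.001
#' with the Adam optimizer and cross-entropy loss; desk-scale experiments
#' override epochs and batch size.
#'
#' @param batch_size minibatch size.
#' @param epochs number of passes over the training split.
#' @param lr Adam learning rate.
#' @param seed training seed (shuffling, initialization).
#' @param rcj_range gain range for random contrast jittering (used by the
#'   `rcj` mode only); matches the adaptive module's (1, 3) range.
#' @param eval_each_epoch record test accuracy after every epoch.
#' @return a list of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, epochs = 20L, lr = 1e-3,
                         seed = 1L, rcj_range = c(1, 3),
                         eval_each_epoch = TRUE) {
  if (batch_size < 1 || epochs < 1 || lr <= 0) {
    stop("batch size, epochs and learning rate must be positive",
         call. = FALSE)
  }
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed), rcj_range = rcj_range,
                 eval_each_epoch = isTRUE(eval_each_epoch)),
            class = "train_config")
}

#' Stage-1 (contrast-generation) training configuration
#'
#' Stage 1 regresses the mean of the K generated contrasts onto the
#' recorded ideal restoring contrast alpha* with a mean-squared-error loss.
#'
#' @param epochs passes over the training split.
#' @param lr initial Adam learning rate; a step decay (x0.3 after 60% of
#'   the epochs, x0.1 after 85%) refines the fit.
#' @param batch_size minibatch size.
#' @return a list of class `stage1_config`.
#' @export
stage1_config <- function(epochs = 40L, lr = 1e-2, batch_size = 32L) {
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size)),
            class = "stage1_config")
}

#' Random contrast jittering
#'
#' The augmentation baseline: applies the linear contrast transform with a
#' gain drawn uniformly from `range` (default `[1, 3]`, matching the
#' adaptive module's output range).
#'
#' @param img numeric H x W matrix.
#' @param seed seed for the gain draw.
#' @param range gain range.
#' @return augmented image.
#' @export
rcj_augment <- function(img, seed = 1L, range = c(1, 3)) {
  g <- with_seed(seed, stats::runif(1, range[1], range[2]))
  apply_contrast(img, g)
}

split_indices <- function(dataset, split) {
  which(dataset$manifest$split == split)
}

#' Train the contrast generator against recorded ideal contrasts (stage 1)
#'
#' Minimizes the mean squared error between the mean of the K generated
#' contrasts and each sample's recorded ideal restoring contrast alpha* on
#' the training split. Deterministic under a fixed seed and serial data
#' order.
#'
#' @param dataset a `phantom_dataset` whose manifest carries `alpha_star`.
#' @param cfg a [stage1_config()].
#' @param K number of contrast outputs.
#' @param seed seed for initialization and shuffling.
#' @param input_size optional decision-branch resize (NULL = native size).
#' @return list with `params` (trained `texture_net`) and `history`
#'   (per-epoch mean training loss).
#' @export
train_stage1 <- function(dataset, cfg = stage1_config(), K = 10L, seed = 1L,
                         input_size = NULL) {
  if (is.null(dataset$manifest$alpha_star)) {
    stop("manifest lacks the `alpha_star` supervision column",
         call. = FALSE)
  }
  params <- texture_net_init(K = K, seed = derive_seed(seed, 11))
  state <- adam_init(params$layers)
  train_idx <- split_indices(dataset, "train")
  if (length(train_idx) == 0) stop("empty training split", call. = FALSE)
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    lr_t <- cfg$lr * if (epoch > 0.85 * cfg$epochs) 0.1 else
      if (epoch > 0.6 * cfg$epochs) 0.3 else 1
    order_idx <- with_seed(derive_seed(seed, 100 + epoch),
                           sample(train_idx))
    batches <- split(order_idx,
                     ceiling(seq_along(order_idx) / cfg$batch_size))
    ep_loss <- 0
    for (batch in batches) {
      gsum <- NULL
      for (i in batch) {
        img <- dataset$images[[i]]
        target <- dataset$manifest$alpha_star[i]
        fw <- texture_forward_cached(img, params, input_size)
        contrasts <- map_to_contrast(fw$x)
        err <- mean(contrasts) - target
        ep_loss <- ep_loss + err^2
        # d(err^2)/dx_k = 2 err * f'(x_k) / K
        dx <- 2 * err * map_to_contrast_grad(fw$x) / length(fw$x)
        tb <- texture_backward(dx, fw)
        gsum <- if (is.null(gsum)) tb$grads else add_grads(gsum, tb$grads)
      }
      gavg <- scale_grads(gsum, 1 / length(batch))
      st <- adam_step(params$layers, gavg, state, lr = lr_t)
      params$layers <- st$params
      state <- st$state
    }
    history[epoch] <- ep_loss / length(train_idx)
  }
  list(params = params, history = history)
}

#' Mean absolute error of the predicted mean contrast vs alpha*
#'
#' @param params a `texture_net`.
#' @param dataset a `phantom_dataset`.
#' @param split which split to score.
#' @param input_size optional decision-branch resize.
#' @return scalar MAE.
#' @export
stage1_mae <- function(params, dataset, split = "test", input_size = NULL) {
  idx <- split_indices(dataset, split)
  if (length(idx) == 0) stop("empty split", call. = FALSE)
  errs <- vapply(idx, function(i) {
    pred <- mean(generate_contrasts(dataset$images[[i]], params, input_size))
    abs(pred - dataset$manifest$alpha_star[i])
  }, numeric(1))
  mean(errs)
}

# Forward pass of one sample through the configured model; returns logits
# and the caches needed for the backward pass.
model_forward <- function(img, model) {
  if (model$mode %in% c("acam", "acam_two_stage")) {
    fw_tex <- texture_forward_cached(img, model$texture,
                                     model$acam_input_size)
    contrasts <- map_to_contrast(fw_tex$x)
    stack <- expand_views(img, contrasts)
    fw <- fused_forward(stack, model$fused)
    list(logits = fw$logits, fused_fw = fw, tex_fw = fw_tex, stack = stack)
  } else {
    fw <- fused_forward(img, model$fused)
    list(logits = fw$logits, fused_fw = fw)
  }
}

model_backward <- function(dlogits, img, sfw, model) {
  fb <- fused_backward(dlogits, sfw$fused_fw, model$fused)
  out <- list(backbone = fb$grads, texture = NULL)
  if (model$mode %in% c("acam", "acam_two_stage") &&
      !isTRUE(model$texture$frozen)) {
    ab <- acam_backward(img, model$texture, fb$dstack,
                        input_size = model$acam_input_size,
                        fw = sfw$tex_fw, stack = sfw$stack)
    out$texture <- ab$grads
  }
  out
}

#' Train a classifier in one of the four experiment modes
#'
#' Modes: `plain` (backbone on the raw image), `rcj` (random contrast
#' jittering augmentation at train time), `acam` (the adaptive contrast
#' block trained jointly with the backbone — the default usage), and
#' `acam_two_stage` (a generator pre-trained on recorded contrasts, frozen,
#' with only the backbone trained). Cross-entropy loss, Adam optimizer.
#'
#' @param dataset a `phantom_dataset`.
#' @param cfg a [train_config()].
#' @param mode one of `"plain"`, `"rcj"`, `"acam"`, `"acam_two_stage"`.
#' @param acam_cfg an [acam_config()] (adaptive modes only).
#' @param acam_params optional pre-trained `texture_net`; required (and
#'   expected frozen) in `acam_two_stage` mode.
#' @param n_classes number of classes.
#' @return a fitted model of class `acam_fit` (see [acam()]).
#' @export
train_classifier <- function(dataset, cfg = train_config(),
                             mode = c("plain", "rcj", "acam",
                                      "acam_two_stage"),
                             acam_cfg = acam_config(),
                             acam_params = NULL, n_classes = 6L) {
  mode <- match.arg(mode)
  adaptive <- mode %in% c("acam", "acam_two_stage")
  if (!adaptive && !is.null(acam_params)) {
    stop(sprintf("mode '%s' does not accept texture-network parameters",
                 mode), call. = FALSE)
  }
  if (mode == "acam_two_stage") {
    if (is.null(acam_params)) {
      stop("acam_two_stage mode requires pre-trained generator parameters",
           call. = FALSE)
    }
    if (!isTRUE(acam_params$frozen)) {
      stop("acam_two_stage mode requires a frozen generator (see freeze_generator())",
           call. = FALSE)
    }
  }
  texture <- NULL
  if (adaptive) {
    texture <- if (is.null(acam_params)) {
      texture_net_init(K = acam_cfg$K, seed = derive_seed(cfg$seed, 21))
    } else {
      validate_texture_net(acam_params, K = acam_cfg$K)
      acam_params
    }
  }
  in_ch <- if (!adaptive || acam_cfg$fusion == "logit-mean") 1L else
    acam_cfg$K
  backbone <- reference_backbone(in_ch, n_classes,
                                 seed = derive_seed(cfg$seed, 31))
  fused <- fuse_input_adapter(if (adaptive) acam_cfg$K else 1L,
                              backbone = backbone,
                              mode = if (adaptive) acam_cfg$fusion else
                                "channel-stack",
                              n_classes = n_classes)
  img_dim <- dim(dataset$images[[1]])
  acam_input_size <- NULL
  if (adaptive && !is.null(acam_cfg$input_size) &&
      any(img_dim != acam_cfg$input_size)) {
    acam_input_size <- acam_cfg$input_size
  }
  model <- list(mode = mode, fused = fused, texture = texture,
                acam_cfg = if (adaptive) acam_cfg else NULL,
                acam_input_size = acam_input_size,
                n_classes = as.integer(n_classes), cfg = cfg)

  state_bb <- adam_init(model$fused$backbone$layers)
  state_tex <- if (adaptive && !isTRUE(texture$frozen)) {
    adam_init(texture$layers)
  } else NULL

  train_idx <- split_indices(dataset, "train")
  test_idx <- split_indices(dataset, "test")
  if (length(train_idx) == 0) stop("empty training split", call. = FALSE)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), test_acc = numeric())
  for (epoch in seq_len(cfg$epochs)) {
    lr_t <- cfg$lr * if (epoch > 0.85 * cfg$epochs) 0.1 else
      if (epoch > 0.6 * cfg$epochs) 0.3 else 1
    order_idx <- with_seed(derive_seed(cfg$seed, 100 + epoch),
                           sample(train_idx))
    rcj_gains <- NULL
    if (mode == "rcj") {
      rcj_gains <- with_seed(derive_seed(cfg$seed, 500 + epoch),
                             stats::runif(length(order_idx),
                                          cfg$rcj_range[1],
                                          cfg$rcj_range[2]))
    }
    batches <- split(seq_along(order_idx),
                     ceiling(seq_along(order_idx) / cfg$batch_size))
    ep_loss <- 0; ep_correct <- 0
    for (batch in batches) {
      g_bb <- NULL; g_tex <- NULL
      for (pos in batch) {
        i <- order_idx[pos]
        img <- dataset$images[[i]]
        if (mode == "rcj") img <- apply_contrast(img, rcj_gains[pos])
        label <- dataset$manifest$class[i] + 1L
        sfw <- model_forward(img, model)
        ce <- softmax_ce(sfw$logits, label)
        ep_loss <- ep_loss + ce$loss
        ep_correct <- ep_correct + (which.max(sfw$logits) == label)
        gb <- model_backward(ce$dlogits, img, sfw, model)
        g_bb <- if (is.null(g_bb)) gb$backbone else
          add_grads(g_bb, gb$backbone)
        if (!is.null(gb$texture)) {
          g_tex <- if (is.null(g_tex)) gb$texture else
            add_grads(g_tex, gb$texture)
        }
      }
      nb <- length(batch)
      st <- adam_step(model$fused$backbone$layers,
                      scale_grads(g_bb, 1 / nb), state_bb, lr = lr_t)
      model$fused$backbone$layers <- st$params
      state_bb <- st$state
      if (!is.null(g_tex)) {
        st <- adam_step(model$texture$layers, scale_grads(g_tex, 1 / nb),
                        state_tex, lr = lr_t)
        model$texture$layers <- st$params
        state_tex <- st$state
      }
    }
    test_acc <- NA_real_
    if (cfg$eval_each_epoch && length(test_idx) > 0) {
      test_acc <- mean(vapply(test_idx, function(i) {
        lg <- model_forward(dataset$images[[i]], model)$logits
        (which.max(lg) - 1L) == dataset$manifest$class[i]
      }, logical(1)))
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / length(order_idx),
      train_acc = ep_correct / length(order_idx), test_acc = test_acc))
  }
  structure(list(mode = mode, fused = model$fused,
                 texture = model$texture,
                 acam_cfg = model$acam_cfg,
                 acam_input_size = acam_input_size,
                 n_classes = as.integer(n_classes),
                 cfg = cfg, history = history,
                 dataset_spec = dataset$spec),
            class = "acam_fit")
}

# Class-score matrix (softmax probabilities) for a set of images.
score_images <- function(fit, images) {
  t(vapply(images, function(img) {
    softmax_probs(model_forward(img, fit)$logits)
  }, numeric(fit$n_classes)))
}

#' Evaluate a fitted model on a dataset split
#'
#' Runs inference on every sample of the split and assembles the full
#' metrics report (confusion matrix, per-class precision/recall/F1, macro
#' and support-weighted aggregates, per-class one-vs-rest ROC/AUC and
#' PR/AP).
#'
#' @param fit an `acam_fit`.
#' @param dataset a `phantom_dataset`.
#' @param split `"test"` or `"train"`.
#' @return a `metrics_report`.
#' @export
evaluate <- function(fit, dataset, split = "test") {
  idx <- split_indices(dataset, split)
  if (length(idx) == 0) stop("empty evaluation split", call. = FALSE)
  scores <- score_images(fit, dataset$images[idx])
  metrics_report(dataset$manifest$class[idx], scores, fit$n_classes)
}
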