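# Minimal convolutional-network primitives with exact analytic gradients.
#
# Feature maps are H x W x C numeric arrays. Convolutions are implemented by
# im2col: a patch matrix (one row per output position) multiplied by a weight
# matrix of shape (k*k*C_in) x C_out. The backward pass is the exact adjoint
# (scatter-add of the patch-matrix gradient), so finite-difference checks
# agree with the analytic gradients to numerical precision.

.conv_idx_cache <- new.env(parent = emptyenv())

conv_im2col_idx <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  H_out <- (Hp - k) %/% stride + 1L
  W_out <- (Wp - k) %/% stride + 1L
  i_out <- rep(seq_len(H_out), times = W_out)
  j_out <- rep(seq_len(W_out), each = H_out)
  n_cols <- k * k * C
  idx <- matrix(0L, H_out * W_out, n_cols)
  col <- 0L
  for (c in seq_len(C)) {
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        col <- col + 1L
        h <- (i_out - 1L) * stride + di
        w <- (j_out - 1L) * stride + dj
        idx[, col] <- h + (w - 1L) * Hp + (c - 1L) * Hp * Wp
      }
    }
  }
  out <- list(idx = idx, H_out = H_out, W_out = W_out, Hp = Hp, Wp = Wp)
  .conv_idx_cache[[key]] <- out
  out
}

conv_forward <- function(x, W, b, stride = 2L, pad = 1L, k = 3L) {
  d <- dim(x)
  C <- if (length(d) == 2L) 1L else d[3]
  H <- d[1]; Wd <- d[2]
  geom <- conv_im2col_idx(H, Wd, C, k, stride, pad)
  xp <- array(0, dim = c(geom$Hp, geom$Wp, C))
  xp[pad + seq_len(H), pad + seq_len(Wd), ] <- x
  P <- matrix(xp[geom$idx], nrow(geom$idx), ncol(geom$idx))
  out_mat <- P %*% W + matrix(b, nrow(P), length(b), byrow = TRUE)
  out <- array(out_mat, dim = c(geom$H_out, geom$W_out, length(b)))
  list(out = out, cache = list(P = P, geom = geom, W = W, dims = c(H, Wd, C),
                               pad = pad))
}

conv_backward <- function(dout, cache) {
  geom <- cache$geom
  C_out <- dim(dout)[3]
  dout_mat <- matrix(dout, nrow(cache$P), C_out)
  dW <- crossprod(cache$P, dout_mat)
  db <- colSums(dout_mat)
  dP <- tcrossprod(dout_mat, cache$W)
  n_pad <- geom$Hp * geom$Wp * cache$dims[3]
  acc <- rowsum(c(dP), c(geom$idx))
  dxp <- numeric(n_pad)
  dxp[as.integer(rownames(acc))] <- acc
  dxp <- array(dxp, dim = c(geom$Hp, geom$Wp, cache$dims[3]))
  pad <- cache$pad
  dx <- dxp[pad + seq_len(cache$dims[1]), pad + seq_len(cache$dims[2]), ,
            drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# Pointwise nonlinearities. Rectification is essential on the texture
# branch: pooled rectified responses scale with local contrast magnitude,
# which a purely linear pooled feature cannot see. The texture branch uses
# softplus — a smooth rectifier, so the whole contrast path is C^infinity
# and finite-difference checks agree with the analytic gradients everywhere;
# the backbone uses plain ReLU.
softplus_forward <- function(x) {
  # overflow-safe: softplus(x) = x + log1p(exp(-x)) for large x
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}
softplus_backward <- function(dout, x) dout * stats::plogis(x)
relu_forward <- function(x) pmax(x, 0)
relu_backward <- function(dout, x) dout * (x > 0)

gap_forward <- function(x) {
  apply(x, 3, mean)
}
gap_backward <- function(dvec, dims) {
  n <- dims[1] * dims[2]
  array(rep(dvec / n, each = n), dim = dims)
}

fc_forward <- function(g, W, b) {
  as.vector(crossprod(W, g)) + b
}
fc_backward <- function(dy, g, W) {
  list(dW = outer(g, dy), db = dy, dg = as.vector(W %*% dy))
}

# Softmax cross-entropy with the log-sum-exp trick; returns the loss, the
# class probabilities and the logit gradient.
softmax_ce <- function(logits, label) {
  m <- max(logits)
  z <- exp(logits - m)
  p <- z / sum(z)
  loss <- -(logits[label] - m - log(sum(z)))
  dlogits <- p
  dlogits[label] <- dlogits[label] - 1
  list(loss = loss, prob = p, dlogits = dlogits)
}

softmax_probs <- function(logits) {
  m <- max(logits)
  z <- exp(logits - m)
  z / sum(z)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- function(x) {
    if (is.list(x)) lapply(x, zeros) else x * 0
  }
  list(m = zeros(params), v = zeros(params), t = 0L)
}

# One Adam update over a nested list of parameter arrays (weights only —
# callers pass the `$layers` sub-list, never metadata). `grads` mirrors the
# structure of `params`.
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      mh <- m2 / (1 - beta1^t)
      vh <- v2 / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
    }
  }
  r <- upd(params, grads, state$m, state$v)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}

# Total number of scalar parameters in a nested weight list.
count_params <- function(params) {
  n <- 0L
  walk <- function(x) {
    for (nm in names(x)) {
      el <- x[[nm]]
      if (is.list(el)) walk(el)
      else if (is.numeric(el) && nm %in% c("W", "b")) n <<- n + length(el)
    }
  }
  walk(params)
  n
}
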