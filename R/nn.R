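# Compact feed-forward network machinery: just enough to train the small
# 2D/3D conv nets used for candidate classification on a CPU. Convolutions
# are valid (no padding) and implemented as im2col matrix products; gradients
# are hand-derived and verified against numerical differentiation in the test
# suite. All tensors are R arrays with dim = c(spatial..., channels).

im2col_index <- function(in_dim, k) {
  nd <- length(in_dim)
  out_dim <- in_dim - k + 1L
  offs <- as.matrix(expand.grid(lapply(rep(k, nd), seq_len))) - 1L
  base <- as.matrix(expand.grid(lapply(out_dim, seq_len)))
  mult <- cumprod(c(1L, in_dim[-nd]))
  lin_base <- as.vector((base - 1L) %*% mult) + 1L
  lin_off <- as.vector(offs %*% mult)
  idx <- outer(lin_base, lin_off, "+")          # n_out x k^nd
  list(idx = idx, out_dim = out_dim, n_patch = ncol(idx))
}

nn_conv <- function(out_ch, k = 3L) {
  structure(list(type = "conv", out_ch = out_ch, k = k), class = "nn_layer")
}
nn_relu <- function() structure(list(type = "relu"), class = "nn_layer")
nn_pool <- function(s = 2L) structure(list(type = "pool", s = s),
                                      class = "nn_layer")
nn_flatten <- function() structure(list(type = "flatten"), class = "nn_layer")
nn_dense <- function(out_n) structure(list(type = "dense", out_n = out_n),
                                      class = "nn_layer")

# Initialize parameters and cache geometry for a fixed input shape
# (spatial dims + channel count).
nn_init <- function(layers, input_shape, seed = 1L) {
  with_seed(seed, {
    shape <- input_shape
    net <- list()
    for (L in layers) {
      l <- L
      if (L$type == "conv") {
        sp <- shape[-length(shape)]; ch <- shape[length(shape)]
        l$im <- im2col_index(sp, L$k)
        fan_in <- L$k^length(sp) * ch
        l$W <- matrix(stats::rnorm(fan_in * L$out_ch, 0,
                                   sqrt(2 / fan_in)), fan_in, L$out_ch)
        l$b <- numeric(L$out_ch)
        l$in_shape <- shape
        shape <- c(l$im$out_dim, L$out_ch)
      } else if (L$type == "pool") {
        sp <- shape[-length(shape)]; ch <- shape[length(shape)]
        l$in_shape <- shape
        shape <- c(sp %/% L$s, ch)
      } else if (L$type == "flatten") {
        l$in_shape <- shape
        shape <- prod(shape)
      } else if (L$type == "dense") {
        fan_in <- prod(shape)
        l$W <- matrix(stats::rnorm(fan_in * L$out_n, 0, sqrt(2 / fan_in)),
                      fan_in, L$out_n)
        l$b <- numeric(L$out_n)
        l$in_shape <- shape
        shape <- L$out_n
      } else l$in_shape <- shape
      net[[length(net) + 1L]] <- l
    }
    structure(list(layers = net, input_shape = input_shape,
                   output_n = shape), class = "nn_net")
  })
}

pool_index <- function(sp, ch, s) {
  out_sp <- sp %/% s
  nd <- length(sp)
  # linear indices of each pooling window, per output cell, one channel
  cell <- as.matrix(expand.grid(lapply(out_sp, function(n)
    seq(0, by = s, length.out = n))))
  offs <- as.matrix(expand.grid(lapply(rep(s, nd), seq_len))) - 1L
  mult <- cumprod(c(1L, sp[-nd]))
  outer(as.vector(cell %*% mult) + 1L, as.vector(offs %*% mult), "+")
}

nn_forward <- function(net, x, keep = FALSE) {
  acts <- list()
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    if (keep) acts[[li]] <- x
    if (l$type == "conv") {
      sp <- l$in_shape[-length(l$in_shape)]
      ch <- l$in_shape[length(l$in_shape)]
      xm <- matrix(x, ncol = ch)
      patches <- do.call(cbind, lapply(seq_len(ch), function(c)
        matrix(xm[, c][l$im$idx], nrow = nrow(l$im$idx))))
      y <- patches %*% l$W
      y <- sweep(y, 2, l$b, "+")
      if (keep) attr(acts[[li]], "patches") <- patches
      x <- array(y, dim = c(l$im$out_dim, l$out_ch))
    } else if (l$type == "relu") {
      x <- pmax(x, 0)
    } else if (l$type == "pool") {
      sp <- l$in_shape[-length(l$in_shape)]
      ch <- l$in_shape[length(l$in_shape)]
      pidx <- pool_index(sp, ch, l$s)
      xm <- matrix(x, ncol = ch)
      out_sp <- sp %/% l$s
      y <- matrix(0, nrow(pidx), ch)
      argm <- matrix(0L, nrow(pidx), ch)
      for (c in seq_len(ch)) {
        vals <- matrix(xm[, c][pidx], nrow = nrow(pidx))
        am <- max.col(vals, ties.method = "first")
        argm[, c] <- pidx[cbind(seq_len(nrow(pidx)), am)]
        y[, c] <- vals[cbind(seq_len(nrow(pidx)), am)]
      }
      if (keep) attr(acts[[li]], "argmax") <- argm
      x <- array(y, dim = c(out_sp, ch))
    } else if (l$type == "flatten") {
      x <- as.numeric(x)
    } else if (l$type == "dense") {
      x <- as.numeric(crossprod(l$W, as.numeric(x)) + l$b)
    }
  }
  if (keep) list(out = x, acts = acts) else x
}

# Returns gradient lists (same shape as parameters) given d(loss)/d(output).
nn_backward <- function(net, fw, dout) {
  grads <- vector("list", length(net$layers))
  dx <- dout
  for (li in rev(seq_along(net$layers))) {
    l <- net$layers[[li]]
    a <- fw$acts[[li]]
    if (l$type == "dense") {
      xin <- as.numeric(a)
      grads[[li]] <- list(W = outer(xin, as.numeric(dx)),
                          b = as.numeric(dx))
      dx <- as.numeric(l$W %*% as.numeric(dx))
      dim(dx) <- if (length(l$in_shape) > 1L) l$in_shape else NULL
    } else if (l$type == "flatten") {
      dim(dx) <- l$in_shape
    } else if (l$type == "relu") {
      dx <- dx * (a > 0)
    } else if (l$type == "pool") {
      ch <- l$in_shape[length(l$in_shape)]
      argm <- attr(a, "argmax")
      dnew <- array(0, dim = l$in_shape)
      dm <- matrix(dx, ncol = ch)
      nsp <- prod(l$in_shape[-length(l$in_shape)])
      for (c in seq_len(ch)) {
        col <- numeric(nsp)
        col[argm[, c]] <- col[argm[, c]] + dm[, c]
        dnew[(c - 1L) * nsp + seq_len(nsp)] <- col
      }
      dx <- dnew
    } else if (l$type == "conv") {
      ch <- l$in_shape[length(l$in_shape)]
      patches <- attr(a, "patches")
      dm <- matrix(dx, ncol = l$out_ch)
      grads[[li]] <- list(W = crossprod(patches, dm), b = colSums(dm))
      dpatch <- dm %*% t(l$W)                   # n_out x (k^nd * ch)
      npat <- l$im$n_patch
      nsp <- prod(l$in_shape[-length(l$in_shape)])
      dnew <- array(0, dim = l$in_shape)
      idxv <- as.vector(l$im$idx)
      for (c in seq_len(ch)) {
        dp <- as.vector(dpatch[, (c - 1L) * npat + seq_len(npat)])
        acc <- rowsum(dp, idxv)
        col <- numeric(nsp)
        col[as.integer(rownames(acc))] <- acc[, 1]
        dnew[(c - 1L) * nsp + seq_len(nsp)] <- col
      }
      dx <- dnew
    }
  }
  grads
}

# one momentum-SGD step with weight decay over an accumulated gradient
nn_sgd_step <- function(net, grads, state, lr, momentum, weight_decay) {
  for (li in seq_along(net$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    l <- net$layers[[li]]
    for (p in c("W", "b")) {
      wd <- if (p == "W") weight_decay else 0
      key <- paste0(li, p)
      v <- state[[key]]
      if (is.null(v)) v <- 0 * g[[p]]
      v <- momentum * v - lr * (g[[p]] + wd * l[[p]])
      state[[key]] <- v
      net$layers[[li]][[p]] <- l[[p]] + v
    }
  }
  list(net = net, state = state)
}

nn_zero_like <- function(grads1) grads1

nn_acc_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (li in seq_along(g)) {
    if (is.null(g[[li]])) next
    acc[[li]]$W <- acc[[li]]$W + g[[li]]$W
    acc[[li]]$b <- acc[[li]]$b + g[[li]]$b
  }
  acc
}

# binary cross-entropy on a single logistic output
nn_predict_prob <- function(net, x) stats::plogis(nn_forward(net, x)[1])

nn_train_batch <- function(net, xs, ys, state, lr, momentum, weight_decay) {
  acc <- NULL
  for (i in seq_along(xs)) {
    fw <- nn_forward(net, xs[[i]], keep = TRUE)
    p <- stats::plogis(fw$out[1])
    dout <- (p - ys[i]) / length(xs)              # d BCE / d logit, averaged
    acc <- nn_acc_grads(acc, nn_backward(net, fw, dout))
  }
  nn_sgd_step(net, acc, state, lr, momentum, weight_decay)
}
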