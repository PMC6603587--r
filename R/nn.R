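# Internal neural-network machinery: a small, fully deterministic,
# CPU-only implementation of 3x3 convolutions (valid or zero-padded
# "same"), 2x2 max pooling and dense layers, trained by mini-batch
# SGD with momentum.
#
# Activations are stored as n x (C*H*W) matrices, one sample per row,
# with flat feature index f = (c-1)*H*W + (y-1)*W + x (channel
# slowest, then row, then column). Convolutions run as im2col matrix
# products; the gather/scatter between the activation layout and the
# im2col layout is done by the compiled helpers im2col_gather() /
# col2im_scatter(), everything else is BLAS.

conv_maps <- function(cin, h, w, padding = "valid") {
  if (padding == "valid" && (h < 3L || w < 3L))
    abort_config("input too small for a valid 3x3 convolution")
  ho <- if (padding == "valid") h - 2L else h
  wo <- if (padding == "valid") w - 2L else w
  off <- if (padding == "valid") 1L else 0L
  hw <- ho * wo
  idx <- integer(hw * cin * 9L)
  j <- 0L
  for (y0 in seq_len(ho)) {
    for (x0 in seq_len(wo)) {
      for (ci in seq_len(cin)) {
        for (ky in -1:1) {
          for (kx in -1:1) {
            j <- j + 1L
            y <- y0 + off + ky; x <- x0 + off + kx
            idx[j] <- if (y < 1L || y > h || x < 1L || x > w) 0L
                      else (ci - 1L) * h * w + (y - 1L) * w + x
          }
        }
      }
    }
  }
  list(idx = idx, hw = hw, cin9 = cin * 9L, ho = ho, wo = wo,
       f_in = cin * h * w)
}

pool_maps <- function(ch, h, w) {
  ho <- ceiling(h / 2); wo <- ceiling(w / 2)
  m <- ch * ho * wo
  src <- matrix(NA_integer_, 4L, m)
  fo <- 0L
  for (c0 in seq_len(ch)) {
    for (yo in seq_len(ho)) {
      for (xo in seq_len(wo)) {
        fo <- fo + 1L
        k <- 0L
        for (dy in 0:1) {
          for (dx in 0:1) {
            k <- k + 1L
            y <- 2L * yo - 1L + dy; x <- 2L * xo - 1L + dx
            if (y <= h && x <= w)
              src[k, fo] <- (c0 - 1L) * h * w + (y - 1L) * w + x
          }
        }
      }
    }
  }
  list(src = src, ho = ho, wo = wo, m = m)
}

# ---- layer constructors (called at build time, under the model seed)

nn_init_layers <- function(spec, input_shape, class_count) {
  shape <- input_shape   # c(channels, h, w) or c(features) once flat
  layers <- list()
  for (li in seq_along(spec)) {
    ls <- spec[[li]]
    if (ls$type == "conv") {
      if (length(shape) != 3L)
        abort_config("conv layer after flattening is not supported")
      if (!is.null(ls$size) && ls$size != 3L)
        abort_config("only 3x3 convolutions are supported")
      padding <- if (is.null(ls$padding)) "valid" else ls$padding
      if (!padding %in% c("valid", "same"))
        abort_config("conv padding must be 'valid' or 'same'")
      maps <- conv_maps(shape[1], shape[2], shape[3], padding)
      fan_in <- shape[1] * 9L
      layers[[li]] <- list(
        type = "conv", maps = maps, cout = ls$filters,
        in_shape = shape,
        W = matrix(rnorm(fan_in * ls$filters, sd = sqrt(2 / fan_in)),
                   fan_in, ls$filters),
        b = numeric(ls$filters))
      shape <- c(ls$filters, maps$ho, maps$wo)
    } else if (ls$type == "pool") {
      if (length(shape) != 3L)
        abort_config("pool layer after flattening is not supported")
      if (!is.null(ls$size) && ls$size != 2L)
        abort_config("only 2x2 max pooling is supported")
      maps <- pool_maps(shape[1], shape[2], shape[3])
      layers[[li]] <- list(type = "pool", maps = maps, in_shape = shape)
      shape <- c(shape[1], maps$ho, maps$wo)
    } else if (ls$type == "fc") {
      din <- prod(shape)
      layers[[li]] <- list(
        type = "fc", din = din, dout = ls$units,
        W = matrix(rnorm(din * ls$units, sd = sqrt(2 / din)),
                   din, ls$units),
        b = numeric(ls$units))
      shape <- ls$units
    } else abort_config(sprintf("unknown layer type '%s'", ls$type))
    layers[[li]]$activation <-
      if (li == length(spec)) "linear"
      else if (spec[[li]]$type == "pool") "none" else "relu"
  }
  if (tail(shape, 1) != class_count)
    abort_config(sprintf("final layer must output %d scores", class_count))
  layers
}

nn_param_count <- function(layers) {
  sum(vapply(layers, function(l)
    if (is.null(l$W)) 0L else length(l$W) + length(l$b), numeric(1)))
}

# ---- forward / backward -------------------------------------------------

nn_forward <- function(layers, X, want_cache = FALSE) {
  n <- nrow(X)
  caches <- if (want_cache) vector("list", length(layers)) else NULL
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (l$type == "conv") {
      mp <- l$maps
      B <- im2col_gather(X, mp$idx, mp$hw)
      Z <- B %*% l$W
      Z <- Z + rep(l$b, each = n * mp$hw)
      dim(Z) <- c(n, mp$hw * l$cout)
      if (l$activation == "relu") {
        Y <- Z * (Z > 0)
      } else Y <- Z
      if (want_cache) caches[[li]] <- list(B = B, Z = Z, X = X)
      X <- Y
    } else if (l$type == "pool") {
      mp <- l$maps
      Y <- matrix(-Inf, n, mp$m)
      Arg <- matrix(0L, n, mp$m)
      for (k in 1:4) {
        vc <- which(!is.na(mp$src[k, ]))
        if (!length(vc)) next
        Xk <- X[, mp$src[k, vc], drop = FALSE]
        Ys <- Y[, vc, drop = FALSE]
        sel <- Xk > Ys
        if (any(sel)) {
          Ys[sel] <- Xk[sel]
          As <- Arg[, vc, drop = FALSE]
          As[sel] <- k
          Arg[, vc] <- As
          Y[, vc] <- Ys
        }
      }
      if (want_cache) caches[[li]] <- list(Arg = Arg, in_ncol = ncol(X))
      X <- Y
    } else {                                  # fc
      Z <- X %*% l$W
      Z <- Z + rep(l$b, each = n)
      Yl <- if (l$activation == "relu") Z * (Z > 0) else Z
      if (want_cache) caches[[li]] <- list(X = X, Z = Z)
      X <- Yl
    }
  }
  list(out = X, caches = caches)
}

nn_backward <- function(layers, caches, dY) {
  n <- nrow(dY)
  grads <- vector("list", length(layers))
  for (li in rev(seq_along(layers))) {
    l <- layers[[li]]
    ch <- caches[[li]]
    if (l$type == "conv") {
      if (l$activation == "relu") dY <- dY * (ch$Z > 0)
      mp <- l$maps
      dOut <- dY
      dim(dOut) <- c(n * mp$hw, l$cout)
      gW <- crossprod(ch$B, dOut)
      gb <- colSums(dOut)
      dcols <- tcrossprod(dOut, l$W)          # (n*hw) x cin9
      dY <- col2im_scatter(dcols, mp$idx, n, mp$f_in)
      grads[[li]] <- list(W = gW, b = gb)
    } else if (l$type == "pool") {
      mp <- l$maps
      dX <- matrix(0, n, ch$in_ncol)
      for (k in 1:4) {
        vc <- which(!is.na(mp$src[k, ]))
        if (!length(vc)) next
        As <- ch$Arg[, vc, drop = FALSE]
        pos <- which(As == k)
        if (!length(pos)) next
        rows <- ((pos - 1L) %% n) + 1L
        ci <- ((pos - 1L) %/% n) + 1L
        dOs <- dY[, vc, drop = FALSE]
        dX[cbind(rows, mp$src[k, vc[ci]])] <- dOs[pos]
      }
      dY <- dX
      grads[[li]] <- list()
    } else {
      if (l$activation == "relu") dY <- dY * (ch$Z > 0)
      grads[[li]] <- list(W = crossprod(ch$X, dY), b = colSums(dY))
      dY <- tcrossprod(dY, l$W)
    }
  }
  grads
}

nn_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# One SGD-with-momentum step, in place on the layer list.
nn_sgd_step <- function(layers, grads, vel, lr, mu) {
  for (li in seq_along(layers)) {
    if (is.null(layers[[li]]$W)) next
    vel[[li]]$W <- mu * vel[[li]]$W - lr * grads[[li]]$W
    vel[[li]]$b <- mu * vel[[li]]$b - lr * grads[[li]]$b
    layers[[li]]$W <- layers[[li]]$W + vel[[li]]$W
    layers[[li]]$b <- layers[[li]]$b + vel[[li]]$b
  }
  list(layers = layers, vel = vel)
}
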