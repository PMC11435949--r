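## Minimal layer framework for the ResTCN: each layer is an environment with
## `params`/`grads` (named lists of arrays), `forward(x, train)` and
## `backward(dout)`. Composite layers expose `children`. Convolutions are
## im2col + GEMM; gradients are exact (verified by finite differences in the
## test suite). All tensors are column-major R arrays:
##   2-D feature maps: (C, H, W, B)  [channels, range, time, batch]
##   sequences:        (C, T, B)
##   vectors:          (C, B)

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  e$children <- list()
  e
}

## He-normal initialisation (draws from the caller's RNG stream)
he_init <- function(n_out, fan_in) {
  matrix(stats::rnorm(n_out * fan_in, sd = sqrt(2 / fan_in)), n_out, fan_in)
}

## ---- conv2d -----------------------------------------------------------

layer_conv2d <- function(c_in, c_out, kernel = c(3L, 3L), stride = c(1L, 1L),
                         pad = c(1L, 1L)) {
  self <- new_layer("conv2d")
  self$c_in <- c_in; self$c_out <- c_out
  self$kernel <- as.integer(kernel); self$stride <- as.integer(stride)
  self$pad <- as.integer(pad)
  self$params$W <- he_init(c_out, c_in * prod(kernel))
  self$params$b <- numeric(c_out)

  self$forward <- function(x, train = FALSE) {
    d <- dim(x)
    k <- self$kernel; st <- self$stride; pd <- self$pad
    Hout <- (d[2L] + 2L * pd[1L] - k[1L]) %/% st[1L] + 1L
    Wout <- (d[3L] + 2L * pd[2L] - k[2L]) %/% st[2L] + 1L
    cols <- cpp_im2col2d(x, d[1L], d[2L], d[3L], d[4L],
                         k[1L], k[2L], st[1L], st[2L], pd[1L], pd[2L])
    self$cache <- list(cols = cols, dims = d)
    out <- self$params$W %*% cols + self$params$b
    dim(out) <- c(self$c_out, Hout, Wout, d[4L])
    out
  }

  self$backward <- function(dout) {
    ca <- self$cache
    d <- ca$dims
    k <- self$kernel; st <- self$stride; pd <- self$pad
    dmat <- dout
    dim(dmat) <- c(self$c_out, length(dout) %/% self$c_out)
    self$grads$W <- tcrossprod(dmat, ca$cols)
    self$grads$b <- rowSums(dmat)
    dcols <- crossprod(self$params$W, dmat)
    dx <- cpp_col2im2d(dcols, d[1L], d[2L], d[3L], d[4L],
                       k[1L], k[2L], st[1L], st[2L], pd[1L], pd[2L])
    dim(dx) <- d
    self$cache <- NULL
    dx
  }
  self
}

## ---- causal dilated conv1d -------------------------------------------

layer_conv1d <- function(c_in, c_out, kernel = 3L, dilation = 1L) {
  self <- new_layer("conv1d")
  self$c_in <- c_in; self$c_out <- c_out
  self$kernel <- as.integer(kernel); self$dilation <- as.integer(dilation)
  self$params$W <- he_init(c_out, c_in * kernel)
  self$params$b <- numeric(c_out)

  self$forward <- function(x, train = FALSE) {
    d <- dim(x)
    cols <- cpp_im2col1d(x, d[1L], d[2L], d[3L], self$kernel, self$dilation)
    self$cache <- list(cols = cols, dims = d)
    out <- self$params$W %*% cols + self$params$b
    dim(out) <- c(self$c_out, d[2L], d[3L])
    out
  }

  self$backward <- function(dout) {
    ca <- self$cache
    d <- ca$dims
    dmat <- dout
    dim(dmat) <- c(self$c_out, length(dout) %/% self$c_out)
    self$grads$W <- tcrossprod(dmat, ca$cols)
    self$grads$b <- rowSums(dmat)
    dcols <- crossprod(self$params$W, dmat)
    dx <- cpp_col2im1d(dcols, d[1L], d[2L], d[3L], self$kernel, self$dilation)
    dim(dx) <- d
    self$cache <- NULL
    dx
  }
  self
}

## ---- batch normalisation ---------------------------------------------

## channel-wise batch normalisation over all non-channel axes (channel is the
## first axis of every tensor layout here); running statistics for eval mode
layer_batchnorm <- function(c_in, momentum = 0.1, eps = 1e-5) {
  self <- new_layer("batchnorm")
  self$params$gamma <- rep(1, c_in)
  self$params$beta <- rep(0, c_in)
  self$run_mean <- rep(0, c_in)
  self$run_var <- rep(1, c_in)
  self$momentum <- momentum
  self$eps <- eps

  self$forward <- function(x, train = FALSE) {
    d <- dim(x)
    C <- d[1L]
    xm <- x
    dim(xm) <- c(C, length(x) %/% C)
    if (train) {
      mu <- rowMeans(xm)
      xc <- xm - mu
      v <- rowMeans(xc * xc)
      self$run_mean <- (1 - self$momentum) * self$run_mean + self$momentum * mu
      self$run_var <- (1 - self$momentum) * self$run_var + self$momentum * v
    } else {
      mu <- self$run_mean
      v <- self$run_var
      xc <- xm - mu
    }
    inv <- 1 / sqrt(v + self$eps)
    xhat <- xc * inv
    y <- xhat * self$params$gamma + self$params$beta
    if (train) self$cache <- list(xhat = xhat, inv = inv, dims = d)
    dim(y) <- d
    y
  }

  self$backward <- function(dout) {
    ca <- self$cache
    d <- ca$dims
    C <- d[1L]
    n <- length(dout) %/% C
    dm <- dout
    dim(dm) <- c(C, n)
    self$grads$gamma <- rowSums(dm * ca$xhat)
    self$grads$beta <- rowSums(dm)
    dxhat <- dm * self$params$gamma
    ## dx = inv/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
    dx <- (ca$inv / n) *
      (n * dxhat - rowSums(dxhat) - ca$xhat * rowSums(dxhat * ca$xhat))
    dim(dx) <- d
    self$cache <- NULL
    dx
  }
  self
}

## ---- parameter-free layers -------------------------------------------

layer_relu <- function() {
  self <- new_layer("relu")
  self$forward <- function(x, train = FALSE) {
    self$cache <- x > 0
    x * self$cache
  }
  self$backward <- function(dout) {
    dx <- dout * self$cache
    self$cache <- NULL
    dx
  }
  self
}

layer_dropout <- function(p) {
  self <- new_layer("dropout")
  self$p <- p
  self$forward <- function(x, train = FALSE) {
    if (!train || self$p <= 0) {
      self$cache <- NULL
      return(x)
    }
    mask <- array((stats::runif(length(x)) >= self$p) / (1 - self$p), dim(x))
    self$cache <- mask
    x * mask
  }
  self$backward <- function(dout) {
    if (is.null(self$cache)) return(dout)
    dx <- dout * self$cache
    self$cache <- NULL
    dx
  }
  self
}

## replicate a 1-channel (H, W, B) image to 3 channels (3, H, W, B)
layer_clone3 <- function() {
  self <- new_layer("clone3")
  self$forward <- function(x, train = FALSE) {
    d <- dim(x)
    self$cache <- d
    aperm(array(x, c(d, 3L)), c(4L, 1L, 2L, 3L))
  }
  self$backward <- function(dout) {
    d <- self$cache
    self$cache <- NULL
    array(colSums(matrix(dout, nrow = 3L)), d)
  }
  self
}

## average pool along the time axis (3rd of (C,H,W,B)) by integer factor
layer_tpool <- function(factor) {
  self <- new_layer("tpool")
  self$factor <- as.integer(factor)
  self$forward <- function(x, train = FALSE) {
    f <- self$factor
    d <- dim(x); Tout <- d[3L] %/% f
    y <- array(0, c(d[1L], d[2L], Tout, d[4L]))
    for (b in seq_len(f)) {
      y <- y + x[, , seq.int(b, Tout * f, by = f), , drop = FALSE]
    }
    self$cache <- d
    y / f
  }
  self$backward <- function(dout) {
    f <- self$factor
    d <- self$cache; Tout <- dim(dout)[3L]
    dx <- array(0, d)
    g <- dout / f
    for (b in seq_len(f)) dx[, , seq.int(b, Tout * f, by = f), ] <- g
    self$cache <- NULL
    dx
  }
  self
}

## collapse the range axis by mean: (C,H,T,B) -> (C,T,B)
layer_range_mean <- function() {
  self <- new_layer("range_mean")
  self$forward <- function(x, train = FALSE) {
    d <- dim(x)
    self$cache <- d
    y <- array(0, c(d[1L], d[3L], d[4L]))
    for (h in seq_len(d[2L])) {
      y <- y + array(x[, h, , , drop = FALSE], c(d[1L], d[3L], d[4L]))
    }
    y / d[2L]
  }
  self$backward <- function(dout) {
    d <- self$cache
    self$cache <- NULL
    dx <- array(0, d)
    g <- dout / d[2L]
    for (h in seq_len(d[2L])) dx[, h, , ] <- g
    dx
  }
  self
}

## global mean over time: (C,T,B) -> (C,B)
layer_time_mean <- function() {
  self <- new_layer("time_mean")
  self$forward <- function(x, train = FALSE) {
    d <- dim(x)
    self$cache <- d
    y <- matrix(0, d[1L], d[3L])
    for (t in seq_len(d[2L])) y <- y + matrix(x[, t, ], d[1L], d[3L])
    y / d[2L]
  }
  self$backward <- function(dout) {
    d <- self$cache
    self$cache <- NULL
    dx <- array(0, d)
    g <- dout / d[2L]
    for (t in seq_len(d[2L])) dx[, t, ] <- g
    dx
  }
  self
}

## take the last time step: (C,T,B) -> (C,B)
layer_last_step <- function() {
  self <- new_layer("last_step")
  self$forward <- function(x, train = FALSE) {
    d <- dim(x)
    self$cache <- d
    matrix(x[, d[2L], ], d[1L], d[3L])
  }
  self$backward <- function(dout) {
    d <- self$cache
    self$cache <- NULL
    dx <- array(0, d)
    dx[, d[2L], ] <- dout
    dx
  }
  self
}

layer_linear <- function(c_in, c_out) {
  self <- new_layer("linear")
  self$params$W <- he_init(c_out, c_in)
  self$params$b <- numeric(c_out)
  self$forward <- function(x, train = FALSE) {
    self$cache <- x
    self$params$W %*% x + self$params$b
  }
  self$backward <- function(dout) {
    self$grads$W <- tcrossprod(dout, self$cache)
    self$grads$b <- rowSums(dout)
    self$cache <- NULL
    crossprod(self$params$W, dout)
  }
  self
}

## ---- composite blocks -------------------------------------------------

## residual 2-D block, canonical conv-BN-relu form:
## conv(3x3, range stride s) -> BN -> relu -> conv(3x3) -> BN, plus a 1x1
## strided conv + BN shortcut when the shape changes; relu after the sum
layer_res2d <- function(c_in, c_out, stride_h = 2L) {
  self <- new_layer("res2d")
  conv1 <- layer_conv2d(c_in, c_out, stride = c(stride_h, 1L))
  bn1 <- layer_batchnorm(c_out)
  conv2 <- layer_conv2d(c_out, c_out)
  bn2 <- layer_batchnorm(c_out)
  proj <- if (c_in != c_out || stride_h != 1L) {
    layer_conv2d(c_in, c_out, kernel = c(1L, 1L), stride = c(stride_h, 1L),
                 pad = c(0L, 0L))
  } else NULL
  bnp <- if (!is.null(proj)) layer_batchnorm(c_out) else NULL
  relu1 <- layer_relu()
  self$children <- c(list(conv1 = conv1, bn1 = bn1, conv2 = conv2, bn2 = bn2),
                     if (!is.null(proj)) list(proj = proj, bnp = bnp))
  self$forward <- function(x, train = FALSE) {
    h <- conv1$forward(x, train)
    h <- relu1$forward(bn1$forward(h, train), train)
    h <- bn2$forward(conv2$forward(h, train), train)
    sc <- if (is.null(proj)) x else bnp$forward(proj$forward(x, train), train)
    y <- h + sc
    self$cache <- y > 0
    y * self$cache
  }
  self$backward <- function(dout) {
    d <- dout * self$cache
    self$cache <- NULL
    dh <- conv2$backward(bn2$backward(d))
    dh <- conv1$backward(bn1$backward(relu1$backward(dh)))
    dx_sc <- if (is.null(proj)) d else proj$backward(bnp$backward(d))
    dh + dx_sc
  }
  self
}

## causal temporal residual block (canonical form, no normalisation): two
## dilated causal convolutions, each followed by relu + dropout, plus a 1x1
## downsample shortcut when the channel count changes; relu after the sum
layer_tcn_block <- function(c_in, c_out, kernel = 3L, dilation = 1L,
                            dropout = 0.1) {
  self <- new_layer("tcn_block")
  conv1 <- layer_conv1d(c_in, c_out, kernel, dilation)
  conv2 <- layer_conv1d(c_out, c_out, kernel, dilation)
  down <- if (c_in != c_out) layer_conv1d(c_in, c_out, kernel = 1L) else NULL
  relu1 <- layer_relu(); relu2 <- layer_relu()
  drop1 <- layer_dropout(dropout); drop2 <- layer_dropout(dropout)
  self$children <- c(list(conv1 = conv1, conv2 = conv2),
                     if (!is.null(down)) list(down = down))
  self$forward <- function(x, train = FALSE) {
    h <- drop1$forward(relu1$forward(conv1$forward(x, train), train), train)
    h <- drop2$forward(relu2$forward(conv2$forward(h, train), train), train)
    sc <- if (is.null(down)) x else down$forward(x, train)
    y <- h + sc
    self$cache <- y > 0
    y * self$cache
  }
  self$backward <- function(dout) {
    d <- dout * self$cache
    self$cache <- NULL
    dh <- conv2$backward(relu2$backward(drop2$backward(d)))
    dh <- conv1$backward(relu1$backward(drop1$backward(dh)))
    dsc <- if (is.null(down)) d else down$backward(d)
    dh + dsc
  }
  self
}

## ---- traversal --------------------------------------------------------

## flatten a layer list into the primitive layers that own parameters/state
collect_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (length(l$children) > 0L) {
      out <- c(out, collect_layers(l$children))
    } else {
      out <- c(out, list(l))
    }
  }
  out
}
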