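# Minimal CNN engine: 1D/2D convolution ("same"-style padding), max
# pooling, dense layers, softmax cross-entropy and Adam, implemented on
# base-R arrays with im2col so the inner products run through BLAS.
# Shapes: 1D activations are (channels, width, batch) arrays, 2D
# activations (channels, height, width, batch); dense activations are
# (features x batch) matrices.  All geometry (patch index maps) is
# precomputed at build time for a fixed input shape.

conv_out_width <- function(w, stride) as.integer(ceiling(w / stride))
pool_out_width <- function(w) as.integer(floor(w / 2))

geom1d <- function(cin, W, k, stride) {
  Wout <- conv_out_width(W, stride)
  pad <- max((Wout - 1L) * stride + k - W, 0L)
  pl <- pad %/% 2L
  Wp <- W + pad
  list(kind = "1d", cin = cin, k = k, stride = as.integer(stride),
       W = W, Wout = Wout, pl = pl, pr = pad - pl, Wp = Wp,
       per = cin * Wp, patch = cin * k, nout = Wout)
}

geom2d <- function(cin, H, W, kh, kw, stride = 1L) {
  Hout <- conv_out_width(H, stride); Wout <- conv_out_width(W, stride)
  padh <- max((Hout - 1L) * stride + kh - H, 0L)
  padw <- max((Wout - 1L) * stride + kw - W, 0L)
  pt <- padh %/% 2L; pl <- padw %/% 2L
  Hp <- H + padh; Wp <- W + padw
  list(kind = "2d", cin = cin, kh = kh, kw = kw,
       stride = as.integer(stride), H = H, W = W, Hout = Hout,
       Wout = Wout, pt = pt, pb = padh - pt, pl = pl, pr = padw - pl,
       Hp = Hp, Wp = Wp, per = cin * Hp * Wp, patch = cin * kh * kw,
       nout = Hout * Wout)
}

# patch-matrix extraction / accumulation via per-tap strided slices: one
# vectorized copy per kernel tap instead of a scattered index gather, which
# keeps both directions allocation-light.
im2col <- function(xp, g, B) {
  cols <- matrix(0, g$patch, g$nout * B)
  if (g$kind == "1d") {
    cin <- g$cin
    for (t in seq_len(g$k)) {
      sub <- xp[, (seq_len(g$Wout) - 1L) * g$stride + t, , drop = FALSE]
      cols[(t - 1L) * cin + seq_len(cin), ] <- matrix(sub, nrow = cin)
    }
  } else {
    cin <- g$cin
    hi <- (seq_len(g$Hout) - 1L) * g$stride
    wi <- (seq_len(g$Wout) - 1L) * g$stride
    for (tw in seq_len(g$kw)) {
      for (th in seq_len(g$kh)) {
        sub <- xp[, hi + th, wi + tw, , drop = FALSE]
        rows <- ((tw - 1L) * g$kh + th - 1L) * cin + seq_len(cin)
        cols[rows, ] <- matrix(sub, nrow = cin)
      }
    }
  }
  cols
}

col2im <- function(dcols, g, B) {
  cin <- g$cin
  if (g$kind == "1d") {
    dxp <- array(0, c(cin, g$Wp, B))
    dc <- array(dcols, c(cin, g$k, g$Wout, B))
    for (t in seq_len(g$k)) {
      at <- (seq_len(g$Wout) - 1L) * g$stride + t
      dxp[, at, ] <- dxp[, at, , drop = FALSE] +
        array(dc[, t, , , drop = FALSE], c(cin, g$Wout, B))
    }
    dxp
  } else {
    dxp <- array(0, c(cin, g$Hp, g$Wp, B))
    dc <- array(dcols, c(cin, g$kh, g$kw, g$Hout, g$Wout, B))
    hi <- (seq_len(g$Hout) - 1L) * g$stride
    wi <- (seq_len(g$Wout) - 1L) * g$stride
    for (tw in seq_len(g$kw)) {
      for (th in seq_len(g$kh)) {
        dxp[, hi + th, wi + tw, ] <-
          dxp[, hi + th, wi + tw, , drop = FALSE] +
          array(dc[, th, tw, , , , drop = FALSE],
                c(cin, g$Hout, g$Wout, B))
      }
    }
    dxp
  }
}

pad_activation <- function(x, g) {
  d <- dim(x)
  if (g$kind == "1d") {
    if (g$pl + g$pr == 0L) return(x)
    xp <- array(0, c(d[1L], g$Wp, d[3L]))
    xp[, g$pl + seq_len(d[2L]), ] <- x
    xp
  } else {
    if (g$pt + g$pb + g$pl + g$pr == 0L) return(x)
    xp <- array(0, c(d[1L], g$Hp, g$Wp, d[4L]))
    xp[, g$pt + seq_len(d[2L]), g$pl + seq_len(d[3L]), ] <- x
    xp
  }
}

unpad_gradient <- function(dxp, g, B) {
  if (g$kind == "1d") {
    dxp <- array(dxp, c(g$per / g$Wp, g$Wp, B))
    dxp[, g$pl + seq_len(g$W), , drop = FALSE]
  } else {
    cin <- g$per / (g$Hp * g$Wp)
    dxp <- array(dxp, c(cin, g$Hp, g$Wp, B))
    dxp[, g$pt + seq_len(g$H), g$pl + seq_len(g$W), , drop = FALSE]
  }
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

layer_conv <- function(g, cout) {
  list(type = "conv", geom = g, cout = cout,
       W = he_init(cout, g$patch, g$patch), b = numeric(cout))
}
layer_relu <- function() list(type = "relu")
layer_pool <- function(ndim) list(type = if (ndim == 1L) "pool1d" else
                                    "pool2d")
layer_flatten <- function() list(type = "flatten")
layer_dense <- function(fin, fout) {
  list(type = "dense", W = he_init(fout, fin, fin), b = numeric(fout))
}

batch_of <- function(x) {
  d <- dim(x)
  d[length(d)]
}

layer_forward <- function(ly, x) {
  switch(ly$type,
    conv = {
      g <- ly$geom
      B <- batch_of(x)
      xp <- pad_activation(x, g)
      cols <- im2col(xp, g, B)
      y <- ly$W %*% cols + ly$b
      out <- if (g$kind == "1d") array(y, c(ly$cout, g$Wout, B))
             else array(y, c(ly$cout, g$Hout, g$Wout, B))
      list(out = out, cache = list(cols = cols, B = B))
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = mask)
    },
    pool1d = {
      d <- dim(x); Wout <- d[2L] %/% 2L
      a1 <- x[, 2L * seq_len(Wout) - 1L, , drop = FALSE]
      a2 <- x[, 2L * seq_len(Wout), , drop = FALSE]
      m <- a1 >= a2
      list(out = a1 * m + a2 * !m, cache = list(m = m, d = d))
    },
    pool2d = {
      d <- dim(x); Hout <- d[2L] %/% 2L; Wout <- d[3L] %/% 2L
      hi <- 2L * seq_len(Hout); wi <- 2L * seq_len(Wout)
      cand <- list(x[, hi - 1L, wi - 1L, , drop = FALSE],
                   x[, hi, wi - 1L, , drop = FALSE],
                   x[, hi - 1L, wi, , drop = FALSE],
                   x[, hi, wi, , drop = FALSE])
      best <- cand[[1L]]
      which <- array(1L, dim(best))
      for (i in 2:4) {
        sel <- cand[[i]] > best
        best[sel] <- cand[[i]][sel]
        which[sel] <- i
      }
      list(out = best, cache = list(which = which, d = d))
    },
    flatten = list(out = matrix(x, ncol = batch_of(x)), cache = dim(x)),
    dense = list(out = ly$W %*% x + ly$b, cache = x),
    stop_fmt("unknown layer type %s", ly$type))
}

layer_backward <- function(ly, cache, dout) {
  switch(ly$type,
    conv = {
      g <- ly$geom
      B <- cache$B
      dY <- matrix(dout, nrow = ly$cout)
      dW <- dY %*% t(cache$cols)
      db <- rowSums(dY)
      dcols <- crossprod(ly$W, dY)
      list(dx = unpad_gradient(col2im(dcols, g, B), g, B),
           grads = list(W = dW, b = db))
    },
    relu = list(dx = dout * cache, grads = NULL),
    pool1d = {
      m <- cache$m; d <- cache$d
      dx <- array(0, d)
      Wout <- dim(m)[2L]
      dx[, 2L * seq_len(Wout) - 1L, ] <- dout * m
      dx[, 2L * seq_len(Wout), ] <- dout * !m
      list(dx = dx, grads = NULL)
    },
    pool2d = {
      wch <- cache$which; d <- cache$d
      dx <- array(0, d)
      Hout <- dim(wch)[2L]; Wout <- dim(wch)[3L]
      hi <- 2L * seq_len(Hout); wi <- 2L * seq_len(Wout)
      dx[, hi - 1L, wi - 1L, ] <- dout * (wch == 1L)
      dx[, hi, wi - 1L, ] <- dout * (wch == 2L)
      dx[, hi - 1L, wi, ] <- dout * (wch == 3L)
      dx[, hi, wi, ] <- dout * (wch == 4L)
      list(dx = dx, grads = NULL)
    },
    flatten = list(dx = array(dout, cache), grads = NULL),
    dense = list(dx = crossprod(ly$W, dout),
                 grads = list(W = dout %*% t(cache), b = rowSums(dout))),
    stop_fmt("unknown layer type %s", ly$type))
}

seq_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    st <- layer_forward(layers[[i]], x)
    x <- st$out
    caches[[i]] <- st$cache
  }
  list(out = x, caches = caches)
}

seq_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    st <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- st$dx
    grads[i] <- list(st$grads)  # keep NULL placeholders for paramless layers
  }
  list(dx = dout, grads = grads)
}

# ---- whole-network interface -------------------------------------------

nn_forward <- function(net, x) {
  if (inherits(net, "nn_late")) {
    tr <- seq_forward(net$trunk, x$img)
    au <- seq_forward(net$aux, x$dist)
    joint <- rbind(tr$out, au$out)
    hd <- seq_forward(net$head, joint)
    list(out = hd$out,
         caches = list(trunk = tr$caches, aux = au$caches,
                       head = hd$caches, nt = nrow(tr$out)))
  } else {
    seq_forward(net$layers, x)
  }
}

nn_backward <- function(net, caches, dout) {
  if (inherits(net, "nn_late")) {
    hd <- seq_backward(net$head, caches$head, dout)
    nt <- caches$nt
    tr <- seq_backward(net$trunk, caches$trunk,
                       hd$dx[seq_len(nt), , drop = FALSE])
    au <- seq_backward(net$aux, caches$aux,
                       hd$dx[-seq_len(nt), , drop = FALSE])
    list(trunk = tr$grads, aux = au$grads, head = hd$grads)
  } else {
    seq_backward(net$layers, caches, dout)$grads
  }
}

# Flat named parameter list (and its inverse), used by Adam and checkpoints.
nn_params <- function(net) {
  grab <- function(layers, prefix) {
    out <- list()
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      if (!is.null(ly$W)) {
        out[[sprintf("%s%d.W", prefix, i)]] <- ly$W
        out[[sprintf("%s%d.b", prefix, i)]] <- ly$b
      }
    }
    out
  }
  if (inherits(net, "nn_late"))
    c(grab(net$trunk, "trunk."), grab(net$aux, "aux."),
      grab(net$head, "head."))
  else grab(net$layers, "L")
}

nn_set_params <- function(net, params) {
  put <- function(layers, prefix) {
    for (i in seq_along(layers)) {
      wk <- sprintf("%s%d.W", prefix, i)
      if (!is.null(params[[wk]])) {
        layers[[i]]$W <- params[[wk]]
        layers[[i]]$b <- params[[sprintf("%s%d.b", prefix, i)]]
      }
    }
    layers
  }
  if (inherits(net, "nn_late")) {
    net$trunk <- put(net$trunk, "trunk.")
    net$aux <- put(net$aux, "aux.")
    net$head <- put(net$head, "head.")
  } else {
    net$layers <- put(net$layers, "L")
  }
  net
}

grads_flat <- function(net, grads) {
  grab <- function(glist, prefix) {
    out <- list()
    for (i in seq_along(glist)) {
      if (!is.null(glist[[i]])) {
        out[[sprintf("%s%d.W", prefix, i)]] <- glist[[i]]$W
        out[[sprintf("%s%d.b", prefix, i)]] <- glist[[i]]$b
      }
    }
    out
  }
  if (inherits(net, "nn_late"))
    c(grab(grads$trunk, "trunk."), grab(grads$aux, "aux."),
      grab(grads$head, "head."))
  else grab(grads, "L")
}

# ---- loss and optimizer -------------------------------------------------

# logits: 2 x B; y: 0/1 integer vector (1 = sweep class)
softmax_xent <- function(logits, y) {
  B <- ncol(logits)
  m <- pmax(logits[1L, ], logits[2L, ])
  e <- exp(logits - rep(m, each = 2L))
  p <- e / rep(colSums(e), each = 2L)
  picked <- p[cbind(y + 1L, seq_len(B))]
  dl <- p
  dl[cbind(y + 1L, seq_len(B))] <- picked - 1
  list(loss = -mean(log(pmax(picked, 1e-300))), dlogits = dl / B,
       prob = p)
}

softmax_prob <- function(logits) {
  m <- pmax(logits[1L, ], logits[2L, ])
  e <- exp(logits - rep(m, each = 2L))
  e / rep(colSums(e), each = 2L)
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (k in names(params)) {
    g <- grads[[k]]
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * g
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (st$m[[k]] / bc1) / (sqrt(st$v[[k]] / bc2) + eps)
  }
  list(params = params, state = st)
}
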