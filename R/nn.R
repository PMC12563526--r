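# Minimal NHWC convolutional-network engine.
#
# A network is a list of layer objects. Composite layers ("res", "cat")
# carry nested layer lists, which keeps residual blocks and fire modules
# expressible while the forward/backward passes stay a simple recursion.
# Convolution im2col/col2im and depthwise kernels live in C++; all matrix
# products go through BLAS.

layer_conv <- function(kh, kw, cin, cout, stride = c(1L, 1L), groups = 1L) {
  if (groups > 1L && (kh != 1L || kw != 1L))
    stop("grouped convolutions are supported for 1x1 kernels only")
  if (cin %% groups || cout %% groups)
    stop("channel counts must be divisible by groups")
  list(type = "conv", kh = as.integer(kh), kw = as.integer(kw),
       cin = as.integer(cin), cout = as.integer(cout),
       stride = as.integer(stride), groups = as.integer(groups),
       w = NULL, b = NULL)
}
layer_dwconv <- function(k, c, stride = c(1L, 1L))
  list(type = "dwconv", k = as.integer(k), cin = as.integer(c),
       cout = as.integer(c), stride = as.integer(stride), w = NULL, b = NULL)
layer_dense <- function(cin, cout)
  list(type = "dense", cin = as.integer(cin), cout = as.integer(cout),
       w = NULL, b = NULL)
layer_relu <- function() list(type = "relu")
layer_gap <- function() list(type = "gap")
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_avgpool <- function(k, stride)
  list(type = "avgpool", k = as.integer(k), stride = as.integer(stride))
layer_shuffle <- function(groups) list(type = "shuffle", groups = as.integer(groups))
layer_res <- function(body) list(type = "res", body = body)
layer_cat <- function(branches) list(type = "cat", branches = branches)

# --- initialization ---------------------------------------------------------

init_layers <- function(layers) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      fan_in <- l$kh * l$kw * l$cin / l$groups
      l$w <- matrix(stats::rnorm(l$kh * l$kw * l$cin / l$groups * l$cout,
                                 sd = sqrt(2 / fan_in)),
                    l$kh * l$kw * l$cin / l$groups, l$cout)
      l$b <- numeric(l$cout)
    } else if (l$type == "dwconv") {
      l$w <- matrix(stats::rnorm(l$k * l$k * l$cin, sd = sqrt(2 / (l$k * l$k))),
                    l$k * l$k, l$cin)
      l$b <- numeric(l$cin)
    } else if (l$type == "dense") {
      l$w <- matrix(stats::rnorm(l$cin * l$cout, sd = sqrt(2 / l$cin)),
                    l$cin, l$cout)
      l$b <- numeric(l$cout)
    } else if (l$type == "res") {
      l$body <- init_layers(l$body)
    } else if (l$type == "cat") {
      l$branches <- lapply(l$branches, init_layers)
    }
    layers[[i]] <- l
  }
  layers
}

# --- forward / backward -----------------------------------------------------

add_bias <- function(m, b) m + rep(b, each = nrow(m))

layer_forward <- function(l, x, train = FALSE) {
  switch(l$type,
    conv = {
      dm <- dim(x)
      if (l$kh == 1L && l$kw == 1L && all(l$stride == 1L)) {
        out <- pw_fwd(x, l$w, l$b, l$groups)
        list(out = out, cache = list(x = x, dims = dm))
      } else {
        r <- im2col_nhwc(x, l$kh, l$kw, l$stride[1], l$stride[2])
        out <- conv_mm_fwd(r$col, l$w, l$b, dm[1], r$Hout, r$Wout)
        list(out = out, cache = list(col = r$col, dims = dm))
      }
    },
    dwconv = {
      out <- dwconv_fwd(x, l$w, l$b, l$k, l$stride[1], l$stride[2])
      list(out = out, cache = list(x = x))
    },
    avgpool = {
      w <- matrix(1 / (l$k * l$k), l$k * l$k, dim(x)[4])
      out <- dwconv_fwd(x, w, numeric(dim(x)[4]), l$k, l$stride[1], l$stride[2])
      list(out = out, cache = list(x = x))
    },
    dense = list(out = add_bias(x %*% l$w, l$b), cache = list(x = x)),
    relu = {
      out <- relu_fwd(x)
      list(out = out, cache = list(out = out))
    },
    gap = {
      dm <- dim(x)
      list(out = gap_fwd(x), cache = list(dims = dm))
    },
    dropout = {
      if (!train || l$rate <= 0) return(list(out = x, cache = NULL))
      mask <- (stats::runif(length(x)) >= l$rate) / (1 - l$rate)
      dim(mask) <- dim(x)
      list(out = x * mask, cache = list(mask = mask))
    },
    shuffle = {
      C <- dim(x)[4]; g <- l$groups; m <- C %/% g
      perm <- as.vector(t(matrix(seq_len(C), m, g)))
      out <- x[, , , perm, drop = FALSE]
      list(out = out, cache = list(perm = perm))
    },
    res = {
      r <- nn_forward(l$body, x, train)
      list(out = x + r$out, cache = list(body = r$caches))
    },
    cat = {
      rs <- lapply(l$branches, nn_forward, x = x, train = train)
      cs <- vapply(rs, function(r) dim(r$out)[4], integer(1))
      dm <- dim(rs[[1]]$out)
      out <- array(0, c(dm[1:3], sum(cs)))
      at <- 0L
      for (r in rs) {
        cc <- dim(r$out)[4]
        out[, , , at + seq_len(cc)] <- r$out
        at <- at + cc
      }
      list(out = out, cache = list(branches = lapply(rs, `[[`, "caches"),
                                   splits = cs))
    },
    stop("unknown layer type: ", l$type)
  )
}

layer_backward <- function(l, cache, dout) {
  switch(l$type,
    conv = {
      dm <- cache$dims
      if (l$kh == 1L && l$kw == 1L && all(l$stride == 1L)) {
        r <- pw_bwd(cache$x, l$w, dout, l$groups)
        list(dx = r$dx, grads = list(w = r$dw, b = as.vector(r$db)))
      } else {
        r <- conv_mm_bwd(cache$col, l$w, dout)
        dx <- col2im_nhwc(r$dcol, dm[1], dm[2], dm[3], dm[4],
                          l$kh, l$kw, l$stride[1], l$stride[2])
        list(dx = dx, grads = list(w = r$dw, b = as.vector(r$db)))
      }
    },
    dwconv = {
      r <- dwconv_bwd(cache$x, l$w, dout, l$k, l$stride[1], l$stride[2])
      list(dx = r$dx, grads = list(w = r$dw, b = r$db))
    },
    avgpool = {
      C <- dim(cache$x)[4]
      w <- matrix(1 / (l$k * l$k), l$k * l$k, C)
      r <- dwconv_bwd(cache$x, w, dout, l$k, l$stride[1], l$stride[2])
      list(dx = r$dx, grads = NULL)
    },
    dense = list(dx = tcrossprod(dout, l$w),
                 grads = list(w = crossprod(cache$x, dout), b = colSums(dout))),
    relu = list(dx = relu_bwd(dout, cache$out), grads = NULL),
    gap = {
      dm <- cache$dims
      list(dx = gap_bwd(dout, dm[2], dm[3]), grads = NULL)
    },
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    shuffle = {
      inv <- order(cache$perm)
      list(dx = dout[, , , inv, drop = FALSE], grads = NULL)
    },
    res = {
      r <- nn_backward(l$body, cache$body, dout)
      list(dx = dout + r$dx, grads = r$grads)
    },
    cat = {
      at <- 0L
      dx <- NULL
      grads <- vector("list", length(l$branches))
      for (bi in seq_along(l$branches)) {
        cc <- cache$splits[bi]
        dsub <- dout[, , , at + seq_len(cc), drop = FALSE]
        at <- at + cc
        r <- nn_backward(l$branches[[bi]], cache$branches[[bi]], dsub)
        grads[[bi]] <- r$grads
        dx <- if (is.null(dx)) r$dx else dx + r$dx
      }
      list(dx = dx, grads = grads)
    },
    stop("unknown layer type: ", l$type)
  )
}

nn_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train)
    x <- r$out
    caches[i] <- list(r$cache)
  }
  list(out = x, caches = caches)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)
  }
  list(dx = dout, grads = grads)
}

# --- parameter plumbing -----------------------------------------------------

layer_param_arrays <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type %in% c("conv", "dwconv", "dense"))
      out <- c(out, list(l$w, l$b))
    else if (l$type == "res")
      out <- c(out, layer_param_arrays(l$body))
    else if (l$type == "cat")
      for (br in l$branches) out <- c(out, layer_param_arrays(br))
  }
  out
}

nn_get_params <- function(layers)
  unlist(layer_param_arrays(layers), use.names = FALSE)

nn_set_params <- function(layers, theta) {
  pos <- new.env()
  pos$at <- 0L
  take <- function(n) {
    v <- theta[pos$at + seq_len(n)]
    pos$at <- pos$at + n
    v
  }
  set_rec <- function(layers) {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (l$type %in% c("conv", "dwconv", "dense")) {
        l$w <- matrix(take(length(l$w)), nrow(l$w), ncol(l$w))
        l$b <- take(length(l$b))
      } else if (l$type == "res") {
        l$body <- set_rec(l$body)
      } else if (l$type == "cat") {
        l$branches <- lapply(l$branches, set_rec)
      }
      layers[[i]] <- l
    }
    layers
  }
  out <- set_rec(layers)
  stopifnot(pos$at == length(theta))
  out
}

grads_flatten <- function(grads, layers) {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    g <- grads[[i]]
    if (l$type %in% c("conv", "dwconv", "dense"))
      out <- c(out, list(g$w, g$b))
    else if (l$type == "res")
      out <- c(out, list(grads_flatten(g, l$body)))
    else if (l$type == "cat")
      for (bi in seq_along(l$branches))
        out <- c(out, list(grads_flatten(g[[bi]], l$branches[[bi]])))
  }
  out
}

nn_grad_vector <- function(grads, layers)
  unlist(grads_flatten(grads, layers), use.names = FALSE)

# --- Adam -------------------------------------------------------------------

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, g, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

# --- shape propagation (build validation + MAC accounting) ------------------

same_out <- function(len, k, s) as.integer(ceiling(len / s))

# returns list(shape=final c(H,W,C) or c(C), macs=total multiply-accumulates)
shape_prop <- function(layers, shape) {
  macs <- 0
  for (l in layers) {
    if (l$type == "conv") {
      if (length(shape) != 3L || shape[3] != l$cin)
        stop("layer expects ", l$cin, " channels, got ",
             paste(shape, collapse = "x"))
      ho <- same_out(shape[1], l$kh, l$stride[1])
      wo <- same_out(shape[2], l$kw, l$stride[2])
      macs <- macs + l$kh * l$kw * (l$cin / l$groups) * l$cout * ho * wo
      shape <- c(ho, wo, l$cout)
    } else if (l$type == "dwconv") {
      if (shape[3] != l$cin) stop("depthwise channel mismatch")
      ho <- same_out(shape[1], l$k, l$stride[1])
      wo <- same_out(shape[2], l$k, l$stride[2])
      macs <- macs + l$k * l$k * l$cin * ho * wo
      shape <- c(ho, wo, l$cin)
    } else if (l$type == "avgpool") {
      shape <- c(same_out(shape[1], l$k, l$stride[1]),
                 same_out(shape[2], l$k, l$stride[2]), shape[3])
    } else if (l$type == "gap") {
      shape <- shape[3]
    } else if (l$type == "dense") {
      if (length(shape) != 1L || shape != l$cin)
        stop("dense layer expects ", l$cin, " inputs")
      macs <- macs + l$cin * l$cout
      shape <- l$cout
    } else if (l$type == "res") {
      r <- shape_prop(l$body, shape)
      if (!identical(r$shape, shape))
        stop("residual body changes shape: cannot add skip connection")
      macs <- macs + r$macs
    } else if (l$type == "cat") {
      outs <- lapply(l$branches, shape_prop, shape = shape)
      hw <- unique(lapply(outs, function(o) o$shape[1:2]))
      if (length(hw) != 1L) stop("cat branches disagree on spatial shape")
      macs <- macs + sum(vapply(outs, `[[`, numeric(1), "macs"))
      shape <- c(hw[[1]], sum(vapply(outs, function(o) o$shape[3], numeric(1))))
    }
    # relu / dropout / shuffle leave the shape unchanged
  }
  list(shape = shape, macs = macs)
}
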