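# Minimal tape-based reverse-mode autodiff over 4D feature maps
# (nx, ny, nz, channels). Nodes and parameters are environments; forward ops
# append nodes to an active tape, and ag_backward() replays it in reverse,
# accumulating gradients into parameter environments. With no active tape
# (evaluation mode) the same ops run value-only with no bookkeeping.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

ag_recording <- function() !is.null(.ag$tape)

ag_start_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 128L)
  t$n <- 0L
  .ag$tape <- t
  invisible(t)
}

ag_end_tape <- function() .ag$tape <- NULL

ag_node <- function(value, bwd = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$bwd <- bwd
  if (!is.null(bwd) && ag_recording()) {
    t <- .ag$tape
    t$n <- t$n + 1L
    if (t$n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
    t$nodes[[t$n]] <- e
  }
  e
}

ag_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$is_param <- TRUE
  e
}

ag_acc <- function(e, g) {
  if (is.null(e$grad)) e$grad <- g else e$grad <- e$grad + g
  invisible(NULL)
}

# Seed the output gradient and sweep the tape in reverse creation order.
ag_backward <- function(out, seed) {
  t <- .ag$tape
  if (is.null(t)) stop("no active tape: forward pass was not recorded")
  out$grad <- seed
  for (i in rev(seq_len(t$n))) {
    nd <- t$nodes[[i]]
    if (!is.null(nd$grad)) nd$bwd(nd$grad)
    nd$grad <- NULL
  }
  invisible(NULL)
}

# --- ops ---------------------------------------------------------------

op_input <- function(x) ag_node(x)

op_conv3 <- function(x, W, b, stride = 1L) {
  sp <- dim(x$value)[1:3]
  if (stride > 1L && any(sp < 2L))
    stop("invalid shape: spatial axis of size 1 cannot be strided")
  y <- cpp_conv3_fwd(x$value, W$value, b$value, as.integer(stride))
  if (!ag_recording()) return(ag_node(y))
  ag_node(y, bwd = function(g) {
    bw <- cpp_conv3_bwd(x$value, W$value, g, as.integer(stride))
    ag_acc(x, bw$dx); ag_acc(W, bw$dW); ag_acc(b, bw$db)
  })
}

# 1x1x1 convolution: a per-voxel linear map across channels.
op_conv1 <- function(x, W, b) {
  d <- dim(x$value)
  nvox <- prod(d[1:3])
  xm <- matrix(x$value, nvox, d[4])
  ym <- xm %*% W$value
  ym <- sweep(ym, 2, b$value, "+")
  y <- array(ym, c(d[1:3], ncol(W$value)))
  if (!ag_recording()) return(ag_node(y))
  ag_node(y, bwd = function(g) {
    gm <- matrix(g, nvox, ncol(W$value))
    ag_acc(W, crossprod(xm, gm))
    ag_acc(b, colSums(gm))
    dx <- tcrossprod(gm, W$value)
    dim(dx) <- d
    ag_acc(x, dx)
  })
}

op_relu <- function(x) {
  y <- x$value
  y[y < 0] <- 0
  if (!ag_recording()) return(ag_node(y))
  ag_node(y, bwd = function(g) ag_acc(x, g * (x$value > 0)))
}

op_sigmoid <- function(x) {
  y <- plogis(x$value)
  if (!ag_recording()) return(ag_node(y))
  ag_node(y, bwd = function(g) ag_acc(x, g * y * (1 - y)))
}

op_maxpool <- function(x) {
  if (any(dim(x$value)[1:3] < 2L))
    stop("invalid shape: spatial axis of size 1 cannot be pooled")
  r <- cpp_maxpool_fwd(x$value)
  if (!ag_recording()) return(ag_node(r$y))
  xdim <- dim(x$value)
  ag_node(r$y, bwd = function(g) ag_acc(x, cpp_maxpool_bwd(g, r$idx, xdim)))
}

op_resize <- function(x, target_sp) {
  y <- cpp_resize3_fwd(x$value, as.integer(target_sp))
  if (!ag_recording()) return(ag_node(y))
  sdim <- dim(x$value)[1:3]
  ag_node(y, bwd = function(g) ag_acc(x, cpp_resize3_bwd(g, as.integer(sdim))))
}

op_concat <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  if (!identical(da[1:3], db[1:3])) stop("invalid shape: concat spatial mismatch")
  y <- array(c(a$value, b$value), c(da[1:3], da[4] + db[4]))
  if (!ag_recording()) return(ag_node(y))
  na <- prod(da)
  ag_node(y, bwd = function(g) {
    ga <- g[seq_len(na)]; dim(ga) <- da
    gb <- g[-seq_len(na)]; dim(gb) <- db
    ag_acc(a, ga); ag_acc(b, gb)
  })
}

op_add <- function(a, b) {
  y <- a$value + b$value
  if (!ag_recording()) return(ag_node(y))
  ag_node(y, bwd = function(g) { ag_acc(a, g); ag_acc(b, g) })
}

# skip (.., C) reweighted by a single-channel coefficient map alpha (.., 1);
# alpha broadcasts across channels (channel index is the slowest axis).
op_gate_mul <- function(skip, alpha) {
  d <- dim(skip$value)
  av <- as.vector(alpha$value)
  y <- skip$value * av
  if (!ag_recording()) return(ag_node(y))
  ag_node(y, bwd = function(g) {
    ag_acc(skip, g * av)
    da <- rowSums(matrix(g * skip$value, prod(d[1:3]), d[4]))
    dim(da) <- c(d[1:3], 1L)
    ag_acc(alpha, da)
  })
}

# Batch normalization for batch size 1: moments over the spatial extent per
# channel. Training mode uses batch statistics and updates running moments;
# evaluation mode applies the stored running moments.
op_batchnorm <- function(x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  nvox <- prod(d[1:3]); C <- d[4]
  xm <- matrix(x$value, nvox, C)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, inv, "*")
  ym <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
  y <- array(ym, d)
  if (!ag_recording()) return(ag_node(y))
  ag_node(y, bwd = function(g) {
    gm <- matrix(g, nvox, C)
    ag_acc(gamma, colSums(gm * xhat))
    ag_acc(beta, colSums(gm))
    dxhat <- sweep(gm, 2, gamma$value, "*")
    if (training) {
      s1 <- colMeans(dxhat)
      s2 <- colMeans(dxhat * xhat)
      dx <- sweep(dxhat, 2, s1, "-") - sweep(xhat, 2, s2, "*")
      dx <- sweep(dx, 2, inv, "*")
    } else {
      dx <- sweep(dxhat, 2, inv, "*")
    }
    dim(dx) <- d
    ag_acc(x, dx)
  })
}
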