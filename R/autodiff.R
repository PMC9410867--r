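# Minimal reverse-mode automatic differentiation over dense 5D tensors
# (L, W, H, C, N). Each op records a closure on a tape; backward() replays
# the tape in reverse, accumulating gradients into leaf nodes. With a NULL
# tape the ops run forward-only (inference mode, nothing retained).

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

ag_leaf <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd
}

ag_node <- function(tape, value, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  if (!is.null(tape) && !is.null(backfn)) {
    nd$backfn <- backfn
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

ag_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

ag_backward <- function(tape, root, seed_grad = 1) {
  root$grad <- seed_grad
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

dim5 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 5L)
  as.integer(d)
}

# ---- tensor ops ------------------------------------------------------------

op_conv3d <- function(tape, x, w, b, K, pad = (K - 1L) %/% 2L) {
  xd <- dim5(x$value)
  wd <- dim(w$value)  # (K,K,K,Cin,Cout)
  Cin <- wd[4]; Cout <- wd[5]
  y <- .conv3d_fw(x$value, xd, w$value, K, Cin, Cout, b$value, pad)
  dim(y) <- c(xd[1:3], Cout, xd[5])
  ag_node(tape, y, function(g) {
    dx <- .conv3d_bw_x(g, xd, w$value, K, Cin, Cout, pad)
    dim(dx) <- xd
    ag_accum(x, dx)
    gw <- .conv3d_bw_w(x$value, xd, g, K, Cin, Cout, pad)
    dw <- gw$dw; dim(dw) <- wd
    ag_accum(w, dw)
    ag_accum(b, gw$db)
  })
}

op_convtr2 <- function(tape, x, w, b) {
  xd <- dim5(x$value)
  wd <- dim(w$value)  # (2,2,2,Cin,Cout)
  Cin <- wd[4]; Cout <- wd[5]
  y <- .convtr2_fw(x$value, xd, w$value, Cin, Cout, b$value)
  dim(y) <- c(2L * xd[1:3], Cout, xd[5])
  ag_node(tape, y, function(g) {
    gr <- .convtr2_bw(x$value, xd, g, w$value, Cin, Cout)
    dx <- gr$dx; dim(dx) <- xd
    ag_accum(x, dx)
    dw <- gr$dw; dim(dw) <- wd
    ag_accum(w, dw)
    ag_accum(b, gr$db)
  })
}

op_maxpool2 <- function(tape, x) {
  xd <- dim5(x$value)
  r <- .maxpool2_fw(x$value, xd)
  y <- r$y
  dim(y) <- c(xd[1:3] %/% 2L, xd[4:5])
  idx <- r$idx
  ag_node(tape, y, function(g) {
    dx <- numeric(prod(xd))
    dx[idx] <- g  # argmax indices are distinct across pooling cells
    dim(dx) <- xd
    ag_accum(x, dx)
  })
}

op_relu <- function(tape, x) {
  y <- x$value * (x$value > 0)
  ag_node(tape, y, function(g) ag_accum(x, g * (x$value > 0)))
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  ag_node(tape, y, function(g) ag_accum(x, g * y * (1 - y)))
}

op_add <- function(tape, a, b) {
  ag_node(tape, a$value + b$value, function(g) {
    ag_accum(a, g)
    ag_accum(b, g)
  })
}

op_concat_c <- function(tape, a, b) {
  ad <- dim5(a$value); bd <- dim5(b$value)
  Ca <- ad[4]; Cb <- bd[4]
  y <- array(0, c(ad[1:3], Ca + Cb, ad[5]))
  y[, , , seq_len(Ca), ] <- a$value
  y[, , , Ca + seq_len(Cb), ] <- b$value
  ag_node(tape, y, function(g) {
    ag_accum(a, g[, , , seq_len(Ca), , drop = FALSE])
    ag_accum(b, g[, , , Ca + seq_len(Cb), , drop = FALSE])
  })
}

op_slice_c <- function(tape, x, channels) {
  xd <- dim5(x$value)
  y <- x$value[, , , channels, , drop = FALSE]
  ag_node(tape, y, function(g) {
    dx <- array(0, xd)
    dx[, , , channels, ] <- g
    ag_accum(x, dx)
  })
}

# global average pooling: (L,W,H,C,N) -> (C,N)
op_gap <- function(tape, x) {
  xd <- dim5(x$value)
  V <- prod(xd[1:3])
  m <- array(x$value, c(V, xd[4], xd[5]))
  y <- colMeans(m)  # (C,N)
  if (is.null(dim(y))) dim(y) <- c(xd[4], xd[5])
  ag_node(tape, y, function(g) {
    dx <- array(rep(as.vector(g) / V, each = V), xd)
    ag_accum(x, dx)
  })
}

# multiply a tensor by a per-channel, per-sample scalar map m (C,N)
op_scale_c <- function(tape, x, m) {
  xd <- dim5(x$value)
  V <- prod(xd[1:3])
  mb <- array(rep(as.vector(m$value), each = V), xd)
  ag_node(tape, x$value * mb, function(g) {
    ag_accum(x, g * mb)
    gm <- colSums(array(g * x$value, c(V, xd[4], xd[5])))
    if (is.null(dim(gm))) dim(gm) <- c(xd[4], xd[5])
    ag_accum(m, gm)
  })
}

# multiply a tensor by a single-channel spatial map a (L,W,H,1,N),
# broadcast over channels
op_scale_s <- function(tape, x, a) {
  xd <- dim5(x$value)
  ab <- a$value[, , , rep(1L, xd[4]), , drop = FALSE]
  ag_node(tape, x$value * ab, function(g) {
    ag_accum(x, g * ab)
    ga <- g * x$value
    dim(ga) <- c(prod(xd[1:3]), xd[4], xd[5])
    da <- array(0, dim(a$value))
    da[] <- colSums(aperm(ga, c(2, 1, 3)))  # sum over channels
    ag_accum(a, da)
  })
}

# batch normalization per channel over (L,W,H,N); running stats updated in
# training mode, used verbatim in eval mode
op_batchnorm <- function(tape, x, gamma, beta, state, key, train,
                         momentum = 0.1, eps = 1e-5) {
  xd <- dim5(x$value)
  V <- prod(xd[1:3])
  C <- xd[4]; N <- xd[5]
  m <- array(x$value, c(V, C, N))
  if (train) {
    mu <- as.numeric(rowMeans(colMeans(m)))           # per-channel mean
    ex2 <- array(x$value^2, c(V, C, N))
    mu2 <- as.numeric(rowMeans(colMeans(ex2)))
    varc <- pmax(mu2 - mu^2, 0)
    rs <- state$bn[[key]]
    if (is.null(rs)) rs <- list(mean = numeric(C), var = rep(1, C))
    state$bn[[key]] <- list(mean = (1 - momentum) * rs$mean + momentum * mu,
                            var = (1 - momentum) * rs$var + momentum * varc)
  } else {
    rs <- state$bn[[key]]
    if (is.null(rs)) rs <- list(mean = numeric(C), var = rep(1, C))
    mu <- rs$mean
    varc <- rs$var
  }
  istd <- 1 / sqrt(varc + eps)
  cidx <- rep(rep(seq_len(C), each = V), N)
  xhat <- (x$value - mu[cidx]) * istd[cidx]
  dim(xhat) <- xd
  y <- gamma$value[cidx] * xhat + beta$value[cidx]
  dim(y) <- xd
  ag_node(tape, y, function(g) {
    gm <- array(g, c(V, C, N))
    dbeta <- as.numeric(rowSums(colSums(gm)))
    gx <- array(g * xhat, c(V, C, N))
    dgamma <- as.numeric(rowSums(colSums(gx)))
    ag_accum(gamma, dgamma)
    ag_accum(beta, dbeta)
    if (train) {
      # batch statistics depend on x
      Ne <- V * N
      dx <- (gamma$value[cidx] * istd[cidx] / Ne) *
        (Ne * g - dbeta[cidx] - xhat * dgamma[cidx])
    } else {
      # running statistics are constants
      dx <- gamma$value[cidx] * istd[cidx] * g
    }
    dim(dx) <- xd
    ag_accum(x, dx)
  })
}

# 1D convolution along the rows of a (T, N) matrix, single in/out channel,
# same padding; used for the channel-fusion attention statistic
op_conv1d <- function(tape, s, w, b) {
  sv <- s$value
  Tn <- nrow(sv)
  n <- length(w$value)
  pad <- (n - 1L) %/% 2L
  y <- matrix(b$value, Tn, ncol(sv))
  for (u in seq_len(n)) {
    off <- u - 1L - pad
    src <- seq_len(Tn) + off
    ok <- src >= 1L & src <= Tn
    y[ok, ] <- y[ok, ] + w$value[u] * sv[src[ok], , drop = FALSE]
  }
  ag_node(tape, y, function(g) {
    ds <- matrix(0, Tn, ncol(sv))
    dw <- numeric(n)
    for (u in seq_len(n)) {
      off <- u - 1L - pad
      src <- seq_len(Tn) + off
      ok <- src >= 1L & src <= Tn
      ds[src[ok], ] <- ds[src[ok], ] + w$value[u] * g[ok, , drop = FALSE]
      dw[u] <- sum(g[ok, , drop = FALSE] * sv[src[ok], , drop = FALSE])
    }
    ag_accum(s, ds)
    ag_accum(w, dw)
    ag_accum(b, sum(g))
  })
}

# rbind of two (C,N) statistics into (2C,N)
op_rbind <- function(tape, a, b) {
  Ca <- nrow(a$value)
  ag_node(tape, rbind(a$value, b$value), function(g) {
    ag_accum(a, g[seq_len(Ca), , drop = FALSE])
    ag_accum(b, g[-seq_len(Ca), , drop = FALSE])
  })
}

op_rows <- function(tape, x, rows) {
  nr <- nrow(x$value)
  ag_node(tape, x$value[rows, , drop = FALSE], function(g) {
    dx <- matrix(0, nr, ncol(x$value))
    dx[rows, ] <- g
    ag_accum(x, dx)
  })
}

op_sigmoid_m <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  ag_node(tape, y, function(g) ag_accum(x, g * y * (1 - y)))
}
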