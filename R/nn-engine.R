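# Reverse-mode tape engine for the network layers.
#
# Activations are 4-D arrays with dim (H, W, N, C): height, width, batch,
# channels. Channels-last keeps every reshape between array and matrix form
# a plain dim change (no element movement): a (Ho, Wo, N, C) block IS the
# (Ho*Wo*N) x C matrix BLAS wants. Every op appends a node to a per-forward
# tape; nn_backward() walks the tape in reverse, calling each node's closure
# to push gradients into its parents. Parameters enter a forward pass as
# leaf nodes (see nn_pctx below) so their gradients can be collected by name
# after backward().

nn_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 64L)
  e$n <- 0L
  e
}

nn_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

nn_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Seeds the output node with gradient 1 and propagates back through the tape.
nn_backward <- function(tape, out) {
  out$grad <- if (length(out$value) == 1L) 1 else array(1, dim(out$value))
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# Parameter context: lazily wraps arrays from a flat named list as tape
# leaves, at most once per forward, so gradients accumulate per parameter.
nn_pctx <- function(tape, params, running = NULL, training = FALSE) {
  e <- new.env(parent = emptyenv())
  e$tape <- tape
  e$params <- params
  e$leaves <- new.env(parent = emptyenv())
  e$running <- running    # environment of batch-norm running statistics
  e$training <- training
  e
}

nn_pref <- function(ctx, name) {
  nd <- ctx$leaves[[name]]
  if (is.null(nd)) {
    val <- ctx$params[[name]]
    if (is.null(val)) stop("unknown parameter: ", name)
    nd <- nn_node(ctx$tape, val)
    ctx$leaves[[name]] <- nd
  }
  nd
}

nn_grads <- function(ctx) {
  out <- list()
  for (nm in ls(ctx$leaves)) {
    g <- ctx$leaves[[nm]]$grad
    if (!is.null(g)) out[[nm]] <- g
  }
  out
}

## ---- convolution -----------------------------------------------------------

.pad_hw <- function(X, pad) {
  d <- dim(X)
  if (pad == 0L) return(X)
  Xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  Xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- X
  Xp
}

# Weight array (k, k, Cin, Cout) as the (k*k*Cin) x Cout matrix whose row
# order (Cin fastest, then kh, then kw) matches the im2col buffer below.
.conv_wmat <- function(W) {
  dW <- dim(W)
  matrix(aperm(W, c(3L, 1L, 2L, 4L)), dW[1] * dW[2] * dW[3], dW[4])
}

# im2col: one column block of Cin channels per kernel tap.
.im2col <- function(Xp, k, stride, Ho, Wo) {
  d <- dim(Xp); N <- d[3]; Cin <- d[4]
  M <- Ho * Wo * N
  Xcol <- matrix(0, M, k * k * Cin)
  t <- 0L
  for (kw in seq_len(k)) for (kh in seq_len(k)) {
    xs <- Xp[seq.int(kh, by = stride, length.out = Ho),
             seq.int(kw, by = stride, length.out = Wo), , , drop = FALSE]
    dim(xs) <- c(M, Cin)
    Xcol[, t * Cin + seq_len(Cin)] <- xs
    t <- t + 1L
  }
  Xcol
}

# k x k convolution, stride s, zero padding p, as a single GEMM over the
# im2col buffer; the buffer is cached on the node for the backward pass.
op_conv2d <- function(tape, x, w, b, stride = 1L, pad = 0L) {
  X <- x$value
  d <- dim(X); H <- d[1]; Wd <- d[2]; N <- d[3]
  k <- dim(w$value)[1]; Cin <- dim(w$value)[3]; Cout <- dim(w$value)[4]
  Xp <- .pad_hw(X, pad)
  Hp <- H + 2L * pad; Wp <- Wd + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L; Wo <- (Wp - k) %/% stride + 1L
  M <- Ho * Wo * N
  Xcol <- .im2col(Xp, k, stride, Ho, Wo)
  Wm <- .conv_wmat(w$value)
  Y <- Xcol %*% Wm + rep(b$value, each = M)
  dim(Y) <- c(Ho, Wo, N, Cout)
  nn_node(tape, Y, function(g) {
    dim(g) <- c(M, Cout)
    nn_accum(b, colSums(g))
    dWm <- crossprod(Xcol, g)
    nn_accum(w, aperm(array(dWm, c(Cin, k, k, Cout)), c(2L, 3L, 1L, 4L)))
    dXcol <- tcrossprod(g, Wm)
    dXp <- array(0, c(Hp, Wp, N, Cin))
    t <- 0L
    for (kw in seq_len(k)) for (kh in seq_len(k)) {
      ih <- seq.int(kh, by = stride, length.out = Ho)
      iw <- seq.int(kw, by = stride, length.out = Wo)
      blk <- dXcol[, t * Cin + seq_len(Cin)]
      dim(blk) <- c(Ho, Wo, N, Cin)
      dXp[ih, iw, , ] <- dXp[ih, iw, , , drop = FALSE] + blk
      t <- t + 1L
    }
    nn_accum(x, if (pad > 0L) {
      dXp[pad + seq_len(H), pad + seq_len(Wd), , , drop = FALSE]
    } else dXp)
  })
}

# 2x2 stride-2 transposed convolution (exact x2 upsampling, no overlap).
op_convt2 <- function(tape, x, w, b) {
  X <- x$value
  d <- dim(X); H <- d[1]; Wd <- d[2]; N <- d[3]
  Cin <- dim(w$value)[3]; Cout <- dim(w$value)[4]
  M <- H * Wd * N
  Xm <- X; dim(Xm) <- c(M, Cin)
  Y <- array(0, c(2L * H, 2L * Wd, N, Cout))
  for (i in 1:2) for (j in 1:2) {
    Ym <- Xm %*% matrix(w$value[i, j, , ], Cin, Cout) + rep(b$value, each = M)
    dim(Ym) <- c(H, Wd, N, Cout)
    Y[seq.int(i, by = 2L, length.out = H),
      seq.int(j, by = 2L, length.out = Wd), , ] <- Ym
  }
  nn_node(tape, Y, function(g) {
    dXm <- matrix(0, M, Cin)
    dW <- array(0, dim(w$value)); db <- numeric(Cout)
    for (i in 1:2) for (j in 1:2) {
      Gij <- g[seq.int(i, by = 2L, length.out = H),
               seq.int(j, by = 2L, length.out = Wd), , , drop = FALSE]
      dim(Gij) <- c(M, Cout)
      dW[i, j, , ] <- crossprod(Xm, Gij)
      db <- db + colSums(Gij)
      dXm <- dXm + tcrossprod(Gij, matrix(w$value[i, j, , ], Cin, Cout))
    }
    dim(dXm) <- c(H, Wd, N, Cin)
    nn_accum(x, dXm)
    nn_accum(w, dW); nn_accum(b, db)
  })
}

## ---- batch normalisation ---------------------------------------------------

# Broadcast a per-channel vector over an (H, W, N, C) array.
cvec <- function(v, d) rep(v, each = d[1] * d[2] * d[3])

# Per-channel sums (sum over H, W, N), no copy.
csum <- function(X) colSums(X, dims = 3L)

# Training mode uses batch statistics and updates the running estimates held
# in ctx$running (keyed "<name>.mean"/"<name>.var"); inference uses the
# running estimates.
op_bn <- function(ctx, x, name, eps = 1e-5, momentum = 0.9) {
  gamma <- nn_pref(ctx, paste0(name, ".gamma"))
  beta <- nn_pref(ctx, paste0(name, ".beta"))
  X <- x$value; d <- dim(X); m <- d[1] * d[2] * d[3]
  if (ctx$training) {
    mu <- csum(X) / m
    vr <- csum(X * X) / m - mu^2
    vr[vr < 0] <- 0
    kM <- paste0(name, ".mean"); kV <- paste0(name, ".var")
    ctx$running[[kM]] <- momentum * ctx$running[[kM]] + (1 - momentum) * mu
    ctx$running[[kV]] <- momentum * ctx$running[[kV]] + (1 - momentum) * vr
  } else {
    mu <- ctx$running[[paste0(name, ".mean")]]
    vr <- ctx$running[[paste0(name, ".var")]]
  }
  ivstd <- 1 / sqrt(vr + eps)
  xhat <- (X - cvec(mu, d)) * cvec(ivstd, d)
  val <- xhat * cvec(gamma$value, d) + cvec(beta$value, d)
  dim(val) <- d
  training <- ctx$training
  nn_node(ctx$tape, val, function(g) {
    dxhat <- g * cvec(gamma$value, d)
    nn_accum(gamma, csum(g * xhat))
    nn_accum(beta, csum(g))
    if (training) {
      s1 <- csum(dxhat) / m
      s2 <- csum(dxhat * xhat) / m
      dx <- cvec(ivstd, d) * (dxhat - cvec(s1, d) - xhat * cvec(s2, d))
    } else {
      dx <- dxhat * cvec(ivstd, d)
    }
    dim(dx) <- d
    nn_accum(x, dx)
  })
}

bn_running_init <- function(running, name, channels) {
  running[[paste0(name, ".mean")]] <- numeric(channels)
  running[[paste0(name, ".var")]] <- rep(1, channels)
  invisible(NULL)
}

## ---- pointwise / shape ops -------------------------------------------------

op_lrelu <- function(tape, x, slope = 0.2) {
  X <- x$value
  val <- pmax(X, 0) + slope * pmin(X, 0)
  nn_node(tape, val, function(g) nn_accum(x, g * (slope + (1 - slope) * (X > 0))))
}

op_relu <- function(tape, x) op_lrelu(tape, x, slope = 0)

op_maxpool2 <- function(tape, x) {
  X <- x$value; d <- dim(X); H <- d[1]; W <- d[2]
  oH <- seq.int(1L, H, 2L); eH <- seq.int(2L, H, 2L)
  a <- X[oH, , , , drop = FALSE]; b2 <- X[eH, , , , drop = FALSE]
  ta <- a >= b2
  m1 <- pmax(a, b2)
  oW <- seq.int(1L, W, 2L); eW <- seq.int(2L, W, 2L)
  c1 <- m1[, oW, , , drop = FALSE]; c2 <- m1[, eW, , , drop = FALSE]
  tc <- c1 >= c2
  val <- pmax(c1, c2)
  nn_node(tape, val, function(g) {
    gh <- array(0, dim(m1))
    gh[, oW, , ] <- g * tc
    gh[, eW, , ] <- g * !tc
    dX <- array(0, d)
    dX[oH, , , ] <- gh * ta
    dX[eH, , , ] <- gh * !ta
    nn_accum(x, dX)
  })
}

op_upnn <- function(tape, x) {
  X <- x$value; d <- dim(X); H <- d[1]; W <- d[2]
  val <- X[rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), , ,
           drop = FALSE]
  nn_node(tape, val, function(g) {
    oH <- seq.int(1L, 2L * H, 2L); eH <- seq.int(2L, 2L * H, 2L)
    oW <- seq.int(1L, 2L * W, 2L); eW <- seq.int(2L, 2L * W, 2L)
    nn_accum(x, g[oH, oW, , , drop = FALSE] + g[oH, eW, , , drop = FALSE] +
                g[eH, oW, , , drop = FALSE] + g[eH, eW, , , drop = FALSE])
  })
}

# Concatenate along the channel (last) dimension.
op_concat_c <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[1:3] == db[1:3]))
  val <- array(0, c(da[1:3], da[4] + db[4]))
  val[, , , seq_len(da[4])] <- a$value
  val[, , , da[4] + seq_len(db[4])] <- b$value
  nn_node(tape, val, function(g) {
    nn_accum(a, g[, , , seq_len(da[4]), drop = FALSE])
    nn_accum(b, g[, , , da[4] + seq_len(db[4]), drop = FALSE])
  })
}

# Clip to [0, 1]; gradient passes only strictly inside the box.
op_clip01 <- function(tape, x) {
  X <- x$value
  val <- pmin(pmax(X, 0), 1)
  nn_node(tape, val, function(g) nn_accum(x, g * (X > 0 & X < 1)))
}

## ---- self-attention --------------------------------------------------------

row_softmax <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

# Non-local self-attention over the spatial positions of a feature map.
# Query/key/value are 1x1 convolutions (plain channel matmuls); the output
# is the gated residual x + gamma * (A %*% V) with A the row-stochastic
# attention. Wq/Wk have dim (C, Cq); Wv is (C, C); gamma is a scalar.
op_sa <- function(tape, x, Wq, bq, Wk, bk, Wv, bv, gam) {
  X <- x$value; d <- dim(X); HW <- d[1] * d[2]; N <- d[3]; C <- d[4]
  cache <- vector("list", N)
  val <- array(0, d)
  g0 <- gam$value[1]
  for (n in seq_len(N)) {
    Xm <- X[, , n, , drop = FALSE]
    dim(Xm) <- c(HW, C)
    Q <- Xm %*% Wq$value + rep(bq$value, each = HW)
    K <- Xm %*% Wk$value + rep(bk$value, each = HW)
    V <- Xm %*% Wv$value + rep(bv$value, each = HW)
    A <- row_softmax(tcrossprod(Q, K))
    O <- A %*% V
    cache[[n]] <- list(Xm = Xm, Q = Q, K = K, V = V, A = A, O = O)
    val[, , n, ] <- Xm + g0 * O
  }
  nn_node(tape, val, function(g) {
    dX <- array(0, d)
    dWq <- 0; dWk <- 0; dWv <- 0
    dbq <- 0; dbk <- 0; dbv <- 0; dgam <- 0
    for (n in seq_len(N)) {
      cc <- cache[[n]]
      Gm <- g[, , n, , drop = FALSE]
      dim(Gm) <- c(HW, C)
      dgam <- dgam + sum(Gm * cc$O)
      dO <- g0 * Gm
      dA <- tcrossprod(dO, cc$V)
      dV <- crossprod(cc$A, dO)
      dS <- cc$A * (dA - rowSums(dA * cc$A))
      dQ <- dS %*% cc$K
      dK <- crossprod(dS, cc$Q)
      dXm <- Gm + tcrossprod(dQ, Wq$value) + tcrossprod(dK, Wk$value) +
        tcrossprod(dV, Wv$value)
      dWq <- dWq + crossprod(cc$Xm, dQ)
      dWk <- dWk + crossprod(cc$Xm, dK)
      dWv <- dWv + crossprod(cc$Xm, dV)
      dbq <- dbq + colSums(dQ); dbk <- dbk + colSums(dK); dbv <- dbv + colSums(dV)
      dX[, , n, ] <- dXm
    }
    nn_accum(x, dX)
    nn_accum(Wq, dWq); nn_accum(Wk, dWk); nn_accum(Wv, dWv)
    nn_accum(bq, dbq); nn_accum(bk, dbk); nn_accum(bv, dbv)
    nn_accum(gam, dgam)
  })
}

## ---- scalar losses ---------------------------------------------------------

# mean((x - target)^2) for a scalar target (LSGAN terms).
op_mean_sq_target <- function(tape, x, target) {
  X <- x$value; n <- length(X)
  nn_node(tape, mean((X - target)^2),
          function(g) nn_accum(x, g * 2 * (X - target) / n))
}

# mean(|x - ref|) where ref is a constant array.
op_mean_abs <- function(tape, x, ref) {
  X <- x$value; n <- length(X)
  nn_node(tape, mean(abs(X - ref)),
          function(g) nn_accum(x, g * sign(X - ref) / n))
}

# mean(softplus(sgn * x)): the numerically stable log-form adversarial
# terms, -mean(log sigmoid(x)) for sgn = -1 and -mean(log(1 - sigmoid(x)))
# for sgn = +1.
op_softplus_mean <- function(tape, x, sgn = 1) {
  X <- sgn * x$value; n <- length(X)
  sp <- ifelse(X > 30, X, log1p(exp(pmin(X, 30))))
  nn_node(tape, mean(sp),
          function(g) nn_accum(x, g * sgn * (1 / (1 + exp(-X))) / n))
}

# Weighted sum of scalar nodes.
op_wsum <- function(tape, nodes, weights) {
  val <- sum(vapply(nodes, function(nd) nd$value, numeric(1)) * weights)
  nn_node(tape, val, function(g) {
    for (i in seq_along(nodes)) nn_accum(nodes[[i]], g * weights[i])
  })
}

## ---- optimiser -------------------------------------------------------------

adam_init <- function() list(m = list(), v = list(), t = 0L)

# Adam step over the named gradients; returns updated (params, opt). Betas
# (0.5, 0.999) are the usual adversarial-training setting.
adam_step <- function(params, opt, grads, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m0 <- opt$m[[nm]]; v0 <- opt$v[[nm]]
    if (is.null(m0)) { m0 <- g * 0; v0 <- g * 0 }
    m0 <- beta1 * m0 + (1 - beta1) * g
    v0 <- beta2 * v0 + (1 - beta2) * g * g
    opt$m[[nm]] <- m0; opt$v[[nm]] <- v0
    params[[nm]] <- params[[nm]] - lr * (m0 / bc1) / (sqrt(v0 / bc2) + eps)
  }
  list(params = params, opt = opt)
}

## ---- parameter initialisers ------------------------------------------------

init_conv <- function(k, cin, cout, sd = NULL, bias = 0) {
  if (is.null(sd)) sd <- sqrt(2 / (k * k * cin))
  list(W = array(stats::rnorm(k * k * cin * cout, sd = sd), c(k, k, cin, cout)),
       b = rep(bias, cout))
}

init_mat <- function(cin, cout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / cin)
  matrix(stats::rnorm(cin * cout, sd = sd), cin, cout)
}
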