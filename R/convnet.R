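# Minimal convolutional network engine used by the self-supervised encoder
# and the artifact classifier. Batch-first layout throughout: activations are
# arrays (B, H, W, C), so per-sample statistics broadcast naturally via R's
# column-major recycling (B varies fastest).
#
# Architecture family: n blocks of [3x3 conv (pad 1) -> group norm -> ReLU],
# 2x2 average pooling between blocks, global average pooling after the last
# block, then a fully-connected head. Training is plain SGD with momentum.

conv_fwd <- function(x, W, b) {
  d <- dim(x); B <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  Cout <- dim(W)[4]
  xp <- array(0, c(B, H + 2, Wd + 2, Cin))
  xp[, 2:(H + 1), 2:(Wd + 1), ] <- x
  n <- B * H * Wd
  Y <- matrix(rep(b, each = n), n, Cout)
  for (di in 0:2) for (dj in 0:2) {
    S <- xp[, (1 + di):(H + di), (1 + dj):(Wd + dj), , drop = FALSE]
    dim(S) <- c(n, Cin)
    Y <- Y + S %*% matrix(W[di + 1, dj + 1, , ], Cin, Cout)
  }
  dim(Y) <- c(B, H, Wd, Cout)
  list(y = Y, xp = xp, dims = d)
}

conv_bwd <- function(dY, cache, W) {
  d <- cache$dims; B <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  Cout <- dim(W)[4]
  n <- B * H * Wd
  dYf <- dY; dim(dYf) <- c(n, Cout)
  dW <- array(0, dim(W))
  dXp <- array(0, dim(cache$xp))
  for (di in 0:2) for (dj in 0:2) {
    S <- cache$xp[, (1 + di):(H + di), (1 + dj):(Wd + dj), , drop = FALSE]
    dim(S) <- c(n, Cin)
    dW[di + 1, dj + 1, , ] <- crossprod(S, dYf)
    dS <- dYf %*% t(matrix(W[di + 1, dj + 1, , ], Cin, Cout))
    dim(dS) <- c(B, H, Wd, Cin)
    dXp[, (1 + di):(H + di), (1 + dj):(Wd + dj), ] <-
      dXp[, (1 + di):(H + di), (1 + dj):(Wd + dj), ] + dS
  }
  list(dx = dXp[, 2:(H + 1), 2:(Wd + 1), , drop = FALSE],
       dW = dW, db = colSums(dYf))
}

gn_fwd <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x); B <- d[1]; C <- d[4]; Cg <- C %/% groups
  hw <- d[2] * d[3]
  y <- array(0, d)
  xhat <- array(0, d)
  istd <- matrix(0, B, groups)
  for (g in seq_len(groups)) {
    idx <- ((g - 1) * Cg + 1):(g * Cg)
    xg <- x[, , , idx, drop = FALSE]
    xf <- xg; dim(xf) <- c(B, hw * Cg)
    m <- rowMeans(xf)
    v <- rowMeans(xf * xf) - m * m
    is <- 1 / sqrt(v + eps)
    xh <- (xf - m) * is           # B-first recycling: per-sample stats
    istd[, g] <- is
    dim(xh) <- c(B, d[2], d[3], Cg)
    xhat[, , , idx] <- xh
    sc <- rep(gamma[idx], each = B * hw)
    sh <- rep(beta[idx], each = B * hw)
    dim(xh) <- NULL
    y[, , , idx] <- array(xh * sc + sh, c(B, d[2], d[3], Cg))
  }
  list(y = y, xhat = xhat, istd = istd, groups = groups)
}

gn_bwd <- function(dy, cache, gamma) {
  d <- dim(dy); B <- d[1]; C <- d[4]
  groups <- cache$groups; Cg <- C %/% groups
  hw <- d[2] * d[3]
  dx <- array(0, d)
  dgamma <- numeric(C); dbeta <- numeric(C)
  for (g in seq_len(groups)) {
    idx <- ((g - 1) * Cg + 1):(g * Cg)
    dyg <- dy[, , , idx, drop = FALSE]
    xh <- cache$xhat[, , , idx, drop = FALSE]
    for (j in seq_along(idx)) {
      c <- idx[j]
      dgamma[c] <- sum(dyg[, , , j] * xh[, , , j])
      dbeta[c] <- sum(dyg[, , , j])
    }
    sc <- rep(gamma[idx], each = B * hw)
    dxh <- dyg; dim(dxh) <- NULL
    dxh <- array(dxh * sc, c(B, hw * Cg))
    xhf <- xh; dim(xhf) <- c(B, hw * Cg)
    t2 <- rowMeans(dxh)
    t3 <- rowMeans(dxh * xhf)
    dxf <- cache$istd[, g] * (dxh - t2 - xhf * t3)
    dx[, , , idx] <- array(dxf, c(B, d[2], d[3], Cg))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

pool_fwd <- function(x) {
  d <- dim(x); H <- d[2]; Wd <- d[3]
  io <- seq(1, H, by = 2); ie <- io + 1
  jo <- seq(1, Wd, by = 2); je <- jo + 1
  (x[, io, jo, , drop = FALSE] + x[, ie, jo, , drop = FALSE] +
   x[, io, je, , drop = FALSE] + x[, ie, je, , drop = FALSE]) / 4
}

pool_bwd <- function(dy, in_dims) {
  dx <- array(0, in_dims)
  io <- seq(1, in_dims[2], by = 2); jo <- seq(1, in_dims[3], by = 2)
  q <- dy / 4
  dx[, io, jo, ] <- q; dx[, io + 1, jo, ] <- q
  dx[, io, jo + 1, ] <- q; dx[, io + 1, jo + 1, ] <- q
  dx
}

gap_fwd <- function(x) {
  d <- dim(x); B <- d[1]; hw <- d[2] * d[3]
  xf <- x; dim(xf) <- c(B * hw, d[4])
  rowsum(xf, rep_len(seq_len(B), B * hw)) / hw
}

gap_bwd <- function(dy, in_dims) {
  B <- in_dims[1]; hw <- in_dims[2] * in_dims[3]
  dxf <- dy[rep_len(seq_len(B), B * hw), , drop = FALSE] / hw
  dim(dxf) <- in_dims
  dxf
}

# --- network ----------------------------------------------------------------

cnn_init <- function(input_size, in_channels = 3L, widths = c(16L, 32L, 64L, 128L),
                     head_dims = c(128L, 128L), groups = 4L, seed = 1L) {
  stopifnot(input_size %% 2^(length(widths) - 1) == 0)
  arch <- list(input_size = as.integer(input_size), in_channels = as.integer(in_channels),
               widths = as.integer(widths), head_dims = as.integer(head_dims),
               groups = as.integer(groups))
  params <- with_seed(seed, {
    p <- list()
    cin <- in_channels
    for (i in seq_along(widths)) {
      cout <- widths[i]
      p[[paste0("conv", i, "_W")]] <- array(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                                            c(3, 3, cin, cout))
      p[[paste0("conv", i, "_b")]] <- numeric(cout)
      p[[paste0("gn", i, "_g")]] <- rep(1, cout)
      p[[paste0("gn", i, "_b")]] <- numeric(cout)
      cin <- cout
    }
    din <- widths[length(widths)]
    for (j in seq_along(head_dims)) {
      dout <- head_dims[j]
      p[[paste0("fc", j, "_W")]] <- matrix(rnorm(din * dout, sd = sqrt(2 / din)), din, dout)
      p[[paste0("fc", j, "_b")]] <- numeric(dout)
      din <- dout
    }
    p
  })
  list(arch = arch, params = params)
}

# x: (B, S, S, C). Returns list(out = B x head_out matrix, cache or NULL).
cnn_forward <- function(params, arch, x, keep_cache = TRUE) {
  nb <- length(arch$widths)
  cache <- if (keep_cache) list(blocks = vector("list", nb), fcs = NULL) else NULL
  h <- x
  for (i in seq_len(nb)) {
    cv <- conv_fwd(h, params[[paste0("conv", i, "_W")]], params[[paste0("conv", i, "_b")]])
    gn <- gn_fwd(cv$y, params[[paste0("gn", i, "_g")]], params[[paste0("gn", i, "_b")]],
                 arch$groups)
    mask <- gn$y > 0
    a <- gn$y * mask
    if (keep_cache) {
      cache$blocks[[i]] <- list(conv = cv[c("xp", "dims")], gn = gn[c("xhat", "istd", "groups")],
                                relu_mask = mask, act_dims = dim(a))
    }
    h <- if (i < nb) pool_fwd(a) else gap_fwd(a)
  }
  nf <- length(arch$head_dims)
  fc_caches <- vector("list", nf)
  for (j in seq_len(nf)) {
    Wm <- params[[paste0("fc", j, "_W")]]
    z <- h %*% Wm + rep(params[[paste0("fc", j, "_b")]], each = nrow(h))
    if (j < nf) {
      m <- z > 0
      if (keep_cache) fc_caches[[j]] <- list(x = h, relu_mask = m)
      h <- z * m
    } else {
      if (keep_cache) fc_caches[[j]] <- list(x = h)
      h <- z
    }
  }
  if (keep_cache) cache$fcs <- fc_caches
  list(out = h, cache = cache)
}

cnn_backward <- function(params, arch, cache, dout) {
  grads <- list()
  nf <- length(arch$head_dims)
  d <- dout
  for (j in rev(seq_len(nf))) {
    fc <- cache$fcs[[j]]
    if (j < nf) d <- d * fc$relu_mask
    grads[[paste0("fc", j, "_W")]] <- crossprod(fc$x, d)
    grads[[paste0("fc", j, "_b")]] <- colSums(d)
    d <- d %*% t(params[[paste0("fc", j, "_W")]])
  }
  nb <- length(arch$widths)
  for (i in rev(seq_len(nb))) {
    bl <- cache$blocks[[i]]
    da <- if (i < nb) pool_bwd(d, bl$act_dims) else gap_bwd(d, bl$act_dims)
    da <- da * bl$relu_mask
    gb <- gn_bwd(da, bl$gn, params[[paste0("gn", i, "_g")]])
    grads[[paste0("gn", i, "_g")]] <- gb$dgamma
    grads[[paste0("gn", i, "_b")]] <- gb$dbeta
    cb <- conv_bwd(gb$dx, bl$conv, params[[paste0("conv", i, "_W")]])
    grads[[paste0("conv", i, "_W")]] <- cb$dW
    grads[[paste0("conv", i, "_b")]] <- cb$db
    d <- cb$dx
  }
  grads
}

sgd_state <- function(params) lapply(params, function(p) array(0, dim(p) %||% length(p)))

`%||%` <- function(a, b) if (is.null(a)) b else a

sgd_step <- function(params, grads, state, lr, momentum = 0.9, weight_decay = 1e-4) {
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state[[nm]] <- momentum * state[[nm]] + g
    params[[nm]] <- params[[nm]] - lr * state[[nm]]
  }
  list(params = params, state = state)
}

# Stack a list of HxWxC arrays into (B,H,W,C)
stack_images <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(length(lst), d))
  for (i in seq_along(lst)) out[i, , , ] <- lst[[i]]
  out
}
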