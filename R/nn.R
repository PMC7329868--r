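# Minimal dense-array neural network engine.
#
# Tensors are plain R arrays laid out (spatial..., batch, channel):
# (H, W, N, C) in 2D and (D, H, W, N, C) in 3D. Convolutions are computed as
# a sum of zero-padded spatial shifts, each reduced to one BLAS matrix
# multiply over channels, which keeps forward and backward passes fully
# vectorised. Backward passes are hand-derived and verified against
# numerical differentiation in the test suite.

# Zero-padded shift: out[i] = x[i + off] on the first length(off) axes.
# Explicit 2D/3D branches: generic do.call indexing is an order of magnitude
# slower and this sits in the innermost convolution loop.
shift_zero <- function(x, off) {
  d <- dim(x)
  if (all(off == 0)) return(x)
  a1 <- max(1L, 1L - off[1]); b1 <- min(d[1], d[1] - off[1])
  a2 <- max(1L, 1L - off[2]); b2 <- min(d[2], d[2] - off[2])
  if (a1 > b1 || a2 > b2) return(array(0, d))
  out <- array(0, d)
  if (length(off) == 2L) {
    out[a1:b1, a2:b2, , ] <- x[(a1 + off[1]):(b1 + off[1]),
                               (a2 + off[2]):(b2 + off[2]), , , drop = FALSE]
  } else {
    a3 <- max(1L, 1L - off[3]); b3 <- min(d[3], d[3] - off[3])
    if (a3 > b3) return(out)
    out[a1:b1, a2:b2, a3:b3, , ] <- x[(a1 + off[1]):(b1 + off[1]),
                                      (a2 + off[2]):(b2 + off[2]),
                                      (a3 + off[3]):(b3 + off[3]), , , drop = FALSE]
  }
  out
}

conv_offsets <- function(k, nd, dilation = 1L) {
  taps <- if (k == 1L) list(0L) else list(c(-dilation, 0L, dilation))
  as.matrix(expand.grid(rep(taps, nd)))
}

.w_mat <- function(W, r) {
  d <- dim(W)
  matrix(W[r, , ], d[2], d[3])
}

# x: (spatial..., N, Cin); W: (n_offsets, Cin, Cout); b: length Cout.
# Returns the output plus the shifted input matrices, which the backward
# pass reuses for the weight gradients (avoids recomputing the shifts).
conv_fwd_cached <- function(x, W, b, offsets) {
  d <- dim(x)
  nd <- ncol(offsets)
  M <- prod(d[seq_len(nd + 1L)])
  cout <- dim(W)[3]
  acc <- matrix(rep(b, each = M), M, cout)
  shifted <- vector("list", nrow(offsets))
  for (r in seq_len(nrow(offsets))) {
    Xs <- shift_zero(x, offsets[r, ])
    dim(Xs) <- c(M, d[nd + 2L])
    shifted[[r]] <- Xs
    acc <- acc + Xs %*% .w_mat(W, r)
  }
  dim(acc) <- c(d[seq_len(nd + 1L)], cout)
  list(y = acc, shifted = shifted, xdim = d)
}

conv_fwd <- function(x, W, b, offsets) conv_fwd_cached(x, W, b, offsets)$y

conv_bwd <- function(x, W, offsets, dy, fwd_cache = NULL) {
  d <- dim(x)
  nd <- ncol(offsets)
  M <- prod(d[seq_len(nd + 1L)])
  cin <- d[nd + 2L]
  dY <- matrix(dy, M, dim(W)[3])
  dW <- array(0, dim(W))
  dx <- array(0, d)
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    Xs <- if (!is.null(fwd_cache)) fwd_cache$shifted[[r]] else {
      tmp <- shift_zero(x, off); dim(tmp) <- c(M, cin); tmp
    }
    dW[r, , ] <- crossprod(Xs, dY)
    dxc <- dY %*% t(.w_mat(W, r))
    dim(dxc) <- c(d[seq_len(nd + 1L)], cin)
    dx <- dx + shift_zero(dxc, -off)
  }
  list(dx = dx, dW = dW, db = colSums(dY))
}

# Instance normalisation: per (sample, channel) over spatial positions.
inorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  nsp <- length(d) - 2L
  S <- prod(d[seq_len(nsp)]); N <- d[nsp + 1L]; C <- d[nsp + 2L]
  m <- matrix(x, S, N * C)
  mu <- colMeans(m)
  va <- colMeans(m * m) - mu^2
  sdv <- sqrt(va + eps)
  xhat <- (m - rep(mu, each = S)) / rep(sdv, each = S)
  gcol <- rep(gamma, each = N)
  y <- xhat * rep(gcol, each = S) + rep(rep(beta, each = N), each = S)
  list(y = array(y, d), cache = list(xhat = xhat, sdv = sdv, d = d, S = S, N = N, C = C))
}

inorm_bwd <- function(cache, gamma, dy) {
  S <- cache$S; N <- cache$N; C <- cache$C
  dm <- matrix(dy, S, N * C)
  xhat <- cache$xhat
  dgamma_col <- colSums(dm * xhat)
  dbeta_col <- colSums(dm)
  dgamma <- colSums(matrix(dgamma_col, N, C))
  dbeta <- colSums(matrix(dbeta_col, N, C))
  gcol <- rep(gamma, each = N)
  dxhat <- dm * rep(gcol, each = S)
  t1 <- colSums(dxhat)
  t2 <- colSums(dxhat * xhat)
  dx <- (dxhat - rep(t1 / S, each = S) - xhat * rep(t2 / S, each = S)) /
    rep(cache$sdv, each = S)
  list(dx = array(dx, cache$d), dgamma = dgamma, dbeta = dbeta)
}

lrelu_fwd <- function(x, slope = 1e-2) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  list(y = x, cache = neg)
}

lrelu_bwd <- function(cache, dy, slope = 1e-2) {
  dy[cache] <- dy[cache] * slope
  dy
}

# 2x max pooling over every spatial axis; requires even spatial dims.
pool_fwd <- function(x) {
  d <- dim(x)
  nsp <- length(d) - 2L
  if (any(d[seq_len(nsp)] %% 2L != 0L)) {
    stop("spatial dims must be even for 2x pooling, got ",
         paste(d[seq_len(nsp)], collapse = "x"))
  }
  halves <- lapply(seq_len(nsp), function(a) list(seq(1L, d[a], 2L), seq(2L, d[a], 2L)))
  combos <- as.matrix(expand.grid(rep(list(1:2), nsp)))
  sub <- function(ci) {
    i <- lapply(seq_len(nsp), function(a) halves[[a]][[combos[ci, a]]])
    if (nsp == 2L) x[i[[1]], i[[2]], , , drop = FALSE]
    else x[i[[1]], i[[2]], i[[3]], , , drop = FALSE]
  }
  cands <- lapply(seq_len(nrow(combos)), sub)
  m <- Reduce(pmax, cands)
  claimed <- array(FALSE, dim(m))
  masks <- vector("list", length(cands))
  for (ci in seq_along(cands)) {
    mk <- (cands[[ci]] == m) & !claimed
    claimed <- claimed | mk
    masks[[ci]] <- mk
  }
  list(y = m, cache = list(masks = masks, combos = combos, halves = halves, d = d))
}

pool_bwd <- function(cache, dy) {
  d <- cache$d
  nsp <- length(d) - 2L
  dx <- array(0, d)
  for (ci in seq_along(cache$masks)) {
    tmp <- array(0, dim(dy))
    mk <- cache$masks[[ci]]
    tmp[mk] <- dy[mk]
    i <- lapply(seq_len(nsp), function(a) cache$halves[[a]][[cache$combos[ci, a]]])
    if (nsp == 2L) dx[i[[1]], i[[2]], , ] <- tmp
    else dx[i[[1]], i[[2]], i[[3]], , ] <- tmp
  }
  dx
}

# Nearest-neighbour 2x upsampling over every spatial axis.
upsample_fwd <- function(x) {
  d <- dim(x)
  nsp <- length(d) - 2L
  if (nsp == 2L) {
    x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
  } else {
    x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L),
      rep(seq_len(d[3]), each = 2L), , , drop = FALSE]
  }
}

upsample_bwd <- function(dy) {
  d <- dim(dy)
  nsp <- length(d) - 2L
  halves <- lapply(seq_len(nsp), function(a) list(seq(1L, d[a], 2L), seq(2L, d[a], 2L)))
  combos <- as.matrix(expand.grid(rep(list(1:2), nsp)))
  acc <- NULL
  for (ci in seq_len(nrow(combos))) {
    i <- lapply(seq_len(nsp), function(a) halves[[a]][[combos[ci, a]]])
    part <- if (nsp == 2L) dy[i[[1]], i[[2]], , , drop = FALSE]
            else dy[i[[1]], i[[2]], i[[3]], , , drop = FALSE]
    acc <- if (is.null(acc)) part else acc + part
  }
  acc
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  nc <- length(da)
  out <- array(0, c(da[-nc], da[nc] + db[nc]))
  if (nc == 4L) {
    out[, , , seq_len(da[4])] <- a
    out[, , , da[4] + seq_len(db[4])] <- b
  } else {
    out[, , , , seq_len(da[5])] <- a
    out[, , , , da[5] + seq_len(db[5])] <- b
  }
  out
}

split_ch <- function(x, c1) {
  d <- dim(x)
  nc <- length(d)
  if (nc == 4L) {
    list(x[, , , seq_len(c1), drop = FALSE],
         x[, , , (c1 + 1L):d[4], drop = FALSE])
  } else {
    list(x[, , , , seq_len(c1), drop = FALSE],
         x[, , , , (c1 + 1L):d[5], drop = FALSE])
  }
}

# He-style initialisation for a conv weight (n_off, cin, cout).
init_conv <- function(n_off, cin, cout, rng) {
  sd <- sqrt(2 / (n_off * cin))
  array(rs_norm(rng, n_off * cin * cout, 0, sd), c(n_off, cin, cout))
}

# --- ADAM -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
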