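# ---------------------------------------------------------------------------
# Minimal batched neural-network primitives with hand-written backward passes.
#
# Feature maps are carried as a list `fm`: a (H*W*B) x C matrix `x` (rows
# ordered h fastest, then w, then batch) plus its dimensions. This keeps
# every channel-wise operation a plain matrix operation, which is what base
# R does fast. A static computation graph is executed by paired forward /
# backward calls sharing a cache stack in a context environment; backward
# calls must mirror forward calls in exact reverse order.
# ---------------------------------------------------------------------------

fm_new <- function(x, H, W, B) {
  list(x = x, H = H, W = W, B = B, C = ncol(x))
}

fm_rows_group <- function(fm) rep(seq_len(fm$B), each = fm$H * fm$W)

# (C, H, W) array (single sample, channel-first) -> fm with B = 1
fm_from_chw <- function(a) {
  d <- dim(a)
  m <- matrix(aperm(a, c(2, 3, 1)), nrow = d[2] * d[3], ncol = d[1])
  fm_new(m, d[2], d[3], 1L)
}

fm_to_chw <- function(fm) {
  aperm(array(fm$x, c(fm$H, fm$W, fm$C)), c(3, 1, 2))
}

new_ctx <- function(params, state = list(), training = FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- params
  ctx$state <- state
  ctx$training <- training
  ctx$grads <- list()
  ctx$cache <- vector("list", 0L)
  ctx
}

push_cache <- function(ctx, cache) {
  ctx$cache[[length(ctx$cache) + 1L]] <- cache
  invisible(NULL)
}

pop_cache <- function(ctx, tag) {
  n <- length(ctx$cache)
  if (n == 0L) stop("cache underflow at ", tag)
  cache <- ctx$cache[[n]]
  ctx$cache[[n]] <- NULL
  if (!identical(cache$tag, tag)) {
    stop(sprintf("cache mismatch: expected %s, found %s", tag, cache$tag))
  }
  cache
}

add_grad <- function(ctx, name, g) {
  cur <- ctx$grads[[name]]
  ctx$grads[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

P <- function(ctx, name) {
  p <- ctx$params[[name]]
  if (is.null(p)) stop("missing parameter ", name)
  p
}

# --- k x k same-padding convolution --------------------------------------
# Weights: matrix (k*k*Cin, Cout), column block order (ky, kx) column-major.

# Flat-index tables for im2col are memoised per shape: building the column
# matrix is then a single vector-indexing operation.
.conv_cache <- new.env(parent = emptyenv())

conv_indices <- function(H, W, B, Cin, k) {
  key <- paste(H, W, B, Cin, k, sep = "x")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- (k - 1L) %/% 2L
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  block_idx <- function(ky, kx) {
    hw <- outer(seq_len(H) + ky - 1L, (seq_len(W) + kx - 2L) * Hp, `+`)
    hwb <- outer(as.vector(hw), (seq_len(B) - 1L) * (Hp * Wp), `+`)
    as.vector(outer(as.vector(hwb), (seq_len(Cin) - 1L) * (Hp * Wp * B), `+`))
  }
  blocks <- vector("list", k * k)
  m <- 1L
  for (kx in seq_len(k)) {
    for (ky in seq_len(k)) {
      blocks[[m]] <- block_idx(ky, kx)
      m <- m + 1L
    }
  }
  center <- block_idx(pad + 1L, pad + 1L)
  out <- list(cols = unlist(blocks), blocks = blocks, center = center,
              padded_len = Hp * Wp * B * Cin)
  .conv_cache[[key]] <- out
  out
}

conv2d_cols <- function(xm, H, W, B, Cin, k) {
  if (k == 1L) return(xm)
  ci <- conv_indices(H, W, B, Cin, k)
  xpad <- numeric(ci$padded_len)
  xpad[ci$center] <- xm
  out <- xpad[ci$cols]
  dim(out) <- c(H * W * B, k * k * Cin)
  out
}

conv2d_cols_backward <- function(dXc, H, W, B, Cin, k) {
  if (k == 1L) return(dXc)
  ci <- conv_indices(H, W, B, Cin, k)
  dxpad <- numeric(ci$padded_len)
  nb <- H * W * B * Cin
  for (m in seq_along(ci$blocks)) {
    sel <- ci$blocks[[m]]
    dxpad[sel] <- dxpad[sel] + dXc[, (m - 1L) * Cin + seq_len(Cin)]
  }
  out <- dxpad[ci$center]
  dim(out) <- c(H * W * B, Cin)
  out
}

f_conv2d <- function(ctx, name, fm, k = 3L) {
  Wm <- P(ctx, paste0(name, ".W"))
  b <- P(ctx, paste0(name, ".b"))
  Xc <- conv2d_cols(fm$x, fm$H, fm$W, fm$B, fm$C, k)
  y <- Xc %*% Wm
  y <- y + rep(b, each = nrow(y))
  push_cache(ctx, list(tag = name, Xc = Xc, fm = fm, k = k))
  fm_new(y, fm$H, fm$W, fm$B)
}

b_conv2d <- function(ctx, name, dfm) {
  cache <- pop_cache(ctx, name)
  Wm <- P(ctx, paste0(name, ".W"))
  dy <- dfm$x
  add_grad(ctx, paste0(name, ".W"), crossprod(cache$Xc, dy))
  add_grad(ctx, paste0(name, ".b"), colSums(dy))
  dXc <- dy %*% t(Wm)
  dx <- conv2d_cols_backward(dXc, cache$fm$H, cache$fm$W, cache$fm$B,
                             cache$fm$C, cache$k)
  fm_new(dx, cache$fm$H, cache$fm$W, cache$fm$B)
}

# --- grouped pointwise (1x1) convolution ---------------------------------
# Weights: array (Cin/g, Cout/g, g) plus bias (Cout).

f_gconv <- function(ctx, name, fm) {
  Wa <- P(ctx, paste0(name, ".W"))
  b <- P(ctx, paste0(name, ".b"))
  g <- dim(Wa)[3]
  cig <- dim(Wa)[1]; cog <- dim(Wa)[2]
  if (fm$C != cig * g) stop_dim("gconv %s: input has %d channels, expects %d",
                                name, fm$C, cig * g)
  y <- matrix(0, nrow(fm$x), cog * g)
  for (gi in seq_len(g)) {
    ic <- (gi - 1L) * cig + seq_len(cig)
    oc <- (gi - 1L) * cog + seq_len(cog)
    y[, oc] <- fm$x[, ic, drop = FALSE] %*% Wa[, , gi]
  }
  y <- y + rep(b, each = nrow(y))
  push_cache(ctx, list(tag = name, fm = fm, g = g, cig = cig, cog = cog))
  fm_new(y, fm$H, fm$W, fm$B)
}

b_gconv <- function(ctx, name, dfm) {
  cache <- pop_cache(ctx, name)
  Wa <- P(ctx, paste0(name, ".W"))
  dW <- array(0, dim(Wa))
  dy <- dfm$x
  dx <- matrix(0, nrow(dy), cache$fm$C)
  for (gi in seq_len(cache$g)) {
    ic <- (gi - 1L) * cache$cig + seq_len(cache$cig)
    oc <- (gi - 1L) * cache$cog + seq_len(cache$cog)
    dyg <- dy[, oc, drop = FALSE]
    dW[, , gi] <- crossprod(cache$fm$x[, ic, drop = FALSE], dyg)
    dx[, ic] <- dyg %*% t(Wa[, , gi])
  }
  add_grad(ctx, paste0(name, ".W"), dW)
  add_grad(ctx, paste0(name, ".b"), colSums(dy))
  fm_new(dx, cache$fm$H, cache$fm$W, cache$fm$B)
}

# --- channel shuffle ------------------------------------------------------

shuffle_perm <- function(N, g) {
  if (N %% g != 0) stop_dim("channel count %d not divisible by groups %d", N, g)
  as.vector(t(matrix(seq_len(N), nrow = g)))
}

f_shuffle <- function(ctx, name, fm, g) {
  perm <- shuffle_perm(fm$C, g)
  push_cache(ctx, list(tag = name, perm = perm, fm_dims = fm[c("H", "W", "B")]))
  fm_new(fm$x[, perm, drop = FALSE], fm$H, fm$W, fm$B)
}

b_shuffle <- function(ctx, name, dfm) {
  cache <- pop_cache(ctx, name)
  inv <- order(cache$perm)
  fm_new(dfm$x[, inv, drop = FALSE], dfm$H, dfm$W, dfm$B)
}

# --- batch normalization --------------------------------------------------
# Normalizes each channel over batch and space. Running statistics live in
# ctx$state and are refreshed in training mode.

f_bn <- function(ctx, name, fm, eps = 1e-5, momentum = 0.1) {
  gamma <- P(ctx, paste0(name, ".gamma"))
  beta <- P(ctx, paste0(name, ".beta"))
  x <- fm$x
  n <- nrow(x)
  if (ctx$training) {
    mu <- .colMeans(x, n, fm$C)
    v <- .colMeans(x * x, n, fm$C) - mu^2
    v[v < 0] <- 0
    rkey_m <- paste0(name, ".running_mean")
    rkey_v <- paste0(name, ".running_var")
    rm <- ctx$state[[rkey_m]] %||% rep(0, fm$C)
    rv <- ctx$state[[rkey_v]] %||% rep(1, fm$C)
    ctx$state[[rkey_m]] <- (1 - momentum) * rm + momentum * mu
    ctx$state[[rkey_v]] <- (1 - momentum) * rv + momentum * v
  } else {
    mu <- ctx$state[[paste0(name, ".running_mean")]] %||% rep(0, fm$C)
    v <- ctx$state[[paste0(name, ".running_var")]] %||% rep(1, fm$C)
  }
  invstd <- 1 / sqrt(v + eps)
  a <- gamma * invstd
  y <- x * rep(a, each = n) + rep(beta - mu * a, each = n)
  push_cache(ctx, list(tag = name, x = x, mu = mu, invstd = invstd,
                       fm_dims = fm[c("H", "W", "B")]))
  fm_new(y, fm$H, fm$W, fm$B)
}

b_bn <- function(ctx, name, dfm) {
  cache <- pop_cache(ctx, name)
  gamma <- P(ctx, paste0(name, ".gamma"))
  dy <- dfm$x
  n <- nrow(dy)
  xhat <- (cache$x - rep(cache$mu, each = n)) * rep(cache$invstd, each = n)
  add_grad(ctx, paste0(name, ".gamma"), colSums(dy * xhat))
  add_grad(ctx, paste0(name, ".beta"), colSums(dy))
  if (ctx$training) {
    dxhat <- dy * rep(gamma, each = n)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dx <- (dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
      rep(cache$invstd, each = n)
  } else {
    dx <- dy * rep(gamma * cache$invstd, each = n)
  }
  fm_new(dx, dfm$H, dfm$W, dfm$B)
}

# --- elementwise activations ---------------------------------------------

f_relu <- function(ctx, name, fm) {
  y <- pmax(fm$x, 0)
  push_cache(ctx, list(tag = name, mask = fm$x > 0))
  fm_new(y, fm$H, fm$W, fm$B)
}

b_relu <- function(ctx, name, dfm) {
  cache <- pop_cache(ctx, name)
  fm_new(dfm$x * cache$mask, dfm$H, dfm$W, dfm$B)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- global average pooling: fm -> (B x C) matrix ------------------------

f_gap <- function(ctx, name, fm) {
  grp <- fm_rows_group(fm)
  z <- rowsum(fm$x, grp) / (fm$H * fm$W)
  push_cache(ctx, list(tag = name, fm_dims = fm[c("H", "W", "B")]))
  z
}

b_gap <- function(ctx, name, dz) {
  cache <- pop_cache(ctx, name)
  d <- cache$fm_dims
  grp <- rep(seq_len(d$B), each = d$H * d$W)
  fm_new(dz[grp, , drop = FALSE] / (d$H * d$W), d$H, d$W, d$B)
}

# --- broadcast channel scaling: y = x * s[b, c] --------------------------

f_scale_bc <- function(ctx, name, fm, s) {
  grp <- fm_rows_group(fm)
  y <- fm$x * s[grp, , drop = FALSE]
  push_cache(ctx, list(tag = name, fm = fm, s = s, grp = grp))
  fm_new(y, fm$H, fm$W, fm$B)
}

# returns list(dx = fm gradient, ds = (B x C) gradient)
b_scale_bc <- function(ctx, name, dfm) {
  cache <- pop_cache(ctx, name)
  dx <- dfm$x * cache$s[cache$grp, , drop = FALSE]
  ds <- rowsum(dfm$x * cache$fm$x, cache$grp)
  list(dx = fm_new(dx, dfm$H, dfm$W, dfm$B), ds = ds)
}

# --- fully connected on (B x F) matrices ---------------------------------

f_fc <- function(ctx, name, x) {
  Wm <- P(ctx, paste0(name, ".W"))
  b <- P(ctx, paste0(name, ".b"))
  y <- x %*% Wm + rep(b, each = nrow(x))
  push_cache(ctx, list(tag = name, x = x))
  y
}

b_fc <- function(ctx, name, dy) {
  cache <- pop_cache(ctx, name)
  Wm <- P(ctx, paste0(name, ".W"))
  add_grad(ctx, paste0(name, ".W"), crossprod(cache$x, dy))
  add_grad(ctx, paste0(name, ".b"), colSums(dy))
  dy %*% t(Wm)
}

f_relu_mat <- function(ctx, name, x) {
  push_cache(ctx, list(tag = name, mask = x > 0))
  pmax(x, 0)
}

b_relu_mat <- function(ctx, name, dy) {
  cache <- pop_cache(ctx, name)
  dy * cache$mask
}

f_dropout_mat <- function(ctx, name, x, rate) {
  if (!ctx$training || rate <= 0) {
    push_cache(ctx, list(tag = name, mask = NULL))
    return(x)
  }
  mask <- matrix(stats::rbinom(length(x), 1, 1 - rate) / (1 - rate),
                 nrow(x), ncol(x))
  push_cache(ctx, list(tag = name, mask = mask))
  x * mask
}

b_dropout_mat <- function(ctx, name, dy) {
  cache <- pop_cache(ctx, name)
  if (is.null(cache$mask)) dy else dy * cache$mask
}

# --- softmax + cross-entropy ---------------------------------------------

softmax_rows <- function(scores) {
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

# labels: 0-based integer class ids. Returns loss and dscores (mean-reduced).
softmax_ce <- function(scores, labels) {
  probs <- softmax_rows(scores)
  n <- nrow(scores)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dscores <- probs
  dscores[idx] <- dscores[idx] - 1
  list(loss = loss, dscores = dscores / n, probs = probs)
}

# --- initializers ---------------------------------------------------------

kaiming_uniform <- function(fan_in, dims) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

init_conv2d <- function(cin, cout, k = 3L) {
  list(W = matrix(kaiming_uniform(k * k * cin, c(k * k * cin, cout)),
                  k * k * cin, cout),
       b = rep(0, cout))
}

init_gconv <- function(cin, cout, g) {
  if (cin %% g != 0 || cout %% g != 0) {
    stop_dim("channel counts (%d -> %d) must be divisible by groups %d",
             cin, cout, g)
  }
  list(W = kaiming_uniform(cin / g, c(cin / g, cout / g, g)),
       b = rep(0, cout))
}

init_fc <- function(fin, fout) {
  list(W = matrix(kaiming_uniform(fin, c(fin, fout)), fin, fout),
       b = rep(0, fout))
}

init_bn <- function(c, gamma = 1) {
  list(gamma = rep(gamma, c), beta = rep(0, c))
}

# flatten a module init (list of arrays) into `params` under a name prefix
put_params <- function(params, prefix, mod) {
  for (nm in names(mod)) params[[paste0(prefix, ".", nm)]] <- mod[[nm]]
  params
}
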