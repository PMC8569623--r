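# ---------------------------------------------------------------------------
# Composite blocks and the multi-stream residual ConvLSTM network.
# ---------------------------------------------------------------------------

se_hidden_width <- function(channels, ratio) max(1L, as.integer(ceiling(channels / ratio)))

init_se <- function(channels, ratio) {
  hidden <- se_hidden_width(channels, ratio)
  c(stats::setNames(init_fc(channels, hidden), c("fc1.W", "fc1.b")),
    stats::setNames(init_fc(hidden, channels), c("fc2.W", "fc2.b")))
}

# squeeze-and-excitation: channel gates from globally pooled descriptors
f_se <- function(ctx, name, fm) {
  z <- f_gap(ctx, paste0(name, ".gap"), fm)
  h <- f_fc(ctx, paste0(name, ".fc1"), z)
  h <- f_relu_mat(ctx, paste0(name, ".r"), h)
  sraw <- f_fc(ctx, paste0(name, ".fc2"), h)
  s <- sigmoid(sraw)
  push_cache(ctx, list(tag = paste0(name, ".sig"), s = s))
  f_scale_bc(ctx, paste0(name, ".sc"), fm, s)
}

b_se <- function(ctx, name, dfm) {
  sc <- b_scale_bc(ctx, paste0(name, ".sc"), dfm)
  sig <- pop_cache(ctx, paste0(name, ".sig"))
  dsraw <- sc$ds * sig$s * (1 - sig$s)
  dh <- b_fc(ctx, paste0(name, ".fc2"), dsraw)
  dh <- b_relu_mat(ctx, paste0(name, ".r"), dh)
  dz <- b_fc(ctx, paste0(name, ".fc1"), dh)
  dx2 <- b_gap(ctx, paste0(name, ".gap"), dz)
  fm_new(sc$dx$x + dx2$x, dfm$H, dfm$W, dfm$B)
}

# Residual unit with SE recalibration of the branch before the addition:
#   y = shortcut(x) + SE(BN(gconv(relu(BN(conv3x3(shuffle(gconv(x))))))))
init_rese <- function(cin, cout, groups, se_ratio) {
  params <- list()
  params <- put_params(params, "pg1", init_gconv(cin, cout, groups))
  params <- put_params(params, "conv", init_conv2d(cout, cout, 3L))
  params <- put_params(params, "bn1", init_bn(cout))
  params <- put_params(params, "pg2", init_gconv(cout, cout, groups))
  params <- put_params(params, "bn2", init_bn(cout, gamma = 0))  # identity at init
  params <- put_params(params, "se", init_se(cout, se_ratio))
  if (cin != cout) params <- put_params(params, "proj", init_gconv(cin, cout, 1L))
  params
}

f_rese <- function(ctx, name, fm, groups) {
  br <- f_gconv(ctx, paste0(name, ".pg1"), fm)
  br <- f_shuffle(ctx, paste0(name, ".sh"), br, groups)
  br <- f_conv2d(ctx, paste0(name, ".conv"), br, 3L)
  br <- f_bn(ctx, paste0(name, ".bn1"), br)
  br <- f_relu(ctx, paste0(name, ".r1"), br)
  br <- f_gconv(ctx, paste0(name, ".pg2"), br)
  br <- f_bn(ctx, paste0(name, ".bn2"), br)
  br <- f_se(ctx, paste0(name, ".se"), br)
  has_proj <- !is.null(ctx$params[[paste0(name, ".proj.W")]])
  sc <- if (has_proj) f_gconv(ctx, paste0(name, ".proj"), fm) else fm
  push_cache(ctx, list(tag = paste0(name, ".add"), has_proj = has_proj))
  fm_new(sc$x + br$x, fm$H, fm$W, fm$B)
}

b_rese <- function(ctx, name, dfm, groups) {
  add <- pop_cache(ctx, paste0(name, ".add"))
  dsc <- if (add$has_proj) b_gconv(ctx, paste0(name, ".proj"), dfm) else dfm
  dbr <- b_se(ctx, paste0(name, ".se"), dfm)
  dbr <- b_bn(ctx, paste0(name, ".bn2"), dbr)
  dbr <- b_gconv(ctx, paste0(name, ".pg2"), dbr)
  dbr <- b_relu(ctx, paste0(name, ".r1"), dbr)
  dbr <- b_bn(ctx, paste0(name, ".bn1"), dbr)
  dbr <- b_conv2d(ctx, paste0(name, ".conv"), dbr)
  dbr <- b_shuffle(ctx, paste0(name, ".sh"), dbr)
  dbr <- b_gconv(ctx, paste0(name, ".pg1"), dbr)
  fm_new(dsc$x + dbr$x, dfm$H, dfm$W, dfm$B)
}

# ---------------------------------------------------------------------------
# Variant ConvLSTM cell: convolution only on the candidate path; forget,
# input and output gates act on globally pooled per-channel descriptors
# through fully connected maps and are broadcast over space.
# ---------------------------------------------------------------------------

init_vconvlstm <- function(cin, ch, k = 3L) {
  params <- list()
  cx <- init_conv2d(cin, ch, k); hx <- init_conv2d(ch, ch, k)
  params[["Wcx"]] <- cx$W
  params[["Wch"]] <- hx$W
  params[["bc"]] <- rep(0, ch)
  for (gate in c("f", "i", "o")) {
    params[[paste0("W", gate, "x")]] <- init_fc(cin, ch)$W
    params[[paste0("W", gate, "h")]] <- init_fc(ch, ch)$W
    params[[paste0("b", gate)]] <- rep(0, ch)
  }
  params
}

f_vcell <- function(ctx, name, X, Hp, Cp, k = 3L) {
  pfx <- function(s) P(ctx, paste0(name, ".", s))
  grp <- fm_rows_group(X)
  hw <- X$H * X$W
  px <- rowsum(X$x, grp) / hw
  ph <- rowsum(Hp$x, grp) / hw
  gates <- list()
  for (gate in c("f", "i", "o")) {
    pre <- px %*% pfx(paste0("W", gate, "x")) +
      ph %*% pfx(paste0("W", gate, "h"))
    pre <- pre + rep(pfx(paste0("b", gate)), each = nrow(pre))
    gates[[gate]] <- sigmoid(pre)
  }
  Xcx <- conv2d_cols(X$x, X$H, X$W, X$B, X$C, k)
  Xch <- conv2d_cols(Hp$x, Hp$H, Hp$W, Hp$B, Hp$C, k)
  pre_c <- Xcx %*% pfx("Wcx") + Xch %*% pfx("Wch")
  pre_c <- pre_c + rep(pfx("bc"), each = nrow(pre_c))
  cand <- tanh(pre_c)
  fb <- gates$f[grp, , drop = FALSE]
  ib <- gates$i[grp, , drop = FALSE]
  ob <- gates$o[grp, , drop = FALSE]
  Cn <- Cp$x * fb + cand * ib
  tC <- tanh(Cn)
  Hn <- tC * ob
  push_cache(ctx, list(tag = name, px = px, ph = ph, gates = gates,
                       Xcx = Xcx, Xch = Xch, cand = cand, Cp = Cp,
                       tC = tC, grp = grp, hw = hw, k = k,
                       dims = X[c("H", "W", "B", "C")],
                       hdims = Hp[c("H", "W", "B", "C")]))
  list(H = fm_new(Hn, X$H, X$W, X$B), C = fm_new(Cn, X$H, X$W, X$B))
}

b_vcell <- function(ctx, name, dH, dC) {
  cc <- pop_cache(ctx, name)
  pfx <- function(s) P(ctx, paste0(name, ".", s))
  grp <- cc$grp; hw <- cc$hw
  gates <- cc$gates
  ob <- gates$o[grp, , drop = FALSE]
  do_ <- rowsum(dH$x * cc$tC, grp)
  dtC <- dH$x * ob
  dCn <- dC$x + dtC * (1 - cc$tC^2)
  fb <- gates$f[grp, , drop = FALSE]
  ib <- gates$i[grp, , drop = FALSE]
  dCp <- dCn * fb
  df <- rowsum(dCn * cc$Cp$x, grp)
  dcand <- dCn * ib
  di <- rowsum(dCn * cc$cand, grp)
  dpre_c <- dcand * (1 - cc$cand^2)
  add_grad(ctx, paste0(name, ".Wcx"), crossprod(cc$Xcx, dpre_c))
  add_grad(ctx, paste0(name, ".Wch"), crossprod(cc$Xch, dpre_c))
  add_grad(ctx, paste0(name, ".bc"), colSums(dpre_c))
  dX <- conv2d_cols_backward(dpre_c %*% t(pfx("Wcx")), cc$dims$H, cc$dims$W,
                             cc$dims$B, cc$dims$C, cc$k)
  dHp <- conv2d_cols_backward(dpre_c %*% t(pfx("Wch")), cc$hdims$H,
                              cc$hdims$W, cc$hdims$B, cc$hdims$C, cc$k)
  dpx <- matrix(0, nrow(cc$px), ncol(cc$px))
  dph <- matrix(0, nrow(cc$ph), ncol(cc$ph))
  dgate <- list(f = df, i = di, o = do_)
  for (gate in c("f", "i", "o")) {
    g <- gates[[gate]]
    dpre <- dgate[[gate]] * g * (1 - g)
    add_grad(ctx, paste0(name, ".W", gate, "x"), crossprod(cc$px, dpre))
    add_grad(ctx, paste0(name, ".W", gate, "h"), crossprod(cc$ph, dpre))
    add_grad(ctx, paste0(name, ".b", gate), colSums(dpre))
    dpx <- dpx + dpre %*% t(pfx(paste0("W", gate, "x")))
    dph <- dph + dpre %*% t(pfx(paste0("W", gate, "h")))
  }
  dX <- dX + dpx[grp, , drop = FALSE] / hw
  dHp <- dHp + dph[grp, , drop = FALSE] / hw
  list(dX = fm_new(dX, cc$dims$H, cc$dims$W, cc$dims$B),
       dHp = fm_new(dHp, cc$hdims$H, cc$hdims$W, cc$hdims$B),
       dCp = fm_new(dCp, cc$dims$H, cc$dims$W, cc$dims$B))
}

# ---------------------------------------------------------------------------
# Public single-sample operations (channel-first arrays), the building
# blocks of the network exposed for direct use and verification.
# ---------------------------------------------------------------------------

#' Squeeze: per-channel global average pooling
#'
#' @param feature_map Numeric array `N x H x W` (channels first).
#' @return Numeric vector of length N: `z_n = mean(I_n)`.
#' @export
se_squeeze <- function(feature_map) {
  d <- dim(feature_map)
  if (length(d) != 3) stop_dim("feature_map must be N x H x W")
  rowMeans(matrix(feature_map, nrow = d[1]))
}

#' Excitation: two fully connected layers producing channel gates
#'
#' The first layer compresses N channels to `ceiling(N/k)` (minimum 1), the
#' second restores N; a sigmoid maps the result into (0, 1).
#'
#' @param z Numeric vector of pooled channel descriptors (length N).
#' @param weights List with `W1` (N x hidden), `b1`, `W2` (hidden x N), `b2`,
#'   e.g. from [se_weights()].
#' @return Gate vector `s` with entries strictly in (0, 1).
#' @export
se_excite <- function(z, weights) {
  h <- pmax(as.numeric(z %*% weights$W1) + weights$b1, 0)
  as.numeric(sigmoid(as.numeric(h %*% weights$W2) + weights$b2))
}

#' @rdname se_excite
#' @param channels Number of channels N.
#' @param ratio Compression divisor k.
#' @param seed Seed for the weight draw.
#' @export
se_weights <- function(channels, ratio, seed = 1L) {
  with_local_seed(seed, {
    m <- init_se(channels, ratio)
    list(W1 = m[["fc1.W"]], b1 = m[["fc1.b"]],
         W2 = m[["fc2.W"]], b2 = m[["fc2.b"]])
  })
}

#' Channel shuffle permutation
#'
#' Reindexes channels by reshaping to (g, N/g), transposing and flattening,
#' so information can flow between the groups of a preceding grouped
#' convolution. A pure permutation: values are untouched.
#'
#' @param x Numeric array whose first dimension indexes channels.
#' @param g Number of groups; must divide the channel count.
#' @return `x` with permuted channels.
#' @export
channel_shuffle <- function(x, g) {
  d <- dim(x) %||% length(x)
  N <- d[1]
  perm <- shuffle_perm(N, g)
  if (is.null(dim(x))) return(x[perm])
  idx <- as.list(rep(TRUE, length(d)))
  idx[[1]] <- perm
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Grouped pointwise (1x1) convolution
#'
#' A 1x1 convolution computed independently inside each of `g` channel
#' groups, with `N_in * N_out / g` weights (plus `N_out` biases) instead of
#' the dense `N_in * N_out`.
#'
#' @param x Numeric array `N_in x H x W`.
#' @param g Number of groups; must divide both channel counts.
#' @param weights List with `W` (array `N_in/g x N_out/g x g`) and `b`
#'   (length `N_out`), e.g. from [grouped_pointwise_weights()].
#' @return Numeric array `N_out x H x W`.
#' @export
grouped_pointwise_conv <- function(x, g, weights) {
  d <- dim(x)
  if (length(d) != 3) stop_dim("x must be N x H x W")
  if (dim(weights$W)[3] != g) stop_dim("weights are for %d groups, g = %d",
                                       dim(weights$W)[3], g)
  ctx <- new_ctx(list(pw.W = weights$W, pw.b = weights$b))
  out <- f_gconv(ctx, "pw", fm_from_chw(x))
  fm_to_chw(out)
}

#' @rdname grouped_pointwise_conv
#' @param cin,cout Input/output channel counts.
#' @param seed Seed for the weight draw.
#' @export
grouped_pointwise_weights <- function(cin, cout, g, seed = 1L) {
  with_local_seed(seed, init_gconv(cin, cout, g))
}

#' @rdname grouped_pointwise_conv
#' @param bias Include bias parameters in the count.
#' @return `grouped_pointwise_param_count`: number of trainable parameters.
#' @export
grouped_pointwise_param_count <- function(cin, cout, g, bias = TRUE) {
  cin * cout / g + if (bias) cout else 0
}

#' Residual unit with squeeze-and-excitation recalibration
#'
#' Computes `y = shortcut(x) + SE(F(x))` where the branch `F` is
#' grouped 1x1 convolution, channel shuffle, 3x3 convolution, batch norm,
#' ReLU, grouped 1x1 convolution, batch norm, and SE rescales the branch
#' channel-wise before the addition. The shortcut is the identity, or a 1x1
#' projection when the channel counts differ.
#'
#' @param x Numeric array `C_in x H x W`.
#' @param params Parameter list from [re_se_params()] (modifiable by name).
#' @return Numeric array `C_out x H x W`.
#' @export
re_se_block <- function(x, params) {
  groups <- attr(params, "groups")
  ctx <- new_ctx(params)
  out <- f_rese(ctx, "u", fm_from_chw(x), groups)
  fm_to_chw(out)
}

#' @rdname re_se_block
#' @param cin,cout Input/output channel counts.
#' @param groups Groups of the pointwise convolutions.
#' @param se_ratio SE compression divisor.
#' @param seed Seed for the weight draw.
#' @export
re_se_params <- function(cin, cout, groups = 2, se_ratio = 4, seed = 1L) {
  p <- with_local_seed(seed, init_rese(cin, cout, groups, se_ratio))
  names(p) <- paste0("u.", names(p))
  attr(p, "groups") <- groups
  p
}

#' ConvLSTM cell step (all-convolutional gates)
#'
#' The baseline spatiotemporal cell: forget, input and output gates and the
#' candidate are all convolutions of the input map and previous hidden map,
#' with sigmoid/tanh nonlinearities, `C_t = f o C_{t-1} + i o tanh(cand)`
#' and `H_t = o o tanh(C_t)`.
#'
#' @param X Input map, array `C_in x H x W`.
#' @param H_prev,C_prev Previous hidden and cell maps, `C_h x H x W`.
#' @param params Parameter list from [convlstm_params()].
#' @return List with updated maps `H` and `C`.
#' @export
convlstm_step <- function(X, H_prev, C_prev, params) {
  k <- attr(params, "kernel")
  xf <- fm_from_chw(X); hf <- fm_from_chw(H_prev); cf <- fm_from_chw(C_prev)
  if (!identical(dim(H_prev)[2:3], dim(X)[2:3])) {
    stop_dim("H_prev spatial dims must match X")
  }
  Xcx <- conv2d_cols(xf$x, xf$H, xf$W, xf$B, xf$C, k)
  Xch <- conv2d_cols(hf$x, hf$H, hf$W, hf$B, hf$C, k)
  gate <- function(gx, gh, b) {
    sigmoid(Xcx %*% params[[gx]] + Xch %*% params[[gh]] +
              rep(params[[b]], each = nrow(Xcx)))
  }
  f <- gate("Wfx", "Wfh", "bf")
  i <- gate("Wix", "Wih", "bi")
  o <- gate("Wox", "Woh", "bo")
  cand <- tanh(Xcx %*% params[["Wcx"]] + Xch %*% params[["Wch"]] +
                 rep(params[["bc"]], each = nrow(Xcx)))
  Cn <- cf$x * f + cand * i
  Hn <- tanh(Cn) * o
  list(H = fm_to_chw(fm_new(Hn, xf$H, xf$W, 1L)),
       C = fm_to_chw(fm_new(Cn, xf$H, xf$W, 1L)))
}

#' @rdname convlstm_step
#' @param cin Input channel count.
#' @param ch Hidden channel count.
#' @param kernel Convolution kernel size (odd).
#' @param seed Seed for the weight draw.
#' @export
convlstm_params <- function(cin, ch, kernel = 3L, seed = 1L) {
  p <- with_local_seed(seed, {
    params <- list()
    for (gate in c("f", "i", "o", "c")) {
      params[[paste0("W", gate, "x")]] <- init_conv2d(cin, ch, kernel)$W
      params[[paste0("W", gate, "h")]] <- init_conv2d(ch, ch, kernel)$W
      params[[paste0("b", gate)]] <- rep(0, ch)
    }
    params
  })
  attr(p, "kernel") <- as.integer(kernel)
  p
}

#' @rdname convlstm_step
#' @return `convlstm_param_count` / `vconvlstm_param_count`: total trainable
#'   parameter count of the respective cell.
#' @export
convlstm_param_count <- function(cin, ch, kernel = 3L) {
  4 * (kernel^2 * cin * ch + kernel^2 * ch * ch + ch)
}

#' Variant ConvLSTM cell step (pooled-descriptor gates)
#'
#' Keeps convolution only on the candidate path; the three gates are
#' computed from globally pooled per-channel descriptors of the input and
#' previous hidden map through fully connected maps, giving one scalar gate
#' per channel that is broadcast over space:
#' `f_t = sigma(W_fh GP(H_{t-1}) + W_fx GP(X_t) + b_f)`, analogously for
#' `i_t` and `o_t`, `C_t = f_t o C_{t-1} + i_t o tanh(W_ch * H_{t-1} +
#' W_cx * X_t + b_c)`, `H_t = o_t o tanh(C_t)`.
#'
#' @param X Input map, array `C_in x H x W`.
#' @param H_prev,C_prev Previous hidden and cell maps, `C_h x H x W`.
#' @param params Parameter list from [vconvlstm_params()].
#' @return List with updated maps `H` and `C`.
#' @export
vconvlstm_step <- function(X, H_prev, C_prev, params) {
  k <- attr(params, "kernel")
  p <- params
  names(p) <- paste0("cell.", names(p))
  ctx <- new_ctx(p)
  out <- f_vcell(ctx, "cell", fm_from_chw(X), fm_from_chw(H_prev),
                 fm_from_chw(C_prev), k)
  list(H = fm_to_chw(out$H), C = fm_to_chw(out$C))
}

#' @rdname vconvlstm_step
#' @param cin Input channel count.
#' @param ch Hidden channel count.
#' @param kernel Candidate convolution kernel size (odd).
#' @param seed Seed for the weight draw.
#' @export
vconvlstm_params <- function(cin, ch, kernel = 3L, seed = 1L) {
  p <- with_local_seed(seed, init_vconvlstm(cin, ch, kernel))
  attr(p, "kernel") <- as.integer(kernel)
  p
}

#' @rdname vconvlstm_step
#' @export
vconvlstm_param_count <- function(cin, ch, kernel = 3L) {
  conv <- kernel^2 * cin * ch + kernel^2 * ch * ch + ch
  gates <- 3 * (cin * ch + ch * ch + ch)
  conv + gates
}

# ---------------------------------------------------------------------------
# Full network: multi-stream residual front end, fusion, Variant ConvLSTM
# temporal integration, accelerometer branch, classifier head.
# ---------------------------------------------------------------------------

#' Network architecture configuration
#'
#' @param mode Input representation: `"feature"` (4 x C feature images) or
#'   `"raw"` (channels x time sEMG images).
#' @param streams Number of streams n; the input image is decomposed into n
#'   equal patches along time, one per stream.
#' @param widths Channel widths: stem, first and second residual unit.
#' @param groups Groups of the pointwise convolutions (must divide widths).
#' @param se_ratio SE compression divisor k.
#' @param lstm_hidden Hidden channel count of the Variant ConvLSTM.
#' @param lstm_kernel Candidate convolution kernel size.
#' @param fusion_channels Channels after the fusion 1x1 grouped convolution
#'   (default: last width).
#' @param fc_dim Width of the fully connected layer before the classifier.
#' @param dropout Dropout rate after that layer (default 0.5).
#' @param n_classes Number of gesture classes.
#' @param use_acc Add the accelerometer branch.
#' @param acc_hidden Widths of the two accelerometer FC layers.
#' @param raw_decimation Decimation factor applied along time to raw sEMG
#'   images before the network (reduces the 1000 Hz time axis to a
#'   tractable map height; not used in feature mode).
#' @export
model_config <- function(mode = c("feature", "raw"), streams = 4,
                         widths = c(16, 32, 64), groups = 2, se_ratio = 4,
                         lstm_hidden = 32, lstm_kernel = 3,
                         fusion_channels = NULL, fc_dim = 64, dropout = 0.5,
                         n_classes = 6, use_acc = TRUE, acc_hidden = c(16, 8),
                         raw_decimation = 10) {
  mode <- match.arg(mode)
  if (any(widths %% groups != 0)) stop_config("widths must be divisible by groups")
  if (dropout < 0 || dropout >= 1) stop_config("dropout must be in [0, 1)")
  # default fusion width: widen for multi-stream nets so concatenating the
  # streams is not immediately compressed back to a single stream's width
  fusion_channels <- fusion_channels %||%
    (if (streams > 1) 2L * widths[3] else widths[3])
  fuse_groups <- if (streams > 1) streams else 1L
  if ((streams * widths[3]) %% fuse_groups != 0 ||
      fusion_channels %% fuse_groups != 0) {
    stop_config("fusion_channels must be divisible by the stream count")
  }
  structure(list(mode = mode, streams = as.integer(streams), widths = widths,
                 groups = as.integer(groups), se_ratio = se_ratio,
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_kernel = as.integer(lstm_kernel),
                 fusion_channels = as.integer(fusion_channels),
                 fuse_groups = as.integer(fuse_groups),
                 fc_dim = as.integer(fc_dim), dropout = dropout,
                 n_classes = as.integer(n_classes), use_acc = use_acc,
                 acc_hidden = as.integer(acc_hidden),
                 raw_decimation = as.integer(raw_decimation),
                 acc_features = 9L),
            class = "semg_model_config")
}

#' Initialise network weights
#'
#' Kaiming-uniform convolution/FC weights, zero biases, and zero scale on
#' the last batch norm of each residual branch so every unit starts as the
#' identity.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the weight draw.
#' @return An object of class `semg_model`: list with `cfg`, flat named
#'   `params` and batch-norm `state`.
#' @export
init_model <- function(cfg, seed = 1L) {
  w <- cfg$widths
  params <- with_local_seed(seed, {
    p <- list()
    for (s in seq_len(cfg$streams)) {
      pre <- paste0("st", s)
      p <- put_params(p, paste0(pre, ".stem"), init_conv2d(1L, w[1], 3L))
      p <- put_params(p, paste0(pre, ".sbn"), init_bn(w[1]))
      u1 <- init_rese(w[1], w[2], cfg$groups, cfg$se_ratio)
      names(u1) <- paste0(pre, ".u1.", names(u1))
      p <- c(p, u1)
      u2 <- init_rese(w[2], w[3], cfg$groups, cfg$se_ratio)
      names(u2) <- paste0(pre, ".u2.", names(u2))
      p <- c(p, u2)
    }
    p <- put_params(p, "fuse", init_gconv(cfg$streams * w[3],
                                          cfg$fusion_channels,
                                          cfg$fuse_groups))
    p <- put_params(p, "fbn", init_bn(cfg$fusion_channels))
    cell <- init_vconvlstm(cfg$fusion_channels, cfg$lstm_hidden,
                           cfg$lstm_kernel)
    names(cell) <- paste0("lstm.", names(cell))
    p <- c(p, cell)
    head_in <- cfg$lstm_hidden
    if (cfg$use_acc) {
      p <- put_params(p, "acc1", init_fc(cfg$acc_features, cfg$acc_hidden[1]))
      p <- put_params(p, "acc2", init_fc(cfg$acc_hidden[1], cfg$acc_hidden[2]))
      head_in <- head_in + cfg$acc_hidden[2]
    }
    p <- put_params(p, "cbn", init_bn(head_in))
    p <- put_params(p, "head1", init_fc(head_in, cfg$fc_dim))
    p <- put_params(p, "hbn", init_bn(cfg$fc_dim))
    p <- put_params(p, "head2", init_fc(cfg$fc_dim, cfg$n_classes))
    p
  })
  structure(list(cfg = cfg, params = params, state = list()),
            class = "semg_model")
}

#' @export
print.semg_model <- function(x, ...) {
  n <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<semg_model> mode=%s streams=%d params=%d\n",
              x$cfg$mode, x$cfg$streams, n))
  invisible(x)
}

stream_forward <- function(ctx, pre, fm, cfg) {
  y <- f_conv2d(ctx, paste0(pre, ".stem"), fm, 3L)
  y <- f_bn(ctx, paste0(pre, ".sbn"), y)
  y <- f_relu(ctx, paste0(pre, ".sr"), y)
  y <- f_rese(ctx, paste0(pre, ".u1"), y, cfg$groups)
  f_rese(ctx, paste0(pre, ".u2"), y, cfg$groups)
}

stream_backward <- function(ctx, pre, dfm, cfg) {
  d <- b_rese(ctx, paste0(pre, ".u2"), dfm, cfg$groups)
  d <- b_rese(ctx, paste0(pre, ".u1"), d, cfg$groups)
  d <- b_relu(ctx, paste0(pre, ".sr"), d)
  d <- b_bn(ctx, paste0(pre, ".sbn"), d)
  b_conv2d(ctx, paste0(pre, ".stem"), d)
}

# Forward pass over a prepared batch.
# emg: array (H, Wfull, steps, B); acc: B x 9 matrix or NULL.
# Returns logits (B x n_classes); caches stay on ctx for the backward pass.
network_forward <- function(ctx, cfg, emg, acc) {
  d <- dim(emg)
  H <- d[1]; Wfull <- d[2]; steps <- d[3]; B <- d[4]
  if (Wfull %% cfg$streams != 0) {
    stop_dim("image width %d not divisible by %d streams", Wfull, cfg$streams)
  }
  wp <- Wfull %/% cfg$streams
  hfm <- NULL; cfm <- NULL
  for (t in seq_len(steps)) {
    outs <- vector("list", cfg$streams)
    for (s in seq_len(cfg$streams)) {
      cols <- (s - 1L) * wp + seq_len(wp)
      patch <- emg[, cols, t, , drop = FALSE]
      x <- fm_new(matrix(patch, H * wp * B, 1L), H, wp, B)
      outs[[s]] <- stream_forward(ctx, paste0("st", s), x, cfg)
    }
    xf <- fm_new(do.call(cbind, lapply(outs, `[[`, "x")), H, wp, B)
    xf <- f_gconv(ctx, "fuse", xf)
    xf <- f_bn(ctx, "fbn", xf)
    xf <- f_relu(ctx, "fr", xf)
    if (is.null(hfm)) {
      zero <- fm_new(matrix(0, H * wp * B, cfg$lstm_hidden), H, wp, B)
      hfm <- zero; cfm <- zero
    }
    st <- f_vcell(ctx, "lstm", xf, hfm, cfm, cfg$lstm_kernel)
    hfm <- st$H; cfm <- st$C
  }
  feat <- f_gap(ctx, "hgap", hfm)
  if (cfg$use_acc) {
    if (is.null(acc)) stop_config("model requires accelerometer input")
    a <- f_fc(ctx, "acc1", acc)
    a <- f_relu_mat(ctx, "accr1", a)
    a <- f_fc(ctx, "acc2", a)
    a <- f_relu_mat(ctx, "accr2", a)
    feat <- cbind(feat, a)
  }
  # normalise the fused feature vector: the pooled hidden maps and the
  # accelerometer branch live on very different scales, and without this
  # the larger branch drowns the other in the shared head
  featfm <- f_bn(ctx, "cbn", fm_new(feat, 1L, 1L, nrow(feat)))
  feat <- featfm$x
  y <- f_fc(ctx, "head1", feat)
  yfm <- f_bn(ctx, "hbn", fm_new(y, 1L, 1L, nrow(y)))
  y <- f_relu_mat(ctx, "hr", yfm$x)
  y <- f_dropout_mat(ctx, "hdrop", y, cfg$dropout)
  f_fc(ctx, "head2", y)
}

network_backward <- function(ctx, cfg, dscores, dims) {
  H <- dims$H; wp <- dims$wp; steps <- dims$steps; B <- dims$B
  dy <- b_fc(ctx, "head2", dscores)
  dy <- b_dropout_mat(ctx, "hdrop", dy)
  dy <- b_relu_mat(ctx, "hr", dy)
  dyf <- b_bn(ctx, "hbn", fm_new(dy, 1L, 1L, nrow(dy)))
  dfeat <- b_fc(ctx, "head1", dyf$x)
  dfeat <- b_bn(ctx, "cbn", fm_new(dfeat, 1L, 1L, nrow(dfeat)))$x
  if (cfg$use_acc) {
    nh <- cfg$lstm_hidden
    da <- dfeat[, (nh + 1):ncol(dfeat), drop = FALSE]
    dfeat <- dfeat[, seq_len(nh), drop = FALSE]
    da <- b_relu_mat(ctx, "accr2", da)
    da <- b_fc(ctx, "acc2", da)
    da <- b_relu_mat(ctx, "accr1", da)
    b_fc(ctx, "acc1", da)
  }
  dH <- b_gap(ctx, "hgap", dfeat)
  dC <- fm_new(matrix(0, H * wp * B, cfg$lstm_hidden), H, wp, B)
  for (t in seq(steps, 1L)) {
    cell <- b_vcell(ctx, "lstm", dH, dC)
    dX <- cell$dX
    if (t > 1L) {
      dH <- cell$dHp; dC <- cell$dCp
    }
    dX <- b_relu(ctx, "fr", dX)
    dX <- b_bn(ctx, "fbn", dX)
    dX <- b_gconv(ctx, "fuse", dX)
    w3 <- cfg$widths[3]
    for (s in seq(cfg$streams, 1L)) {
      cols <- (s - 1L) * w3 + seq_len(w3)
      stream_backward(ctx, paste0("st", s),
                      fm_new(dX$x[, cols, drop = FALSE], H, wp, B), cfg)
    }
  }
  invisible(NULL)
}

#' Forward pass: class probabilities for a prepared batch
#'
#' Runs the network in inference mode (dropout off, batch norm using running
#' statistics) and returns softmax class scores.
#'
#' @param model A `semg_model`.
#' @param emg Array `H x W x steps x B` of windowed image sequences.
#' @param acc Optional `B x 9` accelerometer feature matrix (required when
#'   the model was configured with `use_acc`).
#' @return `B x n_classes` matrix of probabilities; rows sum to 1.
#' @export
predict_scores <- function(model, emg, acc = NULL) {
  ctx <- new_ctx(model$params, model$state, training = FALSE)
  scores <- network_forward(ctx, model$cfg, emg, acc)
  unname(softmax_rows(scores))
}

#' Per-layer parameter counts of a model
#'
#' @param model A `semg_model`.
#' @return A data.frame with layer name and parameter count, plus the total
#'   as an attribute.
#' @export
model_summary <- function(model) {
  counts <- vapply(model$params, length, numeric(1))
  layer <- sub("\\.[^.]+$", "", names(counts))
  agg <- stats::aggregate(counts, by = list(layer = layer), FUN = sum)
  names(agg)[2] <- "parameters"
  attr(agg, "total") <- sum(counts)
  agg
}
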