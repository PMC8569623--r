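# Independent brute-force oracles: explicit scalar loops, no shared code
# with the package implementation.

# same-padding 2-D convolution of a (C,H,W) array with weight matrix
# (k*k*Cin x Cout); column blocks ordered (kx, ky) with ky fastest, channels
# fastest within a block.
oracle_conv_chw <- function(x, Wm, b, k) {
  d <- dim(x); Cin <- d[1]; H <- d[2]; W <- d[3]
  Cout <- ncol(Wm)
  p <- (k - 1) / 2
  out <- array(0, c(Cout, H, W))
  for (co in seq_len(Cout)) {
    for (h in seq_len(H)) {
      for (w in seq_len(W)) {
        acc <- b[co]
        for (kx in seq_len(k)) {
          for (ky in seq_len(k)) {
            hh <- h + ky - 1 - p
            ww <- w + kx - 1 - p
            if (hh >= 1 && hh <= H && ww >= 1 && ww <= W) {
              m <- (kx - 1) * k + ky
              for (ci in seq_len(Cin)) {
                acc <- acc + Wm[(m - 1) * Cin + ci, co] * x[ci, hh, ww]
              }
            }
          }
        }
        out[co, h, w] <- acc
      }
    }
  }
  out
}

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# ConvLSTM cell: every gate and the candidate are convolutions.
oracle_convlstm_step <- function(X, Hp, Cp, params) {
  k <- attr(params, "kernel")
  ch <- dim(Hp)[1]
  gate <- function(wx, wh, bb) {
    oracle_sigmoid(oracle_conv_chw(X, params[[wx]], rep(0, ch), k) +
                     oracle_conv_chw(Hp, params[[wh]], rep(0, ch), k) +
                     array(rep(params[[bb]], prod(dim(Hp)[2:3])), dim(Hp)))
  }
  f <- gate("Wfx", "Wfh", "bf")
  i <- gate("Wix", "Wih", "bi")
  o <- gate("Wox", "Woh", "bo")
  cand <- tanh(oracle_conv_chw(X, params$Wcx, rep(0, ch), k) +
                 oracle_conv_chw(Hp, params$Wch, rep(0, ch), k) +
                 array(rep(params$bc, prod(dim(Hp)[2:3])), dim(Hp)))
  Cn <- f * Cp + i * cand
  list(H = o * tanh(Cn), C = Cn)
}

# Variant ConvLSTM cell: gates from per-channel global means through FC
# maps (scalar per channel, broadcast over space); candidate convolutional.
oracle_vconvlstm_step <- function(X, Hp, Cp, params) {
  k <- attr(params, "kernel")
  ch <- dim(Hp)[1]
  px <- apply(X, 1, mean)
  ph <- apply(Hp, 1, mean)
  gate <- function(wx, wh, bb) {
    g <- numeric(ch)
    for (n in seq_len(ch)) {
      acc <- params[[bb]][n]
      for (c in seq_along(px)) acc <- acc + params[[wx]][c, n] * px[c]
      for (m in seq_along(ph)) acc <- acc + params[[wh]][m, n] * ph[m]
      g[n] <- oracle_sigmoid(acc)
    }
    g
  }
  f <- gate("Wfx", "Wfh", "bf")
  i <- gate("Wix", "Wih", "bi")
  o <- gate("Wox", "Woh", "bo")
  cand <- tanh(oracle_conv_chw(X, params$Wcx, rep(0, ch), k) +
                 oracle_conv_chw(Hp, params$Wch, rep(0, ch), k) +
                 array(rep(params$bc, prod(dim(Hp)[2:3])), dim(Hp)))
  Cn <- Cp * f + cand * i  # per-channel gates broadcast over space
  for (n in seq_len(ch)) Cn[n, , ] <- f[n] * Cp[n, , ] + i[n] * cand[n, , ]
  Hn <- Cn
  for (n in seq_len(ch)) Hn[n, , ] <- o[n] * tanh(Cn[n, , ])
  list(H = Hn, C = Cn)
}

# intersection-over-union of two half-open integer intervals
interval_iou <- function(a_start, a_end, b_start, b_end) {
  inter <- max(0, min(a_end, b_end) - max(a_start, b_start))
  uni <- (a_end - a_start) + (b_end - b_start) - inter
  if (uni <= 0) return(0)
  inter / uni
}
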