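test_that("squeeze equals the per-channel mean (loop oracle)", {
  expect_equal(se_squeeze(array(4.2, c(3, 2, 2))), rep(4.2, 3))
  expect_equal(se_squeeze(array(c(1, 3, 2, 4), c(1, 2, 2))), 2.5)
  set.seed(101)
  m <- array(rnorm(8 * 5 * 7), c(8, 5, 7))
  z <- numeric(8)
  for (n in 1:8) {
    for (i in 1:5) for (j in 1:7) z[n] <- z[n] + m[n, i, j]
  }
  expect_equal(se_squeeze(m), z / 35, tolerance = 1e-12)
})

test_that("excitation gates are strictly inside (0,1), 0.5 at zero weights", {
  w0 <- se_weights(6, 2, seed = 1)
  for (nm in names(w0)) w0[[nm]][] <- 0
  expect_equal(se_excite(rnorm(6), w0), rep(0.5, 6))
  set.seed(103)
  for (i in 1:5) {
    w <- se_weights(8, 4, seed = i)
    s <- se_excite(rnorm(8), w)
    expect_true(all(s > 0 & s < 1))
  }
  # declared shapes: N=8, k=4 compresses to hidden width 2; 42 parameters
  w <- se_weights(8, 4)
  expect_equal(dim(w$W1), c(8, 2))
  expect_equal(length(w$W1) + length(w$b1) + length(w$W2) + length(w$b2), 42)
})

test_that("channel shuffle is the reshape-transpose permutation", {
  x <- array(1:(4 * 2 * 2), c(4, 2, 2))
  expect_identical(channel_shuffle(x, 1), x)
  expect_equal(channel_shuffle(1:4, 2), c(1L, 3L, 2L, 4L))
  for (N in 2:12) {
    for (g in (1:N)[N %% (1:N) == 0]) {
      v <- seq_len(N) * 10
      s <- channel_shuffle(v, g)
      expect_equal(sort(s), sort(v))                    # permutation
      expect_equal(channel_shuffle(s, N / g), v)        # inverse
    }
  }
})

test_that("grouped pointwise conv isolates groups and counts parameters", {
  set.seed(107)
  x <- array(rnorm(8 * 3 * 4), c(8, 3, 4))
  # g = 1 equals a dense 1x1 convolution with the same weights
  w1 <- grouped_pointwise_weights(8, 6, 1, seed = 2)
  y <- grouped_pointwise_conv(x, 1, w1)
  dense <- apply(x, c(2, 3), function(v) as.numeric(v %*% w1$W[, , 1]) + w1$b)
  expect_equal(y, aperm(dense, c(1, 2, 3)), tolerance = 1e-12)
  # parameter economy: exactly dense / g
  for (cfg in list(c(8, 2), c(16, 4), c(32, 8))) {
    N <- cfg[1]; g <- cfg[2]
    expect_equal(grouped_pointwise_param_count(N, N, g, bias = FALSE),
                 N * N / g)
    expect_equal(grouped_pointwise_param_count(N, N, 1, bias = FALSE) /
                   grouped_pointwise_param_count(N, N, g, bias = FALSE), g)
  }
  w2 <- grouped_pointwise_weights(8, 8, 2, seed = 3)
  expect_equal(length(w2$W), 32)
  # zeroing the second input group leaves first-group outputs unchanged
  y_full <- grouped_pointwise_conv(x, 2, w2)
  x0 <- x; x0[5:8, , ] <- 0
  y_zero <- grouped_pointwise_conv(x0, 2, w2)
  expect_equal(y_zero[1:4, , ], y_full[1:4, , ], tolerance = 1e-12)
  expect_error(grouped_pointwise_conv(x, 3, w2), "groups")
})

test_that("the Re-SE unit reduces to its parts", {
  set.seed(109)
  x <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  # zeroed branch: identity shortcut passes x through exactly
  p <- re_se_params(4, 4, groups = 2, se_ratio = 2, seed = 4)
  for (nm in grep("(pg1|pg2|conv)\\.(W|b)", names(p), value = TRUE)) {
    p[[nm]][] <- 0
  }
  expect_equal(re_se_block(x, p), x, tolerance = 1e-12)
  # random weights: equals manual composition of the standalone ops
  p2 <- re_se_params(4, 4, groups = 2, se_ratio = 2, seed = 5)
  y <- re_se_block(x, p2)
  gp1 <- grouped_pointwise_conv(x, 2, list(W = p2[["u.pg1.W"]],
                                           b = p2[["u.pg1.b"]]))
  sh <- channel_shuffle(gp1, 2)
  cv <- oracle_conv_chw(sh, p2[["u.conv.W"]], p2[["u.conv.b"]], 3)
  # inference-mode batch norm with fresh running stats: y = gamma*x + beta
  bn1 <- cv * p2[["u.bn1.gamma"]] / sqrt(1 + 1e-5) + p2[["u.bn1.beta"]]
  r1 <- pmax(bn1, 0)
  gp2 <- grouped_pointwise_conv(r1, 2, list(W = p2[["u.pg2.W"]],
                                            b = p2[["u.pg2.b"]]))
  bn2 <- gp2 * p2[["u.bn2.gamma"]] / sqrt(1 + 1e-5) + p2[["u.bn2.beta"]]
  z <- se_squeeze(bn2)
  s <- se_excite(z, list(W1 = p2[["u.se.fc1.W"]], b1 = p2[["u.se.fc1.b"]],
                         W2 = p2[["u.se.fc2.W"]], b2 = p2[["u.se.fc2.b"]]))
  manual <- x + bn2 * s
  expect_equal(y, manual, tolerance = 1e-9)
  # SE gates in (0,1) never flip activation signs before the addition
  expect_true(all(sign(bn2 * s) == sign(bn2) | bn2 == 0))
})

test_that("both cells obey the zero-weight closed form", {
  set.seed(113)
  X <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  Hp <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  Cp <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  pz <- vconvlstm_params(2, 3, seed = 1)
  for (nm in names(pz)) pz[[nm]][] <- 0
  st <- vconvlstm_step(X, Hp, Cp, pz)
  expect_equal(st$H, 0.5 * tanh(0.5 * Cp), tolerance = 1e-12)
  expect_equal(st$C, 0.5 * Cp, tolerance = 1e-12)
  cz <- convlstm_params(2, 3, seed = 1)
  for (nm in names(cz)) cz[[nm]][] <- 0
  st2 <- convlstm_step(X, Hp, Cp, cz)
  expect_equal(st2$H, 0.5 * tanh(0.5 * Cp), tolerance = 1e-12)
  expect_equal(st2$C, 0.5 * Cp, tolerance = 1e-12)
})

test_that("saturated gates hold the cell memory", {
  set.seed(127)
  p <- convlstm_params(2, 2, seed = 6)
  p$bf[] <- 30; p$bi[] <- -30; p$bo[] <- 0
  X <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  Hp <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  Cp <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  st <- convlstm_step(X, Hp, Cp, p)
  expect_equal(st$C, Cp, tolerance = 1e-3)
})

test_that("cells match independent scalar-loop oracles", {
  set.seed(131)
  for (i in 1:8) {
    cin <- sample(1:4, 1); ch <- sample(1:4, 1)
    H <- sample(2:6, 1); W <- sample(2:6, 1)
    X <- array(rnorm(cin * H * W), c(cin, H, W))
    Hp <- array(rnorm(ch * H * W), c(ch, H, W))
    Cp <- array(rnorm(ch * H * W), c(ch, H, W))
    pv <- vconvlstm_params(cin, ch, seed = 1000 + i)
    for (nm in names(pv)) pv[[nm]][] <- rnorm(length(pv[[nm]]), 0, 0.5)
    got <- vconvlstm_step(X, Hp, Cp, pv)
    want <- oracle_vconvlstm_step(X, Hp, Cp, pv)
    expect_lt(max(abs(got$H - want$H)), 1e-6)
    expect_lt(max(abs(got$C - want$C)), 1e-6)
    pc <- convlstm_params(cin, ch, seed = 2000 + i)
    for (nm in names(pc)) pc[[nm]][] <- rnorm(length(pc[[nm]]), 0, 0.5)
    got2 <- convlstm_step(X, Hp, Cp, pc)
    want2 <- oracle_convlstm_step(X, Hp, Cp, pc)
    expect_lt(max(abs(got2$H - want2$H)), 1e-6)
    expect_lt(max(abs(got2$C - want2$C)), 1e-6)
  }
})

test_that("with 1x1 maps and kernels the variant reduces to the ConvLSTM", {
  set.seed(137)
  pv <- vconvlstm_params(2, 3, kernel = 1, seed = 7)
  for (nm in names(pv)) pv[[nm]][] <- rnorm(length(pv[[nm]]), 0, 0.6)
  pc <- convlstm_params(2, 3, kernel = 1, seed = 8)
  for (nm in c("Wfx", "Wfh", "bf", "Wix", "Wih", "bi",
               "Wox", "Woh", "bo", "Wcx", "Wch", "bc")) {
    pc[[nm]][] <- pv[[nm]]
  }
  X <- array(rnorm(2), c(2, 1, 1))
  Hp <- array(rnorm(3), c(3, 1, 1))
  Cp <- array(rnorm(3), c(3, 1, 1))
  a <- vconvlstm_step(X, Hp, Cp, pv)
  b <- convlstm_step(X, Hp, Cp, pc)
  expect_equal(a$H, b$H, tolerance = 1e-12)
  expect_equal(a$C, b$C, tolerance = 1e-12)
})

test_that("the variant cell is strictly lighter for matched sizes", {
  for (cin in c(4, 8, 16)) {
    for (ch in c(4, 8, 32)) {
      expect_lt(vconvlstm_param_count(cin, ch, 3),
                convlstm_param_count(cin, ch, 3))
      # closed forms match the declared parameter shapes
      pv <- vconvlstm_params(cin, ch, seed = 1)
      pc <- convlstm_params(cin, ch, seed = 1)
      expect_equal(sum(sapply(pv, length)), vconvlstm_param_count(cin, ch, 3))
      expect_equal(sum(sapply(pc, length)), convlstm_param_count(cin, ch, 3))
    }
  }
})

tiny_cfg <- function(n_classes = 6, ...) {
  model_config(mode = "feature", streams = 2, widths = c(4, 4, 4),
               groups = 2, se_ratio = 2, lstm_hidden = 4, fc_dim = 8,
               n_classes = n_classes, use_acc = TRUE, acc_hidden = c(4, 4),
               ...)
}

tiny_batch <- function(B, seed = 1) {
  set.seed(seed)
  list(emg = array(rnorm(4 * 8 * 3 * B), c(4, 8, 3, B)),
       acc = matrix(rnorm(B * 9), B, 9))
}

test_that("forward scores are a softmax and deterministic in eval mode", {
  for (k in c(6, 52)) {
    model <- init_model(tiny_cfg(n_classes = k), seed = 11)
    b <- tiny_batch(4, seed = k)
    s1 <- predict_scores(model, b$emg, b$acc)
    expect_equal(dim(s1), c(4L, k))
    expect_true(all(s1 >= 0))
    expect_equal(rowSums(s1), rep(1, 4), tolerance = 1e-6)
    s2 <- predict_scores(model, b$emg, b$acc)
    expect_identical(s1, s2)  # dropout off in eval mode
  }
})

test_that("a sample's eval score is unchanged inside a batch", {
  model <- init_model(tiny_cfg(), seed = 13)
  b <- tiny_batch(8, seed = 3)
  full <- predict_scores(model, b$emg, b$acc)
  single <- predict_scores(model, b$emg[, , , 5, drop = FALSE],
                           b$acc[5, , drop = FALSE])
  expect_equal(as.numeric(single), as.numeric(full[5, ]), tolerance = 1e-9)
})

test_that("missing accelerometer input and patch mismatch raise errors", {
  model <- init_model(tiny_cfg(), seed = 17)
  b <- tiny_batch(2)
  expect_error(predict_scores(model, b$emg, NULL), "accelerometer")
  cfg3 <- model_config(mode = "feature", streams = 3, widths = c(4, 4, 4),
                       groups = 2, se_ratio = 2, lstm_hidden = 4, fc_dim = 8,
                       n_classes = 6, use_acc = FALSE, fusion_channels = 6)
  m3 <- init_model(cfg3, seed = 1)
  expect_error(predict_scores(m3, b$emg, NULL), "divisible")
})

test_that("loss gradients reach the first layer (no dead network)", {
  cfg <- tiny_cfg()
  cfg$dropout <- 0
  model <- init_model(cfg, seed = 19)
  b <- tiny_batch(6, seed = 5)
  y <- c(0L, 1L, 2L, 3L, 4L, 5L)
  ctx <- semgesture:::new_ctx(model$params, model$state, training = TRUE)
  scores <- semgesture:::network_forward(ctx, cfg, b$emg, b$acc)
  sm <- semgesture:::softmax_ce(scores, y)
  semgesture:::network_backward(ctx, cfg, sm$dscores,
                                list(H = 4, wp = 4, steps = 3, B = 6))
  g <- ctx$grads[["st1.stem.W"]]
  expect_false(is.null(g))
  expect_gt(max(abs(g)), 0)
})

test_that("model summary accounts for every parameter", {
  model <- init_model(tiny_cfg(), seed = 23)
  s <- model_summary(model)
  expect_equal(attr(s, "total"),
               sum(vapply(model$params, length, numeric(1))))
  expect_true(all(s$parameters > 0))
})
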