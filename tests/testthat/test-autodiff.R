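# The autodiff engine backs every network in the package; these checks pin
# its gradients to central finite differences on small random problems.

numGrad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

checkGrad <- function(buildLoss, x0, tol = 1e-5) {
  ad <- asNamespace("pituitexture")
  p <- ad$adParam(x0)
  ad$adTapeBegin()
  loss <- buildLoss(p)
  ad$adBackward(loss)
  ad$adTapeEnd()
  analytic <- p$grad
  numeric <- numGrad(function(v) {
    p2 <- ad$adParam(v)
    ad$adTapeBegin()
    l <- buildLoss(p2)
    ad$adTapeEnd()
    ad$adValue(l)
  }, x0)
  max(abs(analytic - numeric)) / max(1e-8, max(abs(numeric)))
}

test_that("convolution, normalization and pooling gradients match finite differences", {
  ad <- asNamespace("pituitexture")
  set.seed(11)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  tgt <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w0 <- array(rnorm(3 * 3 * 2 * 2, sd = 0.3), c(3, 3, 2, 2))
  expect_lt(checkGrad(function(p)
    ad$adMseLoss(ad$adConv2d(ad$adInput(x), p, ad$adParam(c(0.1, -0.2)), 1L, 1L),
                 ad$adInput(tgt)), w0), 1e-5)
  wfix <- array(rnorm(4 * 4 * 2 * 3, sd = 0.3), c(4, 4, 2, 3))
  expect_lt(checkGrad(function(p)
    ad$adMseLoss(ad$adConv2d(p, ad$adInput(wfix), ad$adInput(numeric(3)), 2L, 1L),
                 ad$adInput(array(1, c(3, 3, 3, 2)))), x), 1e-5)
  expect_lt(checkGrad(function(p)
    ad$adMseLoss(ad$adInstanceNorm(p), ad$adInput(tgt)), x), 1e-4)
  expect_lt(checkGrad(function(p)
    ad$adMseLoss(ad$adUpsample2(ad$adAvgPool2(p)), ad$adInput(tgt)), x), 1e-5)
})

test_that("recurrent-path gradients (matmul, gates, row ops) match finite differences", {
  ad <- asNamespace("pituitexture")
  set.seed(12)
  m <- matrix(rnorm(12), 3, 4)
  b2 <- rnorm(2)
  y <- matrix(c(1, 0, 1, 0, 1, 0), 3, 2)
  expect_lt(checkGrad(function(p)
    ad$adBceLoss(ad$adSigmoid(ad$adAddBiasRow(ad$adMatmul(ad$adInput(m), p),
                                              ad$adParam(b2))),
                 ad$adInput(y)), matrix(rnorm(8, sd = 0.5), 4, 2)), 1e-5)
  # duplicated row selection must accumulate gradients
  expect_lt(checkGrad(function(p)
    ad$adMseLoss(ad$adSelectRows(p, c(1, 1, 3)),
                 ad$adInput(matrix(0.5, 3, 4))), m), 1e-6)
})

test_that("whole-network gradients are exact for generator, autoencoder and CRNN", {
  ad <- asNamespace("pituitexture")
  set.seed(13)
  xg <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  gen <- buildGenerator(generatorSpec(n_down = 2, n_up = 2, base_channels = 4), seed = 7)
  expect_lt(checkGrad(function(p) {
    gen$params$down[[1]]$w <- p
    ad$adMaeLoss(ad$genForward(gen, ad$adInput(xg)),
                 ad$adInput(array(0, c(8, 8, 1, 2))))
  }, gen$params$down[[1]]$w$value), 1e-4)

  sp <- autoencoderSpec(dense_layers_per_block = 2, growth_rate = 4)
  enc <- buildEncoder(sp, seed = 3)
  dec <- buildDecoder(sp, seed = 4)
  expect_lt(checkGrad(function(p) {
    enc$params$block1[[1]]$w <- p
    xn <- ad$adInput(xg)
    ad$adMseLoss(ad$decForward(dec, ad$encForward(enc, xn)), xn)
  }, enc$params$block1[[1]]$w$value), 1e-4)

  for (rt in c("lstm", "gru")) {
    cs <- crnnSpec(conv_channels = 3L, recurrent_type = rt, hidden_size = 5,
                   dropout_rate = 0)
    mod <- buildCrnn(cs, input_shape = c(4L, 4L, 4L), seed = 11)
    feats <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))
    yl <- matrix(c(1, 0), 2, 1)
    expect_lt(checkGrad(function(p) {
      mod$params$rnn_fwd$W <- p
      ad$adBceLoss(ad$crnnForward(mod, feats, training = FALSE), ad$adInput(yl))
    }, mod$params$rnn_fwd$W$value), 1e-4, label = rt)
  }
})
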