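# Network architectures: U-Net style generator, patch discriminator,
# dense-block encoder, residual-block decoder, and the CRNN classifier.
# Each build* function returns a plain list holding the spec and a nested
# parameter list of adParam environments; net*Forward functions run the
# forward pass on the active autodiff tape.

heConv <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  list(w = adParam(array(stats::rnorm(kh * kw * cin * cout, sd = sd),
                         dim = c(kh, kw, cin, cout))),
       b = adParam(numeric(cout)))
}

glorotMat <- function(din, dout) {
  lim <- sqrt(6 / (din + dout))
  adParam(matrix(stats::runif(din * dout, -lim, lim), din, dout))
}

## ---- generator ------------------------------------------------------------

#' Generator architecture specification
#'
#' An encoder-decoder translation network: \code{n_down} stride-2
#' convolutions (LeakyReLU + instance normalization, none on the first
#' layer), then \code{n_up} upsample+convolution stages (ReLU + instance
#' normalization) whose last stage ends in tanh so outputs lie strictly in
#' \eqn{(-1, 1)}. Skip connections concatenate encoder stage \eqn{k} with
#' decoder stage \eqn{n_{up} - k}. Channel widths double per stage from
#' \code{base_channels}, capped at \code{8 * base_channels}.
#'
#' @param n_down,n_up number of down/up stages; must be equal so the output
#'   shape equals the input shape.
#' @param base_channels first-stage channel count.
#' @param skip_connections concatenate mirrored encoder features.
#' @return a validated list of class \code{"GeneratorSpec"}.
#' @export
generatorSpec <- function(n_down = 4L, n_up = 4L, base_channels = 64L,
                          skip_connections = TRUE) {
  if (n_down != n_up) stop("n_down must equal n_up (shape preservation)")
  sp <- list(n_down = assertCount(n_down, "n_down", 1L),
             n_up = assertCount(n_up, "n_up", 1L),
             base_channels = assertCount(base_channels, "base_channels", 1L),
             skip_connections = assertFlag(skip_connections, "skip_connections"))
  class(sp) <- "GeneratorSpec"
  sp
}

#' Discriminator architecture specification
#'
#' A patch discriminator: \code{n_layers} stride-2 convolutions
#' (LeakyReLU + instance normalization, no normalization on the first layer)
#' followed by a 1-channel convolution, producing a score map whose side is
#' the input side divided by \code{2^n_layers}.
#'
#' @param n_layers stride-2 convolution stages.
#' @param base_channels first-stage channel count.
#' @return a validated list of class \code{"DiscriminatorSpec"}.
#' @export
discriminatorSpec <- function(n_layers = 4L, base_channels = 64L) {
  sp <- list(n_layers = assertCount(n_layers, "n_layers", 1L),
             base_channels = assertCount(base_channels, "base_channels", 1L))
  class(sp) <- "DiscriminatorSpec"
  sp
}

stageChannels <- function(base, n) pmin(base * 2^(seq_len(n) - 1L), 8L * base)

#' Build an initialized generator network
#'
#' @param spec a \code{generatorSpec()}.
#' @param in_channels input channels (1 for grayscale slices).
#' @param seed initialization seed.
#' @return a network list usable with \code{applyNetwork()} and
#'   \code{translate()}.
#' @export
buildGenerator <- function(spec = generatorSpec(), in_channels = 1L, seed = 1L) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  withSeed(seed, {
    ch <- stageChannels(spec$base_channels, spec$n_down)
    down <- vector("list", spec$n_down)
    for (k in seq_len(spec$n_down)) {
      cin <- if (k == 1L) in_channels else ch[k - 1L]
      down[[k]] <- heConv(4L, 4L, cin, ch[k])
    }
    up <- vector("list", spec$n_up)
    prev <- ch[spec$n_down]
    for (j in seq_len(spec$n_up)) {
      ke <- spec$n_down - j
      # mirrored skips, including stage 0 = the input itself at full
      # resolution (a pixel-level path the translation map needs)
      skip_ch <- if (!spec$skip_connections) 0L
                 else if (ke >= 1L) ch[ke] else in_channels
      cin <- prev + skip_ch
      cout <- if (j < spec$n_up) ch[ke] else in_channels
      up[[j]] <- heConv(3L, 3L, cin, cout)
      prev <- cout
    }
    list(type = "generator", spec = spec, in_channels = in_channels,
         params = list(down = down, up = up))
  })
}

genForward <- function(net, x) {
  sp <- net$spec
  d <- dim(adValue(x))
  div <- 2^sp$n_down
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop(sprintf("input side (%dx%d) must be divisible by 2^n_down = %d",
                 d[1], d[2], div))
  e <- vector("list", sp$n_down)
  h <- x
  for (k in seq_len(sp$n_down)) {
    h <- adConv2d(h, net$params$down[[k]]$w, net$params$down[[k]]$b, 2L, 1L)
    h <- adLeakyRelu(h)
    if (k > 1L) h <- adInstanceNorm(h)
    e[[k]] <- h
  }
  for (j in seq_len(sp$n_up)) {
    h <- adUpsample2(h)
    ke <- sp$n_down - j
    if (sp$skip_connections) {
      if (ke >= 1L) h <- adConcatChannels(h, e[[ke]])
      else h <- adConcatChannels(h, x)
    }
    h <- adConv2d(h, net$params$up[[j]]$w, net$params$up[[j]]$b, 1L, 1L)
    if (j < sp$n_up) {
      h <- adRelu(h)
      h <- adInstanceNorm(h)
    } else {
      h <- adTanh(h)
    }
  }
  h
}

#' Build an initialized patch discriminator
#'
#' @param spec a \code{discriminatorSpec()}.
#' @param in_channels input channels.
#' @param seed initialization seed.
#' @return a network list.
#' @export
buildDiscriminator <- function(spec = discriminatorSpec(), in_channels = 1L,
                               seed = 1L) {
  stopifnot(inherits(spec, "DiscriminatorSpec"))
  withSeed(seed, {
    ch <- stageChannels(spec$base_channels, spec$n_layers)
    layers <- vector("list", spec$n_layers)
    for (k in seq_len(spec$n_layers)) {
      cin <- if (k == 1L) in_channels else ch[k - 1L]
      layers[[k]] <- heConv(4L, 4L, cin, ch[k])
    }
    head <- heConv(3L, 3L, ch[spec$n_layers], 1L)
    list(type = "discriminator", spec = spec, in_channels = in_channels,
         params = list(layers = layers, head = head))
  })
}

discForward <- function(net, x) {
  sp <- net$spec
  d <- dim(adValue(x))
  div <- 2^sp$n_layers
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop(sprintf("input side (%dx%d) must be divisible by 2^n_layers = %d",
                 d[1], d[2], div))
  h <- x
  for (k in seq_len(sp$n_layers)) {
    h <- adConv2d(h, net$params$layers[[k]]$w, net$params$layers[[k]]$b, 2L, 1L)
    h <- adLeakyRelu(h)
    if (k > 1L) h <- adInstanceNorm(h)
  }
  adConv2d(h, net$params$head$w, net$params$head$b, 1L, 1L)
}

#' Apply a network to a batch of slices (no gradient tracking)
#'
#' @param net a network list from one of the build functions.
#' @param x array \code{[H, W, C, N]} or a single matrix.
#' @return the network output array.
#' @export
applyNetwork <- function(net, x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  fwd <- switch(net$type,
                generator = genForward,
                discriminator = discForward,
                encoder = encForward,
                decoder = decForward,
                stop("unknown network type: ", net$type))
  adValue(fwd(net, adInput(x)))
}

## ---- autoencoder ----------------------------------------------------------

#' Autoencoder architecture specification
#'
#' The encoder stacks two dense blocks (each layer consumes the concatenation
#' of all previous layer outputs within its block) separated by 1x1
#' convolution + average-pooling transitions, and collapses the bottleneck to
#' a single-channel feature map of side \code{input_side / 4}. The decoder
#' mirrors it with two residual blocks interleaved with upsampling and a tanh
#' output. The block counts are fixed at two by design.
#'
#' @param dense_layers_per_block layers per dense block.
#' @param growth_rate channels added by each dense layer.
#' @param steps training epochs over the slice set.
#' @param loss "mse" (default) or "mae" pixel reconstruction loss.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size in slices.
#' @return a validated list of class \code{"AutoencoderSpec"}.
#' @export
autoencoderSpec <- function(dense_layers_per_block = 4L, growth_rate = 12L,
                            steps = 100L, loss = "mse", learning_rate = 1e-3,
                            batch_size = 32L) {
  sp <- list(n_dense_blocks = 2L, n_residual_blocks = 2L,
             dense_layers_per_block = assertCount(dense_layers_per_block,
                                                  "dense_layers_per_block", 1L),
             growth_rate = assertCount(growth_rate, "growth_rate", 1L),
             steps = assertCount(steps, "steps", 0L),
             loss = assertChoice(loss, c("mse", "mae"), "loss"),
             learning_rate = assertNumber(learning_rate, "learning_rate", 0),
             batch_size = assertCount(batch_size, "batch_size", 1L))
  class(sp) <- "AutoencoderSpec"
  sp
}

denseBlockParams <- function(cin, L, g) {
  lapply(seq_len(L), function(l) heConv(3L, 3L, cin + (l - 1L) * g, g))
}

#' Build an initialized dense-block encoder
#'
#' @param spec an \code{autoencoderSpec()}.
#' @param seed initialization seed.
#' @return a network list mapping \code{[H, W, 1, N]} slices to
#'   \code{[H/4, W/4, 1, N]} feature maps.
#' @export
buildEncoder <- function(spec = autoencoderSpec(), seed = 1L) {
  stopifnot(inherits(spec, "AutoencoderSpec"))
  g <- spec$growth_rate
  L <- spec$dense_layers_per_block
  withSeed(seed, {
    params <- list(
      stem = heConv(3L, 3L, 1L, g),
      block1 = denseBlockParams(g, L, g),
      trans1 = heConv(1L, 1L, g + L * g, g),
      block2 = denseBlockParams(g, L, g),
      trans2 = heConv(1L, 1L, g + L * g, g),
      head = heConv(3L, 3L, g, 1L))
    list(type = "encoder", spec = spec, params = params)
  })
}

denseBlockForward <- function(h, blockParams) {
  for (lp in blockParams) {
    out <- adRelu(adConv2d(h, lp$w, lp$b, 1L, 1L))
    h <- adConcatChannels(h, out)
  }
  h
}

encForward <- function(net, x) {
  d <- dim(adValue(x))
  if (d[1] %% 4 != 0 || d[2] %% 4 != 0 || d[1] < 8 || d[2] < 8)
    stop("encoder input sides must be multiples of 4 and at least 8")
  p <- net$params
  h <- adRelu(adConv2d(x, p$stem$w, p$stem$b, 1L, 1L))
  h <- denseBlockForward(h, p$block1)
  h <- adAvgPool2(adRelu(adConv2d(h, p$trans1$w, p$trans1$b, 1L, 0L)))
  h <- denseBlockForward(h, p$block2)
  h <- adAvgPool2(adRelu(adConv2d(h, p$trans2$w, p$trans2$b, 1L, 0L)))
  adConv2d(h, p$head$w, p$head$b, 1L, 1L)
}

#' Build an initialized residual-block decoder
#'
#' @param spec an \code{autoencoderSpec()}.
#' @param seed initialization seed.
#' @return a network list mapping \code{[h', w', 1, N]} feature maps back to
#'   \code{[4h', 4w', 1, N]} slices in \eqn{(-1, 1)}.
#' @export
buildDecoder <- function(spec = autoencoderSpec(), seed = 1L) {
  stopifnot(inherits(spec, "AutoencoderSpec"))
  c0 <- 2L * spec$growth_rate
  withSeed(seed, {
    params <- list(
      stem = heConv(3L, 3L, 1L, c0),
      res1 = list(heConv(3L, 3L, c0, c0), heConv(3L, 3L, c0, c0)),
      up1 = heConv(3L, 3L, c0, c0),
      res2 = list(heConv(3L, 3L, c0, c0), heConv(3L, 3L, c0, c0)),
      up2 = heConv(3L, 3L, c0, c0),
      head = heConv(3L, 3L, c0, 1L))
    list(type = "decoder", spec = spec, channels = c0, params = params)
  })
}

# out = x + conv(relu(conv(x))): with all-zero weights the block is the
# identity (no activation after the shortcut sum).
residualBlockForward <- function(h, rp) {
  f <- adRelu(adConv2d(h, rp[[1]]$w, rp[[1]]$b, 1L, 1L))
  f <- adConv2d(f, rp[[2]]$w, rp[[2]]$b, 1L, 1L)
  adAdd(h, f)
}

decForward <- function(net, x) {
  p <- net$params
  h <- adRelu(adConv2d(x, p$stem$w, p$stem$b, 1L, 1L))
  h <- residualBlockForward(h, p$res1)
  h <- adRelu(adConv2d(adUpsample2(h), p$up1$w, p$up1$b, 1L, 1L))
  h <- residualBlockForward(h, p$res2)
  h <- adRelu(adConv2d(adUpsample2(h), p$up2$w, p$up2$b, 1L, 1L))
  adTanh(adConv2d(h, p$head$w, p$head$b, 1L, 1L))
}

## ---- CRNN -----------------------------------------------------------------

#' CRNN classifier specification
#'
#' Per-position 2-D convolutions + pooling reduce each feature map of the
#' sequence to a vector; the vector sequence feeds a (by default
#' bidirectional) recurrent layer whose final hidden state passes through
#' dropout to a single sigmoid unit. Exactly one label per sequence is
#' produced and consumed.
#'
#' @param conv_channels channel counts of the convolutional stages (each
#'   stage halves the spatial side while it remains >= 4).
#' @param recurrent_type "lstm" or "gru".
#' @param bidirectional run the recurrent layer in both directions.
#' @param hidden_size recurrent state size.
#' @param dropout_rate dropout probability before the output unit
#'   (0.5 by default: each unit is dropped with probability 50\% during
#'   training).
#' @param decision_threshold probability cutoff; probabilities at or above it
#'   are labeled "soft" (ties resolve to "soft").
#' @param learning_rate Adam learning rate.
#' @param max_epochs epoch cap for training with early stopping.
#' @param batch_size minibatch size in patients.
#' @return a validated list of class \code{"CrnnSpec"}.
#' @export
crnnSpec <- function(conv_channels = c(32L, 64L), recurrent_type = "lstm",
                     bidirectional = TRUE, hidden_size = 128L,
                     dropout_rate = 0.5, decision_threshold = 0.5,
                     learning_rate = 1e-3, max_epochs = 100L, batch_size = 16L) {
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  sp <- list(conv_channels = vapply(conv_channels, assertCount, integer(1),
                                    name = "conv_channels", min = 1L),
             recurrent_type = assertChoice(recurrent_type, c("lstm", "gru"),
                                           "recurrent_type"),
             bidirectional = assertFlag(bidirectional, "bidirectional"),
             hidden_size = assertCount(hidden_size, "hidden_size", 1L),
             dropout_rate = assertNumber(dropout_rate, "dropout_rate", 0, 1),
             decision_threshold = assertNumber(decision_threshold,
                                               "decision_threshold", 0, 1),
             learning_rate = assertNumber(learning_rate, "learning_rate", 0),
             max_epochs = assertCount(max_epochs, "max_epochs", 1L),
             batch_size = assertCount(batch_size, "batch_size", 1L))
  class(sp) <- "CrnnSpec"
  sp
}

rnnCellParams <- function(din, h, type) {
  ngate <- if (type == "lstm") 4L else 3L
  list(W = glorotMat(din, ngate * h), U = glorotMat(h, ngate * h),
       b = adParam(numeric(ngate * h)))
}

#' Build an initialized CRNN classifier
#'
#' @param spec a \code{crnnSpec()}.
#' @param input_shape integer vector \code{(seq_len, h', w')} of the feature
#'   sequences it will consume. \code{seq_len} may vary at prediction time;
#'   \code{h'} and \code{w'} are fixed by the convolutional stage.
#' @param seed initialization seed.
#' @return a network list for \code{trainCrnn()} / \code{predictCrnn()}.
#' @export
buildCrnn <- function(spec = crnnSpec(), input_shape, seed = 1L) {
  stopifnot(inherits(spec, "CrnnSpec"), length(input_shape) == 3L)
  h <- input_shape[2]
  w <- input_shape[3]
  withSeed(seed, {
    convs <- list()
    cin <- 1L
    for (i in seq_along(spec$conv_channels)) {
      convs[[i]] <- heConv(3L, 3L, cin, spec$conv_channels[i])
      cin <- spec$conv_channels[i]
      if (h %% 2 == 0 && w %% 2 == 0 && h >= 4 && w >= 4) {
        h <- h %/% 2L
        w <- w %/% 2L
        attr(convs[[i]], "pool") <- TRUE
      } else {
        attr(convs[[i]], "pool") <- FALSE
      }
    }
    dvec <- h * w * cin
    ndir <- if (spec$bidirectional) 2L else 1L
    params <- list(
      convs = convs,
      rnn_fwd = rnnCellParams(dvec, spec$hidden_size, spec$recurrent_type),
      rnn_bwd = if (spec$bidirectional)
        rnnCellParams(dvec, spec$hidden_size, spec$recurrent_type) else NULL,
      out_W = glorotMat(ndir * spec$hidden_size, 1L),
      out_b = adParam(0))
    list(type = "crnn", spec = spec, feat_hw = input_shape[2:3],
         vec_dim = dvec, params = params)
  })
}

rnnRun <- function(xs, cell, h0, type, hsize) {
  # xs: list of B x d nodes (time order); returns final hidden node (B x h)
  h <- h0
  cc <- h0
  for (x_t in xs) {
    z <- adAddBiasRow(adAdd(adMatmul(x_t, cell$W), adMatmul(h, cell$U)), cell$b)
    if (type == "lstm") {
      i <- adSigmoid(adSliceCols(z, 1L, hsize))
      f <- adSigmoid(adSliceCols(z, hsize + 1L, 2L * hsize))
      g <- adTanh(adSliceCols(z, 2L * hsize + 1L, 3L * hsize))
      o <- adSigmoid(adSliceCols(z, 3L * hsize + 1L, 4L * hsize))
      cc <- adAdd(adMul(f, cc), adMul(i, g))
      h <- adMul(o, adTanh(cc))
    } else {  # gru (candidate uses gated recurrent term via a second matmul)
      u <- adSigmoid(adSliceCols(z, 1L, hsize))
      r <- adSigmoid(adSliceCols(z, hsize + 1L, 2L * hsize))
      cand_in <- adSliceCols(z, 2L * hsize + 1L, 3L * hsize)
      # subtract the ungated recurrent part and add the gated one
      n <- adTanh(adAdd(cand_in,
                        adMul(adAdd(r, adScale(adInput(matrix(1, nrow(adValue(r)),
                                                              ncol(adValue(r)))), -1)),
                              adMatmul(h, adSliceColsU(cell$U, 2L * hsize + 1L, 3L * hsize)))))
      h <- adAdd(adMul(u, h), adMul(adAdd(adInput(matrix(1, nrow(adValue(u)),
                                                         ncol(adValue(u)))),
                                          adScale(u, -1)), n))
    }
  }
  h
}

# column slice of a parameter matrix (keeps gradient flow into the slice)
adSliceColsU <- function(p, from, to) adSliceCols(p, from, to)

crnnForward <- function(net, feats, training = FALSE) {
  # feats: array [B, T, h', w'] (batch of feature sequences)
  sp <- net$spec
  d <- dim(feats)
  B <- d[1]
  Tn <- d[2]
  if (!all(d[3:4] == net$feat_hw))
    stop(sprintf("feature map shape %dx%d does not match the model's %dx%d",
                 d[3], d[4], net$feat_hw[1], net$feat_hw[2]))
  # -> [h', w', 1, B*T] with sample index n = t + T*(b-1)
  x <- array(aperm(feats, c(3, 4, 2, 1)), dim = c(d[3], d[4], 1L, B * Tn))
  h <- adInput(x)
  for (cv in net$params$convs) {
    h <- adRelu(adConv2d(h, cv$w, cv$b, 1L, 1L))
    if (isTRUE(attr(cv, "pool"))) h <- adAvgPool2(h)
  }
  flat <- adFlattenSamples(h)  # (B*T) x dvec, row n = (b-1)*T + t
  xs <- lapply(seq_len(Tn), function(t) adSelectRows(flat, t + Tn * (seq_len(B) - 1L)))
  h0 <- adInput(matrix(0, B, sp$hidden_size))
  hf <- rnnRun(xs, net$params$rnn_fwd, h0, sp$recurrent_type, sp$hidden_size)
  hh <- if (sp$bidirectional) {
    hb <- rnnRun(rev(xs), net$params$rnn_bwd, h0, sp$recurrent_type, sp$hidden_size)
    adConcatCols(hf, hb)
  } else hf
  hh <- adDropout(hh, sp$dropout_rate, training = training)
  adSigmoid(adAddBiasRow(adMatmul(hh, net$params$out_W), net$params$out_b))
}
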