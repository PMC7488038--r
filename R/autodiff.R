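# Tape-based reverse-mode automatic differentiation over R arrays.
#
# The engine is deliberately small: a node is an environment holding a value,
# an accumulated gradient, its parent nodes and a backward closure. Forward
# ops append nodes to the active tape; adBackward() walks the tape in reverse.
# Trainable parameters are environments created by adParam(); they live off
# the tape and accumulate gradients across a forward/backward pass.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

adTapeBegin <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  .ad$tape <- t
  invisible(t)
}

adTapeEnd <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

adNode <- function(value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  t <- .ad$tape
  if (!is.null(t) && !is.null(backfn)) {
    t$n <- t$n + 1L
    if (t$n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
    t$nodes[[t$n]] <- nd
  }
  nd
}

#' @keywords internal
adParam <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- NULL  # Adam first moment
  p$v <- NULL  # Adam second moment
  p$is_param <- TRUE
  p
}

adInput <- function(value) adNode(value)

adValue <- function(x) if (is.environment(x)) x$value else x

adAccGrad <- function(x, g) {
  if (!is.environment(x)) return(invisible(NULL))
  if (is.null(x$grad)) x$grad <- g else x$grad <- x$grad + g
  invisible(NULL)
}

adBackward <- function(loss) {
  t <- .ad$tape
  if (is.null(t)) stop("adBackward() called with no active tape")
  loss$grad <- 1
  for (i in seq.int(t$n, 1L)) {
    nd <- t$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd)
  }
  invisible(NULL)
}

# Detach a node from the graph (value only, no gradient flow).
adDetach <- function(x) adNode(adValue(x))

## ---- elementwise and shape ops -------------------------------------------

adAdd <- function(a, b) {
  adNode(adValue(a) + adValue(b), list(a, b), function(nd) {
    adAccGrad(nd$parents[[1]], nd$grad)
    adAccGrad(nd$parents[[2]], nd$grad)
  })
}

adMul <- function(a, b) {
  adNode(adValue(a) * adValue(b), list(a, b), function(nd) {
    adAccGrad(nd$parents[[1]], nd$grad * adValue(nd$parents[[2]]))
    adAccGrad(nd$parents[[2]], nd$grad * adValue(nd$parents[[1]]))
  })
}

adScale <- function(a, k) {
  adNode(adValue(a) * k, list(a), function(nd) {
    adAccGrad(nd$parents[[1]], nd$grad * k)
  })
}

adRelu <- function(a) {
  v <- adValue(a)
  adNode(pmax(v, 0), list(a), function(nd) {
    adAccGrad(nd$parents[[1]], nd$grad * (adValue(nd$parents[[1]]) > 0))
  })
}

adLeakyRelu <- function(a, alpha = 0.2) {
  v <- adValue(a)
  out <- ifelse(v > 0, v, alpha * v)
  dim(out) <- dim(v)
  adNode(out, list(a), function(nd) {
    v1 <- adValue(nd$parents[[1]])
    g <- nd$grad * ifelse(v1 > 0, 1, alpha)
    dim(g) <- dim(v1)
    adAccGrad(nd$parents[[1]], g)
  })
}

adTanh <- function(a) {
  y <- tanh(adValue(a))
  adNode(y, list(a), function(nd) {
    adAccGrad(nd$parents[[1]], nd$grad * (1 - nd$value^2))
  })
}

adSigmoid <- function(a) {
  y <- 1 / (1 + exp(-adValue(a)))
  adNode(y, list(a), function(nd) {
    adAccGrad(nd$parents[[1]], nd$grad * nd$value * (1 - nd$value))
  })
}

## ---- convolution stack ----------------------------------------------------

# x: [H, W, C, N]; w: [kh, kw, Cin, Cout]; b: length Cout
adConv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  y <- conv2d_fwd(adValue(x), adValue(w), adValue(b), as.integer(stride), as.integer(pad))
  adNode(y, list(x, w, b), function(nd) {
    gr <- conv2d_bwd(adValue(nd$parents[[1]]), adValue(nd$parents[[2]]), nd$grad,
                     as.integer(stride), as.integer(pad))
    adAccGrad(nd$parents[[1]], gr$gx)
    adAccGrad(nd$parents[[2]], gr$gw)
    adAccGrad(nd$parents[[3]], gr$gb)
  })
}

# Per-sample, per-channel normalization over spatial dims (instance norm).
adInstanceNorm <- function(x, eps = 1e-5) {
  v <- adValue(x)
  d <- dim(v)
  hw <- d[1] * d[2]
  m <- matrix(v, nrow = hw)
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  va <- colMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  out <- array(xhat, dim = d)
  adNode(out, list(x), function(nd) {
    g <- matrix(nd$grad, nrow = hw)
    xh <- matrix(nd$value, nrow = hw)
    gm <- colMeans(g)
    gx <- colMeans(g * xh)
    # dx = inv * (g - mean(g) - xhat * mean(g*xhat))
    dx <- sweep(g, 2, gm) - sweep(xh, 2, gx, `*`)
    dx <- sweep(dx, 2, inv, `*`)
    adAccGrad(nd$parents[[1]], array(dx, dim = d))
  })
}

# 2x2 average pooling, stride 2; H and W must be even.
adAvgPool2 <- function(x) {
  v <- adValue(x)
  d <- dim(v)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  i1 <- seq(1, d[1], by = 2)
  j1 <- seq(1, d[2], by = 2)
  y <- 0.25 * (v[i1, j1, , , drop = FALSE] + v[i1 + 1, j1, , , drop = FALSE] +
               v[i1, j1 + 1, , , drop = FALSE] + v[i1 + 1, j1 + 1, , , drop = FALSE])
  adNode(y, list(x), function(nd) {
    g <- nd$grad * 0.25
    gx <- array(0, dim = d)
    gx[i1, j1, , ] <- g
    gx[i1 + 1, j1, , ] <- g
    gx[i1, j1 + 1, , ] <- g
    gx[i1 + 1, j1 + 1, , ] <- g
    adAccGrad(nd$parents[[1]], gx)
  })
}

# Nearest-neighbour 2x upsampling.
adUpsample2 <- function(x) {
  v <- adValue(x)
  d <- dim(v)
  ri <- rep(seq_len(d[1]), each = 2)
  rj <- rep(seq_len(d[2]), each = 2)
  y <- v[ri, rj, , , drop = FALSE]
  adNode(y, list(x), function(nd) {
    g <- nd$grad
    i1 <- seq(1, 2 * d[1], by = 2)
    j1 <- seq(1, 2 * d[2], by = 2)
    gx <- g[i1, j1, , , drop = FALSE] + g[i1 + 1, j1, , , drop = FALSE] +
      g[i1, j1 + 1, , , drop = FALSE] + g[i1 + 1, j1 + 1, , , drop = FALSE]
    adAccGrad(nd$parents[[1]], gx)
  })
}

# Concatenate along the channel axis (3rd of [H, W, C, N]).
adConcatChannels <- function(a, b) {
  va <- adValue(a); vb <- adValue(b)
  da <- dim(va); db <- dim(vb)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  y <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- va
  y[, , da[3] + seq_len(db[3]), ] <- vb
  adNode(y, list(a, b), function(nd) {
    g <- nd$grad
    adAccGrad(nd$parents[[1]], g[, , seq_len(da[3]), , drop = FALSE])
    adAccGrad(nd$parents[[2]], g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# [H, W, C, N] -> N x (H*W*C) matrix (one flattened row per sample).
adFlattenSamples <- function(x) {
  v <- adValue(x)
  d <- dim(v)
  hwc <- prod(d[1:3])
  y <- t(matrix(v, nrow = hwc, ncol = d[4]))
  adNode(y, list(x), function(nd) {
    adAccGrad(nd$parents[[1]], array(t(nd$grad), dim = d))
  })
}

## ---- dense / recurrent ops ------------------------------------------------

adMatmul <- function(a, b) {
  adNode(adValue(a) %*% adValue(b), list(a, b), function(nd) {
    adAccGrad(nd$parents[[1]], nd$grad %*% t(adValue(nd$parents[[2]])))
    adAccGrad(nd$parents[[2]], t(adValue(nd$parents[[1]])) %*% nd$grad)
  })
}

# a: n x d matrix; b: length-d bias broadcast over rows
adAddBiasRow <- function(a, b) {
  va <- adValue(a)
  adNode(sweep(va, 2, adValue(b), `+`), list(a, b), function(nd) {
    adAccGrad(nd$parents[[1]], nd$grad)
    adAccGrad(nd$parents[[2]], colSums(nd$grad))
  })
}

adSliceCols <- function(a, from, to) {
  v <- adValue(a)
  adNode(v[, from:to, drop = FALSE], list(a), function(nd) {
    g <- matrix(0, nrow(v), ncol(v))
    g[, from:to] <- nd$grad
    adAccGrad(nd$parents[[1]], g)
  })
}

adSelectRows <- function(a, idx) {
  v <- adValue(a)
  adNode(v[idx, , drop = FALSE], list(a), function(nd) {
    g <- matrix(0, nrow(v), ncol(v))
    acc <- rowsum(nd$grad, group = idx)  # duplicates in idx must accumulate
    g[as.integer(rownames(acc)), ] <- acc
    adAccGrad(nd$parents[[1]], g)
  })
}

adConcatCols <- function(a, b) {
  va <- adValue(a); vb <- adValue(b)
  adNode(cbind(va, vb), list(a, b), function(nd) {
    adAccGrad(nd$parents[[1]], nd$grad[, seq_len(ncol(va)), drop = FALSE])
    adAccGrad(nd$parents[[2]], nd$grad[, ncol(va) + seq_len(ncol(vb)), drop = FALSE])
  })
}

# Inverted dropout; draws its mask from the current RNG stream.
adDropout <- function(x, rate, training = TRUE) {
  if (!training || rate <= 0) return(x)
  v <- adValue(x)
  keep <- (array(stats::runif(length(v)), dim = dim(v) %||% length(v)) >= rate) / (1 - rate)
  adNode(v * keep, list(x), function(nd) {
    adAccGrad(nd$parents[[1]], nd$grad * keep)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- losses ---------------------------------------------------------------

adMseLoss <- function(a, target) {
  va <- adValue(a); vt <- adValue(target)
  n <- length(va)
  adNode(mean((va - vt)^2), list(a, target), function(nd) {
    d <- 2 * (adValue(nd$parents[[1]]) - adValue(nd$parents[[2]])) / n
    adAccGrad(nd$parents[[1]], nd$grad * d)
    adAccGrad(nd$parents[[2]], -nd$grad * d)
  })
}

adMaeLoss <- function(a, target) {
  va <- adValue(a); vt <- adValue(target)
  n <- length(va)
  adNode(mean(abs(va - vt)), list(a, target), function(nd) {
    d <- sign(adValue(nd$parents[[1]]) - adValue(nd$parents[[2]])) / n
    adAccGrad(nd$parents[[1]], nd$grad * d)
    adAccGrad(nd$parents[[2]], -nd$grad * d)
  })
}

# Binary cross-entropy on probabilities p in (0,1); y is 0/1.
adBceLoss <- function(p, y, eps = 1e-7) {
  vp <- pmin(pmax(adValue(p), eps), 1 - eps)
  vy <- adValue(y)
  n <- length(vp)
  adNode(-mean(vy * log(vp) + (1 - vy) * log(1 - vp)), list(p, y), function(nd) {
    vp2 <- pmin(pmax(adValue(nd$parents[[1]]), eps), 1 - eps)
    vy2 <- adValue(nd$parents[[2]])
    adAccGrad(nd$parents[[1]], nd$grad * (vp2 - vy2) / (vp2 * (1 - vp2)) / n)
  })
}

# Weighted sum of scalar loss nodes.
adLinComb <- function(nodes, weights) {
  vals <- vapply(nodes, adValue, numeric(1))
  adNode(sum(vals * weights), nodes, function(nd) {
    for (i in seq_along(nd$parents)) adAccGrad(nd$parents[[i]], nd$grad * weights[i])
  })
}

## ---- optimizer ------------------------------------------------------------

adZeroGrads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

#' @keywords internal
adamStep <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, t = 1L) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad
    if (is.null(p$m)) {
      p$m <- g * 0
      p$v <- g * 0
    }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

# Collect all adParam environments from a nested list structure.
collectParams <- function(x) {
  out <- list()
  walk <- function(e) {
    if (is.environment(e) && isTRUE(e$is_param)) {
      out[[length(out) + 1L]] <<- e
    } else if (is.list(e)) {
      for (el in e) walk(el)
    }
  }
  walk(x)
  out
}

# Snapshot / restore parameter values (for checkpointing and early stopping).
paramSnapshot <- function(params) lapply(params, function(p) p$value)

paramRestore <- function(params, snapshot) {
  for (i in seq_along(params)) params[[i]]$value <- snapshot[[i]]
  invisible(NULL)
}
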