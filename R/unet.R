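## Volumetric residual U-Net, implemented directly in R.
##
## Layers: 3x3x3 zero-padded convolutions organized as repeated
## InstanceNorm -> ReLU -> Conv blocks (normalization is per volume and
## per channel: desk-scale batches are tiny), average-pooling
## down-sampling, learned transposed-convolution (kernel 2, stride 2)
## up-sampling with concatenative skip connections, and a residual output
## (the network predicts a correction added to its input, so a
## zero-initialized final layer starts as the identity map).  All
## convolutions are evaluated as 27 shifted GEMMs, and backpropagation is
## hand-derived; a numeric gradient check in the test suite guards the
## derivatives.

#' U-Net architecture specification
#'
#' @param stages number of down-sampling (and up-sampling) stages; the
#'   input side must be divisible by 2^stages.
#' @param baseChannels channels of the first hidden layer; doubled at each
#'   lower stage.
#' @param kernel convolution kernel size (fixed at 3).
#' @param residual use residual learning (network output added to input).
#' @return A list of class `"UNetSpec"`.
#' @export
unetSpec <- function(stages = 5, baseChannels = 4, kernel = 3,
                     residual = TRUE) {
  stopifnot(stages >= 1, baseChannels >= 1, kernel == 3)
  structure(list(stages = as.integer(stages),
                 baseChannels = as.integer(baseChannels),
                 kernel = 3L, residual = isTRUE(residual)),
            class = "UNetSpec")
}

.unetOffsets <- local({
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o[order(seq_len(nrow(o))), , drop = FALSE]
})

## Shift a 4D array [n,n,n,C] by (dx,dy,dz) with zero padding.
.shift4 <- function(x, d) {
  n <- dim(x)[1]
  out <- array(0, dim(x))
  sx <- max(1, 1 - d[1]):min(n, n - d[1])
  sy <- max(1, 1 - d[2]):min(n, n - d[2])
  sz <- max(1, 1 - d[3]):min(n, n - d[3])
  out[sx + d[1], sy + d[2], sz + d[3], ] <- x[sx, sy, sz, , drop = FALSE]
  out
}

## ---- conv 3x3x3, zero padding, weights W[27, Cin, Cout] ----------------

## im2col layout: columns grouped as 27 offset blocks of cin channels, so
## the whole convolution is one GEMM against the (27*cin) x cout weight
## matrix; the weight array W[27, cin, cout] maps onto that matrix with
## offsets varying fastest matching aperm(W, c(2, 1, 3)).
.convIm2col <- function(x) {
  n <- dim(x)[1]; cin <- dim(x)[4]
  A <- array(0, c(n, n, n, cin, 27L))
  for (o in seq_len(27)) {
    d <- .unetOffsets[o, ]
    sx <- max(1, 1 - d[1]):min(n, n - d[1])
    sy <- max(1, 1 - d[2]):min(n, n - d[2])
    sz <- max(1, 1 - d[3]):min(n, n - d[3])
    A[sx + d[1], sy + d[2], sz + d[3], , o] <- x[sx, sy, sz, , drop = FALSE]
  }
  dim(A) <- c(n^3, 27L * cin)
  A
}

.convWmat <- function(W) {
  cin <- dim(W)[2]; cout <- dim(W)[3]
  matrix(aperm(W, c(2, 1, 3)), 27L * cin, cout)
}

.convF <- function(x, W, b) {
  n <- dim(x)[1]; cout <- dim(W)[3]
  M <- .convIm2col(x)
  outM <- M %*% .convWmat(W)
  outM <- sweep(outM, 2, b, `+`)
  list(out = array(outM, c(n, n, n, cout)), M = M, W = W, dims = dim(x))
}

.convB <- function(cache, dOut) {
  W <- cache$W
  n <- cache$dims[1]; cin <- cache$dims[4]; cout <- dim(W)[3]
  dOutM <- matrix(dOut, n^3, cout)
  dWmat <- crossprod(cache$M, dOutM)                # (27*cin) x cout
  dW <- aperm(array(dWmat, c(cin, 27L, cout)), c(2, 1, 3))
  dM <- dOutM %*% t(.convWmat(W))                   # n^3 x (27*cin)
  dim(dM) <- c(n, n, n, cin, 27L)
  dx <- array(0, cache$dims)
  for (o in seq_len(27)) {
    d <- .unetOffsets[o, ]
    sx <- max(1, 1 - d[1]):min(n, n - d[1])
    sy <- max(1, 1 - d[2]):min(n, n - d[2])
    sz <- max(1, 1 - d[3]):min(n, n - d[3])
    blk <- dM[sx + d[1], sy + d[2], sz + d[3], , o, drop = FALSE]
    dim(blk) <- dim(blk)[1:4]
    dx[sx, sy, sz, ] <- dx[sx, sy, sz, , drop = FALSE] + blk
  }
  list(dx = dx, dW = dW, db = colSums(dOutM))
}

## ---- instance norm (per channel, per volume, no affine) ----------------

.inormF <- function(x, eps = 1e-5) {
  n3 <- prod(dim(x)[1:3]); cc <- dim(x)[4]
  xm <- matrix(x, n3, cc)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  istd <- 1 / sqrt(colMeans(xc^2) + eps)
  y <- sweep(xc, 2, istd, `*`)
  list(out = array(y, dim(x)), y = y, istd = istd)
}

.inormB <- function(cache, dOut) {
  y <- cache$y; istd <- cache$istd
  d <- dim(dOut); n3 <- prod(d[1:3]); cc <- d[4]
  dyM <- matrix(dOut, n3, cc)
  t1 <- sweep(dyM, 2, colMeans(dyM))
  t2 <- sweep(y, 2, colMeans(dyM * y), `*`)
  array(sweep(t1 - t2, 2, istd, `*`), d)
}

## ---- ReLU ---------------------------------------------------------------

.reluF <- function(x) list(out = pmax(x, 0), mask = x > 0)
.reluB <- function(cache, dOut) dOut * cache$mask

## ---- average pooling 2x2x2 ----------------------------------------------

.poolF <- function(x) {
  n <- dim(x)[1]; cc <- dim(x)[4]; h <- n %/% 2
  out <- array(0, c(h, h, h, cc))
  for (a in 0:1) for (b in 0:1) for (c3 in 0:1) {
    out <- out + x[seq(1 + a, n, 2), seq(1 + b, n, 2), seq(1 + c3, n, 2),
                   , drop = FALSE]
  }
  list(out = out / 8, n = n)
}

.poolB <- function(cache, dOut) {
  n <- cache$n; cc <- dim(dOut)[4]
  dx <- array(0, c(n, n, n, cc))
  g <- dOut / 8
  for (a in 0:1) for (b in 0:1) for (c3 in 0:1) {
    dx[seq(1 + a, n, 2), seq(1 + b, n, 2), seq(1 + c3, n, 2), ] <- g
  }
  dx
}

## ---- transposed conv, kernel 2 stride 2, weights W[8, Cin, Cout] --------

.tconvParity <- as.matrix(expand.grid(a = 0:1, b = 0:1, c = 0:1))

.tconvF <- function(x, W, b) {
  h <- dim(x)[1]; cin <- dim(x)[4]; cout <- dim(W)[3]
  n <- 2L * h
  xm <- matrix(x, h^3, cin)
  out <- array(rep(b, each = n^3), c(n, n, n, cout))
  for (p in seq_len(8)) {
    pa <- .tconvParity[p, ]
    out[seq(1 + pa[1], n, 2), seq(1 + pa[2], n, 2), seq(1 + pa[3], n, 2), ] <-
      out[seq(1 + pa[1], n, 2), seq(1 + pa[2], n, 2),
          seq(1 + pa[3], n, 2), , drop = FALSE] +
      array(xm %*% matrix(W[p, , ], cin, cout), c(h, h, h, cout))
  }
  list(out = out, x = x, W = W)
}

.tconvB <- function(cache, dOut) {
  x <- cache$x; W <- cache$W
  h <- dim(x)[1]; cin <- dim(x)[4]; cout <- dim(W)[3]
  n <- 2L * h
  xm <- matrix(x, h^3, cin)
  dW <- array(0, dim(W))
  dxm <- matrix(0, h^3, cin)
  for (p in seq_len(8)) {
    pa <- .tconvParity[p, ]
    sl <- matrix(dOut[seq(1 + pa[1], n, 2), seq(1 + pa[2], n, 2),
                      seq(1 + pa[3], n, 2), , drop = FALSE], h^3, cout)
    dW[p, , ] <- crossprod(xm, sl)
    dxm <- dxm + sl %*% t(matrix(W[p, , ], cin, cout))
  }
  list(dx = array(dxm, dim(x)), dW = dW,
       db = colSums(matrix(dOut, n^3, cout)))
}

## ---- parameter initialization -------------------------------------------

.heConv <- function(cin, cout, fan = 27) {
  list(W = array(rnorm(27 * cin * cout, sd = sqrt(2 / (fan * cin))),
                 c(27, cin, cout)),
       b = numeric(cout))
}

.heTconv <- function(cin, cout) {
  list(W = array(rnorm(8 * cin * cout, sd = sqrt(2 / cin)), c(8, cin, cout)),
       b = numeric(cout))
}

## Channel plan: stage s works at side n/2^(s-1) with C*2^(s-1) channels;
## the bottom (after the last pool) uses C*2^S channels.
.unetChannels <- function(spec) spec$baseChannels * 2^(seq_len(spec$stages) - 1)

#' Initialize U-Net parameters
#'
#' The final convolution is zero-initialized so the freshly constructed
#' residual network is the identity map.
#'
#' @param spec a [unetSpec()].
#' @param seed integer seed.
#' @return Nested parameter list.
#' @export
unetInit <- function(spec, seed = 1) {
  set.seed(seed)
  S <- spec$stages
  ch <- .unetChannels(spec)
  bott <- spec$baseChannels * 2^S
  p <- list(enc = vector("list", S), dec = vector("list", S))
  cin <- 1L
  for (s in seq_len(S)) {
    p$enc[[s]] <- list(conv1 = .heConv(cin, ch[s]),
                       conv2 = .heConv(ch[s], ch[s]))
    cin <- ch[s]
  }
  p$bottom <- list(conv1 = .heConv(ch[S], bott), conv2 = .heConv(bott, bott))
  up <- bott
  for (s in rev(seq_len(S))) {
    p$dec[[s]] <- list(tconv = .heTconv(up, ch[s]),
                       conv1 = .heConv(2 * ch[s], ch[s]),
                       conv2 = .heConv(ch[s], ch[s]))
    up <- ch[s]
  }
  p$final <- list(W = array(0, c(27, ch[1], 1)), b = numeric(1))
  p
}

.blockF <- function(x, prm) {
  n1 <- .inormF(x)
  r1 <- .reluF(n1$out)
  c1 <- .convF(r1$out, prm$W, prm$b)
  list(out = c1$out, n1 = n1, r1 = r1, c1 = c1)
}

.blockB <- function(cache, dOut) {
  cb <- .convB(cache$c1, dOut)
  dr <- .reluB(cache$r1, cb$dx)
  dn <- .inormB(cache$n1, dr)
  list(dx = dn, dW = cb$dW, db = cb$db)
}

#' U-Net forward pass
#'
#' @param x3 real 3D array (standardized volume), side divisible by
#'   2^stages.
#' @param params parameter list from [unetInit()].
#' @param spec the matching [unetSpec()].
#' @param wantCache keep activations for backpropagation.
#' @return A list with `out` (3D array; includes the residual input when
#'   `spec$residual`) and, if requested, `cache`.
#' @export
unetForward <- function(x3, params, spec, wantCache = FALSE) {
  n <- dim(x3)[1]
  S <- spec$stages
  if (n %% 2^S != 0)
    stop(sprintf("input side %d not divisible by 2^%d", n, S))
  x <- array(x3, c(dim(x3), 1))
  cache <- list(enc = vector("list", S), dec = vector("list", S))
  skips <- vector("list", S)
  for (s in seq_len(S)) {
    b1 <- .blockF(x, params$enc[[s]]$conv1)
    b2 <- .blockF(b1$out, params$enc[[s]]$conv2)
    skips[[s]] <- b2$out
    pl <- .poolF(b2$out)
    x <- pl$out
    cache$enc[[s]] <- list(b1 = b1, b2 = b2, pool = pl)
  }
  bb1 <- .blockF(x, params$bottom$conv1)
  bb2 <- .blockF(bb1$out, params$bottom$conv2)
  cache$bottom <- list(b1 = bb1, b2 = bb2)
  x <- bb2$out
  for (s in rev(seq_len(S))) {
    tc <- .tconvF(x, params$dec[[s]]$tconv$W, params$dec[[s]]$tconv$b)
    cc <- dim(tc$out)[4]
    xcat <- array(c(tc$out, skips[[s]]), c(dim(tc$out)[1:3], 2 * cc))
    d1 <- .blockF(xcat, params$dec[[s]]$conv1)
    d2 <- .blockF(d1$out, params$dec[[s]]$conv2)
    x <- d2$out
    cache$dec[[s]] <- list(tc = tc, cc = cc, d1 = d1, d2 = d2)
  }
  fin <- .convF(x, params$final$W, params$final$b)
  out <- fin$out[, , , 1]
  if (spec$residual) out <- out + x3
  cache$final <- fin
  list(out = out, cache = if (wantCache) cache else NULL)
}

#' U-Net backward pass
#'
#' @param cache cache from [unetForward()] with `wantCache = TRUE`.
#' @param dOut gradient of the loss with respect to the output (3D array).
#' @param params parameter list (for structure).
#' @param spec the [unetSpec()].
#' @return Parameter-gradient list with the same structure as `params`
#'   (the residual path contributes no parameter gradients).
#' @export
unetBackward <- function(cache, dOut, params, spec) {
  S <- spec$stages
  g <- list(enc = vector("list", S), dec = vector("list", S))
  d4 <- array(dOut, c(dim(dOut), 1))
  fb <- .convB(cache$final, d4)
  g$final <- list(W = fb$dW, b = fb$db)
  dx <- fb$dx
  dskips <- vector("list", S)
  for (s in seq_len(S)) {
    cd <- cache$dec[[s]]
    b2 <- .blockB(cd$d2, dx)
    b1 <- .blockB(cd$d1, b2$dx)
    cc <- cd$cc
    dcat <- b1$dx
    dtc <- dcat[, , , seq_len(cc), drop = FALSE]
    dskips[[s]] <- dcat[, , , cc + seq_len(cc), drop = FALSE]
    tb <- .tconvB(cd$tc, dtc)
    g$dec[[s]] <- list(tconv = list(W = tb$dW, b = tb$db),
                       conv1 = list(W = b1$dW, b = b1$db),
                       conv2 = list(W = b2$dW, b = b2$db))
    dx <- tb$dx
  }
  bb2 <- .blockB(cache$bottom$b2, dx)
  bb1 <- .blockB(cache$bottom$b1, bb2$dx)
  g$bottom <- list(conv1 = list(W = bb1$dW, b = bb1$db),
                   conv2 = list(W = bb2$dW, b = bb2$db))
  dx <- bb1$dx
  for (s in rev(seq_len(S))) {
    ce <- cache$enc[[s]]
    dpool <- .poolB(ce$pool, dx)
    dpool <- dpool + dskips[[s]]
    b2 <- .blockB(ce$b2, dpool)
    b1 <- .blockB(ce$b1, b2$dx)
    g$enc[[s]] <- list(conv1 = list(W = b1$dW, b = b1$db),
                       conv2 = list(W = b2$dW, b = b2$db))
    dx <- b1$dx
  }
  g
}

## ---- flat parameter walking for the optimizer ---------------------------

## Recurse two parameter trees in parallel; lists are matched by name so
## construction order never matters.
.paramWalk <- function(p, g, f) {
  if (is.list(p)) {
    out <- p
    for (nm in .listKeys(p)) out[[nm]] <- .paramWalk(p[[nm]], g[[nm]], f)
    out
  } else f(p, g)
}

.listKeys <- function(p) {
  nm <- names(p)
  if (!is.null(nm) && all(nzchar(nm))) nm else seq_along(p)
}

#' Adam optimizer state
#' @param params parameter list.
#' @return opaque optimizer state.
#' @export
adamInit <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

#' One Adam update
#'
#' @param params parameter list; @param grads matching gradient list;
#'   @param state from [adamInit()]; @param lr learning rate;
#'   @param beta1,beta2,eps Adam moments; @param weightDecay L2 penalty
#'   added to the gradients.
#' @return list(params, state).
#' @export
adamStep <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8, weightDecay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, parts) {
    g <- parts$g + weightDecay * p
    m <- beta1 * parts$m + (1 - beta1) * g
    v <- beta2 * parts$v + (1 - beta2) * g^2
    list(p = p - lr * (m / bc1) / (sqrt(v / bc2) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      ps <- p; ms <- m; vs <- v
      for (i in .listKeys(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        ps[[i]] <- r$p; ms[[i]] <- r$m; vs[[i]] <- r$v
      }
      list(p = ps, m = ms, v = vs)
    } else {
      r <- upd(p, list(g = g, m = m, v = v))
      list(p = r$p, m = r$m, v = r$v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

## Denoiser handle wrapping trained weights.
.unetHandle <- function(params, spec, name, trainedOn) {
  force(params); force(spec)
  d <- denoiserHandle(name,
                      function(a) unetForward(a, params, spec)$out,
                      trainedOn = trainedOn)
  attr(d, "weights") <- params
  attr(d, "spec") <- spec
  d
}
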