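#' @include AllClasses.R metrics.R
NULL

# ---------------------------------------------------------------------------
# A compact reverse-mode automatic-differentiation tape.
#
# Values are plain numeric arrays whose last axis is the channel axis for
# network tensors (scalars are length-1 vectors).  Every operation appends a
# node holding the computed value, its parents, and a backward closure that
# maps the node's output gradient to parent gradients.  Creation order is a
# topological order, so adBackward() is a single reverse sweep.
# ---------------------------------------------------------------------------

newTape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

adNode <- function(tape, value, parents = list(), back = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$parents <- parents
  n$back <- back
  n$grad <- NULL
  tape$n <- tape$n + 1L
  n$i <- tape$n
  tape$nodes[[tape$n]] <- n
  n
}

adLeaf <- function(tape, value, requires = FALSE) {
  n <- adNode(tape, value)
  n$requires <- requires
  n
}

adAccum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

adBackward <- function(tape, node) {
  stopifnot(length(node$value) == 1L)
  node$grad <- 1
  for (i in seq(node$i, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$back)) next
    gs <- nd$back(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) adAccum(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

# --- elementwise and reduction ops -----------------------------------------

adAdd <- function(x, y, tape) adNode(tape, x$value + y$value, list(x, y),
  function(g) list(g, g))

adSub <- function(x, y, tape) adNode(tape, x$value - y$value, list(x, y),
  function(g) list(g, -g))

adMul <- function(x, y, tape) {
  xv <- x$value; yv <- y$value
  adNode(tape, xv * yv, list(x, y), function(g) list(g * yv, g * xv))
}

adDiv <- function(x, y, tape) {
  xv <- x$value; yv <- y$value
  adNode(tape, xv / yv, list(x, y),
         function(g) list(g / yv, -g * xv / yv^2))
}

adScale <- function(x, s, tape) adNode(tape, s * x$value, list(x),
  function(g) list(s * g))

adShift <- function(x, c, tape) adNode(tape, x$value + c, list(x),
  function(g) list(g))

adAbs <- function(x, tape) {
  xv <- x$value
  adNode(tape, abs(xv), list(x), function(g) list(g * sign(xv)))
}

adMean <- function(x, tape) {
  n <- length(x$value)
  dm <- dim(x$value)
  adNode(tape, mean(x$value), list(x),
         function(g) list(array(as.numeric(g) / n, dim = if (is.null(dm)) n else dm)))
}

adLog <- function(x, tape) {
  xv <- x$value
  adNode(tape, log(xv), list(x), function(g) list(g / xv))
}

adPowC <- function(x, p, tape) {
  xv <- x$value
  adNode(tape, xv^p, list(x), function(g) list(g * p * xv^(p - 1)))
}

adClampMin <- function(x, lo, tape) {
  xv <- x$value
  adNode(tape, pmax(xv, lo), list(x),
         function(g) list(g * as.numeric(xv > lo)))
}

adClamp01 <- function(x, eps, tape) {
  xv <- x$value
  adNode(tape, pmin(pmax(xv, eps), 1 - eps), list(x),
         function(g) list(g * as.numeric(xv > eps & xv < 1 - eps)))
}

adLeakyRelu <- function(x, slope, tape) {
  xv <- x$value
  fac <- (xv > 0) + slope * (xv <= 0)
  adNode(tape, xv * fac, list(x), function(g) list(g * fac))
}

adSigmoid <- function(x, tape) {
  s <- 1 / (1 + exp(-x$value))
  adNode(tape, s, list(x), function(g) list(g * s * (1 - s)))
}

# --- structural ops ---------------------------------------------------------

# concatenate along the trailing channel axis
adConcatC <- function(x, y, tape) {
  dx <- dim(x$value); dy <- dim(y$value)
  nd <- length(dx)
  v <- array(c(x$value, y$value), dim = c(dx[-nd], dx[nd] + dy[nd]))
  adNode(tape, v, list(x, y), function(g) {
    g <- array(g, dim = dim(v))
    sp <- prod(dx[-nd])
    gm <- matrix(g, sp)
    list(array(gm[, seq_len(dx[nd])], dim = dx),
         array(gm[, dx[nd] + seq_len(dy[nd])], dim = dy))
  })
}

# truncate or zero-pad the channel axis to `cout` channels
adFitChannels <- function(x, cout, tape) {
  dx <- dim(x$value)
  nd <- length(dx)
  cin <- dx[nd]
  if (cin == cout) return(x)
  sp <- prod(dx[-nd])
  m <- matrix(x$value, sp)
  v <- matrix(0, sp, cout)
  keep <- seq_len(min(cin, cout))
  v[, keep] <- m[, keep]
  adNode(tape, array(v, dim = c(dx[-nd], cout)), list(x), function(g) {
    gm <- matrix(g, sp)
    gx <- matrix(0, sp, cin)
    gx[, keep] <- gm[, keep]
    list(array(gx, dim = dx))
  })
}

adCrop <- function(x, half, tape) {
  dm <- dim(x$value)
  idx <- lapply(dm, function(n) (half + 1L):(n - half))
  v <- do.call(`[`, c(list(x$value), idx, list(drop = FALSE)))
  adNode(tape, v, list(x), function(g) {
    gx <- array(0, dm)
    gx <- do.call(`[<-`, c(list(gx), idx, list(array(g, dim(v)))))
    list(gx)
  })
}

adAvgPoolHalf <- function(x, tape) {
  dm <- dim(x$value)
  v <- avgPoolHalf(x$value)
  adNode(tape, v, list(x), function(g) {
    g <- array(g, dim(v))
    nd <- length(dm)
    for (d in rev(seq_len(nd))) {
      gd <- dim(g)
      up <- array(0, dim = replace(gd, d, dm[d]))
      i1 <- seq_len(gd[d]) * 2L - 1L
      idxA <- lapply(seq_len(nd), function(dd)
        if (dd == d) i1 else seq_len(gd[dd]))
      idxB <- idxA; idxB[[d]] <- i1 + 1L
      up <- do.call(`[<-`, c(list(up), idxA, list(g / 2)))
      up <- do.call(`[<-`, c(list(up), idxB,
                             list(do.call(`[`, c(list(up), idxB,
                                                 list(drop = FALSE))) + g / 2)))
      g <- up
    }
    list(g)
  })
}

# Gaussian window filtering (self-adjoint: symmetric kernel, zero padding)
adWinFilter <- function(x, win, sigma, tape) {
  adNode(tape, winFilter(x$value, win, sigma), list(x),
         function(g) list(winFilter(array(g, dim(x$value)), win, sigma)))
}

# --- compiled network ops ---------------------------------------------------

# convolution: x has dims (spatial..., Cin); w is Cout x (prod(k) * Cin)
adConv <- function(x, w, b, kernel, stride, pad, tape) {
  dx <- dim(x$value)
  nd <- length(dx) - 1L
  sdim <- dx[seq_len(nd)]
  cin <- dx[nd + 1L]
  r <- cpp_conv_fwd(as.numeric(x$value), as.integer(sdim), as.integer(cin),
                    w$value, as.numeric(b$value),
                    as.integer(kernel), as.integer(stride), as.integer(pad))
  v <- array(r$out, dim = c(r$odim, nrow(w$value)))
  adNode(tape, v, list(x, w, b), function(g) {
    bw <- cpp_conv_bwd(as.numeric(g), as.numeric(x$value), as.integer(sdim),
                       as.integer(cin), w$value, as.integer(kernel),
                       as.integer(stride), as.integer(pad),
                       TRUE, TRUE)
    gw <- bw$gw; dim(gw) <- dim(w$value)
    list(array(bw$gx, dim = dx), gw, as.numeric(bw$gb))
  })
}

adMaxPool <- function(x, win, stride, pad, tape) {
  dx <- dim(x$value)
  nd <- length(dx) - 1L
  C <- dx[nd + 1L]
  r <- cpp_maxpool_fwd(as.numeric(x$value), as.integer(dx[seq_len(nd)]),
                       as.integer(C), as.integer(win), as.integer(stride),
                       as.integer(pad))
  v <- array(r$out, dim = c(r$odim, C))
  adNode(tape, v, list(x), function(g) {
    gx <- cpp_maxpool_bwd(as.numeric(g), r$argmax, length(x$value))
    list(array(gx, dim = dx))
  })
}

# channel-to-space rearrangement by factor 2 (value-preserving permutation)
shuffleValue <- function(v, inverse = FALSE) {
  dm <- dim(v)
  nd <- length(dm) - 1L
  r <- 2L
  if (!inverse) {
    C <- dm[nd + 1L] / r^nd
    if (C != round(C))
      stop("invalid argument: channel count not divisible by 2^dim")
    if (nd == 2L) {
      a <- array(v, c(dm[1], dm[2], r, r, C))      # (X, Y, dj, di, C)
      out <- aperm(a, c(4, 1, 3, 2, 5))            # (di, X, dj, Y, C)
      array(out, c(r * dm[1], r * dm[2], C))
    } else {
      a <- array(v, c(dm[1], dm[2], dm[3], r, r, r, C)) # (X,Y,Z,dk,dj,di,C)
      out <- aperm(a, c(6, 1, 5, 2, 4, 3, 7))
      array(out, c(r * dm[1], r * dm[2], r * dm[3], C))
    }
  } else {
    C <- dm[nd + 1L]
    if (nd == 2L) {
      a <- array(v, c(r, dm[1] / r, r, dm[2] / r, C))
      out <- aperm(a, c(2, 4, 3, 1, 5))
      array(out, c(dm[1] / r, dm[2] / r, C * r^2))
    } else {
      a <- array(v, c(r, dm[1] / r, r, dm[2] / r, r, dm[3] / r, C))
      out <- aperm(a, c(2, 4, 6, 5, 3, 1, 7))
      array(out, c(dm[1] / r, dm[2] / r, dm[3] / r, C * r^3))
    }
  }
}

adPixelShuffle <- function(x, tape) {
  v <- shuffleValue(x$value)
  adNode(tape, v, list(x), function(g)
    list(shuffleValue(array(g, dim(v)), inverse = TRUE)))
}

# per-channel spatial normalization with learned gain/bias
adInstanceNorm <- function(x, gain, bias, tape, eps = 1e-5) {
  dx <- dim(x$value)
  nd <- length(dx) - 1L
  C <- dx[nd + 1L]
  sp <- prod(dx[seq_len(nd)])
  m <- matrix(x$value, sp, C)
  mu <- colMeans(m)
  va <- colMeans(m^2) - mu^2
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(m, 2, mu), 2, istd, `*`)
  out <- sweep(sweep(xhat, 2, gain$value, `*`), 2, bias$value, `+`)
  adNode(tape, array(out, dim = dx), list(x, gain, bias), function(g) {
    gm <- matrix(g, sp, C)
    dgain <- colSums(gm * xhat)
    dbias <- colSums(gm)
    gh <- sweep(gm, 2, gain$value, `*`)
    t1 <- sweep(gh, 2, colMeans(gh))
    t2 <- xhat * matrix(colMeans(gh * xhat), sp, C, byrow = TRUE)
    gx <- sweep(t1 - t2, 2, istd, `*`)
    list(array(gx, dim = dx), dgain, dbias)
  })
}

# multiply whole channels by a fixed 0/scale mask (spatial dropout)
adChannelMask <- function(x, mask, tape) {
  dx <- dim(x$value)
  nd <- length(dx) - 1L
  sp <- prod(dx[seq_len(nd)])
  mm <- matrix(mask, sp, length(mask), byrow = TRUE)
  v <- array(matrix(x$value, sp) * mm, dim = dx)
  adNode(tape, v, list(x), function(g)
    list(array(matrix(g, sp) * mm, dim = dx)))
}

# --- differentiable SSIM / MS-SSIM ------------------------------------------

# luminance/contrast-structure means as scalar nodes; `a` differentiable,
# `b` a constant leaf
adSSIMComponents <- function(a, b, config, tape) {
  win <- config@windowSize; sigma <- config@windowSigma
  if (any(dim(a$value) < win))
    stop("invalid argument: window larger than image")
  C1 <- (config@k1 * config@dynamicRange)^2
  C2 <- (config@k2 * config@dynamicRange)^2
  half <- (win - 1L) %/% 2L
  ua <- adCrop(adWinFilter(a, win, sigma, tape), half, tape)
  ub <- adCrop(adWinFilter(b, win, sigma, tape), half, tape)
  uaa <- adCrop(adWinFilter(adMul(a, a, tape), win, sigma, tape), half, tape)
  ubb <- adCrop(adWinFilter(adMul(b, b, tape), win, sigma, tape), half, tape)
  uab <- adCrop(adWinFilter(adMul(a, b, tape), win, sigma, tape), half, tape)
  va <- adSub(uaa, adMul(ua, ua, tape), tape)
  vb <- adSub(ubb, adMul(ub, ub, tape), tape)
  vab <- adSub(uab, adMul(ua, ub, tape), tape)
  lum <- adDiv(adShift(adScale(adMul(ua, ub, tape), 2, tape), C1, tape),
               adShift(adAdd(adMul(ua, ua, tape), adMul(ub, ub, tape), tape),
                       C1, tape), tape)
  cs <- adDiv(adShift(adScale(vab, 2, tape), C2, tape),
              adShift(adAdd(va, vb, tape), C2, tape), tape)
  list(lum = lum, cs = cs)
}

# MS-SSIM as a differentiable scalar node; mirrors msSSIM()
adMsSSIM <- function(a, b, config, tape) {
  sc <- resolveScales(dim(a$value), config)
  m <- sc$m; w <- sc$weights
  score <- NULL
  for (j in seq_len(m)) {
    comp <- adSSIMComponents(a, b, config, tape)
    term <- if (j == m) adMean(adMul(comp$lum, comp$cs, tape), tape)
            else adMean(comp$cs, tape)
    term <- adPowC(adClampMin(term, 1e-8, tape), w[j], tape)
    score <- if (is.null(score)) term else adMul(score, term, tape)
    if (j < m) { a <- adAvgPoolHalf(a, tape); b <- adAvgPoolHalf(b, tape) }
  }
  score
}
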