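tinySpec2d <- function(...) GeneratorSpec(dim = 2, baseWidth = 4, levels = 2,
                                          ...)

test_that("spec validity enforces the dimension-specific couplings", {
  expect_error(new("GeneratorSpec", dim = 2L, inChannels = 1L, baseWidth = 4L,
                   widthCap = 8L, levels = 2L, convsPerBlock = 2L,
                   upsample = "transposed", batchnorm = FALSE, dropout = 0,
                   kernel = 3L), "pixel-shuffle")
  expect_error(new("GeneratorSpec", dim = 3L, inChannels = 2L, baseWidth = 4L,
                   widthCap = 8L, levels = 2L, convsPerBlock = 2L,
                   upsample = "pixel_shuffle", batchnorm = TRUE, dropout = 0.2,
                   kernel = 3L), "transposed")
  expect_error(new("GeneratorSpec", dim = 2L, inChannels = 1L, baseWidth = 4L,
                   widthCap = 8L, levels = 2L, convsPerBlock = 2L,
                   upsample = "pixel_shuffle", batchnorm = TRUE, dropout = 0,
                   kernel = 3L), "omit")
})

test_that("generator preserves spatial shape in 2D and 3D", {
  g2 <- buildGenerator(tinySpec2d(), seed = 1)
  out2 <- networkForward(g2, array(runif(32 * 48), c(32, 48, 1)))
  expect_equal(dim(out2), c(32L, 48L))
  expect_true(all(out2 > 0 & out2 < 1)) # sigmoid output

  g3 <- buildGenerator(GeneratorSpec(dim = 3, baseWidth = 2, levels = 2,
                                     dropout = 0), seed = 2)
  out3 <- networkForward(g3, array(runif(16^3 * 2), c(16, 16, 16, 2)))
  expect_equal(dim(out3), c(16L, 16L, 16L))

  expect_error(networkForward(g2, array(0.5, c(30, 30, 1))), "divisible")
})

test_that("default architectures honor the 17-layer accounting and parameter anchors", {
  for (d in c(2L, 3L)) {
    plan <- palocal:::genLayerPlan(GeneratorSpec(dim = d))
    expect_equal(sum(vapply(plan, function(l) l$type == "conv", logical(1))),
                 17L)
  }
  # printed anchors: ~43M (3D) and ~102M (2D) trainable parameters
  expect_gt(countParameters(GeneratorSpec(dim = 3)), 35e6)
  expect_lt(countParameters(GeneratorSpec(dim = 3)), 50e6)
  expect_gt(countParameters(GeneratorSpec(dim = 2)), 85e6)
  expect_lt(countParameters(GeneratorSpec(dim = 2)), 120e6)
  # discriminators: exactly 5 conv layers, ~5M / ~1.5M parameters
  for (d in c(2L, 3L))
    expect_equal(length(palocal:::discLayerPlan(DiscriminatorSpec(dim = d))), 5L)
  expect_true(abs(countParameters(DiscriminatorSpec(dim = 3)) - 5e6) < 1e6)
  expect_true(abs(countParameters(DiscriminatorSpec(dim = 2)) - 1.5e6) < 2e5)
})

test_that("parameter counts: analytic equals materialized equals hand computation", {
  spec <- tinySpec2d()
  net <- buildGenerator(spec, seed = 3)
  expect_equal(countParameters(net), countParameters(spec))

  # hand computation for a tiny discriminator: blocks 1->4->8->16->32 (k3)
  # plus the output convolution 32->1
  dspec <- DiscriminatorSpec(dim = 2, baseWidth = 4)
  hand <- 4 * (9 * 1 + 1) + 8 * (9 * 4 + 1) + 16 * (9 * 8 + 1) +
    32 * (9 * 16 + 1) + 1 * (9 * 32 + 1)
  expect_equal(countParameters(dspec), hand)
  expect_equal(countParameters(buildDiscriminator(dspec, seed = 1)), hand)

  # a single 3x3 conv layer mapping 1 -> 1 channels carries 10 scalars
  expect_equal(palocal:::layerParamCount(
    list(type = "conv", cin = 1, cout = 1, kernel = 3), nd = 2), 10)
})

test_that("discriminator outputs patch probabilities strictly inside (0, 1)", {
  d <- buildDiscriminator(DiscriminatorSpec(dim = 2, baseWidth = 4), seed = 4)
  p <- networkForward(d, array(runif(64 * 64), c(64, 64, 1)))
  expect_true(all(p > 0 & p < 1))
  expect_equal(dim(p), c(4L, 4L)) # 64 / 2^4

  # zero weights give sigmoid(0) = 0.5 exactly
  d0 <- d
  d0@params <- lapply(d0@params, function(p) p * 0)
  p0 <- networkForward(d0, array(0, c(32, 32, 1)))
  expect_true(all(p0 == 0.5))
})

test_that("pixel shuffle is the exact index permutation and inverts cleanly", {
  x <- array(rnorm(3 * 3 * 8), c(3, 3, 8))
  up <- pixelShuffleUpsample(x)
  expect_equal(dim(up), c(6L, 6L, 2L))
  expect_equal(sort(as.numeric(up)), sort(as.numeric(x))) # pure permutation
  # index-formula oracle: out[c, 2i+di, 2j+dj] = in[c*4 + 2di + dj, i, j]
  for (cc in 0:1) for (i in 0:2) for (j in 0:2)
    for (di in 0:1) for (dj in 0:1)
      expect_identical(up[2 * i + di + 1, 2 * j + dj + 1, cc + 1],
                       x[i + 1, j + 1, cc * 4 + 2 * di + dj + 1])
  expect_identical(spaceToDepth(up), x)

  x3 <- array(rnorm(2 * 2 * 2 * 8), c(2, 2, 2, 8))
  up3 <- pixelShuffleUpsample(x3)
  expect_equal(dim(up3), c(4L, 4L, 4L, 1L))
  expect_identical(spaceToDepth(up3), x3)

  expect_error(pixelShuffleUpsample(array(0, c(3, 3, 6))), "divisible")
})

test_that("initialization is seeded and forward passes are deterministic", {
  g1 <- buildGenerator(tinySpec2d(), seed = 11)
  g2 <- buildGenerator(tinySpec2d(), seed = 11)
  expect_identical(g1@params, g2@params)
  x <- array(runif(16 * 16), c(16, 16, 1))
  expect_identical(networkForward(g1, x), networkForward(g2, x))
})

test_that("autodiff gradients agree with finite differences", {
  spec <- GeneratorSpec(dim = 2, baseWidth = 3, levels = 1)
  g <- jitterZeroLayers(buildGenerator(spec, seed = 2))
  xa <- array(runif(8 * 8), c(8, 8, 1))
  ya <- matrix(runif(64), 8)
  mcfg <- MetricConfig(windowSize = 3L, scales = 1)
  lossOf <- function(params) {
    tape <- palocal:::newTape()
    pn <- palocal:::paramNodes(tape, params)
    xn <- palocal:::adLeaf(tape, xa)
    yc <- palocal:::adLeaf(tape, ya)
    go <- palocal:::dropChannelNode(
      palocal:::genForward(tape, g, xn, pn, train = FALSE), tape)
    list(l = palocal:::lossNode(tape, "pretrain2d", yc, go, NULL, mcfg),
         tape = tape, pn = pn)
  }
  r <- lossOf(g@params)
  palocal:::adBackward(r$tape, r$l)
  eps <- 1e-6
  set.seed(99)
  for (nm in names(g@params)) {
    p <- g@params[[nm]]
    for (j in sample(length(p), min(2, length(p)))) {
      p2 <- g@params
      p2[[nm]][j] <- p2[[nm]][j] + eps
      lp <- lossOf(p2)$l$value
      p2[[nm]][j] <- p2[[nm]][j] - 2 * eps
      lm <- lossOf(p2)$l$value
      fd <- (lp - lm) / (2 * eps)
      an <- r$pn[[nm]]$grad[j]
      expect_lt(abs(fd - an) / max(1e-4, abs(fd), abs(an)), 1e-3)
    }
  }
})

test_that("a 3D instance-normalized block also passes a gradient check", {
  spec <- GeneratorSpec(dim = 3, inChannels = 1, baseWidth = 2, levels = 1,
                        dropout = 0)
  g <- jitterZeroLayers(buildGenerator(spec, seed = 5))
  xa <- array(runif(4^3), c(4, 4, 4, 1))
  ya <- array(runif(4^3), c(4, 4, 4))
  lossOf <- function(params) {
    tape <- palocal:::newTape()
    pn <- palocal:::paramNodes(tape, params)
    xn <- palocal:::adLeaf(tape, xa)
    yc <- palocal:::adLeaf(tape, ya)
    go <- palocal:::dropChannelNode(
      palocal:::genForward(tape, g, xn, pn, train = FALSE), tape)
    dn <- palocal:::adLeaf(tape, 0.6) # fixed pseudo-probability
    l <- palocal:::adAdd(
      palocal:::adScale(palocal:::adMean(palocal:::adAbs(
        palocal:::adSub(go, yc, tape), tape), tape), 0.01, tape),
      palocal:::adScale(palocal:::adLog(dn, tape), -1, tape), tape)
    list(l = l, tape = tape, pn = pn)
  }
  r <- lossOf(g@params)
  palocal:::adBackward(r$tape, r$l)
  eps <- 1e-6
  set.seed(7)
  for (nm in sample(names(g@params), 6)) {
    p <- g@params[[nm]]
    j <- sample(length(p), 1)
    p2 <- g@params
    p2[[nm]][j] <- p2[[nm]][j] + eps
    lp <- lossOf(p2)$l$value
    p2[[nm]][j] <- p2[[nm]][j] - 2 * eps
    lm <- lossOf(p2)$l$value
    fd <- (lp - lm) / (2 * eps)
    an <- r$pn[[nm]]$grad[j]
    expect_lt(abs(fd - an) / max(1e-4, abs(fd), abs(an)), 1e-3)
  }
})
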