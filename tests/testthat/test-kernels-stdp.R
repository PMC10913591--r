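test_that("outer-product STDP matches hand-worked cases", {
  # pre=(T,F), post=(F,T), lr=1 on a 2x2 zero dst_major matrix
  W <- weightMatrix(matrix(0, 2, 2), layout = "dst_major")
  pre <- spikeVector(c(TRUE, FALSE))
  post <- spikeVector(c(FALSE, TRUE))
  expect_equal(weightData(stdpOuter(W, pre, post, 1)),
               matrix(c(0, 1, 0, 0), 2, 2))
  # no post spikes -> unchanged
  expect_identical(weightData(stdpOuter(W, pre, spikeVector(c(FALSE, FALSE)),
                                        1)),
                   weightData(W))
  expect_error(stdpOuter(W, spikeVector(TRUE), post, 1), "sizes")
})

test_that("mesh construction follows layout and counts |pre|*|post|", {
  pre <- spikeVector(c(TRUE, FALSE))
  post <- spikeVector(c(FALSE, TRUE))
  m <- meshFromSpikes(pre, post, "dst_major")
  expect_identical(meshRows(m), 2L)
  expect_identical(meshCols(m), 1L)
  ms <- meshFromSpikes(pre, post, "src_major")
  expect_identical(meshRows(ms), 1L)
  expect_identical(meshCols(ms), 2L)
  expect_identical(meshSize(meshFromSpikes(spikeVector(logical(5)),
                                           spikeVector(logical(5)))), 0L)
  set.seed(21)
  for (t in 1:50) {
    a <- spikeVector(runif(40) < 0.2)
    b <- spikeVector(runif(30) < 0.2)
    expect_identical(meshSize(meshFromSpikes(a, b, "dst_major")),
                     length(activeIndices(a)) * length(activeIndices(b)))
  }
})

test_that("mesh STDP is bit-identical to the outer-product oracle", {
  set.seed(22)
  for (t in 1:300) {
    inst <- randomInstance()
    lr <- runif(1)
    Wo <- stdpOuter(inst$W, inst$src, inst$dst, lr)
    Wm <- stdpMesh(inst$W, meshFromSpikes(inst$src, inst$dst, inst$layout), lr)
    expect_identical(weightData(Wo), weightData(Wm))
  }
  # identity also on reduced-precision grids
  for (dt in c("f32", "f16")) {
    set.seed(23)
    inst <- randomInstance(spikeRate = 0.1)
    W <- castPrecision(inst$W, dt)
    expect_identical(
      weightData(stdpOuter(W, inst$src, inst$dst, 0.25)),
      weightData(stdpMesh(W, meshFromSpikes(inst$src, inst$dst, inst$layout),
                          0.25)))
  }
  # empty mesh leaves weights untouched
  W <- genWeightMatrix(10, 10)
  empty <- meshFromSpikes(spikeVector(logical(10)), spikeVector(logical(10)))
  expect_identical(weightData(stdpMesh(W, empty, 1)), weightData(W))
  expect_error(stdpMesh(W, new("IndexMesh", rows = 11L, cols = 1L), 1),
               "out of range")
})

test_that("the naive update's multiplication count is the full index space", {
  set.seed(24)
  for (t in 1:10) {
    S <- sample.int(40, 1); D <- sample.int(40, 1)
    W <- genWeightMatrix(S, D)
    expect_equal(naiveStdpMultiplications(W), as.numeric(S) * D)
  }
  # enumeration and closed form agree at the crossover
  W <- genWeightMatrix(100, 50)
  expect_equal(naiveStdpMultiplications(W, enumerateLimit = 1e6),
               naiveStdpMultiplications(W, enumerateLimit = 0))
})

test_that("masked clipping clamps mesh entries and preserves the rest", {
  data <- matrix(c(0.5, 7, -2, 0.2), 2, 2)
  W <- weightMatrix(data, layout = "dst_major")
  mesh <- new("IndexMesh", rows = 1L, cols = c(1L, 2L))
  Wc <- clipMesh(W, mesh, 0, 1)
  expect_equal(weightData(Wc)[1, ], c(0.5, 0))   # -2 clamped up
  expect_equal(weightData(Wc)[2, ], c(7, 0.2))   # out-of-range 7 untouched
  expect_error(clipMesh(W, mesh, 1, 0), "wMin")
  # in-range mesh entries unchanged
  expect_identical(weightData(clipMesh(W, new("IndexMesh", rows = 2L,
                                              cols = 2L), 0, 1)),
                   data)
  # multiset of non-mesh entries is always preserved
  set.seed(25)
  for (t in 1:30) {
    inst <- randomInstance(sizeCap = 50, spikeRate = 0.2)
    m <- meshFromSpikes(inst$src, inst$dst, inst$layout)
    before <- weightData(inst$W)
    after <- weightData(clipMesh(inst$W, m, 0.3, 0.6))
    sel <- matrix(FALSE, nrow(before), ncol(before))
    sel[meshRows(m), meshCols(m)] <- TRUE
    expect_identical(after[!sel], before[!sel])
    expect_true(all(after[sel] >= 0.3 & after[sel] <= 0.6))
  }
})

test_that("full clipping bounds every entry", {
  W <- genWeightMatrix(20, 20)
  Wc <- clipWeights(stdpOuter(W, spikeVector(rep(TRUE, 20)),
                              spikeVector(rep(TRUE, 20)), 5), 0, 1)
  expect_true(all(weightData(Wc) >= 0 & weightData(Wc) <= 1))
})

test_that("spike history is a bounded most-recent-first ring", {
  h <- spikeHistory(depth = 3, size = 4)
  expect_identical(historyLength(h), 0L)
  svs <- lapply(1:5, function(i) spikeVector(seq_len(4) == (i %% 4 + 1)))
  for (sv in svs) h <- pushSpikes(h, sv)
  expect_identical(historyLength(h), 3L)
  expect_identical(spikesAtLag(h, 0), svs[[5]])
  expect_identical(spikesAtLag(h, 2), svs[[3]])
  expect_error(spikesAtLag(h, 3), "insufficient")
  expect_error(pushSpikes(h, spikeVector(logical(5))))
})

test_that("multi-lag STDP equals sequential outer applications bit for bit", {
  set.seed(26)
  for (t in 1:100) {
    S <- sample.int(60, 1); D <- sample.int(60, 1)
    W <- genWeightMatrix(S, D, layout = sample(c("dst_major", "src_major"), 1),
                         seed = t)
    L <- 5L
    hp <- spikeHistory(L, S); hq <- spikeHistory(L, D)
    for (i in seq_len(L)) {
      hp <- pushSpikes(hp, spikeVector(runif(S) < 0.1))
      hq <- pushSpikes(hq, spikeVector(runif(D) < 0.1))
    }
    amps <- defaultMultiLagAmplitudes(0.05, lags = -4:4)
    Wm <- stdpMultiLag(W, hp, hq, amps)
    Ws <- W
    for (l in as.integer(names(amps))) {
      Ws <- stdpOuter(Ws, spikesAtLag(hp, max(l, 0L)),
                      spikesAtLag(hq, max(-l, 0L)), amps[[as.character(l)]])
    }
    expect_identical(weightData(Wm), weightData(Ws))
  }
  # zero amplitudes leave W unchanged; single lag reduces to the 1-step rule
  W <- genWeightMatrix(10, 10)
  hp <- pushSpikes(pushSpikes(spikeHistory(2, 10),
                              genSpikeVector(10, 0.5, 1)),
                   genSpikeVector(10, 0.5, 2))
  hq <- pushSpikes(pushSpikes(spikeHistory(2, 10),
                              genSpikeVector(10, 0.5, 3)),
                   genSpikeVector(10, 0.5, 4))
  expect_identical(
    weightData(stdpMultiLag(W, hp, hq, c("1" = 0, "-1" = 0))),
    weightData(W))
  expect_identical(
    weightData(stdpMultiLag(W, hp, hq, c("1" = 0.3))),
    weightData(stdpOuter(W, spikesAtLag(hp, 1), spikesAtLag(hq, 0), 0.3)))
  expect_error(stdpMultiLag(W, hp, hq, c("3" = 0.1)), "insufficient")
})
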