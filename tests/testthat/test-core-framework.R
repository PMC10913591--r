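test_that("behavior attachment enforces per-component key uniqueness", {
  net <- newNetwork(seed = 1)
  g <- addNeuronGroup(net, 10)
  attachBehavior(g, 2, behavior(name = "a"))
  attachBehavior(g, 5, behavior(name = "b"))
  attachBehavior(g, 9, behavior(name = "c"))
  expect_equal(sort(as.numeric(names(g$behaviors))), c(2, 5, 9))
  expect_error(attachBehavior(g, 5, behavior(name = "dup")), "5")
  # same key on a different component is fine
  expect_silent(attachBehavior(net, 5, behavior(name = "net_b")))
})

test_that("schedule is globally sorted with ties broken by registration order", {
  net <- newNetwork(seed = 1)
  gA <- addNeuronGroup(net, 5, name = "A")
  gB <- addNeuronGroup(net, 5, name = "B")
  sg <- addSynapseGroup(net, gA, gB, name = "S")
  attachBehavior(gA, 5, behavior(name = "a5"))
  attachBehavior(net, 2, behavior(name = "n2"))
  attachBehavior(sg, 3, behavior(name = "s3"))
  attachBehavior(gB, 5, behavior(name = "b5"))
  sched <- buildSchedule(net)
  expect_equal(scheduleKeys(sched), c(2, 3, 5, 5))
  # tie at key 5: gA registered before gB
  expect_equal(sched@behaviorNames, c("n2", "s3", "a5", "b5"))
  # repeated builds give the identical order
  expect_equal(buildSchedule(net)@behaviorNames, sched@behaviorNames)
  # empty network -> empty schedule
  expect_length(buildSchedule(newNetwork(seed = 1)), 0)
})

test_that("schedule totality holds under random attachment orders", {
  for (rep in 1:10) {
    set.seed(rep)
    net <- newNetwork(seed = 1)
    comps <- list(net, addNeuronGroup(net, 3), addNeuronGroup(net, 3))
    n <- 0L
    for (comp in comps) {
      for (k in sample(1:20, sample(1:6, 1))) {
        attachBehavior(comp, k, behavior(name = paste0("b", n)))
        n <- n + 1L
      }
    }
    sched <- buildSchedule(net)
    expect_length(sched, n)
    expect_false(is.unsorted(scheduleKeys(sched)))
    expect_equal(sort(sched@behaviorNames), sort(paste0("b", seq_len(n) - 1L)))
  }
})

test_that("initialize runs setups once in key order and rejects a second call", {
  net <- newNetwork(seed = 1)
  g <- addNeuronGroup(net, 4)
  tr <- new.env()
  attachBehavior(g, 2, probeBehavior(tr, "second"))
  attachBehavior(net, 1, probeBehavior(tr, "first"))
  # a key-1 variable must be visible to a key-2 setup
  attachBehavior(g, 3, behavior(
    setup = function(comp, self)
      tr$sawFirst <- "first" %in% tr$setupTrace,
    name = "visibility_probe"))
  initializeNetwork(net)
  expect_equal(tr$setupTrace, c("first", "second"))
  expect_true(tr$sawFirst)
  expect_identical(net$iteration, 0L)
  expect_error(initializeNetwork(net), "already initialized")
})

test_that("a failing setup reports the behavior identity", {
  net <- newNetwork(seed = 1)
  g <- addNeuronGroup(net, 2, name = "grp")
  attachBehavior(g, 1, behavior(setup = function(comp, self) stop("boom"),
                                name = "broken_setup"))
  expect_error(initializeNetwork(net), "broken_setup")
})

test_that("each iteration executes every step hook once, in key order", {
  net <- newNetwork(seed = 1)
  g <- addNeuronGroup(net, 2)
  tr <- new.env()
  attachBehavior(g, 7, probeBehavior(tr, "late"))
  attachBehavior(net, 1, probeBehavior(tr, "early"))
  initializeNetwork(net)
  simulateIterations(net, 0)
  expect_null(tr$stepTrace)
  expect_identical(net$iteration, 0L)
  simulateIterations(net, 3)
  expect_equal(tr$stepTrace, rep(c("early", "late"), 3))
  expect_identical(net$iteration, 3L)
})

test_that("a failing step reports behavior identity and iteration", {
  net <- newNetwork(seed = 1)
  g <- addNeuronGroup(net, 2, name = "grp")
  attachBehavior(g, 1, behavior(
    step = function(comp, self)
      if (comp$net$iteration == 2L) stop("boom"),
    name = "broken_step"))
  initializeNetwork(net)
  expect_error(simulateIterations(net, 5), "broken_step.*iteration 2")
})

test_that("neuronVector honors fill modes and the group stream", {
  net <- newNetwork(seed = 11)
  g <- addNeuronGroup(net, 10)
  expect_equal(neuronVector(g, "zeros"), rep(0, 10))
  expect_equal(neuronVector(g, "value", value = -65), rep(-65, 10))
  u <- neuronVector(g, "uniform")
  expect_true(all(u >= 0 & u < 1))
  expect_error(neuronVector(g, "bogus"))
  # same master seed, fresh network -> identical draw sequence
  net2 <- newNetwork(seed = 11)
  g2 <- addNeuronGroup(net2, 10)
  expect_equal(neuronVector(g2, "zeros"), rep(0, 10))
  expect_equal(neuronVector(g2, "value", value = -65), rep(-65, 10))
  expect_identical(neuronVector(g2, "uniform"), u)
})

test_that("synapseMatrix produces layout-consistent seeded matrices", {
  net <- newNetwork(seed = 5)
  src <- addNeuronGroup(net, 50)
  dst <- addNeuronGroup(net, 100)
  sg <- addSynapseGroup(net, src, dst)
  W <- synapseMatrix(sg, layout = "dst_major", init = "uniform")
  expect_equal(dim(weightData(W)), c(100L, 50L))
  expect_equal(srcSize(W), 50L)
  # src_major from the same seed carries the same semantic weights
  net2 <- newNetwork(seed = 5)
  src2 <- addNeuronGroup(net2, 50)
  dst2 <- addNeuronGroup(net2, 100)
  sg2 <- addSynapseGroup(net2, src2, dst2)
  W2 <- synapseMatrix(sg2, layout = "src_major", init = "uniform")
  expect_equal(dim(weightData(W2)), c(50L, 100L))
  expect_identical(weightData(transposeLayout(W2)), weightData(W))
  expect_equal(weightData(synapseMatrix(sg, layout = "src_major",
                                        init = "zeros")),
               matrix(0, 50, 100))
})

test_that("findByTag returns exactly the entities carrying the tag", {
  net <- newNetwork(seed = 1)
  g1 <- addNeuronGroup(net, 2, tags = c("exc", "cortex"))
  g2 <- addNeuronGroup(net, 2, tags = "exc")
  g3 <- addNeuronGroup(net, 2, tags = "inh")
  b <- behavior(name = "tagged_beh", tags = "plastic")
  attachBehavior(g3, 1, b)
  hits <- findByTag(net, "exc")
  expect_length(hits, 2)
  expect_identical(hits[[1]], g1)
  expect_identical(hits[[2]], g2)
  expect_identical(findByTag(net, "plastic")[[1]], b)
  expect_length(findByTag(net, "nothing"), 0)
  # exhaustive-scan oracle
  all_tags <- unlist(lapply(net$components, function(cp)
    c(cp$tags, unlist(lapply(cp$behaviors, function(bb) bb$tags)))))
  for (tg in unique(all_tags))
    expect_equal(length(findByTag(net, tg)), sum(all_tags == tg))
})

test_that("synapse registries stay consistent with src/dst references", {
  net <- newNetwork(seed = 1)
  a <- addNeuronGroup(net, 3)
  b <- addNeuronGroup(net, 3)
  s1 <- addSynapseGroup(net, a, b, tags = "GLU")
  s2 <- addSynapseGroup(net, b, b, tags = "GLU")
  for (sg in net$synapseGroups) {
    expect_true(any(vapply(sg$dst$afferent[["all"]], identical, logical(1), sg)))
    expect_true(any(vapply(sg$src$efferent[["all"]], identical, logical(1), sg)))
  }
  expect_length(b$afferent[["GLU"]], 2)
  expect_length(a$efferent[["all"]], 1)
})

test_that("subgroup views write through to the parent on masked positions", {
  net <- newNetwork(seed = 1)
  g <- addNeuronGroup(net, 6)
  g$state$v <- as.numeric(1:6)
  expect_error(subgroup(g, c(TRUE, FALSE)), "mask length")
  allv <- subgroup(g, rep(TRUE, 6))
  expect_equal(getStateVar(allv, "v"), as.numeric(1:6))
  none <- subgroup(g, rep(FALSE, 6))
  expect_length(getStateVar(none, "v"), 0)
  half <- subgroup(g, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  setStateVar(half, "v", 1)
  expect_equal(getStateVar(g, "v"), c(1, 1, 1, 4, 5, 6))
  expect_equal(half$size, 3L)
})

test_that("recorder buffers respect cadence and record in key order", {
  for (k in c(1L, 3L, 7L, 100L)) {
    net <- newNetwork(seed = 2)
    g <- addNeuronGroup(net, 4)
    attachBehavior(g, 1, behavior(
      setup = function(comp, self) comp$state$x <- 0,
      step = function(comp, self) comp$state$x <- comp$state$x + 1,
      name = "counter"))
    rec <- addRecorder(net, g, "x", cadence = k)
    initializeNetwork(net)
    T <- 23L
    simulateIterations(net, T)
    expect_identical(recorderLength(rec), as.integer(floor(T / k)))
    expect_equal(recordedIterations(rec), seq_len(floor(T / k)) * k)
    # snapshot holds the value *after* the step of that iteration
    vals <- vapply(recordedValues(rec), identity, numeric(1))
    expect_equal(vals, as.numeric(seq_len(floor(T / k)) * k))
  }
})

test_that("fixed master seed gives bit-identical runs; recorders do not perturb", {
  run <- function(extraRecorder) {
    net <- buildReferenceModel("lif_onestep", n = 120, seed = 9)
    if (extraRecorder) addRecorder(net, net$neuronGroups[[1]], "v")
    simulateIterations(net, 60)
    rasterFromRecorder(net$recorders[[1]])
  }
  r1 <- run(FALSE); r2 <- run(FALSE); r3 <- run(TRUE)
  expect_identical(r1, r2)
  expect_identical(r1, r3)  # added recorder leaves dynamics untouched
})
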