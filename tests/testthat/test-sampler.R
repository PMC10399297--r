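test_that("Fubini numbers match brute-force ordered-partition counts", {
  p <- fubiniNumbers(4)
  counts <- vapply(1:4, function(k) length(enumOrderedPartitions(seq_len(k))),
                   numeric(1))
  expect_equal(p, c(1, counts))          # 1 1 3 13 75
  expect_equal(fubiniNumbers(0), 1)
  expect_error(fubiniNumbers(17), "exceed")
})

test_that("ordered partitions are sampled uniformly", {
  set.seed(101)
  # |X| = 1: only one outcome
  expect_equal(sampleOrderedPartition(7L), list(7L))
  # |X| = 2: three equiprobable ordered partitions
  keys2 <- replicate(30000, partitionKey(sampleOrderedPartition(1:2)))
  tb2 <- table(keys2)
  expect_equal(length(tb2), 3)
  expect_gt(chisqUniformP(tb2), 0.001)
  # |X| = 3: thirteen equiprobable outcomes, all realized
  keys3 <- replicate(30000, partitionKey(sampleOrderedPartition(1:3)))
  tb3 <- table(keys3)
  oracle <- sort(vapply(enumOrderedPartitions(1:3), partitionKey, character(1)))
  expect_equal(sort(names(tb3)), oracle)
  expect_gt(chisqUniformP(tb3), 0.001)
  expect_error(sampleOrderedPartition(integer(0)), "empty")
})

test_that("the first-block size follows C(k,j) p_{k-j} / p_k", {
  set.seed(102)
  k <- 5
  p <- fubiniNumbers(k)
  probs <- choose(k, 1:k) * p[k:1] / p[k + 1]
  sizes <- replicate(20000, length(sampleOrderedPartition(seq_len(k))[[1]]))
  counts <- vapply(1:k, function(j) sum(sizes == j), numeric(1))
  expect_gt(chisqUniformP(counts, probs), 0.001)
})

test_that("noncanalizing rejection sampling hits exactly the accepted class", {
  set.seed(103)
  # m = 0: the only nonzero constant
  expect_equal(tableBits(sampleNoncanalizing(0)), 1L)
  # m = 1: both literals are canalizing, zero excluded, so always constant 1
  draws1 <- replicate(200, tableBits(sampleNoncanalizing(1)))
  expect_true(all(draws1 == 1L))
  # m = 2: brute-force the accepted class and compare empirically
  accepted <- Filter(function(v) {
    f <- ttFromIndex(v, 2)
    !isCanalizing(f) && !all(tableBits(f) == 0L)
  }, 0:15)
  expect_equal(length(accepted), 3)     # 1, x1+x2, x1+x2+1
  draws2 <- replicate(6000, ttIndex(sampleNoncanalizing(2)))
  expect_setequal(unique(draws2), accepted)
  expect_gt(chisqUniformP(table(draws2)), 0.001)
  # with the zero function allowed it reappears
  set.seed(104)
  draws0 <- replicate(4000, ttIndex(sampleNoncanalizing(2, excludeZero = FALSE)))
  expect_setequal(unique(draws0), c(0, accepted))
})

test_that("depth-k sampling is uniform over the brute-force classes", {
  classes2 <- depthClassification(2)
  classes3 <- depthClassification(3)
  cases <- list(list(n = 2, k = 0, cls = classes2),
                list(n = 2, k = 1, cls = classes2),
                list(n = 2, k = 2, cls = classes2),
                list(n = 3, k = 1, cls = classes3),
                list(n = 3, k = 3, cls = classes3))
  set.seed(105)
  for (cs in cases) {
    target <- which(cs$cls == cs$k) - 1
    draws <- replicate(30000, ttIndex(sampleDepthKFunction(cs$n, cs$k)))
    expect_setequal(unique(draws), target)
    counts <- table(factor(draws, levels = target))
    expect_gt(chisqUniformP(counts), 0.001)
  }
})

test_that("sampled functions always have the requested exact depth", {
  set.seed(106)
  grid <- expand.grid(n = 4:8, k = 0:4)
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]; k <- grid$k[i]
    for (r in 1:40)
      expect_equal(canalizingDepth(sampleDepthKFunction(n, k)), k)
  }
})

test_that("output negation preserves the sampled depth class", {
  set.seed(107)
  for (i in 1:200) {
    f <- sampleDepthKFunction(4, sample(0:4, 1))
    expect_equal(canalizingDepth(truthTable(1L - tableBits(f), 4)),
                 canalizingDepth(f))
  }
})

test_that("networks draw independent coordinates of the requested depth", {
  set.seed(108)
  net <- sampleNetwork(3, 1)
  expect_equal(nVars(net), 3)
  expect_equal(vapply(networkFunctions(net), canalizingDepth, numeric(1)),
               rep(1, 3))
  # coordinate marginals match the single-function class
  target <- which(depthClassification(3) == 1) - 1
  set.seed(109)
  draws <- replicate(4000, ttIndex(networkFunctions(sampleNetwork(3, 1))[[2]]))
  expect_setequal(unique(draws), target)
  expect_gt(chisqUniformP(table(factor(draws, levels = target))), 0.001)
  # fixed seed reproduces the network bit for bit
  set.seed(110); a <- sampleNetwork(5, 2)
  set.seed(110); b <- sampleNetwork(5, 2)
  expect_identical(lapply(networkFunctions(a), tableBits),
                   lapply(networkFunctions(b), tableBits))
  expect_error(sampleNetwork(3, 4), "k <= n")
})
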