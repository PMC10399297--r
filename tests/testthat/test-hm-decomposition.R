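test_that("the worked four-variable decomposition is recovered", {
  # f = x1 (x2+1) (x3 x4 + x3 + x4): nested, two layers, constant-1 core
  f <- tt(4, function(x) x[1] * ((x[2] + 1) %% 2) *
            ((x[3] * x[4] + x[3] + x[4]) %% 2))
  d <- hmDecompose(f)
  expect_equal(outerConstant(d), 0L)
  expect_equal(numLayers(d), 2)
  expect_equal(canalizingDepth(d), 4)
  expect_equal(layers(d)[[1]], list(vars = c(1L, 2L), a = c(0L, 1L)))
  expect_equal(layers(d)[[2]], list(vars = c(3L, 4L), a = c(1L, 1L)))
  expect_equal(length(coreVars(d)), 0)
  expect_equal(tableBits(coreFunction(d)), 1L)
  expect_identical(tableBits(hmRecompose(d)), tableBits(f))
})

test_that("a multi-layer function with a nonconstant core decomposes", {
  # g = x5 ((x3+1) x4 (x1+x2) + 1) + 1: layers {x5}, {x3, x4}, b = 1,
  # core x1 + x2 on the complement variables
  g <- tt(5, function(x)
    (x[5] * ((((x[3] + 1) %% 2) * x[4] * ((x[1] + x[2]) %% 2) + 1) %% 2) + 1) %% 2)
  d <- hmDecompose(g)
  expect_equal(outerConstant(d), 1L)
  expect_equal(numLayers(d), 2)
  expect_equal(canalizingDepth(d), 3)
  expect_equal(layers(d)[[1]], list(vars = 5L, a = 0L))
  expect_equal(layers(d)[[2]], list(vars = c(3L, 4L), a = c(1L, 0L)))
  expect_equal(coreVars(d), c(1L, 2L))
  expect_equal(tableBits(coreFunction(d)), tableBits(ttXOR2()))  # x1 + x2
  expect_identical(tableBits(hmRecompose(d)), tableBits(g))
})

test_that("absorbing the inner literal collapses adjacent layers", {
  # h = 1 + x5 x4 (x3+1)(x1+x2): x4 and x3 canalize h directly, so the
  # unique form has a single three-variable layer, not {x5} then {x3,x4}
  h <- tt(5, function(x)
    (1 + x[5] * x[4] * ((x[3] + 1) %% 2) * ((x[1] + x[2]) %% 2)) %% 2)
  d <- hmDecompose(h)
  expect_equal(numLayers(d), 1)
  expect_equal(layers(d)[[1]], list(vars = c(3L, 4L, 5L), a = c(1L, 0L, 0L)))
  expect_equal(outerConstant(d), 1L)
  expect_equal(canalizingDepth(d), 3)
  expect_equal(tableBits(coreFunction(d)), tableBits(ttXOR2()))
  expect_identical(tableBits(hmRecompose(d)), tableBits(h))
})

test_that("single literals take the b = 0 branch of the exceptional case", {
  d <- hmDecompose(truthTable(c(0L, 1L)))   # f = x1
  expect_equal(numLayers(d), 1)
  expect_equal(layers(d)[[1]], list(vars = 1L, a = 0L))
  expect_equal(outerConstant(d), 0L)
  expect_equal(tableBits(coreFunction(d)), 1L)
  dn <- hmDecompose(truthTable(c(1L, 0L)))  # f = 1 + x1
  expect_equal(layers(dn)[[1]], list(vars = 1L, a = 1L))
  expect_equal(outerConstant(dn), 0L)
  # degenerate literal on a larger variable set
  d2 <- hmDecompose(tt(3, function(x) x[2]))
  expect_equal(layers(d2)[[1]], list(vars = 2L, a = 0L))
  expect_equal(outerConstant(d2), 0L)
  expect_identical(tableBits(hmRecompose(d2)), tableBits(tt(3, function(x) x[2])))
})

test_that("noncanalizing functions decompose trivially and recompose", {
  d <- hmDecompose(ttPARITY3())
  expect_equal(numLayers(d), 0)
  expect_equal(outerConstant(d), 0L)
  expect_equal(coreVars(d), 1:3)
  expect_identical(tableBits(hmRecompose(d)), tableBits(ttPARITY3()))
  # the constant 1 is noncanalizing with itself as core
  d1 <- hmDecompose(truthTable(rep(1L, 4)))
  expect_equal(numLayers(d1), 0)
  expect_identical(tableBits(hmRecompose(d1)), rep(1L, 4))
})

test_that("the identically-zero function is rejected", {
  expect_error(hmDecompose(truthTable(rep(0L, 8))), "identically 0")
})

test_that("decompose/recompose round-trips exhaustively and at random", {
  # every nonzero function on up to 3 variables
  for (n in 1:3) {
    for (v in 1:(2^(2^n) - 1)) {
      f <- ttFromIndex(v, n)
      d <- hmDecompose(f)
      expect_identical(tableBits(hmRecompose(d)), tableBits(f))
      # depth from the decomposition agrees with iterative peeling
      expect_equal(canalizingDepth(d), canalizingDepth(f))
    }
  }
  # random 6-variable functions
  set.seed(21)
  for (i in 1:1000) {
    f <- randomTable(6)
    if (all(tableBits(f) == 0L)) next
    expect_identical(tableBits(hmRecompose(hmDecompose(f))), tableBits(f))
  }
})

test_that("maximal depth is equivalent to a constant-1 empty-set core", {
  for (v in 1:255) {
    f <- ttFromIndex(v, 3)
    d <- hmDecompose(f)
    nested <- canalizingDepth(f) == 3
    expect_equal(length(coreVars(d)) == 0 && all(tableBits(coreFunction(d)) == 1L),
                 nested)
  }
})

test_that("decomposition invariants hold on random functions", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(2:5, 1)
    f <- randomTable(n)
    if (all(tableBits(f) == 0L)) next
    d <- hmDecompose(f)
    allVars <- c(unlist(lapply(layers(d), `[[`, "vars")), coreVars(d))
    expect_setequal(allVars, seq_len(n))
    expect_equal(anyDuplicated(allVars), 0)
    expect_false(isCanalizing(coreFunction(d)))
    expect_true(any(tableBits(coreFunction(d)) == 1L))
    expect_true(validObject(d))
  }
})
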