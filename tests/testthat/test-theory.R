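test_that("the cycle-string weights take their defining values", {
  expect_equal(weightF(0, 2, 2), 1 / 2)
  expect_equal(weightF(0, 1, 2), 1 / 2)
  for (l in 1:4) expect_equal(weightF(2^l - 1, 2^l - 1, l), 2^(-l))
  expect_equal(weightF(1, 0, 2), 0)   # alpha OR beta != beta
  expect_equal(weightG(0, 1, 2), 1 / 4)
  expect_equal(weightG(3, 1, 2), 1 / 4)
  # negation symmetry in the first argument, and l = 1 is constant 1/2
  for (a in 0:3) for (b in 0:3)
    expect_equal(weightG(a, b, 2), weightG(3 - a, b, 2))
  for (a in 0:1) for (b in 0:1) expect_equal(weightG(a, b, 1), 1 / 2)
  expect_error(weightF(4, 0, 2), "cycle strings")
})

test_that("the transfer matrix reproduces the known small cases exactly", {
  G1 <- buildTransferMatrix(1)
  expect_equal(transferMatrixValues(G1), matrix(1 / 2, 2, 2))
  G2 <- buildTransferMatrix(2)
  expected <- rbind(c(3, 2, 2, 3),
                    c(1, 2, 2, 1),
                    c(1, 2, 2, 1),
                    c(3, 2, 2, 3)) / 8
  expect_equal(transferMatrixValues(G2), expected)
  expect_error(buildTransferMatrix(11), "between 1 and")
})

test_that("transfer-matrix columns are exactly stochastic with the symmetries", {
  for (l in 1:8) {
    G <- buildTransferMatrix(l)
    N <- 2^l
    # integer numerators over 2^(l+2): exact column sums
    expect_true(all(colSums(G@num) == G@den))
    vals <- transferMatrixValues(G)
    expect_true(all(colSums(vals) == 1))
    neg <- (N - 1):0
    expect_identical(vals, vals[neg + 1, , drop = FALSE])
    expect_identical(vals, vals[, neg + 1, drop = FALSE])
  }
  # shift invariance g(s(a), s(b)) = g(a, b)
  for (l in 1:5) {
    N <- 2^l
    sh <- CanalDyn:::.shiftRight(0:(N - 1), l)
    for (a in 0:(N - 1)) for (b in 0:(N - 1))
      expect_equal(weightG(sh[a + 1], sh[b + 1], l), weightG(a, b, l))
  }
})

test_that("characteristic polynomials are exact and have the (t-1) factor", {
  # l = 1: the all-1/2 matrix has polynomial t^2 - t
  p1 <- charPoly(buildTransferMatrix(1))
  expect_equal(p1$num / p1$den, c(1, -1, 0))
  # l = 2: t^4 - (5/4) t^3 + (1/4) t^2, by direct exact expansion
  p2 <- charPoly(buildTransferMatrix(2))
  expect_equal(p2$num, c(1, -5, 1, 0, 0))
  expect_equal(p2$den, c(1, 4, 4, 1, 1))
  # constant term = +/- det(G): zero for the rank-deficient G2
  expect_equal(p2$num[5], 0)
  # P(1) = 0 exactly (eigenvalue 1 from column stochasticity), l <= 4
  for (l in 1:4) {
    p <- charPoly(buildTransferMatrix(l))
    expect_equal(sum(p$num / p$den), 0)
  }
})

test_that("the depth-one attractor limits match the closed forms", {
  A1 <- attractorLimit(1)
  expect_true(A1@exact)
  expect_equal(c(A1@valueNum, A1@valueDen), c(1, 1))
  A2 <- attractorLimit(2)
  expect_equal(c(A2@valueNum, A2@valueDen), c(2, 3))
  A3 <- attractorLimit(3)
  expect_equal(c(A3@valueNum, A3@valueDen), c(64, 189))
  expect_equal(A3@oneMultiplicity, 1L)
  # the numeric eigenvalue path agrees with the exact path
  for (l in 1:4)
    expect_equal(attractorLimit(l, exact = FALSE)@value,
                 attractorLimit(l)@value, tolerance = 1e-10)
})

test_that("depth-one networks beat the unconstrained 1/l baseline", {
  # exact baseline: 1 for l = 1, 1/l in the large-n limit
  expect_equal(expectedAttractorsRandom(1, 1), 1)
  expect_equal(expectedAttractorsRandom(12, 1), 1)
  expect_equal(expectedAttractorsRandom(20, 3), 1 / 3, tolerance = 1e-4)
  # l = 2, n = 1: brute force over all 4 maps on 2 states
  maps <- expand.grid(s0 = 0:1, s1 = 0:1)
  twoCycles <- mean(apply(maps, 1, function(s) {
    succ <- c(s[1], s[2])
    sum(succ[succ + 1] == 0:1 & succ != 0:1) / 2
  }))
  expect_equal(expectedAttractorsRandom(1, 2), twoCycles)  # 1/4
  # Remark-6 style inequality, tight at l = 5 (0.2004 > 0.2)
  for (l in 2:6) expect_gt(attractorLimit(l)@value, 1 / l)
})

test_that("Monte-Carlo attractor counts approach the analytic values", {
  set.seed(301)
  # depth-0 (noncanalizing) networks sit close to the unconstrained baseline
  mc <- monteCarloExpected(6, 0, 1, samples = 3000)
  expect_lt(abs(mc$mean - expectedAttractorsRandom(6, 1)), 3 * mc$se)
  # the finite-size gap to the depth-one limit shrinks as n grows (2-SE slack)
  for (l in 1:2) {
    A <- attractorLimit(l)@value
    res <- lapply(c(8, 10, 12), function(n)
      monteCarloExpected(n, 1, l, samples = 400))
    gaps <- vapply(res, function(r) abs(r$mean - A), numeric(1))
    ses <- vapply(res, function(r) r$se, numeric(1))
    for (i in 1:2)
      expect_lt(gaps[i + 1], gaps[i] + 2 * (ses[i] + ses[i + 1]))
  }
})
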