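#' @include hm-decomposition.R
NULL

#' Fubini numbers (ordered Bell numbers)
#'
#' \code{p_i} counts the ordered partitions of an i-element set into a
#' sequence of nonempty blocks, via the recurrence
#' \eqn{p_j = \sum_{m=1}^{j} \binom{j}{m} p_{j-m}}, \eqn{p_0 = 1}.
#'
#' @param k largest set size; must be at most 16 so the counts stay exact
#'   in double precision (\code{p_17 > 2^53}).
#' @return Numeric vector \code{c(p_0, ..., p_k)} of length \code{k + 1}.
#' @examples
#' fubiniNumbers(3)  # 1 1 3 13
#' @export
fubiniNumbers <- function(k) {
  stopifnot(k >= 0)
  if (k > 16)
    stop("Fubini numbers beyond k = 16 exceed exact double-precision integers")
  p <- numeric(k + 1)
  p[1] <- 1
  for (j in seq_len(k))
    p[j + 1] <- sum(choose(j, 1:j) * p[j:1])
  p
}

#' Sample a uniformly random ordered set partition
#'
#' Draws an ordered partition of \code{x} into nonempty blocks, uniform over
#' all \code{p_{|x|}} such partitions: the first-block size \code{j} is
#' drawn with probability \eqn{\binom{k}{j} p_{k-j} / p_k}, the block itself
#' is a uniform j-subset, and the remainder is partitioned recursively.
#' Uses the R RNG (seed with [set.seed()]).
#'
#' @param x nonempty vector of distinct elements (at most 16).
#' @return List of blocks (each sorted), in order.
#' @export
sampleOrderedPartition <- function(x) {
  if (length(x) == 0L) stop("cannot partition an empty set")
  if (anyDuplicated(x)) stop("set elements must be distinct")
  p <- fubiniNumbers(length(x))
  blocks <- list()
  rem <- x
  while (length(rem) > 0L) {
    k <- length(rem)
    w <- choose(k, 1:k) * p[k:1]          # w[j] = C(k,j) p_{k-j}
    u <- stats::runif(1) * p[k + 1]
    j <- which(cumsum(w) >= u)[1L]
    pick <- if (k == 1L) 1L else sample.int(k, j)
    blocks[[length(blocks) + 1L]] <- sort(rem[pick])
    rem <- rem[-pick]
  }
  blocks
}

## raw-bits noncanalizing sampler
.sampleNCBits <- function(m, excludeZero = TRUE, maxRejections = 10000L) {
  if (m == 0L) {
    if (excludeZero) return(1L)
    return(sample(0:1, 1L))
  }
  size <- 2^m
  for (i in seq_len(maxRejections)) {
    bits <- sample(0:1, size, replace = TRUE)
    if (excludeZero && all(bits == 0L)) next
    if (!.hasCertificate(bits, m)) return(bits)
  }
  stop("rejection sampler exceeded maxRejections = ", maxRejections)
}

#' Sample a uniformly random noncanalizing Boolean function
#'
#' Rejection sampling: uniform truth tables on \code{m} variables are drawn
#' until one has no canalization certificate (and, if \code{excludeZero},
#' is not identically 0).  Acceptance is fast because canalizing functions
#' are rare among all Boolean functions.  Constants count as noncanalizing.
#'
#' @param m number of variables (>= 0).
#' @param excludeZero reject the constant-0 function (needed when the result
#'   serves as the core of a layered form).
#' @param maxRejections abort after this many rejected draws.
#' @return A \linkS4class{TruthTable}, uniform over the accepted class.
#' @export
sampleNoncanalizing <- function(m, excludeZero = TRUE,
                                maxRejections = 10000L) {
  truthTable(.sampleNCBits(as.integer(m), excludeZero, maxRejections),
             as.integer(m))
}

## raw-bits depth-k sampler (Boolean function of exact canalizing depth k)
.sampleDepthKBits <- function(n, k) {
  if (k == 0L) return(.sampleNCBits(n, excludeZero = FALSE))
  repeat {
    b <- sample(0:1, 1L)
    a <- sample(0:1, n, replace = TRUE)
    X <- if (n == 1L) 1L else sort(sample.int(n, k))
    part <- sampleOrderedPartition(X)
    r <- length(part)
    pcBits <- .sampleNCBits(n - k, excludeZero = TRUE)
    if (all(pcBits == 1L)) {
      # exceptional cases of the unique form: with a constant-1 core the
      # last layer must have >= 2 variables unless r = 1, and a single
      # one-variable layer forces b = 0.  Restart the whole draw.
      if (r != 1L && length(part[[r]]) < 2L) next
      if (r == 1L && k == 1L && b == 1L) next
    }
    lays <- lapply(part, function(v) list(vars = v, a = a[v]))
    coreV <- setdiff(seq_len(n), X)
    return(.recomposeBits(b, lays, pcBits, coreV, n))
  }
}

#' Sample a uniformly random Boolean function of exact canalizing depth
#'
#' Draws uniformly from all Boolean functions on \code{n} variables whose
#' canalizing depth is exactly \code{k}, by drawing the ingredients of the
#' unique layered form uniformly (outer constant, per-variable canalizing
#' inputs, a uniform k-subset of layer variables, a uniform ordered
#' partition of it into layers, and a uniform nonzero noncanalizing core)
#' and restarting whenever the exceptional-case constraints are violated.
#' For \code{k = 0} a uniform noncanalizing function (constants included)
#' is returned.  Uses the R RNG.
#'
#' @param n number of variables.
#' @param k required canalizing depth, \code{0 <= k <= n}.
#' @return A \linkS4class{TruthTable} with \code{canalizingDepth(f) == k}.
#' @export
sampleDepthKFunction <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 0L || k > n) stop("need 0 <= k <= n")
  truthTable(.sampleDepthKBits(n, k), n)
}

#' Sample a random Boolean network of a given canalizing depth
#'
#' A Boolean network has canalizing depth \code{k} when every coordinate
#' function has depth \code{k}; the coordinates are drawn independently
#' with [sampleDepthKFunction()].
#'
#' @inheritParams sampleDepthKFunction
#' @return A \linkS4class{BooleanNetwork}.
#' @examples
#' set.seed(1)
#' net <- sampleNetwork(4, 2)
#' vapply(networkFunctions(net), canalizingDepth, numeric(1))
#' @export
sampleNetwork <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 0L || k > n) stop("need 0 <= k <= n")
  fns <- lapply(seq_len(n), function(i) truthTable(.sampleDepthKBits(n, k), n))
  new("BooleanNetwork", nVars = n, functions = fns)
}
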