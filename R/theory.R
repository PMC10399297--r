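#' @include statistics.R
NULL

.ELL_CAP <- 10L

#' Cycle-consistency weight f(alpha, beta)
#'
#' For length-\code{ell} binary cycle strings \code{alpha}, \code{beta}
#' (0-based integers, string position t = bit t-1), returns
#' \eqn{2^{-|\beta|}} if \eqn{\alpha \vee \beta = \beta} componentwise
#' (\eqn{|\beta|} = number of ones) and 0 otherwise.  This is the
#' probability that a random depth-one coordinate function maps a trace
#' compatible with \code{alpha} onto the trace \code{beta}.  The value is a
#' dyadic rational, represented exactly by the returned double.
#'
#' @param alpha,beta integers in \code{0:(2^ell - 1)}.
#' @param ell the string length.
#' @return Exact dyadic value in \code{[0, 1]}.
#' @examples
#' weightF(0, 2, 2)  # 1/2
#' @export
weightF <- function(alpha, beta, ell) {
  N <- 2^ell
  if (alpha < 0 || alpha >= N || beta < 0 || beta >= N)
    stop("cycle strings must lie in 0:(2^ell - 1)")
  if (bitwOr(alpha, beta) != beta) return(0)
  2^(-popCount(beta, ell))
}

#' Negation-averaged weight g(alpha, beta)
#'
#' The average of [weightF()] over the four combinations of componentwise
#' negations of its arguments:
#' \eqn{g = (f(\alpha,\beta) + f(\bar\alpha,\beta) + f(\alpha,\bar\beta) +
#' f(\bar\alpha,\bar\beta))/4}.  Invariant under negating either argument.
#'
#' @inheritParams weightF
#' @return Exact dyadic value.
#' @examples
#' weightG(0, 1, 2)  # 1/4
#' @export
weightG <- function(alpha, beta, ell) {
  N <- 2^ell
  na <- N - 1 - alpha
  nb <- N - 1 - beta
  (weightF(alpha, beta, ell) + weightF(na, beta, ell) +
     weightF(alpha, nb, ell) + weightF(na, nb, ell)) / 4
}

## right cyclic shift: s(alpha)_t = alpha_{t-1 mod ell}
.shiftRight <- function(b, ell) {
  N <- 2^ell
  ((b * 2) %% N) + (b %/% (N / 2))
}

#' Build the exact transfer matrix G_ell
#'
#' Constructs the \code{2^ell x 2^ell} column-stochastic matrix with entry
#' \code{(a, b)} equal to \code{g(a, s(b))}, where \code{s} is the right
#' cyclic shift of cycle strings and \code{g} is [weightG()].  Entries are
#' dyadic rationals with denominator \code{2^(ell+2)} and are stored
#' exactly (integer numerators plus common denominator).
#'
#' @param ell cycle length, \code{1 <= ell <= 10} (the default cap keeps
#'   the exact matrix a practical size).
#' @return A \linkS4class{TransferMatrix}.
#' @export
buildTransferMatrix <- function(ell) {
  ell <- as.integer(ell)
  if (ell < 1L || ell > .ELL_CAP)
    stop("ell must be between 1 and ", .ELL_CAP)
  N <- 2^ell
  idx <- 0:(N - 1)
  pc <- popCount(idx, ell)
  neg <- (N - 1) - idx
  # numerators of f over denominator 2^ell
  ok <- outer(idx, idx, function(a, b) bitwOr(a, b) == b)
  fnum <- sweep(ok, 2, 2^(ell - pc), `*`)
  # numerators of g over denominator 2^(ell+2) (sum of four f-numerators)
  gnum <- fnum + fnum[neg + 1, ] + fnum[, neg + 1] + fnum[neg + 1, neg + 1]
  sh <- .shiftRight(idx, ell)
  num <- gnum[, sh + 1, drop = FALSE]
  dimnames(num) <- NULL
  new("TransferMatrix", ell = ell, num = num, den = 2^(ell + 2))
}

#' Numeric matrix of a TransferMatrix
#'
#' @param G a \linkS4class{TransferMatrix}.
#' @return The matrix \code{G_ell} as doubles; exact, since every entry is
#'   a dyadic rational well within double precision.
#' @export
transferMatrixValues <- function(G) G@num / G@den

## ---- exact rational characteristic polynomial -----------------------------
## Faddeev-LeVerrier over rationals, with matrices kept as an integer
## numerator matrix plus one common denominator (exact doubles).  Every
## product is guarded against exceeding 2^53; entries are re-reduced by
## their collective gcd after each step, which keeps the iteration small
## for the low-rank transfer matrices.

.flCharPoly <- function(Anum, Aden) {
  N <- nrow(Anum)
  cn <- numeric(N + 1)
  cd <- numeric(N + 1)
  cn[1] <- 1; cd[1] <- 1
  Mnum <- Anum
  Mden <- Aden
  for (k in seq_len(N)) {
    tr <- sum(diag(Mnum))
    ck <- ratReduce(-tr, k * Mden)
    cn[k + 1] <- ck[1]; cd[k + 1] <- ck[2]
    if (k == N) break
    # M <- A %*% M + c_k * A, over the common denominator Aden * L
    L <- lcmNum(Mden, ck[2])
    checkExactInt(max(abs(Anum)) * max(abs(Mnum), 1) * N * (L / Mden),
                  "characteristic polynomial recursion")
    checkExactInt(abs(ck[1]) * (L / ck[2]) * max(abs(Anum)),
                  "characteristic polynomial recursion")
    Mnum <- (Anum %*% Mnum) * (L / Mden) + (ck[1] * (L / ck[2])) * Anum
    Mden <- Aden * L
    g <- gcdNum(gcdAll(Mnum), Mden)
    if (g > 1) { Mnum <- Mnum / g; Mden <- Mden / g }
    checkExactInt(c(Mnum, Mden), "characteristic polynomial recursion")
  }
  list(num = cn, den = cd)
}

#' Exact characteristic polynomial of the transfer matrix
#'
#' Coefficients of \eqn{\det(tI - G_\ell)} in exact rational arithmetic
#' (Faddeev-LeVerrier recursion on the dyadic numerator matrix), monic,
#' descending powers.
#'
#' @param G a \linkS4class{TransferMatrix}.
#' @return A data.frame with columns \code{power} (from \code{2^ell} down
#'   to 0), \code{num} and \code{den}: coefficient of \code{t^power} is
#'   \code{num/den} in lowest terms.
#' @examples
#' charPoly(buildTransferMatrix(1))  # t^2 - t
#' @export
charPoly <- function(G) {
  stopifnot(is(G, "TransferMatrix"))
  co <- .flCharPoly(G@num, G@den)
  N <- 2^G@ell
  data.frame(power = N:0, num = co$num, den = co$den)
}

## exact rational P(1) and P'(1) from monic descending coefficients
.polyAtOne <- function(num, den) {
  s <- c(0, 1)
  for (i in seq_along(num)) {
    # s <- s + num[i]/den[i]
    nn <- s[1] * den[i] + num[i] * s[2]
    dd <- s[2] * den[i]
    checkExactInt(c(nn, dd), "polynomial evaluation")
    s <- ratReduce(nn, dd)
  }
  s
}

.truncDecimal <- function(x, digits) trunc(x * 10^digits) / 10^digits

#' Limiting expected number of length-ell attractors (depth-one networks)
#'
#' Computes \eqn{A_\ell}, the limit as \eqn{n \to \infty} of the expected
#' number of attractors of length \eqn{\ell} in a random n-node Boolean
#' network of canalizing depth one:
#' \deqn{A_\ell = \frac{1}{\ell \, P'_{G_\ell}(1)},}
#' where \eqn{P_{G_\ell}} is the characteristic polynomial of the transfer
#' matrix.  Because \eqn{G_\ell} is column stochastic, 1 is always an
#' eigenvalue; the computation verifies that it is simple (otherwise the
#' formula does not apply and an error is raised).  Equivalently
#' \eqn{A_\ell = 1 / (\ell \prod_{\lambda \neq 1} (1 - \lambda))} over the
#' remaining eigenvalues.
#'
#' By default the characteristic polynomial is computed in exact rational
#' arithmetic and \eqn{A_\ell} is returned as an exact fraction; set
#' \code{exact = FALSE} (or exceed the exact range) to use high-precision
#' eigenvalues instead, which is accurate to far more digits than are ever
#' reported.
#'
#' @param ell attractor length, \code{1 <= ell <= 10}.
#' @param exact attempt the exact rational path (default).
#' @return An \linkS4class{AttractorLimit}.
#' @examples
#' attractorLimit(2)  # A_2 = 2/3
#' @export
attractorLimit <- function(ell, exact = TRUE) {
  G <- buildTransferMatrix(ell)
  N <- 2^G@ell
  if (exact) {
    # the exact path aborts (only) when reduced intermediates would leave
    # the exactly-representable integer range; fall back to eigenvalues then
    out <- tryCatch({
      res <- .flCharPoly(G@num, G@den)
      p1 <- .polyAtOne(res$num, res$den)
      if (p1[1] != 0)
        stop("eigenvalue 1 missing: the transfer matrix is not stochastic?")
      dnum <- res$num * (N:0)          # P'(t) coefficients at matching dens
      dp1 <- .polyAtOne(utils::head(dnum, -1), utils::head(res$den, -1))
      if (dp1[1] == 0)
        stop("eigenvalue 1 of the transfer matrix is not simple; ",
             "the limit formula does not apply")
      A <- ratReduce(ell * dp1[1], dp1[2])   # A = 1/(ell * P'(1)) = den/num
      A <- ratReduce(A[2], A[1])
      new("AttractorLimit", ell = as.integer(ell),
          value = A[1] / A[2], valueNum = A[1], valueDen = A[2],
          charPolyNum = res$num, charPolyDen = res$den,
          exact = TRUE, oneMultiplicity = 1L)
    }, error = function(e) {
      if (grepl("exceed double precision", conditionMessage(e))) NULL
      else stop(e)
    })
    if (!is.null(out)) return(out)
  }
  ev <- eigen(transferMatrixValues(G), only.values = TRUE)$values
  isOne <- abs(ev - 1) < 1e-9
  mult <- sum(isOne)
  if (mult != 1L)
    stop("eigenvalue 1 of the transfer matrix is not simple; ",
         "the limit formula does not apply")
  dp1 <- Re(prod(1 - ev[!isOne]))
  if (abs(dp1) < 1e-12)
    stop("P'(1) vanished numerically; the limit formula does not apply")
  new("AttractorLimit", ell = as.integer(ell), value = 1 / (ell * dp1),
      valueNum = NA_real_, valueDen = NA_real_,
      charPolyNum = numeric(0), charPolyDen = numeric(0),
      exact = FALSE, oneMultiplicity = 1L)
}

#' Expected length-ell attractor count of an unconstrained random map
#'
#' The exact expected number of length-\code{ell} attractors of a uniformly
#' random map on the \code{2^n} states (no canalization constraint):
#' \deqn{\frac{1}{\ell} \prod_{i=0}^{\ell-1} \frac{2^n - i}{2^n},}
#' which tends to \eqn{1/\ell} as \eqn{n \to \infty}.  This is the baseline
#' against which the depth-one limits \eqn{A_\ell > 1/\ell} are compared.
#'
#' @param n number of nodes.
#' @param ell attractor length.
#' @return A double.
#' @export
expectedAttractorsRandom <- function(n, ell) {
  stopifnot(n >= 1, ell >= 1)
  if (ell > 2^n) return(0)
  prod((2^n - seq(0, ell - 1)) / 2^n) / ell
}

#' Monte-Carlo mean attractor count for depth-k networks
#'
#' Samples random Boolean networks of exact canalizing depth \code{k} and
#' counts the attractors of length exactly \code{ell} in each (vectorized
#' fixed-point counting on the successor array).  Used to validate the
#' analytic depth-one limits at finite n.  Uses the R RNG.
#'
#' @param n number of nodes (guarded to <= 16 since each sample touches all
#'   \code{2^n} states).
#' @param k canalizing depth of the sampled networks.
#' @param ell attractor length to count.
#' @param samples number of sampled networks.
#' @return List with \code{mean}, \code{se} (standard error of the mean),
#'   \code{samples} and the raw \code{counts}.
#' @examples
#' set.seed(1)
#' monteCarloExpected(6, 1, 1, samples = 50)$mean
#' @export
monteCarloExpected <- function(n, k, ell, samples) {
  if (n > 16L) stop("Monte-Carlo path is guarded to n <= 16")
  counts <- numeric(samples)
  for (i in seq_len(samples)) {
    net <- sampleNetwork(n, k)
    counts[i] <- countAttractorsOfLength(net, ell)
  }
  list(mean = mean(counts),
       se = stats::sd(counts) / sqrt(samples),
       samples = samples,
       counts = counts)
}
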