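#' @include truth-table.R
NULL

## Internal decomposition on raw bits.  Returns list(b, layers, coreBits,
## coreVars) with layers outermost first, variables within a layer in
## ascending original order.
.decomposeBits <- function(bits, n) {
  if (all(bits == 0L))
    stop("the layered form is defined only for functions not identically 0")
  vars <- seq_len(n)
  g <- bits
  m <- n
  lays <- list()
  outs <- integer(0)
  repeat {
    certs <- .certsBits(g, m)
    if (nrow(certs) == 0L) break
    if (anyDuplicated(certs$variable)) {
      # g is a single literal: both input values canalize, with opposite
      # canalized outputs.  The unique form takes the branch whose canalized
      # output is 0 (this is exactly the exceptional case forcing b = 0).
      # After a full peel the remainder is never a literal, so this can only
      # happen for the input function itself.
      if (length(lays) > 0L)
        stop("internal error: literal remainder after a full peel")
      certs <- certs[certs$output == 0L, , drop = FALSE]
    }
    out <- unique(certs$output)
    if (length(out) != 1L)
      stop("internal error: canalized outputs disagree within one layer")
    ord <- order(vars[certs$variable])
    lays[[length(lays) + 1L]] <- list(vars = vars[certs$variable][ord],
                                      a = as.integer(certs$value[ord]))
    outs <- c(outs, out)
    # peel: fix every layer variable to the complement of its canalizing
    # input (highest local index first, so indices stay valid)
    for (j in order(certs$variable, decreasing = TRUE)) {
      g <- .restrictBits(g, m, certs$variable[j], 1L - certs$value[j])
      m <- m - 1L
    }
    vars <- vars[-certs$variable]
  }
  r <- length(lays)
  if (r == 0L)
    return(list(b = 0L, layers = list(), coreBits = bits,
                coreVars = seq_len(n)))
  b <- outs[1L]
  # the canalized outputs along the peel alternate by construction of the
  # nested "+1" bookkeeping; uniqueness of the form guarantees this
  if (!all(outs == (b + seq_len(r) - 1L) %% 2L))
    stop("internal error: canalized outputs do not alternate")
  coreBits <- if (outs[r] == 1L) 1L - g else g
  list(b = b, layers = lays, coreBits = coreBits, coreVars = vars)
}

## Internal recomposition: evaluates the layered form on all assignments.
.recomposeBits <- function(b, lays, coreBits, coreVarsIdx, n) {
  m <- 0:(2^n - 1)
  if (length(coreVarsIdx)) {
    ci <- numeric(2^n)
    for (j in seq_along(coreVarsIdx))
      ci <- ci + bitAt(m, coreVarsIdx[j]) * 2^(j - 1)
    val <- coreBits[ci + 1]
  } else {
    val <- rep(coreBits[1L], 2^n)
  }
  r <- length(lays)
  if (r > 0L) {
    for (i in r:1) {
      lay <- lays[[i]]
      Mi <- rep(1L, 2^n)
      for (j in seq_along(lay$vars))
        Mi <- Mi * as.integer(bitAt(m, lay$vars[j]) != lay$a[j])
      val <- Mi * val
      if (i > 1L) val <- 1L - val
    }
  }
  as.integer((val + b) %% 2)
}

#' Layered (He-Macaulay) decomposition of a Boolean function
#'
#' Computes the unique layered form of a not-identically-zero Boolean
#' function (see \linkS4class{HMDecomposition}).  The outermost layer is
#' the set of all canalizing variables of \code{f} with their canalizing
#' inputs; restricting every layer variable to the complement of its input
#' exposes the next layer, and the final noncanalizing remainder
#' (sign-adjusted so recomposition is bit-exact) is the core \eqn{p_C}.
#' Variables within a layer are reported in ascending order, which is a
#' pure canonicalization (factors of a product commute).
#'
#' @param f a \linkS4class{TruthTable}, not identically 0.
#' @return An \linkS4class{HMDecomposition}; [hmRecompose()] inverts it
#'   bit-exactly.
#' @examples
#' f <- truthTableFromFunction(3, function(x) x[1] * x[2] * x[3])
#' d <- hmDecompose(f)
#' canalizingDepth(d)  # 3: x1 x2 x3 is nested canalizing
#' identical(tableBits(hmRecompose(d)), tableBits(f))
#' @export
hmDecompose <- function(f) {
  stopifnot(is(f, "TruthTable"))
  parts <- .decomposeBits(f@bits, f@nVars)
  new("HMDecomposition", nVars = f@nVars, b = parts$b, layers = parts$layers,
      core = truthTable(parts$coreBits, length(parts$coreVars)),
      coreVars = as.integer(parts$coreVars))
}

#' Recompose a Boolean function from its layered decomposition
#'
#' Evaluates \eqn{M_1(M_2(\cdots(M_r p_C + 1)\cdots + 1) + 1) + b} over
#' GF(2) on every assignment; the bit-exact inverse of [hmDecompose()].
#'
#' @param d an \linkS4class{HMDecomposition}.
#' @return A \linkS4class{TruthTable} on \code{nVars(d)} variables.
#' @export
hmRecompose <- function(d) {
  stopifnot(is(d, "HMDecomposition"))
  methods::validObject(d)
  truthTable(.recomposeBits(d@b, d@layers, d@core@bits, d@coreVars, d@nVars),
             d@nVars)
}

#' @rdname canalizingDepth
#' @export
setMethod("canalizingDepth", "HMDecomposition",
          function(f, randomize = FALSE)
            sum(lengths(lapply(f@layers, `[[`, "vars"))))

#' Is the function nested canalizing?
#'
#' A function is nested canalizing when its canalizing depth equals its
#' number of variables, i.e. the core of its layered form is the constant 1
#' on an empty variable set.
#'
#' @param f a \linkS4class{TruthTable}.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
isNestedCanalizing <- function(f) {
  canalizingDepth(f) == f@nVars
}
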