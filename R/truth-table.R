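#' @include AllClasses.R
NULL

## ---- internal fast paths on raw bit vectors -------------------------------
## These work on plain integer vectors so the samplers and classifiers can
## avoid S4 construction in tight loops; the exported methods wrap them.

# Per-n cache of the index sets selecting each half-table, used by restrict
# and the canalization test.
.maskCache <- new.env(parent = emptyenv())

.halfIndices <- function(n) {
  key <- as.character(n)
  cached <- .maskCache[[key]]
  if (!is.null(cached)) return(cached)
  m <- 0:(2^n - 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    b <- bitAt(m, i)
    out[[i]] <- list(which(b == 0), which(b == 1))
  }
  .maskCache[[key]] <- out
  out
}

.restrictBits <- function(bits, n, variable, value) {
  stopifnot(variable >= 1, variable <= n)
  bits[.halfIndices(n)[[variable]][[value + 1L]]]
}

# All canalization certificates as a data.frame(variable, value, output).
.certsBits <- function(bits, n) {
  empty <- data.frame(variable = integer(0), value = integer(0),
                      output = integer(0))
  if (n == 0L || all(bits == bits[1L])) return(empty)  # constants excluded
  halves <- .halfIndices(n)
  len <- 2^(n - 1)
  vs <- integer(0); as <- integer(0); os <- integer(0)
  for (i in seq_len(n)) {
    for (a in 0:1) {
      s <- sum(bits[halves[[i]][[a + 1L]]])
      if (s == 0 || s == len) {
        vs <- c(vs, i); as <- c(as, a)
        os <- c(os, if (s == 0) 0L else 1L)
      }
    }
  }
  data.frame(variable = vs, value = as, output = os)
}

# TRUE if some variable/value pair canalizes (early exit; constants FALSE).
.hasCertificate <- function(bits, n) {
  if (n == 0L || all(bits == bits[1L])) return(FALSE)
  halves <- .halfIndices(n)
  len <- 2^(n - 1)
  for (i in seq_len(n)) {
    s0 <- sum(bits[halves[[i]][[1L]]])
    if (s0 == 0 || s0 == len) return(TRUE)
    s1 <- sum(bits[halves[[i]][[2L]]])
    if (s1 == 0 || s1 == len) return(TRUE)
  }
  FALSE
}

.depthBits <- function(bits, n, randomize = FALSE) {
  k <- 0L
  while (n > 0L) {
    certs <- .certsBits(bits, n)
    if (nrow(certs) == 0L) break
    j <- if (randomize) sample.int(nrow(certs), 1L) else 1L
    bits <- .restrictBits(bits, n, certs$variable[j], 1L - certs$value[j])
    n <- n - 1L
    k <- k + 1L
  }
  k
}

## ---- exported surface -----------------------------------------------------

#' Construct a TruthTable
#'
#' @param bits 0/1 vector of length \code{2^n}; entry \code{m + 1} is the
#'   function value on the assignment encoded by \code{m} (variable
#'   \code{x_i} is bit \code{i - 1} of \code{m}, \code{x_1} least
#'   significant).
#' @param n number of variables; defaults to \code{log2(length(bits))}.
#' @return A \linkS4class{TruthTable}.
#' @examples
#' truthTable(c(0, 0, 0, 1))  # AND(x1, x2)
#' @export
truthTable <- function(bits, n = as.integer(round(log2(length(bits))))) {
  new("TruthTable", nVars = as.integer(n), bits = as.integer(bits))
}

#' Build a TruthTable by evaluating an R function on every assignment
#'
#' @param n number of variables.
#' @param fn an R function taking a 0/1 assignment vector of length \code{n}
#'   (entry \code{i} = value of \code{x_i}) and returning 0 or 1.
#' @return A \linkS4class{TruthTable}.
#' @examples
#' xor2 <- truthTableFromFunction(2, function(x) (x[1] + x[2]) %% 2)
#' @export
truthTableFromFunction <- function(n, fn) {
  bits <- vapply(0:(2^n - 1),
                 function(m) as.integer(fn(decodeAssignment(m, n))),
                 integer(1))
  truthTable(bits, n)
}

#' @rdname evaluateAt
#' @export
setMethod("evaluateAt", "TruthTable", function(f, assignment) {
  if (length(assignment) != f@nVars)
    stop("assignment length must equal nVars(f)")
  f@bits[encodeAssignment(assignment) + 1]
})

#' @rdname restrictVariable
#' @export
setMethod("restrictVariable", "TruthTable", function(f, variable, value) {
  if (variable < 1 || variable > f@nVars)
    stop("variable index out of range")
  truthTable(.restrictBits(f@bits, f@nVars, variable, value), f@nVars - 1L)
})

#' @rdname canalizingCertificates
#' @export
setMethod("canalizingCertificates", "TruthTable",
          function(f) .certsBits(f@bits, f@nVars))

#' Is the function canalizing?
#'
#' @param f a \linkS4class{TruthTable}.
#' @return \code{TRUE} if some variable has a canalizing input value.
#'   Constant functions are not canalizing.
#' @export
isCanalizing <- function(f) .hasCertificate(f@bits, f@nVars)

#' @rdname canalizingDepth
#' @export
setMethod("canalizingDepth", "TruthTable",
          function(f, randomize = FALSE) .depthBits(f@bits, f@nVars, randomize))
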