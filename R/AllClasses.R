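#' @include AllGenerics.R
NULL

#' TruthTable: a Boolean function as a bit vector
#'
#' A Boolean function on \code{nVars} variables stored as its full truth
#' table: \code{bits[m + 1]} is the function value on the assignment encoded
#' by \code{m}, where variable \code{x_i} is bit \code{i - 1} of \code{m}
#' (\code{x_1} least significant).  Functions on zero variables (constants)
#' are allowed and have a single table entry.
#'
#' @slot nVars number of variables (0 to 24).
#' @slot bits integer 0/1 vector of length \code{2^nVars}.
#' @seealso [truthTable()], [truthTableFromFunction()]
#' @export
setClass("TruthTable",
         representation(nVars = "integer", bits = "integer"))

setValidity("TruthTable", function(object) {
  n <- object@nVars
  if (length(n) != 1L || is.na(n) || n < 0L || n > 24L)
    return("nVars must be a single integer in 0..24")
  if (length(object@bits) != 2^n)
    return(sprintf("bits must have length 2^nVars = %d", 2^n))
  if (any(is.na(object@bits)) || !all(object@bits %in% c(0L, 1L)))
    return("bits must be 0/1 with no NA")
  TRUE
})

#' HMDecomposition: the unique layered form of a Boolean function
#'
#' The unique layered representation of a nonzero Boolean function
#' \deqn{f = M_1(M_2(\cdots(M_r \, p_C + 1)\cdots + 1) + 1) + b}
#' over GF(2), where each layer \eqn{M_i = \prod_j (x_{i_j} + a_{i_j})} is a
#' product of literals, \eqn{p_C} is a noncanalizing, not identically zero
#' core on the remaining variables, and \eqn{b \in \{0,1\}}.  The number of
#' variables in the layers is the canalizing depth.  Noncanalizing functions
#' have \eqn{r = 0}, \eqn{b = 0} and core equal to the function itself.
#'
#' Two exceptional-case constraints make the form unique: if \eqn{p_C \equiv
#' 1} and \eqn{r \neq 1}, the last layer has at least two variables; if
#' \eqn{p_C \equiv 1}, \eqn{r = 1} and the single layer has one variable,
#' then \eqn{b = 0}.
#'
#' @slot nVars number of variables of the represented function.
#' @slot b the additive constant.
#' @slot layers list of layers, outermost first; each layer is a list with
#'   \code{vars} (ascending original variable indices) and \code{a}
#'   (matching canalizing inputs).
#' @slot core the core \eqn{p_C} as a [TruthTable-class] on the complement
#'   variable set (in ascending original order).
#' @slot coreVars ascending original indices of the core's variables.
#' @seealso [hmDecompose()], [hmRecompose()]
#' @export
setClass("HMDecomposition",
         representation(nVars = "integer", b = "integer", layers = "list",
                        core = "TruthTable", coreVars = "integer"))

setValidity("HMDecomposition", function(object) {
  n <- object@nVars
  layVars <- unlist(lapply(object@layers, `[[`, "vars"))
  allVars <- c(layVars, object@coreVars)
  if (length(allVars) != n || anyDuplicated(allVars) ||
      !setequal(allVars, seq_len(max(n, 0L))))
    return("layer and core variables must partition 1..nVars without repeats")
  if (!(object@b %in% c(0L, 1L)))
    return("b must be 0 or 1")
  if (object@core@nVars != length(object@coreVars))
    return("core variable count must match coreVars")
  cb <- object@core@bits
  if (all(cb == 0L))
    return("core must not be identically 0")
  if (nrow(.certsBits(cb, object@core@nVars)) > 0L)
    return("core must be noncanalizing")
  for (lay in object@layers) {
    if (length(lay$vars) == 0L || length(lay$vars) != length(lay$a))
      return("each layer needs matching nonempty vars and a")
    if (!all(lay$a %in% c(0L, 1L)))
      return("layer canalizing inputs must be 0/1")
  }
  r <- length(object@layers)
  coreIsOne <- all(cb == 1L)
  if (coreIsOne && r >= 2L && length(object@layers[[r]]$vars) < 2L)
    return("with a constant-1 core and r > 1, the last layer needs >= 2 variables")
  if (coreIsOne && r == 1L && length(object@layers[[1L]]$vars) == 1L &&
      object@b != 0L)
    return("with a constant-1 core and a single one-variable layer, b must be 0")
  TRUE
})

#' BooleanNetwork: an n-tuple of Boolean coordinate functions
#'
#' A synchronous Boolean network on \code{nVars} nodes: coordinate \code{i}
#' of the successor state is \code{functions[[i]]} evaluated on the current
#' state.  All coordinate functions are truth tables on the same
#' \code{nVars} variables, and states share the assignment encoding of
#' [TruthTable-class].
#'
#' @slot nVars number of nodes.
#' @slot functions list of \code{nVars} [TruthTable-class] objects.
#' @seealso [booleanNetwork()], [attractorsAndBasins()]
#' @export
setClass("BooleanNetwork",
         representation(nVars = "integer", functions = "list"))

setValidity("BooleanNetwork", function(object) {
  n <- object@nVars
  if (length(object@functions) != n)
    return("need exactly nVars coordinate functions")
  for (f in object@functions) {
    if (!is(f, "TruthTable")) return("functions must be TruthTable objects")
    if (f@nVars != n) return("all coordinate functions must have nVars variables")
  }
  TRUE
})

#' AttractorReport: attractors and basin sizes of a Boolean network
#'
#' The complete attractor structure of a synchronous Boolean network:
#' every limit cycle of the 2^n-state functional graph together with the
#' size of its basin of attraction.  Cycles are stored as 0-based state
#' indices in cyclic order, rotated so the smallest state comes first, and
#' attractors are sorted by that smallest state.  Basins partition the state
#' space, so basin sizes sum to 2^n.
#'
#' @slot nVars number of network nodes.
#' @slot cycles list of integer vectors of distinct 0-based states.
#' @slot basins numeric vector of basin sizes, one per cycle.
#' @seealso [attractorsAndBasins()], [summarizeNetwork()]
#' @export
setClass("AttractorReport",
         representation(nVars = "integer", cycles = "list", basins = "numeric"))

setValidity("AttractorReport", function(object) {
  if (length(object@cycles) != length(object@basins))
    return("one basin size per attractor required")
  if (length(object@cycles) == 0L)
    return("a functional graph always has at least one attractor")
  for (cyc in object@cycles)
    if (anyDuplicated(cyc)) return("attractor states must be distinct")
  if (any(object@basins < lengths(object@cycles)))
    return("each basin contains its attractor")
  if (sum(object@basins) != 2^object@nVars)
    return("basin sizes must sum to 2^nVars")
  TRUE
})

#' TransferMatrix: exact per-coordinate cycle-consistency matrix
#'
#' The 2^l x 2^l column-stochastic matrix G_l whose spectrum governs the
#' limiting expected number of length-l attractors in a large random
#' depth-one Boolean network.  Rows and columns are indexed by length-l
#' binary cycle strings (0-based integers, string position t is bit t-1).
#' All entries are dyadic rationals with denominator 2^(l+2), stored as an
#' integer numerator matrix plus the common denominator, so the matrix is
#' exact.
#'
#' @slot ell the cycle length l.
#' @slot num numerator matrix (entries of \code{2^(l+2) * G_l}).
#' @slot den the common denominator \code{2^(l+2)}.
#' @seealso [buildTransferMatrix()], [attractorLimit()]
#' @export
setClass("TransferMatrix",
         representation(ell = "integer", num = "matrix", den = "numeric"))

setValidity("TransferMatrix", function(object) {
  l <- object@ell
  N <- 2^l
  if (nrow(object@num) != N || ncol(object@num) != N)
    return("numerator matrix must be 2^ell x 2^ell")
  if (object@den != 2^(l + 2))
    return("denominator must be 2^(ell+2)")
  if (any(object@num < 0))
    return("entries must be nonnegative")
  if (any(colSums(object@num) != object@den))
    return("columns must sum to exactly 1")
  neg <- (N - 1):0
  if (any(object@num != object@num[neg + 1, , drop = FALSE]))
    return("rows indexed by a string and its negation must be equal")
  if (any(object@num != object@num[, neg + 1, drop = FALSE]))
    return("columns indexed by a string and its negation must be equal")
  TRUE
})

#' AttractorLimit: limiting expected attractor count of depth-one networks
#'
#' Result container for the limit A_l of the expected number of length-l
#' attractors in a random depth-one Boolean network as the number of nodes
#' grows.  When the computation is exact, the value is the rational
#' \code{valueNum / valueDen} and \code{charPolyNum / charPolyDen} hold the
#' exact monic characteristic polynomial coefficients of G_l (descending
#' powers); otherwise the value comes from high-precision eigenvalues and
#' the rational slots are NA/empty.
#'
#' @slot ell the attractor length l.
#' @slot value A_l as a double.
#' @slot valueNum,valueDen exact rational A_l (NA when not exact).
#' @slot charPolyNum,charPolyDen exact coefficient numerators/denominators
#'   of the characteristic polynomial, descending powers (empty if inexact).
#' @slot exact whether the rational path was used.
#' @slot oneMultiplicity algebraic multiplicity found for eigenvalue 1
#'   (always 1 on success).
#' @seealso [attractorLimit()]
#' @export
setClass("AttractorLimit",
         representation(ell = "integer", value = "numeric",
                        valueNum = "numeric", valueDen = "numeric",
                        charPolyNum = "numeric", charPolyDen = "numeric",
                        exact = "logical", oneMultiplicity = "integer"))

## ---- accessors ----

#' @rdname nVars
#' @export
setMethod("nVars", "TruthTable", function(x) x@nVars)

#' @rdname nVars
#' @export
setMethod("nVars", "BooleanNetwork", function(x) x@nVars)

#' @rdname nVars
#' @export
setMethod("nVars", "HMDecomposition", function(x) x@nVars)

#' @rdname nVars
#' @export
setMethod("nVars", "AttractorReport", function(x) x@nVars)

#' @rdname tableBits
#' @export
setMethod("tableBits", "TruthTable", function(x) x@bits)

#' @rdname decomposition-accessors
#' @export
setMethod("layers", "HMDecomposition", function(x) x@layers)

#' @rdname decomposition-accessors
#' @export
setMethod("coreFunction", "HMDecomposition", function(x) x@core)

#' @rdname decomposition-accessors
#' @export
setMethod("coreVars", "HMDecomposition", function(x) x@coreVars)

#' @rdname decomposition-accessors
#' @export
setMethod("outerConstant", "HMDecomposition", function(x) x@b)

#' @rdname decomposition-accessors
#' @export
setMethod("numLayers", "HMDecomposition", function(x) length(x@layers))

#' @rdname networkFunctions
#' @export
setMethod("networkFunctions", "BooleanNetwork", function(x) x@functions)

#' @rdname report-accessors
#' @export
setMethod("attractors", "AttractorReport", function(x) x@cycles)

#' @rdname report-accessors
#' @export
setMethod("basinSizes", "AttractorReport", function(x) x@basins)

#' @rdname report-accessors
#' @export
setMethod("attractorLengths", "AttractorReport",
          function(x) lengths(x@cycles))

## ---- show methods ----

setMethod("show", "TruthTable", function(object) {
  n <- object@nVars
  cat(sprintf("TruthTable on %d variable%s\n", n, if (n == 1) "" else "s"))
  if (n <= 4) {
    cat("  bits:", paste(object@bits, collapse = ""), "\n")
  } else {
    cat("  bits:", paste(object@bits[1:16], collapse = ""), "... (",
        2^n, "entries )\n")
  }
})

setMethod("show", "HMDecomposition", function(object) {
  r <- length(object@layers)
  cat(sprintf("HMDecomposition: n = %d, depth k = %d, r = %d layer%s, b = %d\n",
              object@nVars, sum(lengths(lapply(object@layers, `[[`, "vars"))),
              r, if (r == 1) "" else "s", object@b))
  for (i in seq_len(r)) {
    lay <- object@layers[[i]]
    cat(sprintf("  M%d: %s\n", i,
                paste(sprintf("(x%d + %d)", lay$vars, lay$a), collapse = "")))
  }
  if (length(object@coreVars)) {
    cat("  core p_C on x{", paste(object@coreVars, collapse = ","), "}\n")
  } else {
    cat("  core p_C = ", object@core@bits[1], " (no free variables)\n", sep = "")
  }
})

setMethod("show", "BooleanNetwork", function(object) {
  cat(sprintf("BooleanNetwork with %d nodes (%g states)\n",
              object@nVars, 2^object@nVars))
})

setMethod("show", "AttractorReport", function(object) {
  lens <- lengths(object@cycles)
  cat(sprintf("AttractorReport: %d attractor%s over %g states\n",
              length(lens), if (length(lens) == 1) "" else "s",
              2^object@nVars))
  cat("  lengths:", paste(lens, collapse = ", "), "\n")
  cat("  basins :", paste(object@basins, collapse = ", "), "\n")
})

setMethod("show", "TransferMatrix", function(object) {
  cat(sprintf("TransferMatrix G_%d: %d x %d, entries k/%g (exact)\n",
              object@ell, nrow(object@num), ncol(object@num), object@den))
})

setMethod("show", "AttractorLimit", function(object) {
  cat(sprintf("AttractorLimit A_%d = %.10g", object@ell, object@value))
  if (object@exact && !is.na(object@valueNum))
    cat(sprintf(" (= %g/%g exactly)", object@valueNum, object@valueDen))
  cat("\n")
})
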