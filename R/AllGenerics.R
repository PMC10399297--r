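#' @include utils-bits.R
NULL

#' Number of variables
#'
#' Number of variables of a Boolean function, network, decomposition or
#' attractor report.
#'
#' @param x a \linkS4class{TruthTable}, \linkS4class{BooleanNetwork},
#'   \linkS4class{HMDecomposition} or \linkS4class{AttractorReport}.
#' @return Integer scalar.
#' @export
setGeneric("nVars", function(x) standardGeneric("nVars"))

#' Truth-table bit vector
#'
#' The raw bit vector of a Boolean function: entry \code{m + 1} is the value
#' of the function on the assignment encoded by \code{m} (variable
#' \code{x_i} is bit \code{i - 1}, \code{x_1} least significant).
#'
#' @param x a \linkS4class{TruthTable}.
#' @return Integer vector of 0/1 of length \code{2^nVars(x)}.
#' @export
setGeneric("tableBits", function(x) standardGeneric("tableBits"))

#' Evaluate a Boolean function on one assignment
#'
#' @param f a \linkS4class{TruthTable}.
#' @param assignment 0/1 vector of length \code{nVars(f)}; entry \code{i} is
#'   the value of variable \code{x_i}.
#' @return 0 or 1.
#' @examples
#' f <- truthTableFromFunction(2, function(x) x[1] * x[2])  # AND
#' evaluateAt(f, c(1, 1))
#' @export
setGeneric("evaluateAt", function(f, assignment) standardGeneric("evaluateAt"))

#' Restrict a Boolean function by fixing one variable
#'
#' Returns the function on \code{nVars(f) - 1} variables obtained by fixing
#' \code{variable} to \code{value}; the remaining variables keep their
#' relative order (and are renumbered \code{1..n-1}).
#'
#' @param f a \linkS4class{TruthTable}.
#' @param variable variable index in \code{1:nVars(f)}.
#' @param value 0 or 1.
#' @return A \linkS4class{TruthTable} on one variable fewer.
#' @export
setGeneric("restrictVariable",
           function(f, variable, value) standardGeneric("restrictVariable"))

#' Canalization certificates of a Boolean function
#'
#' All triples (variable, canalizing input, canalized output) such that
#' fixing the variable to the input makes the function constant equal to the
#' output.  Constant functions are by convention not canalizing and return
#' zero rows.
#'
#' @param f a \linkS4class{TruthTable}.
#' @return A data.frame with columns \code{variable}, \code{value} (the
#'   canalizing input) and \code{output} (the canalized constant).
#' @export
setGeneric("canalizingCertificates",
           function(f) standardGeneric("canalizingCertificates"))

#' Canalizing depth
#'
#' The canalizing depth of a Boolean function: the number of variables that
#' can be peeled off by repeatedly fixing a canalizing variable to the
#' complement of its canalizing input, until a noncanalizing remainder is
#' reached.  The result does not depend on the peeling order; constants and
#' other noncanalizing functions have depth 0, nested canalizing functions
#' have depth \code{nVars(f)}.  For an \linkS4class{HMDecomposition} the
#' depth is the total number of variables in its layers.
#'
#' @param f a \linkS4class{TruthTable} or \linkS4class{HMDecomposition}.
#' @param randomize if \code{TRUE}, pick each peeled certificate uniformly at
#'   random (uses the R RNG); the returned depth is provably unchanged, the
#'   switch exists to exercise order-independence.
#' @return Integer depth in \code{0:nVars(f)}.
#' @examples
#' f <- truthTableFromFunction(3, function(x) ((x[1] + x[2]) %% 2) * x[3])
#' canalizingDepth(f)  # 1
#' @export
setGeneric("canalizingDepth",
           function(f, randomize = FALSE) standardGeneric("canalizingDepth"))

#' Layered (He-Macaulay) decomposition accessors
#'
#' @param x an \linkS4class{HMDecomposition}.
#' @return \code{layers}: list of layers, outermost first, each a list with
#'   elements \code{vars} (ascending original variable indices) and \code{a}
#'   (their canalizing inputs). \code{coreFunction}: the noncanalizing core
#'   \code{p_C} as a \linkS4class{TruthTable} on the complement variables.
#'   \code{coreVars}: ascending original indices of the core variables.
#'   \code{outerConstant}: the additive constant \code{b}.
#'   \code{numLayers}: the number of layers \code{r}.
#' @name decomposition-accessors
NULL

#' @rdname decomposition-accessors
#' @export
setGeneric("layers", function(x) standardGeneric("layers"))

#' @rdname decomposition-accessors
#' @export
setGeneric("coreFunction", function(x) standardGeneric("coreFunction"))

#' @rdname decomposition-accessors
#' @export
setGeneric("coreVars", function(x) standardGeneric("coreVars"))

#' @rdname decomposition-accessors
#' @export
setGeneric("outerConstant", function(x) standardGeneric("outerConstant"))

#' @rdname decomposition-accessors
#' @export
setGeneric("numLayers", function(x) standardGeneric("numLayers"))

#' Network accessors
#'
#' @param x a \linkS4class{BooleanNetwork}.
#' @return \code{networkFunctions}: the list of coordinate
#'   \linkS4class{TruthTable}s.
#' @export
setGeneric("networkFunctions", function(x) standardGeneric("networkFunctions"))

#' Attractor report accessors
#'
#' @param x an \linkS4class{AttractorReport}.
#' @return \code{attractors}: list of attractor cycles, each an integer
#'   vector of 0-based state indices in cyclic order, rotated so the
#'   smallest state comes first; attractors sorted by that state.
#'   \code{basinSizes}: basin size per attractor (same order).
#'   \code{attractorLengths}: cycle length per attractor.
#' @name report-accessors
NULL

#' @rdname report-accessors
#' @export
setGeneric("attractors", function(x) standardGeneric("attractors"))

#' @rdname report-accessors
#' @export
setGeneric("basinSizes", function(x) standardGeneric("basinSizes"))

#' @rdname report-accessors
#' @export
setGeneric("attractorLengths", function(x) standardGeneric("attractorLengths"))
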