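#' @include theory.R
NULL

## bits <-> hex: nibble j (0-based, least significant first) packs bits
## 4j+1..4j+4 of the table; the string is written most-significant nibble
## first, i.e. it is the standard hex rendering of the bit-packed table
## with bit 0 as the least significant bit.
.bitsToHex <- function(bits) {
  nNib <- max(1L, ceiling(length(bits) / 4))
  padded <- c(bits, integer(nNib * 4L - length(bits)))
  nib <- vapply(seq_len(nNib) - 1L, function(j)
    sum(padded[4L * j + 1:4] * c(1L, 2L, 4L, 8L)), numeric(1))
  paste(rev(format.hexmode(as.integer(nib))), collapse = "")
}

.hexToBits <- function(hex, n) {
  nib <- rev(strtoi(strsplit(hex, "")[[1]], base = 16L))
  bits <- as.integer(unlist(lapply(nib, function(v) (v %/% c(1, 2, 4, 8)) %% 2)))
  if (length(bits) < 2^n) stop("hex string too short for n = ", n)
  bits[seq_len(2^n)]
}

#' JSON serialization of truth tables and networks
#'
#' A truth table serializes to \code{{"n": <int>, "bits": "<hex>"}} where
#' the hex string is the bit-packed table (bit 0 = function value on the
#' all-zero assignment = least significant bit).  A network serializes to
#' \code{{"n": <int>, "functions": [<table>, ...]}}.  Round-trips are
#' bit-exact.
#'
#' @param f a \linkS4class{TruthTable}.
#' @param net a \linkS4class{BooleanNetwork}.
#' @param json a JSON string (or path for the \code{read*}/\code{write*}
#'   helpers).
#' @param file path to write to / read from.
#' @return Serializers return a JSON string (or the path, invisibly);
#'   parsers return the reconstructed object.
#' @examples
#' f <- truthTable(c(0, 1, 1, 0))
#' identical(tableBits(truthTableFromJSON(truthTableToJSON(f))), tableBits(f))
#' @name json-io
NULL

#' @rdname json-io
#' @export
truthTableToJSON <- function(f) {
  stopifnot(is(f, "TruthTable"))
  jsonlite::toJSON(list(n = f@nVars, bits = .bitsToHex(f@bits)),
                   auto_unbox = TRUE)
}

#' @rdname json-io
#' @export
truthTableFromJSON <- function(json) {
  obj <- jsonlite::fromJSON(json)
  truthTable(.hexToBits(obj$bits, obj$n), as.integer(obj$n))
}

#' @rdname json-io
#' @export
networkToJSON <- function(net) {
  stopifnot(is(net, "BooleanNetwork"))
  jsonlite::toJSON(list(
    n = net@nVars,
    functions = lapply(net@functions, function(f)
      list(n = f@nVars, bits = .bitsToHex(f@bits)))),
    auto_unbox = TRUE)
}

#' @rdname json-io
#' @export
networkFromJSON <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  fns <- lapply(obj$functions, function(o)
    truthTable(.hexToBits(o$bits, o$n), as.integer(o$n)))
  new("BooleanNetwork", nVars = as.integer(obj$n), functions = fns)
}

#' @rdname json-io
#' @export
writeNetwork <- function(net, file) {
  writeLines(as.character(networkToJSON(net)), file)
  invisible(file)
}

#' @rdname json-io
#' @export
readNetwork <- function(file) {
  networkFromJSON(paste(readLines(file), collapse = "\n"))
}

#' Export a network in BoolNet-style .bnet text
#'
#' Writes the header line \code{targets, factors} followed by one line per
#' node whose update rule is the disjunctive normal form read off the truth
#' table's minterms (operators \code{!}, \code{&}, \code{|}; constants are
#' written as \code{0}/\code{1}).  Export only; no importer is provided.
#'
#' @param net a \linkS4class{BooleanNetwork}.
#' @param file output path.
#' @return The file path, invisibly.
#' @export
exportBNet <- function(net, file) {
  n <- net@nVars
  lines <- "targets, factors"
  for (i in seq_len(n)) {
    bits <- net@functions[[i]]@bits
    ones <- which(bits == 1L) - 1L
    expr <- if (length(ones) == 0L) {
      "0"
    } else if (length(ones) == 2^n) {
      "1"
    } else {
      terms <- vapply(ones, function(m) {
        lit <- vapply(seq_len(n), function(v)
          if (bitAt(m, v) == 1) sprintf("x%d", v) else sprintf("!x%d", v),
          character(1))
        paste(lit, collapse = " & ")
      }, character(1))
      paste(terms, collapse = " | ")
    }
    lines <- c(lines, sprintf("x%d, %s", i, expr))
  }
  writeLines(lines, file)
  invisible(file)
}
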