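# Bit-level helpers shared across the package.
#
# Assignment encoding convention (used everywhere): variable x_i is bit i-1
# of the state/assignment index, with x_1 the least significant bit.  Index
# m in 0:(2^n - 1) therefore encodes the assignment
# (bitAt(m, 1), ..., bitAt(m, n)).  Doubles are used for indices so that
# state spaces up to 2^24 are handled without integer overflow.

bitAt <- function(m, i) (m %/% 2^(i - 1)) %% 2

encodeAssignment <- function(assignment) {
  if (length(assignment) == 0L) return(0)
  sum(assignment * 2^(seq_along(assignment) - 1))
}

decodeAssignment <- function(m, n) {
  if (n == 0L) return(integer(0))
  as.integer(bitAt(m, seq_len(n)))
}

popCount <- function(x, nbits) {
  out <- numeric(length(x))
  for (i in seq_len(nbits)) out <- out + bitAt(x, i)
  as.integer(out)
}

# Euclid on non-negative doubles holding exact integers.
gcdNum <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  a
}

gcdAll <- function(x) {
  g <- 0
  for (v in x) {
    g <- gcdNum(g, v)
    if (g == 1) break
  }
  g
}

lcmNum <- function(a, b) (a / gcdNum(a, b)) * b

# Reduce a fraction num/den (exact integers in doubles); den > 0 on output.
ratReduce <- function(num, den) {
  stopifnot(den != 0)
  if (den < 0) { num <- -num; den <- -den }
  g <- gcdNum(num, den)
  if (g > 1) { num <- num / g; den <- den / g }
  c(num, den)
}

# Guard: doubles represent integers exactly only below 2^53.
.INT_EXACT_MAX <- 2^52

checkExactInt <- function(x, what = "value") {
  if (max(abs(x)) > .INT_EXACT_MAX)
    stop("exact integer arithmetic would exceed double precision in ", what,
         call. = FALSE)
  invisible(TRUE)
}
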