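# Shared fixtures and independent oracles, built in code.

# truth table from an R expression over the assignment vector
tt <- function(n, fn) truthTableFromFunction(n, fn)

ttAND2 <- function() tt(2, function(x) x[1] * x[2])
ttXOR2 <- function() tt(2, function(x) (x[1] + x[2]) %% 2)
ttXORAND3 <- function() tt(3, function(x) ((x[1] + x[2]) %% 2) * x[3])  # (x1+x2)x3
ttAND3 <- function() tt(3, function(x) x[1] * x[2] * x[3])
ttPARITY3 <- function() tt(3, function(x) (x[1] + x[2] + x[3]) %% 2)

# truth table with table-index value v (0-based bit packing) on n variables
ttFromIndex <- function(v, n) {
  truthTable(as.integer((v %/% 2^(0:(2^n - 1))) %% 2), n)
}

ttIndex <- function(f) sum(tableBits(f) * 2^(seq_along(tableBits(f)) - 1))

# uniform random truth table / network (no canalization constraint)
randomTable <- function(n) truthTable(sample(0:1, 2^n, replace = TRUE), n)
randomNetwork <- function(n) booleanNetwork(lapply(seq_len(n), function(i) randomTable(n)))

# canalizing depth of every function on n variables (n <= 3), index-ordered
depthClassification <- function(n) {
  vapply(0:(2^(2^n) - 1), function(v) canalizingDepth(ttFromIndex(v, n)),
         numeric(1))
}

# independent oracle: enumerate every ordered partition of a set
enumOrderedPartitions <- function(set) {
  k <- length(set)
  if (k == 0L) return(list(list()))
  out <- list()
  # first block = any nonempty subset, then recurse
  for (mask in 1:(2^k - 1)) {
    pick <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    first <- set[pick]
    for (rest in enumOrderedPartitions(set[-pick]))
      out[[length(out) + 1L]] <- c(list(sort(first)), rest)
  }
  out
}

partitionKey <- function(blocks) {
  paste(vapply(blocks, function(b) paste(sort(b), collapse = ","),
               character(1)), collapse = "|")
}

# chi-square goodness of fit of observed category counts vs probabilities
chisqUniformP <- function(counts, p = NULL) {
  if (is.null(p)) p <- rep(1 / length(counts), length(counts))
  suppressWarnings(stats::chisq.test(counts, p = p)$p.value)
}
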