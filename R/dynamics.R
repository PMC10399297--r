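#' @include sampler.R
NULL

.N_GUARD <- 24L  # the flat successor array needs 2^n entries

#' Construct a Boolean network
#'
#' @param functions list of \linkS4class{TruthTable} objects, all on the
#'   same number of variables, with exactly one function per variable.
#' @return A \linkS4class{BooleanNetwork}.
#' @export
booleanNetwork <- function(functions) {
  stopifnot(length(functions) >= 1L)
  new("BooleanNetwork", nVars = functions[[1L]]@nVars, functions = functions)
}

#' Synchronous update of one state
#'
#' Applies the network map once: coordinate \code{i} of the successor is
#' coordinate function \code{i} evaluated on the current state.  States are
#' 0-based integers under the shared assignment encoding.
#'
#' @param net a \linkS4class{BooleanNetwork}.
#' @param state integer in \code{0:(2^n - 1)}.
#' @return The successor state index.
#' @export
stepState <- function(net, state) {
  if (state < 0 || state >= 2^net@nVars) stop("state out of range")
  bits <- vapply(net@functions, function(f) as.numeric(f@bits[state + 1]),
                 numeric(1))
  encodeAssignment(bits)
}

#' Full successor array of the state space
#'
#' The functional graph of the synchronous dynamics as a flat array: entry
#' \code{m + 1} is the successor of state \code{m}.  Because states and
#' assignments share one encoding, coordinate \code{i} of the successor of
#' every state is just the truth table of function \code{i}, so the array
#' is assembled with vectorized arithmetic.
#'
#' @param net a \linkS4class{BooleanNetwork} with at most 24 nodes (memory
#'   guard for the flat array).
#' @return Numeric vector of length \code{2^n} of 0-based successor states.
#' @export
transitionMap <- function(net) {
  n <- net@nVars
  if (n > .N_GUARD) stop("state space too large: need n <= ", .N_GUARD)
  succ <- numeric(2^n)
  for (i in seq_len(n))
    succ <- succ + as.numeric(net@functions[[i]]@bits) * 2^(i - 1)
  succ
}

## cycle detection on a 1-based successor array via pointer doubling:
## after n doublings every state has been advanced 2^n >= transient steps,
## so it sits on its attractor cycle.
.cyclesFromSucc <- function(succ1, n) {
  far <- succ1
  for (d in seq_len(max(n, 1L))) far <- far[far]
  cycStates <- sort(unique(far))
  onCycle <- logical(length(succ1))
  cycles <- list()
  for (s in cycStates) {
    if (onCycle[s]) next
    path <- s
    cur <- succ1[s]
    while (cur != s) {
      path <- c(path, cur)
      cur <- succ1[cur]
    }
    onCycle[path] <- TRUE
    cycles[[length(cycles) + 1L]] <- path
  }
  list(cycles = cycles, far = far)
}

.canonicalReport <- function(n, cycles, basins) {
  canon <- lapply(cycles, function(cyc) {
    i0 <- which.min(cyc)
    if (i0 > 1L) cyc <- c(cyc[i0:length(cyc)], cyc[seq_len(i0 - 1L)])
    cyc
  })
  ord <- order(vapply(canon, `[`, numeric(1), 1L))
  new("AttractorReport", nVars = as.integer(n),
      cycles = unname(lapply(canon[ord], as.integer)),
      basins = unname(as.numeric(basins[ord])))
}

#' Enumerate all attractors and basins of attraction
#'
#' Exhaustively analyzes the functional graph on all \code{2^n} states:
#' every weakly connected component contains exactly one cycle (an
#' attractor), and the component is that cycle's basin of attraction.
#' Cycles are located by vectorized pointer doubling on the successor
#' array (iterative, no recursion), and each state is assigned to the
#' basin its forward orbit enters.
#'
#' @param net a \linkS4class{BooleanNetwork} (n <= 24).
#' @return An \linkS4class{AttractorReport}; cycles are rotated so the
#'   smallest state leads and sorted by that state, so reports are
#'   deterministic and comparable.
#' @examples
#' id2 <- booleanNetwork(list(
#'   truthTableFromFunction(2, function(x) x[1]),
#'   truthTableFromFunction(2, function(x) x[2])))
#' attractorsAndBasins(id2)  # four steady states, basin size 1 each
#' @export
attractorsAndBasins <- function(net) {
  n <- net@nVars
  succ1 <- transitionMap(net) + 1
  res <- .cyclesFromSucc(succ1, n)
  cycId <- numeric(length(succ1))
  for (i in seq_along(res$cycles)) cycId[res$cycles[[i]]] <- i
  basins <- tabulate(cycId[res$far], nbins = length(res$cycles))
  .canonicalReport(n, lapply(res$cycles, function(p) p - 1), basins)
}

#' Independent trajectory-iteration oracle for attractors and basins
#'
#' A deliberately naive cross-check for [attractorsAndBasins()]: from every
#' state the map is iterated step by step until a state repeats, which
#' identifies the cycle the orbit falls into; states are then grouped by
#' cycle.  Quadratic per orbit, so guarded to small networks.
#'
#' @param net a \linkS4class{BooleanNetwork} with at most 10 nodes.
#' @return An \linkS4class{AttractorReport} in the same canonical order as
#'   [attractorsAndBasins()].
#' @export
bruteForceReport <- function(net) {
  n <- net@nVars
  if (n > 10L) stop("brute-force oracle is limited to n <= 10")
  succ1 <- transitionMap(net) + 1
  size <- 2^n
  keyOf <- numeric(size)   # smallest cycle state reached from each state
  cycles <- list()
  for (s in seq_len(size)) {
    seen <- numeric(0)
    cur <- s
    while (!(cur %in% seen)) {
      seen <- c(seen, cur)
      cur <- succ1[cur]
    }
    cyc <- seen[which(seen == cur):length(seen)]
    key <- min(cyc)
    keyOf[s] <- key
    if (is.null(cycles[[as.character(key)]]))
      cycles[[as.character(key)]] <- cyc
  }
  keys <- as.numeric(names(cycles))
  basins <- vapply(keys, function(k) sum(keyOf == k), numeric(1))
  .canonicalReport(n, lapply(cycles, function(p) p - 1), basins)
}

#' Count attractors of an exact length
#'
#' Number of attractors of \code{net} whose cycle length is exactly
#' \code{len}.  Uses a vectorized fixed-point count: the states on cycles
#' whose length divides \code{p} are exactly the fixed points of the p-fold
#' composite map, so the exact-length count follows by subtracting shorter
#' divisors and dividing by \code{len}.  Agrees with filtering the full
#' [attractorsAndBasins()] report.
#'
#' @param net a \linkS4class{BooleanNetwork} (n <= 24).
#' @param len attractor length, >= 1.
#' @return Integer count (possibly 0).
#' @export
countAttractorsOfLength <- function(net, len) {
  stopifnot(len >= 1)
  succ1 <- transitionMap(net) + 1
  states <- seq_along(succ1)
  fixCount <- function(p) {
    cur <- states
    for (i in seq_len(p)) cur <- succ1[cur]
    sum(cur == states)
  }
  countExact <- function(l) {
    total <- fixCount(l)
    divs <- which(l %% seq_len(l - 1) == 0)
    for (d in divs) total <- total - d * countExact(d)
    total / l
  }
  countExact(len)
}
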