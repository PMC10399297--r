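---
title: "Canalizing depth, layered forms, and the attractor structure of random Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canalizing depth, layered forms, and the attractor structure of random Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CanalDyn)
```

## The model

A synchronous Boolean network on $n$ nodes is a tuple $f = (f_1, \dots,
f_n)$ of Boolean functions, each on all $n$ variables; the state
$a_{t+1} = f(a_t)$ applies every coordinate rule simultaneously. The map
$f$ on the $2^n$ states is a *functional graph*: every weakly connected
component contains exactly one cycle (an **attractor**) and the component
is that cycle's **basin of attraction**. In gene-network modeling,
attractors are read as stable expression programs (cell types), attractor
length as the complexity of the program, and basin size as the robustness
with which the program is reached.

A nonconstant function is **canalizing** if some variable has an input
value that forces a constant output. Iterating the idea yields the
**canalizing depth** $k$: peel off a canalizing variable (fix it to the
*non*-canalizing value), and repeat on the restriction until the remainder
is noncanalizing. Noncanalizing functions — including the constants, which
by convention are not canalizing — have depth $0$; functions of maximal
depth $k = n$ are **nested canalizing**. The depth is well defined: it
does not depend on which certificate is peeled at each stage, a fact the
test suite exercises directly by re-peeling random functions in random
orders.

## The layered (He–Macaulay) form

Every Boolean function $f \not\equiv 0$ has a unique representation over
GF(2)

$$ f = M_1\bigl(M_2(\cdots(M_r\,p_C + 1)\cdots + 1) + 1\bigr) + b, $$

with layers $M_i = \prod_j (x_{i_j} + a_{i_j})$, a noncanalizing core
$p_C \not\equiv 0$ on the remaining variables, and $b \in \{0,1\}$; the
layer variables count the canalizing depth. Uniqueness needs two
exceptional-case constraints: if $p_C \equiv 1$ and $r \neq 1$ the last
layer has at least two variables (otherwise the lone literal would be
absorbed into the previous layer), and if $p_C \equiv 1$, $r = 1$ with a
single-variable layer then $b = 0$ (otherwise $(x+a)+1 = x+\bar a$ would
give the same function twice).

`hmDecompose()` computes the form by *full peeling*: the outermost layer
is the set of **all** certificates of $f$ (they provably share one
canalized output, which the code asserts), the next layer is the
certificate set of the restriction with every layer variable fixed to its
non-canalizing value, and so on; the canalized outputs alternate down the
peel because of the nested "+1" bookkeeping, and the final remainder is
sign-adjusted by the last output so that `hmRecompose()` is a bit-exact
inverse. Two degenerate situations deserve note:

* a function equal to a single literal is canalized by *both* input values
  with opposite outputs; the algorithm takes the output-0 branch, which is
  exactly what the second exceptional case prescribes. After a full peel a
  literal remainder cannot occur (if the restricted function were a
  literal, that variable would already have been a certificate of the
  parent), so the choice only ever arises for the input function itself;
* degenerate functions that ignore some of their variables are
  first-class: the core's variable set is the full complement of the layer
  variables whether or not the core depends on all of them. This is the
  reading consistent with the sampler, which draws the core uniformly from
  *all* noncanalizing functions on the complement set.

## Uniform sampling of prescribed depth

`sampleDepthKFunction(n, k)` inverts the bijection behind the unique form:
draw $b$ and per-variable bits $a_i$ uniformly, a uniform $k$-subset of
layer variables, a uniform ordered partition of it into layers, and a
uniform noncanalizing nonzero core on the complement; if the draw violates
an exceptional case (possible only when $p_C \equiv 1$), the *entire* draw
is restarted, which preserves uniformity at a small expected cost.
For $k = 0$ the sampler returns a uniform noncanalizing function with the
constants included — depth 0 simply means "noncanalizing", and excluding
constants would bias the ensemble; a switch (`excludeZero` in
`sampleNoncanalizing()`) exists where the nonzero variant is needed.

Ordered partitions are drawn exactly: with $p_j$ the Fubini numbers
($p_j = \sum_{m=1}^{j}\binom{j}{m} p_{j-m}$, $p_0 = 1$), the first block
has size $j$ with probability $\binom{k}{j} p_{k-j}/p_k$, and the rest is
partitioned recursively. A commonly printed threshold form of this search
is typographically garbled (its cumulative sum starts at the full count,
so it would always stop at $j = 1$); the recurrence used here is the
standard one and is validated against brute-force enumeration
of all ordered partitions for $k \le 4$ and by chi-square goodness of fit
on the sampled first-block sizes. Fubini numbers are kept in doubles,
which hold integers exactly up to $2^{53}$; $p_{17}$ exceeds that, so the
partition sampler refuses sets larger than 16 elements rather than sample
from a silently inexact distribution. Networks of depth up to 16 cover
everything the package's experiments touch.

Noncanalizing cores are drawn by rejection (uniform tables until one has
no certificate), with `maxRejections = 10000`: the acceptance probability
is $3/16$ at $m = 2$, the worst nontrivial case, and tends to 1 rapidly as
$m$ grows, so the cap is effectively unreachable in normal use and exists
to turn a misconfiguration into an error instead of a hang.

All randomness flows through R's global RNG: seed once with `set.seed()`
and every draw — functions, networks, sweeps — is reproducible. This is
the idiomatic R contract and replaces an explicit generator object
threaded through calls.

## Dynamics and enumeration

States and assignments share one encoding (variable $x_i$ is bit $i-1$,
$x_1$ least significant), so the successor array of a network is assembled
from the coordinate truth tables with vectorized arithmetic — no per-state
evaluation. `attractorsAndBasins()` finds the cycles by pointer doubling
(after $n$ squarings every state has advanced $2^n$ steps and sits on its
cycle), walks each cycle once, and reads basin sizes off the table of
far-future cycle representatives; everything is iterative, so deep
transients cannot overflow the call stack. Reports are canonicalized —
each cycle rotated so its smallest state leads, attractors sorted by that
state — making reports comparable across implementations. A deliberately
naive per-state trajectory oracle (`bruteForceReport()`) provides the
independent cross-check; the suite compares the two on hundreds of random
networks. The flat successor array caps the package at $n \le 24$
(a $2^{24}$-entry table; beyond that memory, not time, is the binding
constraint).

`countAttractorsOfLength()` avoids full enumeration when only counts are
needed: states on cycles whose length divides $p$ are exactly the fixed
points of the $p$-fold composite, so exact-length counts follow by
divisor subtraction — this is what makes the Monte-Carlo validation at
$n = 14$ cheap.

## Ensemble statistics

For a network $f$, $N(f)$ is the number of attractors, $S(f)$ the sum of
attractor lengths, and $AS(f) = S(f)/N(f)$ their average size ($S/N$ is
computed in exact integer arithmetic per network and only rendered to 6
decimals in the CSV). `runSweep()` samples cells of an $(n, k)$ grid and
emits one row per network under a fixed schema; `sampleMeans()`,
`relativeDecrease()` (cell mean at depth $k$ over cell mean at depth 0)
and `attractorHistogram()` summarize it. The binning of the $AS$
histograms is not prescribed anywhere; fixed-width bins with a
user-settable width (default 0.25) are the package's documented choice.

The full-scale campaign this machinery supports (tens of millions of
networks, $n$ up to 20, $5 \times 10^4$–$3 \times 10^5$ samples per cell)
is far beyond a sensible default run. The package's tests reproduce the
qualitative findings at desk scale — $n = 8$, depths $\{0, 1, 3, 8\}$,
2000 networks per cell — checking that both cell means are non-increasing
in depth (one inversion within two standard errors allowed) and that the
drop in mean $AS$ from depth 0 to 1 exceeds the drop from 1 to full
depth. What desk scale *cannot* show is the sharpening of the relative
decrease as $n$ grows into the teens; users with more compute can rerun
`runSweep()` at larger grids unchanged.

What the sampled ensembles do **not** emulate about real regulatory
networks: biological rules have sparse inputs (each gene reads a few
regulators, not all $n$), correlated and structured wiring, and biased
truth tables. Passing tests therefore validate the mathematics of the
uniform fixed-depth ensembles, not fidelity to any particular biological
network.

## The depth-one limit theory

For cycle strings $\alpha, \beta \in \{0,1\}^\ell$, define
$f(\alpha,\beta) = 2^{-|\beta|}$ if $\alpha \vee \beta = \beta$ and 0
otherwise, and $g$ as the average of $f$ over the four negation
combinations of its arguments. The transfer matrix is
$(G_\ell)_{a,b} = g(a, s(b))$ with $s$ the right cyclic shift
($s(\alpha)_t = \alpha_{t-1 \bmod \ell}$); rows/columns are indexed
$0 \dots 2^\ell - 1$ with string position $t$ stored in bit $t-1$. The
limiting expected number of length-$\ell$ attractors of a random
depth-one network is

$$ A_\ell = \frac{1}{\ell\, P'_{G_\ell}(1)}
          = \frac{1}{\ell \prod_{\lambda \neq 1} (1-\lambda)}, $$

where $P_{G_\ell}$ is the characteristic polynomial and the product runs
over the non-unit eigenvalues. Two reading choices behind this
implementation are worth recording as design decisions. First, the
formula is taken as $1/(\ell P'(1))$, not $(1/\ell) P'(1)$: only the
former reproduces $A_1 = 1$ and $A_2 = 2/3$ from $G_1, G_2$ and satisfies
$A_\ell > 1/\ell$. Second, the $t^2$ coefficient of $P_{G_2}$ is $1/4$ by
direct exact expansion of $G_2$ (the value that yields $A_2 = 2/3$); a
circulating rendering with $1/2$ is inconsistent with the matrix itself
and is not used. The index and shift conventions are pinned by two
independent anchors in the tests: the worked $G_2$ matrix entry-for-entry,
and the exact value $A_3 = 64/189$.

### Exact arithmetic

Every entry of $G_\ell$ is a dyadic rational with denominator
$2^{\ell+2}$, which doubles represent *exactly*; the matrix is stored as
an integer numerator matrix plus that common denominator, so column sums
and the negation symmetries are checked with exact equality, not
tolerances. The characteristic polynomial is computed by the
Faddeev–LeVerrier recursion carried out on the numerator matrix with one
common denominator, re-reduced by the collective gcd after every step and
guarded so that no intermediate leaves the exactly-representable integer
range below $2^{53}$; within that range the computation is exact rational
arithmetic with no external big-number dependency. The guard admits
$\ell \le 4$ (giving exact fractions such as $A_4 = 16384/57375$); for
$\ell = 5, 6$ the evaluation of $P(1)$ and $P'(1)$ would overflow, the
guard raises, and `attractorLimit()` falls back to the product of numeric
eigenvalues of the (still exact) matrix — stable to about $10^{-12}$,
versus the four decimals ever reported. Simplicity of the eigenvalue 1 is
verified on either path ($P(1) = 0$ with $P'(1) \neq 0$ exactly, or a
unit-disk multiplicity count numerically); if it failed, the limit formula
would not apply and the function errors rather than returning a number.
The matrix cap is $\ell \le 10$ ($1024 \times 1024$), a practical desk
limit.

`expectedAttractorsRandom()` provides the unconstrained baseline
$\frac{1}{\ell}\prod_{i<\ell}(2^n - i)/2^n \to 1/\ell$, and
`monteCarloExpected()` validates the limits at finite $n$; the package's
checks use 2000 depth-one networks at $n = 12$ for $\ell = 1$ (where the
expectation is exactly 1 at every $n$ by output-negation symmetry) and
1000 networks at $n = 14$ for $\ell = 2$ with a 0.03 finite-size allowance
on top of three standard errors, plus a shrinking-gap check over
$n \in \{8, 10, 12\}$. Depth-0 networks are compared against the
unconstrained baseline with a three-standard-error tolerance; the two
ensembles differ (noncanalizing functions are a strict subset of all
functions) but the difference is far below sampling noise at the sizes
used, which is why the cruder tolerance is documented rather than an
exact depth-0 formula, none being available.

## Known limitations

* Truth tables are dense: $n \le 24$ per function, and exhaustive
  dynamics are practical well below that; no BDD/SAT representation is
  provided for larger networks.
* Only the synchronous update scheme is implemented; asynchronous or
  probabilistic semantics change the attractor concept entirely.
* The limit formula is specific to depth one; no analogue for higher
  depth is implemented (none is known in closed form), though the
  Monte-Carlo machinery accepts any $k$.
* The `.bnet` writer is export-only, intended to hand networks to
  BoolNet-compatible tools; no importer or validation against those tools
  is included.
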