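#' Small analytically tractable networks
#'
#' Generators for toy networks whose ODE solutions and SSA moments have closed
#' forms, used throughout the test-suite as independent oracles:
#' \describe{
#'   \item{`decay`}{`A -> 0` at rate `d`: `A(t) = A0 * exp(-d t)`; the SSA
#'     count at time `t` is Binomial(`A0`, `exp(-d t)`).}
#'   \item{`birth_death`}{`0 -> A` at rate `k`, `A -> 0` at rate `d`
#'     (immigration-death): stationary distribution Poisson with mean `k/d`.}
#'   \item{`dimerization`}{`A + A -> B` at rate `k`: `A + 2B` is conserved.}
#'   \item{`two_state_switch`}{`A <-> B` with rates `kon`, `koff`:
#'     equilibrium fraction in `B` is `kon / (kon + koff)`; `A + B` conserved.}
#' }
#'
#' @param kind One of `"decay"`, `"birth_death"`, `"dimerization"`,
#'   `"two_state_switch"`.
#' @param A0,B0 Initial counts.
#' @param d,k,kon,koff Rate constants (per minute).
#' @return A [reaction_network()].
#' @export
toy_network <- function(kind = c("decay", "birth_death", "dimerization",
                                 "two_state_switch"),
                        A0 = 1000, B0 = 0, d = 0.01, k = 50,
                        kon = 0.1, koff = 0.1) {
  kind <- match.arg(kind)
  switch(kind,
    decay = reaction_network(
      list(species_def("A", A0)),
      list(reaction("decay", "A", character(), mass_action(d))),
      parameters = c(d = d, A0 = A0)),
    birth_death = reaction_network(
      list(species_def("A", A0)),
      list(reaction("birth", character(), "A", mass_action(k)),
           reaction("death", "A", character(), mass_action(d))),
      parameters = c(k = k, d = d, A0 = A0)),
    dimerization = reaction_network(
      list(species_def("A", A0), species_def("B", B0, role = "complex")),
      list(reaction("dimerize", c("A", "A"), "B", mass_action(k))),
      parameters = c(k = k, A0 = A0, B0 = B0)),
    two_state_switch = reaction_network(
      list(species_def("A", A0), species_def("B", B0, variant_of = "A")),
      list(reaction("on", "A", "B", mass_action(kon)),
           reaction("off", "B", "A", mass_action(koff))),
      list(conservation(c("A", "B"), A0 + B0)),
      parameters = c(kon = kon, koff = koff, A0 = A0, B0 = B0)))
}

#' Reproducible iid Bernoulli sampler
#'
#' Returns a zero-argument closure producing an iid 0/1 stream with success
#' probability `p`, using its own RNG stream so that repeated construction
#' with the same seed replays the same outcomes.  This is the synthetic stand-
#' in for "simulate a trace and model-check it" used to exercise the
#' sequential tester at known ground truth.
#'
#' @param p Success probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Function of no arguments returning 0 or 1.
#' @export
bernoulli_sampler <- function(p, seed) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  rng <- new.env(parent = emptyenv())
  set.seed(as.integer(seed))
  rng$state <- .Random.seed
  function() {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    assign(".Random.seed", rng$state, globalenv())
    x <- as.integer(stats::runif(1) < p)
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    x
  }
}

#' Random BLTL formulas and random traces for fuzz testing
#'
#' `random_formula` samples a formula tree of the given depth: internal nodes
#' choose uniformly among negation, conjunction, disjunction, until, and the
#' derived F/G operators with integer bounds in `bound_range`; leaves are
#' atomic propositions comparing a species to a threshold drawn from
#' `threshold_range`.  `random_trace` samples a piecewise-constant trace whose
#' counts follow reflected random walks and whose sojourns are exponential.
#' Both are deterministic given the RNG state (wrap in [set.seed()]).
#'
#' @param depth Maximum tree depth (0 gives a bare atomic proposition).
#' @param species Character vector of species names to draw from.
#' @param bound_range Integer range for temporal bounds.
#' @param threshold_range Numeric range for AP thresholds.
#' @return `random_formula`: a [parse_formula()]-style formula object.
#' @export
random_formula <- function(depth, species, bound_range = c(1, 100),
                           threshold_range = c(0, 20)) {
  stopifnot(depth >= 0, length(species) > 0)
  rnd_ap <- function() {
    sp <- sample(species, 1)
    cmp <- sample(c(">", "<", ">=", "<="), 1)
    thr <- round(stats::runif(1, threshold_range[1], threshold_range[2]), 1)
    bltl_ap(str2lang(sp), cmp, thr)
  }
  build <- function(d) {
    if (d == 0L) return(rnd_ap())
    bound <- sample(seq(bound_range[1], bound_range[2]), 1)
    switch(sample(6, 1),
           rnd_ap(),
           bltl_not(build(d - 1L)),
           bltl_and(build(d - 1L), build(d - 1L)),
           bltl_or(build(d - 1L), build(d - 1L)),
           bltl_until(bound, build(d - 1L), build(d - 1L)),
           if (stats::runif(1) < 0.5) bltl_F(bound, build(d - 1L))
           else bltl_G(bound, build(d - 1L)))
  }
  build(as.integer(depth))
}

#' @rdname random_formula
#' @param length Number of states in the trace.
#' @param mean_sojourn Mean of the exponential sojourn times (minutes).
#' @param max_count Cap for the reflected random-walk counts.
#' @return `random_trace`: a [new_trace()] with `origin = "ssa"`-style
#'   piecewise-constant states.
#' @export
random_trace <- function(length, species, mean_sojourn = 20, max_count = 20) {
  stopifnot(length >= 1, length(species) > 0)
  n <- as.integer(length)
  soj <- stats::rexp(n, rate = 1 / mean_sojourn)
  tm <- c(0, cumsum(soj))[seq_len(n)]
  st <- vapply(species, function(s) {
    x <- cumsum(sample(c(-1L, 0L, 1L), n, replace = TRUE)) +
      sample.int(max_count, 1)
    as.integer(pmin(pmax(x, 0L), max_count))
  }, integer(n))
  if (n == 1L) st <- matrix(st, nrow = 1, dimnames = list(NULL, species))
  new_trace(tm, st, origin = "ssa", horizon = tm[n] + soj[n])
}
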