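#' Specification of a Bayesian sequential hypothesis test
#'
#' Decides between `H0: p >= theta` and `H1: p < theta` for the unknown
#' probability `p` that a sampled trace satisfies a property, using the Bayes
#' factor with a Beta(`alpha`, `beta`) prior on `p` and prior hypothesis
#' probabilities `p_h0`, `p_h1`.
#'
#' @param theta Probability threshold in (0, 1).  Default 0.9, the threshold
#'   used throughout the shipped property suite.
#' @param T Bayes-factor threshold, > 1.  The test accepts H0 when the Bayes
#'   factor exceeds `T` and rejects it below `1/T`; the error probability is
#'   bounded by `1/T`.
#' @param alpha,beta Beta prior parameters, > 0.  Default uniform Beta(1, 1).
#' @param p_h0,p_h1 Prior hypothesis probabilities, positive, summing to 1.
#' @param max_samples Safety cap on the number of sequential samples; the test
#'   returns verdict `"undecided"` if it is reached.
#' @return A `hypothesis_test_spec` object.
#' @export
hypothesis_test_spec <- function(theta = 0.9, T = 1000, alpha = 1, beta = 1,
                                 p_h0 = 0.5, p_h1 = 0.5, max_samples = 1e5) {
  stopifnot(theta > 0, theta < 1, T > 1, alpha > 0, beta > 0,
            p_h0 > 0, p_h1 > 0, abs(p_h0 + p_h1 - 1) < 1e-12,
            max_samples >= 1)
  structure(list(theta = theta, T = T, alpha = alpha, beta = beta,
                 p_h0 = p_h0, p_h1 = p_h1,
                 max_samples = as.integer(max_samples)),
            class = "hypothesis_test_spec")
}

#' @export
print.hypothesis_test_spec <- function(x, ...) {
  cat(sprintf(
    "Bayesian test of H0: p >= %g vs H1: p < %g | T = %g, Beta(%g, %g) prior, P(H0) = %g\n",
    x$theta, x$theta, x$T, x$alpha, x$beta, x$p_h0))
  invisible(x)
}

#' Bayes factor for Bernoulli samples
#'
#' Closed form for the Bayes factor of `H0: p >= theta` against
#' `H1: p < theta` after observing `x` successes in `n` Bernoulli samples
#' under a Beta(`alpha`, `beta`) prior:
#' \deqn{B_n = \frac{P(H_1)}{P(H_0)} \left( \frac{1}{F_{(x+\alpha,\; n-x+\beta)}(\theta)} - 1 \right)}
#' where `F` is the Beta distribution function, evaluated with the
#' regularised incomplete beta function ([stats::pbeta()]); no numerical
#' integration is involved.
#'
#' @param x Number of successes, `0 <= x <= n`.
#' @param n Number of samples.
#' @param spec A [hypothesis_test_spec()].
#' @return Positive Bayes factor (may be `Inf` when the posterior mass below
#'   `theta` underflows).
#' @examples
#' bayes_factor(0, 0, hypothesis_test_spec(theta = 0.9))  # 1/0.9 - 1
#' @export
bayes_factor <- function(x, n, spec = hypothesis_test_spec()) {
  stopifnot(inherits(spec, "hypothesis_test_spec"),
            length(x) == length(n), all(x >= 0), all(n >= x))
  Ftheta <- stats::pbeta(spec$theta, x + spec$alpha, n - x + spec$beta)
  if (any(Ftheta == 0))
    # mathematically impossible for theta in (0,1) with positive shapes;
    # reachable only by floating-point underflow far past any stopping point
    stop("internal error: Beta distribution function vanished at theta")
  # 1/F - 1 written as the ratio of the two tail masses: identical
  # algebraically, but accurate in both tails (no 1 - F cancellation)
  upper <- stats::pbeta(spec$theta, x + spec$alpha, n - x + spec$beta,
                        lower.tail = FALSE)
  (spec$p_h1 / spec$p_h0) * upper / Ftheta
}

#' Error bound of the sequential test
#'
#' The probability that the sequential Bayesian test returns a wrong verdict
#' (accepting a false H0 or rejecting a true one) is bounded above by `1/T`.
#'
#' @param spec A [hypothesis_test_spec()] (or a Bayes-factor threshold).
#' @return `1/T`.
#' @examples
#' error_bound(hypothesis_test_spec(T = 1000))  # 1e-3
#' @export
error_bound <- function(spec) {
  T <- if (inherits(spec, "hypothesis_test_spec")) spec$T else spec
  stopifnot(is.numeric(T), T > 1)
  1 / T
}

new_smc_result <- function(verdict, n, x, B, spec, sample_log = NULL,
                           seeds = NULL) {
  structure(list(verdict = verdict, n = n, x = x, final_bayes_factor = B,
                 spec = spec, sample_log = sample_log, seeds = seeds),
            class = "smc_result")
}

#' @export
print.smc_result <- function(x, ...) {
  cat(sprintf("SMC verdict: %s (n = %d samples, x = %d successes, B = %.4g)\n",
              x$verdict, x$n, x$x, x$final_bayes_factor))
  cat(sprintf("error bound: %g\n", error_bound(x$spec)))
  invisible(x)
}

#' Sequential Bayesian statistical model checking decision
#'
#' Draws iid Bernoulli samples one at a time, recomputing the Bayes factor
#' `B` after each: the test stops with `accept_h0` as soon as `B > T`, with
#' `reject_h0` as soon as `B < 1/T`, and keeps sampling while
#' `1/T <= B <= T` (ties continue).  If `max_samples` is reached (or a
#' pre-drawn sample vector is exhausted) the verdict is `"undecided"`.
#'
#' @param sampler Either a function of no arguments returning 0/1 (an iid
#'   sample of "does a fresh trace satisfy the property?"), or a numeric
#'   vector of pre-drawn 0/1 outcomes consumed left to right.
#' @param spec A [hypothesis_test_spec()].
#' @return An `smc_result` with the verdict, sample and success counts, final
#'   Bayes factor and the outcome log.
#' @examples
#' smc_decide(rep(1, 100), hypothesis_test_spec())$n  # accepts at n = 65
#' @export
smc_decide <- function(sampler, spec = hypothesis_test_spec()) {
  stopifnot(inherits(spec, "hypothesis_test_spec"))
  if (is.numeric(sampler)) {
    outcomes <- sampler
    if (any(!(outcomes %in% c(0, 1)))) stop("outcomes must be 0/1")
    m <- min(length(outcomes), spec$max_samples)
    if (m == 0L) {
      return(new_smc_result("undecided", 0L, 0L, bayes_factor(0, 0, spec), spec,
                            integer()))
    }
    xs <- cumsum(outcomes[seq_len(m)])
    ns <- seq_len(m)
    B <- bayes_factor(xs, ns, spec)
    hit <- which(B > spec$T | B < 1 / spec$T)
    if (length(hit) == 0L) {
      return(new_smc_result("undecided", m, xs[m], B[m], spec,
                            outcomes[seq_len(m)]))
    }
    s <- hit[1]
    verdict <- if (B[s] > spec$T) "accept_h0" else "reject_h0"
    return(new_smc_result(verdict, s, xs[s], B[s], spec, outcomes[seq_len(s)]))
  }
  stopifnot(is.function(sampler))
  n <- 0L; x <- 0L
  log <- integer(0)
  B <- bayes_factor(0, 0, spec)
  while (n < spec$max_samples) {
    xi <- tryCatch(sampler(), error = function(e)
      stop("sampler failed at sample ", n + 1L, ": ", conditionMessage(e)))
    if (!xi %in% c(0, 1)) stop("sampler must return 0 or 1")
    n <- n + 1L
    x <- x + as.integer(xi)
    log[n] <- as.integer(xi)
    B <- bayes_factor(x, n, spec)
    if (B > spec$T)
      return(new_smc_result("accept_h0", n, x, B, spec, log))
    if (B < 1 / spec$T)
      return(new_smc_result("reject_h0", n, x, B, spec, log))
  }
  new_smc_result("undecided", n, x, B, spec, log)
}

#' Verify a BLTL property of a network by statistical model checking
#'
#' Composes the SSA engine with the BLTL checker as the Bernoulli sampler for
#' [smc_decide()]: the i-th sample simulates an event-resolved trace with seed
#' `base_seed + i - 1` and horizon [required_horizon()] of the formula
#' (restricted to the species the formula reads), then model-checks it.
#' Per-sample seeds are recorded so any individual trace can be replayed, and
#' the whole run is reproducible from `base_seed`.
#'
#' @param network A [reaction_network()].
#' @param formula A `bltl_formula` or formula string.
#' @param spec A [hypothesis_test_spec()].
#' @param base_seed Integer seed for the first sample.
#' @return An `smc_result`; `$seeds` holds the per-sample seeds.
#' @examples
#' \donttest{
#' net <- hmgb1_network(hmgb1_init = 1e5)
#' verify_property(net, "F^20(PI3K_a/(PI3K_a + PI3K) > 0.5)",
#'                 hypothesis_test_spec(T = 100), base_seed = 1)
#' }
#' @export
verify_property <- function(network, formula, spec = hypothesis_test_spec(),
                            base_seed = 1L) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(network, "reaction_network"),
            inherits(formula, "bltl_formula"))
  horizon <- required_horizon(formula)
  if (horizon <= 0) stop("formula has no temporal extent; nothing to simulate")
  species <- intersect(bltl_species(formula), network$species_names)
  unknown <- setdiff(bltl_species(formula), network$species_names)
  if (length(unknown) > 0L)
    stop("formula references species absent from the network: ",
         paste(unknown, collapse = ", "))
  i <- 0L
  sampler <- function() {
    i <<- i + 1L
    tr <- simulate_ssa(network, t_end = horizon, seed = base_seed + i - 1L,
                       record = species)
    as.integer(check_formula(formula, tr))
  }
  res <- smc_decide(sampler, spec)
  res$seeds <- base_seed + seq_len(res$n) - 1L
  res
}
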