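#' Deterministic (ODE) simulation of a reaction network
#'
#' Integrates `d(count)/dt = S * rate(state)` with the stiff-capable `lsoda`
#' integrator, where `S` is the stoichiometry matrix and rates use the
#' deterministic mass-action/Hill forms (see [reaction_rate()]).  All species
#' are integrated; conservation relations are not eliminated but are verified
#' by the caller or test-suite post hoc (the stoichiometry preserves them
#' exactly, so drift only reflects solver tolerance).
#'
#' @param network A [reaction_network()].
#' @param t_end Simulation horizon in minutes.
#' @param grid_dt Output grid spacing (minutes); each grid state's sojourn is
#'   `grid_dt`.  Default 1 min, matching the resolution at which temporal
#'   properties are stated.
#' @param rtol,atol Relative/absolute solver tolerances.  The defaults
#'   (`1e-6`, `1e-3` molecules) suit networks mixing 1-1e5 molecule scales.
#' @return A [new_trace()] of origin `"ode"`.
#' @examples
#' net <- toy_network("decay", A0 = 1000, d = 0.01)
#' tr <- simulate_ode(net, t_end = 100)
#' tail(tr$state[, "A"], 1)  # ~ 1000 * exp(-1)
#' @export
simulate_ode <- function(network, t_end, grid_dt = 1, rtol = 1e-6, atol = 1e-3) {
  stopifnot(inherits(network, "reaction_network"), t_end > 0, grid_dt > 0)
  comp <- compile_network(network)
  times <- seq(0, t_end, by = grid_dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  rhs <- function(t, y, parms) {
    list(as.vector(parms$stoich %*% compiled_rates_det(parms$comp, y)))
  }
  sol <- deSolve::lsoda(y = network$init, times = times, func = rhs,
                        parms = list(stoich = network$stoich, comp = comp),
                        rtol = rtol, atol = atol)
  if (nrow(sol) < length(times)) {
    stop("ODE integration failed at t = ", sol[nrow(sol), 1],
         " min (of ", t_end, ")")
  }
  state <- pmax(sol[, -1, drop = FALSE], 0)  # clip solver-tolerance negatives
  colnames(state) <- network$species_names
  new_trace(sol[, 1], state, origin = "ode", seed = NA_integer_, horizon = t_end)
}

#' Stochastic simulation (Gillespie's direct method)
#'
#' Exact SSA: waiting times are exponential with rate equal to the total
#' propensity, the next reaction is chosen with probability proportional to
#' its propensity, and the state jumps by the reaction's stoichiometry.  The
#' simulation ends at `t_end`, or earlier if the total propensity reaches 0
#' (the final state's sojourn then extends to `t_end`).  The same seed always
#' yields a bit-identical event sequence.
#'
#' By default every event is recorded, so BLTL evaluation on the returned
#' trace is exact.  For long runs of large networks, `record` can restrict the
#' trace to the species of interest: events that leave all recorded species
#' unchanged are merged into the current state's sojourn, which is invisible
#' to the piecewise-constant BLTL semantics.  Alternatively `grid_dt` samples
#' the state on a uniform grid (suitable for plotting/readouts, not for exact
#' property checking).
#'
#' @param network A [reaction_network()]; initial counts must be integers.
#' @param t_end Simulation horizon (minutes).
#' @param seed Integer RNG seed (required: traces are meant to be replayable).
#' @param record `"all"` or a character vector of species to record.
#' @param grid_dt `NULL` for event-resolved output, or a grid spacing.
#' @return A [new_trace()] of origin `"ssa"`.
#' @examples
#' net <- toy_network("decay", A0 = 100, d = 0.05)
#' tr <- simulate_ssa(net, t_end = 10, seed = 1)
#' @export
simulate_ssa <- function(network, t_end, seed, record = "all", grid_dt = NULL) {
  stopifnot(inherits(network, "reaction_network"), t_end > 0)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("an integer seed is required")
  init <- network$init
  if (any(abs(init - round(init)) > 1e-9))
    stop("SSA requires integer initial counts; offending species: ",
         paste(network$species_names[abs(init - round(init)) > 1e-9], collapse = ", "))
  comp <- compile_network(network)
  if (identical(record, "all")) {
    rec_idx <- seq_len(comp$ns)
  } else {
    rec_idx <- match(record, comp$names)
    if (anyNA(rec_idx))
      stop("unknown species in record: ",
           paste(record[is.na(rec_idx)], collapse = ", "))
  }
  set.seed(as.integer(seed))
  res <- ssa_core(round(init), comp, as.numeric(t_end), as.integer(rec_idx),
                  if (is.null(grid_dt)) -1.0 else as.numeric(grid_dt))
  state <- res$state
  colnames(state) <- comp$names[rec_idx]
  new_trace(res$time, state, origin = "ssa", seed = as.integer(seed),
            horizon = t_end)
}
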