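#' Mass-action rate law
#'
#' Elementary kinetics: the reaction rate is the rate constant times the
#' product of the reactant counts.  In stochastic (propensity) mode a
#' homodimerisation pair contributes `c * (c - 1) / 2`; in deterministic mode
#' the continuous analogue `c^2 / 2` is used, so the ODE is the thermodynamic
#' limit of the jump process.
#'
#' @param k Non-negative rate constant, per minute (scaled by reaction order).
#' @return A `rate_law` object of kind `"mass_action"`.
#' @seealso [hill()], [reaction_rate()]
#' @export
mass_action <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k >= 0)
  structure(list(kind = "mass_action", k = as.numeric(k)),
            class = "rate_law")
}

#' Hill rate law
#'
#' Sigmoidal synthesis kinetics `basal + vmax * R^n / (K^n + R^n)` where `R`
#' is the count of the regulator species (typically a transcription factor).
#' Used for transcription-driven protein synthesis, which responds
#' cooperatively to its transcription factor.
#'
#' @param vmax Maximal synthesis rate (molecules/min), non-negative.
#' @param K Half-activation count (molecules), positive.
#' @param n Hill coefficient, positive (cooperativity).
#' @param regulator Name of the regulating species.
#' @param basal Basal (regulator-independent) rate, molecules/min, default 0.
#' @return A `rate_law` object of kind `"hill"`.
#' @export
hill <- function(vmax, K, n, regulator, basal = 0) {
  stopifnot(is.numeric(vmax), vmax >= 0, is.numeric(K), K > 0,
            is.numeric(n), n > 0,
            is.character(regulator), length(regulator) == 1L,
            is.numeric(basal), basal >= 0)
  structure(list(kind = "hill", vmax = as.numeric(vmax), K = as.numeric(K),
                 n = as.numeric(n), regulator = regulator,
                 basal = as.numeric(basal)),
            class = "rate_law")
}

#' @export
format.rate_law <- function(x, ...) {
  if (x$kind == "mass_action") {
    sprintf("mass_action(k=%.6g)", x$k)
  } else {
    sprintf("hill(vmax=%.6g, K=%.6g, n=%.6g, regulator=%s%s)",
            x$vmax, x$K, x$n, x$regulator,
            if (x$basal > 0) sprintf(", basal=%.6g", x$basal) else "")
  }
}

#' @export
print.rate_law <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Evaluate the rate of a single reaction in a given state
#'
#' @param reaction A [reaction()] object.
#' @param state Named numeric vector mapping species names to counts; must
#'   cover every species the rate law reads.  Counts must be non-negative.
#' @param mode `"stochastic"` for SSA propensities (combinatorial counting of
#'   reactant pairs, `c*(c-1)/2` for a homodimer) or `"deterministic"` for the
#'   ODE right-hand side (`c^2/2`).
#' @return Non-negative rate in events/min.
#' @examples
#' r <- reaction("bind", c("A", "B"), "C", mass_action(0.1))
#' reaction_rate(r, c(A = 10, B = 5, C = 0))  # 0.1 * 10 * 5 = 5
#' @export
reaction_rate <- function(reaction, state, mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(reaction, "pathmc_reaction"))
  need <- union(names(reaction$reactants),
                if (reaction$rate$kind == "hill") reaction$rate$regulator else character())
  miss <- setdiff(need, names(state))
  if (length(miss) > 0L)
    stop("state does not define species: ", paste(miss, collapse = ", "))
  if (any(state[need] < 0))
    stop("negative species count in state")
  rl <- reaction$rate
  if (rl$kind == "hill") {
    R <- as.numeric(state[[rl$regulator]])
    return(rl$basal + rl$vmax * R^rl$n / (rl$K^rl$n + R^rl$n))
  }
  rate <- rl$k
  if (length(reaction$reactants) > 0L) {
    for (i in seq_along(reaction$reactants)) {
      sp <- names(reaction$reactants)[i]
      m <- reaction$reactants[[i]]
      c0 <- as.numeric(state[[sp]])
      if (m == 1L) {
        rate <- rate * c0
      } else if (m == 2L) {
        rate <- rate * if (mode == "stochastic") c0 * (c0 - 1) / 2 else c0^2 / 2
      } else {
        stop("mass-action reactant multiplicity > 2 is not supported")
      }
    }
  }
  max(rate, 0)
}
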