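#' Local maxima with a prominence filter
#'
#' Detects local maxima of a (piecewise) series and keeps those whose
#' prominence -- the drop from the peak to the highest of the two reference
#' minima, each taken between the peak and the nearest strictly higher point
#' (or the series end) -- reaches `prominence`.  Plateaus count once.  Used to
#' quantify oscillation persistence in noisy stochastic trajectories.
#'
#' @param x Numeric series.
#' @param prominence Minimum prominence.
#' @param smooth Odd window width for a running-median pre-filter (1 = none);
#'   useful on SSA series where shot noise would otherwise create spurious
#'   local maxima.
#' @return Integer vector of peak indices (into `x`).
#' @export
find_peaks <- function(x, prominence = 0, smooth = 1) {
  stopifnot(is.numeric(x), length(x) >= 3, smooth >= 1)
  if (smooth > 1) x <- as.numeric(stats::runmed(x, k = smooth %/% 2 * 2 + 1))
  r <- rle(x)
  v <- r$values
  ends <- cumsum(r$lengths)
  m <- length(v)
  if (m < 3) return(integer())
  cand <- which(v[-c(1, m)] > v[-c(m - 1, m)] & v[-c(1, m)] > v[-c(1, 2)]) + 1L
  keep <- vapply(cand, function(i) {
    lmin <- v[i]
    j <- i - 1L
    while (j >= 1L && v[j] <= v[i]) { lmin <- min(lmin, v[j]); j <- j - 1L }
    rmin <- v[i]
    j <- i + 1L
    while (j <= m && v[j] <= v[i]) { rmin <- min(rmin, v[j]); j <- j + 1L }
    v[i] - max(lmin, rmin) >= prominence
  }, logical(1))
  ends[cand[keep]] - r$lengths[cand[keep]] %/% 2L
}

#' Baseline simulation of the HMGB1 model
#'
#' Simulates the default network (HMGB1 = 1e3 molecules unless overridden)
#' for `t_end` minutes and summarises the four readout proteins p53, MDM2_p,
#' CyclinD and CyclinE: the CyclinE peak (level and time, the model's G1-S
#' landmark) and an oscillation-persistence statistic, the number of p53
#' local maxima after `phase_end` whose prominence exceeds
#' `prominence_frac` of the pre-`phase_end` p53 peak-to-trough amplitude.
#' Deterministic runs damp towards the p53 fixed point, so they show few or
#' no late peaks; stochastic runs keep oscillating.
#'
#' @param engine `"ode"` or `"ssa"`.
#' @param seed Integer seed (used by the SSA engine).
#' @param hmgb1_init Initial HMGB1 molecules.
#' @param t_end Horizon in minutes (default 1200 = 20 h).
#' @param params Model parameters ([hmgb1_params()]).
#' @param phase_end G1-S transition time used to split early/late behaviour
#'   (default 600 min = 10 h).
#' @param prominence_frac Fraction of the early p53 amplitude a late peak
#'   must reach to be counted (default 0.1).
#' @return A list of class `baseline_run` with the grid trace (`$trace`,
#'   1-min grid over the four readouts) and `$summary`.
#' @export
baseline_run <- function(engine = c("ode", "ssa"), seed = 1L, hmgb1_init = 1e3,
                         t_end = 1200, params = hmgb1_params(),
                         phase_end = 600, prominence_frac = 0.1) {
  engine <- match.arg(engine)
  net <- hmgb1_network(hmgb1_init = hmgb1_init, params = params)
  readouts <- c("p53", "MDM2_p", "CyclinD", "CyclinE")
  tr <- if (engine == "ode") {
    full <- simulate_ode(net, t_end = t_end, grid_dt = 1)
    new_trace(full$time, full$state[, readouts], origin = "ode",
              horizon = t_end)
  } else {
    simulate_ssa(net, t_end = t_end, seed = seed, record = readouts,
                 grid_dt = 1)
  }
  tm <- tr$time
  ce <- tr$state[, "CyclinE"]
  p53 <- tr$state[, "p53"]
  early <- tm <= phase_end
  amp <- max(p53[early]) - min(p53[early])
  sm <- if (engine == "ssa") 5 else 1
  pk <- find_peaks(p53, prominence = prominence_frac * amp, smooth = sm)
  late_peaks <- sum(tm[pk] > phase_end)
  summary <- list(
    cycline_peak = max(ce),
    cycline_peak_time = tm[which.max(ce)],
    p53_early_amplitude = amp,
    p53_late_peaks = late_peaks,
    engine = engine)
  structure(list(trace = tr, summary = summary, network = net),
            class = "baseline_run")
}

#' @export
print.baseline_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Baseline %s run (%g min horizon)\n", toupper(s$engine),
              x$trace$horizon))
  cat(sprintf("  CyclinE peak: %.0f molecules at %.0f min\n",
              s$cycline_peak, s$cycline_peak_time))
  cat(sprintf("  p53 amplitude before G1-S: %.0f molecules\n",
              s$p53_early_amplitude))
  cat(sprintf("  p53 peaks after G1-S: %d\n", s$p53_late_peaks))
  invisible(x)
}

#' Dose-response sweeps over initial counts or parameters
#'
#' For each grid value, rebuilds the HMGB1 network with the varied quantity
#' (an initial species count such as `"HMGB1"`/`"AKT"`, or a rate parameter
#' such as `"d_RAS"`), simulates it, and extracts the requested readouts:
#' either the species levels at `time` or their maxima over `window`.
#' Stochastic sweeps run `replicates` traces per value and report
#' mean +/- standard error.
#'
#' @param vary Name of the varied quantity.
#' @param values Numeric grid.
#' @param species Character vector of readout species.
#' @param engine `"ode"` or `"ssa"`.
#' @param readout `"at_time"` (default) or `"max"`.
#' @param time Readout time (default 600 min, the G1-S transition).
#' @param window Window for `readout = "max"`.
#' @param replicates SSA replicates per grid value (default 10).
#' @param seed Base seed for SSA replicates.
#' @param params,hmgb1_init Base model configuration.
#' @return A data frame of class `sweep_result` with columns `value`,
#'   `species`, `mean`, `se` (`se` is `NA` for deterministic runs or a single
#'   replicate).
#' @export
run_sweep <- function(vary, values, species, engine = c("ode", "ssa"),
                      readout = c("at_time", "max"), time = 600,
                      window = c(0, 600), replicates = 10, seed = 1L,
                      params = hmgb1_params(), hmgb1_init = 1e3) {
  engine <- match.arg(engine)
  readout <- match.arg(readout)
  stopifnot(length(values) >= 1, replicates >= 1)
  proto <- hmgb1_network(hmgb1_init = hmgb1_init, params = params)
  bad <- setdiff(species, proto$species_names)
  if (length(bad) > 0L)
    stop("unknown readout species: ", paste(bad, collapse = ", "))
  is_species <- vary %in% proto$species_names
  if (!is_species && !(vary %in% names(params)))
    stop("'", vary, "' is neither a species nor a parameter of the model")
  t_end <- if (readout == "at_time") time else window[2]
  build <- function(v) {
    if (is_species) {
      if (vary == "HMGB1") hmgb1_network(hmgb1_init = v, params = params)
      else hmgb1_network(hmgb1_init = hmgb1_init, params = params,
                         init = stats::setNames(v, vary))
    } else {
      p2 <- params; p2[vary] <- v
      hmgb1_network(hmgb1_init = hmgb1_init, params = p2)
    }
  }
  extract <- function(tr) {
    if (readout == "at_time") {
      drop(trace_at(tr, time, species))
    } else {
      sel <- tr$time >= window[1] & tr$time <= window[2]
      apply(tr$state[sel, species, drop = FALSE], 2, max)
    }
  }
  rows <- list()
  for (iv in seq_along(values)) {
    net <- build(values[iv])
    if (engine == "ode") {
      tr <- simulate_ode(net, t_end = t_end, grid_dt = 1)
      y <- extract(tr)
      rows[[iv]] <- data.frame(value = values[iv], species = species,
                               mean = as.numeric(y[species]), se = NA_real_)
    } else {
      reps <- vapply(seq_len(replicates), function(r) {
        tr <- simulate_ssa(net, t_end = t_end,
                           seed = seed + (iv - 1L) * replicates + r - 1L,
                           record = species, grid_dt = 1)
        as.numeric(extract(tr)[species])
      }, numeric(length(species)))
      reps <- matrix(reps, nrow = length(species))
      rows[[iv]] <- data.frame(
        value = values[iv], species = species,
        mean = rowMeans(reps),
        se = if (replicates > 1)
               apply(reps, 1, stats::sd) / sqrt(replicates) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "vary") <- vary
  attr(out, "engine") <- engine
  attr(out, "readout") <- readout
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' @export
plot.sweep_result <- function(x, ...) {
  sp <- unique(x$species)
  graphics::matplot(unique(x$value),
                    matrix(x$mean, ncol = length(sp), byrow = TRUE),
                    type = "b", pch = 1, lty = 1, log = "x",
                    xlab = attr(x, "vary"), ylab = "molecules", ...)
  graphics::legend("topleft", legend = sp, col = seq_along(sp), lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' The seven BLTL properties of the HMGB1 model
#'
#' Named vector of formula strings over the model's species:
#' \describe{
#'   \item{P1}{p53 settles: within `t` min it drops below 3.3e4 and stays
#'     there for 900 min.}
#'   \item{P2}{p53 responds: it exceeds 5.3e4 within 100 min.}
#'   \item{P3}{half of PI3K is activated within 20 min.}
#'   \item{P4}{CyclinE exceeds 900 within 600 min (G1-S promotion).}
#'   \item{P5}{CyclinD exceeds 900 within 600 min.}
#'   \item{P6}{CyclinE stays below 10 until half of RAS is active, within
#'     300 min.}
#'   \item{P7}{the first p53 pulse reaches `a * 1e4` within 100 min and falls
#'     back below 0.4e4 within the following 100 min.}
#' }
#'
#' @param t Outer bound of P1 (minutes).
#' @param a Pulse-height threshold of P7 (units of 1e4 molecules).
#' @return Named character vector of length 7.
#' @export
hmgb1_properties <- function(t = 600, a = 5.0) {
  c(P1 = sprintf("F^%g(G^900(p53 < 33000))", t),
    P2 = "F^100(p53 > 53000)",
    P3 = "F^20(PI3K_a/(PI3K_a + PI3K) > 0.5)",
    P4 = "F^600(CyclinE > 900)",
    P5 = "F^600(CyclinD > 900)",
    P6 = "(CyclinE < 10) U^300 (RAS_a/(RAS_a + RAS) > 0.5)",
    P7 = sprintf("F^100(p53/10000 >= %g & F^100(p53/10000 <= 0.4))", a))
}

#' Verification suite over the printed property/condition grid
#'
#' Runs statistical model checking for every (property, condition) pair of
#' the study: P1 at `t` in \{400, 500, 600\}; P2; P3 at HMGB1 in \{1e3, 9e3,
#' 1e5\}; P4 at HMGB1 in \{1e2, 1e3, 1e6\}; P5 at RAS deactivation rate
#' `d_RAS` in \{1e-6, 1e-2, 1e-1\}; P6; and P7 at five (HMGB1, a) pairs.
#' Each run composes SSA sampling with the BLTL checker under the Bayesian
#' sequential test and is fully replayable from `seed`.
#'
#' @param seed Base seed; condition `i` uses `seed + 1000 * i` as its
#'   [verify_property()] base seed.
#' @param spec [hypothesis_test_spec()]; defaults to theta = 0.9, T = 1000.
#' @param conditions Optional character vector to run a subset, e.g.
#'   `c("P3_hmgb1_1e+05", "P6")`; see the `condition` column of the result.
#' @param params Base model parameters.
#' @return Data frame with columns `property`, `condition`, `formula`,
#'   `verdict`, `n`, `x`, `final_bayes_factor`.
#' @export
property_suite <- function(seed = 1L, spec = hypothesis_test_spec(),
                           conditions = NULL, params = hmgb1_params()) {
  grid <- list()
  for (t in c(400, 500, 600))
    grid[[paste0("P1_t_", t)]] <-
      list(property = "P1", formula = hmgb1_properties(t = t)[["P1"]], hmgb1 = 1e3)
  grid[["P2"]] <- list(property = "P2", formula = hmgb1_properties()[["P2"]],
                       hmgb1 = 1e3)
  for (h in c(1e3, 9e3, 1e5))
    grid[[paste0("P3_hmgb1_", format(h))]] <-
      list(property = "P3", formula = hmgb1_properties()[["P3"]], hmgb1 = h)
  for (h in c(1e2, 1e3, 1e6))
    grid[[paste0("P4_hmgb1_", format(h))]] <-
      list(property = "P4", formula = hmgb1_properties()[["P4"]], hmgb1 = h)
  for (d in c(1e-6, 1e-2, 1e-1))
    grid[[paste0("P5_dRAS_", format(d))]] <-
      list(property = "P5", formula = hmgb1_properties()[["P5"]], hmgb1 = 1e3,
           d_RAS = d)
  grid[["P6"]] <- list(property = "P6", formula = hmgb1_properties()[["P6"]],
                       hmgb1 = 1e3)
  for (pa in list(c(1e3, 5.0), c(1e3, 5.5), c(1e2, 5.5), c(1e2, 6.0),
                  c(10, 6.5)))
    grid[[sprintf("P7_hmgb1_%s_a_%g", format(pa[1]), pa[2])]] <-
      list(property = "P7", formula = hmgb1_properties(a = pa[2])[["P7"]],
           hmgb1 = pa[1])
  if (!is.null(conditions)) {
    miss <- setdiff(conditions, names(grid))
    if (length(miss) > 0L)
      stop("unknown condition(s): ", paste(miss, collapse = ", "),
           "; available: ", paste(names(grid), collapse = ", "))
    grid <- grid[conditions]
  }
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    g <- grid[[i]]
    p <- params
    if (!is.null(g$d_RAS)) p["d_RAS"] <- g$d_RAS
    net <- hmgb1_network(hmgb1_init = g$hmgb1, params = p)
    res <- verify_property(net, g$formula, spec,
                           base_seed = seed + 1000L * i)
    rows[[i]] <- data.frame(property = g$property, condition = names(grid)[i],
                            formula = g$formula, verdict = res$verdict,
                            n = res$n, x = res$x,
                            final_bayes_factor = res$final_bayes_factor)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
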