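#' Timed simulation traces
#'
#' A trace is a sequence of time-stamped states \eqn{\sigma = (s_0,t_0),
#' (s_1,t_1), \ldots}: the system sojourns for time \eqn{t_i} in state
#' \eqn{s_i} before jumping to \eqn{s_{i+1}}.  Traces are the shared currency
#' between the simulation engines and the BLTL checker; the dynamics are
#' piecewise constant, so no interpolation is ever involved.
#'
#' Internally a trace stores the *entry time* of each state (`time`, starting
#' at 0), a state matrix with one named column per recorded species, the
#' engine of `origin` (`"ssa"` or `"ode"`), the RNG `seed` (or `NA`), and the
#' `horizon` (total simulated time); the final state's sojourn extends to the
#' horizon.
#'
#' @param time Numeric vector of non-decreasing entry times starting at 0.
#' @param state Numeric matrix, `length(time)` rows, named columns.
#' @param origin `"ssa"` or `"ode"`.
#' @param seed Integer seed or `NA`.
#' @param horizon Total simulated time (minutes), at least `max(time)`.
#' @return An object of class `pathmc_trace`.
#' @export
new_trace <- function(time, state, origin = c("ssa", "ode"), seed = NA_integer_,
                      horizon = max(time)) {
  origin <- match.arg(origin)
  state <- as.matrix(state)
  if (is.null(colnames(state)) || any(!nzchar(colnames(state))))
    stop("state matrix must have named columns")
  if (length(time) != nrow(state)) stop("time and state dimensions differ")
  if (length(time) == 0L) stop("empty trace")
  if (time[1] != 0) stop("trace must start at time 0")
  if (is.unsorted(time)) stop("entry times must be non-decreasing")
  if (horizon < time[length(time)]) stop("horizon earlier than last entry time")
  if (any(state < 0)) stop("negative counts in trace")
  structure(list(time = as.numeric(time), state = state, origin = origin,
                 seed = seed, horizon = as.numeric(horizon)),
            class = "pathmc_trace")
}

#' Sojourn times of a trace
#'
#' @param trace A `pathmc_trace`.
#' @return Numeric vector: time spent in each state (the last state's sojourn
#'   runs to the horizon).
#' @export
sojourns <- function(trace) {
  stopifnot(inherits(trace, "pathmc_trace"))
  c(diff(trace$time), trace$horizon - trace$time[length(trace$time)])
}

#' @export
print.pathmc_trace <- function(x, ...) {
  cat(sprintf("%s trace: %d states over %g min, %d species (%s)\n",
              toupper(x$origin), length(x$time), x$horizon, ncol(x$state),
              paste(utils::head(colnames(x$state), 6),
                    collapse = ", ")))
  if (!is.na(x$seed)) cat("seed:", x$seed, "\n")
  invisible(x)
}

#' @export
as.data.frame.pathmc_trace <- function(x, ...) {
  data.frame(time = x$time, x$state, check.names = FALSE)
}

#' Plot species trajectories of a trace
#'
#' @param x A `pathmc_trace`.
#' @param species Character vector of columns to draw (default: all).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.pathmc_trace <- function(x, species = colnames(x$state), ...) {
  bad <- setdiff(species, colnames(x$state))
  if (length(bad) > 0L) stop("species not in trace: ", paste(bad, collapse = ", "))
  graphics::matplot(x$time, x$state[, species, drop = FALSE], type = "s",
                    lty = 1, xlab = "time (min)", ylab = "molecules", ...)
  graphics::legend("topright", legend = species, lty = 1,
                   col = seq_along(species), bty = "n", cex = 0.8)
  invisible(x)
}

#' Value of a trace at arbitrary times
#'
#' Piecewise-constant lookup: the state at time `t` is the last state entered
#' at or before `t`.
#'
#' @param trace A `pathmc_trace`.
#' @param at Numeric vector of times in `[0, horizon]`.
#' @param species Columns to return (default all).
#' @return Matrix with `length(at)` rows.
#' @export
trace_at <- function(trace, at, species = colnames(trace$state)) {
  stopifnot(inherits(trace, "pathmc_trace"))
  if (any(at < 0) || any(at > trace$horizon))
    stop("lookup times must lie within [0, ", trace$horizon, "]")
  idx <- findInterval(at, trace$time)
  trace$state[idx, species, drop = FALSE]
}

#' Write / read a trace as tab-separated text
#'
#' The file has comment lines `# origin:`, `# seed:`, `# horizon:` followed by
#' a header `time<TAB>species...`; the time column holds the entry time of
#' each state.  Sojourns are recomputed from consecutive times and the
#' horizon, so `read_trace(write_trace(x))` reproduces `x`.
#'
#' @param trace A `pathmc_trace`.
#' @param path File path.
#' @return `read_trace` returns a `pathmc_trace`; `write_trace` returns `path`
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pathmc_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# origin: ", trace$origin),
               paste0("# seed: ", ifelse(is.na(trace$seed), "NA", trace$seed)),
               paste0("# horizon: ", format(trace$horizon, digits = 17))), con)
  utils::write.table(as.data.frame(trace), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty trace file: ", path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE)
  if (length(body) < 2L) stop("trace file has no data rows: ", path)
  getmeta <- function(key, default = NA_character_) {
    hit <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(hit) == 0L) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", hit[1]))
  }
  header <- strsplit(lines[body[1]], "\t", fixed = TRUE)[[1]]
  if (header[1] != "time") stop("first column must be 'time'")
  rows <- strsplit(lines[body[-1]], "\t", fixed = TRUE)
  nc <- length(header)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != nc)
      stop("ragged row ", i + 1L, " in ", path, ": expected ", nc, " fields, got ",
           length(rows[[i]]))
  }
  vals <- suppressWarnings(matrix(as.numeric(unlist(rows)), ncol = nc, byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop("non-numeric cell in data row ", bad, " of ", path)
  }
  tm <- vals[, 1]
  if (any(diff(tm) < 0)) {
    bad <- which(diff(tm) < 0)[1]
    stop("decreasing time column at data row ", bad + 1L, " of ", path)
  }
  state <- vals[, -1, drop = FALSE]
  colnames(state) <- header[-1]
  seed <- getmeta("seed")
  new_trace(tm, state,
            origin = getmeta("origin", "ssa"),
            seed = if (identical(seed, "NA") || is.na(seed)) NA_integer_
                   else as.integer(seed),
            horizon = as.numeric(getmeta("horizon", max(tm))))
}
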