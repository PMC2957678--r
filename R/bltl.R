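#' BLTL formula constructors
#'
#' Bounded Linear Temporal Logic formulas are finite trees over atomic
#' propositions `e1 ~ e2` (arithmetic expressions over species, compared with
#' `>=, <=, <, >, =`), boolean connectives, and the bounded until
#' `phi1 U^t phi2`.  The bounded eventually and globally operators are stored
#' as derived nodes: `F^t phi = true U^t phi` and `G^t phi = !F^t !phi`.
#'
#' @param lhs,rhs For `bltl_ap`: R language objects (or numbers) for the two
#'   arithmetic expressions; for the connectives: formula objects.
#' @param cmp Comparison operator, one of `">="`, `"<="`, `"<"`, `">"`, `"="`.
#' @param bound Temporal bound in minutes, strictly positive.
#' @param phi A formula object.
#' @return A `bltl_formula` object.
#' @seealso [parse_formula()], [check_formula()], [required_horizon()]
#' @name bltl_constructors
NULL

new_bltl <- function(x) structure(x, class = "bltl_formula")

#' @rdname bltl_constructors
#' @export
bltl_ap <- function(lhs, cmp, rhs) {
  cmp <- match.arg(cmp, c(">=", "<=", "<", ">", "=", "=="))
  if (cmp == "==") cmp <- "="
  new_bltl(list(kind = "ap", lhs = lhs, cmp = cmp, rhs = rhs))
}

#' @rdname bltl_constructors
#' @export
bltl_true <- function() new_bltl(list(kind = "true"))

#' @rdname bltl_constructors
#' @export
bltl_not <- function(phi) new_bltl(list(kind = "not", phi = phi))

#' @rdname bltl_constructors
#' @export
bltl_and <- function(lhs, rhs) new_bltl(list(kind = "and", lhs = lhs, rhs = rhs))

#' @rdname bltl_constructors
#' @export
bltl_or <- function(lhs, rhs) new_bltl(list(kind = "or", lhs = lhs, rhs = rhs))

#' @rdname bltl_constructors
#' @export
bltl_until <- function(bound, lhs, rhs) {
  if (!is.numeric(bound) || length(bound) != 1L || !is.finite(bound) || bound <= 0)
    stop("temporal bound must be a positive number")
  new_bltl(list(kind = "until", bound = as.numeric(bound), lhs = lhs, rhs = rhs))
}

#' @rdname bltl_constructors
#' @export
bltl_F <- function(bound, phi) {
  f <- bltl_until(bound, bltl_true(), phi)
  attr(f, "sugar") <- "F"
  f
}

#' @rdname bltl_constructors
#' @export
bltl_G <- function(bound, phi) {
  g <- bltl_not(bltl_F(bound, bltl_not(phi)))
  attr(g, "sugar") <- "G"
  attr(g, "sugar_bound") <- bound
  attr(g, "sugar_phi") <- phi
  g
}

#' Time horizon needed to decide a formula
#'
#' The nesting sum of temporal bounds: 0 for an atomic proposition, `h(phi)`
#' for negation, the maximum over branches for conjunction/disjunction, and
#' `t + max(h(phi1), h(phi2))` for `phi1 U^t phi2`.  A trace whose cumulative
#' sojourn is at least this value suffices to decide the formula.
#'
#' @param formula A `bltl_formula`.
#' @return Horizon in minutes.
#' @examples
#' required_horizon(parse_formula("F^400(G^900(p53 < 33000))"))  # 1300
#' @export
required_horizon <- function(formula) {
  stopifnot(inherits(formula, "bltl_formula"))
  switch(formula$kind,
         ap = 0, true = 0,
         not = required_horizon(formula$phi),
         and = ,
         or = max(required_horizon(formula$lhs), required_horizon(formula$rhs)),
         until = formula$bound + max(required_horizon(formula$lhs),
                                     required_horizon(formula$rhs)),
         stop("unknown node kind: ", formula$kind))
}

bltl_species <- function(formula) {
  switch(formula$kind,
         true = character(),
         ap = unique(c(all.vars(formula$lhs), all.vars(formula$rhs))),
         not = bltl_species(formula$phi),
         and = ,
         or = ,
         until = unique(c(bltl_species(formula$lhs), bltl_species(formula$rhs))))
}

#' @export
format.bltl_formula <- function(x, ...) {
  sugar <- attr(x, "sugar")
  if (identical(sugar, "G"))
    return(sprintf("G^%g(%s)", attr(x, "sugar_bound"),
                   format(attr(x, "sugar_phi"))))
  if (identical(sugar, "F"))
    return(sprintf("F^%g(%s)", x$bound, format(x$rhs)))
  dep <- function(e) {
    d <- deparse(e, width.cutoff = 500L)
    paste(d, collapse = "")
  }
  switch(x$kind,
         true = "true",
         ap = paste(dep(x$lhs), x$cmp, dep(x$rhs)),
         not = sprintf("!(%s)", format(x$phi)),
         and = sprintf("(%s & %s)", format(x$lhs), format(x$rhs)),
         or = sprintf("(%s | %s)", format(x$lhs), format(x$rhs)),
         until = sprintf("(%s U^%g %s)", format(x$lhs), x$bound, format(x$rhs)))
}

#' @export
print.bltl_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

## ---- parser -------------------------------------------------------------

bltl_tokenize <- function(text) {
  pats <- c(ws = "\\s+",
            num = "[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?|\\.[0-9]+([eE][+-]?[0-9]+)?",
            id = "[A-Za-z_][A-Za-z0-9_]*",
            op = "<=|>=|==|!=|[-+*/^()<>=&|!]")
  toks <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    hit <- NULL
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(paste0("^(", pats[[ty]], ")"), rest))
      if (length(m) == 1L && nzchar(m)) { hit <- list(type = ty, value = m); break }
    }
    if (is.null(hit))
      stop("syntax error at character ", pos, ": unexpected '",
           substr(text, pos, pos), "'")
    if (hit$type != "ws")
      toks[[length(toks) + 1L]] <- list(type = hit$type, value = hit$value,
                                        pos = pos)
    pos <- pos + nchar(hit$value)
  }
  toks
}

#' Parse a BLTL formula string
#'
#' Grammar (precedence low to high): disjunction `|`, conjunction `&`,
#' negation `!`, temporal operators.  Temporal operators carry their bound
#' after a caret: `F^t(phi)`, `G^t(phi)`, `phi U^t psi`.  Atomic propositions
#' compare two infix arithmetic expressions (`+ - * / ^`, parentheses,
#' species identifiers, numeric literals) with `>=, <=, <, >, =`.
#' Identifiers follow species naming, including `_a`/`_p` suffixes.
#' `parse_formula(format(f))` reproduces `f`.
#'
#' @param text Formula string, e.g.
#'   `"(CyclinE < 10) U^300 (RAS_a/(RAS_a+RAS) > 0.5)"`.
#' @return A `bltl_formula`.
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- bltl_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$i <- 1L
  peek <- function() if (st$i <= length(toks)) toks[[st$i]] else NULL
  advance <- function() { t <- toks[[st$i]]; st$i <- st$i + 1L; t }
  expect <- function(val) {
    t <- peek()
    if (is.null(t) || t$value != val)
      stop("syntax error at character ", if (is.null(t)) nchar(text) + 1L else t$pos,
           ": expected '", val, "'")
    advance()
  }
  at <- function(val) { t <- peek(); !is.null(t) && t$value == val }

  parse_bound <- function() {
    expect("^")
    t <- peek()
    if (is.null(t) || t$type != "num")
      stop("syntax error at character ",
           if (is.null(t)) nchar(text) + 1L else t$pos, ": expected a bound")
    advance()
    b <- as.numeric(t$value)
    if (!is.finite(b) || b <= 0)
      stop("temporal bound must be a positive number (got ", t$value, ")")
    b
  }

  ## arithmetic expressions -> R calls
  parse_atom <- function() {
    t <- peek()
    if (is.null(t)) stop("syntax error: unexpected end of input")
    if (t$value == "-") { advance(); return(call("-", parse_atom())) }
    if (t$type == "num") { advance(); return(as.numeric(t$value)) }
    if (t$type == "id") { advance(); return(as.name(t$value)) }
    if (t$value == "(") {
      advance()
      e <- parse_arith()
      expect(")")
      return(e)
    }
    stop("syntax error at character ", t$pos, ": unexpected '", t$value, "'")
  }
  parse_pow <- function() {
    base <- parse_atom()
    if (at("^")) { advance(); return(call("^", base, parse_pow())) }
    base
  }
  parse_term <- function() {
    e <- parse_pow()
    while (at("*") || at("/")) {
      op <- advance()$value
      e <- call(op, e, parse_pow())
    }
    e
  }
  parse_arith <- function() {
    e <- parse_term()
    while (at("+") || at("-")) {
      op <- advance()$value
      e <- call(op, e, parse_term())
    }
    e
  }
  try_ap <- function() {
    save <- st$i
    ap <- tryCatch({
      lhs <- parse_arith()
      t <- peek()
      if (is.null(t) || !(t$value %in% c(">=", "<=", "<", ">", "=", "==")))
        stop("not an atomic proposition")
      advance()
      rhs <- parse_arith()
      bltl_ap(lhs, t$value, rhs)
    }, error = function(e) NULL)
    if (is.null(ap)) st$i <- save
    ap
  }

  parse_primary <- function() {
    t <- peek()
    if (is.null(t)) stop("syntax error: unexpected end of input")
    if (t$type == "id" && t$value %in% c("F", "G") &&
        st$i < length(toks) && toks[[st$i + 1L]]$value == "^") {
      op <- advance()$value
      b <- parse_bound()
      expect("(")
      phi <- parse_or()
      expect(")")
      return(if (op == "F") bltl_F(b, phi) else bltl_G(b, phi))
    }
    if (t$type == "id" && t$value == "true" &&
        (st$i == length(toks) || toks[[st$i + 1L]]$type != "op" ||
         !(toks[[st$i + 1L]]$value %in% c("+", "-", "*", "/", "^", "<", ">",
                                          "<=", ">=", "=", "==")))) {
      advance()
      return(bltl_true())
    }
    ap <- try_ap()
    if (!is.null(ap)) return(ap)
    if (at("(")) {
      advance()
      phi <- parse_or()
      expect(")")
      return(phi)
    }
    stop("syntax error at character ", t$pos, ": unexpected '", t$value, "'")
  }
  parse_until <- function() {
    lhs <- parse_primary()
    t <- peek()
    if (!is.null(t) && t$type == "id" && t$value == "U") {
      advance()
      b <- parse_bound()
      rhs <- parse_until()
      return(bltl_until(b, lhs, rhs))
    }
    lhs
  }
  parse_not <- function() {
    if (at("!")) { advance(); return(bltl_not(parse_not())) }
    parse_until()
  }
  parse_and <- function() {
    e <- parse_not()
    while (at("&")) { advance(); e <- bltl_and(e, parse_not()) }
    e
  }
  parse_or <- function() {
    e <- parse_and()
    while (at("|")) { advance(); e <- bltl_or(e, parse_and()) }
    e
  }

  f <- parse_or()
  t <- peek()
  if (!is.null(t))
    stop("syntax error at character ", t$pos, ": unexpected trailing '",
         t$value, "'")
  f
}

## ---- checker ------------------------------------------------------------

# first index m >= k with b[m] TRUE, as numeric (Inf when none)
first_true_at_or_after <- function(b) {
  first_true_scan(b)
}

eval_ap <- function(node, state) {
  vars <- unique(c(all.vars(node$lhs), all.vars(node$rhs)))
  unknown <- setdiff(vars, colnames(state))
  if (length(unknown) > 0L)
    stop("unknown identifier(s) in formula: ", paste(unknown, collapse = ", "))
  env <- lapply(seq_len(ncol(state)), function(j) unname(state[, j]))
  names(env) <- colnames(state)
  l <- eval(node$lhs, env, baseenv())
  r <- eval(node$rhs, env, baseenv())
  n <- nrow(state)
  if (length(l) == 1L) l <- rep(l, n)
  if (length(r) == 1L) r <- rep(r, n)
  switch(node$cmp,
         ">=" = l >= r, "<=" = l <= r, "<" = l < r, ">" = l > r,
         "=" = l == r)
}

# logical satisfaction vector over all start indices of the trace
eval_formula_states <- function(formula, trace) {
  tm <- trace$time
  n <- length(tm)
  ev <- function(node) {
    switch(node$kind,
           true = rep(TRUE, n),
           ap = eval_ap(node, trace$state),
           not = !ev(node$phi),
           and = ev(node$lhs) & ev(node$rhs),
           or = ev(node$lhs) | ev(node$rhs),
           until = {
             v2 <- ev(node$rhs)
             # first phi2-state m0 >= k; the until holds iff phi1 is
             # unbroken before m0 and m0 is entered within the bound
             nt2 <- first_true_at_or_after(v2)
             ok <- is.finite(nt2)
             if (node$lhs$kind != "true")  # F^t has no phi1 obligation
               ok <- ok & nt2 <= first_true_at_or_after(!ev(node$lhs))
             # entry time of m0 (dummy index where none exists; masked by ok)
             ok & tm[pmin(nt2, n)] <= tm + node$bound
           },
           stop("unknown node kind: ", node$kind))
  }
  ev(formula)
}

#' Model-check a BLTL formula on a timed trace
#'
#' Implements the BLTL semantics literally on the piecewise-constant trace:
#' an atomic proposition is evaluated on the state `s_k`; `phi1 U^t phi2`
#' holds at step `k` iff some step `k+i` satisfies `phi2`, is entered within
#' cumulative sojourn `t` of step `k` (i.e. `sum_{l<i} t_{k+l} <= t`), and
#' `phi1` holds at all steps strictly before `k+i`.  ODE traces are checked on
#' their grid states; event-resolved SSA traces are checked exactly.
#'
#' The trace must be long enough: its horizon past the start state must reach
#' [required_horizon()] of the formula, otherwise an error is raised (never a
#' silent `FALSE`).
#'
#' @param formula A `bltl_formula` or a string for [parse_formula()].
#' @param trace A [new_trace()].
#' @param start Start state index (1-based), default 1.
#' @return `TRUE` or `FALSE`.
#' @examples
#' tr <- new_trace(c(0, 5), cbind(x = c(0, 8)), origin = "ssa", horizon = 910)
#' check_formula("F^10(x > 5)", tr)   # TRUE
#' check_formula("G^900(x < 10)", tr) # TRUE
#' @export
check_formula <- function(formula, trace, start = 1L) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "bltl_formula"), inherits(trace, "pathmc_trace"),
            start >= 1L, start <= length(trace$time))
  need <- required_horizon(formula)
  have <- trace$horizon - trace$time[start]
  if (have < need)
    stop("trace horizon insufficient: formula needs ", need,
         " min past the start state but only ", have, " are available")
  eval_formula_states(formula, trace)[start]
}
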