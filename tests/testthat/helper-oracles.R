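# Independent oracles used across the suite.

# Brute-force BLTL evaluation: literal recursion over the semantic clauses,
# quantifying explicitly over state indices.  Deliberately naive (quadratic),
# independent of the vectorised checker.
brute_check <- function(formula, trace, k = 1L) {
  tm <- trace$time
  n <- length(tm)
  st <- trace$state
  eval_ap_at <- function(node, i) {
    env <- as.list(st[i, ])
    l <- eval(node$lhs, env, baseenv())
    r <- eval(node$rhs, env, baseenv())
    switch(node$cmp, ">=" = l >= r, "<=" = l <= r, "<" = l < r, ">" = l > r,
           "=" = l == r)
  }
  rec <- function(node, k) {
    switch(node$kind,
           true = TRUE,
           ap = eval_ap_at(node, k),
           not = !rec(node$phi, k),
           and = rec(node$lhs, k) && rec(node$rhs, k),
           or = rec(node$lhs, k) || rec(node$rhs, k),
           until = {
             for (i in 0:(n - k)) {
               # (a) cumulative sojourn of states k .. k+i-1 within the bound
               elapsed <- if (i == 0) 0 else tm[k + i] - tm[k]
               if (elapsed > node$bound) break
               # (b) phi2 at step k+i
               if (rec(node$rhs, k + i)) {
                 # (c) phi1 at every step before
                 ok <- TRUE
                 for (j in seq_len(i)) {
                   if (!rec(node$lhs, k + j - 1L)) { ok <- FALSE; break }
                 }
                 if (ok) return(TRUE)
               }
             }
             FALSE
           })
  }
  rec(formula, k)
}

# Posterior odds by adaptive quadrature of the Beta density over the two
# hypothesis regions -- the numerical-integration oracle for the closed-form
# Bayes factor (1/F(theta) - 1 equals the upper/lower tail-mass ratio).
bayes_factor_oracle <- function(x, n, theta, alpha = 1, beta = 1,
                                p_h0 = 0.5, p_h1 = 0.5) {
  a <- x + alpha
  b <- n - x + beta
  kern <- function(t) t^(a - 1) * (1 - t)^(b - 1)
  # when a shape parameter is below 1 the kernel has an integrable endpoint
  # singularity; substituting v = t^a (resp. u = (1-t)^b) removes it, leaving
  # a smooth integrand.  The Beta-function normalisation cancels in the ratio.
  lower <- if (a < 1) {
    stats::integrate(function(v) (1 - v^(1 / a))^(b - 1) / a,
                     0, theta^a, rel.tol = 1e-11, abs.tol = 0)$value
  } else {
    stats::integrate(kern, 0, theta, rel.tol = 1e-11, abs.tol = 0)$value
  }
  upper <- if (b < 1) {
    stats::integrate(function(u) (1 - u^(1 / b))^(a - 1) / b,
                     0, (1 - theta)^b, rel.tol = 1e-11, abs.tol = 0)$value
  } else {
    stats::integrate(kern, theta, 1, rel.tol = 1e-11, abs.tol = 0)$value
  }
  (p_h1 / p_h0) * upper / lower
}
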