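test_that("the formula grammar parses the property shapes", {
  f <- parse_formula("F^100(p53 > 5.3*10^4)")
  expect_s3_class(f, "bltl_formula")
  expect_equal(f$kind, "until")
  expect_equal(f$bound, 100)
  expect_equal(f$lhs$kind, "true")
  expect_equal(f$rhs$kind, "ap")

  g <- parse_formula("(CyclinE < 10) U^300 (RAS_a/(RAS_a + RAS) > 0.5)")
  expect_equal(g$kind, "until")
  expect_equal(g$bound, 300)
  expect_equal(g$lhs$cmp, "<")

  h <- parse_formula("F^400(G^900(p53 < 33000))")
  expect_equal(required_horizon(h), 1300)

  # parse/print round trip
  for (txt in c("F^100(p53 > 5.3*10^4)",
                "(CyclinE < 10) U^300 (RAS_a/(RAS_a + RAS) > 0.5)",
                "F^100(p53/10000 >= 5 & F^100(p53/10000 <= 0.4))",
                "!(x < 2) | G^50(y >= 1)")) {
    f1 <- parse_formula(txt)
    expect_equal(format(parse_formula(format(f1))), format(f1))
  }

  expect_error(parse_formula("G^0(x<1)"), "positive")
  expect_error(parse_formula("F^10(x <)"), "syntax error")
  expect_error(parse_formula("x > 1 ;"), "character 7")
})

test_that("required_horizon follows the nesting recursion", {
  expect_equal(required_horizon(parse_formula("x > 1")), 0)
  expect_equal(required_horizon(parse_formula("F^100(x>1 & F^100(x>2))")), 200)
  expect_equal(required_horizon(parse_formula("(x>1) U^50 (y>1)")), 50)
  expect_equal(required_horizon(parse_formula("G^30(F^20(x>1))")), 50)
})

test_that("until obeys the cumulative-sojourn clause", {
  # (s0, t0=5), (s1, t1=900): phi1 true only at s0, phi2 only at s1
  tr <- new_trace(c(0, 5), cbind(a = c(1, 0), b = c(0, 1)), origin = "ssa",
                  horizon = 905)
  expect_false(check_formula("(a > 0) U^4 (b > 0)", tr))
  expect_true(check_formula("(a > 0) U^5 (b > 0)", tr))
  # phi2 at the start state satisfies any until immediately
  tr2 <- new_trace(c(0, 5), cbind(a = c(0, 0), b = c(1, 0)), origin = "ssa",
                   horizon = 100)
  expect_true(check_formula("(a > 0) U^1 (b > 0)", tr2))
})

test_that("constant traces decide G trivially and horizons are enforced", {
  tr <- new_trace(c(0, 10, 20), cbind(x = c(5, 5, 5)), origin = "ssa",
                  horizon = 60)
  expect_true(check_formula("G^50(x < 10)", tr))
  expect_error(check_formula("G^70(x < 10)", tr), "horizon insufficient")
  expect_error(check_formula("G^50(nope < 10)", tr), "unknown identifier")
})

test_that("checker agrees with the brute-force oracle on fuzzed cases", {
  set.seed(4242)
  species <- c("x", "y")
  n_agree <- 0L
  for (i in 1:1000) {
    f <- random_formula(depth = sample(0:4, 1), species = species,
                        bound_range = c(1, 100))
    tr <- random_trace(length = sample(1:30, 1), species = species)
    # keep the trace long enough to decide the formula
    need <- required_horizon(f)
    if (tr$horizon < need)
      tr <- new_trace(tr$time, tr$state, origin = tr$origin, horizon = need)
    expect_identical(check_formula(f, tr), brute_check(f, tr))
    n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 1000L)
})

test_that("G/F duality and F-monotonicity hold on random traces", {
  set.seed(99)
  for (i in 1:60) {
    tr <- random_trace(length = sample(2:25, 1), species = "x")
    tr <- new_trace(tr$time, tr$state, origin = tr$origin,
                    horizon = max(tr$horizon, 400))
    thr <- sample(0:20, 1)
    phi <- sprintf("x > %d", thr)
    for (t in c(10, 50, 150)) {
      expect_identical(
        check_formula(sprintf("G^%d(%s)", t, phi), tr),
        !check_formula(sprintf("F^%d(!(%s))", t, phi), tr))
    }
    # monotonicity: F^t phi implies F^t' phi for t' >= t
    res <- vapply(c(10, 50, 150, 350), function(t)
      check_formula(sprintf("F^%d(%s)", t, phi), tr), logical(1))
    expect_true(all(diff(res) >= 0))
  }
})

test_that("checking is insensitive to splitting states", {
  set.seed(7)
  for (i in 1:25) {
    tr <- random_trace(length = 12, species = "x")
    tr <- new_trace(tr$time, tr$state, origin = tr$origin,
                    horizon = max(tr$horizon, 200))
    # split state 5 into two identical states whose sojourns sum
    tsplit <- tr$time[5] + diff(tr$time[5:6]) / 2
    tm2 <- append(tr$time, tsplit, after = 5)
    st2 <- tr$state[c(1:5, 5, 6:12), , drop = FALSE]
    tr2 <- new_trace(tm2, st2, origin = tr$origin, horizon = tr$horizon)
    f <- random_formula(depth = 3, species = "x", bound_range = c(1, 80))
    expect_identical(check_formula(f, tr), check_formula(f, tr2))
  }
})
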