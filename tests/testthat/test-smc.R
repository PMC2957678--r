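test_that("bayes_factor matches hand-derived values and the quadrature oracle", {
  spec <- hypothesis_test_spec(theta = 0.9)
  expect_equal(bayes_factor(0, 0, spec), 1 / 0.9 - 1)
  spec5 <- hypothesis_test_spec(theta = 0.5)
  expect_equal(bayes_factor(0, 1, spec5), 1 / 3)   # F_(1,2)(0.5) = 0.75
  # 65 consecutive successes at theta = 0.9: F_(66,1)(0.9) = 0.9^66
  expect_equal(bayes_factor(65, 65, spec), 1 / 0.9^66 - 1)
  expect_gt(bayes_factor(65, 65, spec), 1000)

  # quadrature oracle across a parameter grid
  for (theta in c(0.1, 0.5, 0.9)) {
    for (ab in list(c(0.5, 0.5), c(1, 1), c(2, 2), c(2, 0.5))) {
      for (n in c(0, 3, 17, 50)) {
        for (x in unique(c(0, n %/% 2, n))) {
          sp <- hypothesis_test_spec(theta = theta, alpha = ab[1], beta = ab[2])
          expect_equal(bayes_factor(x, n, sp),
                       bayes_factor_oracle(x, n, theta, ab[1], ab[2]),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("bayes_factor is monotone in successes and in theta", {
  spec <- hypothesis_test_spec(theta = 0.7)
  b <- bayes_factor(0:20, rep(20, 21), spec)
  expect_true(all(diff(b) > 0))
  bt <- vapply(seq(0.1, 0.9, 0.1), function(th)
    bayes_factor(12, 20, hypothesis_test_spec(theta = th)), numeric(1))
  expect_true(all(diff(bt) < 0))
})

test_that("error_bound is 1/T", {
  expect_equal(error_bound(hypothesis_test_spec(T = 1000)), 1e-3)
  expect_equal(error_bound(2), 0.5)
  expect_equal(error_bound(1e6), 1e-6)
})

test_that("sequential test stops at the derived closed-form counts", {
  spec <- hypothesis_test_spec(theta = 0.9, T = 1000)
  acc <- smc_decide(rep(1, 200), spec)
  expect_equal(acc$verdict, "accept_h0")
  expect_equal(acc$n, 65L)          # smallest n with 0.9^(n+1) < 1/1001
  expect_equal(acc$x, 65L)
  expect_gt(acc$final_bayes_factor, 1000)

  rej <- smc_decide(rep(0, 200), spec)
  expect_equal(rej$verdict, "reject_h0")
  expect_equal(rej$n, 3L)           # smallest n with 1/(1-0.1^(n+1)) - 1 < 1e-3
  expect_lt(rej$final_bayes_factor, 1e-3)

  # function samplers give identical decisions to the pre-drawn path
  s1 <- bernoulli_sampler(1, seed = 1)
  expect_equal(smc_decide(s1, spec)$n, 65L)
  und <- smc_decide(rep(1, 30), spec)   # B(30,30) ~ 26, inside (1/T, T)
  expect_equal(und$verdict, "undecided")
})

test_that("verify_property composes SSA sampling with the checker, replayably", {
  net <- toy_network("birth_death", A0 = 0, k = 50, d = 0.1)
  spec <- hypothesis_test_spec(theta = 0.9, T = 100)
  # tautology over valid traces: counts are non-negative
  r <- verify_property(net, "G^10(A >= 0)", spec, base_seed = 5)
  expect_equal(r$verdict, "accept_h0")
  expect_equal(r$x, r$n)
  expect_equal(r$seeds, 5L + seq_len(r$n) - 1L)
  # replay
  r2 <- verify_property(net, "G^10(A >= 0)", spec, base_seed = 5)
  expect_identical(r$sample_log, r2$sample_log)
  expect_identical(r$final_bayes_factor, r2$final_bayes_factor)
  # an impossible property is rejected quickly
  r3 <- verify_property(net, "F^5(A > 1e6)", spec, base_seed = 5)
  expect_equal(r3$verdict, "reject_h0")
  expect_error(verify_property(net, "F^5(FOO > 1)", spec, 1), "absent from")
})

test_that("bernoulli sampler frequencies converge to p", {
  s <- bernoulli_sampler(0.9, seed = 31)
  draws <- vapply(1:10000, function(i) s(), numeric(1))
  expect_lt(abs(mean(draws) - 0.9), 3 * sqrt(0.9 * 0.1 / 10000))
  expect_true(all(bernoulli_sampler(1, 1)() == 1))
  expect_true(all(bernoulli_sampler(0, 1)() == 0))
  # reproducible stream
  a <- bernoulli_sampler(0.5, seed = 8)
  b <- bernoulli_sampler(0.5, seed = 8)
  expect_equal(vapply(1:50, function(i) a(), numeric(1)),
               vapply(1:50, function(i) b(), numeric(1)))
})
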