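test_that("ODE engine matches closed forms on the decay network", {
  net <- toy_network("decay", A0 = 1000, d = 0.01)
  tr <- simulate_ode(net, t_end = 100, grid_dt = 1)
  expect_equal(as.numeric(tr$state[101, "A"]), 1000 * exp(-1),
               tolerance = 1e-5)
  # invariance under halving tolerances and grid
  tr2 <- simulate_ode(net, 100, grid_dt = 0.5, rtol = 5e-7, atol = 5e-4)
  expect_equal(as.numeric(tr2$state[201, "A"]),
               as.numeric(tr$state[101, "A"]), tolerance = 1e-4)
})

test_that("SSA is exact on the decay ensemble and deterministic under seed", {
  net <- toy_network("decay", A0 = 1000, d = 0.01)
  finals <- vapply(1:1000, function(s) {
    tr <- simulate_ssa(net, t_end = 100, seed = s)
    tr$state[nrow(tr$state), "A"]
  }, numeric(1))
  # count at t is Binomial(A0, e^-1): mean 367.88, sd 15.25
  p <- exp(-1)
  se <- sqrt(1000 * p * (1 - p)) / sqrt(1000)
  expect_lt(abs(mean(finals) - 1000 * p), 3 * se)

  t1 <- simulate_ssa(net, 100, seed = 7)
  t2 <- simulate_ssa(net, 100, seed = 7)
  expect_identical(t1$time, t2$time)
  expect_identical(t1$state, t2$state)
  t3 <- simulate_ssa(net, 100, seed = 8)
  expect_false(identical(t1$time, t3$time))
})

test_that("birth-death SSA reaches the k/d stationary mean", {
  net <- toy_network("birth_death", A0 = 0, k = 50, d = 0.1)
  # stationary distribution is Poisson(500); sample the ensemble at t = 80
  finals <- vapply(1:400, function(s) {
    tr <- simulate_ssa(net, t_end = 80, seed = 1000 + s, grid_dt = 80)
    tr$state[nrow(tr$state), "A"]
  }, numeric(1))
  expect_lt(abs(mean(finals) - 500), 3 * sqrt(500) / sqrt(400))
})

test_that("SSA ensemble mean tracks the ODE for a linear network", {
  net <- toy_network("two_state_switch", A0 = 200, B0 = 0, kon = 0.1,
                     koff = 0.05)
  ode <- simulate_ode(net, 50, grid_dt = 5)
  runs <- vapply(1:1000, function(s)
    simulate_ssa(net, 50, seed = 2000 + s, grid_dt = 5)$state[, "B"],
    numeric(11))
  m <- rowMeans(runs)
  se <- apply(runs, 1, sd) / sqrt(1000)
  for (i in 2:11)
    expect_lt(abs(m[i] - ode$state[i, "B"]), 3 * se[i] + 1e-9)
})

test_that("absorbing states terminate the trace with an extended sojourn", {
  net <- toy_network("dimerization", A0 = 5, B0 = 0, k = 10)
  tr <- simulate_ssa(net, t_end = 50, seed = 1)
  expect_equal(as.numeric(tr$state[nrow(tr$state), "A"]), 1)  # one monomer cannot pair
  expect_equal(tr$horizon, 50)
  expect_equal(sum(sojourns(tr)), 50)
  # A + 2B conserved throughout
  expect_true(all(tr$state[, "A"] + 2 * tr$state[, "B"] == 5))

  # no reactions possible at all -> single state spanning the horizon
  empty <- reaction_network(list(species_def("A", 0)),
                            list(reaction("r", "A", character(), mass_action(1))))
  tr0 <- simulate_ssa(empty, t_end = 30, seed = 1)
  expect_equal(nrow(tr0$state), 1L)
  expect_equal(sojourns(tr0), 30)
})

test_that("SSA rejects non-integer initial counts", {
  bad <- reaction_network(list(species_def("A", 10.5)),
                          list(reaction("r", "A", character(), mass_action(1))))
  expect_error(simulate_ssa(bad, 10, seed = 1), "integer")
})

test_that("conservation holds exactly in SSA and to tolerance in the ODE", {
  net <- hmgb1_network()
  tr <- simulate_ssa(net, t_end = 20, seed = 3)  # event-resolved, all species
  for (cs in net$conservation) {
    tot <- rowSums(tr$state[, cs$members, drop = FALSE])
    expect_true(all(tot == cs$total))
  }
  ode <- simulate_ode(net, t_end = 1200, grid_dt = 5)
  for (cs in net$conservation) {
    tot <- rowSums(ode$state[, cs$members, drop = FALSE])
    expect_lt(max(abs(tot - cs$total)) / cs$total, 1e-6)
  }
})

test_that("species never go negative in either engine", {
  net <- hmgb1_network()
  tr <- simulate_ssa(net, t_end = 15, seed = 11)
  expect_true(all(tr$state >= 0))
  ode <- simulate_ode(net, t_end = 600, grid_dt = 2)
  expect_true(all(ode$state >= 0))
})

test_that("restricted recording merges unobserved jumps without changing times", {
  net <- toy_network("two_state_switch", A0 = 50, B0 = 0)
  full <- simulate_ssa(net, 20, seed = 5)
  onlyA <- simulate_ssa(net, 20, seed = 5, record = "A")
  # A changes at every event here, so the records agree
  expect_equal(onlyA$state[, "A"], full$state[, "A"])
  expect_equal(onlyA$time, full$time)
  expect_error(simulate_ssa(net, 10, seed = 1, record = "Z"), "unknown species")
})
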