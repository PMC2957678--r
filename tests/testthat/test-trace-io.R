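test_that("trace TSV round-trips states, sojourns, origin and seed", {
  net <- toy_network("birth_death", A0 = 10, k = 5, d = 0.1)
  tr <- simulate_ssa(net, t_end = 20, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$time, tr$time)
  expect_equal(back$state, tr$state)
  expect_equal(back$origin, "ssa")
  expect_equal(back$seed, 9L)
  expect_equal(back$horizon, tr$horizon)
  expect_equal(sojourns(back), sojourns(tr))
})

test_that("trace parsing rejects malformed files with located errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time\tA", "0\t5", "2\t4", "1\t3"), path)
  expect_error(read_trace(path), "decreasing time.*row 3")
  writeLines(c("time\tA", "0\t5", "1"), path)
  expect_error(read_trace(path), "ragged row")
  writeLines(c("time\tA", "0\t5", "1\tfoo"), path)
  expect_error(read_trace(path), "non-numeric")
  writeLines(character(), path)
  expect_error(read_trace(path), "empty")
})

test_that("trace_at does piecewise-constant lookup", {
  tr <- new_trace(c(0, 5, 12), cbind(x = c(1, 7, 2)), origin = "ssa",
                  horizon = 20)
  expect_equal(as.numeric(trace_at(tr, c(0, 4.9, 5, 11, 12, 20), "x")),
               c(1, 1, 7, 7, 2, 2))
  expect_error(trace_at(tr, 25), "must lie within")
})

test_that("network config round-trips through YAML", {
  net <- hmgb1_network()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_network(net, path, header = "test copy")
  back <- load_network(path)
  expect_equal(back$species_names, net$species_names)
  expect_equal(back$init, net$init)
  expect_equal(back$stoich, net$stoich)
  expect_equal(back$parameters, net$parameters)
  expect_equal(vapply(back$reactions, format, character(1)),
               vapply(net$reactions, format, character(1)))
  expect_length(back$conservation, 8)

  # a toy with a homodimer coefficient survives too
  dimer <- toy_network("dimerization", A0 = 100, k = 0.5)
  save_network(dimer, path)
  back2 <- load_network(path)
  expect_equal(back2$reactions[[1]]$reactants, c(A = 2L))
})

test_that("configs referencing undeclared species fail validation", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("species:",
               "- name: A",
               "  initial: 1",
               "reactions:",
               "  r1: A -> FOO @ mass_action(k=1)"), path)
  expect_error(load_network(path), "undeclared species")
  writeLines(c("species: []", "reactions:",
               "  r1: A -> 0 @ mass_action(k=1)"), path)
  expect_error(load_network(path))
  writeLines(c("species:", "- name: A", "  initial: 1"), path)
  expect_error(load_network(path), "reactions")
})

test_that("the shipped config loads into the default network", {
  path <- system.file("extdata", "hmgb1_network.yaml", package = "pathmc")
  net <- load_network(path)
  ref <- hmgb1_network()
  expect_equal(net$init, ref$init)
  expect_equal(net$stoich, ref$stoich)
})

test_that("the command-line wrapper simulates and checks a trace", {
  script <- system.file("scripts", "pathmc.R", package = "pathmc")
  cfg <- system.file("extdata", "hmgb1_network.yaml", package = "pathmc")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  out1 <- system2("Rscript", c(script, "simulate", "--engine", "ssa",
                               "--model", cfg, "--t-end", "25", "--seed", "4",
                               "--grid-dt", "1", "--out", tsv),
                  stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(tsv))
  out2 <- system2("Rscript", c(script, "check", "--trace", tsv,
                               "--formula", shQuote("G^20(p53 >= 0)")),
                  stdout = TRUE, stderr = TRUE)
  expect_match(tail(out2, 1), "true")
})
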