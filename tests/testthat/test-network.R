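test_that("rate laws evaluate by mass action and Hill kinetics", {
  r <- reaction("bind", c("A", "B"), "C", mass_action(0.1))
  expect_equal(reaction_rate(r, c(A = 10, B = 5, C = 0)), 5.0)

  # half-saturation point of the Hill law
  h <- reaction("syn", character(), "X", hill(1, 100, 2, "R"))
  expect_equal(reaction_rate(h, c(R = 100, X = 0)), 0.5)
  expect_equal(reaction_rate(h, c(R = 200, X = 0)), 200^2 / (100^2 + 200^2))

  # homodimer counting: c(c-1)/2 stochastic, c^2/2 deterministic
  d <- reaction("dim", c("A", "A"), "B", mass_action(2))
  expect_equal(reaction_rate(d, c(A = 10, B = 0), "stochastic"), 2 * 45)
  expect_equal(reaction_rate(d, c(A = 10, B = 0), "deterministic"), 2 * 50)

  expect_error(reaction_rate(r, c(A = -1, B = 5)), "negative")
  expect_error(reaction_rate(r, c(A = 1)), "does not define")
})

test_that("hill rates are bounded and monotone in the regulator", {
  h <- reaction("syn", character(), "X", hill(3, 250, 4, "R", basal = 0.2))
  rates <- vapply(c(0, 10, 100, 250, 1000, 1e5), function(R)
    reaction_rate(h, c(R = R, X = 0)), numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_true(all(rates >= 0.2 & rates < 3.2))
  expect_equal(rates[4], 0.2 + 1.5)
})

test_that("network validation catches broken cross-references", {
  sp <- list(species_def("A", 10), species_def("B", 0))
  expect_error(
    reaction_network(sp, list(reaction("r", "A", "FOO", mass_action(1)))),
    "undeclared species")
  expect_error(
    reaction_network(list(species_def("A", 1), species_def("A", 2)),
                     list(reaction("r", "A", character(), mass_action(1)))),
    "duplicate")
  # conservation violated by stoichiometry is detected statically
  expect_error(
    reaction_network(sp, list(reaction("r", "A", character(), mass_action(1))),
                     list(conservation(c("A", "B"), 10))),
    "violated by reaction")
  # conservation total must match initial counts
  expect_error(
    reaction_network(sp, list(reaction("r", "A", "B", mass_action(1))),
                     list(conservation(c("A", "B"), 99))),
    "initial counts")
})

test_that("the HMGB1 network has the published structure", {
  net <- hmgb1_network()
  expect_length(net$species, 31)
  expect_length(net$reactions, 59)
  expect_length(net$conservation, 8)
  expect_equal(n_free_variables(net), 23)

  # Table of initial values
  init <- net$init
  expect_equal(unname(init[c("RAGE", "PI3K", "PIP2", "AKT", "MDM2", "MDM2_p",
                             "p53", "RAS", "RAF", "MEK", "ERK", "RE")]),
               c(1e3, 1e5, 1e5, 1e5, 1e4, 2e4, 2e4, 1e4, 1e4, 1e4, 1e4, 1e5))
  expect_equal(unname(init["HMGB1"]), 1e3)
  # unlisted species start at zero
  expect_equal(unname(init[c("PTEN", "CyclinD", "CyclinE", "E2F", "Myc",
                             "ARF", "P21", "INK4A", "mdm2", "Rb")]),
               rep(0, 10))

  # exactly six Hill-law reactions: the transcription-driven syntheses
  hills <- Filter(function(r) r$rate$kind == "hill", net$reactions)
  expect_length(hills, 6)
  expect_setequal(vapply(hills, `[[`, character(1), "label"),
                  c("PTEN_syn", "mdm2_transcription", "CD_syn", "Myc_syn",
                    "E2F_syn", "CE_syn"))

  # conserved pairs
  pairs <- lapply(net$conservation, `[[`, "members")
  expect_setequal(vapply(pairs, paste, character(1), collapse = "+"),
                  c("RAGE+RAGE_a", "PI3K+PI3K_a", "PIP2+PIP3", "AKT+AKT_p",
                    "RAS+RAS_a", "RAF+RAF_a", "MEK+MEK_p", "ERK+ERK_p"))
})

test_that("the HMGB1 builder honours dose, overrides and completeness", {
  net <- hmgb1_network(hmgb1_init = 1e5)
  expect_equal(unname(net$init["HMGB1"]), 1e5)
  net2 <- hmgb1_network(init = c(AKT = 3e5))
  akt <- Filter(function(cs) "AKT" %in% cs$members, net2$conservation)[[1]]
  expect_equal(akt$total, 3e5)
  expect_error(hmgb1_network(params = hmgb1_params()[-1]), "missing parameter")
  expect_error(hmgb1_params(not_a_knob = 1), "unknown parameter")
  expect_error(hmgb1_network(init = c(FOO = 1)), "unknown species")
})
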