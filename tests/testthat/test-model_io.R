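test_that("network validation errors name the offending entity", {
  mets <- tibble::tibble(id = c("X0", "M"), balanced = c(FALSE, TRUE))
  enz <- tibble::tibble(id = "E1", subunits = 1L)
  # undeclared metabolite in a reaction
  expect_error(
    kin_network(mets, enz, tibble::tibble(
      id = "r1", mechanism = "irreversible_modular", enzyme = "E1",
      stoichiometry = list(c(X = -1, M = 1)))),
    "'X'")
  # drain with an enzyme
  expect_error(
    kin_network(mets, enz, tibble::tibble(
      id = "r1", mechanism = "drain", enzyme = "E1",
      stoichiometry = list(c(M = 1)))),
    "r1")
  # regulation of an undeclared enzyme
  expect_error(
    kin_network(mets, enz,
      tibble::tibble(id = "r1", mechanism = "irreversible_modular",
                     enzyme = "E1", stoichiometry = list(c(X0 = -1, M = 1))),
      tibble::tibble(type = "competitive_inhibition", enzyme = "EZ",
                     effector = "M")),
    "'EZ'")
  # fully balanced network without drains has only the trivial steady state
  expect_error(
    kin_network(tibble::tibble(id = c("A", "B"), balanced = c(TRUE, TRUE)),
                enz,
                tibble::tibble(id = "r1", mechanism = "irreversible_modular",
                               enzyme = "E1",
                               stoichiometry = list(c(A = -1, B = 1)))),
    "trivial")
})

test_that("a conserved moiety triggers a rank-deficiency warning, not an error", {
  mets <- tibble::tibble(id = c("A", "B"), balanced = c(TRUE, TRUE))
  enz <- tibble::tibble(id = "E1", subunits = 1L)
  # A <-> B interconversion conserves A + B: balanced rows are dependent
  expect_warning(
    kin_network(mets, enz, tibble::tibble(
      id = c("r1", "r2"),
      mechanism = c("irreversible_modular", "drain"),
      enzyme = c("E1", NA),
      stoichiometry = list(c(A = -1, B = 1), c(B = -1, A = 1)))),
    "rank deficient")
})

test_that("stoichiometric matrix reproduces declared coefficients exactly", {
  st <- ac3_study()
  S <- stoich_matrix(st$model$network)
  expect_identical(S["X0", "r1"], -1)
  expect_identical(S["A", "r1"], 1)
  expect_identical(S["B", "r3"], -1)
  # half coefficients survive exactly as rationals
  net <- kin_network(
    tibble::tibble(id = c("A", "B"), balanced = c(FALSE, FALSE)),
    tibble::tibble(id = "E1", subunits = 1L),
    tibble::tibble(id = "r1", mechanism = "irreversible_modular",
                   enzyme = "E1", stoichiometry = list(c(A = -1, B = "1/2"))))
  Sr <- stoich_matrix(net, rational = TRUE)
  expect_identical(Sr$num["B", "r1"], 1)
  expect_identical(Sr$den["B", "r1"], 2)
})

test_that("free-flux accounting warns on over- and dependent measurement sets", {
  st <- lc2_study()
  net <- st$model$network  # chain X0 -> M -> X1, only M balanced: f = 1
  # two flux measurements in one experiment exceed the single free flux
  ms <- kin_measurements(c("e1", "e1"), c("flux", "flux"), c("r1", "r2"),
                        c(1, 1), c(0.1, 0.1))
  w <- validate_free_fluxes(net, ms)
  expect_length(w, 1)
  expect_match(w, "double counted")
  # a single measured flux is fine
  expect_length(validate_free_fluxes(net, ms[1, ]), 0)
  # with zero balanced metabolites every flux is free
  net2 <- kin_network(
    tibble::tibble(id = c("S", "P"), balanced = c(FALSE, FALSE)),
    tibble::tibble(id = "E1", subunits = 1L),
    tibble::tibble(id = "r1", mechanism = "irreversible_modular",
                   enzyme = "E1", stoichiometry = list(c(S = -1, P = 1))))
  ms2 <- kin_measurements("e1", "flux", "r1", 1, 0.1)
  expect_length(validate_free_fluxes(net2, ms2), 0)
})

test_that("parse_input/write_input round-trip an entire model directory", {
  st <- ac3_study()
  d1 <- withr::local_tempdir()
  write_input(st$model, d1)
  m2 <- parse_input(d1)
  expect_equal(m2$network$metabolites, st$model$network$metabolites)
  expect_equal(m2$network$reactions$stoichiometry,
               st$model$network$reactions$stoichiometry)
  expect_equal(m2$network$regulations, st$model$network$regulations)
  expect_equal(m2$params, st$model$params)
  expect_equal(m2$priors$formation_energy$covariance,
               st$model$priors$formation_energy$covariance)
  expect_equal(as.data.frame(m2$measurements),
               as.data.frame(st$model$measurements))
  expect_equal(unclass(m2$solver), unclass(st$model$solver))
  expect_equal(unclass(m2$sampler), unclass(st$model$sampler))
  # a second round trip is byte-identical
  d2 <- withr::local_tempdir()
  write_input(m2, d2)
  for (f in c("model.toml", "priors.toml", "experiments.toml", "config.toml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("parse_input reports missing files and dangling references", {
  d <- withr::local_tempdir()
  expect_error(parse_input(d), "model.toml")
  st <- lc2_study()
  write_input(st$model, d)
  # corrupt a prior target
  pr <- readLines(file.path(d, "priors.toml"))
  pr <- sub('enzyme = "E2"', 'enzyme = "EZZ"', pr)
  writeLines(pr, file.path(d, "priors.toml"))
  expect_error(parse_input(d), "EZZ|E2")
})

test_that("structured draws JSON round-trips every group", {
  m <- gauss_model(sampler_config(n_chains = 2, n_warmup = 50, n_draws = 5,
                                  seed = 3))
  dr <- sample_posterior(m)
  expect_equal(dim(dr$theta)[1:2], c(2L, 5L))
  path <- withr::local_tempfile(fileext = ".json")
  write_draws(dr, path)
  g <- read_draws(path)
  expect_setequal(names(g), c("posterior", "posterior_predictive",
                              "log_likelihood", "sample_stats", "derived"))
  orig <- kinfer:::as_draws_groups(dr)
  for (grp in names(orig)) {
    for (v in names(orig[[grp]])) {
      expect_identical(unname(g[[grp]][[v]]), unname(orig[[grp]][[v]]),
                       info = paste(grp, v))
    }
  }
  # divergence and R-hat inputs survive the round trip
  expect_identical(g$sample_stats$divergent, orig$sample_stats$divergent)
  # empty sample_stats is rejected
  bad <- dr
  bad$sample_stats <- list()
  expect_error(write_draws(bad, path), "sample_stats")
})
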