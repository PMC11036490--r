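test_that("standard reaction Gibbs energy is the stoichiometry-weighted sum", {
  net <- kin_network(
    tibble::tibble(id = c("A", "B"), balanced = c(FALSE, FALSE)),
    tibble::tibble(id = "E1", subunits = 1L),
    tibble::tibble(id = c("r1", "r2", "rd"),
                   mechanism = c("reversible_modular", "reversible_modular",
                                 "drain"),
                   enzyme = c("E1", "E1", NA),
                   stoichiometry = list(c(A = -1, B = 1), c(A = -2, B = 1),
                                        c(A = 1))))
  expect_equal(reaction_delta_g_standard(net, "r1", c(A = -7, B = -7)), 0)
  expect_equal(reaction_delta_g_standard(net, "r1", c(A = -10, B = -15)), -5)
  expect_equal(reaction_delta_g_standard(net, "r2", c(A = -3, B = -10)), -4)
  expect_error(reaction_delta_g_standard(net, "rd", c(A = 0, B = 0)), "drain")
  expect_error(reaction_delta_g_standard(net, "r1", c(A = -1)), "'B'")
})

test_that("reversibility factor is 1 - Q/Keq with the right limits", {
  RT <- 0.008314 * 298.15
  # equilibrium: Q = Keq for several Keq values
  for (keq in c(0.1, 1, 10)) {
    dg <- -RT * log(keq)
    expect_equal(reversibility(dg, Q = keq), 0, tolerance = 1e-12)
  }
  # closed form on a grid
  for (keq in c(0.5, 2, 10)) {
    for (Q in c(0.1, 1, 5)) {
      expect_equal(reversibility(-RT * log(keq), Q), 1 - Q / keq,
                   tolerance = 1e-12)
    }
  }
  expect_equal(reversibility(-RT * log(10), 1), 0.9, tolerance = 1e-12)
  # strongly exergonic limit approaches 1
  expect_equal(reversibility(-500, 1), 1, tolerance = 1e-10)
  expect_identical(reversibility(5, 1, irreversible = TRUE), 1)
  expect_error(reversibility(0, -1), "positive")
})

test_that("saturation follows the common modular denominator", {
  net <- kin_network(
    tibble::tibble(id = c("S", "P", "I"), balanced = c(FALSE, FALSE, FALSE)),
    tibble::tibble(id = c("Er", "Ei"), subunits = c(1L, 1L)),
    tibble::tibble(id = c("rr", "ri"),
                   mechanism = c("reversible_modular", "irreversible_modular"),
                   enzyme = c("Er", "Ei"),
                   stoichiometry = list(c(S = -1, P = 1), c(S = -1, P = 1))),
    tibble::tibble(type = "competitive_inhibition", enzyme = "Ei",
                   effector = "I"))
  km <- c(S = 1, P = 1)
  # single substrate at C = Km, no products in the denominator: 1/2
  s <- saturation(net, "ri", c(S = 1, P = 9, I = 1e-9), km, ki = c(I = 1e9))
  expect_equal(s$saturation, 0.5, tolerance = 1e-9)
  # reversible, substrate x = 2, product x = 1: 2 / ((1+2) + (1+1) - 1) = 0.5
  s <- saturation(net, "rr", c(S = 2, P = 1), km)
  expect_equal(s$saturation, 2 / 4)
  expect_equal(s$free_enzyme_ratio, 1 / 4)
  # saturation limit
  s <- saturation(net, "rr", c(S = 1e9, P = 1), km)
  expect_gt(s$saturation, 0.999999)
  # competitive inhibitor enters the denominator additively
  s0 <- saturation(net, "ri", c(S = 1, P = 1, I = 0.5), km, ki = c(I = 0.5))
  expect_equal(s0$saturation, 1 / (2 + 1))
  # missing Km is a configuration error naming the pair
  expect_error(saturation(net, "rr", c(S = 1, P = 1), c(S = 1)), "Er, P")
})

test_that("saturation is monotone in substrates and competitive inhibitors", {
  net <- kin_network(
    tibble::tibble(id = c("S", "P", "I"), balanced = rep(FALSE, 3)),
    tibble::tibble(id = "E1", subunits = 1L),
    tibble::tibble(id = "r1", mechanism = "reversible_modular", enzyme = "E1",
                   stoichiometry = list(c(S = -1, P = 1))),
    tibble::tibble(type = "competitive_inhibition", enzyme = "E1",
                   effector = "I"))
  km <- c(S = 0.8, P = 1.2)
  ki <- c(I = 0.6)
  s_grid <- c(0.1, 0.5, 1, 3, 10)
  sat_s <- vapply(s_grid, function(S)
    saturation(net, "r1", c(S = S, P = 1, I = 1), km, ki)$saturation, numeric(1))
  expect_true(all(diff(sat_s) > 0))
  expect_true(all(sat_s > 0 & sat_s < 1))
  sat_i <- vapply(s_grid, function(I)
    saturation(net, "r1", c(S = 1, P = 1, I = I), km, ki)$saturation, numeric(1))
  expect_true(all(diff(sat_i) < 0))
})

test_that("generalized MWC allostery matches direct evaluation", {
  expect_equal(allostery(0, 0.3, inhibitors = 5), 1)
  expect_equal(allostery(1, 0.5, inhibitors = 1, n = 2), 1 / (1 + 1), tolerance = 1e-12)
  # direct formula on a grid
  for (L in c(0.5, 2)) for (fer in c(0.2, 0.8)) for (n in 1:3) {
    q <- fer * (1 + 0.7) / (1 + 0.3)
    expect_equal(allostery(L, fer, activators = 0.3, inhibitors = 0.7, n = n),
                 1 / (1 + L * q^n))
  }
  # activators increase, inhibitors decrease the factor
  base <- allostery(1, 0.5, activators = 0.5, inhibitors = 0.5, n = 2)
  expect_gt(allostery(1, 0.5, activators = 1, inhibitors = 0.5, n = 2), base)
  expect_lt(allostery(1, 0.5, activators = 0.5, inhibitors = 1, n = 2), base)
  expect_error(allostery(1, 0.5, n = 0), "positive integer")
})

test_that("phosphorylation factor is (1 + p/d)^-n", {
  expect_equal(phosphorylation_factor(0, 1, 3), 1)
  expect_equal(phosphorylation_factor(1, 1, 1), 0.5)
  expect_equal(phosphorylation_factor(2, 2, 2), 0.25)
  p_grid <- c(0, 0.5, 1, 2, 5)
  f <- phosphorylation_factor(p_grid, 1, 2)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0 & f <= 1))
  expect_error(phosphorylation_factor(1, 0), "positive")
})

test_that("reaction flux assembles Michaelis-Menten and handles knockouts/drains", {
  st <- lc2_study()
  m <- st$model
  theta <- theta_at_prior(m)
  theta <- set_param(theta, m, "enzyme_conc", 1, enzyme = "E2", experiment = "e1")
  theta <- set_param(theta, m, "kcat", 10, enzyme = "E2")
  theta <- set_param(theta, m, "km", 1, enzyme = "E2", metabolite = "M")
  fx <- reaction_flux(m, "r2", "e1", theta, c(M = 1))
  expect_equal(fx$flux, 5)          # E kcat C / (Km + C) at C = Km
  # drain flux equals its parameter, identity factors
  theta <- set_param(theta, m, "drain_flux", 0.7, reaction = "r1", experiment = "e1")
  fd <- reaction_flux(m, "r1", "e1", theta, c(M = 1))
  expect_equal(fd$flux, 0.7)
  expect_equal(unlist(fd[c("enzyme", "kcat", "reversibility", "saturation",
                           "allostery", "phosphorylation")]),
               c(enzyme = 1, kcat = 1, reversibility = 1, saturation = 1,
                 allostery = 1, phosphorylation = 1))
  # knocked-out enzyme gives exactly zero flux
  m5 <- met5_model()
  th5 <- theta_at_prior(m5)
  ko <- reaction_flux(m5, "r6", "e2", th5,
                      c(M1 = 1, M2 = 1, M3 = 1, M4 = 1, M5 = 1))
  expect_identical(ko$flux, 0)
  expect_identical(ko$enzyme, 0)
})

test_that("the factor product equals the flux and matches the C++ engine", {
  m5 <- met5_model()
  th5 <- theta_at_prior(m5)
  conc <- c(M1 = 0.8, M2 = 1.4, M3 = 0.6, M4 = 2.1, M5 = 0.9)
  dec <- flux_decomposition(m5, "e1", th5, conc)
  prod6 <- dec$enzyme * dec$kcat * dec$reversibility * dec$saturation *
    dec$allostery * dec$phosphorylation
  enzymatic <- m5$network$reactions$mechanism != "drain"
  expect_equal(prod6[enzymatic], dec$flux[enzymatic], tolerance = 1e-12)
  # engine agreement, factor by factor
  cm <- m5$compiled[["e1"]]
  r <- kinfer:::kin_eval_cpp(cm, matrix(as_theta(m5, th5), ncol = 1),
                             matrix(log(conc), ncol = 1), TRUE)
  expect_equal(drop(r$flux), dec$flux, tolerance = 1e-12)
  for (f in c("enzyme", "kcat", "reversibility", "saturation", "allostery",
              "phosphorylation")) {
    expect_equal(drop(r[[f]]), dec[[f]], tolerance = 1e-12, info = f)
  }
})

test_that("Haldane-parameterized reversible MM equals the factored flux on a grid", {
  m <- uniuni_model()
  theta <- theta_at_prior(m)
  p <- m$params
  kcat_f <- theta[["kcat[E1]"]]
  km_s <- theta[["km[E1,S]"]]
  km_p <- theta[["km[E1,P]"]]
  E <- theta[["enzyme_conc[e1,E1]"]]
  RT <- R_GAS * m$temperature
  dg <- reaction_delta_g_standard(m$network, "r1",
    c(S = theta[["formation_energy[S]"]], P = theta[["formation_energy[P]"]]))
  keq <- exp(-dg / RT)
  kcat_r <- kcat_f * km_p / (km_s * keq)  # Haldane: kcat- = kcat+ KmP / (KmS Keq)
  for (S in c(0.2, 1, 4)) {
    for (P in c(0.1, 0.9, 3)) {
      th <- set_param(theta, m, "boundary_conc", S, metabolite = "S",
                      experiment = "e1")
      th <- set_param(th, m, "boundary_conc", P, metabolite = "P",
                      experiment = "e1")
      got <- reaction_flux(m, "r1", "e1", th, numeric(0))$flux
      # brute-force reversible Michaelis-Menten oracle
      want <- E * (kcat_f * S / km_s - kcat_r * P / km_p) /
        (1 + S / km_s + P / km_p)
      expect_equal(got, want, tolerance = 1e-10)
      # thermodynamic consistency: the flux sign follows the reversibility sign
      Q <- P / S
      expect_equal(sign(got), sign(1 - Q / keq))
    }
  }
  # exact zero at equilibrium
  th <- set_param(theta, m, "boundary_conc", 1, metabolite = "S", experiment = "e1")
  th <- set_param(th, m, "boundary_conc", keq, metabolite = "P", experiment = "e1")
  expect_equal(reaction_flux(m, "r1", "e1", th, numeric(0))$flux, 0,
               tolerance = 1e-12)
})

test_that("ode_rhs balances production and consumption and is linear in enzymes", {
  st <- lc2_study()
  m <- st$model
  theta <- theta_at_prior(m)
  theta <- set_param(theta, m, "enzyme_conc", 1, enzyme = "E2", experiment = "e1")
  theta <- set_param(theta, m, "kcat", 2, enzyme = "E2")
  theta <- set_param(theta, m, "km", 1, enzyme = "E2", metabolite = "M")
  # v1 = 1, v2 = 2 * 1/(1+1) = 1 at M = Km: balance
  theta <- set_param(theta, m, "drain_flux", 1, reaction = "r1", experiment = "e1")
  expect_equal(unname(ode_rhs(m, "e1", theta, c(M = 1))["M"]), 0)
  # v1 = 2, v2 = 1: dM/dt = 1
  theta <- set_param(theta, m, "drain_flux", 2, reaction = "r1", experiment = "e1")
  theta <- set_param(theta, m, "kcat", 2, enzyme = "E2")
  expect_equal(unname(ode_rhs(m, "e1", theta, c(M = 1))), 1)
  # all-enzymatic network: doubling every enzyme concentration doubles dC/dt
  st3 <- ac3_study()
  m3 <- st3$model
  th3 <- as_theta(m3, theta_at_prior(m3))
  idx <- which(m3$params$kind == "enzyme_conc")
  th3x2 <- th3
  th3x2[idx] <- 2 * th3[idx]
  names(th3) <- names(th3x2) <- m3$params$name
  C0 <- c(A = 0.7, B = 1.3)
  expect_equal(ode_rhs(m3, "e1", th3x2, C0), 2 * ode_rhs(m3, "e1", th3, C0),
               tolerance = 1e-12)
  # explicit-Euler sanity: one small step moves amounts by rhs * dt
  rhs <- ode_rhs(m3, "e1", th3, C0)
  dt <- 1e-6
  C1 <- C0 + rhs * dt
  rhs1 <- ode_rhs(m3, "e1", th3, C1)
  expect_equal(rhs1, rhs, tolerance = 1e-4)
})
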