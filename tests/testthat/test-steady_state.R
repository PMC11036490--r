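test_that("Rosenbrock integrator matches closed-form linear decay", {
  # y' = -3y, y(0) = 2: y(t) = 2 exp(-3t); stiffish companion lambda = -500
  f <- function(y) c(-3 * y[1], -500 * y[2])
  jac <- function(y) diag(c(-3, -500))
  out <- kinfer:::ode_rosenbrock(f, jac, c(2, 1), t_end = 1,
                                 rel_tol = 1e-9, abs_tol = 1e-12)
  expect_true(out$success)
  expect_equal(out$y[1], 2 * exp(-3), tolerance = 1e-6)
  expect_equal(out$y[2], exp(-500), tolerance = 1e-6)
})

test_that("hybrid solver reproduces the linear-chain closed form", {
  st <- lc2_study()
  m <- st$model
  theta <- st$truth$theta
  ss <- solve_steady_state(m, "e1", theta)
  expect_true(ss$converged)
  d <- theta[["drain_flux[e1,r1]"]]
  Km <- theta[["km[E2,M]"]]
  Vmax <- theta[["enzyme_conc[e1,E2]"]] * theta[["kcat[E2]"]]
  expect_equal(unname(ss$c_star["M"]), d * Km / (Vmax - d), tolerance = 1e-8)
  # both fluxes carry the drain value at steady state
  expect_equal(unname(ss$v_star), c(d, d), tolerance = 1e-8)
  # converged result satisfies its own residual contract
  expect_lte(max(abs(ode_rhs(m, "e1", theta, ss$c_star))), m$solver$newton_tol)
})

test_that("a drain exceeding Vmax yields a structured failure, not an error", {
  st <- lc2_study()
  m <- st$model
  theta <- st$truth$theta
  Vmax <- theta[["enzyme_conc[e1,E2]"]] * theta[["kcat[E2]"]]
  theta <- set_param(theta, m, "drain_flux", 2 * Vmax, reaction = "r1",
                     experiment = "e1")
  cfg <- solver_config(t_evolve = 1, max_retries = 1)
  ss <- solve_steady_state(m, "e1", theta, cfg = cfg)
  expect_false(ss$converged)
  expect_true(is.finite(ss$residual_norm) || is.infinite(ss$residual_norm))
  expect_s3_class(ss, "kin_steady_state")
})

test_that("hybrid result equals plain long-time ODE integration", {
  st <- ac3_study()
  m <- st$model
  theta <- as_theta(m, st$truth$theta)
  for (ex in c("e1", "e3")) {
    ss <- solve_steady_state(m, ex, st$truth$theta)
    expect_true(ss$converged)
    cm <- m$compiled[[ex]]
    rhs_ln <- function(ln) kinfer:::f_bal(cm, theta, ln) / exp(ln)
    jac_ln <- function(ln) {
      J <- kinfer:::jac_bal_lnC(cm, theta, ln)
      sweep(J, 1, exp(ln), "/") - diag(rhs_ln(ln), length(ln))
    }
    long <- kinfer:::ode_rosenbrock(rhs_ln, jac_ln, log(c(A = 1, B = 1)),
                                    t_end = 10 * m$solver$t_evolve,
                                    rel_tol = 1e-11, abs_tol = 1e-13)
    expect_true(long$success)
    expect_equal(unname(exp(long$y)), unname(ss$c_star), tolerance = 1e-6)
  }
})

test_that("the steady state is invariant to the initial guess within the basin", {
  st <- ac3_study()
  m <- st$model
  ss1 <- solve_steady_state(m, "e1", st$truth$theta, init = c(A = 0.3, B = 0.3))
  ss2 <- solve_steady_state(m, "e1", st$truth$theta, init = c(A = 3, B = 3))
  expect_true(ss1$converged && ss2$converged)
  expect_equal(ss1$c_star, ss2$c_star, tolerance = 1e-7)
})

test_that("fluxes recomputed from factors reproduce v_star at the fixed point", {
  st <- ac3_study()
  m <- st$model
  ss <- solve_steady_state(m, "e2", st$truth$theta)
  dec <- flux_decomposition(m, "e2", st$truth$theta, ss$c_star)
  expect_equal(dec$flux, unname(ss$v_star), tolerance = 1e-10)
})

test_that("implicit-function sensitivities match the closed form and finite differences", {
  st <- lc2_study()
  m <- st$model
  theta <- st$truth$theta
  ss <- solve_steady_state(m, "e1", theta)
  sens <- steady_state_sensitivities(m, "e1", theta, ss)
  # closed form: M* = d Km / (Vmax - d)  =>  dM*/dKm = M*/Km
  Km <- theta[["km[E2,M]"]]
  expect_equal(sens$dC["M", "km[E2,M]"], unname(ss$c_star["M"]) / Km,
               tolerance = 1e-5)
  # central finite differences of the full solve
  for (pname in c("km[E2,M]", "kcat[E2]", "drain_flux[e1,r1]")) {
    h <- 1e-5 * max(abs(theta[[pname]]), 1e-3)
    tp <- theta; tp[[pname]] <- tp[[pname]] + h
    tm <- theta; tm[[pname]] <- tm[[pname]] - h
    fd_C <- (solve_steady_state(m, "e1", tp)$c_star -
               solve_steady_state(m, "e1", tm)$c_star) / (2 * h)
    expect_equal(sens$dC["M", pname], unname(fd_C["M"]), tolerance = 1e-4,
                 info = pname)
  }
  # parameters of other experiments do not touch this steady state
  expect_equal(unname(sens$dC["M", "drain_flux[e2,r1]"]), 0)
  expect_equal(unname(sens$dv[, "enzyme_conc[e2,E2]"]), c(0, 0))
  # a boundary metabolite downstream of an irreversible step has no effect
  expect_equal(unname(sens$dC["M", "boundary_conc[e1,X1]"]), 0, tolerance = 1e-10)
})

test_that("sensitivities agree with finite differences on the allosteric model", {
  st <- ac3_study()
  m <- st$model
  theta <- st$truth$theta
  ss <- solve_steady_state(m, "e1", theta)
  pick <- c("kcat[E1]", "km[E2,A]", "transfer_constant[E1]",
            "dissociation_constant[E1,B]", "enzyme_conc[e1,E3]",
            "boundary_conc[e1,X0]")
  sens <- steady_state_sensitivities(m, "e1", theta, ss, parameters = pick)
  for (pname in pick) {
    h <- 1e-5 * abs(theta[[pname]])
    tp <- theta; tp[[pname]] <- tp[[pname]] + h
    tm <- theta; tm[[pname]] <- tm[[pname]] - h
    sp <- solve_steady_state(m, "e1", tp)
    sm <- solve_steady_state(m, "e1", tm)
    fd_C <- (sp$c_star - sm$c_star) / (2 * h)
    fd_v <- (sp$v_star - sm$v_star) / (2 * h)
    scale_C <- pmax(abs(fd_C), 1e-4)
    scale_v <- pmax(abs(fd_v), 1e-4)
    expect_lt(max(abs(sens$dC[, pname] - fd_C) / scale_C), 1e-4)
    expect_lt(max(abs(sens$dv[, pname] - fd_v) / scale_v), 1e-4)
  }
})
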