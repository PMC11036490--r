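test_that("pack/unpack is the identity and maps to the right scales", {
  st <- ac3_study()
  m <- st$model
  theta <- st$truth$theta
  u <- pack_theta(m, theta)
  expect_equal(length(u), nrow(m$params))
  expect_equal(unpack_theta(m, u), theta)
  pos <- m$params$positive
  expect_equal(u[pos], log(as_theta(m, theta)[pos]))
  expect_equal(u[!pos], as_theta(m, theta)[!pos])
})

test_that("log_prior matches an independently coded reference density", {
  st <- ac3_study()
  m <- st$model
  theta <- st$truth$theta
  p <- m$params
  v <- as_theta(m, theta)
  fe_idx <- m$fe_block$idx
  ref <- 0
  for (i in setdiff(seq_len(nrow(p)), fe_idx)) {
    ref <- ref + if (p$positive[i]) {
      # lognormal density written out from first principles
      -log(v[i] * p$prior_scale[i] * sqrt(2 * pi)) -
        (log(v[i]) - p$prior_location[i])^2 / (2 * p$prior_scale[i]^2)
    } else {
      -log(p$prior_scale[i] * sqrt(2 * pi)) -
        (v[i] - p$prior_location[i])^2 / (2 * p$prior_scale[i]^2)
    }
  }
  z <- v[fe_idx] - m$fe_block$mean
  ref <- ref - 0.5 * (length(z) * log(2 * pi) +
                        determinant(m$fe_block$cov, log = TRUE)$modulus[1] +
                        drop(z %*% solve(m$fe_block$cov) %*% z))
  expect_equal(log_prior(m, theta), unname(ref), tolerance = 1e-10)

  # a lognormal parameter at its prior median contributes
  # -ln(scale sqrt(2 pi)) - location
  m2 <- gauss_model()
  th2 <- theta_at_prior(m2)  # boundary_conc at exp(location)
  loc <- 0; sc <- 0.3
  expect_equal(log_prior(m2, th2),
               stats::dnorm(0, 0, 1, log = TRUE) +      # drain at prior mean
                 (-log(sc * sqrt(2 * pi)) - loc),
               tolerance = 1e-12)
  # one prior sd away drops the log density by exactly 0.5
  th3 <- set_param(th2, m2, "drain_flux", 1, reaction = "d1", experiment = "e1")
  expect_equal(log_prior(m2, th2) - log_prior(m2, th3), 0.5)
})

test_that("formation-energy block at its mean with identity covariance gives -(k/2) ln(2 pi)", {
  m <- corr_gauss_model(rho = 0)   # identity covariance
  theta <- theta_at_prior(m)
  p <- m$params
  scalar_ref <- sum(vapply(which(p$kind != "formation_energy"), function(i) {
    v <- exp(p$prior_location[i])
    -log(v * p$prior_scale[i] * sqrt(2 * pi)) # lognormal at median
  }, numeric(1)))
  expect_equal(log_prior(m, theta) - scalar_ref, -log(2 * pi),  # k = 2
               tolerance = 1e-10)
})

test_that("log_likelihood matches the measurement-model densities", {
  st <- lc2_study()
  m0 <- st$model
  fx <- build_fixture("linear_chain_2")
  ms <- kin_measurements(
    experiment = c("e1", "e1", "e1"),
    type = c("conc", "flux", "conc"),
    target = c("M", "r2", "M"),
    value = c(1, 0.8, exp(0.1)),
    sd = c(0.1, 0.5, 0.1))
  m <- kin_model(fx$network, fx$priors, fx$experiments, ms)
  theta <- st$truth$theta
  ss_fake <- list(e1 = list(c_star = c(M = 1), v_star = c(r1 = 0.8, r2 = 0.8)))
  ll <- log_likelihood(m, ss_fake, theta)
  # matched conc record with sigma = 0.1: -ln(0.1 sqrt(2 pi)) = 1.38364...
  expect_equal(ll$per_record[1], 1.383647, tolerance = 1e-6)
  expect_equal(ll$per_record[1], stats::dlnorm(1, 0, 0.1, log = TRUE))
  # flux at the modeled mean
  expect_equal(ll$per_record[2], -log(0.5 * sqrt(2 * pi)))
  # one log-sd off: 0.5 lower, plus the -ln y Jacobian shift
  expect_equal(ll$per_record[3], ll$per_record[1] - 0.5 - 0.1, tolerance = 1e-9)
  expect_equal(ll$total, sum(ll$per_record))
})

test_that("log_joint is prior + likelihood + Jacobian, with a matching gradient", {
  st <- lc2_study()
  m <- st$model
  ctx <- kinfer:::stat_context(m)
  u <- pack_theta(m, st$truth$theta)
  r <- log_joint(m, u, ctx = ctx)
  theta <- unpack_theta(m, u)
  ssl <- lapply(m$experiments$id, function(ex) solve_steady_state(m, ex, theta))
  names(ssl) <- m$experiments$id
  jac_term <- sum(u[m$params$positive])
  expect_equal(r$value,
               log_prior(m, theta) + log_likelihood(m, ssl, theta)$total + jac_term,
               tolerance = 1e-7)
  expect_equal(sum(r$per_record), r$loglik, tolerance = 1e-7)
  # gradient against central finite differences
  g_fd <- vapply(seq_along(u), function(k) {
    h <- 1e-5
    up <- u; up[k] <- up[k] + h
    um <- u; um[k] <- um[k] - h
    (log_joint(m, up, ctx = ctx, want_grad = FALSE)$value -
       log_joint(m, um, ctx = ctx, want_grad = FALSE)$value) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(r$grad - g_fd) / pmax(abs(g_fd), 1)), 1e-5)
})

test_that("with zero measurements the joint density reduces to the prior", {
  m <- gauss_model()
  u <- c(0.4, -0.2)
  r <- log_joint(m, u, ctx = kinfer:::stat_context(m))
  jac_term <- sum(u[m$params$positive])
  expect_equal(r$value - jac_term, log_prior(m, unpack_theta(m, u)),
               tolerance = 1e-12)
  expect_equal(r$loglik, 0)
})

test_that("steady-state failure inside log_joint signals rejection", {
  st <- lc2_study()
  m <- st$model
  theta <- st$truth$theta
  Vmax <- theta[["enzyme_conc[e1,E2]"]] * theta[["kcat[E2]"]]
  theta <- set_param(theta, m, "drain_flux", 2 * Vmax, reaction = "r1",
                     experiment = "e1")
  r <- log_joint(m, pack_theta(m, theta))
  expect_identical(r$value, -Inf)
})
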