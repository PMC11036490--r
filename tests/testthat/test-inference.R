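test_that("NUTS recovers a standard-normal target", {
  m <- gauss_model()
  dr <- sample_posterior(m)
  v <- as.vector(dr$theta[, , "drain_flux[e1,d1]"])
  diag <- compute_diagnostics(dr)
  ess <- diag$per_parameter$ess_bulk[
    diag$per_parameter$parameter == "drain_flux[e1,d1]"]
  expect_lt(abs(mean(v)), 3 * stats::sd(v) / sqrt(ess))
  expect_lt(abs(stats::sd(v) - 1), 0.05)
  expect_equal(diag$n_divergent, 0)
})

test_that("NUTS recovers the correlation of a correlated Gaussian target", {
  m <- corr_gauss_model(rho = 0.8)
  dr <- sample_posterior(m)
  x <- as.vector(dr$theta[, , "formation_energy[S]"])
  y <- as.vector(dr$theta[, , "formation_energy[P]"])
  expect_lt(abs(stats::cor(x, y) - 0.8), 0.05)
  expect_lt(abs(mean(x) - (-10)), 0.15)
  expect_lt(abs(stats::sd(x) - 1), 0.1)
})

test_that("identical seed and configuration give bitwise-identical draws", {
  m <- gauss_model(sampler_config(n_chains = 2, n_warmup = 100, n_draws = 50,
                                  seed = 5))
  d1 <- sample_posterior(m)
  d2 <- sample_posterior(m)
  expect_identical(d1$theta, d2$theta)
  expect_identical(d1$sample_stats, d2$sample_stats)
  # a different seed moves the draws
  m2 <- gauss_model(sampler_config(n_chains = 2, n_warmup = 100, n_draws = 50,
                                   seed = 6))
  expect_false(identical(sample_posterior(m2)$theta, d1$theta))
})

test_that("prior sampling through the full MCMC machinery recovers the prior", {
  # no-data model: the posterior IS the prior; standard prior-recovery check
  st <- lc2_study()
  fx <- build_fixture("linear_chain_2")
  m <- kin_model(fx$network, fx$priors, fx$experiments,
                 sampler = sampler_config(n_chains = 4, n_warmup = 300,
                                          n_draws = 500, seed = 12))
  dr <- sample_posterior(m)
  diag <- compute_diagnostics(dr)
  for (pname in c("kcat[E2]", "km[E2,M]", "drain_flux[e1,r1]")) {
    i <- match(pname, m$params$name)
    v <- as.vector(dr$theta[, , pname])
    if (m$params$positive[i]) v <- log(v)
    ess <- diag$per_parameter$ess_bulk[diag$per_parameter$parameter == pname]
    mc_se <- stats::sd(v) / sqrt(ess)
    expect_lt(abs(mean(v) - m$params$prior_location[i]), 3 * mc_se)
    expect_lt(abs(stats::sd(v) / m$params$prior_scale[i] - 1), 0.1)
  }
})

test_that("rank-normalized split R-hat and ESS behave under null and failure cases", {
  set.seed(1)
  # 4 chains of iid standard normals: R-hat close to 1, ESS near total draws
  a <- array(stats::rnorm(4 * 1000 * 3), c(4, 1000, 3),
             dimnames = list(NULL, NULL, paste0("p", 1:3)))
  d <- compute_diagnostics(a)
  expect_lt(max(d$per_parameter$rhat), 1.01)
  expect_true(all(abs(d$per_parameter$ess_bulk - 4000) / 4000 < 0.2))
  expect_true(all(d$per_parameter$ess_tail > 1000))
  # two chains stuck at different locations: R-hat far above 1.1
  b <- array(c(stats::rnorm(500, 0), stats::rnorm(500, 10)), c(2, 500, 1))
  expect_gt(compute_diagnostics(b)$per_parameter$rhat, 1.5)
  # single chain: computable with a warning via 4-way splitting
  s <- array(stats::rnorm(400), c(1, 400, 1))
  expect_warning(ds <- compute_diagnostics(s), "single chain")
  expect_lt(ds$per_parameter$rhat, 1.05)
  expect_error(compute_diagnostics(array(0, c(2, 2, 1))), "at least 4 draws")
})

test_that("Laplace equals the exact conjugate posterior on the linear-Gaussian fixture", {
  mu0 <- 1; s0 <- 0.5; y <- 1.4; sigma <- 0.25
  m <- conjugate_model(mu0, s0, y, sigma)
  la <- laplace_approximation(m, n_samples = 400, seed = 2)
  post_prec <- 1 / s0^2 + 1 / sigma^2
  post_mean <- (mu0 / s0^2 + y / sigma^2) / post_prec
  i <- match("drain_flux[e1,d1]", m$params$name)
  expect_equal(unname(la$map$u[i]), post_mean, tolerance = 1e-6)
  cov <- solve(-la$map$hessian)
  expect_equal(cov[i, i], 1 / post_prec, tolerance = 1e-6)
  expect_equal(la$n_failed, 0L)
  # draws follow the conjugate posterior
  v <- as.vector(la$draws$theta[, , i])
  expect_lt(abs(mean(v) - post_mean), 4 * sqrt(1 / post_prec) / sqrt(400))
})

test_that("Laplace MAP of a lognormal-prior-only coordinate sits at the prior location", {
  m <- gauss_model()
  la <- laplace_approximation(m, n_samples = 0, seed = 3)
  i <- match("boundary_conc[e1,X]", m$params$name)
  expect_equal(unname(la$map$u[i]), 0, tolerance = 1e-5)  # prior location
  expect_null(la$draws)
})

test_that("two-sample KS statistic matches enumerable cases", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1.5, 2.5))$statistic, 0.5)
  # p-value agrees with the stats reference implementation
  set.seed(4)
  x <- stats::rnorm(100); y <- stats::rnorm(120, 0.5)
  ks <- ks_two_sample(x, y)
  ref <- stats::ks.test(x, y)
  expect_equal(ks$statistic, unname(ref$statistic))
  expect_equal(ks$p_value, ref$p.value)
})

test_that("tree-depth cap is respected and recorded", {
  m <- banana_model()
  m$sampler <- sampler_config(n_chains = 1, n_warmup = 100, n_draws = 50,
                              max_tree_depth = 3, seed = 8)
  dr <- sample_posterior(m)
  expect_lte(max(dr$sample_stats$tree_depth), 3)
})
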