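test_that("posterior predictive draws collapse onto the modeled values as noise vanishes", {
  fit <- ac3_fit_small()
  dr <- fit$draws
  m <- dr$model
  ms <- kin_measurements(
    experiment = c("e1", "e1", "e1"),
    type = c("conc", "enzyme", "flux"),
    target = c("A", "E1", "r3"),
    value = c(1, 0.01, 0.01),
    sd = c(1e-12, 1e-12, 1e-12))
  pp <- posterior_predict(dr, ms, seed = 1)
  dr2 <- compute_derived(dr)
  expect_equal(as.vector(pp$draws[, , 1]),
               as.vector(dr2$derived$c_star[, , "e1", "A"]), tolerance = 1e-9)
  expect_equal(as.vector(pp$draws[, , 3]),
               as.vector(dr2$derived$v_star[, , "e1", "r3"]), tolerance = 1e-9)
  expect_equal(pp$n_failed, 0L)
})

test_that("a knocked-out enzyme's flux is exactly zero in every derived draw", {
  m5 <- met5_model()
  set.seed(2)
  thetas <- t(vapply(1:4, function(i) draw_true_parameters(m5, seed = 100 + i),
                     numeric(nrow(m5$params))))
  dr <- draws_from_theta(m5, thetas)
  dr <- compute_derived(dr)
  expect_true(all(dr$derived$v_star[, , "e2", "r6"] == 0))
  expect_true(all(dr$derived$v_star[, , "e1", "r6"] != 0))
})

test_that("predictive intervals cover the training data of a well-specified fit", {
  fit <- ac3_fit_small()
  pp <- posterior_predict(fit$draws, seed = 5)
  # 24 records at a nominal 95% rate: allow the binomial slack
  expect_gte(sum(pp$summary$covered), qbinom(0.001, nrow(pp$summary), 0.95))
  expect_equal(pp$n_failed, 0L)
})

test_that("regulatory log-ratios are zero for identical conditions and sum to the flux ratio", {
  fit <- ac3_fit_small()
  dr <- fit$draws
  rr_same <- regulatory_log_ratios(dr, "r1", "e1", "e1")
  expect_true(all(rr_same$ratios == 0))
  rr <- regulatory_log_ratios(dr, "r1", "e2", "e1")
  incl <- names(rr$excluded)[!rr$excluded]
  sums <- rowSums(rr$ratios[, incl, drop = FALSE])
  expect_equal(sums, unname(rr$ratios[, "flux"]), tolerance = 1e-9)
  # kcat is shared across conditions: excluded with ratio identically zero
  expect_true(rr$excluded[["kcat"]])
  expect_true(all(rr$ratios[, "kcat"] == 0))
  # irreversible r3: reversibility exclusion is structural
  rr3 <- regulatory_log_ratios(dr, "r3", "e2", "e1")
  expect_true(rr3$excluded[["reversibility"]])
  expect_false(rr3$excluded[["saturation"]])
  # probability masses are consistent (structurally constant factors put all
  # their mass exactly at zero)
  p_zero <- colMeans(rr$ratios == 0)[rr$summary$factor]
  expect_equal(rr$summary$prob_positive + rr$summary$prob_negative +
                 unname(p_zero), rep(1, nrow(rr$summary)), tolerance = 1e-9)
})

test_that("a pure enzyme-dose contrast shows up only in the enzyme component", {
  st <- ac3_study()
  m <- st$model
  theta <- as_theta(m, st$truth$theta)
  names(theta) <- m$params$name
  # make e2 a copy of e1 except all three enzymes doubled
  for (e in c("E1", "E2", "E3")) {
    theta <- set_param(theta, m, "enzyme_conc",
                       2 * theta[[paste0("enzyme_conc[e1,", e, "]")]],
                       enzyme = e, experiment = "e2")
  }
  theta <- set_param(theta, m, "boundary_conc",
                     theta[["boundary_conc[e1,X0]"]],
                     metabolite = "X0", experiment = "e2")
  theta <- set_param(theta, m, "boundary_conc",
                     theta[["boundary_conc[e1,X1]"]],
                     metabolite = "X1", experiment = "e2")
  dr <- draws_from_theta(m, rbind(theta))
  rr <- regulatory_log_ratios(dr, "r2", "e2", "e1")
  expect_equal(unname(rr$ratios[1, "enzyme"]), log(2), tolerance = 1e-8)
  # oracle: factor ratios recomputed directly from both steady states
  ss1 <- solve_steady_state(m, "e1", theta)
  ss2 <- solve_steady_state(m, "e2", theta)
  d1 <- flux_decomposition(m, "e1", theta, ss1$c_star)
  d2 <- flux_decomposition(m, "e2", theta, ss2$c_star)
  for (f in c("saturation", "allostery", "reversibility")) {
    expect_equal(unname(rr$ratios[1, f]),
                 log(d2[[f]][2]) - log(d1[[f]][2]), tolerance = 1e-7, info = f)
  }
  # doubling every enzyme scales all fluxes by 2 at an unchanged steady state
  expect_equal(unname(rr$ratios[1, "flux"]), log(2), tolerance = 1e-7)
})

test_that("control coefficients on the linear chain match the analytic solution", {
  st <- lc2_study()
  m <- st$model
  theta <- st$truth$theta
  cc <- control_coefficients(m, "e1", theta)
  d <- theta[["drain_flux[e1,r1]"]]
  Vmax <- theta[["enzyme_conc[e1,E2]"]] * theta[["kcat[E2]"]]
  # the drain sets both steady-state fluxes: full flux control to the drain
  expect_equal(unname(cc$flux_control[, "r1"]), c(1, 1), tolerance = 1e-6)
  expect_equal(unname(cc$flux_control[, "E2"]), c(0, 0), tolerance = 1e-6)
  # analytic concentration control from M* = d Km / (Vmax - d)
  expect_equal(unname(cc$conc_control["M", "E2"]), -Vmax / (Vmax - d),
               tolerance = 1e-5)
  expect_equal(unname(cc$conc_control["M", "r1"]), Vmax / (Vmax - d),
               tolerance = 1e-5)
})

test_that("summation theorems hold on the nontrivial fixtures", {
  st <- ac3_study()
  cc <- control_coefficients(st$model, "e1", st$truth$theta)
  expect_equal(unname(rowSums(cc$flux_control)), rep(1, 3), tolerance = 1e-6)
  expect_equal(unname(rowSums(cc$conc_control)), rep(0, 2), tolerance = 1e-6)
  m5 <- met5_model()
  th5 <- draw_true_parameters(m5, seed = 31)
  for (ex in c("e1", "e2")) {
    cc5 <- control_coefficients(m5, ex, th5)
    ko <- m5$experiments$knockouts[[match(ex, m5$experiments$id)]]
    live <- !m5$network$reactions$enzyme %in% ko
    expect_equal(unname(rowSums(cc5$flux_control))[live],
                 rep(1, sum(live)), tolerance = 1e-6)
    expect_equal(unname(rowSums(cc5$conc_control)), rep(0, 5), tolerance = 1e-6)
  }
})

test_that("an enzyme on a disconnected dead branch has zero control elsewhere", {
  # linear chain plus an isolated boundary-to-boundary side reaction
  net <- kin_network(
    tibble::tibble(id = c("X0", "M", "X1"), balanced = c(FALSE, TRUE, FALSE)),
    tibble::tibble(id = c("E2", "E9"), subunits = c(1L, 1L)),
    tibble::tibble(
      id = c("r1", "r2", "r9"),
      mechanism = c("drain", "irreversible_modular", "irreversible_modular"),
      enzyme = c(NA, "E2", "E9"),
      stoichiometry = list(c(X0 = -1, M = 1), c(M = -1, X1 = 1),
                           c(X0 = -1, X1 = 1))))
  pri <- kin_priors(dplyr::bind_rows(
    kinfer:::prior_row("kcat", log(5), 0.2, enzyme = "E2"),
    kinfer:::prior_row("kcat", log(5), 0.2, enzyme = "E9"),
    kinfer:::prior_row("km", 0, 0.2, enzyme = "E2", metabolite = "M"),
    kinfer:::prior_row("km", 0, 0.2, enzyme = "E9", metabolite = "X0"),
    kinfer:::prior_row("enzyme_conc", 0, 0.1, enzyme = "E2"),
    kinfer:::prior_row("enzyme_conc", 0, 0.1, enzyme = "E9"),
    kinfer:::prior_row("boundary_conc", 0, 0.1, metabolite = "X0"),
    kinfer:::prior_row("boundary_conc", 0, 0.1, metabolite = "X1"),
    kinfer:::prior_row("drain_flux", 1, 0.05, reaction = "r1")))
  m <- kin_model(net, pri, kin_experiments("e1", init_conc = list(c(M = 1))))
  theta <- theta_at_prior(m)
  cc <- control_coefficients(m, "e1", theta)
  expect_equal(unname(cc$flux_control[c("r1", "r2"), "E9"]), c(0, 0),
               tolerance = 1e-8)
  expect_equal(unname(cc$conc_control["M", "E9"]), 0, tolerance = 1e-8)
  # the side reaction controls itself completely
  expect_equal(unname(cc$flux_control["r9", "E9"]), 1, tolerance = 1e-6)
})

test_that("residuals are zero for a perfect fit and follow their definition", {
  st <- ac3_study()
  m0 <- st$model
  theta <- st$truth$theta
  # measurements equal to the modeled values exactly (degenerate recipe)
  base <- kin_model(m0$network, m0$priors, m0$experiments)
  sim <- simulate_measurements(base, theta,
                               simulation_recipe(conc_sd = 0, flux_sd_frac = 0,
                                                 flux_sd_floor = 0, seed = 1))
  # sds of zero are not valid measurement models; give them nominal values
  ms <- sim$measurements
  ms$sd <- 0.1
  m <- kin_model(m0$network, m0$priors, m0$experiments, ms)
  dr <- draws_from_theta(m, rbind(as_theta(m, theta)))
  rr <- residual_report(dr)
  expect_equal(rr$residual, rep(0, nrow(rr)), tolerance = 1e-7)
  # definition: ln(measured) - ln(median modeled) for concentrations
  ms2 <- ms
  ms2$value[1] <- ms$value[1] * exp(0.2)
  m2 <- kin_model(m0$network, m0$priors, m0$experiments, ms2)
  rr2 <- residual_report(draws_from_theta(m2, rbind(as_theta(m2, theta))))
  expect_equal(rr2$residual[1], 0.2, tolerance = 1e-7)
})

test_that("joint posterior predictive fluxes are tighter than marginal resampling", {
  # the sloppiness witness: information lives in parameter correlations, so
  # breaking them by independently permuting each parameter's draws widens
  # the flux predictive distribution
  fit <- ac3_fit_small()
  dr <- compute_derived(fit$draws)
  m <- dr$model
  v_joint <- as.vector(dr$derived$v_star[, , "e1", "r3"])
  theta_flat <- kinfer:::flatten_cd(dr$theta)
  set.seed(9)
  n <- nrow(theta_flat)
  shuffled <- apply(theta_flat, 2, function(col) col[sample.int(n)])
  keep <- seq_len(150)
  v_indep <- rep(NA_real_, length(keep))
  for (i in keep) {
    th <- stats::setNames(shuffled[i, ], m$params$name)
    ss <- solve_steady_state(m, "e1", th)
    if (ss$converged) v_indep[i] <- ss$v_star[["r3"]]
  }
  v_indep <- v_indep[is.finite(v_indep)]
  width <- function(v) diff(stats::quantile(v, c(0.05, 0.95), names = FALSE))
  expect_lt(width(v_joint), width(v_indep))
})
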