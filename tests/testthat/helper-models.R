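# Shared fixtures, built in code and memoized across test files.

.fixture_memo <- new.env(parent = emptyenv())

memo_fixture <- function(key, fn) {
  if (is.null(.fixture_memo[[key]])) .fixture_memo[[key]] <- fn()
  .fixture_memo[[key]]
}

# linear chain with simulated measurements
lc2_study <- function() {
  memo_fixture("lc2_study", function() {
    synthetic_study("linear_chain_2", seed = 11)
  })
}

# allosteric 3-reaction study (4 conditions, simulated data)
ac3_study <- function() {
  memo_fixture("ac3_study", function() {
    synthetic_study("allosteric_cycle_3", seed = 7)
  })
}

# methionine-like 5-state model, no measurements
met5_model <- function() {
  memo_fixture("met5_model", function() {
    fx <- build_fixture("methionine_like_5")
    kin_model(fx$network, fx$priors, fx$experiments)
  })
}

# one sign-free parameter with a standard-normal prior, no data: the
# posterior is exactly N(0, 1) in the drain-flux coordinate
gauss_model <- function(sampler = sampler_config(n_chains = 4, n_warmup = 300,
                                                 n_draws = 500, seed = 42)) {
  net <- kin_network(
    metabolites = tibble::tibble(id = "X", balanced = FALSE),
    enzymes = tibble::tibble(id = character(0), subunits = integer(0)),
    reactions = tibble::tibble(id = "d1", mechanism = "drain",
                               enzyme = NA_character_,
                               stoichiometry = list(c(X = -1)))
  )
  pri <- kin_priors(dplyr::bind_rows(
    kinfer:::prior_row("drain_flux", 0, 1, reaction = "d1"),
    kinfer:::prior_row("boundary_conc", 0, 0.3, metabolite = "X")
  ))
  kin_model(net, pri, kin_experiments("e1"), sampler = sampler)
}

# two formation energies under a correlated MVN prior (rho = 0.8), no data
corr_gauss_model <- function(rho = 0.8,
                             sampler = sampler_config(n_chains = 4,
                                                      n_warmup = 300,
                                                      n_draws = 500,
                                                      seed = 99)) {
  net <- kin_network(
    metabolites = tibble::tibble(id = c("S", "P"), balanced = c(FALSE, FALSE)),
    enzymes = tibble::tibble(id = "E1", subunits = 1L),
    reactions = tibble::tibble(id = "r1", mechanism = "reversible_modular",
                               enzyme = "E1",
                               stoichiometry = list(c(S = -1, P = 1)))
  )
  pri <- kin_priors(
    dplyr::bind_rows(
      kinfer:::prior_row("kcat", log(1), 0.2, enzyme = "E1"),
      kinfer:::prior_row("km", 0, 0.2, enzyme = "E1", metabolite = "S"),
      kinfer:::prior_row("km", 0, 0.2, enzyme = "E1", metabolite = "P"),
      kinfer:::prior_row("enzyme_conc", 0, 0.2, enzyme = "E1"),
      kinfer:::prior_row("boundary_conc", 0, 0.2, metabolite = "S"),
      kinfer:::prior_row("boundary_conc", 0, 0.2, metabolite = "P")
    ),
    formation_energy = list(ids = c("S", "P"), mean = c(-10, -12),
                            covariance = matrix(c(1, rho, rho, 1), 2, 2))
  )
  kin_model(net, pri, kin_experiments("e1"), sampler = sampler)
}

# linear-Gaussian fixture: drain flux with a normal prior measured with
# normal noise -> the posterior is the exact conjugate normal
conjugate_model <- function(prior_mean = 1, prior_sd = 0.5, y = 1.4,
                            sigma = 0.25) {
  net <- kin_network(
    metabolites = tibble::tibble(id = "X", balanced = FALSE),
    enzymes = tibble::tibble(id = character(0), subunits = integer(0)),
    reactions = tibble::tibble(id = "d1", mechanism = "drain",
                               enzyme = NA_character_,
                               stoichiometry = list(c(X = -1)))
  )
  pri <- kin_priors(dplyr::bind_rows(
    kinfer:::prior_row("drain_flux", prior_mean, prior_sd, reaction = "d1"),
    kinfer:::prior_row("boundary_conc", 0, 0.3, metabolite = "X")
  ))
  kin_model(net, pri, kin_experiments("e1"),
            kin_measurements("e1", "flux", "d1", y, sigma),
            sampler = sampler_config(n_chains = 4, n_warmup = 300,
                                     n_draws = 400, seed = 7))
}

# deliberately curved two-parameter posterior: a single irreversible
# Michaelis-Menten flux measured tightly, with wide kcat/Km priors, bends
# the (ln kcat, ln Km) ridge along ln v = ln E + ln kcat - ln(1 + Km/C)
banana_model <- function() {
  net <- kin_network(
    metabolites = tibble::tibble(id = c("S", "P"), balanced = c(FALSE, FALSE)),
    enzymes = tibble::tibble(id = "E1", subunits = 1L),
    reactions = tibble::tibble(id = "r1", mechanism = "irreversible_modular",
                               enzyme = "E1",
                               stoichiometry = list(c(S = -1, P = 1)))
  )
  pri <- kin_priors(dplyr::bind_rows(
    kinfer:::prior_row("kcat", log(2), 1.5, enzyme = "E1"),
    kinfer:::prior_row("km", 0, 1.5, enzyme = "E1", metabolite = "S"),
    kinfer:::prior_row("enzyme_conc", 0, 0.01, enzyme = "E1"),
    kinfer:::prior_row("boundary_conc", 0, 0.01, metabolite = "S"),
    kinfer:::prior_row("boundary_conc", 0, 0.01, metabolite = "P")
  ))
  kin_model(net, pri, kin_experiments("e1"),
            kin_measurements("e1", "flux", "r1", 1.0, 0.02),
            sampler = sampler_config(n_chains = 4, n_warmup = 400,
                                     n_draws = 200, seed = 31))
}

# uni-uni reversible reaction between two boundary metabolites; used for the
# Haldane-consistency grid (no steady state involved)
uniuni_model <- function() {
  net <- kin_network(
    metabolites = tibble::tibble(id = c("S", "P"), balanced = c(FALSE, FALSE)),
    enzymes = tibble::tibble(id = "E1", subunits = 1L),
    reactions = tibble::tibble(id = "r1", mechanism = "reversible_modular",
                               enzyme = "E1",
                               stoichiometry = list(c(S = -1, P = 1)))
  )
  pri <- kin_priors(
    dplyr::bind_rows(
      kinfer:::prior_row("kcat", log(10), 0.3, enzyme = "E1"),
      kinfer:::prior_row("km", log(0.7), 0.3, enzyme = "E1", metabolite = "S"),
      kinfer:::prior_row("km", log(1.3), 0.3, enzyme = "E1", metabolite = "P"),
      kinfer:::prior_row("enzyme_conc", log(0.5), 0.2, enzyme = "E1"),
      kinfer:::prior_row("boundary_conc", 0, 0.2, metabolite = "S"),
      kinfer:::prior_row("boundary_conc", 0, 0.2, metabolite = "P")
    ),
    formation_energy = list(ids = c("S", "P"), mean = c(-10, -12),
                            covariance = diag(2))
  )
  kin_model(net, pri, kin_experiments("e1"))
}

# named theta at the prior locations (median of each prior)
theta_at_prior <- function(model) {
  unpack_theta(model, model$params$prior_location)
}

set_param <- function(theta, model, kind, value, ...) {
  key <- list(...)
  idx <- which(model$params$kind == kind)
  for (col in names(key)) {
    idx <- idx[!is.na(model$params[[col]][idx]) &
                 model$params[[col]][idx] == key[[col]]]
  }
  stopifnot(length(idx) == 1)
  theta[idx] <- value
  theta
}

# small posterior fit of the allosteric study, shared by analysis tests
ac3_fit_small <- function() {
  memo_fixture("ac3_fit_small", function() {
    st <- ac3_study()
    m <- st$model
    m$sampler <- sampler_config(n_chains = 2, n_warmup = 200, n_draws = 200,
                                seed = 21)
    list(draws = sample_posterior(m), study = st)
  })
}

# wrap explicit theta draws (rows) into a kin_draws object
draws_from_theta <- function(model, theta_matrix) {
  nd <- nrow(theta_matrix)
  a <- array(NA_real_, c(1L, nd, ncol(theta_matrix)),
             dimnames = list(NULL, NULL, model$params$name))
  a[1L, , ] <- theta_matrix
  stats_ <- list(lp = matrix(0, 1L, nd), divergent = matrix(0, 1L, nd))
  exps <- model$experiments$id
  nbal <- length(model$compiled[[1]]$bal_ids)
  steady <- lapply(exps, function(e) array(NA_real_, c(1L, nd, nbal)))
  names(steady) <- exps
  kinfer:::new_kin_draws(model, a, stats_, steady, NULL, method = "manual",
                         seed = 1L)
}

# the benchmark fit used by the acceptance suite: allosteric study, 4 chains
# of 500 warmup + 500 draws
acceptance_fit <- function() {
  memo_fixture("acceptance_fit", function() {
    st <- synthetic_study("allosteric_cycle_3", seed = 1,
                          sampler = sampler_config(n_chains = 4, n_warmup = 500,
                                                   n_draws = 500, seed = 1))
    list(study = st, draws = sample_posterior(st$model))
  })
}
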