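# Synthetic fixtures and measurement simulation.
#
# Three built-in networks cover the testing ladder: a two-reaction linear
# chain with a closed-form steady state, a three-reaction chain exercising
# every regulatory mechanism except phosphorylation, and a five-state cycle
# with a knockout condition and phosphorylation, loosely shaped like the
# methionine cycle.  Ground truth is drawn from the priors (optionally
# offset), steady states are solved, and noisy measurements are generated
# from the measurement model: log-scale sd 0.1 for concentrations and
# enzymes, flux sd 10% of the simulated value.

FIXTURE_BUILDERS <- c("linear_chain_2", "allosteric_cycle_3", "methionine_like_5")

prior_row <- function(parameter, location, scale,
                      enzyme = NA_character_, metabolite = NA_character_,
                      effector = NA_character_, reaction = NA_character_,
                      experiment = NA_character_) {
  tibble::tibble(
    parameter = parameter, enzyme = enzyme, metabolite = metabolite,
    effector = effector, reaction = reaction, experiment = experiment,
    location = location, scale = scale,
    distribution = if (parameter %in% SIGN_FREE_KINDS) "normal" else "lognormal"
  )
}

fixture_linear_chain_2 <- function(n_experiments = 2L) {
  net <- kin_network(
    metabolites = tibble::tibble(id = c("X0", "M", "X1"),
                                 balanced = c(FALSE, TRUE, FALSE)),
    enzymes = tibble::tibble(id = "E2", subunits = 1L),
    reactions = tibble::tibble(
      id = c("r1", "r2"),
      mechanism = c("drain", "irreversible_modular"),
      enzyme = c(NA_character_, "E2"),
      stoichiometry = list(c(X0 = -1, M = 1), c(M = -1, X1 = 1))
    )
  )
  priors <- kin_priors(dplyr::bind_rows(
    prior_row("kcat", log(5), 0.2, enzyme = "E2"),
    prior_row("km", log(1), 0.2, enzyme = "E2", metabolite = "M"),
    prior_row("enzyme_conc", log(1), 0.1, enzyme = "E2"),
    prior_row("boundary_conc", log(1), 0.1, metabolite = "X0"),
    prior_row("boundary_conc", log(1), 0.1, metabolite = "X1"),
    prior_row("drain_flux", 1, 0.05, reaction = "r1")
  ))
  experiments <- kin_experiments(
    id = paste0("e", seq_len(n_experiments)),
    init_conc = rep(list(c(M = 1)), n_experiments)
  )
  list(network = net, priors = priors, experiments = experiments)
}

fixture_allosteric_cycle_3 <- function(n_experiments = 4L) {
  net <- kin_network(
    metabolites = tibble::tibble(id = c("X0", "A", "B", "X1"),
                                 balanced = c(FALSE, TRUE, TRUE, FALSE)),
    enzymes = tibble::tibble(id = c("E1", "E2", "E3"), subunits = c(2L, 1L, 1L)),
    reactions = tibble::tibble(
      id = c("r1", "r2", "r3"),
      mechanism = c("reversible_modular", "reversible_modular",
                    "irreversible_modular"),
      enzyme = c("E1", "E2", "E3"),
      stoichiometry = list(c(X0 = -1, A = 1), c(A = -1, B = 1),
                           c(B = -1, X1 = 1))
    ),
    regulations = tibble::tibble(
      type = c("allosteric_inhibition", "allosteric_activation",
               "competitive_inhibition"),
      enzyme = c("E1", "E1", "E2"),
      effector = c("B", "X0", "X1")
    )
  )
  # per-condition boundary substrate levels create the flux contrast between
  # experiments
  x0_locs <- rep_len(log(c(1, 2.5, 0.4, 1.5, 3, 0.7)), n_experiments)
  exp_ids <- paste0("e", seq_len(n_experiments))
  priors <- kin_priors(
    dplyr::bind_rows(
      prior_row("kcat", log(20), 0.3, enzyme = "E1"),
      prior_row("kcat", log(15), 0.3, enzyme = "E2"),
      prior_row("kcat", log(25), 0.3, enzyme = "E3"),
      prior_row("km", log(1.0), 0.4, enzyme = "E1", metabolite = "X0"),
      prior_row("km", log(0.8), 0.4, enzyme = "E1", metabolite = "A"),
      prior_row("km", log(0.6), 0.4, enzyme = "E2", metabolite = "A"),
      prior_row("km", log(1.2), 0.4, enzyme = "E2", metabolite = "B"),
      prior_row("km", log(0.9), 0.4, enzyme = "E3", metabolite = "B"),
      prior_row("ki", log(1.5), 0.4, enzyme = "E2", metabolite = "X1"),
      prior_row("transfer_constant", log(1), 0.5, enzyme = "E1"),
      prior_row("dissociation_constant", log(1.0), 0.4, enzyme = "E1", effector = "B"),
      prior_row("dissociation_constant", log(1.5), 0.4, enzyme = "E1", effector = "X0"),
      prior_row("enzyme_conc", log(0.01), 0.15, enzyme = "E1"),
      prior_row("enzyme_conc", log(0.01), 0.15, enzyme = "E2"),
      prior_row("enzyme_conc", log(0.01), 0.15, enzyme = "E3"),
      dplyr::bind_rows(lapply(seq_along(exp_ids), function(j) {
        prior_row("boundary_conc", x0_locs[j], 0.15, metabolite = "X0",
                  experiment = exp_ids[j])
      })),
      prior_row("boundary_conc", log(0.5), 0.15, metabolite = "X1")
    ),
    formation_energy = list(
      ids = c("X0", "A", "B"),
      mean = c(-20, -22, -24),
      covariance = matrix(c(1, 0.5, 0.25,
                            0.5, 1, 0.5,
                            0.25, 0.5, 1), 3, 3)
    )
  )
  experiments <- kin_experiments(
    id = exp_ids,
    init_conc = rep(list(c(A = 1, B = 1)), n_experiments)
  )
  list(network = net, priors = priors, experiments = experiments)
}

fixture_methionine_like_5 <- function(n_experiments = 2L) {
  mets <- tibble::tibble(
    id = c("X0", "M1", "M2", "M3", "M4", "M5", "X1", "X2"),
    balanced = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  enz <- tibble::tibble(id = c(paste0("E", 1:8), "K1", "P1"),
                        subunits = c(2L, rep(1L, 7), 1L, 1L))
  net <- kin_network(
    metabolites = mets, enzymes = enz,
    reactions = tibble::tibble(
      id = paste0("r", 1:8),
      mechanism = c("irreversible_modular", rep("reversible_modular", 5),
                    "irreversible_modular", "irreversible_modular"),
      enzyme = paste0("E", 1:8),
      stoichiometry = list(
        c(X0 = -1, M1 = 1), c(M1 = -1, M2 = 1), c(M2 = -1, M3 = 1),
        c(M3 = -1, M4 = 2), c(M4 = -1, M5 = 1), c(M5 = -1, M1 = 1),
        c(M3 = -1, X1 = 1), c(M5 = -1, X2 = 1)
      )
    ),
    regulations = tibble::tibble(
      type = c("allosteric_inhibition", "phosphorylation", "dephosphorylation"),
      enzyme = c("E1", "E4", "E4"),
      effector = c("M5", "K1", "P1")
    )
  )
  km_pairs <- list(
    c("E1", "X0"), c("E2", "M1"), c("E2", "M2"), c("E3", "M2"), c("E3", "M3"),
    c("E4", "M3"), c("E4", "M4"), c("E5", "M4"), c("E5", "M5"),
    c("E6", "M5"), c("E6", "M1"), c("E7", "M3"), c("E8", "M5")
  )
  priors <- kin_priors(
    dplyr::bind_rows(
      dplyr::bind_rows(lapply(1:8, function(i)
        prior_row("kcat", log(20), 0.3, enzyme = paste0("E", i)))),
      dplyr::bind_rows(lapply(km_pairs, function(p)
        prior_row("km", log(1), 0.4, enzyme = p[1], metabolite = p[2]))),
      prior_row("transfer_constant", log(1), 0.5, enzyme = "E1"),
      prior_row("dissociation_constant", log(1), 0.4, enzyme = "E1", effector = "M5"),
      # capacities sized so that the entry flux (E1) is the bottleneck: the
      # internal and exit reactions keep headroom even under the E6 knockout
      # and the 2x stoichiometric amplification through r4
      prior_row("enzyme_conc", log(0.005), 0.15, enzyme = "E1"),
      dplyr::bind_rows(lapply(paste0("E", 2:6), function(e)
        prior_row("enzyme_conc", log(0.02), 0.15, enzyme = e))),
      prior_row("enzyme_conc", log(0.03), 0.15, enzyme = "E7"),
      prior_row("enzyme_conc", log(0.03), 0.15, enzyme = "E8"),
      prior_row("enzyme_conc", log(0.01), 0.15, enzyme = "K1"),
      prior_row("enzyme_conc", log(0.01), 0.15, enzyme = "P1"),
      prior_row("boundary_conc", log(2), 0.15, metabolite = "X0"),
      prior_row("boundary_conc", log(0.5), 0.15, metabolite = "X1"),
      prior_row("boundary_conc", log(0.5), 0.15, metabolite = "X2"),
      prior_row("phos_rate", log(0.5), 0.3, enzyme = "E4", effector = "K1"),
      prior_row("phos_rate", log(0.5), 0.3, enzyme = "E4", effector = "P1")
    ),
    formation_energy = list(
      ids = paste0("M", 1:5),
      mean = c(-20, -22, -24, -23, -25),
      covariance = diag(5) + 0.5 - 0.5 * diag(5)
    )
  )
  ko <- rep(list(character(0)), n_experiments)
  if (n_experiments >= 2) ko[[2]] <- "E6"   # cycle-closure knockout condition
  experiments <- kin_experiments(
    id = paste0("e", seq_len(n_experiments)),
    knockouts = ko,
    init_conc = rep(list(c(M1 = 1, M2 = 1, M3 = 1, M4 = 1, M5 = 1)),
                    n_experiments)
  )
  list(network = net, priors = priors, experiments = experiments)
}

#' Build a benchmark fixture
#'
#' @param builder One of `r FIXTURE_BUILDERS`:
#'   `linear_chain_2` (drain feeding an irreversible Michaelis-Menten step;
#'   closed-form steady state), `allosteric_cycle_3` (three reactions with
#'   allosteric activation/inhibition, competitive inhibition and an
#'   irreversible step) or `methionine_like_5` (five balanced metabolites,
#'   a cycle with a knockout condition and a phosphorylated enzyme).
#' @param n_experiments Number of experimental conditions.
#' @return List with `network`, `priors`, `experiments`.
#' @export
build_fixture <- function(builder, n_experiments = NULL) {
  switch(builder,
    linear_chain_2 = fixture_linear_chain_2(n_experiments %||% 2L),
    allosteric_cycle_3 = fixture_allosteric_cycle_3(n_experiments %||% 4L),
    methionine_like_5 = fixture_methionine_like_5(n_experiments %||% 2L),
    stop("unknown fixture builder '", builder, "'", call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation settings
#'
#' @param conc_sd Measurement sd of concentration/enzyme records on the
#'   natural-log scale (default 0.1, roughly 10 percent error).
#' @param flux_sd_frac Flux measurement sd as a fraction of the simulated
#'   value (default 0.10).
#' @param flux_sd_floor Lower bound (mM/s) on flux sds, guarding near-zero
#'   fluxes.
#' @param seed RNG seed.
#' @return List of class `simulation_recipe`.
#' @export
simulation_recipe <- function(conc_sd = 0.1, flux_sd_frac = 0.10,
                              flux_sd_floor = 1e-6, seed = 1L) {
  # zero sds are allowed as a degenerate override (measurements then equal
  # the modeled values exactly); the floor only guards near-zero fluxes
  stopifnot(conc_sd >= 0, flux_sd_frac >= 0, flux_sd_floor >= 0)
  structure(list(conc_sd = conc_sd, flux_sd_frac = flux_sd_frac,
                 flux_sd_floor = flux_sd_floor, seed = as.integer(seed)),
            class = "simulation_recipe")
}

#' Draw ground-truth parameters from the priors
#'
#' Optionally offsets selected parameters from their prior locations on the
#' unconstrained scale (in units of the prior sd), emulating the realistic
#' situation where in-vitro-derived priors disagree with in-vivo truth.
#'
#' @param model A `kin_model`.
#' @param seed RNG seed.
#' @param offset Named numeric vector: parameter name -> offset in prior sds.
#' @return Named vector of constrained parameter values.
#' @export
draw_true_parameters <- function(model, seed = 1L, offset = NULL) {
  set.seed(seed)
  p <- model$params
  u <- stats::rnorm(nrow(p), p$prior_location, p$prior_scale)
  fe <- model$fe_block
  if (!is.null(fe)) {
    z <- stats::rnorm(length(fe$idx))
    u[fe$idx] <- fe$mean + drop(t(fe$chol) %*% z)
  }
  if (!is.null(offset)) {
    j <- match(names(offset), p$name)
    if (anyNA(j)) stop("unknown parameter in offset: ",
                       names(offset)[which(is.na(j))[1]], call. = FALSE)
    u[j] <- p$prior_location[j] + offset * p$prior_scale[j]
  }
  unpack_theta(model, u)
}

# greedy exact-arithmetic selection of an independent set of free fluxes
select_free_fluxes <- function(net) {
  sb <- stoich_matrix(net, balanced_only = TRUE, rational = TRUE)
  ns <- rat_nullspace(sb$num, sb$den)
  f <- ncol(ns$num)
  chosen <- integer(0)
  for (j in seq_len(nrow(net$reactions))) {
    cand <- c(chosen, j)
    if (rat_rank(ns$num[cand, , drop = FALSE],
                 ns$den[cand, , drop = FALSE]) == length(cand)) {
      chosen <- cand
      if (length(chosen) == f) break
    }
  }
  net$reactions$id[chosen]
}

#' Simulate noisy measurements from ground-truth parameters
#'
#' Solves the steady state of every experiment at `theta_true`, then draws
#' one measurement per balanced metabolite (log-normal, log-sd
#' `recipe$conc_sd`), per non-knocked-out enzyme (log-normal), and per free
#' flux (normal, sd `flux_sd_frac` of the simulated value, floored).  Only a
#' linearly independent set of free fluxes is measured, so
#' [validate_free_fluxes()] is clean by construction.
#'
#' @param model A `kin_model` (its measurement table is ignored).
#' @param theta_true Constrained parameter values.
#' @param recipe A [simulation_recipe()].
#' @return List with `measurements` (a [kin_measurements()] table) and
#'   `truth` (theta, per-experiment steady states, flux decompositions, free
#'   fluxes, seed).
#' @export
simulate_measurements <- function(model, theta_true, recipe = simulation_recipe()) {
  set.seed(recipe$seed)
  theta <- as_theta(model, theta_true)
  named_theta <- stats::setNames(theta, model$params$name)
  net <- model$network
  free_fluxes <- select_free_fluxes(net)
  bal_ids <- net$metabolites$id[net$metabolites$balanced]
  p <- model$params
  rows <- list()
  steady <- list()
  decomposition <- list()
  for (j in seq_len(nrow(model$experiments))) {
    ex <- model$experiments$id[j]
    ss <- solve_steady_state(model, ex, named_theta)
    if (!ss$converged) {
      stop("steady-state failure while simulating experiment '", ex, "'",
           call. = FALSE)
    }
    steady[[ex]] <- ss
    decomposition[[ex]] <- flux_decomposition(model, ex, named_theta, ss$c_star)
    for (m in bal_ids) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        experiment = ex, type = "conc", target = m,
        value = stats::rlnorm(1, log(ss$c_star[[m]]), recipe$conc_sd),
        sd = recipe$conc_sd)
    }
    ko <- model$experiments$knockouts[[j]]
    for (e in setdiff(net$enzymes$id, ko)) {
      E <- theta[which(p$kind == "enzyme_conc" & p$enzyme == e &
                       p$experiment == ex)]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        experiment = ex, type = "enzyme", target = e,
        value = stats::rlnorm(1, log(E), recipe$conc_sd), sd = recipe$conc_sd)
    }
    for (r in free_fluxes) {
      v <- ss$v_star[[r]]
      sd <- max(recipe$flux_sd_frac * abs(v), recipe$flux_sd_floor)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        experiment = ex, type = "flux", target = r,
        value = stats::rnorm(1, v, sd), sd = sd)
    }
  }
  ms <- dplyr::bind_rows(rows)
  class(ms) <- c("kin_measurements", class(ms))
  list(
    measurements = ms,
    truth = list(theta = named_theta, steady = steady,
                 decomposition = decomposition, free_fluxes = free_fluxes,
                 seed = recipe$seed)
  )
}

#' Assign train/validation roles by flux contrast
#'
#' The `k` experiments with the largest total flux magnitude (sum of
#' absolute steady-state fluxes in the truth record) become the validation
#' set, so that validation probes extrapolation to the most extreme flux
#' conditions rather than interpolation.  Deterministic given the truth
#' record.
#'
#' @param experiments A [kin_experiments()] table.
#' @param truth Truth record from [simulate_measurements()].
#' @param n_validation Number of validation experiments.
#' @return The experiments table with updated `role`.
#' @export
split_conditions <- function(experiments, truth, n_validation = 2L) {
  if (nrow(experiments) < 2) {
    stop("need at least 2 experiments to split", call. = FALSE)
  }
  stopifnot(n_validation >= 1, n_validation < nrow(experiments))
  total_flux <- vapply(experiments$id, function(ex)
    sum(abs(truth$steady[[ex]]$v_star)), numeric(1))
  ord <- order(total_flux, decreasing = TRUE)
  experiments$role <- "train"
  experiments$role[ord[seq_len(n_validation)]] <- "validation"
  experiments
}

#' One-call synthetic study
#'
#' Builds a fixture, draws ground truth, simulates measurements and returns
#' the ready-to-fit model together with the truth record.
#'
#' @param builder Fixture builder id (see [build_fixture()]).
#' @param seed RNG seed (drives both the truth draw and the measurement
#'   noise).
#' @param n_experiments Number of conditions (builder default if `NULL`).
#' @param recipe A [simulation_recipe()]; its seed is overridden by `seed`.
#' @param offset Optional prior-offset spec (see [draw_true_parameters()]).
#' @param solver,sampler Optional configs for the returned model.
#' @return List with `model` (measurements attached) and `truth`.
#' @export
synthetic_study <- function(builder, seed = 1L, n_experiments = NULL,
                            recipe = simulation_recipe(), offset = NULL,
                            solver = solver_config(), sampler = sampler_config()) {
  fx <- build_fixture(builder, n_experiments)
  base <- kin_model(fx$network, fx$priors, fx$experiments,
                    solver = solver, sampler = sampler)
  theta_true <- draw_true_parameters(base, seed = seed, offset = offset)
  recipe$seed <- as.integer(seed + 1L)
  sim <- simulate_measurements(base, theta_true, recipe)
  model <- kin_model(fx$network, fx$priors, fx$experiments, sim$measurements,
                     solver = solver, sampler = sampler)
  list(model = model, truth = sim$truth)
}
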