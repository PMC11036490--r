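# Factorized rate law: reversibility, saturation, allostery,
# phosphorylation, and their assembly into reaction fluxes and the ODE
# right-hand side.
#
# These functions are the readable reference path, written directly from the
# factor formulas; the sampler uses the batched C++ evaluator, and the test
# suite holds the two paths together.

#' Coerce a parameter value object to the packed numeric vector
#'
#' Accepts a named numeric vector or a data frame with `name` and `value`
#' columns; returns values ordered as in `model$params`.
#' @param model A `kin_model`.
#' @param theta Named numeric vector or data frame.
#' @return Numeric vector of length `nrow(model$params)`.
#' @export
as_theta <- function(model, theta) {
  if (is.data.frame(theta)) theta <- stats::setNames(theta$value, theta$name)
  missing <- setdiff(model$params$name, names(theta))
  if (length(missing) > 0) {
    stop("theta is missing parameter '", missing[1], "'", call. = FALSE)
  }
  unname(theta[model$params$name])
}

#' Standard Gibbs energy change of a reaction
#'
#' The stoichiometry-weighted sum of the participating metabolites' standard
#' formation energies, \eqn{\Delta_r G^\circ = \sum_i s_i \Delta_f G^\circ_i}.
#'
#' @param net A `kin_network`.
#' @param reaction_id Reaction id (must not be a drain).
#' @param formation_energy Named vector of formation energies (kJ/mol).
#' @return \eqn{\Delta_r G^\circ} in kJ/mol.
#' @export
reaction_delta_g_standard <- function(net, reaction_id, formation_energy) {
  i <- match(reaction_id, net$reactions$id)
  if (is.na(i)) stop("unknown reaction '", reaction_id, "'", call. = FALSE)
  if (net$reactions$mechanism[i] == "drain") {
    stop("reaction '", reaction_id, "' is a drain; drains carry no thermodynamics",
         call. = FALSE)
  }
  st <- net$reactions$stoichiometry[[i]]
  missing <- setdiff(st$ids, names(formation_energy))
  if (length(missing) > 0) {
    stop("no formation energy for metabolite '", missing[1], "'", call. = FALSE)
  }
  sum((st$num / st$den) * formation_energy[st$ids])
}

#' Thermodynamic reversibility factor
#'
#' \eqn{1 - \exp((\Delta_r G^\circ + RT \ln Q)/RT) = 1 - Q/K_{eq}} with
#' \eqn{K_{eq} = \exp(-\Delta_r G^\circ / RT)}.  Zero at equilibrium
#' (\eqn{Q = K_{eq}}), positive for a thermodynamically downhill reaction,
#' approaching 1 as the reaction becomes strongly favourable.  Irreversible
#' mechanisms use the constant factor 1.
#'
#' @param delta_g Standard reaction Gibbs energy (kJ/mol).
#' @param Q Reaction quotient (products over substrates, stoichiometry
#'   powers); must be positive.
#' @param temperature Temperature (K).
#' @param irreversible If `TRUE`, return exactly 1.
#' @return Factor in \eqn{(-\infty, 1]}.
#' @export
reversibility <- function(delta_g, Q, temperature = 298.15, irreversible = FALSE) {
  if (irreversible) return(1)
  if (any(Q <= 0)) stop("reaction quotient must be positive", call. = FALSE)
  stopifnot(temperature > 0)
  RT <- R_GAS * temperature
  1 - exp(delta_g / RT + log(Q))
}

#' Enzyme saturation under the common modular rate law
#'
#' With normalized concentrations \eqn{x_i = C_i / K_{m,i}} and absolute
#' stoichiometries \eqn{|s_i|}, the numerator is
#' \eqn{\prod_{substrates} x_i^{|s_i|}} and the denominator
#' \eqn{D = \prod_{sub}(1+x_i)^{|s_i|} + \prod_{prod}(1+x_j)^{|s_j|} - 1
#'   + \sum_k C_k / K_{i,k}}; the product binding polynomial is omitted for
#' irreversible mechanisms.  Returns both the saturation `num/D` and the free
#' enzyme ratio `1/D` (which feeds the allostery factor).
#'
#' @param net A `kin_network`.
#' @param reaction_id Enzymatic reaction id.
#' @param conc Named concentration vector (mM), covering all participants and
#'   declared competitive inhibitors.
#' @param km Named vector of Michaelis constants (mM) keyed by metabolite id
#'   (for this reaction's enzyme).
#' @param ki Named vector of competitive-inhibition constants (mM) keyed by
#'   inhibitor metabolite id.
#' @return List with `saturation` and `free_enzyme_ratio`.
#' @export
saturation <- function(net, reaction_id, conc, km, ki = NULL) {
  i <- match(reaction_id, net$reactions$id)
  if (is.na(i)) stop("unknown reaction '", reaction_id, "'", call. = FALSE)
  rx <- net$reactions[i, ]
  if (rx$mechanism == "drain") stop("drains have no saturation factor", call. = FALSE)
  st <- rx$stoichiometry[[1]]
  coef <- st$num / st$den
  subs <- st$ids[coef < 0]; prods <- st$ids[coef > 0]
  s_sub <- abs(coef[coef < 0]); s_prod <- coef[coef > 0]
  need <- if (rx$mechanism == "reversible_modular") c(subs, prods) else subs
  for (m in need) {
    if (is.na(km[m])) {
      stop("missing Km for (", rx$enzyme, ", ", m, ")", call. = FALSE)
    }
  }
  stopifnot(all(conc[need] > 0), all(km[need] > 0))
  x_sub <- conc[subs] / km[subs]
  num <- prod(x_sub^s_sub)
  D <- prod((1 + x_sub)^s_sub)
  if (rx$mechanism == "reversible_modular") {
    x_prod <- conc[prods] / km[prods]
    D <- D + prod((1 + x_prod)^s_prod) - 1
  }
  inhibitors <- net$regulations$effector[
    net$regulations$type == "competitive_inhibition" &
      net$regulations$enzyme == rx$enzyme]
  for (m in inhibitors) {
    if (is.null(ki) || is.na(ki[m])) {
      stop("missing Ki for (", rx$enzyme, ", ", m, ")", call. = FALSE)
    }
    D <- D + conc[m] / ki[m]
  }
  list(saturation = unname(num / D), free_enzyme_ratio = unname(1 / D))
}

#' Generalized Monod-Wyman-Changeux allostery factor
#'
#' Two-state model: the enzyme balances between a relaxed (active) and a
#' tense (inactive) conformation with transfer constant `L`; inhibitors bind
#' the tense state, activators the relaxed state, and the free-enzyme ratio
#' couples allostery to active-site occupancy.  The activity factor is
#' \deqn{1 / (1 + L (r (1 + \sum C/K_{inh}) / (1 + \sum C/K_{act}))^n)}
#' with `r` the free enzyme ratio and `n` the subunit count.
#'
#' @param L Transfer constant (\eqn{\ge 0}; 0 disables allostery).
#' @param free_enzyme_ratio From [saturation()].
#' @param activators,inhibitors Vectors of effector ratios \eqn{C/K}.
#' @param n Subunit count (positive integer).
#' @return Factor in (0, 1].
#' @export
allostery <- function(L, free_enzyme_ratio, activators = numeric(0),
                      inhibitors = numeric(0), n = 1) {
  if (n < 1 || n != round(n)) stop("subunit count must be a positive integer",
                                   call. = FALSE)
  stopifnot(L >= 0, all(activators >= 0), all(inhibitors >= 0))
  q <- free_enzyme_ratio * (1 + sum(inhibitors)) / (1 + sum(activators))
  1 / (1 + L * q^n)
}

#' Phosphorylation factor
#'
#' Activity reduction from coupled phosphorylation/dephosphorylation,
#' \eqn{(1 + p/d)^{-n}} with kinase weight `p`, phosphatase weight `d` and
#' subunit count `n`; equals 1 when there is no kinase activity and is
#' strictly decreasing in `p`.
#'
#' @param p Kinase weight (\eqn{\ge 0}).
#' @param d Phosphatase weight (must be positive).
#' @param n Subunit count.
#' @return Factor in (0, 1].
#' @export
phosphorylation_factor <- function(p, d, n = 1) {
  if (any(d <= 0)) stop("phosphatase weight must be positive", call. = FALSE)
  stopifnot(all(p >= 0))
  (1 + p / d)^(-n)
}

# full concentration vector for an experiment: balanced from `conc`,
# unbalanced from the boundary_conc parameters
full_conc <- function(model, experiment_id, theta, conc_balanced) {
  net <- model$network
  mets <- net$metabolites$id
  bal <- net$metabolites$balanced
  C <- stats::setNames(numeric(length(mets)), mets)
  C[mets[bal]] <- conc_balanced[mets[bal]]
  for (m in mets[!bal]) {
    j <- which(model$params$kind == "boundary_conc" &
               model$params$metabolite == m &
               model$params$experiment == experiment_id)
    C[m] <- theta[j]
  }
  C
}

#' Reaction flux and its factor decomposition
#'
#' Computes one reaction's flux in one experiment as the product
#' `enzyme x kcat x reversibility x saturation x allostery x phosphorylation`
#' (mM/s).  A knocked-out enzyme gives flux exactly 0; a drain returns its
#' flux parameter with all factors set to 1.
#'
#' @param model A `kin_model`.
#' @param reaction_id,experiment_id Ids.
#' @param theta Parameter values (named vector or data frame, see
#'   [as_theta()]).
#' @param conc Named concentrations (mM) of the balanced metabolites (and
#'   optionally others; boundary values are taken from `theta`).
#' @return A one-row tibble with the six factors and the flux.
#' @export
reaction_flux <- function(model, reaction_id, experiment_id, theta, conc) {
  theta <- as_theta(model, theta)
  net <- model$network
  i <- match(reaction_id, net$reactions$id)
  if (is.na(i)) stop("unknown reaction '", reaction_id, "'", call. = FALSE)
  rx <- net$reactions[i, ]
  out <- tibble::tibble(reaction = reaction_id, experiment = experiment_id,
                        enzyme = 1, kcat = 1, reversibility = 1, saturation = 1,
                        allostery = 1, phosphorylation = 1, flux = NA_real_)
  params <- model$params
  if (rx$mechanism == "drain") {
    j <- which(params$kind == "drain_flux" & params$reaction == reaction_id &
               params$experiment == experiment_id)
    out$flux <- theta[j]
    return(out)
  }
  C <- full_conc(model, experiment_id, theta, conc)
  e <- rx$enzyme
  ko <- model$experiments$knockouts[[match(experiment_id, model$experiments$id)]]
  kcat <- theta[which(params$kind == "kcat" & params$enzyme == e)]
  E <- if (e %in% ko) 0 else
    theta[which(params$kind == "enzyme_conc" & params$enzyme == e &
                params$experiment == experiment_id)]
  km_idx <- which(params$kind == "km" & params$enzyme == e)
  km <- stats::setNames(theta[km_idx], params$metabolite[km_idx])
  ki_idx <- which(params$kind == "ki" & params$enzyme == e)
  ki <- stats::setNames(theta[ki_idx], params$metabolite[ki_idx])
  st <- rx$stoichiometry[[1]]
  coef <- st$num / st$den
  rev <- 1
  if (rx$mechanism == "reversible_modular") {
    fe_idx <- which(params$kind == "formation_energy")
    fe <- stats::setNames(theta[fe_idx], params$metabolite[fe_idx])
    dg <- reaction_delta_g_standard(net, reaction_id, fe)
    Q <- prod(C[st$ids]^coef)
    rev <- reversibility(dg, Q, model$temperature)
  }
  satr <- saturation(net, reaction_id, C, km, ki)
  n <- net$enzymes$subunits[match(e, net$enzymes$id)]
  allo <- 1
  regs <- net$regulations[net$regulations$enzyme == e, , drop = FALSE]
  acts <- regs$effector[regs$type == "allosteric_activation"]
  inhs <- regs$effector[regs$type == "allosteric_inhibition"]
  if (length(acts) + length(inhs) > 0) {
    L <- theta[which(params$kind == "transfer_constant" & params$enzyme == e)]
    ratio <- function(mm) {
      K <- theta[which(params$kind == "dissociation_constant" &
                       params$enzyme == e & params$effector == mm)]
      C[mm] / K
    }
    allo <- allostery(L, satr$free_enzyme_ratio,
                      vapply(acts, ratio, numeric(1)),
                      vapply(inhs, ratio, numeric(1)), n)
  }
  phos <- 1
  p_reg <- regs[regs$type == "phosphorylation", , drop = FALSE]
  d_reg <- regs[regs$type == "dephosphorylation", , drop = FALSE]
  if (nrow(p_reg) > 0) {
    rate <- function(rg_type, eff) {
      theta[which(params$kind == "phos_rate" & params$enzyme == e &
                  params$effector == eff & params$experiment == experiment_id &
                  params$ptm_type == rg_type)]
    }
    p <- sum(vapply(p_reg$effector, function(f) rate("phosphorylation", f), numeric(1)))
    d <- if (nrow(d_reg) > 0) {
      sum(vapply(d_reg$effector, function(f) rate("dephosphorylation", f), numeric(1)))
    } else 1
    phos <- phosphorylation_factor(p, d, n)
  }
  out$enzyme <- unname(E); out$kcat <- unname(kcat); out$reversibility <- unname(rev)
  out$saturation <- satr$saturation; out$allostery <- unname(allo)
  out$phosphorylation <- unname(phos)
  out$flux <- unname(E * kcat * rev * satr$saturation * allo * phos)
  out
}

#' Flux decomposition for all reactions of one experiment
#'
#' @inheritParams reaction_flux
#' @param conc_balanced Named concentrations of the balanced metabolites (mM),
#'   typically a solved steady state.
#' @return Tibble with one row per reaction (six factors and the flux).
#' @export
flux_decomposition <- function(model, experiment_id, theta, conc_balanced) {
  dplyr::bind_rows(lapply(model$network$reactions$id, function(r) {
    reaction_flux(model, r, experiment_id, theta, conc_balanced)
  }))
}

#' ODE right-hand side for the balanced metabolites
#'
#' \eqn{dC/dt = S_{bal} \, v(E, C, \theta)} with unbalanced metabolites held
#' at their boundary-condition parameter values.  (The growth-dilution term
#' is neglected: intracellular turnover is assumed fast relative to growth.)
#'
#' @inheritParams flux_decomposition
#' @return Named vector of time derivatives (mM/s) for balanced metabolites.
#' @export
ode_rhs <- function(model, experiment_id, theta, conc_balanced) {
  theta <- stats::setNames(as_theta(model, theta), model$params$name)
  dec <- flux_decomposition(model, experiment_id, theta, conc_balanced)
  cm <- model$compiled[[experiment_id]]
  drop(cm$S_bal %*% dec$flux)
}

# --- engine wrappers --------------------------------------------------------

# Batched engine call: theta (npar x B), lnC (nbal x B).
eng_eval <- function(cm, theta, lnC, want_factors = FALSE) {
  kin_eval_cpp(cm, theta, lnC, want_factors)
}

# Single evaluation convenience: returns list(flux, fbal) as vectors.
eng_eval1 <- function(cm, theta, lnC, want_factors = FALSE) {
  r <- kin_eval_cpp(cm, matrix(theta, ncol = 1), matrix(lnC, ncol = 1), want_factors)
  out <- lapply(r, drop)
  out
}
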