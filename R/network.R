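# Network specification: topology, mechanisms, regulation.

MECHANISMS <- c("reversible_modular", "irreversible_modular", "drain")
REGULATION_TYPES <- c(
  "competitive_inhibition", "allosteric_activation", "allosteric_inhibition",
  "phosphorylation", "dephosphorylation"
)

#' Define a metabolic network
#'
#' Assembles the structural description of a kinetic model: metabolites (with
#' a `balanced` flag separating state variables from boundary species),
#' enzymes, reactions (with a mechanism and exact-rational stoichiometry),
#' and regulatory interactions.
#'
#' Balanced metabolites are constrained to steady state; unbalanced ones act
#' as per-experiment boundary conditions.  A `drain` reaction has no enzyme
#' and carries a fixed (per-experiment) flux parameter, representing exchange
#' with unmodeled pathways.
#'
#' @param metabolites Data frame with columns `id`, `balanced` (logical) and
#'   optionally `compartment` (default `"c"`).
#' @param enzymes Data frame with columns `id` and optionally `subunits`
#'   (positive integer, default 1).
#' @param reactions Data frame with columns `id`, `mechanism` (one of
#'   `r MECHANISMS`), `enzyme` (`NA` for drains) and `stoichiometry`, a list
#'   column of named vectors (coefficients may be numbers or strings like
#'   `"1/2"`; substrates negative, products positive).
#' @param regulations Optional data frame with columns `type` (one of
#'   `r REGULATION_TYPES`), `enzyme` (the regulated enzyme) and `effector`
#'   (a metabolite id, or a modifying-enzyme id for the phosphorylation
#'   types).
#' @return An object of class `kin_network`.
#' @examples
#' net <- kin_network(
#'   metabolites = tibble::tibble(id = c("X0", "M", "X1"),
#'                                balanced = c(FALSE, TRUE, FALSE)),
#'   enzymes = tibble::tibble(id = "E2"),
#'   reactions = tibble::tibble(
#'     id = c("r1", "r2"),
#'     mechanism = c("drain", "irreversible_modular"),
#'     enzyme = c(NA, "E2"),
#'     stoichiometry = list(c(X0 = -1, M = 1), c(M = -1, X1 = 1))
#'   )
#' )
#' stoich_matrix(net)
#' @export
kin_network <- function(metabolites, enzymes, reactions, regulations = NULL) {
  metabolites <- tibble::as_tibble(metabolites)
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  metabolites <- metabolites[, c("id", "compartment", "balanced")]
  enzymes <- tibble::as_tibble(enzymes)
  if (!"subunits" %in% names(enzymes)) enzymes$subunits <- rep(1L, nrow(enzymes))
  enzymes <- enzymes[, c("id", "subunits")]
  reactions <- tibble::as_tibble(reactions)
  if (is.null(regulations)) {
    regulations <- tibble::tibble(type = character(0), enzyme = character(0),
                                  effector = character(0))
  }
  regulations <- tibble::as_tibble(regulations)

  # normalize stoichiometry to exact rational records
  reactions$stoichiometry <- lapply(reactions$stoichiometry, function(s) {
    ids <- names(s)
    parsed <- lapply(s, rat_parse)
    list(
      ids = ids,
      num = vapply(parsed, `[[`, numeric(1), "num"),
      den = vapply(parsed, `[[`, numeric(1), "den")
    )
  })
  net <- structure(
    list(metabolites = metabolites, enzymes = enzymes,
         reactions = reactions, regulations = regulations),
    class = "kin_network"
  )
  validate_network(net)
  net
}

#' Validate a network specification
#'
#' Checks all cross-references and structural invariants; every error names
#' the offending entity id.  A rank-deficient balanced stoichiometric
#' submatrix (a conserved moiety) is reported as a warning, not an error.
#'
#' @param net A `kin_network`.
#' @return `net`, invisibly.
#' @export
validate_network <- function(net) {
  m <- net$metabolites; e <- net$enzymes; r <- net$reactions; g <- net$regulations
  fail <- function(...) stop("network validation: ", ..., call. = FALSE)
  if (anyDuplicated(m$id)) fail("duplicated metabolite id '", m$id[duplicated(m$id)][1], "'")
  if (nrow(e) > 0 && anyDuplicated(e$id)) fail("duplicated enzyme id '", e$id[duplicated(e$id)][1], "'")
  if (anyDuplicated(r$id)) fail("duplicated reaction id '", r$id[duplicated(r$id)][1], "'")
  if (nrow(e) > 0 && any(e$subunits < 1 | e$subunits != round(e$subunits))) {
    fail("enzyme '", e$id[which(e$subunits < 1)[1]], "' has non-positive-integer subunits")
  }
  for (i in seq_len(nrow(r))) {
    rx <- r[i, ]
    if (!rx$mechanism %in% MECHANISMS) {
      fail("reaction '", rx$id, "' has unknown mechanism '", rx$mechanism, "'")
    }
    st <- rx$stoichiometry[[1]]
    missing_met <- setdiff(st$ids, m$id)
    if (length(missing_met) > 0) {
      fail("reaction '", rx$id, "' references undeclared metabolite '", missing_met[1], "'")
    }
    if (rx$mechanism == "drain") {
      if (!is.na(rx$enzyme)) fail("drain reaction '", rx$id, "' must not have an enzyme")
    } else {
      if (is.na(rx$enzyme)) fail("reaction '", rx$id, "' needs an enzyme")
      if (!rx$enzyme %in% e$id) {
        fail("reaction '", rx$id, "' references undeclared enzyme '", rx$enzyme, "'")
      }
    }
  }
  for (i in seq_len(nrow(g))) {
    rg <- g[i, ]
    if (!rg$type %in% REGULATION_TYPES) {
      fail("regulation of enzyme '", rg$enzyme, "' has unknown type '", rg$type, "'")
    }
    if (!rg$enzyme %in% e$id) {
      fail("regulation references undeclared enzyme '", rg$enzyme, "'")
    }
    if (rg$type %in% c("phosphorylation", "dephosphorylation")) {
      if (!rg$effector %in% e$id) {
        fail("regulation of '", rg$enzyme, "' references undeclared modifying enzyme '",
             rg$effector, "'")
      }
    } else if (!rg$effector %in% m$id) {
      fail("regulation of '", rg$enzyme, "' references undeclared effector '",
           rg$effector, "'")
    }
  }
  has_drain <- any(r$mechanism == "drain")
  if (all(m$balanced) && !has_drain) {
    fail("all metabolites are balanced and no drain exists: ",
         "the only steady state is trivial")
  }
  sb <- stoich_matrix(net, balanced_only = TRUE, rational = TRUE)
  if (nrow(sb$num) > 0) {
    rk <- rat_rank(sb$num, sb$den)
    if (rk < nrow(sb$num)) {
      warning("balanced stoichiometric submatrix is rank deficient (rank ", rk,
              " < ", nrow(sb$num), " balanced metabolites): ",
              "the network contains a conserved moiety", call. = FALSE)
    }
  }
  invisible(net)
}

#' Stoichiometric matrix of a network
#'
#' Rows are metabolites, columns reactions; element (i, j) is the signed
#' coefficient of metabolite i in reaction j, exactly as declared.
#'
#' @param net A `kin_network`.
#' @param balanced_only Restrict rows to balanced metabolites.
#' @param rational Return exact numerator/denominator matrices instead of a
#'   numeric matrix.
#' @return A numeric matrix with dimnames, or a list `num`/`den` when
#'   `rational = TRUE`.
#' @export
stoich_matrix <- function(net, balanced_only = FALSE, rational = FALSE) {
  mets <- if (balanced_only) net$metabolites$id[net$metabolites$balanced] else net$metabolites$id
  rxns <- net$reactions$id
  num <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  den <- matrix(1, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- net$reactions$stoichiometry[[j]]
    keep <- st$ids %in% mets
    num[st$ids[keep], j] <- st$num[keep]
    den[st$ids[keep], j] <- st$den[keep]
  }
  if (rational) list(num = num, den = den) else num / den
}

#' @export
print.kin_network <- function(x, ...) {
  cat("<kin_network> ", nrow(x$metabolites), " metabolites (",
      sum(x$metabolites$balanced), " balanced), ",
      nrow(x$enzymes), " enzymes, ", nrow(x$reactions), " reactions, ",
      nrow(x$regulations), " regulations\n", sep = "")
  invisible(x)
}

#' Define the experimental conditions
#'
#' @param id Character vector of experiment ids.
#' @param role `"train"` or `"validation"` per experiment.
#' @param knockouts List column (one set of enzyme ids per experiment).
#' @param init_conc List column of named vectors: initial guesses (mM) for the
#'   balanced metabolite concentrations used by the steady-state solver.
#' @return A tibble with class `kin_experiments`.
#' @export
kin_experiments <- function(id, role = "train", knockouts = NULL, init_conc = NULL) {
  n <- length(id)
  if (is.null(knockouts)) knockouts <- rep(list(character(0)), n)
  if (is.null(init_conc)) init_conc <- rep(list(numeric(0)), n)
  out <- tibble::tibble(id = id, role = rep_len(role, n),
                        knockouts = knockouts, init_conc = init_conc)
  class(out) <- c("kin_experiments", class(out))
  out
}

validate_experiments <- function(experiments, net) {
  stopifnot(!anyDuplicated(experiments$id))
  if (!all(experiments$role %in% c("train", "validation"))) {
    stop("experiment role must be 'train' or 'validation'", call. = FALSE)
  }
  for (i in seq_len(nrow(experiments))) {
    ko <- experiments$knockouts[[i]]
    bad <- setdiff(ko, net$enzymes$id)
    if (length(bad) > 0) {
      stop("experiment '", experiments$id[i], "' knocks out undeclared enzyme '",
           bad[1], "'", call. = FALSE)
    }
    ic <- experiments$init_conc[[i]]
    bad <- setdiff(names(ic), net$metabolites$id)
    if (length(bad) > 0) {
      stop("experiment '", experiments$id[i],
           "' has an initial concentration for undeclared metabolite '",
           bad[1], "'", call. = FALSE)
    }
    if (any(ic <= 0)) {
      stop("experiment '", experiments$id[i],
           "' has a non-positive initial concentration", call. = FALSE)
    }
  }
  invisible(experiments)
}

#' Define a measurement table
#'
#' @param experiment,type,target,value,sd Vectors describing one measurement
#'   per row.  `type` is one of `"conc"`, `"enzyme"`, `"flux"`; `target` is a
#'   metabolite, enzyme or reaction id; concentrations are in mM, fluxes in
#'   mM/s; `sd` is the known measurement standard deviation (natural-log
#'   scale for `conc`/`enzyme`, mM/s for `flux`).
#' @return A tibble with class `kin_measurements`.
#' @export
kin_measurements <- function(experiment, type, target, value, sd) {
  out <- tibble::tibble(experiment = experiment, type = type, target = target,
                        value = as.numeric(value), sd = as.numeric(sd))
  class(out) <- c("kin_measurements", class(out))
  out
}

validate_measurements <- function(ms, net, experiments) {
  for (i in seq_len(nrow(ms))) {
    r <- ms[i, ]
    if (!r$experiment %in% experiments$id) {
      stop("measurement ", i, " references undeclared experiment '",
           r$experiment, "'", call. = FALSE)
    }
    if (!r$type %in% c("conc", "enzyme", "flux")) {
      stop("measurement ", i, " has unknown type '", r$type, "'", call. = FALSE)
    }
    ok <- switch(r$type,
      conc = r$target %in% net$metabolites$id,
      enzyme = r$target %in% net$enzymes$id,
      flux = r$target %in% net$reactions$id
    )
    if (!ok) {
      stop("measurement ", i, " (", r$type, ") references undeclared target '",
           r$target, "'", call. = FALSE)
    }
    if (r$sd <= 0) {
      stop("measurement ", i, " of '", r$target, "' has non-positive sd", call. = FALSE)
    }
    if (r$type %in% c("conc", "enzyme") && r$value <= 0) {
      stop("measurement ", i, " of '", r$target, "' has non-positive value", call. = FALSE)
    }
  }
  invisible(ms)
}

#' Check flux measurements against the network's free fluxes
#'
#' At steady state the balanced rows of the stoichiometric matrix constrain
#' the flux vector to an `f`-dimensional null space, `f = #reactions - rank`.
#' Measuring more than `f` fluxes in one experiment, or a linearly dependent
#' set of fluxes, double-counts information.  Both situations are reported as
#' warnings (returned as a character vector), never errors.
#'
#' @param net A `kin_network`.
#' @param ms A measurement table (see [kin_measurements()]).
#' @return Character vector of warnings (empty if the measurements are fine).
#' @export
validate_free_fluxes <- function(net, ms) {
  sb <- stoich_matrix(net, balanced_only = TRUE, rational = TRUE)
  nrxn <- nrow(net$reactions)
  r <- rat_rank(sb$num, sb$den)
  f <- nrxn - r
  ns <- rat_nullspace(sb$num, sb$den)   # nrxn x f rational basis
  warnings <- character(0)
  flux_ms <- ms[ms$type == "flux", , drop = FALSE]
  for (ex in unique(flux_ms$experiment)) {
    targets <- unique(flux_ms$target[flux_ms$experiment == ex])
    k <- length(targets)
    if (k > f) {
      warnings <- c(warnings, paste0(
        "experiment '", ex, "': ", k, " flux measurements but only ", f,
        " free fluxes; information will be double counted"))
      next
    }
    idx <- match(targets, net$reactions$id)
    sub_rank <- rat_rank(ns$num[idx, , drop = FALSE], ns$den[idx, , drop = FALSE])
    if (sub_rank < k) {
      warnings <- c(warnings, paste0(
        "experiment '", ex, "': measured fluxes {",
        paste(targets, collapse = ", "),
        "} are linearly dependent at steady state"))
    }
  }
  warnings
}
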