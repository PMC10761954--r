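#' Chemical species of a transaminase reaction network
#'
#' A species is one amine enantiomer or the cognate ketone of a compound
#' (one carbon skeleton). The three species of a compound are grouped by
#' `compound_id`, e.g. `S-D2`, `R-D2` and `A2` all belong to compound `D2`.
#'
#' @param id Short unique identifier, e.g. `"S-D2"`.
#' @param role One of `"amine_S"`, `"amine_R"`, `"ketone"`.
#' @param compound_id Identifier of the carbon skeleton, e.g. `"D2"`.
#' @return A one-row `data.frame` with columns `id`, `role`, `compound_id`.
#' @examples
#' species("S-D2", "amine_S", "D2")
#' @export
species <- function(id, role, compound_id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  role <- match.arg(role, c("amine_S", "amine_R", "ketone"))
  stopifnot(is.character(compound_id), length(compound_id) == 1L)
  data.frame(id = id, role = role, compound_id = compound_id,
             stringsAsFactors = FALSE)
}

#' Elemental reaction: one amine-enantiomer/ketone interconversion
#'
#' An elemental reaction couples one amine enantiomer to its cognate ketone
#' through the two cofactor states of the enzyme:
#' oxidative deamination (OD), amine + E-PLP -> ketone + E-PMP, with rate
#' `v_OD = k_OD [amine][E-PLP]`, and reductive amination (RA),
#' ketone + E-PMP -> amine + E-PLP, with rate `v_RA = k_RA [ketone][E-PMP]`.
#' Strict stereoselectivity is expressed as `k = 0`, never by omitting the
#' reaction, so the same topology serves wild-type and engineered enzymes.
#'
#' @param label Reaction label, conventionally `"<family>^<S|R>"`, e.g.
#'   `"II^S"`.
#' @param donor Id of the amine species (the amino donor).
#' @param ketone Id of the ketone species of the same compound.
#' @param k_OD,k_RA Second-order rate constants, mM^-1 h^-1; must be >= 0.
#' @return An object of class `elemental_reaction`.
#' @examples
#' elemental_reaction("II^S", "S-D2", "A2", k_OD = 2, k_RA = 4)
#' @export
elemental_reaction <- function(label, donor, ketone, k_OD, k_RA) {
  stopifnot(is.character(label), length(label) == 1L,
            is.character(donor), is.character(ketone))
  if (!is.numeric(k_OD) || length(k_OD) != 1L || is.na(k_OD) || k_OD < 0)
    stop("k_OD must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(k_RA) || length(k_RA) != 1L || is.na(k_RA) || k_RA < 0)
    stop("k_RA must be a single nonnegative number", call. = FALSE)
  structure(list(label = label, donor = donor, ketone = ketone,
                 k_OD = as.numeric(k_OD), k_RA = as.numeric(k_RA)),
            class = "elemental_reaction")
}

#' @export
print.elemental_reaction <- function(x, ...) {
  cat(sprintf("%s: %s <-> %s   k_OD = %g, k_RA = %g mM^-1 h^-1\n",
              x$label, x$donor, x$ketone, x$k_OD, x$k_RA))
  invisible(x)
}

#' Reaction system: species, elemental reactions and enzyme
#'
#' The object consumed by the ODE builder. Internal units are fixed to mM
#' and hours; [read_system_config()] converts declared uM/minute inputs on
#' load. Species referenced by reactions but absent from
#' `initial_concentrations` start at 0 mM.
#'
#' @param species `data.frame` with columns `id`, `role`, `compound_id`
#'   (rows typically built with [species()] and `rbind`).
#' @param reactions List of [elemental_reaction()] objects.
#' @param enzyme_total Total enzyme concentration, mM; must be > 0 for
#'   simulation.
#' @param initial_concentrations Named numeric vector, mM, keyed by species
#'   id.
#' @param initial_E_PLP_fraction Fraction of the enzyme in the E-PLP state
#'   at t = 0, in \[0, 1\]. Default 1 (holoenzyme fully in the internal
#'   aldimine state).
#' @return An object of class `reaction_system`.
#' @examples
#' sp <- rbind(species("S-D2", "amine_S", "D2"),
#'             species("R-D2", "amine_R", "D2"),
#'             species("A2", "ketone", "D2"))
#' rx <- list(elemental_reaction("II^S", "S-D2", "A2", 2, 4),
#'            elemental_reaction("II^R", "R-D2", "A2", 0.1, 0.2))
#' reaction_system(sp, rx, enzyme_total = 0.1,
#'                 initial_concentrations = c("S-D2" = 50, "A2" = 50))
#' @export
reaction_system <- function(species, reactions, enzyme_total,
                            initial_concentrations = numeric(),
                            initial_E_PLP_fraction = 1) {
  errs <- character()
  if (!is.data.frame(species) ||
      !all(c("id", "role", "compound_id") %in% names(species)))
    stop("species must be a data.frame with columns id, role, compound_id",
         call. = FALSE)
  if (anyDuplicated(species$id))
    errs <- c(errs, sprintf("duplicated species ids: %s",
                            paste(unique(species$id[duplicated(species$id)]),
                                  collapse = ", ")))
  if (!all(species$role %in% c("amine_S", "amine_R", "ketone")))
    errs <- c(errs, "species roles must be amine_S, amine_R or ketone")
  ket <- species[species$role == "ketone", ]
  if (anyDuplicated(ket$compound_id))
    errs <- c(errs, "a compound may declare at most one ketone species")
  if (!is.list(reactions) ||
      !all(vapply(reactions, inherits, logical(1), "elemental_reaction")))
    stop("reactions must be a list of elemental_reaction objects",
         call. = FALSE)
  for (r in reactions) {
    for (sid in c(r$donor, r$ketone)) {
      if (!sid %in% species$id)
        errs <- c(errs, sprintf("reaction %s references undeclared species '%s'",
                                r$label, sid))
    }
    if (r$donor %in% species$id && r$ketone %in% species$id) {
      drow <- species[species$id == r$donor, ]
      krow <- species[species$id == r$ketone, ]
      if (!drow$role %in% c("amine_S", "amine_R"))
        errs <- c(errs, sprintf("reaction %s donor '%s' is not an amine",
                                r$label, r$donor))
      if (krow$role != "ketone")
        errs <- c(errs, sprintf("reaction %s ketone '%s' has role %s",
                                r$label, r$ketone, krow$role))
      if (drow$compound_id != krow$compound_id)
        errs <- c(errs, sprintf(
          "reaction %s couples species of different compounds (%s vs %s)",
          r$label, drow$compound_id, krow$compound_id))
    }
  }
  if (anyDuplicated(vapply(reactions, `[[`, character(1), "label")))
    errs <- c(errs, "reaction labels must be unique")
  if (!is.numeric(enzyme_total) || length(enzyme_total) != 1L ||
      is.na(enzyme_total) || enzyme_total < 0)
    errs <- c(errs, "enzyme_total must be a single nonnegative number (mM)")
  if (length(initial_concentrations)) {
    if (is.null(names(initial_concentrations)) ||
        any(!nzchar(names(initial_concentrations))))
      errs <- c(errs, "initial_concentrations must be a named vector")
    else {
      unknown <- setdiff(names(initial_concentrations), species$id)
      if (length(unknown))
        errs <- c(errs, sprintf("initial concentration for undeclared species: %s",
                                paste(unknown, collapse = ", ")))
    }
    if (any(initial_concentrations < 0, na.rm = TRUE))
      errs <- c(errs, "initial concentrations must be >= 0")
  }
  if (!is.numeric(initial_E_PLP_fraction) ||
      length(initial_E_PLP_fraction) != 1L ||
      is.na(initial_E_PLP_fraction) ||
      initial_E_PLP_fraction < 0 || initial_E_PLP_fraction > 1)
    errs <- c(errs, "initial_E_PLP_fraction must be in [0, 1]")
  if (length(errs))
    stop(paste0("invalid reaction system:\n  - ",
                paste(errs, collapse = "\n  - ")), call. = FALSE)

  init <- stats::setNames(numeric(nrow(species)), species$id)
  init[names(initial_concentrations)] <- as.numeric(initial_concentrations)
  structure(list(species = species, reactions = reactions,
                 enzyme_total = as.numeric(enzyme_total),
                 init = init,
                 initial_E_PLP_fraction = as.numeric(initial_E_PLP_fraction)),
            class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("Transaminase reaction system: %d species, %d elemental reactions\n",
              nrow(x$species), length(x$reactions)))
  cat(sprintf("  enzyme_total = %g mM (initial E-PLP fraction %g)\n",
              x$enzyme_total, x$initial_E_PLP_fraction))
  for (r in x$reactions) print(r)
  nz <- x$init[x$init > 0]
  if (length(nz))
    cat("  initial mM:", paste(sprintf("%s = %g", names(nz), nz),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Number of state variables of a system
#'
#' Chemical species plus the two enzyme states (E-PLP, E-PMP).
#' @param system A [reaction_system()].
#' @return Integer count.
#' @export
n_state_variables <- function(system) {
  stopifnot(inherits(system, "reaction_system"))
  nrow(system$species) + 2L
}

#' Enantiomeric excess as a signed percent
#'
#' `ee = (S - R) / (S + R) * 100`; positive values indicate S-excess
#' (the `ee^S` convention), negative values R-excess (`ee^R`).
#'
#' @param conc_S,conc_R Concentrations of the S and R enantiomers (same
#'   units, both >= 0).
#' @return Signed percent in \[-100, 100\].
#' @examples
#' ee_percent(25, 25)           # racemic: 0
#' ee_percent(0.225, 49.775)    # -99.1 (a 99.1% ee^R stock)
#' @export
ee_percent <- function(conc_S, conc_R) {
  stopifnot(is.numeric(conc_S), is.numeric(conc_R))
  if (any(conc_S < 0) || any(conc_R < 0))
    stop("concentrations must be nonnegative", call. = FALSE)
  tot <- conc_S + conc_R
  if (any(tot == 0))
    stop("undefined ee: both enantiomer concentrations are zero",
         call. = FALSE)
  (conc_S - conc_R) / tot * 100
}

#' Enantiomeric ratio E^S = k^S / k^R
#'
#' The kinetic stereoselectivity of one reaction direction: the ratio of
#' the second-order rate constant for the favored (S) enantiomer to that
#' for the disfavored (R) one.
#'
#' @param k_S,k_R Rate constants (same units); `k_S >= 0`, `k_R > 0`.
#' @return `k_S / k_R`.
#' @examples
#' enantiomeric_ratio(20, 1)  # E^S = 20
#' @export
enantiomeric_ratio <- function(k_S, k_R) {
  if (any(k_S < 0) || any(k_R < 0))
    stop("rate constants must be nonnegative", call. = FALSE)
  if (any(k_R == 0))
    stop("strict selectivity: k_R = 0, enantiomeric ratio is unbounded",
         call. = FALSE)
  k_S / k_R
}

#' Equilibrium constant of an elemental reaction
#'
#' `K_eq = k_OD / k_RA`, from the detailed-balance condition
#' `v_OD = v_RA` at equilibrium.
#'
#' @param k_OD,k_RA Second-order rate constants; `k_RA > 0`.
#' @return Dimensionless `K_eq`.
#' @export
equilibrium_constant <- function(k_OD, k_RA) {
  if (any(k_OD < 0) || any(k_RA < 0))
    stop("rate constants must be nonnegative", call. = FALSE)
  if (any(k_RA == 0))
    stop("irreversible reaction: k_RA = 0, K_eq is undefined", call. = FALSE)
  k_OD / k_RA
}

#' Equilibrium constant of a coupled futile cycle
#'
#' For the coupled cycle X/Y (X running forward, Y in reverse) the overall
#' equilibrium constant is `K_eq,X / K_eq,Y`. For two elemental reactions
#' that are enantiomer partners with equal `K_eq` this is 1, which is why
#' an enantiomer-coupled futile cycle racemizes until `[S] = [R]`.
#'
#' @param rxn_X,rxn_Y [elemental_reaction()] objects.
#' @return Dimensionless equilibrium constant of the coupled cycle.
#' @export
coupled_cycle_keq <- function(rxn_X, rxn_Y) {
  stopifnot(inherits(rxn_X, "elemental_reaction"),
            inherits(rxn_Y, "elemental_reaction"))
  equilibrium_constant(rxn_X$k_OD, rxn_X$k_RA) /
    equilibrium_constant(rxn_Y$k_OD, rxn_Y$k_RA)
}

# compounds that carry both enantiomer species (ee is defined for these)
chiral_compounds <- function(system) {
  sp <- system$species
  ids <- unique(sp$compound_id)
  ids[vapply(ids, function(cid) {
    r <- sp$role[sp$compound_id == cid]
    all(c("amine_S", "amine_R") %in% r)
  }, logical(1))]
}

enantiomer_ids <- function(system, compound) {
  sp <- system$species
  s <- sp$id[sp$compound_id == compound & sp$role == "amine_S"]
  r <- sp$id[sp$compound_id == compound & sp$role == "amine_R"]
  if (length(s) != 1L || length(r) != 1L)
    stop(sprintf("compound '%s' does not have both enantiomer species",
                 compound), call. = FALSE)
  c(S = s, R = r)
}
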