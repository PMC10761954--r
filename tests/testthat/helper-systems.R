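# shared fixture builders (all inputs are generated in code)

# single reversible reaction D <-> A, for algebraic equilibrium oracles
single_reaction_system <- function(k_OD = 2, k_RA = 1, D0 = 10, A0 = 0,
                                   enzyme = 0.5) {
  sp <- rbind(species("S-D", "amine_S", "D"),
              species("A", "ketone", "D"))
  reaction_system(sp, list(elemental_reaction("I^S", "S-D", "A",
                                              k_OD, k_RA)),
                  enzyme_total = enzyme,
                  initial_concentrations = c("S-D" = D0, "A" = A0))
}

# enantiomer-coupled futile cycle with configurable constants
racemase_system <- function(k_OD_S = 2, k_RA_S = 4, k_OD_R = 0.1,
                            k_RA_R = 0.2, S0 = 50, R0 = 0, A0 = 50,
                            enzyme = 0.1) {
  sp <- rbind(species("S-D2", "amine_S", "D2"),
              species("R-D2", "amine_R", "D2"),
              species("A2", "ketone", "D2"))
  rx <- list(elemental_reaction("II^S", "S-D2", "A2", k_OD_S, k_RA_S),
             elemental_reaction("II^R", "R-D2", "A2", k_OD_R, k_RA_R))
  reaction_system(sp, rx, enzyme_total = enzyme,
                  initial_concentrations = c("S-D2" = S0, "R-D2" = R0,
                                             "A2" = A0))
}

# algebraic equilibrium of the single-reaction system by root finding
# (conservation-reduced: one unknown x = [D] at equilibrium)
single_reaction_equilibrium_oracle <- function(sys) {
  r <- sys$reactions[[1]]
  C1 <- sum(sys$init[c(r$donor, r$ketone)])
  E <- sys$enzyme_total
  C2 <- sys$init[[r$donor]] + E * (1 - sys$initial_E_PLP_fraction)
  f <- function(x) {
    eplp <- E - (C2 - x)
    r$k_OD * x * eplp - r$k_RA * (C1 - x) * (C2 - x)
  }
  lo <- max(0, C2 - E) + 1e-12
  hi <- min(C1, C2) - 1e-12
  x <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  c(D = x, A = C1 - x, E_PLP = E - (C2 - x), E_PMP = C2 - x)
}

expect_conserved <- function(traj, tol = 1e-6) {
  sys <- traj$system
  conc <- traj$concentrations
  for (cid in unique(sys$species$compound_id)) {
    ids <- sys$species$id[sys$species$compound_id == cid]
    tot <- rowSums(conc[, ids, drop = FALSE])
    expect_lt(max(abs(tot - tot[1])), tol)
  }
  etot <- conc[, "E_PLP"] + conc[, "E_PMP"]
  expect_lt(max(abs(etot - sys$enzyme_total)), tol)
  amines <- sys$species$id[sys$species$role %in% c("amine_S", "amine_R")]
  ab <- rowSums(conc[, amines, drop = FALSE]) + conc[, "E_PMP"]
  expect_lt(max(abs(ab - ab[1])), tol)
}
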