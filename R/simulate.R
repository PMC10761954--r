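#' Mass-action time derivatives of a reaction system
#'
#' Right-hand side of the ODE model. The state vector stacks the chemical
#' species (in the order of `system$species`) followed by the two enzyme
#' states `E_PLP` and `E_PMP`. For every elemental reaction,
#' `v_OD = k_OD [donor][E-PLP]` consumes the donor amine and E-PLP and
#' produces the ketone and E-PMP; `v_RA = k_RA [ketone][E-PMP]` is the
#' exact reverse. Every flux therefore conserves the compound skeleton
#' totals, the enzyme total and the amino-group balance
#' (sum of amines + E-PMP).
#'
#' @param state Named numeric state vector, mM.
#' @param system A [reaction_system()].
#' @param suppress Character vector of `"<label>:OD"` / `"<label>:RA"`
#'   terms to clamp to zero (suppressed futile-cycle runs).
#' @return Named numeric vector of time derivatives, mM h^-1.
#' @export
derivatives <- function(state, system, suppress = NULL) {
  stopifnot(inherits(system, "reaction_system"))
  ids <- c(system$species$id, "E_PLP", "E_PMP")
  if (length(state) != length(ids))
    stop(sprintf("state has %d components; system needs %d (%d species + 2 enzyme states)",
                 length(state), length(ids), nrow(system$species)),
         call. = FALSE)
  if (is.null(names(state))) names(state) <- ids
  sup <- normalize_suppress(suppress, system)
  d <- stats::setNames(numeric(length(ids)), ids)
  eplp <- state[["E_PLP"]]; epmp <- state[["E_PMP"]]
  for (r in system$reactions) {
    v_od <- if (paste0(r$label, ":OD") %in% sup) 0 else
      r$k_OD * state[[r$donor]] * eplp
    v_ra <- if (paste0(r$label, ":RA") %in% sup) 0 else
      r$k_RA * state[[r$ketone]] * epmp
    net <- v_od - v_ra
    d[r$donor] <- d[r$donor] - net
    d[r$ketone] <- d[r$ketone] + net
    d["E_PLP"] <- d["E_PLP"] - net
    d["E_PMP"] <- d["E_PMP"] + net
  }
  d
}

# validate and canonicalize suppress = c("I^S:RA", ...) entries
normalize_suppress <- function(suppress, system) {
  if (is.null(suppress) || !length(suppress)) return(character())
  suppress <- as.character(suppress)
  labels <- vapply(system$reactions, `[[`, character(1), "label")
  ok <- grepl(":(OD|RA)$", suppress) &
    sub(":(OD|RA)$", "", suppress) %in% labels
  if (any(!ok))
    stop(sprintf("unknown suppressed rate term(s): %s (expect '<label>:OD' or '<label>:RA')",
                 paste(suppress[!ok], collapse = ", ")), call. = FALSE)
  unique(suppress)
}

initial_state <- function(system) {
  c(system$init,
    E_PLP = system$enzyme_total * system$initial_E_PLP_fraction,
    E_PMP = system$enzyme_total * (1 - system$initial_E_PLP_fraction))
}

# per-reaction v_OD, v_RA, net at one state
reaction_rates <- function(state, system, suppress = NULL) {
  sup <- normalize_suppress(suppress, system)
  do.call(rbind, lapply(system$reactions, function(r) {
    v_od <- if (paste0(r$label, ":OD") %in% sup) 0 else
      r$k_OD * state[[r$donor]] * state[["E_PLP"]]
    v_ra <- if (paste0(r$label, ":RA") %in% sup) 0 else
      r$k_RA * state[[r$ketone]] * state[["E_PMP"]]
    data.frame(label = r$label, v_OD = v_od, v_RA = v_ra,
               v_net = v_od - v_ra, stringsAsFactors = FALSE)
  }))
}

#' Integrate a reaction system
#'
#' Solves the second-order mass-action ODE system with a stiff-capable
#' adaptive integrator (deSolve's `lsoda`, rtol 1e-8 / atol 1e-10 by
#' default) and returns a `trajectory`: species and enzyme-state
#' concentrations on the output grid, per-compound enantiomeric-excess
#' series and per-reaction rate traces (`v_OD`, `v_RA`, net
#' `v = v_OD - v_RA`).
#'
#' @param object A [reaction_system()].
#' @param nsim,seed Ignored (the model is deterministic); present for
#'   compatibility with the [stats::simulate()] generic.
#' @param t_end End time, h (> 0). Ignored when `times` is given.
#' @param times Optional explicit output grid, h, starting at 0.
#' @param suppress Optional character vector of rate terms
#'   (`"<label>:OD"` / `"<label>:RA"`) to clamp to zero, e.g.
#'   `c("I^S:RA", "II^S:OD", "II^R:OD")` for a suppressed-futile-cycle run.
#' @param n_out Number of output points when `times` is not given.
#' @param rtol,atol Relative/absolute integrator tolerances.
#' @param ... Passed to [deSolve::ode()].
#' @return An object of class `trajectory`.
#' @examples
#' sys <- stereoinversion_demo_system()
#' traj <- simulate(sys, t_end = 24)
#' head(as.data.frame(traj))
#' @export
simulate.reaction_system <- function(object, nsim = 1, seed = NULL,
                                     t_end = 24, times = NULL,
                                     suppress = NULL, n_out = 401,
                                     rtol = 1e-8, atol = 1e-10, ...) {
  system <- object
  if (is.null(times)) {
    if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) ||
        t_end <= 0)
      stop("t_end must be a single positive time (h)", call. = FALSE)
    times <- seq(0, t_end, length.out = n_out)
  } else {
    if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
      stop("times must be strictly increasing and start at 0", call. = FALSE)
  }
  sup <- normalize_suppress(suppress, system)
  if (system$enzyme_total <= 0)
    stop("enzyme_total must be > 0 for simulation", call. = FALSE)
  y0 <- initial_state(system)
  rhs <- function(t, y, parms) list(derivatives(y, system, sup))
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol, ...)
  diagn <- attributes(sol)$istate
  if (!is.null(diagn) && diagn[1] < 0)
    stop(sprintf("integrator failed; last good time %.6g h",
                 max(sol[, "time"], na.rm = TRUE)), call. = FALSE)
  build_trajectory(sol, system, sup, atol = atol)
}

build_trajectory <- function(sol, system, suppress, atol) {
  tm <- sol[, "time"]
  conc <- sol[, -1, drop = FALSE]
  ee <- lapply(chiral_compounds(system), function(cid) {
    en <- enantiomer_ids(system, cid)
    s <- conc[, en[["S"]]]; r <- conc[, en[["R"]]]
    ifelse(s + r > 0, (s - r) / (s + r) * 100, NA_real_)
  })
  names(ee) <- chiral_compounds(system)
  sup <- suppress
  rates <- do.call(rbind, lapply(system$reactions, function(r) {
    v_od <- if (paste0(r$label, ":OD") %in% sup) rep(0, length(tm)) else
      r$k_OD * conc[, r$donor] * conc[, "E_PLP"]
    v_ra <- if (paste0(r$label, ":RA") %in% sup) rep(0, length(tm)) else
      r$k_RA * conc[, r$ketone] * conc[, "E_PMP"]
    data.frame(time_h = tm, label = r$label, v_OD = v_od, v_RA = v_ra,
               v_net = v_od - v_ra, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  structure(list(times = tm, concentrations = conc,
                 ee = if (length(ee)) as.data.frame(ee, check.names = FALSE)
                      else NULL,
                 rates = rates[, c("time_h", "label", "v_OD", "v_RA", "v_net")],
                 system = system, suppress = suppress, atol = atol),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d time points over [0, %g] h, %d state variables\n",
              length(x$times), max(x$times), ncol(x$concentrations)))
  if (!is.null(x$ee))
    cat("  ee traces for compound(s):", paste(names(x$ee), collapse = ", "),
        "\n")
  if (length(x$suppress))
    cat("  suppressed rate terms:", paste(x$suppress, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.trajectory <- function(object, ...) {
  conc <- object$concentrations
  last <- conc[nrow(conc), ]
  cat("Final state (mM):\n")
  print(round(last, 6))
  if (!is.null(object$ee)) {
    cat("Final ee (%):\n")
    print(round(unlist(object$ee[nrow(conc), , drop = FALSE]), 4))
  }
  invisible(object)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  df <- data.frame(time_h = x$times, x$concentrations, check.names = FALSE)
  if (!is.null(x$ee)) {
    ee <- x$ee
    names(ee) <- paste0("ee_", names(ee))
    df <- cbind(df, ee)
  }
  df
}

#' @export
plot.trajectory <- function(x, which = c("concentrations", "ee", "rates"),
                            ...) {
  which <- match.arg(which)
  if (which == "concentrations") {
    graphics::matplot(x$times, x$concentrations, type = "l", lty = 1,
                      xlab = "time (h)", ylab = "concentration (mM)", ...)
    graphics::legend("topright", legend = colnames(x$concentrations),
                     col = seq_len(ncol(x$concentrations)), lty = 1,
                     bty = "n", cex = 0.8)
  } else if (which == "ee") {
    if (is.null(x$ee)) stop("no chiral compound in this system", call. = FALSE)
    graphics::matplot(x$times, as.matrix(x$ee), type = "l", lty = 1,
                      xlab = "time (h)", ylab = "ee (%)", ...)
    graphics::legend("topright", legend = names(x$ee),
                     col = seq_along(x$ee), lty = 1, bty = "n", cex = 0.8)
  } else {
    labs <- unique(x$rates$label)
    net <- sapply(labs, function(l) x$rates$v_net[x$rates$label == l])
    graphics::matplot(x$times, net, type = "l", lty = 1,
                      xlab = "time (h)", ylab = "net rate (mM/h)", ...)
    graphics::legend("topright", legend = labs, col = seq_along(labs),
                     lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Fixed-step classical Runge-Kutta (RK4) reference integration
#'
#' A deliberately simple fixed-step fourth-order Runge-Kutta integrator
#' used as an independent cross-check of the adaptive solver in tests. Not
#' meant for production use: cost grows as `t_end / dt`.
#'
#' @param system A [reaction_system()].
#' @param t_end End time, h.
#' @param dt Fixed step, h (default 1e-3).
#' @param suppress As in [simulate.reaction_system()].
#' @param keep_every Store every `keep_every`-th step (plus the last).
#' @return A `trajectory` object.
#' @export
rk4_integrate <- function(system, t_end, dt = 1e-3, suppress = NULL,
                          keep_every = 10L) {
  stopifnot(inherits(system, "reaction_system"), t_end > 0, dt > 0)
  sup <- normalize_suppress(suppress, system)
  f <- function(y) derivatives(y, system, sup)
  y <- initial_state(system)
  n <- ceiling(t_end / dt)
  keep <- unique(c(seq(0L, n, by = as.integer(keep_every)), n))
  out <- matrix(NA_real_, nrow = length(keep), ncol = length(y),
                dimnames = list(NULL, names(y)))
  tms <- numeric(length(keep))
  ki <- 1L
  if (keep[1] == 0L) { out[1, ] <- y; tms[1] <- 0; ki <- 2L }
  for (i in seq_len(n)) {
    h <- min(dt, t_end - (i - 1) * dt)
    k1 <- f(y)
    k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (ki <= length(keep) && i == keep[ki]) {
      out[ki, ] <- y
      tms[ki] <- min(i * dt, t_end)
      ki <- ki + 1L
    }
  }
  sol <- cbind(time = tms, out)
  build_trajectory(sol, system, sup, atol = 0)
}

#' Demo system: stereoinversion of a chiral amine product
#'
#' A ready-made three-reaction system with the topology of a transamination
#' between an enantiopure amine donor (compound D1, strictly S-selective)
#' and a prochiral ketone acceptor (compound A2) whose amine product D2 is
#' handled with incomplete stereoselectivity, so the enantiomer-coupled
#' futile cycle slowly racemizes the product. Rate constants are synthetic
#' (mM^-1 h^-1) but ordered like a real S-selective transaminase: donor OD
#' fastest, product-cycle RA of the disfavored enantiomer slowest (the
#' rate-determining step of the S-to-R inversion).
#'
#' @param k Named numeric vector of the six rate constants; defaults
#'   `c(k_OD_IS = 10, k_RA_IS = 1, k_OD_IIS = 2, k_RA_IIS = 4,
#'   k_OD_IIR = 0.1, k_RA_IIR = 0.2)`. Equal `K_eq` for the two D2
#'   enantiomer reactions.
#' @param donor0,acceptor0 Initial amine donor / ketone acceptor, mM.
#' @param enzyme_total Total enzyme, mM (default 0.75, i.e. 750 uM).
#' @return A [reaction_system()] with seven state variables.
#' @export
stereoinversion_demo_system <- function(
    k = c(k_OD_IS = 10, k_RA_IS = 1, k_OD_IIS = 2, k_RA_IIS = 4,
          k_OD_IIR = 0.1, k_RA_IIR = 0.2),
    donor0 = 50, acceptor0 = 50, enzyme_total = 0.75) {
  sp <- rbind(
    species("S-D1", "amine_S", "D1"),
    species("A1", "ketone", "D1"),
    species("S-D2", "amine_S", "D2"),
    species("R-D2", "amine_R", "D2"),
    species("A2", "ketone", "D2"))
  rx <- list(
    elemental_reaction("I^S", "S-D1", "A1", k[["k_OD_IS"]], k[["k_RA_IS"]]),
    elemental_reaction("II^S", "S-D2", "A2", k[["k_OD_IIS"]], k[["k_RA_IIS"]]),
    elemental_reaction("II^R", "R-D2", "A2", k[["k_OD_IIR"]], k[["k_RA_IIR"]]))
  reaction_system(sp, rx, enzyme_total = enzyme_total,
                  initial_concentrations = c("S-D1" = donor0,
                                             "A2" = acceptor0))
}

#' Demo system: direct racemization futile cycle
#'
#' The five-variable enantiomer-coupled futile cycle (compound D2 only):
#' both enantiomer reactions strictly positive with equal equilibrium
#' constants, so the only net chemistry is a change of chiral composition.
#'
#' @param k_OD_S,k_RA_S,k_OD_R,k_RA_R Rate constants, mM^-1 h^-1.
#' @param amine0 Initial amine, mM, placed entirely on `start`.
#' @param ketone0 Initial cognate ketone, mM.
#' @param enzyme_total Total enzyme, mM.
#' @param start Which enantiomer carries the initial amine.
#' @return A [reaction_system()] with five state variables.
#' @export
racemization_demo_system <- function(k_OD_S = 2, k_RA_S = 4,
                                     k_OD_R = 0.1, k_RA_R = 0.2,
                                     amine0 = 50, ketone0 = 50,
                                     enzyme_total = 0.1,
                                     start = c("S", "R")) {
  start <- match.arg(start)
  sp <- rbind(
    species("S-D2", "amine_S", "D2"),
    species("R-D2", "amine_R", "D2"),
    species("A2", "ketone", "D2"))
  rx <- list(
    elemental_reaction("II^S", "S-D2", "A2", k_OD_S, k_RA_S),
    elemental_reaction("II^R", "R-D2", "A2", k_OD_R, k_RA_R))
  init <- c(ifelse(start == "S", amine0, 0), ifelse(start == "R", amine0, 0),
            ketone0)
  names(init) <- c("S-D2", "R-D2", "A2")
  reaction_system(sp, rx, enzyme_total = enzyme_total,
                  initial_concentrations = init)
}
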