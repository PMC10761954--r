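# state at an arbitrary time, integrating from a known (time, state) pair
state_at <- function(system, y_from, t_from, t_to, suppress,
                     rtol = 1e-10, atol = 1e-12) {
  if (t_to <= t_from) return(y_from)
  rhs <- function(t, y, parms) list(derivatives(y, system, suppress))
  sol <- deSolve::ode(y = y_from, times = c(t_from, t_to), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  out <- sol[nrow(sol), -1]
  names(out) <- names(y_from)
  out
}

# bisection on g(t) over [lo, hi] with g(lo), g(hi) of opposite sign;
# g evaluated from re-integrated states, refined to width <= tol_t
bisect_time <- function(system, traj, lo_i, hi_i, g_of_state,
                        tol_t = 1e-3) {
  tm <- traj$times
  y_lo <- traj$concentrations[lo_i, ]
  t_lo <- tm[lo_i]; t_hi <- tm[hi_i]
  g_lo <- g_of_state(y_lo)
  y_at_tlo <- y_lo
  while (t_hi - t_lo > tol_t) {
    t_mid <- (t_lo + t_hi) / 2
    y_mid <- state_at(system, y_at_tlo, t_lo, t_mid, traj$suppress)
    g_mid <- g_of_state(y_mid)
    if (sign(g_mid) == sign(g_lo) || g_mid == 0 && g_lo == 0) {
      t_lo <- t_mid; y_at_tlo <- y_mid; g_lo <- g_mid
    } else {
      t_hi <- t_mid
    }
  }
  (t_lo + t_hi) / 2
}

#' Detect the onset of stereoinversion of a species
#'
#' The onset is the first strict maximum of the species' concentration
#' after t = 0: the first downward zero-crossing of its analytic time
#' derivative following an initial rise. The crossing is bracketed on the
#' trajectory's output grid and refined by bisection (re-integrating
#' inside the bracket) to +/- 0.01 h or better.
#'
#' @param traj A `trajectory` from [simulate.reaction_system()].
#' @param species Id of the species to inspect (e.g. `"S-D2"`).
#' @param tol_t Bisection refinement width, h (default 1e-3).
#' @return Onset time in h, or `NA` if the species never turns over
#'   (monotone trajectory — not an error).
#' @export
detect_stereoinversion_onset <- function(traj, species, tol_t = 1e-3) {
  stopifnot(inherits(traj, "trajectory"))
  system <- traj$system
  if (!species %in% colnames(traj$concentrations))
    stop(sprintf("species '%s' not in trajectory", species), call. = FALSE)
  dsp <- apply(traj$concentrations, 1, function(y)
    derivatives(y, system, traj$suppress)[[species]])
  rising <- which(dsp > 0)
  if (!length(rising)) return(NA_real_)
  # first + -> - sign change after the rise begins
  i0 <- rising[1]
  cross <- which(dsp[-length(dsp)] > 0 & dsp[-1] <= 0)
  cross <- cross[cross >= i0]
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  g <- function(y) derivatives(y, system, traj$suppress)[[species]]
  bisect_time(system, traj, i, i + 1L, g, tol_t = tol_t)
}

#' Detect the onset of stereoinversion from a net rate trace
#'
#' Alternative detector: the first sign change (positive to negative) of a
#' reaction's net rate `v = v_OD - v_RA`. For the enantiomer-coupled
#' futile cycle this coincides with the turnover of the favored
#' enantiomer's concentration.
#'
#' @inheritParams detect_stereoinversion_onset
#' @param label Reaction label whose net rate is inspected.
#' @return Onset time in h, or `NA` if the net rate never changes sign.
#' @export
detect_net_rate_sign_change <- function(traj, label, tol_t = 1e-3) {
  stopifnot(inherits(traj, "trajectory"))
  system <- traj$system
  labels <- vapply(system$reactions, `[[`, character(1), "label")
  if (!label %in% labels)
    stop(sprintf("unknown reaction label '%s'", label), call. = FALSE)
  vn <- traj$rates$v_net[traj$rates$label == label]
  s <- sign(vn)
  cross <- which(s[-length(s)] != 0 & s[-1] != s[-length(s)])
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  g <- function(y) {
    rr <- reaction_rates(as.list(y), system, traj$suppress)
    rr$v_net[rr$label == label]
  }
  bisect_time(system, traj, i, i + 1L, g, tol_t = tol_t)
}

#' Detect completion of racemization
#'
#' The first time at which the magnitude of the enantiomeric excess of a
#' compound falls below `threshold` and stays below it for the rest of the
#' trajectory (transient crossings are not completion). The threshold
#' crossing is refined by bisection to +/- `tol_t` h.
#'
#' @param traj A `trajectory`.
#' @param compound Compound id with both enantiomer species present.
#' @param threshold Completion threshold, percent ee (> 0); default 1
#'   (the conventional "complete racemization" cutoff |ee| < 1%).
#' @param tol_t Bisection refinement width, h.
#' @return Completion time in h (0 if the start is already below the
#'   threshold), or `NA` if never completed within the trajectory.
#' @export
detect_racemization_completion <- function(traj, compound, threshold = 1,
                                           tol_t = 1e-3) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a positive percent", call. = FALSE)
  system <- traj$system
  en <- enantiomer_ids(system, compound)
  conc <- traj$concentrations
  abs_ee <- abs((conc[, en[["S"]]] - conc[, en[["R"]]]) /
                  pmax(conc[, en[["S"]]] + conc[, en[["R"]]],
                       .Machine$double.xmin)) * 100
  below <- abs_ee < threshold
  if (!any(below)) return(NA_real_)
  # last index from which |ee| stays below threshold to the end
  stays <- rev(cumprod(rev(below))) > 0
  if (!stays[length(stays)]) return(NA_real_)
  first <- which(stays)[1]
  if (first == 1L) return(0)
  g <- function(y) {
    s <- y[[en[["S"]]]]; r <- y[[en[["R"]]]]
    abs((s - r) / (s + r)) * 100 - threshold
  }
  bisect_time(system, traj, first - 1L, first, g, tol_t = tol_t)
}

#' Steady state of a reaction system
#'
#' Integrates the system with a steady-state stopping rule (the solver
#' halts when `max |dy/dt| < tol_rate` mM/h) and cross-checks the
#' detailed-balance conditions `v_OD = v_RA` for every reaction.
#'
#' @param system A [reaction_system()] with at least one reversible
#'   reaction (`k_RA > 0`).
#' @param tol_rate Steady-state stopping tolerance, mM/h (default 1e-9).
#' @param t_cap Hard time cap, h; if the rule has not fired by then the
#'   result carries `converged = FALSE` and the residual.
#' @return A list of class `steady_state` with elements `concentrations`
#'   (named, mM, incl. `E_PLP`, `E_PMP`), `enzyme_fractions` (E-PLP and
#'   E-PMP as fractions of the total), `time` (h at which the rule fired),
#'   `residual` (max |dy/dt|), `balance` (per-reaction `v_OD`, `v_RA`),
#'   and `converged`.
#' @export
equilibrium_state <- function(system, tol_rate = 1e-9, t_cap = 1e6) {
  stopifnot(inherits(system, "reaction_system"))
  if (!any(vapply(system$reactions, function(r) r$k_RA > 0, logical(1))))
    stop("system has no reversible reaction; no finite steady state",
         call. = FALSE)
  y0 <- initial_state(system)
  rhs <- function(t, y, parms) list(derivatives(y, system, NULL))
  root <- function(t, y, parms) {
    max(abs(derivatives(y, system, NULL))) - tol_rate
  }
  sol <- deSolve::lsodar(y = y0, times = c(0, t_cap), func = rhs,
                         parms = NULL, rootfunc = root,
                         rtol = 1e-10, atol = 1e-12)
  t_root <- attr(sol, "troot")
  y_end <- sol[nrow(sol), -1]
  names(y_end) <- names(y0)
  resid <- max(abs(derivatives(y_end, system, NULL)))
  conv <- length(t_root) > 0 && resid <= tol_rate * 1.01
  bal <- reaction_rates(as.list(y_end), system, NULL)
  structure(list(
    concentrations = y_end,
    enzyme_fractions = c(E_PLP = y_end[["E_PLP"]] / system$enzyme_total,
                         E_PMP = y_end[["E_PMP"]] / system$enzyme_total),
    time = if (conv) sol[nrow(sol), "time"] else NA_real_,
    residual = resid,
    balance = bal,
    converged = conv), class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady state (%s), max |dy/dt| = %.3g mM/h%s\n",
              if (x$converged) "converged" else "NOT converged",
              x$residual,
              if (x$converged) sprintf(" at t = %.4g h", x$time) else ""))
  print(round(x$concentrations, 8))
  cat(sprintf("enzyme fractions: E-PLP %.6f, E-PMP %.6f\n",
              x$enzyme_fractions[["E_PLP"]], x$enzyme_fractions[["E_PMP"]]))
  invisible(x)
}

#' Scan racemization speed against kinetic stereoselectivity
#'
#' Builds, from a template enantiomer-coupled futile-cycle system, a
#' family of hypothetical enzymes with enantiomeric ratio `E` by scaling
#' both rate constants of the disfavored enantiomer's reaction:
#' `k^R = k^S / E` for OD and RA alike, which preserves the equality of
#' the two equilibrium constants (chemical equilibrium does not depend on
#' chirality). Each variant is simulated from an enantiopure start and the
#' racemization completion time recorded. Completion time is
#' non-decreasing in `E`; at `E = 1` the S-start and R-start |ee|
#' trajectories coincide.
#'
#' @param template A [reaction_system()] containing the compound's S- and
#'   R-amine reactions; the S reaction supplies the favored constants.
#' @param compound Compound id to racemize.
#' @param E_values Numeric vector of enantiomeric ratios, all >= 1.
#' @param direction `"S-start"` (default) or `"R-start"`: which pure
#'   enantiomer carries the initial amine pool.
#' @param t_end Simulation horizon per variant, h.
#' @param threshold Completion threshold, percent ee.
#' @param n_out Output-grid size per variant.
#' @return A list of class `selectivity_scan` with `E_values`,
#'   `completion_times` (h, `NA` when not completed within `t_end` — the
#'   kinetic trap at large `E`), and `trajectories`.
#' @export
selectivity_scan <- function(template, compound, E_values,
                             direction = c("S-start", "R-start"),
                             t_end = 500, threshold = 1, n_out = 2001) {
  direction <- match.arg(direction)
  stopifnot(inherits(template, "reaction_system"))
  if (!length(E_values)) stop("E_values must be non-empty", call. = FALSE)
  if (any(E_values < 1))
    stop("E_values must be >= 1 (the favored enantiomer defines k^S)",
         call. = FALSE)
  en <- enantiomer_ids(template, compound)
  rx_S <- rx_R <- NULL
  for (r in template$reactions) {
    if (r$donor == en[["S"]]) rx_S <- r
    if (r$donor == en[["R"]]) rx_R <- r
  }
  if (is.null(rx_S) || is.null(rx_R))
    stop(sprintf("template must contain reactions for both enantiomers of '%s'",
                 compound), call. = FALSE)
  amine0 <- sum(template$init[en])
  res <- lapply(E_values, function(E) {
    rx <- lapply(template$reactions, function(r) {
      if (identical(r$label, rx_R$label))
        elemental_reaction(r$label, r$donor, r$ketone,
                           rx_S$k_OD / E, rx_S$k_RA / E)
      else r
    })
    init <- template$init
    init[en] <- 0
    init[en[[if (direction == "S-start") "S" else "R"]]] <- amine0
    sys <- reaction_system(template$species, rx, template$enzyme_total,
                           init, template$initial_E_PLP_fraction)
    traj <- simulate(sys, t_end = t_end, n_out = n_out)
    list(traj = traj,
         completion = detect_racemization_completion(traj, compound,
                                                     threshold = threshold))
  })
  structure(list(
    E_values = E_values,
    completion_times = vapply(res, function(x)
      if (is.na(x$completion)) NA_real_ else x$completion, numeric(1)),
    trajectories = lapply(res, `[[`, "traj"),
    compound = compound, direction = direction, threshold = threshold),
    class = "selectivity_scan")
}

#' @export
print.selectivity_scan <- function(x, ...) {
  cat(sprintf("selectivity scan of compound %s (%s, |ee| < %g%% completion):\n",
              x$compound, x$direction, x$threshold))
  print(data.frame(E = x$E_values, completion_h = x$completion_times))
  invisible(x)
}
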