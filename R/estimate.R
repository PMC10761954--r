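#' Replicate initial-rate assay
#'
#' One progress-curve replicate measured at fixed enzyme and substrate
#' concentrations, from which an initial rate is taken by linear
#' regression over the early (low-conversion) window.
#'
#' @param time_h Sampling times, h, strictly increasing.
#' @param product_mM Product concentrations, mM; must not exceed
#'   `substrate0`.
#' @param enzyme Enzyme concentration, mM (> 0).
#' @param substrate0 Initial substrate concentration, mM (> 0).
#' @param cosubstrate Optional cosubstrate id (documentation only; the
#'   pseudo-one-substrate limiting conditions are assay metadata, not
#'   enforced by the second-order model).
#' @param replicate_id Optional replicate label.
#' @return An object of class `rate_assay`.
#' @export
rate_assay <- function(time_h, product_mM, enzyme, substrate0,
                       cosubstrate = NA_character_, replicate_id = NA) {
  stopifnot(is.numeric(time_h), is.numeric(product_mM),
            length(time_h) == length(product_mM))
  if (is.unsorted(time_h, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (!is.numeric(enzyme) || enzyme <= 0)
    stop("enzyme must be > 0 mM", call. = FALSE)
  if (!is.numeric(substrate0) || substrate0 <= 0)
    stop("substrate0 must be > 0 mM", call. = FALSE)
  if (any(product_mM < 0) || any(product_mM > substrate0 + 1e-9))
    stop("product must lie in [0, substrate0]", call. = FALSE)
  structure(list(time_h = time_h, product_mM = product_mM,
                 enzyme = enzyme, substrate0 = substrate0,
                 cosubstrate = cosubstrate, replicate_id = replicate_id),
            class = "rate_assay")
}

#' @export
print.rate_assay <- function(x, ...) {
  cat(sprintf("rate assay%s: %d points to %.3g h, E = %g mM, S0 = %g mM\n",
              if (is.na(x$replicate_id)) "" else
                sprintf(" [%s]", x$replicate_id),
              length(x$time_h), max(x$time_h), x$enzyme, x$substrate0))
  invisible(x)
}

#' Initial rate by linear regression over the low-conversion window
#'
#' Fits an ordinary least-squares line (with intercept, tolerating a
#' baseline offset) of product against time, using only the points with
#' conversion `product / substrate0` below `conversion_limit`. The slope
#' is the initial rate v_i.
#'
#' @param assay A [rate_assay()].
#' @param conversion_limit Fractional conversion cutoff (default 0.20:
#'   initial rates are taken below 20% conversion).
#' @return List with `rate` (mM/h), `se` (standard error of the slope),
#'   `n_used`, `n_excluded`.
#' @export
initial_rate <- function(assay, conversion_limit = 0.20) {
  stopifnot(inherits(assay, "rate_assay"))
  keep <- assay$product_mM / assay$substrate0 < conversion_limit
  if (sum(keep) < 3L)
    stop(sprintf(
      "insufficient data: %d point(s) below %.0f%% conversion, need >= 3",
      sum(keep), conversion_limit * 100), call. = FALSE)
  fit <- stats::lm(p ~ t, data = data.frame(t = assay$time_h[keep],
                                            p = assay$product_mM[keep]))
  # suppressWarnings: summary.lm warns on exactly linear (noise-free) data
  sm <- suppressWarnings(summary(fit))$coefficients
  list(rate = unname(stats::coef(fit)[["t"]]),
       se = if (nrow(sm) >= 2) unname(sm["t", "Std. Error"]) else NA_real_,
       n_used = sum(keep), n_excluded = sum(!keep))
}

#' Second-order rate constant from replicate initial rates
#'
#' Under the pseudo-one-substrate limiting conditions the rate law reduces
#' to `v_i = k [E][S]`, so each replicate yields `k = v_i / ([E][S0])`.
#' Replicates are aggregated as mean +/- sample standard deviation
#' (n - 1 denominator).
#'
#' @param rates Numeric vector of replicate initial rates, mM/h (>= 1).
#' @param enzyme Enzyme concentration, mM (> 0).
#' @param substrate0 Initial substrate concentration, mM (> 0).
#' @return An object of class `constant_estimate`: `k` (mM^-1 h^-1), `sd`,
#'   `n_replicates`.
#' @examples
#' second_order_constant(1, enzyme = 0.001, substrate0 = 10)  # k = 100
#' @export
second_order_constant <- function(rates, enzyme, substrate0) {
  if (!is.numeric(rates) || !length(rates))
    stop("need at least one replicate rate", call. = FALSE)
  if (!is.numeric(enzyme) || length(enzyme) != 1L || enzyme <= 0)
    stop("enzyme must be > 0", call. = FALSE)
  if (!is.numeric(substrate0) || length(substrate0) != 1L || substrate0 <= 0)
    stop("substrate0 must be > 0", call. = FALSE)
  ks <- rates / (enzyme * substrate0)
  structure(list(k = mean(ks),
                 sd = if (length(ks) > 1) stats::sd(ks) else 0,
                 n_replicates = length(ks)),
            class = "constant_estimate")
}

#' @export
print.constant_estimate <- function(x, ...) {
  cat(sprintf("k = %.6g +/- %.3g mM^-1 h^-1 (n = %d)\n",
              x$k, x$sd, x$n_replicates))
  invisible(x)
}

#' @export
coef.constant_estimate <- function(object, ...) c(k = object$k)

#' Fit a second-order rate constant from replicate assays
#'
#' Convenience wrapper: takes replicate [rate_assay()] objects sharing
#' enzyme and substrate concentrations, extracts each initial rate by
#' [initial_rate()], and aggregates with [second_order_constant()].
#'
#' @param assays A list of [rate_assay()] objects (same `enzyme`,
#'   `substrate0`).
#' @param conversion_limit Passed to [initial_rate()].
#' @return A `constant_estimate` carrying also the per-replicate `rates`.
#' @export
fit_rate_constant <- function(assays, conversion_limit = 0.20) {
  if (inherits(assays, "rate_assay")) assays <- list(assays)
  stopifnot(all(vapply(assays, inherits, logical(1), "rate_assay")))
  E <- unique(vapply(assays, `[[`, numeric(1), "enzyme"))
  S0 <- unique(vapply(assays, `[[`, numeric(1), "substrate0"))
  if (length(E) != 1L || length(S0) != 1L)
    stop("replicates must share enzyme and substrate0", call. = FALSE)
  vi <- vapply(assays, function(a)
    initial_rate(a, conversion_limit)$rate, numeric(1))
  est <- second_order_constant(vi, E, S0)
  est$rates <- vi
  est
}

# parse "II^S" -> family "II", enantiomer "S"
parse_reaction_label <- function(label) {
  m <- regmatches(label, regexec("^(.*)\\^([SR])$", label))[[1]]
  if (length(m) != 3L)
    stop(sprintf("cannot parse reaction label '%s' (expected '<family>^<S|R>')",
                 label), call. = FALSE)
  list(family = m[2], enantiomer = m[3])
}

#' Stereochemistry table from estimated rate constants
#'
#' Assembles per-reaction `k_OD`, `k_RA` and `K_eq`, and per-family
#' (compound) enantiomeric ratios `E^S_OD = k^S_OD / k^R_OD` and
#' `E^S_RA = k^S_RA / k^R_RA`. Strict selectivity (an R constant of 0 or
#' absent) is reported as `Inf` with `strict = TRUE`, never divided by
#' zero; an irreversible reaction gets `K_eq = NA`.
#'
#' @param estimates A `data.frame` with columns `label` (e.g. `"II^S"`),
#'   `direction` (`"OD"` or `"RA"`) and `k` (mM^-1 h^-1); optionally `sd`.
#' @return A list of class `stereochemistry_table` with data frames
#'   `reactions` (label, k_OD, k_RA, K_eq) and `compounds` (family,
#'   E_S_OD, E_S_RA, strict_OD, strict_RA).
#' @export
stereochemistry_table <- function(estimates) {
  req <- c("label", "direction", "k")
  if (!is.data.frame(estimates) || !all(req %in% names(estimates)))
    stop("estimates must be a data.frame with columns label, direction, k",
         call. = FALSE)
  if (!all(estimates$direction %in% c("OD", "RA")))
    stop("direction must be 'OD' or 'RA'", call. = FALSE)
  key <- paste(estimates$label, estimates$direction)
  if (anyDuplicated(key))
    stop(sprintf("duplicated entries: %s",
                 paste(unique(key[duplicated(key)]), collapse = ", ")),
         call. = FALSE)
  labs <- unique(estimates$label)
  getk <- function(lab, dir) {
    i <- which(estimates$label == lab & estimates$direction == dir)
    if (length(i)) estimates$k[i] else NA_real_
  }
  rx <- do.call(rbind, lapply(labs, function(lab) {
    k_od <- getk(lab, "OD"); k_ra <- getk(lab, "RA")
    data.frame(label = lab, k_OD = k_od, k_RA = k_ra,
               K_eq = if (!is.na(k_ra) && k_ra > 0 && !is.na(k_od))
                 k_od / k_ra else NA_real_,
               stringsAsFactors = FALSE)
  }))
  parsed <- lapply(labs, parse_reaction_label)
  fams <- unique(vapply(parsed, `[[`, character(1), "family"))
  unmatched <- character()
  cmp <- do.call(rbind, lapply(fams, function(fam) {
    labS <- paste0(fam, "^S"); labR <- paste0(fam, "^R")
    if (!labS %in% labs) {
      unmatched <<- c(unmatched, labR)
      return(NULL)
    }
    ratio <- function(dir) {
      kS <- getk(labS, dir); kR <- getk(labR, dir)
      if (is.na(kS)) return(list(E = NA_real_, strict = NA))
      if (is.na(kR) || kR == 0) return(list(E = Inf, strict = TRUE))
      list(E = kS / kR, strict = FALSE)
    }
    od <- ratio("OD"); ra <- ratio("RA")
    data.frame(family = fam, E_S_OD = od$E, E_S_RA = ra$E,
               strict_OD = od$strict, strict_RA = ra$strict,
               stringsAsFactors = FALSE)
  }))
  if (length(unmatched))
    stop(sprintf("S-enantiomer constants missing for: %s",
                 paste(unmatched, collapse = ", ")), call. = FALSE)
  structure(list(reactions = rx, compounds = cmp),
            class = "stereochemistry_table")
}

#' @export
print.stereochemistry_table <- function(x, ...) {
  cat("Per-reaction constants (mM^-1 h^-1):\n")
  print(x$reactions, row.names = FALSE)
  cat("Per-compound enantiomeric ratios:\n")
  print(x$compounds, row.names = FALSE)
  invisible(x)
}
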