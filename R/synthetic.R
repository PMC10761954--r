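# run expr with a local RNG state seeded at `seed`; restores global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Measurement-noise model for synthetic chiral-HPLC data
#'
#' Multiplicative Gaussian noise (sd = cv * value) with an absolute
#' detection floor: noisy values are truncated at 0 and values below the
#' floor are reported as 0. A generic stand-in for chiral-HPLC peak-area
#' error; identical seeds give identical output.
#'
#' @param cv Fractional coefficient of variation (default 0.03).
#' @param floor Detection floor, mM (default 0.01).
#' @param seed Integer seed (mandatory: no hidden global randomness).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.03, floor = 0.01, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an integer seed is required", call. = FALSE)
  if (cv < 0 || floor < 0)
    stop("cv and floor must be >= 0", call. = FALSE)
  structure(list(cv = cv, floor = floor, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(x, noise) {
  y <- pmax(0, x * (1 + noise$cv * stats::rnorm(length(x))))
  y[y < noise$floor] <- 0
  y
}

#' Generate a noisy time-course dataset from a reaction system
#'
#' Simulates the system, samples the chemical-species concentrations at
#' the requested times (the enzyme states are not observable by HPLC) and
#' applies the noise model.
#'
#' @param system A [reaction_system()].
#' @param sample_times Sampling times, h (> 0, increasing); default the
#'   typical chiral-HPLC schedule `c(0.5, 1, 2, 3, 6, 12, 24)`.
#' @param noise A [noise_model()].
#' @return A `data.frame` with `time_h` and one column per chemical
#'   species, mM.
#' @export
generate_timecourse <- function(system,
                                sample_times = c(0.5, 1, 2, 3, 6, 12, 24),
                                noise) {
  stopifnot(inherits(system, "reaction_system"),
            inherits(noise, "noise_model"))
  if (any(sample_times <= 0) || is.unsorted(sample_times, strictly = TRUE))
    stop("sample_times must be positive and strictly increasing",
         call. = FALSE)
  traj <- simulate(system, times = c(0, sample_times))
  truth <- traj$concentrations[-1, system$species$id, drop = FALSE]
  noisy <- with_seed(noise$seed, apply(truth, 2, apply_noise, noise = noise))
  noisy <- matrix(noisy, nrow = length(sample_times),
                  dimnames = list(NULL, system$species$id))
  data.frame(time_h = sample_times, noisy, check.names = FALSE)
}

#' Generate replicate initial-rate assays from a known rate constant
#'
#' Uses the closed-form solution of a single second-order reaction whose
#' enzyme state is held constant by cosubstrate recycling (the standard
#' assay design): `P(t) = S0 (1 - exp(-k E t))`. Sampling times default to
#' early points reaching ~2% conversion, well inside the 20% initial-rate
#' window, so progress-curve curvature biases the regression slope by
#' about 1% at most. Each replicate gets its own noise stream,
#' deterministically derived from the master seed.
#'
#' @param k_true Ground-truth second-order constant, mM^-1 h^-1.
#' @param enzyme Enzyme concentration, mM.
#' @param substrate0 Initial substrate, mM.
#' @param n_points Points per replicate (default 5).
#' @param n_replicates Number of replicates (default 3).
#' @param noise A [noise_model()].
#' @param times Optional explicit sampling times, h; all true conversions
#'   must stay below 20%.
#' @return A list of [rate_assay()] objects.
#' @export
generate_initial_rate_dataset <- function(k_true, enzyme, substrate0,
                                          n_points = 5, n_replicates = 3,
                                          noise, times = NULL) {
  stopifnot(k_true > 0, enzyme > 0, substrate0 > 0,
            inherits(noise, "noise_model"))
  t20 <- -log(0.8) / (k_true * enzyme)   # time of 20% conversion
  if (is.null(times)) {
    # sample well inside the window (~2% conversion) so the secant slope
    # of the exponential tracks the true initial rate to ~1%
    times <- seq_len(n_points) * (0.1 * t20 / n_points)
  } else {
    conv <- 1 - exp(-k_true * enzyme * times)
    if (any(conv >= 0.20))
      stop(sprintf(
        "requested points reach >= 20%% conversion; use times below %.4g h",
        t20), call. = FALSE)
  }
  truth <- substrate0 * (1 - exp(-k_true * enzyme * times))
  lapply(seq_len(n_replicates), function(i) {
    rep_seed <- (noise$seed + 7919L * i) %% .Machine$integer.max
    p <- with_seed(rep_seed, apply_noise(truth, noise))
    rate_assay(times, pmin(p, substrate0), enzyme = enzyme,
               substrate0 = substrate0,
               replicate_id = sprintf("rep%d", i))
  })
}

#' Split a stock concentration into enantiomers at a given ee
#'
#' Models an enantio-impure commercial stock: a total concentration and a
#' signed enantiomeric excess determine the two enantiomer
#' concentrations, `S = total (1 + ee/100) / 2`,
#' `R = total (1 - ee/100) / 2`.
#'
#' @param total Total amine concentration, mM (> 0).
#' @param ee Signed percent ee in \[-100, 100\] (positive = S-excess).
#' @return Named numeric vector `c(S = ..., R = ...)`, mM.
#' @examples
#' impure_stock(50, -99.1)  # a 99.1% ee^R stock: S = 0.225, R = 49.775
#' @export
impure_stock <- function(total, ee) {
  if (!is.numeric(total) || total <= 0)
    stop("total must be > 0", call. = FALSE)
  if (!is.numeric(ee) || abs(ee) > 100)
    stop("ee must lie in [-100, 100] percent", call. = FALSE)
  c(S = total * (1 + ee / 100) / 2, R = total * (1 - ee / 100) / 2)
}

# NeRF internal-coordinate placement: position D from chain A-B-C with
# bond length r = |CD|, planar angle theta = angle(B,C,D) and torsion
# phi = torsion(A,B,C,D), both in degrees
place_atom <- function(A, B, C, r, theta, phi) {
  theta <- theta * pi / 180; phi <- phi * pi / 180
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  bc <- C - B; bc <- bc / vnorm(bc)
  n <- cross3(B - A, bc)
  n <- n / vnorm(n)
  m <- cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi),
         r * sin(theta) * sin(phi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

random_rotation <- function() {
  # uniform rotation from QR decomposition of a Gaussian matrix
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a six-atom PDB pose fixture with prescribed NAT geometry
#'
#' Constructs the six mechanistic atoms by sequential internal-coordinate
#' placement so that the measured NAT length, Buergi-Dunitz angle,
#' dihedral and Halpha metrics reproduce the prescription exactly (up to
#' the 0.001 Angstrom quantization of the PDB format when written to
#' file), then applies a seeded random rigid-body rotation and
#' translation. The seed only moves the arbitrary laboratory frame; the
#' internal geometry is deterministic.
#'
#' @param d_NAT NAT length Nalpha-C4', Angstrom (> 0.5).
#' @param theta_BD Buergi-Dunitz angle, degrees, in (0, 180).
#' @param theta_DH NAT dihedral, degrees, in (0, 180).
#' @param d_Halpha_Neps Halpha-Nepsilon distance, Angstrom (> 0.5).
#' @param same_face Should Halpha lie on the Nepsilon face of the attack
#'   plane?
#' @param seed Integer seed for the rigid-body frame.
#' @param path Optional file path; when given, the PDB text is written
#'   there.
#' @return List with `pose` (the exact [pose_geometry()]), `pdb_lines`
#'   (PDB text), `map` (the matching [atom_map()]) and `path` (or `NA`).
#' @export
generate_pose <- function(d_NAT, theta_BD, theta_DH, d_Halpha_Neps,
                          same_face = TRUE, seed, path = NULL) {
  if (missing(seed)) stop("an integer seed is required", call. = FALSE)
  if (d_NAT <= 0.5 || d_Halpha_Neps <= 0.5)
    stop("distances must exceed 0.5 Angstrom", call. = FALSE)
  if (theta_BD <= 0 || theta_BD >= 180 || theta_DH <= 0 || theta_DH >= 180)
    stop("angles must lie strictly inside (0, 180) degrees", call. = FALSE)

  h_neps <- 1.0                       # Nepsilon offset above the plane
  s_h <- if (same_face) h_neps else -h_neps
  perp <- s_h - h_neps
  if (d_Halpha_Neps <= abs(perp))
    stop(sprintf(
      "geometrically infeasible: opposite-face Halpha needs d_Halpha_Neps > %.2f Angstrom",
      abs(perp)), call. = FALSE)
  rho <- sqrt(d_Halpha_Neps^2 - perp^2)

  n_sb <- c(0, 0, 0)
  c4p <- c(1.28, 0, 0)                # imine C=N bond
  c4 <- 1.5 * c(cos(2 * pi / 3), sin(2 * pi / 3), 0)
  nalpha <- place_atom(c4, n_sb, c4p, d_NAT, theta_BD, theta_DH)

  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  u <- c4p - nalpha; v <- n_sb - nalpha
  nrm <- cross3(u, v); nrm <- nrm / vnorm(nrm)
  e1 <- u - sum(u * nrm) * nrm; e1 <- e1 / vnorm(e1)
  e2 <- cross3(nrm, e1)
  neps <- nalpha + 1.2 * e1 + h_neps * nrm

  build <- function(a) {
    halpha <- neps + rho * (cos(a) * e1 + sin(a) * e2) + perp * nrm
    rbind(nalpha = nalpha, halpha = halpha, c4p = c4p, n_sb = n_sb,
          c4 = c4, neps = neps)
  }
  coords <- with_seed(seed, {
    # pick an in-plane direction for Halpha that avoids atom clashes
    angles <- stats::runif(32, 0, 2 * pi)
    co <- NULL
    for (a in angles) {
      cand <- build(a)
      d <- as.matrix(stats::dist(cand)); diag(d) <- Inf
      if (all(d > 0.1)) { co <- cand; break }
    }
    if (is.null(co))
      stop("geometrically infeasible prescription: atoms always clash",
           call. = FALSE)
    R <- random_rotation()
    shift <- stats::runif(3, -10, 10)
    t(apply(co, 1, function(p) as.vector(R %*% p) + shift))
  })
  colnames(coords) <- c("x", "y", "z")
  pose <- pose_geometry(coords)

  resid <- c("AMN", "AMN", "PLP", "PLP", "PLP", "LYS")
  resno <- c(501L, 501L, 401L, 401L, 401L, 287L)
  elety <- c("N", "HA", "C4A", "NZ", "C4", "NZ")
  map <- atom_map(
    nalpha = list(chain = "A", resno = 501, name = "N"),
    halpha = list(chain = "A", resno = 501, name = "HA"),
    c4p = list(chain = "A", resno = 401, name = "C4A"),
    n_sb = list(chain = "A", resno = 401, name = "NZ"),
    c4 = list(chain = "A", resno = 401, name = "C4"),
    neps = list(chain = "A", resno = 287, name = "NZ"))
  lines <- vapply(seq_len(6), function(i) {
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            i, elety[i], resid[i], "A", resno[i],
            coords[i, 1], coords[i, 2], coords[i, 3], 1.00, 0.00)
  }, character(1))
  lines <- c(lines, "END")
  out_path <- NA_character_
  if (!is.null(path)) {
    writeLines(lines, path)
    out_path <- path
  }
  list(pose = pose, pdb_lines = lines, map = map, path = out_path)
}
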