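# vector helpers ----------------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

angle_deg <- function(a, b, c) {
  # planar angle a-b-c at vertex b, degrees
  u <- a - b; v <- c - b
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-12 || nv < 1e-12)
    stop("degenerate geometry: zero-length vector in angle", call. = FALSE)
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

torsion_deg <- function(p1, p2, p3, p4) {
  # torsion p1-p2-p3-p4 about p2-p3, magnitude in [0, 180]
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (vnorm(n1) < 1e-12 || vnorm(n2) < 1e-12)
    stop("undefined dihedral: three consecutive atoms are collinear",
         call. = FALSE)
  cosang <- sum(n1 * n2) / (vnorm(n1) * vnorm(n2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

NAT_ATOMS <- c("nalpha", "halpha", "c4p", "n_sb", "c4", "neps")

#' Atom-selection map for NAT geometry
#'
#' Names the six mechanistically relevant atoms of a docking pose, each by
#' a (chain, residue number, atom name) triple: the substrate amine
#' nitrogen Nalpha and alpha proton Halpha, the cofactor aldimine carbon
#' C4' and ring carbon C4, the Schiff-base (internal aldimine imine)
#' nitrogen N_sb, and the catalytic lysine Nepsilon.
#'
#' @param nalpha,halpha,c4p,n_sb,c4,neps Each a list/vector with elements
#'   `chain`, `resno`, `name`.
#' @return An object of class `atom_map`.
#' @examples
#' atom_map(nalpha = list(chain = "A", resno = 501, name = "N"),
#'          halpha = list(chain = "A", resno = 501, name = "HA"),
#'          c4p    = list(chain = "A", resno = 401, name = "C4A"),
#'          n_sb   = list(chain = "A", resno = 401, name = "NZ"),
#'          c4     = list(chain = "A", resno = 401, name = "C4"),
#'          neps   = list(chain = "A", resno = 287, name = "NZ"))
#' @export
atom_map <- function(nalpha, halpha, c4p, n_sb, c4, neps) {
  sel <- list(nalpha = nalpha, halpha = halpha, c4p = c4p,
              n_sb = n_sb, c4 = c4, neps = neps)
  sel <- lapply(sel, function(s) {
    s <- as.list(s)
    if (!all(c("chain", "resno", "name") %in% names(s)))
      stop("each selector needs chain, resno and name", call. = FALSE)
    list(chain = as.character(s$chain), resno = as.integer(s$resno),
         name = as.character(s$name))
  })
  key <- vapply(sel, function(s) paste(s$chain, s$resno, s$name), "")
  if (anyDuplicated(key))
    stop("atom selectors must be pairwise distinct", call. = FALSE)
  structure(sel, class = "atom_map")
}

#' Labeled coordinates of the six NAT atoms
#'
#' @param coords A 6 x 3 numeric matrix of coordinates in Angstrom with
#'   row names `nalpha`, `halpha`, `c4p`, `n_sb`, `c4`, `neps`.
#' @return An object of class `pose_geometry`.
#' @export
pose_geometry <- function(coords) {
  coords <- as.matrix(coords)
  if (!all(NAT_ATOMS %in% rownames(coords)) || ncol(coords) != 3L)
    stop("coords must be a 6 x 3 matrix with the NAT atom row names",
         call. = FALSE)
  coords <- coords[NAT_ATOMS, , drop = FALSE]
  storage.mode(coords) <- "double"
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  if (any(d <= 0.1))
    stop("invalid pose: two atoms closer than 0.1 Angstrom", call. = FALSE)
  structure(list(coords = coords), class = "pose_geometry")
}

#' @export
print.pose_geometry <- function(x, ...) {
  cat("pose geometry (Angstrom):\n")
  print(round(x$coords, 3))
  invisible(x)
}

#' Read the six NAT atoms from a PDB file
#'
#' Parses ATOM/HETATM records (via `bio3d`) and resolves each selector of
#' the [atom_map()] to exactly one atom. A selector matching several atoms
#' (e.g. alternate locations) is an ambiguity error; a missing alpha
#' proton raises an explicit hydrogens-required error.
#'
#' @param pdb_source Path to a PDB file.
#' @param map An [atom_map()].
#' @return A [pose_geometry()].
#' @export
read_pose <- function(pdb_source, map) {
  stopifnot(inherits(map, "atom_map"))
  pdb <- bio3d::read.pdb(pdb_source)
  at <- pdb$atom
  coords <- matrix(NA_real_, nrow = length(NAT_ATOMS), ncol = 3,
                   dimnames = list(NAT_ATOMS, c("x", "y", "z")))
  for (nm in NAT_ATOMS) {
    s <- map[[nm]]
    hit <- which(at$chain == s$chain & at$resno == s$resno &
                   at$elety == s$name)
    if (length(hit) == 0L) {
      if (nm == "halpha")
        stop(sprintf(
          "alpha proton selector (%s %d %s) not found: explicit hydrogens are required",
          s$chain, s$resno, s$name), call. = FALSE)
      stop(sprintf("selector '%s' (%s %d %s) matches no atom",
                   nm, s$chain, s$resno, s$name), call. = FALSE)
    }
    if (length(hit) > 1L)
      stop(sprintf(
        "selector '%s' (%s %d %s) is ambiguous: %d matching atoms (altLoc: %s)",
        nm, s$chain, s$resno, s$name, length(hit),
        paste(unique(at$alt[hit]), collapse = "/")), call. = FALSE)
    coords[nm, ] <- as.numeric(at[hit, c("x", "y", "z")])
  }
  pose_geometry(coords)
}

#' NAT length: distance from the substrate Nalpha to the aldimine C4'
#'
#' The length of the nucleophilic attack trajectory, i.e. the distance the
#' amine lone pair must travel to the electrophilic aldimine carbon.
#' Around 3.0-3.1 Angstrom is typical of reactive poses.
#'
#' @param pose A [pose_geometry()].
#' @return Distance in Angstrom.
#' @export
nat_length <- function(pose) {
  stopifnot(inherits(pose, "pose_geometry"))
  vnorm(pose$coords["nalpha", ] - pose$coords["c4p", ])
}

#' Buergi-Dunitz angle of the attack trajectory
#'
#' The approach angle of the nucleophile onto the sp2 aldimine carbon:
#' the planar angle Nalpha-C4'-N_sb between the attack vector and the
#' C4'=N_sb imine bond. The canonical optimum is about 105 degrees.
#'
#' @param pose A [pose_geometry()].
#' @return Angle in degrees, in \[0, 180\].
#' @export
burgi_dunitz <- function(pose) {
  stopifnot(inherits(pose, "pose_geometry"))
  angle_deg(pose$coords["nalpha", ], pose$coords["c4p", ],
            pose$coords["n_sb", ])
}

#' NAT dihedral angle
#'
#' Torsion magnitude of the attack trajectory about the imine bond. The
#' default quadruple is Nalpha-C4'-N_sb-C4; the atoms are configurable
#' through the [atom_map()] since conventions differ. The optimum is
#' about 90 degrees (attack perpendicular to the imine plane).
#'
#' @param pose A [pose_geometry()].
#' @return Torsion magnitude in degrees, in \[0, 180\].
#' @export
nat_dihedral <- function(pose) {
  stopifnot(inherits(pose, "pose_geometry"))
  torsion_deg(pose$coords["nalpha", ], pose$coords["c4p", ],
              pose$coords["n_sb", ], pose$coords["c4", ])
}

#' Accessibility of the substrate alpha proton to the catalytic lysine
#'
#' After the nucleophilic attack the catalytic lysine's Nepsilon must
#' abstract the substrate's alpha proton, so Halpha has to point toward
#' it. Measured as the Halpha-Nepsilon distance together with a face
#' test: whether Halpha and Nepsilon lie on the same side of the plane
#' through Nalpha, C4' and N_sb. A pose with the alpha proton on the far
#' face is non-productive regardless of the other metrics.
#'
#' @param pose A [pose_geometry()].
#' @return List with `d_Halpha_Neps` (Angstrom) and `same_face` (logical).
#' @export
halpha_accessibility <- function(pose) {
  stopifnot(inherits(pose, "pose_geometry"))
  p <- pose$coords
  u <- p["c4p", ] - p["nalpha", ]
  v <- p["n_sb", ] - p["nalpha", ]
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  if (vnorm(n) < 1e-10)
    stop("degenerate plane: Nalpha, C4' and N_sb are collinear",
         call. = FALSE)
  n <- n / vnorm(n)
  s_h <- sum((p["halpha", ] - p["nalpha", ]) * n)
  s_k <- sum((p["neps", ] - p["nalpha", ]) * n)
  list(d_Halpha_Neps = vnorm(p["halpha", ] - p["neps", ]),
       same_face = sign(s_h) == sign(s_k) && s_h != 0 && s_k != 0)
}

#' Classification thresholds for productive binding
#'
#' Defaults encode what reactive poses look like: a short attack distance,
#' approach and dihedral angles near their stereoelectronic optima
#' (105 and 90 degrees), and an alpha proton facing the catalytic lysine.
#' Set any numeric threshold to `NA` (or `require_same_face = FALSE`) to
#' disable that criterion.
#'
#' @param d_nat_max Maximum NAT length, Angstrom (default 3.5).
#' @param theta_bd_opt,theta_bd_tol Buergi-Dunitz optimum and half-window,
#'   degrees (defaults 105 +/- 30).
#' @param theta_dh_opt,theta_dh_tol Dihedral optimum and half-window,
#'   degrees (defaults 90 +/- 30).
#' @param d_halpha_neps_max Maximum Halpha-Nepsilon distance, Angstrom
#'   (default 4.5).
#' @param require_same_face Require Halpha on the catalytic-lysine face of
#'   the attack plane (default TRUE; the decisive criterion).
#' @return A list of class `nat_thresholds`.
#' @export
nat_thresholds <- function(d_nat_max = 3.5,
                           theta_bd_opt = 105, theta_bd_tol = 30,
                           theta_dh_opt = 90, theta_dh_tol = 30,
                           d_halpha_neps_max = 4.5,
                           require_same_face = TRUE) {
  num <- c(d_nat_max, theta_bd_opt, theta_bd_tol, theta_dh_opt,
           theta_dh_tol, d_halpha_neps_max)
  if (any(!is.na(num) & num < 0))
    stop("thresholds must be positive (or NA to disable)", call. = FALSE)
  structure(list(d_nat_max = d_nat_max, theta_bd_opt = theta_bd_opt,
                 theta_bd_tol = theta_bd_tol, theta_dh_opt = theta_dh_opt,
                 theta_dh_tol = theta_dh_tol,
                 d_halpha_neps_max = d_halpha_neps_max,
                 require_same_face = isTRUE(require_same_face)),
            class = "nat_thresholds")
}

#' Classify a pose's NAT metrics as productive or not
#'
#' @param metrics A list with `d_NAT`, `theta_BD`, `theta_DH`,
#'   `d_Halpha_Neps`, `halpha_same_face` (as produced by [nat_report()]).
#' @param thresholds A [nat_thresholds()].
#' @return List with `verdict` (`"productive"` / `"nonproductive"`) and
#'   `reasons` (character vector of failed criteria, empty if productive).
#' @export
classify_pose <- function(metrics, thresholds = nat_thresholds()) {
  stopifnot(inherits(thresholds, "nat_thresholds"))
  th <- thresholds
  reasons <- character()
  if (!is.na(th$d_nat_max) && metrics$d_NAT > th$d_nat_max)
    reasons <- c(reasons, sprintf("NAT length %.2f A > %.2f A",
                                  metrics$d_NAT, th$d_nat_max))
  if (!is.na(th$theta_bd_tol) && !is.na(th$theta_bd_opt) &&
      abs(metrics$theta_BD - th$theta_bd_opt) > th$theta_bd_tol)
    reasons <- c(reasons, sprintf(
      "Buergi-Dunitz angle %.1f deg outside %g +/- %g deg",
      metrics$theta_BD, th$theta_bd_opt, th$theta_bd_tol))
  if (!is.na(th$theta_dh_tol) && !is.na(th$theta_dh_opt) &&
      abs(metrics$theta_DH - th$theta_dh_opt) > th$theta_dh_tol)
    reasons <- c(reasons, sprintf(
      "NAT dihedral %.1f deg outside %g +/- %g deg",
      metrics$theta_DH, th$theta_dh_opt, th$theta_dh_tol))
  if (!is.na(th$d_halpha_neps_max) &&
      metrics$d_Halpha_Neps > th$d_halpha_neps_max)
    reasons <- c(reasons, sprintf("Halpha-Neps distance %.2f A > %.2f A",
                                  metrics$d_Halpha_Neps,
                                  th$d_halpha_neps_max))
  if (th$require_same_face && !isTRUE(metrics$halpha_same_face))
    reasons <- c(reasons,
                 "Halpha points away from the catalytic lysine Nepsilon")
  list(verdict = if (length(reasons)) "nonproductive" else "productive",
       reasons = reasons)
}

#' Full NAT geometry report for one pose
#'
#' Computes all NAT metrics and the productive/non-productive verdict.
#'
#' @param pose A [pose_geometry()] (or a PDB path together with `map`).
#' @param thresholds A [nat_thresholds()].
#' @param map Optional [atom_map()] when `pose` is a PDB path.
#' @return An object of class `nat_report` with fields `d_NAT`,
#'   `theta_BD`, `theta_DH`, `d_Halpha_Neps`, `halpha_same_face`,
#'   `verdict`, `reasons`.
#' @examples
#' fx <- generate_pose(d_NAT = 3.1, theta_BD = 91, theta_DH = 78,
#'                     d_Halpha_Neps = 3.0, same_face = TRUE, seed = 1)
#' nat_report(fx$pose)
#' @export
nat_report <- function(pose, thresholds = nat_thresholds(), map = NULL) {
  if (is.character(pose)) {
    if (is.null(map)) stop("reading a PDB pose requires an atom map",
                           call. = FALSE)
    pose <- read_pose(pose, map)
  }
  stopifnot(inherits(pose, "pose_geometry"))
  acc <- halpha_accessibility(pose)
  metrics <- list(d_NAT = nat_length(pose),
                  theta_BD = burgi_dunitz(pose),
                  theta_DH = nat_dihedral(pose),
                  d_Halpha_Neps = acc$d_Halpha_Neps,
                  halpha_same_face = acc$same_face)
  cls <- classify_pose(metrics, thresholds)
  structure(c(metrics, cls), class = "nat_report")
}

#' @export
print.nat_report <- function(x, ...) {
  cat(sprintf(
    "NAT report: d_NAT %.3f A, theta_BD %.2f deg, theta_DH %.2f deg\n",
    x$d_NAT, x$theta_BD, x$theta_DH))
  cat(sprintf("  Halpha-Neps %.3f A, same face: %s\n",
              x$d_Halpha_Neps, x$halpha_same_face))
  cat(sprintf("  verdict: %s\n", x$verdict))
  if (length(x$reasons)) cat("  -", paste(x$reasons, collapse = "\n  - "),
                             "\n")
  invisible(x)
}
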